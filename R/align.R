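# Internal seeded local alignment. A shared exact k-mer gates each
# query/subject/strand combination; gated pairs are scored by full
# affine-gap dynamic programming (Gotoh), so a reported hit is the optimal
# local alignment for that pair, not a heuristic extension.

.DNA_ALPHA <- c("A", "C", "G", "T", "N")

.dna_codes <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], .DNA_ALPHA) - 1L
  if (anyNA(codes)) abort("sequence contains non-ACGTN characters")
  codes
}

.dna_submat <- function(scoring) {
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(.DNA_ALPHA, .DNA_ALPHA))
  diag(m) <- scoring$match
  m[5, ] <- 0  # N is scored neutrally against everything
  m[, 5] <- 0
  m
}

#' Reverse-complement a DNA string
#'
#' @param seq character vector of A/C/G/T/N strings.
#' @return The reverse complements.
#' @export
revcomp <- function(seq) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", seq))
}

.kmers <- function(seq, k, stride = 1L) {
  n <- nchar(seq)
  if (n < k) return(character())
  starts <- seq.int(1L, n - k + 1L, by = stride)
  substring(seq, starts, starts + k - 1L)
}

.shares_kmer <- function(a, b, k) {
  ka <- .kmers(a, k)
  any(ka %in% .kmers(b, k))
}

# run the C++ aligner on two DNA strings
.align_dna <- function(a, b, scoring, global = FALSE, traceback = TRUE) {
  align_codes_cpp(.dna_codes(a), .dna_codes(b), .dna_submat(scoring),
                  scoring$gap_open, scoring$gap_extend, global, traceback)
}

# summarise a traceback into hit statistics; x_idx/y_idx are 1-based
# aligned positions with 0 marking a gap
.aln_stats <- function(a, b, aln) {
  xi <- aln$x_idx; yi <- aln$y_idx
  ax <- strsplit(a, "", fixed = TRUE)[[1]]
  bx <- strsplit(b, "", fixed = TRUE)[[1]]
  qa <- ifelse(xi == 0, "-", ax[pmax(xi, 1)])
  sa <- ifelse(yi == 0, "-", bx[pmax(yi, 1)])
  both <- xi > 0 & yi > 0
  matches <- sum(both & qa == sa)
  len <- length(xi)
  gap <- xi == 0 | yi == 0
  gap_opens <- sum(gap & !c(FALSE, gap[-len]))
  list(align_length = len,
       matches = matches,
       percent_id = 100 * matches / len,
       mismatches = sum(both & qa != sa),
       gap_opens = gap_opens,
       qstart = min(xi[xi > 0]), qend = max(xi[xi > 0]),
       sstart = min(yi[yi > 0]), send = max(yi[yi > 0]),
       query_aln = paste(qa, collapse = ""),
       subject_aln = paste(sa, collapse = ""))
}

#' Karlin-Altschul E-value for a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` between a query of length `m` and a
#' search space of length `n`.
#'
#' @param raw_score raw alignment score.
#' @param query_len,db_len positive sequence / search-space lengths.
#' @param scoring a [scoring_scheme()] supplying `karlin_lambda`, `karlin_k`.
#' @return The E-value (vectorised over `raw_score`).
#' @export
karlin_altschul_evalue <- function(raw_score, query_len, db_len,
                                   scoring = scoring_scheme()) {
  if (any(query_len <= 0) || any(db_len <= 0)) {
    abort("sequence lengths must be positive")
  }
  scoring$karlin_k * query_len * db_len *
    exp(-scoring$karlin_lambda * raw_score)
}

#' Seeded local alignment of two sequences
#'
#' Finds the highest-scoring affine-gap local alignment between `query` and
#' `subject`, provided the pair shares at least one exact k-mer on that
#' strand (the seed requirement). Both subject strands are considered and
#' the better alignment kept; minus-strand hits are reported with
#' `sstart > send`. Absence of a seed or a non-positive optimal score
#' yields no hit (an empty tibble), not an error.
#'
#' @param query,subject either one-row sequence tibbles (`id`, `seq`) or
#'   single named/unnamed DNA strings.
#' @param scoring a [scoring_scheme()].
#' @param kmer seed length (>= 8).
#' @param db_len search-space length for the E-value; defaults to the
#'   subject length.
#' @return A tibble with the 12 standard hit columns plus `raw_score`,
#'   `query_aln`, `subject_aln`; zero rows when there is no hit.
#' @export
seed_and_extend_align <- function(query, subject, scoring = scoring_scheme(),
                                  kmer = 11, db_len = NULL) {
  stopifnot(kmer >= 8)
  q <- .as_seq_entry(query); s <- .as_seq_entry(subject)
  if (!nzchar(q$seq) || !nzchar(s$seq)) abort("sequences must be non-empty")
  db_len <- db_len %||% nchar(s$seq)
  best <- NULL; best_strand <- "+"
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") s$seq else revcomp(s$seq)
    if (!.shares_kmer(q$seq, subj, kmer)) next
    aln <- .align_dna(q$seq, subj, scoring, global = FALSE, traceback = TRUE)
    if (aln$score <= 0 || is.null(aln$x_idx)) next
    if (is.null(best) || aln$score > best$score) {
      best <- aln; best_strand <- strand
    }
  }
  if (is.null(best)) return(.empty_hits())
  subj <- if (best_strand == "+") s$seq else revcomp(s$seq)
  st <- .aln_stats(q$seq, subj, best)
  slen <- nchar(s$seq)
  if (best_strand == "-") {
    # rc-space [min,max] maps to original coordinates with sstart > send
    ss <- slen - min(best$y_idx[best$y_idx > 0]) + 1L
    se <- slen - max(best$y_idx[best$y_idx > 0]) + 1L
    st$sstart <- ss; st$send <- se
  }
  ev <- karlin_altschul_evalue(best$score, nchar(q$seq), db_len, scoring)
  tibble(qseqid = q$id, sseqid = s$id,
         pident = st$percent_id, length = st$align_length,
         mismatch = st$mismatches, gapopen = st$gap_opens,
         qstart = st$qstart, qend = st$qend,
         sstart = st$sstart, send = st$send,
         evalue = ev, bitscore = as.numeric(best$score),
         raw_score = as.numeric(best$score),
         query_aln = st$query_aln, subject_aln = st$subject_aln)
}

.empty_hits <- function() {
  tibble(qseqid = character(), sseqid = character(), pident = double(),
         length = integer(), mismatch = integer(), gapopen = integer(),
         qstart = integer(), qend = integer(), sstart = integer(),
         send = integer(), evalue = double(), bitscore = double(),
         raw_score = double(), query_aln = character(),
         subject_aln = character())
}

.as_seq_entry <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1, all(c("id", "seq") %in% names(x)))
    list(id = x$id[[1]], seq = x$seq[[1]])
  } else if (is.character(x) && length(x) == 1) {
    list(id = names(x) %||% "seq", seq = unname(x))
  } else {
    abort("expected a one-row sequence tibble or a single string")
  }
}
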