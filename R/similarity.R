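# All-vs-all self search and reciprocal-best-hit pairing (workflow Step 2).

# canonical k-mer (lexicographic min of a k-mer and its reverse complement)
# so one index covers both strands
.canonical_kmers <- function(seq, k, stride = 1L) {
  km <- .kmers(seq, k, stride)
  rc <- revcomp(km)
  unique(pmin(km, rc))
}

# unordered candidate pairs of sequences sharing canonical k-mers; chance
# single-k-mer collisions between unrelated sequences are frequent at
# realistic set sizes, so pairs must share at least `min_shared` distinct
# seeds (any pair passing the workflow thresholds shares hundreds)
.kmer_candidate_pairs <- function(seqs, k, min_shared = 5L) {
  km <- lapply(seqs$seq, .canonical_kmers, k = k)
  idx <- rep.int(seq_along(seqs$id), lengths(km))
  by_kmer <- split(idx, unlist(km))
  by_kmer <- by_kmer[lengths(by_kmer) > 1]
  if (!length(by_kmer)) {
    return(tibble(i = integer(), j = integer()))
  }
  keys <- unlist(lapply(by_kmer, function(v) {
    v <- unique(v)
    if (length(v) < 2) return(NULL)
    cmb <- utils::combn(sort(v), 2)
    cmb[1, ] * 1e6 + cmb[2, ]
  }), use.names = FALSE)
  counts <- table(keys)
  keep <- as.numeric(names(counts)[counts >= min_shared])
  if (!length(keep)) return(tibble(i = integer(), j = integer()))
  tibble(i = as.integer(keep %/% 1e6), j = as.integer(keep %% 1e6))
}

# mirror a hit so subject becomes query; strand information is preserved
# by the sstart/send order
.mirror_hit <- function(h) {
  minus <- h$sstart > h$send
  tibble(qseqid = h$sseqid, sseqid = h$qseqid,
         pident = h$pident, length = h$length,
         mismatch = h$mismatch, gapopen = h$gapopen,
         qstart = ifelse(minus, h$send, h$sstart),
         qend = ifelse(minus, h$sstart, h$send),
         sstart = ifelse(minus, h$qend, h$qstart),
         send = ifelse(minus, h$qstart, h$qend),
         evalue = h$evalue, bitscore = h$bitscore,
         raw_score = h$raw_score,
         query_aln = h$subject_aln, subject_aln = h$query_aln)
}

#' All-vs-all self search within a sequence set
#'
#' Runs the internal seeded aligner over every pair of distinct sequences
#' that shares at least one k-mer (either strand), keeps hits at or below
#' the configured E-value threshold, and reports both search directions so
#' coverage is symmetric. Self-hits are excluded.
#'
#' @param seqs sequence tibble (`id`, `seq`) with unique ids.
#' @param config a [pipeline_config()].
#' @return A hit tibble (12 standard columns plus `raw_score` and the
#'   gapped alignment strings).
#' @export
all_vs_all_self_search <- function(seqs, config = pipeline_config()) {
  if (anyDuplicated(seqs$id)) {
    abort(paste0("duplicate sequence id: ",
                 seqs$id[duplicated(seqs$id)][1]))
  }
  db_len <- sum(nchar(seqs$seq))
  cand <- .kmer_candidate_pairs(seqs, config$kmer)
  if (!nrow(cand)) return(.empty_hits())
  hits <- pmap(cand, function(i, j) {
    h <- seed_and_extend_align(seqs[i, ], seqs[j, ],
                               scoring = config$scoring,
                               kmer = config$kmer, db_len = db_len)
    if (!nrow(h)) return(NULL)
    bind_rows(h, .mirror_hit(h))
  })
  out <- bind_rows(hits)
  if (!nrow(out)) return(.empty_hits())
  out |> filter(.data$evalue <= config$evalue_threshold)
}

#' Reciprocal best pairs from a hit table
#'
#' A pair \{A, B\} is kept when A's best-scoring subject is B and B's
#' best-scoring subject is A (mutual top hit). "Best" is decided by higher
#' score (`raw_score` when present, `bitscore` otherwise), then longer
#' alignment, then lexicographically smaller subject id, so the result is
#' deterministic. Each id appears in at most one pair.
#'
#' @param hits hit tibble; must not contain self-hits.
#' @return A tibble of candidate pairs with canonical ordering
#'   (`id_a < id_b`) and the pairing hit's `pident`, `length`, `evalue`,
#'   `bitscore`.
#' @export
reciprocal_best_pairs <- function(hits) {
  if (!nrow(hits)) {
    return(tibble(id_a = character(), id_b = character(), pident = double(),
                  length = integer(), evalue = double(), bitscore = double()))
  }
  if (any(hits$qseqid == hits$sseqid)) abort("self-hits are not allowed")
  score <- if ("raw_score" %in% names(hits)) hits$raw_score else hits$bitscore
  ranked <- hits |>
    mutate(.score = score) |>
    arrange(.data$qseqid, desc(.data$.score), desc(.data$length),
            .data$sseqid) |>
    distinct(.data$qseqid, .keep_all = TRUE)
  best <- ranked |> select("qseqid", "sseqid", "pident", "length",
                           "evalue", "bitscore")
  mutual <- best |>
    inner_join(best |> select(q2 = "qseqid", s2 = "sseqid"),
               by = c("qseqid" = "s2", "sseqid" = "q2"))
  mutual |>
    transmute(id_a = pmin(.data$qseqid, .data$sseqid),
              id_b = pmax(.data$qseqid, .data$sseqid),
              pident = .data$pident, length = .data$length,
              evalue = .data$evalue, bitscore = .data$bitscore) |>
    distinct(.data$id_a, .data$id_b, .keep_all = TRUE) |>
    arrange(.data$id_a, .data$id_b)
}
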