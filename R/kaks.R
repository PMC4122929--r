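# Frame selection, ORF extraction, protein and codon alignment, and
# Nei-Gojobori Ka/Ks with Jukes-Cantor correction.
#
# Site-counting conventions (pinned by the enumeration tests): single-
# nucleotide changes that would create a stop codon count as nonsynonymous
# when counting sites; mutational pathways passing through a stop codon are
# excluded when averaging multi-nucleotide codon differences (all pathways
# are weighted equally if every pathway is blocked).

.NTS <- c("A", "C", "G", "T")

.genetic_code <- function() Biostrings::GENETIC_CODE

.translate_codons <- function(codons) {
  aa <- .genetic_code()[codons]
  aa[is.na(aa)] <- "X"  # codons containing N or gaps
  unname(aa)
}

.translate <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  cods <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  paste(.translate_codons(cods), collapse = "")
}

.PERMS <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# lazily built Nei-Gojobori lookup tables: per-codon synonymous site
# fractions and pathway-averaged (Sd, Nd) for every codon pair
.ng_tables <- function() {
  if (!is.null(.pkg_cache$ng)) return(.pkg_cache$ng)
  gc_map <- .genetic_code()
  codons <- names(gc_map)
  aa <- unname(gc_map)
  chars <- strsplit(codons, "", fixed = TRUE)

  syn_sites <- numeric(64)
  for (ci in seq_len(64)) {
    if (aa[ci] == "*") { syn_sites[ci] <- NA_real_; next }
    s <- 0
    for (p in 1:3) {
      for (nt in setdiff(.NTS, chars[[ci]][p])) {
        alt <- chars[[ci]]; alt[p] <- nt
        altc <- paste(alt, collapse = "")
        if (gc_map[[altc]] != "*" && gc_map[[altc]] == aa[ci]) s <- s + 1 / 3
      }
    }
    syn_sites[ci] <- s
  }
  names(syn_sites) <- codons

  SD <- ND <- matrix(0, 64, 64, dimnames = list(codons, codons))
  for (i in seq_len(64)) {
    for (j in seq_len(64)) {
      d <- which(chars[[i]] != chars[[j]])
      if (!length(d)) next
      paths <- .PERMS[[length(d)]]
      sd_p <- nd_p <- numeric(length(paths))
      blocked <- logical(length(paths))
      for (k in seq_along(paths)) {
        cur <- chars[[i]]
        sd <- nd <- 0
        for (step in seq_along(paths[[k]])) {
          pos <- d[paths[[k]][step]]
          nxt <- cur; nxt[pos] <- chars[[j]][pos]
          from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
          if (gc_map[[from]] != "*" && gc_map[[to]] != "*" &&
              gc_map[[from]] == gc_map[[to]]) sd <- sd + 1 else nd <- nd + 1
          if (step < length(paths[[k]]) && gc_map[[to]] == "*") {
            blocked[k] <- TRUE
          }
          cur <- nxt
        }
        sd_p[k] <- sd; nd_p[k] <- nd
      }
      use <- if (all(blocked)) rep(TRUE, length(paths)) else !blocked
      SD[i, j] <- mean(sd_p[use]); ND[i, j] <- mean(nd_p[use])
    }
  }
  .pkg_cache$ng <- list(syn_sites = syn_sites, SD = SD, ND = ND,
                        codons = codons, aa = aa)
  .pkg_cache$ng
}

.blosum62 <- function(stop_penalty = NULL) {
  key <- if (is.null(stop_penalty)) "b62" else paste0("b62s", stop_penalty)
  if (is.null(.pkg_cache[[key]])) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    if (!is.null(stop_penalty)) {
      m["*", ] <- stop_penalty
      m[, "*"] <- stop_penalty
    }
    .pkg_cache[[key]] <- m
  }
  .pkg_cache[[key]]
}

.aa_codes <- function(pep, alphabet) {
  ch <- strsplit(pep, "", fixed = TRUE)[[1]]
  ch[!ch %in% alphabet] <- "X"
  match(ch, alphabet) - 1L
}

.align_protein <- function(p1, p2, submat, gap_open = -10, gap_extend = -1,
                           global = FALSE, traceback = TRUE) {
  alphabet <- rownames(submat)
  align_codes_cpp(.aa_codes(p1, alphabet), .aa_codes(p2, alphabet),
                  submat, gap_open, gap_extend, global, traceback)
}

.oriented <- function(seq, frame) if (frame > 0) seq else revcomp(seq)

.frame_peptide <- function(seq, frame) {
  o <- .oriented(seq, frame)
  .translate(substring(o, abs(frame)))
}

#' Best translated reading-frame pair for two sequences
#'
#' Translates both sequences in all six frames (stop codons become the
#' terminator symbol, scored `stop_penalty` against everything) and finds
#' the frame combination maximising the local protein alignment score, the
#' frame evidence a translated similarity search would provide.
#'
#' @param a,b DNA strings or one-row sequence tibbles; each at least 60 nt.
#' @param stop_penalty substitution score of the terminator symbol.
#' @return A list with `frame_a`, `frame_b` (in +1..+3, -1..-3), `score`,
#'   and `region_a`, `region_b`: the nucleotide span `[start, end]` of the
#'   aligned region on each *oriented* sequence. `NULL` when no frame
#'   combination scores above zero (the pair is unusable).
#' @export
best_translated_frames <- function(a, b, stop_penalty = -10) {
  a <- .as_seq_entry(a)$seq; b <- .as_seq_entry(b)$seq
  if (nchar(a) < 60 || nchar(b) < 60) abort("sequences must be >= 60 nt")
  sub <- .blosum62(stop_penalty)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  pep_a <- lapply(frames, function(f) .frame_peptide(a, f))
  pep_b <- lapply(frames, function(f) .frame_peptide(b, f))
  best <- list(score = 0)
  for (i in seq_along(frames)) {
    for (j in seq_along(frames)) {
      if (nchar(pep_a[[i]]) < 1 || nchar(pep_b[[j]]) < 1) next
      sc <- .align_protein(pep_a[[i]], pep_b[[j]], sub,
                           traceback = FALSE)$score
      if (sc > best$score) best <- list(score = sc, i = i, j = j)
    }
  }
  if (best$score <= 0) return(NULL)
  aln <- .align_protein(pep_a[[best$i]], pep_b[[best$j]], sub,
                        traceback = TRUE)
  fa <- frames[best$i]; fb <- frames[best$j]
  pa <- range(aln$x_idx[aln$x_idx > 0])
  pb <- range(aln$y_idx[aln$y_idx > 0])
  list(frame_a = fa, frame_b = fb, score = best$score,
       region_a = c(abs(fa) + 3L * (pa[1] - 1L), abs(fa) + 3L * pa[2] - 1L),
       region_b = c(abs(fb) + 3L * (pb[1] - 1L), abs(fb) + 3L * pb[2] - 1L))
}

#' Longest open reading frame overlapping an aligned region
#'
#' Scans the given frame of the (oriented) sequence for the longest
#' stop-free codon run that intersects `region` and spans at least
#' `min_codons` codons. ORFs are stop-to-stop runs; no start codon is
#' required.
#'
#' @param seq DNA string (already oriented if the frame was negative).
#' @param frame frame in +1..+3, -1..-3; only its offset is used, the
#'   caller orients the sequence.
#' @param region nucleotide span `c(start, end)` on the oriented sequence.
#' @param min_codons minimum ORF length in codons.
#' @return `c(start, end)` nucleotide interval (1-based, inclusive, length
#'   a multiple of three) or `NULL` when no qualifying run exists.
#' @export
longest_orf_overlapping <- function(seq, frame, region, min_codons = 30) {
  seq <- .as_seq_entry(seq)$seq
  f <- abs(frame)
  n_cod <- (nchar(seq) - f + 1L) %/% 3L
  if (n_cod < 1) return(NULL)
  starts <- f + 3L * (seq_len(n_cod) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  is_stop <- .translate_codons(codons) == "*"
  r <- rle(!is_stop)
  ends_c <- cumsum(r$lengths)
  starts_c <- ends_c - r$lengths + 1L
  runs <- tibble(c1 = starts_c[r$values], c2 = ends_c[r$values]) |>
    mutate(nt1 = f + 3L * (.data$c1 - 1L), nt2 = f + 3L * .data$c2 - 1L,
           len = .data$c2 - .data$c1 + 1L) |>
    filter(.data$len >= min_codons,
           .data$nt1 <= region[2], .data$nt2 >= region[1]) |>
    arrange(desc(.data$len), .data$nt1)
  if (!nrow(runs)) return(NULL)
  c(runs$nt1[1], runs$nt2[1])
}

#' Global protein alignment
#'
#' Needleman-Wunsch with BLOSUM62 scoring and affine gaps; ties prefer a
#' substitution over a gap, so the result is deterministic.
#'
#' @param p1,p2 non-empty peptide strings.
#' @param gap_open,gap_extend negative affine gap penalties (a gap of
#'   length L costs `gap_open + L * gap_extend`).
#' @return A list with gapped strings `a`, `b` and the `score`.
#' @export
global_protein_align <- function(p1, p2, gap_open = -10, gap_extend = -1) {
  if (!nzchar(p1) || !nzchar(p2)) abort("peptides must be non-empty")
  sub <- .blosum62()
  aln <- .align_protein(p1, p2, sub, gap_open, gap_extend,
                        global = TRUE, traceback = TRUE)
  c1 <- strsplit(p1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(p2, "", fixed = TRUE)[[1]]
  list(a = paste(ifelse(aln$x_idx == 0, "-", c1[pmax(aln$x_idx, 1)]),
                 collapse = ""),
       b = paste(ifelse(aln$y_idx == 0, "-", c2[pmax(aln$y_idx, 1)]),
                 collapse = ""),
       score = aln$score)
}

#' Back-align codons onto a protein alignment
#'
#' Expands each aligned residue column to its source codon and each protein
#' gap to a `---` codon, so the concatenated non-gap codons reconstruct each
#' ORF exactly. A residue that does not translate its codon is rejected by
#' position.
#'
#' @param alignment list with gapped peptide strings `a` and `b`.
#' @param orf_a,orf_b the in-frame DNA of the two ORFs (lengths three times
#'   the ungapped peptide lengths).
#' @return A list of class `codon_alignment` with character vectors
#'   `codon_a`, `codon_b` and `n_aligned_codons` (gap-free columns).
#' @export
backalign_codons <- function(alignment, orf_a, orf_b) {
  ga <- strsplit(alignment$a, "", fixed = TRUE)[[1]]
  gb <- strsplit(alignment$b, "", fixed = TRUE)[[1]]
  if (length(ga) != length(gb)) abort("gapped peptides differ in length")
  expand <- function(gapped, orf, which) {
    n_res <- sum(gapped != "-")
    if (nchar(orf) != 3L * n_res) {
      abort(paste0("ORF ", which, " length ", nchar(orf),
                   " does not match ", n_res, " residues"))
    }
    cods <- substring(orf, seq(1, nchar(orf), 3), seq(3, nchar(orf), 3))
    out <- rep("---", length(gapped))
    out[gapped != "-"] <- cods
    tr <- .translate_codons(out[gapped != "-"])
    res <- gapped[gapped != "-"]
    bad <- which(tr != res & res != "X" & tr != "X")
    if (length(bad)) {
      abort(paste0("peptide/codon mismatch in ", which, " at residue ",
                   bad[1], ": codon ", cods[bad[1]], " vs residue ",
                   res[bad[1]]))
    }
    out
  }
  codon_a <- expand(ga, orf_a, "a")
  codon_b <- expand(gb, orf_b, "b")
  structure(list(codon_a = codon_a, codon_b = codon_b,
                 n_aligned_codons = sum(codon_a != "---" & codon_b != "---")),
            class = "codon_alignment")
}

.jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Nei-Gojobori Ka/Ks from a codon alignment
#'
#' Counts synonymous and nonsynonymous sites per codon from the universal
#' genetic code, averages multi-nucleotide codon differences over all
#' mutational pathways (pathways through stop codons excluded), and applies
#' the Jukes-Cantor correction `d = -(3/4) ln(1 - (4/3) p)` to the observed
#' proportions. Columns with a gap codon, an ambiguous base or a stop codon
#' are excluded. Saturation (`p >= 3/4`) and `Ks = 0` are reported as
#' flags, not errors; `Ka/Ks` with `Ks = 0` is undefined (`NA`), not
#' infinite.
#'
#' @param codon_alignment a [backalign_codons()] result, or a list with
#'   character vectors `codon_a`, `codon_b`.
#' @param min_codons minimum gap-free codon columns for a trusted estimate;
#'   fewer flags the result `TOO_SHORT`.
#' @return A one-row tibble: `n_aligned_codons`, `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `Ks`, `Ka`, `ka_ks`, `flags`.
#' @export
nei_gojobori <- function(codon_alignment, min_codons = 100) {
  tb <- .ng_tables()
  ca <- codon_alignment$codon_a
  cb <- codon_alignment$codon_b
  ia <- match(ca, tb$codons)
  ib <- match(cb, tb$codons)
  use <- !is.na(ia) & !is.na(ib) & tb$aa[ia] != "*" & tb$aa[ib] != "*"
  n <- sum(use)
  flags <- character()
  if (n < min_codons) flags <- c(flags, "TOO_SHORT")
  if (n == 0) {
    return(tibble(n_aligned_codons = 0L, S = NA_real_, N = NA_real_,
                  Sd = NA_real_, Nd = NA_real_, pS = NA_real_,
                  pN = NA_real_, Ks = NA_real_, Ka = NA_real_,
                  ka_ks = NA_real_,
                  flags = paste(flags, collapse = ",")))
  }
  ia <- ia[use]; ib <- ib[use]
  S <- (sum(tb$syn_sites[ia]) + sum(tb$syn_sites[ib])) / 2
  N <- 3 * n - S
  Sd <- sum(tb$SD[cbind(ia, ib)])
  Nd <- sum(tb$ND[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- .jc_correct(pS)
  Ka <- .jc_correct(pN)
  if (!is.na(pS) && pS >= 0.75) flags <- c(flags, "KS_SATURATED")
  if (!is.na(pN) && pN >= 0.75) flags <- c(flags, "KA_SATURATED")
  if (!is.na(Sd) && Sd == 0) flags <- c(flags, "KS_ZERO")
  if (!length(flags)) flags <- "OK"
  ratio <- if (!is.na(Ks) && Ks > 0 && !is.na(Ka)) Ka / Ks else NA_real_
  tibble(n_aligned_codons = as.integer(n), S = S, N = N, Sd = Sd, Nd = Nd,
         pS = pS, pN = pN, Ks = Ks, Ka = Ka, ka_ks = ratio,
         flags = paste(flags, collapse = ","))
}

#' Ka/Ks estimation for a table of paralog pairs
#'
#' For each pair: select the best translated frame combination, extract the
#' longest ORF overlapping the translated alignment in each member, align
#' the peptides globally, back-align to codons and run the Nei-Gojobori
#' estimator. Pairs failing a stage carry the failure flag.
#'
#' @param pairs tibble with `id_a`, `id_b`.
#' @param seqs sequence tibble (`id`, `seq`) containing all pair members.
#' @param config a [pipeline_config()] (supplies `min_codons`).
#' @return A tibble with one row per pair: frames, ORF intervals (on the
#'   oriented sequences), and the [nei_gojobori()] columns.
#' @export
estimate_kaks <- function(pairs, seqs, config = pipeline_config()) {
  seq_of <- setNames(seqs$seq, seqs$id)
  fail_row <- function(id_a, id_b, flag) {
    tibble(id_a = id_a, id_b = id_b,
           frame_a = NA_integer_, frame_b = NA_integer_,
           orf_a_start = NA_integer_, orf_a_end = NA_integer_,
           orf_b_start = NA_integer_, orf_b_end = NA_integer_,
           n_aligned_codons = 0L, S = NA_real_, N = NA_real_,
           Sd = NA_real_, Nd = NA_real_, pS = NA_real_, pN = NA_real_,
           Ks = NA_real_, Ka = NA_real_, ka_ks = NA_real_, flags = flag)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    id_a <- pairs$id_a[i]; id_b <- pairs$id_b[i]
    sa <- seq_of[[id_a]]; sb <- seq_of[[id_b]]
    if (is.null(sa) || is.null(sb)) return(fail_row(id_a, id_b, "NO_SEQ"))
    if (nchar(sa) < 60 || nchar(sb) < 60) {
      return(fail_row(id_a, id_b, "TOO_SHORT"))
    }
    fr <- best_translated_frames(sa, sb)
    if (is.null(fr)) return(fail_row(id_a, id_b, "TOO_SHORT"))
    oa <- .oriented(sa, fr$frame_a); ob <- .oriented(sb, fr$frame_b)
    orf_a <- longest_orf_overlapping(oa, fr$frame_a, fr$region_a)
    orf_b <- longest_orf_overlapping(ob, fr$frame_b, fr$region_b)
    if (is.null(orf_a) || is.null(orf_b)) {
      return(fail_row(id_a, id_b, "TOO_SHORT"))
    }
    dna_a <- substring(oa, orf_a[1], orf_a[2])
    dna_b <- substring(ob, orf_b[1], orf_b[2])
    aln <- global_protein_align(.translate(dna_a), .translate(dna_b))
    codons <- backalign_codons(aln, dna_a, dna_b)
    ng <- nei_gojobori(codons, min_codons = config$min_codons)
    bind_cols(tibble(id_a = id_a, id_b = id_b,
                     frame_a = fr$frame_a, frame_b = fr$frame_b,
                     orf_a_start = orf_a[1], orf_a_end = orf_a[2],
                     orf_b_start = orf_b[1], orf_b_end = orf_b[2]),
              ng)
  })
  bind_rows(rows)
}

#' Relative divergence time from a Ks ratio
#'
#' Scales a reference event age by the ratio of synonymous divergences:
#' `t = t_reference * ks_focal / ks_reference`.
#'
#' @param ks_focal synonymous divergence of the focal event(s).
#' @param ks_reference synonymous divergence of the calibration event
#'   (must be positive).
#' @param t_reference_ma age of the calibration event in Ma.
#' @return A tibble with `t_point` (Ma), `calibration_t`, `ks_focal`,
#'   `ks_reference` (vectorised).
#' @export
divergence_time <- function(ks_focal, ks_reference, t_reference_ma) {
  if (any(ks_reference <= 0)) abort("ks_reference must be positive")
  tibble(t_point = t_reference_ma * ks_focal / ks_reference,
         calibration_t = t_reference_ma,
         ks_focal = ks_focal, ks_reference = ks_reference)
}

#' Compare sequence divergence between duplication origins
#'
#' Percent identity is compared between the two origin groups after the
#' arcsine square-root transform standard for percentages, with a
#' Shapiro-Wilk normality check recorded, using a two-sided rank-sum
#' (Mann-Whitney) test. Ks is compared on the natural-log scale (zero or
#' undefined Ks excluded, count reported) with a Welch two-sample t-test.
#'
#' @param data tibble with columns `label`, `percent_id`, `ks`.
#' @param groups the two labels to compare (default WGD vs LGD).
#' @return An object of class `divergence_comparison`; `tidy()` returns the
#'   per-test rows, `glance()` a one-row summary.
#' @export
compare_divergence_between_origins <- function(data,
                                               groups = c("WGD", "LGD")) {
  stopifnot(length(groups) == 2)
  d <- data |> filter(.data$label %in% groups)
  split_by <- function(x) split(x, factor(d$label, levels = groups))
  pid <- split_by(d$percent_id)
  if (any(lengths(pid) < 2)) abort("need >= 2 observations per group")
  shap <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3 || length(x) > 5000 || length(unique(x)) < 3) {
      return(NA_real_)
    }
    shapiro.test(x)$p.value
  }
  asin_pid <- lapply(pid, function(x) asin(sqrt(x / 100)))
  wt <- wilcox.test(asin_pid[[1]], asin_pid[[2]], exact = FALSE)
  ks <- split_by(d$ks)
  ks_clean <- lapply(ks, function(x) x[!is.na(x) & x > 0])
  n_excluded <- sum(lengths(ks)) - sum(lengths(ks_clean))
  ks_test <- if (all(lengths(ks_clean) >= 2)) {
    t.test(log(ks_clean[[1]]), log(ks_clean[[2]]), var.equal = FALSE)
  } else {
    NULL
  }
  tests <- bind_rows(
    tibble(test = "percent_id_rank_sum",
           transform = "arcsin_sqrt",
           statistic = unname(wt$statistic), df = NA_real_,
           p_value = wt$p.value,
           shapiro_p_1 = shap(asin_pid[[1]]),
           shapiro_p_2 = shap(asin_pid[[2]]),
           n_1 = length(pid[[1]]), n_2 = length(pid[[2]])),
    if (!is.null(ks_test)) {
      tibble(test = "log_ks_welch_t",
             transform = "log",
             statistic = unname(ks_test$statistic),
             df = unname(ks_test$parameter),
             p_value = ks_test$p.value,
             shapiro_p_1 = shap(log(ks_clean[[1]])),
             shapiro_p_2 = shap(log(ks_clean[[2]])),
             n_1 = length(ks_clean[[1]]), n_2 = length(ks_clean[[2]]))
    })
  group_stats <- d |>
    group_by(label = factor(.data$label, levels = groups)) |>
    summarise(n = n(),
              mean_percent_id = mean(.data$percent_id),
              median_percent_id = median(.data$percent_id),
              mean_ks = mean(.data$ks[!is.na(.data$ks) & .data$ks > 0]),
              median_ks = median(.data$ks[!is.na(.data$ks) & .data$ks > 0]),
              .groups = "drop") |>
    mutate(label = as.character(.data$label))
  structure(list(tests = tests, groups = group_stats,
                 n_ks_excluded = n_excluded),
            class = "divergence_comparison")
}

#' @export
print.divergence_comparison <- function(x, ...) {
  cat("Divergence comparison between duplication origins\n")
  print(x$groups)
  print(x$tests |> select("test", "statistic", "df", "p_value"))
  if (x$n_ks_excluded > 0) {
    cat(sprintf("  (%d Ks values excluded from the log-scale test)\n",
                x$n_ks_excluded))
  }
  invisible(x)
}
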