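# Control-set construction, annotation-hit concordance, GO-term Jaccard,
# coding-potential differences and the permutation test on median and IQR,
# and GO enrichment among paralog sets.

#' Control pairs from within isogroups (C1, "same genes")
#'
#' Samples pairs of isotigs drawn from the same isogroup; only isogroups
#' with at least two isotigs are eligible and no isogroup is used twice.
#' These pairs represent splice and allelic variants, where little or no
#' functional change is expected.
#'
#' @param isogroup_map tibble (`isotig_id`, `isogroup_id`).
#' @param n requested number of pairs.
#' @param seed integer RNG seed (the sampling is reproducible by seed).
#' @return An object of class `control_pairs`: a list with `kind`,
#'   `pairs` (tibble `id_a`, `id_b`), `seed`, `n_requested`, `n_realized`.
#' @export
build_control_same_isogroup <- function(isogroup_map, n, seed) {
  sizes <- isogroup_map |> count(.data$isogroup_id)
  eligible <- sizes$isogroup_id[sizes$n >= 2]
  if (!length(eligible)) abort("no isogroup has >= 2 isotigs")
  n_realized <- min(n, length(eligible))
  if (n_realized < n) {
    warn(paste0("only ", n_realized, " isogroups with >= 2 isotigs; ",
                "requested ", n, " pairs"))
  }
  members <- split(isogroup_map$isotig_id, isogroup_map$isogroup_id)
  pairs <- withr::with_seed(seed, {
    chosen <- sample(eligible, n_realized)
    bind_rows(lapply(chosen, function(g) {
      ids <- sample(members[[g]], 2)
      tibble(id_a = min(ids), id_b = max(ids))
    }))
  })
  structure(list(kind = "C1_SAME_ISOGROUP", pairs = pairs, seed = seed,
                 n_requested = n, n_realized = n_realized),
            class = "control_pairs")
}

#' Control pairs across isogroups (C2, "different genes")
#'
#' Samples pairs whose members come from different isogroups, by rejection
#' sampling (a same-isogroup partner is redrawn, up to 1000 attempts per
#' slot). No sequence is used twice across the whole set; pool exhaustion
#' ends sampling early with `n_realized < n`.
#'
#' @inheritParams build_control_same_isogroup
#' @return A `control_pairs` object of kind `C2_DIFFERENT_ISOGROUP`.
#' @export
build_control_different_isogroup <- function(isogroup_map, n, seed) {
  if (length(unique(isogroup_map$isogroup_id)) < 2) {
    abort("need >= 2 isogroups for cross-isogroup pairs")
  }
  grp <- setNames(isogroup_map$isogroup_id, isogroup_map$isotig_id)
  pairs <- withr::with_seed(seed, {
    avail <- sample(isogroup_map$isotig_id)  # random order, used left to right
    out <- vector("list", n)
    k <- 0L
    while (k < n && length(avail) >= 2) {
      first <- avail[1]
      avail <- avail[-1]
      cand <- which(grp[avail] != grp[[first]])
      if (!length(cand)) next  # first is unpairable; drop it and go on
      ok <- FALSE
      for (attempt in seq_len(1000)) {
        pick <- sample(length(avail), 1)
        if (grp[[avail[pick]]] != grp[[first]]) { ok <- TRUE; break }
      }
      if (!ok) break
      second <- avail[pick]
      avail <- avail[-pick]
      k <- k + 1L
      out[[k]] <- tibble(id_a = min(first, second),
                         id_b = max(first, second))
    }
    bind_rows(out[seq_len(k)])
  })
  n_realized <- nrow(pairs)
  if (n_realized < n) {
    warn(paste0("pool exhausted after ", n_realized, " of ", n,
                " cross-isogroup pairs"))
  }
  structure(list(kind = "C2_DIFFERENT_ISOGROUP", pairs = pairs, seed = seed,
                 n_requested = n, n_realized = n_realized),
            class = "control_pairs")
}

#' Classify annotation-hit concordance within pairs
#'
#' Each pair is `SAME_HIT` when both members have the same best annotation
#' hit, `DIFFERENT_HIT` when both have hits that differ *or* exactly one
#' member has a hit, and `NO_HIT` when neither does.
#'
#' @param pairs tibble with `id_a`, `id_b`.
#' @param annotation tibble (`id`, `accession`); ids absent from the table
#'   have no hit.
#' @return `pairs` with a `category` column.
#' @export
classify_hit_concordance <- function(pairs, annotation) {
  acc_a <- annotation$accession[match(pairs$id_a, annotation$id)]
  acc_b <- annotation$accession[match(pairs$id_b, annotation$id)]
  category <- case_when(
    is.na(acc_a) & is.na(acc_b) ~ "NO_HIT",
    !is.na(acc_a) & !is.na(acc_b) & acc_a == acc_b ~ "SAME_HIT",
    .default = "DIFFERENT_HIT")
  pairs |> mutate(category = category)
}

#' Concordance counts for several pair groups
#'
#' @param grouped_pairs named list of pair tibbles (e.g. `PARALOG`, `C1`,
#'   `C2`).
#' @param annotation tibble (`id`, `accession`).
#' @return A tibble with columns `group`, `SAME_HIT`, `DIFFERENT_HIT`,
#'   `NO_HIT`; row sums equal the group sizes.
#' @export
concordance_table <- function(grouped_pairs, annotation) {
  bind_rows(lapply(names(grouped_pairs), function(g) {
    cl <- classify_hit_concordance(grouped_pairs[[g]], annotation)
    tibble(group = g,
           SAME_HIT = sum(cl$category == "SAME_HIT"),
           DIFFERENT_HIT = sum(cl$category == "DIFFERENT_HIT"),
           NO_HIT = sum(cl$category == "NO_HIT"))
  }))
}

#' Pearson chi-squared test on a concordance table
#'
#' Tests whether the proportions of hit-concordance categories differ
#' between groups (3 groups x 3 categories gives 4 degrees of freedom).
#'
#' @param table a [concordance_table()] result.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
chi_square_concordance <- function(table) {
  m <- as.matrix(table[, c("SAME_HIT", "DIFFERENT_HIT", "NO_HIT")])
  rownames(m) <- table$group
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    abort("zero expected count; merge categories before testing")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(statistic = unname(ct$statistic),
         df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' Jaccard index of two sets
#'
#' `|A intersect B| / |A union B|`; undefined (`NA`) when both sets are
#' empty.
#'
#' @param set_a,set_b character vectors (treated as sets).
#' @return A number in \[0, 1\], or `NA`.
#' @export
jaccard_index <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Per-pair GO-term Jaccard indices
#'
#' @param pairs tibble with `id_a`, `id_b`.
#' @param go_map tibble (`id`, `go_term`).
#' @param drop_undefined drop pairs where both members have empty term sets.
#' @return `pairs` with a `jaccard` column.
#' @export
pairwise_go_jaccard <- function(pairs, go_map, drop_undefined = TRUE) {
  terms <- split(go_map$go_term, go_map$id)
  j <- map2_dbl_safe(pairs$id_a, pairs$id_b, function(a, b) {
    jaccard_index(terms[[a]] %||% character(), terms[[b]] %||% character())
  })
  out <- pairs |> mutate(jaccard = j)
  if (drop_undefined) out <- out |> filter(!is.na(.data$jaccard))
  out
}

map2_dbl_safe <- function(x, y, f) {
  vapply(seq_along(x), function(i) f(x[[i]], y[[i]]), numeric(1))
}

#' Compare Jaccard distributions across pair groups
#'
#' Kruskal-Wallis across all groups, then pairwise two-sided rank-sum
#' (Mann-Whitney) tests with Bonferroni correction for the repeated tests.
#'
#' @param jaccard_by_group named list of numeric Jaccard vectors.
#' @return A list with `kruskal` (tibble) and `pairwise` (tibble with raw
#'   and Bonferroni-adjusted p-values).
#' @export
compare_jaccard_distributions <- function(jaccard_by_group) {
  stopifnot(length(jaccard_by_group) >= 2,
            all(lengths(jaccard_by_group) >= 2))
  kw <- kruskal.test(jaccard_by_group)
  combos <- utils::combn(names(jaccard_by_group), 2)
  pw <- bind_rows(apply(combos, 2, function(gs) {
    wt <- wilcox.test(jaccard_by_group[[gs[1]]], jaccard_by_group[[gs[2]]],
                      exact = FALSE)
    tibble(group_1 = gs[1], group_2 = gs[2],
           statistic = unname(wt$statistic), p_value = wt$p.value)
  }))
  pw$p_adjusted <- p.adjust(pw$p_value, method = "bonferroni")
  list(kruskal = tibble(statistic = unname(kw$statistic),
                        df = unname(kw$parameter),
                        p_value = kw$p.value),
       pairwise = pw)
}

#' Absolute coding-potential differences within pairs
#'
#' @param pairs tibble with `id_a`, `id_b`.
#' @param scores tibble (`id`, `score`) of per-sequence coding-potential
#'   scores in \[0, 1\].
#' @return `pairs` with a `delta_score` column; pairs with an unscored
#'   member are dropped and the count reported via attribute
#'   `n_unscored_dropped`.
#' @export
pairwise_score_difference <- function(pairs, scores) {
  sa <- scores$score[match(pairs$id_a, scores$id)]
  sb <- scores$score[match(pairs$id_b, scores$id)]
  keep <- !is.na(sa) & !is.na(sb)
  out <- pairs[keep, ] |> mutate(delta_score = abs(sa - sb)[keep])
  attr(out, "n_unscored_dropped") <- sum(!keep)
  out
}

#' Permutation test for differences in median and IQR
#'
#' The observed statistics are the absolute differences in group medians
#' and in group interquartile ranges. Each round permutes the pooled values
#' over the two group labels (sizes preserved) and recomputes both; the
#' p-value is the fraction of rounds reaching at least the observed
#' difference (`>=`; ties are common with medians, so the non-strict count
#' is the conservative default -- `strict = TRUE` restores a strict
#' `greater than` count). A zero count is reported at the test's resolution
#' `1 / n_rounds`.
#'
#' @param group_x,group_y numeric vectors (>= 5 values each).
#' @param n_rounds permutation rounds (>= 1000).
#' @param seed integer RNG seed.
#' @param strict count strictly greater permuted differences only.
#' @return An object of class `permutation_result`.
#' @export
permutation_median_iqr_test <- function(group_x, group_y, n_rounds = 100000,
                                        seed = 1, strict = FALSE) {
  stopifnot(length(group_x) >= 5, length(group_y) >= 5, n_rounds >= 1000)
  n1 <- length(group_x); n2 <- length(group_y)
  # sorting the pool leaves the permutation null unchanged but makes the
  # p-value exactly invariant to exchanging equal-sized group labels
  pool <- sort(c(group_x, group_y))
  iqr <- function(sorted, n) {
    h <- (n - 1) * c(0.25, 0.75) + 1
    lo <- floor(h); frac <- h - lo
    q <- sorted[lo] + frac * (sorted[pmin(lo + 1, n)] - sorted[lo])
    q[2] - q[1]
  }
  med <- function(sorted, n) {
    if (n %% 2 == 1) sorted[(n + 1) / 2]
    else (sorted[n / 2] + sorted[n / 2 + 1]) / 2
  }
  obs_med <- abs(median(group_x) - median(group_y))
  obs_iqr <- abs(quantile(group_x, 0.75, names = FALSE) -
                   quantile(group_x, 0.25, names = FALSE) -
                   (quantile(group_y, 0.75, names = FALSE) -
                      quantile(group_y, 0.25, names = FALSE)))
  counts <- withr::with_seed(seed, {
    cm <- ci <- 0L
    chunk <- 2000L
    done <- 0L
    while (done < n_rounds) {
      nr <- min(chunk, n_rounds - done)
      perm <- matrix(0, n1 + n2, nr)
      for (r in seq_len(nr)) perm[, r] <- pool[sample.int(n1 + n2)]
      for (r in seq_len(nr)) {
        s1 <- sort.int(perm[seq_len(n1), r], method = "quick")
        s2 <- sort.int(perm[n1 + seq_len(n2), r], method = "quick")
        dm <- abs(med(s1, n1) - med(s2, n2))
        di <- abs(iqr(s1, n1) - iqr(s2, n2))
        if (strict) {
          if (dm > obs_med) cm <- cm + 1L
          if (di > obs_iqr) ci <- ci + 1L
        } else {
          if (dm >= obs_med) cm <- cm + 1L
          if (di >= obs_iqr) ci <- ci + 1L
        }
      }
      done <- done + nr
    }
    c(cm, ci)
  })
  p_of <- function(count) {
    p <- count / n_rounds
    list(p = p, display = if (count == 0) {
      paste0("< ", format(1 / n_rounds))
    } else {
      format(p)
    })
  }
  pm <- p_of(counts[1]); pi <- p_of(counts[2])
  structure(list(observed_median_diff = obs_med,
                 observed_iqr_diff = unname(obs_iqr),
                 p_median = pm$p, p_iqr = pi$p,
                 p_median_display = pm$display, p_iqr_display = pi$display,
                 n_rounds = as.integer(n_rounds), seed = as.integer(seed),
                 strict = strict),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test on median and IQR (", x$n_rounds, " rounds, seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  |median diff| = %.4g, p %s\n",
              x$observed_median_diff, x$p_median_display))
  cat(sprintf("  |IQR diff|    = %.4g, p %s\n",
              x$observed_iqr_diff, x$p_iqr_display))
  invisible(x)
}

#' GO-term enrichment by Fisher's exact test
#'
#' For every term annotated in the background, tests the 2x2 table of
#' foreground vs rest-of-background membership (two-sided Fisher's exact
#' test), adjusts p-values by Benjamini-Hochberg and flags terms at
#' `q <= fdr`.
#'
#' @param foreground_ids,background_ids sequence id vectors; the foreground
#'   must be a subset of the background.
#' @param go_map tibble (`id`, `go_term`).
#' @param fdr false-discovery-rate threshold for the significance flag.
#' @return A tibble per term: counts, `fold`, `p_value`, `q_value`,
#'   `significant`.
#' @export
go_enrichment_fisher <- function(foreground_ids, background_ids, go_map,
                                 fdr = 0.05) {
  foreground_ids <- unique(foreground_ids)
  background_ids <- unique(background_ids)
  if (!length(foreground_ids)) abort("empty foreground")
  if (!all(foreground_ids %in% background_ids)) {
    abort("foreground must be a subset of the background")
  }
  gm <- go_map |> filter(.data$id %in% background_ids)
  n_fg <- length(foreground_ids)
  n_bg <- length(background_ids) - n_fg  # rest of background
  terms <- unique(gm$go_term)
  rows <- lapply(terms, function(tm) {
    with_term <- unique(gm$id[gm$go_term == tm])
    a <- sum(with_term %in% foreground_ids)
    c_ <- length(with_term) - a
    b <- n_fg - a
    d <- n_bg - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    fg_rate <- a / n_fg
    bg_rate <- length(with_term) / (n_fg + n_bg)
    tibble(go_term = tm, fg_with = a, fg_total = n_fg,
           bg_with = length(with_term), bg_total = n_fg + n_bg,
           fold = if (bg_rate > 0) fg_rate / bg_rate else NA_real_,
           p_value = ft$p.value)
  })
  out <- bind_rows(rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= fdr
  out |> arrange(.data$q_value, .data$p_value)
}
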