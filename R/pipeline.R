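# End-to-end orchestration: simulate -> search -> classify -> Ka/Ks ->
# divergence and functional statistics, with per-stage TSV hand-off and a
# JSON run manifest, plus the threshold sensitivity grid.

#' Threshold sensitivity grid
#'
#' Re-runs the candidate filtering and classification over a grid of
#' percent-identity and alignment-length thresholds (the similarity search
#' and genome anchoring are computed once; only the thresholds change).
#' Raising either threshold can never increase the number of candidate
#' pairs.
#'
#' @inheritParams run_workflow
#' @param id_thresholds percent-identity thresholds to scan.
#' @param length_thresholds alignment-length thresholds (bp) to scan.
#' @return A tibble with one row per threshold combination and the
#'   workflow summary counts.
#' @export
sensitivity_grid <- function(transcripts, isogroup_map, genome, linkage_map,
                             config = pipeline_config(),
                             annotation = NULL,
                             id_thresholds = c(70, 75, 80, 85),
                             length_thresholds = c(300, 600)) {
  if (!length(id_thresholds) || !length(length_thresholds)) {
    abort("threshold lists must be non-empty")
  }
  collapsed <- collapse_isogroups(transcripts, isogroup_map)
  hits <- all_vs_all_self_search(collapsed, config)
  rbh <- reciprocal_best_pairs(hits)
  loose <- filter_candidate_pairs(rbh, min(length_thresholds),
                                  min(id_thresholds))
  pair_ids <- unique(c(loose$id_a, loose$id_b))
  anchors <- if (is.null(genome) || !length(pair_ids)) NULL else {
    anchor_transcripts(collapsed |> filter(.data$id %in% pair_ids),
                       genome, config)
  }
  anchor_split <- if (is.null(anchors)) list() else {
    split(anchors, anchors$transcript_id)
  }
  grid <- tidyr::expand_grid(min_id = sort(id_thresholds),
                             min_len = sort(length_thresholds))
  bind_rows(lapply(seq_len(nrow(grid)), function(g) {
    cand <- filter_candidate_pairs(rbh, grid$min_len[g], grid$min_id[g])
    labels <- if (nrow(cand)) {
      vapply(seq_len(nrow(cand)), function(i) {
        classify_pair(cand[i, ], anchor_split[[cand$id_a[i]]],
                      anchor_split[[cand$id_b[i]]], linkage_map,
                      annotation, config)$label
      }, "")
    } else {
      character()
    }
    tibble(min_id = grid$min_id[g], min_len = grid$min_len[g],
           n_candidate_pairs = nrow(cand),
           n_allelic = sum(labels == "ALLELIC"),
           n_retained = nrow(cand) - sum(labels == "ALLELIC"),
           n_wgd = sum(labels == "WGD"),
           n_lgd = sum(labels == "LGD"),
           n_ambiguous = sum(labels == "AMBIGUOUS"),
           n_unassigned = sum(labels == "UNASSIGNED"))
  }))
}

#' Run the complete analysis pipeline
#'
#' Executes the full analysis on a dataset (typically a
#' [simulate_dataset()] object or equivalently structured inputs):
#' paralog identification, Ka/Ks estimation on the retained pairs,
#' divergence comparison between origins, homeology concordance, control
#' sets, hit concordance, GO Jaccard, coding-potential differences with
#' permutation tests, and GO enrichment. When `outdir` is given, stage
#' tables are written as TSVs along with a JSON manifest (config snapshot,
#' seeds, row counts and file checksums).
#'
#' @param data a `paralog_simulation` or a list with `transcripts`,
#'   `isogroup_map`, `genome`, `linkage_map` and optionally `annotation`,
#'   `go_map`, `homeologs`, `truth`.
#' @param config a [pipeline_config()].
#' @param outdir optional output directory for TSV reports and manifest.
#' @param n_permutations overrides `config$n_permutations` (the permutation
#'   test is the slow stage).
#' @return A list of class `paralog_pipeline` with all stage results.
#' @export
run_pipeline <- function(data, config = pipeline_config(), outdir = NULL,
                         n_permutations = config$n_permutations) {
  wf <- run_workflow(data$transcripts, data$isogroup_map, data$genome,
                     data$linkage_map, config)
  retained <- wf$pairs |> filter(.data$label != "ALLELIC")
  kaks <- estimate_kaks(retained, data$transcripts, config)
  div_tbl <- retained |>
    select("id_a", "id_b", "label", percent_id = "pident") |>
    left_join(kaks |> select("id_a", "id_b", ks = "Ks"),
              by = c("id_a", "id_b"))
  divergence <- if (sum(div_tbl$label == "WGD") >= 2 &&
                    sum(div_tbl$label == "LGD") >= 2) {
    compare_divergence_between_origins(div_tbl)
  } else {
    NULL
  }
  homeology <- if (!is.null(data$homeologs)) {
    homeology_concordance(wf$pairs |> filter(.data$label == "WGD"),
                          data$homeologs)
  } else {
    NULL
  }

  c1 <- build_control_same_isogroup(data$isogroup_map,
                                    config$n_control_pairs, config$rng_seed)
  c2 <- build_control_different_isogroup(data$isogroup_map,
                                         config$n_control_pairs,
                                         config$rng_seed + 1L)
  groups <- list(PARALOG = retained |> select("id_a", "id_b"),
                 C1 = c1$pairs, C2 = c2$pairs)
  functional <- NULL
  if (!is.null(data$annotation)) {
    conc <- concordance_table(groups, data$annotation)
    chi <- chi_square_concordance(conc)
    functional <- list(concordance = conc, chi_square = chi)
  }
  jaccard <- if (!is.null(data$go_map)) {
    jac <- lapply(groups, function(g) {
      pairwise_go_jaccard(g, data$go_map)$jaccard
    })
    ok <- lengths(jac) >= 2
    if (sum(ok) >= 2) {
      list(values = jac, tests = compare_jaccard_distributions(jac[ok]))
    } else {
      NULL
    }
  }
  scores <- coding_potential_score(data$transcripts)
  deltas <- lapply(groups, function(g) {
    pairwise_score_difference(g, scores)$delta_score
  })
  perm <- list(
    paralog_vs_c1 = permutation_median_iqr_test(
      deltas$PARALOG, deltas$C1, n_rounds = n_permutations,
      seed = config$rng_seed),
    paralog_vs_c2 = permutation_median_iqr_test(
      deltas$PARALOG, deltas$C2, n_rounds = n_permutations,
      seed = config$rng_seed + 1L))
  enrichment <- if (!is.null(data$go_map)) {
    fg <- unique(c(retained$id_a, retained$id_b))
    go_enrichment_fisher(fg, data$transcripts$id, data$go_map)
  }

  res <- structure(list(workflow = wf, kaks = kaks,
                        divergence = divergence, homeology = homeology,
                        controls = list(c1 = c1, c2 = c2),
                        functional = functional, jaccard = jaccard,
                        scores = scores, score_deltas = deltas,
                        permutation = perm, enrichment = enrichment,
                        config = config),
                   class = "paralog_pipeline")
  if (!is.null(outdir)) .write_pipeline_reports(res, data, outdir)
  res
}

.write_pipeline_reports <- function(res, data, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  readr::write_tsv(res$workflow$pairs, p("pairs.tsv"))
  readr::write_tsv(res$workflow$summary, p("summary.tsv"))
  readr::write_tsv(res$kaks, p("kaks.tsv"))
  if (!is.null(res$functional)) {
    readr::write_tsv(res$functional$concordance, p("concordance.tsv"))
  }
  if (!is.null(res$homeology)) {
    readr::write_tsv(res$homeology$per_pair, p("homeology.tsv"))
  }
  if (!is.null(res$enrichment)) {
    readr::write_tsv(res$enrichment, p("enrichment.tsv"))
  }
  delta_tbl <- bind_rows(lapply(names(res$score_deltas), function(g) {
    tibble(group = g, delta_score = res$score_deltas[[g]])
  }))
  readr::write_tsv(delta_tbl, p("score_deltas.tsv"))
  files <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    config = res$config[setdiff(names(res$config), "scoring")],
    scoring = unclass(res$config$scoring),
    seeds = list(rng_seed = res$config$rng_seed,
                 c1 = res$controls$c1$seed, c2 = res$controls$c2$seed,
                 permutation = vapply(res$permutation, function(x) x$seed,
                                      0L)),
    stage_counts = as.list(res$workflow$summary),
    n_kaks_estimates = sum(!is.na(res$kaks$Ks)),
    n_score_deltas = lengths(res$score_deltas),
    files = lapply(setNames(files, basename(files)), function(f) {
      list(md5 = unname(tools::md5sum(f)), rows = length(readLines(f)))
    }))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.paralog_pipeline <- function(x, ...) {
  print(x$workflow)
  ok <- !is.na(x$kaks$Ks)
  cat(sprintf("  Ka/Ks estimates:      %d (median Ks %.3f, median Ka/Ks %.3f)\n",
              sum(ok), median(x$kaks$Ks[ok]),
              median(x$kaks$ka_ks[!is.na(x$kaks$ka_ks)])))
  if (!is.null(x$homeology) && !is.na(x$homeology$fraction)) {
    cat(sprintf("  homeology concordance: %d/%d (%.0f%%)\n",
                x$homeology$n_matched, x$homeology$n_total,
                100 * x$homeology$fraction))
  }
  invisible(x)
}
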