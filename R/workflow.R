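# The duplicate-gene decision procedure: collapse isogroup variants, keep
# reciprocal-best pairs passing the length/identity thresholds, anchor both
# members to the genome, and label each pair ALLELIC / LGD / WGD /
# UNASSIGNED / AMBIGUOUS.

PAIR_LABELS <- c("ALLELIC", "LGD", "WGD", "UNASSIGNED", "AMBIGUOUS")

#' Collapse isogroups to their longest isotig
#'
#' One sequence survives per isogroup: the longest, ties broken by the
#' lexicographically smaller id. Sequences absent from the map are treated
#' as singleton isogroups.
#'
#' @param seqs sequence tibble (`id`, `seq`).
#' @param isogroup_map tibble (`isotig_id`, `isogroup_id`).
#' @return The surviving rows of `seqs`, with an `isogroup_id` column.
#' @export
collapse_isogroups <- function(seqs, isogroup_map) {
  seqs |>
    left_join(isogroup_map, by = c(id = "isotig_id")) |>
    mutate(isogroup_id = coalesce(.data$isogroup_id, .data$id)) |>
    arrange(.data$isogroup_id, desc(nchar(.data$seq)), .data$id) |>
    distinct(.data$isogroup_id, .keep_all = TRUE) |>
    arrange(.data$id)
}

#' Filter candidate pairs on alignment length and identity
#'
#' Keeps pairs aligning over at least `min_len` bp (inclusive) at more than
#' `min_id` percent identity (strict), the working thresholds of the
#' paralog screen.
#'
#' @param pairs candidate-pair tibble with `length` and `pident` columns.
#' @param min_len minimum alignment length (bp), inclusive.
#' @param min_id percent-identity threshold, strict.
#' @return The surviving rows.
#' @export
filter_candidate_pairs <- function(pairs, min_len = 300, min_id = 80) {
  pairs |> filter(.data$length >= min_len, .data$pident > min_id)
}

# cluster sorted seed positions into loci separated by more than `gap`
.cluster_positions <- function(pos, gap) {
  pos <- sort(pos)
  grp <- cumsum(c(1L, diff(pos) > gap))
  split(pos, grp)
}

#' Anchor transcripts onto genome contigs
#'
#' Seeds each transcript against every contig with exact k-mers (both
#' strands), aligns it to the seeded windows with the affine-gap aligner,
#' and keeps per transcript the best-scoring genome locus plus any further
#' loci scoring within `anchor_score_window` of the best (multiple anchors
#' are needed to classify duplications). Minus-strand hits are normalised
#' to forward-strand intervals. Unanchored transcripts are simply absent
#' from the result.
#'
#' @param transcripts sequence tibble (`id`, `seq`).
#' @param genome contig sequence tibble (`id`, `seq`), or a precomputed
#'   tabular hit table (transcript vs contig) from which anchors are taken.
#' @param config a [pipeline_config()].
#' @return A tibble with columns `transcript_id`, `contig_id`, `start`,
#'   `end`, `strand`, `score`.
#' @export
anchor_transcripts <- function(transcripts, genome,
                               config = pipeline_config()) {
  if (is.data.frame(genome) && "qseqid" %in% names(genome)) {
    return(.hits_to_anchors(genome, config))
  }
  stopifnot(all(c("id", "seq") %in% names(genome)))
  k <- config$kmer
  min_seeds <- 3L  # a genuine locus is supported by many seeds
  contigs <- Biostrings::DNAStringSet(setNames(genome$seq, genome$id))
  contigs_rc <- Biostrings::reverseComplement(contigs)

  # one shared dictionary over all transcript seeds (sampled at stride k/2)
  km_by_t <- lapply(transcripts$seq, function(s) {
    km <- unique(.kmers(s, k, stride = max(1L, k %/% 2)))
    km[!grepl("N", km, fixed = TRUE)]
  })
  all_km <- unique(unlist(km_by_t))
  if (!length(all_km)) {
    return(tibble(transcript_id = character(), contig_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  score = double()))
  }
  pd <- Biostrings::PDict(all_km)
  # which transcripts carry each dictionary k-mer
  t_of_km <- split(rep.int(seq_len(nrow(transcripts)), lengths(km_by_t)),
                   match(unlist(km_by_t), all_km))

  # collect seed positions per (transcript, contig, strand), vectorised
  seed_tbls <- list()
  for (ci in seq_along(contigs)) {
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") contigs[[ci]] else contigs_rc[[ci]]
      mt <- Biostrings::matchPDict(pd, subj)
      sidx <- Biostrings::startIndex(mt)
      nhit <- lengths(sidx)
      if (!sum(nhit)) next
      flat <- tibble(kmer_id = rep.int(seq_along(sidx), nhit),
                     pos = unlist(sidx, use.names = FALSE))
      tn <- t_of_km[as.character(flat$kmer_id)]
      seed_tbls[[length(seed_tbls) + 1L]] <-
        tibble(t = unlist(tn, use.names = FALSE),
               ci = ci, strand = strand,
               pos = rep.int(flat$pos, lengths(tn)))
    }
  }
  if (!length(seed_tbls)) {
    return(tibble(transcript_id = character(), contig_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  score = double()))
  }
  seeds <- bind_rows(seed_tbls)
  seeds <- split(seeds$pos,
                 paste(seeds$t, seeds$ci, seeds$strand, sep = "|"))

  # cluster seeds into loci; rank loci by seed support per transcript and
  # skip weakly seeded loci when a strongly seeded one exists (their
  # alignment cannot reach the retained score window)
  clusters <- list()
  for (key in names(seeds)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    t <- as.integer(parts[1])
    qlen <- nchar(transcripts$seq[t])
    for (cl in .cluster_positions(seeds[[key]], gap = qlen)) {
      if (length(cl) < min_seeds) next
      clusters[[length(clusters) + 1L]] <-
        list(t = t, ci = as.integer(parts[2]), strand = parts[3],
             n_seeds = length(cl), lo = min(cl), hi = max(cl))
    }
  }
  if (length(clusters)) {
    support <- vapply(clusters, function(x) x$n_seeds, 0L)
    t_id <- vapply(clusters, function(x) x$t, 0L)
    max_support <- tapply(support, t_id, max)
    keep_cl <- support >= 0.3 * max_support[as.character(t_id)]
    clusters <- clusters[keep_cl]
  }

  rows <- list()
  for (cl in clusters) {
    t <- cl$t; ci <- cl$ci; strand <- cl$strand
    tseq <- transcripts$seq[t]
    qlen <- nchar(tseq)
    clen <- nchar(genome$seq[ci])
    subj <- if (strand == "+") contigs[[ci]] else contigs_rc[[ci]]
    {
      span <- cl$hi - cl$lo
      pad <- min(qlen, max(200L, qlen - span + 200L))
      ws <- max(1L, cl$lo - pad)
      we <- min(clen, cl$hi + k + pad)
      aln <- .align_dna(tseq, as.character(Biostrings::subseq(subj, ws, we)),
                        config$scoring, global = FALSE, traceback = TRUE)
      if (aln$score <= 0 || is.null(aln$x_idx)) next
      yi <- aln$y_idx[aln$y_idx > 0]
      s1 <- ws + min(yi) - 1L; s2 <- ws + max(yi) - 1L
      if (strand == "-") {
        tmp <- clen - s2 + 1L
        s2 <- clen - s1 + 1L
        s1 <- tmp
      }
      rows[[length(rows) + 1L]] <-
        tibble(transcript_id = transcripts$id[t],
               contig_id = genome$id[ci],
               start = s1, end = s2, strand = strand,
               score = as.numeric(aln$score))
    }
  }
  out <- list()
  if (length(rows)) {
    all_anch <- bind_rows(rows)
    out <- lapply(split(all_anch, all_anch$transcript_id), function(anch) {
      # collapse duplicate loci (same contig, overlapping interval), keep best
      anch <- anch |>
        group_by(.data$contig_id) |>
        mutate(.locus = .overlap_group(.data$start, .data$end)) |>
        group_by(.data$contig_id, .data$.locus) |>
        slice_max(.data$score, n = 1, with_ties = FALSE) |>
        ungroup() |>
        select(-".locus")
      anch |>
        filter(.data$score >= max(.data$score) *
                 (1 - config$anchor_score_window)) |>
        arrange(desc(.data$score))
    })
  }
  res <- bind_rows(out)
  if (!nrow(res)) {
    res <- tibble(transcript_id = character(), contig_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  score = double())
  }
  res
}

# assign overlapping-interval group ids (intervals are pre-grouped by contig)
.overlap_group <- function(start, end) {
  o <- order(start)
  grp <- integer(length(start))
  cur <- 0L; cur_end <- -Inf
  for (i in o) {
    if (start[i] > cur_end) cur <- cur + 1L
    grp[i] <- cur
    cur_end <- max(cur_end, end[i])
  }
  grp
}

# convert an external transcript-vs-genome hit table into anchors
.hits_to_anchors <- function(hits, config) {
  hits |>
    mutate(start = pmin(.data$sstart, .data$send),
           end = pmax(.data$sstart, .data$send),
           strand = ifelse(.data$sstart <= .data$send, "+", "-"),
           score = .data$bitscore) |>
    group_by(.data$qseqid) |>
    filter(.data$score >= max(.data$score) *
             (1 - config$anchor_score_window)) |>
    ungroup() |>
    transmute(transcript_id = .data$qseqid, contig_id = .data$sseqid,
              start = .data$start, end = .data$end, strand = .data$strand,
              score = .data$score) |>
    arrange(.data$transcript_id, desc(.data$score))
}

#' Chromosome of a transcript's anchors
#'
#' Looks the anchors' contigs up in the linkage map. The chromosome is taken
#' from the top-scoring anchor; if lower-scoring anchors map to a different
#' chromosome the conflict is reported, never silently dropped.
#'
#' @param anchors anchor tibble for one transcript, best score first.
#' @param linkage_map tibble (`contig_id`, `chromosome`), or `NULL`.
#' @return A list with `chromosome` (string or `NA`) and `conflict`
#'   (logical).
#' @export
assign_chromosome <- function(anchors, linkage_map) {
  if (is.null(linkage_map) || is.null(anchors) || !nrow(anchors)) {
    return(list(chromosome = NA_character_, conflict = FALSE))
  }
  chroms <- linkage_map$chromosome[match(anchors$contig_id,
                                         linkage_map$contig_id)]
  top <- chroms[1]
  known <- unique(chroms[!is.na(chroms)])
  list(chromosome = top,
       conflict = !is.na(top) && length(known) > 1)
}

# gap in bases between two disjoint 1-based inclusive intervals
.interval_gap <- function(s1, e1, s2, e2) {
  if (s1 > s2) {
    tmp <- s1; s1 <- s2; s2 <- tmp
    tmp <- e1; e1 <- e2; e2 <- tmp
  }
  s2 - e1 - 1L
}

#' Classify one candidate pair as allelic, local or genome duplication
#'
#' Applies the anchoring rules in order: (1) any anchor combination on the
#' same contig with overlapping intervals marks the pair an allelic variant;
#' (2) same contig with a gap greater than `lgd_min_distance` (and, when an
#' annotation table is supplied, distinct best annotation hits) marks a
#' local gene duplication; (3) same contig, non-overlapping but closer than
#' that is ambiguous; (4) different contigs are compared at chromosome
#' level: same chromosome is a local duplication, different chromosomes a
#' whole-genome-duplication pair, unmapped contigs leave the pair
#' unassigned; (5) an unanchored member leaves the pair unassigned. The
#' evidence string records the firing rule.
#'
#' @param pair one-row candidate-pair tibble (`id_a`, `id_b`, ...).
#' @param anchors_a,anchors_b anchor tibbles for the two members (best
#'   score first); `NULL` or zero rows means unanchored.
#' @param linkage_map tibble (`contig_id`, `chromosome`) or `NULL`.
#' @param annotation optional tibble (`id`, `accession`) of best hits.
#' @param config a [pipeline_config()].
#' @return `pair` extended with anchor columns, `chrom_a`, `chrom_b`,
#'   `label` and `evidence`.
#' @export
classify_pair <- function(pair, anchors_a, anchors_b, linkage_map = NULL,
                          annotation = NULL, config = pipeline_config()) {
  res <- list(contig_a = NA_character_, start_a = NA_integer_,
              end_a = NA_integer_, contig_b = NA_character_,
              start_b = NA_integer_, end_b = NA_integer_,
              chrom_a = NA_character_, chrom_b = NA_character_,
              label = "UNASSIGNED", evidence = "")
  has_a <- !is.null(anchors_a) && nrow(anchors_a) > 0
  has_b <- !is.null(anchors_b) && nrow(anchors_b) > 0
  if (has_a) {
    res$contig_a <- anchors_a$contig_id[1]
    res$start_a <- anchors_a$start[1]; res$end_a <- anchors_a$end[1]
  }
  if (has_b) {
    res$contig_b <- anchors_b$contig_id[1]
    res$start_b <- anchors_b$start[1]; res$end_b <- anchors_b$end[1]
  }
  if (!has_a || !has_b) {
    res$evidence <- "rule5: member without genome anchor"
    return(bind_cols(pair, as_tibble(res)))
  }

  # rule 1: overlapping anchors on a shared contig => allelic variants
  shared <- inner_join(anchors_a, anchors_b, by = "contig_id",
                       suffix = c("_a", "_b"), relationship = "many-to-many")
  if (nrow(shared)) {
    ovl <- shared |> filter(.data$start_a <= .data$end_b,
                            .data$start_b <= .data$end_a)
    if (nrow(ovl)) {
      res$contig_a <- res$contig_b <- ovl$contig_id[1]
      res$start_a <- ovl$start_a[1]; res$end_a <- ovl$end_a[1]
      res$start_b <- ovl$start_b[1]; res$end_b <- ovl$end_b[1]
      res$label <- "ALLELIC"
      res$evidence <- paste0("rule1: overlapping anchors on ",
                             ovl$contig_id[1])
      return(bind_cols(pair, as_tibble(res)))
    }
  }

  ca <- assign_chromosome(anchors_a, linkage_map)
  cb <- assign_chromosome(anchors_b, linkage_map)
  res$chrom_a <- ca$chromosome; res$chrom_b <- cb$chromosome
  conflict_note <- paste0(
    if (ca$conflict) paste0("; chromosome conflict among anchors of ",
                            pair$id_a) else "",
    if (cb$conflict) paste0("; chromosome conflict among anchors of ",
                            pair$id_b) else "")

  if (res$contig_a == res$contig_b) {
    gap <- .interval_gap(res$start_a, res$end_a, res$start_b, res$end_b)
    if (gap > config$lgd_min_distance) {
      distinct_hits <- TRUE
      if (!is.null(annotation)) {
        acc_a <- annotation$accession[match(pair$id_a, annotation$id)]
        acc_b <- annotation$accession[match(pair$id_b, annotation$id)]
        # one annotated / one not counts as distinct; both unannotated does not
        distinct_hits <- !(is.na(acc_a) && is.na(acc_b)) &&
          (is.na(acc_a) || is.na(acc_b) || acc_a != acc_b)
      }
      if (distinct_hits) {
        res$label <- "LGD"
        res$evidence <- paste0("rule2: same contig, gap ", gap, " bp > ",
                               config$lgd_min_distance, conflict_note)
      } else {
        res$label <- "AMBIGUOUS"
        res$evidence <- paste0("rule2: same contig, gap ", gap,
                               " bp but identical annotation hit",
                               conflict_note)
      }
    } else {
      res$label <- "AMBIGUOUS"
      res$evidence <- paste0("rule3: same contig, non-overlapping, gap ",
                             gap, " bp <= ", config$lgd_min_distance,
                             conflict_note)
    }
    return(bind_cols(pair, as_tibble(res)))
  }

  # rule 4: different contigs, compare chromosomes
  if (is.na(res$chrom_a) || is.na(res$chrom_b)) {
    res$label <- "UNASSIGNED"
    res$evidence <- paste0("rule4: contig without chromosome assignment",
                           conflict_note)
  } else if (res$chrom_a == res$chrom_b) {
    res$label <- "LGD"
    res$evidence <- paste0("rule4: different contigs on chromosome ",
                           res$chrom_a, conflict_note)
  } else {
    res$label <- "WGD"
    res$evidence <- paste0("rule4: chromosomes ", res$chrom_a, " vs ",
                           res$chrom_b, conflict_note)
  }
  bind_cols(pair, as_tibble(res))
}

#' Chromosome-pair concordance of WGD pairs against a reference set
#'
#' Compares the unordered chromosome pairs of WGD-labelled paralog pairs
#' with a reference set of known homeologous chromosome pairs.
#'
#' @param wgd_pairs tibble with `chrom_a`, `chrom_b` columns (WGD pairs).
#' @param reference tibble with `chrom_a`, `chrom_b` of known homeologies.
#' @return A list with `n_matched`, `n_total`, `fraction` (NA when there
#'   are no pairs) and `per_pair`, a tibble of per-chromosome-pair counts.
#' @export
homeology_concordance <- function(wgd_pairs, reference) {
  canon <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "__")
  ref_keys <- unique(canon(reference$chrom_a, reference$chrom_b))
  if (!nrow(wgd_pairs)) {
    return(list(n_matched = 0L, n_total = 0L, fraction = NA_real_,
                per_pair = tibble(chrom_pair = character(), n = integer(),
                                  matched = logical())))
  }
  keys <- canon(wgd_pairs$chrom_a, wgd_pairs$chrom_b)
  per <- tibble(chrom_pair = keys) |>
    count(.data$chrom_pair) |>
    mutate(matched = .data$chrom_pair %in% ref_keys) |>
    arrange(desc(.data$n))
  n_matched <- sum(per$n[per$matched])
  list(n_matched = n_matched, n_total = length(keys),
       fraction = n_matched / length(keys), per_pair = per)
}

#' Run the full paralog-identification workflow
#'
#' Executes the four stages in order: collapse isogroup variants to their
#' longest isotig, find reciprocal-best-hit candidate pairs above the
#' length/identity thresholds, anchor pair members to the genome to remove
#' allelic variants, and assign WGD/LGD origin via the linkage map.
#' Deterministic given its inputs and configuration.
#'
#' @param transcripts sequence tibble (`id`, `seq`).
#' @param isogroup_map tibble (`isotig_id`, `isogroup_id`).
#' @param genome contig sequence tibble, or a precomputed transcript-vs-
#'   genome hit table; `NULL` skips anchoring (all pairs unassigned).
#' @param linkage_map tibble (`contig_id`, `chromosome`) or `NULL` (pairs
#'   on different contigs stay unassigned).
#' @param config a [pipeline_config()].
#' @param annotation optional best-hit tibble (`id`, `accession`) used by
#'   the same-contig distance rule.
#' @param hits optional precomputed self-search hit table replacing the
#'   internal all-vs-all search.
#' @return An object of class `paralog_workflow`: a list with `pairs` (the
#'   labelled pair tibble), `summary` (one-row count tibble), `candidates`,
#'   and `anchors`. `tidy()` returns the pairs, `glance()` the summary.
#' @export
run_workflow <- function(transcripts, isogroup_map, genome, linkage_map,
                         config = pipeline_config(), annotation = NULL,
                         hits = NULL) {
  stopifnot(all(c("id", "seq") %in% names(transcripts)))
  collapsed <- collapse_isogroups(transcripts, isogroup_map)
  if (is.null(hits)) {
    hits <- all_vs_all_self_search(collapsed, config)
  } else {
    hits <- hits |> filter(.data$qseqid %in% collapsed$id,
                           .data$sseqid %in% collapsed$id,
                           .data$qseqid != .data$sseqid)
    if (config$refilter_external_hits) {
      hits <- hits |> filter(.data$evalue <= config$evalue_threshold)
    }
  }
  rbh <- reciprocal_best_pairs(hits)
  cand <- filter_candidate_pairs(rbh, config$min_alignment_length,
                                 config$min_percent_id)
  pair_ids <- unique(c(cand$id_a, cand$id_b))
  anchors <- if (is.null(genome) || !length(pair_ids)) {
    tibble(transcript_id = character(), contig_id = character(),
           start = integer(), end = integer(), strand = character(),
           score = double())
  } else {
    anchor_transcripts(collapsed |> filter(.data$id %in% pair_ids),
                       genome, config)
  }
  anchor_split <- split(anchors, anchors$transcript_id)
  pairs <- if (nrow(cand)) {
    bind_rows(lapply(seq_len(nrow(cand)), function(i) {
      classify_pair(cand[i, ],
                    anchor_split[[cand$id_a[i]]],
                    anchor_split[[cand$id_b[i]]],
                    linkage_map, annotation, config)
    }))
  } else {
    bind_cols(cand,
              tibble(contig_a = character(), start_a = integer(),
                     end_a = integer(), contig_b = character(),
                     start_b = integer(), end_b = integer(),
                     chrom_a = character(), chrom_b = character(),
                     label = character(), evidence = character()))
  }
  n_allelic <- sum(pairs$label == "ALLELIC")
  summary <- tibble(
    n_isotigs_in = nrow(transcripts),
    n_after_collapse = nrow(collapsed),
    n_candidate_pairs = nrow(cand),
    n_allelic = n_allelic,
    n_retained = nrow(cand) - n_allelic,
    n_chromosome_assigned = sum(pairs$label != "ALLELIC" &
                                  !is.na(pairs$chrom_a) &
                                  !is.na(pairs$chrom_b)),
    n_wgd = sum(pairs$label == "WGD"),
    n_lgd = sum(pairs$label == "LGD"),
    n_ambiguous = sum(pairs$label == "AMBIGUOUS"),
    n_unassigned = sum(pairs$label == "UNASSIGNED"))
  structure(list(pairs = pairs, summary = summary, candidates = cand,
                 anchors = anchors, config = config),
            class = "paralog_workflow")
}

#' @export
print.paralog_workflow <- function(x, ...) {
  s <- x$summary
  cat("Paralog identification workflow\n")
  cat(sprintf("  input isotigs:        %d\n", s$n_isotigs_in))
  cat(sprintf("  after isogroup collapse: %d\n", s$n_after_collapse))
  cat(sprintf("  candidate pairs:      %d\n", s$n_candidate_pairs))
  cat(sprintf("  allelic (discarded):  %d\n", s$n_allelic))
  cat(sprintf("  retained pairs:       %d (WGD %d, LGD %d, ambiguous %d, unassigned %d)\n",
              s$n_retained, s$n_wgd, s$n_lgd, s$n_ambiguous, s$n_unassigned))
  invisible(x)
}
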