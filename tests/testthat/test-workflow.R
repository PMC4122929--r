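mk_anchor <- function(id, contig, start, end, score = 1000, strand = "+") {
  tibble::tibble(transcript_id = id, contig_id = contig,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, score = score)
}

mk_pair <- function(id_a = "A", id_b = "B", pident = 90, len = 400) {
  tibble::tibble(id_a = id_a, id_b = id_b, pident = pident,
                 length = as.integer(len), evalue = 1e-60, bitscore = 500)
}

test_that("isogroup collapse keeps the longest isotig, ties by id", {
  seqs <- tibble::tibble(
    id = c("iso1", "iso2", "iso3", "iso4", "lonely"),
    seq = c(strrep("A", 300), strrep("A", 500), strrep("C", 200),
            strrep("G", 200), strrep("T", 100)))
  map <- tibble::tibble(isotig_id = c("iso1", "iso2", "iso3", "iso4"),
                        isogroup_id = c("g1", "g1", "g2", "g2"))
  out <- collapse_isogroups(seqs, map)
  expect_setequal(out$id, c("iso2", "iso3", "lonely"))
  # iso3/iso4 equal length: lexicographically smaller id kept
  expect_true("iso3" %in% out$id)
  # unmapped sequence survives as singleton isogroup
  expect_equal(out$isogroup_id[out$id == "lonely"], "lonely")
})

test_that("candidate filtering applies inclusive length, strict identity", {
  pairs <- dplyr::bind_rows(
    mk_pair("A", "B", pident = 85, len = 300),   # kept: >= 300, > 80
    mk_pair("C", "D", pident = 99, len = 299),   # dropped: length
    mk_pair("E", "F", pident = 80, len = 400))   # dropped: identity strict
  out <- filter_candidate_pairs(pairs, 300, 80)
  expect_equal(out$id_a, "A")
})

test_that("pair classification applies the anchoring rules in order", {
  cfg <- pipeline_config()
  lm <- tibble::tibble(contig_id = c("ctg1", "ctg9"),
                       chromosome = c("ssa01", "ssa12"))

  # overlapping intervals on one contig: allelic variants
  p <- classify_pair(mk_pair(), mk_anchor("A", "ctg1", 100, 700),
                     mk_anchor("B", "ctg1", 500, 1100), lm, config = cfg)
  expect_equal(p$label, "ALLELIC")

  # same contig, gap 5299 > 5000, distinct annotations: local duplication
  ann <- tibble::tibble(id = c("A", "B"), accession = c("P1", "P2"))
  p <- classify_pair(mk_pair(), mk_anchor("A", "ctg1", 100, 700),
                     mk_anchor("B", "ctg1", 6000, 6600), lm, ann, cfg)
  expect_equal(p$label, "LGD")
  expect_match(p$evidence, "5299")

  # same gap but identical annotation hit: not called a duplication
  ann_same <- tibble::tibble(id = c("A", "B"), accession = c("P1", "P1"))
  p <- classify_pair(mk_pair(), mk_anchor("A", "ctg1", 100, 700),
                     mk_anchor("B", "ctg1", 6000, 6600), lm, ann_same, cfg)
  expect_equal(p$label, "AMBIGUOUS")

  # no annotation table: distance alone decides
  p <- classify_pair(mk_pair(), mk_anchor("A", "ctg1", 100, 700),
                     mk_anchor("B", "ctg1", 6000, 6600), lm, NULL, cfg)
  expect_equal(p$label, "LGD")

  # same contig, non-overlapping, gap 3299 <= 5000: ambiguous
  p <- classify_pair(mk_pair(), mk_anchor("A", "ctg1", 100, 700),
                     mk_anchor("B", "ctg1", 4000, 4600), lm, config = cfg)
  expect_equal(p$label, "AMBIGUOUS")
  expect_match(p$evidence, "3299")

  # different contigs on different chromosomes: WGD
  p <- classify_pair(mk_pair(), mk_anchor("A", "ctg1", 100, 700),
                     mk_anchor("B", "ctg9", 100, 700), lm, config = cfg)
  expect_equal(p$label, "WGD")

  # different contigs mapping to one chromosome: local duplication
  lm2 <- tibble::tibble(contig_id = c("ctg1", "ctg9"),
                        chromosome = c("ssa01", "ssa01"))
  p <- classify_pair(mk_pair(), mk_anchor("A", "ctg1", 100, 700),
                     mk_anchor("B", "ctg9", 100, 700), lm2, config = cfg)
  expect_equal(p$label, "LGD")

  # unmapped contig or missing anchor: unassigned
  p <- classify_pair(mk_pair(), mk_anchor("A", "ctg1", 100, 700),
                     mk_anchor("B", "ctgX", 100, 700), lm, config = cfg)
  expect_equal(p$label, "UNASSIGNED")
  p <- classify_pair(mk_pair(), mk_anchor("A", "ctg1", 100, 700), NULL,
                     lm, config = cfg)
  expect_equal(p$label, "UNASSIGNED")
})

test_that("chromosome assignment uses the top anchor and flags conflicts", {
  lm <- tibble::tibble(contig_id = c("ctg7", "ctg8"),
                       chromosome = c("ssa03", "ssa05"))
  a <- mk_anchor("T", "ctg7", 1, 500, score = 900)
  expect_equal(assign_chromosome(a, lm)$chromosome, "ssa03")
  expect_equal(assign_chromosome(mk_anchor("T", "ctgZ", 1, 500), lm),
               list(chromosome = NA_character_, conflict = FALSE))
  multi <- dplyr::bind_rows(mk_anchor("T", "ctg7", 1, 500, 900),
                            mk_anchor("T", "ctg8", 1, 500, 850))
  got <- assign_chromosome(multi, lm)
  expect_equal(got$chromosome, "ssa03")
  expect_true(got$conflict)
})

test_that("homeology concordance counts unordered chromosome pairs", {
  ref <- tibble::tibble(chrom_a = sprintf("c%02d", 1:27),
                        chrom_b = sprintf("c%02d", 28:54))
  wgd <- tibble::tibble(
    chrom_a = c(sprintf("c%02d", rep(1:21, length.out = 46)), rep("x1", 33)),
    chrom_b = c(sprintf("c%02d", rep(28:48, length.out = 46)), rep("x2", 33)))
  hc <- homeology_concordance(wgd, ref)
  expect_equal(hc$n_matched, 46L)
  expect_equal(hc$n_total, 79L)
  expect_equal(round(100 * hc$fraction), 58)

  empty_ref <- homeology_concordance(wgd, ref[0, ])
  expect_equal(empty_ref$n_matched, 0L)
  expect_true(is.na(homeology_concordance(wgd[0, ], ref)$fraction))
  # reversed order still matches
  hc2 <- homeology_concordance(
    tibble::tibble(chrom_a = "c28", chrom_b = "c01"), ref)
  expect_equal(hc2$fraction, 1)
})

test_that("genome anchoring finds exact and duplicated loci", {
  set.seed(808)
  insert <- rand_dna(500)
  ctg1 <- paste0(rand_dna(1000), insert, rand_dna(800))
  ctg2 <- paste0(rand_dna(400), insert, rand_dna(1500))
  genome <- tibble::tibble(id = c("ctg1", "ctg2"), seq = c(ctg1, ctg2))
  tr <- tibble::tibble(id = c("hit", "orphan"),
                       seq = c(insert, rand_dna(400)))
  anch <- anchor_transcripts(tr, genome)
  a1 <- anch[anch$transcript_id == "hit" & anch$contig_id == "ctg1", ]
  expect_equal(c(a1$start, a1$end), c(1001L, 1500L))
  # equally scoring second locus retained as a second anchor
  expect_setequal(anch$contig_id[anch$transcript_id == "hit"],
                  c("ctg1", "ctg2"))
  # transcript with no genome hit is absent
  expect_false("orphan" %in% anch$transcript_id)
  # minus-strand copy is normalised to a forward interval
  tr_rc <- tibble::tibble(id = "rc", seq = revcomp(insert))
  anch_rc <- anchor_transcripts(tr_rc, genome[1, ])
  expect_equal(anch_rc$strand, "-")
  expect_equal(c(anch_rc$start, anch_rc$end), c(1001L, 1500L))
})

test_that("the full workflow recovers planted structure deterministically", {
  sim <- tiny_sim()
  wf <- run_workflow(sim$transcripts, sim$isogroup_map, sim$genome,
                     sim$linkage_map)
  s <- wf$summary
  expect_equal(s$n_retained, s$n_candidate_pairs - s$n_allelic)
  expect_true(s$n_wgd + s$n_lgd <= s$n_chromosome_assigned)
  expect_true(all(wf$pairs$label %in%
                    c("ALLELIC", "LGD", "WGD", "UNASSIGNED", "AMBIGUOUS")))
  rec <- evaluate_truth_recovery(wf$pairs, sim$truth)
  expect_gte(rec$label_accuracy, 0.99)
  expect_equal(rec$allelic_exclusion, 1)

  # determinism: identical rerun
  wf2 <- run_workflow(sim$transcripts, sim$isogroup_map, sim$genome,
                      sim$linkage_map)
  expect_equal(wf$pairs, wf2$pairs)
  expect_equal(wf$summary, wf2$summary)
})

test_that("a single-sequence transcriptome yields no pairs", {
  seqs <- tibble::tibble(id = "only", seq = rand_codon_dna(150))
  wf <- run_workflow(seqs, tibble::tibble(isotig_id = "only",
                                          isogroup_id = "g1"),
                     genome = NULL, linkage_map = NULL)
  expect_equal(wf$summary$n_after_collapse, 1L)
  expect_equal(wf$summary$n_candidate_pairs, 0L)
  expect_equal(nrow(wf$pairs), 0)
})

test_that("raising thresholds never increases candidate counts", {
  sim <- tiny_sim()
  grid <- sensitivity_grid(sim$transcripts, sim$isogroup_map, sim$genome,
                           sim$linkage_map,
                           id_thresholds = c(70, 75, 80, 85),
                           length_thresholds = c(300, 600))
  expect_equal(nrow(grid), 8)
  by_len <- split(grid, grid$min_len)
  for (g in by_len) {
    g <- g[order(g$min_id), ]
    expect_true(all(diff(g$n_candidate_pairs) <= 0))
  }
  by_id <- split(grid, grid$min_id)
  for (g in by_id) {
    g <- g[order(g$min_len), ]
    expect_true(all(diff(g$n_candidate_pairs) <= 0))
  }
  # the default cell equals a default workflow run
  wf <- run_workflow(sim$transcripts, sim$isogroup_map, sim$genome,
                     sim$linkage_map)
  cell <- grid[grid$min_id == 80 & grid$min_len == 300, ]
  expect_equal(cell$n_candidate_pairs, wf$summary$n_candidate_pairs)
  expect_equal(cell$n_wgd, wf$summary$n_wgd)
  expect_error(sensitivity_grid(sim$transcripts, sim$isogroup_map,
                                sim$genome, sim$linkage_map,
                                id_thresholds = numeric()), "non-empty")
})
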