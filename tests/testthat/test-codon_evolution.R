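test_that("frame selection recovers identity, shifts and strand", {
  set.seed(11)
  a <- rand_codon_dna(120)
  fr <- best_translated_frames(a, a)
  expect_equal(c(fr$frame_a, fr$frame_b), c(1L, 1L))

  # deleting the first nucleotide shifts the best frame of b
  fr2 <- best_translated_frames(a, substring(a, 2))
  expect_equal(fr2$frame_a, 1L)
  expect_true(fr2$frame_b %in% c(2L, 3L))

  fr3 <- best_translated_frames(a, revcomp(a))
  expect_equal(fr3$frame_a, 1L)
  expect_true(fr3$frame_b < 0)
})

test_that("longest overlapping ORF follows the stop-free-run rules", {
  set.seed(12)
  sense <- rand_codon_dna(100)
  expect_equal(longest_orf_overlapping(substring(sense, 1, 300), 1,
                                       c(1, 300)),
               c(1L, 300L))

  # stop at codon 50 of 100, alignment within codons 1-49
  with_stop <- paste0(substring(sense, 1, 147), "TAA",
                      substring(sense, 151, 300))
  expect_equal(longest_orf_overlapping(with_stop, 1, c(1, 147)),
               c(1L, 147L))

  # two stop-free runs (40 and 59 codons), both overlapping: longest wins
  two_runs <- paste0(rand_codon_dna(40), "TGA", rand_codon_dna(59))
  got <- longest_orf_overlapping(two_runs, 1, c(1, nchar(two_runs)))
  expect_equal(got, c(124L, 300L))

  # nothing of at least 30 codons
  expect_null(longest_orf_overlapping(rand_codon_dna(20), 1, c(1, 60)))
})

test_that("global protein alignment matches a full-DP oracle", {
  aln <- global_protein_align("MKLVT", "MKLVT")
  expect_equal(aln$a, "MKLVT")
  expect_equal(aln$b, "MKLVT")

  p1 <- "HEAGAWGHEE"; p2 <- "PAWHEAE"
  aln <- global_protein_align(p1, p2)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  oracle <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2), type = "global",
    substitutionMatrix = BLOSUM62, gapOpening = 10, gapExtension = 1)
  expect_equal(aln$score, Biostrings::score(oracle))
  expect_error(global_protein_align("", "MK"), "non-empty")
})

test_that("codon back-alignment expands residues and round-trips ORFs", {
  set.seed(13)
  orf <- rand_codon_dna(10)
  pep <- paralogr:::.translate(orf)
  aln <- list(a = pep, b = pep)
  ca <- backalign_codons(aln, orf, orf)
  expect_equal(length(ca$codon_a), 10)
  expect_equal(ca$n_aligned_codons, 10)

  # a one-residue gap becomes a --- codon
  orf_b <- substring(orf, 4)  # drop first codon
  aln2 <- global_protein_align(pep, paralogr:::.translate(orf_b))
  ca2 <- backalign_codons(aln2, orf, orf_b)
  expect_true("---" %in% ca2$codon_b)
  # reconstruction invariant, byte-exact
  expect_equal(paste(ca2$codon_a[ca2$codon_a != "---"], collapse = ""), orf)
  expect_equal(paste(ca2$codon_b[ca2$codon_b != "---"], collapse = ""), orf_b)

  # mismatching peptide is rejected by position
  expect_error(backalign_codons(list(a = "MK", b = "MK"), "ATGAAA", "ATGCCC"),
               "residue 2")
})

test_that("Nei-Gojobori matches the worked single-difference example", {
  ng <- nei_gojobori(list(codon_a = rep("GGT", 9),
                          codon_b = c(rep("GGT", 8), "GGC")),
                     min_codons = 1)
  expect_equal(ng$S, 9)
  expect_equal(ng$N, 18)
  expect_equal(ng$Sd, 1)
  expect_equal(ng$Nd, 0)
  expect_equal(ng$pS, 0.1111, tolerance = 1e-3)
  expect_equal(ng$Ks, 0.1203, tolerance = 1e-3)
  expect_equal(ng$Ka, 0)
})

test_that("Nei-Gojobori flags degenerate situations instead of failing", {
  ident <- nei_gojobori(list(codon_a = rep("GAT", 120),
                             codon_b = rep("GAT", 120)))
  expect_equal(ident$Ks, 0)
  expect_equal(ident$Ka, 0)
  expect_match(ident$flags, "KS_ZERO")
  expect_true(is.na(ident$ka_ks))

  short <- nei_gojobori(list(codon_a = "TTT", codon_b = "TTA"))
  expect_match(short$flags, "TOO_SHORT")
})

test_that("site and pathway counts match exhaustive enumeration", {
  # random sample of the 61x61 sense-codon grid against the independent
  # recursive oracle (the full grid is covered by the acceptance suite)
  gc_map <- Biostrings::GENETIC_CODE
  sense <- names(gc_map)[gc_map != "*"]
  set.seed(14)
  tb <- paralogr:::.ng_tables()
  for (k in 1:80) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    o <- oracle_ng_pair(c1, c2)
    expect_equal(unname(tb$syn_sites[c1]), o$s1, tolerance = 1e-12)
    expect_equal(unname(tb$SD[c1, c2]), o$sd, tolerance = 1e-12)
    expect_equal(unname(tb$ND[c1, c2]), o$nd, tolerance = 1e-12)
  }
})

test_that("site conservation and the Jukes-Cantor limit hold", {
  set.seed(15)
  for (i in 1:5) {
    n <- sample(100:200, 1)
    ca <- substring(rand_codon_dna(n), 3 * (seq_len(n) - 1) + 1,
                    3 * seq_len(n))
    cb <- substring(rand_codon_dna(n), 3 * (seq_len(n) - 1) + 1,
                    3 * seq_len(n))
    ng <- nei_gojobori(list(codon_a = ca, codon_b = cb), min_codons = 1)
    expect_equal(ng$S + ng$N, 3 * ng$n_aligned_codons)
    expect_lte(ng$Sd, ng$S)
    expect_lte(ng$Nd, ng$N)
  }
  p <- 1e-4
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_equal(d / p, 1, tolerance = 1e-3)
})

test_that("divergence-time scaling reproduces the Ks-ratio arithmetic", {
  expect_equal(divergence_time(0.23, 0.40, 100)$t_point, 57.5)
  expect_equal(divergence_time(0.21, 0.27, 100)$t_point, 77.78,
               tolerance = 1e-3)
  expect_equal(divergence_time(0.37, 0.37, 88)$t_point, 88)
  expect_error(divergence_time(0.2, 0, 100), "positive")
})

test_that("origin comparison runs the prescribed transformed tests", {
  set.seed(16)
  # clearly separated groups on the log scale
  d <- tibble::tibble(
    label = rep(c("WGD", "LGD"), each = 200),
    percent_id = c(runif(200, 82, 90), runif(200, 85, 93)),
    ks = c(exp(rnorm(200, 0, 1)), exp(rnorm(200, 2, 1))))
  cmp <- compare_divergence_between_origins(d)
  tt <- tidy(cmp)
  expect_setequal(tt$test, c("percent_id_rank_sum", "log_ks_welch_t"))
  expect_lt(tt$p_value[tt$test == "log_ks_welch_t"], 1e-10)
  expect_equal(glance(cmp)$n_ks_excluded, 0)

  # identical groups: rank-sum p of 1
  d2 <- tibble::tibble(label = rep(c("WGD", "LGD"), each = 50),
                       percent_id = rep(runif(50, 81, 99), 2),
                       ks = rep(exp(rnorm(50)), 2))
  cmp2 <- compare_divergence_between_origins(d2)
  expect_equal(tidy(cmp2)$p_value[1], 1, tolerance = 1e-6)

  # zero and missing Ks values are excluded with a count
  d3 <- d
  d3$ks[1:7] <- 0
  d3$ks[8:10] <- NA
  expect_equal(compare_divergence_between_origins(d3)$n_ks_excluded, 10)
})
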