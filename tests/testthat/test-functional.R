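iso_map <- function(sizes) {
  # sizes: named vector isogroup -> member count
  tibble::tibble(
    isotig_id = unlist(lapply(names(sizes), function(g) {
      paste0(g, "_t", seq_len(sizes[[g]]))
    })),
    isogroup_id = rep(names(sizes), sizes))
}

test_that("same-isogroup controls never reuse an isogroup", {
  m <- iso_map(c(a = 3, b = 2, c = 2, d = 2, e = 4, f = 1))
  cp <- build_control_same_isogroup(m, 3, seed = 9)
  expect_equal(cp$n_realized, 3)
  grp <- m$isogroup_id[match(cp$pairs$id_a, m$isotig_id)]
  grp2 <- m$isogroup_id[match(cp$pairs$id_b, m$isotig_id)]
  expect_equal(grp, grp2)               # members share an isogroup
  expect_false(anyDuplicated(grp) > 0)  # no isogroup used twice

  expect_warning(cp2 <- build_control_same_isogroup(m, 50, seed = 9),
                 "requested")
  expect_equal(cp2$n_realized, 5)  # f has a single isotig

  cp3 <- build_control_same_isogroup(m, 3, seed = 9)
  expect_equal(cp$pairs, cp3$pairs)  # reproducible by seed

  expect_error(build_control_same_isogroup(iso_map(c(x = 1)), 2, 1),
               "no isogroup")
})

test_that("different-isogroup controls never reuse a sequence", {
  m <- iso_map(c(a = 1, b = 1, c = 1, d = 1))
  cp <- build_control_different_isogroup(m, 2, seed = 4)
  expect_equal(cp$n_realized, 2)
  expect_false(anyDuplicated(c(cp$pairs$id_a, cp$pairs$id_b)) > 0)

  expect_error(build_control_different_isogroup(iso_map(c(a = 2)), 1, 1),
               ">= 2 isogroups")

  m2 <- iso_map(c(a = 5, b = 5, c = 5, d = 2, e = 2))
  for (seed in 1:20) {
    cp <- suppressWarnings(build_control_different_isogroup(m2, 9, seed))
    ids <- c(cp$pairs$id_a, cp$pairs$id_b)
    expect_false(anyDuplicated(ids) > 0)
    ga <- m2$isogroup_id[match(cp$pairs$id_a, m2$isotig_id)]
    gb <- m2$isogroup_id[match(cp$pairs$id_b, m2$isotig_id)]
    expect_true(all(ga != gb))
  }
})

test_that("hit-concordance categories follow the one-sided-hit rule", {
  ann <- tibble::tibble(id = c("x1", "x2", "y1"),
                        accession = c("P1", "P1", "P2"))
  pairs <- tibble::tibble(id_a = c("x1", "x1", "z1", "x1"),
                          id_b = c("x2", "y1", "z2", "z1"))
  got <- classify_hit_concordance(pairs, ann)
  expect_equal(got$category,
               c("SAME_HIT", "DIFFERENT_HIT", "NO_HIT", "DIFFERENT_HIT"))

  tbl <- concordance_table(list(G = pairs), ann)
  expect_equal(tbl$SAME_HIT + tbl$DIFFERENT_HIT + tbl$NO_HIT, nrow(pairs))
})

test_that("chi-squared concordance test matches hand-computed values", {
  t0 <- tibble::tibble(group = c("PARALOG", "C1", "C2"),
                       SAME_HIT = c(30L, 30L, 30L),
                       DIFFERENT_HIT = c(50L, 50L, 50L),
                       NO_HIT = c(20L, 20L, 20L))
  got <- chi_square_concordance(t0)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
  expect_equal(got$df, 4L)

  t1 <- tibble::tibble(group = c("A", "B", "C"),
                       SAME_HIT = c(50L, 0L, 50L),
                       DIFFERENT_HIT = c(50L, 50L, 0L),
                       NO_HIT = c(0L, 50L, 50L))
  got1 <- chi_square_concordance(t1)
  expect_equal(got1$statistic, 150)  # direct Pearson formula
  expect_equal(got1$df, 4L)

  t2 <- t1
  t2$SAME_HIT <- c(0L, 0L, 0L)
  expect_error(chi_square_concordance(t2), "expected")
})

test_that("Jaccard index follows its definition", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index("a", "b"), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_true(is.na(jaccard_index(character(), character())))
  set.seed(21)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(1:10, 1))
    expect_equal(jaccard_index(a, b), jaccard_index(b, a))
    expect_equal(jaccard_index(a, b) == 1, setequal(a, b))
  }
})

test_that("Jaccard group comparisons use rank tests with Bonferroni", {
  set.seed(22)
  same <- runif(60)
  cmp <- compare_jaccard_distributions(list(a = same, b = same, c = same))
  expect_gt(cmp$kruskal$p_value, 0.99)

  g1 <- rbeta(200, 5, 1); g2 <- rbeta(200, 1, 5)
  cmp2 <- compare_jaccard_distributions(list(hi = g1, lo = g2))
  expect_lt(cmp2$pairwise$p_value[1], 1e-10)
  expect_equal(cmp2$pairwise$p_adjusted, cmp2$pairwise$p_value)  # one test

  cmp3 <- compare_jaccard_distributions(list(a = g1, b = g2, c = runif(50)))
  expect_equal(cmp3$pairwise$p_adjusted,
               pmin(1, cmp3$pairwise$p_value * 3))
})

test_that("coding-potential scores separate coding from shuffled input", {
  set.seed(23)
  cds <- rand_codon_dna(200)
  coding <- paste0(rand_dna(60), cds, rand_dna(60))
  shuffled <- paste(sample(strsplit(coding, "")[[1]]), collapse = "")
  sc <- coding_potential_score(tibble::tibble(id = c("c", "n"),
                                              seq = c(coding, shuffled)))
  expect_gt(sc$score[sc$id == "c"], 0.5)
  expect_lt(sc$score[sc$id == "n"], 0.5)

  # external table is a pass-through
  ext <- coding_potential_score(tibble::tibble(id = "c", seq = coding),
                                score_table = tibble::tibble(id = "c",
                                                             score = 0.73))
  expect_equal(ext$score, 0.73)

  # short sequences are undefined
  short <- coding_potential_score(tibble::tibble(id = "s", seq = "ACGTAC"))
  expect_true(is.na(short$score))
})

test_that("pairwise score differences drop unscored pairs with a count", {
  scores <- tibble::tibble(id = c("a", "b", "c"), score = c(0.9, 0.9, 0.2))
  pairs <- tibble::tibble(id_a = c("a", "a", "a"), id_b = c("b", "c", "zz"))
  d <- pairwise_score_difference(pairs, scores)
  expect_equal(d$delta_score, c(0, 0.7))
  expect_equal(attr(d, "n_unscored_dropped"), 1L)
})

test_that("permutation test is exact on identical groups and detects spread", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  p <- permutation_median_iqr_test(x, x, n_rounds = 1000, seed = 3)
  expect_equal(p$p_median, 1)
  expect_equal(p$p_iqr, 1)

  set.seed(24)
  a <- rnorm(200, 0, 1); b <- rnorm(200, 0, 3)
  p2 <- permutation_median_iqr_test(a, b, n_rounds = 2000, seed = 5)
  expect_lt(p2$p_iqr, 0.001)
  expect_gt(p2$p_median, 0.05)

  # label symmetry
  p3 <- permutation_median_iqr_test(b, a, n_rounds = 2000, seed = 5)
  expect_equal(p2$p_iqr, p3$p_iqr)
  expect_equal(p2$p_median, p3$p_median)

  expect_error(permutation_median_iqr_test(1:3, 1:8, 1000, 1), "length")
})

test_that("GO enrichment matches the hypergeometric tail and flags by FDR", {
  # uniform term: no enrichment
  gm <- tibble::tibble(id = sprintf("s%02d", 1:40), go_term = "GO:0000001")
  res <- go_enrichment_fisher(sprintf("s%02d", 1:10), sprintf("s%02d", 1:40),
                              gm)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  # 2x2 table (8,2 / 10,40) against the exhaustive hypergeometric tail
  fg <- sprintf("f%02d", 1:10)
  bg <- c(fg, sprintf("b%02d", 1:50))
  gm2 <- tibble::tibble(id = c(fg[1:8], sprintf("b%02d", 1:10)),
                        go_term = "GO:0000002")
  res2 <- go_enrichment_fisher(fg, bg, gm2)
  ft <- fisher.test(matrix(c(8, 2, 10, 40), 2, byrow = TRUE))
  expect_equal(res2$p_value, ft$p.value)
  # two-sided Fisher p equals the sum of table probabilities <= observed
  dh <- dhyper(0:10, 18, 42, 10)
  expect_equal(res2$p_value, sum(dh[dh <= dh[9] * (1 + 1e-7)]))

  # equal p-values keep their value under Benjamini-Hochberg
  gm3 <- tibble::tibble(
    id = rep(c(fg[1:8], sprintf("b%02d", 1:10)), times = 20),
    go_term = rep(sprintf("GO:%07d", 1:20), each = 18))
  res3 <- go_enrichment_fisher(fg, bg, gm3)
  expect_true(all(res3$q_value == res3$p_value[1]))
  expect_true(all(res3$q_value >= res3$p_value - 1e-12))
  expect_error(go_enrichment_fisher(character(), bg, gm3), "foreground")
  expect_error(go_enrichment_fisher("zz", bg, gm3), "subset")
})
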