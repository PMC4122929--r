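test_that("ancestral gene simulation honours length, frame and spacing", {
  cfg <- simulation_config(n_ancestral_genes = 10,
                           gene_length_range = c(200, 300), seed = 31)
  genes <- withr::with_seed(31, simulate_ancestral_genes(cfg))
  expect_equal(nrow(genes), 10)
  gc_map <- Biostrings::GENETIC_CODE
  for (cds in genes$cds) {
    n <- nchar(cds) / 3
    expect_true(n >= 200 && n <= 300)
    codons <- substring(cds, 3 * (seq_len(n) - 1) + 1, 3 * seq_len(n))
    expect_false(any(gc_map[codons] == "*"))  # stop-free in frame +1
  }
  genes2 <- withr::with_seed(31, simulate_ancestral_genes(cfg))
  expect_equal(genes, genes2)  # deterministic

  located <- paralogr:::.locate_genes(genes)
  by_contig <- split(located, located$contig_id)
  for (g in by_contig) {
    g <- g[order(g$t_start), ]
    if (nrow(g) > 1) {
      gaps <- g$t_start[-1] - g$t_end[-nrow(g)] - 1
      expect_true(all(gaps >= cfg$intergenic_spacing))
    }
  }
})

test_that("whole-genome duplication doubles genes onto homeolog pairs", {
  cfg <- simulation_config(n_ancestral_genes = 8, n_chromosomes = 2,
                           seed = 32)
  genes <- withr::with_seed(32, simulate_ancestral_genes(cfg))
  w <- withr::with_seed(33, apply_wgd(genes, cfg))
  expect_equal(nrow(w$genes), 16)             # gene count doubles exactly
  expect_equal(nrow(w$homeologs), 2)          # one pair per chromosome
  expect_setequal(unique(w$genes$chrom),
                  c(w$homeologs$chrom_a, w$homeologs$chrom_b))
  copies <- w$genes[w$genes$origin == "WGD", ]
  parents <- w$genes[match(copies$parent_id, w$genes$gene_id), ]
  # every copy sits on the homeolog of its parent's chromosome
  key <- paste(pmin(parents$chrom, copies$chrom),
               pmax(parents$chrom, copies$chrom))
  ref <- paste(pmin(w$homeologs$chrom_a, w$homeologs$chrom_b),
               pmax(w$homeologs$chrom_a, w$homeologs$chrom_b))
  expect_true(all(key %in% ref))
})

test_that("tandem duplications are planted beyond the distance rule", {
  cfg <- simulation_config(n_ancestral_genes = 10, n_chromosomes = 2,
                           lgd_fraction = 0.5, seed = 34)
  genes <- withr::with_seed(34, simulate_ancestral_genes(cfg))
  w <- withr::with_seed(35, apply_wgd(genes, cfg))
  g2 <- withr::with_seed(36, apply_lgds(w$genes, cfg))
  copies <- g2[g2$origin == "LGD", ]
  expect_gt(nrow(copies), 0)
  expect_true(all(copies$pre_gap > 5000))

  cfg0 <- cfg; cfg0$lgd_fraction <- 0
  expect_equal(withr::with_seed(36, apply_lgds(w$genes, cfg0)), w$genes)
})

test_that("emitted genome contains each locus at its recorded coordinates", {
  sim <- tiny_sim()
  genes <- sim$genes
  contig_seq <- setNames(sim$genome$seq, sim$genome$id)
  for (i in sample(nrow(genes), 8)) {
    locus <- paste0(genes$utr5[i], genes$cds[i], genes$utr3[i])
    expect_equal(substring(contig_seq[[genes$contig_id[i]]],
                           genes$t_start[i], genes$t_end[i]),
                 locus)
  }
  # truth rows cover every planted event
  expect_equal(nrow(sim$truth),
               sum(genes$origin %in% c("WGD", "LGD")) +
                 sum(sim$transcripts$role %in% c("allelic", "isoform")))
})

test_that("the codon mutator hits its divergence targets and stays sense", {
  cds <- withr::with_seed(37, rand_codon_dna(500))
  same <- mutate_codon_sequence(cds, 0, 0, seed = 1)
  expect_equal(same$seq, cds)

  gc_map <- Biostrings::GENETIC_CODE
  est <- withr::with_seed(38, vapply(1:10, function(i) {
    mut <- mutate_codon_sequence(cds, 0.2, 0.05)
    codons <- substring(mut$seq, 3 * (0:499) + 1, 3 * (1:500))
    expect_false(any(gc_map[codons] == "*"))  # output remains stop-free
    ng <- nei_gojobori(list(
      codon_a = substring(cds, 3 * (0:499) + 1, 3 * (1:500)),
      codon_b = codons))
    ng$Ks
  }, 0))
  expect_equal(mean(est), 0.2, tolerance = 0.15)
  expect_error(mutate_codon_sequence(cds, -0.1, 0), "non-negative")
})

test_that("transcript variants respect isogroup and length rules", {
  cfg <- simulation_config(n_ancestral_genes = 12, n_chromosomes = 2,
                           allelic_fraction = 1, isoform_fraction = 1,
                           noncoding_drift_fraction = 0, seed = 39)
  genes <- withr::with_seed(39, simulate_ancestral_genes(cfg))
  v <- withr::with_seed(40, add_transcript_variants(genes, cfg))
  tr <- v$transcripts
  loci <- tr[tr$role == "locus", ]
  for (i in seq_len(nrow(loci))) {
    fam <- tr[tr$locus_id == loci$locus_id[i], ]
    al <- fam[fam$role == "allelic", ]
    iso <- fam[fam$role == "isoform", ]
    expect_equal(nrow(al), 1)
    expect_equal(nrow(iso), 1)
    # variants are strictly shorter than their locus transcript
    expect_lt(nchar(al$seq), nchar(loci$seq[i]))
    expect_lt(nchar(iso$seq), nchar(loci$seq[i]))
    # allelic variants are near-identical to the locus transcript
    h <- seed_and_extend_align(loci$seq[i], al$seq)
    expect_gt(h$pident, 98.5)
  }
  # clustered variants share the parent's isogroup
  im <- v$isogroup_map
  iso_ids <- tr$id[tr$role == "isoform"]
  expect_equal(im$isogroup_id[match(iso_ids, im$isotig_id)],
               paste0("ig_", tr$locus_id[tr$role == "isoform"]))
})

test_that("frame-disrupted copies lose coding potential", {
  # 200 genes drawn at the generator's default dimensions
  set.seed(41)
  cfg <- simulation_config()
  disrupted <- vapply(seq_len(200), function(i) {
    n_cod <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], 1)
    cds <- paralogr:::.random_codon_string(n_cod)
    ufrac <- runif(1, cfg$utr_fraction_range[1], cfg$utr_fraction_range[2])
    utr_total <- round(3 * n_cod * ufrac / (1 - ufrac))
    u5 <- sample.int(utr_total + 1, 1) - 1
    paste0(paralogr:::.random_nt_string(u5),
           paralogr:::.frame_disrupt(cds, cfg$anchor_fraction),
           paralogr:::.random_nt_string(utr_total - u5))
  }, "")
  sc <- coding_potential_score(tibble::tibble(id = as.character(1:200),
                                              seq = disrupted))
  expect_gte(mean(sc$score < 0.5), 0.9)
})

test_that("dataset emission is deterministic and round-trips", {
  sim <- tiny_sim()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_dataset(sim, d1)
  emit_dataset(sim, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  tr <- read_fasta(file.path(d1, "transcriptome.fasta"))
  expect_equal(tr$id, sim$transcripts$id)
  expect_equal(tr$seq, sim$transcripts$seq)
  im <- read_isogroup_map(file.path(d1, "isogroups.tsv"))
  expect_equal(im, sim$isogroup_map)
  lmap <- read_linkage_map(file.path(d1, "linkage.tsv"))
  expect_equal(lmap, sim$linkage_map)
  gm <- read_go_map(file.path(d1, "go.tsv"))
  expect_setequal(paste(gm$id, gm$go_term),
                  paste(sim$go_map$id, sim$go_map$go_term))
  an <- read_annotation_hits(file.path(d1, "annotation.tsv"))
  expect_equal(an, sim$annotation)
})

test_that("simulation is reproducible from its seed", {
  cfg <- simulation_config(n_ancestral_genes = 6, n_chromosomes = 2,
                           contigs_per_chromosome = 1, seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_equal(s1$transcripts, s2$transcripts)
  expect_equal(s1$genome, s2$genome)
  expect_equal(s1$truth, s2$truth)
})
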