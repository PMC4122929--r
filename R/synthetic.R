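# Synthetic dataset generator: plants whole-genome duplication (WGD)
# paralogs on homeologous chromosomes, tandem (LGD) copies on the same
# contig, allelic variants and exon-skipping isoforms clustered into
# isogroups, coding->noncoding drift, and inherited-but-perturbed
# annotations -- together with a truth table, so every pipeline stage can
# be benchmarked without external data.

.SENSE_CODONS <- NULL  # filled lazily

.sense_codons <- function() {
  if (is.null(.pkg_cache$sense)) {
    gc_map <- .genetic_code()
    .pkg_cache$sense <- names(gc_map)[gc_map != "*"]
  }
  .pkg_cache$sense
}

.random_codon_string <- function(n_codons, gc_skew = 0) {
  sense <- .sense_codons()
  w <- if (gc_skew == 0) NULL else {
    gcn <- vapply(strsplit(sense, ""), function(x) sum(x %in% c("G", "C")), 0)
    exp(gc_skew * gcn)
  }
  paste(sample(sense, n_codons, replace = TRUE, prob = w), collapse = "")
}

.random_nt_string <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# expected proportion of differing nucleotide sites for a coding sequence
# diverged to (ks, ka): inverse Jukes-Cantor per site class, weighted by
# the typical synonymous site fraction
.expected_p <- function(ks, ka, syn_fraction = 0.23) {
  inv_jc <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  syn_fraction * inv_jc(ks) + (1 - syn_fraction) * inv_jc(ka)
}

# point mutations at per-site probability p (never to the same base)
.mutate_nt <- function(seq, p) {
  if (!nzchar(seq) || p <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < p)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Simulation configuration
#'
#' Defaults plant the study conditions the pipeline is designed for: WGD
#' paralogs diverged to an expected Ks of 0.40 and tandem (LGD) copies to
#' 0.23 -- inside the 80 percent-identity screening threshold -- with
#' Ka/Ks 0.21, tandem gaps of 6-50 kb (all beyond the 5 kb distance rule),
#' and near-identical allelic variants (0.5 percent divergence).
#'
#' @param n_ancestral_genes genes before any duplication.
#' @param gene_length_range CDS length range in codons.
#' @param n_chromosomes ancestral chromosomes (doubled by the WGD).
#' @param contigs_per_chromosome genome contigs per chromosome.
#' @param wgd apply the whole-genome duplication.
#' @param target_ks_wgd,target_ks_lgd expected synonymous divergence of
#'   WGD / tandem copies.
#' @param target_ka_ks expected Ka/Ks of all planted duplications.
#' @param lgd_fraction fraction of (post-WGD) genes receiving one tandem
#'   copy downstream on the same contig.
#' @param lgd_gap_range genomic gap between a gene and its tandem copy (bp).
#' @param allelic_fraction fraction of loci emitting an allelic variant.
#' @param allelic_divergence per-site divergence of allelic variants.
#' @param unclustered_allelic_fraction fraction of allelic variants placed
#'   in their own isogroup (emulating assembly failure to cluster them;
#'   these are the variants the genome-anchoring step must catch).
#' @param isoform_fraction fraction of loci emitting an exon-skipping
#'   isoform (in-frame internal deletion).
#' @param noncoding_drift_fraction fraction of duplicate copies whose
#'   reading frame is disrupted (1-nt deletion plus codon shuffle outside a
#'   preserved anchor region), modelling drift to noncoding function.
#' @param anchor_fraction preserved 5' fraction of a disrupted CDS.
#' @param go_terms_per_gene GO terms per annotated gene family.
#' @param n_go_vocabulary size of the GO term vocabulary.
#' @param annotation_coverage fraction of gene families with a database
#'   hit at all (annotation sparsity of a real protein database).
#' @param accession_switch_prob probability that a duplicate copy's best
#'   hit lands on a different (redundant) database entry than its parent's.
#' @param go_turnover per-term replacement probability in duplicate copies.
#' @param utr_fraction_range untranslated fraction of a transcript.
#' @param utr_jitter_sd lognormal sd of UTR-length change in duplicate
#'   copies (transcript-boundary divergence between duplicate loci).
#' @param intergenic_spacing minimum spacing between neighbouring genes (bp).
#' @param gc_skew GC skew of the sense-codon draw (0 = uniform).
#' @param seed master seed of the simulation.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_ancestral_genes = 120,
                              gene_length_range = c(250, 350),
                              n_chromosomes = 6,
                              contigs_per_chromosome = 2,
                              wgd = TRUE,
                              target_ks_wgd = 0.40,
                              target_ks_lgd = 0.23,
                              target_ka_ks = 0.21,
                              lgd_fraction = 0.3,
                              lgd_gap_range = c(6000, 50000),
                              allelic_fraction = 0.4,
                              allelic_divergence = 0.005,
                              unclustered_allelic_fraction = 0.3,
                              isoform_fraction = 0.3,
                              noncoding_drift_fraction = 0.15,
                              anchor_fraction = 0.4,
                              go_terms_per_gene = 5,
                              n_go_vocabulary = 200,
                              annotation_coverage = 0.6,
                              accession_switch_prob = 0.5,
                              go_turnover = 0.1,
                              utr_fraction_range = c(0.05, 0.5),
                              utr_jitter_sd = 0.4,
                              intergenic_spacing = 10000,
                              gc_skew = 0,
                              seed = 1L) {
  fracs <- c(lgd_fraction, allelic_fraction, unclustered_allelic_fraction,
             isoform_fraction, noncoding_drift_fraction, anchor_fraction,
             annotation_coverage, accession_switch_prob, go_turnover)
  stopifnot(n_ancestral_genes >= 1, all(gene_length_range >= 30),
            n_chromosomes >= 1, contigs_per_chromosome >= 1,
            target_ks_wgd > 0, target_ks_lgd > 0, target_ka_ks >= 0,
            all(fracs >= 0 & fracs <= 1),
            all(lgd_gap_range > 0), allelic_divergence >= 0,
            all(utr_fraction_range > 0 & utr_fraction_range < 1),
            intergenic_spacing > 0)
  structure(as.list(environment())[names(formals(simulation_config))],
            class = "simulation_config")
}

#' Simulate ancestral genes on proto-chromosomes
#'
#' Draws stop-free random codon sequences with untranslated flanks and
#' places them non-overlapping, at least `intergenic_spacing` apart, across
#' the ancestral chromosomes/contigs.
#'
#' @param config a [simulation_config()].
#' @return A gene tibble (one row per gene, with chromosome, contig, slot
#'   order, spacing, CDS and UTR sequences).
#' @export
simulate_ancestral_genes <- function(config) {
  n <- config$n_ancestral_genes
  chroms <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  contigs <- as.vector(outer(chroms, seq_len(config$contigs_per_chromosome),
                             function(c, k) paste0(c, "_c", k)))
  gene_contig <- rep_len(contigs, n)
  genes <- lapply(seq_len(n), function(i) {
    n_cod <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1)
    cds <- .random_codon_string(n_cod, config$gc_skew)
    ufrac <- runif(1, config$utr_fraction_range[1],
                   config$utr_fraction_range[2])
    utr_total <- round(3 * n_cod * ufrac / (1 - ufrac))
    u5 <- if (utr_total > 0) sample.int(utr_total + 1, 1) - 1 else 0
    tibble(gene_id = sprintf("g%03d", i),
           family = sprintf("fam%03d", i),
           origin = "ANCESTRAL", parent_id = NA_character_,
           chrom = sub("_c\\d+$", "", gene_contig[i]),
           contig_id = gene_contig[i],
           slot = 0, pre_gap = config$intergenic_spacing +
             sample.int(5000, 1),
           cds = cds,
           utr5 = .random_nt_string(u5),
           utr3 = .random_nt_string(utr_total - u5),
           expected_ks = 0, expected_ka = 0,
           realized_syn = 0L, realized_non = 0L,
           coding = TRUE)
  })
  genes <- bind_rows(genes)
  genes$slot <- ave(seq_len(nrow(genes)), genes$contig_id,
                    FUN = seq_along)
  genes
}

#' Apply a whole-genome duplication
#'
#' Every chromosome gains a homeolog (`chrNN` becomes `chrNNa`/`chrNNb`)
#' and every gene a partner at the corresponding position on the
#' homeologous contig, diverged to the configured expected Ks/Ka. Duplicate
#' copies also redraw their untranslated extents (lognormal jitter),
#' modelling transcript-boundary divergence between duplicate loci.
#'
#' @param genes gene tibble from [simulate_ancestral_genes()].
#' @param config a [simulation_config()].
#' @return A list with the duplicated `genes` tibble and `homeologs`, the
#'   reference tibble of homeologous chromosome pairs.
#' @export
apply_wgd <- function(genes, config) {
  if (!config$wgd) {
    genes$chrom <- paste0(genes$chrom, "a")
    genes$contig_id <- sub("_c", "a_c", genes$contig_id)
    return(list(genes = genes,
                homeologs = tibble(chrom_a = character(),
                                   chrom_b = character())))
  }
  ka_wgd <- config$target_ka_ks * config$target_ks_wgd
  orig <- genes
  orig$chrom <- paste0(genes$chrom, "a")
  orig$contig_id <- sub("_c", "a_c", genes$contig_id)
  copies <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    mut <- mutate_codon_sequence(g$cds, config$target_ks_wgd, ka_wgd)
    g$gene_id <- paste0(g$gene_id, "w")
    g$origin <- "WGD"
    g$parent_id <- genes$gene_id[i]
    g$chrom <- paste0(genes$chrom[i], "b")
    g$contig_id <- sub("_c", "b_c", genes$contig_id[i])
    g$cds <- mut$seq
    g$utr5 <- .jitter_utr(g$utr5, config)
    g$utr3 <- .jitter_utr(g$utr3, config)
    g$expected_ks <- config$target_ks_wgd
    g$expected_ka <- ka_wgd
    g$realized_syn <- mut$n_syn
    g$realized_non <- mut$n_non
    g
  })
  homeologs <- tibble(chrom_a = paste0(unique(genes$chrom), "a"),
                      chrom_b = paste0(unique(genes$chrom), "b"))
  list(genes = bind_rows(orig, bind_rows(copies)), homeologs = homeologs)
}

# mutate a UTR at the duplicate's expected per-site rate and jitter its
# length (truncate, or extend with fresh sequence)
.jitter_utr <- function(utr, config, ks = config$target_ks_wgd) {
  p <- .expected_p(ks, config$target_ka_ks * ks)
  u <- .mutate_nt(utr, p)
  new_len <- max(0L, round(nchar(u) * exp(rnorm(1, 0, config$utr_jitter_sd))))
  if (new_len <= nchar(u)) substring(u, 1, new_len)
  else paste0(u, .random_nt_string(new_len - nchar(u)))
}

#' Apply local (tandem) gene duplications
#'
#' A sampled fraction of genes receives one downstream copy on the same
#' contig, separated by a gap drawn from `lgd_gap_range`, diverged to the
#' configured tandem Ks/Ka.
#'
#' @param genes post-WGD gene tibble.
#' @param config a [simulation_config()].
#' @return The gene tibble with tandem copies inserted after their parents.
#' @export
apply_lgds <- function(genes, config) {
  n_lgd <- round(config$lgd_fraction * nrow(genes))
  if (n_lgd == 0) return(genes)
  ka_lgd <- config$target_ka_ks * config$target_ks_lgd
  picks <- sort(sample.int(nrow(genes), n_lgd))
  copies <- lapply(picks, function(i) {
    g <- genes[i, ]
    mut <- mutate_codon_sequence(g$cds, config$target_ks_lgd, ka_lgd)
    g$gene_id <- paste0(genes$gene_id[i], "t")
    g$origin <- "LGD"
    g$parent_id <- genes$gene_id[i]
    g$slot <- genes$slot[i] + 0.5
    g$pre_gap <- sample(config$lgd_gap_range[1]:config$lgd_gap_range[2], 1)
    g$cds <- mut$seq
    g$utr5 <- .jitter_utr(g$utr5, config, ks = config$target_ks_lgd)
    g$utr3 <- .jitter_utr(g$utr3, config, ks = config$target_ks_lgd)
    g$expected_ks <- config$target_ks_lgd
    g$expected_ka <- ka_lgd
    g$realized_syn <- mut$n_syn
    g$realized_non <- mut$n_non
    g
  })
  bind_rows(genes, bind_rows(copies)) |>
    arrange(.data$contig_id, .data$slot)
}

#' Mutate a codon sequence to target synonymous/nonsynonymous divergence
#'
#' Applies synonymous and nonsynonymous substitutions as independent
#' Poisson processes with expectations `expected_ks * S` and
#' `expected_ka * N`, where S and N are the sequence's Nei-Gojobori site
#' counts. Substitutions are applied sequentially (multiple hits at one
#' site can occur, as in real divergence; the Jukes-Cantor correction
#' de-biases the estimate); substitutions creating stop codons are
#' rejected and redrawn.
#'
#' @param seq stop-free in-frame codon string.
#' @param expected_ks,expected_ka expected per-site divergences (>= 0).
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @return A list with `seq` (mutated string) and the realized counts
#'   `n_syn`, `n_non`.
#' @export
mutate_codon_sequence <- function(seq, expected_ks, expected_ka,
                                  seed = NULL) {
  if (expected_ks < 0 || expected_ka < 0) {
    abort("expected divergences must be non-negative")
  }
  run <- function() {
    tb <- .ng_tables()
    gc_map <- .genetic_code()
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    stopifnot(length(ch) %% 3 == 0)
    n_cod <- length(ch) / 3
    codon_at <- function(i) paste(ch[(3 * i - 2):(3 * i)], collapse = "")
    codons <- vapply(seq_len(n_cod), codon_at, "")
    if (any(gc_map[codons] == "*")) abort("sequence contains a stop codon")
    S <- sum(tb$syn_sites[codons])
    N <- 3 * n_cod - S
    n_syn <- rpois(1, expected_ks * S)
    n_non <- rpois(1, expected_ka * N)
    apply_sub <- function(want_syn) {
      repeat {
        i <- sample.int(n_cod, 1)
        pos <- sample.int(3, 1)
        old <- codon_at(i)
        nt <- sample(setdiff(c("A", "C", "G", "T"), ch[3 * (i - 1) + pos]), 1)
        new <- old
        substr(new, pos, pos) <- nt
        if (gc_map[[new]] == "*") next
        is_syn <- gc_map[[new]] == gc_map[[old]]
        if (is_syn == want_syn) {
          ch[3 * (i - 1) + pos] <<- nt
          return(invisible())
        }
      }
    }
    for (k in seq_len(n_syn)) apply_sub(TRUE)
    for (k in seq_len(n_non)) apply_sub(FALSE)
    list(seq = paste(ch, collapse = ""), n_syn = n_syn, n_non = n_non)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# disrupt a CDS: keep a 5' anchor, delete one nucleotide (frameshift), and
# shuffle the codon triplets of the remainder
.frame_disrupt <- function(cds, anchor_fraction) {
  n_cod <- nchar(cds) / 3
  anchor_nt <- 3 * ceiling(anchor_fraction * n_cod)
  head_ <- substring(cds, 1, anchor_nt)
  tail_ <- substring(cds, anchor_nt + 2)  # drops one nucleotide
  nt <- nchar(tail_)
  n_tri <- nt %/% 3
  if (n_tri > 1) {
    tri <- substring(tail_, 3 * (seq_len(n_tri) - 1) + 1, 3 * seq_len(n_tri))
    rest <- substring(tail_, 3 * n_tri + 1)
    tail_ <- paste0(paste(sample(tri), collapse = ""), rest)
  }
  paste0(head_, tail_)
}

#' Add transcript variants and coding drift
#'
#' Per locus: an allelic variant (near-identical, slightly 3'-trimmed so
#' the locus transcript stays the longest isotig) and/or an exon-skipping
#' isoform (in-frame internal deletion of 10-30 percent of codons) are
#' emitted into the locus's isogroup; a configurable fraction of allelic
#' variants lands in its own isogroup instead (the un-clustered variants
#' the genome-anchoring filter must catch). A fraction of duplicate copies
#' is frame-disrupted before emission and marked noncoding.
#'
#' @param genes gene tibble after duplications.
#' @param config a [simulation_config()].
#' @return A list: updated `genes`, `transcripts` (tibble `id`, `seq`,
#'   `role`, `locus_id`, `coding`), `isogroup_map`, and `truth` rows for
#'   the variant events.
#' @export
add_transcript_variants <- function(genes, config) {
  # coding -> noncoding drift on duplicate copies
  dup_idx <- which(genes$origin %in% c("WGD", "LGD"))
  drift <- dup_idx[runif(length(dup_idx)) < config$noncoding_drift_fraction]
  for (i in drift) {
    genes$cds[i] <- .frame_disrupt(genes$cds[i], config$anchor_fraction)
    genes$coding[i] <- FALSE
  }

  locus_seq <- paste0(genes$utr5, genes$cds, genes$utr3)
  transcripts <- tibble(id = genes$gene_id, seq = locus_seq,
                        role = "locus", locus_id = genes$gene_id,
                        coding = genes$coding)
  iso <- tibble(isotig_id = genes$gene_id,
                isogroup_id = paste0("ig_", genes$gene_id))
  truth <- list()
  extra_t <- list(); extra_i <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    if (runif(1) < config$allelic_fraction) {
      vid <- paste0(gid, "al")
      vseq <- .mutate_nt(locus_seq[i], config$allelic_divergence)
      vseq <- substring(vseq, 1, nchar(vseq) - sample.int(10, 1))
      unclustered <- runif(1) < config$unclustered_allelic_fraction
      extra_t[[length(extra_t) + 1]] <-
        tibble(id = vid, seq = vseq, role = "allelic", locus_id = gid,
               coding = genes$coding[i])
      extra_i[[length(extra_i) + 1]] <-
        tibble(isotig_id = vid,
               isogroup_id = if (unclustered) paste0("ig_", vid)
                             else paste0("ig_", gid))
      truth[[length(truth) + 1]] <-
        tibble(id_a = gid, id_b = vid, event = "ALLELIC",
               chrom_a = genes$chrom[i], chrom_b = genes$chrom[i],
               contig = genes$contig_id[i], gap = NA_integer_,
               expected_ks = NA_real_, expected_ka = NA_real_,
               clustered = !unclustered,
               coding_a = genes$coding[i], coding_b = genes$coding[i])
    }
    if (runif(1) < config$isoform_fraction && genes$coding[i]) {
      vid <- paste0(gid, "is")
      n_cod <- nchar(genes$cds[i]) / 3
      del <- max(1L, round(runif(1, 0.1, 0.3) * n_cod))
      start <- sample.int(n_cod - del - 1L, 1) + 1L
      cds2 <- paste0(substring(genes$cds[i], 1, 3 * (start - 1)),
                     substring(genes$cds[i], 3 * (start + del - 1) + 1))
      vseq <- paste0(genes$utr5[i], cds2, genes$utr3[i])
      extra_t[[length(extra_t) + 1]] <-
        tibble(id = vid, seq = vseq, role = "isoform", locus_id = gid,
               coding = genes$coding[i])
      extra_i[[length(extra_i) + 1]] <-
        tibble(isotig_id = vid, isogroup_id = paste0("ig_", gid))
      truth[[length(truth) + 1]] <-
        tibble(id_a = gid, id_b = vid, event = "ISOFORM",
               chrom_a = genes$chrom[i], chrom_b = genes$chrom[i],
               contig = genes$contig_id[i], gap = NA_integer_,
               expected_ks = NA_real_, expected_ka = NA_real_,
               clustered = TRUE,
               coding_a = genes$coding[i], coding_b = genes$coding[i])
    }
  }
  list(genes = genes,
       transcripts = bind_rows(transcripts, bind_rows(extra_t)),
       isogroup_map = bind_rows(iso, bind_rows(extra_i)),
       truth = bind_rows(truth))
}

# sequential placement of ordered genes along their contigs
.locate_genes <- function(genes) {
  genes <- genes |> arrange(.data$contig_id, .data$slot)
  genes |>
    group_by(.data$contig_id) |>
    mutate(t_len = nchar(.data$utr5) + nchar(.data$cds) + nchar(.data$utr3),
           t_start = cumsum(.data$pre_gap + lag(.data$t_len, default = 0)) + 1,
           t_end = .data$t_start + .data$t_len - 1) |>
    ungroup()
}

#' Simulate a complete dataset with planted duplication events
#'
#' Chains the generator stages under one master seed and derives the
#' genome, annotation tables and the truth ledger of planted events.
#'
#' @param config a [simulation_config()].
#' @return An object of class `paralog_simulation`: a list with
#'   `transcripts`, `isogroup_map`, `genome`, `linkage_map`, `go_map`,
#'   `annotation`, `truth`, `homeologs`, `genes` (located), and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  withr::with_seed(config$seed, {
    genes <- simulate_ancestral_genes(config)
    w <- apply_wgd(genes, config)
    genes <- apply_lgds(w$genes, config)
    v <- add_transcript_variants(genes, config)
    genes <- .locate_genes(v$genes)

    # duplication truth rows (gap = genomic gap for same-contig events)
    dup <- genes |> filter(.data$origin %in% c("WGD", "LGD"))
    par_row <- genes[match(dup$parent_id, genes$gene_id), ]
    dup_truth <- tibble(
      id_a = dup$parent_id, id_b = dup$gene_id, event = dup$origin,
      chrom_a = par_row$chrom, chrom_b = dup$chrom,
      contig = ifelse(dup$origin == "LGD", dup$contig_id, NA_character_),
      gap = ifelse(dup$origin == "LGD",
                   as.integer(dup$t_start - par_row$t_end - 1L), NA_integer_),
      expected_ks = dup$expected_ks, expected_ka = dup$expected_ka,
      clustered = NA,
      coding_a = par_row$coding, coding_b = dup$coding)
    truth <- bind_rows(dup_truth, v$truth)

    # genome: random background with locus transcripts written in
    contigs <- genes |>
      group_by(.data$contig_id, .data$chrom) |>
      arrange(.data$slot, .by_group = TRUE) |>
      summarise(seq = {
        parts <- character(2 * n() + 1)
        parts[2 * seq_len(n()) - 1] <- vapply(.data$pre_gap,
                                              .random_nt_string, "")
        parts[2 * seq_len(n())] <- paste0(.data$utr5, .data$cds, .data$utr3)
        parts[2 * n() + 1] <- .random_nt_string(500L)
        paste(parts, collapse = "")
      }, .groups = "drop")
    genome <- tibble(id = contigs$contig_id, seq = contigs$seq)
    linkage_map <- tibble(contig_id = contigs$contig_id,
                          chromosome = contigs$chrom)

    # annotation: per-family accession with database sparsity; duplicate
    # copies may hit a different (redundant) entry; disrupted copies lose
    # their hit; variants inherit their locus's hit
    fams <- unique(genes$family)
    fam_acc <- setNames(sprintf("ACC%05d", seq_along(fams)), fams)
    fam_annotated <- setNames(runif(length(fams)) < config$annotation_coverage,
                              fams)
    locus_acc <- vapply(seq_len(nrow(genes)), function(i) {
      if (!fam_annotated[[genes$family[i]]] || !genes$coding[i]) {
        return(NA_character_)
      }
      acc <- fam_acc[[genes$family[i]]]
      if (genes$origin[i] != "ANCESTRAL" &&
          runif(1) < config$accession_switch_prob) {
        acc <- paste0(acc, "x", genes$gene_id[i])
      }
      acc
    }, "")
    names(locus_acc) <- genes$gene_id
    annotation <- tibble(id = v$transcripts$id,
                         accession = unname(locus_acc[v$transcripts$locus_id]))

    # GO terms: family set inherited with per-copy turnover
    vocab <- sprintf("GO:%07d", seq_len(config$n_go_vocabulary))
    fam_go <- lapply(fams, function(f) sample(vocab, config$go_terms_per_gene))
    names(fam_go) <- fams
    locus_go <- lapply(seq_len(nrow(genes)), function(i) {
      if (!fam_annotated[[genes$family[i]]] || !genes$coding[i]) {
        return(character())
      }
      terms <- fam_go[[genes$family[i]]]
      if (genes$origin[i] != "ANCESTRAL") {
        flip <- runif(length(terms)) < config$go_turnover
        terms[flip] <- sample(setdiff(vocab, terms), sum(flip))
      }
      terms
    })
    names(locus_go) <- genes$gene_id
    tr_go <- locus_go[v$transcripts$locus_id]
    go_map <- tibble(id = rep(v$transcripts$id, lengths(tr_go)),
                     go_term = unlist(tr_go, use.names = FALSE))

    structure(list(transcripts = v$transcripts |> select("id", "seq",
                                                         "role", "locus_id",
                                                         "coding"),
                   isogroup_map = v$isogroup_map,
                   genome = genome, linkage_map = linkage_map,
                   go_map = go_map, annotation = annotation |> filter(
                     !is.na(.data$accession)),
                   truth = truth, homeologs = w$homeologs,
                   genes = genes, config = config),
              class = "paralog_simulation")
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the transcriptome and genome FASTA files and the isogroup,
#' linkage, GO, annotation and truth TSVs, all readable by the package's
#' readers. Deterministic given the simulation object.
#'
#' @param sim a [simulate_dataset()] result.
#' @param outdir output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
emit_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_fasta(sim$transcripts, p("transcriptome.fasta"))
  write_fasta(sim$genome, p("genome.fasta"))
  readr::write_tsv(sim$isogroup_map, p("isogroups.tsv"), col_names = FALSE)
  readr::write_tsv(sim$linkage_map, p("linkage.tsv"), col_names = FALSE)
  readr::write_tsv(sim$go_map, p("go.tsv"), col_names = FALSE)
  readr::write_tsv(sim$annotation, p("annotation.tsv"), col_names = FALSE)
  readr::write_tsv(sim$truth, p("truth.tsv"), col_names = TRUE)
  invisible(outdir)
}

#' Score workflow labels against the planted truth
#'
#' Matches the workflow's labelled pairs to the truth table by id set and
#' reports label accuracy over recovered WGD/LGD pairs, allelic exclusion,
#' and which planted pairs were recovered at all. A planted pair can only
#' be scored if the reciprocal-best-hit stage recovered it; genes whose
#' best hit is a closer duplicate (e.g. a tandem copy outcompeting the WGD
#' partner) are not recoverable by construction and are reported in
#' `n_planted_unrecovered`.
#'
#' @param pairs labelled pair tibble from [run_workflow()].
#' @param truth truth tibble from a simulation.
#' @return A list of recovery statistics.
#' @export
evaluate_truth_recovery <- function(pairs, truth) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  truth_dup <- truth |> filter(.data$event %in% c("WGD", "LGD"))
  truth_all <- truth |> filter(.data$event == "ALLELIC")
  pk <- key(pairs$id_a, pairs$id_b)
  tk_dup <- key(truth_dup$id_a, truth_dup$id_b)
  tk_all <- key(truth_all$id_a, truth_all$id_b)
  m <- match(pk, tk_dup)
  scored <- !is.na(m)
  n_correct <- sum(pairs$label[scored] == truth_dup$event[m[scored]])
  allelic_hit <- pk %in% tk_all
  n_allelic_recovered <- sum(allelic_hit)
  n_allelic_excluded <- sum(allelic_hit & pairs$label == "ALLELIC")
  list(n_planted_dup = nrow(truth_dup),
       n_recovered_dup = sum(scored),
       n_planted_unrecovered = nrow(truth_dup) - sum(scored),
       n_correct_label = n_correct,
       label_accuracy = if (sum(scored)) n_correct / sum(scored) else NA_real_,
       n_allelic_recovered = n_allelic_recovered,
       n_allelic_excluded = n_allelic_excluded,
       allelic_exclusion = if (n_allelic_recovered) {
         n_allelic_excluded / n_allelic_recovered
       } else {
         NA_real_
       },
       n_nontruth_pairs = sum(!scored & !allelic_hit))
}
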