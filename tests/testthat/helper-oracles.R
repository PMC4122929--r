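# Shared fixtures and independent oracles for the test suite.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_codon_dna <- function(n_codons) {
  gc_map <- Biostrings::GENETIC_CODE
  sense <- names(gc_map)[gc_map != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# independent local-alignment oracle: full dynamic programming through
# Biostrings, both subject strands
oracle_local_strand <- function(a, b, match = 2, mismatch = -3,
                                gap_open = -5, gap_extend = -2) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match, mismatch,
                                                 baseOnly = TRUE)
  s1 <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = sm, gapOpening = -gap_open, gapExtension = -gap_extend)
  s2 <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a),
    Biostrings::reverseComplement(Biostrings::DNAString(b)), type = "local",
    substitutionMatrix = sm, gapOpening = -gap_open, gapExtension = -gap_extend)
  c(plus = Biostrings::score(s1), minus = Biostrings::score(s2))
}

oracle_local_score <- function(a, b, ...) max(oracle_local_strand(a, b, ...))

# the DP optimum restricted to subject strands carrying a shared seed;
# NA when neither strand is seeded
oracle_seeded_score <- function(a, b, kmer) {
  per_strand <- oracle_local_strand(a, b)
  seeded <- c(paralogr:::.shares_kmer(a, b, kmer),
              paralogr:::.shares_kmer(a, revcomp(b), kmer))
  if (!any(seeded)) return(NA_real_)
  max(per_strand[seeded])
}

# independent Nei-Gojobori oracle: direct recursive enumeration of all
# mutational orderings between two sense codons, written at character
# level and sharing no code with the package tables
oracle_ng_pair <- function(c1, c2) {
  gc_map <- Biostrings::GENETIC_CODE
  syn_sites <- function(codon) {
    ch <- strsplit(codon, "")[[1]]
    s <- 0
    for (p in 1:3) {
      for (nt in setdiff(c("A", "C", "G", "T"), ch[p])) {
        alt <- ch; alt[p] <- nt
        altc <- paste(alt, collapse = "")
        if (gc_map[[altc]] != "*" && gc_map[[altc]] == gc_map[[codon]]) {
          s <- s + 1 / 3
        }
      }
    }
    s
  }
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- if (length(d) == 0) list() else {
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      unlist(lapply(seq_along(v), function(i) {
        lapply(perms(v[-i]), function(p) c(v[i], p))
      }), recursive = FALSE)
    }
    perms(d)
  }
  sd_v <- nd_v <- numeric(0); blocked <- logical(0)
  for (path in paths) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    sd <- nd <- 0; blk <- FALSE
    for (step in seq_along(path)) {
      nxt <- cur; nxt[path[step]] <- tgt[path[step]]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (gc_map[[from]] != "*" && gc_map[[to]] != "*" &&
          gc_map[[from]] == gc_map[[to]]) sd <- sd + 1 else nd <- nd + 1
      if (step < length(path) && gc_map[[to]] == "*") blk <- TRUE
      cur <- nxt
    }
    sd_v <- c(sd_v, sd); nd_v <- c(nd_v, nd); blocked <- c(blocked, blk)
  }
  use <- if (length(blocked) && all(blocked)) !logical(length(blocked)) else
    !blocked
  list(s1 = syn_sites(c1), s2 = syn_sites(c2),
       sd = if (length(paths)) mean(sd_v[use]) else 0,
       nd = if (length(paths)) mean(nd_v[use]) else 0)
}

# brute-force mutual-argmax reciprocal best pairs from a hit table
oracle_rbh <- function(hits) {
  best_of <- function(q) {
    h <- hits[hits$qseqid == q, ]
    score <- if ("raw_score" %in% names(h)) h$raw_score else h$bitscore
    h <- h[order(-score, -h$length, h$sseqid), ]
    h$sseqid[1]
  }
  qs <- unique(hits$qseqid)
  out <- character(0)
  for (q in qs) {
    b <- best_of(q)
    if (b %in% qs && best_of(b) == q) {
      out <- c(out, paste(min(q, b), max(q, b), sep = "|"))
    }
  }
  sort(unique(out))
}

# small simulated dataset reused across workflow tests
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(simulation_config(
        n_ancestral_genes = 12, n_chromosomes = 2,
        contigs_per_chromosome = 1, seed = 42))
    }
    cache
  }
})

# default-scale dataset and workflow shared by the acceptance tests
acceptance_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_dataset(simulation_config())  # default study conditions
      wf <- run_workflow(sim$transcripts, sim$isogroup_map, sim$genome,
                         sim$linkage_map)
      cache <<- list(sim = sim, wf = wf)
    }
    cache
  }
})
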