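#' Scoring scheme for the internal nucleotide aligner
#'
#' Match/mismatch scores default to the values used for the transcriptome
#' read-processing alignments (+2 / -3); gap penalties follow the common
#' convention that a gap of length L costs `gap_open + L * gap_extend`.
#' `karlin_lambda` and `karlin_k` are the Karlin-Altschul constants used to
#' turn raw scores into E-values; they are fixed, documented defaults rather
#' than values estimated from the scoring matrix, because only the ranking of
#' hits and a threshold crossing matter to the workflow.
#'
#' @param match positive match score.
#' @param mismatch negative mismatch score.
#' @param gap_open negative gap-opening penalty.
#' @param gap_extend negative per-residue gap-extension penalty.
#' @param karlin_lambda,karlin_k Karlin-Altschul statistics parameters.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = -5,
                           gap_extend = -2, karlin_lambda = 0.625,
                           karlin_k = 0.41) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            karlin_lambda > 0, karlin_k > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, karlin_lambda = karlin_lambda,
                 karlin_k = karlin_k),
            class = "scoring_scheme")
}

#' Pipeline configuration
#'
#' Central thresholds of the duplicate-gene workflow. Defaults are the
#' headline working points: candidate paralog pairs must align over at least
#' `min_alignment_length` bp (inclusive) at more than `min_percent_id`
#' percent identity (strict); same-contig pairs further apart than
#' `lgd_min_distance` bp are tandem-duplication candidates; internal search
#' hits are kept at E-value `evalue_threshold` or below.
#'
#' @param min_alignment_length minimum alignment length in bp (inclusive).
#' @param min_percent_id percent-identity threshold (strict `>`).
#' @param lgd_min_distance minimum same-contig gap, in bp, for a local
#'   (tandem) duplication call (strict `>`).
#' @param evalue_threshold E-value cutoff for internal search hits.
#' @param n_control_pairs control-set size for functional comparisons.
#' @param n_permutations rounds for the permutation median/IQR test.
#' @param rng_seed integer seed stamped on stochastic outputs.
#' @param kmer seed k-mer size for the internal aligner.
#' @param min_codons minimum gap-free codon columns for a Ka/Ks estimate.
#' @param anchor_score_window keep genome anchors scoring within this
#'   fraction of the best anchor (0.1 = within 10 percent).
#' @param refilter_external_hits re-apply `evalue_threshold` to ingested hit
#'   tables (they are otherwise trusted as already thresholded).
#' @param scoring a [scoring_scheme()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_alignment_length = 300,
                            min_percent_id = 80,
                            lgd_min_distance = 5000,
                            evalue_threshold = 1e-20,
                            n_control_pairs = 3000,
                            n_permutations = 100000,
                            rng_seed = 1L,
                            kmer = 11,
                            min_codons = 100,
                            anchor_score_window = 0.1,
                            refilter_external_hits = FALSE,
                            scoring = scoring_scheme()) {
  stopifnot(min_alignment_length > 0,
            min_percent_id > 0, min_percent_id < 100,
            lgd_min_distance > 0, evalue_threshold > 0,
            n_control_pairs > 0, n_permutations >= 1,
            kmer >= 8, min_codons >= 1,
            anchor_score_window >= 0, anchor_score_window < 1,
            inherits(scoring, "scoring_scheme"))
  structure(list(min_alignment_length = as.integer(min_alignment_length),
                 min_percent_id = min_percent_id,
                 lgd_min_distance = as.integer(lgd_min_distance),
                 evalue_threshold = evalue_threshold,
                 n_control_pairs = as.integer(n_control_pairs),
                 n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed),
                 kmer = as.integer(kmer),
                 min_codons = as.integer(min_codons),
                 anchor_score_window = anchor_score_window,
                 refilter_external_hits = refilter_external_hits,
                 scoring = scoring),
            class = "pipeline_config")
}

#' Read a key/value configuration file
#'
#' Plain `key: value` (YAML-style scalar) or `key = value` lines; comments
#' start with `#`. Recognised keys are the arguments of [pipeline_config()]
#' and [scoring_scheme()]; unknown keys are an error.
#'
#' @param path file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*[:=]\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) abort(paste0("malformed config line: '", lines[bad][1], "'"))
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, `[[`, "", 2)
  pc_args <- setdiff(names(formals(pipeline_config)), "scoring")
  sc_args <- names(formals(scoring_scheme))
  unknown <- setdiff(keys, c(pc_args, sc_args))
  if (length(unknown)) abort(paste0("unknown config key: ", unknown[1]))
  conv <- function(x) {
    if (tolower(x) %in% c("true", "false")) return(as.logical(toupper(x)))
    as.numeric(x)
  }
  pc <- lapply(setNames(vals[keys %in% pc_args], keys[keys %in% pc_args]), conv)
  sc <- lapply(setNames(vals[keys %in% sc_args], keys[keys %in% sc_args]), conv)
  pc$scoring <- do.call(scoring_scheme, sc)
  do.call(pipeline_config, pc)
}
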