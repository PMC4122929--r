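# Coding-potential scoring. The built-in model is a small ridge-regularised
# logistic classifier over two sequence features -- the fraction of the
# sequence covered by its longest stop-free reading frame (any of the six
# frames) and a hexamer log-odds score -- fitted once on a deterministic
# synthetic corpus of coding (UTR + codon sequence + UTR) and noncoding
# (uniform-random) sequences. It is NOT a reimplementation of any published
# coding-potential program; only the [0, 1] range and the 0.5 decision
# threshold are fixed semantics, and an external per-sequence score table
# is the fidelity path for real data.

.orf_coverage <- function(seq) {
  best <- 0L
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    pep <- .frame_peptide(seq, frame)
    if (!nzchar(pep)) next
    r <- rle(strsplit(pep, "", fixed = TRUE)[[1]] != "*")
    runs <- r$lengths[r$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  3 * best / nchar(seq)
}

.hexamer_counts <- function(seqs) {
  tab <- integer(0)
  for (s in seqs) {
    h <- .kmers(s, 6L)
    h <- h[!grepl("N", h, fixed = TRUE)]
    t1 <- table(h)
    tab <- if (length(tab)) {
      all_k <- union(names(tab), names(t1))
      out <- setNames(integer(length(all_k)), all_k)
      out[names(tab)] <- tab
      out[names(t1)] <- out[names(t1)] + as.integer(t1)
      out
    } else {
      setNames(as.integer(t1), names(t1))
    }
  }
  tab
}

.hexamer_score <- function(seq, log_odds) {
  h <- .kmers(seq, 6L)
  h <- h[!grepl("N", h, fixed = TRUE)]
  if (!length(h)) return(0)
  lo <- log_odds[h]
  lo[is.na(lo)] <- 0
  mean(lo)
}

# two-feature logistic fit by iteratively reweighted least squares with an
# L2 penalty on the (standardised) slopes; the penalty keeps the fit away
# from quasi-separation so scores spread smoothly over (0, 1) instead of
# saturating at the extremes
.irls_ridge_logistic <- function(X, y, lambda, iter = 25) {
  Xs <- cbind(1, X)
  beta <- numeric(ncol(Xs))
  pen <- diag(c(0, rep(lambda, ncol(X))))
  for (i in seq_len(iter)) {
    eta <- drop(Xs %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    beta <- solve(crossprod(Xs, Xs * w) + pen, crossprod(Xs, w * z))
  }
  drop(beta)
}

#' Build the default coding-potential model
#'
#' Generates a deterministic synthetic training corpus (coding: random
#' sense-codon CDS flanked by untranslated ends, ORF coverage 0.5-1;
#' noncoding: uniform random nucleotides), derives a hexamer log-odds table
#' and fits the ridge-penalised logistic model on the two features.
#'
#' @param n_per_class training sequences per class.
#' @param seed corpus seed (fixed default so the packaged model is stable).
#' @param lambda ridge penalty on the standardised slopes.
#' @return An object of class `coding_model`.
#' @export
build_coding_model <- function(n_per_class = 150, seed = 101, lambda = 25) {
  corpus <- withr::with_seed(seed, {
    coding <- replicate(n_per_class, {
      n_cod <- sample(100:400, 1)
      cds <- .random_codon_string(n_cod)
      cov <- runif(1, 0.5, 1)
      utr_total <- round(3 * n_cod * (1 - cov) / cov)
      u5 <- sample.int(utr_total + 1, 1) - 1
      paste0(.random_nt_string(u5), cds, .random_nt_string(utr_total - u5))
    })
    noncoding <- replicate(n_per_class, {
      .random_nt_string(sample(300:1200, 1))
    })
    list(coding = coding, noncoding = noncoding)
  })
  cod_counts <- .hexamer_counts(corpus$coding)
  non_counts <- .hexamer_counts(corpus$noncoding)
  all_k <- union(names(cod_counts), names(non_counts))
  cc <- setNames(numeric(length(all_k)), all_k)
  nc <- cc
  cc[names(cod_counts)] <- cod_counts
  nc[names(non_counts)] <- non_counts
  log_odds <- log((cc + 1) / sum(cc + 1)) - log((nc + 1) / sum(nc + 1))
  feats <- function(seqs) {
    cbind(cov = vapply(seqs, .orf_coverage, 0),
          hex = vapply(seqs, .hexamer_score, 0, log_odds = log_odds))
  }
  X <- rbind(feats(corpus$coding), feats(corpus$noncoding))
  y <- rep(c(1, 0), each = n_per_class)
  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  beta <- .irls_ridge_logistic(Xs, y, lambda)
  structure(list(log_odds = log_odds, center = center, scale = scale_,
                 beta = beta, seed = seed, lambda = lambda),
            class = "coding_model")
}

.default_coding_model <- function() {
  if (is.null(.pkg_cache$coding_model)) {
    .pkg_cache$coding_model <- build_coding_model()
  }
  .pkg_cache$coding_model
}

#' Coding-potential scores for sequences
#'
#' Scores each sequence in \[0, 1\]; scores below 0.5 indicate a low
#' probability that the sequence codes for a protein. When `score_table`
#' is supplied (e.g. scores from an external coding-potential program) its
#' values are returned unchanged and the built-in model is not consulted.
#' Sequences shorter than 60 nt are undefined (`NA`).
#'
#' @param seqs sequence tibble (`id`, `seq`).
#' @param model a [build_coding_model()] object; default model if `NULL`.
#' @param score_table optional tibble (`id`, `score`) of external scores.
#' @return A tibble with columns `id`, `score`.
#' @export
coding_potential_score <- function(seqs, model = NULL, score_table = NULL) {
  if (!is.null(score_table)) {
    return(tibble(id = seqs$id,
                  score = score_table$score[match(seqs$id, score_table$id)]))
  }
  model <- model %||% .default_coding_model()
  score <- vapply(seqs$seq, function(s) {
    if (nchar(s) < 60) return(NA_real_)
    x <- c(.orf_coverage(s), .hexamer_score(s, model$log_odds))
    xs <- (x - model$center) / model$scale
    plogis(model$beta[1] + sum(model$beta[-1] * xs))
  }, 0, USE.NAMES = FALSE)
  tibble(id = seqs$id, score = score)
}
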