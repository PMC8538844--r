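## Single-sample gene-set enrichment: kernel-CDF normalization, weighted
## running-sum enrichment score, permutation significance, cohort z-scoring.

#' Enrichment scoring parameters
#'
#' @param alpha Rank-weight exponent applied to ascending abundance ranks
#'   (0 = unweighted KS-like walk; default 0.25, the conventional ssGSEA
#'   weight).
#' @param kcdf Apply kernel-CDF normalization across samples before ranking
#'   (GSVA-style). Requires >= 2 samples.
#' @param B Permutation count for [permutation_pvalues()] (0 = no
#'   permutation stage).
#' @param seed RNG seed for the permutation null.
#' @return A list of class `EnrichmentParams`.
#' @export
enrichment_params <- function(alpha = 0.25, kcdf = FALSE, B = 1000L,
                              seed = 1L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(B), B >= 0)
  structure(list(alpha = alpha, kcdf = isTRUE(kcdf), B = as.integer(B),
                 seed = as.integer(seed)),
            class = "EnrichmentParams")
}

#' Kernel-CDF normalization of an expression matrix
#'
#' Replaces each value by its smoothed empirical CDF position within its
#' gene row: `z_ij = mean_k Phi((x_ij - x_ik) / h_i)` with bandwidth
#' `h_i = s_i / 4` (`s_i` = sample sd of gene i). Constant rows map to 0.5.
#'
#' @param em An [expression_matrix()].
#' @return An [expression_matrix()] of values in (0, 1).
#' @export
kernel_cdf_normalize <- function(em) {
  x <- em$values
  if (ncol(x) < 2L)
    stop("kernel-CDF normalization undefined for a single sample")
  z <- x
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    s <- stats::sd(xi)
    if (s == 0) {
      z[i, ] <- 0.5
    } else {
      h <- s / 4
      z[i, ] <- rowMeans(stats::pnorm(outer(xi, xi, "-") / h))
    }
  }
  expression_matrix(z, em$cohort_of)
}

#' Enrichment score of one gene set in one sample
#'
#' Genes are ranked ascending by abundance (rank N = most abundant; tied
#' weights use average ranks). Walking positions 1..N in descending
#' abundance (ties broken by gene id for determinism), the score is the
#' summed difference between the weighted fraction of in-set genes passed
#' and the fraction of out-of-set genes passed:
#' `ES = sum_i P_in(i) - P_out(i)`.
#'
#' @param sample_values Named numeric vector of per-gene abundance.
#' @param set Character vector of gene ids; must intersect the names of
#'   `sample_values` and must not cover all genes.
#' @param alpha Rank-weight exponent (>= 0).
#' @return Scalar enrichment score.
#' @export
score_set <- function(sample_values, set, alpha = 0.25) {
  genes <- names(sample_values)
  if (is.null(genes)) stop("sample_values must be named by gene id")
  inset <- genes %in% set
  n_in <- sum(inset)
  if (n_in == 0L) stop("gene set does not intersect the gene universe")
  if (n_in == length(genes)) stop("gene set covers the whole universe")
  score_set_core(sample_values, inset, genes, alpha)
}

## shared fast path: `inset` logical over `genes`
score_set_core <- function(values, inset, genes, alpha) {
  n <- length(values)
  w <- rank(values, ties.method = "average")^alpha
  ord <- order(-values, genes)               # descending, stable by gene id
  in_ord <- inset[ord]
  p_in <- cumsum(ifelse(in_ord, w[ord], 0)) / sum(w[inset])
  p_out <- cumsum(!in_ord) / (n - sum(inset))
  sum(p_in - p_out)
}

#' Score every (gene set, sample) pair
#'
#' Applies [kernel_cdf_normalize()] first when `params$kcdf`, then
#' [score_set()] per set and sample. Sets partially absent from the gene
#' universe are intersected with a warning; a set with empty intersection
#' is an error.
#'
#' @param em An [expression_matrix()].
#' @param sets A [gene_set_collection()].
#' @param params An [enrichment_params()].
#' @return An `EnrichmentMatrix`: list with `scores` (sets x samples),
#'   `cohort_of`, `scale = "raw"`.
#' @export
score_matrix <- function(em, sets, params = enrichment_params()) {
  if (params$kcdf) em <- kernel_cdf_normalize(em)
  x <- em$values
  genes <- rownames(x)
  inset_list <- lapply(names(sets$sets), function(nm) {
    s <- sets$sets[[nm]]
    hit <- genes %in% s
    k <- sum(hit)
    if (k == 0L) stop("set '", nm, "' has empty intersection with the gene universe")
    if (k == length(genes)) stop("set '", nm, "' covers the whole gene universe")
    if (k < length(s))
      warning("set '", nm, "': ", length(s) - k,
              " gene(s) absent from the expression matrix")
    hit
  })
  scores <- matrix(NA_real_, length(sets$sets), ncol(x),
                   dimnames = list(names(sets$sets), colnames(x)))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    for (k in seq_along(inset_list))
      scores[k, j] <- score_set_core(v, inset_list[[k]], genes, params$alpha)
  }
  enrichment_matrix(scores, em$cohort_of, scale = "raw")
}

enrichment_matrix <- function(scores, cohort_of, scale = c("raw", "cohort_z")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(scores), all(is.finite(scores)),
            !is.null(rownames(scores)), !is.null(colnames(scores)))
  cohort_of <- as.character_named(cohort_of, colnames(scores), "cohort_of")
  structure(list(scores = scores, cohort_of = cohort_of, scale = scale),
            class = "EnrichmentMatrix")
}

#' @export
print.EnrichmentMatrix <- function(x, ...) {
  cat(sprintf("EnrichmentMatrix (%s): %d set(s) x %d sample(s)\n",
              x$scale, nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Permutation p-values for one gene set across samples
#'
#' The null is built from `B` random gene sets of the same size drawn
#' without replacement from the gene universe; the same draws are shared by
#' all samples. Two-sided add-one empirical p:
#' `p_j = (1 + #\{b : |ES*_bj| >= |ES_j|\}) / (B + 1)`.
#'
#' @param em An [expression_matrix()].
#' @param set Character vector of gene ids.
#' @param params An [enrichment_params()] with `B >= 1`.
#' @return Named numeric vector of per-sample p-values.
#' @export
permutation_pvalues <- function(em, set, params = enrichment_params()) {
  if (params$B < 1L) stop("B must be >= 1")
  if (params$kcdf) em <- kernel_cdf_normalize(em)
  x <- em$values
  genes <- rownames(x)
  k <- sum(genes %in% set)
  if (k == 0L) stop("gene set does not intersect the gene universe")
  if (k == length(genes)) stop("gene set covers the whole universe")
  inset_obs <- genes %in% set
  obs <- vapply(seq_len(ncol(x)), function(j)
    score_set_core(x[, j], inset_obs, genes, params$alpha), numeric(1))
  old <- local_seed(params$seed)
  on.exit(restore_seed(old))
  exceed <- integer(ncol(x))
  for (b in seq_len(params$B)) {
    inset_b <- logical(length(genes))
    inset_b[sample.int(length(genes), k)] <- TRUE
    null_b <- vapply(seq_len(ncol(x)), function(j)
      score_set_core(x[, j], inset_b, genes, params$alpha), numeric(1))
    exceed <- exceed + (abs(null_b) >= abs(obs))
  }
  stats::setNames((1 + exceed) / (params$B + 1), colnames(x))
}

#' Within-cohort z-scoring of enrichment scores
#'
#' Standardizes each gene set's scores to mean 0 / sd 1 within every cohort,
#' yielding the "relative activity" scale the TMM classifier consumes.
#' Zero-variance (cohort, set) strata map to 0. Cohorts of size 1 are an
#' error.
#'
#' @param em_scores An `EnrichmentMatrix` from [score_matrix()].
#' @return An `EnrichmentMatrix` with `scale = "cohort_z"`.
#' @export
cohort_zscore <- function(em_scores) {
  sc <- em_scores$scores
  z <- sc
  for (co in unique(em_scores$cohort_of)) {
    cols <- which(em_scores$cohort_of == co)
    if (length(cols) < 2L)
      stop("cohort '", co, "' has fewer than 2 samples")
    sub <- sc[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1L, stats::sd)
    zi <- (sub - mu) / ifelse(sdv == 0, 1, sdv)
    zi[sdv == 0, ] <- 0
    z[, cols] <- zi
  }
  enrichment_matrix(z, em_scores$cohort_of, scale = "cohort_z")
}

## seed helpers: save/restore .Random.seed so library code does not disturb
## the caller's RNG stream
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
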