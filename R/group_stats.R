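## Between-group statistics: empirical-Bayes moderated-t differential
## expression, BH adjustment, hypergeometric over-representation,
## Mann-Whitney, mutation / copy-number burden, contingency, correlation.

#' Empirical-Bayes moderated-t differential expression
#'
#' Two-group comparison with gene-wise variances shrunk toward a prior
#' estimated across genes by moment matching on
#' `e_g = log s_g^2 - psi(d_g/2) + log(d_g/2)`:
#' `psi'(d0/2) = max(var(e) - mean psi'(d_g/2), 0)` solved for `d0` by
#' monotone root-finding (`d0 = Inf` when the right-hand side is 0), and
#' `s0^2 = exp(mean(e) + psi(d0/2) - log(d0/2))`. Posterior variance
#' `s2_post = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`; the moderated t uses
#' `d0 + d_g` degrees of freedom. Zero-variance genes are excluded from the
#' prior fit but still moderated.
#'
#' @param em An [expression_matrix()] (log2 scale).
#' @param groupA,groupB Character vectors of sample ids (>= 2 each).
#' @param d0_override Force the prior df (e.g. `0` for the ordinary pooled
#'   t, `Inf` for full shrinkage); `NULL` = estimate.
#' @return A `data.frame` of class `DEGTable`: `gene_id`, `log_fc`
#'   (meanA - meanB), `t_mod`, `p_value`, `q_value`, `s2_post`, plus
#'   attributes `d0` and `s0_sq`.
#' @export
moderated_t_deg <- function(em, groupA, groupB, d0_override = NULL) {
  x <- em$values
  missing <- setdiff(c(groupA, groupB), colnames(x))
  if (length(missing))
    stop("sample id(s) not in expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2L || nB < 2L) stop("need >= 2 samples per group")
  xa <- x[, groupA, drop = FALSE]
  xb <- x[, groupB, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  lfc <- ma - mb
  dg <- nA + nB - 2
  sg2 <- (rowSums((xa - ma)^2) + rowSums((xb - mb)^2)) / dg
  if (is.null(d0_override)) {
    prior <- fit_variance_prior(sg2, dg)
  } else {
    d0 <- d0_override
    pos <- sg2 > 0
    s0 <- if (is.infinite(d0)) {
      exp(mean(log(sg2[pos]) - digamma(dg / 2) + log(dg / 2)))
    } else if (d0 > 0) {
      exp(mean(log(sg2[pos]) - digamma(dg / 2) + log(dg / 2)) +
            digamma(d0 / 2) - log(d0 / 2))
    } else NA_real_
    prior <- list(d0 = d0, s0_sq = s0)
  }
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  if (any(sg2 == 0) && !is.na(d0) && d0 == 0)
    stop("gene with zero variance in both groups and d0 = 0: moderated t undefined")
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(sg2))
             else if (d0 == 0) sg2
             else (d0 * s0_sq + dg * sg2) / (d0 + dg)
  tstat <- lfc / sqrt(s2_post * (1 / nA + 1 / nB))
  df_total <- d0 + dg
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat))
       else 2 * stats::pt(-abs(tstat), df_total)
  p[lfc == 0 & s2_post == 0] <- 1    # degenerate 0/0 genes: no evidence
  tstat[lfc == 0 & is.nan(tstat)] <- 0
  out <- data.frame(gene_id = rownames(x), log_fc = lfc, t_mod = tstat,
                    p_value = p, q_value = bh_adjust(p), s2_post = s2_post,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "df_total") <- df_total
  class(out) <- c("DEGTable", "data.frame")
  out
}

## moment-matching fit of the scaled inverse-chi-square variance prior
fit_variance_prior <- function(sg2, dg) {
  pos <- is.finite(sg2) & sg2 > 0
  if (sum(pos) < 2L) stop("too few positive gene variances to fit a prior")
  e <- log(sg2[pos]) - digamma(dg / 2) + log(dg / 2)
  rhs <- max(stats::var(e) - trigamma(dg / 2), 0)
  if (rhs == 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    # trigamma is strictly decreasing: bracket then uniroot on log(d0)
    f <- function(ld0) trigamma(exp(ld0) / 2) - rhs
    lo <- -10; hi <- 10
    while (f(hi) > 0 && hi < 60) hi <- hi + 10
    while (f(lo) < 0 && lo > -60) lo <- lo - 10
    d0 <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} min(1, m p_(j) / j)` mapped back to input order.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q <- pmin(1, m * p[o] / seq_len(m))
  q <- rev(cummin(rev(q)))
  q[order(o)]
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation set, the upper-tail hypergeometric probability of
#' observing at least the seen overlap between the query and the set within
#' the universe: `p = sum_{k=x}^{min(K,n)} C(K,k) C(N-K,n-k) / C(N,n)`.
#' Annotation sets are intersected with the universe first; BH across sets.
#'
#' @param query Character vector of genes (must be a subset of `universe`).
#' @param universe Character vector: the gene universe.
#' @param annotation A [gene_set_collection()].
#' @return A `data.frame`: `set_name`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p_value`, `q_value`.
#' @export
hypergeom_ora <- function(query, universe, annotation) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query")
  if (!all(query %in% universe))
    stop("query contains genes outside the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(annotation$sets), function(nm) {
    K <- sum(annotation$sets[[nm]] %in% universe)
    x <- sum(annotation$sets[[nm]] %in% query)
    # P(X >= x), X ~ Hypergeom(N, K, n); phyper upper tail is P(X > x-1)
    p <- if (x == 0L) 1 else stats::phyper(x - 1, K, N - K, n,
                                           lower.tail = FALSE)
    data.frame(set_name = nm, overlap = x, set_size = K, query_size = n,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact null distribution (via the Wilcoxon rank-sum distribution) when
#' `nA + nB <= 12` and there are no ties; otherwise a normal approximation
#' with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors (>= 1 value each).
#' @return List with `U` (statistic for group `a`), `p_value`, `method`.
#' @export
mannwhitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  nA <- length(a); nB <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (nA + nB <= 12L && !ties) {
    # exact two-sided p = 2 min(P(U <= u), P(U >= u)), capped at 1
    p <- min(1, 2 * min(stats::pwilcox(U, nA, nB),
                        stats::pwilcox(U - 1, nA, nB, lower.tail = FALSE)))
    method <- "exact"
  } else {
    mu <- nA * nB / 2
    tie_tab <- table(c(a, b))
    n <- nA + nB
    sigma2 <- nA * nB / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
    z <- max(abs(U - mu) - 0.5, 0) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal"
  }
  list(U = unname(U), p_value = unname(p), method = method)
}

#' Per-sample tumor mutational burden
#'
#' Count of variants per sample whose class is in `nonsyn_classes`.
#' Samples listed in `all_samples` but absent from the table get 0.
#'
#' @param mut A `MutationTable`.
#' @param nonsyn_classes Variant classes to count (default
#'   [NONSYN_CLASSES]); must be a subset of the declared vocabulary.
#' @param all_samples Optional full sample-id vector.
#' @return Named integer vector of counts.
#' @export
tmb <- function(mut, nonsyn_classes = NONSYN_CLASSES, all_samples = NULL) {
  unknown <- setdiff(nonsyn_classes, MAF_VOCABULARY)
  if (length(unknown))
    stop("unknown variant class(es): ", paste(unknown, collapse = ", "))
  ids <- unique(c(mut$sample_id, all_samples))
  keep <- mut$variant_classification %in% nonsyn_classes
  counts <- table(factor(mut$sample_id[keep], levels = ids))
  stats::setNames(as.integer(counts), ids)
}

#' Per-sample fraction of genome altered
#'
#' `fga = sum(length of segments with |seg_mean| >= threshold) /
#' sum(length of all segments)` per sample, with 1-based inclusive segment
#' lengths `end - start + 1`.
#'
#' @param cnv A `CNVSegmentTable`.
#' @param seg_mean_threshold Absolute log2 copy-ratio cutoff (default 0.2).
#' @return Named numeric vector of FGA values in \[0, 1\].
#' @export
cnv_burden <- function(cnv, seg_mean_threshold = 0.2) {
  len <- cnv$end - cnv$start + 1
  tot <- tapply(len, cnv$sample_id, sum)
  alt <- tapply(len * (abs(cnv$seg_mean) >= seg_mean_threshold),
                cnv$sample_id, sum)
  if (any(tot == 0)) stop("sample with zero covered length")
  fga <- alt / tot
  stats::setNames(as.numeric(fga), names(tot))
}

#' Per-gene mutation-frequency comparison between two groups
#'
#' For every gene, the mutated-sample fraction in each group and a
#' two-sided Fisher exact test on the 2x2 mutated/not x group table, with
#' BH adjustment across genes.
#'
#' @param mut A `MutationTable`.
#' @param labels A `TMMLabeling` table.
#' @param groupA,groupB Labels to compare (e.g. `"ALT"`, `"NDTMM"`).
#' @param genes Optional gene subset; default = all genes in `mut`.
#' @return A `data.frame`: `gene_id`, `freqA`, `freqB`, `p_value`,
#'   `q_value`.
#' @export
mutation_frequency_compare <- function(mut, labels, groupA = "ALT",
                                       groupB = "NDTMM", genes = NULL) {
  sa <- labels$sample_id[labels$label == groupA]
  sb <- labels$sample_id[labels$label == groupB]
  if (length(sa) == 0L || length(sb) == 0L)
    stop("empty group after label filtering")
  if (is.null(genes)) genes <- sort(unique(mut$gene_id))
  rows <- lapply(genes, function(g) {
    mutated <- unique(mut$sample_id[mut$gene_id == g])
    xa <- sum(sa %in% mutated); xb <- sum(sb %in% mutated)
    p <- if (xa + xb == 0L) 1 else stats::fisher.test(
      matrix(c(xa, length(sa) - xa, xb, length(sb) - xb), 2))$p.value
    data.frame(gene_id = g, freqA = xa / length(sa), freqB = xb / length(sb),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' TMM x category contingency table and chi-square test
#'
#' Pearson chi-square without continuity correction on the label-by-category
#' count table (missing categories dropped); cells with expected count < 5
#' are flagged.
#'
#' @param labels A `TMMLabeling` table.
#' @param category Per-sample category vector (e.g. stage/grade), aligned
#'   with `labels$sample_id` or named by sample id.
#' @return List: `table` (counts), `proportions` (per-category TMM
#'   composition, columns sum to 1), `statistic`, `df`, `p_value`,
#'   `low_expected` (logical matrix).
#' @export
contingency_chisq <- function(labels, category) {
  if (!is.null(names(category))) category <- category[labels$sample_id]
  stopifnot(length(category) == nrow(labels))
  keep <- !is.na(category) & !is.na(labels$label)
  tab <- table(label = labels$label[keep], category = category[keep])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("degenerate margin: need >= 2 levels on each axis")
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - expd)^2 / expd)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(table = tab,
       proportions = sweep(tab, 2L, colSums(tab), "/"),
       statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       low_expected = expd < 5)
}

#' Pearson correlation between two gene panels
#'
#' `r_ab` across samples for every gene a in `genes_a` and b in `genes_b`.
#' Constant genes yield `NA` entries, recorded in the `flagged` attribute
#' rather than propagated as errors.
#'
#' @param em An [expression_matrix()] with >= 3 samples.
#' @param genes_a,genes_b Gene-id vectors; all must be present.
#' @return Matrix of Pearson r (rows = `genes_a`), with attribute
#'   `flagged` listing constant genes.
#' @export
correlation_matrix <- function(em, genes_a, genes_b) {
  x <- em$values
  missing <- setdiff(c(genes_a, genes_b), rownames(x))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  if (ncol(x) < 3L) stop("need >= 3 samples for correlation")
  const <- c(genes_a, genes_b)[apply(x[c(genes_a, genes_b), , drop = FALSE],
                                     1L, stats::sd) == 0]
  r <- suppressWarnings(
    stats::cor(t(x[genes_a, , drop = FALSE]), t(x[genes_b, , drop = FALSE])))
  r <- matrix(r, length(genes_a), length(genes_b),
              dimnames = list(genes_a, genes_b))
  attr(r, "flagged") <- unique(const)
  r
}
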