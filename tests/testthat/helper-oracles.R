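# Independent oracle implementations, deliberately written in a different
# style from the package (O(N^2) prefix re-scans, plain loops) so agreement
# is evidence, not tautology.

# Brute-force running-sum enrichment score: for each walk position, rescan
# the whole prefix.
oracle_es <- function(values, set_genes, alpha) {
  genes <- names(values)
  N <- length(genes)
  rho <- rank(values, ties.method = "average")      # ascending, N = top
  names(rho) <- genes
  walk <- genes[order(-values, genes)]              # descending, ties by id
  denom_in <- 0
  for (g in genes) if (g %in% set_genes) denom_in <- denom_in + rho[[g]]^alpha
  n_out <- N - sum(genes %in% set_genes)
  es <- 0
  for (i in seq_len(N)) {
    p_in <- 0; n_pass_out <- 0
    for (j in seq_len(i)) {
      g <- walk[j]
      if (g %in% set_genes) p_in <- p_in + rho[[g]]^alpha
      else n_pass_out <- n_pass_out + 1
    }
    es <- es + p_in / denom_in - n_pass_out / n_out
  }
  es
}

# Direct double-sum kernel CDF for one gene row.
oracle_kcdf_row <- function(xi) {
  s <- sd(xi)
  if (s == 0) return(rep(0.5, length(xi)))
  h <- s / 4
  sapply(xi, function(v) mean(pnorm((v - xi) / h)))
}

# Step-up BH from the literal definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in i:m) cand <- min(cand, min(1, m * p[o[j]] / j))
    q[o[i]] <- cand
  }
  q
}

# Moderated-t oracle: direct per-gene loops, bisection (not uniroot) for
# the trigamma inverse.
oracle_moderated_t <- function(xa, xb) {
  nA <- ncol(xa); nB <- ncol(xb); dg <- nA + nB - 2
  G <- nrow(xa)
  lfc <- s2 <- numeric(G)
  for (g in seq_len(G)) {
    a <- xa[g, ]; b <- xb[g, ]
    lfc[g] <- mean(a) - mean(b)
    s2[g] <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / dg
  }
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  rhs <- max(var(e) - trigamma(dg / 2), 0)
  if (rhs == 0) {
    d0 <- Inf; s0 <- exp(mean(e))
  } else {
    lo <- 1e-8; hi <- 1e8
    for (it in 1:200) {
      mid <- sqrt(lo * hi)
      if (trigamma(mid / 2) > rhs) lo <- mid else hi <- mid
    }
    d0 <- sqrt(lo * hi)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  s2p <- if (is.infinite(d0)) rep(s0, G) else (d0 * s0 + dg * s2) / (d0 + dg)
  tm <- lfc / sqrt(s2p * (1 / nA + 1 / nB))
  df <- d0 + dg
  p <- if (is.infinite(df)) 2 * pnorm(-abs(tm)) else 2 * pt(-abs(tm), df)
  list(d0 = d0, s0_sq = s0, t = tm, p = p, lfc = lfc)
}

# Exact hypergeometric upper tail from binomial coefficients.
oracle_hyper_upper <- function(x, K, N, n) {
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
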