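test_that("moderated_t_deg matches the independent oracle and limma", {
  set.seed(31)
  nA <- 6; nB <- 8
  m <- matrix(rnorm(200 * (nA + nB), 5, runif(200, 0.3, 2)), 200, nA + nB,
              dimnames = list(sprintf("g%03d", 1:200),
                              sprintf("s%02d", 1:(nA + nB))))
  m[1:10, 1:nA] <- m[1:10, 1:nA] + 1.5
  em <- expression_matrix(m, rep("X", nA + nB))
  ga <- colnames(m)[1:nA]; gb <- colnames(m)[nA + 1:nB]

  deg <- moderated_t_deg(em, ga, gb)
  orc <- oracle_moderated_t(m[, ga], m[, gb])
  expect_equal(attr(deg, "d0"), orc$d0, tolerance = 1e-6)
  expect_equal(attr(deg, "s0_sq"), orc$s0_sq, tolerance = 1e-6)
  expect_equal(deg$t_mod, unname(orc$t), tolerance = 1e-6)
  expect_equal(deg$p_value, unname(orc$p), tolerance = 1e-6)
  expect_equal(deg$log_fc, unname(orc$lfc), tolerance = 1e-12)

  # cross-check against limma's empirical-Bayes fit
  design <- cbind(mean = 1, diff = rep(c(1, 0), c(nA, nB)))
  fit <- limma::eBayes(limma::lmFit(m[, c(ga, gb)], design))
  expect_equal(attr(deg, "d0"), fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(deg, "s0_sq"), fit$s2.prior, tolerance = 1e-4)
  expect_equal(deg$t_mod, unname(fit$t[, "diff"]), tolerance = 1e-6)

  # s2_post lies between the gene variance and the prior
  sg2 <- deg$s2_post * 0 + apply(cbind(m[, ga] - rowMeans(m[, ga]),
                                       m[, gb] - rowMeans(m[, gb])), 1,
                                 function(r) sum(r^2)) / (nA + nB - 2)
  lo <- pmin(sg2, attr(deg, "s0_sq")); hi <- pmax(sg2, attr(deg, "s0_sq"))
  expect_true(all(deg$s2_post >= lo - 1e-9 & deg$s2_post <= hi + 1e-9))
})

test_that("moderated_t_deg limits: identical groups, d0 = 0 and d0 = Inf", {
  set.seed(8)
  m <- matrix(rnorm(50 * 8, 5, 1), 50, 8,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
  # groupA values identical to groupB values
  mm <- cbind(m[, 1:4], m[, 1:4])
  colnames(mm) <- sprintf("t%d", 1:8)
  em2 <- expression_matrix(mm, rep("X", 8))
  deg <- moderated_t_deg(em2, sprintf("t%d", 1:4), sprintf("t%d", 5:8))
  expect_equal(deg$log_fc, rep(0, 50))
  expect_equal(deg$t_mod, rep(0, 50))
  expect_equal(deg$p_value, rep(1, 50))

  ga <- sprintf("s%d", 1:4); gb <- sprintf("s%d", 5:8)
  em3 <- expression_matrix(m, rep("X", 8))
  # d0 = 0 reduces to the ordinary pooled two-sample t
  deg0 <- moderated_t_deg(em3, ga, gb, d0_override = 0)
  ordinary <- apply(m, 1, function(r)
    t.test(r[1:4], r[5:8], var.equal = TRUE)$statistic)
  expect_equal(deg0$t_mod, unname(ordinary), tolerance = 1e-9)
  # d0 = Inf: every gene shares s0^2
  degInf <- moderated_t_deg(em3, ga, gb, d0_override = Inf)
  s0 <- attr(degInf, "s0_sq")
  expect_equal(degInf$t_mod, degInf$log_fc / sqrt(s0 * (1 / 4 + 1 / 4)),
               tolerance = 1e-9)
})

test_that("bh_adjust matches the step-up definition and base R", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(17)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # order-preserving
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("hypergeom_ora computes exact tail probabilities", {
  ann <- gene_set_collection(list(SET = sprintf("g%d", 1:5)))
  uni <- sprintf("g%d", 1:10)
  res <- hypergeom_ora(sprintf("g%d", 1:5), uni, ann)
  expect_equal(res$p_value, 1 / 252, tolerance = 1e-12)   # C(5,5)/C(10,5)

  # zero overlap -> p = 1; p always <= 1
  res0 <- hypergeom_ora(sprintf("g%d", 6:10), uni,
                        gene_set_collection(list(S = sprintf("g%d", 1:3))))
  expect_equal(res0$overlap, 0L)
  expect_equal(res0$p_value, 1)

  set.seed(2)
  for (rep in 1:20) {
    K <- sample(2:8, 1); n <- sample(2:8, 1); N <- 12
    q <- sample(sprintf("g%d", 1:N), n)
    r <- hypergeom_ora(q, sprintf("g%d", 1:N),
                       gene_set_collection(list(S = sprintf("g%d", 1:K))))
    expect_equal(r$p_value, oracle_hyper_upper(r$overlap, K, N, n),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_ora(character(0), uni, ann), "empty query")
  expect_error(hypergeom_ora("gX", uni, ann), "outside the universe")
})

test_that("mannwhitney: exact enumeration, symmetry and normal approximation", {
  r <- mannwhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)   # 2 / C(6,3)
  expect_identical(r$method, "exact")

  expect_equal(mannwhitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # approximation close to wilcox.test's corrected normal p on larger data
  set.seed(77)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  r2 <- mannwhitney(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(r2$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(mannwhitney(numeric(0), 1), "empty")
})

test_that("tmb counts nonsynonymous records and fills absent samples", {
  mut <- tmmpipe:::validate_mutations(data.frame(
    sample_id = c(rep("S1", 5), "S2"),
    gene_id = c("A", "B", "C", "D", "E", "A"),
    variant_classification = c(rep("Missense_Mutation", 3),
                               "Silent", "Silent", "Nonsense_Mutation")))
  counts <- tmb(mut, all_samples = c("S1", "S2", "S3"))
  expect_equal(counts[["S1"]], 3L)
  expect_equal(counts[["S3"]], 0L)
  # record order is irrelevant
  expect_equal(sort(tmb(mut[sample(nrow(mut)), ], all_samples = c("S1", "S2", "S3"))),
               sort(counts))
  expect_error(tmb(mut, nonsyn_classes = "Bogus"), "unknown")
  empty <- tmmpipe:::validate_mutations(mut[0, 1:3])
  expect_equal(unname(tmb(empty, all_samples = "S9")), 0L)
})

test_that("cnv_burden computes length-weighted altered fraction", {
  seg <- tmmpipe:::validate_seg(data.frame(
    sample_id = c("S1", "S1"), chromosome = "1",
    start = c(1, 101), end = c(100, 200), seg_mean = c(0.5, 0.0)))
  expect_equal(unname(cnv_burden(seg, 0.2)), 0.5)
  seg$seg_mean <- 0
  expect_equal(unname(cnv_burden(seg, 0.2)), 0)
})

test_that("mutation_frequency_compare runs Fisher tests per gene", {
  lab <- two_group_labels(3, 3)
  mut <- tmmpipe:::validate_mutations(data.frame(
    sample_id = lab$sample_id[1:3], gene_id = "KRAS",
    variant_classification = "Missense_Mutation"))
  res <- mutation_frequency_compare(mut, lab, "ALT", "NDTMM")
  expect_equal(res$freqA, 1); expect_equal(res$freqB, 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-9)  # [[3,0],[0,3]] two-sided

  # gene mutated nowhere among labeled samples: freqs 0, p 1
  mut2 <- tmmpipe:::validate_mutations(data.frame(
    sample_id = "OTHER", gene_id = "TP53",
    variant_classification = "Missense_Mutation"))
  res2 <- mutation_frequency_compare(mut2, lab, "ALT", "NDTMM")
  expect_equal(res2$freqA, 0)
  expect_equal(res2$p_value, 1)
})

test_that("contingency_chisq reproduces the hand 2x2 example", {
  lab <- data.frame(sample_id = sprintf("s%d", 1:20),
                    label = rep(c("ALT", "NDTMM"), each = 10),
                    z_tel = 0, z_alt = 0, cohort = "X")
  ct <- contingency_chisq(lab, rep(c("g3", "g4"), each = 10))
  expect_equal(ct$statistic, 20, tolerance = 1e-12)
  expect_equal(ct$df, 1L)
  expect_equal(unname(colSums(ct$proportions)), c(1, 1), tolerance = 1e-12)
  expect_error(contingency_chisq(lab, rep("g3", 20)), "degenerate")
})

test_that("correlation_matrix matches the direct formula and flags constants", {
  em <- toy_expression(5, 6, seed = 55)
  r <- correlation_matrix(em, rownames(em$values)[1:2], rownames(em$values)[3:5])
  for (a in 1:2) for (b in 1:3) {
    x <- em$values[a, ]; y <- em$values[b + 2, ]
    expect_equal(r[a, b],
                 sum((x - mean(x)) * (y - mean(y))) /
                   sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
                 tolerance = 1e-12)
  }
  expect_equal(correlation_matrix(em, "G01", "G01")[1, 1], 1)
  # exact anti-correlation
  m <- em$values
  m[2, ] <- -m[1, ]
  em2 <- expression_matrix(m, em$cohort_of)
  expect_equal(correlation_matrix(em2, "G01", "G02")[1, 1], -1, tolerance = 1e-12)
  # constant gene flagged
  m[3, ] <- 7
  em3 <- expression_matrix(m, em$cohort_of)
  r3 <- correlation_matrix(em3, "G01", "G03")
  expect_true(is.na(r3[1, 1]))
  expect_identical(attr(r3, "flagged"), "G03")
  expect_error(correlation_matrix(em, "NOPE", "G01"), "absent")
})
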