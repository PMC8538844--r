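test_that("cohort_config validates its invariants", {
  expect_s3_class(cohort_config(), "CohortConfig")
  expect_error(cohort_config(mixing = c("TEL+ALT" = 0.5, "ALT" = 0.5,
                                        "TEL" = 0.2, "NDTMM" = -0.2)),
               "non-negative")
  expect_error(cohort_config(n_genes = 30, n_signature_genes = 20), ">=")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(hazards = c("TEL+ALT" = 1, "ALT" = 0,
                                         "TEL" = 1, "NDTMM" = 1)),
               "hazards")
})

test_that("generate_expression plants the configured shift and is deterministic", {
  cfg <- cohort_config(n_samples = 400, effect = 3, noise_sd = 0.5,
                       n_genes = 500, seed = 19)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$expression$values, b$expression$values)  # bit-identical
  expect_identical(a$truth_labels, b$truth_labels)

  tel_genes <- a$gene_sets$sets$TEL
  tel_samples <- names(a$truth_labels)[a$truth_labels == "TEL"]
  nd_samples <- names(a$truth_labels)[a$truth_labels == "NDTMM"]
  gap <- mean(a$expression$values[tel_genes, tel_samples]) -
         mean(a$expression$values[tel_genes, nd_samples])
  # sample-mean oracle: shift recovered within 3 SE
  se <- 0.5 * sqrt(1 / (length(tel_genes) * length(tel_samples)) +
                   1 / (length(tel_genes) * length(nd_samples)))
  expect_lt(abs(gap - 3), 3 * se + 0.05)

  # label mixing within binomial fluctuation
  ph <- prop.table(table(a$truth_labels))[TMM_LABELS]
  expect_true(all(abs(ph - cfg$mixing) < 3 * sqrt(cfg$mixing * (1 - cfg$mixing) / 400) + 0.01))
})

test_that("null configuration (effect = 0) removes all group structure", {
  cfg <- cohort_config(n_samples = 120, effect = 0, n_genes = 300, seed = 3)
  a <- generate_expression(cfg)
  tel <- a$gene_sets$sets$TEL
  on <- names(a$truth_labels)[a$truth_labels %in% c("TEL", "TEL+ALT")]
  off <- setdiff(names(a$truth_labels), on)
  gap <- mean(a$expression$values[tel, on]) - mean(a$expression$values[tel, off])
  expect_lt(abs(gap), 0.1)
})

test_that("generate_survival: censoring limit and hazard-ratio recovery", {
  labels <- setNames(rep(c("ALT", "NDTMM"), each = 100),
                     sprintf("S%04d", 1:200))
  hz <- c("TEL+ALT" = 1, "ALT" = 3, "TEL" = 1, "NDTMM" = 1)
  # censor_rate -> 0: every event observed
  cl0 <- generate_survival(labels, hz, censor_rate = 0, seed = 2)
  expect_true(all(cl0$os_event == 1))

  # hazard ratio 3: median-time ratio ~ 1/3 (Monte-Carlo, averaged over reps)
  ratios <- vapply(1:20, function(s) {
    cl <- generate_survival(labels, hz, censor_rate = 0, seed = 1000 + s)
    median(cl$os_time[1:100]) / median(cl$os_time[101:200])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1 / 3), 1 / 3 * 0.2)
  expect_error(generate_survival(labels, hz * 0, 0.1, 1), "positive")
})

test_that("generate_cohort composes consistent tables with planted burdens", {
  cfg <- cohort_config(n_samples = 200, seed = 7)
  ch <- generate_cohort(cfg)
  ids <- names(ch$truth_labels)
  expect_identical(ch$clinical$sample_id, ids)
  expect_identical(colnames(ch$expression$values), ids)
  expect_true(all(ch$mutations$sample_id %in% ids))
  expect_true(all(ch$cnv$sample_id %in% ids))

  # KRAS frequency in ALT within binomial 95% bounds of the planted 0.6
  alt <- ids[ch$truth_labels == "ALT"]
  kras <- mean(alt %in% ch$mutations$sample_id[ch$mutations$gene_id == "KRAS"])
  expect_lt(abs(kras - 0.6), 1.96 * sqrt(0.6 * 0.4 / length(alt)) + 0.02)

  # CNV burden ordering ALT > NDTMM in group means
  fga <- cnv_burden(ch$cnv, 0.2)
  expect_gt(mean(fga[ids[ch$truth_labels == "ALT"]]),
            mean(fga[ids[ch$truth_labels == "NDTMM"]]))

  # group mean TMB ordering matches planted nonsynonymous rate ordering
  counts <- tmb(ch$mutations, all_samples = ids)
  expect_gt(mean(counts[ids[ch$truth_labels == "ALT"]]),
            mean(counts[ids[ch$truth_labels == "TEL"]]))
})

test_that("write_cohort emits files that read back identically", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_samples = 30, n_genes = 60, n_signature_genes = 10,
                       seed = 9)
  ch <- generate_cohort(cfg)
  write_cohort(ch, dir)
  expect_true(all(file.exists(file.path(dir,
    c("expression.tsv", "gene_sets.gmt", "clinical.tsv", "mutations.maf.tsv",
      "cnv.seg.tsv", "truth_labels.tsv", "manifest.json")))))
  em <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(em$values, ch$expression$values, tolerance = 1e-9)
  expect_identical(read_gmt(file.path(dir, "gene_sets.gmt"))$sets,
                   ch$gene_sets$sets)
  cl <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(cl$os_event, ch$clinical$os_event)
  mut <- read_maf_lite(file.path(dir, "mutations.maf.tsv"))
  expect_equal(nrow(mut), nrow(ch$mutations))
  seg <- read_seg(file.path(dir, "cnv.seg.tsv"))
  expect_equal(seg$seg_mean, ch$cnv$seg_mean, tolerance = 1e-9)
})
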