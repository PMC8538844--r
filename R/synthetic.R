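## Synthetic TCGA-like multi-cohort generator with planted TMM structure:
## signature-shifted expression, group-linked censored survival, a driver
## mutation panel with group-specific rates, and group-linked copy-number
## burden. Everything downstream of the pipeline is testable against the
## planted truth without any external download.

#' Synthetic cohort configuration
#'
#' Defaults encode the stated world the pipeline is tested against: the
#' pan-cancer TMM composition (47% TEL+ALT, 27% ALT, 9% TEL, 17% NDTMM), a
#' 3 log2-unit signature shift over residual sd 0.5, exponential survival
#' with hazards (TEL+ALT 1, ALT 3, TEL 1, NDTMM 0.5) and censoring rate
#' 0.5, a KRAS-enriched-in-ALT / TP53-enriched-in-NDTMM driver panel, and
#' copy-number burden 0.4 (ALT) vs 0.1 (NDTMM).
#'
#' @param n_samples Number of samples.
#' @param mixing Named proportions over [TMM_LABELS], summing to 1.
#' @param n_genes Total genes (>= 2 x `n_signature_genes`).
#' @param n_signature_genes Size of each of the TEL and ALT signature sets.
#' @param effect Mean log2 shift added to a signature's genes in samples
#'   where that mechanism is active (>= 0).
#' @param noise_sd Residual expression sd (> 0).
#' @param baseline_mean Baseline log2 abundance (default 5).
#' @param hazards Named per-group exponential event rates.
#' @param censor_rate Independent exponential censoring rate (0 = none).
#' @param mutation_rates Gene x group matrix (or named-list) of per-sample
#'   mutation probabilities for the driver panel.
#' @param cnv_burden_mean Named per-group mean fraction genome altered.
#' @param n_cohorts Number of cancer-type cohorts samples are split into.
#' @param n_segments Copy-number segments per sample.
#' @param stage_probs Optional list: per-group probabilities over stages
#'   I-IV (defaults to a shared uniform-ish distribution).
#' @param seed RNG seed; per-component substreams are derived from it.
#' @return A validated list of class `CohortConfig`.
#' @export
cohort_config <- function(n_samples = 400L,
                          mixing = c("TEL+ALT" = 0.47, "ALT" = 0.27,
                                     "TEL" = 0.09, "NDTMM" = 0.17),
                          n_genes = 2000L,
                          n_signature_genes = 25L,
                          effect = 3,
                          noise_sd = 0.5,
                          baseline_mean = 5,
                          hazards = c("TEL+ALT" = 1, "ALT" = 3,
                                      "TEL" = 1, "NDTMM" = 0.5),
                          censor_rate = 0.5,
                          mutation_rates = default_mutation_rates(),
                          cnv_burden_mean = c("TEL+ALT" = 0.25, "ALT" = 0.4,
                                              "TEL" = 0.25, "NDTMM" = 0.1),
                          n_cohorts = 2L,
                          n_segments = 50L,
                          stage_probs = NULL,
                          seed = 1L) {
  mixing <- mixing[TMM_LABELS]
  if (anyNA(mixing)) stop("mixing must name all four TMM labels")
  if (any(mixing < 0) || abs(sum(mixing) - 1) > 1e-9)
    stop("mixing must be non-negative and sum to 1")
  if (n_genes < 2L * n_signature_genes)
    stop("n_genes must be >= 2 * n_signature_genes")
  if (effect < 0) stop("effect must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  hazards <- hazards[TMM_LABELS]
  if (anyNA(hazards) || any(hazards <= 0)) stop("hazards must be positive per group")
  if (censor_rate < 0) stop("censor_rate must be >= 0")
  mutation_rates <- as.matrix(as.data.frame(mutation_rates))[, TMM_LABELS,
                                                             drop = FALSE]
  if (any(mutation_rates < 0 | mutation_rates > 1))
    stop("mutation rates must be in [0,1]")
  cnv_burden_mean <- cnv_burden_mean[TMM_LABELS]
  if (anyNA(cnv_burden_mean) || any(cnv_burden_mean < 0 | cnv_burden_mean > 1))
    stop("cnv_burden_mean must be in [0,1] per group")
  structure(list(n_samples = as.integer(n_samples), mixing = mixing,
                 n_genes = as.integer(n_genes),
                 n_signature_genes = as.integer(n_signature_genes),
                 effect = effect, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, hazards = hazards,
                 censor_rate = censor_rate, mutation_rates = mutation_rates,
                 cnv_burden_mean = cnv_burden_mean,
                 n_cohorts = as.integer(n_cohorts),
                 n_segments = as.integer(n_segments),
                 stage_probs = stage_probs, seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Default driver-panel mutation rates
#'
#' KRAS strongly enriched in ALT and TP53 in NDTMM, with a low background
#' across a small panel of telomere-relevant drivers.
#' @return Gene x group probability matrix.
#' @export
default_mutation_rates <- function() {
  genes <- c("KRAS", "TP53", "ATRX", "DAXX", "TERT", "BRAF", "EGFR", "PTEN")
  m <- matrix(0.05, length(genes), 4,
              dimnames = list(genes, TMM_LABELS))
  m["KRAS", "ALT"] <- 0.6
  m["TP53", "NDTMM"] <- 0.5
  m["ATRX", "ALT"] <- 0.35
  m["DAXX", "ALT"] <- 0.2
  m["TERT", "TEL"] <- 0.3
  m["TERT", "TEL+ALT"] <- 0.25
  m
}

## deterministic per-component substream seeds (kept < 2^31)
derive_seed <- function(seed, component) {
  offsets <- c(expression = 11L, survival = 23L, mutations = 37L,
               cnv = 53L, stage = 71L, cohorts = 89L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[component]]
}

#' Generate planted-signature expression
#'
#' Baseline `Normal(baseline_mean, noise_sd)` per gene per sample; the TEL
#' signature genes gain `+effect` in TEL and TEL+ALT samples, the ALT
#' signature genes gain `+effect` in ALT and TEL+ALT samples; NDTMM samples
#' are unshifted. Labels are drawn from `mixing`. Deterministic under the
#' config seed.
#'
#' @param config A [cohort_config()].
#' @return List: `expression` ([expression_matrix()]), `truth_labels`
#'   (named character vector), `gene_sets` (the planted TEL and ALT sets).
#' @export
generate_expression <- function(config) {
  old <- local_seed(derive_seed(config$seed, "expression"))
  on.exit(restore_seed(old))
  n <- config$n_samples
  g <- config$n_genes
  k <- config$n_signature_genes
  sample_ids <- sprintf("S%04d", seq_len(n))
  gene_ids <- sprintf("G%05d", seq_len(g))
  tel_set <- gene_ids[seq_len(k)]
  alt_set <- gene_ids[k + seq_len(k)]
  labels <- sample(TMM_LABELS, n, replace = TRUE, prob = config$mixing)
  x <- matrix(stats::rnorm(g * n, config$baseline_mean, config$noise_sd),
              g, n, dimnames = list(gene_ids, sample_ids))
  tel_on <- labels %in% c("TEL", "TEL+ALT")
  alt_on <- labels %in% c("ALT", "TEL+ALT")
  x[seq_len(k), tel_on] <- x[seq_len(k), tel_on] + config$effect
  x[k + seq_len(k), alt_on] <- x[k + seq_len(k), alt_on] + config$effect
  co_seed <- local_seed(derive_seed(config$seed, "cohorts"))
  cohorts <- sample(sprintf("COH%02d", seq_len(config$n_cohorts)), n,
                    replace = TRUE)
  restore_seed(co_seed)
  list(expression = expression_matrix(x, stats::setNames(cohorts, sample_ids)),
       truth_labels = stats::setNames(labels, sample_ids),
       gene_sets = gene_set_collection(
         list(TEL = tel_set, ALT = alt_set),
         c(TEL = "planted telomerase signature",
           ALT = "planted ALT signature")))
}

#' Generate group-linked censored survival
#'
#' Event times are exponential with the group's hazard; censoring times are
#' independent exponential with rate `censor_rate` (no censoring when 0).
#' `os_time = min(event, censor)`, `os_event = 1(event <= censor)`.
#'
#' @param truth_labels Named per-sample TMM labels.
#' @param hazards Named per-group rates (> 0).
#' @param censor_rate Censoring rate (>= 0).
#' @param seed RNG seed.
#' @param cohort_of Optional named cohort map (defaults to `"ALL"`).
#' @param stage Optional named stage vector.
#' @return A `ClinicalTable`.
#' @export
generate_survival <- function(truth_labels, hazards, censor_rate, seed,
                              cohort_of = NULL, stage = NULL) {
  if (any(hazards <= 0)) stop("hazards must be positive")
  if (censor_rate < 0) stop("censor_rate must be >= 0")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n <- length(truth_labels)
  ev <- stats::rexp(n, rate = hazards[truth_labels])
  cs <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate) else rep(Inf, n)
  ids <- names(truth_labels)
  df <- data.frame(sample_id = ids,
                   os_time = pmin(ev, cs),
                   os_event = as.numeric(ev <= cs),
                   stage = if (is.null(stage)) NA_character_ else stage[ids],
                   cohort = if (is.null(cohort_of)) "ALL" else cohort_of[ids],
                   stringsAsFactors = FALSE)
  validate_clinical(df)
}

generate_mutations <- function(truth_labels, rates, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  recs <- list()
  for (g in rownames(rates)) {
    p <- rates[g, truth_labels]
    hit <- stats::runif(length(p)) < p
    if (any(hit))
      recs[[g]] <- data.frame(
        sample_id = names(truth_labels)[hit], gene_id = g,
        variant_classification = sample(
          c("Missense_Mutation", "Nonsense_Mutation", "Silent"),
          sum(hit), replace = TRUE, prob = c(0.7, 0.2, 0.1)),
        stringsAsFactors = FALSE)
  }
  df <- if (length(recs)) do.call(rbind, c(recs, make.row.names = FALSE))
        else data.frame(sample_id = character(0), gene_id = character(0),
                        variant_classification = character(0))
  validate_mutations(df)
}

generate_cnv <- function(truth_labels, burden_mean, seed, n_segments = 50L,
                         concentration = 30) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  seg_len <- 2e6
  recs <- lapply(names(truth_labels), function(id) {
    mu <- burden_mean[[truth_labels[[id]]]]
    f <- if (mu == 0) 0 else if (mu == 1) 1 else
      stats::rbeta(1, mu * concentration, (1 - mu) * concentration)
    altered <- stats::runif(n_segments) < f
    seg_mean <- ifelse(altered,
                       sample(c(-1, 1), n_segments, TRUE) *
                         stats::rnorm(n_segments, 0.8, 0.1),
                       stats::rnorm(n_segments, 0, 0.04))
    starts <- (seq_len(n_segments) - 1L) * seg_len + 1
    data.frame(sample_id = id,
               chromosome = as.character(1 + (seq_len(n_segments) - 1L) %/% 5L),
               start = starts, end = starts + seg_len - 1,
               seg_mean = seg_mean, stringsAsFactors = FALSE)
  })
  validate_seg(do.call(rbind, recs))
}

generate_stage <- function(truth_labels, stage_probs, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  stages <- c("I", "II", "III", "IV")
  if (is.null(stage_probs))
    stage_probs <- stats::setNames(
      rep(list(c(0.2, 0.3, 0.3, 0.2)), 4), TMM_LABELS)
  vapply(truth_labels, function(l)
    sample(stages, 1L, prob = stage_probs[[l]]), character(1))
}

#' Generate a fully joined synthetic cohort
#'
#' Composes expression, survival, driver-panel mutations, copy-number
#' segments and stage from one [cohort_config()], with per-component RNG
#' substreams derived from the single seed.
#'
#' @param config A [cohort_config()].
#' @return A list of class `SyntheticCohort`: `expression`, `truth_labels`,
#'   `clinical`, `mutations`, `cnv`, `gene_sets`, `config`.
#' @export
generate_cohort <- function(config) {
  ex <- generate_expression(config)
  stage <- generate_stage(ex$truth_labels, config$stage_probs,
                          derive_seed(config$seed, "stage"))
  clinical <- generate_survival(ex$truth_labels, config$hazards,
                                config$censor_rate,
                                derive_seed(config$seed, "survival"),
                                cohort_of = ex$expression$cohort_of,
                                stage = stage)
  mutations <- generate_mutations(ex$truth_labels, config$mutation_rates,
                                  derive_seed(config$seed, "mutations"))
  cnv <- generate_cnv(ex$truth_labels, config$cnv_burden_mean,
                      derive_seed(config$seed, "cnv"),
                      n_segments = config$n_segments)
  out <- list(expression = ex$expression, truth_labels = ex$truth_labels,
              clinical = clinical, mutations = mutations, cnv = cnv,
              gene_sets = ex$gene_sets, config = config)
  class(out) <- "SyntheticCohort"
  out
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d samples, %d genes, %d cohort(s)\n",
              x$config$n_samples, x$config$n_genes, x$config$n_cohorts))
  print(round(prop.table(table(x$truth_labels))[TMM_LABELS], 3))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `expression.tsv`, `gene_sets.gmt`, `clinical.tsv`,
#' `mutations.maf.tsv`, `cnv.seg.tsv`, `truth_labels.tsv` and a
#' `manifest.json` recording the configuration and seed.
#'
#' @param cohort A `SyntheticCohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_tsv(data.frame(Tumor_Sample_Barcode = cohort$mutations$sample_id,
                       Hugo_Symbol = cohort$mutations$gene_id,
                       Variant_Classification =
                         cohort$mutations$variant_classification),
            file.path(dir, "mutations.maf.tsv"))
  write_tsv(data.frame(Sample = cohort$cnv$sample_id,
                       Chromosome = cohort$cnv$chromosome,
                       Start = cohort$cnv$start, End = cohort$cnv$end,
                       `Seg.Mean` = cohort$cnv$seg_mean, check.names = FALSE),
            file.path(dir, "cnv.seg.tsv"))
  write_tsv(data.frame(sample_id = names(cohort$truth_labels),
                       label = unname(cohort$truth_labels)),
            file.path(dir, "truth_labels.tsv"))
  cfg <- cohort$config
  cfg$mutation_rates <- as.data.frame(cfg$mutation_rates)
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
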