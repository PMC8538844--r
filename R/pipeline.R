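## Configuration-driven orchestration: simulate/load -> score -> classify
## -> survival -> DEG -> ORA -> burden/contingency/correlation, with a
## manifest and schema-checked TSV/JSON artifacts per stage.

CONFIG_KEYS <- c("inputs", "simulate", "enrichment", "classifier",
                 "outcome_split", "thresholds", "out_dir", "seed")

#' Validate a pipeline run configuration
#'
#' The configuration is a JSON file (keys below); unknown keys are
#' rejected and defaults are filled in. Exactly one of `simulate` (a
#' [cohort_config()] block) or `inputs` (paths: `expression`, `gmt`,
#' `clinical`, optional `mutations`, `cnv`, `annotation_gmt`) must be
#' given.
#'
#' @param path Path to a JSON config file.
#' @return A validated list of class `RunConfig`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$simulate) == is.null(raw$inputs))
    stop("exactly one of 'simulate' or 'inputs' must be given")
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)

  enr <- raw$enrichment
  if (!is.null(enr$alpha) && (!is.numeric(enr$alpha) || enr$alpha < 0))
    stop("enrichment.alpha: must be a non-negative number")
  ep <- enrichment_params(
    alpha = enr$alpha %||% 0.25,
    kcdf = enr$kcdf %||% FALSE,
    B = enr$B %||% 0L,
    seed = seed)

  tau <- raw$classifier$tau %||% 0
  if (!is.numeric(tau) || !is.finite(tau))
    stop("classifier.tau: must be a finite number")

  thr <- raw$thresholds
  thresholds <- list(
    fdr = thr$fdr %||% 0.05,
    seg_mean_threshold = thr$seg_mean_threshold %||% 0.2,
    nonsyn_classes = thr$nonsyn_classes %||% NONSYN_CLASSES)
  if (thresholds$fdr <= 0 || thresholds$fdr > 1)
    stop("thresholds.fdr: must be in (0, 1]")

  simulate <- NULL
  inputs <- NULL
  if (!is.null(raw$simulate)) {
    sim <- raw$simulate
    sim$seed <- sim$seed %||% seed
    if (!is.null(sim$mixing)) sim$mixing <- unlist(sim$mixing)
    if (!is.null(sim$hazards)) sim$hazards <- unlist(sim$hazards)
    if (!is.null(sim$cnv_burden_mean))
      sim$cnv_burden_mean <- unlist(sim$cnv_burden_mean)
    simulate <- do.call(cohort_config, sim)
  } else {
    inputs <- raw$inputs
    req <- c("expression", "gmt", "clinical")
    missing <- setdiff(req, names(inputs))
    if (length(missing))
      stop("inputs missing required path(s): ", paste(missing, collapse = ", "))
    for (k in names(inputs))
      if (!file.exists(inputs[[k]]))
        stop("inputs.", k, ": file not found: ", inputs[[k]])
  }
  structure(list(simulate = simulate, inputs = inputs,
                 enrichment = ep, tau = tau,
                 outcome_split = match.arg(raw$outcome_split %||% "median_event",
                                           c("median_event", "event")),
                 thresholds = thresholds,
                 out_dir = raw$out_dir %||% "tmm_run",
                 seed = seed),
            class = "RunConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full TMM analysis pipeline
#'
#' Stages: simulate (or load inputs) -> enrichment scoring -> cohort
#' z-scoring -> TMM classification -> label frequencies -> stratified
#' survival -> good/poor outcome DEG -> over-representation of the
#' significant DEGs -> mutation / copy-number burden profile ->
#' stage contingency -> signature-vs-driver correlation. Each stage writes
#' its artifact before the next starts, so a failure leaves completed
#' outputs intact; `manifest.json` records config, seed and row counts.
#'
#' @param config A `RunConfig` from [validate_config()], or a path to one.
#' @param force Overwrite an existing output directory.
#' @return The output directory, invisibly.
#' @export
run_full <- function(config, force = TRUE) {
  if (is.character(config)) config <- validate_config(config)
  out <- config$out_dir
  if (dir.exists(out) && !force)
    stop("output directory exists (use force = TRUE): ", out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("tmmpipe")),
                   seed = config$seed, stages = list())
  log_line <- function(...) message("[tmm] ", ...)

  ## stage: data
  if (!is.null(config$simulate)) {
    log_line("simulate: n = ", config$simulate$n_samples)
    cohort <- generate_cohort(config$simulate)
    em <- cohort$expression
    gsc <- cohort$gene_sets
    clinical <- cohort$clinical
    mutations <- cohort$mutations
    cnv <- cohort$cnv
    annotation <- gsc
    write_tsv(data.frame(sample_id = names(cohort$truth_labels),
                         label = unname(cohort$truth_labels)),
              file.path(out, "truth_labels.tsv"))
    sim_cfg <- cohort$config
    sim_cfg$mutation_rates <- as.data.frame(sim_cfg$mutation_rates)
    manifest$config <- unclass(sim_cfg)
  } else {
    inp <- config$inputs
    log_line("load inputs")
    em0 <- read_expression(inp$expression)
    gsc <- read_gmt(inp$gmt)
    clinical <- read_clinical(inp$clinical)
    co <- stats::setNames(clinical$cohort, trimws(clinical$sample_id))
    keep <- intersect(colnames(em0$values), names(co))
    dropped <- ncol(em0$values) - length(keep)
    if (dropped > 0) log_line(dropped, " expression sample(s) without clinical record dropped")
    if (length(keep) < 1L) stop("no samples shared between expression and clinical")
    em <- expression_matrix(em0$values[, keep, drop = FALSE], co[keep])
    mutations <- if (!is.null(inp$mutations)) read_maf_lite(inp$mutations) else NULL
    cnv <- if (!is.null(inp$cnv)) read_seg(inp$cnv) else NULL
    annotation <- if (!is.null(inp$annotation_gmt)) read_gmt(inp$annotation_gmt) else gsc
    manifest$config <- list(inputs = inp)
  }
  manifest$stages$data <- list(n_samples = ncol(em$values),
                               n_genes = nrow(em$values))

  ## stage: enrichment + z-scoring
  log_line("score: ", length(gsc$sets), " set(s)")
  sc <- score_matrix(em, gsc, config$enrichment)
  write_scores(sc, file.path(out, "scores.tsv"))
  zs <- cohort_zscore(sc)
  manifest$stages$score <- list(n_sets = nrow(sc$scores))

  ## stage: classification
  tel_name <- if ("TEL" %in% rownames(zs$scores)) "TEL" else rownames(zs$scores)[1L]
  alt_name <- if ("ALT" %in% rownames(zs$scores)) "ALT" else rownames(zs$scores)[2L]
  labels <- classify_cohorts(zs, tel_name, alt_name, config$tau)
  write_tsv(labels, file.path(out, "labels.tsv"))
  freqs <- rbind(tmm_frequencies(labels, "overall"),
                 tmm_frequencies(labels, "cohort"))
  write_tsv(freqs, file.path(out, "frequencies.tsv"))
  manifest$stages$classify <- list(n_labeled = nrow(labels))

  ## stage: survival
  strat <- stratified_survival(clinical, labels)
  write_tsv(km_tidy(strat$curves), file.path(out, "km.tsv"))
  jsonlite::write_json(list(statistic = strat$logrank$statistic,
                            df = strat$logrank$df,
                            p_value = strat$logrank$p_value,
                            observed = as.list(strat$logrank$observed),
                            expected = as.list(strat$logrank$expected)),
                       file.path(out, "logrank.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$stages$survival <- list(logrank_p = strat$logrank$p_value)

  ## stage: DEG (good vs poor outcome) + ORA of significant genes
  split <- outcome_split(clinical, config$outcome_split)
  good <- intersect(split$sample_id[split$outcome %in% "good"], colnames(em$values))
  poor <- intersect(split$sample_id[split$outcome %in% "poor"], colnames(em$values))
  if (length(good) >= 2L && length(poor) >= 2L) {
    deg <- moderated_t_deg(em, good, poor)
    write_tsv(deg, file.path(out, "deg.tsv"))
    sig <- deg$gene_id[deg$q_value < config$thresholds$fdr]
    manifest$stages$deg <- list(n_good = length(good), n_poor = length(poor),
                                n_significant = length(sig),
                                d0 = attr(deg, "d0"), s0_sq = attr(deg, "s0_sq"))
    if (length(sig) >= 1L) {
      ora <- hypergeom_ora(sig, rownames(em$values), annotation)
      write_tsv(ora, file.path(out, "ora.tsv"))
      manifest$stages$ora <- list(n_sets = nrow(ora))
    } else log_line("ora: no significant DEGs, stage skipped")
  } else {
    log_line("deg: fewer than 2 samples per outcome arm, stage skipped")
  }

  ## stage: molecular burden
  if (!is.null(mutations) || !is.null(cnv)) {
    ids <- labels$sample_id
    burden <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
    if (!is.null(mutations)) {
      counts <- tmb(mutations, config$thresholds$nonsyn_classes, all_samples = ids)
      total <- tmb(mutations, MAF_VOCABULARY, all_samples = ids)
      burden$tmb <- counts[ids]
      burden$tmb_total <- total[ids]
    }
    if (!is.null(cnv)) {
      fga <- cnv_burden(cnv, config$thresholds$seg_mean_threshold)
      burden$fga <- unname(fga[burden$sample_id])
    }
    write_tsv(burden, file.path(out, "burden.tsv"))
    manifest$stages$burden <- list(n_samples = nrow(burden))
    if (!is.null(mutations) &&
        all(c("ALT", "NDTMM") %in% labels$label)) {
      mfc <- mutation_frequency_compare(mutations, labels, "ALT", "NDTMM")
      write_tsv(mfc, file.path(out, "mutation_freq_alt_vs_ndtmm.tsv"))
    }
  } else log_line("burden: no mutation/cnv inputs, stage skipped")

  ## stage: stage contingency
  stage <- stats::setNames(clinical$stage, trimws(clinical$sample_id))
  if (sum(!is.na(stage)) > 0 &&
      length(unique(stats::na.omit(stage[labels$sample_id]))) >= 2L &&
      length(unique(labels$label)) >= 2L) {
    ct <- contingency_chisq(labels, stage)
    ctab <- as.data.frame.matrix(ct$table)
    ctab <- data.frame(label = rownames(ctab), ctab, check.names = FALSE)
    write_tsv(ctab, file.path(out, "contingency.tsv"))
    manifest$stages$contingency <- list(statistic = ct$statistic,
                                        df = ct$df, p_value = ct$p_value)
  }

  ## stage: signature-vs-panel correlation (first set vs second set genes)
  sets_in <- lapply(gsc$sets, intersect, rownames(em$values))
  if (length(sets_in) >= 2L &&
      length(sets_in[[1L]]) >= 1L && length(sets_in[[2L]]) >= 1L) {
    cm <- correlation_matrix(em, sets_in[[1L]], sets_in[[2L]])
    cdf <- data.frame(gene_a = rownames(cm)[row(cm)],
                      gene_b = colnames(cm)[col(cm)],
                      r = as.numeric(cm), stringsAsFactors = FALSE)
    write_tsv(cdf, file.path(out, "correlations.tsv"))
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  check_output_schemas(out)
  log_line("done: ", out)
  invisible(out)
}

write_scores <- function(em_scores, path) {
  df <- data.frame(set_name = rownames(em_scores$scores), em_scores$scores,
                   check.names = FALSE)
  write_tsv(df, path)
}

OUTPUT_SCHEMAS <- list(
  "labels.tsv" = c("sample_id", "label", "z_tel", "z_alt", "cohort"),
  "frequencies.tsv" = c("stratum", "label", "n", "proportion"),
  "km.tsv" = c("stratum", "time", "at_risk", "events", "survival", "se"),
  "deg.tsv" = c("gene_id", "log_fc", "t_mod", "p_value", "q_value", "s2_post"),
  "ora.tsv" = c("set_name", "overlap", "set_size", "query_size",
                "universe_size", "p_value", "q_value"),
  "burden.tsv" = c("sample_id"))

## every emitted file must carry its declared columns
check_output_schemas <- function(dir) {
  for (f in names(OUTPUT_SCHEMAS)) {
    p <- file.path(dir, f)
    if (!file.exists(p)) next
    hdr <- strsplit(readLines(p, n = 1L), "\t", fixed = TRUE)[[1L]]
    missing <- setdiff(OUTPUT_SCHEMAS[[f]], hdr)
    if (length(missing))
      stop("output ", f, " missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
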