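## Four-way TMM classification from telomerase / ALT enrichment z-scores.

#' Canonical TMM label set
#' @export
TMM_LABELS <- c("TEL+ALT", "ALT", "TEL", "NDTMM")

#' Classify one sample from its two activity z-scores
#'
#' Threshold rule on within-cohort z-scores (inclusive at the boundary):
#' `TEL+ALT` if both activities >= `tau`; `TEL` if only telomerase; `ALT`
#' if only ALT; `NDTMM` when both fall below `tau`.
#'
#' @param z_tel,z_alt Finite z-scores of the telomerase and ALT signatures.
#' @param tau Activity threshold (default 0 = cohort-median split).
#' @return One of [TMM_LABELS]. Vectorized over `z_tel`/`z_alt`.
#' @export
classify_sample <- function(z_tel, z_alt, tau = 0) {
  if (any(!is.finite(z_tel)) || any(!is.finite(z_alt)))
    stop("non-finite activity score")
  ifelse(z_tel >= tau,
         ifelse(z_alt >= tau, "TEL+ALT", "TEL"),
         ifelse(z_alt >= tau, "ALT", "NDTMM"))
}

#' Classify every sample of a cohort-z enrichment matrix
#'
#' @param em_z An `EnrichmentMatrix` with `scale = "cohort_z"` (from
#'   [cohort_zscore()]); raw-scale input is rejected.
#' @param tel_set,alt_set Row names of the telomerase and ALT signatures.
#' @param tau Activity threshold passed to [classify_sample()].
#' @return A `data.frame` of class `TMMLabeling` with columns `sample_id`,
#'   `label`, `z_tel`, `z_alt`, `cohort`.
#' @export
classify_cohorts <- function(em_z, tel_set = "TEL", alt_set = "ALT", tau = 0) {
  if (!identical(em_z$scale, "cohort_z"))
    stop("classifier requires cohort-z-scored input (got scale '",
         em_z$scale, "'); run cohort_zscore() first")
  missing <- setdiff(c(tel_set, alt_set), rownames(em_z$scores))
  if (length(missing))
    stop("set(s) not in enrichment matrix: ", paste(missing, collapse = ", "))
  z_tel <- em_z$scores[tel_set, ]
  z_alt <- em_z$scores[alt_set, ]
  out <- data.frame(sample_id = colnames(em_z$scores),
                    label = classify_sample(z_tel, z_alt, tau),
                    z_tel = unname(z_tel), z_alt = unname(z_alt),
                    cohort = unname(em_z$cohort_of),
                    stringsAsFactors = FALSE)
  class(out) <- c("TMMLabeling", "data.frame")
  out
}

#' TMM label frequencies, overall or per cohort
#'
#' @param labels A `TMMLabeling` table from [classify_cohorts()].
#' @param by `"overall"` or `"cohort"`.
#' @return A `data.frame` with columns `stratum`, `label`, `n`,
#'   `proportion`; proportions sum to 1 within each stratum.
#' @export
tmm_frequencies <- function(labels, by = c("overall", "cohort")) {
  by <- match.arg(by)
  if (nrow(labels) == 0L) stop("empty label table")
  strata <- if (by == "overall") rep("overall", nrow(labels)) else labels$cohort
  out <- do.call(rbind, lapply(split(labels$label, strata), function(lv) {
    n <- table(factor(lv, levels = TMM_LABELS))
    data.frame(label = names(n), n = as.integer(n),
               proportion = as.numeric(n) / length(lv),
               stringsAsFactors = FALSE)
  }))
  out <- data.frame(stratum = rep(names(split(labels$label, strata)),
                                  each = length(TMM_LABELS)),
                    out, row.names = NULL, stringsAsFactors = FALSE)
  out
}
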