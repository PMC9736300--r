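#' Estimate IRSB from sex-specific case counts
#'
#' IRSB can be estimated without population sizes from the case-count ratio
#' corrected by the background population sex ratio
#' (female population / male population):
#' `log2(cases_m / cases_f * sex_ratio)`.
#'
#' @param cases_m,cases_f Male and female case counts.
#' @param sex_ratio Background population sex ratio (female/male), default 1.
#' @return Estimated IRSB; `NA` where either count is zero or missing.
#' @export
estimate_irsb <- function(cases_m, cases_f, sex_ratio = 1) {
  a <- recycle_args(cases_m = cases_m, cases_f = cases_f, sex_ratio = sex_ratio)
  ok <- !is.na(a$cases_m) & !is.na(a$cases_f) & a$cases_m > 0 & a$cases_f > 0 &
    !is.na(a$sex_ratio) & a$sex_ratio > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- log2(a$cases_m[ok] / a$cases_f[ok] * a$sex_ratio[ok])
  out
}

#' Estimate the female incidence rate
#'
#' `IR_F = IR_TOTAL * (cases_f / cases_total) * (1 + 1/sex_ratio)`.
#' Exact when the sex ratio is the true one (algebraic identity).
#'
#' @param ir_total Total incidence rate.
#' @param cases_f,cases_total Female and total case counts.
#' @param sex_ratio Background population sex ratio (female/male), default 1.
#' @return Estimated female rate; `NA` where `cases_total` is zero or missing.
#' @export
estimate_ir_f <- function(ir_total, cases_f, cases_total, sex_ratio = 1) {
  a <- recycle_args(ir_total = ir_total, cases_f = cases_f,
                    cases_total = cases_total, sex_ratio = sex_ratio)
  ok <- !is.na(a$ir_total) & !is.na(a$cases_f) & !is.na(a$cases_total) &
    a$cases_total > 0 & !is.na(a$sex_ratio) & a$sex_ratio > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- a$ir_total[ok] * (a$cases_f[ok] / a$cases_total[ok]) *
    (1 + 1 / a$sex_ratio[ok])
  out
}

#' Estimate the male incidence rate
#'
#' `IR_M = IR_TOTAL * (cases_m / cases_total) * (1 + sex_ratio)`.
#'
#' @inheritParams estimate_ir_f
#' @param cases_m Male case count.
#' @return Estimated male rate; `NA` where `cases_total` is zero or missing.
#' @export
estimate_ir_m <- function(ir_total, cases_m, cases_total, sex_ratio = 1) {
  a <- recycle_args(ir_total = ir_total, cases_m = cases_m,
                    cases_total = cases_total, sex_ratio = sex_ratio)
  ok <- !is.na(a$ir_total) & !is.na(a$cases_m) & !is.na(a$cases_total) &
    a$cases_total > 0 & !is.na(a$sex_ratio) & a$sex_ratio > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- a$ir_total[ok] * (a$cases_m[ok] / a$cases_total[ok]) *
    (1 + a$sex_ratio[ok])
  out
}

#' Estimate the total incidence rate
#'
#' Population-weighted mean of the sex-specific rates:
#' `IR_TOTAL = IR_M / (1 + sex_ratio) + IR_F * sex_ratio / (1 + sex_ratio)`.
#' Always lies between the two input rates.
#'
#' @param ir_m,ir_f Male and female incidence rates.
#' @param sex_ratio Background population sex ratio (female/male), default 1.
#' @return Estimated total rate.
#' @export
estimate_ir_total <- function(ir_m, ir_f, sex_ratio = 1) {
  a <- recycle_args(ir_m = ir_m, ir_f = ir_f, sex_ratio = sex_ratio)
  ok <- !is.na(a$ir_m) & !is.na(a$ir_f) & !is.na(a$sex_ratio) & a$sex_ratio > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- a$ir_m[ok] / (1 + a$sex_ratio[ok]) +
    a$ir_f[ok] * a$sex_ratio[ok] / (1 + a$sex_ratio[ok])
  out
}

# Estimator inputs per measure (counts feed IRSB; rates + counts feed the
# sex-specific rates; the sex-specific rates feed the total).
measure_inputs_present <- function(records, measure) {
  switch(measure,
    irsb = !is.na(records$cases_m) & !is.na(records$cases_f),
    ir_f = ,
    ir_m = !is.na(records$ir_total) & !is.na(records$cases_m) &
      !is.na(records$cases_f),
    ir_total = !is.na(records$ir_m) & !is.na(records$ir_f),
    stop("unknown measure: ", measure)
  )
}

#' Partition records by measure availability
#'
#' For one measure, records fall into four disjoint groups: (1) the measure's
#' value is reported but its estimator inputs are not; (2) both the value and
#' the inputs are reported; (3) only the inputs are reported; (4) neither.
#' Group 2 supports estimator validation; group 3 is where estimation adds
#' data.
#'
#' @param records Study-record data frame.
#' @param measure One of `"irsb"`, `"ir_f"`, `"ir_m"`, `"ir_total"`.
#' @return Object of class `availability_partition`: the four id lists and
#'   their sizes.
#' @export
partition_by_availability <- function(records,
                                      measure = c("irsb", "ir_f", "ir_m", "ir_total")) {
  measure <- match.arg(measure)
  records <- validate_records(records, allow_extra = TRUE)
  has_value <- !is.na(records[[measure]])
  has_inputs <- measure_inputs_present(records, measure)
  groups <- list(
    group1 = records$study_id[has_value & !has_inputs],
    group2 = records$study_id[has_value & has_inputs],
    group3 = records$study_id[!has_value & has_inputs],
    group4 = records$study_id[!has_value & !has_inputs]
  )
  structure(
    list(measure = measure, groups = groups,
         counts = vapply(groups, length, integer(1)), n = nrow(records)),
    class = "availability_partition"
  )
}

#' @export
print.availability_partition <- function(x, ...) {
  cat("Availability partition for measure '", x$measure, "' (n = ", x$n, ")\n",
      sep = "")
  lab <- c("value only", "value + inputs", "inputs only", "neither")
  for (i in 1:4)
    cat(sprintf("  group%d (%s): %d\n", i, lab[i], x$counts[i]))
  invisible(x)
}

estimate_measure <- function(records, measure, variant) {
  sr <- switch(variant,
    ratio_1_1 = rep(1, nrow(records)),
    ratio_external = records$sex_ratio,
    stop("unknown estimator variant: ", variant)
  )
  if (variant == "ratio_external" && anyNA(sr))
    stop("ratio_external estimator requested but `sex_ratio` is missing for ",
         sum(is.na(sr)), " record(s)")
  switch(measure,
    irsb = estimate_irsb(records$cases_m, records$cases_f, sr),
    ir_f = estimate_ir_f(records$ir_total, records$cases_f, records$cases_total, sr),
    ir_m = estimate_ir_m(records$ir_total, records$cases_m, records$cases_total, sr),
    ir_total = estimate_ir_total(records$ir_m, records$ir_f, sr)
  )
}

#' Validate an estimator against directly reported values
#'
#' On the group-2 records of a measure (those reporting both the measure and
#' its estimator inputs) the estimate is compared with the reported value in
#' two ways: Pearson's correlation with a one-sided t-test (alternative:
#' positive correlation, df = n - 2), and an ordinary least-squares fit
#' `actual = beta * estimate + alpha` with its r-squared.
#'
#' @param records Study-record data frame.
#' @param measure Measure to validate.
#' @param variant `"ratio_1_1"` (sex ratio fixed at 1) or `"ratio_external"`
#'   (each record's own `sex_ratio`).
#' @return Object of class `validation_report`.
#' @export
validate_estimators <- function(records,
                                measure = c("irsb", "ir_f", "ir_m", "ir_total"),
                                variant = c("ratio_1_1", "ratio_external")) {
  measure <- match.arg(measure)
  variant <- match.arg(variant)
  records <- validate_records(records, allow_extra = TRUE)
  part <- partition_by_availability(records, measure)
  g2 <- records[records$study_id %in% part$groups$group2, , drop = FALSE]
  est <- estimate_measure(g2, measure, variant)
  actual <- g2[[measure]]
  keep <- !is.na(est) & !is.na(actual)
  est <- est[keep]; actual <- actual[keep]
  n <- length(est)
  if (n < 3L)
    stop("estimator validation needs >= 3 group-2 records with a defined ",
         "estimate; got ", n)
  if (sd(est) == 0 || sd(actual) == 0)
    stop("constant vector: correlation between actual and estimated '",
         measure, "' is undefined")
  r <- cor(est, actual)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  fit <- lm(actual ~ est)
  structure(
    list(measure = measure, estimator_variant = variant,
         pearson_r = r, p_one_sided = pt(tt, df = n - 2, lower.tail = FALSE),
         beta = unname(coef(fit)[2L]), alpha = unname(coef(fit)[1L]),
         r_squared = r^2, n = n),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Estimator validation: %s [%s]\n  n = %d, Pearson r = %.4f (one-sided p = %.3g)\n  OLS actual ~ estimate: beta = %.4f, alpha = %.4f, r^2 = %.4f\n",
    x$measure, x$estimator_variant, x$n, x$pearson_r, x$p_one_sided,
    x$beta, x$alpha, x$r_squared))
  invisible(x)
}

#' Fill missing measures from reported quantities
#'
#' For every measure, group-3 records (estimator inputs reported, value not)
#' get the estimated value with provenance `estimated`; reported values are
#' never overwritten, and estimates are never chained (only originally
#' reported quantities feed the estimators).
#'
#' @param records Study-record data frame, scale-normalised.
#' @param variant Estimator variant; the default `"ratio_1_1"` uses a 1:1
#'   population sex ratio.
#' @return `records` with completed measure columns and `prov_*` provenance
#'   columns (`given` / `estimated` / `missing`).
#' @export
complete_measures <- function(records, variant = c("ratio_1_1", "ratio_external")) {
  variant <- match.arg(variant)
  records <- validate_records(records, allow_extra = TRUE)
  records <- ensure_provenance(records)
  if (nrow(records) == 0L) return(records)
  given <- records # estimators read only the original, reported quantities
  for (m in .MEASURES) {
    fill <- is.na(given[[m]]) & measure_inputs_present(given, m)
    if (!any(fill)) next
    est <- estimate_measure(given[fill, , drop = FALSE], m, variant)
    got <- !is.na(est)
    idx <- which(fill)[got]
    records[[m]][idx] <- est[got]
    records[[paste0("prov_", m)]][idx] <- "estimated"
  }
  records
}
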