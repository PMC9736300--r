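#' Crude incidence rate from cases and population
#'
#' Computes `cases / population`, rescaled to cases per year per 1e5 persons
#' (the scale every downstream function assumes).
#'
#' @param cases Non-negative case count (vectorised).
#' @param population Positive person count of the population at risk.
#' @param scale Denominator of the returned rate; default `1e5` persons.
#' @return Incidence rate, cases per year per `scale` persons.
#' @examples
#' compute_ir(50, 1e6) # 5 per 1e5
#' @export
compute_ir <- function(cases, population, scale = 1e5) {
  stopifnot(is.numeric(cases), is.numeric(population), is.numeric(scale))
  if (any(population <= 0, na.rm = TRUE))
    stop("`population` must be strictly positive")
  if (any(cases < 0, na.rm = TRUE))
    stop("`cases` must be non-negative")
  cases / population * scale
}

#' Incidence rate sex bias (IRSB)
#'
#' IRSB = log2(IR_male / IR_female). Zero means no bias; positive values mean
#' a higher incidence rate in males. Non-positive rates leave the measure
#' undefined (`NA`), never +/-Inf.
#'
#' @param ir_m,ir_f Male and female incidence rates on a common scale.
#' @return log2 ratio, `NA` where either rate is missing or non-positive.
#' @examples
#' compute_irsb(10, 5) #  1: twice as frequent in males
#' compute_irsb(5, 10) # -1: twice as frequent in females
#' @export
compute_irsb <- function(ir_m, ir_f) {
  a <- recycle_args(ir_m = ir_m, ir_f = ir_f)
  ok <- !is.na(a$ir_m) & !is.na(a$ir_f) & a$ir_m > 0 & a$ir_f > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- log2(a$ir_m[ok] / a$ir_f[ok])
  out
}

#' Rescale reported rates to the canonical per-1e5 scale
#'
#' Rates reported per `rate_scale` persons are converted to per 1e5 persons;
#' counts and the (scale-free) IRSB are unchanged. Idempotent.
#'
#' @param records Study-record data frame (see [read_incidence()]).
#' @return The records with `ir_m`, `ir_f`, `ir_total` per 1e5 persons and
#'   `rate_scale` set to 1e5.
#' @export
normalize_scale <- function(records) {
  records <- validate_records(records)
  if (nrow(records) == 0L) return(records)
  if (anyNA(records$rate_scale))
    stop("`rate_scale` is missing for ",
         sum(is.na(records$rate_scale)), " record(s)")
  if (any(records$rate_scale <= 0))
    stop("`rate_scale` must be strictly positive")
  f <- 1e5 / records$rate_scale
  for (col in c("ir_m", "ir_f", "ir_total"))
    records[[col]] <- records[[col]] * f
  records$rate_scale <- rep(1e5, nrow(records))
  records
}

#' Eligibility filtering of study records
#'
#' Applies the curation rules: studies must be population-based and use
#' clinical diagnostic criteria; at least `min_cases` total cases (evaluated
#' only where a total count is known or derivable); sex-specific tissues are
#' excluded; and each autoimmune disease must retain records from at least
#' `min_countries` distinct countries (cancers, coming from registries, are
#' exempt from the country floor).
#'
#' @param records Study-record data frame.
#' @param min_cases Minimum total case count, default 25.
#' @param min_countries Minimum distinct countries per AID, default 3.
#' @param excluded_tissues Character vector of tissues to drop (e.g.
#'   sex-specific tissues).
#' @param verbose Log dropped-record counts per rule to stderr.
#' @return The surviving subset of `records` (possibly empty).
#' @export
filter_eligible <- function(records, min_cases = 25, min_countries = 3,
                            excluded_tissues = character(), verbose = FALSE) {
  records <- validate_records(records)
  if (nrow(records) == 0L) return(records)
  note <- function(rule, n) {
    if (verbose && n > 0) message("filter_eligible: dropped ", n, " record(s): ", rule)
  }

  keep <- records$population_based & records$clinical_criteria
  keep[is.na(keep)] <- FALSE
  note("not population-based or no clinical criteria", sum(!keep))
  records <- records[keep, , drop = FALSE]

  total <- derive_total_cases(records)
  keep <- is.na(total) | total >= min_cases
  note(sprintf("fewer than %d cases", min_cases), sum(!keep))
  records <- records[keep, , drop = FALSE]

  keep <- !(records$tissue %in% excluded_tissues)
  note("excluded tissue", sum(!keep))
  records <- records[keep, , drop = FALSE]

  is_aid <- records$disease_class == "AID"
  n_countries <- tapply(records$country[is_aid], records$disease_id[is_aid],
                        function(x) length(unique(x)))
  low <- names(n_countries)[n_countries < min_countries]
  keep <- !(is_aid & records$disease_id %in% low)
  note(sprintf("AID observed in fewer than %d countries", min_countries), sum(!keep))
  records[keep, , drop = FALSE]
}

# Total cases: reported value, else sum of sex-specific counts.
derive_total_cases <- function(records) {
  total <- records$cases_total
  both <- is.na(total) & !is.na(records$cases_m) & !is.na(records$cases_f)
  total[both] <- records$cases_m[both] + records$cases_f[both]
  total
}

#' Aggregate study records into disease-country points
#'
#' For each (disease, country) group, each incidence measure is the
#' arithmetic mean over the studies in which that measure is present;
#' different measures of one point may therefore average over different
#' study subsets. A measure is missing only when missing in every study.
#' Provenance is `given` when all contributing values were given,
#' `estimated` when any was estimated, `missing` otherwise.
#'
#' @param records Study-record data frame, already scale-normalised and
#'   (optionally) estimator-completed via [complete_measures()]. Provenance
#'   columns `prov_*` are used when present.
#' @return Data frame of disease-country points: identifiers, mean measures,
#'   per-measure provenance and `n_studies`.
#' @export
aggregate_studies <- function(records) {
  records <- validate_records(records, allow_extra = TRUE)
  if (nrow(records) == 0L) stop("cannot aggregate an empty record set")
  records <- ensure_provenance(records)
  key <- interaction(records$disease_id, records$country, drop = TRUE)
  parts <- split(records, key)
  out <- do.call(rbind, lapply(parts, aggregate_measure_rows))
  rownames(out) <- NULL
  out[order(out$disease_class, out$disease_id, out$country), , drop = FALSE]
}

aggregate_measure_rows <- function(g) {
  point <- data.frame(
    disease_id = g$disease_id[1L], disease_class = g$disease_class[1L],
    tissue = g$tissue[1L], country = g$country[1L],
    stringsAsFactors = FALSE
  )
  for (m in .MEASURES) {
    v <- g[[m]]
    prov <- g[[paste0("prov_", m)]]
    have <- !is.na(v)
    point[[m]] <- if (any(have)) mean(v[have]) else NA_real_
    point[[paste0("prov_", m)]] <-
      if (!any(have)) "missing"
      else if (all(prov[have] == "given")) "given"
      else "estimated"
  }
  point$age_adjusted <- any(g$age_adjusted, na.rm = TRUE)
  point$n_studies <- nrow(g)
  point
}

#' Average yearly measures of one disease-country series
#'
#' Registry data arrive as one record per year; the point value of each
#' measure is the arithmetic mean of its yearly values (over the years in
#' which it is defined).
#'
#' @param yearly Data frame of per-year measure values with at least the
#'   measure columns `irsb`, `ir_f`, `ir_m`, `ir_total`.
#' @return One-row data frame with the averaged measures.
#' @export
aggregate_years <- function(yearly) {
  if (nrow(yearly) == 0L) stop("cannot aggregate an empty year set")
  out <- yearly[1L, intersect(names(yearly), c(
    "disease_id", "disease_class", "tissue", "country")), drop = FALSE]
  for (m in .MEASURES) {
    v <- yearly[[m]]
    out[[m]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out$n_years <- nrow(yearly)
  rownames(out) <- NULL
  out
}

ensure_provenance <- function(records) {
  for (m in .MEASURES) {
    pc <- paste0("prov_", m)
    if (is.null(records[[pc]]))
      records[[pc]] <- ifelse(is.na(records[[m]]), "missing", "given")
  }
  records
}

#' Read a study-record table
#'
#' One UTF-8 TSV row per study record, empty fields for missing values.
#' The strict reader (default) rejects unknown columns; set `lenient = TRUE`
#' to ignore them. Missing sex-specific or total case counts are derived
#' from the other two counts where possible.
#'
#' @param path Path to a tab-separated file with the canonical columns
#'   (`study_id`, `disease_id`, `disease_class`, `tissue`, `country`,
#'   `year_start`, `year_end`, `cases_m`, `cases_f`, `cases_total`,
#'   `ir_m`, `ir_f`, `ir_total`, `irsb`, `sex_ratio`, `rate_scale`,
#'   `age_adjusted`, `population_based`, `clinical_criteria`,
#'   `prior_disease_excluded`).
#' @param lenient Ignore (drop) unknown columns instead of failing.
#' @return Validated study-record data frame.
#' @export
read_incidence <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("incidence file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("", "NA"), check.names = FALSE,
                   fileEncoding = "UTF-8")
  extra <- setdiff(names(df), .RECORD_COLS)
  if (length(extra)) {
    if (!lenient)
      stop("unknown column(s) in ", path, ": ", paste(extra, collapse = ", "))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  missing_cols <- setdiff(.RECORD_COLS, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  df <- df[, .RECORD_COLS]
  for (col in c("year_start", "year_end", "cases_m", "cases_f", "cases_total"))
    df[[col]] <- as.integer(df[[col]])
  for (col in c("ir_m", "ir_f", "ir_total", "irsb", "sex_ratio", "rate_scale"))
    df[[col]] <- as.numeric(df[[col]])
  for (col in c("age_adjusted", "population_based", "clinical_criteria",
                "prior_disease_excluded"))
    df[[col]] <- as.logical(df[[col]])
  validate_records(derive_counts(df))
}

# Fill any one missing count from the other two (cases_total = m + f).
derive_counts <- function(records) {
  m <- records$cases_m; f <- records$cases_f; tot <- records$cases_total
  i <- is.na(tot) & !is.na(m) & !is.na(f); records$cases_total[i] <- m[i] + f[i]
  i <- is.na(m) & !is.na(tot) & !is.na(f); records$cases_m[i] <- tot[i] - f[i]
  i <- is.na(f) & !is.na(tot) & !is.na(m); records$cases_f[i] <- tot[i] - m[i]
  records
}

validate_records <- function(records, allow_extra = FALSE) {
  if (!is.data.frame(records)) stop("`records` must be a data frame")
  missing_cols <- setdiff(.RECORD_COLS, names(records))
  if (length(missing_cols))
    stop("record table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!allow_extra)
    records <- records[, union(.RECORD_COLS, grep("^prov_", names(records), value = TRUE)),
                       drop = FALSE]
  if (nrow(records) == 0L) return(records)
  if (!all(records$disease_class %in% c("AID", "cancer")))
    stop("`disease_class` must be 'AID' or 'cancer'")
  if (any(records$year_end < records$year_start, na.rm = TRUE))
    stop("`year_end` before `year_start`")
  both <- complete.cases(records[, c("cases_m", "cases_f", "cases_total")])
  bad <- both & records$cases_total != records$cases_m + records$cases_f
  if (any(bad))
    stop("cases_total != cases_m + cases_f for record(s): ",
         paste(records$study_id[bad], collapse = ", "))
  for (col in c("ir_m", "ir_f", "ir_total"))
    if (any(records[[col]] < 0, na.rm = TRUE)) stop("negative rate in `", col, "`")
  if (any(records$sex_ratio <= 0, na.rm = TRUE))
    stop("`sex_ratio` must be strictly positive")
  records
}

#' Write aggregated disease-country points as TSV
#'
#' @param points Data frame from [aggregate_studies()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path) {
  write.table(points, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
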