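# Independent reference implementations used as test oracles. These stay
# deliberately naive (explicit loops, direct formulas) and share no code
# with the package internals they check.

# Full O(N) walk of the GSEA running sum.
es_brute <- function(scores, hits, exponent = 1) {
  n <- length(scores)
  k <- sum(hits)
  nr <- sum(abs(scores[hits])^exponent)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hits[i]) {
      cur <- cur + if (nr > 0) abs(scores[i])^exponent / nr else 1 / k
    } else {
      cur <- cur - 1 / (n - k)
    }
    running[i] <- cur
  }
  max_p <- max(running)
  min_p <- min(running)
  if (max_p + min_p >= -1e-10) max_p else min_p
}

# Partial correlation as the correlation of simple-regression residuals.
partial_resid_oracle <- function(x, y, z) {
  cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
}

# Pearson correlation from the raw sum formula.
pearson_brute <- function(x, y) {
  n <- length(x)
  sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx <- sx + x[i]; sy <- sy + y[i]
    sxx <- sxx + x[i]^2; syy <- syy + y[i]^2; sxy <- sxy + x[i] * y[i]
  }
  (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}

# Benjamini-Hochberg step-up, written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running_min <- 1
  for (i in rev(seq_len(m))) {
    running_min <- min(running_min, p[ord[i]] * m / i)
    q[ord[i]] <- running_min
  }
  q
}

# One fully specified study record; any field can be overridden.
make_record <- function(...) {
  rec <- data.frame(
    study_id = "s1", disease_id = "d1", disease_class = "AID",
    tissue = "thyroid", country = "UK", year_start = 2010L, year_end = 2019L,
    cases_m = NA_integer_, cases_f = NA_integer_, cases_total = NA_integer_,
    ir_m = NA_real_, ir_f = NA_real_, ir_total = NA_real_, irsb = NA_real_,
    sex_ratio = NA_real_, rate_scale = 1e5,
    age_adjusted = FALSE, population_based = TRUE, clinical_criteria = TRUE,
    prior_disease_excluded = TRUE,
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  rec
}

# Several records with varying fields (vectorised make_record).
make_records <- function(...) {
  dots <- list(...)
  n <- max(vapply(dots, length, integer(1)))
  recs <- do.call(rbind, replicate(n, make_record(), simplify = FALSE))
  for (nm in names(dots)) recs[[nm]] <- rep_len(dots[[nm]], n)
  if (is.null(dots$study_id)) recs$study_id <- paste0("s", seq_len(n))
  recs
}

# Complete records derived from explicit per-sex populations and case
# counts, so every incidence identity holds exactly.
records_from_populations <- function(cases_m, cases_f, pop_m, pop_f) {
  ir_m <- cases_m / pop_m * 1e5
  ir_f <- cases_f / pop_f * 1e5
  make_records(
    cases_m = as.integer(cases_m), cases_f = as.integer(cases_f),
    cases_total = as.integer(cases_m + cases_f),
    ir_m = ir_m, ir_f = ir_f,
    ir_total = (cases_m + cases_f) / (pop_m + pop_f) * 1e5,
    irsb = log2(ir_m / ir_f),
    sex_ratio = pop_f / pop_m
  )
}
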