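test_that("compute_ir rescales cases per population to the 1e5 scale", {
  expect_equal(compute_ir(50, 1e6), 5.0)
  expect_equal(compute_ir(0, 1e5), 0.0)
  expect_equal(compute_ir(123, 456789), 123 / 456789 * 1e5)
  expect_error(compute_ir(5, 0), "positive")
  expect_error(compute_ir(-1, 100), "non-negative")
})

test_that("total rate is the population-weighted mean of the sex rates", {
  set.seed(11)
  for (i in 1:20) {
    pop_m <- runif(1, 1e5, 5e6); pop_f <- runif(1, 1e5, 5e6)
    cm <- rpois(1, 500); cf <- rpois(1, 700)
    ir_m <- compute_ir(cm, pop_m); ir_f <- compute_ir(cf, pop_f)
    expect_equal(compute_ir(cm + cf, pop_m + pop_f),
                 (ir_m * pop_m + ir_f * pop_f) / (pop_m + pop_f))
  }
})

test_that("compute_irsb follows the log2 male-over-female convention", {
  expect_equal(compute_irsb(5, 5), 0.0)
  expect_equal(compute_irsb(10, 5), 1.0)
  expect_equal(compute_irsb(5, 10), -1.0)
  # undefined (never infinite) at zero rates
  expect_true(is.na(compute_irsb(0, 5)))
  expect_true(is.na(compute_irsb(5, 0)))
  set.seed(7)
  a <- runif(50, 0.01, 100); b <- runif(50, 0.01, 100)
  expect_equal(compute_irsb(a, b), -compute_irsb(b, a))
})

test_that("normalize_scale converts reported rates to per-1e5 and is idempotent", {
  recs <- make_records(ir_f = c(2, NA, NA), ir_m = c(NA, 7, NA),
                       ir_total = c(NA, NA, 0.34),
                       rate_scale = c(1e6, 1e5, 1e4))
  out <- normalize_scale(recs)
  expect_equal(out$ir_f[1], 0.2)
  expect_equal(out$ir_m[2], 7)
  expect_equal(out$ir_total[3], 3.4)
  expect_equal(out$rate_scale, rep(1e5, 3))
  expect_equal(normalize_scale(out), out)
  recs$rate_scale[2] <- NA
  expect_error(normalize_scale(recs), "rate_scale")
})

test_that("filter_eligible applies the case, flag, tissue and country rules", {
  recs <- rbind(
    make_records(study_id = paste0("a", 1:3), disease_id = "aid1",
                 country = c("UK", "US", "DK"), cases_total = 30L),
    make_records(study_id = "a4", disease_id = "aid1", country = "SE",
                 cases_total = 24L),                      # below case floor
    make_records(study_id = "a5", disease_id = "aid2",
                 country = c("UK"), cases_total = 100L),  # AID, 1 country
    make_records(study_id = "a6", disease_id = "aid3", country = "UK",
                 cases_total = 50L, population_based = FALSE),
    make_records(study_id = "a7", disease_id = "aid4", country = c("UK"),
                 cases_total = 99L, tissue = "prostate"),
    make_records(study_id = paste0("c", 1:2), disease_id = "can1",
                 disease_class = "cancer", country = "UK", cases_total = 60L)
  )
  out <- filter_eligible(recs, excluded_tissues = "prostate")
  # aid1 keeps its three >=25-case countries; the 24-case record is gone
  expect_setequal(out$study_id, c("a1", "a2", "a3", "c1", "c2"))
  # cancers are exempt from the min_countries rule
  expect_true(all(c("c1", "c2") %in% out$study_id))
  expect_equal(nrow(filter_eligible(recs[0, ])), 0L)
})

test_that("filter_eligible output is an order-independent subset of its input", {
  set.seed(21)
  recs <- generate_incidence(n_aid = 6, n_cancer = 4, n_countries = 5,
                             seed = 21)$records
  out <- filter_eligible(recs)
  expect_true(all(out$study_id %in% recs$study_id))
  shuffled <- recs[sample(nrow(recs)), ]
  expect_setequal(filter_eligible(shuffled)$study_id, out$study_id)
})

test_that("aggregate_studies averages each measure over the studies providing it", {
  recs <- make_records(irsb = c(-1, -2))
  out <- aggregate_studies(recs)
  expect_equal(out$irsb, -1.5)
  expect_equal(out$n_studies, 2L)
  expect_equal(out$prov_irsb, "given")

  # single study: its measures pass through unchanged
  one <- make_record(irsb = 0.3, ir_f = 12, sex_ratio = 1.02)
  agg <- aggregate_studies(one)
  expect_equal(agg$irsb, 0.3)
  expect_equal(agg$ir_f, 12)
  expect_equal(agg$prov_ir_m, "missing")

  # measure present in 2 of 3 studies: mean over the available two
  recs <- make_records(irsb = c(0.4, 0.8, NA), ir_total = c(NA, NA, 9))
  out <- aggregate_studies(recs)
  expect_equal(out$irsb, 0.6)
  expect_equal(out$ir_total, 9)
  expect_equal(out$n_studies, 3L)

  # n identical measure sets aggregate to the same measure set
  recs <- make_records(study_id = paste0("s", 1:4), irsb = 0.25, ir_m = 8,
                       ir_f = 2, ir_total = 5)
  out <- aggregate_studies(recs)
  expect_equal(unlist(out[, c("irsb", "ir_m", "ir_f", "ir_total")]),
               c(irsb = 0.25, ir_m = 8, ir_f = 2, ir_total = 5))
  expect_error(aggregate_studies(make_records(irsb = 1)[0, ]), "empty")
})

test_that("aggregate_years averages yearly measures", {
  yearly <- data.frame(irsb = c(0.9, 1.1), ir_f = NA_real_, ir_m = NA_real_,
                       ir_total = c(10, 12))
  out <- aggregate_years(yearly)
  expect_equal(out$irsb, 1.0)
  expect_equal(out$ir_total, 11)
  expect_equal(out$n_years, 2L)
  expect_equal(aggregate_years(yearly[1, ])$irsb, 0.9)

  set.seed(5)
  v <- runif(20, 1, 50)
  twenty <- data.frame(irsb = NA_real_, ir_f = NA_real_, ir_m = NA_real_,
                       ir_total = v)
  expect_equal(aggregate_years(twenty)$ir_total, sum(v) / 20)
  expect_error(aggregate_years(yearly[0, ]), "empty")
})

test_that("the incidence TSV reader is strict, typed, and round-trips", {
  recs <- make_records(cases_m = c(40L, NA), cases_f = c(60L, NA),
                       ir_m = c(NA, 4), ir_f = c(NA, 8), irsb = c(NA, -1),
                       sex_ratio = c(1.04, NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_points(recs, path)
  out <- read_incidence(path)
  expect_equal(out$cases_total[1], 100L) # derived from the sex counts
  expect_equal(out$irsb[2], -1)
  expect_true(is.na(out$ir_m[1]))
  expect_type(out$population_based, "logical")

  # unknown columns are rejected unless lenient
  recs2 <- cbind(recs, surprise = 1)
  write_points(recs2, path)
  expect_error(read_incidence(path), "unknown column")
  expect_equal(nrow(read_incidence(path, lenient = TRUE)), 2L)

  # count identity violations are refused
  bad <- make_record(cases_m = 10L, cases_f = 10L, cases_total = 30L)
  write_points(bad, path)
  expect_error(read_incidence(path), "cases_total")
})
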