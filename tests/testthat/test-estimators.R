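test_that("the four measure estimators evaluate their formulas", {
  expect_equal(estimate_irsb(100, 100, 1.0), 0.0)
  expect_equal(estimate_irsb(200, 100, 1.0), 1.0)
  expect_equal(estimate_irsb(100, 100, 1.06), log2(1.06))
  expect_true(is.na(estimate_irsb(0, 100, 1)))

  expect_equal(estimate_ir_f(10, 150, 200, 1.0), 15.0)
  expect_equal(estimate_ir_f(10, 0, 200, 1.0), 0.0)
  expect_true(is.na(estimate_ir_f(10, 0, 0, 1.0)))

  expect_equal(estimate_ir_m(10, 50, 200, 1.0), 5.0)
  expect_equal(estimate_ir_m(10, 200, 200, 1.0), 20.0)

  expect_equal(estimate_ir_total(6, 14, 1.0), 10.0)
  expect_equal(estimate_ir_total(7, 7, 3.7), 7.0)
  expect_equal(estimate_ir_total(0, 14, 1.0), 7.0)
})

test_that("estimators are exact identities at the true sex ratio", {
  set.seed(31)
  for (i in 1:50) {
    pop_m <- runif(1, 1e5, 2e6); pop_f <- runif(1, 1e5, 2e6)
    cm <- rpois(1, 400) + 1L; cf <- rpois(1, 600) + 1L
    rec <- records_from_populations(cm, cf, pop_m, pop_f)
    sr <- rec$sex_ratio
    expect_equal(estimate_irsb(cm, cf, sr), rec$irsb, tolerance = 1e-12)
    expect_equal(estimate_ir_f(rec$ir_total, cf, cm + cf, sr), rec$ir_f,
                 tolerance = 1e-12)
    expect_equal(estimate_ir_m(rec$ir_total, cm, cm + cf, sr), rec$ir_m,
                 tolerance = 1e-12)
    expect_equal(estimate_ir_total(rec$ir_m, rec$ir_f, sr), rec$ir_total,
                 tolerance = 1e-12)
  }
})

test_that("composing the sex-specific estimators recovers the total rate for any sex ratio", {
  set.seed(32)
  for (s in runif(20, 0.5, 2)) {
    ir_total <- runif(1, 1, 50)
    cm <- rpois(1, 300) + 1L; cf <- rpois(1, 500) + 1L
    expect_equal(
      estimate_ir_total(estimate_ir_m(ir_total, cm, cm + cf, s),
                        estimate_ir_f(ir_total, cf, cm + cf, s), s),
      ir_total)
  }
  # antisymmetry in the counts at a balanced ratio
  expect_equal(estimate_irsb(350, 120, 1), -estimate_irsb(120, 350, 1))
  # the total always lies between the sex-specific rates
  expect_true(all(estimate_ir_total(3, 9, runif(20, 0.1, 10)) >= 3 &
                    estimate_ir_total(3, 9, runif(20, 0.1, 10)) <= 9))
})

test_that("partition_by_availability forms the four disjoint groups", {
  recs <- make_records(
    study_id = c("v_only", "v_and_in", "in_only", "neither"),
    irsb = c(0.5, 0.5, NA, NA),
    cases_m = c(NA, 100L, 100L, NA), cases_f = c(NA, 200L, 200L, NA),
    cases_total = c(NA, 300L, 300L, 400L), ir_total = 10
  )
  part <- partition_by_availability(recs, "irsb")
  expect_equal(part$groups$group1, "v_only")
  expect_equal(part$groups$group2, "v_and_in")
  expect_equal(part$groups$group3, "in_only")
  expect_equal(part$groups$group4, "neither")
  expect_equal(sum(part$counts), nrow(recs))

  # a record with only ir_total has neither IR_F value nor its inputs beyond it
  part_f <- partition_by_availability(recs, "ir_f")
  expect_true("neither" %in% part_f$groups$group4)
  # ir_total inputs are the two sex-specific rates
  recs2 <- make_records(ir_m = c(4, NA), ir_f = c(8, NA), ir_total = c(NA, 7))
  part_t <- partition_by_availability(recs2, "ir_total")
  expect_equal(part_t$counts[["group3"]], 1L)
  expect_equal(part_t$counts[["group1"]], 1L)
})

test_that("generator masking bookkeeping matches the availability partition", {
  syn <- generate_incidence(n_aid = 40, n_cancer = 0, n_countries = 10,
                            population = 5e6, mask_probs = c(0.2, 0.4, 0.3, 0.1),
                            seed = 33)
  part <- partition_by_availability(syn$records, "irsb")
  tab <- table(factor(syn$truth$masking$pattern, levels = 1:4))
  expect_equal(unname(part$counts), as.vector(tab))
})

test_that("validate_estimators reports a perfect estimator as exact", {
  set.seed(34)
  recs <- records_from_populations(rpois(30, 400) + 1L, rpois(30, 600) + 1L,
                                   runif(30, 1e5, 1e6), runif(30, 1e5, 1e6))
  recs$study_id <- paste0("s", 1:30)
  for (m in c("irsb", "ir_f", "ir_m", "ir_total")) {
    rep <- validate_estimators(recs, m, "ratio_external")
    expect_equal(rep$pearson_r, 1, tolerance = 1e-9)
    expect_equal(rep$beta, 1, tolerance = 1e-9)
    expect_equal(rep$alpha, 0, tolerance = 1e-6)
    expect_equal(rep$r_squared, 1, tolerance = 1e-9)
    expect_lt(rep$p_one_sided, 1e-10)
  }
  expect_error(validate_estimators(recs[1:2, ], "irsb"), ">= 3")
  const <- make_records(study_id = paste0("k", 1:5), irsb = 1,
                        cases_m = 100L, cases_f = 50L, cases_total = 150L)
  expect_error(validate_estimators(const, "irsb"), "constant")
})

test_that("complete_measures fills only missing measures from given inputs", {
  recs <- make_records(
    study_id = c("fill_irsb", "keep_irsb", "fill_rates", "counts_only"),
    irsb = c(NA, 2.5, NA, NA),
    cases_m = c(300L, 300L, 50L, 80L), cases_f = c(600L, 600L, 150L, 20L),
    cases_total = c(900L, 900L, 200L, 100L),
    ir_total = c(NA, NA, 10, NA)
  )
  out <- complete_measures(recs)
  expect_equal(out$irsb[1], -1.0)
  expect_equal(out$prov_irsb[1], "estimated")
  # a given value is never overwritten
  expect_equal(out$irsb[2], 2.5)
  expect_equal(out$prov_irsb[2], "given")
  # sex-specific rates from total rate and counts at ratio 1:1
  expect_equal(out$ir_m[3], 5)
  expect_equal(out$ir_f[3], 15)
  expect_equal(out$prov_ir_f[3], "estimated")
  # no chaining: counts alone cannot produce rates (no given ir_total),
  # even though IRSB itself is estimable
  expect_equal(out$irsb[4], 2.0)
  expect_true(is.na(out$ir_m[4]) && is.na(out$ir_f[4]))
  expect_equal(out$prov_ir_m[4], "missing")

  expect_error(complete_measures(recs, "ratio_external"), "sex_ratio")
  recs$sex_ratio <- 2
  out2 <- complete_measures(recs, "ratio_external")
  expect_equal(out2$irsb[1], log2(300 / 600 * 2))
})
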