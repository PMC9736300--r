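#' Generate a synthetic incidence catalogue with known ground truth
#'
#' Emulates a curated incidence collection: each disease has a true IRSB
#' composed of a class-level offset plus a tissue-level driver shared (with
#' mixing weight `rho`) between the AID and cancer sets, so the two classes'
#' sex biases are coupled across tissues. Per (disease, country) the male
#' and female case counts are Poisson draws from rates implied by the true
#' IRSB plus country-level log2 noise; observed rates are then computed from
#' the counts and the recorded populations (so all incidence identities hold
#' exactly). AID records are masked to one of four availability patterns
#' (value only / value + inputs / inputs only / neither, with respect to
#' IRSB) with the configured probabilities; cancer records are registry
#' style, generated per year with full reporting and no masking.
#'
#' @param n_aid,n_cancer Diseases per class, default 17 each.
#' @param n_tissues Number of tissues, default 12; diseases are assigned
#'   round-robin so every tissue hosts both classes.
#' @param n_countries Number of countries, default 30.
#' @param base_rate_meanlog,base_rate_sdlog Log-normal parameters of each
#'   disease's base total rate (cases / year / 1e5 persons); defaults give a
#'   median of 20.
#' @param irsb_mean Named class offsets of the true IRSB (log2 units),
#'   default `c(AID = -1, cancer = 0.5)`.
#' @param irsb_sd Across-disease IRSB spread (log2), default 0.6.
#' @param rho Mixing weight in `[0, 1]` of the shared tissue driver in each
#'   disease's true IRSB, default 0.5.
#' @param sigma_country Country-level log2 noise on the IRSB, default 0.3.
#' @param population Male population per country; the female population is
#'   `population * sex_ratio`. Default 1e6.
#' @param sex_ratio_mean,sex_ratio_sd Per-country background sex ratio
#'   (female/male) distribution, default N(1.04, 0.02).
#' @param mask_probs Probabilities of the four AID availability patterns,
#'   default `c(0.11, 0.56, 0.33, 0)`.
#' @param cancer_years Years per cancer registry series, default 5.
#' @param drivers Optional named per-tissue driver vector (e.g. to share
#'   drivers with [generate_expression()]); drawn N(0, 1) if `NULL`.
#' @param seed Optional integer seed.
#' @return Object of class `synth_incidence`: `records` (study-record data
#'   frame) and `truth` (drivers, per-disease true IRSB, sex ratios, masking
#'   assignment, config, seed).
#' @export
generate_incidence <- function(n_aid = 17, n_cancer = 17, n_tissues = 12,
                               n_countries = 30,
                               base_rate_meanlog = log(20),
                               base_rate_sdlog = 0.7,
                               irsb_mean = c(AID = -1, cancer = 0.5),
                               irsb_sd = 0.6, rho = 0.5,
                               sigma_country = 0.3,
                               population = 1e6,
                               sex_ratio_mean = 1.04, sex_ratio_sd = 0.02,
                               mask_probs = c(0.11, 0.56, 0.33, 0),
                               cancer_years = 5,
                               drivers = NULL, seed = NULL) {
  stopifnot(rho >= 0, rho <= 1, length(mask_probs) == 4L,
            abs(sum(mask_probs) - 1) < 1e-8, all(mask_probs >= 0))
  if (!is.null(seed)) set.seed(seed)
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  countries <- sprintf("country%02d", seq_len(n_countries))
  if (is.null(drivers)) drivers <- setNames(rnorm(n_tissues), tissues)
  else tissues <- names(drivers)

  diseases <- data.frame(
    disease_id = c(sprintf("aid%02d", seq_len(n_aid)),
                   sprintf("can%02d", seq_len(n_cancer))),
    disease_class = rep(c("AID", "cancer"), c(n_aid, n_cancer)),
    tissue = c(tissues[(seq_len(n_aid) - 1L) %% n_tissues + 1L],
               tissues[(seq_len(n_cancer) - 1L) %% n_tissues + 1L]),
    stringsAsFactors = FALSE
  )
  diseases$irsb_true <- irsb_mean[diseases$disease_class] +
    irsb_sd * (sqrt(rho) * drivers[diseases$tissue] +
                 sqrt(1 - rho) * rnorm(nrow(diseases)))
  diseases$base_rate <- rlnorm(nrow(diseases), base_rate_meanlog, base_rate_sdlog)
  sex_ratio <- setNames(rnorm(n_countries, sex_ratio_mean, sex_ratio_sd),
                        countries)

  grid <- expand.grid(d = seq_len(nrow(diseases)), country = countries,
                      stringsAsFactors = FALSE)
  years <- pmax(1L, ifelse(diseases$disease_class[grid$d] == "AID",
                           1L, as.integer(cancer_years)))
  grid <- grid[rep(seq_len(nrow(grid)), years), , drop = FALSE]
  grid$year <- unlist(lapply(years, seq_len))

  irsb_dc <- diseases$irsb_true[grid$d] + rnorm(nrow(grid), 0, sigma_country)
  # same country-level deviation for every year of one registry series
  key <- paste(grid$d, grid$country)
  irsb_dc <- ave(irsb_dc, key, FUN = function(v) v[1L])
  base <- diseases$base_rate[grid$d]
  ir_m_true <- base * 2^(irsb_dc / 2)
  ir_f_true <- base * 2^(-irsb_dc / 2)
  pop_m <- population
  pop_f <- population * sex_ratio[grid$country]
  lambda_m <- ir_m_true / 1e5 * pop_m
  lambda_f <- ir_f_true / 1e5 * pop_f
  if (min(lambda_m, lambda_f) < 1)
    warning("configuration implies expected case counts < 1 in some cells")
  cases_m <- rpois(nrow(grid), lambda_m)
  cases_f <- rpois(nrow(grid), lambda_f)

  is_aid <- diseases$disease_class[grid$d] == "AID"
  records <- data.frame(
    study_id = ifelse(is_aid,
                      paste0(diseases$disease_id[grid$d], "_", grid$country, "_s1"),
                      paste0(diseases$disease_id[grid$d], "_", grid$country,
                             "_y", grid$year)),
    disease_id = diseases$disease_id[grid$d],
    disease_class = diseases$disease_class[grid$d],
    tissue = diseases$tissue[grid$d],
    country = grid$country,
    year_start = ifelse(is_aid, 2010L, 2010L + grid$year - 1L),
    year_end = ifelse(is_aid, 2019L, 2010L + grid$year - 1L),
    cases_m = cases_m, cases_f = cases_f, cases_total = cases_m + cases_f,
    ir_m = compute_ir(cases_m, pop_m),
    ir_f = compute_ir(cases_f, pop_f),
    ir_total = compute_ir(cases_m + cases_f, pop_m + pop_f),
    irsb = NA_real_,
    sex_ratio = unname(sex_ratio[grid$country]),
    rate_scale = 1e5,
    age_adjusted = FALSE, population_based = TRUE, clinical_criteria = TRUE,
    prior_disease_excluded = TRUE,
    stringsAsFactors = FALSE
  )
  records$irsb <- compute_irsb(records$ir_m, records$ir_f)

  pattern <- rep(2L, nrow(records))
  pattern[is_aid] <- sample.int(4L, sum(is_aid), replace = TRUE,
                                prob = mask_probs)
  mask1 <- is_aid & pattern == 1L # measure values only
  records[mask1, c("cases_m", "cases_f", "cases_total")] <- NA_integer_
  mask3 <- is_aid & pattern == 3L # estimator inputs only
  records[mask3, c("irsb", "ir_m", "ir_f")] <- NA_real_
  mask4 <- is_aid & pattern == 4L # neither value nor inputs
  records[mask4, c("irsb", "ir_m", "ir_f")] <- NA_real_
  records[mask4, c("cases_m", "cases_f")] <- NA_integer_

  structure(
    list(records = records,
         truth = list(seed = seed, drivers = drivers, diseases = diseases,
                      sex_ratio = sex_ratio,
                      masking = data.frame(study_id = records$study_id,
                                           pattern = pattern,
                                           stringsAsFactors = FALSE),
                      config = list(n_aid = n_aid, n_cancer = n_cancer,
                                    n_tissues = n_tissues,
                                    n_countries = n_countries,
                                    irsb_mean = irsb_mean, irsb_sd = irsb_sd,
                                    rho = rho, sigma_country = sigma_country,
                                    population = population,
                                    mask_probs = mask_probs,
                                    cancer_years = cancer_years))),
    class = "synth_incidence"
  )
}

#' @export
print.synth_incidence <- function(x, ...) {
  cat("Synthetic incidence catalogue:", nrow(x$records), "records,",
      nrow(x$truth$diseases), "diseases,",
      length(x$truth$sex_ratio), "countries\n")
  invisible(x)
}

#' Generate a synthetic TPM matrix with a planted sex-biased gene set
#'
#' Background genes are sex-symmetric log-normal TPM. Planted genes carry a
#' per-tissue expression sex bias `b = coupling * driver(tissue) +
#' N(0, sigma_gene)` (log2 units), split as +b/2 on the male mean and -b/2
#' on the female mean, so the planted set's per-tissue ESB/ASB tracks the
#' tissue driver — the same driver that can be fed to
#' [generate_incidence()] to couple expression sex bias to disease IRSB.
#'
#' @param n_genes Background genes, default 2000.
#' @param planted_size Planted set size, default 37.
#' @param n_tissues Tissues (ignored when `drivers` is given), default 12.
#' @param samples_per_group Samples per (tissue, sex) cell, default 15.
#' @param drivers Optional named per-tissue driver vector; drawn N(0, 1) if
#'   `NULL`.
#' @param coupling Linear coupling of the planted bias to the driver,
#'   default 1.
#' @param sigma_gene Per-gene log2 bias noise around the coupled value,
#'   default 0.3.
#' @param sigma_sample Per-sample log2 expression noise, default 0.5.
#' @param base_log2_mean,base_log2_sd Distribution of per-gene baseline
#'   log2 TPM, default N(5, 1.5).
#' @param seed Optional integer seed.
#' @return Object of class `synth_expression`: `tpm` (genes x samples),
#'   `attrs` (sample attributes) and `truth` (drivers, planted gene ids,
#'   realised per-tissue biases, config, seed).
#' @export
generate_expression <- function(n_genes = 2000, planted_size = 37,
                                n_tissues = 12, samples_per_group = 15,
                                drivers = NULL, coupling = 1,
                                sigma_gene = 0.3, sigma_sample = 0.5,
                                base_log2_mean = 5, base_log2_sd = 1.5,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(drivers))
    drivers <- setNames(rnorm(n_tissues), sprintf("tissue%02d", seq_len(n_tissues)))
  tissues <- names(drivers)
  n_tissues <- length(tissues)
  genes <- c(sprintf("planted%03d", seq_len(planted_size)),
             sprintf("gene%04d", seq_len(n_genes)))
  n_all <- length(genes)
  mu <- rnorm(n_all, base_log2_mean, base_log2_sd)

  # realised planted bias per (planted gene, tissue), log2 units
  bias <- matrix(0, n_all, n_tissues, dimnames = list(genes, tissues))
  bias[seq_len(planted_size), ] <-
    coupling * rep(drivers, each = planted_size) +
    rnorm(planted_size * n_tissues, 0, sigma_gene)

  sample_grid <- expand.grid(rep = seq_len(samples_per_group),
                             sex = c("male", "female"), tissue = tissues,
                             stringsAsFactors = FALSE)
  attrs <- data.frame(
    sample_id = sprintf("%s_%s_%02d", sample_grid$tissue,
                        ifelse(sample_grid$sex == "male", "M", "F"),
                        sample_grid$rep),
    tissue = sample_grid$tissue, sex = sample_grid$sex,
    stringsAsFactors = FALSE
  )
  tpm <- matrix(0, n_all, nrow(attrs), dimnames = list(genes, attrs$sample_id))
  for (j in seq_len(nrow(attrs))) {
    b <- bias[, attrs$tissue[j]]
    center <- mu + (if (attrs$sex[j] == "male") b / 2 else -b / 2)
    tpm[, j] <- 2^(center + rnorm(n_all, 0, sigma_sample))
  }

  structure(
    list(tpm = tpm, attrs = attrs,
         truth = list(seed = seed, drivers = drivers,
                      planted_genes = genes[seq_len(planted_size)],
                      bias = bias[seq_len(planted_size), , drop = FALSE],
                      config = list(n_genes = n_genes,
                                    planted_size = planted_size,
                                    samples_per_group = samples_per_group,
                                    coupling = coupling,
                                    sigma_gene = sigma_gene,
                                    sigma_sample = sigma_sample))),
    class = "synth_expression"
  )
}

#' @export
print.synth_expression <- function(x, ...) {
  cat("Synthetic expression matrix:", nrow(x$tpm), "genes x", ncol(x$tpm),
      "samples;", length(x$truth$planted_genes), "planted genes across",
      length(x$truth$drivers), "tissues\n")
  invisible(x)
}

#' Random gene sets from a gene universe
#'
#' Draws `n_sets` sets of sizes uniform in `size_range`, useful as a null
#' collection around a planted set. Uses the current RNG stream.
#'
#' @param universe Character vector of gene ids to draw from.
#' @param n_sets Number of sets, default 19.
#' @param size_range Inclusive size range, default `c(10, 100)`.
#' @return Named list of gene-id vectors (`nullset01`, ...).
#' @export
random_gene_sets <- function(universe, n_sets = 19, size_range = c(10, 100)) {
  sizes <- sample(seq(size_range[1L], size_range[2L]), n_sets, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(universe, k))
  names(sets) <- sprintf("nullset%02d", seq_len(n_sets))
  sets
}
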