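#' Run the incidence stage end-to-end
#'
#' Chains curation to correlation: scale normalisation, eligibility
#' filtering, estimator completion, aggregation to disease-country points
#' (yearly registry rows of one series average exactly as
#' [aggregate_years()]), tissue/country pair matching at the country level,
#' global (across-country mean) pair matching, the global Pearson and
#' Spearman tests (two-sided) and the per-country one-sided scan with BH
#' correction.
#'
#' @param records Study-record data frame (e.g. from [read_incidence()] or
#'   [generate_incidence()]).
#' @param min_cases,min_countries,excluded_tissues Passed to
#'   [filter_eligible()].
#' @param variant Estimator variant for [complete_measures()].
#' @param min_pairs Country qualification threshold for
#'   [country_level_scan()].
#' @param output_dir Optional directory; when given, writes `points.tsv`,
#'   `pairs_country.tsv`, `pairs_global.tsv` and `incidence_summary.json`.
#' @param verbose Log record counts per step to stderr.
#' @return List with `points`, `pairs_country`, `pairs_global`,
#'   `cor_global_pearson`, `cor_global_spearman`, `country_scan` and the
#'   per-step `counts`.
#' @export
run_incidence_stage <- function(records, min_cases = 25, min_countries = 3,
                                excluded_tissues = character(),
                                variant = "ratio_1_1", min_pairs = 18,
                                output_dir = NULL, verbose = FALSE) {
  if (inherits(records, "synth_incidence")) records <- records$records
  counts <- list(records_in = nrow(records))
  records <- normalize_scale(records)
  records <- filter_eligible(records, min_cases, min_countries,
                             excluded_tissues, verbose = verbose)
  counts$records_eligible <- nrow(records)
  if (nrow(records) == 0L) {
    warning("no eligible records; reports are empty")
    return(list(points = NULL, pairs_country = NULL, pairs_global = NULL,
                cor_global_pearson = NULL, cor_global_spearman = NULL,
                country_scan = NULL, counts = counts))
  }
  records <- complete_measures(records, variant)
  points <- aggregate_studies(records)
  counts$points <- nrow(points)

  aid <- points[points$disease_class == "AID", , drop = FALSE]
  cancer <- points[points$disease_class == "cancer", , drop = FALSE]
  counts$aid_points <- nrow(aid)
  counts$cancer_points <- nrow(cancer)

  pairs_country <- match_pairs(aid, cancer)
  pairs_global <- match_pairs(global_disease_means(aid),
                              global_disease_means(cancer))
  counts$pairs_country <- nrow(pairs_country)
  counts$pairs_global <- nrow(pairs_global)
  if (verbose)
    message("run_incidence_stage: ", counts$records_in, " records -> ",
            counts$points, " points -> ", counts$pairs_country,
            " country pairs, ", counts$pairs_global, " global pairs")

  cor_p <- correlate_pairs(pairs_global, "pearson", "two_sided")
  cor_s <- correlate_pairs(pairs_global, "spearman", "two_sided")
  scan <- country_level_scan(pairs_country, min_pairs = min_pairs)

  out <- list(points = points, pairs_country = pairs_country,
              pairs_global = pairs_global, cor_global_pearson = cor_p,
              cor_global_spearman = cor_s, country_scan = scan,
              counts = counts)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_points(points, file.path(output_dir, "points.tsv"))
    write_points(pairs_country, file.path(output_dir, "pairs_country.tsv"))
    write_points(pairs_global, file.path(output_dir, "pairs_global.tsv"))
    summary <- list(
      counts = counts,
      global = list(
        pearson = list(r = cor_p$r, n = cor_p$n, p = cor_p$p),
        spearman = list(r = cor_s$r, n = cor_s$n, p = cor_s$p)),
      country_scan = scan
    )
    jsonlite::write_json(summary, file.path(output_dir, "incidence_summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' Run the expression stage end-to-end
#'
#' From a TPM matrix and the incidence stage's points: per-tissue ESB,
#' per-gene across-tissue ESB-IRSB correlations for the AID, cancer and
#' joint phenotypes, preranked GSEA of each phenotype's ranking, the
#' designated set's per-tissue ASB with its IRSB correlations, and the
#' partial correlation of the global cancer-AID IRSB pairs given the
#' designated set's ASB.
#'
#' @param incidence Result of [run_incidence_stage()] (or a list with
#'   `points` and `pairs_global`).
#' @param tpm TPM matrix, genes x samples.
#' @param attrs Sample attributes (`sample_id`, `tissue`, `sex`).
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param designated_set Name of the collection entry used for the ASB and
#'   partial-correlation analyses; default the first set.
#' @param n_perm,min_size,max_size,exponent,seed GSEA parameters, passed to
#'   [gsea_prerank()].
#' @param min_obs Minimum observations per gene for [corr_esb_irsb()].
#' @param tissue_map Optional sub-tissue pooling map.
#' @param output_dir Optional directory; when given, writes `esb.tsv`,
#'   `gene_correlations.tsv`, `gsea_<phenotype>.tsv` and
#'   `expression_summary.json`.
#' @return List with `esb`, `gene_correlations`, `gsea` (per phenotype),
#'   `asb`, `asb_cor_aid`, `asb_cor_cancer` and `partial`.
#' @export
run_expression_stage <- function(incidence, tpm, attrs, collection,
                                 designated_set = names(collection)[1L],
                                 n_perm = 1000, min_size = 5, max_size = 2000,
                                 exponent = 1, seed = NULL, min_obs = 3,
                                 tissue_map = NULL, output_dir = NULL) {
  points <- incidence$points
  attrs <- apply_tissue_map(attrs, tissue_map)
  tissues <- intersect(sort(unique(attrs$tissue)), unique(points$tissue))
  if (length(tissues) < 3L)
    stop("fewer than 3 tissues shared between expression and incidence data")
  expr <- tissue_expression_summary(tpm, attrs, tissues)

  aid_global <- global_disease_means(points[points$disease_class == "AID", ])
  can_global <- global_disease_means(points[points$disease_class == "cancer", ])

  corr_aid <- corr_esb_irsb(expr$esb, aid_global, min_obs = min_obs)
  corr_can <- corr_esb_irsb(expr$esb, can_global, min_obs = min_obs)
  gene_cor <- data.frame(gene = corr_aid$gene, aid = corr_aid$corr,
                         cancer = corr_can$corr,
                         joint = joint_corr(corr_aid$corr, corr_can$corr),
                         stringsAsFactors = FALSE)

  gsea <- lapply(setNames(nm = c("aid", "cancer", "joint")), function(ph) {
    ranked <- rank_genes(setNames(gene_cor[[ph]], gene_cor$gene))
    gsea_prerank(ranked, collection, n_perm = n_perm, seed = seed,
                 min_size = min_size, max_size = max_size, exponent = exponent)
  })

  asb <- asb_by_tissue(tpm, attrs, collection[[designated_set]], tissues)
  asb_cor_aid <- asb_irsb_correlation(asb, aid_global)
  asb_cor_can <- asb_irsb_correlation(asb, can_global)

  pairs <- incidence$pairs_global
  pairs <- pairs[pairs$tissue %in% names(asb)[!is.na(asb)], , drop = FALSE]
  partial <- partial_correlation(pairs$cancer_irsb, pairs$aid_irsb,
                                 asb[pairs$tissue])

  out <- list(esb = expr$esb, gene_correlations = gene_cor, gsea = gsea,
              asb = asb, asb_cor_aid = asb_cor_aid,
              asb_cor_cancer = asb_cor_can, partial = partial)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(data.frame(gene = rownames(expr$esb), expr$esb,
                           check.names = FALSE),
                file.path(output_dir, "esb.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    write_points(gene_cor, file.path(output_dir, "gene_correlations.tsv"))
    for (ph in names(gsea)) {
      tab <- as.data.frame(gsea[[ph]])
      tab$leading_edge <- vapply(tab$leading_edge, paste, character(1),
                                 collapse = ",")
      write_points(tab, file.path(output_dir, paste0("gsea_", ph, ".tsv")))
    }
    summary <- list(
      seed = seed, n_perm = n_perm, designated_set = designated_set,
      asb = as.list(asb),
      asb_irsb = list(
        aid = list(r = asb_cor_aid$r, n = asb_cor_aid$n, p = asb_cor_aid$p),
        cancer = list(r = asb_cor_can$r, n = asb_cor_can$n, p = asb_cor_can$p)),
      partial = list(r_raw = partial$r_xy, r_partial = partial$r_xy_given_z,
                     p = partial$p, n = partial$n)
    )
    jsonlite::write_json(summary, file.path(output_dir, "expression_summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
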