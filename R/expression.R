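#' Read a GTEx-style wide TPM matrix
#'
#' Expects a tab-separated table whose first two columns identify the gene
#' (id, symbol) and whose remaining columns are samples. A leading GCT-style
#' preamble (`#1.2` plus a dimensions line) is skipped if present. Gzipped
#' files are read transparently.
#'
#' @param path Path to the TSV (optionally `.gz`).
#' @return Numeric matrix of TPM values, genes in rows (rownames = gene ids)
#'   and samples in columns, with the gene symbols as the `"symbols"`
#'   attribute.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  skip <- 0L
  if (startsWith(first, "#1.2")) {
    readLines(con, n = 1L) # dimensions line
  } else {
    pushBack(first, con)
  }
  df <- read.delim(con, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (ncol(df) < 3L)
    stop("expression table needs two gene columns plus >= 1 sample column")
  if (anyDuplicated(df[[1L]]))
    stop("duplicated gene ids in expression table")
  tpm <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(tpm)) stop("non-numeric TPM values in expression table")
  if (any(tpm < 0, na.rm = TRUE)) stop("negative TPM values")
  rownames(tpm) <- df[[1L]]
  attr(tpm, "symbols") <- setNames(as.character(df[[2L]]), df[[1L]])
  tpm
}

#' Read a sample-attribute table
#'
#' @param path TSV with columns `sample_id`, `tissue`, `sex`
#'   (`"male"`/`"female"`).
#' @return Data frame of sample attributes.
#' @export
read_sample_attributes <- function(path) {
  if (!file.exists(path)) stop("sample attribute file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "sex")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("sample attributes lack column(s): ", paste(missing_cols, collapse = ", "))
  df$sex <- tolower(df$sex)
  if (!all(df$sex %in% c("male", "female")))
    stop("`sex` must be 'male' or 'female'")
  df
}

# Apply a sub-tissue -> parent-tissue mapping (named character vector);
# unmapped labels pass through unchanged.
apply_tissue_map <- function(attrs, tissue_map = NULL) {
  if (is.null(tissue_map)) return(attrs)
  mapped <- tissue_map[attrs$tissue]
  attrs$tissue <- ifelse(is.na(mapped), attrs$tissue, unname(mapped))
  attrs
}

samples_for <- function(tpm, attrs, tissue, sex) {
  ids <- attrs$sample_id[attrs$tissue == tissue & attrs$sex == sex]
  ids <- intersect(ids, colnames(tpm))
  if (length(ids) == 0L)
    stop("no samples for tissue '", tissue, "', sex '", sex, "'")
  ids
}

#' Mean expression per gene for one (tissue, sex) cell
#'
#' Per-gene arithmetic mean TPM over the samples of the given tissue and sex.
#'
#' @param tpm TPM matrix, genes x samples.
#' @param attrs Sample attributes (`sample_id`, `tissue`, `sex`).
#' @param tissue,sex Cell selector; `sex` is `"male"` or `"female"`.
#' @param tissue_map Optional named vector mapping sub-tissue labels to a
#'   parent tissue (e.g. pooling brain subregions under `"brain"`).
#' @return Named numeric vector of mean TPM per gene.
#' @export
mean_expression <- function(tpm, attrs, tissue, sex, tissue_map = NULL) {
  attrs <- apply_tissue_map(attrs, tissue_map)
  ids <- samples_for(tpm, attrs, tissue, sex)
  rowMeans(tpm[, ids, drop = FALSE])
}

#' Expression sex bias (ESB) per gene
#'
#' `ESB = log2(GE_male / GE_female)`, defined only where both mean
#' expressions are strictly positive (`NA` otherwise).
#'
#' @param ge_m,ge_f Per-gene mean TPM for the male and female samples of one
#'   tissue.
#' @return Numeric vector of log2 ratios.
#' @export
expression_sex_bias <- function(ge_m, ge_f) {
  ok <- !is.na(ge_m) & !is.na(ge_f) & ge_m > 0 & ge_f > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- log2(ge_m[ok] / ge_f[ok])
  names(out) <- names(ge_m)
  out
}

#' Per-tissue expression summary (GE by sex and ESB)
#'
#' @inheritParams mean_expression
#' @param tissues Tissues to summarise; default all tissues present in
#'   `attrs` (after mapping).
#' @return List with genes-x-tissues matrices `ge_m`, `ge_f` and `esb`.
#' @export
tissue_expression_summary <- function(tpm, attrs, tissues = NULL,
                                      tissue_map = NULL) {
  attrs <- apply_tissue_map(attrs, tissue_map)
  if (is.null(tissues)) tissues <- sort(unique(attrs$tissue))
  ge_m <- sapply(tissues, function(t) mean_expression(tpm, attrs, t, "male"))
  ge_f <- sapply(tissues, function(t) mean_expression(tpm, attrs, t, "female"))
  esb <- ge_m
  for (j in seq_along(tissues)) esb[, j] <- expression_sex_bias(ge_m[, j], ge_f[, j])
  list(ge_m = ge_m, ge_f = ge_f, esb = esb)
}

#' Gene set activity (GSA)
#'
#' Geometric mean (computed in log space) of the per-gene mean TPM over a
#' gene set, for one (tissue, sex) cell. Undefined (`NA`, with a warning)
#' when any member gene has zero mean expression, unless a positive
#' expression floor `eps` is supplied.
#'
#' @inheritParams mean_expression
#' @param gene_set Character vector of member gene ids; all must be present
#'   in the matrix.
#' @param eps Optional expression floor in TPM applied before the geometric
#'   mean (default `NULL`: no floor; its use is logged).
#' @return Scalar activity value.
#' @export
gene_set_activity <- function(tpm, attrs, gene_set, tissue, sex,
                              tissue_map = NULL, eps = NULL) {
  if (length(gene_set) == 0L) stop("`gene_set` is empty")
  absent <- setdiff(gene_set, rownames(tpm))
  if (length(absent))
    stop("gene set member(s) absent from matrix: ", paste(absent, collapse = ", "))
  ge <- mean_expression(tpm, attrs, tissue, sex, tissue_map)[gene_set]
  if (!is.null(eps)) {
    if (any(ge < eps)) message("gene_set_activity: applying expression floor eps = ", eps)
    ge <- pmax(ge, eps)
  }
  if (any(ge <= 0)) {
    warning("gene set activity undefined: ", sum(ge <= 0),
            " member gene(s) with zero mean expression in (", tissue, ", ", sex, ")")
    return(NA_real_)
  }
  exp(mean(log(ge)))
}

#' Activity sex bias (ASB) of a gene set
#'
#' `ASB = log2(GSA_male / GSA_female)`. When every member gene has a defined
#' ESB this equals the arithmetic mean of the member ESBs (an algebraic
#' identity of the geometric mean).
#'
#' @inheritParams gene_set_activity
#' @return Scalar log2 activity ratio (`NA` if either GSA is undefined).
#' @export
activity_sex_bias <- function(tpm, attrs, gene_set, tissue,
                              tissue_map = NULL, eps = NULL) {
  gsa_m <- gene_set_activity(tpm, attrs, gene_set, tissue, "male", tissue_map, eps)
  gsa_f <- gene_set_activity(tpm, attrs, gene_set, tissue, "female", tissue_map, eps)
  if (is.na(gsa_m) || is.na(gsa_f)) return(NA_real_)
  log2(gsa_m / gsa_f)
}

#' Activity sex bias across tissues
#'
#' @inheritParams gene_set_activity
#' @param tissues Tissues to evaluate; default all in `attrs`.
#' @return Named numeric vector of per-tissue ASB values.
#' @export
asb_by_tissue <- function(tpm, attrs, gene_set, tissues = NULL,
                          tissue_map = NULL, eps = NULL) {
  attrs <- apply_tissue_map(attrs, tissue_map)
  if (is.null(tissues)) tissues <- sort(unique(attrs$tissue))
  vapply(setNames(tissues, tissues), function(t)
    activity_sex_bias(tpm, attrs, gene_set, t, eps = eps), numeric(1))
}
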