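#' Per-gene across-tissue correlation of ESB with disease IRSB
#'
#' Each disease contributes one observation pairing its global IRSB with the
#' ESB of the gene in the disease's tissue of origin; tissues hosting two
#' diseases contribute two observations with identical ESB. The correlation
#' is Spearman's, computed per gene over the observations in which the
#' gene's ESB is defined.
#'
#' @param esb Genes-x-tissues ESB matrix (from
#'   [tissue_expression_summary()]).
#' @param disease_points Disease-level points (one row per disease, e.g.
#'   from [global_disease_means()]) with columns `disease_id`, `tissue`,
#'   `irsb`.
#' @param min_obs Minimum observations for a gene to receive a correlation,
#'   default 3.
#' @param collapse_tissues Collapse to one observation per tissue (averaging
#'   the IRSBs of diseases sharing a tissue) instead of one per disease.
#' @return Data frame with `gene`, `corr`, `n` (`corr` is `NA` for genes
#'   with insufficient coverage or constant ESB).
#' @export
corr_esb_irsb <- function(esb, disease_points, min_obs = 3,
                          collapse_tissues = FALSE) {
  pts <- disease_points[!is.na(disease_points$irsb), , drop = FALSE]
  pts <- pts[pts$tissue %in% colnames(esb), , drop = FALSE]
  if (collapse_tissues) {
    agg <- aggregate(pts["irsb"], by = list(tissue = pts$tissue), FUN = mean)
    pts <- data.frame(disease_id = agg$tissue, tissue = agg$tissue,
                      irsb = agg$irsb, stringsAsFactors = FALSE)
  }
  x <- esb[, pts$tissue, drop = FALSE] # genes x observations
  y <- pts$irsb
  n_obs <- rowSums(!is.na(x))
  corr <- rep(NA_real_, nrow(x))
  complete <- n_obs == length(y)
  if (any(complete) && length(y) >= min_obs) {
    xr <- t(apply(x[complete, , drop = FALSE], 1L, rank))
    yr <- rank(y)
    sds <- apply(xr, 1L, sd)
    const <- sds == 0
    if (any(const))
      message("corr_esb_irsb: ", sum(const), " gene(s) with constant ESB ",
              "across observations left missing")
    cc <- rep(NA_real_, nrow(xr))
    cc[!const] <- as.vector(cor(t(xr[!const, , drop = FALSE]), yr))
    corr[complete] <- cc
  }
  partial <- !complete & n_obs >= min_obs
  for (i in which(partial)) {
    keep <- !is.na(x[i, ])
    xi <- rank(x[i, keep]); yi <- rank(y[keep])
    if (sd(xi) > 0 && sd(yi) > 0) corr[i] <- cor(xi, yi)
  }
  data.frame(gene = rownames(esb), corr = corr, n = n_obs,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Joint ESB-IRSB correlation
#'
#' Per-gene average of the AID and cancer correlations; missing when either
#' is missing.
#'
#' @param corr_aid,corr_cancer Numeric vectors (aligned by position or name).
#' @return Numeric vector of averaged correlations.
#' @export
joint_corr <- function(corr_aid, corr_cancer) {
  out <- (corr_aid + corr_cancer) / 2
  out[is.na(corr_aid) | is.na(corr_cancer)] <- NA_real_
  out
}

#' Correlate gene-set activity sex bias with disease IRSB
#'
#' Pairs each disease-level observation's tissue ASB with the disease's
#' global IRSB and tests the correlation (one-sided positive by default).
#'
#' @param asb Named per-tissue ASB vector (from [asb_by_tissue()]).
#' @param disease_points Disease-level points with `disease_id`, `tissue`,
#'   `irsb`.
#' @param method Correlation method, default Pearson.
#' @param sidedness Test sidedness, default one-sided (positive).
#' @return Object of class `cor_result`.
#' @export
asb_irsb_correlation <- function(asb, disease_points,
                                 method = c("pearson", "spearman"),
                                 sidedness = c("one_sided", "two_sided")) {
  pts <- disease_points[disease_points$tissue %in% names(asb), , drop = FALSE]
  cor_test_t(asb[pts$tissue], pts$irsb, match.arg(method), match.arg(sidedness))
}

#' First-order partial correlation
#'
#' Pearson correlation between `x` and `y` after removing the linear
#' contribution of `z`:
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`,
#' tested two-sided with `t = r * sqrt((n - 3) / (1 - r^2))` on `n - 3`
#' degrees of freedom. Identical to correlating the residuals of the simple
#' regressions of `x` and `y` on `z`.
#'
#' @param x,y,z Equal-length numeric vectors, n >= 4 complete triples.
#' @return Object of class `partial_cor_result` with the three pairwise
#'   correlations, `r_xy_given_z`, `n` and the two-sided `p`. When `z` is
#'   (numerically) collinear with `x` or `y` the control is degenerate: the
#'   partial correlation is `NA` with a warning.
#' @export
partial_correlation <- function(x, y, z) {
  keep <- complete.cases(x, y, z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  n <- length(x)
  if (n < 4L) stop("partial correlation needs >= 4 complete triples, got ", n)
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0)
    stop("constant vector: partial correlation undefined")
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  res <- list(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz, n = n)
  if (1 - r_xz^2 < 1e-12 || 1 - r_yz^2 < 1e-12) {
    warning("degenerate control: z is collinear with x or y")
    res$r_xy_given_z <- NA_real_
    res$p <- NA_real_
  } else {
    r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
    r <- max(-1, min(1, r))
    res$r_xy_given_z <- r
    res$p <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 3) / (1 - r^2))
      2 * pt(-abs(tt), df = n - 3)
    }
  }
  structure(res, class = "partial_cor_result")
}

#' @export
print.partial_cor_result <- function(x, ...) {
  cat(sprintf(
    "Partial correlation (n = %d):\n  r_xy = %.4f, r_xz = %.4f, r_yz = %.4f\n  r_xy.z = %.4f, two-sided p = %.4g (df = %d)\n",
    x$n, x$r_xy, x$r_xz, x$r_yz, x$r_xy_given_z, x$p, x$n - 3L))
  invisible(x)
}
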