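#' Match AID and cancer points by tissue and country
#'
#' Within every (tissue, country) cell the full cross product of AID points
#' and cancer points is formed: two thyroid AIDs and two thyroid cancers in
#' one country give four pairs. Output order is deterministic
#' (tissue, country, AID id, cancer id).
#'
#' @param aid_points,cancer_points Disease-country point tables (from
#'   [aggregate_studies()] / [aggregate_years()] or [global_disease_means()]),
#'   with columns `disease_id`, `tissue`, `country`, `irsb`.
#' @return Data frame of matched pairs with both IRSBs.
#' @export
match_pairs <- function(aid_points, cancer_points) {
  need <- c("disease_id", "tissue", "country", "irsb")
  stopifnot(all(need %in% names(aid_points)), all(need %in% names(cancer_points)))
  a <- aid_points[, need]; names(a) <- c("aid_id", "tissue", "country", "aid_irsb")
  c_ <- cancer_points[, need]; names(c_) <- c("cancer_id", "tissue", "country", "cancer_irsb")
  pairs <- merge(a, c_, by = c("tissue", "country"))
  pairs <- pairs[order(pairs$tissue, pairs$country, pairs$aid_id, pairs$cancer_id), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  pairs[, c("tissue", "country", "aid_id", "cancer_id", "aid_irsb", "cancer_irsb")]
}

#' Across-country global means per disease
#'
#' Collapses country-level points to one global point per disease by the
#' arithmetic mean of the country-level IRSBs (and of the other measures
#' where present). Diseases with no defined IRSB in any country are excluded
#' with a message. The returned points carry the `"GLOBAL"` country sentinel
#' so they can be paired with [match_pairs()].
#'
#' @param points Disease-country point table.
#' @return One row per disease with mean measures, `country = "GLOBAL"` and
#'   `n_countries`.
#' @export
global_disease_means <- function(points) {
  parts <- split(points, points$disease_id)
  rows <- lapply(parts, function(g) {
    if (all(is.na(g$irsb))) {
      message("global_disease_means: excluding '", g$disease_id[1L],
              "': no defined IRSB in any country")
      return(NULL)
    }
    out <- data.frame(
      disease_id = g$disease_id[1L], disease_class = g$disease_class[1L],
      tissue = g$tissue[1L], country = "GLOBAL", stringsAsFactors = FALSE
    )
    for (m in .MEASURES)
      out[[m]] <- if (all(is.na(g[[m]]))) NA_real_ else mean(g[[m]], na.rm = TRUE)
    out$n_countries <- length(unique(g$country[!is.na(g$irsb)]))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Correlation with t-based p-value. Spearman uses the t approximation on the
# rank correlation with average ranks (ties shared), the small-n convention.
cor_test_t <- function(x, y, method = c("pearson", "spearman"),
                       sidedness = c("two_sided", "one_sided")) {
  method <- match.arg(method)
  sidedness <- match.arg(sidedness)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs, got ", n)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: correlation undefined")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- if (sidedness == "two_sided") 2 * pt(-abs(tt), df = n - 2)
         else pt(tt, df = n - 2, lower.tail = FALSE) # alternative: r > 0
  }
  structure(
    list(method = method, r = r, n = n, p = p, sidedness = sidedness, q = NULL),
    class = "cor_result"
  )
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.4f (n = %d), %s p = %.4g",
              x$method, x$r, x$n, sub("_", "-", x$sidedness), x$p))
  if (!is.null(x$q)) cat(sprintf(", BH q = %.4g", x$q))
  cat("\n")
  invisible(x)
}

#' Correlate cancer and AID IRSBs over matched pairs
#'
#' Cancer IRSB is the x variable and AID IRSB the y variable. The t statistic
#' is `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom;
#' one-sided tests take the alternative of positive correlation.
#'
#' @param pairs Matched-pair table from [match_pairs()].
#' @param method `"pearson"` or `"spearman"`.
#' @param sidedness `"two_sided"` (global-level convention) or `"one_sided"`
#'   (country-level convention).
#' @return Object of class `cor_result` (`r`, `n`, `p`).
#' @export
correlate_pairs <- function(pairs, method = c("pearson", "spearman"),
                            sidedness = c("two_sided", "one_sided")) {
  cor_test_t(pairs$cancer_irsb, pairs$aid_irsb, match.arg(method),
             match.arg(sidedness))
}

#' Per-country correlation scan with BH correction
#'
#' Runs a one-sided (positive) correlation test per country with at least
#' `min_pairs` complete pairs and adjusts the p-values with the
#' Benjamini-Hochberg method across the qualifying countries only.
#'
#' @param pairs Country-level matched-pair table.
#' @param min_pairs Minimum complete pairs for a country to qualify,
#'   default 18.
#' @param method Correlation method.
#' @return Data frame with one row per qualifying country: `country`, `n`,
#'   `r`, `p`, `q`. Empty (zero rows) when no country qualifies.
#' @export
country_level_scan <- function(pairs, min_pairs = 18,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  complete <- !is.na(pairs$aid_irsb) & !is.na(pairs$cancer_irsb)
  pairs <- pairs[complete, , drop = FALSE]
  counts <- table(pairs$country)
  qualifying <- sort(names(counts)[counts >= min_pairs])
  rows <- lapply(qualifying, function(cty) {
    g <- pairs[pairs$country == cty, , drop = FALSE]
    res <- correlate_pairs(g, method, "one_sided")
    data.frame(country = cty, n = res$n, r = res$r, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(country = character(), n = integer(), r = numeric(),
                    p = numeric(), stringsAsFactors = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
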