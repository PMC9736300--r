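#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Duplicate members within a set are dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (member ids) with a
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, ": expected >= 3 tab-separated fields")
    nm[i] <- fields[1L]
    descs[i] <- fields[2L]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicated member id(s) in set '", nm[i], "'; deduplicated")
      members <- unique(members)
    }
    sets[[i]] <- members
  }
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(descs, nm)
  sets
}

#' Write gene sets in GMT format
#'
#' @param collection Named list of character vectors; descriptions taken
#'   from the `"descriptions"` attribute when present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  descs <- attr(collection, "descriptions") %||%
    setNames(rep("na", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, descs[[nm]] %||% "na", collection[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Rank genes by score for preranked GSEA
#'
#' Orders genes from greatest to least score; ties are broken
#' deterministically by gene id. Genes with missing scores are excluded
#' (never scored as zero).
#'
#' @param scores Named numeric vector of per-gene scores (e.g. ESB-IRSB
#'   correlations).
#' @return Object of class `ranked_list`: `genes`, `scores` (descending) and
#'   the tie policy.
#' @export
rank_genes <- function(scores) {
  stopifnot(!is.null(names(scores)))
  scores <- scores[!is.na(scores)]
  ord <- order(-scores, names(scores), method = "radix")
  structure(
    list(genes = names(scores)[ord], scores = unname(scores[ord]),
         tie_policy = "descending score, ties broken by gene id (ascending)"),
    class = "ranked_list"
  )
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("Ranked list of", length(x$genes), "genes (", x$tie_policy, ")\n")
  invisible(x)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: a member gene ("hit") increments the running sum
#' by its `|score|^exponent`, normalised by the sum over all member hits;
#' every non-member decrements by `1/(N - n_members)`. The enrichment score
#' is the running sum's maximum deviation from zero (signed); a tie between
#' the positive and negative extreme resolves to the positive one.
#'
#' @param ranked A `ranked_list` (see [rank_genes()]).
#' @param members Character vector of member gene ids.
#' @param exponent Weighting exponent on `|score|`; default 1 (the standard
#'   weighted statistic; 0 gives the classic unweighted KS walk).
#' @return List with `es`, the full `running` profile, the logical `hits`
#'   vector along the ranking, and the `leading_edge` gene ids.
#' @export
enrichment_score <- function(ranked, members, exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  hits <- ranked$genes %in% members
  n <- length(hits)
  k <- sum(hits)
  if (k == 0L) stop("no gene set member present in the ranked list")
  if (k == n) stop("gene set covers the whole ranked list; misses undefined")
  w <- abs(ranked$scores[hits])^exponent
  nr <- sum(w)
  step <- rep(-1 / (n - k), n)
  # all-zero hit scores: fall back to equal hit weights
  step[hits] <- if (nr > 0) w / nr else 1 / k
  running <- cumsum(step)
  max_p <- max(running); min_p <- min(running)
  # signed maximum deviation; near-exact ties go to the positive extreme
  if (max_p + min_p >= -1e-10) {
    es <- max_p; peak <- which.max(running)
  } else {
    es <- min_p; peak <- which.min(running)
  }
  leading <- if (es >= 0) ranked$genes[seq_len(peak)][hits[seq_len(peak)]]
             else ranked$genes[peak:n][hits[peak:n]]
  list(es = es, running = running, hits = hits, leading_edge = leading)
}

# Null ES distribution for a set of size k: ES of n_perm uniformly drawn
# same-size gene sets, computed in C++ over the hit positions only.
null_es <- function(absw_exp, k, n_perm) {
  gsea_null_cpp(absw_exp, as.integer(k), as.integer(n_perm))
}

#' Preranked gene set enrichment analysis
#'
#' For every gene set within the size bounds: the enrichment score on the
#' ranked list; a null ES distribution from `n_perm` random same-size gene
#' draws (gene-label permutation, shared across sets of equal size); the
#' normalised enrichment score `NES = ES / mean(|null ES| of matching
#' sign)`; a one-tailed nominal p against the matching-sign null (with the
#' add-one correction); and Benjamini-Hochberg adjustment across all tested
#' sets. Deterministic given `seed`.
#'
#' @param ranked A `ranked_list`.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param n_perm Number of permutations, >= 100; default 1000.
#' @param seed Optional integer seed for the permutation null.
#' @param min_size,max_size Size bounds on the intersection of a set with
#'   the ranked list; sets outside the bounds are skipped with a message.
#' @param exponent Hit-weighting exponent, default 1.
#' @return Object of class `gsea_result`: a data frame with one row per
#'   tested set (`pathway`, `size`, `es`, `nes`, `p_nominal`, `p_adj`,
#'   `leading_edge` list column), ordered by decreasing NES; the tie policy
#'   and seed are attached as attributes.
#' @export
gsea_prerank <- function(ranked, collection, n_perm = 1000, seed = NULL,
                         min_size = 5, max_size = 2000, exponent = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  genes <- ranked$genes
  sizes <- vapply(collection, function(s) length(intersect(s, genes)), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep))
    message("gsea_prerank: skipping ", sum(!keep),
            " set(s) outside size bounds [", min_size, ", ", max_size, "]")
  collection <- collection[keep]
  sizes <- sizes[keep]
  if (length(collection) == 0L)
    stop("no gene set within size bounds overlaps the ranked list")

  absw_exp <- abs(ranked$scores)^exponent
  nulls <- lapply(setNames(nm = sort(unique(sizes))), function(k)
    null_es(absw_exp, k, n_perm))

  rows <- lapply(seq_along(collection), function(i) {
    esr <- enrichment_score(ranked, collection[[i]], exponent)
    null <- nulls[[as.character(sizes[i])]]
    same <- if (esr$es >= 0) null[null >= 0] else null[null < 0]
    p <- (1 + sum(abs(same) >= abs(esr$es))) / (1 + length(same))
    nes <- if (length(same) > 0) esr$es / mean(abs(same)) else NA_real_
    data.frame(pathway = names(collection)[i], size = sizes[i],
               es = esr$es, nes = nes, p_nominal = p,
               leading_edge = I(list(esr$leading_edge)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_nominal, method = "BH")
  out <- out[order(-out$nes), c("pathway", "size", "es", "nes",
                                "p_nominal", "p_adj", "leading_edge")]
  rownames(out) <- NULL
  structure(out, class = c("gsea_result", "data.frame"),
            tie_policy = ranked$tie_policy, n_perm = n_perm, seed = seed,
            exponent = exponent)
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("Preranked GSEA:", nrow(x), "sets tested,",
      attr(x, "n_perm"), "permutations\n")
  show <- utils::head(as.data.frame(x)[, c("pathway", "size", "es", "nes",
                                           "p_nominal", "p_adj")], 10L)
  print(show, digits = 3)
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more sets\n")
  invisible(x)
}
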