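#' Sires eligible for model-comparison validation
#'
#' Counts phenotyped offspring per sire and flags sires reaching the
#' minimum progeny count used in sire-ranking validations.
#'
#' @param ped a [as_pedigree()] object.
#' @param phenotypes data.frame with an `animal` column (phenotyped
#'   records for one trait).
#' @param min_offspring minimum phenotyped offspring (default 10).
#' @return data.frame (sire, n_offspring, eligible) sorted by sire id;
#'   only sires with at least one phenotyped offspring appear.
#' @export
eligible_sires <- function(ped, phenotypes, min_offspring = 10) {
  ped <- as_pedigree(ped)
  sire <- ped$sire[match(phenotypes$animal, ped$animal)]
  sire <- sire[!is.na(sire) & sire != "0"]
  if (!length(sire)) {
    warning("no phenotyped offspring with known sires")
    return(data.frame(sire = character(0), n_offspring = integer(0),
                      eligible = logical(0)))
  }
  counts <- table(sire)
  out <- data.frame(sire = names(counts),
                    n_offspring = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$eligible <- out$n_offspring >= min_offspring
  out <- out[order(out$sire), , drop = FALSE]
  rownames(out) <- NULL
  if (!any(out$eligible)) warning("no sires reach min_offspring = ", min_offspring)
  out
}

#' Select the top fraction of animals by GEBV
#'
#' `k = ceiling(fraction * n)` animals are selected -- the ceiling
#' convention is the one consistent with published selected-group sizes
#' for this kind of validation. For defect traits the desirable direction
#' is a low GEBV (low defect liability), the default. Ties are broken by
#' id order, deterministically.
#'
#' @param gebv GEBV table (animal, value).
#' @param fraction selected fraction in (0, 1].
#' @param direction `"desirable_low"` (select smallest values) or
#'   `"desirable_high"`.
#' @return character vector of selected animal ids (length `k`).
#' @export
select_top <- function(gebv, fraction = 0.10,
                       direction = c("desirable_low", "desirable_high")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(gebv), all(c("animal", "value") %in% names(gebv)))
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  n <- nrow(gebv)
  k <- ceiling(fraction * n)
  v <- if (direction == "desirable_low") gebv$value else -gebv$value
  ord <- order(v, gebv$animal)
  gebv$animal[ord[seq_len(k)]]
}

#' Four-way selection concordance between two models
#'
#' Classifies an eligible sire set against equal-size selections made
#' under two models: selected by both, by one model only, or by neither
#' (`neither = n - (2k - both)`), and reports the Spearman correlation of
#' the paired GEBVs over the whole set and over the union of selected
#' sires.
#'
#' @param sel_a,sel_b selected id sets (equal size) from the two models.
#' @param all_ids the full eligible sire set.
#' @param gebv_a,gebv_b optional GEBV tables for the two models (for the
#'   Spearman correlations).
#' @return list of class `concordance_report`: n, k, both, only_a, only_b,
#'   neither, spearman_all, spearman_selected.
#' @export
concordance <- function(sel_a, sel_b, all_ids,
                        gebv_a = NULL, gebv_b = NULL) {
  sel_a <- as.character(sel_a); sel_b <- as.character(sel_b)
  all_ids <- as.character(all_ids)
  if (length(sel_a) != length(sel_b))
    stop("selections must have equal size")
  if (!all(sel_a %in% all_ids) || !all(sel_b %in% all_ids))
    stop("selections must be subsets of the eligible set")
  k <- length(sel_a)
  n <- length(all_ids)
  both <- length(intersect(sel_a, sel_b))
  out <- list(n = n, k = k, both = both,
              only_a = k - both, only_b = k - both,
              neither = n - (2L * k - both),
              spearman_all = NA_real_, spearman_selected = NA_real_)
  if (!is.null(gebv_a) && !is.null(gebv_b)) {
    va <- gebv_a$value[match(all_ids, gebv_a$animal)]
    vb <- gebv_b$value[match(all_ids, gebv_b$animal)]
    out$spearman_all <- spearman_cor(va, vb)
    sel <- union(sel_a, sel_b)
    idx <- match(sel, all_ids)
    if (length(sel) >= 3)
      out$spearman_selected <- spearman_cor(va[idx], vb[idx])
  }
  class(out) <- "concordance_report"
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance: n = %d eligible, k = %d selected per model\n", x$n, x$k))
  cat(sprintf("  both %d | only model A %d | only model B %d | neither %d\n",
              x$both, x$only_a, x$only_b, x$neither))
  if (!is.na(x$spearman_all))
    cat(sprintf("  Spearman (all: %.3f, selected: %.3f)\n",
                x$spearman_all, x$spearman_selected))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties).
#'
#' @param x,y paired numeric vectors (at least 3 finite pairs).
#' @return correlation in `[-1, 1]`; NA with a warning if either ranking
#'   has zero variance.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance; Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Pairwise Pearson correlations among per-trait GEBV tables
#'
#' GEBV correlations over a common animal set (typically proven sires)
#' serve as a proxy for genetic correlations when multi-trait models are
#' not estimable.
#'
#' @param tables named list of GEBV tables, one per trait.
#' @param common_ids animal ids present in every table (>= 3).
#' @return list of class `gebv_cor_matrix`: `r` (correlation matrix) and
#'   `n` (per-cell sample size).
#' @export
gebv_correlation_matrix <- function(tables, common_ids) {
  stopifnot(is.list(tables), length(tables) >= 1, !is.null(names(tables)))
  common_ids <- as.character(common_ids)
  if (length(common_ids) < 3) stop("common set must contain at least 3 animals")
  vals <- sapply(tables, function(tb) {
    idx <- match(common_ids, tb$animal)
    if (anyNA(idx)) stop("a table does not cover the common set")
    tb$value[idx]
  })
  r <- stats::cor(vals)
  nmat <- matrix(length(common_ids), ncol(vals), ncol(vals),
                 dimnames = dimnames(r))
  structure(list(r = r, n = nmat), class = "gebv_cor_matrix")
}
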