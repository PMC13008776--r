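# Validation against manual pathologist annotations.
#
# Manual point clicks are matched to segmented cell polygons by
# point-in-polygon with polygon consumption (a polygon can absorb only
# one click), giving TP/FP/FN counts, the Dice score 2TP/(2TP+FP+FN),
# specificity and precision-recall curves. Agreement between paired
# density measurements is tested with Spearman's rank correlation; for
# small samples without ties the two-sided p-value is computed exactly by
# full enumeration of rank permutations.

#' Match manual point annotations to segmented cell polygons
#'
#' Points are processed in file order. A point falling inside a
#' not-yet-consumed polygon is a true positive and consumes that polygon
#' (the lowest-index containing polygon when several remain); a point
#' inside no remaining polygon is a false negative (marked for the QC
#' overlay as a 3-px radius circle); polygons never consumed are false
#' positives.
#'
#' @param points data.frame with `x`, `y` in the cells' coordinate frame.
#' @param polygons list of n x 2 cell boundary matrices.
#' @return List: `counts` (`tp`, `fp`, `fn`), `point_status` ("tp" or
#'   "fn" per point), `consumed` (logical per polygon), `fn_markers`
#'   (data.frame x, y, radius_px = 3).
#' @export
match_points_to_cells <- function(points, polygons) {
  consumed <- rep(FALSE, length(polygons))
  status <- character(nrow(points))
  for (i in seq_len(nrow(points))) {
    hit <- 0L
    for (j in seq_along(polygons)) {
      if (consumed[j]) next
      if (point_in_polygon(points$x[i], points$y[i], polygons[[j]])) {
        hit <- j; break
      }
    }
    if (hit > 0L) { consumed[hit] <- TRUE; status[i] <- "tp" }
    else status[i] <- "fn"
  }
  fn <- points[status == "fn", c("x", "y"), drop = FALSE]
  if (nrow(fn) > 0) fn$radius_px <- 3
  list(counts = list(tp = sum(status == "tp"),
                     fp = sum(!consumed),
                     fn = sum(status == "fn")),
       point_status = status, consumed = consumed, fn_markers = fn)
}

#' Sorensen-Dice score from match counts
#'
#' `2 tp / (2 tp + fp + fn)`; `NA` when the denominator is zero.
#'
#' @param counts list with `tp`, `fp`, `fn`.
#' @export
dice_score <- function(counts) {
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) return(NA_real_)
  2 * counts$tp / den
}

#' Specificity and precision-recall curve for cell-level calls
#'
#' @param predicted,truth aligned logical vectors of per-cell calls.
#' @param tiers optional [cluster_tiers()] and `tier_order` (tier paths
#'   in descending inclusion order) to sweep a precision-recall curve by
#'   growing the positive tier set.
#' @param tier_order see `tiers`.
#' @return List: `specificity` (`NA` when there are no true negatives to
#'   measure), `confusion` (tp/fp/fn/tn), `prevalence` (the random-model
#'   precision baseline), and `pr` (data.frame precision/recall per
#'   sweep step) when a sweep is requested.
#' @export
classification_metrics <- function(predicted, truth, tiers = NULL,
                                   tier_order = NULL) {
  stopifnot(length(predicted) == length(truth))
  tp <- sum(predicted & truth); fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth); tn <- sum(!predicted & !truth)
  spec <- if ((tn + fp) == 0) NA_real_ else tn / (tn + fp)
  out <- list(specificity = spec,
              confusion = list(tp = tp, fp = fp, fn = fn, tn = tn),
              prevalence = mean(truth))
  if (!is.null(tiers) && !is.null(tier_order)) {
    pr <- data.frame(tier = tier_order, precision = NA_real_,
                     recall = NA_real_)
    pos <- rep(FALSE, length(truth))
    for (i in seq_along(tier_order)) {
      pos <- pos | tier_descends(tiers$paths, tier_order[i])
      pr$precision[i] <- if (sum(pos) > 0) sum(pos & truth) / sum(pos)
                         else NA_real_
      pr$recall[i] <- if (sum(truth) > 0) sum(pos & truth) / sum(truth)
                      else 0
    }
    out$pr <- pr
  }
  out
}

rank_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  prev <- rank_permutations(n - 1L)
  out <- matrix(0L, n * nrow(prev), n)
  for (i in seq_len(n)) {
    block <- (i - 1L) * nrow(prev) + seq_len(nrow(prev))
    out[block, 1] <- i
    rest <- prev
    rest[rest >= i] <- rest[rest >= i] + 1L
    out[block, -1] <- rest
  }
  out
}

#' Spearman rank correlation with an exact small-sample p-value
#'
#' rho is computed from ranks (average ranks on ties; without ties this
#' equals `1 - 6 * sum(d^2) / (n (n^2 - 1))`). For `n <= 9` without ties
#' the two-sided p-value is exact: the tail probability
#' `P(|rho_perm| >= |rho|)` over all `n!` equally likely rank
#' permutations. Larger samples or ties fall back to the t
#' approximation, flagged in the result.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return List: `rho`, `p`, `n`, `method` ("exact" or "t-approximation"),
#'   `ties` (logical). Constant input yields `rho = NA`.
#' @export
spearman_exact <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("spearman_exact: need n >= 3")
  if (anyNA(x) || anyNA(y)) stop("spearman_exact: missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined",
                ties = anyDuplicated(x) > 0 || anyDuplicated(y) > 0))
  rx <- rank(x); ry <- rank(y)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  rho <- stats::cor(rx, ry)
  if (!ties && n <= 9) {
    perms <- rank_permutations(n)
    # rho for every permutation of y-ranks against fixed x-ranks 1..n
    s <- rowSums((perms - matrix(seq_len(n), nrow(perms), n,
                                 byrow = TRUE))^2)
    rho_perm <- 1 - 6 * s / (n * (n^2 - 1))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    list(rho = rho, p = p, n = n, method = "exact", ties = FALSE)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    list(rho = rho, p = min(1, p), n = n, method = "t-approximation",
         ties = ties)
  }
}
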