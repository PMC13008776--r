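# Unsupervised cell classification.
#
# Each marker is clustered independently: its own intensity statistics
# plus the shared morphology features are z-scored, reduced by PCA to the
# components explaining 90% of the variance, and clustered with
# mini-batch k-means (fast default) or a batched Gaussian-mixture
# alternative. Cluster labels form hierarchical tiers ("3", "3.2", ...)
# that a reviewer binarizes per marker; binarization and manual per-cell
# overrides are plain data, so decisions are scriptable and replayable.

#' Reduce a feature matrix by PCA to a variance target
#'
#' Features are z-scored; zero-variance features are dropped with a
#' warning. Components are kept until the cumulative explained variance
#' reaches `var_target` (at least one, at most `n - 1`).
#'
#' @param x numeric matrix (cells x features).
#' @param var_target cumulative explained-variance target (default 0.90).
#' @return List: `scores` (cells x k), `rotation`, `center`, `scale`,
#'   `explained` (per-component fractions), `kept` (column names used).
#' @export
reduce_features_pca <- function(x, var_target = 0.90) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (nrow(x) < 2) stop("reduce_features_pca: need at least 2 cells")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    warning("reduce_features_pca: dropping ",
            sum(sds == 0 | !is.finite(sds)), " zero-variance feature(s)")
    x <- x[, sds > 0 & is.finite(sds), drop = FALSE]
  }
  if (ncol(x) == 0) stop("reduce_features_pca: no informative features")
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  k <- which(cumsum(expl) >= var_target - 1e-12)[1]
  if (is.na(k)) k <- length(expl)
  k <- max(1L, min(k, nrow(x) - 1L))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       rotation = p$rotation[, seq_len(k), drop = FALSE],
       center = p$center, scale = p$scale,
       explained = expl, kept = colnames(x))
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  if (k > 1) for (j in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1, prob = p)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

assign_nearest <- function(x, centers) {
  # squared distances via the expansion ||x||^2 - 2 x.c + ||c||^2
  cross <- x %*% t(centers)
  d2 <- matrix(rowSums(centers^2), nrow(x), nrow(centers), byrow = TRUE) -
    2 * cross
  max.col(-d2, ties.method = "first")
}

#' Mini-batch k-means clustering
#'
#' Web-scale k-means variant: k-means++ initialisation on the first
#' random batch, then per-batch assignment with per-centre counts as
#' decaying learning rates. Deterministic for a given seed.
#'
#' @param x numeric matrix (cells x features), typically PCA scores.
#' @param k number of clusters (`1 <= k <= n`).
#' @param seed RNG seed.
#' @param batch_size mini-batch size (default 1024).
#' @param iters number of mini-batch iterations (default 100).
#' @param nstart independent restarts (each with its own derived seed);
#'   the run with the lowest inertia wins.
#' @return List: `labels` (1..k), `centers`, `inertia` (total
#'   within-cluster sum of squares over all points).
#' @export
cluster_minibatch_kmeans <- function(x, k, seed = 1, batch_size = 1024,
                                     iters = 100, nstart = 5) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("cluster_minibatch_kmeans: k exceeds number of cells")
  if (k < 1) stop("cluster_minibatch_kmeans: k must be >= 1")
  if (nstart > 1) {
    runs <- lapply(seq_len(nstart), function(r)
      cluster_minibatch_kmeans(x, k, seed = seed + (r - 1) * 1009L,
                               batch_size = batch_size, iters = iters,
                               nstart = 1))
    return(runs[[which.min(vapply(runs, `[[`, 1, "inertia"))]])
  }
  with_seed(seed, {
    b <- min(batch_size, n)
    first <- sample.int(n, b)
    centers <- kmeanspp_init(x[first, , drop = FALSE], k)
    counts <- rep(0, k)
    for (it in seq_len(iters)) {
      batch <- x[sample.int(n, b), , drop = FALSE]
      lab <- assign_nearest(batch, centers)
      for (j in unique(lab)) {
        pts <- batch[lab == j, , drop = FALSE]
        m <- nrow(pts)
        # per-centre count learning rate 1/count makes the centre the
        # running mean of every point ever assigned to it
        centers[j, ] <- (counts[j] * centers[j, ] + colSums(pts)) /
          (counts[j] + m)
        counts[j] <- counts[j] + m
      }
    }
    # re-seed any centre that never saw a point
    dead <- which(counts == 0)
    if (length(dead) > 0)
      centers[dead, ] <- x[sample.int(n, length(dead)), , drop = FALSE]
    labels <- assign_nearest(x, centers)
    inertia <- sum((x - centers[labels, , drop = FALSE])^2)
    list(labels = labels, centers = centers, inertia = inertia)
  })
}

#' Hierarchical cluster tiers for one marker
#'
#' @param marker marker name.
#' @param labels integer cluster labels (1..k) per cell.
#' @return `cluster_tier` object: per-cell deepest tier paths ("3",
#'   "3.2", ...).
#' @export
cluster_tiers <- function(marker, labels) {
  structure(list(marker = marker, paths = as.character(labels)),
            class = "cluster_tier")
}

#' @export
print.cluster_tier <- function(x, ...) {
  cat(sprintf("<cluster_tier '%s': %d cells, %d tier(s)>\n",
              x$marker, length(x$paths), length(unique(x$paths))))
  invisible(x)
}

tier_descends <- function(paths, parent) {
  paths == parent | startsWith(paths, paste0(parent, "."))
}

#' Reclassify one tier into subtiers
#'
#' Runs k-means on the cells of one tier only, extending their paths
#' ("3" -> "3.1" ... "3.k"); every other cell is untouched, so child
#' paths always partition their parent.
#'
#' @param tiers a [cluster_tiers()] object.
#' @param x full feature/score matrix (all cells, rows aligned to tiers).
#' @param parent_path tier to subdivide (deepest-path match).
#' @param k_sub number of subtiers.
#' @param seed RNG seed.
#' @return Updated `cluster_tier`.
#' @export
reclassify_cluster <- function(tiers, x, parent_path, k_sub, seed = 1) {
  sel <- which(tiers$paths == parent_path)
  if (length(sel) == 0) stop("reclassify_cluster: empty parent tier ",
                             parent_path)
  if (k_sub > length(sel))
    stop("reclassify_cluster: k_sub exceeds cells in parent")
  sub <- with_seed(seed,
    stats::kmeans(x[sel, , drop = FALSE], centers = k_sub, nstart = 5))
  tiers$paths[sel] <- paste0(parent_path, ".", sub$cluster)
  tiers
}

#' Batched Gaussian-mixture clustering alternative
#'
#' Mirrors the slower high-resolution path: sample up to `n_sample`
#' cells, PCA to `pca_var`, project to a deterministic 2-D embedding
#' (the two leading principal components), split the sample into up to
#' `max_models` batches, fit one `k_final`-component Gaussian mixture
#' per batch (EM started from shared initial centroids), pool the
#' component means, z-score them per feature and merge by k-means into
#' `k_final` final centroids. Unsampled cells inherit the label of their
#' nearest sampled neighbour in PCA space.
#'
#' @param x numeric feature matrix (cells x features).
#' @param k_final final number of clusters.
#' @param seed RNG seed.
#' @param n_sample cells sampled for model fitting (default 50000).
#' @param batch_target target batch size (default 833, giving ~60
#'   batches at a full sample).
#' @param max_models cap on the number of batch models (default 60).
#' @param pca_var PCA variance target.
#' @return List: `labels` (1..k_final for every cell), `n_models`,
#'   `merged_centers` (in embedding space).
#' @export
cluster_gmm_alternative <- function(x, k_final, seed = 1, n_sample = 50000,
                                    batch_target = 833, max_models = 60,
                                    pca_var = 0.90) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  n <- nrow(x)
  if (n < k_final) stop("cluster_gmm_alternative: fewer cells than clusters")
  with_seed(seed, {
    ns <- min(n, n_sample)
    if (n < n_sample)
      warning("cluster_gmm_alternative: ", n, " cells < ", n_sample,
              "; model count scaled down")
    idx <- sample.int(n, ns)
    red <- reduce_features_pca(x[idx, , drop = FALSE], var_target = pca_var)
    # project all cells with the sampled basis
    xs <- scale(x[, red$kept, drop = FALSE], center = red$center,
                scale = red$scale)
    all_scores <- xs %*% red$rotation
    emb_cols <- seq_len(min(2L, ncol(all_scores)))
    emb <- all_scores[idx, emb_cols, drop = FALSE]

    n_batches <- max(1L, min(max_models, ceiling(ns / batch_target)))
    batch_of <- sample(rep_len(seq_len(n_batches), ns))
    shared_init <- with_seed(seed + 1L,
      stats::kmeans(emb, centers = min(k_final, nrow(emb)),
                    nstart = 3, iter.max = 50))$centers

    comp_means <- list(); sample_labels <- integer(ns); comp_of_batch <- list()
    for (bidx in seq_len(n_batches)) {
      rows <- which(batch_of == bidx)
      eb <- emb[rows, , drop = FALSE]
      ass <- assign_nearest(eb, shared_init)
      z <- matrix(1e-6, nrow(eb), nrow(shared_init))
      z[cbind(seq_len(nrow(eb)), ass)] <- 1
      z <- z / rowSums(z)
      fit <- tryCatch(
        mclust::me(modelName = "VVI", data = eb, z = z),
        error = function(e) NULL)
      if (is.null(fit) || is.null(fit$parameters$mean) ||
          anyNA(fit$parameters$mean)) {
        # degenerate batch: fall back to the shared-centroid assignment
        mu <- t(shared_init)
        zf <- z
      } else {
        mu <- fit$parameters$mean
        zf <- fit$z
      }
      comp <- max.col(zf, ties.method = "first")
      offset <- length(comp_means)
      sample_labels[rows] <- comp + offset
      for (j in seq_len(ncol(mu))) comp_means[[offset + j]] <- mu[, j]
    }
    M <- do.call(rbind, comp_means)
    Mz <- scale(M)
    Mz[!is.finite(Mz)] <- 0
    if (nrow(Mz) <= k_final) {
      # as many pooled component means as final clusters: nothing to merge
      merged <- list(cluster = seq_len(nrow(Mz)), centers = Mz)
    } else {
      merged <- stats::kmeans(Mz, centers = k_final, nstart = 10,
                              iter.max = 100)
    }
    lab_sampled <- merged$cluster[sample_labels]

    labels <- integer(n)
    labels[idx] <- lab_sampled
    rest <- setdiff(seq_len(n), idx)
    if (length(rest) > 0) {
      nn <- assign_nearest(all_scores[rest, , drop = FALSE],
                           all_scores[idx, , drop = FALSE])
      labels[rest] <- lab_sampled[nn]
    }
    list(labels = labels, n_models = n_batches, merged_centers = merged$centers)
  })
}

#' Construct a binarization decision for one marker
#'
#' @param marker marker name.
#' @param positive_paths tier paths marked positive (cells in them or in
#'   any descendant subtier are positive).
#' @param overrides data.frame with `cell` (row index) and `positive`
#'   (logical); overrides take precedence over tier decisions.
#' @export
binarization_decision <- function(marker, positive_paths = character(0),
                                  overrides = data.frame(cell = integer(0),
                                                         positive = logical(0))) {
  structure(list(marker = marker, positive_paths = positive_paths,
                 overrides = overrides),
            class = "binarization_decision")
}

#' Apply a binarization decision to cluster tiers
#'
#' A cell is positive iff its deepest tier path is in (or descends from)
#' a positive path, unless a manual override says otherwise. Unknown
#' paths in the decision are an error.
#'
#' @param tiers a [cluster_tiers()] object.
#' @param decision a [binarization_decision()].
#' @return Logical vector of per-cell marker calls.
#' @export
apply_binarization <- function(tiers, decision) {
  known <- unique(tiers$paths)
  for (p in decision$positive_paths) {
    if (!any(tier_descends(known, p)))
      stop("apply_binarization: unknown tier path ", p)
  }
  call <- rep(FALSE, length(tiers$paths))
  for (p in decision$positive_paths)
    call <- call | tier_descends(tiers$paths, p)
  ov <- decision$overrides
  if (nrow(ov) > 0) call[ov$cell] <- ov$positive
  call
}

#' Rank tiers by mean marker intensity and pick the top mass
#'
#' Helper for programmatic binarization and precision-recall sweeps:
#' tiers are ordered by descending mean chromogen OD; the positive set is
#' grown in that order until it covers at least `target_count` cells.
#'
#' @param tiers a [cluster_tiers()] object.
#' @param intensity per-cell chromogen intensity (e.g. cytoplasm mean OD).
#' @param target_count number of cells the positive set should cover.
#' @return List: `order` (tier paths, descending intensity), `positive`
#'   (selected paths), `cum_count`.
#' @export
select_top_tiers <- function(tiers, intensity, target_count) {
  means <- tapply(intensity, tiers$paths, mean)
  sizes <- table(tiers$paths)
  ord <- names(sort(means, decreasing = TRUE))
  cum <- cumsum(as.numeric(sizes[ord]))
  n_take <- if (any(cum >= target_count)) which(cum >= target_count)[1]
            else length(ord)
  list(order = ord, positive = ord[seq_len(n_take)], cum_count = cum)
}
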