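# Shared fixture builders (everything is generated in code at test time).

# nearest-neighbour distance from each row of a to rows of b
min_dists <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# a clean raster of disc nuclei with known centres; returns list(od, centres)
disc_field <- function(n, h, w, r = 5, sep = 16, od = 0.8, seed = 1) {
  set.seed(seed)
  xs <- ys <- numeric(0)
  while (length(xs) < n) {
    x <- runif(1, r + 2, w - r - 3); y <- runif(1, r + 2, h - r - 3)
    if (length(xs) == 0 || min((xs - x)^2 + (ys - y)^2) >= sep^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  m <- matrix(0, h, w)
  for (i in seq_len(n))
    m <- stainplex:::paint_ellipse(m, xs[i], ys[i], r, r, 0, od)
  list(od = EBImage::gblur(m, 0.7), centres = cbind(x = xs, y = ys))
}

# independent union-find consensus oracle for composite reconciliation:
# groups detections across stains by single linkage at `radius`, then keeps
# groups with at least ceil(consensus * n_stains) members (at most one per
# stain); valid when true objects are separated by >> 2 * radius.
oracle_consensus <- function(per_stain, radius, consensus) {
  pts <- do.call(rbind, lapply(seq_along(per_stain), function(s) {
    ns <- per_stain[[s]]
    if (nrow(ns) == 0) return(NULL)
    cbind(stain = s, x = ns$cx, y = ns$cy)
  }))
  if (is.null(pts)) return(NULL)
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (pts[i, "stain"] == pts[j, "stain"]) next
    if ((pts[i, "x"] - pts[j, "x"])^2 + (pts[i, "y"] - pts[j, "y"])^2 <=
        radius^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  groups <- split(seq_len(n), roots)
  need <- ceiling(consensus * length(per_stain) - 1e-9)
  keep <- Filter(function(g) length(unique(pts[g, "stain"])) >= need, groups)
  t(vapply(keep, function(g) c(x = mean(pts[g, "x"]), y = mean(pts[g, "y"])),
           numeric(2)))
}
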