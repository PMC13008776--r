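# Compartment reconciliation and spatial proximity statistics.
#
# Cells are assigned to pathologist-annotated compartments by
# point-in-polygon (boundary counted inside, overlaps resolved by
# annotation file order). Proximity between two cell populations is
# summarized as the mode of the Gaussian kernel density estimate of the
# nearest-neighbour distance distribution: for each cell of population A,
# the Euclidean distance (between centroids, in um) to its nearest
# neighbour in population B.

#' Point-in-polygon test (boundary inclusive)
#'
#' Ray casting with an explicit on-edge check, so points exactly on a
#' polygon edge or vertex count as inside.
#'
#' @param x,y point coordinate vectors.
#' @param poly n x 2 vertex matrix (closed implicitly).
#' @param eps tolerance for the on-edge test.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, poly, eps = 1e-9) {
  n <- nrow(poly)
  if (n < 3) stop("point_in_polygon: need at least 3 vertices")
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-segment test
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx^2 + dy^2
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((x - xi) * dx + (y - yi) * dy) / len2))
      d2 <- (x - (xi + t * dx))^2 + (y - (yi + t * dy))^2
      on_edge <- on_edge | d2 <= eps^2
    } else {
      on_edge <- on_edge | ((x - xi)^2 + (y - yi)^2 <= eps^2)
    }
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Assign cells to annotated compartments
#'
#' Boundary points count as inside; where polygons overlap the first
#' matching polygon in annotation file order wins (pathologist annotation
#' order is the only available priority signal); cells outside every
#' polygon are labelled `"unassigned"`. Degenerate polygons (< 3 vertices
#' or non-finite coordinates) are skipped with a warning.
#'
#' @param x,y cell centroid vectors (level-0 px, same frame as the
#'   annotations).
#' @param annotations an [annotation_set()].
#' @return Character vector of compartment names.
#' @export
assign_compartments <- function(x, y, annotations) {
  out <- rep("unassigned", length(x))
  todo <- rep(TRUE, length(x))
  for (p in annotations$polygons) {
    if (nrow(p$coords) < 3 || any(!is.finite(p$coords))) {
      warning("assign_compartments: skipping invalid polygon '", p$name, "'")
      next
    }
    if (!any(todo)) break
    hit <- todo
    hit[todo] <- point_in_polygon(x[todo], y[todo], p$coords)
    out[hit] <- p$name
    todo <- todo & !hit
  }
  out
}

#' Polygon area (shoelace formula)
#' @param poly n x 2 vertex matrix.
#' @return Area in squared input units.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Cell density in cells per mm^2
#'
#' @param count number of (positive) cells.
#' @param area_mm2 compartment or tissue area in mm^2.
#' @export
compute_density <- function(count, area_mm2) {
  if (area_mm2 <= 0) stop("compute_density: area must be positive")
  count / area_mm2
}

#' Compartment areas in mm^2 from polygon annotations
#' @param annotations an [annotation_set()] with level-0 px coordinates.
#' @param mpp microns per pixel.
#' @return Named numeric vector (summed per compartment name).
#' @export
compartment_areas_mm2 <- function(annotations, mpp) {
  areas <- sapply(annotations$polygons, function(p) polygon_area(p$coords))
  names(areas) <- sapply(annotations$polygons, `[[`, "name")
  tapply(areas * mpp^2 / 1e6, names(areas), sum)
}

#' Nearest-neighbour distances between two cell populations
#'
#' For every point of A, the exact Euclidean distance to its nearest
#' neighbour in B. When `same_population` the self-match at distance 0 is
#' excluded (A and B must then be the same matrix, row for row).
#'
#' @param a,b point matrices (columns x, y) in um.
#' @param same_population logical.
#' @return Numeric vector, one distance per row of `a`.
#' @export
nn_distances <- function(a, b, same_population = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(b) == 0) stop("nn_distances: population B is empty")
  if (same_population) {
    if (nrow(a) < 2) stop("nn_distances: population A needs >= 2 cells")
    if (!isTRUE(all.equal(a, b, check.attributes = FALSE)))
      stop("nn_distances: same_population requires A == B")
  }
  out <- numeric(nrow(a))
  chunk <- max(1L, floor(4e6 / nrow(b)))
  for (start in seq(1, nrow(a), by = chunk)) {
    rows <- start:min(start + chunk - 1, nrow(a))
    # difference form (not the expanded quadratic): exact, matching an
    # elementwise brute force bit for bit
    d2 <- outer(a[rows, 1], b[, 1], "-")^2 + outer(a[rows, 2], b[, 2], "-")^2
    if (same_population)
      d2[cbind(seq_along(rows), rows)] <- Inf
    out[rows] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Mode of a Gaussian kernel density estimate
#'
#' The KDE is evaluated on a 512-point grid over `[0, max + 3 *
#' bandwidth]`; the mode is the grid argmax (ties resolved to the
#' smallest distance). The default bandwidth is Scott's rule,
#' `sd(x) * n^(-1/5)`. Identical distances short-circuit to that value.
#'
#' @param distances numeric vector (um), at least 2 finite values.
#' @param bandwidth optional KDE bandwidth (um).
#' @return List: `mode` (um), `bandwidth`.
#' @export
kde_mode <- function(distances, bandwidth = NULL) {
  d <- distances[is.finite(distances)]
  if (length(d) < 2) stop("kde_mode: need at least 2 finite distances")
  if (diff(range(d)) < 1e-12)
    return(list(mode = d[1], bandwidth = bandwidth %||% 0))
  if (is.null(bandwidth)) bandwidth <- stats::sd(d) * length(d)^(-1 / 5)
  dens <- stats::density(d, bw = bandwidth, kernel = "gaussian",
                         from = 0, to = max(d) + 3 * bandwidth, n = 512)
  list(mode = dens$x[which.max(dens$y)], bandwidth = bandwidth)
}

#' Proximity summary over population pairs and compartments
#'
#' For each ordered pair (A, B) and each compartment, computes the
#' nearest-neighbour distance distribution of A's cells to B's cells and
#' its KDE mode. Pairs with fewer than 2 A cells, an empty B, or (for
#' A = B) fewer than 2 shared cells are skipped.
#'
#' @param cells data.frame with `x_um`, `y_um`, `compartment`, and one
#'   logical call column per population name.
#' @param pairs data.frame with columns `a`, `b` naming call columns.
#' @param sample_id identifier copied into the output.
#' @return data.frame: sample, compartment, pop_a, pop_b, n_a, n_b,
#'   mode_um, bandwidth_um.
#' @export
proximity_summary <- function(cells, pairs, sample_id = "sample") {
  comps <- unique(cells$compartment)
  rows <- list()
  for (ci in comps) {
    sub <- cells[cells$compartment == ci, , drop = FALSE]
    for (pi in seq_len(nrow(pairs))) {
      an <- pairs$a[pi]; bn <- pairs$b[pi]
      A <- as.matrix(sub[sub[[an]], c("x_um", "y_um")])
      B <- as.matrix(sub[sub[[bn]], c("x_um", "y_um")])
      same <- identical(an, bn)
      if (nrow(A) < 2 || nrow(B) < 1 || (same && nrow(B) < 2)) next
      d <- nn_distances(A, B, same_population = same)
      km <- kde_mode(d)
      rows[[length(rows) + 1]] <- data.frame(
        sample = sample_id, compartment = ci, pop_a = an, pop_b = bn,
        n_a = nrow(A), n_b = nrow(B),
        mode_um = km$mode, bandwidth_um = km$bandwidth,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(sample = character(0), compartment = character(0),
                      pop_a = character(0), pop_b = character(0),
                      n_a = integer(0), n_b = integer(0),
                      mode_um = numeric(0), bandwidth_um = numeric(0)))
  do.call(rbind, rows)
}
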