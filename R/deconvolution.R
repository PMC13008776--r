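# Colour deconvolution of chromogenic brightfield stains.
#
# Stain concentrations mix linearly in optical-density (OD) space
# (Beer-Lambert): od = M %*% c, where M has one unit-norm column per stain.
# We estimate M from the slide thumbnail (Macenko-style percentile angles in
# the principal OD plane) and unmix each tile by a per-pixel linear solve.

#' Convert RGB intensities to optical density
#'
#' `od = -log10(max(rgb, 1) / i0)`, elementwise. White (`i0`) maps to 0;
#' intensities are clamped at 1 so the result is always finite.
#'
#' @param rgb raster (matrix or array) with values in `[0, i0]`.
#' @param i0 incident (white) level, default 255.
#' @return Raster of the same shape, non-negative.
#' @export
rgb_to_od <- function(rgb, i0 = 255) {
  -log10(pmax(rgb, 1) / i0)
}

#' Convert optical density back to RGB intensities
#' @param od non-negative raster.
#' @inheritParams rgb_to_od
#' @export
od_to_rgb <- function(od, i0 = 255) {
  pmin(pmax(i0 * 10^(-od), 0), i0)
}

#' Reference stain OD vectors (unit norm)
#'
#' Standard published hues for the haematoxylin nuclear counterstain and
#' the AEC chromogen, used to label the columns of an estimated stain
#' matrix and as rendering defaults for the synthetic generator.
#'
#' @return Named list of unit 3-vectors `haematoxylin`, `aec`, `dab`.
#' @export
reference_stain_vectors <- function() {
  unit <- function(v) v / sqrt(sum(v^2))
  list(
    haematoxylin = unit(c(0.651, 0.701, 0.290)),
    aec          = unit(c(0.2743, 0.6796, 0.6803)),
    dab          = unit(c(0.269, 0.568, 0.778))
  )
}

#' Build a stain matrix from chromogen and nuclear OD vectors
#'
#' The residual column is the unit cross product of the two stain vectors,
#' so the three columns always span OD space.
#'
#' @param chromogen,nuclear OD 3-vectors (need not be unit norm).
#' @return A 3x3 matrix of class `stain_matrix`, columns
#'   `chromogen`, `nuclear`, `residual`, each unit norm.
#' @export
stain_matrix <- function(chromogen, nuclear) {
  unit <- function(v) v / sqrt(sum(v^2))
  ch <- unit(chromogen); nu <- unit(nuclear)
  res <- c(ch[2] * nu[3] - ch[3] * nu[2],
           ch[3] * nu[1] - ch[1] * nu[3],
           ch[1] * nu[2] - ch[2] * nu[1])
  if (sqrt(sum(res^2)) < 1e-9)
    stop("stain_matrix: chromogen and nuclear vectors are collinear")
  res <- unit(res)
  if (sum(res) < 0) res <- -res
  m <- cbind(chromogen = ch, nuclear = nu, residual = res)
  class(m) <- c("stain_matrix", class(m))
  m
}

#' Estimate a stain matrix from a slide thumbnail
#'
#' Macenko-style estimation: tissue pixels (OD norm above `od_floor`) are
#' projected onto the plane of the two leading principal components of OD;
#' the stain vectors are taken at the `percentile` and `1 - percentile`
#' extremes of the angular distribution in that plane. Columns are labelled
#' chromogen/nuclear by cosine similarity against the reference hues
#' (AEC is red-shifted, haematoxylin blue-purple).
#'
#' @param thumbnail RGB raster (h x w x 3, values 0-255).
#' @param od_floor minimum OD Euclidean norm for a pixel to count as tissue.
#' @param percentile angular percentile (default 0.01, i.e. 1%/99%).
#' @param reference named list with elements `chromogen` and `nuclear`
#'   giving reference hues; defaults to AEC and haematoxylin.
#' @return A [stain_matrix()].
#' @export
estimate_stain_matrix <- function(thumbnail, od_floor = 0.15, percentile = 0.01,
                                  reference = NULL) {
  if (is.null(reference)) {
    refs <- reference_stain_vectors()
    reference <- list(chromogen = refs$aec, nuclear = refs$haematoxylin)
  }
  od <- rgb_to_od(thumbnail)
  pix <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  keep <- sqrt(rowSums(pix^2)) > od_floor
  if (sum(keep) < 100) stop("estimate_stain_matrix: insufficient tissue")
  pix <- pix[keep, , drop = FALSE]
  v <- eigen(stats::cov(pix), symmetric = TRUE)$vectors[, 1:2, drop = FALSE]
  # orient the plane basis so projections are mostly positive
  for (j in 1:2) if (sum(pix %*% v[, j]) < 0) v[, j] <- -v[, j]
  proj <- pix %*% v
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(percentile, 1 - percentile), names = FALSE)
  vec_at <- function(a) {
    s <- as.vector(v %*% c(cos(a), sin(a)))
    if (sum(s) < 0) s <- -s
    s / sqrt(sum(s^2))
  }
  s1 <- vec_at(q[1]); s2 <- vec_at(q[2])
  cs <- function(a, b) sum(a * b)
  # assign extremes to chromogen/nuclear by reference-hue similarity
  if (cs(s1, reference$chromogen) + cs(s2, reference$nuclear) >=
      cs(s2, reference$chromogen) + cs(s1, reference$nuclear)) {
    stain_matrix(chromogen = s1, nuclear = s2)
  } else {
    stain_matrix(chromogen = s2, nuclear = s1)
  }
}

#' Unmix an RGB tile into chromogen, nuclear and residual OD channels
#'
#' Per-pixel solve of `od = M %*% c`; since `M` is square the solve is
#' exact, and negative concentrations are clipped to zero.
#'
#' @param tile RGB raster (h x w x 3, values 0-255).
#' @param m a [stain_matrix()] (or any invertible 3x3 matrix with columns
#'   chromogen, nuclear, residual).
#' @return List of three h x w matrices: `chromogen`, `nuclear`, `residual`.
#' @export
deconvolve_tile <- function(tile, m) {
  if (!is.matrix(unclass(m)) || any(dim(unclass(m)) != c(3, 3)))
    stop("deconvolve_tile: stain matrix must be 3x3")
  mm <- unclass(m)
  if (kappa(mm) > 1e8) stop("deconvolve_tile: singular stain matrix")
  d <- dim(tile)
  od <- rgb_to_od(tile)
  odm <- rbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  conc <- solve(mm, odm)
  conc[conc < 0] <- 0
  shape <- function(i) matrix(conc[i, ], nrow = d[1], ncol = d[2])
  list(chromogen = shape(1), nuclear = shape(2), residual = shape(3))
}

#' Re-compose OD concentrations into an RGB raster
#'
#' Inverse of [deconvolve_tile()] for rendering and round-trip checks.
#'
#' @param conc list of three h x w concentration matrices in the column
#'   order of `m`.
#' @param m a [stain_matrix()].
#' @inheritParams rgb_to_od
#' @return RGB raster (h x w x 3, values 0-255).
#' @export
compose_rgb <- function(conc, m, i0 = 255) {
  mm <- unclass(m)
  h <- nrow(conc[[1]]); w <- ncol(conc[[1]])
  out <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    od <- mm[ch, 1] * conc[[1]] + mm[ch, 2] * conc[[2]] + mm[ch, 3] * conc[[3]]
    out[, , ch] <- od_to_rgb(od, i0)
  }
  out
}
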