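# Ground-truthed synthetic slides.
#
# The generator emulates the data model of iterative chromogenic multiplex
# staining: one RGB slide per staining round, a haematoxylin-stained
# nucleus for every cell on every round it survives, an AEC-stained
# cytoplasm ring on rounds where the cell is positive for that round's
# marker, anucleate red-blood-cell-like discs, single-round artefacts, a
# known per-round geometric warp, and Gaussian pixel noise. Everything
# rendered is recorded in the returned ground truth, so segmentation,
# registration and classification error are measurable against analytic
# truth rather than image similarity alone.

place_points <- function(n, width, height, min_sep, margin) {
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L; max_attempts <- 200L * max(n, 1L)
  while (length(xs) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("place_points: cannot place ", n,
           " objects without touching; lower the density")
    x <- stats::runif(1, margin, width - 1 - margin)
    y <- stats::runif(1, margin, height - 1 - margin)
    if (length(xs) == 0 || min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  cbind(x = xs, y = ys)
}

# paint an ellipse (additively) into a concentration matrix
paint_ellipse <- function(conc, cx, cy, a, b, theta, value, grow = 0) {
  h <- nrow(conc); w <- ncol(conc)
  a <- a + grow; b <- b + grow
  r <- ceiling(max(a, b)) + 1
  x0 <- max(0, floor(cx - r)); x1 <- min(w - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(h - 1, ceiling(cy + r))
  if (x1 < x0 || y1 < y0) return(conc)
  xs <- x0:x1; ys <- y0:y1
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE) - cx
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs)) - cy
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- conc[ys + 1, xs + 1, drop = FALSE]
  sub[inside] <- sub[inside] + value
  conc[ys + 1, xs + 1] <- sub
  conc
}

forward_warp_points <- function(x, y, warp, width, height) {
  cx <- (width - 1) / 2; cy <- (height - 1) / 2
  th <- warp$theta_deg * pi / 180
  xr <- cos(th) * (x - cx) - sin(th) * (y - cy) + cx + warp$dx
  yr <- sin(th) * (x - cx) + cos(th) * (y - cy) + cy + warp$dy
  if (warp$elastic_amp > 0) {
    xr <- xr + warp$elastic_amp * sin(2 * pi * y / warp$elastic_wavelength + warp$phase[1])
    yr <- yr + warp$elastic_amp * sin(2 * pi * x / warp$elastic_wavelength + warp$phase[2])
  }
  cbind(x = xr, y = yr)
}

#' The identity (no-op) warp parameter set
#'
#' Template for per-round warp parameters accepted by
#' [render_micsss_panel()]: an affine part (`theta_deg`, `dx`, `dy`,
#' rotation about the slide centre plus translation) and a smooth
#' sinusoidal elastic part (`elastic_amp`, `elastic_wavelength`,
#' `phase`).
#'
#' @return Named list of warp parameters describing no deformation.
#' @export
identity_warp <- function() {
  list(theta_deg = 0, dx = 0, dy = 0, elastic_amp = 0,
       elastic_wavelength = 300, phase = c(0, 0))
}

#' Render a synthetic iterative-staining panel with known ground truth
#'
#' Produces one RGB slide raster per staining round plus a complete
#' ground-truth record. Cells carry a haematoxylin-like nuclear OD on
#' every round they survive (per-round dropout), an AEC-like cytoplasm
#' ring on rounds whose marker they are positive for, plus optional
#' anucleate high-residual discs (red-blood-cell stand-ins) and
#' single-round nuclear artefacts. Rounds after the first can be warped
#' by a known affine plus smooth sinusoidal elastic displacement.
#'
#' @param n_stains number of staining rounds (round 1 is the reference).
#' @param n_cells number of true cells.
#' @param width,height slide size in pixels.
#' @param positive_frac fraction of cells positive per round's marker
#'   (scalar or vector of length `n_stains`); planted exactly.
#' @param artifact_count nuclear-like objects appearing in exactly one round.
#' @param rbc_count anucleate high-residual discs present in all rounds.
#' @param dropout_rate per-round probability a cell fails to appear.
#' @param warp_magnitude maximum displacement (px) of the per-round random
#'   warps; 0 renders all rounds in the common frame. Ignored when `warps`
#'   is supplied.
#' @param warps optional list (length `n_stains`) of warp parameter lists
#'   (`theta_deg`, `dx`, `dy`, `elastic_amp`, `elastic_wavelength`,
#'   `phase`); see [identity_warp()] for the shape.
#' @param noise_sd Gaussian pixel noise (grey levels, RGB scale).
#' @param nucleus_radius range (min, max) of nucleus semi-major axes, px.
#' @param cytoplasm_px ring width of the rendered positive chromogen, px.
#' @param min_separation minimum centre distance between objects, px.
#' @param mpp microns per pixel.
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @param stain_names character vector of round (marker) names.
#' @return List with `slides` (list of h x w x 3 rasters), `truth`
#'   (see Details), `stain_matrix`, `mpp`, `stain_names`.
#'   `truth$objects` is a data.frame (id, x, y, a, b, theta, nuclear_od,
#'   type); `truth$present`, `truth$positive` are objects x rounds logical
#'   matrices; `truth$warped[[s]]` the forward-warped centroids on round s;
#'   `truth$warps` the warp parameters.
#' @export
render_micsss_panel <- function(n_stains = 5, n_cells = 500,
                                width = 1400, height = 1400,
                                positive_frac = 0.2, artifact_count = 20,
                                rbc_count = 0, dropout_rate = 0.1,
                                warp_magnitude = 0, warps = NULL,
                                noise_sd = 2, nucleus_radius = c(4.5, 6.5),
                                cytoplasm_px = 3, min_separation = 17,
                                mpp = 0.5, seed = 1,
                                stain_names = paste0("M", seq_len(n_stains))) {
  stopifnot(n_stains >= 1, n_cells >= 0, dropout_rate >= 0, dropout_rate < 1)
  positive_frac <- rep_len(positive_frac, n_stains)
  refs <- reference_stain_vectors()
  M <- stain_matrix(chromogen = refs$aec, nuclear = refs$haematoxylin)

  with_seed(seed, {
    n_obj <- n_cells + rbc_count + artifact_count
    pos <- if (n_obj > 0)
      place_points(n_obj, width, height, min_separation,
                   margin = max(nucleus_radius) + cytoplasm_px + 2)
    else cbind(x = numeric(0), y = numeric(0))
    type <- rep(c("cell", "rbc", "artifact"),
                c(n_cells, rbc_count, artifact_count))
    a <- stats::runif(n_obj, nucleus_radius[1], nucleus_radius[2])
    b <- a * stats::runif(n_obj, 0.8, 1)
    th <- stats::runif(n_obj, 0, pi)
    nuclear_od <- stats::runif(n_obj, 0.6, 1.0)
    nuclear_od[type == "rbc"] <- 0.22
    residual_od <- rep(0, n_obj)
    residual_od[type == "rbc"] <- 0.6
    artifact_stain <- rep(NA_integer_, n_obj)
    if (artifact_count > 0)
      artifact_stain[type == "artifact"] <-
        sample(seq_len(n_stains), artifact_count, replace = TRUE)

    # presence: cells drop out per round; RBCs always present; artefacts
    # present only on their single round
    present <- matrix(TRUE, n_obj, n_stains)
    if (n_cells > 0 && dropout_rate > 0)
      present[type == "cell", ] <-
        matrix(stats::runif(n_cells * n_stains) >= dropout_rate,
               n_cells, n_stains)
    for (i in which(type == "artifact"))
      present[i, ] <- seq_len(n_stains) == artifact_stain[i]

    positive <- matrix(FALSE, n_obj, n_stains)
    cell_idx <- which(type == "cell")
    for (s in seq_len(n_stains)) {
      npos <- round(positive_frac[s] * n_cells)
      if (npos > 0)
        positive[sample(cell_idx, npos), s] <- TRUE
    }

    if (is.null(warps)) {
      warps <- vector("list", n_stains)
      warps[[1]] <- identity_warp()
      if (n_stains > 1) for (s in 2:n_stains) {
        w <- identity_warp()
        if (warp_magnitude > 0) {
          w$theta_deg <- stats::runif(1, -0.4, 0.4)
          w$dx <- stats::runif(1, -1, 1) * warp_magnitude / 2
          w$dy <- stats::runif(1, -1, 1) * warp_magnitude / 2
          w$elastic_amp <- warp_magnitude / 2
          w$phase <- stats::runif(2, 0, 2 * pi)
        }
        warps[[s]] <- w
      }
    }

    slides <- vector("list", n_stains)
    warped <- vector("list", n_stains)
    for (s in seq_len(n_stains)) {
      wp <- if (n_obj > 0)
        forward_warp_points(pos[, "x"], pos[, "y"], warps[[s]], width, height)
      else cbind(x = numeric(0), y = numeric(0))
      warped[[s]] <- wp
      conc <- list(chromogen = matrix(0, height, width),
                   nuclear = matrix(0, height, width),
                   residual = matrix(0, height, width))
      for (i in seq_len(n_obj)) {
        if (!present[i, s]) next
        conc$nuclear <- paint_ellipse(conc$nuclear, wp[i, 1], wp[i, 2],
                                      a[i], b[i], th[i], nuclear_od[i])
        if (residual_od[i] > 0)
          conc$residual <- paint_ellipse(conc$residual, wp[i, 1], wp[i, 2],
                                         a[i], b[i], th[i], residual_od[i])
        if (positive[i, s]) {
          # chromogen ring: ellipse grown by cytoplasm_px minus the nucleus
          conc$chromogen <- paint_ellipse(conc$chromogen, wp[i, 1], wp[i, 2],
                                          a[i], b[i], th[i], 0.7,
                                          grow = cytoplasm_px)
          conc$chromogen <- paint_ellipse(conc$chromogen, wp[i, 1], wp[i, 2],
                                          a[i], b[i], th[i], -0.7)
        }
      }
      conc <- lapply(conc, function(m) EBImage::gblur(m, sigma = 0.7))
      conc <- lapply(conc, function(m) { m[m < 0] <- 0; m })
      rgb <- compose_rgb(conc, M)
      if (noise_sd > 0)
        rgb <- rgb + array(stats::rnorm(length(rgb), 0, noise_sd), dim = dim(rgb))
      slides[[s]] <- pmin(pmax(rgb, 0), 255)
    }

    objects <- data.frame(
      id = seq_len(n_obj),
      x = if (n_obj > 0) pos[, "x"] else numeric(0),
      y = if (n_obj > 0) pos[, "y"] else numeric(0),
      a = a, b = b, theta = th,
      nuclear_od = nuclear_od, residual_od = residual_od,
      type = type, artifact_stain = artifact_stain,
      stringsAsFactors = FALSE
    )
    list(slides = slides,
         truth = list(objects = objects, present = present,
                      positive = positive, warps = warps, warped = warped),
         stain_matrix = M, mpp = mpp, stain_names = stain_names)
  })
}

#' Render a synthetic multichannel fluorescence stack
#'
#' Emulates a pre-aligned multiplex immunofluorescence acquisition: one
#' nuclear (DAPI-like) channel plus one additive marker channel per
#' round, no geometric warps.
#'
#' @param n_channels total channels including the nuclear channel 1.
#' @param n_cells number of cells.
#' @param width,height stack size in pixels.
#' @param positive_frac fraction of cells positive per marker channel.
#' @param noise_sd additive Gaussian noise on the 0-1 intensity scale.
#' @param seed RNG seed.
#' @return List with `stack` (h x w x n_channels array, intensities 0-1)
#'   and `truth` (as in [render_micsss_panel()], with `positive` covering
#'   marker channels 2..n_channels).
#' @export
render_if_stack <- function(n_channels = 4, n_cells = 150,
                            width = 600, height = 600,
                            positive_frac = 0.2, noise_sd = 0.01, seed = 1) {
  stopifnot(n_channels >= 1, n_cells >= 0)
  n_markers <- n_channels - 1
  positive_frac <- rep_len(positive_frac, max(n_markers, 1))
  with_seed(seed, {
    pos <- if (n_cells > 0) place_points(n_cells, width, height, 17, 10)
           else cbind(x = numeric(0), y = numeric(0))
    a <- stats::runif(n_cells, 4.5, 6.5)
    b <- a * stats::runif(n_cells, 0.8, 1)
    th <- stats::runif(n_cells, 0, pi)
    amp <- stats::runif(n_cells, 0.6, 0.9)
    positive <- matrix(FALSE, n_cells, max(n_markers, 0))
    if (n_markers > 0) for (k in seq_len(n_markers)) {
      npos <- round(positive_frac[k] * n_cells)
      if (npos > 0) positive[sample(seq_len(n_cells), npos), k] <- TRUE
    }
    stack <- array(0, dim = c(height, width, n_channels))
    nuc <- matrix(0, height, width)
    for (i in seq_len(n_cells))
      nuc <- paint_ellipse(nuc, pos[i, 1], pos[i, 2], a[i], b[i], th[i], amp[i])
    stack[, , 1] <- nuc
    if (n_markers > 0) for (k in seq_len(n_markers)) {
      ch <- matrix(0, height, width)
      for (i in which(positive[, k])) {
        ch <- paint_ellipse(ch, pos[i, 1], pos[i, 2], a[i], b[i], th[i], 0.7,
                            grow = 3)
      }
      stack[, , k + 1] <- ch
    }
    for (k in seq_len(n_channels)) {
      m <- EBImage::gblur(stack[, , k], sigma = 0.7)
      if (noise_sd > 0) m <- m + matrix(stats::rnorm(length(m), 0, noise_sd),
                                        height, width)
      stack[, , k] <- pmin(pmax(m, 0), 1)
    }
    objects <- data.frame(id = seq_len(n_cells),
                          x = if (n_cells > 0) pos[, "x"] else numeric(0),
                          y = if (n_cells > 0) pos[, "y"] else numeric(0),
                          a = a, b = b, theta = th, amplitude = amp,
                          stringsAsFactors = FALSE)
    list(stack = stack, truth = list(objects = objects, positive = positive))
  })
}

#' Sample labelled point patterns with known nearest-neighbour structure
#'
#' @param type one of `"paired"` (every A point has its B partner at exact
#'   distance `d`), `"regular"` (square grid of spacing `spacing`,
#'   A = B), or `"clustered"` (Gaussian clusters).
#' @param n number of A points (regular pattern rounds down to a square).
#' @param d pair distance in the same units as `window` (paired type).
#' @param spacing grid spacing (regular type).
#' @param window extent `c(xmin, xmax, ymin, ymax)`.
#' @param n_clusters,cluster_sd clustered-type parameters.
#' @param seed RNG seed.
#' @return List with point matrices `A` and `B` (columns x, y) and `meta`.
#' @export
sample_point_pattern <- function(type = c("paired", "regular", "clustered"),
                                 n = 100, d = 20, spacing = 25,
                                 window = c(0, 1000, 0, 1000),
                                 n_clusters = 5, cluster_sd = 10, seed = 1) {
  type <- match.arg(type)
  stopifnot(n >= 2)
  with_seed(seed, {
    if (type == "paired") {
      # A points separated by > 3d so each A's nearest B is its own partner
      wx <- window[2] - window[1]; wy <- window[4] - window[3]
      A <- place_points(n, wx - 2 * d, wy - 2 * d, 3 * d, 0)
      A[, 1] <- A[, 1] + window[1] + d; A[, 2] <- A[, 2] + window[3] + d
      ang <- stats::runif(n, 0, 2 * pi)
      B <- cbind(x = A[, 1] + d * cos(ang), y = A[, 2] + d * sin(ang))
      list(A = A, B = B, meta = list(type = type, d = d))
    } else if (type == "regular") {
      k <- floor(sqrt(n))
      g <- expand.grid(x = window[1] + spacing * seq_len(k),
                       y = window[3] + spacing * seq_len(k))
      A <- cbind(x = g$x, y = g$y)
      list(A = A, B = A, meta = list(type = type, spacing = spacing))
    } else {
      centres <- cbind(stats::runif(n_clusters, window[1], window[2]),
                       stats::runif(n_clusters, window[3], window[4]))
      idx <- sample(seq_len(n_clusters), n, replace = TRUE)
      A <- cbind(x = stats::rnorm(n, centres[idx, 1], cluster_sd),
                 y = stats::rnorm(n, centres[idx, 2], cluster_sd))
      list(A = A, B = A, meta = list(type = type, n_clusters = n_clusters))
    }
  })
}
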