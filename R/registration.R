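# Co-registration of staining iterations.
#
# Registration operates only on the deconvolved nuclear channel, which is
# the one channel assumed consistent across staining rounds. A coarse
# whole-slide translation from thumbnail phase correlation pre-aligns the
# crops; each moving tile is then registered to the reference-round tile
# by an affine stage (multiresolution Nelder-Mead maximisation of
# normalized cross-correlation) followed by an elastic stage (block
# matching of local patches on a control grid, interpolated to a dense
# displacement field). The ladder identity -> affine -> affine+elastic is
# scored by NCC and the best-scoring field is returned, so the reported
# post-metric can never fall below the identity metric.

#' Normalized cross-correlation of two rasters
#' @param a,b equally sized matrices.
#' @return Pearson correlation of the flattened pixels (0 when one input
#'   is constant).
#' @export
ncc_metric <- function(a, b) {
  av <- as.vector(a); bv <- as.vector(b)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(0)
  stats::cor(av, bv)
}

#' Coarse translation by phase correlation
#'
#' Estimates the integer translation aligning `moving` to `fixed` from
#' the phase-correlation peak, then rescales it to level-0 pixels.
#'
#' @param fixed,moving equally sized single-channel thumbnails.
#' @param downscale thumbnail downscale relative to level 0.
#' @param min_confidence NCC (after applying the shift) below which the
#'   result is flagged low-confidence and zeroed.
#' @return List `dx`, `dy` (level-0 px; amount to add to fixed-frame
#'   coordinates to reach the moving frame), `confidence` (NCC after
#'   shifting), `low_confidence`.
#' @export
coarse_translate <- function(fixed, moving, downscale = 1,
                             min_confidence = 0.3) {
  stopifnot(all(dim(fixed) == dim(moving)))
  h <- nrow(fixed); w <- ncol(fixed)
  win <- outer(0.5 - 0.5 * cos(2 * pi * seq_len(h) / (h + 1)),
               0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1)))
  f <- stats::fft((fixed - mean(fixed)) * win)
  m <- stats::fft((moving - mean(moving)) * win)
  cross <- f * Conj(m)
  r <- Re(stats::fft(cross / pmax(Mod(cross), 1e-12), inverse = TRUE))
  peak <- which.max(r)
  py <- (peak - 1) %% h; px <- (peak - 1) %/% h
  if (py > h / 2) py <- py - h
  if (px > w / 2) px <- px - w
  # the cross-power spectrum F * Conj(M) peaks at minus the shift
  px <- -px; py <- -py
  # (px, py) now means moving is fixed shifted by (px, py):
  # moving coords = fixed coords + (px, py)
  shifted <- shift_raster(moving, -px, -py)
  ov <- !is.na(shifted)
  conf <- if (any(ov)) ncc_metric(fixed[ov], shifted[ov]) else 0
  low <- !is.finite(conf) || conf < min_confidence
  list(dx = if (low) 0 else px * downscale,
       dy = if (low) 0 else py * downscale,
       confidence = conf, low_confidence = low)
}

shift_raster <- function(m, dx, dy) {
  # integer shift with NA fill (moving content moves by +dx, +dy)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(NA_real_, h, w)
  sx <- max(0, dx); sy <- max(0, dy)
  ex <- min(w, w + dx); ey <- min(h, h + dy)
  if (ex > sx && ey > sy)
    out[(sy + 1):ey, (sx + 1):ex] <-
      m[(sy + 1 - dy):(ey - dy), (sx + 1 - dx):(ex - dx)]
  out
}

affine_map <- function(par, x, y, cx, cy) {
  # par = (theta_rad, log_scale, dx, dy); fixed (x, y) -> moving coords
  th <- par[1]; s <- exp(par[2])
  xm <- s * (cos(th) * (x - cx) - sin(th) * (y - cy)) + cx + par[3]
  ym <- s * (sin(th) * (x - cx) + cos(th) * (y - cy)) + cy + par[4]
  list(x = xm, y = ym)
}

warp_affine <- function(moving, par, fill = 0) {
  h <- nrow(moving); w <- ncol(moving)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  g <- affine_map(par, rep(0:(w - 1), each = h), rep(0:(h - 1), times = w),
                  cx, cy)
  matrix(bilinear_sample(moving, g$x, g$y, fill = fill), h, w)
}

register_affine <- function(fixed, moving, init = c(0, 0, 0, 0),
                            levels = c(4, 2, 1), maxit = c(150, 80, 50),
                            optimize_scale = TRUE) {
  par <- init
  for (li in seq_along(levels)) {
    f <- if (levels[li] > 1) downsample_raster(fixed, levels[li]) else fixed
    m <- if (levels[li] > 1) downsample_raster(moving, levels[li]) else moving
    scale_par <- function(p) c(p[1], p[2], p[3] / levels[li], p[4] / levels[li])
    unscale_par <- function(p) c(p[1], p[2], p[3] * levels[li], p[4] * levels[li])
    obj <- function(p) {
      if (!optimize_scale) p[2] <- 0
      -ncc_metric(f, warp_affine(m, p, fill = mean(m)))
    }
    res <- stats::optim(scale_par(par), obj, method = "Nelder-Mead",
                        control = list(maxit = maxit[li],
                                       reltol = 1e-6))
    par <- unscale_par(res$par)
    if (!optimize_scale) par[2] <- 0
  }
  par
}

# local block matching on a control grid: for each node, find the integer
# (+ quadratic subpixel) displacement of the affine-warped moving patch
# that best matches the fixed patch
block_match_grid <- function(fixed, warped, spacing = 100, patch = 40,
                             search = 8, min_ncc = 0.2) {
  h <- nrow(fixed); w <- ncol(fixed)
  gx <- unique(round(seq(patch + search, w - 1 - patch - search,
                         length.out = max(2, floor(w / spacing) + 1))))
  gy <- unique(round(seq(patch + search, h - 1 - patch - search,
                         length.out = max(2, floor(h / spacing) + 1))))
  if (length(gx) < 2 || length(gy) < 2 || any(gx < 0) || any(gy < 0))
    return(NULL)
  ux <- matrix(0, length(gy), length(gx))
  uy <- matrix(0, length(gy), length(gx))
  for (iy in seq_along(gy)) for (ix in seq_along(gx)) {
    x <- gx[ix]; y <- gy[iy]
    fpatch <- fixed[(y - patch + 1):(y + patch + 1),
                    (x - patch + 1):(x + patch + 1)]
    if (stats::sd(fpatch) < 1e-6) next
    best <- -Inf; bx <- 0; by <- 0
    scores <- matrix(-Inf, 2 * search + 1, 2 * search + 1)
    for (dy in -search:search) for (dx in -search:search) {
      mp <- warped[(y + dy - patch + 1):(y + dy + patch + 1),
                   (x + dx - patch + 1):(x + dx + patch + 1)]
      s <- ncc_metric(fpatch, mp)
      scores[dy + search + 1, dx + search + 1] <- s
      if (s > best) { best <- s; bx <- dx; by <- dy }
    }
    if (best < min_ncc) next
    # quadratic subpixel refinement around the integer peak
    sub <- function(sm1, s0, sp1) {
      den <- sm1 - 2 * s0 + sp1
      if (is.finite(den) && den < 0) max(-0.5, min(0.5, 0.5 * (sm1 - sp1) / den)) else 0
    }
    fx <- fy <- 0
    i <- by + search + 1; j <- bx + search + 1
    if (j > 1 && j < ncol(scores))
      fx <- sub(scores[i, j - 1], scores[i, j], scores[i, j + 1])
    if (i > 1 && i < nrow(scores))
      fy <- sub(scores[i - 1, j], scores[i, j], scores[i + 1, j])
    ux[iy, ix] <- bx + fx
    uy[iy, ix] <- by + fy
  }
  list(gx = gx, gy = gy, ux = ux, uy = uy)
}

interp_grid <- function(grid, h, w) {
  # bilinear interpolation of node displacements to a dense field,
  # constant extension beyond the outer nodes
  xq <- pmin(pmax(rep(0:(w - 1), each = h), grid$gx[1]),
             grid$gx[length(grid$gx)])
  yq <- pmin(pmax(rep(0:(h - 1), times = w), grid$gy[1]),
             grid$gy[length(grid$gy)])
  ix <- findInterval(xq, grid$gx, rightmost.closed = TRUE)
  iy <- findInterval(yq, grid$gy, rightmost.closed = TRUE)
  ix <- pmin(ix, length(grid$gx) - 1); iy <- pmin(iy, length(grid$gy) - 1)
  x0 <- grid$gx[ix]; x1 <- grid$gx[ix + 1]
  y0 <- grid$gy[iy]; y1 <- grid$gy[iy + 1]
  tx <- (xq - x0) / (x1 - x0); ty <- (yq - y0) / (y1 - y0)
  bl <- function(u) {
    v00 <- u[cbind(iy, ix)]; v01 <- u[cbind(iy, ix + 1)]
    v10 <- u[cbind(iy + 1, ix)]; v11 <- u[cbind(iy + 1, ix + 1)]
    matrix((1 - ty) * ((1 - tx) * v00 + tx * v01) +
           ty * ((1 - tx) * v10 + tx * v11), h, w)
  }
  list(dx = bl(grid$ux), dy = bl(grid$uy))
}

#' Dense identity deformation field
#' @param h,w field dimensions.
#' @export
field_identity <- function(h, w) {
  structure(list(dx = matrix(0, h, w), dy = matrix(0, h, w),
                 affine = c(0, 0, 0, 0), method = "identity",
                 metric_pre = NA_real_, metric_post = NA_real_),
            class = "deformation_field")
}

#' Register a moving nuclear tile to the fixed (reference-stain) tile
#'
#' Affine stage (rotation, scale, translation; multiresolution
#' Nelder-Mead on NCC) followed by an elastic stage (patch block matching
#' on a control grid, bilinearly interpolated), composed into one dense
#' per-pixel displacement field mapping fixed coordinates into the moving
#' tile. The candidates identity / affine / affine+elastic are scored by
#' NCC and the best is returned, so the post metric never falls below the
#' identity metric.
#'
#' @param fixed,moving equally sized nuclear OD rasters (padded tiles).
#' @param params optional list: `elastic_spacing_px` (control grid
#'   spacing, default 50), `patch` (block-match half-size, default 20),
#'   `search` (maximum elastic displacement, default 8),
#'   `optimize_scale` (default TRUE).
#' @return A `deformation_field`: matrices `dx`, `dy` (sampling
#'   positions are `x + dx`, `y + dy`), `affine` parameters
#'   (theta, log-scale, tx, ty), `method`, `metric_pre`, `metric_post`.
#' @export
register_tile_pair <- function(fixed, moving, params = list()) {
  if (any(!is.finite(fixed)) || any(!is.finite(moving)))
    stop("register_tile_pair: non-finite input")
  stopifnot(all(dim(fixed) == dim(moving)))
  h <- nrow(fixed); w <- ncol(fixed)
  spacing <- params$elastic_spacing_px %||% 50
  patch <- params$patch %||% 20
  search <- params$search %||% 8
  opt_scale <- params$optimize_scale %||% TRUE

  metric_id <- ncc_metric(fixed, moving)

  ct <- coarse_translate(fixed, moving, min_confidence = 0.1)
  par <- register_affine(fixed, moving, init = c(0, 0, ct$dx, ct$dy),
                         optimize_scale = opt_scale)
  warped_aff <- warp_affine(moving, par, fill = mean(moving))
  metric_aff <- ncc_metric(fixed, warped_aff)

  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  gmaps <- affine_map(par, rep(0:(w - 1), each = h), rep(0:(h - 1), times = w),
                      cx, cy)
  aff_dx <- matrix(gmaps$x, h, w) - matrix(rep(0:(w - 1), each = h), h, w)
  aff_dy <- matrix(gmaps$y, h, w) - matrix(rep(0:(h - 1), times = w), h, w)

  metric_el <- -Inf; el_dx <- NULL; el_dy <- NULL
  # two block-matching passes: the second refines the residual of the
  # first with a tighter search, composing additively (fields are smooth)
  e_dx <- matrix(0, h, w); e_dy <- matrix(0, h, w)
  compose_and_warp <- function() {
    xq <- rep(0:(w - 1), each = h) + as.vector(e_dx)
    yq <- rep(0:(h - 1), times = w) + as.vector(e_dy)
    g2 <- affine_map(par, xq, yq, cx, cy)
    list(g2 = g2,
         warped = matrix(bilinear_sample(moving, g2$x, g2$y,
                                         fill = mean(moving)), h, w))
  }
  cur_warped <- warped_aff
  found <- FALSE
  for (pass in 1:2) {
    grid <- block_match_grid(fixed, cur_warped, spacing = spacing,
                             patch = patch,
                             search = if (pass == 1) search
                                      else max(3, ceiling(search / 2)))
    if (is.null(grid)) break
    dense <- interp_grid(grid, h, w)
    e_dx <- e_dx + dense$dx; e_dy <- e_dy + dense$dy
    cw <- compose_and_warp()
    cur_warped <- cw$warped
    found <- TRUE
  }
  if (found) {
    cw <- compose_and_warp()
    el_dx <- matrix(cw$g2$x, h, w) - matrix(rep(0:(w - 1), each = h), h, w)
    el_dy <- matrix(cw$g2$y, h, w) - matrix(rep(0:(h - 1), times = w), h, w)
    metric_el <- ncc_metric(fixed, cw$warped)
  }

  choice <- which.max(c(metric_id, metric_aff, metric_el))
  out <- if (choice == 1) {
    f <- field_identity(h, w); f$method <- "identity"; f
  } else if (choice == 2) {
    structure(list(dx = aff_dx, dy = aff_dy, affine = par,
                   method = "affine"), class = "deformation_field")
  } else {
    structure(list(dx = el_dx, dy = el_dy, affine = par,
                   method = "affine+elastic"), class = "deformation_field")
  }
  out$metric_pre <- metric_id
  out$metric_post <- max(metric_id, metric_aff, metric_el)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a deformation field to a raster
#'
#' Backward warping: output pixel (x, y) samples the input at
#' `(x + dx, y + dy)` with bilinear interpolation, each channel
#' independently; out-of-bounds samples are filled with `fill`
#' (background white by default).
#'
#' @param raster matrix or h x w x c array.
#' @param field a `deformation_field` whose grid matches the raster.
#' @param fill fill value.
#' @export
apply_deformation <- function(raster, field, fill = 255) {
  d <- dim(raster)
  h <- d[1]; w <- d[2]
  stopifnot(all(dim(field$dx) == c(h, w)))
  xq <- rep(0:(w - 1), each = h) + as.vector(field$dx)
  yq <- rep(0:(h - 1), times = w) + as.vector(field$dy)
  if (length(d) == 2)
    return(matrix(bilinear_sample(raster, xq, yq, fill = fill), h, w))
  out <- array(0, dim = d)
  for (k in seq_len(d[3]))
    out[, , k] <- matrix(bilinear_sample(raster[, , k], xq, yq, fill = fill),
                         h, w)
  out
}

#' Map fixed-frame points through a deformation field
#'
#' Returns the moving-frame positions of fixed-frame points, i.e.
#' `(x + dx(x, y), y + dy(x, y))` with bilinear interpolation of the
#' field.
#'
#' @param field a `deformation_field`.
#' @param x,y fixed-frame coordinates (0-based px).
#' @export
deform_points <- function(field, x, y) {
  cbind(x = x + bilinear_sample(field$dx, x, y, fill = 0),
        y = y + bilinear_sample(field$dy, x, y, fill = 0))
}
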