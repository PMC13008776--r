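# Coordinate conventions used throughout the package:
#   * origin at the top-left pixel, x = column (rightward), y = row (downward)
#   * 0-based pixel indices; the pixel at array position [row, col] has
#     coordinates (x, y) = (col - 1, row - 1)
#   * all rectangles are half-open: [x0, x1) x [y0, y1)
# RGB rasters are arrays dim c(h, w, 3) with values in [0, 255];
# single-channel rasters are h x w matrices.

#' Construct a half-open pixel rectangle
#'
#' Rectangles are `[x0, x1) x [y0, y1)` in 0-based level-0 pixel
#' coordinates; the right and bottom edges are exclusive so that a grid of
#' rectangles can partition a raster exactly.
#'
#' @param x0,y0 inclusive top-left corner (0-based).
#' @param x1,y1 exclusive bottom-right corner.
#' @return An object of class `px_rect` (named numeric of length 4).
#' @export
px_rect <- function(x0, y0, x1, y1) {
  r <- c(x0 = as.numeric(x0), y0 = as.numeric(y0),
         x1 = as.numeric(x1), y1 = as.numeric(y1))
  if (any(!is.finite(r))) stop("px_rect: non-finite bounds")
  if (r["x1"] < r["x0"] || r["y1"] < r["y0"]) stop("px_rect: inverted bounds")
  class(r) <- "px_rect"
  r
}

#' @export
print.px_rect <- function(x, ...) {
  cat(sprintf("<px_rect [%g,%g) x [%g,%g)>\n", x["x0"], x["x1"], x["y0"], x["y1"]))
  invisible(x)
}

#' Width, height and area of a pixel rectangle
#' @param r a [px_rect()].
#' @return Numeric scalar.
#' @export
rect_width <- function(r) unname(r["x1"] - r["x0"])

#' @rdname rect_width
#' @export
rect_height <- function(r) unname(r["y1"] - r["y0"])

#' @rdname rect_width
#' @export
rect_area <- function(r) rect_width(r) * rect_height(r)

#' Intersect or clip rectangles
#' @param a,b [px_rect()] objects.
#' @return A `px_rect`; the intersection is empty (zero area) when disjoint.
#' @export
rect_intersect <- function(a, b) {
  x0 <- max(a["x0"], b["x0"]); y0 <- max(a["y0"], b["y0"])
  x1 <- min(a["x1"], b["x1"]); y1 <- min(a["y1"], b["y1"])
  px_rect(x0, y0, max(x0, x1), max(y0, y1))
}

#' Test half-open containment of points in a rectangle
#' @param r a [px_rect()].
#' @param x,y point coordinates (vectors, 0-based pixels).
#' @return Logical vector: `x0 <= x < x1` and `y0 <= y < y1`.
#' @export
rect_contains <- function(r, x, y) {
  x >= r["x0"] & x < r["x1"] & y >= r["y0"] & y < r["y1"]
}

#' Expand a rectangle by a margin, optionally clipping to an extent
#' @param r a [px_rect()].
#' @param margin pixels added on every side.
#' @param clip optional `px_rect` the result is clipped to.
#' @export
rect_expand <- function(r, margin, clip = NULL) {
  out <- px_rect(r["x0"] - margin, r["y0"] - margin,
                 r["x1"] + margin, r["y1"] + margin)
  if (!is.null(clip)) out <- rect_intersect(out, clip)
  out
}

#' Crop a raster to a half-open rectangle
#'
#' @param raster a matrix (h x w) or array (h x w x c).
#' @param r a [px_rect()] with integer bounds inside the raster.
#' @return Raster of shape `rect_height(r)` x `rect_width(r)`.
#' @export
crop_raster <- function(raster, r) {
  d <- dim(raster)
  if (rect_area(r) <= 0) stop("crop_raster: zero-area bounds")
  if (r["x0"] < 0 || r["y0"] < 0 || r["x1"] > d[2] || r["y1"] > d[1])
    stop("crop_raster: bounds outside raster")
  rows <- (r["y0"] + 1):r["y1"]
  cols <- (r["x0"] + 1):r["x1"]
  if (length(d) == 2) raster[rows, cols, drop = FALSE]
  else raster[rows, cols, , drop = FALSE]
}

#' Create a blank RGB raster
#' @param h,w dimensions in pixels.
#' @param value fill value per channel (default 255, background white).
#' @export
blank_rgb <- function(h, w, value = 255) {
  array(rep(value, length.out = 3)[rep(1:3, each = h * w)], dim = c(h, w, 3))
}

#' Bilinear sampling of a single-channel raster at fractional coordinates
#'
#' Coordinates are 0-based pixel centres; positions outside the raster
#' return `fill`.
#'
#' @param m matrix (h x w).
#' @param x,y coordinate vectors (same length).
#' @param fill value for out-of-bounds samples.
#' @return Numeric vector of samples.
#' @export
bilinear_sample <- function(m, x, y, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x >= 0 & y >= 0 & x <= w - 1 & y <= h - 1
  # clamp the integer corners so indexing is always legal, mask afterwards
  x0c <- pmin(pmax(x0, 0), w - 1); y0c <- pmin(pmax(y0, 0), h - 1)
  x1c <- pmin(x0c + 1, w - 1);     y1c <- pmin(y0c + 1, h - 1)
  i00 <- y0c + 1 + h * x0c; i10 <- y1c + 1 + h * x0c
  i01 <- y0c + 1 + h * x1c; i11 <- y1c + 1 + h * x1c
  v <- (1 - fx) * ((1 - fy) * m[i00] + fy * m[i10]) +
       fx       * ((1 - fy) * m[i01] + fy * m[i11])
  v[!ok] <- fill
  v
}

#' Box-downsample a raster by an integer factor
#' @param raster matrix or h x w x c array.
#' @param factor integer >= 1.
#' @export
downsample_raster <- function(raster, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(raster)
  d <- dim(raster)
  h2 <- d[1] %/% factor; w2 <- d[2] %/% factor
  if (h2 < 1 || w2 < 1) stop("downsample_raster: factor larger than raster")
  ds1 <- function(m) {
    m <- m[seq_len(h2 * factor), seq_len(w2 * factor), drop = FALSE]
    # average factor x factor blocks
    m <- rowsum(m, rep(seq_len(h2), each = factor)) / factor
    t(rowsum(t(m), rep(seq_len(w2), each = factor)) / factor)
  }
  if (length(d) == 2) ds1(raster)
  else {
    out <- array(0, dim = c(h2, w2, d[3]))
    for (k in seq_len(d[3])) out[, , k] <- ds1(raster[, , k])
    out
  }
}

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

#' Otsu threshold of a numeric vector
#'
#' Histogram-based maximisation of between-class variance, used by the
#' tissue mask and the red-blood-cell filter.
#'
#' @param x numeric vector.
#' @param nbins number of histogram bins.
#' @return Threshold value; `x` values strictly below it form the low class.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("otsu_threshold: no finite values")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  counts <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE),
                                nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(counts); total <- w[nbins]
  mu <- cumsum(counts * mids); mu_t <- mu[nbins]
  w0 <- w[-nbins]; w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1)
  bcv[valid] <- (mu_t * w0[valid] - total * mu[-nbins][valid])^2 /
    (w0[valid] * w1[valid])
  br[which.max(bcv) + 1]
}
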