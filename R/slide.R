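# Slide container and region access.
#
# A slide is held as a small pyramid of in-memory RGB rasters (level 0 at
# full resolution, coarser levels at integer downscales) plus the physical
# scale in microns per pixel. Multi-page TIFF read/write is provided for
# persistence; vendor slide formats are out of scope.

#' Construct a slide image from pyramid levels
#'
#' @param levels list of RGB rasters (h x w x 3, values 0-255) ordered by
#'   increasing downscale; level 1 of the list is level 0 (full
#'   resolution).
#' @param mpp microns per pixel at level 0 (default 0.5, i.e. a
#'   1000-pixel tile spans ~500 um).
#' @return Object of class `slide_image` with fields `levels` (raster
#'   list), `meta` (data.frame: level, downscale, width, height), `mpp`.
#' @export
slide_image <- function(levels, mpp = 0.5) {
  stopifnot(length(levels) >= 1, mpp > 0)
  d0 <- dim(levels[[1]])
  meta <- do.call(rbind, lapply(seq_along(levels), function(i) {
    d <- dim(levels[[i]])
    data.frame(level = i - 1L, downscale = d0[2] / d[2],
               width = d[2], height = d[1])
  }))
  if (is.unsorted(meta$downscale))
    stop("slide_image: levels must be ordered by increasing downscale")
  structure(list(levels = levels, meta = meta, mpp = mpp),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image %d x %d px, %.3g um/px, %d level(s)>\n",
              x$meta$width[1], x$meta$height[1], x$mpp, nrow(x$meta)))
  invisible(x)
}

#' Build a pyramidal slide from a level-0 raster
#'
#' @param raster RGB raster (h x w x 3).
#' @param mpp microns per pixel at level 0.
#' @param n_levels pyramid depth; level k is downscaled by `2^k`.
#' @export
slide_from_raster <- function(raster, mpp = 0.5, n_levels = 1) {
  levels <- vector("list", n_levels)
  levels[[1]] <- raster
  if (n_levels > 1) for (k in 2:n_levels)
    levels[[k]] <- downsample_raster(levels[[k - 1]], 2)
  slide_image(levels, mpp)
}

#' Read a rectangular region from a slide level
#'
#' @param slide a [slide_image()].
#' @param level pyramid level (0-based).
#' @param bounds [px_rect()] in that level's pixel coordinates.
#' @return RGB raster; its pixel (0,0) corresponds to the bounds origin.
#' @export
read_region <- function(slide, level, bounds) {
  if (level < 0 || level >= nrow(slide$meta)) stop("read_region: no such level")
  crop_raster(slide$levels[[level + 1]], bounds)
}

#' Thumbnail of a slide
#' @param slide a [slide_image()].
#' @param max_dim target maximum dimension in pixels.
#' @return List with `raster` and `downscale` (thumbnail px -> level-0 px).
#' @export
slide_thumbnail <- function(slide, max_dim = 512) {
  d0 <- c(slide$meta$height[1], slide$meta$width[1])
  factor <- max(1L, ceiling(max(d0) / max_dim))
  # start from the coarsest stored level not coarser than needed
  base <- max(which(slide$meta$downscale <= factor))
  raster <- slide$levels[[base]]
  rem <- factor / slide$meta$downscale[base]
  if (rem > 1) raster <- downsample_raster(raster, rem)
  list(raster = raster, downscale = factor)
}

#' Read / write a slide as a multi-page TIFF
#'
#' Pages hold the pyramid levels in order. Values are stored as 8-bit.
#'
#' @param path file path.
#' @param mpp microns per pixel at level 0 (not all TIFFs carry it).
#' @export
read_slide_tiff <- function(path, mpp = 0.5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  slide_image(lapply(pages, function(p) {
    if (length(dim(p)) == 2) p <- array(rep(p, 3), dim = c(dim(p), 3))
    p[, , 1:3, drop = FALSE] * 255
  }), mpp = mpp)
}

#' @rdname read_slide_tiff
#' @param slide a [slide_image()].
#' @export
write_slide_tiff <- function(slide, path) {
  tiff::writeTIFF(lapply(slide$levels, function(r) r / 255), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' Stitch processed tiles back into a whole-slide raster
#'
#' Each output pixel is taken from the unique tile whose *core* contains
#' it (tile cores are half-open and pairwise disjoint, so no pixel is
#' written twice). Regions of the extent covered by no core are filled
#' with background white and trigger a warning.
#'
#' @param tiles list of `list(spec = <tile_spec>, raster = <padded RGB or
#'   matrix raster>)`; each raster's origin is its spec's padded origin.
#' @param mode `"rgb"` (3-channel), `"multichannel"` (single matrix per
#'   tile) or `"overlay"` (rgb plus painted centroid markers).
#' @param extent optional [px_rect()] of the output; defaults to the
#'   union of tile cores.
#' @param points for `mode = "overlay"`: data.frame with `x`, `y` and
#'   optional `class` (level-0 px); each class gets a distinct colour.
#' @param background fill value for uncovered pixels.
#' @return Stitched raster with origin at `extent`'s top-left corner.
#' @export
stitch_tiles <- function(tiles, mode = c("rgb", "multichannel", "overlay"),
                         extent = NULL, points = NULL, background = 255) {
  mode <- match.arg(mode)
  if (length(tiles) == 0) stop("stitch_tiles: no tiles")
  cores <- lapply(tiles, function(t) t$spec$core)
  if (is.null(extent)) {
    extent <- px_rect(min(sapply(cores, `[`, "x0")),
                      min(sapply(cores, `[`, "y0")),
                      max(sapply(cores, `[`, "x1")),
                      max(sapply(cores, `[`, "y1")))
  }
  h <- rect_height(extent); w <- rect_width(extent)
  nch <- if (mode == "multichannel") 1L else 3L
  out <- if (nch == 1) matrix(background, h, w) else blank_rgb(h, w, background)
  covered <- matrix(FALSE, h, w)
  for (t in tiles) {
    core <- rect_intersect(t$spec$core, extent)
    if (rect_area(core) <= 0) next
    pad <- t$spec$padded
    local <- px_rect(core["x0"] - pad["x0"], core["y0"] - pad["y0"],
                     core["x1"] - pad["x0"], core["y1"] - pad["y0"])
    piece <- crop_raster(t$raster, local)
    rows <- (core["y0"] - extent["y0"] + 1):(core["y1"] - extent["y0"])
    cols <- (core["x0"] - extent["x0"] + 1):(core["x1"] - extent["x0"])
    if (covered[rows[1], cols[1]])
      stop("stitch_tiles: overlapping tile cores")
    if (nch == 1) out[rows, cols] <- piece else out[rows, cols, ] <- piece
    covered[rows, cols] <- TRUE
  }
  if (!all(covered))
    warning("stitch_tiles: ", sum(!covered),
            " uncovered pixel(s) filled with background")
  if (mode == "overlay" && !is.null(points) && nrow(points) > 0) {
    cls <- if ("class" %in% names(points)) as.factor(points$class)
           else factor(rep("cell", nrow(points)))
    palette <- matrix(c(220, 30, 30,  30, 110, 220,  30, 170, 60,
                        240, 160, 20, 150, 60, 200), ncol = 3, byrow = TRUE)
    for (i in seq_len(nrow(points))) {
      px <- round(points$x[i] - extent["x0"]); py <- round(points$y[i] - extent["y0"])
      col <- palette[(as.integer(cls[i]) - 1) %% nrow(palette) + 1, ]
      for (dy in -1:1) for (dx in -1:1) {
        yy <- py + dy + 1; xx <- px + dx + 1
        if (yy >= 1 && yy <= h && xx >= 1 && xx <= w) out[yy, xx, ] <- col
      }
    }
  }
  out
}

#' Write / read the per-cell features table as CSV
#'
#' Numeric fields are written with 17 significant digits so a write/read
#' round trip is lossless at double precision. Rows must carry unique
#' `cell_id`s.
#'
#' @param records data.frame of feature records (one row per cell).
#' @param path output path.
#' @export
write_features_table <- function(records, path) {
  if (!"cell_id" %in% names(records))
    stop("write_features_table: records need a cell_id column")
  if (anyDuplicated(records$cell_id))
    stop("write_features_table: duplicate cell ids")
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 17,
                                                 format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_features_table
#' @export
read_features_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
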