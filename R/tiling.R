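# Tissue masking and tile planning.
#
# The thumbnail is thresholded in HSV space (background glass is bright
# and unsaturated), cleaned morphologically, and the resulting mask drives
# an overlap-padded tile grid: non-overlapping tile-size-aligned cores
# covering the mask bounding box, each padded by half the overlap fraction
# per side so neighbouring padded tiles share a 10% strip at the defaults.

#' Rasterize polygons to a binary mask
#'
#' Pixel centres (0-based coordinates) falling inside any polygon
#' (boundary inclusive) are set.
#'
#' @param polygons list of n x 2 vertex matrices (x, y), or a single
#'   matrix.
#' @param h,w mask dimensions.
#' @return Logical h x w matrix.
#' @export
rasterize_polygons <- function(polygons, h, w) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  mask <- matrix(FALSE, h, w)
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  for (p in polygons) {
    if (is.list(p) && !is.null(p$coords)) p <- p$coords
    inside <- point_in_polygon(xs, ys, p)
    mask[inside] <- TRUE
  }
  mask
}

#' Compute a binary tissue mask from a slide thumbnail
#'
#' Automatic rule: a pixel is tissue when its HSV saturation exceeds
#' `s_min` and its value is below `v_max` (removing bright unsaturated
#' glass), followed by morphological closing, hole filling and removal of
#' objects smaller than `min_object_px`. When `manual_regions` is given
#' it *replaces* the automatic mask entirely (rasterized exactly).
#'
#' @param thumbnail RGB raster (values 0-255).
#' @param s_min,v_max HSV thresholds.
#' @param min_object_px smallest kept connected component, mask pixels.
#' @param close_radius radius of the morphological closing brush.
#' @param manual_regions optional polygon list in thumbnail pixel coords.
#' @return Logical matrix; warns when empty.
#' @export
compute_tissue_mask <- function(thumbnail, s_min = 0.05, v_max = 0.95,
                                min_object_px = 64, close_radius = 3,
                                manual_regions = NULL) {
  h <- dim(thumbnail)[1]; w <- dim(thumbnail)[2]
  if (!is.null(manual_regions))
    return(rasterize_polygons(manual_regions, h, w))
  hsv <- grDevices::rgb2hsv(r = as.vector(thumbnail[, , 1]),
                            g = as.vector(thumbnail[, , 2]),
                            b = as.vector(thumbnail[, , 3]),
                            maxColorValue = 255)
  mask <- matrix(hsv["s", ] > s_min & hsv["v", ] < v_max, h, w)
  if (any(mask)) {
    brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
    m <- EBImage::closing(mask * 1, brush)
    m <- EBImage::fillHull(m)
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    mask <- matrix(lab %in% keep, h, w)
  }
  if (!any(mask)) warning("compute_tissue_mask: no tissue found")
  mask
}

#' Tissue fraction of a tile core
#'
#' @param core [px_rect()] in level-0 pixels.
#' @param mask logical tissue mask.
#' @param downscale mask downscale relative to level 0.
#' @return Fraction of the core covered by tissue, in `[0, 1]`.
#' @export
tissue_fraction <- function(core, mask, downscale = 1) {
  mx0 <- floor(core["x0"] / downscale); my0 <- floor(core["y0"] / downscale)
  mx1 <- ceiling(core["x1"] / downscale); my1 <- ceiling(core["y1"] / downscale)
  mx1 <- min(mx1, ncol(mask)); my1 <- min(my1, nrow(mask))
  if (mx1 <= mx0 || my1 <= my0) return(0)
  mean(mask[(my0 + 1):my1, (mx0 + 1):mx1])
}

#' Construct a tile specification
#' @param row,col grid indices (1-based).
#' @param core,padded [px_rect()] bounds, level-0 px.
#' @param tissue_frac tissue fraction of the core.
#' @param offset stain-specific coarse translation applied when cropping
#'   (dx, dy, level-0 px).
#' @export
tile_spec <- function(row, col, core, padded, tissue_frac = NA_real_,
                      offset = c(0, 0)) {
  structure(list(row = as.integer(row), col = as.integer(col),
                 core = core, padded = padded,
                 tissue_frac = tissue_frac, offset = offset),
            class = "tile_spec")
}

#' Plan the overlap-padded tile grid over a tissue mask
#'
#' Non-overlapping `tile_size` cores are laid over the bounding box of
#' the mask (aligned to the box origin); tiles whose core tissue fraction
#' falls below `min_tissue_frac` are dropped; padded bounds add
#' [tile_margin()] pixels per side, clipped at the slide extent. At the
#' defaults (1000-px tiles, 10% overlap) the margin is 50 px, so
#' neighbouring padded tiles share a 100-px strip.
#'
#' @param mask logical tissue mask.
#' @param cfg a [run_config()].
#' @param downscale mask downscale relative to level 0.
#' @param slide_extent optional [px_rect()] of the level-0 slide; defaults
#'   to the mask extent scaled up.
#' @return List of [tile_spec()]s (row-major order); empty for an empty
#'   mask. Dropped tiles are recorded in the `dropped` attribute so that
#'   analysed-tissue-area denominators can exclude them explicitly.
#' @export
plan_tiles <- function(mask, cfg, downscale = 1, slide_extent = NULL) {
  if (!any(mask)) return(structure(list(), dropped = list()))
  if (is.null(slide_extent))
    slide_extent <- px_rect(0, 0, ncol(mask) * downscale,
                            nrow(mask) * downscale)
  idx <- which(mask, arr.ind = TRUE)
  x0 <- (min(idx[, 2]) - 1) * downscale; x1 <- max(idx[, 2]) * downscale
  y0 <- (min(idx[, 1]) - 1) * downscale; y1 <- max(idx[, 1]) * downscale
  ts <- cfg$tile_size
  ncols <- ceiling((x1 - x0) / ts); nrows <- ceiling((y1 - y0) / ts)
  margin <- tile_margin(cfg)
  kept <- list(); dropped <- list()
  for (r in seq_len(nrows)) for (c in seq_len(ncols)) {
    core <- px_rect(x0 + (c - 1) * ts, y0 + (r - 1) * ts,
                    min(x0 + c * ts, slide_extent["x1"]),
                    min(y0 + r * ts, slide_extent["y1"]))
    if (rect_area(core) <= 0) next
    tf <- tissue_fraction(core, mask, downscale)
    spec <- tile_spec(r, c, core,
                      rect_expand(core, margin, clip = slide_extent), tf)
    if (tf >= cfg$min_tissue_frac) kept[[length(kept) + 1]] <- spec
    else dropped[[length(dropped) + 1]] <- spec
  }
  structure(kept, dropped = dropped)
}

#' Tile manifest as a data.frame
#' @param tiles list of [tile_spec()]s from [plan_tiles()].
#' @export
tile_manifest <- function(tiles) {
  do.call(rbind, lapply(tiles, function(t) {
    data.frame(row = t$row, col = t$col,
               core_x0 = t$core["x0"], core_y0 = t$core["y0"],
               core_x1 = t$core["x1"], core_y1 = t$core["y1"],
               pad_x0 = t$padded["x0"], pad_y0 = t$padded["y0"],
               pad_x1 = t$padded["x1"], pad_y1 = t$padded["y1"],
               tissue_frac = t$tissue_frac, row.names = NULL)
  }))
}
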