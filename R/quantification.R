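# Per-cell feature quantification.
#
# For every composite cell and every staining round, intensity statistics
# of the chromogen OD (min, max, percentiles 10/25/50/75/90, mean, sd)
# and the median nuclear OD are computed over each compartment (nucleus,
# cytoplasm ring, whole cell), plus nucleus morphology (area, perimeter,
# ellipse axes from second moments, eccentricity). Intensities are
# recorded in OD space; OD is a monotone transform of transmitted
# intensity, so rank-based downstream decisions are unaffected.
#
# Tiles overlap, so features are computed on padded rasters but a record
# is only *kept* by the tile whose half-open core contains the cell
# centroid — that rule deduplicates cells exactly.

feature_percentiles <- c(10, 25, 50, 75, 90)

channel_stats <- function(values) {
  if (length(values) == 0) {
    out <- rep(NA_real_, 9)
  } else {
    q <- stats::quantile(values, feature_percentiles / 100, names = FALSE,
                         type = 7)
    out <- c(min(values), max(values), q, mean(values),
             if (length(values) > 1) stats::sd(values) else 0)
  }
  names(out) <- c("min", "max", paste0("p", feature_percentiles),
                  "mean", "std")
  out
}

nucleus_morphology <- function(mask) {
  idx <- which(mask)
  area <- length(idx)
  if (area == 0)
    return(c(area = 0, perimeter = NA_real_, major_axis = NA_real_,
             minor_axis = NA_real_, eccentricity = NA_real_))
  r <- (idx - 1) %% nrow(mask)
  c <- (idx - 1) %/% nrow(mask)
  mu20 <- stats::var(c) * (area - 1) / area
  mu02 <- stats::var(r) * (area - 1) / area
  mu11 <- if (area > 1) stats::cov(c, r) * (area - 1) / area else 0
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc; l2 <- max(0, tr / 2 - disc)
  # crack-boundary perimeter: count exposed pixel edges
  m <- mask
  per <- sum(m & !rbind(FALSE, m[-nrow(m), ])) +
         sum(m & !rbind(m[-1, ], FALSE)) +
         sum(m & !cbind(FALSE, m[, -ncol(m)])) +
         sum(m & !cbind(m[, -1], FALSE))
  c(area = area, perimeter = per,
    major_axis = 4 * sqrt(l1), minor_axis = 4 * sqrt(l2),
    eccentricity = if (l1 > 0) sqrt(1 - l2 / l1) else 0)
}

#' Quantify one cell across stains and compartments
#'
#' @param masks compartment masks from [expand_cytoplasm()] (local
#'   window).
#' @param channels list per stain of `list(chromogen = <matrix>,
#'   nuclear = <matrix>)` cropped to the same local window.
#' @param stain_names names for the per-stain column suffixes.
#' @return One-row data.frame. Per stain and compartment the columns are
#'   `<compartment>_chromogen_<stat>_<stain>` and
#'   `<compartment>_nuclear_p50_<stain>`; morphology columns are shared
#'   (the nucleus mask is the composite mask, common to all stains).
#'   Empty compartments yield `NA` statistics (never zeros).
#' @export
quantify_cell <- function(masks, channels, stain_names = names(channels)) {
  if (is.null(stain_names))
    stain_names <- paste0("stain", seq_along(channels))
  comp_names <- c("nucleus", "cytoplasm", "cell")
  vals <- list()
  for (si in seq_along(channels)) {
    for (comp in comp_names) {
      sel <- masks[[comp]]
      chrom <- channel_stats(channels[[si]]$chromogen[sel])
      names(chrom) <- paste0(comp, "_chromogen_", names(chrom), "_",
                             stain_names[si])
      nuc_med <- if (any(sel)) stats::median(channels[[si]]$nuclear[sel])
                 else NA_real_
      vals[[length(vals) + 1]] <- c(chrom,
        stats::setNames(nuc_med, paste0(comp, "_nuclear_p50_",
                                        stain_names[si])))
    }
  }
  morph <- nucleus_morphology(masks$nucleus)
  as.data.frame(as.list(c(unlist(vals), morph)), check.names = FALSE)
}

#' Quantify all composite cells of one tile
#'
#' Builds the local compartment masks from each cell's boundary polygon
#' footprint (rasterized), expands the cytoplasm, and computes features
#' against the per-stain deconvolved channels of the padded tile.
#'
#' @param cells composite cell table (coordinates in the padded-tile
#'   frame, i.e. relative to the tile's padded origin).
#' @param channels list per stain of `list(chromogen, nuclear, residual)`
#'   matrices for the padded tile.
#' @param spec the [tile_spec()] of the tile.
#' @param cfg a [run_config()].
#' @return data.frame of feature records (one per cell), with centroid in
#'   level-0 px and um, tile indices, support and rbc flag; `cell_id` is
#'   the serialized (tile row, tile col, local label) tuple.
#' @export
quantify_tile <- function(cells, channels, spec, cfg) {
  if (nrow(cells) == 0) return(NULL)
  polys <- object_polygons(cells)
  h <- nrow(channels[[1]]$nuclear); w <- ncol(channels[[1]]$nuclear)
  recs <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    poly <- polys[[i]]
    pad <- cfg$cytoplasm_px + 2
    x0 <- max(0, floor(min(poly[, 1])) - pad)
    y0 <- max(0, floor(min(poly[, 2])) - pad)
    x1 <- min(w - 1, ceiling(max(poly[, 1])) + pad)
    y1 <- min(h - 1, ceiling(max(poly[, 2])) + pad)
    wr <- px_rect(x0, y0, x1 + 1, y1 + 1)
    local_poly <- cbind(poly[, 1] - x0, poly[, 2] - y0)
    nmask <- rasterize_polygons(local_poly, rect_height(wr), rect_width(wr))
    masks <- expand_cytoplasm(nmask, cfg$cytoplasm_px)
    loc <- lapply(channels, function(ch)
      list(chromogen = crop_raster(ch$chromogen, wr),
           nuclear = crop_raster(ch$nuclear, wr)))
    rec <- quantify_cell(masks, loc, stain_names = cfg$stains)
    rec <- cbind(data.frame(
      cell_id = sprintf("r%d_c%d_s%d_%d", spec$row, spec$col,
                        cells$ref_stain[i], cells$ref_label[i]),
      tile_row = spec$row, tile_col = spec$col,
      x_px = cells$cx[i] + spec$padded["x0"],
      y_px = cells$cy[i] + spec$padded["y0"],
      support = cells$support[i], rbc_flag = cells$rbc_flag[i],
      stringsAsFactors = FALSE), rec)
    rec$x_um <- rec$x_px * cfg$mpp
    rec$y_um <- rec$y_px * cfg$mpp
    recs[[i]] <- rec
  }
  do.call(rbind, recs)
}

#' Keep only records whose centroid lies in the tile core
#'
#' Half-open containment (`x0 <= x < x1`, `y0 <= y < y1`) of the level-0
#' centroid in the *unpadded* core: since cores partition the slide, each
#' cell is kept by exactly one tile.
#'
#' @param records data.frame with `x_px`, `y_px` (level-0).
#' @param spec the tile's [tile_spec()].
#' @export
collect_core_records <- function(records, spec) {
  if (is.null(records) || nrow(records) == 0) return(records)
  records[rect_contains(spec$core, records$x_px, records$y_px), ,
          drop = FALSE]
}

#' Assemble the whole-slide features table from per-tile kept records
#'
#' Rows are sorted canonically by (tile row, tile col, local label) so
#' the table is independent of tile processing order; duplicate ids
#' (which would indicate a deduplication failure) are an error.
#'
#' @param per_tile list of data.frames from [collect_core_records()].
#' @return Features table data.frame.
#' @export
assemble_features_table <- function(per_tile) {
  per_tile <- Filter(function(x) !is.null(x) && nrow(x) > 0, per_tile)
  if (length(per_tile) == 0) return(NULL)
  tab <- do.call(rbind, per_tile)
  if (anyDuplicated(tab$cell_id))
    stop("assemble_features_table: duplicate cell ids (dedup failure)")
  lab <- as.integer(sub(".*_", "", tab$cell_id))
  tab <- tab[order(tab$tile_row, tab$tile_col, lab), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
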