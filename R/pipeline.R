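# End-to-end tile-based analysis of an iterative-staining panel.

crop_with_fill <- function(raster, r, fill = 255) {
  d <- dim(raster)
  h <- rect_height(r); w <- rect_width(r)
  inter <- rect_intersect(r, px_rect(0, 0, d[2], d[1]))
  nch <- if (length(d) == 2) 1L else d[3]
  out <- if (nch == 1) matrix(fill, h, w) else blank_rgb(h, w, fill)
  if (rect_area(inter) > 0) {
    piece <- crop_raster(raster, inter)
    rows <- (inter["y0"] - r["y0"] + 1):(inter["y1"] - r["y0"])
    cols <- (inter["x0"] - r["x0"] + 1):(inter["x1"] - r["x0"])
    if (nch == 1) out[rows, cols] <- piece else out[rows, cols, ] <- piece
  }
  out
}

#' Analyse an iterative-staining panel end to end
#'
#' Runs the full tile-based pipeline on one sample: tissue masking and
#' tile planning on the reference round, per-round stain-matrix
#' estimation and colour deconvolution, coarse translation plus per-tile
#' affine/elastic registration of each later round to the reference
#' round (on the nuclear channel), per-round nuclear segmentation,
#' composite consensus reconciliation, red-blood-cell filtering,
#' per-cell feature quantification, and exact core-based deduplication
#' into one features table.
#'
#' @param slides list of [slide_image()]s (or raw RGB rasters), one per
#'   staining round, reference round first. All rounds must share the
#'   level-0 extent.
#' @param cfg a [run_config()]; `cfg$stains` must name the rounds.
#' @param register register later rounds to the reference (disable only
#'   for pre-aligned input).
#' @param thumbnail_dim thumbnail size used for masking, stain-matrix
#'   estimation and coarse translation.
#' @param mask optional precomputed tissue mask at the thumbnail's
#'   downscale (e.g. a manual-region mask, or an all-`TRUE` matrix to
#'   force analysis of the full extent); replaces the automatic mask.
#' @return List: `features` (per-cell table, RBC-flagged cells removed),
#'   `qc_rbc` (the flagged cells), `tiles`, `mask`, `stain_matrices`,
#'   `offsets` (per-round coarse translation), `registration_qc`
#'   (per tile x round pre/post metrics), `cfg`.
#' @export
analyze_panel <- function(slides, cfg, register = TRUE, thumbnail_dim = 256,
                          mask = NULL) {
  slides <- lapply(slides, function(s)
    if (inherits(s, "slide_image")) s else slide_from_raster(s, mpp = cfg$mpp))
  n_stains <- length(slides)
  stopifnot(n_stains >= 1, length(cfg$stains) == n_stains)
  d0 <- c(slides[[1]]$meta$height[1], slides[[1]]$meta$width[1])
  slide_extent <- px_rect(0, 0, d0[2], d0[1])

  thumbs <- lapply(slides, slide_thumbnail, max_dim = thumbnail_dim)
  if (is.null(mask))
    mask <- compute_tissue_mask(thumbs[[1]]$raster, s_min = cfg$s_min,
                                v_max = cfg$v_max,
                                min_object_px = cfg$min_object_px)
  tiles <- plan_tiles(mask, cfg, downscale = thumbs[[1]]$downscale,
                      slide_extent = slide_extent)

  mats <- lapply(seq_len(n_stains), function(s) {
    tryCatch(estimate_stain_matrix(thumbs[[s]]$raster,
                                   od_floor = cfg$od_floor),
             error = function(e) {
               refs <- reference_stain_vectors()
               stain_matrix(refs$aec, refs$haematoxylin)
             })
  })
  names(mats) <- cfg$stains

  offsets <- vector("list", n_stains)
  offsets[[1]] <- list(dx = 0, dy = 0)
  thumb_nuc <- lapply(seq_len(n_stains), function(s)
    deconvolve_tile(thumbs[[s]]$raster, mats[[s]])$nuclear)
  if (n_stains > 1) for (s in 2:n_stains)
    offsets[[s]] <- coarse_translate(thumb_nuc[[1]], thumb_nuc[[s]],
                                     downscale = thumbs[[s]]$downscale)

  per_tile_records <- list()
  reg_qc <- list()
  for (t in tiles) {
    pad <- t$padded
    channels <- vector("list", n_stains)
    fixed_rgb <- crop_with_fill(slides[[1]]$levels[[1]], pad)
    channels[[1]] <- deconvolve_tile(fixed_rgb, mats[[1]])
    if (n_stains > 1) for (s in 2:n_stains) {
      shifted <- px_rect(pad["x0"] + offsets[[s]]$dx,
                         pad["y0"] + offsets[[s]]$dy,
                         pad["x1"] + offsets[[s]]$dx,
                         pad["y1"] + offsets[[s]]$dy)
      mov_rgb <- crop_with_fill(slides[[s]]$levels[[1]], shifted)
      ch <- deconvolve_tile(mov_rgb, mats[[s]])
      if (register) {
        field <- register_tile_pair(channels[[1]]$nuclear, ch$nuclear,
                                    params = list(
                                      elastic_spacing_px = cfg$elastic_spacing_px))
        ch <- lapply(ch, function(m) apply_deformation(m, field, fill = 0))
        reg_qc[[length(reg_qc) + 1]] <- data.frame(
          tile_row = t$row, tile_col = t$col, stain = cfg$stains[s],
          method = field$method, metric_pre = field$metric_pre,
          metric_post = field$metric_post)
      }
      channels[[s]] <- ch
    }
    names(channels) <- cfg$stains
    per_stain <- lapply(channels, function(ch)
      segment_nuclei(ch$nuclear))
    cells <- reconcile_composite(per_stain, cfg)
    recs <- quantify_tile(cells, channels, t, cfg)
    if (!is.null(recs)) {
      # cohort medians used later by the RBC filter
      res_med <- nuc_med <- numeric(nrow(cells))
      polys <- object_polygons(cells)
      th <- nrow(channels[[1]]$nuclear); tw <- ncol(channels[[1]]$nuclear)
      for (i in seq_len(nrow(cells))) {
        poly <- polys[[i]]
        x0 <- max(0, floor(min(poly[, 1]))); y0 <- max(0, floor(min(poly[, 2])))
        x1 <- min(tw - 1, ceiling(max(poly[, 1])))
        y1 <- min(th - 1, ceiling(max(poly[, 2])))
        wr <- px_rect(x0, y0, x1 + 1, y1 + 1)
        mask_i <- rasterize_polygons(cbind(poly[, 1] - x0, poly[, 2] - y0),
                                     rect_height(wr), rect_width(wr))
        nuc_med[i] <- stats::median(sapply(channels, function(ch)
          stats::median(crop_raster(ch$nuclear, wr)[mask_i])))
        res_med[i] <- stats::median(sapply(channels, function(ch)
          stats::median(crop_raster(ch$residual, wr)[mask_i])))
      }
      recs$nuclear_p50_all <- nuc_med
      recs$residual_p50_all <- res_med
      per_tile_records[[length(per_tile_records) + 1]] <-
        collect_core_records(recs, t)
    }
  }
  tab <- assemble_features_table(per_tile_records)
  qc_rbc <- NULL
  if (!is.null(tab) && nrow(tab) >= 10) {
    flagged <- filter_rbc(tab, tab$nuclear_p50_all, tab$residual_p50_all)
    qc_rbc <- flagged[flagged$rbc_flag, , drop = FALSE]
    tab <- flagged[!flagged$rbc_flag, , drop = FALSE]
  }
  list(features = tab, qc_rbc = qc_rbc, tiles = tiles, mask = mask,
       stain_matrices = mats, offsets = offsets,
       registration_qc = if (length(reg_qc)) do.call(rbind, reg_qc) else NULL,
       cfg = cfg)
}
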