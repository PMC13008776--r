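# Run configuration.
#
# One plain-text key=value document holds everything needed to reproduce
# a run: stain names, tiling geometry, consensus parameters, clustering
# settings, the seed, the physical scale, and (once estimated) the stain
# matrices. Unknown keys warn but never fail, so configs written by newer
# versions still load.

config_defaults <- function() {
  list(
    stains = "stain0",          # ordered; first stain is the reference
    tile_size = 1000,           # px; ~500 um at the default mpp
    overlap_frac = 0.10,        # total shared border between neighbours
    min_tissue_frac = 0.05,     # tiles below this tissue content are dropped
    consensus_frac = 0.60,      # fraction of rounds a nucleus must appear in
    match_radius_um = 3.0,      # centroid consensus radius
    cytoplasm_px = 3,           # nuclear boundary expansion
    pca_var = 0.90,             # explained variance kept before clustering
    k_clusters = 20,            # clusters per marker
    seed = 1,
    mpp = 0.5,                  # um per pixel at level 0
    od_floor = 0.15,            # stain-matrix estimation tissue floor
    s_min = 0.05,               # tissue mask: minimum HSV saturation
    v_max = 0.95,               # tissue mask: maximum HSV value
    min_object_px = 64,         # tissue mask: smallest kept object
    elastic_spacing_px = 50,    # elastic registration control-grid spacing
    stain_matrices = list()     # per-stain 3x3 row-major, filled at run time
  )
}

#' Create a run configuration
#'
#' @param ... named overrides of the defaults (see Details). `stains` is
#'   the ordered character vector of stain/marker names; the first stain
#'   is the registration reference.
#' @return Object of class `run_config` (a validated named list).
#' @details Defaults: 1000-px tiles, 10% overlapping borders, 5% minimum
#'   tissue per tile, 60% consensus within 3 um, 3-px cytoplasm
#'   expansion, PCA to 90% variance, 20 clusters per marker, 0.5 um/px.
#' @export
run_config <- function(...) {
  cfg <- config_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    warning("run_config: unknown key(s): ", paste(unknown, collapse = ", "))
  for (k in intersect(names(dots), names(cfg))) cfg[[k]] <- dots[[k]]
  if (cfg$overlap_frac < 0 || cfg$overlap_frac >= 0.5)
    stop("run_config: overlap_frac must be in [0, 0.5)")
  if (cfg$consensus_frac <= 0 || cfg$consensus_frac > 1)
    stop("run_config: consensus_frac must be in (0, 1]")
  if (cfg$mpp <= 0) stop("run_config: mpp must be positive")
  if (cfg$tile_size < 1) stop("run_config: tile_size must be >= 1")
  structure(cfg, class = "run_config")
}

#' Margin (padding per tile side) implied by a configuration
#'
#' Half of the overlap fraction times the tile size, rounded: neighbouring
#' padded tiles then share a strip of `overlap_frac * tile_size` pixels
#' (100 px, i.e. 10%, at the defaults).
#'
#' @param cfg a [run_config()].
#' @export
tile_margin <- function(cfg) round(cfg$overlap_frac / 2 * cfg$tile_size)

#' Write / read a run configuration as plain text
#'
#' One `key = value` pair per line; vectors are comma-separated; stain
#' matrices are stored as nine row-major floats per stain. Unknown keys
#' on read produce a warning, never an error.
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(cfg, path) {
  lines <- character(0)
  for (k in setdiff(names(cfg), "stain_matrices")) {
    v <- cfg[[k]]
    lines <- c(lines, paste0(k, " = ", paste(formatC(v, digits = 17,
                                                     format = "g"),
                                             collapse = ",")))
  }
  for (nm in names(cfg$stain_matrices)) {
    m <- cfg$stain_matrices[[nm]]
    lines <- c(lines, paste0("stain_matrix.", nm, " = ",
                             paste(formatC(as.vector(t(unclass(m))),
                                           digits = 17, format = "g"),
                                   collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  defaults <- config_defaults()
  cfg <- defaults
  mats <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    items <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    if (startsWith(key, "stain_matrix.")) {
      nm <- sub("^stain_matrix\\.", "", key)
      m <- matrix(as.numeric(items), 3, 3, byrow = TRUE)
      colnames(m) <- c("chromogen", "nuclear", "residual")
      mats[[nm]] <- m
      next
    }
    if (!key %in% names(defaults)) {
      warning("read_run_config: unknown key '", key, "' ignored")
      next
    }
    num <- suppressWarnings(as.numeric(items))
    cfg[[key]] <- if (anyNA(num)) items else num
  }
  cfg$stain_matrices <- mats
  do.call(run_config, cfg)
}
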