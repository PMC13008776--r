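# GeoJSON region and point annotations.
#
# Annotations follow common slide-annotation practice: a FeatureCollection
# whose Polygon features are pathologist compartments (tumour, adjacent,
# fibrosis, necrosis, ...) and whose Point features are manual cell
# clicks, with coordinates in level-0 pixel units. The compartment name is
# read from either `properties.classification.name` (QuPath dialect) or
# `properties.name`; features without one are named "unlabelled". File
# order is preserved because it defines compartment precedence downstream.

#' Construct an annotation set
#'
#' @param polygons list of entries `list(name = <chr>, coords = <n x 2
#'   matrix>)` in file order; polygons are closed implicitly (last vertex
#'   need not repeat the first).
#' @param points data.frame with columns `x`, `y`, `class` (may be empty).
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(polygons = list(),
                           points = data.frame(x = numeric(0), y = numeric(0),
                                               class = character(0))) {
  structure(list(polygons = polygons, points = points),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set: %d polygon(s), %d point(s)>\n",
              length(x$polygons), nrow(x$points)))
  invisible(x)
}

feature_name <- function(props) {
  if (!is.null(props$classification) && !is.null(props$classification$name))
    as.character(props$classification$name)
  else if (!is.null(props$name)) as.character(props$name)
  else "unlabelled"
}

#' Read annotations from a GeoJSON file
#'
#' Polygon and Point features are captured with their classification
#' names; MultiPolygon features are split into their member polygons.
#' Other geometry types are skipped with a warning. Only the outer ring
#' of a polygon is used (holes are ignored with a warning).
#'
#' @param path GeoJSON file (a FeatureCollection).
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$type) || g$type != "FeatureCollection")
    stop("read_annotations: not a GeoJSON FeatureCollection")
  polys <- list(); pts_x <- numeric(0); pts_y <- numeric(0); pts_c <- character(0)
  ring_to_matrix <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    # drop an explicit closing vertex
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    m
  }
  for (f in g$features) {
    geom <- f$geometry
    nm <- feature_name(f$properties)
    if (is.null(geom)) next
    if (geom$type == "Polygon") {
      if (length(geom$coordinates) > 1)
        warning("read_annotations: polygon holes ignored for '", nm, "'")
      polys[[length(polys) + 1]] <-
        list(name = nm, coords = ring_to_matrix(geom$coordinates[[1]]))
    } else if (geom$type == "MultiPolygon") {
      for (pg in geom$coordinates)
        polys[[length(polys) + 1]] <-
          list(name = nm, coords = ring_to_matrix(pg[[1]]))
    } else if (geom$type == "Point") {
      pts_x <- c(pts_x, as.numeric(geom$coordinates[[1]]))
      pts_y <- c(pts_y, as.numeric(geom$coordinates[[2]]))
      pts_c <- c(pts_c, nm)
    } else {
      warning("read_annotations: skipping unsupported geometry type ",
              geom$type)
    }
  }
  annotation_set(polys, data.frame(x = pts_x, y = pts_y, class = pts_c,
                                   stringsAsFactors = FALSE))
}

#' Write annotations to a GeoJSON file
#'
#' Inverse of [read_annotations()]; vertex coordinates are written at full
#' double precision so a write/read round trip preserves them exactly.
#'
#' @param ann an [annotation_set()].
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  features <- list()
  for (p in ann$polygons) {
    ring <- lapply(seq_len(nrow(p$coords)), function(i)
      c(p$coords[i, 1], p$coords[i, 2]))
    ring[[length(ring) + 1]] <- ring[[1]]
    features[[length(features) + 1]] <- list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(classification = list(name = p$name))
    )
  }
  if (nrow(ann$points) > 0) for (i in seq_len(nrow(ann$points))) {
    features[[length(features) + 1]] <- list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(ann$points$x[i], ann$points$y[i])),
      properties = list(classification = list(name = ann$points$class[i]))
    )
  }
  json <- jsonlite::toJSON(list(type = "FeatureCollection", features = features),
                           auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}
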