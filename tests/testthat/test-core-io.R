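test_that("half-open rectangles partition and contain as documented", {
  r <- px_rect(10, 20, 30, 50)
  expect_equal(rect_width(r), 20)
  expect_equal(rect_height(r), 30)
  expect_equal(rect_area(r), 600)
  # left/top edge inside, right/bottom edge outside
  expect_true(rect_contains(r, 10, 20))
  expect_false(rect_contains(r, 30, 20))
  expect_false(rect_contains(r, 10, 50))
  expect_error(px_rect(5, 5, 4, 6), "inverted")
})

test_that("read_region round-trips, honours pyramid levels and rejects bad bounds", {
  set.seed(1)
  raster <- array(runif(64 * 48 * 3, 0, 255), dim = c(48, 64, 3))
  slide <- slide_from_raster(raster, mpp = 0.5, n_levels = 2)
  expect_identical(read_region(slide, 0, px_rect(0, 0, 64, 48)), raster)
  # level 1 has half the level-0 dimensions
  expect_equal(dim(slide$levels[[2]]), c(24, 32, 3))
  expect_equal(slide$meta$downscale, c(1, 2))
  sub <- read_region(slide, 0, px_rect(10, 5, 20, 15))
  expect_equal(sub[1, 1, ], raster[6, 11, ])     # output (0,0) = bounds origin
  expect_error(read_region(slide, 0, px_rect(0, 0, 0, 10)), "zero-area")
  expect_error(read_region(slide, 0, px_rect(0, 0, 100, 10)), "outside")
})

test_that("slides survive a multi-page TIFF round trip", {
  set.seed(2)
  raster <- array(sample(0:255, 32 * 32 * 3, TRUE), dim = c(32, 32, 3))
  slide <- slide_from_raster(raster, n_levels = 2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_slide_tiff(slide, path)
  back <- read_slide_tiff(path)
  expect_equal(back$levels[[1]], slide$levels[[1]], tolerance = 1 / 255)
  expect_equal(nrow(back$meta), 2)
})

test_that("GeoJSON annotations read, skip and round-trip as specified", {
  sq <- cbind(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))
  ann <- annotation_set(
    polygons = list(list(name = "tumour", coords = sq)),
    points = data.frame(x = c(1.5, 2.25, 3), y = c(4, 5, 6.125),
                        class = rep("Cell", 3)))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_length(back$polygons, 1)
  expect_equal(back$polygons[[1]]$name, "tumour")
  # vertex lists preserved exactly
  expect_identical(back$polygons[[1]]$coords, sq)
  expect_equal(nrow(back$points), 3)
  expect_identical(back$points, ann$points)

  # unsupported geometry warns and is skipped; missing name -> unlabelled
  writeLines(jsonlite::toJSON(list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(c(0, 0), c(1, 1))),
         properties = list(name = "scribble")),
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(7, 8)),
         properties = NULL)
  )), auto_unbox = TRUE), path)
  expect_warning(back2 <- read_annotations(path), "unsupported")
  expect_length(back2$polygons, 0)
  expect_equal(back2$points$class, "unlabelled")
})

test_that("stitching reassembles the exact mosaic from overlapping padded tiles", {
  # 2x2 grid of distinct constant tiles, padded by 5 px
  extent <- px_rect(0, 0, 40, 40)
  tiles <- list()
  vals <- matrix(c(10, 60, 110, 160), 2, 2)
  full <- blank_rgb(40, 40, 0)
  for (r in 1:2) for (c in 1:2) {
    core <- px_rect((c - 1) * 20, (r - 1) * 20, c * 20, r * 20)
    padded <- rect_expand(core, 5, clip = extent)
    tile <- blank_rgb(rect_height(padded), rect_width(padded), vals[r, c])
    tiles[[length(tiles) + 1]] <- list(spec = tile_spec(r, c, core, padded),
                                       raster = tile)
    full[(core["y0"] + 1):core["y1"], (core["x0"] + 1):core["x1"], ] <-
      vals[r, c]
  }
  out <- stitch_tiles(tiles, mode = "rgb")
  expect_identical(out, full)
  # single tile stitches to its core
  one <- stitch_tiles(tiles[1], mode = "rgb")
  expect_equal(dim(one), c(20, 20, 3))
  expect_true(all(one == 10))
  # tile decomposition of an arbitrary raster reproduces it exactly
  set.seed(3)
  ras <- array(runif(40 * 40 * 3, 0, 255), dim = c(40, 40, 3))
  tiles2 <- lapply(tiles, function(t)
    list(spec = t$spec, raster = crop_raster(ras, t$spec$padded)))
  expect_identical(stitch_tiles(tiles2, mode = "rgb"), ras)
  # a missing tile leaves background and warns
  expect_warning(part <- stitch_tiles(tiles[1:3], extent = extent),
                 "uncovered")
  expect_true(all(part[30, 30, ] == 255))
})

test_that("features tables round-trip losslessly and reject duplicate ids", {
  recs <- data.frame(cell_id = c("a", "b", "c"),
                     nucleus_chromogen_p50_CD3 = c(pi, exp(1), 1 / 3),
                     nucleus_chromogen_p50_FOXP3 = c(0.1, 0.22, 1e-17),
                     area = c(50L, 60L, 70L),
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_table(recs, path)
  back <- read_features_table(path)
  expect_equal(back, recs)
  expect_identical(back$nucleus_chromogen_p50_CD3, recs$nucleus_chromogen_p50_CD3)
  # per-stain columns are suffixed by stain name
  expect_true(all(c("nucleus_chromogen_p50_CD3",
                    "nucleus_chromogen_p50_FOXP3") %in% names(back)))
  # empty table -> header only
  write_features_table(recs[0, ], path)
  expect_equal(nrow(read_features_table(path)), 0)
  expect_named(read_features_table(path), names(recs))
  recs$cell_id <- c("a", "a", "c")
  expect_error(write_features_table(recs, path), "duplicate")
})

test_that("run configuration validates, persists and re-reads faithfully", {
  cfg <- run_config(stains = c("CD3", "FOXP3"), k_clusters = 10, seed = 42)
  expect_equal(cfg$tile_size, 1000)
  expect_equal(cfg$overlap_frac, 0.10)
  expect_equal(cfg$consensus_frac, 0.60)
  expect_equal(cfg$match_radius_um, 3.0)
  expect_equal(cfg$cytoplasm_px, 3)
  expect_equal(cfg$pca_var, 0.90)
  expect_equal(cfg$mpp, 0.5)
  expect_equal(tile_margin(cfg), 50)
  expect_error(run_config(overlap_frac = 0.6), "overlap_frac")
  expect_error(run_config(consensus_frac = 0), "consensus_frac")
  expect_warning(run_config(bogus_key = 1), "unknown")

  refs <- reference_stain_vectors()
  cfg$stain_matrices <- list(CD3 = stain_matrix(refs$aec, refs$haematoxylin))
  path <- withr::local_tempfile(fileext = ".cfg")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$stains, c("CD3", "FOXP3"))
  expect_equal(back$k_clusters, 10)
  expect_equal(back$seed, 42)
  expect_equal(unclass(back$stain_matrices$CD3),
               unclass(cfg$stain_matrices$CD3), ignore_attr = TRUE)
  writeLines(c("tile_size = 500", "mystery = 7"), path)
  expect_warning(back2 <- read_run_config(path), "unknown key")
  expect_equal(back2$tile_size, 500)
})
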