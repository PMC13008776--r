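test_that("the builtin backend finds planted nuclei once each", {
  expect_equal(nrow(segment_nuclei(matrix(0, 64, 64))), 0)
  df <- disc_field(50, 400, 400, r = 5, sep = 14, seed = 10)
  ns <- segment_nuclei(df$od)
  expect_equal(nrow(ns), 50)
  d <- min_dists(cbind(ns$cx, ns$cy), df$centres)
  expect_true(all(apply(d, 1, min) < 1))        # centroid error < 1 px
  # two touching discs split by the watershed
  m <- matrix(0, 60, 60)
  m <- stainplex:::paint_ellipse(m, 24, 30, 5.5, 5.5, 0, 0.8)
  m <- stainplex:::paint_ellipse(m, 36, 30, 5.5, 5.5, 0, 0.8)
  expect_equal(nrow(segment_nuclei(EBImage::gblur(m, 0.7))), 2)
  expect_error(segment_nuclei(df$od, backend = "stardist"), "stardist")
})

# build nucleus sets from plain centroid tables (geometry-free fixtures)
fake_set <- function(xy) {
  if (length(xy) == 0 || nrow(xy) == 0)
    return(stainplex:::empty_nucleus_set())
  tab <- data.frame(label = seq_len(nrow(xy)), cx = xy[, 1], cy = xy[, 2],
                    area = 80)
  polys <- lapply(seq_len(nrow(xy)), function(i)
    cbind(xy[i, 1] + c(-2, 2, 2, -2), xy[i, 2] + c(-2, -2, 2, 2)))
  nucleus_set(tab, polys)
}

test_that("consensus keeps 60% support inclusively and singletons trivially", {
  cfg <- run_config(stains = paste0("s", 1:5))
  base <- cbind(c(10, 50), c(10, 50))
  # object 1 in 3 of 5 stains (3/5 = 0.6 passes), object 2 in 2 of 5 (fails)
  per_stain <- list(fake_set(base), fake_set(base),
                    fake_set(base[1, , drop = FALSE]),
                    fake_set(NULL), fake_set(NULL))
  comp <- reconcile_composite(per_stain, cfg)
  expect_equal(nrow(comp), 1)
  expect_equal(comp$support, 3)
  expect_equal(comp$cx, 10)
  # n_stains = 1 retains everything with support 1
  comp1 <- reconcile_composite(list(fake_set(base)), run_config(stains = "s1"))
  expect_equal(nrow(comp1), 2)
  expect_equal(comp1$support, c(1, 1))
  expect_error(reconcile_composite(list(), cfg), "no stains")
})

test_that("greedy consensus matches the exhaustive oracle on a planted panel", {
  cfg <- run_config(stains = paste0("s", 1:5))
  set.seed(12)
  n <- 100
  xy <- stainplex:::place_points(n, 1000, 1000, 20, 20)
  dropout <- matrix(runif(n * 5) < 0.1, n, 5)
  jitter <- function(p) p + matrix(runif(length(p), -1.5, 1.5), ncol = 2)
  per_stain <- lapply(1:5, function(s) {
    pts <- jitter(xy[!dropout[, s], , drop = FALSE])
    if (s <= 4 && s * 5 <= 20) {
      # 5 single-stain artefacts per stain s = 1..4 (20 total)
      art <- cbind(runif(5, 20, 980), runif(5, 20, 980))
      pts <- rbind(pts, art)
    }
    fake_set(pts)
  })
  comp <- reconcile_composite(per_stain, cfg)
  surviving <- which(rowSums(!dropout) >= 3)
  expect_equal(nrow(comp), length(surviving))
  d <- min_dists(cbind(comp$cx, comp$cy), xy[surviving, , drop = FALSE])
  expect_true(all(apply(d, 1, min) < 3))
  # exhaustive union-find oracle agrees on count and positions
  oracle <- oracle_consensus(per_stain, radius = cfg$match_radius_um / cfg$mpp,
                             consensus = cfg$consensus_frac)
  expect_equal(nrow(comp), nrow(oracle))
  expect_true(all(apply(min_dists(cbind(comp$cx, comp$cy), oracle), 1,
                        min) < 3))
})

test_that("raising the consensus threshold never increases the composite count", {
  set.seed(13)
  n <- 60
  xy <- cbind(runif(n, 10, 490), runif(n, 10, 490))
  dropout <- matrix(runif(n * 5) < 0.25, n, 5)
  per_stain <- lapply(1:5, function(s) fake_set(xy[!dropout[, s], , drop = FALSE]))
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(cf) {
    cfg <- run_config(stains = paste0("s", 1:5), consensus_frac = cf)
    nrow(reconcile_composite(per_stain, cfg))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("reconciliation is stable under within-stain order shuffles", {
  set.seed(14)
  n <- 40
  xy <- stainplex:::place_points(n, 500, 500, 15, 10)
  per_stain <- lapply(1:3, function(s)
    fake_set(xy + matrix(runif(2 * n, -1, 1), ncol = 2)))
  cfg <- run_config(stains = paste0("s", 1:3))
  ref <- reconcile_composite(per_stain, cfg)
  shuffled <- lapply(per_stain, function(ns) {
    ord <- sample(nrow(ns))
    tab <- ns[ord, ]; tab$label <- seq_len(nrow(tab))
    nucleus_set(tab, object_polygons(ns)[ord])
  })
  alt <- reconcile_composite(shuffled, cfg)
  expect_equal(nrow(ref), nrow(alt))
  d <- min_dists(cbind(ref$cx, ref$cy), cbind(alt$cx, alt$cy))
  expect_true(all(apply(d, 1, min) <= cfg$match_radius_um / cfg$mpp))
})

test_that("true-cell retention follows the binomial consensus tail", {
  set.seed(15)
  n <- 400; d <- 0.25; n_stains <- 5
  xy <- stainplex:::place_points(n, 2000, 2000, 18, 15)
  set.seed(152)
  dropout <- matrix(runif(n * n_stains) < d, n, n_stains)
  per_stain <- lapply(seq_len(n_stains), function(s)
    fake_set(xy[!dropout[, s], , drop = FALSE]))
  cfg <- run_config(stains = paste0("s", 1:5))
  comp <- reconcile_composite(per_stain, cfg)
  # sharp invariant: retained composites are exactly the cells present in
  # at least ceil(0.6 * 5) = 3 rounds ...
  realized <- sum(rowSums(!dropout) >= 3)
  expect_equal(nrow(comp), realized)
  # ... and that count is an ordinary binomial-tail draw
  p_keep <- sum(stats::dbinom(3:5, n_stains, 1 - d))
  sd3 <- 3 * sqrt(n * p_keep * (1 - p_keep))
  expect_lt(abs(realized - n * p_keep), sd3)
})

test_that("the RBC filter flags planted anucleate objects and spares cells", {
  set.seed(16)
  n_true <- 200; n_rbc <- 10
  med_nuc <- c(runif(n_true, 0.5, 1.0), runif(n_rbc, 0.1, 0.25))
  med_res <- c(runif(n_true, 0, 0.05), runif(n_rbc, 0.4, 0.7))
  cells <- data.frame(cell_id = seq_len(n_true + n_rbc),
                      rbc_flag = FALSE)
  out <- filter_rbc(cells, med_nuc, med_res)
  planted <- seq(n_true + 1, n_true + n_rbc)
  expect_gte(sum(out$rbc_flag[planted]), 9)
  expect_lte(sum(out$rbc_flag[-planted]), 2)
  # hit/miss scoring against the planted labels
  hits <- sum(out$rbc_flag[planted]); misses <- n_rbc - hits
  expect_equal(hits + misses, n_rbc)
  # a clean cohort with no anucleate population gets no flags
  clean <- filter_rbc(cells[1:n_true, ], med_nuc[1:n_true], med_res[1:n_true])
  expect_false(any(clean$rbc_flag))
  expect_warning(filter_rbc(cells[1:5, ], med_nuc[1:5], med_res[1:5]),
                 "fewer than 10")
})

test_that("cytoplasm expansion dilates by the configured pixel count", {
  disc <- matrix(FALSE, 30, 30)
  disc <- stainplex:::paint_ellipse(disc * 0, 15, 15, 5, 5, 0, 1) > 0
  out0 <- expand_cytoplasm(disc, 0)
  expect_identical(out0$cell, disc)
  expect_false(any(out0$cytoplasm))
  out3 <- expand_cytoplasm(disc, 3)     # the default expansion is 3 px
  expect_equal(run_config()$cytoplasm_px, 3)
  expect_lt(abs(sum(out3$cell) - pi * 8^2) / (pi * 8^2), 0.1)
  expect_identical(out3$cytoplasm, out3$cell & !disc)
  expect_true(all(disc[out3$cell] | TRUE))  # nucleus contained in cell
  expect_true(all(out3$cell[disc]))
})
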