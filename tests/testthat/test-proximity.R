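test_that("point-in-polygon is boundary-inclusive and matches an independent oracle", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_true(point_in_polygon(5, 5, sq))
  expect_true(point_in_polygon(0, 5, sq))    # edge
  expect_true(point_in_polygon(10, 10, sq))  # vertex
  expect_false(point_in_polygon(10.01, 5, sq))
  # non-convex polygon, interior points vs mgcv's ray-casting oracle
  poly <- cbind(c(0, 6, 6, 3, 3, 0), c(0, 0, 6, 6, 3, 3))
  set.seed(25)
  px <- runif(1000, -1, 7); py <- runif(1000, -1, 7)
  mine <- point_in_polygon(px, py, poly)
  oracle <- mgcv::in.out(rbind(poly, poly[1, ]), cbind(px, py))
  # they may legitimately differ only on the boundary
  disagree <- which(mine != oracle)
  if (length(disagree) > 0) {
    d_edge <- vapply(disagree, function(i) {
      segs <- cbind(poly, rbind(poly[-1, ], poly[1, ]))
      min(apply(segs, 1, function(s) {
        v <- s[3:4] - s[1:2]; t <- sum((c(px[i], py[i]) - s[1:2]) * v) / sum(v^2)
        t <- min(1, max(0, t))
        sqrt(sum((c(px[i], py[i]) - s[1:2] - t * v)^2))
      }))
    }, numeric(1))
    expect_lt(max(d_edge), 1e-6)
  } else succeed()
})

test_that("compartment assignment uses file order and partitions the cells", {
  ann <- annotation_set(polygons = list(
    list(name = "tumour", coords = cbind(c(0, 50, 50, 0), c(0, 0, 50, 50))),
    list(name = "fibrosis", coords = cbind(c(30, 80, 80, 30), c(0, 0, 50, 50)))
  ))
  x <- c(10, 40, 70, 90); y <- c(10, 10, 10, 10)
  lab <- assign_compartments(x, y, ann)
  # the overlap zone (x = 40) goes to the first polygon in file order
  expect_equal(lab, c("tumour", "tumour", "fibrosis", "unassigned"))
  expect_equal(sum(table(lab)), length(x))
  bad <- annotation_set(polygons = list(
    list(name = "broken", coords = cbind(c(0, 1), c(0, 1)))))
  expect_warning(lab2 <- assign_compartments(5, 5, bad), "invalid polygon")
  expect_equal(lab2, "unassigned")
})

test_that("densities convert pixel areas to cells per mm^2", {
  expect_equal(compute_density(0, 1), 0)
  expect_equal(compute_density(100, 2), 50)
  expect_error(compute_density(5, 0), "positive")
  # a 2000 x 2000 px square at 0.5 um/px is exactly 1 mm^2
  ann <- annotation_set(polygons = list(
    list(name = "roi", coords = cbind(c(0, 2000, 2000, 0), c(0, 0, 2000, 2000)))))
  expect_equal(unname(compartment_areas_mm2(ann, mpp = 0.5)["roi"]), 1)
})

test_that("nearest-neighbour distances are exact and invariant to rigid motions", {
  g <- expand.grid(x = seq(0, 90, by = 10), y = seq(0, 90, by = 10))
  A <- as.matrix(g)
  expect_equal(nn_distances(A, A, same_population = TRUE),
               rep(10, nrow(A)))
  set.seed(26)
  a <- cbind(runif(80, 0, 500), runif(80, 0, 500))
  b <- cbind(runif(60, 0, 500), runif(60, 0, 500))
  brute <- apply(a, 1, function(p) min(sqrt((b[, 1] - p[1])^2 +
                                            (b[, 2] - p[2])^2)))
  expect_equal(nn_distances(a, b), brute)
  # translation and rotation invariance
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  a2 <- a %*% R + 100; b2 <- b %*% R + 100
  expect_equal(nn_distances(a2, b2), brute, tolerance = 1e-9)
  expect_error(nn_distances(a, a[0, , drop = FALSE]), "empty")
  expect_error(nn_distances(a[1, , drop = FALSE], a[1, , drop = FALSE],
                            same_population = TRUE), ">= 2")
})

test_that("the KDE mode summarises nearest-neighbour distributions", {
  # degenerate: identical distances short-circuit
  expect_equal(kde_mode(rep(12.5, 40))$mode, 12.5)
  # unimodal: mode of a Normal(50, 5) sample within 50 +/- 2
  set.seed(27)
  d <- pmax(0, rnorm(1000, 50, 5))
  expect_lt(abs(kde_mode(d)$mode - 50), 2)
  # Scott bandwidth used by default
  expect_equal(kde_mode(d)$bandwidth, sd(d) * 1000^(-1 / 5))
  # bimodal 80/20 mixture peaks at the heavier component
  d2 <- c(rnorm(800, 20, 2), rnorm(200, 60, 2))
  expect_lt(abs(kde_mode(d2)$mode - 20), 2)
  expect_error(kde_mode(5), "at least 2")
})

test_that("paired synthetic patterns reproduce the planted distance", {
  pat <- sample_point_pattern("paired", n = 60, d = 20, seed = 28)
  d <- nn_distances(pat$A, pat$B)
  expect_equal(d, rep(20, 60), tolerance = 1e-9)
  km <- kde_mode(d)
  expect_equal(km$mode, 20, tolerance = 1e-6)
  reg <- sample_point_pattern("regular", n = 100, spacing = 25, seed = 29)
  expect_equal(kde_mode(nn_distances(reg$A, reg$B,
                                     same_population = TRUE))$mode, 25,
               tolerance = 1e-6)
})

test_that("proximity summaries stratify pair by compartment with counts", {
  set.seed(30)
  n <- 120
  cells <- data.frame(
    x_um = runif(n, 0, 400), y_um = runif(n, 0, 400),
    compartment = sample(c("tumour", "fibrosis"), n, TRUE),
    CD8 = runif(n) < 0.5, B = runif(n) < 0.3)
  out <- proximity_summary(cells, data.frame(a = c("CD8", "CD8"),
                                             b = c("CD8", "B")),
                           sample_id = "s1")
  expect_true(all(out$mode_um >= 0))
  expect_true(all(out$n_a >= 2))
  expect_setequal(unique(out$compartment), c("tumour", "fibrosis"))
  # partition invariant: every cell is in exactly one compartment
  expect_equal(nrow(cells), sum(table(cells$compartment)))
})
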