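test_that("disc-polygon intersection areas are exact", {
  square <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  # disc fully inside
  expect_equal(disc_polygon_area(c(50, 50), 10, square), pi * 100)
  # disc centered on a corner: quarter disc
  expect_equal(disc_polygon_area(c(0, 0), 20, square), pi * 400 / 4,
               tolerance = 1e-9)
  # disc engulfing the polygon: polygon area
  expect_equal(disc_polygon_area(c(50, 50), 1000, square), 1e4)
  # Monte-Carlo oracle on a generic configuration
  set.seed(21)
  hull <- convex_hull(matrix(runif(40, 0, 100), 20, 2))
  ctr <- c(30, 70); r <- 35
  mc <- local({
    n <- 4e5
    th <- runif(n, 0, 2 * pi); rr <- sqrt(runif(n)) * r
    px <- ctr[1] + rr * cos(th); py <- ctr[2] + rr * sin(th)
    mean(in_convex_polygon(px, py, hull)) * pi * r^2
  })
  expect_equal(disc_polygon_area(ctr, r, hull), mc, tolerance = 0.01)
  expect_equal(annulus_polygon_area(ctr, 10, 35, hull),
               disc_polygon_area(ctr, 35, hull) -
                 disc_polygon_area(ctr, 10, hull))
})

test_that("density recovery profile localizes known structure", {
  # two points at distance d: density only in the bin containing d
  ps <- make_point_set(rbind(c(100, 100), c(100, 175), c(0, 0), c(200, 0),
                             c(0, 200), c(200, 200)),
                       labels = c(1, 1, 2, 2, 2, 2))
  pr <- drp(ps, 1, bin_width = 10, r_max = 100)
  nz <- which(pr$counts > 0)
  expect_equal(nz, 8)           # 75 um falls in bin (70, 80]
  expect_true(all(pr$density[-nz] == 0 | !is.finite(pr$density[-nz])))
  # a single point of a type yields the undefined flag
  pr1 <- drp(ps, 3, bin_width = 10, r_max = 100)
  expect_true(pr1$undefined)
})

test_that("Poisson points yield a flat profile and unit density ratio", {
  set.seed(31)
  ratios <- replicate(30, {
    pts <- matrix(runif(2 * 250, 0, 600), ncol = 2)
    ps <- make_point_set(pts, labels = rep(1, nrow(pts)))
    p <- drp(ps, 1, bin_width = 20, r_max = 250)
    density_ratio(p, rf_diameter_deg = 20)   # R ~ 227 um
  })
  expect_lt(abs(mean(ratios) - 1), 0.15)
  # the RF-to-cortex conversion: 20 deg at 88 deg/mm is ~227.3 um
  expect_equal(20 / 88 * 1000, 227.27, tolerance = 1e-3)
  # flat profile (counts proportional to areas) gives exactly 1
  prof <- list(bin_edges = seq(0, 300, 10),
               density = rep(2.5e-3, 30))
  expect_equal(density_ratio(prof, 20), 1)
  expect_error(density_ratio(prof, 100), "extend")
})

test_that("patchy layouts raise the density ratio above 1", {
  set.seed(32)
  centers <- matrix(runif(10, 100, 500), 5, 2)
  pts <- do.call(rbind, lapply(seq_len(5), function(k)
    cbind(rnorm(40, centers[k, 1], 40), rnorm(40, centers[k, 2], 40))))
  ps <- make_point_set(pts, labels = rep(1, nrow(pts)))
  p <- drp(ps, 1, bin_width = 20, r_max = 250)
  expect_gt(density_ratio(p, rf_diameter_deg = 20), 1.2)
})

test_that("cross-type density calibrates to 1 under uniformity", {
  set.seed(33)
  Dsum <- matrix(0, 2, 2)
  nrep <- 20
  for (i in seq_len(nrep)) {
    pts <- matrix(runif(2 * 300, 0, 600), ncol = 2)
    ps <- make_point_set(pts, labels = rep(1:2, 150))
    Dsum <- Dsum + cross_type_density(ps, radius = 50)$D
  }
  expect_true(all(abs(Dsum / nrep - 1) < 0.1))
  # disjoint patches: diagonal enriched, off-diagonal depleted
  p1 <- cbind(rnorm(60, 150, 40), rnorm(60, 150, 40))
  p2 <- cbind(rnorm(60, 450, 40), rnorm(60, 450, 40))
  ps2 <- make_point_set(rbind(p1, p2), labels = rep(1:2, each = 60))
  D2 <- cross_type_density(ps2, radius = 50)$D
  expect_true(all(diag(D2) > 1))
  expect_true(all(D2[upper.tri(D2)] < 1))
  # absent type is flagged
  D3 <- cross_type_density(ps2, radius = 50, types = 1:3)$D
  expect_true(all(is.na(D3[3, ])))
})

test_that("normalized distance separates tight distant clusters", {
  a <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  expect_equal(normalized_distance(a, a), 0)
  set.seed(34)
  eps <- 0.5; s <- 100
  c1 <- cbind(rnorm(50, 0, eps), rnorm(50, 0, eps))
  c2 <- cbind(rnorm(50, s, eps), rnorm(50, 0, eps))
  nd <- normalized_distance(c1, c2)
  # direct evaluation of the definition
  dij <- sqrt(sum((colMeans(c1) - colMeans(c2))^2))
  expect_equal(nd, dij / mean(c(mean(dist(c1)), mean(dist(c2)))),
               tolerance = 1e-12)
  expect_gt(nd, 50)
  expect_equal(normalized_distance(c1, c2), normalized_distance(c2, c1))
  expect_true(is.na(normalized_distance(c1[1, , drop = FALSE], c2)))
})

test_that("separation test distinguishes interleaved from patchy pairs", {
  set.seed(35)
  # fully interleaved: not significant
  pts <- matrix(runif(2 * 60, 0, 600), ncol = 2)
  ps_mix <- make_point_set(pts, labels = rep(1:2, 30))
  res <- separation_test(list(ps_mix), 1, 2, n_boot = 200, alpha = 0.01,
                         seed = 1)
  expect_false(res$significant)
  # disjoint patches, 20 + 20 points: significant at alpha 0.01
  p1 <- cbind(rnorm(20, 150, 30), rnorm(20, 150, 30))
  p2 <- cbind(rnorm(20, 450, 30), rnorm(20, 450, 30))
  ps_sep <- make_point_set(rbind(p1, p2), labels = rep(1:2, each = 20))
  res2 <- separation_test(list(ps_sep), 1, 2, n_boot = 200, alpha = 0.01,
                          seed = 1)
  expect_true(res2$significant)
  # no qualifying session -> undetermined
  small <- make_point_set(rbind(p1[1:5, ], p2[1:5, ]),
                          labels = rep(1:2, each = 5))
  res3 <- separation_test(list(small), 1, 2, n_boot = 200, seed = 1)
  expect_true(is.na(res3$significant))
  expect_error(separation_test(list(ps_sep), 1, 2, n_boot = 10), "at least")
})

test_that("depth composition tables and chi-square match hand values", {
  # all one type: every fraction 1
  dc <- depth_composition(c(50, 150, 250, 300), rep("a", 4))
  expect_true(all(dc$fractions == 1))
  # constructed 2x2 table [[30,10],[10,30]] -> chi-square 20 (no correction)
  depths <- c(rep(50, 40), rep(150, 40))
  labs <- c(rep("x", 30), rep("y", 10), rep("x", 10), rep("y", 30))
  dc2 <- depth_composition(depths, labs, depth_bins = c(0, 100, 200))
  expect_equal(unname(dc2$counts["x", ]), c(30, 10))
  expect_equal(dc2$chisq, 20)
  expect_true(all(abs(colSums(dc2$fractions) - 1) < 1e-12))
  expect_warning(depth_composition(c(50, 60), c("a", "b"),
                                   depth_bins = c(0, 100, 200, 350)),
                 "empty")
})

test_that("density profiles are rigid-motion invariant", {
  set.seed(36)
  pts <- matrix(runif(2 * 80, 0, 400), ncol = 2)
  ps <- make_point_set(pts, labels = rep(1, 80))
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts2 <- sweep(pts %*% Rm, 2, c(1000, -500), "+")
  ps2 <- make_point_set(pts2, labels = rep(1, 80))
  p1 <- drp(ps, 1); p2 <- drp(ps2, 1)
  expect_equal(p1$counts, p2$counts, tolerance = 1e-9)
  expect_equal(p1$density, p2$density, tolerance = 1e-6)
})
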