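test_that("extremum alignment is a circular-shift invariant", {
  x <- c(0, 0.2, 1, 0.4, 0.1, 0, 0, 0.05)
  a <- align_extremum(x)
  expect_equal(which.max(a), floor(length(x) / 2) + 1)
  # already centered -> unchanged
  expect_equal(as.numeric(align_extremum(a)), as.numeric(a))
  # any circular shift aligns to the same output
  for (s in 1:7) {
    shifted <- c(x[(s + 1):8], x[1:s])
    expect_equal(as.numeric(align_extremum(shifted)), as.numeric(a))
  }
  # trough mode centers the minimum; auto picks the larger magnitude
  y <- c(0, -1, 0.3, 0, 0, 0)
  expect_equal(which.min(align_extremum(y, "trough")), 4)
  expect_equal(which.min(align_extremum(y, "auto")), 4)
  flat <- align_extremum(rep(2, 5))
  expect_true(attr(flat, "flat"))
  expect_equal(as.numeric(flat), rep(2, 5))
  expect_error(align_extremum(numeric(0)), "non-empty")
})

test_that("unit normalization maps to [0,1] and flags flat traces", {
  expect_equal(normalize_unit(c(-1, 0, 1)), c(0, 0.5, 1))
  r <- normalize_unit(rnorm(50))
  expect_equal(range(r), c(0, 1))
  z <- normalize_unit(rep(3, 10))
  expect_equal(as.numeric(z), rep(0, 10))
  expect_true(attr(z, "flat"))
})

test_that("sparse PCA recovers exact and disjoint-support structure", {
  set.seed(3)
  # exact rank-1 with sparse support, 1 component
  v <- c(rnorm(10), rep(0, 30)); v <- v / sqrt(sum(v^2))
  u <- rnorm(50)
  D <- u %*% t(v)
  fb <- sparse_pca(D, 1, sparsity = 0.5)
  expect_lt(fb$reconstruction_error, 1e-8)
  # three disjoint-support orthonormal components
  comps <- matrix(0, 3, 60)
  for (k in 1:3) {
    s <- ((k - 1) * 20 + 1):(k * 20)
    comps[k, s] <- rnorm(20)
    comps[k, ] <- comps[k, ] / sqrt(sum(comps[k, ]^2))
  }
  W <- qr.Q(qr(matrix(rnorm(120 * 3), 120, 3))) %*% (diag(c(5, 3, 2)) * 10)
  D3 <- W %*% comps
  fb3 <- sparse_pca(D3, 3, sparsity = 0.5)
  # principal angle between recovered and true component subspaces
  sv <- svd(comps %*% t(fb3$components))$d
  expect_lt(max(acos(pmin(sv, 1))), 1e-3)
  # near-orthonormal rows and the required sparsity
  G <- fb3$components %*% t(fb3$components)
  expect_lt(max(abs(G - diag(3))), 0.05)
  expect_true(all(rowMeans(abs(fb3$components) < 1e-10) >= 0.5))
})

test_that("sparse PCA reconstruction error is monotone in components", {
  set.seed(4)
  D <- matrix(rnorm(80 * 40), 80, 40)
  errs <- vapply(1:6, function(k)
    sparse_pca(D, k, sparsity = 0.5)$reconstruction_error, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  expect_error(sparse_pca(D, 100), "exceeds")
  expect_error(sparse_pca(D, 2, sparsity = 1), "sparsity")
})

test_that("feature matrix has the contracted shape and scaling", {
  ds <- fixture_dataset()
  fe <- build_features(ds)
  expect_equal(ncol(fe$values), 54)
  expect_equal(sum(grepl("^(MB|LOOM|CHIRP|COLOR|FDDS)_", fe$column_names)),
               50)
  expect_setequal(setdiff(fe$column_names,
                          grep("_", fe$column_names, value = TRUE)),
                  c("HI", "DSI", "OSI", "MSI"))
  mu <- colMeans(fe$values)
  sdv <- apply(fe$values, 2, sd)
  expect_true(all(abs(mu) < 1e-6))
  expect_true(all(abs(sdv - 1) < 1e-6))
  expect_error(build_features(ds, n_components = c(MB = 6, LOOM = 6,
                                                   CHIRP = 1000, COLOR = 8,
                                                   FDDS = 10)),
               "fewer neurons|exceeds")
})

test_that("feature matrix is invariant to neuron order up to row permutation", {
  ds <- fixture_dataset()
  perm <- sample(length(ds$neurons))
  ds2 <- ds
  ds2$neurons <- ds$neurons[perm]
  ds2$labels <- ds$labels[perm]
  f1 <- build_features(ds)
  f2 <- build_features(ds2)
  # rows correspond through neuron ids
  m <- match(f1$neuron_ids, f2$neuron_ids)
  expect_equal(abs(f2$values[m, ]), abs(f1$values), tolerance = 1e-6)
})
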