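test_that("well-separated clusters are maximally stable", {
  mix <- simulate_feature_mixture(4, 400, seed = 10)
  fit <- fit_gmm(mix$X, 4, n_restarts = 5, seed = 10)
  st <- jaccard_stability(mix$X, fit, n_subsets = 20, seed = 10)
  expect_true(all(st$jsc >= 0 & st$jsc <= 1))
  expect_true(all(st$jsc > 0.95))
  ca <- coassociation(st$label_sets, fit$labels)
  mg <- merge_unstable(fit$labels, st$jsc, ca$between_cluster_rate)
  expect_equal(mg$labels, fit$labels)
  expect_length(mg$unstable_flags, 0)
  expect_equal(nrow(mg$merged_pairs), 0)
  expect_error(jaccard_stability(mix$X, fit, fraction = 1.5), "fraction")
})

test_that("a split cluster is detected and merged by the rate rule", {
  # last two generative clusters coincide: fitting K+1 splits one cloud
  mix <- simulate_feature_mixture(5, 600, seed = 11, overlap_pair = TRUE)
  fit <- fit_gmm(mix$X, 5, n_restarts = 10, seed = 11)
  st <- jaccard_stability(mix$X, fit, n_subsets = 30, seed = 11)
  ca <- coassociation(st$label_sets, fit$labels)
  expect_true(any(st$jsc < 0.5))
  expect_true(any(st$jsc > 0.9))
  mg <- merge_unstable(fit$labels, st$jsc, ca$between_cluster_rate)
  # the rule must fire exactly per the 35% condition
  for (u in which(st$jsc < 0.5)) {
    rates <- ca$between_cluster_rate[u, -u]
    if (max(rates, na.rm = TRUE) > 0.35) {
      expect_true(u %in% mg$merged_pairs$from || u %in% mg$merged_pairs$to)
    } else {
      expect_true(u %in% mg$unstable_flags)
    }
  }
  if (nrow(mg$merged_pairs) > 0)
    expect_lt(max(mg$labels), fit$K)
})

test_that("co-association counts pairs exactly", {
  # identical partitions: entries are 0/1 with within-pairs at 1
  lab <- c(1, 1, 2, 2)
  ca <- coassociation(list(lab, lab, lab))
  expect_true(all(ca$cam %in% c(0, 1)))
  expect_equal(ca$cam[1, 2], 1)
  expect_equal(ca$cam[1, 3], 0)
  expect_true(isSymmetric(ca$cam))
  expect_equal(diag(ca$cam), rep(1, 4))
  # together in one run of two -> 0.5
  ca2 <- coassociation(list(c(1, 1, 2), c(1, 2, 2)))
  expect_equal(ca2$cam[1, 2], 0.5)
  # absent neurons only contribute where present
  ca3 <- coassociation(list(c(1, 1, NA), c(1, 1, 1)))
  expect_equal(ca3$cam[1, 3], 1)
  expect_error(coassociation(list()), "non-empty")
  # between-cluster rate from a hand partition
  ca4 <- coassociation(list(c(1, 1, 2, 2), c(1, 2, 2, 2)),
                       reference_labels = c(1, 1, 2, 2))
  expect_equal(ca4$between_cluster_rate[1, 1], 0.5)
  expect_equal(ca4$between_cluster_rate[2, 2], 1)
})

test_that("merge rule handles the flag and retain branches", {
  labels <- rep(1:3, each = 10)
  jsc <- c(0.9, 0.3, 0.8)
  rate <- matrix(c(1, 0.6, 0.1,
                   0.6, 1, 0.05,
                   0.1, 0.05, 1), 3, 3)
  mg <- merge_unstable(labels, jsc, rate)
  expect_equal(nrow(mg$merged_pairs), 1)
  expect_equal(mg$merged_pairs$from, 2)
  expect_equal(mg$merged_pairs$to, 1)
  expect_equal(max(mg$labels), 2)
  # rate below 35%: retained and flagged
  rate2 <- matrix(c(1, 0.2, 0.1,
                    0.2, 1, 0.05,
                    0.1, 0.05, 1), 3, 3)
  mg2 <- merge_unstable(labels, jsc, rate2)
  expect_equal(mg2$unstable_flags, 2)
  expect_equal(mg2$labels, labels)
})

test_that("the type dendrogram follows the Ward criterion", {
  m <- rbind(c(0, 0), c(1, 0), c(10, 0))
  d <- build_dendrogram(m)
  expect_equal(length(d$hclust$order), 3)
  # the close pair merges first
  expect_equal(sort(d$hclust$merge[1, ]), c(-2, -1))
  expect_true(all(diff(d$hclust$height) >= 0))
  # two means: a single merge; groups split 1 vs 2
  d2 <- build_dendrogram(rbind(c(0, 0), c(1, 1)))
  expect_equal(nrow(d2$hclust$merge), 1)
  expect_equal(sort(unique(d2$groups)), c(1, 2))
  expect_error(build_dendrogram(rbind(c(0, 0))), "at least 2")
  # newick export round-trips through ape
  path <- tempfile(fileext = ".newick")
  write_newick(build_dendrogram(matrix(rnorm(20), 5, 4)), path)
  tree <- ape::read.tree(path)
  expect_equal(ape::Ntip(tree), 5)
})
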