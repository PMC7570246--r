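test_that("squared-euclidean distance is the count of differing calls", {
  s <- sample_meta(c("x", "y", "z"), "Control")
  m <- band_matrix(rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)),
                   rbind(c(1, 0, 1), c(1, 0, 1), c(1, 0, 0)),
                   s)
  d <- band_distance(m)
  expect_equal(d["x", "y"], 0)
  expect_equal(d["x", "z"], 4)  # 3 M-differences + 1 H-difference
  expect_true(isSymmetric(unname(unclass(d))))
  expect_true(all(diag(d) == 0))
  expect_equal(unclass(band_distance(m, "euclidean")),
               sqrt(unclass(d)), ignore_attr = TRUE)
})

test_that("jaccard matches the shared-presence/union enumeration", {
  s <- sample_meta(c("u", "v"), "Control")
  m <- band_matrix(rbind(c(1, 1, 0), c(1, 0, 1)),
                   rbind(c(0, 0, 0), c(0, 0, 0)), s)
  # M block: shared presence 1, union 3; H block adds nothing
  d <- band_distance(m, "jaccard")
  expect_equal(d["u", "v"], 2 / 3)
})

test_that("missing calls use pairwise deletion with rescaling", {
  s <- sample_meta(c("x", "y"), "Control")
  m <- band_matrix(rbind(c(1, NA, 0, 1), c(0, 1, 0, 1)),
                   rbind(c(1, 1, 1, 1), c(1, 1, 1, 1)), s)
  # 7 shared bands, 1 differing -> rescaled to 8 bands: 8/7
  expect_equal(band_distance(m)["x", "y"], 8 / 7)
  m2 <- band_matrix(rbind(c(NA, NA), c(1, 1)), rbind(c(NA, NA), c(1, 1)), s)
  expect_error(band_distance(m2), "share no non-missing bands")
})

test_that("pcoa recovers closed-form and embeddable configurations", {
  # two samples at euclidean distance 5 -> axis-1 coordinates +/- 2.5
  d2 <- structure(matrix(c(0, 5, 5, 0), 2,
                         dimnames = list(c("a", "b"), c("a", "b"))),
                  metric = "euclidean", class = c("band_dist", "matrix"))
  p2 <- pcoa(d2, n_axes = 1)
  expect_equal(sort(p2$coordinates[, 1]), c(-2.5, 2.5), ignore_attr = TRUE)

  # three equidistant samples -> two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa(structure(d3, metric = "euclidean",
                       class = c("band_dist", "matrix")), n_axes = 2)
  expect_equal(p3$eigenvalues[1], p3$eigenvalues[2], tolerance = 1e-9)

  # euclidean-embeddable distances are reconstructed to 1e-9
  set.seed(5)
  pts <- matrix(rnorm(7 * 3), 7)
  d <- as.matrix(dist(pts))
  res <- suppressMessages(
    pcoa(structure(d, metric = "euclidean",
                   class = c("band_dist", "matrix")), n_axes = 7))
  rec <- as.matrix(dist(res$coordinates))
  expect_lt(max(abs(rec - d)), 1e-9)
  # axes are centered
  expect_lt(max(abs(colSums(res$coordinates))), 1e-9)
  # agrees with the classical-scaling oracle in stats
  cm <- cmdscale(d, k = 2)
  expect_equal(abs(res$coordinates[, 1:2]), abs(cm), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("squared-euclidean band distances embed without re-squaring", {
  m <- random_matrix(6, 20, seed = 13)
  d <- band_distance(m)  # entries are squared distances
  res <- suppressMessages(pcoa(d, n_axes = 6))
  rec <- as.matrix(dist(res$coordinates))^2
  expect_lt(max(abs(rec - unclass(d))), 1e-9)
})

test_that("mantel statistic matches enumeration and respects the seed", {
  set.seed(17)
  mk <- function() {
    m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    m[lower.tri(m)] <- runif(6)
    structure(m + t(m), metric = "euclidean",
              class = c("band_dist", "matrix"))
  }
  d1 <- mk(); d2 <- mk()
  res <- mantel_test(d1, d2, 99, seed = 1)
  expect_equal(res$r, cor(d1[lower.tri(d1)], d2[lower.tri(d2)]),
               tolerance = 1e-12)
  expect_equal(res$r_squared, res$r^2)

  # affine invariance of the Pearson statistic
  aff <- structure(unclass(d1) * 2 + 3, metric = "euclidean",
                   class = c("band_dist", "matrix"))
  diag(aff) <- 0
  expect_equal(mantel_test(d1, aff, 99, seed = 1)$r, 1, tolerance = 1e-12)

  # reproducible p under a fixed seed; lower bound 1/(n+1)
  p1 <- mantel_test(d1, d2, 199, seed = 42)$p_value
  p2 <- mantel_test(d1, d2, 199, seed = 42)$p_value
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 200)
  # r symmetric in the arguments
  expect_equal(mantel_test(d2, d1, 99, seed = 1)$r, res$r)

  zero <- structure(matrix(0, 4, 4,
                           dimnames = list(letters[1:4], letters[1:4])),
                    metric = "euclidean", class = c("band_dist", "matrix"))
  expect_error(mantel_test(d1, zero, 99), "zero-variance")
})
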