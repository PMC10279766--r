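test_that("silhouette matches the independent oracle and the cluster package", {
  set.seed(31)
  pts <- cbind(runif(12, -3, 3), runif(12, -3, 3))
  m <- kmeans_fit(pts, 3, n_init = 30, seed = 2)
  s <- silhouette_mean(m)
  expect_equal(as.numeric(s), silhouette_oracle(pts, unname(m$cluster)))
  skip_if_not_installed("cluster")
  ref <- cluster::silhouette(unname(m$cluster), stats::dist(pts))
  expect_equal(as.numeric(s), mean(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("two tight, far-separated pairs give a near-perfect silhouette", {
  pts <- rbind(c(0, 0), c(0, 0.1), c(50, 50), c(50, 50.1))
  m <- kmeans_fit(pts, 2, n_init = 10, seed = 1)
  expect_gt(as.numeric(silhouette_mean(m)), 0.9)
})

test_that("equidistant points and singleton clusters score zero", {
  pts <- rbind(c(0, 0), c(2, 0), c(4, 0))
  cl <- c(1L, 1L, 2L)
  s <- silhouette_mean(pts, cl)
  w <- attr(s, "widths")
  expect_equal(w[2], 0)  # midpoint: a = b = 2
  expect_equal(w[3], 0)  # singleton convention
  expect_error(silhouette_mean(pts, rep(1L, 3)), "two clusters")
})

test_that("silhouette widths stay in [-1, 1] and are rigid-motion invariant", {
  set.seed(17)
  for (i in 1:5) {
    pts <- cbind(rnorm(15), rnorm(15))
    m <- kmeans_fit(pts, 3, n_init = 20, seed = i)
    w <- attr(silhouette_mean(m), "widths")
    expect_true(all(w >= -1 & w <= 1))
    # rotate by 30 degrees and translate: widths unchanged
    th <- pi / 6
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    pts2 <- pts %*% rot + 5
    w2 <- attr(silhouette_mean(pts2, unname(m$cluster)), "widths")
    expect_equal(w, w2)
  }
})

test_that("the WSS curve is monotone non-increasing with an elbow at planted k", {
  pts <- make_blobs(blob_centers4, n_per = 10, sd = 0.1, seed = 5)
  e <- elbow_wss(pts, k_grid = 1:8, n_init = 20, seed = 3)
  expect_true(all(diff(e$wss) <= 1e-9))
  expect_equal(attr(e, "elbow_k"), 4L)
  # random data: monotonicity still holds
  set.seed(23)
  r <- cbind(runif(20), runif(20))
  e2 <- elbow_wss(r, k_grid = 1:6, n_init = 15, seed = 2)
  expect_true(all(diff(e2$wss) <= 1e-9))
  # a grid ending at n distinct points ends at zero
  pts5 <- cbind(1:5, c(2, 4, 1, 7, 3))
  e3 <- elbow_wss(pts5, k_grid = c(1, 3, 5), n_init = 10, seed = 1)
  expect_equal(e3$wss[3], 0)
})

test_that("the gap statistic picks planted k = 4 and k = 1, reproducibly", {
  for (s in 1:5) {
    blobs <- make_blobs(blob_centers4, n_per = 10, sd = 0.1, seed = 100 + s)
    gp <- gap_statistic(blobs, k_grid = 1:8, B = 50, seed = s)
    expect_equal(attr(gp, "chosen_k"), 4L)
    one <- make_blobs(rbind(c(0, 0)), n_per = 25, sd = 0.5, seed = 200 + s)
    g1 <- gap_statistic(one, k_grid = 1:5, B = 50, seed = s)
    expect_equal(attr(g1, "chosen_k"), 1L)
  }
  blobs <- make_blobs(blob_centers4, n_per = 10, sd = 0.1, seed = 42)
  a <- gap_statistic(blobs, k_grid = 1:6, B = 20, seed = 9)
  b <- gap_statistic(blobs, k_grid = 1:6, B = 20, seed = 9)
  expect_identical(a$gap, b$gap)  # bit-for-bit under the same seed
  # gap choice is invariant under axis-preserving translation
  d <- gap_statistic(blobs + 100, k_grid = 1:6, B = 20, seed = 9)
  expect_identical(attr(a, "chosen_k"), attr(d, "chosen_k"))
})

test_that("gap statistic rejects degenerate input and tiny B", {
  same <- matrix(1, 6, 2)
  expect_error(gap_statistic(same, 1:3, B = 20, seed = 1), "degenerate")
  pts <- cbind(runif(8), runif(8))
  expect_error(gap_statistic(pts, 1:3, B = 5, seed = 1), "B must be")
})

test_that("the three selectors agree on well-separated blobs and vote by majority", {
  blobs <- make_blobs(blob_centers4, n_per = 10, sd = 0.1, seed = 8)
  ks <- select_k(blobs, k_grid = 1:8, n_init = 20, B = 50, seed = 11)
  expect_equal(ks$chosen$elbow, 4L)
  expect_equal(ks$chosen$silhouette, 4L)
  expect_equal(ks$chosen$gap, 4L)
  expect_equal(ks$chosen$consensus, 4L)
  expect_true(all(ks$table$silhouette >= -1 & ks$table$silhouette <= 1,
                  na.rm = TRUE))
  expect_true(all(diff(ks$table$wss) <= 1e-9))
})
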