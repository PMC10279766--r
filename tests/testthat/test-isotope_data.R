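test_that("delta notation follows the ratio equation exactly", {
  expect_equal(delta_from_ratios(0.0112372, 0.0112372), 0)
  expect_equal(delta_from_ratios(0.98 * 0.0112372, 0.0112372), -20)
  # direct evaluation of the formula as oracle
  expect_equal(delta_from_ratios(1.0034 * 0.0112372, 0.0112372), 3.4,
               tolerance = 1e-12)
  expect_error(delta_from_ratios(0, 0.011), "positive")
  expect_error(delta_from_ratios(0.011, -1), "positive")
})

test_that("delta is strictly increasing in the sample ratio, zero only at the standard", {
  set.seed(42)
  r_std <- 0.0112372
  r <- sort(runif(25, 0.5, 1.5)) * r_std
  d <- delta_from_ratios(r, r_std)
  expect_true(all(diff(d) > 0))
  expect_identical(d == 0, r == r_std)
})

test_that("group aggregation reproduces the published sediment summary", {
  m <- make_measurements(
    label = "sediment", compartment = "sediment",
    d13C = c(-21.08, -20.84), d15N = c(5.90, 6.19)
  )
  g <- aggregate_groups(m)
  expect_equal(g$n, 2L)
  expect_equal(round_half_up(g$mean_d13C), -20.96)
  expect_equal(round_half_up(g$sd_d13C), 0.17)
  expect_equal(round_half_up(g$mean_d15N), 6.05)
  expect_equal(round_half_up(g$sd_d15N), 0.21)
})

test_that("aggregation handles singletons, ties and degenerate spreads", {
  one <- aggregate_groups(make_measurements("x", -20, 10))
  expect_equal(one$mean_d13C, -20)
  expect_true(is.na(one$sd_d13C))
  same <- aggregate_groups(
    make_measurements(rep("y", 3), rep(-18, 3), rep(9, 3))
  )
  expect_equal(same$sd_d15N, 0)
  expect_equal(same$n, 3L)
})

test_that("aggregation means are invariant to input ordering", {
  set.seed(7)
  m <- make_measurements(rep(c("a", "b"), each = 5),
                         rnorm(10, -20), rnorm(10, 8))
  g1 <- aggregate_groups(m)
  g2 <- aggregate_groups(m[sample(nrow(m)), ])
  g2 <- g2[match(g1$label, g2$label), ]
  expect_equal(g1$mean_d13C, g2$mean_d13C)
  expect_equal(g1$sd_d15N, g2$sd_d15N)
})

test_that("validation flags empty input, bad compartments and implausible values", {
  expect_error(aggregate_groups(make_measurements("x", -20, 8)[0, ]),
               "no measurements")
  bad <- make_measurements("x", -20, 8, compartment = "plankton")
  expect_error(aggregate_groups(bad), "compartment")
  odd <- make_measurements("x", -70, 8)
  expect_warning(validate_measurements(odd), "plausibility")
  mixed <- make_measurements(c("x", "x"), c(-20, -21), c(8, 9),
                             compartment = c("fauna", "spom"))
  expect_warning(aggregate_groups(mixed), "mixes compartments")
})

test_that("pooling group means reproduces the published POM statistics", {
  g <- angola_reef_groups()
  spom <- pool_groups(g[g$compartment %in% c("spom", "spom_trap"), ])
  expect_equal(round_half_up(spom$mean_d15N), 4.23)
  expect_equal(round_half_up(spom$mean_d13C), -21.87)
  pom <- pool_groups(g[g$compartment != "fauna", ])
  expect_equal(round_half_up(pom$mean_d13C), -21.57)
  expect_equal(round_half_up(pom$mean_d15N), 4.83)
})

test_that("pooling a single group returns it with absent spread", {
  g <- data.frame(mean_d13C = -20.1, mean_d15N = 7.3, n = 3)
  p <- pool_groups(g)
  expect_equal(p$mean_d13C, -20.1)
  expect_true(is.na(p$sd_d15N))
  expect_error(pool_groups(g[0, ]), "empty")
})

test_that("aggregate-then-pool over singletons equals pooling raw values", {
  set.seed(11)
  d13 <- rnorm(6, -19, 2)
  d15 <- rnorm(6, 12, 3)
  m <- make_measurements(paste0("t", 1:6), d13, d15)
  p <- pool_groups(aggregate_groups(m))
  expect_equal(p$mean_d13C, mean(d13))
  expect_equal(p$sd_d13C, sd(d13))
  expect_equal(p$mean_d15N, mean(d15))
  expect_equal(p$sd_d15N, sd(d15))
})

test_that("replicate-weighted pooling is available but changes the result", {
  g <- data.frame(mean_d13C = c(-22, -21), mean_d15N = c(4, 2),
                  n = c(20, 10))
  un <- pool_groups(g)
  wt <- pool_groups(g, weighted = TRUE)
  expect_equal(un$mean_d15N, 3)
  expect_equal(wt$mean_d15N, (20 * 4 + 10 * 2) / 30)
})
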