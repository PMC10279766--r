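zero_noise_spec <- function(seed = 1, t_levels = 3.16, n_taxa = 1L) {
  web_spec(
    sources = data.frame(label = "SPOM", d13C = -22, d15N = 4.23,
                         sd_d13C = 0, sd_d15N = 0),
    guilds = data.frame(label = paste0("g", seq_along(t_levels)),
                        trophic_level = t_levels,
                        n_taxa = n_taxa,
                        offset_sd_d13C = 0, offset_sd_d15N = 0),
    replicate_sd = c(d13C = 0, d15N = 0),
    replicates_per_taxon = 3, replicates_per_source = 5, seed = seed
  )
}

test_that("an invalid specification is rejected with every offender listed", {
  err <- tryCatch(
    web_spec(
      sources = data.frame(label = "S", d13C = -22, d15N = 4,
                           sd_d13C = -1, sd_d15N = 0),
      guilds = data.frame(label = "g", trophic_level = 0.5, n_taxa = 0,
                          offset_sd_d13C = 0, offset_sd_d15N = 0),
      seed = 1
    ),
    error = conditionMessage
  )
  expect_match(err, "source standard deviations")
  expect_match(err, "trophic levels must be >= 1")
  expect_match(err, "n_taxa")
  expect_error(default_web_spec(seed = NULL), "seed is required")
})

test_that("simulation is fully reproducible from the seed", {
  a <- simulate_web(default_web_spec(seed = 42))
  b <- simulate_web(default_web_spec(seed = 42))
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$truth, b$truth)
  c <- simulate_web(default_web_spec(seed = 43))
  expect_false(identical(a$measurements$d15N, c$measurements$d15N))
})

test_that("zero-noise replicates sit exactly at the enrichment-model value", {
  sim <- simulate_web(zero_noise_spec())
  taxa <- sim$measurements[sim$measurements$compartment == "fauna", ]
  # 4.23 + (3.16 - 1) * 3.4 = 11.574, analytically forced
  expect_equal(unique(taxa$d15N), 4.23 + 2.16 * 3.4)
  expect_equal(unique(taxa$d13C), -22 + 2.16 * 1.0)
})

test_that("the zero-noise web is recovered exactly end to end", {
  sim <- simulate_web(zero_noise_spec(seed = 2,
                                      t_levels = c(2, 3.5, 5.7),
                                      n_taxa = c(3L, 4L, 2L)))
  rec <- recovery_report(sim, seed = 1, n_init = 20)
  expect_equal(max(abs(rec$taxa$tp_error)), 0)
  expect_equal(rec$ari, 1)
  # cluster centroids coincide with the true guild means
  truth_means <- unique(sim$truth[c("true_d13C", "true_d15N")])
  fit_means <- rec$model$centers
  expect_equal(
    truth_means[order(truth_means$true_d15N), ],
    data.frame(true_d13C = fit_means[order(fit_means[, 2]), 1],
               true_d15N = sort(fit_means[, 2])),
    ignore_attr = TRUE
  )
})

test_that("replicate noise propagates to TP spread as sd/TEF", {
  spec <- web_spec(
    sources = data.frame(label = "SPOM", d13C = -22, d15N = 4.23,
                         sd_d13C = 0, sd_d15N = 0),
    guilds = data.frame(label = "g", trophic_level = 3, n_taxa = 1L,
                        offset_sd_d13C = 0, offset_sd_d15N = 0),
    replicate_sd = c(d13C = 0.2, d15N = 0.68),  # 0.2 * TEF
    replicates_per_taxon = 1e4, replicates_per_source = 5, seed = 7
  )
  rec <- recovery_report(simulate_web(spec), seed = 1, n_init = 5)
  n <- 1e4
  # sd of the sd estimator ~ sigma / sqrt(2(n-1)); 3 Monte-Carlo SEs
  expect_equal(rec$taxa$tp_sd, 0.2,
               tolerance = 3 * 0.2 / sqrt(2 * (n - 1)) / 0.2)
  # unbiasedness: mean TP error within 3 standard errors of zero
  expect_lt(abs(rec$taxa$tp_error), 3 * 0.2 / sqrt(n))
})

test_that("TEF misspecification bias follows the closed form", {
  t_true <- c(2, 3.5, 5)
  sim <- simulate_web(zero_noise_spec(seed = 3, t_levels = t_true))
  rec <- recovery_report(sim, tef = tef_config(5.0), seed = 1, n_init = 20)
  ord <- match(rec$taxa$label, sim$truth$label)
  t_of <- sim$truth$trophic_level[ord]
  expect_equal(rec$taxa$tp_error, (t_of - 1) * (3.4 / 5.0 - 1),
               tolerance = 1e-12)
  # magnitude form: |bias| = (t - lambda) (1 - TEF_true / TEF_used)
  expect_equal(abs(rec$taxa$tp_error), (t_of - 1) * (1 - 3.4 / 5.0),
               tolerance = 1e-12)
})

test_that("guilds are recovered across seeds under realistic taxon scatter", {
  spec_for <- function(seed) web_spec(
    sources = data.frame(label = "SPOM", d13C = -21.9, d15N = 4.2,
                         sd_d13C = 0.45, sd_d15N = 1.6),
    guilds = data.frame(label = paste0("g", 1:4),
                        trophic_level = c(1, 3.5, 4.2, 5.7),
                        n_taxa = 10L,
                        offset_sd_d13C = 0.5, offset_sd_d15N = 0.5),
    seed = seed
  )
  n_seeds <- 200
  hits <- vapply(seq_len(n_seeds), function(s) {
    sim <- simulate_web(spec_for(s))
    groups <- aggregate_groups(sim$measurements)
    fauna <- groups[groups$compartment == "fauna", ]
    m <- kmeans_fit(fauna, 4, n_init = 25, seed = s)
    truth_g <- sim$truth$guild_index[match(fauna$label, sim$truth$label)]
    mclust::adjustedRandIndex(truth_g, unname(m$cluster)) >= 0.9
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("web specifications round-trip through plain-text configs", {
  # packaged YAML scenario equals the in-code default
  path <- system.file("extdata", "default_web.yaml", package = "isoweb")
  from_yaml <- read_web_spec(path, seed = 21)
  expect_identical(simulate_web(from_yaml)$measurements,
                   simulate_web(default_web_spec(seed = 21))$measurements)
  expect_equal(read_web_spec(path)$seed, 1L)  # seed from the file
  # JSON carries the same structure
  jf <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(sources = from_yaml$sources, guilds = from_yaml$guilds,
         tef = unclass(from_yaml$tef),
         replicate_sd = as.list(from_yaml$replicate_sd),
         replicates_per_taxon = 3, replicates_per_source = 20,
         seed = 21),
    jf, auto_unbox = TRUE, digits = NA
  )
  from_json <- read_web_spec(jf)
  expect_identical(simulate_web(from_json)$truth,
                   simulate_web(from_yaml)$truth)
})

test_that("a label mismatch between truth and outputs is caught", {
  sim <- simulate_web(zero_noise_spec())
  sim$truth$label[1] <- "renamed"
  expect_error(recovery_report(sim, seed = 1), "label mismatch")
})
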