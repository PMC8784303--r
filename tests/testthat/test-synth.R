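test_that("planted population correlations follow the closed form", {
  cfg <- test_cfg(w_cat = 1, w_item = 1, sigma_noise = 1)
  rho <- expected_population_correlation(cfg)
  expect_equal(rho$rho_item, 2 / 3)
  expect_equal(rho$rho_cat, 1 / 3)
  expect_equal(rho$rho_between, 0)

  rho0 <- expected_population_correlation(test_cfg(w_item = 0))
  expect_equal(rho0$rho_item, rho0$rho_cat)

  rho_lim <- expected_population_correlation(
    test_cfg(sigma_noise = 1e-9)
  )
  expect_equal(rho_lim$rho_item, 1, tolerance = 1e-12)

  expect_error(
    expected_population_correlation(test_cfg(w_cat = 0, w_item = 0,
                                             sigma_noise = 0)),
    "zero"
  )
})

test_that("generation is deterministic given the seed and matches the design", {
  cfg <- synth_config(n_subjects = 1, n_categories = 5, n_channels = 3,
                      time_step = 0.2, seed = 123)
  d1 <- generate_subject_tfr(cfg, 1)
  d2 <- generate_subject_tfr(cfg, 1)
  expect_identical(d1$power, d2$power)
  d3 <- generate_subject_tfr(cfg, 2)
  expect_false(identical(d1$power, d3$power))

  expect_equal(dim(d1$power), c(20, 3, 31, 14))
  expect_true(all(d1$power > 0))
  expect_true(validate_tfr(d1)$ok)
  # the 1/f background shows in the mean spectrum: low freqs > high freqs
  mean_spec <- apply(log10(d1$power), 3, mean)
  expect_gt(mean_spec[1], mean_spec[31])
})

test_that("null configuration carries no within-item similarity", {
  cfg <- synth_config(n_subjects = 1, n_categories = 20, n_channels = 3,
                      w_cat = 0, w_item = 0, time_step = 0.1, seed = 55)
  ds <- preprocess_tfr(generate_subject_tfr(cfg, 1))
  wi <- compute_subject_similarity(ds, "within_item")
  gt <- attr(generate_subject_tfr(cfg, 1), "ground_truth")
  tmid <- gt$signal_time_idx[2]
  vals <- as.vector(wi$z[, , tmid, tmid])
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 4 * se + 1e-8)
})

with_seed_rnorm <- function(n, seed) {
  set.seed(seed)
  rnorm(n)
}

test_that("memory-score generator hits the target correlation", {
  delta <- rnorm(50, mean = 1)
  b1 <- generate_memory_scores(delta, r_target = 1, seed = 2)
  expect_equal(cor(delta, b1$item_memory), 1, tolerance = 1e-12)

  b0 <- generate_memory_scores(rnorm(1000), r_target = 0, seed = 3)
  expect_lt(abs(cor(rnorm(1000), b0$item_memory)), 0.1)

  rs <- vapply(1:60, function(s) {
    d <- with_seed_rnorm(200, s)
    cor(d, generate_memory_scores(d, r_target = 0.5,
                                  seed = 7000 + s)$item_memory)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.05)

  # deterministic given seed
  expect_identical(generate_memory_scores(delta, 0.3, seed = 9),
                   generate_memory_scores(delta, 0.3, seed = 9))
})

test_that("two-group generation shares grids and separates planted effects", {
  cfg_a <- synth_config(n_subjects = 2, n_categories = 6, n_channels = 4,
                        time_step = 0.2, group = "adults", seed = 77)
  cfg_b <- synth_config(n_subjects = 2, n_categories = 6, n_channels = 6,
                        time_step = 0.2, group = "children", seed = 77)
  gd <- generate_group_dataset(cfg_a, cfg_b)
  expect_length(gd$a, 2)
  expect_length(gd$b, 2)
  expect_equal(dim(gd$a[[1]]$power)[2], 4)
  expect_equal(dim(gd$b[[1]]$power)[2], 6)  # montages may differ
  expect_equal(gd$a[[1]]$freqs, gd$b[[1]]$freqs)
  # identical base seeds must still give independent groups
  expect_false(identical(gd$a[[1]]$power[, 1:4, , ],
                         gd$b[[1]]$power[, 1:4, , ]))

  cfg_bad <- synth_config(n_subjects = 2, time_step = 0.1, seed = 1)
  expect_error(generate_group_dataset(cfg_a, cfg_bad), "share")
})
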