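test_that("pair enumeration matches the design at each level", {
  tr40 <- make_toy_ds(n_categories = 40)$trials
  wi <- enumerate_pairs(tr40, "within_item")
  expect_equal(nrow(wi), 40)
  expect_true(all(tr40$presentation[wi$a] == 1 & tr40$presentation[wi$b] == 2))
  expect_true(all(tr40$exemplar[wi$a] == 1 & tr40$exemplar[wi$b] == 1))

  wc <- enumerate_pairs(tr40, "within_category")
  expect_true(all(tr40$exemplar[wc$a] == 1 & tr40$exemplar[wc$b] == 2))
  expect_true(all(tr40$presentation[wc$a] == 1 & tr40$presentation[wc$b] == 1))

  tr4 <- make_toy_ds(n_categories = 4)$trials
  bc <- enumerate_pairs(tr4, "between_category")
  expect_equal(nrow(bc), 4 * 3)  # ordered pairs
  expect_equal(sort(bc$unit)[1:3], c("1>2", "1>3", "1>4"))
  expect_true(!any(bc$a == bc$b))
})

test_that("categories missing a required trial are skipped and reported", {
  tr <- make_toy_ds(n_categories = 3)$trials
  tr <- tr[!(tr$category == 2 & tr$exemplar == 1 & tr$presentation == 2), ]
  wi <- enumerate_pairs(tr, "within_item")
  expect_equal(nrow(wi), 2)
  expect_equal(attr(wi, "skipped"), 2)
  # the same category is still usable for within-category similarity
  expect_equal(nrow(enumerate_pairs(tr, "within_category")), 3)
  expect_error(enumerate_pairs(tr[0, ], "within_item"), "no usable")
})

test_that("time-time correlation matches hand-computed and oracle values", {
  a <- matrix(c(1, 2, 3), 3, 1)
  expect_equal(as.vector(time_time_correlation(a, a)), 1)
  b <- matrix(c(3, 2, 1), 3, 1)
  expect_equal(as.vector(time_time_correlation(a, b)), -1)
  expect_equal(
    as.vector(time_time_correlation(matrix(c(1, 2, 4)), matrix(c(2, 1, 3)))),
    0.6547, tolerance = 1e-4
  )

  set.seed(21)
  for (i in 1:10) {
    pa <- matrix(rnorm(35), 5, 7)
    pb <- matrix(rnorm(35), 5, 7)
    r <- time_time_correlation(pa, pb)
    expect_equal(r, oracle_ttcor(pa, pb), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("correlation is invariant to positive affine column rescaling", {
  set.seed(5)
  pa <- matrix(rnorm(40), 8, 5)
  pb <- matrix(rnorm(40), 8, 5)
  r0 <- time_time_correlation(pa, pb)
  scl <- runif(5, 0.5, 3)
  off <- rnorm(5)
  pa2 <- sweep(sweep(pa, 2, scl, "*"), 2, off, "+")
  expect_equal(time_time_correlation(pa2, pb), r0, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero-variance frequency profiles yield r = 0 with a warning", {
  pa <- matrix(rnorm(20), 5, 4)
  pa[, 2] <- 3  # constant column
  pb <- matrix(rnorm(20), 5, 4)
  expect_warning(r <- time_time_correlation(pa, pb), "zero-variance")
  expect_equal(unname(r[2, ]), rep(0, 4))
  expect_equal(attr(r, "n_zero_var"), 4L)
})

test_that("Fisher z is atanh with clipping at |r| = 1", {
  expect_equal(as.vector(fisher_z(0)), 0)
  expect_equal(as.vector(fisher_z(0.6547)), 0.7831, tolerance = 1e-3)
  set.seed(9)
  r <- runif(1000, -1, 1)
  expect_equal(fisher_z(-r), -fisher_z(r), ignore_attr = TRUE)
  z1 <- fisher_z(1)
  expect_true(is.finite(z1))
  expect_equal(attr(z1, "n_clipped"), 1L)
  expect_error(fisher_z(1.001), "> 1")
})

test_that("subject similarity tensor has the design shape; identical trials clip", {
  c1 <- small_cohort()[[1]]
  wi <- compute_subject_similarity(c1$prep, "within_item")
  expect_equal(dim(wi$z), c(8, 4, 27, 27))
  expect_equal(wi$units, as.character(1:8))

  # presentation 2 duplicated from presentation 1 -> diagonal at clip ceiling
  ds <- make_toy_ds(n_categories = 3, n_channels = 2,
                    freqs = c(2, 4, 6, 8), times = c(0, 0.1))
  set.seed(14)
  ds$power <- array(10^rnorm(length(ds$power)), dim(ds$power))
  p1 <- ds$trials$presentation == 1
  p2 <- ds$trials$presentation == 2
  ds$power[p2, , , ] <- ds$power[p1, , , ]
  st <- compute_subject_similarity(log_power(ds), "within_item",
                                   require_preprocessed = FALSE)
  diag_z <- st$z[, , 1, 1]
  expect_true(all(diag_z > 14))  # atanh(1 - 1e-12) ~ 14.2; > any real z
  expect_gt(st$n_clipped, 0)
})

test_that("unit averaging and grand averaging match brute-force means", {
  c1 <- small_cohort()[[1]]
  wi <- compute_subject_similarity(c1$prep, "within_item")
  avg <- average_subject(wi)
  brute <- apply(wi$z, c(2, 3, 4), mean)
  expect_equal(avg$z_mean, brute, tolerance = 1e-12)
  expect_equal(avg$n_units, 8)

  single <- wi
  single$z <- wi$z[1, , , , drop = FALSE]
  expect_equal(average_subject(single)$z_mean, wi$z[1, , , ],
               tolerance = 1e-14)

  subs <- lapply(small_cohort(), function(s) {
    average_subject(compute_subject_similarity(s$prep, "within_item"))
  })
  ga <- grand_average(subs)
  expect_equal(dim(ga$stack), c(2, 4, 27, 27))
  brute_mean <- (apply(subs[[1]]$z_mean, c(2, 3), mean) +
                   apply(subs[[2]]$z_mean, c(2, 3), mean)) / 2
  expect_equal(ga$mean_matrix, brute_mean, tolerance = 1e-12)

  # mixed channel counts within a group are rejected
  bad <- subs
  bad[[2]]$z_mean <- bad[[2]]$z_mean[1:3, , ]
  expect_error(grand_average(bad), "channel count")
})

test_that("mean between-category similarity matrix is symmetric", {
  ds <- make_toy_ds(n_categories = 4, n_channels = 2,
                    freqs = c(2, 3, 5, 8, 13), times = c(0, 0.1, 0.2))
  set.seed(31)
  ds$power <- array(10^rnorm(length(ds$power)), dim(ds$power))
  st <- compute_subject_similarity(log_power(ds), "between_category",
                                   require_preprocessed = FALSE)
  expect_equal(dim(st$z)[1], 12)
  m <- apply(st$z, c(3, 4), mean)
  expect_equal(m, t(m), tolerance = 1e-12)
})

test_that("diagonal extraction equals the elementwise loop", {
  set.seed(2)
  m <- matrix(rnorm(49), 7, 7)
  d <- extract_diagonal(m)
  expect_equal(d, vapply(1:7, function(i) m[i, i], numeric(1)))
  expect_error(extract_diagonal(matrix(1, 2, 3)), "square")
})
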