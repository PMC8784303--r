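mk_spec <- function(delta, group = "adults") {
  tibble::tibble(
    subject_id = sprintf("%s%02d", toupper(substr(group, 1, 1)), seq_along(delta)),
    group = group, specificity = delta
  )
}

test_that("specificity-memory correlation matches hand-computed values", {
  sp <- mk_spec(c(1, 2, 3))
  beh_lin <- tibble::tibble(subject_id = sp$subject_id, group = sp$group,
                            item_memory = 2 * sp$specificity + 1)
  out <- correlate_specificity_memory(sp, beh_lin)
  expect_equal(out$r[out$group == "adults"], 1, tolerance = 1e-12)

  beh <- tibble::tibble(subject_id = sp$subject_id, group = sp$group,
                        item_memory = c(6, 4, 5))
  out2 <- correlate_specificity_memory(sp, beh)
  expect_equal(out2$r[out2$group == "adults"], -0.5, tolerance = 1e-6)
  # pooled row equals the single group here
  expect_equal(out2$r[out2$group == "pooled"], -0.5, tolerance = 1e-6)
})

test_that("per-group and pooled correlations are reported with exact t-based p", {
  set.seed(19)
  sp <- dplyr::bind_rows(mk_spec(rnorm(10), "adults"),
                         mk_spec(rnorm(10), "children"))
  beh <- tibble::tibble(subject_id = sp$subject_id, group = sp$group,
                        item_memory = rnorm(20))
  out <- correlate_specificity_memory(sp, beh)
  expect_setequal(out$group, c("adults", "children", "pooled"))
  for (g in c("adults", "children")) {
    sub <- dplyr::filter(sp, group == g)
    ct <- cor.test(sub$specificity,
                   beh$item_memory[match(sub$subject_id, beh$subject_id)])
    expect_equal(out$r[out$group == g], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(out$p_value[out$group == g], ct$p.value, tolerance = 1e-12)
  }
})

test_that("correlation p matches a permutation null within MC error", {
  set.seed(29)
  x <- rnorm(12)
  y <- 0.4 * x + rnorm(12)
  sp <- mk_spec(x)
  beh <- tibble::tibble(subject_id = sp$subject_id, group = sp$group,
                        item_memory = y)
  p_param <- correlate_specificity_memory(sp, beh)
  p_param <- p_param$p_value[p_param$group == "pooled"]
  r_obs <- cor(x, y)
  n_perm <- 10000
  r_null <- replicate(n_perm, cor(x, sample(y)))
  p_perm <- mean(abs(r_null) >= abs(r_obs))
  expect_lt(abs(p_param - p_perm), 4 / sqrt(n_perm) + 0.02)
})

test_that("invariance under affine transforms; errors on mismatched ids", {
  set.seed(37)
  sp <- mk_spec(rnorm(8))
  beh <- tibble::tibble(subject_id = sp$subject_id, group = sp$group,
                        item_memory = rnorm(8))
  base <- correlate_specificity_memory(sp, beh)
  sp2 <- sp; sp2$specificity <- 3 * sp$specificity + 7
  expect_equal(correlate_specificity_memory(sp2, beh)$r, base$r,
               tolerance = 1e-12)
  sp3 <- sp; sp3$specificity <- -sp$specificity
  expect_equal(correlate_specificity_memory(sp3, beh)$r, -base$r,
               tolerance = 1e-12)

  expect_error(
    correlate_specificity_memory(sp, beh[-1, ]),
    paste0("no memory score.*", sp$subject_id[1])
  )
})
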