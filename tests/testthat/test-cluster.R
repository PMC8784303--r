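# small helper: a tmap_stack built directly from an array
fake_tmaps <- function(t_array, df = 9, group = "sim") {
  n_ch <- dim(t_array)[2]
  theta <- 2 * pi * (seq_len(n_ch) - 1) / n_ch
  structure(
    list(
      t = t_array, df = rep(df, dim(t_array)[1]),
      subject_ids = sprintf("S%02d", seq_len(dim(t_array)[1])),
      group = group, contrast = "within_item - within_category",
      times = seq_len(dim(t_array)[3]),
      channels = tibble::tibble(label = sprintf("c%d", seq_len(n_ch)),
                                x = cos(theta), y = sin(theta))
    ),
    class = "tmap_stack"
  )
}

chain_adjacency <- function(n) {
  build_adjacency(
    tibble::tibble(label = sprintf("c%d", 1:n), x = seq_len(n), y = 0),
    mode = "distance_threshold", param = 1.1
  )
}

test_that("first-level paired t matches hand values and the t.test oracle", {
  # build two similarity tensors whose difference is constant across samples
  mk_tensor <- function(z_by_unit, level) {
    n_u <- length(z_by_unit)
    structure(
      list(z = array(rep(z_by_unit, 2 * 2 * 2), c(n_u, 2, 2, 2)),
           level = level, subject_id = "S01", group = "g",
           units = as.character(seq_len(n_u)), times = c(0, 1),
           channels = tibble::tibble(label = c("a", "b"))),
      class = "similarity_tensor"
    )
  }
  # d = [0, 1, -1] -> t = 0 ; d = [1, 2, 3] -> t = 3.4641
  wi <- mk_tensor(c(1, 2, 0), "within_item")
  wc <- mk_tensor(c(1, 1, 1), "within_category")
  tm <- first_level_tmaps(list(wi), list(wc))
  expect_equal(unique(as.vector(tm$t)), 0)

  wi2 <- mk_tensor(c(2, 3, 4), "within_item")
  tm2 <- first_level_tmaps(list(wi2), list(wc))
  expect_equal(unique(as.vector(tm2$t)), 3.4641, tolerance = 1e-4)
  expect_equal(tm2$df, 2)

  # random tensors vs flattened t.test oracle
  set.seed(17)
  zz1 <- array(rnorm(6 * 2 * 3 * 3), c(6, 2, 3, 3))
  zz2 <- array(rnorm(6 * 2 * 3 * 3), c(6, 2, 3, 3))
  a <- mk_tensor(rep(0, 6), "within_item"); a$z <- zz1
  a$times <- 1:3; a$z <- array(zz1, c(6, 2, 3, 3))
  b <- mk_tensor(rep(0, 6), "within_category"); b$z <- zz2; b$times <- 1:3
  tm3 <- first_level_tmaps(list(a), list(b))
  for (idx in list(c(1, 1, 1), c(2, 3, 2), c(1, 2, 3))) {
    d <- zz1[, idx[1], idx[2], idx[3]] - zz2[, idx[1], idx[2], idx[3]]
    expect_equal(tm3$t[1, idx[1], idx[2], idx[3]],
                 unname(t.test(d)$statistic), tolerance = 1e-10)
  }
  expect_error(
    first_level_tmaps(list(mk_tensor(1:2, "within_item")),
                      list(mk_tensor(1:2, "within_category"))),
    "need >= 3"
  )
})

test_that("adjacency: distance rule, explicit list and degenerate cases", {
  chans <- tibble::tibble(label = c("A", "B", "C"), x = c(0, 1, 2), y = 0)
  adj <- build_adjacency(chans, param = 1.1)
  expect_true(adj$matrix["A", "B"] && adj$matrix["B", "C"])
  expect_false(adj$matrix["A", "C"])
  expect_true(isSymmetric(adj$matrix))
  expect_false(any(diag(adj$matrix)))

  empty <- build_adjacency(chans, param = 0)
  expect_equal(sum(empty$matrix), 0)

  expl <- build_adjacency(chans, mode = "explicit_list",
                          pairs = rbind(c("A", "C")))
  expect_true(expl$matrix["C", "A"])
  expect_equal(sum(expl$matrix), 2)
  expect_error(build_adjacency(chans, mode = "explicit_list",
                               pairs = rbind(c("A", "Z"))), "unknown channel")
  expect_error(build_adjacency(tibble::tibble(label = "A"), param = 1),
               "positions")
})

test_that("cluster labeling matches the BFS oracle on random maps", {
  set.seed(23)
  adj <- chain_adjacency(4)
  for (rep in 1:8) {
    stat <- array(rnorm(4 * 6 * 6), c(4, 6, 6))
    thr <- 1.0
    found <- find_clusters(stat, thr, adj)
    for (sgn in c("positive", "negative")) {
      mask <- if (sgn == "positive") stat > thr else stat < -thr
      oracle <- oracle_bfs_clusters(mask, adj$matrix)
      labels <- if (sgn == "positive") found$labels_pos else found$labels_neg
      got <- split(which(labels > 0), labels[labels > 0])
      expect_equal(length(got), length(oracle))
      expect_setequal(
        vapply(got, function(i) paste(sort(i), collapse = ","), character(1)),
        vapply(oracle, function(i) paste(i, collapse = ","), character(1))
      )
      tab <- found$clusters[found$clusters$sign == sgn, ]
      expect_equal(sort(tab$mass),
                   sort(vapply(oracle, function(i) sum(stat[i]), numeric(1))),
                   tolerance = 1e-12)
    }
  }
})

test_that("cluster structure: crosses join, non-neighbours stay apart", {
  adj <- chain_adjacency(2)
  stat <- array(0, c(1, 3, 3))
  stat[1, 2, ] <- 3
  stat[1, , 2] <- 3  # cross pattern in one channel
  out <- find_clusters(stat[1, , , drop = FALSE], 2, chain_adjacency(1))
  expect_equal(nrow(out$clusters), 1)
  expect_equal(out$clusters$mass, 15)
  expect_equal(out$clusters$n_samples, 5L)

  # same (t1, t2) sample in two non-adjacent channels -> two clusters
  far <- build_adjacency(
    tibble::tibble(label = c("a", "b"), x = c(0, 10), y = 0), param = 1
  )
  stat2 <- array(0, c(2, 3, 3))
  stat2[, 2, 2] <- 5
  out2 <- find_clusters(stat2, 2, far)
  expect_equal(nrow(out2$clusters), 2)
  # with adjacency they merge
  near <- build_adjacency(
    tibble::tibble(label = c("a", "b"), x = c(0, 1), y = 0), param = 1.5
  )
  expect_equal(nrow(find_clusters(stat2, 2, near)$clusters), 1)

  # all samples below threshold -> no clusters
  expect_equal(nrow(find_clusters(array(0.1, c(2, 3, 3)), 2, near)$clusters), 0)

  # diagonal-only neighbours do not connect (no diagonal moves)
  stat3 <- array(0, c(1, 3, 3))
  stat3[1, 1, 1] <- 3; stat3[1, 2, 2] <- 3
  expect_equal(nrow(find_clusters(stat3, 2, chain_adjacency(1))$clusters), 2)
})

test_that("permutation floor: unbeatable observed mass gives p = 1/n_perm", {
  set.seed(41)
  n_sub <- 16
  t_arr <- array(rnorm(n_sub * 1 * 5 * 5, mean = 0, sd = 0.1), c(n_sub, 1, 5, 5))
  t_arr[, 1, 2:4, 2:4] <- t_arr[, 1, 2:4, 2:4] + 5  # huge common effect
  tm <- fake_tmaps(t_arr)
  res <- cluster_permutation_test(tm, chain_adjacency(1), n_perm = 500,
                                  seed = 13)
  top <- res$clusters[res$clusters$sign == "positive", ][1, ]
  expect_equal(top$p_value, 0.002)
  expect_equal(min(res$clusters$p_value), 1 / res$n_perm)
  expect_true(top$significant)
})

test_that("Monte-Carlo p agrees with exhaustive sign-flip enumeration (n = 8)", {
  set.seed(57)
  n_sub <- 8
  dm <- c(1, 5, 5)
  t_arr <- array(rnorm(n_sub * prod(dm), mean = 0.45), c(n_sub, dm))
  tm <- fake_tmaps(t_arr)
  adj <- chain_adjacency(1)
  n_perm <- 256
  res <- cluster_permutation_test(tm, adj, n_perm = n_perm, seed = 3)

  x <- matrix(t_arr, nrow = n_sub)
  exact <- oracle_exact_perm(x, res$threshold, adj$matrix, dm)
  pos <- res$clusters[res$clusters$sign == "positive", ]
  if (nrow(pos)) {
    p_exact <- mean(exact$max_pos >= pos$mass[1])
    expect_lt(abs(pos$p_value[1] - p_exact), 2 / sqrt(n_perm))
  }
  neg <- res$clusters[res$clusters$sign == "negative", ]
  if (nrow(neg)) {
    p_exact_n <- mean(exact$min_neg <= neg$mass[1])
    expect_lt(abs(neg$p_value[1] - p_exact_n), 2 / sqrt(n_perm))
  }
})

test_that("permutation p-values are invariant to subject relabeling and flip signs globally", {
  set.seed(71)
  t_arr <- array(rnorm(6 * 2 * 4 * 4, mean = 0.8), c(6, 2, 4, 4))
  tm <- fake_tmaps(t_arr)
  adj <- chain_adjacency(2)
  r1 <- cluster_permutation_test(tm, adj, n_perm = 200, seed = 5)
  tm_shuf <- fake_tmaps(t_arr[c(4, 1, 6, 2, 3, 5), , , , drop = FALSE])
  r2 <- cluster_permutation_test(tm_shuf, adj, n_perm = 200, seed = 5)
  expect_equal(r1$clusters$mass, r2$clusters$mass, tolerance = 1e-12)
  # observed clusters are exactly invariant; Monte-Carlo p-values agree to
  # within sampling error of the 200-draw reference distribution
  expect_lt(max(abs(r1$clusters$p_value - r2$clusters$p_value)),
            4 * 0.5 / sqrt(200))

  # global sign flip swaps the positive and negative cluster lists
  r3 <- cluster_permutation_test(fake_tmaps(-t_arr), adj, n_perm = 200, seed = 5)
  pos1 <- r1$clusters[r1$clusters$sign == "positive", ]
  neg3 <- r3$clusters[r3$clusters$sign == "negative", ]
  expect_equal(sort(-neg3$mass), sort(pos1$mass), tolerance = 1e-12)
})

test_that("cluster-mask extraction and the specificity identity", {
  set.seed(83)
  n_sub <- 6
  t_arr <- array(rnorm(n_sub * 2 * 4 * 4, mean = 1.2), c(n_sub, 2, 4, 4))
  tm <- fake_tmaps(t_arr)
  adj <- chain_adjacency(2)
  res <- cluster_permutation_test(tm, adj, n_perm = 200, seed = 11)
  stopifnot(any(res$clusters$significant))

  mk_group <- function(stack, level) {
    structure(
      list(stack = stack, mean_matrix = apply(stack, c(3, 4), mean),
           level = level, group = "sim",
           subject_ids = sprintf("S%02d", seq_len(dim(stack)[1])),
           times = 1:4, channels = tm$channels),
      class = "group_similarity"
    )
  }
  wi_stack <- array(rnorm(n_sub * 2 * 4 * 4, mean = 1), c(n_sub, 2, 4, 4))
  wc_stack <- array(rnorm(n_sub * 2 * 4 * 4, mean = 0.3), c(n_sub, 2, 4, 4))
  sp <- extract_cluster_means(mk_group(wi_stack, "within_item"),
                              mk_group(wc_stack, "within_category"), res)
  expect_s3_class(sp, "specificity_summary")
  expect_equal(sp$specificity, sp$within_item - sp$within_category)
  mask <- attr(sp, "mask")
  expect_equal(sp$within_item[3], mean(wi_stack[3, , , ][mask]))

  # identical stacks -> all-zero specificity
  sp0 <- extract_cluster_means(mk_group(wi_stack, "within_item"),
                               mk_group(wi_stack, "within_category"), res)
  expect_equal(unique(sp0$specificity), 0)

  # no significant cluster -> explicit no-mask outcome
  null_res <- res
  null_res$clusters$p_value[] <- 0.5
  null_res$clusters$significant <- FALSE
  expect_s3_class(
    extract_cluster_means(mk_group(wi_stack, "within_item"),
                          mk_group(wc_stack, "within_category"), null_res),
    "no_mask"
  )
})

test_that("group comparison reproduces the pooled-variance t", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_value, 0)
  expect_equal(same$p_value, 1)

  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t_value, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  # oracle via t.test
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r$t_value, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-10)

  const <- compare_groups(c(2, 2), c(2, 2))
  expect_equal(const$t_value, 0)
  expect_equal(const$p_value, 1)
})
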