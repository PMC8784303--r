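#' First-level t-maps: within-item vs within-category similarity
#'
#' For each subject, contrasts within-item against within-category Fisher-z
#' similarity with a two-sided paired t-test across categories at every
#' (channel, t1, t2) sample. Categories usable at both levels are
#' intersected; positive t means higher within-item than within-category
#' similarity, i.e. item-specific neural patterns. The resulting t-maps act
#' as pointwise effect-size measures fed to the second level.
#'
#' @param wi,wc Lists (one element per subject) of `similarity_tensor`
#'   objects at levels `within_item` and `within_category` respectively,
#'   in matching subject order.
#' @return A `tmap_stack`: list with `t` (subject x channel x time x time
#'   array), `df` (per-subject degrees of freedom, categories - 1),
#'   `subject_ids`, `group`, `contrast`, `times`, `channels`.
#' @export
first_level_tmaps <- function(wi, wc) {
  stopifnot(length(wi) == length(wc), length(wi) >= 1)
  n_sub <- length(wi)
  d <- dim(wi[[1]]$z)[-1]
  t_stack <- array(NA_real_, dim = c(n_sub, d))
  df <- integer(n_sub)
  for (i in seq_len(n_sub)) {
    a <- wi[[i]]
    b <- wc[[i]]
    stopifnot(a$level == "within_item", b$level == "within_category")
    common <- intersect(a$units, b$units)
    n <- length(common)
    if (n < 3) {
      stop("first_level_tmaps: subject ", a$subject_id,
           " has only ", n, " categories usable at both levels (need >= 3)")
    }
    diff <- a$z[match(common, a$units), , , , drop = FALSE] -
      b$z[match(common, b$units), , , , drop = FALSE]
    m <- colMeans(diff)
    ss <- colSums(diff^2)
    s2 <- (ss - n * m^2) / (n - 1)
    s2[s2 < 0] <- 0
    tt <- m / sqrt(s2 / n)
    tt[s2 == 0 & m == 0] <- 0
    t_stack[i, , , ] <- tt
    df[i] <- n - 1L
  }
  structure(
    list(
      t = t_stack, df = df,
      subject_ids = vapply(wi, function(s) s$subject_id, character(1)),
      group = wi[[1]]$group,
      contrast = "within_item - within_category",
      times = wi[[1]]$times, channels = wi[[1]]$channels
    ),
    class = "tmap_stack"
  )
}

#' @export
print.tmap_stack <- function(x, ...) {
  d <- dim(x$t)
  cat(sprintf(
    "<tmap_stack> %s (%s): %d subjects x %d channels x %d x %d, df %s\n",
    x$contrast, x$group, d[1], d[2], d[3], d[4],
    paste(range(x$df), collapse = "-")
  ))
  invisible(x)
}

#' Build a channel adjacency graph
#'
#' Defines which channels count as spatial neighbours when clustering over
#' the channel x time x time volume. Either a distance rule (channels are
#' neighbours iff their layout distance is at most `param`) or an explicit
#' pair list (the analogue of a neighbour template file).
#'
#' @param channels Channel table with `label` and, for distance mode, `x`,
#'   `y` (optionally `z`) coordinates.
#' @param mode `"distance_threshold"` or `"explicit_list"`.
#' @param param Distance threshold (same units as the coordinates).
#' @param pairs For explicit mode: two-column matrix/data frame of channel
#'   labels (or 1-based indices).
#' @return An `adjacency` object: symmetric irreflexive logical matrix
#'   `matrix` over channels plus provenance fields.
#' @export
build_adjacency <- function(channels,
                            mode = c("distance_threshold", "explicit_list"),
                            param = NULL, pairs = NULL) {
  mode <- match.arg(mode)
  labels <- channels$label
  n <- length(labels)
  adj <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  if (mode == "distance_threshold") {
    coords_cols <- intersect(c("x", "y", "z"), names(channels))
    if (length(coords_cols) < 1) {
      stop("build_adjacency: channel positions (x, y[, z]) required for distance mode")
    }
    coords <- as.matrix(channels[, coords_cols])
    if (any(!is.finite(coords))) stop("build_adjacency: non-finite channel positions")
    if (is.null(param)) stop("build_adjacency: distance threshold 'param' required")
    d <- as.matrix(stats::dist(coords))
    adj <- d <= param
    diag(adj) <- FALSE
    dimnames(adj) <- list(labels, labels)
  } else {
    if (is.null(pairs)) stop("build_adjacency: 'pairs' required for explicit mode")
    pm <- as.matrix(pairs)
    if (ncol(pm) != 2) stop("build_adjacency: pairs must have two columns")
    idx <- if (is.numeric(pm)) {
      matrix(as.integer(pm), ncol = 2)
    } else {
      matrix(match(pm, labels), ncol = 2)
    }
    if (any(is.na(idx)) || any(idx < 1) || any(idx > n)) {
      stop("build_adjacency: unknown channel in pairs")
    }
    adj[idx] <- TRUE
    adj[idx[, 2:1, drop = FALSE]] <- TRUE
    diag(adj) <- FALSE
  }
  structure(
    list(matrix = adj, labels = labels, source = mode, threshold = param),
    class = "adjacency"
  )
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf(
    "<adjacency> %d channels, %d edges (%s%s)\n",
    length(x$labels), sum(x$matrix) / 2, x$source,
    if (!is.null(x$threshold)) sprintf(", threshold %g", x$threshold) else ""
  ))
  invisible(x)
}

# Connected components of a supra-threshold mask over channel x t1 x t2.
# Connectivity: +/-1 step in t1 OR t2 within a channel (no diagonal moves),
# or the same (t1, t2) in spatially neighbouring channels.
# Returns integer membership (length sum(mask)) and the masked linear indices.
label_components <- function(mask, adj_matrix) {
  dm <- dim(mask)
  n_ch <- dm[1]; n_t1 <- dm[2]; n_t2 <- dm[3]
  pos <- which(mask)
  if (length(pos) == 0L) {
    return(list(pos = integer(0), membership = integer(0)))
  }
  in_mask <- as.vector(mask)
  i0 <- pos - 1L
  ch0 <- i0 %% n_ch
  t10 <- (i0 %/% n_ch) %% n_t1
  edges_from <- integer(0)
  edges_to <- integer(0)
  # t1 neighbours
  cand <- pos[t10 < n_t1 - 1L]
  hit <- cand[in_mask[cand + n_ch]]
  edges_from <- c(edges_from, hit)
  edges_to <- c(edges_to, hit + n_ch)
  # t2 neighbours
  off2 <- n_ch * n_t1
  t20 <- i0 %/% off2
  cand <- pos[t20 < n_t2 - 1L]
  hit <- cand[in_mask[cand + off2]]
  edges_from <- c(edges_from, hit)
  edges_to <- c(edges_to, hit + off2)
  # channel neighbours at identical (t1, t2)
  nb <- which(adj_matrix & upper.tri(adj_matrix), arr.ind = TRUE)
  if (nrow(nb)) {
    for (k in seq_len(nrow(nb))) {
      a <- nb[k, 1]; b <- nb[k, 2]
      cand <- pos[ch0 == a - 1L]
      hit <- cand[in_mask[cand + (b - a)]]
      edges_from <- c(edges_from, hit)
      edges_to <- c(edges_to, hit + (b - a))
    }
  }
  vid <- integer(length(in_mask))
  vid[pos] <- seq_along(pos)
  g <- igraph::make_empty_graph(n = length(pos), directed = FALSE)
  if (length(edges_from)) {
    g <- igraph::add_edges(g, rbind(vid[edges_from], vid[edges_to]))
  }
  list(pos = pos, membership = igraph::components(g)$membership)
}

#' Find supra-threshold clusters in a channel x time x time statistic map
#'
#' Thresholds the map at `+threshold` / `-threshold` and partitions the
#' supra-threshold samples into connected components. Two samples are
#' connected if they differ by one step along t1 or t2 within the same
#' channel (no diagonal moves in the time-time plane), or sit at the same
#' (t1, t2) in neighbouring channels. Positive and negative clusters are
#' labeled separately; each cluster's mass is the sum of its t-values.
#'
#' @param stat_map 3-D numeric array, channel x time x time.
#' @param threshold Positive scalar: the two-sided critical value that a
#'   sample must exceed in magnitude.
#' @param adjacency An [build_adjacency()] object (or logical matrix).
#' @return A list with `clusters` (tibble: `id`, `sign`, `mass`,
#'   `n_samples`, `n_channels`), `labels_pos`, `labels_neg` (integer arrays,
#'   0 = unclustered). Positive ids are ordered by decreasing mass, negative
#'   by increasing (most negative first). Empty result allowed.
#' @export
find_clusters <- function(stat_map, threshold, adjacency) {
  stopifnot(length(dim(stat_map)) == 3, threshold > 0)
  adj <- if (inherits(adjacency, "adjacency")) adjacency$matrix else adjacency
  one_sign <- function(mask, decreasing) {
    lab <- label_components(mask, adj)
    labels <- array(0L, dim = dim(stat_map))
    if (length(lab$pos) == 0L) {
      return(list(
        labels = labels,
        tab = tibble::tibble(id = integer(), mass = numeric(),
                             n_samples = integer(), n_channels = integer())
      ))
    }
    mass <- as.vector(rowsum(stat_map[lab$pos], lab$membership))
    ord <- order(mass, decreasing = decreasing)
    new_id <- integer(length(mass))
    new_id[ord] <- seq_along(ord)
    labels[lab$pos] <- new_id[lab$membership]
    ch_idx <- (lab$pos - 1L) %% dim(stat_map)[1] + 1L
    tab <- tibble::tibble(
      id = seq_along(ord),
      mass = mass[ord],
      n_samples = as.integer(tabulate(lab$membership)[ord]),
      n_channels = vapply(
        ord, function(m) length(unique(ch_idx[lab$membership == m])), integer(1)
      )
    )
    list(labels = labels, tab = tab)
  }
  pos <- one_sign(stat_map > threshold, decreasing = TRUE)
  neg <- one_sign(stat_map < -threshold, decreasing = FALSE)
  clusters <- dplyr::bind_rows(
    dplyr::mutate(pos$tab, sign = "positive"),
    dplyr::mutate(neg$tab, sign = "negative")
  )
  clusters <- clusters[, c("id", "sign", "mass", "n_samples", "n_channels")]
  list(clusters = clusters, labels_pos = pos$labels, labels_neg = neg$labels)
}

# one-sample t over the subject dimension of a (subject x samples) matrix,
# with precomputed column sums of squares (invariant under sign flips)
one_sample_t <- function(x_signed_colmeans, ss, n) {
  m <- x_signed_colmeans
  s2 <- (ss - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  tt <- m / sqrt(s2 / n)
  tt[s2 == 0] <- 0
  tt
}

#' Second-level cluster-based sign-flip permutation test
#'
#' Tests the first-level t-maps against zero at the group level while
#' controlling the family-wise error over the channel x time x time volume.
#' The observed statistic map is the one-sample t of the subject t-maps
#' against 0; clusters are formed by thresholding at the two-sided critical
#' t for `sample_alpha` with `n_subjects - 1` degrees of freedom and grouped
#' per [find_clusters()]. The Monte Carlo reference distribution flips the
#' sign of whole subject maps at random; each draw records the largest
#' positive and most negative cluster mass. The observed labeling counts as
#' one draw, so with `n_perm = 500` the smallest attainable p is
#' 1/500 = 0.002. Clusters are significant at `p < cluster_alpha` per tail
#' (default 0.025, i.e. 97.5th percentile of the reference distribution).
#'
#' @param tmaps A `tmap_stack` from [first_level_tmaps()].
#' @param adjacency Channel adjacency from [build_adjacency()].
#' @param n_perm Number of permutation draws (including the observed one).
#' @param cluster_alpha Per-tail significance level for clusters.
#' @param sample_alpha Two-sided alpha defining the cluster-forming
#'   threshold.
#' @param seed Optional integer seed for the sign draws.
#' @return A `cluster_result`: list with `clusters` (tibble incl. `p_value`
#'   and `significant`), `labels_pos`, `labels_neg`, `observed_t` (channel x
#'   time x time), `ref_pos`, `ref_neg` (permutation max-mass
#'   distributions), `threshold`, `df`, `n_perm`, `cluster_alpha`,
#'   `sample_alpha`, `seed`, `group`, `times`, `channels`.
#' @export
cluster_permutation_test <- function(tmaps, adjacency, n_perm = 500,
                                     cluster_alpha = 0.025,
                                     sample_alpha = 0.05, seed = NULL) {
  stopifnot(inherits(tmaps, "tmap_stack"))
  dm <- dim(tmaps$t)
  n_sub <- dm[1]
  if (n_sub < 2) stop("cluster_permutation_test: need at least 2 subjects")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm < 1 / cluster_alpha) {
    warning("n_perm = ", n_perm, " cannot reject at cluster_alpha = ",
            cluster_alpha, " (minimum attainable p is 1/n_perm)")
  }
  x <- matrix(tmaps$t, nrow = n_sub)  # subjects x samples
  ss <- colSums(x^2)
  df <- n_sub - 1L
  threshold <- stats::qt(1 - sample_alpha / 2, df = df)
  t_obs <- array(one_sample_t(colMeans(x), ss, n_sub), dim = dm[-1])
  found <- find_clusters(t_obs, threshold, adjacency)

  if (!is.null(seed)) set.seed(seed)
  ref_pos <- numeric(n_perm)
  ref_neg <- numeric(n_perm)
  adj <- if (inherits(adjacency, "adjacency")) adjacency$matrix else adjacency
  max_masses <- function(t_map) {
    out <- c(0, 0)
    labp <- label_components(array(t_map, dm[-1]) > threshold, adj)
    if (length(labp$pos)) {
      out[1] <- max(rowsum(t_map[labp$pos], labp$membership))
    }
    labn <- label_components(array(t_map, dm[-1]) < -threshold, adj)
    if (length(labn$pos)) {
      out[2] <- min(rowsum(t_map[labn$pos], labn$membership))
    }
    out
  }
  for (k in seq_len(n_perm)) {
    # draw 1 is the observed labeling (reusing t_obs exactly, so its own
    # mass always ties and the smallest attainable p is 1/n_perm)
    t_perm <- if (k == 1L) {
      as.vector(t_obs)
    } else {
      flips <- sample(c(-1, 1), n_sub, replace = TRUE)
      one_sample_t(as.vector(crossprod(flips, x)) / n_sub, ss, n_sub)
    }
    mm <- max_masses(t_perm)
    ref_pos[k] <- mm[1]
    ref_neg[k] <- mm[2]
  }
  clusters <- found$clusters
  clusters$p_value <- NA_real_
  if (nrow(clusters)) {
    ip <- clusters$sign == "positive"
    clusters$p_value[ip] <- vapply(
      clusters$mass[ip], function(m) mean(ref_pos >= m), numeric(1)
    )
    clusters$p_value[!ip] <- vapply(
      clusters$mass[!ip], function(m) mean(ref_neg <= m), numeric(1)
    )
  }
  clusters$significant <- clusters$p_value < cluster_alpha
  structure(
    list(
      clusters = clusters,
      labels_pos = found$labels_pos, labels_neg = found$labels_neg,
      observed_t = t_obs, ref_pos = ref_pos, ref_neg = ref_neg,
      threshold = threshold, df = df, n_perm = n_perm,
      cluster_alpha = cluster_alpha, sample_alpha = sample_alpha,
      seed = seed, group = tmaps$group,
      times = tmaps$times, channels = tmaps$channels
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  np <- sum(x$clusters$sign == "positive")
  nn <- sum(x$clusters$sign == "negative")
  cat(sprintf(
    "<cluster_result> group %s: %d positive / %d negative clusters (%d significant at p < %g per tail)\n  %d permutations, cluster-forming |t| > %.3f (df = %d)\n",
    x$group, np, nn, sum(x$clusters$significant), x$cluster_alpha,
    x$n_perm, x$threshold, x$df
  ))
  invisible(x)
}

#' Extract per-subject similarity means within significant clusters
#'
#' Builds the union mask of all significant clusters (both signs) from a
#' second-level result and averages each subject's within-item and
#' within-category Fisher-z similarity inside that channel x time x time
#' mask. The per-subject difference is the item-specificity score used for
#' group comparison and brain-behavior analysis.
#'
#' @param group_wi,group_wc `group_similarity` stacks for the within-item
#'   and within-category levels (same subjects, same order).
#' @param result A `cluster_result`.
#' @param alpha Per-tail cluster significance level for the mask (defaults
#'   to the result's `cluster_alpha`).
#' @return A `specificity_summary` tibble: `subject_id`, `group`,
#'   `within_item`, `within_category`, `specificity` (their difference),
#'   with attributes `mask` (logical array), `n_mask_samples`,
#'   `mask_clusters` and `group_test` (one-sample t of specificity vs 0). If
#'   no cluster is significant, an object of class `no_mask` is returned and
#'   downstream steps should skip with a message.
#' @export
extract_cluster_means <- function(group_wi, group_wc, result, alpha = NULL) {
  stopifnot(inherits(group_wi, "group_similarity"),
            inherits(group_wc, "group_similarity"),
            inherits(result, "cluster_result"))
  if (is.null(alpha)) alpha <- result$cluster_alpha
  cl <- result$clusters
  sig <- cl[!is.na(cl$p_value) & cl$p_value < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(structure(
      list(message = "no significant cluster: no mask to extract from"),
      class = "no_mask"
    ))
  }
  mask <- array(FALSE, dim = dim(result$labels_pos))
  for (i in seq_len(nrow(sig))) {
    if (sig$sign[i] == "positive") {
      mask <- mask | (result$labels_pos == sig$id[i])
    } else {
      mask <- mask | (result$labels_neg == sig$id[i])
    }
  }
  n_sub <- dim(group_wi$stack)[1]
  stopifnot(dim(group_wc$stack)[1] == n_sub)
  wi_mean <- vapply(seq_len(n_sub), function(i) {
    mean(group_wi$stack[i, , , ][mask])
  }, numeric(1))
  wc_mean <- vapply(seq_len(n_sub), function(i) {
    mean(group_wc$stack[i, , , ][mask])
  }, numeric(1))
  out <- tibble::tibble(
    subject_id = group_wi$subject_ids,
    group = group_wi$group,
    within_item = wi_mean,
    within_category = wc_mean,
    specificity = wi_mean - wc_mean
  )
  gt <- stats::t.test(out$specificity)
  structure(
    out,
    mask = mask,
    n_mask_samples = sum(mask),
    mask_clusters = sig[, c("id", "sign", "mass", "p_value")],
    group_test = list(t = unname(gt$statistic), p = gt$p.value,
                      df = unname(gt$parameter)),
    class = c("specificity_summary", class(out))
  )
}

#' Compare item specificity between two groups
#'
#' Standard two-sided independent-samples Student t-test (pooled variance)
#' on per-subject item-specificity scores, e.g. children vs adults.
#'
#' @param spec_a,spec_b Numeric vectors of specificity scores, or
#'   `specificity_summary` objects (their `specificity` column is used).
#' @return A one-row tibble: `t_value`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`.
#' @export
compare_groups <- function(spec_a, spec_b) {
  if (inherits(spec_a, "specificity_summary")) spec_a <- spec_a$specificity
  if (inherits(spec_b, "specificity_summary")) spec_b <- spec_b$specificity
  a <- as.numeric(spec_a)
  b <- as.numeric(spec_b)
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) stop("compare_groups: each group needs n >= 2")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  diff <- mean(a) - mean(b)
  tt <- if (se == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else {
    diff / se
  }
  tibble::tibble(
    t_value = tt, df = df,
    p_value = if (is.infinite(tt)) 0 else 2 * stats::pt(-abs(tt), df),
    mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb
  )
}
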