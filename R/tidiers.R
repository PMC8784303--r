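#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cluster result into its cluster table
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return Tibble with one row per cluster: `id`, `sign`, `mass`,
#'   `n_samples`, `n_channels`, `p_value`, `significant`.
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::as_tibble(x$clusters)
}

#' @rdname tidy.cluster_result
#' @return `glance()`: a one-row tibble summarising the test (cluster
#'   counts, permutations, threshold, smallest p).
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    group = x$group,
    n_positive = sum(x$clusters$sign == "positive"),
    n_negative = sum(x$clusters$sign == "negative"),
    n_significant = sum(x$clusters$significant),
    min_p = if (nrow(x$clusters)) min(x$clusters$p_value) else NA_real_,
    n_perm = x$n_perm,
    threshold = x$threshold,
    df = x$df,
    cluster_alpha = x$cluster_alpha
  )
}

#' Tidy a specificity summary
#'
#' @param x A `specificity_summary`.
#' @param ... Unused.
#' @return `tidy()`: the per-subject tibble (`subject_id`, `group`,
#'   `within_item`, `within_category`, `specificity`); `glance()`: one row
#'   with the group-level one-sample test of specificity against zero and
#'   the mask size.
#' @export
tidy.specificity_summary <- function(x, ...) {
  tibble::as_tibble(unclass_summary(x))
}

#' @rdname tidy.specificity_summary
#' @export
glance.specificity_summary <- function(x, ...) {
  gt <- attr(x, "group_test")
  tibble::tibble(
    group = unique(x$group),
    n = nrow(x),
    mean_specificity = mean(x$specificity),
    t_vs_zero = gt$t,
    p_vs_zero = gt$p,
    n_mask_samples = attr(x, "n_mask_samples")
  )
}

unclass_summary <- function(x) {
  class(x) <- setdiff(class(x), "specificity_summary")
  attr(x, "mask") <- NULL
  attr(x, "group_test") <- NULL
  attr(x, "mask_clusters") <- NULL
  attr(x, "n_mask_samples") <- NULL
  x
}

#' Tidy a group similarity average into long form
#'
#' @param x A `group_similarity`.
#' @param ... Unused.
#' @return `tidy()`: long tibble of the grand-mean time-time matrix with
#'   columns `t1`, `t2` (s) and `z`; `glance()`: one-row dimensional
#'   summary including the mean diagonal similarity.
#' @export
tidy.group_similarity <- function(x, ...) {
  tibble::tibble(
    t1 = rep(x$times, times = length(x$times)),
    t2 = rep(x$times, each = length(x$times)),
    z = as.vector(x$mean_matrix)
  )
}

#' @rdname tidy.group_similarity
#' @export
glance.group_similarity <- function(x, ...) {
  d <- dim(x$stack)
  tibble::tibble(
    level = x$level, group = x$group,
    n_subjects = d[1], n_channels = d[2], n_times = d[3],
    mean_diagonal_z = mean(diag(x$mean_matrix))
  )
}
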