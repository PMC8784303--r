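#' Correlate item specificity with memory performance
#'
#' Pearson correlation between per-subject neural item specificity and a
#' scalar memory score, computed separately per group and pooled across
#' groups. Two-sided p-values come from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#' The pooled correlation uses raw scores (no group-mean centering); a
#' centered variant is available via `center_groups = TRUE`, with a warning
#' that between-group mean differences are then removed.
#'
#' @param spec A `specificity_summary` (or tibble with `subject_id`, `group`,
#'   `specificity`), typically rows from both groups bound together.
#' @param behavior Tibble with `subject_id`, `group`, `item_memory`.
#' @param center_groups If `TRUE`, group-mean-center both variables before
#'   the pooled correlation.
#' @return A tibble with one row per group plus one `"pooled"` row:
#'   `group`, `r`, `p_value`, `n`. Groups with fewer than 3 matched
#'   subjects are skipped with a message.
#' @export
correlate_specificity_memory <- function(spec, behavior,
                                         center_groups = FALSE) {
  spec <- tibble::as_tibble(spec)[, c("subject_id", "group", "specificity")]
  behavior <- tibble::as_tibble(behavior)
  stopifnot(all(c("subject_id", "group", "item_memory") %in% names(behavior)))
  unmatched <- setdiff(spec$subject_id, behavior$subject_id)
  if (length(unmatched)) {
    stop("no memory score for subject(s): ", paste(unmatched, collapse = ", "))
  }
  merged <- dplyr::inner_join(
    spec, behavior[, c("subject_id", "item_memory")], by = "subject_id"
  )
  cor_row <- function(x, y, label) {
    n <- length(x)
    if (n < 3) {
      message("group '", label, "' skipped: fewer than 3 subjects")
      return(NULL)
    }
    r <- stats::cor(x, y)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    tibble::tibble(group = label, r = r,
                   p_value = 2 * stats::pt(-abs(tt), n - 2), n = n)
  }
  per_group <- merged |>
    dplyr::group_by(.data$group) |>
    dplyr::group_map(~ cor_row(.x$specificity, .x$item_memory, .y$group)) |>
    dplyr::bind_rows()
  pooled_dat <- merged
  if (center_groups) {
    warning("pooled correlation on group-mean-centered scores: ",
            "between-group differences are removed")
    pooled_dat <- pooled_dat |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(
        specificity = .data$specificity - mean(.data$specificity),
        item_memory = .data$item_memory - mean(.data$item_memory)
      ) |>
      dplyr::ungroup()
  }
  pooled <- cor_row(pooled_dat$specificity, pooled_dat$item_memory, "pooled")
  dplyr::bind_rows(per_group, pooled)
}
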