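#' Construct a single-subject TFR dataset
#'
#' The central container: a 4-D power tensor (trial x channel x frequency x
#' time) with its axes, a channel table and a trial table. Power may be on
#' the linear or log10 scale; the scale is carried as metadata because the
#' preprocessing steps (log transform, background removal) are only valid in
#' a specific order.
#'
#' @param power 4-D numeric array, dimensions trial x channel x frequency x
#'   time.
#' @param freq_grid A [build_frequency_grid()] object (or numeric vector of
#'   center frequencies in Hz).
#' @param time_grid A [build_time_grid()] object (or numeric vector of sample
#'   times in s).
#' @param channels Tibble/data frame with a `label` column (unique channel
#'   names) and optional `x`, `y` (and `z`) layout coordinates.
#' @param trials Tibble/data frame with integer columns `category`,
#'   `exemplar`, `presentation` and optionally `orig_index`; one row per
#'   trial, (category, exemplar, presentation) unique.
#' @param subject_id Subject identifier string.
#' @param group Group label, e.g. `"children"`, `"adults"`, `"other"`.
#' @param scale `"linear"` or `"log10"`.
#' @return A `tfr_dataset` object.
#' @export
tfr_dataset <- function(power, freq_grid, time_grid, channels, trials,
                        subject_id = "S01", group = "other",
                        scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  if (length(dim(power)) != 4) {
    stop("power must be a 4-D array (trial x channel x frequency x time)")
  }
  channels <- tibble::as_tibble(channels)
  trials <- tibble::as_tibble(trials)
  if (!"label" %in% names(channels)) stop("channels must have a 'label' column")
  req <- c("category", "exemplar", "presentation")
  if (!all(req %in% names(trials))) {
    stop("trials must have columns: ", paste(req, collapse = ", "))
  }
  if (!"orig_index" %in% names(trials)) trials$orig_index <- seq_len(nrow(trials))
  freqs <- as_axis(freq_grid)
  times <- as_axis(time_grid)
  d <- dim(power)
  if (d[1] != nrow(trials)) stop("trial dimension (", d[1], ") != trial table rows (", nrow(trials), ")")
  if (d[2] != nrow(channels)) stop("channel dimension (", d[2], ") != channel table rows (", nrow(channels), ")")
  if (d[3] != length(freqs)) stop("frequency dimension (", d[3], ") != frequency axis length (", length(freqs), ")")
  if (d[4] != length(times)) stop("time dimension (", d[4], ") != time axis length (", length(times), ")")
  structure(
    list(
      subject_id = subject_id, group = group,
      power = power, scale = scale,
      freq_grid = if (inherits(freq_grid, "freq_grid")) freq_grid else NULL,
      time_grid = if (inherits(time_grid, "time_grid")) time_grid else NULL,
      freqs = freqs, times = times,
      channels = channels, trials = trials
    ),
    class = "tfr_dataset"
  )
}

#' @export
print.tfr_dataset <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<tfr_dataset> subject %s (%s), %s power\n  %d trials x %d channels x %d freqs x %d times\n",
    x$subject_id, x$group, x$scale, d[1], d[2], d[3], d[4]
  ))
  invisible(x)
}

#' Validate a TFR dataset
#'
#' Report-only check: dimension mismatches, NaN/non-finite cells, non-positive
#' linear power, duplicate (category, exemplar, presentation) triples, and —
#' per similarity level — categories that are missing a trial the level needs
#' (within-item needs exemplar 1 in both presentations; within-category needs
#' both exemplars at presentation 1; between-category needs exemplar 1,
#' presentation 1).
#'
#' @param ds A `tfr_dataset`.
#' @return A list with `ok` (logical) and `issues`, a tibble with columns
#'   `type`, `detail`.
#' @export
validate_tfr <- function(ds) {
  issues <- list()
  add <- function(type, detail) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(type = type, detail = detail)
  }
  d <- dim(ds$power)
  if (d[1] != nrow(ds$trials)) add("dim_mismatch", "trial axis != trial table")
  if (d[2] != nrow(ds$channels)) add("dim_mismatch", "channel axis != channel table")
  if (d[3] != length(ds$freqs)) add("dim_mismatch", "frequency axis length")
  if (d[4] != length(ds$times)) add("dim_mismatch", "time axis length")

  bad <- which(!is.finite(ds$power))
  if (length(bad)) {
    idx <- arrayInd(bad[seq_len(min(20, length(bad)))], d)
    for (i in seq_len(nrow(idx))) {
      add("nonfinite_power", sprintf(
        "non-finite power at [trial %d, channel %d, freq %d, time %d]",
        idx[i, 1], idx[i, 2], idx[i, 3], idx[i, 4]
      ))
    }
    if (length(bad) > 20) add("nonfinite_power", sprintf("... and %d more", length(bad) - 20L))
  }
  if (ds$scale == "linear") {
    nz <- which(is.finite(ds$power) & ds$power <= 0)
    if (length(nz)) {
      idx <- arrayInd(nz[1], d)
      add("nonpositive_power", sprintf(
        "%d non-positive linear power cells (first at [%d, %d, %d, %d])",
        length(nz), idx[1], idx[2], idx[3], idx[4]
      ))
    }
  }
  tr <- ds$trials
  key <- paste(tr$category, tr$exemplar, tr$presentation, sep = "/")
  if (anyDuplicated(key)) {
    add("duplicate_trials", paste(
      "duplicate (category/exemplar/presentation):",
      paste(unique(key[duplicated(key)]), collapse = ", ")
    ))
  }
  for (lev in c("within_item", "within_category", "between_category")) {
    miss <- unusable_categories(tr, lev)
    if (length(miss)) {
      add("unusable_category", sprintf(
        "categories unusable for %s: %s", lev, paste(miss, collapse = ", ")
      ))
    }
  }
  issues <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(type = character(), detail = character())
  list(ok = nrow(issues) == 0L, issues = issues)
}

# categories lacking a trial required by the given similarity level
unusable_categories <- function(trials, level) {
  has <- function(c, e, p) {
    any(trials$category == c & trials$exemplar == e & trials$presentation == p)
  }
  cats <- sort(unique(trials$category))
  need <- switch(level,
    within_item = list(c(1, 1), c(1, 2)),
    within_category = list(c(1, 1), c(2, 1)),
    between_category = list(c(1, 1)),
    stop("unknown level: ", level)
  )
  cats[!vapply(cats, function(cc) {
    all(vapply(need, function(ep) has(cc, ep[1], ep[2]), logical(1)))
  }, logical(1))]
}

#' Select trials by design cell
#'
#' Subsets a dataset by any combination of `category`, `exemplar` and
#' `presentation`, preserving trial order. An empty selector returns all
#' trials; a selector matching nothing returns an empty dataset with a
#' warning (not an error), mirroring how trial counts vary across subjects
#' after artifact rejection.
#'
#' @param ds A `tfr_dataset`.
#' @param category,exemplar,presentation Optional vectors of values to keep.
#' @return A `tfr_dataset` with the selected trials.
#' @export
select_trials <- function(ds, category = NULL, exemplar = NULL,
                          presentation = NULL) {
  keep <- rep(TRUE, nrow(ds$trials))
  if (!is.null(category)) keep <- keep & ds$trials$category %in% category
  if (!is.null(exemplar)) keep <- keep & ds$trials$exemplar %in% exemplar
  if (!is.null(presentation)) keep <- keep & ds$trials$presentation %in% presentation
  if (!any(keep)) warning("selector matched zero trials")
  out <- ds
  out$power <- ds$power[keep, , , , drop = FALSE]
  out$trials <- ds$trials[keep, , drop = FALSE]
  out
}

#' Save / load a TFR dataset
#'
#' Lossless round trip of the full container (tensor, axes, channel and trial
#' tables, metadata) via R's native serialization.
#'
#' @param ds A `tfr_dataset`.
#' @param path File path (conventionally `.rds`).
#' @return `save_tfr` returns `path` invisibly; `load_tfr` returns the
#'   `tfr_dataset`.
#' @export
save_tfr <- function(ds, path) {
  stopifnot(inherits(ds, "tfr_dataset"))
  saveRDS(ds, path)
  invisible(path)
}

#' @rdname save_tfr
#' @export
load_tfr <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "tfr_dataset")) {
    stop("format error: file does not contain a tfr_dataset")
  }
  for (fld in c("power", "freqs", "times", "channels", "trials", "scale")) {
    if (is.null(obj[[fld]])) stop("format error: missing field '", fld, "'")
  }
  obj
}
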