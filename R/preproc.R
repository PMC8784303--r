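#' Log-transform spectral power
#'
#' Elementwise log10 of a linear-scale power tensor. Required before
#' background-spectrum removal: the 1/f background is additive in log-power.
#'
#' @param ds A linear-scale `tfr_dataset` with strictly positive power.
#' @return The dataset with log10 power and `scale = "log10"`.
#' @export
log_power <- function(ds) {
  stopifnot(inherits(ds, "tfr_dataset"))
  if (ds$scale != "linear") stop("log_power: dataset is already on the log scale")
  bad <- which(ds$power <= 0 | !is.finite(ds$power))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(ds$power))
    stop(sprintf(
      "log_power: %d non-positive/non-finite cells (first at [trial %d, channel %d, freq %d, time %d])",
      length(bad), idx[1], idx[2], idx[3], idx[4]
    ))
  }
  ds$power <- log10(ds$power)
  ds$scale <- "log10"
  ds
}

#' Estimate the 1/f background spectrum
#'
#' EEG power falls off with frequency roughly as a power law; without
#' correction this shared spectral shape inflates every between-pattern
#' correlation. Following the background-spectrum step of the better
#' oscillation detection (BOSC) framework, the background is estimated per
#' channel from log10 power:
#'
#' * `mean_spectrum` (default): the mean log-power over all trials and all
#'   time points, at each frequency.
#' * `loglog_fit`: an ordinary least-squares line fit of that mean spectrum
#'   on log10(frequency); the background is the fitted line, and the
#'   per-channel intercept/slope are returned.
#'
#' @param ds A log10-scale `tfr_dataset`.
#' @param mode `"mean_spectrum"` or `"loglog_fit"`.
#' @return A `background_spectrum` object: matrix `background` (channel x
#'   frequency, log10-power units), `mode`, and for `loglog_fit` a tibble
#'   `fit_params` with per-channel `intercept` and `slope`.
#' @export
estimate_background <- function(ds, mode = c("mean_spectrum", "loglog_fit")) {
  stopifnot(inherits(ds, "tfr_dataset"))
  mode <- match.arg(mode)
  if (ds$scale != "log10") stop("estimate_background: log-transform the data first")
  # mean over trials (1) and time (4) -> channel x frequency
  mean_spec <- apply(ds$power, c(2, 3), mean)
  fit_params <- NULL
  if (mode == "loglog_fit") {
    if (length(ds$freqs) < 2) stop("loglog_fit needs at least 2 frequencies")
    lf <- log10(ds$freqs)
    X <- cbind(1, lf)
    # one OLS per channel, solved jointly: coef is 2 x n_channels
    coef <- solve(crossprod(X), crossprod(X, t(mean_spec)))
    bg <- t(X %*% coef)
    fit_params <- tibble::tibble(
      channel = ds$channels$label,
      intercept = coef[1, ], slope = coef[2, ]
    )
  } else {
    bg <- mean_spec
  }
  dimnames(bg) <- list(ds$channels$label, NULL)
  structure(
    list(background = bg, mode = mode, fit_params = fit_params,
         freqs = ds$freqs),
    class = "background_spectrum"
  )
}

#' @export
print.background_spectrum <- function(x, ...) {
  cat(sprintf(
    "<background_spectrum> mode %s, %d channels x %d frequencies\n",
    x$mode, nrow(x$background), ncol(x$background)
  ))
  invisible(x)
}

#' Remove the background spectrum from log power
#'
#' Subtracts the per-channel background log-power curve from every trial and
#' time point, leaving residual log-power fluctuations around the 1/f trend.
#' Residuals may be negative; this is the quantity whose frequency profiles
#' are correlated downstream.
#'
#' @param ds A log10-scale `tfr_dataset`.
#' @param bg A `background_spectrum` from [estimate_background()] matching
#'   the dataset's channels and frequencies.
#' @return The dataset with the background subtracted.
#' @export
remove_background <- function(ds, bg) {
  stopifnot(inherits(ds, "tfr_dataset"), inherits(bg, "background_spectrum"))
  if (ds$scale != "log10") stop("remove_background: log-transform the data first")
  d <- dim(ds$power)
  if (nrow(bg$background) != d[2] || ncol(bg$background) != d[3]) {
    stop(sprintf(
      "background shape (%d x %d) does not match data (channels %d, freqs %d)",
      nrow(bg$background), ncol(bg$background), d[2], d[3]
    ))
  }
  # broadcast channel x freq over trials and time
  expand <- aperm(
    array(bg$background, dim = c(d[2], d[3], d[1], d[4])),
    c(3, 1, 2, 4)
  )
  ds$power <- ds$power - expand
  attr(ds, "background_removed") <- bg$mode
  ds
}

#' Log-transform and remove the background in one call
#'
#' Convenience wrapper: `log_power()`, `estimate_background()`,
#' `remove_background()`.
#'
#' @inheritParams estimate_background
#' @param ds A linear-scale `tfr_dataset`.
#' @return The preprocessed dataset.
#' @export
preprocess_tfr <- function(ds, mode = c("mean_spectrum", "loglog_fit")) {
  mode <- match.arg(mode)
  ds <- log_power(ds)
  remove_background(ds, estimate_background(ds, mode))
}
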