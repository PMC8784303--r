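# run expr with a local RNG state so generators are deterministic
# without clobbering the caller's random stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for the synthetic TFR generator
#'
#' Describes a simulated encoding study. Defaults mirror the reference
#' design: 40 object categories x 2 exemplars x 2 presentations per subject,
#' 10 subjects per group, the 31-bin two-band frequency grid (2-20 Hz step
#' 2, 25-125 Hz step 5), the 326-point time axis (-0.6 to 2 s at 8 ms) and
#' a 1/f-shaped log-power background. Representational structure is planted
#' additively in log10-power inside a signal window: a category-shared
#' spectral pattern (weight `w_cat`), an item-specific pattern (`w_item`)
#' and white trial noise (`sigma_noise`), each an independent standard
#' normal field over (channel, frequency). The implied population
#' correlations between trial patterns at signal samples are
#' `rho_item = (w_cat^2 + w_item^2) / (w_cat^2 + w_item^2 + sigma^2)` and
#' `rho_cat = w_cat^2 / (w_cat^2 + w_item^2 + sigma^2)`; between categories
#' the correlation is 0. Defaults `w_cat = w_item = sigma_noise = 1` give
#' `rho_item = 2/3`, `rho_cat = 1/3`.
#'
#' @param n_subjects Subjects in the group.
#' @param n_categories Number of object categories C.
#' @param freq_low,freq_high Band specs for [build_frequency_grid()].
#' @param time_start,time_stop,time_step Time axis for [build_time_grid()]
#'   in seconds.
#' @param n_channels Number of channels (60 mimics an adult EEG montage, 64
#'   a child montage).
#' @param group Group label.
#' @param background `c(intercept, slope)` of log10 power vs log10
#'   frequency: the 1/f background. The default slope -2 is a plain 1/f^2
#'   power spectrum.
#' @param w_cat,w_item Category-shared and item-specific signal weights in
#'   log10-power units.
#' @param sigma_noise Trial noise standard deviation (log10-power units).
#' @param signal_window `c(start, stop)` in seconds; the patterns are
#'   constant across this block of time points (so the true effect is a
#'   rectangular cluster).
#' @param signal_channels Integer indices of channels carrying signal;
#'   `NULL` = all channels.
#' @param seed Base RNG seed; subject-level seeds are derived from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 10, n_categories = 40,
                         freq_low = c(2, 20, 2), freq_high = c(25, 125, 5),
                         time_start = -0.6, time_stop = 2, time_step = 0.008,
                         n_channels = 60, group = "adults",
                         background = c(intercept = 2, slope = -2),
                         w_cat = 1, w_item = 1, sigma_noise = 1,
                         signal_window = c(0.3, 1.0),
                         signal_channels = NULL, seed = 1) {
  stopifnot(w_cat >= 0, w_item >= 0, sigma_noise >= 0,
            n_subjects >= 1, n_categories >= 1, n_channels >= 1)
  tg <- build_time_grid(time_start, time_stop, time_step)
  if (signal_window[1] > signal_window[2] ||
      signal_window[1] > max(tg$times_s) || signal_window[2] < min(tg$times_s)) {
    stop("signal_window must be an increasing interval inside the time grid")
  }
  if (!is.null(signal_channels) &&
      (any(signal_channels < 1) || any(signal_channels > n_channels))) {
    stop("signal_channels out of range")
  }
  structure(
    list(
      n_subjects = n_subjects, n_categories = n_categories,
      freq_low = freq_low, freq_high = freq_high,
      time_start = time_start, time_stop = time_stop, time_step = time_step,
      n_channels = n_channels, group = group,
      background = background, w_cat = w_cat, w_item = w_item,
      sigma_noise = sigma_noise, signal_window = signal_window,
      signal_channels = signal_channels, seed = seed
    ),
    class = "synth_config"
  )
}

#' Closed-form planted correlations of a synthetic configuration
#'
#' @param cfg A [synth_config()].
#' @return List with `rho_item`, `rho_cat`, `rho_between` (always 0 at
#'   signal samples).
#' @export
expected_population_correlation <- function(cfg) {
  v <- cfg$w_cat^2 + cfg$w_item^2 + cfg$sigma_noise^2
  if (v == 0) stop("all variance components are zero")
  list(
    rho_item = (cfg$w_cat^2 + cfg$w_item^2) / v,
    rho_cat = cfg$w_cat^2 / v,
    rho_between = 0
  )
}

#' Generate one synthetic subject
#'
#' Builds a linear-scale [tfr_dataset()] for one subject of the configured
#' design. Log10 power is `background(f) + sigma * noise` everywhere; inside
#' the signal window and signal channels the category and item patterns are
#' added. The trial noise is independent across trials, channels,
#' frequencies and time points, so time points outside the window (and all
#' between-category comparisons) carry no planted correlation. Deterministic
#' given `cfg$seed` and `subject_index`.
#'
#' @param cfg A [synth_config()].
#' @param subject_index 1-based subject number (also seeds the subject).
#' @return A `tfr_dataset` with a `ground_truth` attribute (planted rho
#'   values, signal indices, pattern fields).
#' @export
generate_subject_tfr <- function(cfg, subject_index = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  fg <- build_frequency_grid(cfg$freq_low, cfg$freq_high)
  tg <- build_time_grid(cfg$time_start, cfg$time_stop, cfg$time_step)
  n_f <- length(fg$freqs_hz)
  n_t <- length(tg$times_s)
  n_ch <- cfg$n_channels
  cc <- cfg$n_categories
  sig_ch <- if (is.null(cfg$signal_channels)) seq_len(n_ch) else
    sort(unique(cfg$signal_channels))
  t_idx <- which(tg$times_s >= cfg$signal_window[1] &
                   tg$times_s <= cfg$signal_window[2])
  design <- expand.grid(presentation = 1:2, exemplar = 1:2,
                        category = seq_len(cc))
  n_trials <- nrow(design)
  seed_i <- (cfg$seed + subject_index * 10007L) %% .Machine$integer.max

  out <- with_local_seed(seed_i, {
    logpow <- array(stats::rnorm(n_trials * n_ch * n_f * n_t,
                                 sd = cfg$sigma_noise),
                    dim = c(n_trials, n_ch, n_f, n_t))
    bg <- cfg$background[1] + cfg$background[2] * log10(fg$freqs_hz)
    logpow <- sweep(logpow, 3, bg, "+")
    g_cat <- array(stats::rnorm(cc * length(sig_ch) * n_f),
                   dim = c(cc, length(sig_ch), n_f))
    g_item <- array(stats::rnorm(cc * 2 * length(sig_ch) * n_f),
                    dim = c(cc, 2, length(sig_ch), n_f))
    if (length(t_idx)) {
      for (tr in seq_len(n_trials)) {
        c_i <- design$category[tr]
        e_i <- design$exemplar[tr]
        sig <- cfg$w_cat * g_cat[c_i, , ] + cfg$w_item * g_item[c_i, e_i, , ]
        sig <- matrix(sig, length(sig_ch), n_f)
        logpow[tr, sig_ch, , t_idx] <-
          logpow[tr, sig_ch, , t_idx] +
          array(sig, dim = c(length(sig_ch), n_f, length(t_idx)))
      }
    }
    list(logpow = logpow, g_cat = g_cat, g_item = g_item)
  })

  ds <- tfr_dataset(
    power = 10^out$logpow, freq_grid = fg, time_grid = tg,
    channels = default_channel_table(n_ch),
    trials = tibble::tibble(
      category = design$category, exemplar = design$exemplar,
      presentation = design$presentation, orig_index = seq_len(n_trials)
    ),
    subject_id = sprintf("%s%02d", toupper(substr(cfg$group, 1, 1)),
                         subject_index),
    group = cfg$group, scale = "linear"
  )
  rho <- expected_population_correlation(cfg)
  attr(ds, "ground_truth") <- list(
    rho_item = rho$rho_item, rho_cat = rho$rho_cat, rho_between = 0,
    signal_time_idx = t_idx, signal_channels = sig_ch,
    w_cat = cfg$w_cat, w_item = cfg$w_item, sigma_noise = cfg$sigma_noise,
    g_cat = out$g_cat, g_item = out$g_item, seed = seed_i
  )
  ds
}

# evenly spaced channels on a circle: enough geometry for distance-based
# adjacency and topographic scatter without a real montage
default_channel_table <- function(n_ch) {
  theta <- 2 * pi * (seq_len(n_ch) - 1) / n_ch
  tibble::tibble(
    label = sprintf("E%02d", seq_len(n_ch)),
    x = cos(theta), y = sin(theta)
  )
}

#' Generate two synthetic groups
#'
#' Independent cohorts from two configurations sharing the frequency and
#' time grids (channel counts may differ, as between EEG montages). The
#' planted group difference in item specificity is the difference of
#' `rho_item - rho_cat` between the configurations.
#'
#' @param cfg_a,cfg_b [synth_config()] objects for the two groups.
#' @return List with elements `a` and `b`, each a list of `tfr_dataset`s.
#' @export
generate_group_dataset <- function(cfg_a, cfg_b) {
  fa <- build_frequency_grid(cfg_a$freq_low, cfg_a$freq_high)
  fb <- build_frequency_grid(cfg_b$freq_low, cfg_b$freq_high)
  ta <- build_time_grid(cfg_a$time_start, cfg_a$time_stop, cfg_a$time_step)
  tb <- build_time_grid(cfg_b$time_start, cfg_b$time_stop, cfg_b$time_step)
  if (!isTRUE(all.equal(fa$freqs_hz, fb$freqs_hz)) ||
      !isTRUE(all.equal(ta$times_s, tb$times_s))) {
    stop("groups must share the frequency and time grids")
  }
  cfg_b_off <- cfg_b
  # decorrelate the groups even when both configs carry the same base seed
  cfg_b_off$seed <- (cfg_b$seed + 500009L) %% .Machine$integer.max
  list(
    a = lapply(seq_len(cfg_a$n_subjects), function(i) generate_subject_tfr(cfg_a, i)),
    b = lapply(seq_len(cfg_b_off$n_subjects), function(i) generate_subject_tfr(cfg_b_off, i))
  )
}

#' Generate memory scores correlated with item specificity
#'
#' Simulates a behavioral score with a target population correlation to the
#' per-subject specificity values:
#' `score = r * z(specificity) + sqrt(1 - r^2) * noise`.
#'
#' @param spec A `specificity_summary` (or tibble with `subject_id`,
#'   `group`, `specificity`), or a bare numeric vector.
#' @param r_target Target correlation, `|r_target| <= 1`.
#' @param seed RNG seed.
#' @return A behavior tibble: `subject_id`, `group`, `item_memory`.
#' @export
generate_memory_scores <- function(spec, r_target, seed = 1) {
  stopifnot(abs(r_target) <= 1)
  if (is.numeric(spec)) {
    spec <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_along(spec)),
      group = "other", specificity = spec
    )
  }
  spec <- tibble::as_tibble(spec)
  delta <- spec$specificity
  zd <- if (stats::sd(delta) > 0) as.vector(scale(delta)) else rep(0, length(delta))
  noise <- with_local_seed(seed, stats::rnorm(length(delta)))
  zn <- if (stats::sd(noise) > 0) as.vector(scale(noise)) else noise
  tibble::tibble(
    subject_id = spec$subject_id,
    group = spec$group,
    item_memory = r_target * zd + sqrt(1 - r_target^2) * zn
  )
}
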