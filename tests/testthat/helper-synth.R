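# shared fixtures, built in code; heavier objects cached per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# minimal hand-built dataset: full C x 2 x 2 design, given power filler
make_toy_ds <- function(n_categories = 2, n_channels = 2, freqs = c(2, 4, 6, 8),
                        times = c(0, 0.1, 0.2), fill = NULL, scale = "linear",
                        subject_id = "T01", group = "other") {
  design <- expand.grid(presentation = 1:2, exemplar = 1:2,
                        category = seq_len(n_categories))
  n_tr <- nrow(design)
  dims <- c(n_tr, n_channels, length(freqs), length(times))
  power <- if (is.null(fill)) array(seq_len(prod(dims)) / prod(dims) + 1, dims)
           else array(fill, dims)
  theta <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
  tfr_dataset(
    power = power, freq_grid = freqs, time_grid = times,
    channels = tibble::tibble(label = paste0("c", seq_len(n_channels)),
                              x = cos(theta), y = sin(theta)),
    trials = tibble::tibble(category = design$category,
                            exemplar = design$exemplar,
                            presentation = design$presentation),
    subject_id = subject_id, group = group, scale = scale
  )
}

# reduced-grid generator config used across tests: the reference design's
# category count and frequency grid at a 40 ms time step
test_cfg <- function(...) {
  synth_config(n_subjects = 3, n_categories = 40, n_channels = 4,
               time_step = 0.04, seed = 20260928, ...)
}

# small cohort shared by several RSA/cluster tests (2 subjects is enough
# for shape and oracle checks; statistics tests build their own)
small_cohort <- function() {
  cached("small_cohort", {
    cfg <- synth_config(n_subjects = 2, n_categories = 8, n_channels = 4,
                        time_step = 0.1, seed = 7)
    lapply(1:2, function(i) {
      ds <- generate_subject_tfr(cfg, i)
      list(raw = ds, prep = preprocess_tfr(ds),
           truth = attr(ds, "ground_truth"))
    })
  })
}
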