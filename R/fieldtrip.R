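#' Import a FieldTrip time-frequency structure from a MAT file
#'
#' Reads a FieldTrip-style TFR struct (fields `powspctrm` with dimensions
#' trial x channel x frequency x time, `label`, `freq`, `time`, `trialinfo`)
#' from a MATLAB MAT file (v7 or v7.3) into a [tfr_dataset()]. Because the
#' mapping of `trialinfo` columns to the design is dataset-specific, it is
#' supplied explicitly as `trialinfo_map`.
#'
#' MAT parsing is delegated to the system Python (`scipy.io` for v7 files,
#' `h5py` for v7.3), which converts the struct to a small JSON header plus a
#' raw float64 stream that R reads directly.
#'
#' @param path Path to the MAT file.
#' @param trialinfo_map Named integer vector mapping trial-table columns to
#'   1-based `trialinfo` columns; names must be a subset of
#'   `c("category", "exemplar", "presentation", "orig_index")` and must
#'   include the first three.
#' @param subject_id,group Metadata for the resulting dataset.
#' @param python Python executable to use.
#' @return A `tfr_dataset` with linear-scale power.
#' @export
import_fieldtrip_mat <- function(path,
                                 trialinfo_map = c(category = 1, exemplar = 2,
                                                   presentation = 3),
                                 subject_id = "S01", group = "other",
                                 python = Sys.which("python")) {
  if (!file.exists(path)) stop("import error: file not found: ", path)
  allowed <- c("category", "exemplar", "presentation", "orig_index")
  if (!all(names(trialinfo_map) %in% allowed) ||
      !all(c("category", "exemplar", "presentation") %in% names(trialinfo_map))) {
    stop(
      "import error: trialinfo_map keys must include category, exemplar, ",
      "presentation (optionally orig_index); got: ",
      paste(names(trialinfo_map), collapse = ", ")
    )
  }
  conv <- system.file("python", "ft_mat_to_raw.py", package = "spectralrsa")
  stopifnot(nzchar(conv))
  out_stem <- tempfile("ftmat")
  res <- system2(python, c(conv, shQuote(path), shQuote(out_stem)),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("import error: MAT conversion failed:\n", paste(res, collapse = "\n"))
  }
  hdr <- jsonlite::read_json(paste0(out_stem, ".json"), simplifyVector = TRUE)
  for (fld in c("dims", "freq", "time", "label")) {
    if (is.null(hdr[[fld]])) stop("import error: missing field '", fld, "' in MAT struct")
  }
  if (is.null(hdr$trialinfo) || length(hdr$trialinfo) == 0) {
    stop("import error: empty or missing trialinfo")
  }
  dims <- as.integer(hdr$dims)
  n <- prod(dims)
  con <- file(paste0(out_stem, ".bin"), "rb")
  on.exit(close(con), add = TRUE)
  dat <- readBin(con, what = "double", n = n, size = 8)
  if (length(dat) != n) stop("import error: truncated power stream")
  # stream is C-ordered (last index fastest); R arrays are Fortran-ordered
  power <- aperm(array(dat, dim = rev(dims)), length(dims):1)
  ti <- hdr$trialinfo
  ti <- if (is.list(ti)) {
    matrix(unlist(ti), nrow = dims[1], byrow = TRUE)
  } else {
    as.matrix(ti)
  }
  if (max(trialinfo_map) > ncol(ti)) {
    stop("import error: trialinfo has ", ncol(ti), " columns but map needs ",
         max(trialinfo_map))
  }
  trials <- tibble::tibble(
    category = as.integer(ti[, trialinfo_map[["category"]]]),
    exemplar = as.integer(ti[, trialinfo_map[["exemplar"]]]),
    presentation = as.integer(ti[, trialinfo_map[["presentation"]]]),
    orig_index = if ("orig_index" %in% names(trialinfo_map)) {
      as.integer(ti[, trialinfo_map[["orig_index"]]])
    } else {
      seq_len(dims[1])
    }
  )
  channels <- tibble::tibble(label = as.character(hdr$label))
  if (!is.null(hdr$pos) && length(hdr$pos)) {
    pos <- matrix(unlist(hdr$pos), nrow = length(channels$label), byrow = TRUE)
    channels$x <- pos[, 1]
    channels$y <- pos[, 2]
  }
  tfr_dataset(
    power = power, freq_grid = as.numeric(hdr$freq),
    time_grid = as.numeric(hdr$time), channels = channels, trials = trials,
    subject_id = subject_id, group = group, scale = "linear"
  )
}

#' Write a dataset as a FieldTrip-style MAT file
#'
#' Emits a minimal FieldTrip TFR struct (`powspctrm`, `label`, `freq`,
#' `time`, `trialinfo`, `dimord = 'rpt_chan_freq_time'`) so round trips
#' through [import_fieldtrip_mat()] can be exercised without MATLAB. Writing
#' uses the system Python's `scipy.io.savemat`.
#'
#' @param ds A `tfr_dataset` (linear scale).
#' @param path Output MAT path.
#' @param python Python executable.
#' @return `path`, invisibly.
#' @export
write_fieldtrip_mat <- function(ds, path, python = Sys.which("python")) {
  stopifnot(inherits(ds, "tfr_dataset"))
  stem <- tempfile("ftout")
  hdr <- list(
    dims = dim(ds$power),
    freq = ds$freqs,
    time = ds$times,
    label = ds$channels$label,
    trialinfo = unname(as.matrix(ds$trials[, c("category", "exemplar",
                                               "presentation", "orig_index")]))
  )
  jsonlite::write_json(hdr, paste0(stem, ".json"),
                       auto_unbox = FALSE, digits = NA)
  con <- file(paste0(stem, ".bin"), "wb")
  # emit in C order so the converter can reshape without copying conventions
  writeBin(as.vector(aperm(ds$power, 4:1)), con, size = 8)
  close(con)
  conv <- system.file("python", "raw_to_ft_mat.py", package = "spectralrsa")
  res <- system2(python, c(conv, shQuote(stem), shQuote(path)),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("MAT export failed:\n", paste(res, collapse = "\n"))
  }
  invisible(path)
}
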