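#' Enumerate trial pairs for a similarity level
#'
#' The three similarity levels compare spectral patterns from different
#' trials of the encoding design (categories x 2 exemplars x 2
#' presentations):
#'
#' * `within_item`: first vs second presentation of the first exemplar of
#'   each category (representational stability).
#' * `within_category`: first presentations of the first vs second exemplar
#'   of each category.
#' * `between_category`: all ordered pairs of distinct categories, first
#'   exemplar / first presentation on each side. Pairs are ordered — each
#'   unordered comparison appears twice, once per direction — which is what
#'   makes the mean between-category matrix exactly symmetric.
#'
#' Categories missing a required trial (e.g. after artifact rejection) are
#' skipped and reported in the `skipped` attribute.
#'
#' @param trials A trial table (tibble with `category`, `exemplar`,
#'   `presentation`).
#' @param level One of `"within_item"`, `"within_category"`,
#'   `"between_category"`.
#' @return A `pair_list`: tibble with columns `a`, `b` (row indices into the
#'   trial table) and `unit` (averaging unit: category, or ordered category
#'   pair `"c1>c2"`), with attributes `level` and `skipped`.
#' @export
enumerate_pairs <- function(trials, level = c("within_item", "within_category",
                                              "between_category")) {
  level <- match.arg(level)
  trials <- tibble::as_tibble(trials)
  find_trial <- function(c, e, p) {
    which(trials$category == c & trials$exemplar == e & trials$presentation == p)[1]
  }
  skipped <- unusable_categories(trials, level)
  cats <- setdiff(sort(unique(trials$category)), skipped)
  if (length(cats) == 0L) stop("enumerate_pairs: no usable categories for ", level)
  pairs <- switch(level,
    within_item = tibble::tibble(
      a = vapply(cats, find_trial, integer(1), e = 1, p = 1),
      b = vapply(cats, find_trial, integer(1), e = 1, p = 2),
      unit = as.character(cats)
    ),
    within_category = tibble::tibble(
      a = vapply(cats, find_trial, integer(1), e = 1, p = 1),
      b = vapply(cats, find_trial, integer(1), e = 2, p = 1),
      unit = as.character(cats)
    ),
    between_category = {
      grid <- expand.grid(c1 = cats, c2 = cats)
      grid <- grid[grid$c1 != grid$c2, , drop = FALSE]
      tibble::tibble(
        a = vapply(grid$c1, find_trial, integer(1), e = 1, p = 1),
        b = vapply(grid$c2, find_trial, integer(1), e = 1, p = 1),
        unit = sprintf("%d>%d", grid$c1, grid$c2)
      )
    }
  )
  structure(pairs, level = level, skipped = skipped,
            class = c("pair_list", class(pairs)))
}

#' Time-time correlation of two spectral patterns
#'
#' Correlates the frequency profile of pattern A at every time point with the
#' frequency profile of pattern B at every time point, giving a full
#' time x time matrix of correlation coefficients: entry (t1, t2) is the
#' correlation over frequencies of column t1 of `pattern_a` with column t2 of
#' `pattern_b`.
#'
#' A frequency profile with zero variance has no defined correlation; such
#' entries are set to 0 and counted in the `n_zero_var` attribute (with one
#' warning), so downstream tensors stay finite.
#'
#' @param pattern_a,pattern_b Numeric matrices, frequency x time, at least 3
#'   frequency rows. Time dimensions may differ.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `ncol(pattern_a)` x `ncol(pattern_b)` matrix of r in `[-1, 1]`.
#' @export
time_time_correlation <- function(pattern_a, pattern_b,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(pattern_a), is.matrix(pattern_b))
  if (nrow(pattern_a) != nrow(pattern_b)) {
    stop("patterns must share the frequency dimension")
  }
  if (nrow(pattern_a) < 3) stop("need at least 3 frequencies to correlate")
  if (method == "spearman") {
    pattern_a <- apply(pattern_a, 2, rank)
    pattern_b <- apply(pattern_b, 2, rank)
  }
  f <- nrow(pattern_a)
  std_cols <- function(m) {
    ctr <- sweep(m, 2, colMeans(m))
    sd <- sqrt(colSums(ctr^2) / (f - 1))
    zero <- sd <= 0
    sd[zero] <- 1
    list(z = sweep(ctr, 2, sd * sqrt(f - 1), "/"), zero = zero)
  }
  za <- std_cols(pattern_a)
  zb <- std_cols(pattern_b)
  r <- crossprod(za$z, zb$z)
  n_zero <- 0L
  if (any(za$zero) || any(zb$zero)) {
    r[za$zero, ] <- 0
    r[, zb$zero] <- 0
    n_zero <- sum(za$zero) * ncol(pattern_b) +
      sum(zb$zero) * ncol(pattern_a) - sum(za$zero) * sum(zb$zero)
    warning(n_zero, " correlation entries set to 0 (zero-variance frequency profile)")
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  attr(r, "n_zero_var") <- n_zero
  r
}

#' Fisher z transform
#'
#' Variance-stabilizing `atanh` of correlation coefficients, applied before
#' averaging and t-testing similarity values. Coefficients at exactly +/-1
#' (identical patterns) are clipped to `1 - 1e-12` in magnitude so averages
#' stay finite; the number of clipped values is recorded in the `n_clipped`
#' attribute.
#'
#' @param r Numeric vector/matrix/array of correlations, `|r| <= 1` (a
#'   tolerance of 1e-9 is allowed for floating-point slack).
#' @return `atanh(r)` with the same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE)) {
    stop("fisher_z: |r| > 1")
  }
  lim <- 1 - 1e-12
  clipped <- abs(r) > lim
  r[r > lim] <- lim
  r[r < -lim] <- -lim
  z <- atanh(r)
  attr(z, "n_zero_var") <- NULL
  attr(z, "n_clipped") <- sum(clipped)
  z
}

#' Compute a subject's similarity tensor
#'
#' For every trial pair of the requested level and every channel, correlates
#' the two patterns' frequency profiles across all time-point combinations
#' and Fisher-z transforms the result, giving a unit x channel x time x time
#' tensor.
#'
#' @param ds A preprocessed `tfr_dataset` (log10 scale, background removed;
#'   enforce with `require_preprocessed = FALSE` to override).
#' @param level Similarity level, see [enumerate_pairs()].
#' @param method Correlation method passed to [time_time_correlation()].
#' @param require_preprocessed If `TRUE` (default), error unless the dataset
#'   is log-scaled with background removed.
#' @return A `similarity_tensor`: list with `z` (unit x channel x time x
#'   time array), `level`, `subject_id`, `group`, `units`, `times`,
#'   `channels`, `pairs`, and counters `n_clipped`, `n_zero_var`.
#' @export
compute_subject_similarity <- function(ds,
                                       level = c("within_item",
                                                 "within_category",
                                                 "between_category"),
                                       method = c("pearson", "spearman"),
                                       require_preprocessed = TRUE) {
  stopifnot(inherits(ds, "tfr_dataset"))
  level <- match.arg(level)
  method <- match.arg(method)
  if (require_preprocessed &&
      (ds$scale != "log10" || is.null(attr(ds, "background_removed")))) {
    stop("dataset must be log-transformed with background removed; see preprocess_tfr()")
  }
  pairs <- enumerate_pairs(ds$trials, level)
  n_u <- nrow(pairs)
  n_ch <- dim(ds$power)[2]
  n_t <- dim(ds$power)[4]
  z <- array(NA_real_, dim = c(n_u, n_ch, n_t, n_t))
  n_clipped <- 0L
  n_zero_var <- 0L
  n_f <- dim(ds$power)[3]
  for (u in seq_len(n_u)) {
    pa <- ds$power[pairs$a[u], , , , drop = FALSE]
    pb <- ds$power[pairs$b[u], , , , drop = FALSE]
    for (ch in seq_len(n_ch)) {
      r <- withCallingHandlers(
        time_time_correlation(
          matrix(pa[1, ch, , ], n_f, n_t),
          matrix(pb[1, ch, , ], n_f, n_t),
          method = method
        ),
        warning = function(w) invokeRestart("muffleWarning")
      )
      n_zero_var <- n_zero_var + attr(r, "n_zero_var")
      zz <- fisher_z(r)
      n_clipped <- n_clipped + attr(zz, "n_clipped")
      z[u, ch, , ] <- zz
    }
  }
  if (n_zero_var > 0) {
    warning(n_zero_var, " zero-variance correlation entries set to 0")
  }
  structure(
    list(
      z = z, level = level, method = method,
      subject_id = ds$subject_id, group = ds$group,
      units = pairs$unit, times = ds$times, channels = ds$channels,
      pairs = pairs, n_clipped = n_clipped, n_zero_var = n_zero_var
    ),
    class = "similarity_tensor"
  )
}

#' @export
print.similarity_tensor <- function(x, ...) {
  d <- dim(x$z)
  cat(sprintf(
    "<similarity_tensor> %s, subject %s: %d units x %d channels x %d x %d (Fisher z)\n",
    x$level, x$subject_id, d[1], d[2], d[3], d[4]
  ))
  invisible(x)
}

#' Average a similarity tensor over units
#'
#' Arithmetic mean of the Fisher-z tensor over its averaging units
#' (categories or ordered category pairs), giving one channel x time x time
#' similarity matrix per subject.
#'
#' @param st A `similarity_tensor`.
#' @return A `subject_similarity`: list with `z_mean` (channel x time x time
#'   array), `n_units`, `level`, `subject_id`, `group`, `times`, `channels`.
#' @export
average_subject <- function(st) {
  stopifnot(inherits(st, "similarity_tensor"))
  structure(
    list(
      z_mean = colMeans(st$z), n_units = dim(st$z)[1],
      level = st$level, subject_id = st$subject_id, group = st$group,
      times = st$times, channels = st$channels
    ),
    class = "subject_similarity"
  )
}

#' @export
print.subject_similarity <- function(x, ...) {
  d <- dim(x$z_mean)
  cat(sprintf(
    "<subject_similarity> %s, subject %s: %d channels x %d x %d (mean of %d units)\n",
    x$level, x$subject_id, d[1], d[2], d[3], x$n_units
  ))
  invisible(x)
}

#' Stack subject similarity matrices into a group average
#'
#' Combines per-subject channel x time x time matrices into a subject x
#' channel x time x time stack, plus the grand-mean time x time matrix
#' (averaged over channels and subjects) used for display.
#'
#' @param subjects List of `subject_similarity` objects sharing level, time
#'   grid and channel count.
#' @param group Optional group label; defaults to the subjects' common label.
#' @return A `group_similarity`: list with `stack`, `mean_matrix`, `level`,
#'   `group`, `subject_ids`, `times`, `channels`.
#' @export
grand_average <- function(subjects, group = NULL) {
  stopifnot(length(subjects) >= 1)
  lev <- unique(vapply(subjects, function(s) s$level, character(1)))
  if (length(lev) != 1) stop("subjects mix similarity levels: ", paste(lev, collapse = ", "))
  nch <- vapply(subjects, function(s) dim(s$z_mean)[1], integer(1))
  if (length(unique(nch)) != 1) {
    stop("subjects within a group must share the channel count (got ",
         paste(unique(nch), collapse = ", "), ")")
  }
  tgrids <- vapply(subjects, function(s) length(s$times), integer(1))
  if (length(unique(tgrids)) != 1) stop("subjects must share the time grid")
  n_t <- tgrids[1]
  stack <- array(NA_real_, dim = c(length(subjects), nch[1], n_t, n_t))
  for (i in seq_along(subjects)) stack[i, , , ] <- subjects[[i]]$z_mean
  if (is.null(group)) {
    g <- unique(vapply(subjects, function(s) s$group, character(1)))
    group <- if (length(g) == 1) g else "mixed"
  }
  structure(
    list(
      stack = stack,
      mean_matrix = apply(stack, c(3, 4), mean),
      level = lev, group = group,
      subject_ids = vapply(subjects, function(s) s$subject_id, character(1)),
      times = subjects[[1]]$times, channels = subjects[[1]]$channels
    ),
    class = "group_similarity"
  )
}

#' @export
print.group_similarity <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf(
    "<group_similarity> %s, group %s: %d subjects x %d channels x %d x %d\n",
    x$level, x$group, d[1], d[2], d[3], d[4]
  ))
  invisible(x)
}

#' Extract the diagonal of a time-time similarity matrix
#'
#' The diagonal holds the similarity of the two spectral patterns at
#' identical time points — the classic time course of pattern similarity.
#'
#' @param m A square time x time matrix (or a `subject_similarity` /
#'   `group_similarity`, whose channel-mean matrix is used).
#' @return Numeric vector of length T.
#' @export
extract_diagonal <- function(m) {
  if (inherits(m, "group_similarity")) m <- m$mean_matrix
  if (inherits(m, "subject_similarity")) m <- apply(m$z_mean, c(2, 3), mean)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("extract_diagonal: matrix must be square")
  diag(m)
}
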