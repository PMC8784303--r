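#' Plot a mean time-time similarity matrix
#'
#' Heatmap of the grand-mean Fisher-z similarity over trial time (pattern A)
#' vs trial time (pattern B). The diagonal is the similarity of the two
#' patterns at identical time points.
#'
#' @param object A `group_similarity` (or `subject_similarity`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.group_similarity <- function(object, ...) {
  df <- tidy.group_similarity(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t1, y = .data$t2, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "z'") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "time, pattern 1 (s)", y = "time, pattern 2 (s)",
      title = sprintf("%s similarity, %s", gsub("_", "-", object$level),
                      object$group)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.subject_similarity <- function(object, ...) {
  gm <- apply(object$z_mean, c(2, 3), mean)
  fake <- list(mean_matrix = gm, times = object$times,
               level = object$level, group = object$subject_id)
  autoplot.group_similarity(structure(fake, class = "group_similarity"))
}

#' Plot similarity-matrix diagonals for one or more levels
#'
#' Line plot of the diagonal (same-time similarity) of each supplied mean
#' similarity matrix; the conventional display for comparing levels or
#' groups over time.
#'
#' @param ... Named `group_similarity` (or `subject_similarity`) objects;
#'   names become legend entries (defaults to their level).
#' @return A ggplot.
#' @export
plot_diagonals <- function(...) {
  objs <- list(...)
  if (length(objs) == 1 && is.list(objs[[1]]) &&
      !inherits(objs[[1]], c("group_similarity", "subject_similarity"))) {
    objs <- objs[[1]]
  }
  if (is.null(names(objs)) || any(names(objs) == "")) {
    names(objs) <- vapply(objs, function(o) gsub("_", "-", o$level), character(1))
  }
  df <- purrr::imap_dfr(objs, function(o, nm) {
    tibble::tibble(time = o$times, z = extract_diagonal(o), level = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$z,
                                   colour = .data$level)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (s)", y = "z'", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cluster extent in the time-time plane
#'
#' Heatmap of the channel-mean observed group t-map with the outline of the
#' significant clusters' time-time footprint (any channel) overlaid.
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_result <- function(object, ...) {
  tmean <- apply(object$observed_t, c(2, 3), mean)
  times <- object$times
  df <- tibble::tibble(
    t1 = rep(times, times = length(times)),
    t2 = rep(times, each = length(times)),
    t = as.vector(tmean)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t1, y = .data$t2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$t)) +
    ggplot2::scale_fill_gradient2(name = "t", low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "time, pattern 1 (s)", y = "time, pattern 2 (s)",
                  title = sprintf("group %s: mean t and significant extent",
                                  object$group)) +
    ggplot2::theme_minimal()
  mask <- significant_mask(object)
  if (!is.null(mask) && any(mask)) {
    foot <- apply(mask, c(2, 3), any)
    df$inmask <- as.vector(foot)
    p <- p + ggplot2::geom_contour(
      data = df, ggplot2::aes(z = as.numeric(.data$inmask)),
      breaks = 0.5, colour = "black", linewidth = 0.4
    )
  }
  p
}

significant_mask <- function(result, alpha = NULL) {
  if (is.null(alpha)) alpha <- result$cluster_alpha
  sig <- result$clusters[!is.na(result$clusters$p_value) &
                           result$clusters$p_value < alpha, , drop = FALSE]
  if (nrow(sig) == 0) return(NULL)
  mask <- array(FALSE, dim = dim(result$labels_pos))
  for (i in seq_len(nrow(sig))) {
    mask <- mask | (if (sig$sign[i] == "positive") result$labels_pos else
      result$labels_neg) == sig$id[i]
  }
  mask
}

#' Topographic scatter of cluster effect sizes
#'
#' Simple 2-D channel scatter colored by the mean observed t over the
#' significant time-time samples; channels belonging to a significant
#' cluster are marked with an asterisk.
#'
#' @param result A `cluster_result` whose channel table carries `x`, `y`
#'   layout coordinates.
#' @return A ggplot.
#' @export
plot_topography <- function(result) {
  ch <- result$channels
  if (!all(c("x", "y") %in% names(ch))) {
    stop("plot_topography: channel table lacks x/y layout positions")
  }
  mask <- significant_mask(result)
  if (is.null(mask)) {
    tt_foot <- array(TRUE, dim = dim(result$observed_t)[2:3])
    in_cluster <- rep(FALSE, nrow(ch))
  } else {
    tt_foot <- apply(mask, c(2, 3), any)
    in_cluster <- apply(mask, 1, any)
  }
  mean_t <- vapply(seq_len(nrow(ch)), function(i) {
    mean(result$observed_t[i, , ][tt_foot])
  }, numeric(1))
  df <- dplyr::mutate(ch, mean_t = mean_t, in_cluster = in_cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$mean_t), size = 4) +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$in_cluster),
      shape = 8, size = 2, colour = "black"
    ) +
    ggplot2::scale_colour_gradient2(name = "mean t", low = "steelblue",
                                    mid = "white", high = "firebrick") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("group %s: channel effect sizes", result$group),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Compare item specificity between groups
#'
#' Violin + boxplot + jittered per-subject points of the item-specificity
#' scores of each group (in place of a raincloud plot).
#'
#' @param ... One or more `specificity_summary` objects (or tibbles with
#'   `group` and `specificity`).
#' @param jitter_seed Seed for the horizontal jitter so output is
#'   reproducible.
#' @return A ggplot.
#' @export
plot_group_comparison <- function(..., jitter_seed = 1) {
  df <- dplyr::bind_rows(lapply(list(...), function(x) {
    tibble::as_tibble(x)[, c("group", "specificity")]
  }))
  set.seed(jitter_seed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$specificity,
                                   fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.4, colour = NA) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA, alpha = 0.7) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 1.6, alpha = 0.8) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "item specificity (Δz')") +
    ggplot2::theme_minimal()
}

#' Scatter of item specificity vs memory performance
#'
#' Per-group scatter with least-squares lines; the conventional display for
#' between-person brain-behavior association.
#'
#' @param spec Tibble with `subject_id`, `group`, `specificity`.
#' @param behavior Tibble with `subject_id`, `item_memory`.
#' @return A ggplot.
#' @export
plot_memory_scatter <- function(spec, behavior) {
  df <- dplyr::inner_join(
    tibble::as_tibble(spec)[, c("subject_id", "group", "specificity")],
    tibble::as_tibble(behavior)[, c("subject_id", "item_memory")],
    by = "subject_id"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$specificity,
                                   y = .data$item_memory,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "item specificity (Δz')", y = "item memory",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Render a pipeline figure to a file
#'
#' Thin dispatcher used by the command-line pipeline: builds the requested
#' figure kind from its inputs and writes it as PNG or SVG (by file
#' extension) with a fixed size, so repeated runs from the same inputs give
#' identical files.
#'
#' @param kind One of `"simmatrix"`, `"diagonals"`, `"cluster_extent"`,
#'   `"topography"`, `"group_comparison"`, `"scatter"`.
#' @param inputs List of inputs for the kind: `simmatrix` a
#'   `group_similarity`; `diagonals` a named list of them;
#'   `cluster_extent`/`topography` a `cluster_result`; `group_comparison` a
#'   list of specificity summaries; `scatter` `list(spec, behavior)`.
#' @param path Output file path ending in `.png` or `.svg`.
#' @param width,height Size in inches.
#' @return `path`, invisibly.
#' @export
render_figure <- function(kind, inputs, path, width = 6, height = 5) {
  kinds <- c("simmatrix", "diagonals", "cluster_extent", "topography",
             "group_comparison", "scatter")
  if (!kind %in% kinds) {
    stop("unknown figure kind '", kind, "'; expected one of: ",
         paste(kinds, collapse = ", "))
  }
  p <- switch(kind,
    simmatrix = ggplot2::autoplot(inputs),
    diagonals = plot_diagonals(inputs),
    cluster_extent = ggplot2::autoplot(inputs),
    topography = plot_topography(inputs),
    group_comparison = do.call(plot_group_comparison, unname(inputs)),
    scatter = plot_memory_scatter(inputs$spec, inputs$behavior)
  )
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  } else {
    stop("unsupported figure format: .", ext, " (use .png or .svg)")
  }
  ok <- FALSE
  tryCatch({
    print(p)
    ok <- TRUE
  }, finally = grDevices::dev.off())
  if (ok && ext == "svg") normalize_svg_ids(path)
  invisible(path)
}

# cairo numbers element ids with a per-session counter, which would make
# otherwise-identical SVG output differ between renders; renumber ids (and
# their references) in order of first appearance so equal figures are
# byte-identical
normalize_svg_ids <- function(path) {
  txt <- readLines(path, warn = FALSE)
  one <- paste(txt, collapse = "\n")
  pat <- "(source|image|clip|glyph|surface|mask|pattern|symbol)-[0-9]+"
  m <- gregexpr(pat, one)[[1]]
  if (m[1] == -1) return(invisible(path))
  toks <- regmatches(one, gregexpr(pat, one))[[1]]
  uniq <- unique(toks)
  prefix <- sub("-[0-9]+$", "", uniq)
  new <- paste0(prefix, "-", stats::ave(seq_along(uniq), prefix,
                                        FUN = seq_along))
  # longest-first so e.g. clip-1 does not clobber clip-10
  ord <- order(nchar(uniq), decreasing = TRUE)
  tmp <- one
  for (i in ord) {
    tmp <- gsub(paste0("\\b", uniq[i], "\\b"), paste0("", i, ""),
                tmp)
  }
  for (i in ord) {
    tmp <- gsub(paste0("", i, ""), new[i], tmp, fixed = TRUE)
  }
  writeLines(tmp, path)
  invisible(path)
}
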