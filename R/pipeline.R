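#' Read and validate a run configuration
#'
#' The step-wise pipeline is driven by a single YAML configuration with
#' sections `paths` (workdir), `data` (trialinfo column map for MAT import),
#' `rsa` (correlation method, background mode), `stats` (permutations,
#' alphas, adjacency rule), `behavior` (memory-score CSV or simulated
#' target correlation) and `synth` (per-group generator settings). Every
#' adjustable parameter of every step lives here; steps receive the parsed
#' config object.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return A validated `run_config` list with defaults filled in.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(
    seed = 1,
    paths = list(workdir = "specsim_run"),
    data = list(trialinfo_map = list(category = 1, exemplar = 2,
                                     presentation = 3)),
    rsa = list(method = "pearson", background_mode = "mean_spectrum"),
    stats = list(n_permutations = 500, sample_alpha = 0.05,
                 cluster_alpha = 0.025,
                 adjacency = list(mode = "distance_threshold", param = 0.7)),
    behavior = list(csv = NULL, r_target = 0.4),
    synth = list(groups = list(
      children = list(n_subjects = 10, n_channels = 64),
      adults = list(n_subjects = 10, n_channels = 60)
    ))
  )
  cfg <- utils::modifyList(defaults, cfg)
  for (a in c("sample_alpha", "cluster_alpha")) {
    v <- cfg$stats[[a]]
    if (!is.numeric(v) || v <= 0 || v >= 0.5) {
      stop("run_config: stats$", a, " must lie in (0, 0.5)")
    }
  }
  if (!cfg$rsa$method %in% c("pearson", "spearman")) {
    stop("run_config: rsa$method must be pearson or spearman")
  }
  structure(cfg, class = "run_config")
}

normalize_level <- function(level) {
  lv <- gsub("-", "_", level)
  lv <- c(within_item = "within_item", within_cat = "within_category",
          within_category = "within_category",
          between_cat = "between_category",
          between_category = "between_category")[lv]
  if (is.na(lv)) stop("unknown level '", level, "'")
  unname(lv)
}

wpath <- function(cfg, ...) {
  p <- file.path(cfg$paths$workdir, ...)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  p
}

need_file <- function(path, producing_step) {
  if (!file.exists(path)) {
    stop("missing input '", basename(path), "': run ", producing_step,
         " first", call. = FALSE)
  }
  path
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_provenance <- function(cfg, step) {
  p <- wpath(cfg, "provenance", paste0(step, ".json"))
  jsonlite::write_json(
    list(step = step, config_hash = config_hash(cfg), seed = cfg$seed,
         package_version = as.character(utils::packageVersion("spectralrsa"))),
    p, auto_unbox = TRUE
  )
  p
}

run_groups <- function(cfg, group) {
  if (!is.null(group)) return(group)
  names(cfg$synth$groups)
}

synth_cfg_for_group <- function(cfg, g, idx) {
  args <- cfg$synth$groups[[g]]
  args$group <- g
  args$seed <- cfg$seed + idx * 104729L
  do.call(synth_config, args)
}

#' Run one step of the analysis pipeline
#'
#' A seven-step workflow, each step loadable from the
#' previous step's saved outputs under the configured working directory:
#'
#' * `synth` — generate the synthetic cohorts and save per-subject TFR
#'   containers.
#' * `step1` — per-subject similarity tensors for a level (preprocessing +
#'   time-time RSA).
#' * `step2` — grand-average similarity per group and level.
#' * `step3` — similarity-matrix and diagonal figures.
#' * `step4a` — first-level t-maps (within-item vs within-category).
#' * `step4b` — second-level cluster permutation test per group.
#' * `step4c` — third level: cluster-mask similarity means, item
#'   specificity, between-group comparison.
#' * `step5` — cluster extent and topography figures.
#' * `step6` — group-comparison figure.
#' * `step7` — correlation of item specificity with memory performance
#'   (+ scatter figure).
#'
#' Each step writes a JSON provenance record (config hash, seed, package
#' version) so any artifact can be regenerated from config + seed alone.
#'
#' @param step_id One of `"synth"`, `"step1"`, `"step2"`, `"step3"`,
#'   `"step4a"`, `"step4b"`, `"step4c"`, `"step5"`, `"step6"`, `"step7"`.
#' @param config A [read_run_config()] object, list or YAML path.
#' @param group Group name(s) to process (default: all configured groups).
#' @param level Similarity level for step1-step3 (`"within-item"`,
#'   `"within-cat"`, `"between-cat"` or underscore forms). step1 with the
#'   default runs both levels the statistics need.
#' @return Invisibly, a list of the step's key outputs (paths and result
#'   objects).
#' @export
run_step <- function(step_id, config, group = NULL, level = NULL) {
  steps <- c("synth", "step1", "step2", "step3", "step4a", "step4b",
             "step4c", "step5", "step6", "step7")
  if (!step_id %in% steps) {
    stop("unknown step '", step_id, "'; expected one of: ",
         paste(steps, collapse = ", "))
  }
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  groups <- run_groups(cfg, group)
  levels <- if (is.null(level)) c("within_item", "within_category") else
    normalize_level(level)
  out <- switch(step_id,
    synth = {
      paths <- list()
      for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        scfg <- synth_cfg_for_group(cfg, g, gi)
        for (i in seq_len(scfg$n_subjects)) {
          ds <- generate_subject_tfr(scfg, i)
          paths[[length(paths) + 1L]] <-
            save_tfr(ds, wpath(cfg, "tfr", g, paste0(ds$subject_id, ".rds")))
        }
      }
      list(tfr_files = unlist(paths))
    },
    step1 = {
      files <- list()
      for (g in groups) {
        tfrs <- list.files(file.path(cfg$paths$workdir, "tfr", g),
                           full.names = TRUE)
        if (!length(tfrs)) {
          stop("missing input TFRs for group ", g,
               ": run synth (or place .rds datasets under tfr/", g, ") first",
               call. = FALSE)
        }
        for (f in tfrs) {
          ds <- preprocess_tfr(load_tfr(f), mode = cfg$rsa$background_mode)
          for (lv in levels) {
            st <- compute_subject_similarity(ds, lv, method = cfg$rsa$method)
            files[[length(files) + 1L]] <- local({
              p <- wpath(cfg, "rsa", g, sprintf("%s_tensor_%s.rds", lv, ds$subject_id))
              saveRDS(st, p)
              p
            })
            saveRDS(average_subject(st),
                    wpath(cfg, "rsa", g, sprintf("%s_subject_%s.rds", lv, ds$subject_id)))
          }
        }
      }
      list(similarity_files = unlist(files))
    },
    step2 = {
      gas <- list()
      for (g in groups) {
        for (lv in levels) {
          fs <- list.files(file.path(cfg$paths$workdir, "rsa", g),
                           pattern = paste0("^", lv, "_subject_"),
                           full.names = TRUE)
          if (!length(fs)) {
            stop("missing per-subject similarity for ", g, "/", lv,
                 ": run step1 first", call. = FALSE)
          }
          ga <- grand_average(lapply(fs, readRDS), group = g)
          saveRDS(ga, wpath(cfg, "ga", sprintf("%s_%s.rds", g, lv)))
          gas[[paste(g, lv, sep = "_")]] <- ga
        }
      }
      gas
    },
    step3 = {
      figs <- character()
      for (g in groups) {
        diags <- list()
        for (lv in levels) {
          ga <- readRDS(need_file(
            file.path(cfg$paths$workdir, "ga", sprintf("%s_%s.rds", g, lv)),
            "step2"
          ))
          figs <- c(figs, render_figure(
            "simmatrix", ga, wpath(cfg, "fig", sprintf("simmatrix_%s_%s.png", g, lv))
          ))
          diags[[gsub("_", "-", lv)]] <- ga
        }
        figs <- c(figs, render_figure(
          "diagonals", diags, wpath(cfg, "fig", sprintf("diagonals_%s.png", g))
        ))
      }
      list(figures = figs)
    },
    step4a = {
      res <- list()
      for (g in groups) {
        load_tensors <- function(lv) {
          fs <- list.files(file.path(cfg$paths$workdir, "rsa", g),
                           pattern = paste0("^", lv, "_tensor_"),
                           full.names = TRUE)
          if (!length(fs)) {
            stop("missing similarity tensors for ", g, "/", lv,
                 ": run step1 first", call. = FALSE)
          }
          lapply(fs, readRDS)
        }
        tm <- first_level_tmaps(load_tensors("within_item"),
                                load_tensors("within_category"))
        saveRDS(tm, wpath(cfg, "stats", sprintf("%s_tmaps.rds", g)))
        res[[g]] <- tm
      }
      res
    },
    step4b = {
      res <- list()
      for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        tm <- readRDS(need_file(
          file.path(cfg$paths$workdir, "stats", sprintf("%s_tmaps.rds", g)),
          "step4a"
        ))
        adj_cfg <- cfg$stats$adjacency
        adj <- build_adjacency(tm$channels, mode = adj_cfg$mode,
                               param = adj_cfg$param, pairs = adj_cfg$pairs)
        cr <- cluster_permutation_test(
          tm, adj, n_perm = cfg$stats$n_permutations,
          cluster_alpha = cfg$stats$cluster_alpha,
          sample_alpha = cfg$stats$sample_alpha,
          seed = cfg$seed + 7919L * gi
        )
        saveRDS(cr, wpath(cfg, "stats", sprintf("%s_cluster.rds", g)))
        jsonlite::write_json(
          tidy.cluster_result(cr),
          wpath(cfg, "stats", sprintf("%s_clusters.json", g)),
          auto_unbox = TRUE, digits = NA
        )
        res[[g]] <- cr
      }
      res
    },
    step4c = {
      specs <- list()
      for (g in groups) {
        cr <- readRDS(need_file(
          file.path(cfg$paths$workdir, "stats", sprintf("%s_cluster.rds", g)),
          "step4b"
        ))
        ga_wi <- readRDS(need_file(
          file.path(cfg$paths$workdir, "ga", sprintf("%s_within_item.rds", g)),
          "step2"
        ))
        ga_wc <- readRDS(need_file(
          file.path(cfg$paths$workdir, "ga", sprintf("%s_within_category.rds", g)),
          "step2"
        ))
        sp <- extract_cluster_means(ga_wi, ga_wc, cr)
        if (inherits(sp, "no_mask")) {
          message("group ", g, ": ", sp$message, "; skipping extraction")
        } else {
          saveRDS(sp, wpath(cfg, "spec", sprintf("%s_specificity.rds", g)))
          specs[[g]] <- sp
        }
      }
      cmp <- NULL
      if (length(specs) >= 2) {
        cmp <- compare_groups(specs[[1]], specs[[2]])
        jsonlite::write_json(
          list(groups = names(specs)[1:2], comparison = cmp),
          wpath(cfg, "spec", "group_comparison.json"),
          auto_unbox = TRUE, digits = NA
        )
      }
      list(specificity = specs, comparison = cmp)
    },
    step5 = {
      figs <- character()
      for (g in groups) {
        cr <- readRDS(need_file(
          file.path(cfg$paths$workdir, "stats", sprintf("%s_cluster.rds", g)),
          "step4b"
        ))
        figs <- c(
          figs,
          render_figure("cluster_extent", cr,
                        wpath(cfg, "fig", sprintf("cluster_extent_%s.png", g))),
          render_figure("topography", cr,
                        wpath(cfg, "fig", sprintf("topography_%s.png", g)))
        )
      }
      list(figures = figs)
    },
    step6 = {
      specs <- load_specificities(cfg, groups)
      fig <- render_figure("group_comparison", specs,
                           wpath(cfg, "fig", "group_comparison.png"))
      list(figures = fig)
    },
    step7 = {
      specs <- load_specificities(cfg, groups)
      all_spec <- dplyr::bind_rows(lapply(specs, tibble::as_tibble))
      beh <- if (!is.null(cfg$behavior$csv)) {
        tibble::as_tibble(utils::read.csv(cfg$behavior$csv))
      } else {
        generate_memory_scores(all_spec, r_target = cfg$behavior$r_target,
                               seed = cfg$seed + 27644437 %% 1e6)
      }
      utils::write.csv(beh, wpath(cfg, "behavior.csv"), row.names = FALSE)
      cors <- correlate_specificity_memory(all_spec, beh)
      jsonlite::write_json(cors, wpath(cfg, "spec", "memory_correlations.json"),
                           auto_unbox = TRUE, digits = NA)
      fig <- render_figure("scatter", list(spec = all_spec, behavior = beh),
                           wpath(cfg, "fig", "memory_scatter.png"))
      list(correlations = cors, figure = fig)
    }
  )
  write_provenance(cfg, step_id)
  invisible(out)
}

load_specificities <- function(cfg, groups) {
  specs <- list()
  for (g in groups) {
    f <- file.path(cfg$paths$workdir, "spec", sprintf("%s_specificity.rds", g))
    if (file.exists(f)) specs[[g]] <- readRDS(f)
  }
  if (!length(specs)) {
    stop("no specificity summaries found: run step4c first", call. = FALSE)
  }
  specs
}

#' Reproduce the reference analysis on the archived sample dataset
#'
#' Runs the complete pipeline (import, preprocessing, RSA, three-level
#' cluster statistics, group comparison, memory correlation) on the openly
#' archived child/adult EEG sample data, which must be downloaded
#' separately and is not bundled (it is a multi-gigabyte MAT deposit). The
#' directory must contain per-subject FieldTrip TFR MAT files under
#' `children/` and `adults/` and a behavior table `item_memory.csv`
#' (`subject_id`, `group`, `item_memory`).
#'
#' Exact cluster counts are sensitive to the channel-neighbour definition
#' and time-time connectivity conventions, which the reference description
#' leaves open; the scalar group-comparison t and the correlations are the
#' robust quantities.
#'
#' @param data_dir Directory holding the downloaded deposit, arranged as
#'   above.
#' @param config Optional [read_run_config()] overrides.
#' @return List with per-group `cluster_result`s, the group comparison
#'   tibble and the memory correlations.
#' @export
run_sample_reproduction <- function(data_dir, config = list()) {
  if (!dir.exists(data_dir)) {
    stop("sample dataset directory not found: ", data_dir,
         "\nDownload the archived deposit and arrange it as documented ",
         "in ?run_sample_reproduction")
  }
  cfg <- read_run_config(config)
  results <- list(clusters = list(), specificity = list())
  for (g in c("children", "adults")) {
    mats <- list.files(file.path(data_dir, g), pattern = "\\.mat$",
                       full.names = TRUE)
    if (!length(mats)) stop("no MAT files under ", file.path(data_dir, g))
    wi <- list(); wc <- list(); swi <- list(); swc <- list()
    for (f in mats) {
      ds <- import_fieldtrip_mat(
        f, trialinfo_map = unlist(cfg$data$trialinfo_map),
        subject_id = tools::file_path_sans_ext(basename(f)), group = g
      )
      ds <- preprocess_tfr(ds, mode = cfg$rsa$background_mode)
      a <- compute_subject_similarity(ds, "within_item", cfg$rsa$method)
      b <- compute_subject_similarity(ds, "within_category", cfg$rsa$method)
      wi <- c(wi, list(a)); wc <- c(wc, list(b))
      swi <- c(swi, list(average_subject(a))); swc <- c(swc, list(average_subject(b)))
    }
    tm <- first_level_tmaps(wi, wc)
    adj <- build_adjacency(tm$channels, mode = cfg$stats$adjacency$mode,
                           param = cfg$stats$adjacency$param,
                           pairs = cfg$stats$adjacency$pairs)
    cr <- cluster_permutation_test(tm, adj, n_perm = cfg$stats$n_permutations,
                                   cluster_alpha = cfg$stats$cluster_alpha,
                                   sample_alpha = cfg$stats$sample_alpha,
                                   seed = cfg$seed)
    results$clusters[[g]] <- cr
    sp <- extract_cluster_means(grand_average(swi, group = g),
                                grand_average(swc, group = g), cr)
    if (!inherits(sp, "no_mask")) results$specificity[[g]] <- sp
  }
  if (length(results$specificity) == 2) {
    results$comparison <- compare_groups(results$specificity[[1]],
                                         results$specificity[[2]])
  }
  beh_file <- file.path(data_dir, "item_memory.csv")
  if (file.exists(beh_file) && length(results$specificity)) {
    all_spec <- dplyr::bind_rows(lapply(results$specificity, tibble::as_tibble))
    results$memory_correlations <- correlate_specificity_memory(
      all_spec, tibble::as_tibble(utils::read.csv(beh_file))
    )
  }
  results
}
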