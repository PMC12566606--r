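#' Read a metric table from CSV
#'
#' @param path CSV path.
#' @param required character vector of columns that must be present; a
#'   missing column is an error listing all the missing names.
#' @return data.frame.
#' @export
read_metric_csv <- function(path, required = c("group")) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("missing required column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  d
}

#' Write a metric table to CSV (lossless round-trip with [read_metric_csv()])
#'
#' @param data data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

## Build per-group scene_params from a config group block (a named list of
## scene_params overrides).
config_group_params <- function(groups, field = list()) {
  lapply(groups, function(g) do.call(scene_params, utils::modifyList(field, as.list(g))))
}

#' Load and validate a pipeline run configuration
#'
#' A run configuration is a YAML file (or an equivalent list) with fields:
#' `seed`, `out`, `n_fields`, `animals_per_group`, `alpha`,
#' `threshold_mode`, `modalities` (subset of `"he"`, `"ihc"`), a `field`
#' block of shared [scene_params()] overrides, and a `groups` block mapping
#' each group label to its own overrides (e.g. `target_dab_fraction`,
#' `n_droplets`).
#'
#' @param config path to a YAML file or a list.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(seed = 1L, n_fields = 5L, animals_per_group = 5L,
                   alpha = 0.05, threshold_mode = "shared-otsu",
                   modalities = c("he", "ihc"), field = list(), out = NULL)
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$groups) || length(cfg$groups) < 2)
    stop("config must define at least 2 groups")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (!all(cfg$modalities %in% c("he", "ihc")))
    stop("modalities must be a subset of 'he', 'ihc'")
  if (!cfg$threshold_mode %in% c("shared-otsu", "otsu", "fixed"))
    stop("unknown threshold_mode: ", cfg$threshold_mode)
  structure(cfg, class = "run_config")
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full simulate -> quantify -> statistics pipeline
#'
#' Simulates per-group synthetic fields for each requested modality, writes
#' the images and ground truth, quantifies every field (H&E morphometry
#' and/or DAB percent-positive area with a threshold uniformly applied
#' across the batch), runs ANOVA + Tukey HSD per metric, and writes
#' `he_metrics.csv` / `ihc_metrics.csv`, `stats.csv`, bar-chart figures
#' with mean +/- SD and pairwise significance, and a `manifest.yaml`
#' recording the seed, configuration and file checksums. Two runs with the
#' same configuration and seed produce byte-identical CSVs.
#'
#' @param config a config list or YAML path (see [read_run_config()]).
#' @param out output directory; overrides `config$out`.
#' @param seed integer seed; overrides `config$seed`.
#' @return Invisibly, a list with the metric tables, the stats table and
#'   the paths of all written files.
#' @export
run_full <- function(config, out = NULL, seed = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(out)) cfg$out <- out
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$out)) stop("an output directory must be given (config$out or out =)")
  if (!dir.exists(cfg$out) && !dir.create(cfg$out, recursive = TRUE))
    stop("cannot create output directory: ", cfg$out)
  group_params <- config_group_params(cfg$groups, cfg$field)
  files <- character(0)
  metrics <- list()
  stats_inputs <- list()

  for (mod in cfg$modalities) {
    img_dir <- file.path(cfg$out, paste0(mod, "_fields"))
    gt <- run_stage(paste0("simulate-", mod), cfg$out,
      generate_group_set(group_params, cfg$n_fields,
                         base_seed = cfg$seed + ifelse(mod == "ihc", 0L, 500000L),
                         out_dir = img_dir, modality = mod,
                         animals_per_group = cfg$animals_per_group))
    paths <- file.path(img_dir, gt$file)
    qt <- run_stage(paste0("quantify-", mod), cfg$out, {
      if (mod == "ihc") {
        q <- quantify_ihc_batch(paths, threshold_mode = cfg$threshold_mode,
                                fixed_value = cfg$fixed_threshold)
      } else {
        q <- quantify_he_batch(paths)
      }
      cbind(gt[, c("group", "animal")], q)
    })
    mpath <- file.path(cfg$out, paste0(mod, "_metrics.csv"))
    write_metric_csv(qt, mpath)
    files <- c(files, mpath)
    metrics[[mod]] <- qt
    stats_inputs[[mod]] <- qt
  }

  metric_cols <- c(he = list(c("rbc_area_pct", "fat_count", "fat_area_pct")),
                   ihc = list("dab_pos_pct"))
  stats_rows <- list()
  for (mod in names(stats_inputs)) {
    st <- run_stage(paste0("stats-", mod), cfg$out,
      compare_all_metrics(stats_inputs[[mod]], metrics = metric_cols[[mod]],
                          alpha = cfg$alpha))
    if (nrow(st)) stats_rows[[mod]] <- st
  }
  stats_tab <- do.call(rbind, stats_rows)
  rownames(stats_tab) <- NULL
  spath <- file.path(cfg$out, "stats.csv")
  write_metric_csv(stats_tab, spath)
  files <- c(files, spath)

  plot_paths <- run_stage("plots", cfg$out, {
    pp <- character(0)
    for (mod in names(stats_inputs)) {
      for (m in metric_cols[[mod]]) {
        p <- file.path(cfg$out, paste0("fig_", m, ".png"))
        plot_group_metric(stats_inputs[[mod]], m, stats_tab, path = p)
        pp <- c(pp, p)
      }
    }
    pp
  })

  manifest <- list(
    package = "hepatoquant",
    version = as.character(utils::packageVersion("hepatoquant")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = unclass(cfg),
    csv_md5 = as.list(tools::md5sum(files)))
  writeLines(yaml::as.yaml(manifest), file.path(cfg$out, "manifest.yaml"))
  files <- c(files, file.path(cfg$out, "manifest.yaml"))

  invisible(list(metrics = metrics, stats = stats_tab, files = files,
                 plots = plot_paths, config = cfg))
}

#' Bar chart of a per-group metric with mean, SD and significance
#'
#' Base-graphics bar chart of group means with SD error bars; pairs flagged
#' significant in the stats table are annotated with brackets and the
#' conventional star codes (* p < 0.05, ** p < 0.01, *** p < 0.001,
#' **** p < 0.0001).
#'
#' @param data per-field metric data.frame with a `group` column.
#' @param metric metric column name.
#' @param stats_tab optional long stats table from [compare_all_metrics()].
#' @param path optional PNG output path; when NULL, plots to the active
#'   device.
#' @return `path` (or NULL), invisibly.
#' @export
plot_group_metric <- function(data, metric, stats_tab = NULL, path = NULL) {
  g <- factor(data$group)
  m <- tapply(data[[metric]], g, mean)
  s <- tapply(data[[metric]], g, stats::sd)
  s[is.na(s)] <- 0
  if (!is.null(path)) grDevices::png(path, width = 900, height = 650, res = 120)
  sig <- NULL
  if (!is.null(stats_tab)) {
    sig <- stats_tab[stats_tab$metric == metric & stats_tab$significant, ,
                     drop = FALSE]
  }
  n_br <- if (is.null(sig)) 0 else nrow(sig)
  top <- max(m + s)
  ylim <- c(0, top * (1.15 + 0.12 * n_br))
  bp <- graphics::barplot(m, ylim = ylim, ylab = metric, col = "grey80",
                          border = "grey30", main = metric)
  has_sd <- s > 0
  if (any(has_sd))   # sub-pixel whiskers would warn about zero-length arrows
    suppressWarnings(
      graphics::arrows(bp[has_sd], (m - s)[has_sd], bp[has_sd], (m + s)[has_sd],
                       angle = 90, code = 3, length = 0.05))
  if (n_br > 0) {
    stars <- function(p) if (p < 1e-4) "****" else if (p < 1e-3) "***"
                         else if (p < 1e-2) "**" else "*"
    lev <- levels(g)
    for (i in seq_len(n_br)) {
      y <- top * (1.08 + 0.12 * (i - 1))
      x1 <- bp[match(sig$group_a[i], lev)]
      x2 <- bp[match(sig$group_b[i], lev)]
      graphics::segments(x1, y, x2, y)
      graphics::text((x1 + x2) / 2, y, stars(sig$p_adj[i]), pos = 3, cex = 0.9)
    }
  }
  if (!is.null(path)) grDevices::dev.off()
  invisible(path)
}
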