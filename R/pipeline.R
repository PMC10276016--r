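#' Default pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]: cohort sizes and
#' seeds, scan geometry, morphometry settings and statistics options. The
#' default cohort sizes mirror the normative study design (92 control
#' left eyes, 37 preterm eyes). A single top-level seed fans out to
#' per-stage seeds drawn from it, so stages can be rerun independently
#' yet the whole pipeline is deterministic.
#'
#' @param seed Top-level integer seed.
#' @param n_control,n_ept Cohort sizes.
#' @param out_dir Output directory.
#' @param smooth_window,search_halfwidth_um,rim_window_um Morphometry
#'   settings (see [extract_foveal_metrics()]).
#' @param render_examples Render one speckled example B-scan per group.
#' @param make_figures Write correlation heatmap PNGs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 20260101L,
                            n_control = 92L,
                            n_ept = 37L,
                            out_dir = tempfile("fovmorph_run_"),
                            smooth_window = 5L,
                            search_halfwidth_um = 750,
                            rim_window_um = c(300, 3000),
                            render_examples = FALSE,
                            make_figures = TRUE) {
  structure(list(seed = as.integer(seed), n_control = as.integer(n_control),
                 n_ept = as.integer(n_ept), out_dir = out_dir,
                 smooth_window = as.integer(smooth_window),
                 search_halfwidth_um = search_halfwidth_um,
                 rim_window_um = rim_window_um,
                 render_examples = isTRUE(render_examples),
                 make_figures = isTRUE(make_figures)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the
#' [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

# deterministic per-stage seed derivation from the top-level seed
.stage_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  stats::setNames(s, c("control", "ept", "asym", "render"))
}

#' Run the full simulate-extract-analyze pipeline
#'
#' End-to-end pipeline: (1) simulate per-eye target metrics for a control
#' and a preterm cohort; (2) build ground-truth boundaries for every eye
#' and re-extract the metrics with the morphometry module; (3) compute
#' normative limits from the extracted control metrics, classify the
#' preterm eyes, and produce the summary table, layer proportions,
#' per-group correlation matrices and the covariate subgroup comparison
#' (from built-in summary statistics). All CSV outputs are deterministic
#' under a fixed config; figures are regenerable artifacts excluded from
#' bit-exactness.
#'
#' Files written to `config$out_dir`: `control_metrics.csv`,
#' `ept_metrics.csv` (extracted), `*_targets.csv` (simulated targets),
#' `limits.csv`, `classification.csv`, `summary_table.csv`,
#' `proportions.csv`, `correlation_<group>.csv` and `_long.csv`,
#' `covariate_comparison.csv`, `provenance.json`, and optionally
#' `figures/`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`control`,
#'   `ept`, `limits`, `classification`, `summary_table`, `proportions`,
#'   `correlations`, `covariates`, `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- .stage_seeds(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (config$n_control < 10 || config$n_ept < 10)
    warning("small cohort size(s): normative limits from n < 10 controls ",
            "are unstable")

  # -- simulate ------------------------------------------------------------
  sim <- stage("simulate", {
    ctrl_spec <- cohort_spec("control", n_eyes = config$n_control,
                             seed = seeds[["control"]],
                             laterality_policy = "all-left")
    ept_spec <- cohort_spec("ept_norop", n_eyes = config$n_ept,
                            seed = seeds[["ept"]],
                            laterality_policy = "mixed")
    list(control = sample_cohort_metrics(ctrl_spec),
         ept = sample_cohort_metrics(ept_spec))
  })
  utils::write.csv(sim$control, file.path(out, "control_targets.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$ept, file.path(out, "ept_targets.csv"),
                   row.names = FALSE)

  # -- extract -------------------------------------------------------------
  extract_cohort <- function(targets) {
    rows <- lapply(seq_len(nrow(targets)), function(i) {
      bset <- build_boundaries(targets[i, ])
      extract_foveal_metrics(
        bset, smooth_window = config$smooth_window,
        search_halfwidth_um = config$search_halfwidth_um,
        rim_window_um = config$rim_window_um,
        group_label = targets$group_label[i])
    })
    do.call(rbind, rows)
  }
  ctrl <- stage("extract", extract_cohort(sim$control))
  ept <- stage("extract", extract_cohort(sim$ept))
  utils::write.csv(ctrl, file.path(out, "control_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(ept, file.path(out, "ept_metrics.csv"),
                   row.names = FALSE)

  if (config$render_examples) stage("render", {
    for (g in c("control", "ept")) {
      targets <- if (g == "control") sim$control else sim$ept
      bset <- build_boundaries(targets[1, ])
      bsc <- render_bscan(bset, noise_level = 0.2,
                          seed = seeds[["render"]])
      write_bscan_image(bsc, file.path(out, paste0("example_", g, ".png")))
    }
  })

  # -- analyze -------------------------------------------------------------
  res <- stage("analyze", {
    limits <- compute_limits(ctrl)
    cls <- classify_eyes(ept, limits)
    tab <- summary_table(ctrl, ept, limits)
    both <- rbind(ctrl, ept)
    props <- layer_proportions(both)
    cors <- list(control = correlation_matrix(ctrl),
                 ept_norop = correlation_matrix(ept))
    cov <- prematurity_covariates()
    cov_rows <- lapply(seq_len(nrow(cov)), function(i) {
      w <- group_compare_summary(cov$mean_outside[i], cov$sd_outside[i],
                                 cov$n_outside[i], cov$mean_within[i],
                                 cov$sd_within[i], cov$n_within[i])
      data.frame(variable = cov$variable[i], unit = cov$unit[i],
                 mean_outside = cov$mean_outside[i],
                 sd_outside = cov$sd_outside[i],
                 mean_within = cov$mean_within[i],
                 sd_within = cov$sd_within[i],
                 t = w$t, df = w$df, p = round(w$p, 3),
                 stringsAsFactors = FALSE)
    })
    list(limits = limits, classification = cls, summary_table = tab,
         proportions = props, correlations = cors,
         covariates = do.call(rbind, cov_rows))
  })

  utils::write.csv(res$limits, file.path(out, "limits.csv"),
                   row.names = FALSE)
  utils::write.csv(res$classification$calls,
                   file.path(out, "classification.csv"), row.names = FALSE)
  utils::write.csv(res$classification$summary,
                   file.path(out, "classification_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$summary_table, file.path(out, "summary_table.csv"),
                   row.names = FALSE)
  utils::write.csv(res$proportions$summary,
                   file.path(out, "proportions.csv"), row.names = FALSE)
  for (g in names(res$correlations)) {
    cm <- res$correlations[[g]]
    utils::write.csv(as.data.frame(cm$r),
                     file.path(out, paste0("correlation_", g, ".csv")))
    utils::write.csv(correlation_long(cm),
                     file.path(out, paste0("correlation_", g, "_long.csv")),
                     row.names = FALSE)
  }
  utils::write.csv(res$covariates,
                   file.path(out, "covariate_comparison.csv"),
                   row.names = FALSE)

  if (config$make_figures) stage("figures", {
    fig_dir <- file.path(out, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    for (g in names(res$correlations))
      .heatmap_png(res$correlations[[g]],
                   file.path(fig_dir, paste0("correlation_", g, ".png")),
                   title = paste("Pearson correlations,", g))
  })

  # -- provenance ----------------------------------------------------------
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(
    list(seed = config$seed, stage_seeds = as.list(seeds),
         config_md5 = unname(tools::md5sum(cfg_path)),
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("fovmorph")),
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out, "provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(control = ctrl, ept = ept, limits = res$limits,
                 classification = res$classification,
                 summary_table = res$summary_table,
                 proportions = res$proportions,
                 correlations = res$correlations,
                 covariates = res$covariates, out_dir = out))
}

# simple correlation heatmap; figures are convenience artifacts only
.heatmap_png <- function(cm, path, title = "") {
  grDevices::png(path, width = 720, height = 640)
  on.exit(grDevices::dev.off())
  k <- nrow(cm$r)
  pal <- grDevices::colorRampPalette(c("#2166ac", "white", "#b2182b"))(101)
  graphics::par(mar = c(6, 6, 3, 2))
  graphics::image(seq_len(k), seq_len(k), t(cm$r[k:1, ]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", main = title)
  graphics::axis(1, at = seq_len(k), labels = colnames(cm$r), las = 2)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(cm$r)), las = 1)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    lab <- sprintf("%.2f%s", cm$r[i, j],
                   if (isTRUE(cm$significant[i, j])) "*" else "")
    graphics::text(j, k + 1 - i, lab, cex = 0.9)
  }
}
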