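#' Pipeline run configuration
#'
#' A validated, serializable description of a full synthetic run:
#' phantom geometry, acquisition scheme, kernel parameters, noise, cohort
#' effect specification, metric configuration and statistical options.
#' Every stochastic stage must carry an explicit seed; validation fails
#' before any stage runs otherwise.
#'
#' @param ... named overrides of the default configuration (nested lists
#'   are merged field-by-field).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- default_run_config()
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  cfg <- modifyList(cfg, over)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

default_run_config <- function() {
  list(
    seeds = list(scheme = 1L, phantom = 2L, noise = 3L, cohort = 4L,
                 feature_importance = 5L),
    phantom = list(grid_shape = c(10L, 10L, 10L), voxel_size = 2,
                   n_bundles = 2L, streamlines_per_bundle = 20L,
                   add_decoy = TRUE,
                   noise_sigma = 0, noise_model = "gaussian"),
    scheme = list(shells = list(c(500, 30), c(1200, 30), c(2400, 60),
                                c(4000, 60), c(6000, 60)),
                  n_b0 = 14L),
    kernels = list(d_par = 1.7e-3, d_par_zep = 1.7e-3, d_perp = 0.61e-3,
                   d_iso_list = c(1.7e-3, 3.0e-3)),
    cohort = list(n = 88L, age_range = c(8, 19), n_female = NULL,
                  nodes_per_group = 4L,
                  effects = list(baseline = 0.3, age_slope = 0,
                                 sex_offset = 0, age_sex_slope = 0,
                                 edge_sd = 0.05, subject_sd = 0.02)),
    metrics = list(gamma = 1, which = c("modularity", "global_efficiency",
                                        "clustering", "mean_strength",
                                        "local_efficiency", "density")),
    stats = list(metric = "mean_strength", alpha = 0.005,
                 feature_group = "visual",
                 l1_grid = c(0.1, 0.5, 0.7, 0.9, 0.95, 0.99, 1),
                 split = 0.8, k_folds = 5L),
    out_dir = "micoconn_run"
  )
}

validate_run_config <- function(cfg) {
  needed <- c("scheme", "phantom", "noise", "cohort", "feature_importance")
  missing <- setdiff(needed, names(cfg$seeds))
  if (length(missing) > 0 || any(vapply(cfg$seeds[needed], is.null, logical(1)))) {
    stop_invalid("config must provide a seed for every stochastic stage (",
                 paste(missing, collapse = ", "), " missing)")
  }
  if (is.null(cfg$out_dir)) stop_invalid("config must name an output directory")
  invisible(cfg)
}

#' Load / save a run configuration as YAML
#' @param path YAML file path.
#' @rdname run_config
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' @param cfg a `run_config`.
#' @rdname run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Executes phantom generation, signal synthesis (plus optional noise),
#' deconvolution, connectome construction (IASF and NOS weighted), cohort
#' simulation, metric tables, the mixed-model/per-network statistical
#' analysis and elastic-net feature importance, writing every intermediate
#' artifact under `config$out_dir` and returning a manifest (file list
#' with checksums, seeds, package version). Rerunning with the same
#' configuration reproduces identical outputs. A stage failure aborts
#' with the stage name; artifacts written so far are kept.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_all <- function(config = run_config()) {
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  logf <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    logf(name, "start")
    tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  sch <- stage("scheme", make_scheme(config$scheme$shells,
                                     n_b0 = config$scheme$n_b0,
                                     seed = config$seeds$scheme))
  write_gradient_table(sch, file.path(out, "scheme"))

  params <- do.call(kernel_params, config$kernels)
  ph_cfg <- config$phantom
  grid <- voxel_grid(ph_cfg$grid_shape, ph_cfg$voxel_size)
  ph <- stage("phantom", make_crossing_phantom(
    grid, n_bundles = ph_cfg$n_bundles,
    streamlines_per_bundle = ph_cfg$streamlines_per_bundle,
    seed = config$seeds$phantom, add_decoy = isTRUE(ph_cfg$add_decoy)))
  write_tck(ph$tractogram, file.path(out, "phantom.tck"))
  write_nifti_volume(ph$parcellation$labels + 0, grid,
                     file.path(out, "parcellation.nii.gz"))

  sig <- stage("signal", {
    s <- simulate_signal(ph$tractogram, ph$ground_truth, grid, sch, params)
    if (ph_cfg$noise_sigma > 0) {
      s <- add_noise(s, ph_cfg$noise_sigma, ph_cfg$noise_model,
                     seed = config$seeds$noise)
    }
    s
  })
  write_nifti_volume(sig, grid, file.path(out, "signal.nii.gz"))

  weights <- stage("deconvolution", {
    op <- build_operator(ph$tractogram, grid, sch, params)
    filter_streamlines(solve_nnls(op, sig))
  })
  write_weights(weights, file.path(out, "weights.csv"))

  stage("connectome", {
    conn_iasf <- build_connectome(ph$tractogram, weights, ph$parcellation, "IASF")
    conn_nos <- build_connectome(ph$tractogram, weights, ph$parcellation, "NOS")
    write_connectome(conn_iasf, file.path(out, "connectome_iasf.csv"))
    write_connectome(conn_nos, file.path(out, "connectome_nos.csv"))
  })

  co_cfg <- config$cohort
  assign <- default_assignment(nodes_per_group = co_cfg$nodes_per_group)
  eff <- do.call(effect_spec, c(list(groups = canonical_networks()),
                                co_cfg$effects))
  # default female count keeps the 46/88 design proportion at any n
  n_female <- co_cfg$n_female %||% round(co_cfg$n * 46 / 88)
  cohort <- stage("cohort", simulate_cohort(
    co_cfg$n, assign, eff, age_range = co_cfg$age_range,
    n_female = n_female, seed = config$seeds$cohort))
  write_cohort(cohort, file.path(out, "cohort"))
  write_assignment(assign, file.path(out, "assignment.tsv"))

  mcfg <- metric_config(gamma = config$metrics$gamma)
  tab <- stage("metrics", compute_metric_table(cohort, assign, mcfg,
                                               metrics = config$metrics$which))
  write_metric_table(tab, file.path(out, "metrics.csv"))

  st <- config$stats
  stats_out <- stage("stats", {
    fits <- fit_metric_lmm(tab, metric = st$metric)
    best <- select_model(fits)
    glms <- lapply(setdiff(unique(tab$group), "whole_brain"), function(g) {
      per_network_glm(tab, g, st$metric, alpha = st$alpha)
    })
    write_model_fits(c(fits, glms), file.path(out, "model_fits.csv"))
    list(selected = best$label,
         glm_significant = vapply(glms, function(f) f$meta$significant,
                                  logical(1)))
  })

  fi <- stage("feature_importance", {
    feats <- node_local_efficiency(cohort, assign, st$feature_group, mcfg)
    ages <- vapply(cohort, `[[`, numeric(1), "age")
    elasticnet_feature_importance(feats, ages, split = st$split,
                                  l1_grid = st$l1_grid,
                                  k_folds = st$k_folds,
                                  seed = config$seeds$feature_importance)
  })
  write_feature_importance(fi, file.path(out, "feature_importance.csv"))

  # run.log carries wall-clock timestamps, so it stays out of the checksum
  # list: the manifest describes the deterministic artifacts
  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        c("manifest.json", "run.log")))
  manifest <- list(
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(file.path(out, f))))
    }),
    seeds = config$seeds,
    selected_model = stats_out$selected,
    version = as.character(utils::packageVersion("micoconn"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("done", paste(length(files), "artifacts"))
  invisible(manifest)
}
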