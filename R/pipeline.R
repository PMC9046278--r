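stage_log <- function(verbose, fmt, ...) {
  if (verbose) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate-or-load, optional fusion feature construction,
#' two-step cross-validated penalty tuning, the structured sparse multiset
#' fit, per-component permutation testing, and report writing.  All
#' randomness flows from `config$seed`, so rerunning the same configuration
#' reproduces every numeric output.
#'
#' Configuration (a named list, or a YAML file path via [read_run_config()]):
#' \describe{
#'   \item{seed}{integer, required.}
#'   \item{output_dir}{where artifacts are written (required).}
#'   \item{simulate}{list passed to [gen_multiset()]; mutually exclusive
#'     with `data`.}
#'   \item{data}{list with `paths` (delimited matrices) and optional
#'     `graph_paths`.}
#'   \item{fusion}{optional list with `eeg`, `eeg_markers`, `fnirs`,
#'     `fnirs_markers`, `roi_map` paths plus [assemble_fusion_matrices()]
#'     settings; its output replaces/augments the datasets.}
#'   \item{tune}{optional list: `alpha_grid`, `lambda_grid`, `folds`,
#'     `repeats`; omit to skip CV and use `penalties`.}
#'   \item{penalties}{list with `lambda`, `alpha` (used when `tune` absent).}
#'   \item{fit}{list: `n_components` (default 4), `restarts`, `tol`,
#'     `max_sweeps`.}
#'   \item{permtest}{optional list: `n_perm` (default 99).}
#'   \item{baselines}{if `TRUE`, also write the mCCA/smCCA/ssmCCA
#'     comparison table.}
#' }
#'
#' @param config Named list (see Details) or path to a YAML file.
#' @param verbose Log each stage with parameters and timing.
#' @return Invisibly, a list with the fitted model, the `component_report`,
#'   selected penalties and output paths.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  if (is.null(config$output_dir)) {
    stop("config$output_dir is required", call. = FALSE)
  }
  seed <- as.integer(config$seed)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  # --- inputs: simulate or load ------------------------------------------
  graphs <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- seed
    sim_args$feature_counts <- as.integer(unlist(sim_args$feature_counts))
    stage_log(verbose, "simulate: n=%s, p=(%s), seed=%d",
              sim_args$n_samples,
              paste(sim_args$feature_counts, collapse = ","), seed)
    sim <- do.call(gen_multiset, sim_args)
    datasets <- sim$datasets
    graphs <- sim$truth$graphs
    for (k in seq_along(datasets)) {
      write_feature_matrix(datasets[[k]],
                           file.path(out_dir, sprintf("dataset_%d.tsv", k)))
    }
  } else if (!is.null(config$data)) {
    stage_log(verbose, "load: %d dataset file(s)",
              length(config$data$paths))
    datasets <- lapply(config$data$paths, read_feature_matrix)
    if (!is.null(config$data$graph_paths)) {
      graphs <- lapply(config$data$graph_paths, read_feature_graph)
    }
  } else if (is.null(config$fusion)) {
    stop("config needs one of simulate/data/fusion", call. = FALSE)
  } else {
    datasets <- NULL
  }

  # --- optional fusion feature construction ------------------------------
  if (!is.null(config$fusion)) {
    fu <- config$fusion
    stage_log(verbose, "fuse-features: band=(%s), target=%s",
              paste(fu$band %||% c(8, 13), collapse = "-"),
              fu$target_samples %||% 300)
    fused <- assemble_fusion_matrices(
      eeg = read_timeseries(fu$eeg),
      eeg_markers = read_markers(fu$eeg_markers),
      fnirs = read_timeseries(fu$fnirs),
      fnirs_markers = read_markers(fu$fnirs_markers),
      roi_map = read_roi_map(fu$roi_map),
      band = fu$band %||% c(8, 13),
      eeg_window = fu$eeg_window %||% c(-1.5, 1.5),
      fnirs_window = fu$fnirs_window %||% c(-5, 25),
      target_samples = fu$target_samples %||% 300,
      invert_mode = fu$invert_mode %||% "reciprocal"
    )
    datasets <- list(fused$E, fused$N)
    graphs <- NULL
    write_feature_matrix(fused$E, file.path(out_dir, "E.tsv"))
    write_feature_matrix(fused$N, file.path(out_dir, "N.tsv"))
  }

  if (is.null(graphs)) {
    graphs <- lapply(datasets, adjacency_from_correlation)
  }

  fit_cfg <- config$fit %||% list()
  n_components <- fit_cfg$n_components %||% 4L
  restarts <- fit_cfg$restarts %||% 5L
  tol <- fit_cfg$tol %||% 1e-6
  max_sweeps <- fit_cfg$max_sweeps %||% 500L

  # --- penalty selection --------------------------------------------------
  if (!is.null(config$tune)) {
    tu <- config$tune
    stage_log(verbose, "tune: %d-fold x %d repeats",
              tu$folds %||% 3, tu$repeats %||% 3)
    cv <- two_step_cv(datasets, graphs = graphs,
                      alpha_grid = tu$alpha_grid %||% c(0, 0.1, 1, 10),
                      lambda_grid = tu$lambda_grid,
                      folds = tu$folds %||% 3L,
                      repeats = tu$repeats %||% 3L,
                      seed = seed)
    penalties <- cv$penalties
    utils::write.csv(rbind(cv$step1, cv$step2),
                     file.path(out_dir, "cv_grid.csv"), row.names = FALSE)
    stage_log(verbose, "tune: selected alpha=%g lambda=%g",
              cv$alpha, cv$lambda)
  } else {
    pn <- config$penalties %||% list(lambda = 0, alpha = 0)
    penalties <- penalty_config(unlist(pn$lambda) %||% 0,
                                unlist(pn$alpha) %||% 0)
  }

  # --- fit ----------------------------------------------------------------
  stage_log(verbose, "fit: %d component(s), %d restart(s)",
            n_components, restarts)
  fit <- suppressWarnings(ssmcca_fit(
    datasets, graphs = graphs, penalties = penalties,
    n_components = n_components, init_seed = seed, restarts = restarts,
    tol = tol, max_sweeps = max_sweeps
  ))

  # --- permutation significance ------------------------------------------
  p_values <- NULL
  if (!is.null(config$permtest)) {
    n_perm <- config$permtest$n_perm %||% 99L
    stage_log(verbose, "permtest: %d permutations per component", n_perm)
    p_values <- vapply(seq_len(n_components), function(ci) {
      pt <- permutation_pvalue(datasets, graphs = graphs,
                               penalties = penalties,
                               component_index = ci, n_perm = n_perm,
                               seed = seed, restarts = 2L)
      pt$p_value
    }, numeric(1))
  }

  # --- baselines (method-comparison table) --------------------------------
  if (isTRUE(config$baselines)) {
    stage_log(verbose, "fit-baselines: mCCA / smCCA / ssmCCA")
    cmp <- fit_baselines(datasets, graphs = graphs, penalties = penalties,
                         n_components = n_components, init_seed = seed,
                         restarts = restarts, tol = tol,
                         max_sweeps = max_sweeps)
    attr(cmp, "fits") <- NULL
    utils::write.csv(cmp, file.path(out_dir, "baseline_comparison.csv"),
                     row.names = FALSE)
  }

  paths <- write_report(fit, out_dir, p_values = p_values)
  report <- component_report(fit, p_values)
  cfg_used <- config
  cfg_used$selected_penalties <- list(lambda = penalties$lambda,
                                      alpha = penalties$alpha)
  jsonlite::write_json(cfg_used, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  stage_log(verbose, "done in %.1f s",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(fit = fit, report = report, penalties = penalties,
                 p_values = p_values, output_dir = out_dir,
                 paths = paths))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file path.
#' @return Named list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  yaml::read_yaml(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
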