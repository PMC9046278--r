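#' Labels of the features a component selects
#'
#' Feature selection reads the solver's sparse iterate (`weights_sparse`),
#' whose exact zeros are meaningful; additionally, entries more than an
#' order of magnitude below the largest absolute weight (`rel_tol`, default
#' 0.1) are not reported — the usual interpretive convention for sparse
#' loadings, where residual near-zero coefficients carry no meaning.
#'
#' @param component A `canonical_component`.
#' @param rel_tol Relative magnitude threshold.
#' @return Named list (per set) of selected feature labels.
#' @export
selected_features <- function(component, rel_tol = 0.1) {
  lapply(component$weights_sparse, function(w) {
    mx <- max(abs(w))
    if (mx == 0) return(character(0))
    names(w)[abs(w) > rel_tol * mx]
  })
}

#' Tabulate fitted components
#'
#' One row per component: index, cross-modality correlation (mean pairwise),
#' selected features per set, and optionally a permutation p-value.
#' Degenerate components are marked and their correlation left empty.
#'
#' @param fit An `ssmcca_result`.
#' @param p_values Optional numeric vector, one per component.
#' @return A data frame of class `component_report`.
#' @export
component_report <- function(fit, p_values = NULL) {
  rows <- lapply(fit$components, function(cp) {
    sel <- selected_features(cp)
    out <- data.frame(component = cp$index,
                      correlation = if (cp$degenerate) NA_real_
                                    else cp$mean_correlation,
                      degenerate = cp$degenerate)
    for (s in names(sel)) {
      out[[paste0("selected_", s)]] <- paste(sel[[s]], collapse = "; ")
    }
    out
  })
  rep <- do.call(rbind, rows)
  if (!is.null(p_values)) {
    rep$p_value <- rep_len(NA_real_, nrow(rep))
    rep$p_value[seq_along(p_values)] <- p_values
  }
  class(rep) <- c("component_report", "data.frame")
  rep
}

#' Write fit artifacts to disk
#'
#' Emits, under `dir`: per-component weight tables per set
#' (`weights_<set>_comp<n>.csv`, columns feature/weight/weight_sparse), the
#' pairwise-correlation table (`correlations.csv`), the component report
#' (`components.csv`, quoted so labels containing commas round-trip), and a
#' machine-readable run summary (`summary.json`: objective, sweeps, seed,
#' penalties).
#'
#' @param fit An `ssmcca_result`.
#' @param dir Output directory (created if missing).
#' @param p_values Optional per-component permutation p-values.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(fit, dir, p_values = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (length(fit$components) == 0) {
    p <- file.path(dir, "components.csv")
    utils::write.csv(data.frame(note = "no components"), p,
                     row.names = FALSE)
    return(invisible(p))
  }
  for (cp in fit$components) {
    for (s in names(cp$weights)) {
      p <- file.path(dir, sprintf("weights_%s_comp%d.csv", s, cp$index))
      utils::write.csv(
        data.frame(feature = names(cp$weights[[s]]),
                   weight = unname(cp$weights[[s]]),
                   weight_sparse = unname(cp$weights_sparse[[s]])),
        p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  cors <- do.call(rbind, lapply(fit$components, function(cp) {
    M <- nrow(cp$correlations)
    idx <- which(upper.tri(cp$correlations), arr.ind = TRUE)
    data.frame(component = cp$index,
               set_a = fit$set_ids[idx[, 1]], set_b = fit$set_ids[idx[, 2]],
               correlation = cp$correlations[idx])
  }))
  p <- file.path(dir, "correlations.csv")
  utils::write.csv(cors, p, row.names = FALSE)
  paths <- c(paths, p)
  rep <- component_report(fit, p_values)
  p <- file.path(dir, "components.csv")
  utils::write.csv(rep, p, row.names = FALSE)
  paths <- c(paths, p)
  summ <- list(
    set_ids = fit$set_ids,
    n_components = fit$n_components,
    init_seed = fit$init_seed,
    restarts = fit$restarts,
    tol = fit$tol,
    max_sweeps = fit$max_sweeps,
    penalties = list(lambda = fit$penalties$lambda,
                     alpha = fit$penalties$alpha),
    components = lapply(fit$components, function(cp) {
      list(index = cp$index, objective = cp$objective,
           sweeps = cp$convergence$sweeps,
           converged = cp$convergence$converged,
           degenerate = cp$degenerate,
           mean_correlation = if (cp$degenerate) NULL
                              else cp$mean_correlation)
    })
  )
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Compare the unregularized, sparse and structured-sparse solvers
#'
#' Fits mCCA, smCCA and ssmCCA on training rows with the supplied penalties
#' and reports each method's per-component correlation, on the training
#' rows and (optionally) on held-out rows — the layout of a
#' method-comparison figure.
#'
#' @param datasets List of `feature_matrix` objects/matrices (training
#'   rows).
#' @param graphs Feature graphs for the structured solver.
#' @param penalties A [penalty_config()] used by smCCA (its `lambda`) and
#'   ssmCCA (both weights).
#' @param test_datasets Optional held-out rows; adds `*_test` columns.
#' @param n_components Number of components.
#' @inheritParams ssmcca_fit
#' @return Data frame with one row per component and one column per method.
#' @export
fit_baselines <- function(datasets, graphs = NULL,
                          penalties = penalty_config(),
                          test_datasets = NULL, n_components = 4L,
                          init_seed = 1L, restarts = 5L, tol = 1e-6,
                          max_sweeps = 500L) {
  pen <- expand_penalties(penalties, length(datasets))
  fits <- list(
    mCCA = mcca_fit(datasets, n_components, init_seed, restarts, tol,
                    max_sweeps),
    smCCA = smcca_fit(datasets, penalty_config(pen$lambda, 0), n_components,
                      init_seed, restarts, tol, max_sweeps),
    ssmCCA = ssmcca_fit(datasets, graphs, penalty_config(pen$lambda,
                                                         pen$alpha),
                        n_components, init_seed, restarts, tol, max_sweeps)
  )
  out <- data.frame(component = seq_len(n_components))
  for (m in names(fits)) {
    out[[m]] <- vapply(fits[[m]]$components, function(cp) {
      if (cp$degenerate) NA_real_ else mean_abs_offdiag(cp$correlations)
    }, numeric(1))
    if (!is.null(test_datasets)) {
      out[[paste0(m, "_test")]] <- vapply(fits[[m]]$components, function(cp) {
        if (cp$degenerate) return(NA_real_)
        mean_abs_offdiag(suppressWarnings(
          holdout_correlation(cp, test_datasets)))
      }, numeric(1))
    }
  }
  attr(out, "fits") <- fits
  out
}
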