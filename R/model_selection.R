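#' Repeated k-fold assignments
#'
#' Per repeat, a partition of `1:n_samples` into `k` near-equal folds
#' (sizes differ by at most one).  Repeats use distinct shuffles;
#' everything is deterministic under `seed`.
#'
#' @param n_samples Number of samples.
#' @param k Number of folds (>= 2).
#' @param repeats Number of independent partitions.
#' @param seed Integer seed.
#' @return A list of length `repeats`; each element is an integer vector of
#'   fold ids in `1:k`, one per sample.
#' @export
kfold_split <- function(n_samples, k, repeats = 1L, seed = 1L) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n_samples) stop("k cannot exceed n_samples", call. = FALSE)
  lapply(seq_len(repeats), function(r) {
    ids <- integer(n_samples)
    ids[with_seed(seed + r - 1L, sample.int(n_samples))] <-
      rep_len(seq_len(k), n_samples)
    ids
  })
}

#' Held-out canonical correlations
#'
#' Applies trained weight vectors to held-out rows and returns the pairwise
#' correlation matrix of the test scores,
#' \eqn{\rho_{kl} = \mathrm{cor}(X_k^{test} w_k,\; X_l^{test} w_l)}.
#' A projection with (near) zero variance — e.g. from an all-zero weight
#' vector — yields `NA` in the affected entries and is flagged in the
#' `"undefined_sets"` attribute rather than propagating NaN.
#'
#' @param components A `canonical_component` (its `weights` are used) or a
#'   plain list of weight vectors, one per set.
#' @param test_datasets List of `feature_matrix` objects/matrices with
#'   feature labels matching the training sets.
#' @return Correlation matrix with attribute `undefined_sets`.
#' @export
holdout_correlation <- function(components, test_datasets) {
  ws <- if (inherits(components, "canonical_component")) {
    components$weights
  } else {
    components
  }
  test_datasets <- lapply(test_datasets, as_feature_matrix)
  M <- length(ws)
  if (length(test_datasets) != M) {
    stop("number of weight vectors and test sets must match", call. = FALSE)
  }
  scores <- matrix(NA_real_, nrow(test_datasets[[1]]$values), M)
  undefined <- logical(M)
  for (k in seq_len(M)) {
    w <- ws[[k]]
    d <- suppressWarnings(standardize_columns(test_datasets[[k]]))
    if (!is.null(names(w)) &&
        !identical(unname(names(w)), unname(d$feature_labels))) {
      if (!all(names(w) %in% d$feature_labels)) {
        stop(sprintf("feature labels of set %d do not match training labels",
                     k), call. = FALSE)
      }
      d$values <- d$values[, names(w), drop = FALSE]
    }
    s <- as.numeric(d$values %*% w)
    if (stats::sd(s) < 1e-12) undefined[k] <- TRUE else scores[, k] <- s
  }
  rho <- suppressWarnings(stats::cor(scores, use = "pairwise.complete.obs"))
  rho[undefined, ] <- NA_real_
  rho[, undefined] <- NA_real_
  diag(rho) <- ifelse(undefined, NA_real_, 1)
  attr(rho, "undefined_sets") <- which(undefined)
  rho
}

mean_abs_offdiag <- function(rho) {
  v <- rho[upper.tri(rho)]
  if (all(is.na(v))) NA_real_ else mean(abs(v), na.rm = TRUE)
}

# Score one penalty cell over all folds/repeats: mean train rho, mean test
# rho and mean absolute train/test gap of the first component.
score_cell <- function(datasets, graphs, lambda, alpha, fold_list,
                       init_seed, restarts, tol, max_sweeps,
                       recompute_graphs, edge_threshold) {
  gaps <- tr <- te <- numeric(0)
  for (r in seq_along(fold_list)) {
    folds <- fold_list[[r]]
    for (f in sort(unique(folds))) {
      train <- lapply(datasets, function(d) {
        feature_matrix(d$values[folds != f, , drop = FALSE],
                       d$feature_labels, d$set_id)
      })
      test <- lapply(datasets, function(d) {
        feature_matrix(d$values[folds == f, , drop = FALSE],
                       d$feature_labels, d$set_id)
      })
      gr <- graphs
      if (recompute_graphs && any(alpha > 0)) {
        gr <- lapply(train, adjacency_from_correlation,
                     edge_threshold = edge_threshold)
      }
      fit <- suppressWarnings(ssmcca_fit(
        train, graphs = gr, penalties = penalty_config(lambda, alpha),
        n_components = 1L, init_seed = init_seed, restarts = restarts,
        tol = tol, max_sweeps = max_sweeps
      ))
      cp <- fit$components[[1]]
      if (cp$degenerate) {
        gaps <- c(gaps, NA_real_); tr <- c(tr, NA_real_); te <- c(te, NA_real_)
        next
      }
      rho_tr <- mean_abs_offdiag(cp$correlations)
      rho_te <- mean_abs_offdiag(
        suppressWarnings(holdout_correlation(cp, test))
      )
      tr <- c(tr, rho_tr)
      te <- c(te, rho_te)
      gaps <- c(gaps, abs(rho_tr - rho_te))
    }
  }
  list(train = mean(tr), test = mean(te), gap = mean(gaps),
       gap_se = stats::sd(gaps) / sqrt(length(gaps)))
}

#' Default sparsity grid scaled to the cross-covariance
#'
#' Eight log-spaced values between `1e-3` and `0.8` times the largest
#' absolute cross-product entry between standardized sets.
#'
#' @param datasets List of `feature_matrix` objects/matrices.
#' @param length_out Grid size.
#' @return Numeric vector of candidate `lambda` values.
#' @export
default_lambda_grid <- function(datasets, length_out = 8L) {
  datasets <- prepare_datasets(datasets)
  M <- length(datasets)
  cmax <- 0
  for (k in seq_len(M - 1)) {
    for (l in (k + 1):M) {
      cmax <- max(cmax, max(abs(crossprod(datasets[[k]]$values,
                                          datasets[[l]]$values))))
    }
  }
  cmax * 10^seq(-3, log10(0.8), length.out = length_out)
}

#' Two-step cross-validated penalty selection
#'
#' Step 1 searches the smoothness weight `alpha` with `lambda = 0`; step 2
#' fixes the chosen `alpha` and searches `lambda`.  Each candidate is scored
#' by the mean (over folds and repeats) absolute difference between the
#' first component's training correlation and its held-out correlation, the
#' criterion being that a well-regularized model generalizes: train and
#' test correlations agree.  The criterion is only meaningful among models
#' that capture an association at all — an over-penalized model whose
#' training correlation has collapsed attains a near-zero gap trivially by
#' generalizing its own failure.  Cells whose training correlation is
#' degenerate in any fold, or falls below `min_train_frac` times the best
#' mean training correlation in the step, are therefore excluded before
#' the arg-min.
#'
#' @param datasets List of `feature_matrix` objects/matrices.
#' @param graphs Optional list of fixed `feature_graph`s.  When `NULL` and
#'   some `alpha > 0`, correlation graphs are recomputed inside each
#'   training fold.
#' @param alpha_grid,lambda_grid Nonnegative candidate vectors.
#'   `lambda_grid = NULL` uses [default_lambda_grid()] (log-spaced, scaled
#'   to the largest cross-covariance entry).  `alpha_grid = NULL` uses
#'   `c(0, 0.1, 1, 10)` divided by the largest Laplacian spectral radius
#'   across sets — the smoothness analogue of the same calibration, making
#'   the grid dimensionless in the graph's scale.
#' @param folds Number of folds (default 3).
#' @param repeats Number of repeated partitions (default 3).
#' @param seed Integer seed controlling folds and solver initialization.
#' @param restarts Random restarts per CV fit (kept small for speed; the
#'   final model is refit separately).
#' @param tol,max_sweeps Solver controls for the CV fits.
#' @param edge_threshold Threshold for fold-wise correlation graphs.
#' @param min_train_frac Cells whose mean training correlation is below
#'   this fraction of the step's best are excluded from selection.
#' @return An object of class `cv_result` with the full grid diagnostics
#'   (`step1`, `step2` data frames), `alpha`, `lambda` (selected),
#'   `fold_list`, `seed`.
#' @export
two_step_cv <- function(datasets, graphs = NULL, alpha_grid = NULL,
                        lambda_grid = NULL, folds = 3L, repeats = 3L,
                        seed = 1L, restarts = 2L, tol = 1e-5,
                        max_sweeps = 200L, edge_threshold = 0,
                        min_train_frac = 0.5) {
  datasets <- prepare_datasets(datasets)
  if (is.null(alpha_grid)) {
    cal_graphs <- if (is.null(graphs)) {
      lapply(datasets, adjacency_from_correlation,
             edge_threshold = edge_threshold)
    } else {
      graphs
    }
    lmax <- max(vapply(cal_graphs, function(G) {
      if (!inherits(G, "feature_graph")) G <- feature_graph(G)
      max(eigen(G$laplacian, symmetric = TRUE, only.values = TRUE)$values, 0)
    }, numeric(1)))
    alpha_grid <- c(0, 0.1, 1, 10) / max(lmax, 1e-12)
  }
  if (length(alpha_grid) < 1 || any(alpha_grid < 0)) {
    stop("alpha_grid must be nonempty and nonnegative", call. = FALSE)
  }
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(datasets)
  if (length(lambda_grid) < 1 || any(lambda_grid < 0)) {
    stop("lambda_grid must be nonempty and nonnegative", call. = FALSE)
  }
  n <- nrow(datasets[[1]]$values)
  if (folds < 2) stop("at least 2 folds are required", call. = FALSE)
  fold_list <- kfold_split(n, folds, repeats, seed)
  if (min(table(fold_list[[1]])) < 3) {
    stop("each fold must contain at least 3 samples", call. = FALSE)
  }
  recompute <- is.null(graphs)
  run_step <- function(cells) {
    out <- t(vapply(seq_len(nrow(cells)), function(i) {
      sc <- score_cell(datasets, graphs, cells$lambda[i], cells$alpha[i],
                       fold_list, init_seed = seed, restarts = restarts,
                       tol = tol, max_sweeps = max_sweeps,
                       recompute_graphs = recompute,
                       edge_threshold = edge_threshold)
      c(sc$train, sc$test, sc$gap, sc$gap_se)
    }, numeric(4)))
    cbind(cells, mean_train = out[, 1], mean_test = out[, 2],
          mean_gap = out[, 3], gap_se = out[, 4])
  }
  # arg-min of the mean gap among admissible cells; cells whose gap is
  # within one standard error of that minimum are statistically
  # indistinguishable, so the one generalizing best (highest mean test
  # correlation) is preferred among them.
  select_cell <- function(step) {
    ok <- which(!is.na(step$mean_gap))
    if (length(ok) == 0) return(NA_integer_)
    ok <- ok[step$mean_train[ok] >= min_train_frac * max(step$mean_train[ok])]
    if (length(ok) == 0) return(NA_integer_)
    imin <- ok[which.min(step$mean_gap[ok])]
    near <- ok[step$mean_gap[ok] <= step$mean_gap[imin] + step$gap_se[imin]]
    near[which.max(step$mean_test[near])]
  }
  step1 <- run_step(data.frame(alpha = alpha_grid, lambda = 0))
  i1 <- select_cell(step1)
  if (is.na(i1)) stop("all alpha candidates degenerate", call. = FALSE)
  alpha_sel <- step1$alpha[i1]
  step2 <- run_step(data.frame(alpha = alpha_sel, lambda = lambda_grid))
  i2 <- select_cell(step2)
  if (is.na(i2)) stop("all lambda candidates degenerate", call. = FALSE)
  lambda_sel <- step2$lambda[i2]
  structure(
    list(step1 = step1, step2 = step2, alpha = alpha_sel,
         lambda = lambda_sel,
         penalties = penalty_config(lambda_sel, alpha_sel),
         fold_list = fold_list, folds = folds, repeats = repeats,
         seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: selected alpha = %g, lambda = %g (%d-fold x %d)>\n",
              x$alpha, x$lambda, x$folds, x$repeats))
  invisible(x)
}

#' Permutation significance for a canonical component
#'
#' Builds the null by independently permuting the sample rows of all but
#' the first dataset, refitting the requested component, and recording its
#' mean absolute pairwise correlation.  The p-value uses the add-one rule
#' \eqn{p = (1 + \#\{null \ge observed\}) / (1 + n_{perm})}, so the
#' smallest attainable value is \eqn{1/(n_{perm}+1)}.
#'
#' @inheritParams ssmcca_fit
#' @param component_index Which component's correlation to test.
#' @param n_perm Number of permutations (>= 19).
#' @param seed Integer seed (controls permutations and solver inits).
#' @param restarts Random restarts per fit (same for observed and null).
#' @return An object of class `perm_test` with `p_value`, `observed`,
#'   `null_stats`.
#' @export
permutation_pvalue <- function(datasets, graphs = NULL,
                               penalties = penalty_config(),
                               component_index = 1L, n_perm = 99L,
                               seed = 1L, restarts = 2L, tol = 1e-5,
                               max_sweeps = 200L) {
  if (n_perm < 19) {
    stop("n_perm must be at least 19 for usable p-value resolution",
         call. = FALSE)
  }
  datasets <- prepare_datasets(datasets)
  n <- nrow(datasets[[1]]$values)
  stat <- function(ds) {
    fit <- suppressWarnings(ssmcca_fit(
      ds, graphs = graphs, penalties = penalties,
      n_components = component_index, init_seed = seed,
      restarts = restarts, tol = tol, max_sweeps = max_sweeps
    ))
    cp <- fit$components[[component_index]]
    if (cp$degenerate) return(NA_real_)
    mean_abs_offdiag(cp$correlations)
  }
  observed <- stat(datasets)
  if (is.na(observed)) {
    stop("observed component is degenerate; nothing to test", call. = FALSE)
  }
  null_stats <- vapply(seq_len(n_perm), function(i) {
    perm_ds <- datasets
    for (k in seq_along(datasets)[-1]) {
      idx <- with_seed(seed + 7919L * i + k, sample.int(n))
      perm_ds[[k]] <- feature_matrix(
        datasets[[k]]$values[idx, , drop = FALSE],
        datasets[[k]]$feature_labels, datasets[[k]]$set_id,
        standardized = TRUE
      )
    }
    stat(perm_ds)
  }, numeric(1))
  p <- (1 + sum(null_stats >= observed, na.rm = TRUE)) / (1 + n_perm)
  structure(list(p_value = p, observed = observed, null_stats = null_stats,
                 n_perm = n_perm, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test: observed = %.4f, p = %.4g (%d permutations)>\n",
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}
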