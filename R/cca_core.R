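#' Penalty configuration for sparse structured solvers
#'
#' Holds the per-set sparsity weights (`lambda`, the Lagrangian counterpart
#' of the L1 budget) and smoothness weights (`alpha`, multiplying the graph
#' Laplacian in the `(I + alpha L)` quadratic).  Scalars are recycled across
#' sets at fit time.
#'
#' @param lambda Nonnegative sparsity weight(s), one per set or a scalar.
#' @param alpha Nonnegative smoothness weight(s), one per set or a scalar.
#' @return An object of class `penalty_config`.
#' @export
penalty_config <- function(lambda = 0, alpha = 0) {
  if (any(lambda < 0) || any(alpha < 0)) {
    stop("penalty weights must be nonnegative", call. = FALSE)
  }
  structure(list(lambda = as.numeric(lambda), alpha = as.numeric(alpha)),
            class = "penalty_config")
}

expand_penalties <- function(penalties, M) {
  if (is.null(penalties)) penalties <- penalty_config()
  if (!inherits(penalties, "penalty_config")) {
    penalties <- do.call(penalty_config, as.list(penalties))
  }
  list(lambda = rep_len(penalties$lambda, M),
       alpha = rep_len(penalties$alpha, M))
}

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

project_ball <- function(w) {
  nrm <- sqrt(sum(w^2))
  if (nrm > 1) w / nrm else w
}

# Block update: maximize g'w - lambda ||w||_1 - (alpha/2) w' L w over the
# unit ball.  The Lagrangian's identity ridge 0.5 ||w||^2 is constant on the
# ball boundary where the maximizer lives and is absorbed by the constraint.
# alpha = 0 has the closed form soft-threshold-then-normalize; alpha > 0 uses
# projected proximal-gradient ascent (each step with step size 1/Lipschitz
# cannot decrease the objective), so full sweeps of these block updates give
# a non-decreasing penalized SUMCOR objective.
solve_block <- function(g, lambda, alpha, L, lip, warm,
                        inner_max = 200L, inner_tol = 1e-10) {
  if (alpha == 0) {
    s <- if (lambda > 0) soft_threshold(g, lambda) else g
    nrm <- sqrt(sum(s^2))
    if (nrm < 1e-300) return(numeric(length(g)))
    return(s / nrm)
  }
  w <- warm
  for (i in seq_len(inner_max)) {
    grad <- g - alpha * as.numeric(L %*% w)
    w_new <- project_ball(soft_threshold(w + grad / lip, lambda / lip))
    delta <- max(abs(w_new - w))
    w <- as.numeric(w_new)
    if (delta < inner_tol) break
  }
  w
}

block_objective <- function(ws, Cs, lambda, alpha, Ls) {
  M <- length(ws)
  obj <- 0
  for (k in seq_len(M - 1)) {
    for (l in (k + 1):M) {
      obj <- obj + drop(crossprod(ws[[k]], Cs[[k]][[l]] %*% ws[[l]]))
    }
  }
  for (k in seq_len(M)) {
    w <- ws[[k]]
    obj <- obj - lambda[k] * sum(abs(w))
    if (alpha[k] > 0) {
      obj <- obj - 0.5 * alpha[k] * drop(crossprod(w, Ls[[k]] %*% w))
    }
  }
  obj
}

# One penalized SUMCOR solve (single component) on already-deflated,
# standardized matrices.  Multi-start; best objective wins, ties go to the
# lowest restart index.  Penalized solves are warm-started from the
# unpenalized solution of the same random start: the threshold-then-
# normalize update has an absorbing all-zero state that a dense random
# initialization falls into whenever lambda exceeds its (small) initial
# gradient entries, while the unpenalized solution already concentrates
# mass where the cross-covariance lives.
sumcor_engine <- function(Xs, Ls, lambda, alpha, init_seed, restarts,
                          tol, max_sweeps, inner_max = 200L) {
  M <- length(Xs)
  ps <- vapply(Xs, ncol, integer(1))
  Cs <- vector("list", M)
  for (k in seq_len(M)) {
    Cs[[k]] <- vector("list", M)
    for (l in seq_len(M)) {
      if (l != k) Cs[[k]][[l]] <- crossprod(Xs[[k]], Xs[[l]])
    }
  }
  lip <- numeric(M)
  for (k in seq_len(M)) {
    lip[k] <- 1e-6
    if (alpha[k] > 0) {
      lmax <- max(eigen(Ls[[k]], symmetric = TRUE, only.values = TRUE)$values)
      lip[k] <- max(alpha[k] * lmax, 1e-6)
    }
  }
  run_sweeps <- function(ws, lam, alp, tol, max_sweeps) {
    trace <- numeric(0)
    obj_prev <- -Inf
    converged <- FALSE
    obj <- -Inf
    for (sweep in seq_len(max_sweeps)) {
      for (k in seq_len(M)) {
        g <- numeric(ps[k])
        for (l in seq_len(M)) {
          if (l != k) g <- g + as.numeric(Cs[[k]][[l]] %*% ws[[l]])
        }
        ws[[k]] <- solve_block(g, lam[k], alp[k], Ls[[k]], lip[k],
                               ws[[k]], inner_max = inner_max)
      }
      obj <- block_objective(ws, Cs, lam, alp, Ls)
      trace <- c(trace, obj)
      if (is.finite(obj_prev) &&
          abs(obj - obj_prev) < tol * max(1, abs(obj_prev))) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
    list(ws = ws, objective = obj, trace = trace, converged = converged)
  }
  penalized <- any(lambda > 0) || any(alpha > 0)
  best <- NULL
  for (r in seq_len(restarts)) {
    ws <- with_seed(init_seed + r - 1L, lapply(ps, function(p) {
      v <- stats::rnorm(p)
      v / sqrt(sum(v^2))
    }))
    if (penalized) {
      warm <- run_sweeps(ws, rep(0, M), rep(0, M), tol, max_sweeps)
      ws <- warm$ws
    }
    fin <- run_sweeps(ws, lambda, alpha, tol, max_sweeps)
    cand <- list(ws = fin$ws, objective = fin$objective, trace = fin$trace,
                 converged = fin$converged, sweeps = length(fin$trace),
                 restart = r)
    if (is.null(best) || cand$objective > best$objective + 1e-12) {
      best <- cand
    }
  }
  best
}

new_canonical_component <- function(index, weights, weights_sparse,
                                    correlations, set_ids, engine_out,
                                    degenerate) {
  rho <- correlations
  dimnames(rho) <- list(set_ids, set_ids)
  ut <- upper.tri(rho)
  structure(
    list(index = index,
         weights = weights,
         weights_sparse = weights_sparse,
         correlations = rho,
         sumcor = sum(abs(rho[ut])),
         mean_correlation = mean(rho[ut]),
         objective = engine_out$objective,
         convergence = list(sweeps = engine_out$sweeps,
                            converged = engine_out$converged,
                            objective_trace = engine_out$trace,
                            restart = engine_out$restart),
         degenerate = degenerate),
    class = "canonical_component"
  )
}

#' @export
print.canonical_component <- function(x, ...) {
  cat(sprintf("<canonical component %d: mean rho = %s%s>\n", x$index,
              if (x$degenerate) "undefined (degenerate)"
              else sprintf("%.4f", x$mean_correlation),
              if (x$convergence$converged) "" else ", not converged"))
  invisible(x)
}

prepare_datasets <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 2) {
    stop("at least 2 datasets are required", call. = FALSE)
  }
  datasets <- lapply(datasets, as_feature_matrix)
  ns <- vapply(datasets, function(d) nrow(d$values), integer(1))
  if (length(unique(ns)) != 1) {
    ids <- vapply(datasets, function(d) d$set_id, character(1))
    stop(sprintf("sample counts differ across sets: %s",
                 paste(sprintf("%s=%d", ids, ns), collapse = ", ")),
         call. = FALSE)
  }
  lapply(datasets, standardize_columns)
}

prepare_laplacians <- function(graphs, datasets, alpha) {
  M <- length(datasets)
  Ls <- vector("list", M)
  for (k in seq_len(M)) {
    if (alpha[k] > 0) {
      if (is.null(graphs) || is.null(graphs[[k]])) {
        stop(sprintf("set %d has alpha > 0 but no feature graph", k),
             call. = FALSE)
      }
      G <- graphs[[k]]
      if (!inherits(G, "feature_graph")) G <- feature_graph(G)
      if (nrow(G$adjacency) != ncol(datasets[[k]]$values)) {
        stop(sprintf("graph %d size (%d) does not match feature count (%d)",
                     k, nrow(G$adjacency), ncol(datasets[[k]]$values)),
             call. = FALSE)
      }
      Ls[[k]] <- G$laplacian
    }
  }
  Ls
}

#' Structured sparse multiset CCA under the SUMCOR objective
#'
#' Extracts `n_components` canonical components from `M` datasets sharing a
#' sample dimension by maximizing the penalized sum-of-correlations
#' Lagrangian
#' \deqn{\sum_{k<l} w_k^T X_k^T X_l w_l - \sum_k \lambda_k \|w_k\|_1
#'       - \tfrac12 \sum_k w_k^T (I + \alpha_k L_k) w_k}
#' subject to \eqn{\|w_k\|_2 \le 1}, via cyclic block updates (monotone
#' proximal steps with L1 soft-thresholding and the Laplacian-smoothed
#' quadratic).  Weight orthogonality across components within each set is
#' enforced by projection deflation: component `n` is fit on
#' `X_k (I - P_k)` with `P_k` the projector onto the earlier weights, and
#' the reported weight is the deflated solution mapped back to the original
#' feature space, which is exactly orthogonal to all earlier components.
#' The solver's sparse iterate is kept in `weights_sparse` for feature
#' selection; for the first component the two coincide.
#'
#' @param datasets List of 2 or more `feature_matrix` objects (or matrices)
#'   with a common number of rows.  Columns are standardized internally.
#' @param graphs List of `feature_graph` objects, one per set (may contain
#'   `NULL` for sets with `alpha = 0`).
#' @param penalties A [penalty_config()]; scalars recycle across sets.
#' @param n_components Number of components to extract (default 4).
#' @param init_seed Integer seed for the random unit-vector initializations.
#' @param restarts Number of random restarts; the best objective wins and
#'   ties go to the lowest restart index.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_sweeps Maximum full update sweeps per component.
#' @return An object of class `ssmcca_result`: a list of
#'   `canonical_component` objects plus metadata.
#' @export
ssmcca_fit <- function(datasets, graphs = NULL, penalties = penalty_config(),
                       n_components = 4L, init_seed = 1L, restarts = 5L,
                       tol = 1e-6, max_sweeps = 500L) {
  datasets <- prepare_datasets(datasets)
  M <- length(datasets)
  pen <- expand_penalties(penalties, M)
  Ls <- prepare_laplacians(graphs, datasets, pen$alpha)
  set_ids <- vapply(datasets, function(d) d$set_id, character(1))
  if (anyDuplicated(set_ids)) set_ids <- paste0(set_ids, "_", seq_len(M))
  n <- nrow(datasets[[1]]$values)
  max_rank <- min(vapply(datasets, function(d) min(dim(d$values)), integer(1)))
  if (n_components > max_rank) {
    stop(sprintf("n_components (%d) exceeds the minimum rank bound (%d)",
                 n_components, max_rank), call. = FALSE)
  }
  Xd <- lapply(datasets, function(d) d$values)
  basis <- lapply(datasets, function(d) NULL)   # orthonormal prior weights
  components <- vector("list", n_components)
  for (comp in seq_len(n_components)) {
    out <- sumcor_engine(Xd, Ls, pen$lambda, pen$alpha,
                         init_seed = init_seed + 1000L * (comp - 1L),
                         restarts = restarts, tol = tol,
                         max_sweeps = max_sweeps)
    vs <- out$ws
    ws <- vector("list", M)
    scores <- matrix(NA_real_, n, M)
    degenerate <- FALSE
    for (k in seq_len(M)) {
      v <- vs[[k]]
      w <- v
      if (!is.null(basis[[k]])) {
        w <- v - basis[[k]] %*% crossprod(basis[[k]], v)
        w <- as.numeric(w)
      }
      names(w) <- datasets[[k]]$feature_labels
      v_named <- v
      names(v_named) <- datasets[[k]]$feature_labels
      ws[[k]] <- w
      vs[[k]] <- v_named
      if (sqrt(sum(w^2)) < 1e-12) degenerate <- TRUE
      else scores[, k] <- datasets[[k]]$values %*% w
    }
    rho <- matrix(NA_real_, M, M)
    diag(rho) <- 1
    if (!degenerate) {
      sds <- apply(scores, 2, stats::sd)
      if (any(sds < 1e-14)) degenerate <- TRUE
      else rho <- stats::cor(scores)
    }
    names(ws) <- names(vs) <- set_ids
    components[[comp]] <- new_canonical_component(
      comp, ws, vs, rho, set_ids, out, degenerate
    )
    # deflate for the next component
    for (k in seq_len(M)) {
      w <- components[[comp]]$weights[[k]]
      nrm <- sqrt(sum(w^2))
      if (nrm > 1e-12) {
        q <- w / nrm
        Xd[[k]] <- Xd[[k]] - (Xd[[k]] %*% q) %*% t(q)
        basis[[k]] <- cbind(basis[[k]], q)
      }
    }
  }
  structure(
    list(components = components, set_ids = set_ids,
         penalties = penalty_config(pen$lambda, pen$alpha),
         n_components = n_components, init_seed = init_seed,
         restarts = restarts, tol = tol, max_sweeps = max_sweeps),
    class = "ssmcca_result"
  )
}

#' @export
print.ssmcca_result <- function(x, ...) {
  cat(sprintf("<ssmcca_result: %d sets, %d components>\n",
              length(x$set_ids), x$n_components))
  for (cp in x$components) print(cp)
  invisible(x)
}

#' Multiset CCA (unpenalized baseline)
#'
#' [ssmcca_fit()] with all penalties zero: plain SUMCOR multiset CCA.
#' @inheritParams ssmcca_fit
#' @return An `ssmcca_result`.
#' @export
mcca_fit <- function(datasets, n_components = 4L, init_seed = 1L,
                     restarts = 5L, tol = 1e-6, max_sweeps = 500L) {
  ssmcca_fit(datasets, graphs = NULL, penalties = penalty_config(0, 0),
             n_components = n_components, init_seed = init_seed,
             restarts = restarts, tol = tol, max_sweeps = max_sweeps)
}

#' Sparse multiset CCA (L1-only baseline)
#'
#' [ssmcca_fit()] with `alpha = 0`: sparsity without graph smoothness.
#' @inheritParams ssmcca_fit
#' @return An `ssmcca_result`.
#' @export
smcca_fit <- function(datasets, penalties = penalty_config(),
                      n_components = 4L, init_seed = 1L, restarts = 5L,
                      tol = 1e-6, max_sweeps = 500L) {
  pen <- expand_penalties(penalties, length(datasets))
  ssmcca_fit(datasets, graphs = NULL,
             penalties = penalty_config(pen$lambda, 0),
             n_components = n_components, init_seed = init_seed,
             restarts = restarts, tol = tol, max_sweeps = max_sweeps)
}

#' First SUMCOR component by the classic normalized iteration
#'
#' Maximizes \eqn{\sum_{k \ne l} w_k^T X_k^T X_l w_l} subject to
#' \eqn{\|w_k\|_2 \le 1} by cyclic updates
#' \eqn{w_k \propto \sum_{l \ne k} X_k^T X_l w_l} (normalized), from random
#' unit-vector initializations.  This is the unpenalized first step of the
#' multiset procedure and doubles as an independent code path for the
#' penalized solver's zero-penalty limit.
#'
#' @inheritParams ssmcca_fit
#' @return A single `canonical_component`.
#' @export
mcca_sumcor_first <- function(datasets, init_seed = 1L, restarts = 5L,
                              tol = 1e-6, max_sweeps = 500L) {
  datasets <- prepare_datasets(datasets)
  M <- length(datasets)
  Xs <- lapply(datasets, function(d) d$values)
  ps <- vapply(Xs, ncol, integer(1))
  Cs <- vector("list", M)
  for (k in seq_len(M)) {
    Cs[[k]] <- vector("list", M)
    for (l in seq_len(M)) if (l != k) Cs[[k]][[l]] <- crossprod(Xs[[k]], Xs[[l]])
  }
  objective <- function(ws) {
    obj <- 0
    for (k in seq_len(M - 1)) {
      for (l in (k + 1):M) {
        obj <- obj + drop(crossprod(ws[[k]], Cs[[k]][[l]] %*% ws[[l]]))
      }
    }
    obj
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    ws <- with_seed(init_seed + r - 1L, lapply(ps, function(p) {
      v <- stats::rnorm(p)
      v / sqrt(sum(v^2))
    }))
    obj_prev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    for (sweep in seq_len(max_sweeps)) {
      for (k in seq_len(M)) {
        g <- numeric(ps[k])
        for (l in seq_len(M)) if (l != k) g <- g + as.numeric(Cs[[k]][[l]] %*% ws[[l]])
        nrm <- sqrt(sum(g^2))
        if (nrm > 0) ws[[k]] <- g / nrm
      }
      obj <- objective(ws)
      trace <- c(trace, obj)
      if (is.finite(obj_prev) && abs(obj - obj_prev) < tol * max(1, abs(obj_prev))) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
    cand <- list(ws = ws, objective = obj, trace = trace,
                 converged = converged, sweeps = length(trace), restart = r)
    if (is.null(best) || cand$objective > best$objective + 1e-12) best <- cand
  }
  set_ids <- vapply(datasets, function(d) d$set_id, character(1))
  if (anyDuplicated(set_ids)) set_ids <- paste0(set_ids, "_", seq_len(M))
  scores <- vapply(seq_len(M), function(k) {
    as.numeric(Xs[[k]] %*% best$ws[[k]])
  }, numeric(nrow(Xs[[1]])))
  ws <- best$ws
  for (k in seq_len(M)) names(ws[[k]]) <- datasets[[k]]$feature_labels
  names(ws) <- set_ids
  new_canonical_component(1L, ws, ws, stats::cor(scores), set_ids, best,
                          degenerate = FALSE)
}

#' Structured sparse two-set CCA
#'
#' Alternating maximization of
#' \eqn{w_1^T X^T Y w_2 - \lambda_1\|w_1\|_1 - \lambda_2\|w_2\|_1
#'  - \tfrac12 w_1^T (I + \alpha_1 L_1) w_1 - \tfrac12 w_2^T (I + \alpha_2 L_2) w_2}
#' over the unit balls.  Thin two-set front end to the multiset engine.
#'
#' @param X,Y `feature_matrix` objects (or matrices) with equal row counts.
#' @param Gx,Gy Feature graphs for the two sets (`NULL` allowed when the
#'   corresponding `alpha` is zero).
#' @param penalties A [penalty_config()] with entries `(lambda, alpha)` per
#'   set.
#' @inheritParams ssmcca_fit
#' @return A single `canonical_component`.
#' @export
sscca_fit <- function(X, Y, Gx = NULL, Gy = NULL,
                      penalties = penalty_config(), init_seed = 1L,
                      restarts = 5L, tol = 1e-6, max_sweeps = 500L) {
  fit <- ssmcca_fit(list(X, Y), graphs = list(Gx, Gy), penalties = penalties,
                    n_components = 1L, init_seed = init_seed,
                    restarts = restarts, tol = tol, max_sweeps = max_sweeps)
  fit$components[[1]]
}

#' Closed-form two-set CCA
#'
#' Classical canonical correlation analysis via the whitened cross-covariance
#' SVD: with \eqn{K = S_{11}^{-1/2} S_{12} S_{22}^{-1/2}}, the canonical
#' correlations are the singular values of `K` and the weights are the
#' back-transformed singular vectors.  Serves as the unpenalized oracle for
#' the iterative solvers.
#'
#' @param X,Y `feature_matrix` objects or matrices with equal row counts.
#' @param n_components Number of canonical pairs to return.
#' @param ridge Nonnegative ridge added to both within-set covariances;
#'   required when either is rank deficient.
#' @return A list with `correlations` (descending), `wx`, `wy` (weight
#'   matrices, one column per component).
#' @export
cca_closed_form <- function(X, Y, n_components = NULL, ridge = 0) {
  X <- as_feature_matrix(X, "X")
  Y <- as_feature_matrix(Y, "Y")
  if (nrow(X$values) != nrow(Y$values)) {
    stop("X and Y must have the same number of samples", call. = FALSE)
  }
  n <- nrow(X$values)
  Xc <- scale(X$values, center = TRUE, scale = FALSE)
  Yc <- scale(Y$values, center = TRUE, scale = FALSE)
  S11 <- crossprod(Xc) / (n - 1) + diag(ridge, ncol(Xc))
  S22 <- crossprod(Yc) / (n - 1) + diag(ridge, ncol(Yc))
  S12 <- crossprod(Xc, Yc) / (n - 1)
  inv_sqrt <- function(S, which) {
    e <- eigen(S, symmetric = TRUE)
    tol <- max(e$values) * 1e-10
    if (any(e$values < tol)) {
      stop(sprintf("covariance of set %s is rank deficient; supply ridge > 0",
                   which), call. = FALSE)
    }
    e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
  }
  W1 <- inv_sqrt(S11, X$set_id)
  W2 <- inv_sqrt(S22, Y$set_id)
  K <- W1 %*% S12 %*% W2
  sv <- svd(K)
  d <- pmin(pmax(sv$d, -1), 1)
  r <- min(length(d), if (is.null(n_components)) length(d) else n_components)
  wx <- W1 %*% sv$u[, seq_len(r), drop = FALSE]
  wy <- W2 %*% sv$v[, seq_len(r), drop = FALSE]
  rownames(wx) <- X$feature_labels
  rownames(wy) <- Y$feature_labels
  list(correlations = d[seq_len(r)], wx = wx, wy = wy)
}
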