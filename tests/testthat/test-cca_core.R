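test_that("standardization centers columns to unit norm and zeroes constants", {
  set.seed(1)
  X <- cbind(rnorm(30, 5, 2), rnorm(30), rep(3, 30))
  expect_warning(S <- standardize_columns(X), "constant")
  expect_equal(colMeans(S$values), c(V1 = 0, V2 = 0, V3 = 0),
               tolerance = 1e-12)
  expect_equal(unname(colSums(S$values^2)), c(1, 1, 0), tolerance = 1e-12)
})

test_that("feature matrices round-trip through delimited text", {
  X <- feature_matrix(matrix(rnorm(40), 10, 4),
                      c("a", "b", "c", "d"), set_id = "demo")
  f <- tempfile(fileext = ".tsv")
  write_feature_matrix(X, f)
  X2 <- read_feature_matrix(f)
  expect_equal(X2$values, X$values, tolerance = 1e-11)
  expect_identical(X2$feature_labels, X$feature_labels)
})

test_that("closed-form CCA finds perfect correlation for permuted copies", {
  set.seed(2)
  X <- matrix(rnorm(200 * 4), 200, 4)
  out <- cca_closed_form(X, X[, c(3, 1, 4, 2)])
  expect_equal(out$correlations[1], 1, tolerance = 1e-8)
})

test_that("closed-form CCA stays near zero for independent noise", {
  rho <- vapply(1:20, function(s) {
    set.seed(s)
    cca_closed_form(matrix(rnorm(5000 * 2), ncol = 2),
                    matrix(rnorm(5000 * 2), ncol = 2))$correlations[1]
  }, numeric(1))
  expect_lt(max(rho), 0.1)
})

test_that("closed-form CCA agrees with stats::cancor", {
  set.seed(3)
  X <- matrix(rnorm(200 * 3), 200, 3)
  Y <- matrix(rnorm(200 * 4), 200, 4)
  Y[, 1] <- Y[, 1] + X[, 1]
  out <- cca_closed_form(X, Y)
  cc <- cancor(X, Y)
  expect_equal(out$correlations, cc$cor, tolerance = 1e-8)
})

test_that("closed-form CCA names the rank-deficient set", {
  set.seed(4)
  X <- matrix(rnorm(50 * 3), 50, 3)
  X <- cbind(X, X[, 1])   # exact collinearity
  Y <- matrix(rnorm(50 * 2), 50, 2)
  expect_error(cca_closed_form(feature_matrix(X, set_id = "EEG"), Y), "EEG")
  expect_silent(cca_closed_form(feature_matrix(X, set_id = "EEG"), Y,
                                ridge = 1e-6))
})

test_that("unpenalized two-set solvers match the closed-form oracle", {
  d <- gen_whitened_pair(300, 5, 6, seed = 11)
  oracle <- cca_closed_form(d$X, d$Y)$correlations[1]
  cp <- sscca_fit(d$X, d$Y, init_seed = 5)
  expect_equal(abs(cp$correlations[1, 2]), oracle, tolerance = 1e-6)
  first <- mcca_sumcor_first(list(d$X, d$Y), init_seed = 6)
  expect_equal(abs(first$correlations[1, 2]), oracle, tolerance = 1e-4)
})

test_that("over-penalization yields a flagged degenerate component", {
  d <- gen_whitened_pair(100, 4, 4, seed = 12)
  cp <- suppressWarnings(
    sscca_fit(d$X, d$Y, penalties = penalty_config(100, 0), init_seed = 7)
  )
  expect_true(cp$degenerate)
  expect_true(all(is.na(cp$correlations[upper.tri(cp$correlations)])))
})

test_that("two-set sparse recovery finds the true support", {
  sim <- gen_multiset(100, c(30, 30), n_latents = 1, sparsity = 3, snr = 1,
                      seed = 11)
  cv <- two_step_cv(sim$datasets, graphs = sim$truth$graphs, seed = 12)
  cp <- sscca_fit(sim$datasets[[1]], sim$datasets[[2]],
                  sim$truth$graphs[[1]], sim$truth$graphs[[2]],
                  penalties = cv$penalties, init_seed = 13)
  for (k in 1:2) {
    est <- match(selected_features(cp)[[k]],
                 names(cp$weights_sparse[[k]]))
    expect_setequal(est, sim$truth$supports[[k]][[1]])
    expect_gte(aligned_cosine(cp$weights_sparse[[k]],
                              sim$truth$loadings[[k]][[1]]), 0.9)
  }
})

test_that("multiset solver handles identical copies and list reordering", {
  set.seed(14)
  X <- matrix(rnorm(80 * 5), 80, 5)
  cp <- mcca_sumcor_first(list(X, X, X), init_seed = 1)
  expect_equal(unname(cp$correlations), matrix(1, 3, 3), tolerance = 1e-6)

  d <- gen_whitened_pair(150, 4, 5, seed = 15)
  a <- mcca_sumcor_first(list(d$X, d$Y), init_seed = 2)
  b <- mcca_sumcor_first(list(d$Y, d$X), init_seed = 2)
  expect_equal(a$objective, b$objective, tolerance = 1e-8)
})

test_that("solver input contracts reject bad shapes", {
  expect_error(mcca_sumcor_first(list(matrix(rnorm(10), 5, 2))),
               "at least 2")
  expect_error(
    ssmcca_fit(list(feature_matrix(matrix(rnorm(10), 5, 2), set_id = "A"),
                    feature_matrix(matrix(rnorm(12), 6, 2), set_id = "B"))),
    "A=5, B=6")
  expect_error(ssmcca_fit(list(matrix(rnorm(20), 10, 2),
                               matrix(rnorm(20), 10, 2)),
                          n_components = 5), "minimum rank")
})

test_that("deflated components satisfy norm and orthogonality contracts", {
  d <- gen_whitened_pair(200, 5, 5, seed = 16)
  fit <- mcca_fit(list(d$X, d$Y), n_components = 3, init_seed = 3)
  for (cp in fit$components) {
    for (w in cp$weights) expect_lte(sqrt(sum(w^2)), 1 + 1e-9)
    expect_true(all(abs(cp$correlations) <= 1 + 1e-9))
  }
  for (k in 1:2) {
    for (i in 1:2) {
      for (j in (i + 1):3) {
        expect_lt(abs(sum(fit$components[[i]]$weights[[k]] *
                          fit$components[[j]]$weights[[k]])), 1e-6)
      }
    }
  }
})

test_that("baseline parameterizations collapse onto ssmcca_fit", {
  d <- gen_whitened_pair(120, 4, 4, seed = 17)
  ds <- list(d$X, d$Y)
  m <- mcca_fit(ds, n_components = 2, init_seed = 4)
  s0 <- smcca_fit(ds, penalty_config(0, 0), n_components = 2, init_seed = 4)
  full <- ssmcca_fit(ds, penalties = penalty_config(0, 0),
                     n_components = 2, init_seed = 4)
  expect_identical(m$components[[1]]$weights, full$components[[1]]$weights)
  expect_identical(m$components[[2]]$weights, s0$components[[2]]$weights)
})

test_that("correlations are invariant to positive rescaling of a dataset", {
  sim <- gen_multiset(80, c(10, 10), n_latents = 1, sparsity = 3, snr = 2,
                      seed = 18)
  f1 <- ssmcca_fit(sim$datasets, penalties = penalty_config(0.1, 0),
                   n_components = 1, init_seed = 5)
  scaled <- sim$datasets
  scaled[[1]]$values <- scaled[[1]]$values * 37
  f2 <- ssmcca_fit(scaled, penalties = penalty_config(0.1, 0),
                   n_components = 1, init_seed = 5)
  expect_equal(f1$components[[1]]$correlations,
               f2$components[[1]]$correlations, tolerance = 1e-10)
})

test_that("support size is non-increasing along the sparsity path", {
  for (s in 1:10) {
    sim <- gen_multiset(60, c(15, 15), n_latents = 1, sparsity = 3, snr = 1,
                        seed = 100 + s)
    grid <- default_lambda_grid(sim$datasets, length_out = 5)
    nnz <- vapply(grid, function(lam) {
      f <- suppressWarnings(
        ssmcca_fit(sim$datasets, penalties = penalty_config(lam, 0),
                   n_components = 1, init_seed = 6, restarts = 2)
      )
      sum(vapply(f$components[[1]]$weights_sparse,
                 function(w) sum(w != 0), integer(1)))
    }, integer(1))
    expect_true(all(diff(nnz) <= 0))
  }
})

test_that("graph smoothing makes adjacent features take similar weights", {
  # the penalty minimizes the edge-difference energy w'Lw; its normalized
  # value must drop (strictly, on average) as alpha grows
  for (s in 1:5) {
    sim <- gen_multiset(120, c(20, 20), n_latents = 1, sparsity = 6,
                        snr = 2, seed = 200 + s)
    L <- sim$truth$graphs[[1]]$laplacian
    rayleigh <- function(alpha) {
      f <- ssmcca_fit(sim$datasets, graphs = sim$truth$graphs,
                      penalties = penalty_config(0, alpha),
                      n_components = 1, init_seed = 7)
      w <- f$components[[1]]$weights_sparse[[1]]
      drop(crossprod(w, L %*% w)) / sum(w^2)
    }
    expect_lt(rayleigh(5), rayleigh(0))
  }
})
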