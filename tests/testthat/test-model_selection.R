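test_that("kfold partitions are near-equal, exhaustive and reproducible", {
  expect_equal(unname(table(kfold_split(6, 3, seed = 1)[[1]])),
               rep(2L, 3), ignore_attr = TRUE)
  sizes <- sort(unname(table(kfold_split(7, 3, seed = 1)[[1]])),
                decreasing = TRUE)
  expect_equal(as.integer(sizes), c(3L, 2L, 2L))

  a <- kfold_split(50, 5, repeats = 3, seed = 9)
  b <- kfold_split(50, 5, repeats = 3, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a[[1]], a[[2]]))
  for (r in a) expect_true(all(table(r) >= 9))   # every sample tested once
  expect_error(kfold_split(4, 5), "exceed")
  expect_error(kfold_split(10, 1), "at least 2")
})

test_that("holdout correlation reproduces training correlations on the
           training rows and flags degenerate projections", {
  sim <- gen_multiset(60, c(8, 8), n_latents = 1, sparsity = 3, snr = 2,
                      seed = 31)
  fit <- ssmcca_fit(sim$datasets, penalties = penalty_config(0, 0),
                    n_components = 1, init_seed = 1)
  cp <- fit$components[[1]]
  rho <- holdout_correlation(cp, sim$datasets)
  expect_equal(abs(rho[1, 2]), abs(cp$correlations[1, 2]), tolerance = 1e-10)

  zero_w <- cp$weights
  zero_w[[1]][] <- 0
  rho0 <- holdout_correlation(zero_w, sim$datasets)
  expect_true(is.na(rho0[1, 2]))
  expect_equal(attr(rho0, "undefined_sets"), 1L)

  bad <- sim$datasets
  bad[[1]]$feature_labels <- paste0("x", 1:8)
  colnames(bad[[1]]$values) <- bad[[1]]$feature_labels
  expect_error(holdout_correlation(cp, bad), "labels")
})

test_that("holdout correlation recovers a known latent correlation", {
  set.seed(32)
  z <- rnorm(400)
  X <- cbind(z + rnorm(400, sd = 0.3), rnorm(400))
  Y <- cbind(z + rnorm(400, sd = 0.3), rnorm(400))
  w <- list(c(1, 0), c(1, 0))
  rho <- holdout_correlation(w, list(X, Y))
  # latent correlation of two noisy copies: 1 / (1 + 0.09)
  expect_equal(rho[1, 2], 1 / 1.09, tolerance = 0.05)
})

test_that("single-candidate grids are selected with their gap reported", {
  sim <- gen_multiset(45, c(6, 6), n_latents = 1, sparsity = 2, snr = 2,
                      seed = 33)
  cv <- two_step_cv(sim$datasets, alpha_grid = 0.5, lambda_grid = 0.05,
                    graphs = sim$truth$graphs, seed = 3, repeats = 1)
  expect_equal(cv$alpha, 0.5)
  expect_equal(cv$lambda, 0.05)
  expect_true(is.finite(cv$step2$mean_gap))
})

test_that("the selected cell attains the minimal admissible gap", {
  sim <- gen_multiset(60, c(10, 10), n_latents = 1, sparsity = 3, snr = 1,
                      seed = 34)
  cv <- two_step_cv(sim$datasets, graphs = sim$truth$graphs, seed = 4,
                    repeats = 2)
  ok <- !is.na(cv$step2$mean_gap)
  gmin <- min(cv$step2$mean_gap[ok])
  sel <- cv$step2$mean_gap[cv$step2$lambda == cv$lambda]
  i_min <- which(ok)[which.min(cv$step2$mean_gap[ok])]
  expect_lte(sel, gmin + cv$step2$gap_se[i_min] + 1e-12)
})

test_that("pure-noise data drives selection into the heavy-sparsity range", {
  upper <- vapply(1:10, function(s) {
    set.seed(s * 77)
    ds <- list(matrix(rnorm(120 * 10), 120, 10),
               matrix(rnorm(120 * 10), 120, 10))
    cv <- two_step_cv(ds, alpha_grid = 0, seed = s)
    grid <- default_lambda_grid(ds)
    which.min(abs(grid - cv$lambda)) >= 5
  }, logical(1))
  expect_gte(sum(upper), 6)   # majority property
})

test_that("two-step selection lands near the joint-grid optimum", {
  sim <- gen_multiset(320, c(20, 20), n_latents = 1, sparsity = 3, snr = 1,
                      seed = 21)
  tr <- lapply(sim$datasets, function(d) {
    feature_matrix(d$values[1:120, ], d$feature_labels, d$set_id)
  })
  te <- lapply(sim$datasets, function(d) {
    feature_matrix(d$values[121:320, ], d$feature_labels, d$set_id)
  })
  G <- sim$truth$graphs
  ag <- c(0, 0.1, 1, 10) / 4
  lg <- default_lambda_grid(tr)
  cv <- two_step_cv(tr, graphs = G, alpha_grid = ag, lambda_grid = lg,
                    seed = 22, repeats = 2)
  heldout <- function(a, l) {
    f <- suppressWarnings(
      ssmcca_fit(tr, graphs = G, penalties = penalty_config(l, a),
                 n_components = 1, init_seed = 23, restarts = 2)
    )
    if (f$components[[1]]$degenerate) return(NA_real_)
    mean_offdiag(suppressWarnings(
      holdout_correlation(f$components[[1]], te)))
  }
  joint <- vapply(ag, function(a) {
    max(vapply(lg, function(l) heldout(a, l), numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_gte(heldout(cv$alpha, cv$lambda), max(joint) - 0.05)
})

test_that("permutation p-values respect the add-one floor and determinism", {
  sim <- gen_multiset(60, c(5, 5), n_latents = 1, sparsity = 2, snr = 4,
                      seed = 35)
  pt <- permutation_pvalue(sim$datasets, n_perm = 199, seed = 5,
                           restarts = 1)
  # strong shared latent: observed beats every null draw
  expect_equal(pt$p_value, 1 / 200)
  pt2 <- permutation_pvalue(sim$datasets, n_perm = 199, seed = 5,
                            restarts = 1)
  expect_identical(pt$null_stats, pt2$null_stats)
  expect_true(pt$p_value >= 1 / 200 && pt$p_value <= 1)
  expect_error(permutation_pvalue(sim$datasets, n_perm = 10), "19")
})
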