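test_that("a huge l1 penalty drives the specific update to zero", {
  ds <- random_instance(8, 4, 2, seed = 1)
  w <- random_weights(ds, 2)
  b <- update_b(1, ds, w, penalty_params(1e12, 0.1))
  expect_lt(max(abs(b)), 1e-6)
})

test_that("a huge group penalty drives whole shared rows to zero jointly", {
  ds <- random_instance(8, 4, 3, seed = 3)
  w <- random_weights(ds, 4)
  S <- sapply(1:3, function(k) update_s(k, ds, w, penalty_params(0.1, 1e12)))
  expect_lt(max(abs(S)), 1e-6)
  expect_true(all(sqrt(rowSums(S^2)) < 2e-6))
})

test_that("an exactly zero shared row is smoothing-capped, not an error", {
  ds <- random_instance(8, 4, 2, seed = 5)
  w <- random_weights(ds, 6)
  S <- w$S; S[2, ] <- 0
  w0 <- weight_decomposition(w$B, S)
  expect_no_error(update_s(1, ds, w0, penalty_params(0.1, 0.5)))
})

test_that("identical views with no penalty reach the identical-view fixed point", {
  set.seed(7)
  X <- scale(matrix(rnorm(10 * 4), 10, 4), scale = FALSE)
  ds <- multiview_dataset(list(X, X))
  ds <- center_views(ds)
  v <- rnorm(4)
  w <- weight_decomposition(B = cbind(v, v), S = matrix(0, 4, 2))
  b1 <- update_b(1, ds, w, penalty_params(0, 0), smoothing_eps = 1e-12)
  # normal equations X'X b1 = X'X v hold exactly
  expect_equal(crossprod(X) %*% b1, crossprod(X) %*% v, tolerance = 1e-8)
})

test_that("rescaling enforces the variate-norm constraint and is idempotent", {
  for (seed in 1:5) {
    ds <- random_instance(9, 5, 3, seed = seed)
    set.seed(seed + 20)
    w <- weight_decomposition(matrix(rnorm(15), 5, 3), matrix(rnorm(15), 5, 3))
    r1 <- rescale_weights(ds, w)
    for (k in 1:3) {
      expect_equal(sqrt(sum((ds$views[[k]]$data %*% r1$V[, k])^2)), 1,
                   tolerance = 1e-10)
    }
    r2 <- rescale_weights(ds, r1)
    expect_equal(r2$B, r1$B, tolerance = 1e-12)
    # per-coordinate b/s ratio untouched by the common divisor
    expect_equal(r1$B / r1$S, w$B / w$S, tolerance = 1e-10)
  }
})

test_that("one solver sweep in compiled code matches the R update operators", {
  ds <- random_instance(12, 6, 3, seed = 9)
  pen <- penalty_params(0.3, 0.7)
  cfg <- solver_config(max_iter = 1, hard_threshold = 0)
  fit1 <- fit_pdsmcca(ds, pen$lambda_B, pen$lambda_S, cfg)
  # replicate: constant init, rescale, then per view b-update, s-update, rescale
  p <- 6; K <- 3
  w <- rescale_weights(ds, weight_decomposition(matrix(0.5 / p, p, K),
                                                matrix(0.5 / p, p, K)))
  B <- w$B; S <- w$S
  for (k in 1:K) {
    cur <- weight_decomposition(B, S)
    B[, k] <- update_b(k, ds, cur, pen)
    cur <- weight_decomposition(B, S)
    S[, k] <- update_s(k, ds, cur, pen)
    cn <- sqrt(sum((ds$views[[k]]$data %*% (B[, k] + S[, k]))^2))
    B[, k] <- B[, k] / cn; S[, k] <- S[, k] / cn
  }
  expect_equal(fit1$weights$B, B, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit1$weights$S, S, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("fits satisfy the constraint and descend overall", {
  for (seed in 1:5) {
    ds <- random_instance(15, 8, 2 + seed %% 2, seed = seed)
    fit <- fit_pdsmcca(ds, 0.1, 0.1)
    tr <- fit$objective_trace
    expect_lt(tail(tr, 1), tr[1])
    for (k in seq_along(ds$views)) {
      expect_equal(sqrt(sum((ds$views[[k]]$data %*% fit$weights$V[, k])^2)),
                   1, tolerance = 1e-6)
    }
  }
})

test_that("the benchmark fit has a monotone objective trace", {
  ds <- generate_multiview(data1_spec(noise_level = 0.01, seed = 7))
  fit <- fit_pdsmcca(ds, 0.01, 0.01)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
})

test_that("the final objective is insensitive to view update order", {
  # permuting the views is equivalent to permuting the sweep order; compare
  # tightly converged solutions so the stopping band does not dominate
  ds <- random_instance(20, 6, 3, seed = 31)
  cfg <- solver_config(tol = 1e-6, max_iter = 3000)
  f1 <- fit_pdsmcca(ds, 0.2, 0.2, cfg)
  perm <- c(3, 1, 2)
  dsp <- center_views(multiview_dataset(
    lapply(perm, function(k) ds$views[[k]]$data)))
  f2 <- fit_pdsmcca(dsp, 0.2, 0.2, cfg)
  expect_true(f1$converged && f2$converged)
  expect_equal(tail(f1$objective_trace, 1), tail(f2$objective_trace, 1),
               tolerance = 1e-4)
})

test_that("noise-free recovery concentrates weight mass on the true support", {
  # random init: with zero noise and sign-mixed true weights, the constant
  # init sits exactly on the saddle where view 1's driving signal cancels
  ds <- generate_multiview(data1_spec(noise_level = 0, seed = 13))
  fit <- fit_pdsmcca(ds, 0.01, 0.01,
                     solver_config(init = "random", seed = 13))
  V <- fit$weights$V
  for (k in 1:3) {
    mass <- sum(abs(V[81:120, k])) / sum(abs(V[, k]))
    expect_gte(mass, 0.95)
  }
})

test_that("recovered variates track the true ones on the noisy benchmark", {
  # mean CCC between fitted and ground-truth canonical variates across seeds
  cccs <- vapply(1:10, function(s) {
    ds <- generate_multiview(data1_spec(noise_level = 0.01, seed = 100 + s))
    dc <- center_views(ds)
    fit <- fit_pdsmcca(ds, 0.1, 0.1)
    mean(vapply(1:3, function(k) {
      abs(ccc(dc$views[[k]], dc$views[[k]], fit$weights$V[, k],
              ds$truth$true_weights[[k]]))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean(cccs), 0.95)
})

test_that("the baseline keeps unit-norm weights and selects the shared block", {
  ds <- generate_multiview(data1_spec(noise_level = 0.01, seed = 17))
  fit <- fit_smcca(ds, lambda = 0.1)
  expect_true(all(abs(sqrt(colSums(fit$weights$V^2)) - 1) < 1e-6))
  expect_true(all(fit$weights$S == 0))
  V <- fit$weights$V
  for (k in 1:3) {
    expect_gt(sum(abs(V[81:120, k])) / sum(abs(V[, k])), 0.5)
  }
})

test_that("a penalty-dominated baseline reports a degenerate solution", {
  ds <- random_instance(10, 5, 2, seed = 23)
  expect_error(fit_smcca(ds, lambda = 1e12), "degenerate")
})

test_that("identity-covariance and relaxed baselines are both available", {
  ds <- generate_multiview(data1_spec(noise_level = 0.01, seed = 19))
  fr <- fit_smcca(ds, 0.1, cov_structure = "relaxed")
  fi <- fit_smcca(ds, 0.1, cov_structure = "identity")
  expect_true(all(abs(sqrt(colSums(fi$weights$V^2)) - 1) < 1e-6))
  expect_false(isTRUE(all.equal(fr$weights$V, fi$weights$V)))
})

test_that("uncalled-for shapes and penalties are rejected", {
  ds <- random_instance(8, 4, 2, seed = 29)
  expect_error(fit_pdsmcca(ds, -1, 0.1))
  expect_error(solver_config(tol = 0))
  expect_error(solver_config(max_iter = 0))
})
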