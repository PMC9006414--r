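#' Solver configuration
#'
#' Numerical knobs shared by [fit_pdsmcca()] and [fit_smcca()].
#'
#' @param tol convergence threshold on `max |(b_k + s_k)^{t+1} - (b_k + s_k)^t|`
#'   taken over all views and coordinates after rescaling (default 1e-5)
#' @param max_iter outer-iteration cap (default 100)
#' @param smoothing_eps small positive guard added to the reweighting
#'   denominators `|b_ik|` and `||s^i||_2`, the standard reweighted-l1/l2,1
#'   safeguard against division by zero (default 1e-6)
#' @param init `"constant"` (all weights 0.5/p, then rescaled — reproducible
#'   without a seed) or `"random"` (seeded standard-normal entries)
#' @param seed integer seed used only when `init = "random"`
#' @param hard_threshold entries with absolute value below this are set to
#'   exactly 0 after convergence (support reporting); the weights are
#'   rescaled afterwards so the variate-norm constraint still holds
#' @return object of class `solver_config`
#' @export
solver_config <- function(tol = 1e-5, max_iter = 100L, smoothing_eps = 1e-6,
                          init = c("constant", "random"), seed = 1L,
                          hard_threshold = 1e-5) {
  init <- match.arg(init)
  stopifnot(tol > 0, smoothing_eps > 0, max_iter >= 1,
            hard_threshold >= 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 smoothing_eps = smoothing_eps, init = init,
                 seed = as.integer(seed), hard_threshold = hard_threshold),
            class = "solver_config")
}

# cross-product cube: slice (k-1)*K + j holds X_k' X_j (1-based k, j)
build_crossprods <- function(mats) {
  K <- length(mats)
  p <- ncol(mats[[1]])
  CP <- array(0, dim = c(p, p, K * K))
  for (k in seq_len(K)) {
    for (j in seq_len(K)) {
      if (j < k) {
        CP[, , (k - 1L) * K + j] <- t(CP[, , (j - 1L) * K + k])
      } else {
        CP[, , (k - 1L) * K + j] <- crossprod(mats[[k]], mats[[j]])
      }
    }
  }
  CP
}

init_weights <- function(p, K, config) {
  if (config$init == "constant") {
    list(B = matrix(0.5 / p, p, K), S = matrix(0.5 / p, p, K))
  } else {
    withr_seed(config$seed,
               list(B = matrix(rnorm(p * K), p, K) / p,
                    S = matrix(rnorm(p * K), p, K) / p))
  }
}

# rescale columns of B, S so w = b_k + s_k satisfies w' G_k w = 1
rescale_on_crossprods <- function(B, S, CP, K) {
  p <- nrow(B)
  for (k in seq_len(K)) {
    w <- B[, k] + S[, k]
    c2 <- drop(crossprod(w, CP[, , (k - 1L) * K + k] %*% w))
    if (!is.finite(c2) || c2 < 1e-24) {
      stop("degenerate solution: zero projected norm in view ", k,
           " (penalties may be too large)", call. = FALSE)
    }
    B[, k] <- B[, k] / sqrt(c2)
    S[, k] <- S[, k] / sqrt(c2)
  }
  list(B = B, S = S)
}

fit_core <- function(CP, K, method, lambda_B = NULL, lambda_S = NULL,
                     lambda = NULL, config = solver_config(),
                     identity_cov = FALSE) {
  p <- dim(CP)[1]
  w0 <- init_weights(p, K, config)
  if (method == "pdsmcca") {
    w0 <- rescale_on_crossprods(w0$B, w0$S, CP, K)
    res <- pdsmcca_core_cpp(CP, K, lambda_B, lambda_S, config$tol,
                            config$max_iter, config$smoothing_eps,
                            w0$B, w0$S)
  } else {
    V0 <- w0$B + w0$S
    V0 <- sweep(V0, 2L, sqrt(colSums(V0^2)), `/`)
    res <- smcca_core_cpp(CP, K, lambda, config$tol, config$max_iter,
                          config$smoothing_eps, V0, identity_cov)
    res$B <- res$V
    res$S <- matrix(0, p, K)
  }
  if (isTRUE(res$degenerate)) {
    stop("degenerate solution: a view's weight collapsed to zero ",
         "(penalties may be too large)", call. = FALSE)
  }
  if (isTRUE(res$nonfinite)) {
    stop("solver diverged: non-finite objective", call. = FALSE)
  }
  # hard-threshold entries driven to (numerical) zero, then restore the
  # constraint; reverted if thresholding would zero out a whole view
  th <- config$hard_threshold
  if (th > 0) {
    B <- res$B; S <- res$S
    B[abs(B) < th] <- 0
    S[abs(S) < th] <- 0
    ok <- tryCatch({
      if (method == "pdsmcca") {
        w <- rescale_on_crossprods(B, S, CP, K)
        res$B <- w$B; res$S <- w$S
      } else {
        nv <- sqrt(colSums(B^2))
        if (any(nv < 1e-12)) stop("degenerate")
        res$B <- sweep(B, 2L, nv, `/`)
      }
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      # keep the unthresholded solution rather than destroy the fit
    }
  }
  res
}

as_fit_result <- function(res, method, lambda_B = NULL, lambda_S = NULL,
                          lambda = NULL, config, feature_names, view_names) {
  B <- res$B; S <- res$S
  rownames(B) <- rownames(S) <- feature_names
  colnames(B) <- colnames(S) <- view_names
  structure(list(
    method = method,
    weights = weight_decomposition(B, S),
    objective_trace = as.numeric(res$objective_trace),
    n_iter = res$n_iter,
    converged = isTRUE(res$converged),
    lambda_B = lambda_B, lambda_S = lambda_S, lambda = lambda,
    config = config
  ), class = "pdsmcca_fit")
}

ensure_centered <- function(dataset) {
  if (!all(vapply(dataset$views, `[[`, logical(1), "centered"))) {
    dataset <- center_views(dataset)
  }
  dataset
}

#' Fit the parameter-decomposition sparse multi-view CCA model
#'
#' Minimizes the pairwise variate-distance loss plus `lambda_B * ||B||_{1,1}
#' + lambda_S * ||S||_{2,1}` subject to `||X_k (b_k + s_k)||_2 = 1`, by
#' alternating convex search: for each view in turn, the specific weight
#' `b_k` and then the shared weight `s_k` are refreshed by solving the
#' iteratively reweighted diagonal linear system
#' `(lambda D + (K-1) X_k' X_k) w = sum_{j != k} X_k' X_j (b_j + s_j)`,
#' after which the view is rescaled onto the constraint set. Iteration stops
#' when the largest coordinate change of any `b_k + s_k` drops to `tol`.
#'
#' Views are centered internally if they are not already.
#'
#' @param dataset a [multiview_dataset()] with K >= 2 views
#' @param lambda_B non-negative l1 penalty on the modality-specific weights
#' @param lambda_S non-negative l2,1 penalty on the modality-shared weights
#' @param config a [solver_config()]
#' @return object of class `pdsmcca_fit`: `weights`
#'   ([weight_decomposition()]), `objective_trace` (one penalized objective
#'   value per outer iteration, non-increasing), `n_iter`, `converged`, and
#'   the penalty/config echo.
#' @export
fit_pdsmcca <- function(dataset, lambda_B, lambda_S,
                        config = solver_config()) {
  stopifnot(inherits(dataset, "multiview_dataset"),
            lambda_B >= 0, lambda_S >= 0)
  dataset <- ensure_centered(dataset)
  mats <- lapply(dataset$views, `[[`, "data")
  CP <- build_crossprods(mats)
  res <- fit_core(CP, n_views(dataset), "pdsmcca",
                  lambda_B = lambda_B, lambda_S = lambda_S, config = config)
  as_fit_result(res, "pdsmcca", lambda_B = lambda_B, lambda_S = lambda_S,
                config = config,
                feature_names = dataset$views[[1]]$feature_names,
                view_names = names(dataset$views))
}

#' Fit the plain sparse multi-view CCA baseline
#'
#' Minimizes `sum_{k<j} 0.5 ||X_k v_k - X_j v_j||_2^2 + lambda sum_k
#' ||v_k||_1` subject to `||v_k||_2 = 1`, by the same alternating
#' reweighted-l1 scheme as [fit_pdsmcca()] but with a single undecomposed
#' weight per view and a unit-norm (rather than unit-variate-norm)
#' constraint. The returned decomposition has `B = V` and `S = 0`.
#'
#' @inheritParams fit_pdsmcca
#' @param lambda non-negative l1 penalty
#' @param cov_structure `"relaxed"` uses the true within-view Gram matrix
#'   `X_k' X_k` in the update (default); `"identity"` uses the classical
#'   identity-covariance shortcut, retained only for comparison
#' @return a `pdsmcca_fit` with `method = "smcca"`
#' @export
fit_smcca <- function(dataset, lambda, config = solver_config(),
                      cov_structure = c("relaxed", "identity")) {
  stopifnot(inherits(dataset, "multiview_dataset"), lambda >= 0)
  cov_structure <- match.arg(cov_structure)
  dataset <- ensure_centered(dataset)
  mats <- lapply(dataset$views, `[[`, "data")
  CP <- build_crossprods(mats)
  res <- fit_core(CP, n_views(dataset), "smcca", lambda = lambda,
                  config = config,
                  identity_cov = cov_structure == "identity")
  as_fit_result(res, "smcca", lambda = lambda, config = config,
                feature_names = dataset$views[[1]]$feature_names,
                view_names = names(dataset$views))
}

#' One reweighted update of a modality-specific weight vector
#'
#' Single step of the `b_k` refresh: solves
#' `(lambda_B D_b + (K-1) X_k' X_k) b = sum_{j != k} X_k' X_j (b_j + s_j)`
#' with `D_b = diag(1 / (|b_ik| + smoothing_eps))` built from the current
#' `b_k`. Iterating this step with the other views held fixed converges to
#' the minimizer of the l1-penalized subproblem.
#'
#' @param k view index (1-based)
#' @param dataset a centered [multiview_dataset()]
#' @param weights current [weight_decomposition()]
#' @param penalties a [penalty_params()]
#' @param smoothing_eps reweighting guard (default 1e-6)
#' @return updated `b_k` (numeric vector of length p)
#' @export
update_b <- function(k, dataset, weights, penalties, smoothing_eps = 1e-6) {
  stopifnot(inherits(dataset, "multiview_dataset"),
            inherits(weights, "weight_decomposition"),
            k >= 1, k <= n_views(dataset))
  K <- n_views(dataset)
  Xk <- dataset$views[[k]]$data
  rhs <- rowSums(vapply(setdiff(seq_len(K), k), function(j) {
    drop(crossprod(Xk, dataset$views[[j]]$data %*% weights$V[, j]))
  }, numeric(ncol(Xk))))
  M <- (K - 1) * crossprod(Xk)
  diag(M) <- diag(M) + penalties$lambda_B / (abs(weights$B[, k]) + smoothing_eps)
  drop(solve_spd(M, rhs))
}

#' One reweighted update of a modality-shared weight vector
#'
#' Single step of the `s_k` refresh: solves
#' `(lambda_S D_s + (K-1) X_k' X_k) s = sum_{j != k} X_k' X_j (b_j + s_j)`
#' with `D_s = diag(1 / (||s^i||_2 + smoothing_eps))` built from the row
#' norms of the *full* current `S` — the l2,1 penalty couples all views'
#' shared weights through these row norms.
#'
#' @inheritParams update_b
#' @return updated `s_k` (numeric vector of length p)
#' @export
update_s <- function(k, dataset, weights, penalties, smoothing_eps = 1e-6) {
  stopifnot(inherits(dataset, "multiview_dataset"),
            inherits(weights, "weight_decomposition"),
            k >= 1, k <= n_views(dataset))
  K <- n_views(dataset)
  Xk <- dataset$views[[k]]$data
  rhs <- rowSums(vapply(setdiff(seq_len(K), k), function(j) {
    drop(crossprod(Xk, dataset$views[[j]]$data %*% weights$V[, j]))
  }, numeric(ncol(Xk))))
  rn <- sqrt(rowSums(weights$S^2))
  M <- (K - 1) * crossprod(Xk)
  diag(M) <- diag(M) + penalties$lambda_S / (rn + smoothing_eps)
  drop(solve_spd(M, rhs))
}

# SPD solve with jitter fallback, mirroring the C++ core
solve_spd <- function(M, rhs) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    diag(M) <- diag(M) + 1e-10
    ch <- chol(M)
  }
  backsolve(ch, forwardsolve(t(ch), rhs))
}

#' Rescale decomposed weights onto the constraint set
#'
#' Divides each view's `b_k` and `s_k` by `||X_k (b_k + s_k)||_2`, so the
#' variate-norm constraint holds exactly afterwards. Idempotent, and leaves
#' the coordinate-wise ratio of `b_k` to `s_k` unchanged.
#'
#' @param dataset a centered [multiview_dataset()]
#' @param weights a [weight_decomposition()]
#' @return rescaled [weight_decomposition()]
#' @export
rescale_weights <- function(dataset, weights) {
  stopifnot(inherits(dataset, "multiview_dataset"),
            inherits(weights, "weight_decomposition"))
  B <- weights$B; S <- weights$S
  for (k in seq_len(n_views(dataset))) {
    cn <- sqrt(sum((dataset$views[[k]]$data %*% weights$V[, k])^2))
    if (!is.finite(cn) || cn < 1e-12) {
      stop("degenerate solution: zero projected norm in view ", k,
           " (penalties may be too large)", call. = FALSE)
    }
    B[, k] <- B[, k] / cn
    S[, k] <- S[, k] / cn
  }
  weight_decomposition(B, S)
}

#' @export
print.pdsmcca_fit <- function(x, ...) {
  lam <- if (x$method == "pdsmcca") {
    sprintf("lambda_B = %g, lambda_S = %g", x$lambda_B, x$lambda_S)
  } else {
    sprintf("lambda = %g", x$lambda)
  }
  cat(sprintf("%s fit: %s; %d iterations (%s), final objective %.6g\n",
              toupper(x$method), lam, x$n_iter,
              if (x$converged) "converged" else "iteration cap reached",
              utils::tail(x$objective_trace, 1)))
  invisible(x)
}
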