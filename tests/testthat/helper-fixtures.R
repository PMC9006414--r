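# Shared fixtures: small random multi-view instances and a lazy cache for
# the cross-validation runs reused across test blocks.

# random centered multi-view instance (equal p across views)
random_instance <- function(n, p, K, seed) {
  set.seed(seed)
  views <- lapply(seq_len(K), function(k) matrix(rnorm(n * p), n, p))
  center_views(multiview_dataset(views))
}

# random feasible decomposition for an instance (constraint satisfied)
random_weights <- function(dataset, seed) {
  set.seed(seed)
  p <- ncol(dataset$views[[1]]$data)
  K <- length(dataset$views)
  w <- weight_decomposition(matrix(rnorm(p * K), p, K),
                            matrix(rnorm(p * K), p, K))
  rescale_weights(dataset, w)
}

# term-by-term re-implementation of the penalized objective, written
# directly from its definition and independent of pdsmcca_objective()
objective_by_hand <- function(dataset, weights, lambda_B, lambda_S) {
  K <- length(dataset$views)
  loss <- 0
  for (k in seq_len(K - 1)) {
    for (j in (k + 1):K) {
      uk <- dataset$views[[k]]$data %*% (weights$B[, k] + weights$S[, k])
      uj <- dataset$views[[j]]$data %*% (weights$B[, j] + weights$S[, j])
      loss <- loss + 0.5 * sum((uk - uj)^2)
    }
  }
  pen_b <- sum(abs(weights$B))
  pen_s <- sum(apply(weights$S, 1, function(r) sqrt(sum(r^2))))
  loss + lambda_B * pen_b + lambda_S * pen_s
}

# memoised store for expensive cross-validation runs shared across blocks
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
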