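# Subobjectives of the two block updates, written directly from their
# definitions, plus the quadratic majorizer and a fixed-point iterator.
# Shared by the oracle and acceptance suites.

# split subobjective of the specific-weight update: other views fixed
F_b <- function(b, k, ds, W_other, lambda_B) {
  K <- length(ds$views)
  loss <- 0
  for (j in setdiff(seq_len(K), k)) {
    cj <- ds$views[[j]]$data %*% W_other[, j]
    loss <- loss + 0.5 * sum((ds$views[[k]]$data %*% b - cj)^2)
  }
  loss + lambda_B * sum(abs(b))
}

# its quadratic majorizer around bt (exact reweighting, no smoothing)
G_b <- function(b, bt, k, ds, W_other, lambda_B) {
  K <- length(ds$views)
  loss <- 0
  for (j in setdiff(seq_len(K), k)) {
    cj <- ds$views[[j]]$data %*% W_other[, j]
    loss <- loss + 0.5 * sum((ds$views[[k]]$data %*% b - cj)^2)
  }
  loss + lambda_B * sum(b^2 / (2 * abs(bt)) + abs(bt) / 2)
}

# shared-weight subobjective: other views and other columns of S fixed
F_s <- function(s, k, ds, W_other, S_other, lambda_S) {
  K <- length(ds$views)
  loss <- 0
  for (j in setdiff(seq_len(K), k)) {
    cj <- ds$views[[j]]$data %*% W_other[, j]
    loss <- loss + 0.5 * sum((ds$views[[k]]$data %*% s - cj)^2)
  }
  Sfull <- S_other
  Sfull[, k] <- s
  loss + lambda_S * sum(sqrt(rowSums(Sfull^2)))
}

# iterate one reweighted update to its fixed point, others held fixed
irls_fixed_point <- function(update, k, ds, w, pen, which = c("B", "S")) {
  which <- match.arg(which)
  for (i in 1:400) {
    new <- update(k, ds, w, pen, smoothing_eps = 1e-9)
    old <- w[[which]][, k]
    M <- w[[which]]; M[, k] <- new
    w <- weight_decomposition(if (which == "B") M else w$B,
                              if (which == "S") M else w$S)
    if (max(abs(new - old)) < 1e-11) break
  }
  w[[which]][, k]
}
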