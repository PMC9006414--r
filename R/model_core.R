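#' Construct a single-view data matrix
#'
#' Wraps one modality's samples-by-features numeric matrix together with its
#' feature names and centering state. All model-fitting functions in the
#' package operate on views wrapped this way.
#'
#' @param data numeric matrix (or object coercible to one), samples in rows,
#'   features in columns. Must be finite; missing values are rejected.
#' @param feature_names optional character vector of length `ncol(data)`;
#'   defaults to the matrix column names, or `f1..fp` when absent.
#' @param centered logical; set `TRUE` only if the columns already have zero
#'   mean. Checked (tolerance 1e-10) when asserted.
#' @return an object of class `view_matrix` with elements `data`,
#'   `feature_names`, `centered` and `center` (the column means subtracted,
#'   `NULL` until centering is applied).
#' @seealso [center_views()], [multiview_dataset()]
#' @export
view_matrix <- function(data, feature_names = NULL, centered = FALSE) {
  data <- as.matrix(data)
  if (!is.numeric(data)) {
    stop("view data must be numeric", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at row %d, column %d", bad[1], bad[2]),
         call. = FALSE)
  }
  if (nrow(data) < 1L || ncol(data) < 1L) {
    stop("view must have at least one row and one column", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(data)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(data)))
  }
  if (length(feature_names) != ncol(data)) {
    stop("feature_names length must equal the number of columns", call. = FALSE)
  }
  colnames(data) <- feature_names
  if (isTRUE(centered)) {
    mu <- colMeans(data)
    if (max(abs(mu)) > 1e-10) {
      stop("centered = TRUE but column means exceed 1e-10", call. = FALSE)
    }
  }
  structure(
    list(data = data, feature_names = feature_names,
         centered = isTRUE(centered), center = NULL),
    class = "view_matrix"
  )
}

as_view_matrix <- function(x) {
  if (inherits(x, "view_matrix")) x else view_matrix(x)
}

#' Bundle K aligned views into a multi-view dataset
#'
#' @param views list of [view_matrix()] objects (bare matrices are wrapped).
#'   All views must share the same number of rows (samples measured across
#'   modalities) and the same number of columns: the l2,1 penalty couples
#'   weights feature-row-wise across views, which presumes a common feature
#'   indexing, e.g. the same ROI atlas applied to every imaging modality.
#' @param truth optional [synthetic_spec()] recording the generating ground
#'   truth, carried along for support-recovery evaluation.
#' @return object of class `multiview_dataset`: list with `views` (named
#'   `view1..viewK` unless the input list is named), `truth`.
#' @export
multiview_dataset <- function(views, truth = NULL) {
  if (!is.list(views) || length(views) < 2L) {
    stop("need a list of at least two views", call. = FALSE)
  }
  views <- lapply(views, as_view_matrix)
  ns <- vapply(views, function(v) nrow(v$data), integer(1))
  if (length(unique(ns)) != 1L) {
    stop("views are misaligned: row counts ", paste(ns, collapse = ", "),
         call. = FALSE)
  }
  ps <- vapply(views, function(v) ncol(v$data), integer(1))
  if (length(unique(ps)) != 1L) {
    stop("all views must share the same feature count (common atlas); got ",
         paste(ps, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(views)) || any(!nzchar(names(views)))) {
    names(views) <- paste0("view", seq_along(views))
  }
  if (!is.null(truth) && !inherits(truth, "synthetic_spec")) {
    stop("truth must be a synthetic_spec", call. = FALSE)
  }
  structure(list(views = views, truth = truth), class = "multiview_dataset")
}

n_samples <- function(dataset) nrow(dataset$views[[1]]$data)
n_features <- function(dataset) ncol(dataset$views[[1]]$data)
n_views <- function(dataset) length(dataset$views)

#' Center every view's columns to zero mean
#'
#' Column means are subtracted per view and retained, so that held-out data
#' can later be centered by *training* means via [apply_centering()] —
#' the leakage-free protocol used by [nested_cv()].
#'
#' @param dataset a [multiview_dataset()]
#' @return the dataset with each view centered and its `center` recorded.
#' @export
center_views <- function(dataset) {
  stopifnot(inherits(dataset, "multiview_dataset"))
  if (n_samples(dataset) < 2L) stop("need at least two samples to center",
                                    call. = FALSE)
  dataset$views <- lapply(dataset$views, function(v) {
    mu <- colMeans(v$data)
    v$data <- sweep(v$data, 2L, mu)
    v$center <- mu
    v$centered <- TRUE
    v
  })
  dataset
}

#' Center views by externally supplied (training-fold) means
#'
#' @param dataset a [multiview_dataset()]
#' @param centers list of K numeric vectors, typically the `center` fields of
#'   a training fold produced by [center_views()].
#' @return the dataset with the given means subtracted. The columns of a
#'   held-out fold centered this way do not in general have exactly zero
#'   mean; the `center` field records what was subtracted.
#' @export
apply_centering <- function(dataset, centers) {
  stopifnot(inherits(dataset, "multiview_dataset"),
            length(centers) == n_views(dataset))
  for (k in seq_along(dataset$views)) {
    v <- dataset$views[[k]]
    stopifnot(length(centers[[k]]) == ncol(v$data))
    v$data <- sweep(v$data, 2L, centers[[k]])
    v$center <- centers[[k]]
    v$centered <- TRUE
    dataset$views[[k]] <- v
  }
  dataset
}

#' l2,1 norm of a matrix
#'
#' Sum over rows of the row-wise Euclidean norm, `sum_i ||m^i||_2`. Applied
#' to the shared weight matrix `S` it acts as a group penalty that zeroes
#' whole feature rows across all views at once.
#'
#' @param M numeric matrix
#' @return non-negative scalar
#' @export
l21_norm <- function(M) {
  M <- as.matrix(M)
  sum(sqrt(rowSums(M^2)))
}

#' Element-wise l1 norm of a matrix
#'
#' `sum_ij |m_ij|`; for a single-column matrix it coincides with [l21_norm()].
#'
#' @param M numeric matrix
#' @return non-negative scalar
#' @export
l11_norm <- function(M) {
  sum(abs(as.matrix(M)))
}

#' Penalty parameters for the decomposed model
#'
#' @param lambda_B non-negative l1 weight on the modality-specific matrix B
#' @param lambda_S non-negative l2,1 weight on the modality-shared matrix S
#' @return object of class `penalty_params`
#' @export
penalty_params <- function(lambda_B, lambda_S) {
  stopifnot(is.numeric(lambda_B), length(lambda_B) == 1L, lambda_B >= 0,
            is.numeric(lambda_S), length(lambda_S) == 1L, lambda_S >= 0)
  structure(list(lambda_B = lambda_B, lambda_S = lambda_S),
            class = "penalty_params")
}

#' Decomposed canonical weights
#'
#' Holds the modality-specific weights `B` and modality-shared weights `S`
#' (both p x K, column k belonging to view k). The total canonical weight is
#' always the derived sum `V = B + S` and is never stored separately.
#'
#' @param B p x K numeric matrix of specific weights
#' @param S p x K numeric matrix of shared weights
#' @return object of class `weight_decomposition` with elements `B`, `S`
#'   and `V` (computed as `B + S`).
#' @export
weight_decomposition <- function(B, S) {
  B <- as.matrix(B); S <- as.matrix(S)
  if (!all(dim(B) == dim(S))) {
    stop("B and S must have identical dimensions", call. = FALSE)
  }
  structure(list(B = B, S = S, V = B + S), class = "weight_decomposition")
}

#' Penalized multi-view association objective
#'
#' The criterion minimized by the PDSMCCA solver: the sum over unordered view
#' pairs of half the squared distance between canonical variates,
#' `sum_{k<j} 0.5 * ||X_k (b_k + s_k) - X_j (b_j + s_j)||_2^2`,
#' plus `lambda_B * ||B||_{1,1} + lambda_S * ||S||_{2,1}`. Each unordered
#' pair is counted once; a constant factor on the loss is absorbed by the
#' penalty weights.
#'
#' @param dataset a centered [multiview_dataset()]
#' @param weights a [weight_decomposition()]
#' @param penalties a [penalty_params()]
#' @return non-negative scalar
#' @export
pdsmcca_objective <- function(dataset, weights, penalties) {
  stopifnot(inherits(dataset, "multiview_dataset"),
            inherits(weights, "weight_decomposition"),
            inherits(penalties, "penalty_params"))
  K <- n_views(dataset)
  if (ncol(weights$V) != K || nrow(weights$V) != n_features(dataset)) {
    stop("weights have shape ", nrow(weights$V), " x ", ncol(weights$V),
         " but dataset needs ", n_features(dataset), " x ", K, call. = FALSE)
  }
  U <- vapply(seq_len(K),
              function(k) drop(dataset$views[[k]]$data %*% weights$V[, k]),
              numeric(n_samples(dataset)))
  loss <- 0
  for (k in seq_len(K - 1L)) {
    for (j in seq.int(k + 1L, K)) {
      loss <- loss + 0.5 * sum((U[, k] - U[, j])^2)
    }
  }
  loss + penalties$lambda_B * l11_norm(weights$B) +
    penalties$lambda_S * l21_norm(weights$S)
}

#' Canonical correlation coefficient between two views
#'
#' Pearson correlation of the two canonical variates `X_i v_i` and `X_j v_j`
#' computed on centered views:
#' `v_i' X_i' X_j v_j / (sqrt(v_i' X_i' X_i v_i) sqrt(v_j' X_j' X_j v_j))`.
#' Because the true projected variances appear in the denominator (no
#' identity-covariance shortcut), the value is guaranteed to lie in
#' \[-1, 1\] by Cauchy-Schwarz.
#'
#' @param Xi,Xj centered [view_matrix()] objects (bare centered matrices are
#'   accepted)
#' @param vi,vj canonical weight vectors for the two views
#' @return scalar in \[-1, 1\]
#' @export
ccc <- function(Xi, Xj, vi, vj) {
  Xi <- as_view_matrix(Xi); Xj <- as_view_matrix(Xj)
  stopifnot(length(vi) == ncol(Xi$data), length(vj) == ncol(Xj$data),
            nrow(Xi$data) == nrow(Xj$data))
  ui <- drop(Xi$data %*% vi)
  uj <- drop(Xj$data %*% vj)
  ni <- sqrt(sum(ui^2)); nj <- sqrt(sum(uj^2))
  if (ni < 1e-12 || nj < 1e-12) {
    stop("undefined canonical correlation: zero projected variance",
         call. = FALSE)
  }
  r <- sum(ui * uj) / (ni * nj)
  min(1, max(-1, r))
}

#' All pairwise canonical correlation coefficients
#'
#' @param dataset a centered [multiview_dataset()]
#' @param weights a [weight_decomposition()] (or bare p x K matrix of total
#'   weights)
#' @return data frame with columns `pair` (e.g. `"view1-view2"`), `ccc`
#' @export
pairwise_ccc <- function(dataset, weights) {
  V <- if (inherits(weights, "weight_decomposition")) weights$V else
    as.matrix(weights)
  K <- n_views(dataset)
  nm <- names(dataset$views)
  out <- list()
  for (k in seq_len(K - 1L)) {
    for (j in seq.int(k + 1L, K)) {
      out[[length(out) + 1L]] <- data.frame(
        pair = paste0(nm[k], "-", nm[j]),
        ccc = ccc(dataset$views[[k]], dataset$views[[j]], V[, k], V[, j]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.multiview_dataset <- function(x, ...) {
  cat(sprintf("multiview_dataset: %d views, %d samples x %d features%s\n",
              n_views(x), n_samples(x), n_features(x),
              if (all(vapply(x$views, `[[`, logical(1), "centered")))
                " (centered)" else ""))
  invisible(x)
}

#' @export
print.weight_decomposition <- function(x, ...) {
  nz <- function(M) sum(abs(M) > 1e-5)
  cat(sprintf("weight_decomposition: p = %d, K = %d; nonzeros B = %d, S rows = %d\n",
              nrow(x$B), ncol(x$B), nz(x$B),
              sum(sqrt(rowSums(x$S^2)) > 1e-5)))
  invisible(x)
}
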