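#' Penalty grid for cross-validated tuning
#'
#' The candidate set for each penalty weight is `{0.01, 0.1, 1, 10, 100}`:
#' values much larger select nothing, much smaller select everything. The
#' decomposed model tunes `(lambda_B, lambda_S)` over the 25-point Cartesian
#' product; the baseline tunes its single `lambda` over the 5 values.
#'
#' @param method `"pdsmcca"` or `"smcca"`
#' @return data frame of candidates, ordered by `lambda_B` then `lambda_S`
#'   (or by `lambda`), the order used for deterministic tie-breaking
#' @export
grid_candidates <- function(method = c("pdsmcca", "smcca")) {
  method <- match.arg(method)
  set <- c(0.01, 0.1, 1, 10, 100)
  if (method == "pdsmcca") {
    g <- expand.grid(lambda_S = set, lambda_B = set,
                     KEEP.OUT.ATTRS = FALSE)[, c("lambda_B", "lambda_S")]
    g <- g[order(g$lambda_B, g$lambda_S), , drop = FALSE]
    rownames(g) <- NULL
    g
  } else {
    data.frame(lambda = set)
  }
}

# sum (and table) of pairwise CCCs from bare centered matrices; NA on
# degenerate projections so cross-validation can flag rather than fail
cccs_from_mats <- function(mats, V) {
  K <- length(mats)
  vals <- c(); pairs <- c()
  for (k in seq_len(K - 1L)) {
    for (j in seq.int(k + 1L, K)) {
      ui <- drop(mats[[k]] %*% V[, k]); uj <- drop(mats[[j]] %*% V[, j])
      ni <- sqrt(sum(ui^2)); nj <- sqrt(sum(uj^2))
      vals <- c(vals, if (ni < 1e-12 || nj < 1e-12) NA_real_ else
        min(1, max(-1, sum(ui * uj) / (ni * nj))))
      pairs <- c(pairs, paste0("view", k, "-view", j))
    }
  }
  data.frame(pair = pairs, ccc = vals, stringsAsFactors = FALSE)
}

center_by <- function(mats, centers) {
  Map(function(m, mu) sweep(m, 2L, mu), mats, centers)
}

fit_candidate <- function(CP, K, method, cand, config,
                          identity_cov = FALSE) {
  tryCatch({
    if (method == "pdsmcca") {
      fit_core(CP, K, "pdsmcca", lambda_B = cand$lambda_B,
               lambda_S = cand$lambda_S, config = config)
    } else {
      fit_core(CP, K, "smcca", lambda = cand$lambda, config = config,
               identity_cov = identity_cov)
    }
  }, error = function(e) NULL)
}

#' Nested cross-validated grid search
#'
#' Tunes the penalty weights by nested K-fold cross-validation: the samples
#' are split into `outer_folds` folds; within each outer training fold an
#' inner `inner_folds`-fold grid search selects the candidate maximizing the
#' mean inner-validation canonical correlation summed over all view pairs
#' (ties broken toward the smallest `lambda_B`, then `lambda_S`). The winner
#' is refit on the full outer training fold and evaluated on the held-out
#' outer fold. All centering uses training-fold means only — held-out data
#' never contribute to the means they are centered by.
#'
#' @param dataset a [multiview_dataset()] (uncentered; folds are centered
#'   internally)
#' @param method `"pdsmcca"` or `"smcca"`
#' @param grid candidate data frame, defaulting to [grid_candidates()]
#' @param outer_folds,inner_folds fold counts (default 5 and 5)
#' @param config a [solver_config()]
#' @param seed integer seed controlling the fold assignment; results are
#'   fully reproducible given `(dataset, seed)`
#' @param cov_structure baseline covariance form passed to the SMCCA solver
#'   (see [fit_smcca()]); ignored for the decomposed model
#' @return object of class `pdsmcca_cv`: `fold_cccs` (per outer fold and
#'   view pair, train and test CCC), `selected` (winning penalties per outer
#'   fold), `mean_sd` (per-pair mean and SD of train/test CCCs over folds,
#'   signed and absolute), `fits` (per-fold refits), `grid`, `folds`,
#'   `flagged` (outer folds excluded for degenerate projections), `seed`.
#' @export
nested_cv <- function(dataset, method = c("pdsmcca", "smcca"), grid = NULL,
                      outer_folds = 5L, inner_folds = 5L,
                      config = solver_config(), seed = 1L,
                      cov_structure = c("relaxed", "identity")) {
  method <- match.arg(method)
  identity_cov <- match.arg(cov_structure) == "identity"
  stopifnot(inherits(dataset, "multiview_dataset"))
  if (is.null(grid)) grid <- grid_candidates(method)
  n <- n_samples(dataset)
  K <- n_views(dataset)
  stopifnot(n >= outer_folds, outer_folds >= 2L, inner_folds >= 2L)

  mats <- lapply(dataset$views, `[[`, "data")
  assign_all <- withr_seed(seed, {
    outer <- sample(rep(seq_len(outer_folds), length.out = n))
    inner <- lapply(seq_len(outer_folds), function(f) {
      sample(rep(seq_len(inner_folds), length.out = sum(outer != f)))
    })
    list(outer = outer, inner = inner)
  })

  fold_rows <- list(); sel_rows <- list(); fits <- list(); flagged <- integer(0)

  for (f in seq_len(outer_folds)) {
    tr <- which(assign_all$outer != f)
    te <- which(assign_all$outer == f)
    inn <- assign_all$inner[[f]]

    scores <- matrix(NA_real_, nrow(grid), inner_folds)
    for (g in seq_len(inner_folds)) {
      it <- tr[inn != g]; iv <- tr[inn == g]
      Xit <- lapply(mats, function(m) m[it, , drop = FALSE])
      centers <- lapply(Xit, colMeans)
      Xit <- center_by(Xit, centers)
      Xiv <- center_by(lapply(mats, function(m) m[iv, , drop = FALSE]),
                       centers)
      CP <- build_crossprods(Xit)
      for (ci in seq_len(nrow(grid))) {
        res <- fit_candidate(CP, K, method, grid[ci, , drop = FALSE], config,
                             identity_cov)
        if (!is.null(res)) {
          cc <- cccs_from_mats(Xiv, res$B + res$S)
          if (!anyNA(cc$ccc)) scores[ci, g] <- sum(cc$ccc)
        }
      }
    }
    cand_score <- rowMeans(scores)
    cand_score[apply(scores, 1L, anyNA)] <- -Inf
    if (all(!is.finite(cand_score))) {
      stop("all grid candidates failed in outer fold ", f, call. = FALSE)
    }
    win <- which.max(cand_score)  # grid pre-sorted: first max = smallest lambdas

    Xtr <- lapply(mats, function(m) m[tr, , drop = FALSE])
    centers <- lapply(Xtr, colMeans)
    Xtr <- center_by(Xtr, centers)
    Xte <- center_by(lapply(mats, function(m) m[te, , drop = FALSE]), centers)
    CP <- build_crossprods(Xtr)
    res <- fit_candidate(CP, K, method, grid[win, , drop = FALSE], config,
                         identity_cov)
    if (is.null(res)) stop("refit of selected candidate failed in outer fold ",
                           f, call. = FALSE)
    V <- res$B + res$S
    cc_tr <- cccs_from_mats(Xtr, V)
    cc_te <- cccs_from_mats(Xte, V)
    if (anyNA(cc_tr$ccc) || anyNA(cc_te$ccc)) {
      warning("outer fold ", f,
              " excluded: zero projected variance in a view pair")
      flagged <- c(flagged, f)
    }
    fold_rows[[f]] <- data.frame(fold = f, pair = cc_tr$pair,
                                 train = cc_tr$ccc, test = cc_te$ccc,
                                 stringsAsFactors = FALSE)
    sel_rows[[f]] <- cbind(data.frame(fold = f), grid[win, , drop = FALSE])
    fits[[f]] <- as_fit_result(
      res, method,
      lambda_B = if (method == "pdsmcca") grid$lambda_B[win] else NULL,
      lambda_S = if (method == "pdsmcca") grid$lambda_S[win] else NULL,
      lambda = if (method == "smcca") grid$lambda[win] else NULL,
      config = config,
      feature_names = dataset$views[[1]]$feature_names,
      view_names = names(dataset$views))
  }

  fold_cccs <- do.call(rbind, fold_rows)
  keep <- fold_cccs[!(fold_cccs$fold %in% flagged), , drop = FALSE]
  agg <- do.call(rbind, lapply(split(keep, keep$pair), function(d) {
    data.frame(pair = d$pair[1],
               train_mean = mean(d$train), train_sd = sd(d$train),
               test_mean = mean(d$test), test_sd = sd(d$test),
               train_mean_abs = mean(abs(d$train)),
               test_mean_abs = mean(abs(d$test)),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL

  structure(list(method = method, grid = grid,
                 selected = do.call(rbind, sel_rows),
                 fold_cccs = fold_cccs, mean_sd = agg, fits = fits,
                 folds = assign_all$outer, flagged = flagged,
                 outer_folds = outer_folds, inner_folds = inner_folds,
                 seed = seed, config = config),
            class = "pdsmcca_cv")
}

#' @export
print.pdsmcca_cv <- function(x, ...) {
  cat(sprintf("%s nested %d x %d-fold CV (seed %d)\n", toupper(x$method),
              x$outer_folds, x$inner_folds, x$seed))
  print(x$mean_sd, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Support-recovery metrics against a known ground truth
#'
#' Compares the nonzero support of fitted weights (entries above
#' `threshold` in absolute value) with the generating truth. Besides
#' per-view precision and recall of the total weight `V = B + S`, it reports
#' how the decomposition *attributes* features: the fraction of true
#' all-view-shared features captured in the row support of `S`
#' (`shared_recall`) and the fraction of true single-view features captured
#' in the owning view's column of `B` (`specific_recall`).
#'
#' @param weights a [weight_decomposition()]
#' @param truth the generating [synthetic_spec()]
#' @param threshold hard support threshold (default 1e-5)
#' @return list with `per_view` (data frame: view, precision, recall,
#'   flagged — precision of an all-zero weight vector is reported as 0 and
#'   flagged), `shared_recall`, `specific_recall`
#' @export
support_metrics <- function(weights, truth, threshold = 1e-5) {
  stopifnot(inherits(weights, "weight_decomposition"),
            inherits(truth, "synthetic_spec"),
            nrow(weights$V) == truth$p, ncol(weights$V) == truth$K)
  tr <- true_supports(truth)
  per_view <- do.call(rbind, lapply(seq_len(truth$K), function(k) {
    pred <- which(abs(weights$V[, k]) > threshold)
    tru <- tr$per_view[[k]]
    flagged <- length(pred) == 0L
    data.frame(
      view = k,
      precision = if (flagged) 0 else length(intersect(pred, tru)) / length(pred),
      recall = if (length(tru) == 0L) NA_real_ else
        length(intersect(pred, tru)) / length(tru),
      flagged = flagged)
  }))
  s_rows <- which(sqrt(rowSums(weights$S^2)) > threshold)
  shared_recall <- if (length(tr$shared) == 0L) NA_real_ else
    mean(tr$shared %in% s_rows)
  priv <- unlist(lapply(seq_len(truth$K), function(k) {
    vapply(tr$private[[k]], function(i) abs(weights$B[i, k]) > threshold,
           logical(1))
  }))
  specific_recall <- if (length(priv) == 0L) NA_real_ else mean(priv)
  list(per_view = per_view, shared_recall = shared_recall,
       specific_recall = specific_recall)
}

#' Normalized absolute-weight table for heatmap display
#'
#' Canonical weights are reported as absolute values, max-normalized within
#' each view so the strongest feature of each row equals 1 — the relative
#' intensity display used to compare feature selection across methods.
#' Rows are the `B`, `S` and `V` blocks of each view (3K rows); an all-zero
#' row is emitted as zeros.
#'
#' @param weights a [weight_decomposition()]
#' @return numeric matrix, `3 * K` rows (named `B.<view>`, `S.<view>`,
#'   `V.<view>`) by p feature columns, values in \[0, 1\]
#' @export
heatmap_table <- function(weights) {
  stopifnot(inherits(weights, "weight_decomposition"))
  K <- ncol(weights$V)
  vn <- colnames(weights$V)
  if (is.null(vn)) vn <- paste0("view", seq_len(K))
  fn <- rownames(weights$V)
  if (is.null(fn)) fn <- paste0("f", seq_len(nrow(weights$V)))
  rows <- list()
  for (block in c("B", "S", "V")) {
    M <- abs(weights[[block]])
    for (k in seq_len(K)) {
      r <- M[, k]
      mx <- max(r)
      rows[[paste0(block, ".", vn[k])]] <- if (mx > 0) r / mx else r
    }
  }
  out <- do.call(rbind, rows)
  colnames(out) <- fn
  out
}
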