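delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read one view from a delimited text file
#'
#' Rows are samples, columns are features; an optional single header row of
#' feature names is auto-detected (a first row with any non-numeric field).
#' The delimiter is chosen by extension: `.tsv`/`.tab`/`.txt` are
#' tab-separated, anything else comma-separated. Ragged rows, blank cells
#' and non-numeric cells are rejected with their 1-based file row and
#' column.
#'
#' @param path file path
#' @return a [view_matrix()]
#' @export
read_view <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]  # drop trailing blanks
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  sep <- delim_for(path)
  # sentinel keeps trailing blank fields, which strsplit would drop
  cells <- lapply(strsplit(paste0(lines, sep, "\x01"), sep, fixed = TRUE),
                  function(f) f[-length(f)])
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("ragged row in %s: row %d has %d fields, expected %d",
                 path, bad, widths[bad], widths[1]), call. = FALSE)
  }
  parse_row <- function(x) suppressWarnings(as.numeric(x))
  first <- parse_row(cells[[1]])
  has_header <- anyNA(first) && !any(trimws(cells[[1]]) %in% c("", "NA", "NaN"))
  feature_names <- if (has_header) trimws(cells[[1]]) else NULL
  data_rows <- if (has_header) cells[-1] else cells
  if (length(data_rows) == 0L) {
    stop("no data rows in ", path, call. = FALSE)
  }
  offset <- if (has_header) 1L else 0L
  mat <- matrix(NA_real_, length(data_rows), widths[1])
  for (i in seq_along(data_rows)) {
    raw <- trimws(data_rows[[i]])
    vals <- parse_row(raw)
    bad <- which(is.na(vals) | raw == "")
    if (length(bad) > 0L) {
      stop(sprintf(
        "invalid cell '%s' in %s at row %d, column %d (expected a number)",
        raw[bad[1]], path, i + offset, bad[1]), call. = FALSE)
    }
    mat[i, ] <- vals
  }
  view_matrix(mat, feature_names = feature_names)
}

#' Write one view to a delimited text file
#'
#' Inverse of [read_view()]: a header row of feature names followed by one
#' line per sample, values printed with 17 significant digits so that a
#' read/write round trip reproduces the matrix exactly.
#'
#' @param view a [view_matrix()] (bare matrices accepted)
#' @param path output path; extension selects the delimiter as in
#'   [read_view()]
#' @return invisibly, `path`
#' @export
write_view <- function(view, path) {
  view <- as_view_matrix(view)
  sep <- delim_for(path)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(view$feature_names, collapse = sep), con)
  body <- apply(view$data, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = sep))
  writeLines(body, con)
  invisible(path)
}

most_frequent_candidate <- function(selected, method) {
  cols <- if (method == "pdsmcca") c("lambda_B", "lambda_S") else "lambda"
  key <- do.call(paste, c(selected[cols], sep = "|"))
  tab <- sort(table(key), decreasing = TRUE)
  winners <- names(tab)[tab == max(tab)]
  rows <- selected[!duplicated(key) & key %in% winners, cols, drop = FALSE]
  rows <- rows[do.call(order, as.list(rows)), , drop = FALSE]
  rows[1, , drop = FALSE]
}

#' Run a full experiment and write its artifacts
#'
#' End-to-end driver: assembles a dataset either from view files on disk or
#' from a synthetic specification (never both), runs either a nested
#' cross-validated grid search or a single fit, and writes five artifacts to
#' `out_dir`: `weights.csv` (per feature: index, name, and the B/S/V weight
#' of every view, from a final refit on the full dataset), `ccc_summary.csv`
#' (per view pair: mean and SD of train/test CCCs, or the in-sample CCCs for
#' a single fit), `cv_result.json`, `objective_trace.json` and
#' `run_log.txt` (seed, configuration, package version). Identical inputs
#' and seed produce byte-identical numeric artifacts.
#'
#' @param out_dir output directory (created if absent)
#' @param view_paths character vector of per-view file paths (see
#'   [read_view()]); mutually exclusive with `synthetic`
#' @param synthetic `"data1"`, `"data2"`, or a [synthetic_spec()]
#' @param noise_level noise variance used when `synthetic` is `"data1"` or
#'   `"data2"`
#' @param method `"pdsmcca"` or `"smcca"`
#' @param cv run [nested_cv()] (default) or, if `FALSE`, a single fit at the
#'   supplied penalties
#' @param outer_folds,inner_folds CV fold counts
#' @param lambda_B,lambda_S,lambda penalties for `cv = FALSE`
#' @param config a [solver_config()]
#' @param seed integer seed for generation and fold assignment (mandatory)
#' @return invisibly, list with `status` (0), `paths`, and the fitted
#'   objects (`cv`, `fit`)
#' @export
run_experiment <- function(out_dir, view_paths = NULL, synthetic = NULL,
                           noise_level = 0.01,
                           method = c("pdsmcca", "smcca"), cv = TRUE,
                           outer_folds = 5L, inner_folds = 5L,
                           lambda_B = 0.1, lambda_S = 0.1, lambda = 0.1,
                           config = solver_config(), seed) {
  method <- match.arg(method)
  if (missing(seed)) stop("seed is required for a reproducible run",
                          call. = FALSE)
  if (is.null(view_paths) == is.null(synthetic)) {
    stop("give exactly one of view_paths or synthetic", call. = FALSE)
  }
  if (!is.null(view_paths)) {
    missing_files <- view_paths[!file.exists(view_paths)]
    if (length(missing_files) > 0L) {
      stop("missing view file(s): ", paste(missing_files, collapse = ", "),
           call. = FALSE)
    }
    dataset <- multiview_dataset(lapply(view_paths, read_view))
  } else {
    spec <- if (inherits(synthetic, "synthetic_spec")) synthetic
            else switch(as.character(synthetic),
                        data1 = data1_spec(noise_level, seed = seed),
                        data2 = data2_spec(noise_level, seed = seed),
                        stop("synthetic must be 'data1', 'data2' or a ",
                             "synthetic_spec", call. = FALSE))
    dataset <- generate_multiview(spec)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c("weights.csv", "ccc_summary.csv",
                                "cv_result.json", "objective_trace.json",
                                "run_log.txt"))
  names(paths) <- c("weights", "ccc_summary", "cv_result", "trace", "log")

  log_lines <- c(sprintf("pdsmcca %s", as.character(packageVersion("pdsmcca"))),
                 sprintf("method: %s", method),
                 sprintf("seed: %d", as.integer(seed)),
                 sprintf("cv: %s", cv),
                 sprintf("config: tol=%g max_iter=%d smoothing_eps=%g init=%s",
                         config$tol, config$max_iter, config$smoothing_eps,
                         config$init))

  result <- tryCatch({
    cvres <- NULL
    if (cv) {
      cvres <- nested_cv(dataset, method, outer_folds = outer_folds,
                         inner_folds = inner_folds, config = config,
                         seed = seed)
      best <- most_frequent_candidate(cvres$selected, method)
      fit <- if (method == "pdsmcca") {
        fit_pdsmcca(dataset, best$lambda_B, best$lambda_S, config)
      } else {
        fit_smcca(dataset, best$lambda, config)
      }
      summary_df <- cvres$mean_sd
    } else {
      fit <- if (method == "pdsmcca") {
        fit_pdsmcca(dataset, lambda_B, lambda_S, config)
      } else {
        fit_smcca(dataset, lambda, config)
      }
      cc <- pairwise_ccc(ensure_centered(dataset), fit$weights)
      summary_df <- data.frame(pair = cc$pair, train_mean = cc$ccc,
                               train_sd = 0, test_mean = NA_real_,
                               test_sd = NA_real_,
                               train_mean_abs = abs(cc$ccc),
                               test_mean_abs = NA_real_)
    }
    list(cv = cvres, fit = fit, summary = summary_df)
  }, error = function(e) {
    writeLines(c(log_lines, paste("ERROR:", conditionMessage(e))),
               paths[["log"]])
    stop(e)
  })

  W <- result$fit$weights
  wdf <- data.frame(feature_index = seq_len(nrow(W$V)),
                    feature = rownames(W$V))
  for (k in seq_len(ncol(W$V))) {
    vn <- colnames(W$V)[k]
    wdf[[paste0("B_", vn)]] <- sprintf("%.17g", W$B[, k])
    wdf[[paste0("S_", vn)]] <- sprintf("%.17g", W$S[, k])
    wdf[[paste0("V_", vn)]] <- sprintf("%.17g", W$V[, k])
  }
  write.csv(wdf, paths[["weights"]], row.names = FALSE, quote = FALSE)
  write.csv(result$summary, paths[["ccc_summary"]], row.names = FALSE,
            quote = FALSE)
  cvjson <- if (is.null(result$cv)) {
    list(cv = FALSE, method = method, seed = as.integer(seed))
  } else {
    list(cv = TRUE, method = method, seed = as.integer(seed),
         grid = result$cv$grid, selected = result$cv$selected,
         fold_cccs = result$cv$fold_cccs, mean_sd = result$cv$mean_sd,
         flagged_folds = result$cv$flagged)
  }
  jsonlite::write_json(cvjson, paths[["cv_result"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(method = method,
         lambda_B = result$fit$lambda_B, lambda_S = result$fit$lambda_S,
         lambda = result$fit$lambda,
         n_iter = result$fit$n_iter, converged = result$fit$converged,
         objective_trace = result$fit$objective_trace),
    paths[["trace"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(log_lines, "status: ok"), paths[["log"]])
  invisible(list(status = 0L, paths = paths, cv = result$cv,
                 fit = result$fit))
}
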