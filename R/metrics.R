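#' Relative root-mean-square error
#'
#' `sqrt(mean((test - reference)^2)) / sqrt(mean(reference^2))`: the RMS of
#' the elementwise error divided by the RMS of the reference. Scale-invariant
#' (both arrays scaled by the same nonzero constant leave it unchanged) and
#' zero exactly when the arrays are equal.
#'
#' @param test numeric vector under test.
#' @param reference numeric reference vector of the same length.
#' @return A dimensionless scalar >= 0.
#' @export
relative_rmse <- function(test, reference) {
  stopifnot(is.numeric(test), is.numeric(reference),
            length(test) == length(reference), length(test) > 0)
  ref_rms <- sqrt(mean(reference^2))
  if (ref_rms == 0) stop("reference is identically zero")
  sqrt(mean((test - reference)^2)) / ref_rms
}

new_comparison <- function(relative_rmse, max_abs_diff, kernel_calls_a,
                           kernel_calls_b, level_usage = NULL) {
  structure(list(relative_rmse = relative_rmse, max_abs_diff = max_abs_diff,
                 kernel_calls_a = kernel_calls_a, kernel_calls_b = kernel_calls_b,
                 work_ratio = kernel_calls_b / kernel_calls_a,
                 level_usage = level_usage),
            class = "esp_comparison")
}

#' @export
print.esp_comparison <- function(x, ...) {
  cat(sprintf("ESP comparison: relative RMSE %.6g, max |diff| %.6g\n",
              x$relative_rmse, x$max_abs_diff))
  cat(sprintf("  kernel calls: reference %.0f, test %.0f (work ratio %.4g)\n",
              x$kernel_calls_a, x$kernel_calls_b, x$work_ratio))
  if (!is.null(x$level_usage)) {
    u <- x$level_usage
    cat(sprintf("  test level usage: complex %.0f, strand %.0f, residue %.0f, atom %.0f\n",
                u[["complex"]], u[["strand"]], u[["residue"]], u[["atom"]]))
  }
  invisible(x)
}

#' Compare the HCP approximation against the exact engine
#'
#' Runs [esp_exact()] (reference) and [esp_hcp()] (test) on the same inputs
#' and reports the relative RMSE, the largest absolute per-vertex deviation,
#' both kernel-call counts, and the work ratio (HCP calls / exact calls).
#'
#' @inheritParams esp_hcp
#' @return An `esp_comparison` object.
#' @export
compare_modes <- function(structure, vertices, params = alpb_params(),
                          thresholds = hcp_thresholds(), order = 2) {
  ref <- esp_exact(structure, vertices, params)
  tst <- esp_hcp(structure, vertices, params, thresholds, order)
  new_comparison(relative_rmse(tst$potentials, ref$potentials),
                 max(abs(tst$potentials - ref$potentials)),
                 ref$kernel_calls, tst$kernel_calls, tst$level_usage)
}

#' Single- versus double-precision evaluation of the same traversal
#'
#' Re-runs the chosen engine with 32-bit kernel arithmetic and accumulation
#' and compares against the 64-bit run. Threshold decisions always use
#' double precision, so both runs visit identical charge sets and the
#' comparison isolates rounding error from approximation-path divergence.
#'
#' @inheritParams esp_hcp
#' @param thresholds an [hcp_thresholds()] to study the HCP traversal, or
#'   `NULL` (default) for the exact all-atom summation.
#' @return An `esp_comparison`; `work_ratio` is 1 by construction.
#' @export
precision_study <- function(structure, vertices, params = alpb_params(),
                            thresholds = NULL, order = 2) {
  run <- function(precision) {
    if (is.null(thresholds))
      esp_exact(structure, vertices, params, precision = precision)
    else esp_hcp(structure, vertices, params, thresholds, order,
                 precision = precision)
  }
  ref <- run("double")
  tst <- run("single")
  new_comparison(relative_rmse(tst$potentials, ref$potentials),
                 max(abs(tst$potentials - ref$potentials)),
                 ref$kernel_calls, tst$kernel_calls, tst$level_usage)
}

#' Accuracy/work trade-off over a threshold grid
#'
#' Evaluates [esp_hcp()] at each (residue, strand) threshold pair of the
#' grid against a single exact reference run, tabulating the relative RMSE
#' and kernel-call count. Enlarging a threshold approximates less, so the
#' kernel-call count is non-decreasing and the error typically shrinks.
#'
#' @inheritParams esp_hcp
#' @param threshold_grid a 2-column matrix or data.frame of
#'   `(h_residue, h_strand)` pairs, or a list of length-2 vectors.
#' @return A `data.frame` with columns `h_residue`, `h_strand`,
#'   `relative_rmse`, `kernel_calls`.
#' @export
threshold_sweep <- function(structure, vertices, params = alpb_params(),
                            threshold_grid, order = 2) {
  if (is.list(threshold_grid) && !is.data.frame(threshold_grid))
    threshold_grid <- do.call(rbind, threshold_grid)
  threshold_grid <- as.matrix(threshold_grid)
  stopifnot(ncol(threshold_grid) == 2, nrow(threshold_grid) >= 1)
  ref <- esp_exact(structure, vertices, params)
  rows <- lapply(seq_len(nrow(threshold_grid)), function(i) {
    h <- threshold_grid[i, ]
    tst <- esp_hcp(structure, vertices, params,
                   hcp_thresholds(residue = h[1], strand = h[2]), order)
    data.frame(h_residue = h[1], h_strand = h[2],
               relative_rmse = relative_rmse(tst$potentials, ref$potentials),
               kernel_calls = tst$kernel_calls)
  })
  do.call(rbind, rows)
}
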