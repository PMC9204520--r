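# Post-processing of Monte Carlo output: percentile bands, contribution
# factors, error traces, and minimum-RMSE model selection.

#' Per-frame percentile band of a Monte Carlo output
#'
#' Empirical per-frame percentiles over iterations (linear interpolation
#' between order statistics, quantile type 7).
#'
#' @param resultset an `mc_result` or a numeric matrix (iterations x frames).
#' @param output which stored output to summarize (only `"kcf"` is stored by
#'   default).
#' @param lo,hi percentiles (default 5 and 95).
#' @param min_iterations minimum number of successful iterations required.
#' @return an object of class `percentile_band`: list with `lower`, `upper`,
#'   `width` (per frame), `lo`, `hi`, `n`.
#' @export
percentile_band <- function(resultset, output = "kcf", lo = 5, hi = 95,
                            min_iterations = 20) {
  x <- if (inherits(resultset, "mc_result")) {
    if (output != "kcf") stopf("unknown output '%s'", output)
    resultset$kcf_bw
  } else resultset
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < min_iterations)
    stopf("need >= %d successful iterations, have %d", min_iterations, nrow(x))
  qs <- apply(x, 2, stats::quantile, probs = c(lo, hi) / 100, names = FALSE,
              type = 7)
  structure(list(lower = qs[1, ], upper = qs[2, ], width = qs[2, ] - qs[1, ],
                 lo = lo, hi = hi, n = nrow(x)),
            class = "percentile_band")
}

#' Contribution factor of one parameter class
#'
#' Per-frame percent ratio of an individual-MC band width to the general-MC
#' band width.  Frames where the general width falls below `tol` are masked
#' (NA).  Contributions are not constrained to sum to 100% across classes;
#' parameter interactions make them overlap.
#'
#' @param individual_band,general_band [percentile_band()]s on a common
#'   frame grid.
#' @param tol minimum general band width (same units as the output).
#' @return an object of class `contribution_profile`: list with
#'   `contribution` (percent, per frame), `mode`.
#' @export
parameter_contribution <- function(individual_band, general_band,
                                   tol = 1e-8) {
  if (length(individual_band$width) != length(general_band$width))
    stopf("bands are on different frame grids")
  contrib <- 100 * individual_band$width / general_band$width
  contrib[general_band$width < tol] <- NA_real_
  structure(list(contribution = contrib, mode = "individual/general"),
            class = "contribution_profile")
}

#' Contribution of muscle groups toward the overall output variability
#'
#' Per-frame percent ratio of each group's general-MC band width to the
#' reference band width (the all-lower-limb general MC).  Overlapping groups
#' (biarticular subsets) are reported as-is and do not sum to 100%.
#'
#' @param group_bands named list of [percentile_band()]s, one per group.
#' @param reference reference [percentile_band()].
#' @param tol minimum reference width.
#' @return named list of `contribution_profile`s.
#' @export
group_contribution <- function(group_bands, reference, tol = 1e-8) {
  if (!length(group_bands)) stopf("no group bands supplied")
  out <- lapply(group_bands, function(b) {
    p <- parameter_contribution(b, reference, tol = tol)
    p$mode <- "group/reference"
    p
  })
  names(out) <- names(group_bands)
  out
}

#' Error of a predicted knee contact force trace
#'
#' @param predicted predicted KCF trace (BW).
#' @param measured measured KCF trace (BW), same grid.
#' @return an object of class `error_trace`: list with `error` (predicted -
#'   measured, BW), `percent` (100 * error / measured, NA where measured <=
#'   0) and `rmse` (BW, over the cycle).
#' @export
kcf_error <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stopf("predicted and measured traces are on different grids")
  err <- predicted - measured
  pct <- 100 * err / measured
  pct[measured <= 0] <- NA_real_
  structure(list(error = err, percent = pct, rmse = sqrt(mean(err^2))),
            class = "error_trace")
}

#' Resample a trace to percent of squat cycle
#'
#' Linear interpolation onto a uniform grid of `n_out` points spanning the
#' cycle (first to last cycle event).
#'
#' @param x numeric trace.
#' @param time time stamps of `x`.
#' @param events `c(start, deepest, end)` frame indices.
#' @param n_out output grid size (default 101 points, 0-100%).
#' @return list with `pct` (0..100) and `value`.
#' @export
resample_cycle <- function(x, time, events, n_out = 101) {
  t0 <- time[events[1]]; t1 <- time[events[3]]
  tt <- seq(t0, t1, length.out = n_out)
  list(pct = seq(0, 100, length.out = n_out),
       value = stats::approx(time, x, xout = tt)$y)
}

#' Select the perturbed model with the lowest KCF error
#'
#' Argmin over iterations of the cycle RMSE between the predicted and the
#' measured KCF trace; the baseline is included as candidate 0, and ties are
#' broken by the lowest iteration id.
#'
#' @param resultset an `mc_result`.
#' @param measured measured KCF trace (BW) on the trial grid.
#' @param include_baseline include the baseline simulation as candidate 0.
#' @return list with `iteration` (0 = baseline), `rmse`, `baseline_rmse`,
#'   `draw` (the selected iteration's scalar parameter draws, NULL for the
#'   baseline), `error` (the selected [kcf_error()] trace).
#' @export
select_best_model <- function(resultset, measured, include_baseline = TRUE) {
  ok <- which(stats::complete.cases(resultset$kcf_bw))
  if (!length(ok)) stopf("all iterations failed")
  if (length(measured) != ncol(resultset$kcf_bw))
    stopf("measured trace grid mismatch")
  rmse <- vapply(ok, function(i)
    sqrt(mean((resultset$kcf_bw[i, ] - measured)^2)), 0)
  base_rmse <- sqrt(mean((resultset$baseline$kcf_bw - measured)^2))
  ids <- ok
  if (include_baseline) { rmse <- c(base_rmse, rmse); ids <- c(0L, ids) }
  best <- ids[which.min(rmse)]
  pred <- if (best == 0L) resultset$baseline$kcf_bw
          else resultset$kcf_bw[best, ]
  list(iteration = best, rmse = min(rmse), baseline_rmse = base_rmse,
       draw = if (best > 0L && !is.null(resultset$draws))
         resultset$draws[best, ] else NULL,
       error = kcf_error(pred, measured))
}
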