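# Parameter distributions, perturbed-model sampling, and the Monte Carlo
# designs (general: all five parameter classes at once; individual: one
# class at a time) with the band-width convergence check.

PARAM_CLASSES <- c("MIF", "TSL", "PEN", "OIP", "VIA")

#' Build per-muscle parameter distributions from a literature table
#'
#' Scalar parameters (MIF, TSL, PEN) get a Gaussian coefficient of variation:
#' when several sources report a CV for the same (muscle, parameter), the
#' subject-count-weighted average is used; muscles with no source for a
#' parameter are filled with the unweighted mean CV of that parameter across
#' the other muscles.  Pathway points (OIP, VIA) get an absolute Gaussian
#' standard deviation (default 5 mm) on each local coordinate.
#'
#' @param literature_table data.frame with columns `muscle`, `parameter`
#'   (MIF/TSL/PEN), `cv`, `n_subjects` (and optionally `source`).
#' @param muscles character vector of muscle names the distributions must
#'   cover.
#' @param point_sd absolute SD for OIP/VIA coordinates (m).
#' @param point_mode `"per_axis"` (independent Gaussian on each coordinate)
#'   or `"magnitude"` (Gaussian-magnitude displacement in a uniform random
#'   direction).
#' @return an object of class `param_dist_spec`: data.frame with columns
#'   `muscle`, `parameter`, `spread_type` (`cv`/`sd`), `value`, `filled`.
#' @export
build_distributions <- function(literature_table, muscles,
                                point_sd = 0.005,
                                point_mode = c("per_axis", "magnitude")) {
  point_mode <- match.arg(point_mode)
  tb <- as.data.frame(literature_table)
  if (!nrow(tb)) stopf("literature table is empty")
  need <- c("muscle", "parameter", "cv", "n_subjects")
  if (!all(need %in% names(tb)))
    stopf("literature table needs columns %s", paste(need, collapse = ", "))
  if (any(tb$cv < 0)) stopf("negative CV in literature table")
  if (any(tb$n_subjects < 1)) stopf("n_subjects must be >= 1")

  scalar <- c("MIF", "TSL", "PEN")
  rows <- list()
  for (par in scalar) {
    sub <- tb[tb$parameter == par, , drop = FALSE]
    wavg <- if (nrow(sub)) {
      sapply(split(sub, sub$muscle),
             function(d) sum(d$cv * d$n_subjects) / sum(d$n_subjects))
    } else numeric(0)
    fallback <- if (length(wavg)) mean(wavg) else 0
    cv <- stats::setNames(rep(fallback, length(muscles)), muscles)
    filled <- !(muscles %in% names(wavg))
    cv[names(wavg)[names(wavg) %in% muscles]] <-
      wavg[names(wavg) %in% muscles]
    rows[[par]] <- data.frame(muscle = muscles, parameter = par,
                              spread_type = "cv", value = unname(cv),
                              filled = filled)
  }
  for (par in c("OIP", "VIA"))
    rows[[par]] <- data.frame(muscle = muscles, parameter = par,
                              spread_type = "sd", value = point_sd,
                              filled = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "point_mode") <- point_mode
  class(out) <- c("param_dist_spec", "data.frame")
  out
}

# Look up the spread for (muscle, parameter) in a param_dist_spec.
spec_value <- function(spec, muscle, parameter) {
  v <- spec$value[spec$muscle == muscle & spec$parameter == parameter]
  if (!length(v)) stopf("no distribution for (%s, %s)", muscle, parameter)
  v[1]
}

#' Define a Monte Carlo design
#'
#' @param kind `"general"` (perturb all five parameter classes) or
#'   `"individual"` (perturb a single class).
#' @param parameter the perturbed class for individual designs (one of
#'   MIF, TSL, PEN, OIP, VIA).
#' @param muscle_group group whose members are perturbed.
#' @param n_iterations iteration count; defaults 2000 (general) / 500
#'   (individual).
#' @param seed base seed; every iteration derives its own substream.
#' @param extra_fraction,threshold convergence-check policy parameters (10%
#'   more iterations must change the mean band width by less than 1%).
#' @return an object of class `mc_design`.
#' @export
mc_design <- function(kind = c("general", "individual"), parameter = NULL,
                      muscle_group = "lower_limb", n_iterations = NULL,
                      seed = 1L, extra_fraction = 0.10, threshold = 0.01) {
  kind <- match.arg(kind)
  if (kind == "individual") {
    if (is.null(parameter) || !(parameter %in% PARAM_CLASSES))
      stopf("individual designs need parameter in %s",
            paste(PARAM_CLASSES, collapse = "/"))
  } else parameter <- NULL
  if (is.null(n_iterations))
    n_iterations <- if (kind == "general") 2000L else 500L
  if (n_iterations < 1) stopf("n_iterations must be > 0")
  structure(list(kind = kind, parameter = parameter,
                 muscle_group = muscle_group,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), extra_fraction = extra_fraction,
                 threshold = threshold),
            class = "mc_design")
}

#' Planned iteration counts of the full probabilistic design
#'
#' Pure design arithmetic: per subject and muscle group one general MC plus
#' one individual MC per parameter class; the muscle-group contribution
#' analysis uses the general MCs of the non-reference groups.
#'
#' @param n_subjects number of subjects (default 6).
#' @param n_groups number of muscle groups (default 7, including the
#'   all-lower-limb reference group).
#' @param n_general general-MC iterations per subject and group (default 2000).
#' @param n_individual individual-MC iterations (default 500).
#' @param n_parameter_classes number of perturbed parameter classes (5).
#' @return list with `per_subject_group`, `per_subject`, `total`,
#'   `general_total`, `individual_total`, and
#'   `group_contribution_jrf_simulations` (general-MC JRF simulations feeding
#'   the muscle-group contribution comparison: non-reference groups only).
#' @export
plan_mc_design <- function(n_subjects = 6, n_groups = 7, n_general = 2000,
                           n_individual = 500, n_parameter_classes = 5) {
  per_sg <- n_general + n_parameter_classes * n_individual
  list(per_subject_group = per_sg,
       per_subject = n_groups * per_sg,
       total = n_subjects * n_groups * per_sg,
       general_total = n_subjects * n_groups * n_general,
       individual_total = n_subjects * n_groups * n_parameter_classes * n_individual,
       group_contribution_jrf_simulations =
         n_subjects * (n_groups - 1) * n_general)
}

#' Draw a perturbed model
#'
#' For every member muscle of the design's group, scalar parameters are drawn
#' from N(baseline, (CV * baseline)^2) and each pathway-point coordinate from
#' N(baseline, SD^2) (per-axis mode).  Draws are truncated to physical bounds
#' (MIF, TSL > 0; PEN in [0, 80 deg]) by resampling; only the design's
#' parameter class is perturbed for individual designs.  Deterministic given
#' `(design$seed, iteration)`.
#'
#' @param baseline baseline [lowerlimb_model()].
#' @param spec a [build_distributions()] result.
#' @param design an [mc_design()].
#' @param iteration iteration index (>= 1).
#' @return the perturbed model; attribute `"draws"` holds the sampled scalar
#'   values and point offsets, attribute `"stream_id"` the RNG substream.
#' @export
sample_perturbed_model <- function(baseline, spec, design, iteration) {
  members <- sort(group_members(baseline, design$muscle_group))
  classes <- if (design$kind == "general") PARAM_CLASSES else design$parameter
  stream <- mix_seed(design$seed, iteration)
  set.seed(stream)
  point_mode <- attr(spec, "point_mode")
  if (is.null(point_mode)) point_mode <- "per_axis"

  draw_trunc <- function(mean, sd, lower, upper, what) {
    if (sd == 0) return(list(v = mean, rej = 0L))
    rej <- 0L
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > lower && v <= upper) return(list(v = v, rej = rej))
      rej <- rej + 1L
      if (rej > 100L) stopf("over 100 consecutive rejections for %s", what)
    }
  }

  model <- baseline
  scal <- c()
  pts <- c()
  rejections <- 0L
  for (nm in members) {
    mu <- model$muscles[[nm]]
    if ("MIF" %in% classes) {
      d <- draw_trunc(mu$mif, spec_value(spec, nm, "MIF") * mu$mif, 0, Inf,
                      paste0(nm, ".MIF"))
      model$muscles[[nm]]$mif <- d$v
      scal[paste0(nm, ".MIF")] <- d$v
      rejections <- rejections + d$rej
    }
    if ("TSL" %in% classes) {
      d <- draw_trunc(mu$tsl, spec_value(spec, nm, "TSL") * mu$tsl, 0, Inf,
                      paste0(nm, ".TSL"))
      model$muscles[[nm]]$tsl <- d$v
      scal[paste0(nm, ".TSL")] <- d$v
      rejections <- rejections + d$rej
    }
    if ("PEN" %in% classes) {
      d <- draw_trunc(mu$pen_opt, spec_value(spec, nm, "PEN") * mu$pen_opt,
                      0, 80 * pi / 180, paste0(nm, ".PEN"))
      model$muscles[[nm]]$pen_opt <- d$v
      scal[paste0(nm, ".PEN")] <- d$v
      rejections <- rejections + d$rej
    }
    for (k in seq_along(mu$pathway)) {
      p <- mu$pathway[[k]]
      cls <- if (p$role == "via") "VIA" else "OIP"
      if (!(cls %in% classes)) next
      sd <- spec_value(spec, nm, cls)
      off <- if (point_mode == "per_axis") {
        stats::rnorm(2, 0, sd)
      } else {
        th <- stats::runif(1, 0, 2 * pi)
        abs(stats::rnorm(1, 0, sd)) * c(cos(th), sin(th))
      }
      model$muscles[[nm]]$pathway[[k]]$position_local <- p$position_local + off
      pts[paste0(nm, ".", cls, k, c(".x", ".y"))] <- off
    }
  }
  model$provenance <- sprintf("perturbed(%d, %s/%s/%s)", iteration,
                              design$kind,
                              if (is.null(design$parameter)) "ALL"
                              else design$parameter,
                              design$muscle_group)
  attr(model, "draws") <- list(scalars = scal, points = pts,
                               rejections = rejections)
  attr(model, "stream_id") <- stream
  model
}

#' Run a Monte Carlo simulation series
#'
#' Draws `design$n_iterations` perturbed models, simulates the trial on each,
#' and collects the knee contact force traces (and optionally activations).
#' Per-iteration failures are recorded, never fatal; the skeleton-dependent
#' part of the simulation (forward kinematics at the trial poses, inverse
#' dynamics) is computed once and shared across iterations.
#'
#' @param baseline baseline [lowerlimb_model()].
#' @param trial a [squat_trial()].
#' @param spec a [build_distributions()] result.
#' @param design an [mc_design()].
#' @param include_flv,quasi_static passed to the simulation.
#' @param keep_activations store per-iteration activation traces (memory!).
#' @return an object of class `mc_result`: list with `design`, `kcf_bw`
#'   (iterations x frames, failed iterations NA), `draws` (scalar draws,
#'   iterations x parameters), `stream_ids`, `failures`, `n_infeasible`,
#'   `baseline` (the baseline `simulation_result`), `time`.
#' @export
run_mc <- function(baseline, trial, spec, design, include_flv = TRUE,
                   quasi_static = TRUE, keep_activations = FALSE) {
  cache <- trial_cache(baseline, trial, quasi_static = quasi_static)
  base_sim <- simulate_with_cache(baseline, trial, cache,
                                  include_flv = include_flv)
  n <- design$n_iterations
  nf <- length(trial$time)
  kcf <- matrix(NA_real_, n, nf)
  stream_ids <- integer(n)
  failures <- integer(0)
  n_infeasible <- integer(n)
  draws <- NULL
  acts <- if (keep_activations)
    array(NA_real_, c(n, nf, length(baseline$muscles)),
          dimnames = list(NULL, NULL, names(baseline$muscles))) else NULL
  for (i in seq_len(n)) {
    stream_ids[i] <- mix_seed(design$seed, i)
    model_i <- tryCatch(sample_perturbed_model(baseline, spec, design, i),
                        error = function(e) e)
    if (inherits(model_i, "error")) {
      failures <- c(failures, i)
      next
    }
    sc <- attr(model_i, "draws")$scalars
    if (is.null(draws) && length(sc))
      draws <- matrix(NA_real_, n, length(sc), dimnames = list(NULL, names(sc)))
    if (length(sc)) draws[i, names(sc)] <- sc
    sim <- tryCatch(
      simulate_with_cache(model_i, trial, cache, include_flv = include_flv),
      error = function(e) e)
    if (inherits(sim, "error")) {
      failures <- c(failures, i)
      next
    }
    kcf[i, ] <- sim$kcf_bw
    n_infeasible[i] <- sum(!sim$feasible)
    if (keep_activations) acts[i, , ] <- sim$activations
  }
  structure(list(design = design, kcf_bw = kcf, draws = draws,
                 stream_ids = stream_ids, failures = failures,
                 n_infeasible = n_infeasible, baseline = base_sim,
                 activations = acts, time = trial$time),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> %s MC (%s%s), %d iterations (%d failed), %d frames\n",
              x$design$kind, x$design$muscle_group,
              if (is.null(x$design$parameter)) ""
              else paste0(", ", x$design$parameter),
              x$design$n_iterations, length(x$failures), ncol(x$kcf_bw)))
  invisible(x)
}

#' Check Monte Carlo convergence
#'
#' Convergence is declared when adding `extra_fraction` (default 10%) more
#' iterations changes the mean (over frames) 5th-95th percentile band width
#' of the output by less than `threshold` (default 1%): the band width is
#' evaluated with the first `N = floor(n / (1 + extra_fraction))` iterations
#' and with the first `ceiling((1 + extra_fraction) * N)` iterations.
#'
#' @param resultset an `mc_result`, or a numeric matrix (iterations x frames)
#'   or vector of per-iteration scalar outputs.
#' @param extra_fraction probe fraction.
#' @param threshold relative band-width change below which the series is
#'   converged.
#' @param lo,hi band percentiles.
#' @return list with `converged` (logical), `width_n`, `width_probe`,
#'   `rel_change`, `n`, `probe_n`.
#' @export
check_convergence <- function(resultset, extra_fraction = 0.10,
                              threshold = 0.01, lo = 5, hi = 95) {
  x <- if (inherits(resultset, "mc_result")) resultset$kcf_bw else resultset
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n_avail <- nrow(x)
  N <- floor(n_avail / (1 + extra_fraction))
  probe <- ceiling((1 + extra_fraction) * N)
  if (N < 2 || probe > n_avail)
    stopf("insufficient iterations: need >= %d successful iterations, have %d",
          max(3, ceiling(2 * (1 + extra_fraction))), n_avail)
  bw <- function(k) {
    qs <- apply(x[seq_len(k), , drop = FALSE], 2, stats::quantile,
                probs = c(lo, hi) / 100, names = FALSE, type = 7)
    mean(qs[2, ] - qs[1, ])
  }
  w1 <- bw(N); w2 <- bw(probe)
  rel <- if (w1 > 0) abs(w2 - w1) / w1 else if (w2 == 0) 0 else Inf
  list(converged = rel < threshold, width_n = w1, width_probe = w2,
       rel_change = rel, n = N, probe_n = probe)
}
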