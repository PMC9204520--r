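# Synthetic data: subjects, squat trials, ground-truth "measured" knee
# contact forces, and EMG-like signals.  Everything is a pure function of
# (spec, seed) so the full pipeline runs without any external data.

#' Synthetic cohort specification
#'
#' Defaults reproduce the study population statistics of the instrumented-TKA
#' cohort the pipeline is designed around: six subjects, mass 89 +/- 13 kg,
#' stature 1.72 +/- 0.04 m, age 74 +/- 6 years.
#'
#' @param n_subjects number of subjects.
#' @param mass_mean,mass_sd mass distribution (kg).
#' @param height_mean,height_sd stature distribution (m).
#' @param age_mean,age_sd age distribution (years; recorded, not used by the
#'   mechanics).
#' @param seed base seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 6, mass_mean = 89, mass_sd = 13,
                        height_mean = 1.72, height_sd = 0.04,
                        age_mean = 74, age_sd = 6, seed = 1L) {
  structure(list(n_subjects = n_subjects, mass_mean = mass_mean,
                 mass_sd = mass_sd, height_mean = height_mean,
                 height_sd = height_sd, age_mean = age_mean, age_sd = age_sd,
                 seed = seed),
            class = "cohort_spec")
}

# Positive truncated normal draw (resampling).
rnorm_pos <- function(n, mean, sd, lower = 0) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out <= lower
  tries <- 0
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out <= lower
    tries <- tries + 1
    if (tries > 100) stopf("could not draw a positive value")
  }
  out
}

#' Draw subject anthropometry
#'
#' Truncated-Gaussian draws of mass, stature and age from the cohort
#' distributions.  Deterministic given `(spec, index)`.
#'
#' @param spec a [cohort_spec()].
#' @param index subject index (1-based).
#' @return list with `mass` (kg), `height` (m), `age` (years), `index`.
#' @export
draw_anthropometry <- function(spec, index = 1L) {
  set.seed(mix_seed(spec$seed, index, 101L))
  mass <- if (spec$mass_sd > 0) rnorm_pos(1, spec$mass_mean, spec$mass_sd, 30)
          else spec$mass_mean
  height <- if (spec$height_sd > 0)
    rnorm_pos(1, spec$height_mean, spec$height_sd, 1.2) else spec$height_mean
  age <- if (spec$age_sd > 0) rnorm_pos(1, spec$age_mean, spec$age_sd, 18)
         else spec$age_mean
  list(mass = mass, height = height, age = age, index = index)
}

#' Generate a synthetic subject
#'
#' Draws anthropometry from the cohort distributions, derives landmark
#' distances allometrically from stature, and scales the generic model.
#' Deterministic given `(spec, index)`.
#'
#' @param spec a [cohort_spec()].
#' @param index subject index (1-based).
#' @return list with `anthropometry` (mass, height, age) and `model` (the
#'   scaled baseline [lowerlimb_model()]).
#' @export
generate_subject <- function(spec, index = 1L) {
  anth <- draw_anthropometry(spec, index)
  generic <- default_model()
  model <- scale_model(generic, landmark_distances_from_height(anth$height),
                       subject_mass = anth$mass, subject_height = anth$height)
  list(anthropometry = anth, model = model)
}

#' Generate a synthetic body-weight squat trial
#'
#' A smooth symmetric descend-ascend knee flexion profile (raised cosine,
#' 0 -> depth -> 0) with hip and ankle angles from the standard squat
#' coupling ([squat_pose()]: foot flat, trunk vertical, centre of mass over
#' the ankle), quasi-static per-limb GRF (vertical component half body weight
#' with a small documented oscillation, centre of pressure under the centre
#' of mass), and cycle events at the first, deepest-flexion, and last frames.
#'
#' @param subject a [generate_subject()] result (or a list with `model`).
#' @param depth_deg squat depth, peak knee flexion (degrees).
#' @param duration_s cycle duration (s).
#' @param n_frames number of frames (uniform grid).
#' @param grf_ripple relative amplitude of the GRF oscillation (default 1%).
#' @param with_markers also synthesize noise-free marker trajectories from
#'   the model marker set (for inverse kinematics tests).
#' @return a [squat_trial()].
#' @export
generate_squat_trial <- function(subject, depth_deg = 90, duration_s = 4,
                                 n_frames = 101, grf_ripple = 0.01,
                                 with_markers = FALSE) {
  model <- subject$model
  depth <- depth_deg * pi / 180
  if (depth > model$dofs$knee_flexion$range[2])
    stopf("squat depth %.0f deg exceeds the knee range", depth_deg)
  time <- seq(0, duration_s, length.out = n_frames)
  knee <- depth / 2 * (1 - cos(2 * pi * time / duration_s))
  Q <- t(vapply(knee, function(qk) squat_pose(model, qk), numeric(3)))
  colnames(Q) <- names(squat_pose(model, 0))

  w <- model$subject_mass * GRAVITY
  fy <- w / 2 * (1 + grf_ripple * sin(2 * pi * 2 * time / duration_s))
  # quasi-static COP: under the model centre of mass (ground frame, origin
  # below the ankle)
  fk <- ground_fk(model, Q)
  tot <- 0; mx <- numeric(n_frames)
  for (s in model$segments) {
    wp <- world_point(fk, s$name, s$com_local)
    tot <- tot + s$mass
    mx <- mx + s$mass * wp$x
  }
  grf <- data.frame(fx = 0, fy = fy, cop_x = mx / tot)

  markers <- NULL
  if (with_markers && !is.null(model$markers)) {
    coords <- array(0, c(n_frames, nrow(model$markers), 3),
                    dimnames = list(NULL, model$markers$name, c("x", "y", "z")))
    for (k in seq_len(nrow(model$markers))) {
      p <- world_point(fk, model$markers$segment[k],
                       c(model$markers$x[k], model$markers$y[k]))
      coords[, k, 1] <- p$x
      coords[, k, 2] <- p$y
    }
    markers <- list(time = time, labels = model$markers$name, coords = coords,
                    rate = (n_frames - 1) / duration_s, units = "m")
  }

  squat_trial(time = time, joint_angles = Q, grf = grf,
              cycle_events = c(1L, which.max(knee), n_frames),
              subject = list(mass = model$subject_mass,
                             height = model$subject_height),
              markers = markers)
}

#' Ground-truth configuration for the synthetic "measured" knee contact force
#'
#' Stands in for an instrumented-implant measurement: the data-generating
#' model is the baseline with a known perturbation applied to one or more
#' parameter classes of one muscle group, and frame-wise Gaussian measurement
#' noise is added to the simulated contact force.
#'
#' @param muscle_group group whose parameters are perturbed.
#' @param mif_scale multiplicative change of maximum isometric forces.
#' @param tsl_scale,pen_scale optional multiplicative changes.
#' @param via_shift displacement (m, length 2) added to every via point of
#'   the member muscles (pathway plant).
#' @param oip_shift displacement (m, length 2) added to every origin and
#'   insertion point of the member muscles.
#' @param noise_bw measurement noise SD (BW).
#' @param seed noise seed.
#' @return an object of class `ground_truth_config`.
#' @export
ground_truth_config <- function(muscle_group = "knee_extensors",
                                mif_scale = 1.3, tsl_scale = 1,
                                pen_scale = 1, via_shift = c(0, 0),
                                oip_shift = c(0, 0), noise_bw = 0.1,
                                seed = 1L) {
  if (noise_bw < 0) stopf("noise_bw must be >= 0")
  structure(list(muscle_group = muscle_group, mif_scale = mif_scale,
                 tsl_scale = tsl_scale, pen_scale = pen_scale,
                 via_shift = as.numeric(via_shift),
                 oip_shift = as.numeric(oip_shift),
                 noise_bw = noise_bw, seed = seed),
            class = "ground_truth_config")
}

# Apply a ground-truth perturbation to a baseline model.
apply_truth <- function(model, truth) {
  members <- group_members(model, truth$muscle_group)
  for (nm in members) {
    model$muscles[[nm]]$mif <- model$muscles[[nm]]$mif * truth$mif_scale
    model$muscles[[nm]]$tsl <- model$muscles[[nm]]$tsl * truth$tsl_scale
    model$muscles[[nm]]$pen_opt <-
      min(model$muscles[[nm]]$pen_opt * truth$pen_scale, 80 * pi / 180)
    for (k in seq_along(model$muscles[[nm]]$pathway)) {
      p <- model$muscles[[nm]]$pathway[[k]]
      shift <- if (p$role == "via") truth$via_shift else truth$oip_shift
      model$muscles[[nm]]$pathway[[k]]$position_local <-
        p$position_local + shift
    }
  }
  model$provenance <- sprintf("truth(%s x%.2f)", truth$muscle_group,
                              truth$mif_scale)
  model
}

#' Generate a synthetic measured knee contact force trace
#'
#' Simulates the trial on the truth-perturbed model and adds frame-wise
#' Gaussian noise.  The truth model and the noise-free trace are returned for
#' recovery tests.
#'
#' @param subject a [generate_subject()] result.
#' @param trial a [squat_trial()].
#' @param truth a [ground_truth_config()].
#' @param include_flv passed to [simulate_trial()].
#' @return list with `measured` (BW trace), `noise_free`, `truth_model`,
#'   `truth`.
#' @export
generate_measured_kcf <- function(subject, trial, truth, include_flv = TRUE) {
  tm <- apply_truth(subject$model, truth)
  sim <- simulate_trial(trial, tm, include_flv = include_flv)
  set.seed(mix_seed(truth$seed, 0L, 202L))
  measured <- sim$kcf_bw + stats::rnorm(length(sim$kcf_bw), 0, truth$noise_bw)
  list(measured = measured, noise_free = sim$kcf_bw, truth_model = tm,
       truth = truth)
}

#' Generate raw synthetic EMG from an activation trace
#'
#' Amplitude modulation of a band-limited noise carrier (white noise
#' band-passed to 20-250 Hz), so the conditioning chain in [process_emg()]
#' approximately recovers the activation shape.
#'
#' @param activation activation trace in [0, 1] (any time grid).
#' @param trial_time time stamps of `activation` (s).
#' @param sampling_rate EMG sampling rate (Hz, > 600).
#' @param baseline_noise additive baseline noise amplitude (relative).
#' @param seed RNG seed.
#' @return list with `raw` (mV-scale arbitrary units), `time`,
#'   `sampling_rate`.
#' @export
generate_emg <- function(activation, trial_time, sampling_rate = 1000,
                         baseline_noise = 0.01, seed = 1L) {
  if (any(activation < 0 | activation > 1))
    stopf("activation must be in [0, 1]")
  set.seed(mix_seed(seed, 0L, 303L))
  t_emg <- seq(min(trial_time), max(trial_time), by = 1 / sampling_rate)
  act <- stats::approx(trial_time, activation, xout = t_emg)$y
  bf <- signal::butter(2, c(20, 250) / (sampling_rate / 2), type = "pass")
  carrier <- signal::filtfilt(bf, stats::rnorm(length(t_emg)))
  carrier <- carrier / stats::sd(carrier)
  raw <- act * carrier + baseline_noise * stats::rnorm(length(t_emg))
  list(raw = raw, time = t_emg, sampling_rate = sampling_rate)
}

#' Default literature variability table
#'
#' The shipped default coefficients of variation per muscle and parameter.
#' Tendon slack length CVs lie in the 2-9% working range; maximum isometric
#' force and pennation angle CVs are documented placeholders at magnitudes
#' typical of cadaver-derived parameter sets.  One muscle per scalar
#' parameter is deliberately left without an entry to exercise the
#' mean-CV fallback rule of [build_distributions()].
#'
#' @return data.frame with columns `muscle`, `parameter`, `cv`, `n_subjects`,
#'   `source`.
#' @export
default_cv_table <- function() {
  path <- system.file("extdata", "default_cv_table.csv", package = "squatmc")
  if (nzchar(path)) return(utils::read.csv(path, stringsAsFactors = FALSE))
  build_default_cv_table()
}

# The table itself, built in code (the CSV under inst/extdata is generated
# from this function and shipped for use as a file-format example).
build_default_cv_table <- function() {
  muscles <- names(default_model()$muscles)
  # placeholder CVs: MIF variability is large across individuals, TSL small
  # (2-9%), PEN intermediate
  mif_cv <- c(vaslat = 0.22, vasmed = 0.20, vasint = 0.21, recfem = 0.18,
              bflh = 0.20, bfsh = 0.25, semimem = 0.22, semiten = 0.24,
              gasmed = 0.18, gaslat = 0.20, soleus = 0.16, tibant = 0.18,
              glmax = 0.20)                       # iliopsoas missing
  tsl_cv <- c(vaslat = 0.05, vasmed = 0.05, vasint = 0.05, recfem = 0.04,
              bflh = 0.06, bfsh = 0.07, semimem = 0.05, semiten = 0.06,
              gasmed = 0.03, gaslat = 0.03, tibant = 0.04,
              glmax = 0.08, iliopsoas = 0.09)     # soleus missing
  pen_cv <- c(vaslat = 0.12, vasmed = 0.12, vasint = 0.12, recfem = 0.10,
              bflh = 0.12, bfsh = 0.15, semimem = 0.12, semiten = 0.14,
              gasmed = 0.10, gaslat = 0.10, soleus = 0.12, iliopsoas = 0.12,
              glmax = 0.10)                       # tibant missing
  rows <- rbind(
    data.frame(muscle = names(mif_cv), parameter = "MIF", cv = unname(mif_cv)),
    data.frame(muscle = names(tsl_cv), parameter = "TSL", cv = unname(tsl_cv)),
    data.frame(muscle = names(pen_cv), parameter = "PEN", cv = unname(pen_cv))
  )
  rows$n_subjects <- 20L
  rows$source <- "squatmc-default"
  # a second source for one muscle exercises the subject-weighted average
  extra <- data.frame(muscle = "vaslat", parameter = "MIF", cv = 0.28,
                      n_subjects = 10L, source = "squatmc-default-b")
  out <- rbind(rows, extra)
  stopifnot(all(out$muscle %in% muscles))
  out
}
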