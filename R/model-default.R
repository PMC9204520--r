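# The shipped generic model: a sagittal-plane lower limb (pelvis, thigh,
# shank, foot; hip/knee/ankle flexion) with 14 muscle-tendon units covering
# every muscle group of the probabilistic design.  Geometry and parameters
# are desk-scale stand-ins with anatomically plausible attachment sites,
# moment arms and strengths; they are not a published cadaver set.

# Allometric constants (fractions of stature) used both to build the generic
# skeleton and to derive subject landmark distances.
SEGMENT_LENGTH_FRACTION <- c(pelvis_width = 0.191, femur_length = 0.245,
                             tibia_length = 0.246, foot_length = 0.152)

# Segment mass fractions of total body mass (standard anthropometric tables).
# The pelvis segment lumps the pelvis, trunk, head, arms and the contralateral
# limb so that the single-limb chain totals the subject mass.
SEGMENT_MASS_FRACTION <- c(foot = 0.0145, shank = 0.0465, thigh = 0.100)

#' Build the generic sagittal-plane lower-limb model
#'
#' Constructs the four-segment, three-DoF, 14-muscle generic model at a given
#' anthropometry.  Tendon slack lengths are calibrated at model construction
#' so that each muscle's fiber reaches optimal length at the longest MTU
#' length the muscle sees over a 0-75 degree knee-flexion sweep (standard
#' squat coupling): baseline fibers operate at or below optimal length over
#' most of the squat and engage the passive curve mildly in the deepest
#' poses.
#'
#' @param mass total subject mass (kg).
#' @param height subject stature (m).
#' @return a [lowerlimb_model()].
#' @export
default_model <- function(mass = 75, height = 1.70) {
  lf <- SEGMENT_LENGTH_FRACTION[["femur_length"]] * height
  lt <- SEGMENT_LENGTH_FRACTION[["tibia_length"]] * height
  lp <- SEGMENT_LENGTH_FRACTION[["pelvis_width"]] * height
  lft <- SEGMENT_LENGTH_FRACTION[["foot_length"]] * height
  s <- height / 1.70  # geometry below is drawn for a 1.70 m frame

  mf <- SEGMENT_MASS_FRACTION
  m_pelvis <- mass * (1 - sum(mf))

  segments <- list(
    body_segment("pelvis", m_pelvis, c(0, 0.25 * s), m_pelvis * (0.25 * s)^2,
                 lp, NA_character_, "hip_flexion"),
    body_segment("femur", mass * mf[["thigh"]], c(0, -0.433 * lf),
                 mass * mf[["thigh"]] * (0.323 * lf)^2, lf,
                 "hip_flexion", "knee_flexion"),
    body_segment("tibia", mass * mf[["shank"]], c(0, -0.433 * lt),
                 mass * mf[["shank"]] * (0.302 * lt)^2, lt,
                 "knee_flexion", "ankle_flexion"),
    body_segment("foot", mass * mf[["foot"]], c(0.05 * s, -0.03 * s),
                 mass * mf[["foot"]] * (0.475 * lft)^2, lft,
                 "ankle_flexion", NA_character_)
  )

  dofs <- list(
    joint_dof("hip_flexion", "pelvis", "femur", +1, c(-30, 130) * pi / 180, c(0, 0)),
    joint_dof("knee_flexion", "femur", "tibia", -1, c(-5, 140) * pi / 180, c(0, -lf)),
    joint_dof("ankle_flexion", "tibia", "foot", +1, c(-50, 45) * pi / 180, c(0, -lt))
  )

  # muscle table: name, mif (N), l_opt (m), pen_opt (rad), pathway points as
  # (segment, x, y, role).  Coordinates are for the 1.70 m generic frame and
  # scaled isotropically with stature.
  pp <- function(seg, x, y, role) path_point(seg, c(x, y) * s, role)
  knee_y <- -lf   # knee centre in the femur frame (y already includes stature)
  via_quad <- function(dx, dy) path_point("femur", c(dx * s, knee_y + dy * s), "via")

  muscle_defs <- list(
    list("vaslat", 5100, 0.120, 0.09, list(
      pp("femur", 0.020, -0.12, "origin"), via_quad(0.050, -0.025),
      pp("tibia", 0.042, -0.075, "insertion"))),
    list("vasmed", 2600, 0.117, 0.10, list(
      pp("femur", 0.015, -0.18, "origin"), via_quad(0.048, -0.025),
      pp("tibia", 0.040, -0.075, "insertion"))),
    list("vasint", 3100, 0.119, 0.08, list(
      pp("femur", 0.020, -0.15, "origin"), via_quad(0.049, -0.025),
      pp("tibia", 0.041, -0.075, "insertion"))),
    list("recfem", 2200, 0.100, 0.24, list(
      pp("pelvis", 0.035, 0.010, "origin"), via_quad(0.052, -0.025),
      pp("tibia", 0.042, -0.075, "insertion"))),
    list("bflh", 1300, 0.110, 0.20, list(
      pp("pelvis", -0.055, -0.065, "origin"),
      pp("tibia", -0.028, -0.038, "insertion"))),
    list("bfsh", 600, 0.110, 0.21, list(
      pp("femur", -0.015, -0.220, "origin"),
      pp("tibia", -0.028, -0.038, "insertion"))),
    list("semimem", 2200, 0.110, 0.26, list(
      pp("pelvis", -0.050, -0.070, "origin"),
      pp("tibia", -0.026, -0.035, "insertion"))),
    list("semiten", 600, 0.190, 0.22, list(
      pp("pelvis", -0.048, -0.075, "origin"),
      pp("tibia", -0.022, -0.040, "insertion"))),
    list("gasmed", 2500, 0.090, 0.30, list(
      pp("femur", -0.022, -0.392, "origin"),
      pp("foot", -0.065, -0.040, "insertion"))),
    list("gaslat", 1100, 0.090, 0.21, list(
      pp("femur", -0.024, -0.390, "origin"),
      pp("foot", -0.063, -0.038, "insertion"))),
    list("soleus", 3500, 0.070, 0.50, list(
      pp("tibia", -0.024, -0.100, "origin"),
      pp("foot", -0.063, -0.040, "insertion"))),
    list("tibant", 1200, 0.098, 0.17, list(
      pp("tibia", 0.026, -0.130, "origin"),
      pp("tibia", 0.033, -0.390, "via"),
      pp("foot", 0.100, -0.020, "insertion"))),
    list("glmax", 3500, 0.147, 0.38, list(
      pp("pelvis", -0.075, 0.060, "origin"),
      pp("pelvis", -0.060, -0.040, "via"),
      pp("femur", -0.030, -0.150, "insertion"))),
    list("iliopsoas", 3200, 0.120, 0.22, list(
      pp("pelvis", 0.030, 0.090, "origin"),
      pp("pelvis", 0.035, -0.010, "via"),
      pp("femur", 0.008, -0.070, "insertion")))
  )

  muscles <- lapply(muscle_defs, function(d)
    mtu(d[[1]], mif = d[[2]], tsl = 0.1, pen_opt = d[[4]], l_opt = d[[3]],
        pathway = d[[5]]))
  names(muscles) <- vapply(muscle_defs, `[[`, "", 1)

  groups <- list(
    muscle_group("lower_limb", names(muscles)),
    muscle_group("knee_extensors", c("recfem", "vasint", "vaslat", "vasmed")),
    muscle_group("knee_flexors",
                 c("bflh", "bfsh", "gaslat", "gasmed", "semimem", "semiten")),
    muscle_group("hip_muscles", c("glmax", "iliopsoas")),
    muscle_group("ankle_muscles", c("soleus", "tibant")),
    muscle_group("knee_hip_biarticular", c("bflh", "recfem", "semimem", "semiten")),
    muscle_group("knee_ankle_biarticular", c("gaslat", "gasmed"))
  )

  markers <- data.frame(
    name = c("SACR", "ASIS", "THI", "KNE", "TIB", "ANK", "HEE", "TOE"),
    segment = c("pelvis", "pelvis", "femur", "femur", "tibia", "tibia",
                "foot", "foot"),
    x = c(-0.10, 0.08, 0.03, 0.05, 0.03, 0.04, -0.06, 0.18) * s,
    y = c(0.05, 0.02, -0.20, knee_y / s + 0.005, -0.20, -0.40, -0.05, -0.04) * s,
    stringsAsFactors = FALSE
  )

  model <- lowerlimb_model(segments, dofs, muscles, groups,
                           subject_mass = mass, subject_height = height,
                           markers = markers, provenance = "baseline")
  calibrate_tsl(model)
}

# Set each muscle's tendon slack length so the fiber reaches optimal length
# at the muscle's longest MTU length over a 0-75 deg knee-flexion sweep
# (standard squat coupling).  Baseline fibers then stay at or below optimal
# length over most of the squat and engage the passive curve mildly in the
# deepest poses, as cadaver-calibrated generic models do when driven beyond
# their validated range.
calibrate_tsl <- function(model, knee_range = c(0, 75) * pi / 180,
                          n_poses = 13) {
  knees <- seq(knee_range[1], knee_range[2], length.out = n_poses)
  Q <- t(vapply(knees, function(qk) squat_pose(model, qk), numeric(3)))
  colnames(Q) <- names(squat_pose(model, 0))
  L <- mtu_length_frames(model, Q)
  for (i in seq_along(model$muscles)) {
    mu <- model$muscles[[i]]
    model$muscles[[i]]$tsl <- max(max(L[, mu$name]) -
                                    mu$l_opt * cos(mu$pen_opt), 0.01)
  }
  model
}

#' Subject landmark distances from stature
#'
#' Derives the landmark-pair distances needed by [scale_model()] from stature
#' using fixed allometric fractions (the same fractions the generic skeleton
#' is built with, so a subject at the generic stature scales by 1).
#'
#' @param height stature (m).
#' @return named numeric vector of landmark distances (m).
#' @export
landmark_distances_from_height <- function(height) {
  c(pelvis_width = SEGMENT_LENGTH_FRACTION[["pelvis_width"]] * height,
    femur_length = SEGMENT_LENGTH_FRACTION[["femur_length"]] * height,
    tibia_length = SEGMENT_LENGTH_FRACTION[["tibia_length"]] * height)
}
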