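# Anthropometric scaling of the generic model to a subject.

# Landmark pair that drives each segment's isotropic scale factor.  The foot
# follows the tibia (no dedicated landmark in the reduced set).
SEGMENT_LANDMARK <- c(pelvis = "pelvis_width", femur = "femur_length",
                      tibia = "tibia_length", foot = "tibia_length")

#' Scale the generic model to a subject
#'
#' Segment lengths, centres of mass and muscle path points are scaled
#' isotropically per segment by the ratio of the subject's landmark distance
#' to the generic model's; segment masses are scaled by the subject/generic
#' total mass ratio (mass fractions preserved); inertias scale with mass and
#' length squared.  Optimal fiber length and tendon slack length are each
#' scaled by the ratio of the scaled to generic total MTU length in the
#' neutral reference pose (all joint angles zero), preserving their ratio.
#' Maximum isometric forces are taken directly from the generic model.
#'
#' @param generic the generic [lowerlimb_model()].
#' @param landmark_distances named numeric vector with entries
#'   `pelvis_width`, `femur_length`, `tibia_length` (m, > 0).
#' @param subject_mass subject mass (kg).
#' @param subject_height optional subject stature (m); recorded on the model.
#' @return the scaled [lowerlimb_model()].
#' @export
scale_model <- function(generic, landmark_distances, subject_mass,
                        subject_height = generic$subject_height) {
  need <- unique(SEGMENT_LANDMARK)
  missing <- setdiff(need, names(landmark_distances))
  if (length(missing))
    stopf("missing landmark pair(s): %s", paste(missing, collapse = ", "))
  if (any(landmark_distances[need] <= 0))
    stopf("landmark distances must be > 0")
  if (!is_scalar_number(subject_mass) || subject_mass <= 0)
    stopf("subject_mass must be > 0")

  generic_lm <- landmark_distances_from_height(generic$subject_height)
  sf <- stats::setNames(
    as.numeric(landmark_distances[SEGMENT_LANDMARK] /
                 generic_lm[SEGMENT_LANDMARK]),
    names(SEGMENT_LANDMARK))
  mass_ratio <- subject_mass / generic$subject_mass

  m <- generic
  for (s in names(m$segments)) {
    k <- sf[[s]]
    m$segments[[s]]$length <- m$segments[[s]]$length * k
    m$segments[[s]]$com_local <- m$segments[[s]]$com_local * k
    m$segments[[s]]$mass <- m$segments[[s]]$mass * mass_ratio
    m$segments[[s]]$inertia_zz <- m$segments[[s]]$inertia_zz * mass_ratio * k^2
  }
  for (d in names(m$dofs))
    m$dofs[[d]]$location_parent <- m$dofs[[d]]$location_parent * sf[[m$dofs[[d]]$parent]]
  for (i in seq_along(m$muscles)) {
    for (k in seq_along(m$muscles[[i]]$pathway)) {
      p <- m$muscles[[i]]$pathway[[k]]
      m$muscles[[i]]$pathway[[k]]$position_local <-
        p$position_local * sf[[p$segment]]
    }
  }
  if (!is.null(m$markers))
    m$markers[, c("x", "y")] <- m$markers[, c("x", "y")] *
      sf[m$markers$segment]

  # MTU-length-based scaling of l_opt and tsl in the neutral reference pose
  ref <- stats::setNames(rep(0, length(m$dofs)), names(m$dofs))
  L_gen <- mtu_length_frames(generic, ref)
  L_new <- mtu_length_frames(m, ref)
  for (i in seq_along(m$muscles)) {
    nm <- m$muscles[[i]]$name
    ratio <- unname(L_new[1, nm] / L_gen[1, nm])
    m$muscles[[i]]$l_opt <- m$muscles[[i]]$l_opt * ratio
    m$muscles[[i]]$tsl <- m$muscles[[i]]$tsl * ratio
  }

  m$subject_mass <- subject_mass
  m$subject_height <- subject_height
  m$provenance <- "baseline"
  validate_model(m)
  m
}

#' Read landmark distances from a CSV file
#'
#' Flat two-column key/value file with a header row `landmark,distance_m`.
#'
#' @param path file path.
#' @return named numeric vector of distances (m).
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("landmark", "distance_m") %in% names(d)))
    stopf("landmark file must have columns landmark,distance_m: %s", path)
  stats::setNames(as.numeric(d$distance_m), d$landmark)
}
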