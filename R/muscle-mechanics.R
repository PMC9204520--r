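# Hill-type muscle mechanics with a rigid tendon.
#
# The fiber operates in series with an inextensible tendon of length tsl and
# at a pennation angle following the constant-thickness assumption:
#   l_fiber * sin(alpha) = l_opt * sin(pen_opt)   (muscle thickness h)
#   l_fiber * cos(alpha) = L_mtu - tsl
# Curve set (documented, normalized so fl(1) = 1, fpe(1) = 0, fv(0) = 1):
#   active force-length:  fl(lt)  = exp(-(lt - 1)^2 / GAMMA_FL)
#   passive force-length: fpe(lt) = (exp(KPE * (lt - 1) / E0) - 1) / (exp(KPE) - 1), lt > 1
#   force-velocity (vt in optimal fiber lengths per second, shortening < 0):
#     concentric: fv = (VMAX + vt) / (VMAX - vt / AF)
#     eccentric:  fv = (FVECC * vt + CECC) / (vt + CECC), slope-continuous at 0

GAMMA_FL <- 0.45
KPE <- 4
E0 <- 0.6
VMAX <- 10      # l_opt / s
AF <- 0.25
FVECC <- 1.8
CECC <- 1.6
MIN_FIBER_FRAC <- 0.01  # lower clamp on the along-tendon fiber component

#' Hill active force-length curve
#' @param lt normalized fiber length.
#' @return active force-length factor in [0, 1].
#' @export
fl_active <- function(lt) exp(-(lt - 1)^2 / GAMMA_FL)

#' Hill passive force-length curve
#' @param lt normalized fiber length.
#' @return passive force factor (0 for lt <= 1, nondecreasing).
#' @export
fl_passive <- function(lt) {
  ifelse(lt > 1, (exp(KPE * (lt - 1) / E0) - 1) / (exp(KPE) - 1), 0)
}

#' Hill force-velocity curve
#' @param vt normalized fiber velocity (l_opt/s, shortening negative).
#' @return force-velocity factor (fv(0) = 1, 0 at -VMAX, asymptote 1.8).
#' @export
fv_curve <- function(vt) {
  ifelse(vt < 0,
         pmax(0, (VMAX + vt) / (VMAX - vt / AF)),
         (FVECC * vt + CECC) / (vt + CECC))
}

#' Rigid-tendon fiber state
#'
#' @param muscle an [mtu()].
#' @param mtu_length MTU length(s) (m).
#' @param mtu_velocity MTU lengthening velocity(ies) (m/s); default 0.
#' @return list with `lt` (normalized fiber length), `vt` (normalized fiber
#'   velocity, l_opt/s), `pen` (pennation, rad), `clamped` (logical; TRUE
#'   where the MTU is at or below tendon slack length and the fiber was held
#'   at its lower clamp).
#' @export
fiber_state <- function(muscle, mtu_length, mtu_velocity = 0) {
  h <- muscle$l_opt * sin(muscle$pen_opt)
  proj <- mtu_length - muscle$tsl
  clamped <- proj <= MIN_FIBER_FRAC * muscle$l_opt
  proj <- pmax(proj, MIN_FIBER_FRAC * muscle$l_opt)
  lf <- sqrt(proj^2 + h^2)
  pen <- atan2(h, proj)
  vf <- ifelse(clamped, 0, mtu_velocity * proj / lf)
  list(lt = lf / muscle$l_opt, vt = vf / muscle$l_opt, pen = pen,
       clamped = clamped)
}

#' Muscle force along the tendon
#'
#' With `include_flv = TRUE` the full Hill model force
#' `mif * (a * fl(lt) * fv(vt) + fpe(lt)) * cos(pen)`; with
#' `include_flv = FALSE` the ideal-generator simplification `mif * a *
#' cos(pen)` (no force-length/velocity or passive contribution).
#'
#' @param muscle an [mtu()].
#' @param activation activation in [0, 1].
#' @param state a [fiber_state()] result.
#' @param include_flv logical; include force-length/velocity characteristics.
#' @return force along the tendon (N).
#' @export
muscle_force_scalar <- function(muscle, activation, state, include_flv = TRUE) {
  if (any(activation < 0 | activation > 1)) stopf("activation must be in [0, 1]")
  if (include_flv) {
    muscle$mif * (activation * fl_active(state$lt) * fv_curve(state$vt) +
                    fl_passive(state$lt)) * cos(state$pen)
  } else {
    muscle$mif * activation * cos(state$pen)
  }
}
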