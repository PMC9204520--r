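# Forward kinematics of the planar chain, muscle-tendon lengths, and
# tendon-excursion moment arms.
#
# Frames: the root segment frame is the world frame.  Each child frame is
# rotated by axis_sign * q relative to its parent and originates at the joint
# centre.  World segment angle alpha accumulates down the tree.

# Topologically ordered dof list (parents before children).  The model's dofs
# are stored in order for the default model; for arbitrary trees we sort by
# depth from the root.
dof_order <- function(model) {
  root <- model$segments[[1]]$name
  depth <- stats::setNames(rep(NA_real_, length(model$segments)),
                           names(model$segments))
  depth[root] <- 0
  dofs <- model$dofs
  remaining <- seq_along(dofs)
  ord <- integer(0)
  while (length(remaining)) {
    placed <- FALSE
    for (i in remaining) {
      if (!is.na(depth[dofs[[i]]$parent])) {
        depth[dofs[[i]]$child] <- depth[dofs[[i]]$parent] + 1
        ord <- c(ord, i)
        remaining <- setdiff(remaining, i)
        placed <- TRUE
      }
    }
    if (!placed) stopf("joint graph is not rooted at '%s'", root)
  }
  ord
}

# Depth of each segment in the chain (root = 0); used to decide which joints
# a pathway segment crosses.
segment_depth <- function(model) {
  root <- model$segments[[1]]$name
  depth <- stats::setNames(rep(NA_real_, length(model$segments)),
                           names(model$segments))
  depth[root] <- 0
  for (i in dof_order(model)) {
    d <- model$dofs[[i]]
    depth[d$child] <- depth[d$parent] + 1
  }
  depth
}

#' Forward kinematics over frames
#'
#' Computes world orientation and origin of every segment for a matrix of
#' poses.
#'
#' @param model a [lowerlimb_model()].
#' @param Q numeric matrix (frames x dofs) with columns named after the
#'   model's dofs; a named vector is treated as a single frame.
#' @return a list with per-segment elements `alpha` (frame vector of world
#'   angles, rad), `ox`, `oy` (frame vectors of world origin coordinates), and
#'   cached `ca`, `sa` cosines/sines.
#' @export
fk_frames <- function(model, Q) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1, dimnames = list(NULL, names(Q)))
  n <- nrow(Q)
  root <- model$segments[[1]]$name
  zero <- numeric(n)
  out <- list()
  out[[root]] <- list(alpha = zero, ox = zero, oy = zero,
                      ca = rep(1, n), sa = zero)
  for (i in dof_order(model)) {
    d <- model$dofs[[i]]
    q <- Q[, d$name]
    par <- out[[d$parent]]
    alpha <- par$alpha + d$axis_sign * q
    jx <- par$ox + par$ca * d$location_parent[1] - par$sa * d$location_parent[2]
    jy <- par$oy + par$sa * d$location_parent[1] + par$ca * d$location_parent[2]
    out[[d$child]] <- list(alpha = alpha, ox = jx, oy = jy,
                           ca = cos(alpha), sa = sin(alpha))
  }
  out
}

# World coordinates of a local point over frames, given an fk_frames() result.
world_point <- function(fk, segment, p) {
  s <- fk[[segment]]
  list(x = s$ox + s$ca * p[1] - s$sa * p[2],
       y = s$oy + s$sa * p[1] + s$ca * p[2])
}

#' Muscle-tendon lengths over frames
#'
#' Sum of Euclidean distances between consecutive pathway points expressed in
#' the world frame.
#'
#' @param model a [lowerlimb_model()].
#' @param Q pose matrix as in [fk_frames()].
#' @param fk optional precomputed [fk_frames()] result for `Q`.
#' @return numeric matrix (frames x muscles) of MTU lengths (m).
#' @export
mtu_length_frames <- function(model, Q, fk = NULL) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1, dimnames = list(NULL, names(Q)))
  if (is.null(fk)) fk <- fk_frames(model, Q)
  n <- nrow(Q)
  L <- matrix(0, n, length(model$muscles),
              dimnames = list(NULL, names(model$muscles)))
  for (mi in seq_along(model$muscles)) {
    mu <- model$muscles[[mi]]
    prev <- world_point(fk, mu$pathway[[1]]$segment, mu$pathway[[1]]$position_local)
    acc <- numeric(n)
    for (k in 2:length(mu$pathway)) {
      cur <- world_point(fk, mu$pathway[[k]]$segment, mu$pathway[[k]]$position_local)
      acc <- acc + sqrt((cur$x - prev$x)^2 + (cur$y - prev$y)^2)
      prev <- cur
    }
    L[, mi] <- acc
  }
  L
}

#' Muscle-tendon length at one pose
#'
#' @param model a [lowerlimb_model()].
#' @param muscle muscle name.
#' @param pose named numeric vector of joint angles (rad).
#' @return MTU length (m).
#' @export
mtu_length <- function(model, muscle, pose) {
  if (!(muscle %in% names(model$muscles))) stopf("unknown muscle '%s'", muscle)
  Q <- matrix(pose, nrow = 1, dimnames = list(NULL, names(pose)))
  unname(mtu_length_frames(model, Q)[1, muscle])
}

#' Tendon-excursion moment arms over frames
#'
#' Moment arm of every muscle about every dof, r = -dL/dq, by central finite
#' difference of [mtu_length_frames()].  Positive moment arms produce positive
#' (flexion) joint moments for positive (tensile) muscle force.
#'
#' @param model a [lowerlimb_model()].
#' @param Q pose matrix (frames x dofs).
#' @param step finite-difference step (rad); default 1e-5.
#' @return array (frames x muscles x dofs), in m.
#' @export
moment_arm_frames <- function(model, Q, step = 1e-5) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1, dimnames = list(NULL, names(Q)))
  n <- nrow(Q)
  dn <- names(model$dofs)
  R <- array(0, dim = c(n, length(model$muscles), length(dn)),
             dimnames = list(NULL, names(model$muscles), dn))
  for (d in dn) {
    Qp <- Q; Qp[, d] <- Qp[, d] + step
    Qm <- Q; Qm[, d] <- Qm[, d] - step
    R[, , d] <- -(mtu_length_frames(model, Qp) - mtu_length_frames(model, Qm)) /
      (2 * step)
  }
  R
}

#' Moment arm of one muscle about one dof
#'
#' Central finite difference with a one-sided fallback (and warning) when the
#' step would leave the joint range.
#'
#' @param model a [lowerlimb_model()].
#' @param muscle muscle name.
#' @param pose named numeric vector of joint angles (rad).
#' @param dof dof name.
#' @param step finite-difference step (rad).
#' @return signed moment arm (m).
#' @export
moment_arm <- function(model, muscle, pose, dof, step = 1e-5) {
  if (!(dof %in% names(model$dofs))) stopf("unknown dof '%s'", dof)
  if (!(muscle %in% names(model$muscles))) stopf("unknown muscle '%s'", muscle)
  rng <- model$dofs[[dof]]$range
  q <- pose[dof]
  lo <- q - step >= rng[1]
  hi <- q + step <= rng[2]
  if (lo && hi) {
    pp <- pose; pp[dof] <- q + step
    pm <- pose; pm[dof] <- q - step
    return(unname(-(mtu_length(model, muscle, pp) -
                      mtu_length(model, muscle, pm)) / (2 * step)))
  }
  {
    warnf("moment_arm: step straddles the range of '%s'; one-sided difference", dof)
    if (!hi) {
      pm <- pose; pm[dof] <- q - step
      unname(-(mtu_length(model, muscle, pose) -
                 mtu_length(model, muscle, pm)) / step)
    } else {
      pp <- pose; pp[dof] <- q + step
      unname(-(mtu_length(model, muscle, pp) -
                 mtu_length(model, muscle, pose)) / step)
    }
  }
}

#' Dofs spanned by a muscle
#'
#' A pathway segment between points on segments at chain depths d1 < d2
#' crosses every joint whose child segment depth lies in (d1, d2].
#'
#' @param model a [lowerlimb_model()].
#' @param muscle muscle name.
#' @return character vector of dof names.
#' @export
spanned_dofs <- function(model, muscle) {
  mu <- model$muscles[[muscle]]
  if (is.null(mu)) stopf("unknown muscle '%s'", muscle)
  depth <- segment_depth(model)
  segs <- vapply(mu$pathway, `[[`, "", "segment")
  crossed <- character(0)
  for (k in seq_len(length(segs) - 1)) {
    d1 <- depth[segs[k]]; d2 <- depth[segs[k + 1]]
    if (d1 == d2) next
    lo <- min(d1, d2); hi <- max(d1, d2)
    for (d in model$dofs)
      if (depth[d$child] > lo && depth[d$child] <= hi)
        crossed <- c(crossed, d$name)
  }
  unique(crossed)
}

# For a muscle crossing `dof`, the index k of the pathway pair (k, k+1) that
# crosses the joint, with the pair ordered so that element `distal` is on the
# distal side.  Used by the joint reaction force assembly.
crossing_pair <- function(model, muscle, dof) {
  mu <- model$muscles[[muscle]]
  depth <- segment_depth(model)
  dchild <- depth[model$dofs[[dof]]$child]
  segs <- vapply(mu$pathway, `[[`, "", "segment")
  for (k in seq_len(length(segs) - 1)) {
    d1 <- depth[segs[k]]; d2 <- depth[segs[k + 1]]
    if (min(d1, d2) < dchild && max(d1, d2) >= dchild)
      return(list(k = k, distal = if (d1 >= dchild) k else k + 1L))
  }
  NULL
}

#' Standard squat pose for a knee flexion angle
#'
#' Kinematic closure used throughout the package: foot flat on the ground and
#' the pelvis (trunk) vertical, which ties hip flexion to `q_hip = q_knee -
#' q_ankle`; ankle dorsiflexion is then solved so the model's centre of mass
#' lies vertically above the ankle.  The closure is a pure function of the
#' knee angle and the model's geometry.
#'
#' @param model a [lowerlimb_model()].
#' @param knee_flexion knee flexion angle (rad, >= 0).
#' @return named numeric vector with hip, knee and ankle angles (rad).
#' @export
squat_pose <- function(model, knee_flexion) {
  if (knee_flexion < 0) stopf("knee_flexion must be >= 0")
  if (knee_flexion == 0)
    return(c(hip_flexion = 0, knee_flexion = 0, ankle_flexion = 0))
  com_offset <- function(qa) {
    q <- c(hip_flexion = knee_flexion - qa, knee_flexion = knee_flexion,
           ankle_flexion = qa)
    fk <- fk_frames(model, q)
    tot <- 0; mx <- 0; ax <- world_point(fk, "foot", c(0, 0))$x
    for (s in model$segments) {
      w <- world_point(fk, s$name, s$com_local)
      tot <- tot + s$mass
      mx <- mx + s$mass * w$x
    }
    mx / tot - ax
  }
  hi <- min(knee_flexion, 44 * pi / 180)
  f_lo <- com_offset(0); f_hi <- com_offset(hi)
  if (f_lo * f_hi > 0) {
    # COM cannot be brought over the ankle exactly; take the boundary closer
    qa <- if (abs(f_lo) < abs(f_hi)) 0 else hi
  } else {
    qa <- stats::uniroot(com_offset, c(0, hi), tol = 1e-10)$root
  }
  c(hip_flexion = knee_flexion - qa, knee_flexion = knee_flexion,
    ankle_flexion = qa)
}
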