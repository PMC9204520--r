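# Squat trial container, planar inverse dynamics, and marker-based inverse
# kinematics.
#
# Trial ground frame: x anterior, y up, origin on the ground vertically below
# the ankle joint at frame 1.  GRF centre of pressure (cop_x) is expressed in
# this frame.  Internally the chain is re-rooted at the ankle each frame
# (foot-flat assumption of the squat), which also supplies the base for
# segment accelerations in dynamic mode.

# Vertical drop from the ankle joint centre to the sole plane where the GRF
# is applied, as a fraction of stature.
SOLE_DROP_FRACTION <- 0.04 / 1.70

#' Create a squat trial
#'
#' @param time time grid (s, uniform).
#' @param joint_angles matrix (frames x dofs) of joint angles (rad), columns
#'   named after the model dofs.
#' @param grf data.frame or matrix with columns `fx`, `fy` (per-limb ground
#'   reaction force, N) and `cop_x` (centre of pressure, m, ground frame).
#' @param cycle_events integer vector `c(start, deepest, end)` of frame
#'   indices; `deepest` must lie strictly between `start` and `end`.
#' @param subject list with `mass` (kg) and `height` (m).
#' @param markers optional marker trajectories (as from [read_trc()]).
#' @param measured_kcf optional measured knee contact force trace (BW).
#' @param emg optional list of raw EMG signals.
#' @return an object of class `squat_trial`.
#' @export
squat_trial <- function(time, joint_angles, grf, cycle_events, subject,
                        markers = NULL, measured_kcf = NULL, emg = NULL) {
  n <- length(time)
  if (n < 1L) stopf("trial must have at least one frame")
  if (n > 1L) {
    dt <- diff(time)
    if (any(abs(dt - dt[1]) > 1e-9 * max(1, abs(dt[1]))))
      stopf("time grid must be uniform")
  }
  joint_angles <- as.matrix(joint_angles)
  if (nrow(joint_angles) != n) stopf("joint_angles must have one row per frame")
  grf <- as.data.frame(grf)
  if (!all(c("fx", "fy", "cop_x") %in% names(grf)))
    stopf("grf must have columns fx, fy, cop_x")
  if (nrow(grf) != n) stopf("grf must have one row per frame")
  if (any(grf$fy < 0)) stopf("vertical GRF must be >= 0")
  if (n > 2L) {
    if (length(cycle_events) != 3L ||
        !(cycle_events[2] > cycle_events[1] && cycle_events[2] < cycle_events[3]))
      stopf("cycle_events must be c(start, deepest, end) with deepest strictly inside")
  }
  structure(list(time = as.numeric(time), joint_angles = joint_angles,
                 grf = grf, cycle_events = as.integer(cycle_events),
                 subject = subject, markers = markers,
                 measured_kcf = measured_kcf, emg = emg),
            class = "squat_trial")
}

#' @export
print.squat_trial <- function(x, ...) {
  cat(sprintf("<squat_trial> %d frames over %.2f s, subject %.1f kg / %.2f m, peak knee flexion %.1f deg\n",
              length(x$time), diff(range(x$time)), x$subject$mass,
              x$subject$height, max(x$joint_angles[, "knee_flexion"]) * 180 / pi))
  invisible(x)
}

# Ground-rooted forward kinematics for a trial: pelvis-rooted fk shifted so
# the ankle joint sits at (0, sole_drop) in every frame.
ground_fk <- function(model, Q) {
  fk <- fk_frames(model, Q)
  ankle <- world_point(fk, "foot", c(0, 0))
  drop <- SOLE_DROP_FRACTION * model$subject_height
  for (s in names(fk)) {
    fk[[s]]$ox <- fk[[s]]$ox - ankle$x
    fk[[s]]$oy <- fk[[s]]$oy - ankle$y + drop
  }
  fk
}

# Low-pass filtered second derivative of each column of x sampled at rate fs.
# Zero-phase 2nd-order Butterworth followed by central differences; ends are
# one-sided.  Used for segment accelerations in dynamic mode.
filtered_accel <- function(x, fs, cutoff_hz = 6) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 7) return(matrix(0, n, ncol(x)))
  wn <- min(cutoff_hz / (fs / 2), 0.99)
  bf <- signal::butter(2, wn, type = "low")
  xf <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  d2 <- apply(xf, 2, function(col) {
    v <- c(NA, diff(col, lag = 2) / 2, NA)
    v[1] <- col[2] - col[1]; v[n] <- col[n] - col[n - 1]
    a <- c(NA, diff(v, lag = 2) / 2, NA)
    a[1] <- a[2]; a[n] <- a[n - 1]
    a
  })
  d2 * fs^2
}

#' Planar inverse dynamics of a squat trial
#'
#' Newton-Euler recursion from the foot upward using the measured GRF,
#' returning net internal joint moments (flexion positive, the moment the
#' muscles must generate) and the knee intersegmental force (force on the
#' tibia from the femur through all structures, ground frame).
#'
#' In quasi-static mode (default) segment accelerations are zero; in dynamic
#' mode they are obtained by low-pass-filtered double differentiation of the
#' ground-rooted segment kinematics.
#'
#' @param trial a [squat_trial()].
#' @param model a [lowerlimb_model()].
#' @param quasi_static logical; zero all accelerations (default TRUE).
#' @param cutoff_hz low-pass cutoff for differentiation (Hz, dynamic mode).
#' @return an object of class `joint_moment_trace`: list with `moments`
#'   (frames x dofs, N m, flexion positive), `knee_intersegmental` (frames x
#'   2, N, ground frame), and the ground-rooted `fk`.
#' @export
inverse_dynamics <- function(trial, model, quasi_static = TRUE, cutoff_hz = 6) {
  Q <- trial$joint_angles
  n <- nrow(Q)
  fk <- ground_fk(model, Q)
  g <- c(0, -GRAVITY)

  # world COM positions and segment angles per frame
  com <- lapply(model$segments, function(s) world_point(fk, s$name, s$com_local))
  if (quasi_static || n < 7) {
    acc <- lapply(model$segments, function(s) list(x = numeric(n), y = numeric(n)))
    angacc <- lapply(model$segments, function(s) numeric(n))
  } else {
    fs <- 1 / diff(trial$time[1:2])
    acc <- lapply(model$segments, function(s) {
      a <- filtered_accel(cbind(com[[s$name]]$x, com[[s$name]]$y), fs, cutoff_hz)
      list(x = a[, 1], y = a[, 2])
    })
    angacc <- lapply(model$segments, function(s) {
      filtered_accel(cbind(fk[[s$name]]$alpha), fs, cutoff_hz)[, 1]
    })
  }

  sole_y <- 0
  copx <- trial$grf$cop_x
  grf_fx <- trial$grf$fx; grf_fy <- trial$grf$fy

  crossz <- function(rx, ry, fx, fy) rx * fy - ry * fx

  # recursion state: force/moment each processed segment receives from its
  # parent (to be reacted onto the parent)
  Fjx <- list(); Fjy <- list(); Mj <- list()
  child_joints <- lapply(names(model$segments), function(s)
    Filter(function(d) d$parent == s, model$dofs))
  names(child_joints) <- names(model$segments)

  moments <- matrix(0, n, length(model$dofs),
                    dimnames = list(NULL, names(model$dofs)))
  knee_f <- matrix(0, n, 2, dimnames = list(NULL, c("fx", "fy")))

  ord <- rev(dof_order(model))  # distal segments first
  for (i in ord) {
    d <- model$dofs[[i]]
    s <- model$segments[[d$child]]
    par <- fk[[d$parent]]
    jx <- par$ox + par$ca * d$location_parent[1] - par$sa * d$location_parent[2]
    jy <- par$oy + par$sa * d$location_parent[1] + par$ca * d$location_parent[2]

    m <- s$mass
    fx <- m * acc[[s$name]]$x - m * g[1]
    fy <- m * acc[[s$name]]$y - m * g[2]
    # moment balance about the segment COM
    mz <- s$inertia_zz * angacc[[s$name]]

    if (s$name == "foot") {
      fx <- fx - grf_fx
      fy <- fy - grf_fy
      mz <- mz - crossz(copx - com[["foot"]]$x, sole_y - com[["foot"]]$y,
                        grf_fx, grf_fy)
    }
    for (cd in child_joints[[s$name]]) {
      cjx <- fk[[s$name]]$ox + fk[[s$name]]$ca * cd$location_parent[1] -
        fk[[s$name]]$sa * cd$location_parent[2]
      cjy <- fk[[s$name]]$oy + fk[[s$name]]$sa * cd$location_parent[1] +
        fk[[s$name]]$ca * cd$location_parent[2]
      fx <- fx + Fjx[[cd$child]]
      fy <- fy + Fjy[[cd$child]]
      mz <- mz + Mj[[cd$child]] +
        crossz(cjx - com[[s$name]]$x, cjy - com[[s$name]]$y,
               Fjx[[cd$child]], Fjy[[cd$child]])
    }
    Mzj <- mz - crossz(jx - com[[s$name]]$x, jy - com[[s$name]]$y, fx, fy)
    Fjx[[s$name]] <- fx; Fjy[[s$name]] <- fy; Mj[[s$name]] <- Mzj
    moments[, d$name] <- d$axis_sign * Mzj
    if (d$name == "knee_flexion") { knee_f[, 1] <- fx; knee_f[, 2] <- fy }
  }

  structure(list(moments = moments, knee_intersegmental = knee_f, fk = fk,
                 time = trial$time),
            class = "joint_moment_trace")
}

#' Marker-based inverse kinematics
#'
#' Per-frame weighted least-squares fit of the model's virtual markers to
#' measured planar marker positions, solving for the pelvis translation and
#' the three joint angles by Gauss-Newton with numeric Jacobians.
#'
#' @param markers list with `time` (s), `labels` (marker names) and `coords`
#'   (array frames x markers x 2, m) as returned by [read_trc()] (the third
#'   TRC axis is dropped).
#' @param model a [lowerlimb_model()] carrying a `markers` table.
#' @param weights optional per-marker weights (default equal).
#' @param tol convergence tolerance on the coordinate update (rad / m).
#' @param max_iter Gauss-Newton iteration cap per frame.
#' @return list with `joint_angles` (frames x dofs, rad), `translation`
#'   (frames x 2, m) and `residual_rms` (frames, m).
#' @export
inverse_kinematics <- function(markers, model, weights = NULL,
                               tol = 1e-10, max_iter = 100) {
  if (is.null(model$markers)) stopf("model carries no marker set")
  lab <- intersect(markers$labels, model$markers$name)
  if (length(lab) < 3L)
    stopf("need >= 3 markers shared with the model; got %d", length(lab))
  mk <- model$markers[match(lab, model$markers$name), ]
  if (is.null(weights)) weights <- rep(1, length(lab))
  w <- sqrt(weights / sum(weights))
  n <- dim(markers$coords)[1]
  obs_idx <- match(lab, markers$labels)

  dofn <- names(model$dofs)
  predict_markers <- function(par) {
    q <- stats::setNames(par[3:(2 + length(dofn))], dofn)
    fk <- fk_frames(model, q)
    out <- matrix(0, length(lab), 2)
    for (k in seq_along(lab)) {
      p <- world_point(fk, mk$segment[k], c(mk$x[k], mk$y[k]))
      out[k, ] <- c(p$x + par[1], p$y + par[2])
    }
    out
  }

  angles <- matrix(0, n, length(dofn), dimnames = list(NULL, dofn))
  trans <- matrix(0, n, 2)
  rms <- numeric(n)
  par <- rep(0, 2 + length(dofn))
  npar <- length(par)
  for (f in seq_len(n)) {
    obs <- markers$coords[f, obs_idx, 1:2, drop = FALSE]
    obs <- matrix(obs, length(lab), 2)
    if (max(stats::dist(obs)) < 1e-9)
      stopf("frame %d is underdetermined: markers coincident", f)
    conv <- FALSE
    hist <- numeric(0)
    for (it in seq_len(max_iter)) {
      pred <- predict_markers(par)
      r <- as.numeric((pred - obs) * w)
      J <- matrix(0, length(r), npar)
      h <- 1e-7
      for (p in seq_len(npar)) {
        pp <- par; pp[p] <- pp[p] + h
        J[, p] <- (as.numeric((predict_markers(pp) - obs) * w) - r) / h
      }
      sv <- svd(J)
      if (min(sv$d) < 1e-8 * max(sv$d))
        stopf("frame %d is underdetermined: singular marker Jacobian", f)
      step <- -sv$v %*% ((t(sv$u) %*% r) / sv$d)
      par <- par + as.numeric(step)
      hist <- c(hist, sqrt(mean(r^2)))
      if (max(abs(step)) < tol) { conv <- TRUE; break }
    }
    if (!conv)
      stopf("inverse kinematics did not converge at frame %d (residual history: %s)",
            f, paste(signif(utils::tail(hist, 5), 4), collapse = ", "))
    pred <- predict_markers(par)
    angles[f, ] <- par[3:(2 + length(dofn))]
    trans[f, ] <- par[1:2]
    rms[f] <- sqrt(mean((pred - obs)^2))
  }
  list(joint_angles = angles, translation = trans, residual_rms = rms)
}
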