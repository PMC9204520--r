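# Static optimization of the muscle redundancy problem and joint reaction
# force assembly.
#
# Per frame:  min sum(a_i^2)  s.t.  sum_i a_i C_ji = m_j  (per dof j),
#             0 <= a_i <= 1,
# with C_ji = (max active along-tendon force at the current state) * moment
# arm, and activation-independent passive fiber forces moved to the
# right-hand side.  The equality-constrained box-bounded QP is solved exactly
# by an active-set method on the bounds; the free-variable subproblem has the
# closed-form least-norm solution a_F = C_F' (C_F C_F')^+ rhs.

#' Solve the bounded minimum-activation quadratic program
#'
#' Minimizes the sum of squared activations subject to joint-moment equality
#' constraints and activation bounds.  Infeasible demands (no activation
#' vector in the box satisfies the constraints) are detected by the final
#' constraint residual; callers then fall back to a bounded least-squares
#' solution (see [solve_frame()]).
#'
#' @param C constraint matrix (dofs x muscles), N m per unit activation.
#' @param m demand vector (N m per dof).
#' @param tol active-set tolerance on bounds and multipliers.
#' @param state optional warm-start activity pattern (integer vector:
#'   0 free, -1 at lower bound, +1 at upper bound).
#' @return list with `a` (activations), `lambda` (constraint multipliers),
#'   `residual` (max abs constraint violation), `objective`, `iterations`,
#'   `state` (final activity pattern).
#' @export
solve_activation_qp <- function(C, m, tol = 1e-8, state = NULL) {
  n <- ncol(C); k <- nrow(C)
  if (is.null(state) || length(state) != n) state <- integer(n)
  max_iter <- 20L * (n + 1L)
  a <- numeric(n)
  lam <- numeric(k)
  it <- 0L
  repeat {
    it <- it + 1L
    free <- which(state == 0L)
    up <- which(state == 1L)
    rhs <- m - (if (length(up)) rowSums(C[, up, drop = FALSE]) else 0)
    a[state == -1L] <- 0
    a[up] <- 1
    if (length(free)) {
      Cf <- C[, free, drop = FALSE]
      sv <- svd(Cf)
      pos <- sv$d > 1e-10 * max(sv$d[1], 1e-300)
      ur <- crossprod(sv$u, rhs)
      a[free] <- sv$v %*% ifelse(pos, ur / sv$d, 0)
      lam <- as.numeric(sv$u %*% ifelse(pos, ur / sv$d^2, 0))
    } else {
      # all variables at bounds: multipliers from least squares C' lam ~ a
      sv <- svd(t(C))
      pos <- sv$d > 1e-10 * max(sv$d[1], 1e-300)
      lam <- as.numeric(sv$v %*% ifelse(pos, crossprod(sv$u, a) / sv$d, 0))
    }
    if (it >= max_iter) break
    viol_lo <- state == 0L & a < -tol
    viol_hi <- state == 0L & a > 1 + tol
    if (any(viol_lo) || any(viol_hi)) {
      excess <- pmax(ifelse(viol_lo, -a, -Inf), ifelse(viol_hi, a - 1, -Inf))
      i <- which.max(excess)
      state[i] <- if (viol_lo[i]) -1L else 1L
      next
    }
    # if the equality is not met on the current free set, release the bound
    # variable that reduces the constraint residual fastest (NNLS-style);
    # only when no such variable exists is the demand genuinely infeasible
    resid_vec <- as.numeric(C %*% a - m)
    if (max(abs(resid_vec)) > tol * max(1, max(abs(m)))) {
      g <- as.numeric(crossprod(C, resid_vec))
      cand_lo <- state == -1L & g < -tol
      cand_hi <- state == 1L & g > tol
      if (any(cand_lo) || any(cand_hi)) {
        score <- ifelse(cand_lo | cand_hi, abs(g), -Inf)
        state[which.max(score)] <- 0L
        next
      }
      break
    }
    gcl <- as.numeric(crossprod(C, lam))
    rel_lo <- state == -1L & gcl > tol
    rel_hi <- state == 1L & gcl < 1 - tol
    if (any(rel_lo) || any(rel_hi)) {
      score <- ifelse(rel_lo, gcl, ifelse(rel_hi, 1 - gcl, -Inf))
      state[which.max(score)] <- 0L
      next
    }
    break
  }
  a <- pmin(pmax(a, 0), 1)
  list(a = a, lambda = lam, residual = max(abs(C %*% a - m)),
       objective = sum(a^2), iterations = it, state = state)
}

# Bounded least-squares fallback for infeasible frames: the
# minimum-constraint-violation activation in the box, with a small activation
# penalty (relative to the constraint scale) to pick a low-co-contraction
# point on flat directions.  Started from the clamped QP solution, which
# already has unloaded antagonists at zero.
ls_fallback <- function(C, m, start = NULL) {
  lam <- 1e-8 * max(sum(C * C), 1)
  fn <- function(a) {
    r <- C %*% a - m
    sum(r * r) + lam * sum(a * a)
  }
  gr <- function(a) as.numeric(2 * crossprod(C, C %*% a - m)) + 2 * lam * a
  if (is.null(start)) start <- rep(0, ncol(C))
  o <- stats::optim(start, fn, gr, method = "L-BFGS-B", lower = 0, upper = 1,
                    control = list(maxit = 200, factr = 1e5))
  o$par
}

#' Solve the muscle redundancy problem for one frame
#'
#' @param moments named demand vector of net internal joint moments (N m,
#'   flexion positive), one per model dof.
#' @param model a [lowerlimb_model()].
#' @param pose named joint-angle vector (rad).
#' @param pose_velocity named joint angular velocity vector (rad/s), or NULL
#'   for a quasi-static solve (force-velocity factor 1).
#' @param include_flv include force-length(-velocity) characteristics; when
#'   FALSE every muscle is an ideal force generator along its tendon and
#'   passive forces vanish.
#' @param tol QP tolerance.
#' @return a `frame_solution`: list with `activations`, `muscle_forces` (N,
#'   along tendon), `feasible`, `objective`, `constraint_residual`, `lambda`.
#' @export
solve_frame <- function(moments, model, pose, pose_velocity = NULL,
                        include_flv = TRUE, tol = 1e-8) {
  Q <- matrix(pose, 1, dimnames = list(NULL, names(pose)))
  L <- mtu_length_frames(model, Q)[1, ]
  R <- moment_arm_frames(model, Q)[1, , , drop = FALSE]
  r <- matrix(R, dim(R)[2], dim(R)[3], dimnames = dimnames(R)[2:3])
  Ldot <- rep(0, length(L))
  if (!is.null(pose_velocity))
    for (d in names(model$dofs))
      Ldot <- Ldot - r[, d] * pose_velocity[d]
  mm <- muscle_matrices(model, matrix(L, 1, dimnames = list(NULL, names(L))),
                        matrix(Ldot, 1), include_flv)
  sol <- solve_frame_core(fmax = mm$fmax[1, ], fpass = mm$fpass[1, ],
                          r = r, moments = moments[names(model$dofs)],
                          tol = tol)
  sol
}

# Vectorized Hill factors over frames: along-tendon max active force and
# passive force per muscle (frames x muscles).
muscle_matrices <- function(model, L, Ldot, include_flv) {
  n <- nrow(L)
  nm <- names(model$muscles)
  fmax <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
  fpass <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
  clamped <- matrix(FALSE, n, length(nm), dimnames = list(NULL, nm))
  for (i in seq_along(nm)) {
    mu <- model$muscles[[i]]
    st <- fiber_state(mu, L[, i], Ldot[, i])
    clamped[, i] <- st$clamped
    if (include_flv) {
      fmax[, i] <- mu$mif * fl_active(st$lt) * fv_curve(st$vt) * cos(st$pen)
      fpass[, i] <- mu$mif * fl_passive(st$lt) * cos(st$pen)
    } else {
      fmax[, i] <- mu$mif * cos(st$pen)
    }
  }
  list(fmax = fmax, fpass = fpass, clamped = clamped)
}

# Shared per-frame core: build C and the passive-adjusted demand, run the QP,
# fall back to bounded least squares on infeasible frames.
solve_frame_core <- function(fmax, fpass, r, moments, tol = 1e-8,
                             state = NULL) {
  C <- t(r * fmax)              # dofs x muscles
  rhs <- moments - as.numeric(t(r) %*% fpass)
  qp <- solve_activation_qp(C, rhs, tol = tol, state = state)
  feas_tol <- 1e-6 * max(1, max(abs(rhs)))
  feasible <- qp$residual <= feas_tol
  a <- qp$a
  if (!feasible) a <- ls_fallback(C, rhs, start = qp$a)
  forces <- fmax * a + fpass
  structure(list(activations = a, muscle_forces = forces,
                 feasible = feasible, objective = sum(a^2),
                 constraint_residual = max(abs(C %*% a - rhs)),
                 lambda = qp$lambda, state = qp$state),
            class = "frame_solution")
}

#' Knee contact force from muscle forces and the intersegmental force
#'
#' Vector sum, on the tibial side, of the intersegmental force (from inverse
#' dynamics) and the pull of every muscle whose pathway crosses the knee,
#' each acting along the unit vector of its knee-crossing pathway segment
#' (from the distal-side attachment toward the proximal-side point).  The
#' result is the bone-on-bone force the femur applies to the tibia, expressed
#' in the tibia frame, with its magnitude reported in units of body weight.
#'
#' @param muscle_forces named vector of along-tendon muscle forces (N).
#' @param intersegmental knee intersegmental force (N, ground frame, length 2).
#' @param model a [lowerlimb_model()].
#' @param pose named joint-angle vector (rad).
#' @return list with `vector` (tibia frame, N), `vector_ground` (N) and `bw`
#'   (magnitude / subject weight).
#' @export
knee_contact_force <- function(muscle_forces, intersegmental, model, pose) {
  fk <- fk_frames(model, pose)
  fx <- intersegmental[1]; fy <- intersegmental[2]
  for (nm in names(model$muscles)) {
    if (!("knee_flexion" %in% spanned_dofs(model, nm))) next
    f <- muscle_forces[[nm]]
    if (is.null(f) || f == 0) next
    cp <- crossing_pair(model, nm, "knee_flexion")
    p1 <- model$muscles[[nm]]$pathway[[cp$k]]
    p2 <- model$muscles[[nm]]$pathway[[cp$k + 1L]]
    w1 <- world_point(fk, p1$segment, p1$position_local)
    w2 <- world_point(fk, p2$segment, p2$position_local)
    # unit vector from the distal-side point toward the proximal-side point
    if (cp$distal == cp$k) { dx <- w2$x - w1$x; dy <- w2$y - w1$y }
    else { dx <- w1$x - w2$x; dy <- w1$y - w2$y }
    len <- sqrt(dx^2 + dy^2)
    # the muscle pulls the distal segment toward the femur side; the equal
    # and opposite share appears in the contact force on the tibia
    fx <- fx - f * dx / len
    fy <- fy - f * dy / len
  }
  at <- fk[["tibia"]]$alpha[1]
  vec_t <- c(cos(at) * fx + sin(at) * fy, -sin(at) * fx + cos(at) * fy)
  bw <- sqrt(fx^2 + fy^2) / (model$subject_mass * GRAVITY)
  list(vector = vec_t, vector_ground = c(fx, fy), bw = bw)
}

# Precompute everything about a trial that does not depend on the muscle
# parameters: ground-rooted fk at the trial poses and at the finite-difference
# poses for moment arms, and the inverse-dynamics demand.  Reused across all
# Monte Carlo iterations (parameter perturbations never alter the skeleton).
trial_cache <- function(model, trial, quasi_static = TRUE, cutoff_hz = 6,
                        step = 1e-5) {
  Q <- trial$joint_angles
  dofn <- names(model$dofs)
  fks <- list(base = fk_frames(model, Q))
  for (d in dofn) {
    Qp <- Q; Qp[, d] <- Qp[, d] + step
    Qm <- Q; Qm[, d] <- Qm[, d] - step
    fks[[paste0(d, "+")]] <- fk_frames(model, Qp)
    fks[[paste0(d, "-")]] <- fk_frames(model, Qm)
  }
  id <- inverse_dynamics(trial, model, quasi_static = quasi_static,
                         cutoff_hz = cutoff_hz)
  dt <- if (length(trial$time) > 1) diff(trial$time[1:2]) else 1
  list(Q = Q, fks = fks, id = id, step = step, dt = dt,
       quasi_static = quasi_static, dofn = dofn,
       weight = trial$subject$mass * GRAVITY)
}

# Knee-crossing bookkeeping for a model (pair indices per crossing muscle).
knee_crossings <- function(model) {
  out <- list()
  for (nm in names(model$muscles))
    if ("knee_flexion" %in% spanned_dofs(model, nm))
      out[[nm]] <- crossing_pair(model, nm, "knee_flexion")
  out
}

# Full simulation of a trial for a given muscle parameter set, using a
# prebuilt trial_cache.  Returns the simulation_result structure.
simulate_with_cache <- function(model, trial, cache, include_flv = TRUE,
                                tol = 1e-8) {
  n <- nrow(cache$Q)
  dofn <- cache$dofn
  musn <- names(model$muscles)
  nmus <- length(musn)

  L <- mtu_length_frames(model, cache$Q, fk = cache$fks$base)
  R <- array(0, c(n, nmus, length(dofn)), dimnames = list(NULL, musn, dofn))
  for (d in dofn) {
    Lp <- mtu_length_frames(model, cache$Q, fk = cache$fks[[paste0(d, "+")]])
    Lm <- mtu_length_frames(model, cache$Q, fk = cache$fks[[paste0(d, "-")]])
    R[, , d] <- -(Lp - Lm) / (2 * cache$step)
  }
  if (cache$quasi_static || n < 3) {
    Ldot <- matrix(0, n, nmus)
  } else {
    Ldot <- apply(L, 2, function(col) {
      v <- c(NA, diff(col, lag = 2) / 2, NA)
      v[1] <- col[2] - col[1]; v[n] <- col[n] - col[n - 1]
      v / cache$dt
    })
  }
  mm <- muscle_matrices(model, L, Ldot, include_flv)

  # world coordinates of knee-crossing pathway segments (pull direction on
  # the tibial side), vectorized over frames
  kc <- knee_crossings(model)
  pull <- list()
  for (nm in names(kc)) {
    cp <- kc[[nm]]
    p1 <- model$muscles[[nm]]$pathway[[cp$k]]
    p2 <- model$muscles[[nm]]$pathway[[cp$k + 1L]]
    w1 <- world_point(cache$fks$base, p1$segment, p1$position_local)
    w2 <- world_point(cache$fks$base, p2$segment, p2$position_local)
    sgn <- if (cp$distal == cp$k) 1 else -1
    dx <- sgn * (w2$x - w1$x); dy <- sgn * (w2$y - w1$y)
    len <- sqrt(dx^2 + dy^2)
    pull[[nm]] <- cbind(dx / len, dy / len)
  }

  moments <- cache$id$moments
  kf <- cache$id$knee_intersegmental
  act <- matrix(0, n, nmus, dimnames = list(NULL, musn))
  forces <- act
  feasible <- logical(n)
  objective <- numeric(n)
  residual <- numeric(n)
  kcf_bw <- numeric(n)
  kcf_t <- matrix(0, n, 2, dimnames = list(NULL, c("x", "y")))
  alpha_t <- cache$fks$base[["tibia"]]$alpha

  state <- NULL
  for (f in seq_len(n)) {
    sol <- solve_frame_core(fmax = mm$fmax[f, ], fpass = mm$fpass[f, ],
                            r = matrix(R[f, , ], nmus, length(dofn),
                                       dimnames = list(musn, dofn)),
                            moments = moments[f, ], tol = tol, state = state)
    state <- sol$state
    act[f, ] <- sol$activations
    forces[f, ] <- sol$muscle_forces
    feasible[f] <- sol$feasible
    objective[f] <- sol$objective
    residual[f] <- sol$constraint_residual
    fx <- kf[f, 1]; fy <- kf[f, 2]
    for (nm in names(pull)) {
      fmus <- forces[f, nm]
      fx <- fx - fmus * pull[[nm]][f, 1]
      fy <- fy - fmus * pull[[nm]][f, 2]
    }
    kcf_bw[f] <- sqrt(fx^2 + fy^2) / cache$weight
    ca <- cos(alpha_t[f]); sa <- sin(alpha_t[f])
    kcf_t[f, ] <- c(ca * fx + sa * fy, -sa * fx + ca * fy)
  }

  structure(list(time = trial$time, activations = act, muscle_forces = forces,
                 kcf_bw = kcf_bw, kcf_tibia = kcf_t, feasible = feasible,
                 objective = objective, constraint_residual = residual,
                 moments = moments, include_flv = include_flv,
                 provenance = model$provenance),
            class = "simulation_result")
}

#' Simulate a squat trial
#'
#' Runs inverse dynamics, per-frame static optimization and joint reaction
#' force assembly over the whole trial.  Deterministic for fixed inputs.
#'
#' @param trial a [squat_trial()].
#' @param model a [lowerlimb_model()].
#' @param include_flv include muscle force-length(-velocity) characteristics
#'   in the optimization (FALSE reproduces the simplified ideal-generator
#'   variant).
#' @param quasi_static zero accelerations and fiber velocities (default).
#' @param cutoff_hz differentiation low-pass cutoff (dynamic mode).
#' @param tol QP tolerance.
#' @return a `simulation_result`: per-frame activations, muscle forces,
#'   knee contact force (`kcf_bw`, body weight; `kcf_tibia`, N in the tibia
#'   frame), feasibility flags and solver diagnostics.
#' @export
simulate_trial <- function(trial, model, include_flv = TRUE,
                           quasi_static = TRUE, cutoff_hz = 6, tol = 1e-8) {
  cache <- trial_cache(model, trial, quasi_static = quasi_static,
                       cutoff_hz = cutoff_hz)
  simulate_with_cache(model, trial, cache, include_flv = include_flv, tol = tol)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d frames, peak KCF %.2f BW, %d infeasible frame(s)\n",
              length(x$kcf_bw), max(x$kcf_bw), sum(!x$feasible)))
  invisible(x)
}
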