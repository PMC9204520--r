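# Shared fixtures: toy hinge models, independent geometric / mechanical
# oracles, and small cached pipeline objects.  Everything is built in code.

# A minimal two-segment hinge: root "arm_a" and child "arm_b" connected by a
# single flexion dof at a configurable joint location, with one straight-line
# muscle from `origin` (on arm_a) to `insertion` (on arm_b).
toy_hinge_model <- function(origin = c(0, 0.10), insertion = c(0, -0.10),
                            joint_loc = c(0, 0), axis_sign = -1,
                            mif = 1000, l_opt = 0.1, tsl = 0.1,
                            pen_opt = 0, via = NULL) {
  segs <- list(
    body_segment("arm_a", 1, c(0, 0.1), 1e-3, 0.3, NA, "hinge"),
    body_segment("arm_b", 1, c(0, -0.1), 1e-3, 0.3, "hinge", NA)
  )
  dofs <- list(joint_dof("hinge", "arm_a", "arm_b", axis_sign,
                         c(-pi, pi), joint_loc))
  pw <- list(path_point("arm_a", origin, "origin"))
  if (!is.null(via)) pw <- c(pw, list(path_point(via$segment, via$position, "via")))
  pw <- c(pw, list(path_point("arm_b", insertion, "insertion")))
  mus <- list(mtu("m1", mif, tsl, pen_opt, l_opt, pw))
  lowerlimb_model(segs, dofs, mus,
                  list(muscle_group("lower_limb", "m1")),
                  subject_mass = 10, subject_height = 1)
}

# Analytic moment arm of a straight-line muscle over a hinge: perpendicular
# distance from the joint centre to the muscle line in the current pose
# (point-to-line geometry, fully independent of the finite-difference route).
analytic_hinge_moment_arm <- function(model, pose) {
  fk <- fk_frames(model, pose)
  d <- model$dofs[[1]]
  par <- fk[[d$parent]]
  jx <- par$ox + par$ca * d$location_parent[1] - par$sa * d$location_parent[2]
  jy <- par$oy + par$sa * d$location_parent[1] + par$ca * d$location_parent[2]
  mu <- model$muscles[[1]]
  p1 <- world_point(fk, mu$pathway[[1]]$segment, mu$pathway[[1]]$position_local)
  p2 <- world_point(fk, mu$pathway[[2]]$segment, mu$pathway[[2]]$position_local)
  ux <- p2$x - p1$x; uy <- p2$y - p1$y
  len <- sqrt(ux^2 + uy^2)
  # unsigned perpendicular distance
  unname(abs(ux * (jy - p1$y) - uy * (jx - p1$x)) / len)
}

# Independent static-equilibrium oracle for inverse dynamics: for each dof,
# minus (flexion-signed) sum of moments about the joint centre of all
# external loads on the distal sub-chain (GRF at the COP plus gravity on the
# distal segments), computed by explicit cross products.
static_moment_oracle <- function(model, trial, frame) {
  Q <- trial$joint_angles[frame, , drop = FALSE]
  fk <- squatmc:::ground_fk(model, Q)
  depth <- squatmc:::segment_depth(model)
  g <- -squatmc:::GRAVITY
  out <- setNames(numeric(length(model$dofs)), names(model$dofs))
  for (d in model$dofs) {
    par <- fk[[d$parent]]
    jx <- par$ox + par$ca * d$location_parent[1] - par$sa * d$location_parent[2]
    jy <- par$oy + par$sa * d$location_parent[1] + par$ca * d$location_parent[2]
    mz <- 0
    for (s in model$segments) {
      if (depth[s$name] < depth[d$child]) next   # proximal side
      com <- world_point(fk, s$name, s$com_local)
      mz <- mz + (com$x - jx) * (s$mass * g)    # cross(r, (0, m g))_z = rx*Fy
    }
    # GRF acts on the foot (distal to every joint in the chain)
    mz <- mz + (trial$grf$cop_x[frame] - jx) * trial$grf$fy[frame] -
      (0 - jy) * trial$grf$fx[frame]
    out[d$name] <- -d$axis_sign * mz
  }
  out
}

# Enumeration oracle for the minimum-activation QP: grid search with step
# `h` on the redundant activations (the remaining ones are solved exactly
# from the equality constraints), followed by a local grid refinement around
# the best coarse point.  Only for tiny problems: n_muscles - n_dofs <= 2.
grid_search_qp <- function(C, m, h = 1e-3) {
  n <- ncol(C); k <- nrow(C)
  stopifnot(n - k <= 2, n - k >= 0)
  if (n == k) {
    a <- tryCatch(solve(C, m), error = function(e) NULL)
    if (is.null(a) || any(a < -1e-9 | a > 1 + 1e-9)) return(Inf)
    return(sum(pmax(pmin(a, 1), 0)^2))
  }
  if (n - k == 1) {
    sub <- C[, -1, drop = FALSE]
    subinv <- solve(sub)
    eval_grid <- function(gr) {
      rest <- t(m - outer(C[, 1], gr)) %*% t(subinv)
      ok <- rowSums(rest < -1e-9 | rest > 1 + 1e-9) == 0
      if (!any(ok)) return(list(val = Inf, at = NA))
      vals <- gr[ok]^2 + rowSums(rest[ok, , drop = FALSE]^2)
      list(val = min(vals), at = gr[ok][which.min(vals)])
    }
    coarse <- eval_grid(seq(0, 1, by = h))
    if (!is.finite(coarse$val)) return(Inf)
    fine <- eval_grid(seq(max(0, coarse$at - 2 * h),
                          min(1, coarse$at + 2 * h), by = h / 200))
    return(min(coarse$val, fine$val))
  }
  sub <- C[, -(1:2), drop = FALSE]
  subinv <- solve(sub)
  eval_grid2 <- function(g1, g2v) {
    g2 <- expand.grid(a1 = g1, a2 = g2v)
    rest <- t(m - outer(C[, 1], g2$a1) - outer(C[, 2], g2$a2)) %*% t(subinv)
    ok <- rowSums(rest < -1e-9 | rest > 1 + 1e-9) == 0
    if (!any(ok)) return(list(val = Inf, at = c(NA, NA)))
    vals <- g2$a1[ok]^2 + g2$a2[ok]^2 + rowSums(rest[ok, , drop = FALSE]^2)
    i <- which.min(vals)
    list(val = vals[i], at = c(g2$a1[ok][i], g2$a2[ok][i]))
  }
  gr <- seq(0, 1, by = h)
  coarse <- eval_grid2(gr, gr)
  if (!is.finite(coarse$val)) return(Inf)
  fine <- eval_grid2(
    seq(max(0, coarse$at[1] - 2 * h), min(1, coarse$at[1] + 2 * h), by = h / 20),
    seq(max(0, coarse$at[2] - 2 * h), min(1, coarse$at[2] + 2 * h), by = h / 20))
  min(coarse$val, fine$val)
}

# Random feasible redundancy problems (1-2 dofs, 2-3 muscles) with an
# interior-ish constructed solution and a well-conditioned constraint matrix
# (so the enumeration oracle resolves the optimum).
random_qp_problem <- function() {
  k <- sample(1:2, 1)
  n <- if (k == 1) sample(2:3, 1) else 3L
  repeat {
    C <- matrix(stats::runif(k * n, 0.3, 2) * sample(c(-1, 1), k * n, TRUE),
                k, n)
    if (min(svd(C)$d) > 0.3) break
  }
  a_star <- stats::runif(n, 0.05, 0.6)
  list(C = C, m = as.numeric(C %*% a_star))
}

# Small shared pipeline fixtures (built once per test session).
shared_subject <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_subject(cohort_spec(seed = 42), 1)
    val
  }
})

shared_trial <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_squat_trial(shared_subject())
    val
  }
})

# A fast low-resolution trial for Monte Carlo unit tests.
small_trial <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_squat_trial(shared_subject(),
                                                   n_frames = 21)
    val
  }
})

zero_spread_spec <- function(model) {
  tab <- default_cv_table()
  tab$cv <- 0
  build_distributions(tab, names(model$muscles), point_sd = 0)
}
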