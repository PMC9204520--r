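# Model construction, scaling rules, pathway geometry and muscle mechanics.

test_that("model validation rejects broken structures", {
  expect_error(body_segment("x", mass = -1, c(0, 0), 0, 0.3), "mass")
  expect_error(mtu("m", mif = 0, tsl = 0.1, pen_opt = 0, l_opt = 0.1,
                   pathway = list()), "mif")
  m <- toy_hinge_model()
  expect_error(
    mtu("m", 100, 0.1, 0, 0.1,
        list(path_point("arm_a", c(0, 0), "via"),
             path_point("arm_b", c(0, 0), "insertion"))),
    "roles")
  # pathway on a single segment is rejected
  expect_error(
    mtu("m", 100, 0.1, 0, 0.1,
        list(path_point("arm_a", c(0, 0), "origin"),
             path_point("arm_a", c(0, 1), "insertion"))),
    "distinct segments")
  expect_silent(validate_model(default_model()))
})

test_that("identity scaling reproduces the generic model field by field", {
  gen <- default_model()
  scaled <- scale_model(gen, landmark_distances_from_height(gen$subject_height),
                        subject_mass = gen$subject_mass)
  expect_equal(scaled, gen, tolerance = 1e-12)
})

test_that("uniform 1.1x landmark scaling stretches geometry and MTU properties", {
  gen <- default_model()
  lm <- landmark_distances_from_height(gen$subject_height) * 1.1
  scaled <- scale_model(gen, lm, subject_mass = gen$subject_mass)
  for (s in names(gen$segments))
    expect_equal(scaled$segments[[s]]$length,
                 gen$segments[[s]]$length * 1.1, tolerance = 1e-12)
  # brute-force oracle: MTU length ratio in the neutral reference pose
  ref <- c(hip_flexion = 0, knee_flexion = 0, ankle_flexion = 0)
  for (nm in names(gen$muscles)) {
    ratio <- mtu_length(scaled, nm, ref) / mtu_length(gen, nm, ref)
    expect_equal(ratio, 1.1, tolerance = 1e-10)
    expect_equal(scaled$muscles[[nm]]$l_opt,
                 gen$muscles[[nm]]$l_opt * ratio, tolerance = 1e-10)
    expect_equal(scaled$muscles[[nm]]$tsl,
                 gen$muscles[[nm]]$tsl * ratio, tolerance = 1e-10)
    expect_identical(scaled$muscles[[nm]]$mif, gen$muscles[[nm]]$mif)
  }
})

test_that("mass-only scaling changes masses, not geometry", {
  gen <- default_model()
  scaled <- scale_model(gen, landmark_distances_from_height(gen$subject_height),
                        subject_mass = gen$subject_mass * 2)
  for (s in names(gen$segments)) {
    expect_equal(scaled$segments[[s]]$mass, gen$segments[[s]]$mass * 2)
    expect_equal(scaled$segments[[s]]$length, gen$segments[[s]]$length)
  }
  expect_equal(mtu_length(scaled, "vaslat", squat_pose(scaled, 0.5)),
               mtu_length(gen, "vaslat", squat_pose(gen, 0.5)))
})

test_that("scale_model reports missing or invalid landmarks", {
  gen <- default_model()
  expect_error(scale_model(gen, c(femur_length = 0.4), 75), "missing landmark")
  lm <- landmark_distances_from_height(1.7); lm["tibia_length"] <- -1
  expect_error(scale_model(gen, lm, 75), "> 0")
})

test_that("mtu_length matches hand geometry on hinge models", {
  # straight two-point muscle, neutral pose: plain distance
  m <- toy_hinge_model(origin = c(0, 0.10), insertion = c(0, -0.20))
  q0 <- c(hinge = 0)
  expect_equal(mtu_length(m, "m1", q0), 0.30, tolerance = 1e-12)

  # collinear via point adds nothing
  mv <- toy_hinge_model(origin = c(0, 0.10), insertion = c(0, -0.20),
                        via = list(segment = "arm_a", position = c(0, -0.05)))
  expect_equal(mtu_length(mv, "m1", q0), 0.30, tolerance = 1e-12)

  # hinge at 90 degrees: chord between two radius-0.1 points at right angle
  m2 <- toy_hinge_model(origin = c(0, 0.10), insertion = c(0, -0.10))
  expect_equal(mtu_length(m2, "m1", c(hinge = pi / 2)), 0.1 * sqrt(2),
               tolerance = 1e-10)
  expect_error(mtu_length(m2, "nope", q0), "unknown muscle")
})

test_that("mtu_length is Lipschitz in the pose", {
  model <- default_model()
  total_len <- sum(vapply(model$segments, `[[`, 0, "length"))
  set.seed(11)
  for (rep in 1:20) {
    q <- squat_pose(model, stats::runif(1, 0.1, 1.4))
    delta <- stats::rnorm(3, 0, 1e-4)
    qd <- q + delta
    L1 <- mtu_length_frames(model, q)
    L2 <- mtu_length_frames(model, qd)
    expect_true(all(abs(L2 - L1) <= total_len * sum(abs(delta)) + 1e-12))
  }
})

test_that("tendon-excursion moment arm agrees with perpendicular-distance geometry", {
  set.seed(7)
  for (rep in 1:25) {
    m <- toy_hinge_model(
      origin = stats::runif(2, -0.2, 0.2),
      insertion = stats::runif(2, -0.2, 0.2),
      joint_loc = stats::runif(2, -0.1, 0.1),
      axis_sign = sample(c(-1, 1), 1))
    pose <- c(hinge = stats::runif(1, -1.2, 1.2))
    fd <- moment_arm(m, "m1", pose, "hinge")
    an <- analytic_hinge_moment_arm(m, pose)
    if (an < 1e-3) next  # near-zero arms are checked separately
    expect_equal(abs(fd), an, tolerance = 1e-4)
  }
})

test_that("a pathway through the joint centre has zero moment arm", {
  m <- toy_hinge_model(origin = c(0, 0.10), insertion = c(0, 0))
  expect_lt(abs(moment_arm(m, "m1", c(hinge = 0.4), "hinge")), 1e-6)
})

test_that("moment arm falls back to a one-sided difference at range limits", {
  m <- toy_hinge_model()
  m$dofs$hinge$range <- c(-0.5, 0.5)
  expect_warning(r <- moment_arm(m, "m1", c(hinge = 0.5), "hinge"),
                 "one-sided")
  expect_true(is.finite(r))
})

test_that("spanned dofs follow the pathway across the chain", {
  model <- default_model()
  expect_setequal(spanned_dofs(model, "vaslat"), "knee_flexion")
  expect_setequal(spanned_dofs(model, "recfem"),
                  c("hip_flexion", "knee_flexion"))
  expect_setequal(spanned_dofs(model, "gasmed"),
                  c("knee_flexion", "ankle_flexion"))
  expect_setequal(spanned_dofs(model, "soleus"), "ankle_flexion")
})

test_that("rigid-tendon fiber state solves the pennation geometry", {
  mu <- mtu("m", 1000, tsl = 0.2, pen_opt = 0, l_opt = 0.1,
            pathway = toy_hinge_model()$muscles$m1$pathway)
  st <- fiber_state(mu, mtu_length = 0.3)
  expect_equal(st$lt, 1); expect_equal(st$pen, 0); expect_false(st$clamped)

  mu2 <- mtu("m", 1000, tsl = 0.2, pen_opt = 0.2, l_opt = 0.1,
             pathway = mu$pathway)
  st2 <- fiber_state(mu2, mtu_length = 0.2 + 0.1 * cos(0.2))
  expect_equal(st2$lt, 1, tolerance = 1e-12)
  expect_equal(st2$pen, 0.2, tolerance = 1e-12)

  st3 <- fiber_state(mu2, mtu_length = 0.2)  # at tendon slack length
  expect_true(st3$clamped)
  expect_equal(st3$vt, 0)
})

test_that("muscle force follows the documented Hill curves", {
  mu <- mtu("m", 1234, tsl = 0.2, pen_opt = 0, l_opt = 0.1,
            pathway = toy_hinge_model()$muscles$m1$pathway)
  st <- fiber_state(mu, 0.3)  # lt = 1, vt = 0, pen = 0
  expect_identical(muscle_force_scalar(mu, 1, st, include_flv = TRUE), 1234)
  expect_identical(muscle_force_scalar(mu, 0, st, include_flv = TRUE), 0)
  expect_equal(muscle_force_scalar(mu, 0.5, st, include_flv = FALSE),
               0.5 * 1234)
  expect_error(muscle_force_scalar(mu, 1.5, st), "activation")

  # curve normalization and shape
  expect_equal(fl_active(1), 1)
  expect_equal(fl_passive(1), 0)
  expect_equal(fv_curve(0), 1)
  lt <- seq(0.2, 2, by = 0.01)
  expect_true(all(fl_active(lt) >= 0))
  expect_true(all(fl_active(lt) <= 1))
  expect_lt(fl_active(3), 1e-3)      # long-length bound
  expect_lt(fl_active(-1), 1e-3)     # short-length bound
  expect_true(all(diff(fl_passive(lt)) >= 0))
  expect_true(all(fv_curve(seq(-15, 5, 0.1)) >= 0))
})
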