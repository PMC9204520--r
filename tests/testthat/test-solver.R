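# Static optimization: QP correctness against closed forms and grid search,
# KKT structure, scaling invariance, and joint reaction force assembly.

test_that("zero demand without passive force yields zero activations", {
  model <- shared_subject()$model
  pose <- squat_pose(model, 0.6)
  sol <- solve_frame(setNames(rep(0, 3), names(model$dofs)), model, pose,
                     include_flv = FALSE)
  expect_true(all(sol$activations == 0))
  expect_identical(sol$objective, 0)
  expect_true(sol$feasible)
})

test_that("two-muscle single-dof problem matches the Lagrange closed form", {
  C <- matrix(c(100, 50), 1, 2)
  qp <- solve_activation_qp(C, 30)
  # a_i = M * C_i / sum(C_k^2), verified against a dense grid in the oracle
  expect_equal(qp$a, c(0.24, 0.12), tolerance = 1e-10)
  expect_equal(grid_search_qp(C, 30), sum(qp$a^2), tolerance = 1e-4)
})

test_that("demands beyond total capacity are flagged infeasible", {
  model <- shared_subject()$model
  pose <- squat_pose(model, 0.6)
  big <- setNames(c(0, -1e5, 0), names(model$dofs))
  sol <- solve_frame(big, model, pose, include_flv = FALSE)
  expect_false(sol$feasible)
  expect_gt(sol$constraint_residual, 1)
  expect_true(all(sol$activations >= 0 & sol$activations <= 1))
})

test_that("the active-set QP matches exhaustive grid search on random problems", {
  set.seed(21)
  for (rep in 1:10) {
    pr <- random_qp_problem()
    qp <- solve_activation_qp(pr$C, pr$m)
    oracle <- grid_search_qp(pr$C, pr$m)
    expect_lt(qp$residual, 1e-8)
    expect_lte(qp$objective, oracle + 1e-4)
    expect_gte(qp$objective, oracle - 1e-4)
  }
})

test_that("interior solutions satisfy the KKT stationarity structure", {
  model <- shared_subject()$model
  tr <- shared_trial()
  id <- inverse_dynamics(tr, model)
  pose <- tr$joint_angles[51, ]
  sol <- solve_frame(id$moments[51, ], model, pose, include_flv = TRUE)
  interior <- sol$activations > 1e-9 & sol$activations < 1 - 1e-9
  # reconstruct C for the active muscles and check a = C' lambda
  Q <- matrix(pose, 1, dimnames = list(NULL, names(pose)))
  L <- mtu_length_frames(model, Q)
  R <- moment_arm_frames(model, Q)
  mm <- squatmc:::muscle_matrices(model, L, matrix(0, 1, ncol(L)), TRUE)
  C <- t(matrix(R[1, , ], ncol(L), 3) * mm$fmax[1, ])
  pred <- as.numeric(crossprod(C, sol$lambda))
  expect_true(any(interior))
  expect_lt(max(abs(sol$activations[interior] - pred[interior])), 1e-6)
})

test_that("uniform scaling of all maximum isometric forces leaves forces unchanged", {
  model <- shared_subject()$model
  tr <- shared_trial()
  id <- inverse_dynamics(tr, model)
  f <- 41  # mid-descent, well-loaded frame
  pose <- tr$joint_angles[f, ]
  base <- solve_frame(id$moments[f, ], model, pose, include_flv = FALSE)
  expect_true(all(base$activations < 0.5))  # no upper bound engages at k=0.5
  for (k in c(0.5, 1.3, 2)) {
    mk <- model
    for (nm in names(mk$muscles)) mk$muscles[[nm]]$mif <- mk$muscles[[nm]]$mif * k
    sk <- solve_frame(id$moments[f, ], mk, pose, include_flv = FALSE)
    rel <- abs(sk$muscle_forces - base$muscle_forces) /
      pmax(abs(base$muscle_forces), 1e-6)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("knee contact force assembles intersegmental and muscle pulls", {
  model <- shared_subject()$model
  pose <- squat_pose(model, 0.8)
  interseg <- c(10, -300)
  zero <- setNames(rep(0, length(model$muscles)), names(model$muscles))
  k0 <- knee_contact_force(zero, interseg, model, pose)
  expect_equal(k0$vector_ground, interseg)
  expect_equal(k0$bw, sqrt(sum(interseg^2)) / (model$subject_mass * 9.81))

  # single loaded knee extensor: explicit vector-addition oracle
  f1 <- zero; f1["vaslat"] <- 800
  k1 <- knee_contact_force(f1, interseg, model, pose)
  fk <- fk_frames(model, pose)
  mu <- model$muscles$vaslat
  w_via <- world_point(fk, mu$pathway[[2]]$segment, mu$pathway[[2]]$position_local)
  w_ins <- world_point(fk, mu$pathway[[3]]$segment, mu$pathway[[3]]$position_local)
  u <- c(w_via$x - w_ins$x, w_via$y - w_ins$y)
  u <- u / sqrt(sum(u^2))              # pull on the tibia, toward the femur
  expect_equal(k1$vector_ground, interseg - 800 * u, tolerance = 1e-12)

  # magnitude is frame-independent (rotation invariance of the norm)
  expect_equal(sqrt(sum(k1$vector^2)), sqrt(sum(k1$vector_ground^2)),
               tolerance = 1e-12)
})

test_that("constant-pose trials give identical frame solutions", {
  model <- shared_subject()$model
  q <- squat_pose(model, 0.7)
  n <- 4
  Q <- matrix(rep(q, each = n), n, 3, dimnames = list(NULL, names(q)))
  w <- model$subject_mass * 9.81 / 2
  tr <- squat_trial(seq(0, 1, length.out = n), Q,
                    data.frame(fx = rep(0, n), fy = rep(w, n),
                               cop_x = rep(0, n)),
                    c(1L, 2L, n),
                    list(mass = model$subject_mass,
                         height = model$subject_height))
  sim <- simulate_trial(tr, model)
  for (f in 2:n) {
    expect_equal(sim$activations[f, ], sim$activations[1, ], tolerance = 1e-9)
    expect_equal(sim$kcf_bw[f], sim$kcf_bw[1], tolerance = 1e-9)
  }
})

test_that("a single-frame trial simulates to a single-frame result", {
  model <- shared_subject()$model
  q <- squat_pose(model, 0.5)
  Q <- matrix(q, 1, dimnames = list(NULL, names(q)))
  tr <- squat_trial(0, Q,
                    data.frame(fx = 0, fy = model$subject_mass * 9.81 / 2,
                               cop_x = 0),
                    c(1L, 1L, 1L),
                    list(mass = model$subject_mass,
                         height = model$subject_height))
  sim <- simulate_trial(tr, model)
  expect_length(sim$kcf_bw, 1)
})

test_that("dropping force-length characteristics alters the KCF trace", {
  sub <- shared_subject()
  tr <- small_trial()
  s1 <- simulate_trial(tr, sub$model, include_flv = TRUE)
  s2 <- simulate_trial(tr, sub$model, include_flv = FALSE)
  # the simplified-variant difference is reported, not asserted in magnitude
  diff_bw <- max(abs(s1$kcf_bw - s2$kcf_bw))
  expect_gt(diff_bw, 0)
  expect_false(identical(s1$kcf_bw, s2$kcf_bw))
})

test_that("simulation is deterministic for fixed inputs", {
  sub <- shared_subject()
  tr <- small_trial()
  expect_identical(simulate_trial(tr, sub$model)$kcf_bw,
                   simulate_trial(tr, sub$model)$kcf_bw)
})
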