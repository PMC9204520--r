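# Synthetic cohort, squat trials, ground-truth measured traces and EMG.

test_that("subject generation is deterministic and honours degenerate specs", {
  spec <- cohort_spec(seed = 3)
  s1 <- generate_subject(spec, 2)
  s2 <- generate_subject(spec, 2)
  expect_identical(s1$anthropometry, s2$anthropometry)
  expect_identical(s1$model, s2$model)

  fixed <- cohort_spec(mass_sd = 0, height_sd = 0, age_sd = 0, seed = 1)
  s3 <- generate_subject(fixed, 1)
  expect_identical(s3$anthropometry$mass, 89)
  expect_identical(s3$anthropometry$height, 1.72)
  expect_identical(s3$anthropometry$age, 74)
  expect_identical(s3$model$subject_mass, 89)
})

test_that("anthropometry draws match the cohort statistics", {
  spec <- cohort_spec(seed = 6)
  draws <- vapply(1:10000, function(i) draw_anthropometry(spec, i)$mass, 0)
  se <- 13 / sqrt(10000)
  expect_lt(abs(mean(draws) - 89), 3 * se)
  expect_lt(abs(stats::sd(draws) - 13), 0.05 * 13)
})

test_that("the squat trial has the constructed profile and quasi-static GRF", {
  sub <- shared_subject()
  tr <- generate_squat_trial(sub, depth_deg = 90, n_frames = 41)
  knee <- tr$joint_angles[, "knee_flexion"]
  expect_equal(knee[1], 0, tolerance = 1e-12)
  expect_equal(knee[41], 0, tolerance = 1e-12)
  expect_equal(max(knee), pi / 2, tolerance = 1e-10)
  expect_identical(tr$cycle_events[2], which.max(knee))

  half_bw <- sub$model$subject_mass * 9.81 / 2
  expect_true(all(abs(tr$grf$fy - half_bw) <= 0.02 * half_bw))
  expect_error(generate_squat_trial(sub, depth_deg = 170), "range")
})

test_that("halving the duration doubles velocities but not angles", {
  sub <- shared_subject()
  t1 <- generate_squat_trial(sub, duration_s = 4, n_frames = 21)
  t2 <- generate_squat_trial(sub, duration_s = 2, n_frames = 21)
  expect_equal(t2$joint_angles, t1$joint_angles, tolerance = 1e-12)
  v1 <- diff(t1$joint_angles[, "knee_flexion"]) / diff(t1$time[1:2])
  v2 <- diff(t2$joint_angles[, "knee_flexion"]) / diff(t2$time[1:2])
  expect_equal(v2, 2 * v1, tolerance = 1e-10)
})

test_that("noise-free truth at the baseline reproduces the baseline exactly", {
  sub <- shared_subject()
  tr <- small_trial()
  truth <- ground_truth_config(mif_scale = 1, noise_bw = 0)
  meas <- generate_measured_kcf(sub, tr, truth)
  base <- simulate_trial(tr, sub$model)
  expect_equal(meas$measured, base$kcf_bw, tolerance = 1e-12)
  expect_identical(kcf_error(base$kcf_bw, meas$measured)$rmse, 0)
})

test_that("group-uniform stronger extensors are nearly invisible; a tendon plant is not", {
  sub <- shared_subject()
  tr <- shared_trial()
  base <- simulate_trial(tr, sub$model)

  # scaling every extensor MIF by the same factor barely moves the KCF: the
  # minimum-activation solution redistributes within the rescaled group and,
  # with a rigid tendon, swaps passive for active force along the same line
  # of action
  t_mif <- ground_truth_config("knee_extensors", mif_scale = 1.3, noise_bw = 0)
  d_mif <- abs(generate_measured_kcf(sub, tr, t_mif)$measured - base$kcf_bw)
  expect_lt(max(d_mif), 0.01)

  # a pathway plant (extensor via points shifted 5 mm anterior) changes the
  # knee moment arms and is clearly observable, most at deep flexion where
  # the extensors are loaded
  t_via <- ground_truth_config("knee_extensors", mif_scale = 1,
                               via_shift = c(0.005, 0), noise_bw = 0)
  d_via <- abs(generate_measured_kcf(sub, tr, t_via)$measured - base$kcf_bw)
  expect_gt(max(d_via), 0.05)
  deep <- which(tr$joint_angles[, "knee_flexion"] >
                  0.6 * max(tr$joint_angles[, "knee_flexion"]))
  expect_true(which.max(d_via) %in% deep)
})

test_that("synthetic EMG is recovered by the processing chain", {
  sub <- shared_subject()
  tr <- shared_trial()
  act <- simulate_trial(tr, sub$model)$activations[, "vaslat"]
  emg <- generate_emg(act, tr$time, sampling_rate = 1000, seed = 12)
  env <- process_emg(emg$raw, emg$sampling_rate)
  act_i <- stats::approx(tr$time, act, xout = emg$time)$y
  expect_gt(stats::cor(env, act_i), 0.9)

  # modulation linearity: constant 0.5 vs constant 1.0 envelopes scale by 2
  e05 <- generate_emg(rep(0.5, 11), seq(0, 2, 0.2), seed = 5)
  e10 <- generate_emg(rep(1.0, 11), seq(0, 2, 0.2), seed = 5)
  m05 <- mean(process_emg(e05$raw, 1000))
  m10 <- mean(process_emg(e10$raw, 1000))
  expect_equal(m05 / m10, 0.5, tolerance = 0.05)

  # zero activation: only the baseline noise floor remains
  e0 <- generate_emg(rep(0, 11), seq(0, 2, 0.2), seed = 5)
  expect_lt(mean(process_emg(e0$raw, 1000)), 0.02)
})

test_that("the default variability table is consistent with its working ranges", {
  tab <- default_cv_table()
  spec <- build_distributions(tab, names(default_model()$muscles))
  expect_s3_class(spec, "param_dist_spec")
  tsl <- tab$cv[tab$parameter == "TSL"]
  expect_true(all(tsl >= 0.02 & tsl <= 0.09))
  # deliberately missing entries are filled by the fallback mean
  expect_true(spec$filled[spec$muscle == "iliopsoas" & spec$parameter == "MIF"])
  given <- tab[tab$parameter == "MIF", ]
  wavg <- sapply(split(given, given$muscle),
                 function(d) sum(d$cv * d$n_subjects) / sum(d$n_subjects))
  expect_equal(spec$value[spec$muscle == "iliopsoas" & spec$parameter == "MIF"],
               mean(wavg))
})
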