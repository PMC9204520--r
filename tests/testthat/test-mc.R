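# Parameter distributions, perturbed-model sampling, Monte Carlo designs,
# replay determinism and the convergence criterion.

test_that("distribution building applies weighted averages and fallbacks", {
  tab <- data.frame(
    muscle = c("a", "a", "b"),
    parameter = c("MIF", "MIF", "MIF"),
    cv = c(0.10, 0.20, 0.30),
    n_subjects = c(10, 30, 5))
  spec <- build_distributions(tab, muscles = c("a", "b", "c"))
  # subject-weighted average for muscle a: (0.10*10 + 0.20*30) / 40
  expect_equal(spec$value[spec$muscle == "a" & spec$parameter == "MIF"], 0.175)
  # single source taken verbatim
  expect_equal(spec$value[spec$muscle == "b" & spec$parameter == "MIF"], 0.30)
  # muscle with no source: unweighted mean of the others' weighted CVs
  expect_equal(spec$value[spec$muscle == "c" & spec$parameter == "MIF"],
               mean(c(0.175, 0.30)))
  expect_true(spec$filled[spec$muscle == "c" & spec$parameter == "MIF"])
  # pathway point spreads default to 5 mm absolute SD
  expect_true(all(spec$value[spec$parameter %in% c("OIP", "VIA")] == 0.005))
  expect_error(build_distributions(transform(tab, cv = -cv), "a"), "negative")
})

test_that("zero spreads reproduce the baseline model exactly", {
  model <- shared_subject()$model
  spec <- zero_spread_spec(model)
  des <- mc_design("general", n_iterations = 3, seed = 5)
  pert <- sample_perturbed_model(model, spec, des, 1)
  attr(pert, "draws") <- NULL
  attr(pert, "stream_id") <- NULL
  pert$provenance <- model$provenance
  expect_identical(pert, model)
})

test_that("individual designs perturb exactly one parameter class", {
  model <- shared_subject()$model
  spec <- build_distributions(default_cv_table(), names(model$muscles))
  des <- mc_design("individual", parameter = "MIF", n_iterations = 5, seed = 9)
  pert <- sample_perturbed_model(model, spec, des, 2)
  for (nm in names(model$muscles)) {
    expect_false(pert$muscles[[nm]]$mif == model$muscles[[nm]]$mif)
    expect_identical(pert$muscles[[nm]]$tsl, model$muscles[[nm]]$tsl)
    expect_identical(pert$muscles[[nm]]$pen_opt, model$muscles[[nm]]$pen_opt)
    for (k in seq_along(model$muscles[[nm]]$pathway))
      expect_identical(pert$muscles[[nm]]$pathway[[k]]$position_local,
                       model$muscles[[nm]]$pathway[[k]]$position_local)
  }
})

test_that("group designs leave non-member muscles untouched", {
  model <- shared_subject()$model
  spec <- build_distributions(default_cv_table(), names(model$muscles))
  des <- mc_design("general", muscle_group = "knee_extensors",
                   n_iterations = 2, seed = 4)
  pert <- sample_perturbed_model(model, spec, des, 1)
  for (nm in setdiff(names(model$muscles), group_members(model, "knee_extensors")))
    expect_identical(pert$muscles[[nm]], model$muscles[[nm]])
  expect_false(identical(pert$muscles$vaslat, model$muscles$vaslat))
})

test_that("sampled parameters follow the specified Gaussian law", {
  m <- toy_hinge_model(mif = 1000)
  spec <- build_distributions(
    data.frame(muscle = "m1", parameter = c("MIF", "TSL", "PEN"),
               cv = c(0.1, 0.05, 0.1), n_subjects = 10),
    muscles = "m1")
  des <- mc_design("individual", parameter = "MIF", n_iterations = 1, seed = 3)
  draws <- vapply(1:10000, function(i)
    sample_perturbed_model(m, spec, des, i)$muscles$m1$mif, 0)
  se <- 0.1 * 1000 / sqrt(10000)
  expect_lt(abs(mean(draws) - 1000), 3 * se)
  expect_lt(abs(stats::sd(draws) / mean(draws) - 0.1), 0.005)
})

test_that("draw truncation resamples out-of-range values", {
  m <- toy_hinge_model(pen_opt = 1.3)  # near the 80 deg truncation bound
  spec <- build_distributions(
    data.frame(muscle = "m1", parameter = "PEN", cv = 0.2, n_subjects = 5),
    muscles = "m1")
  des <- mc_design("individual", parameter = "PEN", n_iterations = 1, seed = 1)
  pens <- vapply(1:300, function(i)
    sample_perturbed_model(m, spec, des, i)$muscles$m1$pen_opt, 0)
  expect_true(all(pens > 0 & pens <= 80 * pi / 180))
})

test_that("the full-design iteration arithmetic matches the study plan", {
  plan <- plan_mc_design()
  expect_identical(plan$per_subject_group, 2000 + 5 * 500)
  expect_identical(plan$per_subject, 7 * 4500)
  expect_identical(plan$total, 189000)
  expect_identical(plan$general_total, 84000)
  expect_identical(plan$group_contribution_jrf_simulations, 72000)
})

test_that("identical seeds replay bit-identical Monte Carlo results", {
  sub <- shared_subject()
  tr <- small_trial()
  spec <- build_distributions(default_cv_table(), names(sub$model$muscles))
  des <- mc_design("general", n_iterations = 5, seed = 11)
  mc1 <- run_mc(sub$model, tr, spec, des)
  mc2 <- run_mc(sub$model, tr, spec, des)
  expect_identical(mc1$kcf_bw, mc2$kcf_bw)
  expect_identical(mc1$draws, mc2$draws)
  expect_identical(mc1$stream_ids, mc2$stream_ids)
})

test_that("degenerate Monte Carlo (zero spreads) returns the baseline each time", {
  sub <- shared_subject()
  tr <- small_trial()
  spec <- zero_spread_spec(sub$model)
  des <- mc_design("general", n_iterations = 1, seed = 2)
  mc <- run_mc(sub$model, tr, spec, des)
  expect_equal(mc$kcf_bw[1, ], mc$baseline$kcf_bw, tolerance = 1e-12)
})

test_that("doubling all spreads does not shrink the band width", {
  sub <- shared_subject()
  tr <- small_trial()
  tab <- default_cv_table()
  spec1 <- build_distributions(tab, names(sub$model$muscles))
  tab2 <- tab; tab2$cv <- tab2$cv * 2
  spec2 <- build_distributions(tab2, names(sub$model$muscles), point_sd = 0.01)
  des <- mc_design("general", n_iterations = 40, seed = 17)
  w1 <- mean(percentile_band(run_mc(sub$model, tr, spec1, des))$width)
  w2 <- mean(percentile_band(run_mc(sub$model, tr, spec2, des))$width)
  expect_gte(w2, w1)
})

test_that("convergence criterion behaves on degenerate and analytic cases", {
  # identical iterations: width 0 at any N, converged
  flat <- matrix(2.5, 50, 7)
  cc <- check_convergence(flat)
  expect_true(cc$converged)
  expect_identical(cc$width_n, 0)

  # i.i.d. Gaussian scalars: width tends to the closed form 2 * z_{0.95}
  set.seed(31)
  x <- stats::rnorm(20000)
  cc2 <- check_convergence(matrix(x, ncol = 1))
  expect_true(cc2$converged)
  expect_equal(cc2$width_probe, 2 * stats::qnorm(0.95), tolerance = 0.02)

  # small high-variance sample: not converged
  set.seed(13)
  y <- stats::rlnorm(10, sdlog = 1.5)
  cc3 <- check_convergence(matrix(y, ncol = 1))
  expect_false(cc3$converged)

  expect_error(check_convergence(matrix(1, 2, 1)), "insufficient")
})

test_that("failed iterations are recorded, not fatal", {
  sub <- shared_subject()
  tr <- small_trial()
  spec <- build_distributions(default_cv_table(), names(sub$model$muscles))
  # absurd pennation CV forces the 100-rejection sampler error in most draws
  spec$value[spec$parameter == "PEN"] <- 50
  des <- mc_design("individual", parameter = "PEN", n_iterations = 4, seed = 1)
  mc <- suppressWarnings(run_mc(sub$model, tr, spec, des))
  expect_true(length(mc$failures) > 0)
  expect_true(all(is.na(mc$kcf_bw[mc$failures, ])))
})
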