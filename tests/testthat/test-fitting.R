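test_that("parameter accounting reports raw and identifiable counts", {
  expect_identical(count_parameters("markov_2"),
                   list(n_rate_coefficients = 2L, n_identifiable = 2L))
  expect_identical(count_parameters("markov_3"),
                   list(n_rate_coefficients = 6L, n_identifiable = 4L))
  expect_identical(count_parameters("nonmarkov_2"),
                   list(n_rate_coefficients = 4L, n_identifiable = 4L))
  expect_identical(count_parameters("nonmarkov_3")$n_identifiable, 7L)
})

test_that("under-determined fits are refused, citing the cap", {
  d <- generate_gv_dataset(generator_profile("trpv1_like", seed = 51,
                                             n_replicates = 1))
  expect_error(fit_equilibrium_model(d, "markov_2",
                                     config = list(free = c("dH", "dS",
                                                            "g_max"))),
               "identifiability cap")
  expect_error(fit_equilibrium_model(d, "markov_2",
                                     config = list(free = c("dH", "dS",
                                                            "m_ref"))),
               "not part of a Markov model")
})

test_that("noiseless equilibrium fits recover the generating truth", {
  prof <- generator_profile("trpv1_like", noise_sd = 0,
                            n_replicates = 1, V_ladder = c(80, 160))
  d <- generate_gv_dataset(prof)
  for (tag in c("markov_2", "nonmarkov_2")) {
    fit <- fit_equilibrium_model(d, tag)
    expect_equal(fit$params$dH, 200e3, tolerance = 1e-4, label = tag)
    expect_equal(fit$params$dS, 635, tolerance = 1e-4, label = tag)
  }
  # three-state variant with a fixed closed-closed ratio still recovers
  # dH/dS when the data are generated with the matching closed weight
  fit3 <- fit_equilibrium_model(d, "markov_3", config = list(c21 = 0))
  expect_equal(fit3$params$dH, 200e3, tolerance = 1e-4)
})

test_that("noisy fits recover dH and dS to about ten percent", {
  rs <- recovery_study(n_reps = 15, seed = 2024)
  expect_lt(rs$summary$median_rel_err_dH, 0.10)
  expect_lt(rs$summary$median_rel_err_dS, 0.10)
})

test_that("record order does not change the fit", {
  d <- generate_gv_dataset(generator_profile("trpv1_like", seed = 52,
                                             n_replicates = 1,
                                             noise_sd = 0.03))
  f1 <- fit_equilibrium_model(d, "markov_2")
  d_perm <- d[sample(nrow(d)), ]
  attr(d_perm, "generator") <- attr(d, "generator")
  f2 <- fit_equilibrium_model(d_perm, "markov_2")
  expect_equal(f1$params, f2$params, tolerance = 1e-10)
  expect_equal(f1$loss, f2$loss, tolerance = 1e-10)
})

test_that("a Markov fit to memory-bearing data leaves a residual trend", {
  th <- thermo_params(dH = 200e3, dS = 680, k_c1 = 20, tau_r = 0.1)
  prof <- generator_profile("custom", thermo = th,
                            T_grid = seq(296, 336, length.out = 16),
                            V_ladder = 80, noise_sd = 0,
                            n_replicates = 1, memory_Ea = 50e3)
  d <- generate_gv_dataset(prof)
  fit <- fit_equilibrium_model(d, "markov_2")
  expect_lt(fit$runs_test_p, 0.05)
  # whereas the matching non-Markov fit absorbs the curvature
  fit_nm <- fit_equilibrium_model(d, "nonmarkov_2")
  expect_lt(fit_nm$loss, fit$loss)
})

test_that("dwell-law MLE recovers exponential and gamma truths", {
  sch <- two_state_scheme(dwell_law("exponential", rate = 7),
                          dwell_law("gamma", shape = 3, scale = 0.05))
  ev <- generate_dwell_events(sch, 2e4, seed = 53)
  fit_exp <- fit_dwell_laws(ev, "exponential")
  lam <- fit_exp$C$estimate[["rate"]]
  expect_lt(abs(lam - 7), 3 * fit_exp$C$se[["rate"]])
  fit_gam <- fit_dwell_laws(ev, "gamma")
  expect_equal(fit_gam$O$law$params$shape, 3, tolerance = 0.15)
  # the correct family has the smaller KS distance on the gamma state
  expect_lt(fit_gam$O$ks_distance, fit_exp$O$ks_distance)
  expect_error(fit_dwell_laws(data.frame(state = character(0),
                                         duration_s = numeric(0))),
               "empty")
  expect_warning(fit_dwell_laws(data.frame(state = "C",
                                           duration_s = runif(10)),
                                "exponential"), "wide confidence")
})

test_that("the Pareto closed-form MLE finds the tail exponent", {
  set.seed(54)
  x <- sample_dwell(dwell_law("pareto", alpha = 1.5, tmin = 0.01), 1e4)
  fit <- fit_dwell_laws(data.frame(state = "C", duration_s = x),
                        "pareto")
  expect_lt(abs(fit$C$estimate[["alpha"]] - 1.5),
            3 * fit$C$se[["alpha"]])
  expect_equal(fit$C$estimate[["tmin"]], min(x))
})

test_that("model comparison ranks by AIC with sensible weights", {
  ds <- discrimination_study(n_reps = 1, n_events = 800, seed = 55)
  expect_true(ds$per_rep$nonmarkov_wins[1])
  sch <- markov_scheme()
  ev <- collapse_to_conductance_events(
    generate_dwell_events(sch, 500, seed = 56))
  f1 <- fit_dwell_model(ev, "markov_2")
  f2 <- fit_dwell_model(ev, "markov_2")
  tab <- compare_models(list(f1, f2))
  expect_equal(tab$delta_AIC, c(0, 0))
  expect_equal(tab$akaike_weight, c(0.5, 0.5))
  single <- compare_models(list(f1))
  expect_identical(nrow(single), 1L)
  ev2 <- collapse_to_conductance_events(
    generate_dwell_events(sch, 400, seed = 57))
  f3 <- fit_dwell_model(ev2, "markov_2")
  expect_error(compare_models(list(f1, f3)), "identical dataset")
})

test_that("observed dwell records need conductance classes", {
  ev3 <- generate_dwell_events(
    three_state_scheme(dwell_law("exponential", rate = 5),
                       dwell_law("exponential", rate = 5),
                       dwell_law("exponential", rate = 5)),
    100, seed = 58)
  expect_error(fit_dwell_model(ev3, "markov_2"), "collapse")
  obs <- collapse_to_conductance_events(ev3)
  expect_true(setequal(unique(obs$state), c("C", "O")))
  # collapsed records alternate strictly
  expect_true(all(obs$state[-1] != obs$state[-nrow(obs)]))
  fit <- fit_dwell_model(obs, "nonmarkov_2", min_events = 10)
  expect_true(is.finite(fit$AIC))
})
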