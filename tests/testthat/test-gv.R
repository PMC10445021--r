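test_that("conductance from current handles the reversal potential", {
  expect_equal(conductance_from_current(160, 160), 1)
  expect_equal(conductance_from_current(0, 80), 0)
  expect_warning(g <- conductance_from_current(c(10, 5), c(80, 0)),
                 "reversal")
  expect_true(is.na(g[2]) && g[1] == 10 / 80)
})

test_that("Boltzmann fits recover noiseless parameters exactly", {
  V <- seq(-120, 160, by = 20)
  g <- 0.9 / (1 + exp((20 - V) / 15))
  fit <- boltzmann_fit(V, g)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimate["V_half"]), 20, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["slope"]), 15, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["g_max"]), 0.9, tolerance = 1e-6)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("flat or under-sampled G-V data fail explicitly", {
  V <- seq(-120, 160, by = 20)
  flat <- boltzmann_fit(V, rep(0.4, length(V)))
  expect_false(flat$converged)
  expect_match(flat$reason, "flat")
  expect_null(flat$estimate)
  expect_error(boltzmann_fit(c(-40, 0, 40, 80), rep(0.1, 4)),
               "5 voltage points")
})

test_that("noisy Boltzmann parameters are recovered within their CIs", {
  V <- seq(-120, 160, by = 20)
  set.seed(31)
  g <- 0.9 / (1 + exp((20 - V) / 15)) + rnorm(length(V), 0, 0.02)
  fit <- boltzmann_fit(V, g)
  expect_true(fit$converged)
  truth <- c(V_half = 20, slope = 15, g_max = 0.9)
  for (p in names(truth)) {
    expect_lt(abs(fit$estimate[p] - truth[p]), 3 * fit$se[p], label = p)
  }
})

test_that("van't Hoff analysis inverts the equilibrium generator exactly", {
  th <- thermo_params(dH = 200e3, dS = 635)
  T_K <- seq(296, 331, by = 5)
  p <- equilibrium_open_probability(epsilon_T(th, T_K), T_K)
  fit <- vant_hoff_fit(T_K, p)
  expect_equal(fit$dH, 200e3, tolerance = 1e-8)
  expect_equal(fit$dS, 635, tolerance = 1e-8)
  expect_equal(fit$T_star, 200e3 / 635, tolerance = 1e-8)
  expect_gt(fit$r_squared, 1 - 1e-12)
})

test_that("saturated probabilities are clipped with a bounded effect", {
  T_K <- seq(290, 320, by = 10)
  expect_warning(fit <- vant_hoff_fit(T_K, c(0, 0.4, 0.8, 1)), "clipped")
  # ln K never exceeds the documented clip bound
  expect_true(all(abs(fit$lm$model$lnK) <= log((1 - 1e-6) / 1e-6)))
  # flat p = 0.5: no enthalpy, no entropy, undefined T*
  flat <- vant_hoff_fit(T_K, rep(0.5, 4))
  expect_equal(flat$dH, 0, tolerance = 1e-10)
  expect_true(is.na(flat$T_star))
  expect_error(vant_hoff_fit(c(300, 310, 320), c(0.2, 0.5, 0.8)),
               "4 temperatures")
})

test_that("Q10 matches analytic and frozen oracle values", {
  expect_equal(q10(1, 2, 300, 310), 2)
  expect_equal(q10(5, 5, 290, 330), 1)
  th <- thermo_params(dG_barrier_o = 100e3, nu0 = 1e9)
  k1 <- rate_constant(th, "open_transition", 300)
  k2 <- rate_constant(th, "open_transition", 310)
  expect_equal(q10(k1, k2, 300, 310), 3.644616435, tolerance = 1e-9)
})

test_that("G-T curves show the generating activation polarity", {
  d_heat <- generate_gv_dataset(generator_profile("trpv1_like",
                                                  seed = 41))
  cv <- g_vs_temperature(d_heat, 80)
  expect_gt(attr(cv, "spearman_rho"), 0)
  expect_lt(attr(cv, "spearman_p"), 0.01)
  d_cold <- generate_gv_dataset(generator_profile("trpm8_like",
                                                  seed = 42))
  cv2 <- g_vs_temperature(d_cold, 80)
  expect_lt(attr(cv2, "spearman_rho"), 0)
  expect_lt(attr(cv2, "spearman_p"), 0.01)
  expect_error(g_vs_temperature(d_heat, 75), "available")
  # degenerate single-temperature dataset: a point, no trend statistics
  one <- d_heat[d_heat$temperature_K == 296, ]
  cv1 <- g_vs_temperature(one, 80)
  expect_identical(nrow(cv1), 1L)
  expect_null(attr(cv1, "spearman_rho"))
})

test_that("conductance normalisation works globally and per temperature", {
  d <- data.frame(temperature_K = rep(c(300, 310), each = 2),
                  voltage_mV = rep(c(80, 160), 2),
                  g = c(1, 2, 2, 4))
  glob <- normalize_conductance(d, "global")
  expect_equal(glob$g_norm, c(0.25, 0.5, 0.5, 1))
  per <- normalize_conductance(d, "per_temperature")
  expect_equal(per$g_norm, c(0.5, 1, 0.5, 1))
})

test_that("datasets round-trip through CSV, including unit conversions", {
  d <- generate_gv_dataset(generator_profile("trpv1_like", seed = 43,
                                             n_replicates = 1))
  p <- tempfile(fileext = ".csv")
  write_gv_dataset(d, p)
  back <- read_gv_dataset(p)
  expect_equal(back$g_norm, d$g_norm, tolerance = 1e-12)
  # current-based table in Celsius
  p2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(temperature_C = c(25, 25, 35, 35, 45, 45),
                       voltage_mV = rep(c(80, 160), 3),
                       current_pA = c(8, 32, 40, 96, 72, 160)),
            p2, row.names = FALSE)
  b2 <- read_gv_dataset(p2)
  expect_equal(sort(unique(b2$temperature_K)),
               celsius_to_kelvin(c(25, 35, 45)))
  expect_equal(max(b2$g_norm), 1)   # global normalisation
})
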