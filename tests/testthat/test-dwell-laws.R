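test_that("densities integrate to one and survival starts at one", {
  for (name in names(all_test_laws())) {
    law <- all_test_laws()[[name]]
    lower <- if (law$family == "pareto") law$params$tmin else 0
    total <- integrate(function(t) dwell_density(law, t),
                       lower = lower, upper = Inf,
                       rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6, label = name)
    expect_identical(dwell_survival(law, 0), 1, label = name)
    expect_equal(dwell_cdf(law, 1e9) + dwell_survival(law, 1e9), 1,
                 label = name)
  }
})

test_that("Laplace transforms equal one at s = 0 and decrease in s", {
  s_grid <- c(0, 0.1, 0.5, 1, 2, 5)
  for (name in names(all_test_laws())) {
    law <- all_test_laws()[[name]]
    psi <- dwell_laplace(law, s_grid)
    expect_equal(psi[1], 1, tolerance = 1e-9, label = name)
    expect_true(all(diff(psi) < 0), label = name)
  }
})

test_that("closed-form Laplace transforms and means are exact", {
  law_exp <- dwell_law("exponential", rate = 2)
  expect_equal(dwell_laplace(law_exp, 1), 2 / 3)
  expect_equal(dwell_mean(law_exp), 0.5)
  law_gam <- dwell_law("gamma", shape = 2, scale = 1)
  expect_equal(dwell_laplace(law_gam, 1), 1 / 4)
  expect_equal(dwell_mean(law_gam), 2)
  law_str <- dwell_law("stretched_exponential", stretch = 0.5, scale = 2)
  expect_equal(dwell_mean(law_str), 2 * gamma(3))   # scale * Gamma(1 + 1/b)
  expect_equal(dwell_mean(dwell_law("pareto", alpha = 2.5, tmin = 0.01)),
               2.5 * 0.01 / 1.5)
})

test_that("infinite Pareto mean is an explicit signal, not an overflow", {
  expect_identical(dwell_mean(dwell_law("pareto", alpha = 0.5,
                                        tmin = 0.01)), Inf)
  expect_identical(dwell_mean(dwell_law("pareto", alpha = 1,
                                        tmin = 0.01)), Inf)
  expect_error(dwell_rescale_mean(dwell_law("pareto", alpha = 0.5,
                                            tmin = 0.01), 1),
               "infinite mean")
})

test_that("stretched-exponential transform matches a closed-form oracle", {
  # for b = 1/2, scale 1: psi-hat(s) = (1/2) sqrt(pi/s) e^{1/(4s)}
  #   erfc(1/(2 sqrt(s))), via t = v^2 and completing the square
  law <- dwell_law("stretched_exponential", stretch = 0.5, scale = 1)
  erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
  for (s in c(0.3, 1, 3)) {
    oracle <- 0.5 * sqrt(pi / s) * exp(1 / (4 * s)) *
      erfc(1 / (2 * sqrt(s)))
    expect_equal(dwell_laplace(law, s), oracle, tolerance = 1e-8)
  }
})

test_that("hazard rates have the family-characteristic time dependence", {
  t <- c(0.1, 0.5, 1, 2, 5)
  expect_equal(dwell_hazard(dwell_law("exponential", rate = 3), t),
               rep(3, 5))
  haz_gamma <- dwell_hazard(dwell_law("gamma", shape = 2, scale = 0.5), t)
  expect_true(all(diff(haz_gamma) > 0))
  law_par <- dwell_law("pareto", alpha = 0.5, tmin = 0.01)
  tt <- c(1, 10, 100)
  expect_equal(dwell_hazard(law_par, tt), 0.5 / tt)  # exactly alpha / t
})

test_that("inverse-CDF sampling reproduces each law", {
  set.seed(7)
  for (name in c("exponential", "gamma", "pareto_light")) {
    law <- all_test_laws()[[name]]
    x <- sample_dwell(law, 5000)
    ks <- suppressWarnings(stats::ks.test(x, function(q)
      dwell_cdf(law, q)))
    expect_gt(ks$p.value, 0.01, label = name)
    m <- dwell_mean(law)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - m), 4 * se, label = name)
  }
})

test_that("rescaling to a target mean preserves family and hits the mean", {
  for (name in c("exponential", "gamma", "stretched_exponential",
                 "pareto_light")) {
    law <- all_test_laws()[[name]]
    new <- dwell_rescale_mean(law, 0.125)
    expect_identical(new$family, law$family)
    expect_equal(dwell_mean(new), 0.125, tolerance = 1e-12, label = name)
  }
})

test_that("domain violations are rejected", {
  law <- dwell_law("exponential", rate = 1)
  expect_error(dwell_density(law, -1), "non-negative")
  expect_error(dwell_laplace(law, -0.5), "non-negative")
  expect_error(dwell_law("stretched_exponential", stretch = 1.5,
                         scale = 1))
  expect_error(dwell_laplace(dwell_law("pareto", alpha = 0.5,
                                       tmin = 0.01), 1 + 2i),
               "complex")
  big_t <- 2000   # survival underflows to 0 for exp(1)
  expect_error(dwell_hazard(law, big_t), "underflow")
})
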