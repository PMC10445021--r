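test_that("identical seeds give bitwise-identical trajectories", {
  sch <- markov_scheme()
  t1 <- sample_trajectory(sch, "C", 20, seed = 123)
  t2 <- sample_trajectory(sch, "C", 20, seed = 123)
  expect_identical(t1, t2)
  t3 <- sample_trajectory(sch, "C", 20, seed = 124)
  expect_false(identical(t1$dwells$duration_s, t3$dwells$duration_s))
})

test_that("a dwell outlasting the run gives one truncated dwell", {
  sch <- two_state_scheme(dwell_law("pareto", alpha = 2, tmin = 5),
                          dwell_law("exponential", rate = 1))
  tr <- sample_trajectory(sch, "C", duration = 1, seed = 1)
  expect_identical(nrow(tr$dwells), 1L)
  expect_true(tr$dwells$truncated)
  expect_equal(tr$dwells$duration_s, 1)
})

test_that("state labels alternate along the chain", {
  tr <- sample_trajectory(markov_scheme(), "C", 50, seed = 2)
  s <- tr$dwells$state
  expect_true(all(s[-1] != s[-length(s)]))
  sch3 <- three_state_scheme(dwell_law("exponential", rate = 5),
                             dwell_law("exponential", rate = 5),
                             dwell_law("exponential", rate = 5))
  tr3 <- sample_trajectory(sch3, "C1", 50, seed = 3)
  s3 <- tr3$dwells$state
  # C1 is always followed by C2, O always by C2 (linear chain)
  expect_true(all(s3[which(s3 == "C1") + 1] == "C2", na.rm = TRUE))
  expect_true(all(s3[which(s3 == "O") + 1] == "C2", na.rm = TRUE))
})

test_that("unknown start states are rejected", {
  expect_error(sample_trajectory(markov_scheme(), "C1", 1, seed = 1),
               "unknown start_state")
  expect_error(mc_occupancy(markov_scheme(), "C", numeric(0), 10),
               "empty")
  expect_error(mc_occupancy(markov_scheme(), "C", c(1, 2), 10),
               "start at 0")
})

test_that("dwell statistics compute means, rates, and exclude truncation", {
  ev <- data.frame(state = c("C", "O", "C"), duration_s = c(2, 1, 4))
  st <- dwell_statistics(ev)
  expect_equal(st$mean_residence_s[st$state == "C"], 3)
  expect_equal(st$mean_residence_s[st$state == "O"], 1)
  expect_equal(st$effective_rate_per_s[st$state == "C"], 1 / 3)
  ev$truncated <- c(FALSE, FALSE, TRUE)
  st2 <- dwell_statistics(ev)
  expect_equal(st2$mean_residence_s[st2$state == "C"], 2)
  expect_error(dwell_statistics(data.frame(state = "C", duration_s = 1,
                                           truncated = TRUE)),
               "no completed dwells")
})

test_that("empirical dwell means match the generating law", {
  sch <- two_state_scheme(dwell_law("exponential", rate = 5),
                          dwell_law("gamma", shape = 2, scale = 0.1))
  ev <- generate_dwell_events(sch, 2e4, seed = 9)
  st <- dwell_statistics(ev)
  for (s in c("C", "O")) {
    m_true <- dwell_mean(sch$dwell_laws[[s]])
    d <- ev$duration_s[ev$state == s]
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - m_true), 3.5 * se, label = s)
    expect_equal(st$mean_residence_s[st$state == s], mean(d))
  }
})

test_that("occupancy at t = 0 is the start-state indicator and sums to 1", {
  occ <- mc_occupancy(markov_scheme(), "C", c(0, 0.5, 1), n_traj = 200,
                      seed = 4)
  expect_identical(occ$p_open[1], 0)
  expect_identical(occ$p_closed[1], 1)
  expect_equal(occ$p_open + occ$p_closed, rep(1, 3))
  sch3 <- three_state_scheme(dwell_law("exponential", rate = 5),
                             dwell_law("exponential", rate = 5),
                             dwell_law("exponential", rate = 5))
  occ3 <- mc_occupancy(sch3, "O", c(0, 0.2, 1), n_traj = 150, seed = 5)
  expect_identical(occ3$p_open[1], 1)
  expect_equal(occ3$p_open + occ3$p_c1 + occ3$p_c2, rep(1, 3))
})

test_that("Monte-Carlo occupancy tracks the closed-form master equation", {
  grid <- c(0, 0.25, 0.5, 1, 2, 4)
  occ <- mc_occupancy(markov_scheme(2, 1), "C", grid, n_traj = 3000,
                      seed = 6)
  ref <- master_equation_occupancy(2, 1, 0, grid)
  expect_true(all(abs(occ$p_open - ref$p_open) <=
                    3 * pmax(occ$stderr, 1e-9)))
})

test_that("master-equation special values are exact", {
  grid <- c(0, 1)
  expect_equal(master_equation_occupancy(2, 1, 0, grid)$p_open,
               c(0, (2 / 3) * (1 - exp(-3))))
  expect_equal(master_equation_occupancy(1, 1, 0.2, c(0, 1e3))$p_open[2],
               0.5)
})

test_that("event lists round-trip through delimited text", {
  ev <- generate_dwell_events(markov_scheme(), 50, seed = 10)
  p <- tempfile(fileext = ".csv")
  write_dwell_events(ev, p)
  back <- read_dwell_events(p)
  expect_equal(back$duration_s, ev$duration_s, tolerance = 1e-12)
  expect_identical(back$state, ev$state)
})
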