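test_that("reproduction pulse moves storage to juveniles and conserves biomass", {
  expect_equal(reproduction_pulse(season_state(1, 0.3, 0.2, 0.1)),
               c(R = 1, J = 0.4, A = 0.2, B = 0))
  s <- season_state(1.3, 0.25, 0.4)
  expect_identical(reproduction_pulse(s), s) # B = 0: identity
  # conservation holds to machine precision (only summation order differs),
  # and post-pulse B is exactly 0
  for (s in list(c(1, 0.3, 0.2, 0.1), c(0.5, 1e-8, 2, 0.7))) {
    ps <- reproduction_pulse(s)
    expect_lt(abs(sum(ps[2:4]) - sum(s[2:4])), 4 * .Machine$double.eps)
    expect_identical(ps[["B"]], 0)
  }
})

test_that("resource-only state is a fixed point of the season", {
  p <- cr_params(theta = 2, mu = 9)
  res <- integrate_season(season_state(p$Kr), p)
  expect_equal(res$end_state, c(R = p$Kr, J = 0, A = 0, B = 0),
               tolerance = 1e-10)
  expect_equal(unname(res$averages), c(0, 0, 0), tolerance = 1e-10)
})

test_that("without feeding the season has a closed-form solution", {
  p <- cr_params(theta = 1, mu = 3, Imax = 0, Kr = 2, rho = 10, Q = 10)
  s0 <- season_state(R = 0.7, J = 0.9)
  res <- integrate_season(s0, p, control = cr_control(rtol = 1e-12,
                                                      atol = 1e-16))
  expect_rel_equal(res$end_state[["J"]], 0.9 * exp(-(10 + 3)), 1e-8)
  expect_rel_equal(res$end_state[["R"]], 2 + (0.7 - 2) * exp(-10), 1e-8)
  # the average accumulator reproduces the integral of the exponential
  expect_rel_equal(res$averages[["Jbar"]], 0.9 * (1 - exp(-13)) / 13, 1e-8)
})

test_that("dense trajectories are monotone in time and non-negative", {
  res <- integrate_season(s_high, p_theta2, dense = TRUE, nt = 101)
  expect_equal(nrow(res$trajectory), 101)
  expect_true(all(diff(res$trajectory$t) > 0))
  expect_true(all(res$trajectory$t >= 0 & res$trajectory$t <= 1))
  expect_true(all(as.matrix(res$trajectory[, c("R", "J", "A", "B")]) > -1e-9))
})

test_that("near the persistence boundary storage dominates at season end", {
  # theta = 2, mu = 9: by the end of the season most consumer biomass sits
  # in the (inert) reproductive storage, the precondition for the strong
  # post-pulse perturbation behind the Allee effect
  res <- integrate_season(s_high, p_theta2)
  expect_gt(res$end_state[["B"]],
            res$end_state[["J"]] + res$end_state[["A"]])
})

test_that("halving solver tolerances barely moves the end state", {
  ctrl1 <- cr_control(rtol = 1e-8, atol = 1e-10)
  ctrl2 <- cr_control(rtol = 5e-9, atol = 5e-11)
  e1 <- integrate_season(s_high, p_theta2, control = ctrl1)$end_state
  e2 <- integrate_season(s_high, p_theta2, control = ctrl2)$end_state
  expect_lt(max(abs(e1 - e2)), 10 * 1e-8)
})

test_that("iterated resource-only seasons converge geometrically to Kr", {
  p <- cr_params(theta = 1, mu = 2)
  # ext_tol = 0 keeps the consumer-free run going (it is "extinct" from
  # the start)
  it <- iterate_seasons(season_state(0.3), p, n_max = 20,
                        control = cr_control(ext_tol = 0, rtol = 1e-12,
                                             atol = 1e-16))
  err <- abs(it$seasons$R_end - p$Kr)
  # each season shrinks the gap by e^{-rho} (checked where it is still
  # clearly above the absolute solver tolerance)
  expect_rel_equal(err[1], abs(0.3 - 2) * exp(-10), 1e-6)
  expect_lt(err[2] / err[1], exp(-10) * 1.01)
})

test_that("season iteration reproduces the bistability scenarios", {
  expect_identical(iterate_seasons(s_high, p_theta2)$flag, "converged")
  expect_identical(iterate_seasons(s_low, p_theta2)$flag, "extinct")
  hi <- iterate_seasons(s_high, p_theta025)
  lo <- iterate_seasons(s_low, p_theta025)
  expect_identical(hi$flag, "converged")
  expect_identical(lo$flag, "converged")
  expect_equal(hi$final_state, lo$final_state, tolerance = 1e-6)
})

test_that("iteration records per-season averages and states coherently", {
  it <- iterate_seasons(s_high, p_theta2, n_max = 5)
  expect_identical(it$flag, "max_iter")
  expect_equal(nrow(it$seasons), 5)
  # next season's start is the pulsed end of the previous one
  expect_equal(it$seasons$J_start[-1],
               (it$seasons$J_end + it$seasons$B_end)[-5], tolerance = 1e-12)
  expect_equal(it$seasons$R_start[-1], it$seasons$R_end[-5],
               tolerance = 1e-12)
  expect_true(all(it$seasons$B_start == 0))
  expect_true(all(it$seasons[, c("Jbar", "Abar", "Bbar")] >= 0))
})
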