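test_that("resource turnover follows the semi-chemostat form", {
  p <- cr_params(theta = 1, mu = 1)
  expect_equal(resource_turnover(p$Kr, p), 0)
  expect_equal(resource_turnover(0, p), 10 * 2)
  expect_equal(resource_turnover(1, p), 10 * (2 - 1))
  expect_error(resource_turnover(-0.1, p), "non-negative")
})

test_that("net production crosses zero at the starvation threshold", {
  p <- cr_params(theta = 1, mu = 8)
  thr <- p$Q / (p$sigma * p$Imax)
  expect_equal(thr, 0.2)
  expect_equal(net_production(thr, p, "juvenile"), 0)
  expect_equal(net_production(2, p, "adult"), 0.5 * 1 * 100 * 2 - 10)
  expect_equal(net_production(0, p, "juvenile"), -p$Q)
  expect_equal(net_production(0, p, "adult"), -p$Q)
  # adult intake scales with theta
  p2 <- cr_params(theta = 2, mu = 8)
  expect_equal(net_production(1, p2, "adult"), 0.5 * 2 * 100 * 1 - 10)
  expect_equal(clip_production(c(90, -10, 0)), c(90, 0, 0))
})

test_that("maturation rate matches its closed form, limit and clipping", {
  expect_equal(maturation_rate(-5, 3, 0.1), 0)
  expect_equal(maturation_rate(0, 3, 0.1), 0)
  # removable singularity at nu_j == mu: limit -nu_j/log(z)
  expect_equal(maturation_rate(8, 8, 0.1), -8 / log(0.1), tolerance = 1e-12)
  expect_equal(maturation_rate(8, 8, 0.1), 3.474356, tolerance = 1e-6)
  # plain evaluation of the closed form
  g <- (90 - 8) / (1 - 0.1^(1 - 8 / 90))
  expect_equal(maturation_rate(90, 8, 0.1), g, tolerance = 1e-14)
  expect_equal(g, 93.4699, tolerance = 1e-5)
  # mu = 0 reduces to nu/(1 - z)
  expect_equal(maturation_rate(50, 0, 0.1), 50 / 0.9, tolerance = 1e-14)
  expect_error(maturation_rate(1, 1, 1.2), "z must")
})

test_that("maturation rate is continuous across both switch points", {
  mu <- 8; z <- 0.1
  # values on a fine grid bracketing nu_j = mu approach the limit smoothly
  nu <- mu * (1 + as.vector(c(-1, 1) %o% 10^seq(-12, -7)))
  g <- maturation_rate(nu, mu, z)
  expect_rel_equal(g, rep(-mu / log(z), length(g)), 1e-6)
  # branch hand-over at the guard edge is seamless: the limit branch just
  # inside and the closed form just outside agree at (nearly) the same nu
  g_in <- maturation_rate(mu * (1 + 0.999e-8), mu, z)
  g_out <- maturation_rate(mu * (1 + 1.001e-8), mu, z)
  expect_rel_equal(g_in, g_out, 1e-8)
  # nu_j -> 0+ tends continuously to 0 (exactly 0 once z^(1 - mu/nu)
  # overflows, hence non-strict monotonicity at the bottom)
  g0 <- maturation_rate(10^seq(-10, -1), mu, z)
  expect_true(all(diff(g0) >= 0))
  expect_gt(g0[length(g0)], g0[1])
  expect_lt(g0[1], 1e-8)
})

test_that("maturation rate increases with net production", {
  for (mu in c(0.5, 3, 8)) {
    g <- maturation_rate(seq(0.01, 120, length.out = 400), mu, 0.1)
    expect_true(all(diff(g) > 0))
  }
})

test_that("total mortality adds the starvation surcharge below threshold", {
  p <- cr_params(theta = 1, mu = 8)
  expect_equal(stage_mortality(2, p, "juvenile"), p$mu)
  expect_equal(stage_mortality(0, p, "juvenile"), 8 + 10)
  expect_equal(stage_mortality(0.2, p, "juvenile"), p$mu) # nu = 0 boundary
  expect_true(all(stage_mortality(seq(0, 2, 0.05), p, "adult") >= p$mu))
})

test_that("derivative field composes the rates and carries accumulators", {
  p <- cr_params(theta = 1, mu = 8)
  # resource-only equilibrium is a zero of the field
  d0 <- season_derivatives(c(p$Kr, 0, 0, 0), p)
  expect_equal(unname(d0), rep(0, 7))
  # composed juvenile derivative at R = 2: nu_j = 90, gamma = 93.47, mu = 8
  d <- season_derivatives(c(2, 1, 0, 0), p)
  expect_equal(d[["J"]], 90 - maturation_rate(90, 8, 0.1) - 8,
               tolerance = 1e-12)
  expect_equal(d[["A"]], maturation_rate(90, 8, 0.1), tolerance = 1e-12)
  expect_equal(d[["Jbar"]], 1)
  expect_error(season_derivatives(c(NA, 0, 0, 0), p), "finite")
})

test_that("starvation conserves biomass: dJ/dt = (nu_j - mu) J below threshold", {
  p <- cr_params(theta = 1, mu = 8)
  for (R in c(0, 0.05, 0.1, 0.19)) {
    nuj <- net_production(R, p, "juvenile")
    expect_lt(nuj, 0)
    d <- season_derivatives(c(R, 2, 1.5, 0.7), p)
    expect_equal(d[["J"]], (nuj - p$mu) * 2, tolerance = 1e-12)
    # idem adults and storage: dA = -(mu - nu_a) A, dB = (nu_a - mu) B
    nua <- net_production(R, p, "adult")
    expect_equal(d[["A"]], (nua - p$mu) * 1.5, tolerance = 1e-12)
    expect_equal(d[["B"]], (nua - p$mu) * 0.7, tolerance = 1e-12)
  }
})

test_that("no feeding collapses the field to exponential decay", {
  p <- cr_params(theta = 1, mu = 3, Imax = 0)
  d <- season_derivatives(c(1, 2, 0, 0), p)
  expect_equal(d[["J"]], -(p$Q + p$mu) * 2, tolerance = 1e-12)
})

test_that("compiled field agrees with the interpreted field", {
  p <- cr_params(theta = 1.7, mu = 4.2)
  rfun <- function(t, y, parms) list(unname(season_derivatives(y, p)))
  states <- list(c(0.1, 0.5, 0.2, 0.1),   # juveniles starving
                 c(0.5, 1, 0.5, 0.2),
                 c(2, 0.3, 0.8, 0.4))
  for (s in states) {
    via_c <- integrate_season(s, p)
    sol_r <- deSolve::ode(y = c(s, 0, 0, 0), times = c(0, 1),
                          func = rfun, parms = NULL, method = "lsoda",
                          rtol = 1e-10, atol = 1e-12, maxsteps = 50000)
    expect_equal(unname(via_c$end_state),
                 unname(sol_r[nrow(sol_r), 2:5]), tolerance = 1e-8)
    expect_equal(unname(via_c$averages),
                 unname(sol_r[nrow(sol_r), 6:8]), tolerance = 1e-7)
  }
})
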