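test_that("invasion multiplier via matrix exponential matches direct integration", {
  for (p in list(cr_params(theta = 2, mu = 5), p_theta025,
                 cr_params(theta = 1, mu = 11))) {
    expect_rel_equal(invasion_eigenvalue(p, method = "expm"),
                     invasion_eigenvalue(p, method = "ode"), 1e-8)
  }
})

test_that("invasion multiplier is monotone decreasing in mortality", {
  mus <- seq(0.5, 15, by = 0.5)
  lam <- vapply(mus, function(m)
    invasion_eigenvalue(cr_params(theta = 2, mu = m)), numeric(1))
  expect_true(all(diff(lam) < 0))
  # overwhelming mortality forbids invasion
  expect_lt(invasion_eigenvalue(cr_params(theta = 2, mu = 100)), 1)
})

test_that("the invasion boundary is a root of the multiplier", {
  p <- cr_params(theta = 2, mu = 0.1)
  mb <- invasion_boundary(p)
  expect_rel_equal(invasion_eigenvalue(update_params(p, mu = mb)), 1, 1e-4)
})

test_that("no feeding means no persistence at any positive mortality", {
  p <- cr_params(theta = 1, mu = 0.5, Imax = 0)
  it <- iterate_seasons(s_high, p, n_max = 200)
  expect_identical(it$flag, "extinct")
  expect_lt(invasion_eigenvalue(p), 1)
})

test_that("mortality sweep shows adult overcompensation at theta = 2", {
  sw <- sweep_mu(cr_params(theta = 2, mu = 0.1), mu_grid = c(0.1, 0.5, 1))
  co <- dplyr::filter(sw, branch == "coexistence")
  expect_equal(nrow(co), 3)
  expect_true(all(diff(co$Abar) > 0))
  expect_true(all(diff(co$Bbar) > 0))
  expect_true(all(diff(co$Jbar) < 0))
  # the extinct branch is always present
  expect_equal(sum(sw$branch == "extinct"), 3)
})

test_that("mortality sweep shows juvenile overcompensation at theta = 0.25", {
  sw <- sweep_mu(cr_params(theta = 0.25, mu = 0.1),
                 mu_grid = c(0.1, 0.5, 1, 2))
  co <- dplyr::filter(sw, branch == "coexistence")
  expect_equal(nrow(co), 4)
  expect_true(all(diff(co$Jbar) > 0))
  expect_true(all(diff(co$Abar) < 0))
})

test_that("sweep picks up the unstable branch inside the bistable band", {
  sw <- sweep_mu(cr_params(theta = 2, mu = 0.1), mu_grid = c(8.5, 9, 9.5))
  un <- dplyr::filter(sw, branch == "unstable")
  expect_gt(nrow(un), 0)
  expect_true(all(un$max_multiplier > 1))
  co <- dplyr::filter(sw, branch == "coexistence")
  # unstable branch lies between extinction (0) and the coexistence branch
  for (m in un$mu) {
    expect_lt(un$J[un$mu == m] + un$A[un$mu == m],
              co$J[co$mu == m] + co$A[co$mu == m])
  }
})

test_that("inside the bistable band the outcome depends on the initial state", {
  # mu between the invasion (~8.25) and persistence (~9.88) boundaries
  p <- cr_params(theta = 2, mu = 9)
  expect_identical(iterate_seasons(s_low, p)$flag, "extinct")
  expect_identical(iterate_seasons(s_high, p)$flag, "converged")
  # below the invasion boundary both initial states reach coexistence
  p7 <- cr_params(theta = 2, mu = 7)
  hi <- find_attractor(p7, s_high)
  lo <- find_attractor(p7, s_low)
  expect_identical(hi$stability, "stable")
  expect_equal(hi$state, lo$state, tolerance = 1e-6)
})

test_that("sweep and persistence boundary agree about the fold location", {
  p <- cr_params(theta = 2, mu = 0.1)
  pb <- as.numeric(persistence_boundary(p))
  grid <- seq(9, 10.5, by = 0.25)
  sw <- sweep_mu(p, mu_grid = grid, unstable = FALSE,
                 state = season_state(1, 0.4, 0.03))
  hi_co <- max(dplyr::filter(sw, branch == "coexistence")$mu)
  expect_lt(abs(hi_co - pb), 0.25 + 1e-3)
  # just above the boundary only the extinct branch remains
  above <- dplyr::filter(sw, mu > pb + 0.25)
  expect_true(all(above$branch == "extinct"))
})

test_that("two-parameter diagram orders the boundaries and flags bistability", {
  tp <- two_parameter_diagram(c(0.25, 1, 2))
  expect_equal(tp$theta, c(0.25, 1, 2))
  # invasion cannot exceed persistence beyond bisection noise
  expect_true(all(tp$mu_invade <= tp$mu_persist + 2e-3))
  expect_identical(tp$bistable, c(FALSE, TRUE, TRUE))
  # both boundaries rise with theta and their gap widens
  expect_true(all(diff(tp$mu_persist) > 0))
  expect_true(all(diff(tp$mu_invade) > 0))
  gap <- tp$mu_persist - tp$mu_invade
  expect_true(all(diff(gap) > 0))
})
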