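#' Dominant multiplier of the season map at the resource-only equilibrium
#'
#' At the resource-only equilibrium the resource sits at `Kr` for the whole
#' season, so the dynamics of a vanishingly rare consumer are linear with
#' constant coefficients: `J' = (nu_j+ - gamma - d_j) J`,
#' `A' = gamma J - d_a A`, `B' = nu_a+ A - d_a B`, all rates evaluated at
#' `R = Kr`.  The one-season transition matrix is the matrix exponential of
#' that system; composing it with the pulse map (`J <- J + B`, `B <- 0`)
#' gives the linearized season map, whose spectral radius determines
#' whether a rare consumer can invade (`> 1`) or not (`< 1`).
#'
#' @param p A [cr_params()] object.
#' @param method `"expm"` (matrix exponential, default) or `"ode"` (direct
#'   numerical integration of the linear system; provided as an
#'   independent cross-check).
#' @param control A [cr_control()] object (used by `method = "ode"`).
#' @return The dominant multiplier modulus (a single number).
#' @examples
#' invasion_eigenvalue(cr_params(theta = 2, mu = 5))
#' @export
invasion_eigenvalue <- function(p, method = c("expm", "ode"),
                                control = cr_control()) {
  stopifnot(inherits(p, "cr_params"))
  method <- match.arg(method)
  nuj <- p$sigma * p$Imax * p$Kr - p$Q
  nua <- p$sigma * p$theta * p$Imax * p$Kr - p$Q
  gam <- maturation_rate(nuj, p$mu, p$z)
  dj <- p$mu + max(0, -nuj)
  da <- p$mu + max(0, -nua)
  M <- rbind(c(max(nuj, 0) - gam - dj, 0, 0),
             c(gam, -da, 0),
             c(0, max(nua, 0), -da))
  if (method == "expm") {
    TT <- as.matrix(Matrix::expm(M))
  } else {
    lin <- function(t, y, parms) list(as.vector(M %*% y))
    TT <- vapply(1:3, function(i) {
      y0 <- numeric(3); y0[i] <- 1
      sol <- deSolve::ode(y = y0, times = c(0, 1), func = lin, parms = NULL,
                          method = control$method, rtol = 1e-12,
                          atol = 1e-14)
      unname(sol[nrow(sol), 2:4])
    }, numeric(3))
  }
  pulse <- rbind(c(1, 0, 1),
                 c(0, 1, 0),
                 c(0, 0, 0))
  max(Mod(eigen(pulse %*% TT, only.values = TRUE)$values))
}

# does a coexistence attractor exist when approached from `state`?
# returns the attractor (cr_equilibrium) or NULL
coexistence_attractor <- function(p, state, control) {
  eq <- tryCatch(find_attractor(p, state, control = control),
                 error = function(e) NULL)
  if (is.null(eq)) return(NULL)
  if (eq$stability %in% c("stable", "marginal") &&
      sum(eq$state[2:3]) > 1e-6) eq else NULL
}

# does the consumer persist when started from `state`?  Unlike
# coexistence_attractor() this accepts non-equilibrium attractors: a run
# that hits the season cap with substantial consumer biomass (a cycle, or
# very slow convergence) counts as persistence.  Returns the warm-start
# state for the next parameter value, or NULL on extinction.
persists_at <- function(p, state, control) {
  it <- iterate_seasons(state, p, control = control)
  if (it$flag == "extinct") return(NULL)
  if (it$flag == "converged") {
    eq <- tryCatch(solve_fixed_point(p, it$final_state[1:3],
                                     control = control),
                   error = function(e) NULL)
    st <- if (!is.null(eq)) eq$state else it$final_state
    return(if (sum(st[2:4]) > 1e-6) st else NULL)
  }
  if (sum(it$final_state[2:4]) > 1e-3) it$final_state else NULL
}

default_mu_max <- function(p) 20 * max(1, p$theta / 2)

#' Persistence boundary in background mortality
#'
#' The highest background mortality rate `mu` at which a coexistence
#' attractor of the season map exists, found by bisection on "forward
#' iteration from the high initial state converges to a coexistence fixed
#' point", warm-starting each trial from the attractor at the last
#' persisting `mu` so that the attractor branch is tracked up to its fold.
#'
#' @param p A [cr_params()] object fixing `theta` (its `mu` is ignored).
#' @param mu_lo A mortality rate at which the consumer is known (or
#'   expected) to persist; the default 0.1 is well inside the coexistence
#'   region for ordinary parameterisations.
#' @param mu_hi Upper end of the scan; defaults to 20, scaled up
#'   proportionally for `theta > 2`.
#' @param tol_mu Bisection tolerance on `mu`.
#' @param state Initial post-pulse state used at `mu_lo`.
#' @param control A [cr_control()] object.
#' @return The boundary `mu` (scalar), with the post-pulse state at the
#'   last persisting `mu` attached as attribute `"state"`.  Persistence is
#'   judged dynamically, so non-equilibrium attractors (cycles) count as
#'   persistence just as fixed points do.
#' @examples
#' \donttest{
#' persistence_boundary(cr_params(theta = 0.25, mu = 0.1))
#' }
#' @export
persistence_boundary <- function(p, mu_lo = 0.1, mu_hi = NULL,
                                 tol_mu = 1e-3,
                                 state = season_state(1, 0.2, 0.2),
                                 control = cr_control()) {
  stopifnot(inherits(p, "cr_params"))
  if (is.null(mu_hi)) mu_hi <- default_mu_max(p)
  warm <- persists_at(update_params(p, mu = mu_lo), state, control)
  if (is.null(warm))
    stop("consumer does not persist at mu = ", mu_lo,
         "; cannot bracket the persistence boundary", call. = FALSE)
  if (!is.null(persists_at(update_params(p, mu = mu_hi), warm, control)))
    stop("consumer still persists at mu = ", mu_hi,
         "; raise mu_hi", call. = FALSE)
  lo <- mu_lo; hi <- mu_hi
  while (hi - lo > tol_mu) {
    mid <- (lo + hi) / 2
    w_mid <- persists_at(update_params(p, mu = mid), warm, control)
    if (!is.null(w_mid)) {
      lo <- mid
      warm <- w_mid
    } else {
      hi <- mid
    }
  }
  structure((lo + hi) / 2, state = warm)
}

#' Invasion boundary in background mortality
#'
#' The mortality rate at which the dominant multiplier of the season map
#' linearized at the resource-only equilibrium equals 1 (see
#' [invasion_eigenvalue()]); above it a rare consumer cannot invade.
#' Located by root bracketing and bisection.
#'
#' @inheritParams persistence_boundary
#' @param mu_lo,mu_hi Bracket for the root; the multiplier must exceed 1 at
#'   `mu_lo` and fall below 1 at `mu_hi`.
#' @return The boundary `mu` (scalar).
#' @examples
#' invasion_boundary(cr_params(theta = 2, mu = 0.1))
#' @export
invasion_boundary <- function(p, mu_lo = 1e-6, mu_hi = NULL, tol_mu = 1e-3) {
  stopifnot(inherits(p, "cr_params"))
  if (is.null(mu_hi)) mu_hi <- default_mu_max(p)
  f <- function(mu) invasion_eigenvalue(update_params(p, mu = mu)) - 1
  flo <- f(mu_lo); fhi <- f(mu_hi)
  if (flo <= 0 || fhi >= 0)
    stop("invasion multiplier does not cross 1 on [", mu_lo, ", ", mu_hi,
         "]", call. = FALSE)
  stats::uniroot(f, c(mu_lo, mu_hi), tol = min(tol_mu, 1e-6) / 10)$root
}

#' One-parameter bifurcation sweep in background mortality
#'
#' For each `mu` on an ascending grid, locates the coexistence attractor
#' from the high initial state (warm-started from the previous grid
#' point), records the extinct (resource-only) equilibrium, and, inside
#' the bistable band (between the invasion and persistence boundaries),
#' continues the intermediate unstable equilibrium by Newton iteration
#' seeded at the midpoint of the two stable states.
#'
#' @param p A [cr_params()] object fixing `theta`.
#' @param mu_grid Ascending vector of mortality rates.
#' @param unstable If `TRUE`, attempt the unstable branch where the
#'   coexistence attractor exists and the invasion multiplier is below 1.
#' @param state Initial post-pulse state for the first grid point.
#' @param control A [cr_control()] object.
#' @return A tibble of class `cr_branches` with columns `theta`, `mu`,
#'   `branch` (`"coexistence"`, `"extinct"`, `"unstable"`), `stability`,
#'   the post-pulse state (`R`, `J`, `A`), season averages (`Jbar`,
#'   `Abar`, `Bbar`) and `max_multiplier`.  Failures at individual grid
#'   points are recorded as missing rows, not errors.
#' @examples
#' \donttest{
#' sweep_mu(cr_params(theta = 0.25, mu = 0.1), mu_grid = c(0.1, 0.5, 1))
#' }
#' @export
sweep_mu <- function(p, mu_grid, unstable = TRUE,
                     state = season_state(1, 0.2, 0.2),
                     control = cr_control()) {
  stopifnot(inherits(p, "cr_params"), !is.unsorted(mu_grid))
  eq_row <- function(eq, mu, branch) {
    tibble::tibble(theta = p$theta, mu = mu, branch = branch,
                   stability = eq$stability,
                   R = eq$state[["R"]], J = eq$state[["J"]],
                   A = eq$state[["A"]],
                   Jbar = eq$averages[["Jbar"]],
                   Abar = eq$averages[["Abar"]],
                   Bbar = eq$averages[["Bbar"]],
                   max_multiplier = max(eq$multipliers))
  }
  warm <- state
  unstable_guess <- NULL
  rows <- vector("list", length(mu_grid))
  for (i in seq_along(mu_grid)) {
    mu <- mu_grid[i]
    pm <- update_params(p, mu = mu)
    out <- list()
    co <- coexistence_attractor(pm, warm, control)
    if (is.null(co)) {
      # forward iteration found no stable fixed point (e.g. the attractor
      # is a cycle at low mortality); continue the fixed-point branch by
      # Newton from the warm start and record its true stability
      co <- tryCatch(solve_fixed_point(pm, warm[1:3], control = control),
                     error = function(e) NULL)
      if (!is.null(co) && sum(co$state[2:3]) <= 1e-6) co <- NULL
    }
    if (!is.null(co)) {
      warm <- co$state
      out$co <- eq_row(co, mu, "coexistence")
    }
    ext <- equilibrium_from_state(c(p$Kr, 0, 0), pm, control, residual = 0)
    out$ext <- eq_row(ext, mu, "extinct")
    if (unstable && !is.null(co) &&
        invasion_eigenvalue(pm) < 1) {
      guess <- if (!is.null(unstable_guess)) unstable_guess
               else (co$state[1:3] + c(p$Kr, 0, 0)) / 2
      un <- tryCatch(solve_fixed_point(pm, guess, control = control),
                     error = function(e) NULL)
      if (!is.null(un) && un$stability == "unstable" &&
          sum(un$state[2:3]) > 1e-6) {
        unstable_guess <- un$state[1:3]
        out$un <- eq_row(un, mu, "unstable")
      }
    }
    rows[[i]] <- dplyr::bind_rows(out)
  }
  res <- dplyr::bind_rows(rows)
  class(res) <- c("cr_branches", class(res))
  res
}

#' Persistence/invasion boundaries across the intake ratio
#'
#' For each `theta` on an ascending grid computes the persistence boundary
#' (fold of the coexistence branch) and the invasion boundary (dominant
#' multiplier at the resource-only equilibrium equal to 1), and flags
#' bistability where the gap between them exceeds `5 * tol_mu` (a gap
#' smaller than that is indistinguishable from bisection noise and would
#' otherwise pick up the tiny alternative-stable-states sliver).
#'
#' @param theta_grid Ascending vector of intake ratios.
#' @param p A [cr_params()] object supplying all other parameters.
#' @param tol_mu Bisection tolerance for both boundaries.
#' @param control A [cr_control()] object.
#' @return A tibble of class `cr_boundaries` with columns `theta`,
#'   `mu_persist`, `mu_invade`, `bistable`.  Per-theta failures yield `NA`
#'   rows rather than aborting.
#' @examples
#' \donttest{
#' two_parameter_diagram(c(0.25, 0.5, 1), cr_params(theta = 1, mu = 0.1))
#' }
#' @export
two_parameter_diagram <- function(theta_grid, p = cr_params(theta = 1,
                                                            mu = 0.1),
                                  tol_mu = 1e-3, control = cr_control()) {
  stopifnot(!is.unsorted(theta_grid))
  rows <- purrr::map(theta_grid, function(th) {
    pt <- update_params(p, theta = th)
    mp <- tryCatch(as.numeric(persistence_boundary(pt, tol_mu = tol_mu,
                                                   control = control)),
                   error = function(e) NA_real_)
    mi <- tryCatch(invasion_boundary(pt, tol_mu = tol_mu),
                   error = function(e) NA_real_)
    tibble::tibble(theta = th, mu_persist = mp, mu_invade = mi,
                   bistable = !is.na(mp) & !is.na(mi) &
                     (mp - mi > 5 * tol_mu))
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("cr_boundaries", class(res))
  res
}

#' Onset of bistability in the intake ratio
#'
#' The smallest `theta` at which the persistence boundary separates from
#' the invasion boundary by more than `5 * tol_mu`, i.e. at which
#' bistability between the coexistence and resource-only equilibria (an
#' Allee effect) appears.  Found by bisection on `theta`.
#'
#' @param p A [cr_params()] object supplying all parameters other than
#'   `theta`.
#' @param theta_range Bracket: no bistability at the lower end, bistability
#'   at the upper end.
#' @param tol_theta Bisection tolerance on `theta`.
#' @param tol_mu Tolerance for the per-theta boundary computations.
#' @param control A [cr_control()] object.
#' @return The onset `theta` (scalar).
#' @export
bistability_onset <- function(p = cr_params(theta = 1, mu = 0.1),
                              theta_range = c(0.25, 0.6),
                              tol_theta = 5e-3, tol_mu = 1e-3,
                              control = cr_control()) {
  gap_ok <- function(th) {
    pt <- update_params(p, theta = th)
    mp <- as.numeric(persistence_boundary(pt, tol_mu = tol_mu,
                                          control = control))
    mi <- invasion_boundary(pt, tol_mu = tol_mu)
    (mp - mi) > 5 * tol_mu
  }
  lo <- theta_range[1]; hi <- theta_range[2]
  if (gap_ok(lo))
    stop("bistable already at theta = ", lo, "; widen theta_range down",
         call. = FALSE)
  if (!gap_ok(hi))
    stop("not bistable at theta = ", hi, "; widen theta_range up",
         call. = FALSE)
  while (hi - lo > tol_theta) {
    mid <- (lo + hi) / 2
    if (gap_ok(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
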