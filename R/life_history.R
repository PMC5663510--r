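#' Within-season environment for life-history calculations
#'
#' The expected-reproductive-output machinery evaluates a newborn cohort
#' against a fixed within-season resource trajectory, in one of two modes:
#' `"coupled"` uses the resource trajectory of the converged fixed-point
#' season of the full model (consumer feedback depresses the resource),
#' while `"decoupled"` holds the resource at its maximum `Kr` (no
#' feedback; formally, the resource-only equilibrium season).
#'
#' @param p A [cr_params()] object.
#' @param mode `"coupled"` or `"decoupled"`.
#' @param state Initial post-pulse state handed to [find_attractor()] in
#'   coupled mode.
#' @param control A [cr_control()] object.
#' @return A list of class `cr_environment` with the post-pulse
#'   `start_state` that generates the season and the `mode`.
#' @export
season_environment <- function(p, mode = c("coupled", "decoupled"),
                               state = season_state(1, 0.2, 0.2),
                               control = cr_control()) {
  stopifnot(inherits(p, "cr_params"))
  mode <- match.arg(mode)
  if (mode == "decoupled") {
    start <- c(R = p$Kr, J = 0, A = 0, B = 0)
  } else {
    eq <- find_attractor(p, state, control = control)
    if (eq$stability == "extinct")
      stop("no coexistence attractor at theta = ", p$theta, ", mu = ",
           p$mu, "; the coupled environment is undefined", call. = FALSE)
    start <- eq$state
  }
  structure(list(mode = mode, start_state = start, params = p),
            class = "cr_environment")
}

# integrate the 12-state augmented system (resident season + R0
# accumulators S, W + unit cohort) along an environment, at given times
lifehist_solve <- function(env, times, control) {
  p <- env$params
  sol <- ode_season(env$start_state, p, times, control,
                    func = "pulsecr_lifehist",
                    extra = c(0, 0, 1, 0, 0))
  colnames(sol) <- c("t", "R", "J", "A", "B", "Jbar", "Abar", "Bbar",
                     "S", "W", "cj", "ca", "cb")
  sol
}

#' Expected end-of-season reproductive output of a newborn
#'
#' For an individual born at the start of the season that matures at time
#' `tm`, the expected contribution to the reproductive output at the end
#' of the season is
#' \deqn{R_0(t_m) = \gamma(\nu_j(R(t_m)), \mu)\,
#'   e^{-\mu + \int_0^{t_m} [\nu_j(R(\tau)) - \gamma(\nu_j(R(\tau)), \mu)]
#'   d\tau}\, \int_{t_m}^{1} \nu_a(R(\tau))\, d\tau,}
#' combining the maturation rate at `tm`, the cohort biomass per capita at
#' maturation (growth net of maturation losses, discounted by whole-season
#' background survival \eqn{e^{-\mu}}), and the storage accumulated over
#' the remaining season.  The two integrals are carried as additional ODE
#' components alongside the within-season dynamics, so a single
#' integration yields the whole curve.  Per unit of newborn biomass,
#' \eqn{\int_0^1 R_0(t_m)\, dt_m} equals the end-of-season storage of a
#' unit juvenile cohort (see [cohort_dynamics()]), which is verified in
#' the package tests.
#'
#' @param p A [cr_params()] object.
#' @param mode `"coupled"` or `"decoupled"` (see [season_environment()]).
#' @param n_tm Number of uniformly spaced maturation times in `[0, 1]`.
#' @param env Optionally, a precomputed [season_environment()] (overrides
#'   `mode`).
#' @param control A [cr_control()] object.
#' @return A tibble of class `r0_curve` with columns `tm`, `r0`,
#'   `cumulative` (\eqn{\int_0^{t_m} R_0(\tau) d\tau}, by cumulative
#'   trapezoidal quadrature) and `R` (the resource trajectory sampled at
#'   `tm`); the mode and environment travel as attributes.
#' @examples
#' \donttest{
#' r0_curve(cr_params(theta = 1, mu = 8), mode = "decoupled", n_tm = 51)
#' }
#' @export
r0_curve <- function(p, mode = c("coupled", "decoupled"), n_tm = 401,
                     env = NULL, control = cr_control()) {
  stopifnot(inherits(p, "cr_params"))
  if (is.null(env)) env <- season_environment(p, match.arg(mode),
                                              control = control)
  tm <- seq(0, 1, length.out = n_tm)
  sol <- lifehist_solve(env, tm, control)
  Wtot <- sol[nrow(sol), "W"]
  nuj <- p$sigma * p$Imax * sol[, "R"] - p$Q
  gam <- maturation_rate(nuj, p$mu, p$z)
  r0 <- gam * exp(-p$mu + sol[, "S"]) * (Wtot - sol[, "W"])
  out <- tibble::tibble(tm = tm, r0 = unname(r0),
                        cumulative = as.vector(pracma::cumtrapz(tm,
                                                                unname(r0))),
                        R = unname(sol[, "R"]))
  attr(out, "mode") <- env$mode
  attr(out, "environment") <- env
  attr(out, "cohort_b_end") <- unname(sol[nrow(sol), "cb"])
  class(out) <- c("r0_curve", class(out))
  out
}

#' Expected reproductive output at given maturation times
#'
#' Point evaluation of the curve computed by [r0_curve()], for arbitrary
#' maturation times in `[0, 1]` against a supplied environment.
#'
#' @param p A [cr_params()] object.
#' @param env A [season_environment()] object.
#' @param tm Maturation time(s) in `[0, 1]`.
#' @param control A [cr_control()] object.
#' @return Numeric vector of expected reproductive outputs.
#' @export
r0_at_tm <- function(p, env, tm, control = cr_control()) {
  stopifnot(inherits(env, "cr_environment"))
  if (any(tm < 0 | tm > 1))
    stop("tm must lie in [0, 1]", call. = FALSE)
  times <- sort(unique(c(0, tm, 1)))
  sol <- lifehist_solve(env, times, control)
  idx <- match(tm, times)
  Wtot <- sol[nrow(sol), "W"]
  nuj <- p$sigma * p$Imax * sol[idx, "R"] - p$Q
  gam <- maturation_rate(nuj, p$mu, p$z)
  unname(gam * exp(-p$mu + sol[idx, "S"]) * (Wtot - sol[idx, "W"]))
}

#' Closed-form decoupled expected reproductive output
#'
#' With the resource held constant at `Kr` the rates `nu_j`, `nu_a` and
#' `gamma` are constants, and the expected-output integral collapses to
#' \deqn{R_0(t_m) = \gamma^* e^{-\mu} e^{(\nu_j^* - \gamma^*) t_m}
#'   \nu_a^* (1 - t_m),}
#' which serves as an independent oracle for the ODE evaluation.
#'
#' @param p A [cr_params()] object.
#' @param tm Maturation time(s) in `[0, 1]`.
#' @return Numeric vector of expected reproductive outputs.
#' @examples
#' decoupled_r0(cr_params(theta = 1, mu = 8), c(0, 0.5, 1))
#' @export
decoupled_r0 <- function(p, tm) {
  stopifnot(inherits(p, "cr_params"))
  if (any(tm < 0 | tm > 1))
    stop("tm must lie in [0, 1]", call. = FALSE)
  nuj <- p$sigma * p$Imax * p$Kr - p$Q
  nua <- p$sigma * p$theta * p$Imax * p$Kr - p$Q
  gam <- maturation_rate(nuj, p$mu, p$z)
  gam * exp(-p$mu) * exp((nuj - gam) * tm) * clip_production(nua) * (1 - tm)
}

#' Within-season dynamics of a unit juvenile cohort
#'
#' Introduces one unit of juvenile biomass at the start of the season and
#' integrates the linear (no resource feedback) cohort equations against
#' the chosen environment: `j' = (nu_j+ - gamma - d_j) j`,
#' `a' = gamma j - d_a a`, `b' = nu_a+ a - d_a b` with `j(0) = 1`,
#' `a(0) = b(0) = 0`.
#'
#' @inheritParams r0_curve
#' @param nt Number of sample points across the season.
#' @return A tibble of class `cohort_trajectory` with columns `t`, `R`,
#'   `J`, `A`, `B` (the cohort components).  Attributes: `peak_B` (time of
#'   the storage maximum, refined by local quadratic interpolation),
#'   `juvenile_depletion` (first time cohort juvenile biomass falls below
#'   1% of its initial value, `NA` if it never does) and `mode`.
#' @examples
#' \donttest{
#' co <- cohort_dynamics(cr_params(theta = 1, mu = 8), mode = "decoupled")
#' attr(co, "peak_B")
#' }
#' @export
cohort_dynamics <- function(p, mode = c("coupled", "decoupled"), nt = 2001,
                            env = NULL, control = cr_control()) {
  stopifnot(inherits(p, "cr_params"))
  if (is.null(env)) env <- season_environment(p, match.arg(mode),
                                              control = control)
  times <- seq(0, 1, length.out = nt)
  sol <- lifehist_solve(env, times, control)
  out <- tibble::tibble(t = sol[, "t"], R = sol[, "R"], J = sol[, "cj"],
                        A = sol[, "ca"], B = sol[, "cb"])
  ipk <- which.max(out$B)
  dep <- which(out$J < 0.01)[1]
  attr(out, "peak_B") <- refine_extremum(out$t, out$B, ipk)
  attr(out, "juvenile_depletion") <- if (is.na(dep)) NA_real_ else
    out$t[dep]
  attr(out, "mode") <- env$mode
  class(out) <- c("cohort_trajectory", class(out))
  out
}

# quadratic refinement of a grid extremum at index i (interior); returns
# the abscissa of the parabola vertex through the three bracketing points
refine_extremum <- function(x, y, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(x[i])
  x0 <- x[i - 1]; x1 <- x[i]; x2 <- x[i + 1]
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  denom <- (y0 - 2 * y1 + y2)
  if (denom == 0) return(x1)
  x1 + 0.5 * (x2 - x1) * (y0 - y2) / denom
}

# root of y = level between grid points, refined by the local quadratic
# through the three nearest points; i indexes the last point before the
# crossing
refine_crossing <- function(x, y, i, level = 1) {
  lin <- x[i] + (x[i + 1] - x[i]) * (level - y[i]) / (y[i + 1] - y[i])
  j <- max(2L, min(i, length(x) - 1L))
  xs <- x[(j - 1):(j + 1)]; ys <- y[(j - 1):(j + 1)] - level
  co <- tryCatch(solve(cbind(1, xs, xs^2), ys), error = function(e) NULL)
  if (is.null(co) || abs(co[3]) < 1e-12) return(lin)
  disc <- co[2]^2 - 4 * co[3] * co[1]
  if (disc < 0) return(lin)
  roots <- (-co[2] + c(-1, 1) * sqrt(disc)) / (2 * co[3])
  roots <- roots[roots >= x[i] - (x[2] - x[1]) &
                 roots <= x[i + 1] + (x[2] - x[1])]
  if (length(roots) == 0) return(lin)
  roots[which.min(abs(roots - lin))]
}

#' Landmark features of an expected-reproductive-output curve
#'
#' Interior local minimum and global maximum locations (refined by local
#' quadratic interpolation) and the crossings of `R0 = 1`, together with
#' the cumulative output over the whole season.
#'
#' @param curve An [r0_curve()] tibble.
#' @return A one-row tibble: `mode`, `tm_min`, `tm_max`, `r0_max`,
#'   `cross_up`, `cross_down` (first upward / last downward crossing of 1,
#'   `NA` when absent) and `cumulative_total`.
#' @export
r0_features <- function(curve) {
  stopifnot(inherits(curve, "r0_curve"))
  tm <- curve$tm; r0 <- curve$r0
  n <- length(tm)
  # interior local minimum: first index whose neighbours are both larger
  imin <- which(diff(sign(diff(r0))) > 0) + 1L
  tm_min <- if (length(imin)) refine_extremum(tm, r0, imin[1]) else NA_real_
  imax <- which.max(r0)
  tm_max <- refine_extremum(tm, r0, imax)
  above <- r0 > 1
  up <- which(!above[-n] & above[-1])
  down <- which(above[-n] & !above[-1])
  cross_up <- if (length(up)) refine_crossing(tm, r0, up[1]) else NA_real_
  cross_down <- if (length(down))
    refine_crossing(tm, r0, down[length(down)]) else NA_real_
  tibble::tibble(mode = attr(curve, "mode"), tm_min = tm_min,
                 tm_max = tm_max, r0_max = r0[imax],
                 cross_up = cross_up, cross_down = cross_down,
                 cumulative_total = curve$cumulative[n])
}
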