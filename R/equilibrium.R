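#' The season map on post-pulse states
#'
#' Composition of one season of within-season dynamics with the
#' reproduction pulse, restricted to the post-pulse coordinates
#' `(R, J, A)` (storage is identically 0 immediately after the pulse, so it
#' is eliminated).  Fixed points of this map are the model's equilibria.
#'
#' @param x Numeric vector `(R, J, A)` of a post-pulse state.
#' @param p A [cr_params()] object.
#' @param control A [cr_control()] object.
#' @return The mapped post-pulse state `(R, J, A)`.
#' @export
season_map <- function(x, p, control = cr_control()) {
  s <- c(R = max(x[[1]], 0), J = max(x[[2]], 0), A = max(x[[3]], 0), B = 0)
  e <- integrate_season(s, p, control = control)$end_state
  ps <- reproduction_pulse(e)
  ps[1:3]
}

#' Jacobian of the season map
#'
#' Either by central finite differences on [season_map()] (default, step
#' `1e-6 * (1 + |x|)` per coordinate) or by transporting the variational
#' equations (the analytic Jacobian of the derivative field) across the
#' season and applying the pulse map.  The two routes agree closely away
#' from switch points and serve as mutual checks.
#'
#' @inheritParams season_map
#' @param method `"fd"` or `"variational"`.
#' @return A 3x3 Jacobian matrix.
#' @export
season_map_jacobian <- function(x, p, method = c("fd", "variational"),
                                control = cr_control()) {
  method <- match.arg(method)
  x <- unname(x[1:3])
  if (method == "fd") {
    jac <- matrix(0, 3, 3)
    for (i in 1:3) {
      h <- 1e-6 * (1 + abs(x[i]))
      xp <- x; xp[i] <- x[i] + h
      xm <- x; xm[i] <- max(x[i] - h, 0)
      jac[, i] <- (season_map(xp, p, control) -
                     season_map(xm, p, control)) / (xp[i] - xm[i])
    }
    return(jac)
  }
  # variational: integrate state + 4x4 fundamental matrix, then apply pulse
  vfun <- function(t, y, parms) {
    s <- y[1:4]
    Y <- matrix(y[5:20], 4, 4)
    f <- unname(season_derivatives(s, p)[1:4])
    list(c(f, as.vector(field_jacobian(s, p) %*% Y)))
  }
  y0 <- c(x[1], x[2], x[3], 0, as.vector(diag(4)))
  sol <- deSolve::ode(y = y0, times = c(0, 1), func = vfun, parms = NULL,
                      method = control$method, rtol = control$rtol,
                      atol = control$atol, maxsteps = 50000)
  Y1 <- matrix(sol[nrow(sol), 6:21], 4, 4)
  pulse <- rbind(c(1, 0, 0, 0),
                 c(0, 1, 0, 1),
                 c(0, 0, 1, 0))
  (pulse %*% Y1)[, 1:3]
}

new_cr_equilibrium <- function(state, averages, multipliers, stability,
                               residual, p) {
  structure(list(state = state, averages = averages,
                 multipliers = multipliers, stability = stability,
                 residual = residual, params = p),
            class = "cr_equilibrium")
}

classify_stability <- function(moduli, state, control) {
  if (sum(state[2:4]) < 1e-8) return("extinct")
  m <- max(moduli)
  if (m < 1 - control$tol_eig) "stable"
  else if (m > 1 + control$tol_eig) "unstable"
  else "marginal"
}

equilibrium_from_state <- function(x, p, control, residual = NA_real_) {
  state <- c(R = max(x[[1]], 0), J = max(x[[2]], 0), A = max(x[[3]], 0),
             B = 0)
  jac <- season_map_jacobian(state[1:3], p, control = control)
  moduli <- Mod(eigen(jac, only.values = TRUE)$values)
  res <- integrate_season(state, p, control = control)
  if (is.na(residual))
    residual <- max(abs(reproduction_pulse(res$end_state)[1:3] - state[1:3]))
  new_cr_equilibrium(state, res$averages, moduli,
                     classify_stability(moduli, state, control), residual, p)
}

#' Locate a fixed point of the season map by Newton iteration
#'
#' Solves `season_map(x) - x = 0` on post-pulse coordinates `(R, J, A)`
#' with a damped Newton method whose Jacobian is obtained by central
#' finite differences.  Used to polish attractors found by forward
#' iteration and to locate unstable equilibria, which forward iteration
#' cannot reach.
#'
#' @param p A [cr_params()] object.
#' @param guess Initial post-pulse state; the `B` component, if present,
#'   must be 0.
#' @param tol Residual (max-norm) at which Newton is declared converged.
#' @param max_iter Maximum number of Newton steps.
#' @param control A [cr_control()] object.
#' @return A `cr_equilibrium` object: `state` (post-pulse, `B = 0`),
#'   `averages` (`Jbar`, `Abar`, `Bbar`), `multipliers` (moduli of the
#'   season-map Jacobian eigenvalues), `stability`
#'   (`"stable"`, `"unstable"`, `"marginal"` or `"extinct"`) and
#'   `residual`.
#' @examples
#' \donttest{
#' p <- cr_params(theta = 2, mu = 9)
#' eq <- solve_fixed_point(p, c(R = 1, J = 0.2, A = 0.2))
#' eq$stability
#' }
#' @export
solve_fixed_point <- function(p, guess, tol = 1e-10, max_iter = 30,
                              control = cr_control()) {
  stopifnot(inherits(p, "cr_params"))
  if (length(guess) >= 4L && abs(guess[[4]]) > 0)
    stop("guess must be a post-pulse state with B = 0", call. = FALSE)
  x <- pmax(unname(guess[1:3]), 0)
  for (iter in seq_len(max_iter)) {
    Fx <- season_map(x, p, control) - x
    if (max(abs(Fx)) < tol)
      return(equilibrium_from_state(x, p, control, residual = max(abs(Fx))))
    jac <- season_map_jacobian(x, p, control = control) - diag(3)
    rc <- rcond(jac)
    if (!is.finite(rc) || rc < 1e-14)
      stop("Newton Jacobian is numerically singular (rcond = ",
           signif(rc, 3), "); the fixed point may sit at a fold",
           call. = FALSE)
    step <- solve(jac, Fx)
    # damp steps that would leave the non-negative orthant badly
    lam <- 1
    repeat {
      x_new <- x - lam * step
      if (all(x_new > -1e-8) || lam < 1e-3) break
      lam <- lam / 2
    }
    x <- pmax(x_new, 0)
    if (any(!is.finite(x)) || max(abs(x)) > 1e6)
      stop("Newton iteration diverged", call. = FALSE)
  }
  stop("Newton did not converge in ", max_iter, " iterations", call. = FALSE)
}

#' Find the attractor of the season map from an initial state
#'
#' Forward-iterates seasons from `state` until convergence or extinction.
#' A converged state is polished with [solve_fixed_point()]; an extinct run
#' returns the resource-only equilibrium `(Kr, 0, 0, 0)` exactly, flagged
#' `"extinct"`.  If the iteration hits the season cap without either
#' outcome a Newton solve is attempted from the final state, and failing
#' that an error of class `pulsecr_no_convergence` is signalled (possible
#' non-equilibrium attractor).
#'
#' @param p A [cr_params()] object.
#' @param state Initial post-pulse state `(R, J, A, B = 0)`.
#' @param control A [cr_control()] object.
#' @return A `cr_equilibrium` object (see [solve_fixed_point()]).
#' @examples
#' \donttest{
#' p <- cr_params(theta = 2, mu = 9)
#' find_attractor(p, season_state(1, 0.2, 0.2))$stability   # coexistence
#' find_attractor(p, season_state(1, 0.01, 0.01))$stability # "extinct"
#' }
#' @export
find_attractor <- function(p, state = season_state(1, 0.2, 0.2),
                           control = cr_control()) {
  stopifnot(inherits(p, "cr_params"))
  it <- iterate_seasons(state, p, control = control)
  if (it$flag == "extinct")
    return(equilibrium_from_state(c(p$Kr, 0, 0), p, control, residual = 0))
  eq <- tryCatch(solve_fixed_point(p, it$final_state[1:3], control = control),
                 error = function(e) NULL)
  if (!is.null(eq)) {
    if (it$flag == "converged" && sum(eq$state[2:3]) < 1e-8)
      return(equilibrium_from_state(c(p$Kr, 0, 0), p, control, residual = 0))
    return(eq)
  }
  if (it$flag == "converged") {
    # Newton failed (e.g. near a fold); fall back on the iterated point
    return(equilibrium_from_state(it$final_state[1:3], p, control))
  }
  stop(structure(class = c("pulsecr_no_convergence", "error", "condition"),
                 list(message = paste0(
                   "forward iteration did not converge within ",
                   control$n_max, " seasons (theta = ", p$theta,
                   ", mu = ", p$mu, "); possible non-equilibrium attractor"),
                   call = NULL)))
}

#' @export
print.cr_equilibrium <- function(x, ...) {
  cat("<cr_equilibrium> ", x$stability, "\n", sep = "")
  cat("  post-pulse state: ",
      paste(sprintf("%s = %.6g", names(x$state), x$state), collapse = ", "),
      "\n", sep = "")
  cat("  season averages:  ",
      paste(sprintf("%s = %.6g", names(x$averages), x$averages),
            collapse = ", "), "\n", sep = "")
  cat("  multiplier moduli: ", paste(signif(x$multipliers, 6),
                                     collapse = ", "), "\n", sep = "")
  invisible(x)
}
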