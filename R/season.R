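#' Construct and validate a within-season state
#'
#' @param R,J,A,B Resource density, juvenile biomass, adult biomass and
#'   reproductive energy storage; all non-negative.
#' @return A named numeric vector `c(R, J, A, B)`.
#' @export
season_state <- function(R, J = 0, A = 0, B = 0) {
  s <- c(R = R, J = J, A = A, B = B)
  if (any(!is.finite(s)) || any(s < 0))
    stop("all state components must be finite and non-negative",
         call. = FALSE)
  s
}

#' Reproduction pulse at a season boundary
#'
#' At the start of each growing season adults release all stored
#' reproductive energy as offspring: juvenile biomass increases by `B`,
#' storage resets to 0, and resource and adult biomass are unchanged.
#' Total consumer biomass `J + A + B` is conserved exactly.
#'
#' @param state Named numeric vector `(R, J, A, B)`.
#' @return The post-pulse state `(R, J + B, A, 0)`.
#' @examples
#' reproduction_pulse(season_state(1, 0.3, 0.2, 0.1))
#' @export
reproduction_pulse <- function(state) {
  if (length(state) < 4L || any(!is.finite(state[1:4])))
    stop("state must contain four finite components (R, J, A, B)",
         call. = FALSE)
  c(R = state[[1]], J = state[[2]] + state[[4]], A = state[[3]], B = 0)
}

# low-level compiled one-season solve; y0 is the 4-state start, returns the
# deSolve matrix for the requested times
ode_season <- function(y0, p, times, control, func = "pulsecr_season",
                       extra = NULL) {
  y <- c(unname(y0[1:4]), 0, 0, 0, extra)
  sol <- deSolve::ode(y = y, times = times, func = func,
                      parms = parm_vector(p), dllname = "pulsecr",
                      initfunc = "pulsecr_init", method = control$method,
                      rtol = control$rtol, atol = control$atol,
                      maxsteps = 50000)
  if (any(!is.finite(sol)))
    stop("within-season integration failed (non-finite solution) at ",
         "state (", paste(signif(y0[1:4], 6), collapse = ", "),
         ") with theta = ", p$theta, ", mu = ", p$mu, call. = FALSE)
  sol
}

#' Integrate the within-season dynamics over one season
#'
#' Solves the within-season ODE system from a given beginning-of-season
#' state over the unit season, accumulating the season averages of `J`, `A`
#' and `B` as additional ODE components.
#'
#' @param state Beginning-of-season state `(R, J, A, B)`, e.g. from
#'   [season_state()].
#' @param p A [cr_params()] object.
#' @param dense If `TRUE`, also return the trajectory sampled at `nt`
#'   equally spaced times in `[0, 1]`.
#' @param nt Number of sample points for the dense trajectory.
#' @param control A [cr_control()] object.
#' @return A list of class `season_result` with components
#'   `end_state` (named state at `t = 1`), `averages` (named vector
#'   `Jbar`, `Abar`, `Bbar`) and `trajectory` (a tibble with columns
#'   `t`, `R`, `J`, `A`, `B`, or `NULL`).
#' @examples
#' p <- cr_params(theta = 2, mu = 9)
#' res <- integrate_season(season_state(1, 0.2, 0.2), p)
#' res$end_state
#' res$averages
#' @export
integrate_season <- function(state, p, dense = FALSE, nt = 201,
                             control = cr_control()) {
  stopifnot(inherits(p, "cr_params"))
  if (any(state[1:4] < 0))
    stop("state components must be non-negative", call. = FALSE)
  times <- if (dense) seq(0, 1, length.out = nt) else c(0, 1)
  sol <- ode_season(state, p, times, control)
  last <- sol[nrow(sol), ]
  end_state <- c(R = last[[2]], J = last[[3]], A = last[[4]], B = last[[5]])
  averages <- c(Jbar = last[[6]], Abar = last[[7]], Bbar = last[[8]])
  traj <- NULL
  if (dense) {
    traj <- tibble::tibble(t = sol[, 1], R = sol[, 2], J = sol[, 3],
                           A = sol[, 4], B = sol[, 5])
  }
  structure(list(end_state = end_state, averages = averages,
                 trajectory = traj),
            class = "season_result")
}

#' Iterate the season map over many seasons
#'
#' Alternates one season of continuous dynamics ([integrate_season()]) with
#' the discrete [reproduction_pulse()], starting from a post-pulse
#' (beginning-of-season) state.  Iteration stops when (a) successive
#' post-pulse states differ by less than `control$tol_fix` in max-norm for
#' `control$conv_run` consecutive seasons (`flag = "converged"`), (b) total
#' consumer biomass falls below `control$ext_tol` (`flag = "extinct"`), or
#' (c) `n_max` seasons have elapsed (`flag = "max_iter"`).
#'
#' @param state Initial post-pulse state `(R, J, A, B)`; `B` should be 0
#'   under the post-pulse convention.
#' @param p A [cr_params()] object.
#' @param n_max Maximum number of seasons (overrides `control$n_max`).
#' @param dense If `TRUE`, keep a dense within-season trajectory for every
#'   season (memory grows with the number of seasons; meant for plotting a
#'   modest number of seasons).
#' @param nt Points per season for dense trajectories.
#' @param control A [cr_control()] object.
#' @return A list of class `season_iteration`: `seasons` (tibble with one
#'   row per season: start state, end state, averages), `flag`,
#'   `final_state` (the last post-pulse state) and `trajectory` (long
#'   tibble with columns `season`, `t`, `time`, `R`, `J`, `A`, `B`, or
#'   `NULL`).
#' @examples
#' p <- cr_params(theta = 0.25, mu = 3.5)
#' it <- iterate_seasons(season_state(1, 0.2, 0.2), p, n_max = 200)
#' it$flag
#' @export
iterate_seasons <- function(state, p, n_max = NULL, dense = FALSE, nt = 201,
                            control = cr_control()) {
  stopifnot(inherits(p, "cr_params"))
  if (is.null(n_max)) n_max <- control$n_max
  n_max <- as.integer(n_max)
  stopifnot(n_max >= 1L)

  rows <- matrix(NA_real_, nrow = n_max, ncol = 12)
  trajs <- if (dense) vector("list", n_max) else NULL
  x <- c(R = state[[1]], J = state[[2]], A = state[[3]], B = state[[4]])
  flag <- "max_iter"
  run <- 0L
  n_done <- 0L

  for (n in seq_len(n_max)) {
    res <- integrate_season(x, p, dense = dense, nt = nt, control = control)
    e <- res$end_state
    rows[n, ] <- c(n, x[1:4], e[1:4], res$averages)
    if (dense) trajs[[n]] <- dplyr::mutate(res$trajectory, season = n,
                                           time = n - 1 + t, .before = 1)
    x_new <- reproduction_pulse(e)
    n_done <- n
    if (sum(x_new[2:4]) < control$ext_tol) {
      x <- x_new
      flag <- "extinct"
      break
    }
    run <- if (max(abs(x_new - x)) < control$tol_fix) run + 1L else 0L
    x <- x_new
    if (run >= control$conv_run) {
      flag <- "converged"
      break
    }
  }

  seasons <- tibble::as_tibble(as.data.frame(rows[seq_len(n_done), ,
                                                  drop = FALSE]))
  names(seasons) <- c("season", "R_start", "J_start", "A_start", "B_start",
                      "R_end", "J_end", "A_end", "B_end",
                      "Jbar", "Abar", "Bbar")
  seasons$season <- as.integer(seasons$season)
  traj <- if (dense) dplyr::bind_rows(trajs[seq_len(n_done)]) else NULL
  structure(list(seasons = seasons, flag = flag, final_state = x,
                 trajectory = traj, params = p),
            class = "season_iteration")
}

#' @export
print.season_iteration <- function(x, ...) {
  cat("<season_iteration> ", nrow(x$seasons), " season(s), flag = ",
      x$flag, "\n", sep = "")
  cat("  final post-pulse state: ",
      paste(sprintf("%s = %.6g", names(x$final_state), x$final_state),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
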