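#' Model parameters for the pulsed consumer-resource model
#'
#' Bundles and validates the eight constants of the biomass model: a
#' semi-chemostat resource, juvenile and adult consumer stages with
#' mass-specific intake, maintenance and background mortality, and a
#' newborn:adult body-size ratio entering the maturation rate.  Defaults are
#' the standard parameterisation of the model; `theta` (adult:juvenile
#' intake ratio) and `mu` (background mortality) are the two parameters that
#' analyses typically vary, so they must be given explicitly.
#'
#' @param theta Adult:juvenile mass-specific intake ratio (dimensionless,
#'   positive).  `theta > 1` means adults out-compete juveniles for the
#'   resource.
#' @param mu Stage-independent background mortality rate (per unit time,
#'   non-negative).
#' @param rho Resource turn-over rate (per unit time).
#' @param Kr Maximum resource density (gram/L).
#' @param Imax Mass-specific attack rate of juveniles (per unit time);
#'   adults attack at `theta * Imax`.
#' @param Q Mass-specific maintenance rate (per unit time).
#' @param sigma Conversion efficiency of ingested resource into consumer
#'   biomass (dimensionless, in (0, 1]).
#' @param z Newborn:adult body-size ratio (dimensionless, in (0, 1)).
#'
#' @return An object of class `cr_params`: a named list with the eight
#'   components above.
#' @examples
#' p <- cr_params(theta = 2, mu = 9)
#' p$Kr
#' @export
cr_params <- function(theta, mu, rho = 10, Kr = 2, Imax = 100, Q = 10,
                      sigma = 0.5, z = 0.1) {
  p <- list(rho = rho, Kr = Kr, theta = theta, Imax = Imax, Q = Q,
            sigma = sigma, mu = mu, z = z)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter `", nm, "` must be a single finite number", call. = FALSE)
  }
  if (any(c(rho, Kr, theta, Q) <= 0))
    stop("rho, Kr, theta and Q must be strictly positive", call. = FALSE)
  if (Imax < 0)
    stop("Imax must be non-negative", call. = FALSE)
  if (sigma <= 0 || sigma > 1)
    stop("sigma must lie in (0, 1]", call. = FALSE)
  if (z <= 0 || z >= 1)
    stop("z must lie in (0, 1)", call. = FALSE)
  if (mu < 0)
    stop("mu must be non-negative", call. = FALSE)
  structure(p, class = "cr_params")
}

#' @export
print.cr_params <- function(x, ...) {
  cat("<cr_params>\n")
  cat(sprintf("  theta = %g, mu = %g\n", x$theta, x$mu))
  cat(sprintf("  rho = %g, Kr = %g, Imax = %g, Q = %g, sigma = %g, z = %g\n",
              x$rho, x$Kr, x$Imax, x$Q, x$sigma, x$z))
  invisible(x)
}

# parameter vector in the order the compiled derivative field expects
parm_vector <- function(p) {
  stopifnot(inherits(p, "cr_params"))
  c(p$rho, p$Kr, p$theta, p$Imax, p$Q, p$sigma, p$mu, p$z)
}

#' Modify one or more parameters
#'
#' Convenience wrapper returning a revalidated copy of `p` with the named
#' components replaced; useful inside parameter sweeps.
#'
#' @param p A [cr_params()] object.
#' @param ... Named scalar replacements, e.g. `mu = 3`.
#' @return A new `cr_params` object.
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "cr_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(p))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  q <- unclass(p)
  q[names(repl)] <- repl
  do.call(cr_params, q[c("theta", "mu", "rho", "Kr", "Imax", "Q", "sigma", "z")])
}

#' Numerical control settings for season-map computations
#'
#' @param rtol,atol Relative and absolute integration tolerances for the
#'   within-season ODE solve.  The field is continuous but non-smooth at the
#'   starvation and maturation switch points, so tolerances are tight by
#'   default.
#' @param method deSolve integration method (stiff-capable by default).
#' @param n_max Maximum number of iterated seasons.
#' @param tol_fix Max-norm tolerance on successive post-pulse states for
#'   declaring convergence of forward iteration (must hold over `conv_run`
#'   consecutive seasons) and target residual of the Newton polish.
#' @param ext_tol Total consumer biomass below which the population is
#'   declared extinct.
#' @param conv_run Number of consecutive seasons the `tol_fix` criterion
#'   must hold.
#' @param tol_eig Half-width of the band around multiplier modulus 1 that is
#'   classified as `"marginal"` rather than stable/unstable.
#' @return A list of class `cr_control`.
#' @export
cr_control <- function(rtol = 1e-10, atol = 1e-12, method = "lsoda",
                       n_max = 5000L, tol_fix = 1e-9, ext_tol = 1e-10,
                       conv_run = 10L, tol_eig = 1e-6) {
  structure(list(rtol = rtol, atol = atol, method = method,
                 n_max = as.integer(n_max), tol_fix = tol_fix,
                 ext_tol = ext_tol, conv_run = as.integer(conv_run),
                 tol_eig = tol_eig),
            class = "cr_control")
}
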