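#' Within-season rate functions
#'
#' Pure vectorised evaluations of the model's rate functions: semi-chemostat
#' resource turn-over, stage-specific net biomass production, its
#' non-negative part (growth/storage halts under starvation), the
#' resource-dependent maturation rate and the total per-capita mortality
#' rates.  These are the building blocks of [season_derivatives()] and are
#' exported mainly for inspection, plotting and testing.
#'
#' @param R Resource density (gram/L), non-negative; vectorised.
#' @param p A [cr_params()] object.
#' @param stage `"juvenile"` or `"adult"`.
#' @return A numeric vector of rates.
#' @name rates
NULL

#' @describeIn rates Resource turn-over `rho * (Kr - R)`.
#' @export
resource_turnover <- function(R, p) {
  stopifnot(inherits(p, "cr_params"))
  if (any(!is.finite(R)) || any(R < 0))
    stop("R must be finite and non-negative", call. = FALSE)
  p$rho * (p$Kr - R)
}

#' @describeIn rates Mass-specific net biomass production
#'   `sigma * I * R - Q` with intake `I = Imax` (juveniles) or
#'   `theta * Imax` (adults); negative values indicate starvation.
#' @export
net_production <- function(R, p, stage = c("juvenile", "adult")) {
  stopifnot(inherits(p, "cr_params"))
  stage <- match.arg(stage)
  if (any(!is.finite(R)) || any(R < 0))
    stop("R must be finite and non-negative", call. = FALSE)
  intake <- if (stage == "adult") p$theta * p$Imax else p$Imax
  p$sigma * intake * R - p$Q
}

#' @describeIn rates Non-negative part `max(nu, 0)` of a net production
#'   rate: somatic growth of juveniles / storage accumulation of adults
#'   ceases while the stage starves.
#' @param nu A net production rate (may be negative).
#' @export
clip_production <- function(nu) {
  pmax(nu, 0)
}

#' Resource-dependent maturation rate
#'
#' Per-capita rate at which juvenile biomass recruits to the adult stage,
#' \deqn{\gamma(\nu_j, \mu) = \frac{\nu_j - \mu}{1 - z^{1 - \mu/\nu_j}}}
#' for positive net juvenile production \eqn{\nu_j}, and 0 otherwise
#' (juveniles can only grow and mature while their net production is
#' positive).  The expression has a removable singularity at
#' \eqn{\nu_j = \mu}, where the rate equals its limit
#' \eqn{-\nu_j / \log z}.  Numerically, the exponent is computed as
#' \eqn{(\nu_j - \mu)/\nu_j} (exact for nearby arguments) and the
#' denominator through `expm1()`; within a narrow guard band around the
#' singularity the limit is used with its first-order correction, so both
#' branches agree to near machine precision at the hand-over.
#'
#' This functional form makes the two-stage biomass model a consistent
#' approximation to a fully size-structured model: the expected lifetime
#' biomass contribution of a juvenile to the adult stage is preserved, with
#' higher mortality discounting survival to maturation.
#'
#' @param nu_j Net juvenile production rate(s) (per unit time); vectorised.
#' @param mu Background mortality rate (scalar, >= 0).
#' @param z Newborn:adult body-size ratio (scalar, in (0, 1)).
#' @return Non-negative maturation rate(s), continuous in `nu_j`.
#' @examples
#' maturation_rate(90, mu = 8, z = 0.1)
#' maturation_rate(8, mu = 8, z = 0.1)  # the singular limit -8/log(0.1)
#' @export
maturation_rate <- function(nu_j, mu, z) {
  if (!is.numeric(z) || length(z) != 1L || z <= 0 || z >= 1)
    stop("z must be a single number in (0, 1)", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0)
    stop("mu must be a single non-negative number", call. = FALSE)
  lz <- log(z)
  out <- numeric(length(nu_j))
  pos <- nu_j > 0
  near <- pos & abs(nu_j - mu) <= 1e-8 * mu
  reg <- pos & !near
  u <- (nu_j - mu) / nu_j
  out[near] <- -nu_j[near] / lz * (1 - 0.5 * u[near] * lz)
  out[reg] <- -(nu_j[reg] - mu) / expm1(u[reg] * lz)
  out
}

# derivative of maturation_rate with respect to nu_j (nu_j > 0), used by the
# variational-equation Jacobian
dmaturation_dnu <- function(nu_j, mu, z) {
  lz <- log(z)
  out <- numeric(length(nu_j))
  pos <- nu_j > 0
  near <- pos & abs(nu_j - mu) <= 1e-6 * max(mu, 1)
  reg <- pos & !near
  out[near] <- -1 / lz + 0.5
  if (any(reg)) {
    nu <- nu_j[reg]
    u <- 1 - mu / nu
    D <- -expm1(u * lz)             # 1 - z^u
    dD <- -(1 - D) * lz * mu / nu^2 # d/dnu (1 - z^u)
    out[reg] <- (D - (nu - mu) * dD) / D^2
  }
  out
}

#' @describeIn rates Total per-capita mortality rate
#'   `mu + max(0, -nu)`: background mortality plus a starvation surcharge
#'   equal to the negative part of net production, so that biomass is
#'   conserved while maintenance exceeds assimilation.
#' @export
stage_mortality <- function(R, p, stage = c("juvenile", "adult")) {
  stage <- match.arg(stage)
  nu <- net_production(R, p, stage)
  p$mu + pmax(0, -nu)
}

#' Within-season derivative field
#'
#' Derivatives of the full within-season state: resource `R`, juvenile
#' biomass `J`, adult biomass `A`, reproductive energy storage `B`, and the
#' three season-average accumulators `Jbar`, `Abar`, `Bbar` (whose
#' derivatives are simply `J`, `A`, `B`, so that their value at the end of
#' the unit season equals the season-average biomass).  The field is
#' continuous in the state: both the maturation rate and the starvation
#' surcharge vanish continuously at their switch points.
#'
#' @param state Named or positional numeric vector `(R, J, A, B)`;
#'   accumulators are appended internally.
#' @param p A [cr_params()] object.
#' @return Named numeric vector of the seven derivatives
#'   `(R, J, A, B, Jbar, Abar, Bbar)`.
#' @examples
#' p <- cr_params(theta = 1, mu = 8)
#' season_derivatives(c(R = 2, J = 1, A = 0.5, B = 0), p)
#' @export
season_derivatives <- function(state, p) {
  stopifnot(inherits(p, "cr_params"))
  if (length(state) < 4L || any(!is.finite(state[1:4])))
    stop("state must contain four finite components (R, J, A, B)",
         call. = FALSE)
  R <- state[[1]]; J <- state[[2]]; A <- state[[3]]; B <- state[[4]]
  nuj <- p$sigma * p$Imax * R - p$Q
  nua <- p$sigma * p$theta * p$Imax * R - p$Q
  gam <- maturation_rate(nuj, p$mu, p$z)
  dj <- p$mu + max(0, -nuj)
  da <- p$mu + max(0, -nua)
  c(R = p$rho * (p$Kr - R) - p$Imax * R * (J + p$theta * A),
    J = max(nuj, 0) * J - gam * J - dj * J,
    A = gam * J - da * A,
    B = max(nua, 0) * A - da * B,
    Jbar = J, Abar = A, Bbar = B)
}

# Jacobian of the 4-state field (R, J, A, B) at a point; analytic, used to
# transport the variational equations for the season-map Jacobian.
field_jacobian <- function(state, p) {
  R <- state[[1]]; J <- state[[2]]; A <- state[[3]]; B <- state[[4]]
  dnuj <- p$sigma * p$Imax
  dnua <- p$sigma * p$theta * p$Imax
  nuj <- dnuj * R - p$Q
  nua <- dnua * R - p$Q
  gam <- maturation_rate(nuj, p$mu, p$z)
  dgam <- dmaturation_dnu(nuj, p$mu, p$z)
  da <- p$mu + max(0, -nua)
  ddj_dR <- if (nuj < 0) -dnuj else 0
  dda_dR <- if (nua < 0) -dnua else 0
  jac <- matrix(0, 4, 4)
  jac[1, 1] <- -p$rho - p$Imax * (J + p$theta * A)
  jac[1, 2] <- -p$Imax * R
  jac[1, 3] <- -p$theta * p$Imax * R
  jac[2, 1] <- ((if (nuj > 0) dnuj else 0) - dgam * dnuj - ddj_dR) * J
  jac[2, 2] <- max(nuj, 0) - gam - (p$mu + max(0, -nuj))
  jac[3, 1] <- dgam * dnuj * J - dda_dR * A
  jac[3, 2] <- gam
  jac[3, 3] <- -da
  jac[4, 1] <- (if (nua > 0) dnua else 0) * A - dda_dR * B
  jac[4, 3] <- max(nua, 0)
  jac[4, 4] <- -da
  jac
}
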