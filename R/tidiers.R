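#' Tidy an equilibrium of the season map
#'
#' @param x A `cr_equilibrium` from [find_attractor()] or
#'   [solve_fixed_point()].
#' @param ... Unused.
#' @return A one-row tibble with the parameters that were varied, the
#'   post-pulse state, the season averages and the stability class.
#' @export
tidy.cr_equilibrium <- function(x, ...) {
  tibble::tibble(theta = x$params$theta, mu = x$params$mu,
                 R = x$state[["R"]], J = x$state[["J"]], A = x$state[["A"]],
                 Jbar = x$averages[["Jbar"]], Abar = x$averages[["Abar"]],
                 Bbar = x$averages[["Bbar"]],
                 stability = x$stability,
                 max_multiplier = max(x$multipliers))
}

#' One-line summary of an equilibrium
#'
#' @inheritParams tidy.cr_equilibrium
#' @return A one-row tibble: stability class, multiplier moduli, residual
#'   of the fixed-point condition and total consumer biomass.
#' @export
glance.cr_equilibrium <- function(x, ...) {
  tibble::tibble(stability = x$stability,
                 max_multiplier = max(x$multipliers),
                 residual = x$residual,
                 consumer_biomass = sum(x$state[2:4]))
}

#' Tidy a season iteration
#'
#' @param x A `season_iteration` from [iterate_seasons()].
#' @param ... Unused.
#' @return The per-season tibble (start state, end state, averages) with
#'   the termination flag attached on the last row's attribute-free
#'   `flag` column.
#' @export
tidy.season_iteration <- function(x, ...) {
  dplyr::mutate(x$seasons, flag = ifelse(.data$season == max(.data$season),
                                         x$flag, NA_character_))
}
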