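#' Plot methods
#'
#' `autoplot()` methods turning the package's result tibbles into the
#' standard diagnostic figures: multi-season time series, one-parameter
#' bifurcation diagrams of season-average biomass, two-parameter
#' persistence/invasion boundary diagrams, expected-reproductive-output
#' curves and unit-cohort trajectories.
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name pulsecr-plots
NULL

#' @rdname pulsecr-plots
#' @export
autoplot.season_iteration <- function(object, ...) {
  if (!is.null(object$trajectory)) {
    df <- tidyr::pivot_longer(object$trajectory,
                              cols = c("J", "A"),
                              names_to = "stage", values_to = "biomass")
    ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$biomass,
                                     colour = .data$stage)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (seasons)", y = "biomass density",
                    colour = NULL)
  } else {
    df <- tidyr::pivot_longer(object$seasons,
                              cols = c("J_start", "A_start"),
                              names_to = "stage", values_to = "biomass")
    ggplot2::ggplot(df, ggplot2::aes(.data$season, .data$biomass,
                                     colour = .data$stage)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "season", y = "post-pulse biomass", colour = NULL)
  }
}

#' @rdname pulsecr-plots
#' @export
autoplot.cr_branches <- function(object, ...) {
  df <- tidyr::pivot_longer(object, cols = c("Jbar", "Abar", "Bbar"),
                            names_to = "component", values_to = "biomass")
  ggplot2::ggplot(df, ggplot2::aes(.data$mu, .data$biomass,
                                   colour = .data$component,
                                   linetype = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(mu), y = "season-average biomass",
                  colour = NULL, linetype = NULL)
}

#' @rdname pulsecr-plots
#' @export
autoplot.cr_boundaries <- function(object, ...) {
  df <- tidyr::pivot_longer(object, cols = c("mu_persist", "mu_invade"),
                            names_to = "boundary", values_to = "mu")
  ggplot2::ggplot(df, ggplot2::aes(.data$theta, .data$mu,
                                   linetype = .data$boundary)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(theta), y = expression(mu),
                  linetype = NULL)
}

#' @rdname pulsecr-plots
#' @export
autoplot.r0_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$tm)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$r0, colour = "R0")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative,
                                    colour = "cumulative")) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = expression(t[m]), y = "expected reproductive output",
                  colour = NULL)
}

#' @rdname pulsecr-plots
#' @export
autoplot.cohort_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(object, cols = c("J", "A", "B"),
                            names_to = "component", values_to = "biomass")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$biomass,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time within season", y = "cohort biomass",
                  colour = NULL)
}
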