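#' Plot a free-energy profile
#'
#' Line plot of the Hopfion free energy against the toroidal winding `P`,
#' with the refined minimum marked.
#'
#' @param object An [energy_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot energy_profile
#' @export
autoplot.energy_profile <- function(object, ...) {
  grid <- object$grid
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$p, y = .data$f)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::annotate("point", x = object$p_min, y = object$f_min,
                      colour = "#d95f02", size = 2) +
    ggplot2::labs(
      x = "toroidal winding P",
      y = expression(F ~ (k[B] * T ~ "per unit arc length")),
      title = sprintf("W = %g, R = %g°, m = %g, n = %g",
                      object$params$w, object$params$r_deg,
                      object$params$m, object$params$n),
      subtitle = sprintf("minimum %.1f at P = %.3f", object$f_min, object$p_min)
    ) +
    ggplot2::theme_minimal()
}

#' Plot integer-factorization energies
#'
#' Bar chart of the free energy at each integer `(P, Q)` factorization of
#' the Hopf charge, the discrete counterpart of the continuous profile.
#'
#' @param object An [integer_minimum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot integer_minimum
#' @export
autoplot.integer_minimum <- function(object, ...) {
  cand <- object$candidates
  cand$best <- cand$p == object$p_best
  ggplot2::ggplot(cand, ggplot2::aes(x = factor(.data$p), y = .data$f,
                                     fill = .data$best)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d95f02", `FALSE` = "#2c7fb8")) +
    ggplot2::labs(
      x = "toroidal winding P (integer factorizations)",
      y = expression(F ~ (k[B] * T ~ "per unit arc length")),
      title = sprintf("W = %g, R = %g°", object$params$w, object$params$r_deg)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the effective B-Z transition potential
#'
#' Curve of the tilted double-well potential with its stationary points
#' marked.
#'
#' @param object A [veff_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot veff_profile
#' @export
autoplot.veff_profile <- function(object, ...) {
  params <- attr(object, "params")
  st <- veff_stationary_points(params)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rho, y = .data$veff)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(data = st,
                        ggplot2::aes(shape = .data$type), size = 2,
                        colour = "#d95f02") +
    ggplot2::labs(
      x = expression(rho ~ "(rad/bp)"),
      y = expression(V[eff] ~ "(J)"),
      shape = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
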