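#' Plot an operating-characteristics result
#'
#' Dot plot of the per-stratum rejection rates, colored by whether the
#' stratum is truly active (power) or inactive (type-I error rate), with
#' Monte Carlo error bars when the result was simulated.
#'
#' @param object An `oc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oc_result <- function(object, ...) {
  dat <- tidy(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$stratum),
                                         y = .data$rejection_rate,
                                         colour = .data$active)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "stratum", y = "rejection rate",
                  colour = "truly active",
                  title = sprintf("ewp = %.3f, fwer = %.3f, ecd = %.2f",
                                  object$ewp, object$fwer, object$ecd)) +
    ggplot2::ylim(0, 1)
  if (!all(is.na(dat$mcse))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$rejection_rate - 2 * .data$mcse, 0),
                   ymax = pmin(.data$rejection_rate + 2 * .data$mcse, 1)),
      width = 0.2)
  }
  p
}

#' Plot an optimizer trajectory
#'
#' Best-so-far utility value against the evaluation index.
#'
#' @param object An `opt_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.opt_result <- function(object, ...) {
  dat <- object$trajectory
  dat$best_so_far <- cummax(ifelse(is.finite(dat$value), dat$value, -Inf))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$eval, y = .data$best_so_far)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "function evaluation", y = "best utility so far",
                  title = object$algorithm)
}

#' Two-stratum borrowing inflation curves
#'
#' Plots the type-I error rate of the inactive basket against the other
#' basket's true response rate, one line per (epsilon, tau) combination,
#' from the `toer_curves` table of [run_extras()].
#'
#' @param curves Tibble with columns `p2`, `epsilon`, `tau`,
#'   `toer_basket1`.
#' @return A ggplot object.
#' @export
plot_toer_curves <- function(curves) {
  curves$setting <- sprintf("eps = %g, tau = %g", curves$epsilon, curves$tau)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$p2, y = .data$toer_basket1,
                                       colour = .data$setting)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "true response rate of basket 2",
                  y = "type-I error rate of basket 1",
                  colour = NULL)
}

#' Extreme borrowing boundary curve
#'
#' Plots \eqn{\epsilon_{extreme}(\tau)} over a grid of cutoffs for one
#' layout: the frontier above which the similarity weights collapse to
#' the equal-responses indicator.
#'
#' @param layout A [basket_layout()].
#' @param taus Cutoff grid strictly inside (0, 1).
#' @param divergence `"jsd"` or `"hellinger"`.
#' @return A ggplot object.
#' @export
plot_extreme_boundary <- function(layout, taus = seq(0.05, 0.95, by = 0.05),
                                  divergence = "jsd") {
  eps <- vapply(taus, function(t)
    extreme_borrowing_boundary(layout, t, divergence), 0)
  dat <- tibble::tibble(tau = taus, epsilon_extreme = eps)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$tau, y = .data$epsilon_extreme)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "similarity cutoff tau",
                  y = "extreme borrowing boundary epsilon")
}
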