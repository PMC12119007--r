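#' Describe the structure of a basket trial
#'
#' A basket trial tests one therapy in `n_strata` parallel strata (baskets)
#' of a single-arm phase II study, each stratum recruiting `sample_sizes[i]`
#' patients with a binary response endpoint. Each stratum carries a beta
#' prior on its response rate and a target rate `target_rates[i]` against
#' which activity is judged.
#'
#' @param sample_sizes Integer vector of per-stratum sample sizes \eqn{n_i}
#'   (length gives the stratum count \eqn{I \ge 1}).
#' @param target_rates Numeric vector of target response rates
#'   \eqn{p^*_i \in (0,1)}; recycled to length \eqn{I} if scalar.
#' @param prior_shape1,prior_shape2 Beta prior shapes \eqn{a_i, b_i > 0};
#'   recycled to length \eqn{I}. Default is the uniform Beta(1, 1) prior.
#'
#' @return An object of class `basket_layout`: a list with elements
#'   `n_strata`, `sample_sizes`, `target_rates`, `prior_shape1`,
#'   `prior_shape2`.
#' @examples
#' basket_layout(sample_sizes = rep(24, 3), target_rates = 0.2)
#' @export
basket_layout <- function(sample_sizes, target_rates,
                          prior_shape1 = 1, prior_shape2 = 1) {
  n_strata <- length(sample_sizes)
  stopifnot(n_strata >= 1, all(sample_sizes >= 1),
            sample_sizes == as.integer(sample_sizes))
  rec <- function(x) {
    if (length(x) == 1L) x <- rep(x, n_strata)
    stopifnot(length(x) == n_strata)
    x
  }
  target_rates <- rec(target_rates)
  prior_shape1 <- rec(prior_shape1)
  prior_shape2 <- rec(prior_shape2)
  stopifnot(all(target_rates > 0 & target_rates < 1),
            all(prior_shape1 > 0), all(prior_shape2 > 0))
  structure(
    list(n_strata = n_strata,
         sample_sizes = as.integer(sample_sizes),
         target_rates = as.numeric(target_rates),
         prior_shape1 = as.numeric(prior_shape1),
         prior_shape2 = as.numeric(prior_shape2)),
    class = "basket_layout"
  )
}

#' @export
print.basket_layout <- function(x, ...) {
  cat("<basket_layout> I =", x$n_strata,
      "| n =", paste(x$sample_sizes, collapse = ", "),
      "| p* =", paste(format(x$target_rates), collapse = ", "), "\n")
  invisible(x)
}

#' Tuning parameters of the borrowing design
#'
#' The borrowing design is governed by the vector
#' \eqn{\phi = (\lambda, \epsilon, \tau)}: the posterior-probability
#' detection threshold \eqn{\lambda \in [0,1]}, the similarity-weight shape
#' exponent \eqn{\epsilon \ge 0}, and the similarity cutoff
#' \eqn{\tau \in [0,1]} below which no borrowing takes place.
#'
#' @param lambda Detection threshold in \[0, 1\].
#' @param epsilon Weight shape exponent, nonnegative.
#' @param tau Similarity cutoff in \[0, 1\].
#' @return A named numeric vector of class `tuning_params`.
#' @examples
#' tuning_params(0.99, 2, 0)  # a commonly suggested setting
#' @export
tuning_params <- function(lambda, epsilon, tau) {
  stopifnot(length(lambda) == 1, length(epsilon) == 1, length(tau) == 1,
            lambda >= 0, lambda <= 1, epsilon >= 0, tau >= 0, tau <= 1)
  structure(c(lambda = as.numeric(lambda), epsilon = as.numeric(epsilon),
              tau = as.numeric(tau)),
            class = "tuning_params")
}

#' @export
print.tuning_params <- function(x, ...) {
  cat(sprintf("<tuning_params> lambda = %g, epsilon = %g, tau = %g\n",
              x[["lambda"]], x[["epsilon"]], x[["tau"]]))
  invisible(x)
}

# Coerce a bare length-3 numeric to tuning_params, validating bounds.
as_tuning <- function(phi) {
  if (inherits(phi, "tuning_params")) return(phi)
  stopifnot(is.numeric(phi), length(phi) == 3)
  tuning_params(phi[[1]], phi[[2]], phi[[3]])
}

validate_outcome <- function(layout, responses) {
  stopifnot(length(responses) == layout$n_strata,
            all(responses >= 0), all(responses <= layout$sample_sizes),
            responses == as.integer(responses))
  as.integer(responses)
}

#' Posterior shape parameters for one stratum without borrowing
#'
#' Beta-binomial conjugacy: with prior Beta(\eqn{a_i, b_i}) and \eqn{r_i}
#' responders among \eqn{n_i} patients, the stratum-wise posterior is
#' Beta(\eqn{a_i + r_i}, \eqn{b_i + n_i - r_i}).
#'
#' @param layout A [basket_layout()].
#' @param responses Integer vector of responder counts \eqn{r_i}, length
#'   `layout$n_strata`.
#' @param stratum Stratum index.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @examples
#' lay <- basket_layout(rep(24, 3), 0.2)
#' posterior_params(lay, c(10, 5, 12), 1)  # Beta(11, 15)
#' @export
posterior_params <- function(layout, responses, stratum) {
  responses <- validate_outcome(layout, responses)
  stopifnot(stratum >= 1, stratum <= layout$n_strata)
  i <- as.integer(stratum)
  c(shape1 = layout$prior_shape1[i] + responses[i],
    shape2 = layout$prior_shape2[i] + layout$sample_sizes[i] - responses[i])
}
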