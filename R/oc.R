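# Vectorized decision engine.
#
# `outcomes` is an N x I integer matrix of responder counts, one row per
# outcome vector. Returns the N x I logical matrix of detections under the
# borrowing design. All pairwise raw similarities come from the memoized
# tables, so the per-row cost is table lookups plus one pbeta per stratum.
decision_matrix <- function(layout, outcomes, phi, divergence = "jsd") {
  phi <- as_tuning(phi)
  I <- layout$n_strata
  eps <- phi[["epsilon"]]
  tau <- phi[["tau"]]
  lambda <- phi[["lambda"]]
  a <- layout$prior_shape1
  b <- layout$prior_shape2
  n <- layout$sample_sizes
  tabs <- if (I > 1) pairwise_tables(layout, divergence) else NULL
  shape1 <- sweep(outcomes, 2, a, "+")            # a_j + r_j
  shape2 <- sweep(-outcomes, 2, b + n, "+")       # b_j + n_j - r_j
  A <- shape1
  B <- shape2
  if (I > 1) {
    for (i in seq_len(I)) {
      for (j in seq_len(I)) {
        if (i == j) next
        w <- tabs[[i]][[j]][cbind(outcomes[, i] + 1L, outcomes[, j] + 1L)]
        w <- w^eps
        w[w <= tau] <- 0
        A[, i] <- A[, i] + w * shape1[, j]
        B[, i] <- B[, i] + w * shape2[, j]
      }
    }
  }
  det <- matrix(FALSE, nrow(outcomes), I)
  for (i in seq_len(I)) {
    det[, i] <- pbeta(layout$target_rates[i], A[, i], B[, i],
                      lower.tail = FALSE) >= lambda
  }
  det
}

# All outcome vectors of a layout as a prod(n_i + 1) x I matrix.
enumerate_outcomes <- function(layout) {
  grids <- lapply(layout$sample_sizes, function(n) 0:n)
  as.matrix(do.call(expand.grid, grids))
}

# Product-binomial probability mass of each row of `outcomes` at `rates`.
outcome_mass <- function(layout, outcomes, rates) {
  mass <- rep(1, nrow(outcomes))
  for (i in seq_len(layout$n_strata)) {
    mass <- mass * dbinom(outcomes[, i], layout$sample_sizes[i], rates[i])
  }
  mass
}

# Operating characteristics from a decision matrix and outcome weights
# (probability masses for exact enumeration, 1/n_mc for Monte Carlo).
oc_from_decisions <- function(decisions, mass, active) {
  I <- ncol(decisions)
  inactive <- setdiff(seq_len(I), active)
  rates <- as.numeric(mass %*% decisions)
  any_active <- if (length(active))
    (rowSums(decisions[, active, drop = FALSE]) > 0) else rep(FALSE, nrow(decisions))
  any_inactive <- if (length(inactive))
    (rowSums(decisions[, inactive, drop = FALSE]) > 0) else rep(FALSE, nrow(decisions))
  ewp <- sum(mass * any_active)
  fwer <- sum(mass * any_inactive)
  ecd <- sum(rates[active]) + sum(1 - rates[inactive])
  list(rejection_rates = rates, ewp = ewp, fwer = fwer, ecd = ecd)
}

new_oc_result <- function(meas, method, scenario, phi, divergence,
                          n_mc = NULL, mcse = NULL) {
  structure(
    list(rejection_rates = meas$rejection_rates, ewp = meas$ewp,
         fwer = meas$fwer, ecd = meas$ecd, method = method,
         scenario = scenario, phi = phi, divergence = divergence,
         n_mc = n_mc, mcse = mcse),
    class = "oc_result"
  )
}

#' Exact operating characteristics by full outcome enumeration
#'
#' Iterates over every outcome vector \eqn{r} of the layout, weights it by
#' its product-binomial probability under the scenario's true response
#' rates (frequentist sampling of a Bayesian decision rule, "pragmatic
#' Bayesianism"), applies the borrowing design's test decision, and
#' accumulates: marginal rejection rates per stratum (type-I error rate in
#' inactive strata, power in active ones), experiment-wise power
#' \eqn{P(\exists i \in R\ \mathrm{detected})}, family-wise error rate
#' \eqn{P(\exists i \in R^c\ \mathrm{detected})}, and the expected number
#' of correct decisions. Exact up to the precision of numerical
#' integration inside the similarity weights.
#'
#' @param layout A [basket_layout()].
#' @param scenario A [scenario()] (true response rates plus active set).
#' @param phi A [tuning_params()] vector.
#' @param divergence `"jsd"` or `"hellinger"`.
#' @param enum_limit Refuse enumeration beyond this many outcome vectors
#'   (use [mc_oc()] instead).
#' @return An `oc_result`: rejection rates, `ewp`, `fwer`, `ecd`.
#' @examples
#' lay <- basket_layout(rep(24, 3), 0.2)
#' sc <- scenario(c(0.2, 0.5, 0.5), target_rates = 0.2)
#' exact_oc(lay, sc, tuning_params(0.99, 2, 0))
#' @export
exact_oc <- function(layout, scenario, phi, divergence = "jsd",
                     enum_limit = 3e6) {
  n_out <- prod(layout$sample_sizes + 1)
  if (n_out > enum_limit)
    stop("enumeration over ", n_out, " outcome vectors exceeds enum_limit (",
         enum_limit, "); use mc_oc()", call. = FALSE)
  outcomes <- enumerate_outcomes(layout)
  mass <- outcome_mass(layout, outcomes, scenario$true_rates)
  if (abs(sum(mass) - 1) > 1e-12)
    stop("outcome probability mass does not sum to 1")
  decisions <- decision_matrix(layout, outcomes, phi, divergence)
  meas <- oc_from_decisions(decisions, mass, scenario$active_set)
  new_oc_result(meas, "exact", scenario, as_tuning(phi), divergence)
}

#' Monte Carlo operating characteristics
#'
#' Draws `n_mc` outcome vectors from the scenario's independent binomial
#' sampling distributions, applies the test decision to each, and averages
#' the detection indicators. Monte Carlo standard errors of all rate-type
#' estimates are attached via [mcse_rate()]; the ECD standard error is the
#' empirical standard error of the per-draw correct-decision count.
#' Reproducible given `seed`.
#'
#' @inheritParams exact_oc
#' @param n_mc Number of simulated data sets (default 1000).
#' @param seed Integer seed for the draws.
#' @return An `oc_result` with `method = "monte_carlo"` and `mcse`.
#' @export
mc_oc <- function(layout, scenario, phi, divergence = "jsd",
                  n_mc = 1000, seed = 1) {
  stopifnot(n_mc >= 1)
  set.seed(seed)
  I <- layout$n_strata
  outcomes <- vapply(seq_len(I), function(i)
    rbinom(n_mc, layout$sample_sizes[i], scenario$true_rates[i]),
    integer(n_mc))
  outcomes <- matrix(outcomes, nrow = n_mc)
  decisions <- decision_matrix(layout, outcomes, phi, divergence)
  mass <- rep(1 / n_mc, n_mc)
  meas <- oc_from_decisions(decisions, mass, scenario$active_set)
  active <- scenario$active_set
  inactive <- setdiff(seq_len(I), active)
  correct <- rowSums(decisions[, active, drop = FALSE]) +
    rowSums(!decisions[, inactive, drop = FALSE])
  mcse <- list(
    rejection_rates = vapply(meas$rejection_rates, mcse_rate, 0, n_mc = n_mc),
    ewp = mcse_rate(meas$ewp, n_mc),
    fwer = mcse_rate(meas$fwer, n_mc),
    ecd = stats::sd(correct) / sqrt(n_mc)
  )
  new_oc_result(meas, "monte_carlo", scenario, as_tuning(phi), divergence,
                n_mc = n_mc, mcse = mcse)
}

#' Monte Carlo standard error of a rejection-rate estimate
#'
#' \eqn{\widehat{SD}(\hat r) = \sqrt{\hat r (1 - \hat r) / n_{MC}}}; at most
#' \eqn{\sqrt{0.25 / n_{MC}}} (0.0158 for \eqn{n_{MC} = 1000}).
#'
#' @param rate_hat Estimated rate in \[0, 1\].
#' @param n_mc Number of Monte Carlo data sets.
#' @return The standard error.
#' @export
mcse_rate <- function(rate_hat, n_mc) {
  stopifnot(n_mc >= 1, rate_hat >= 0, rate_hat <= 1)
  sqrt(rate_hat * (1 - rate_hat) / n_mc)
}

#' @export
print.oc_result <- function(x, ...) {
  cat(sprintf("<oc_result> %s%s | ewp = %.4f fwer = %.4f ecd = %.3f\n",
              x$method,
              if (!is.null(x$n_mc)) paste0(" (n_mc = ", x$n_mc, ")") else "",
              x$ewp, x$fwer, x$ecd))
  cat(" rejection rates:", paste(sprintf("%.4f", x$rejection_rates),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Tidy an operating-characteristics result
#'
#' One row per stratum: rejection rate, whether the stratum is truly
#' active (so the rate reads as power or type-I error), and MCSE when the
#' result was simulated.
#'
#' @param x An `oc_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy oc_result
#' @export
tidy.oc_result <- function(x, ...) {
  I <- length(x$rejection_rates)
  tibble::tibble(
    stratum = seq_len(I),
    true_rate = x$scenario$true_rates,
    active = seq_len(I) %in% x$scenario$active_set,
    rejection_rate = x$rejection_rates,
    mcse = if (is.null(x$mcse)) NA_real_ else x$mcse$rejection_rates
  )
}

#' Summarize an operating-characteristics result in one row
#'
#' @param x An `oc_result`.
#' @param ... Unused.
#' @return A one-row tibble with `ewp`, `fwer`, `ecd`, the tuning
#'   parameters and the computation method.
#' @method glance oc_result
#' @export
glance.oc_result <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario$label %||% NA_character_,
    lambda = x$phi[["lambda"]], epsilon = x$phi[["epsilon"]],
    tau = x$phi[["tau"]], divergence = x$divergence,
    method = x$method, n_mc = x$n_mc %||% NA_integer_,
    ewp = x$ewp, fwer = x$fwer, ecd = x$ecd
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
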