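#' Configuration of the utility-function family
#'
#' Penalty and threshold parameters shared by the twelve utility
#' functions: `xi1`, `xi2` are the first- and second-level penalty weights
#' (default 1), `xi3` the harsh penalty on maximal type-I error inflation
#' (default 1000); `eta1` is the family-wise error bound of the
#' discontinuous utilities (default 0.05), `eta2` the threshold above
#' which the second-level penalty kicks in (default 0.1) and `eta3` the
#' maximal tolerated per-stratum type-I error of the penalized
#' scenario-averaged utilities (default 0.2). `weights` are per-scenario
#' averaging weights (default uniform over the scenario set in use).
#'
#' @param xi1,xi2,xi3 Positive penalty parameters.
#' @param eta1,eta2,eta3 Thresholds in \[0, 1\].
#' @param weights Optional per-scenario weights, nonnegative, summing
#'   to 1.
#' @return A `utility_config` list.
#' @export
utility_config <- function(xi1 = 1, xi2 = 1, xi3 = 1000,
                           eta1 = 0.05, eta2 = 0.1, eta3 = 0.2,
                           weights = NULL) {
  stopifnot(xi1 > 0, xi2 > 0, xi3 > 0,
            eta1 >= 0, eta1 <= 1, eta2 >= 0, eta2 <= 1,
            eta3 >= 0, eta3 <= 1)
  if (!is.null(weights)) {
    stopifnot(all(weights >= 0), abs(sum(weights) - 1) < 1e-8)
  }
  structure(list(xi1 = xi1, xi2 = xi2, xi3 = xi3, eta1 = eta1,
                 eta2 = eta2, eta3 = eta3, weights = weights),
            class = "utility_config")
}

set_weights <- function(cfg, n_scen) {
  w <- cfg$weights %||% rep(1 / n_scen, n_scen)
  stopifnot(length(w) == n_scen)
  w
}

# hinge indicator: 1(x) = 1 iff x > 0, so a rate exactly at the threshold
# incurs no second-level penalty
hinge <- function(x) x * (x > 0)

# -- formulae on already-computed operating characteristics ---------------

u_ewp_formula <- function(ewp1, fwer2, cfg) {
  if (fwer2 < cfg$eta1) ewp1 else -cfg$xi1 * fwer2
}

u_ecd_formula <- function(ecd1, fwer2, cfg) {
  if (fwer2 < cfg$eta1) ecd1 else -cfg$xi1 * fwer2
}

u_2ewp_formula <- function(ewp, fwer, cfg) {
  ewp - (cfg$xi1 * fwer + cfg$xi2 * hinge(fwer - cfg$eta2))
}

u_2pow_formula <- function(meas, active, n_strata, cfg) {
  inactive <- setdiff(seq_len(n_strata), active)
  pows <- meas$rejection_rates[active]
  toers <- meas$rejection_rates[inactive]
  sum(pows) - sum(cfg$xi1 * toers + cfg$xi2 * hinge(toers - cfg$eta2))
}

# Operating characteristics via the exact backend when the outcome space
# is enumerable, else Monte Carlo -- mirroring the exact/simulation split
# of the comparison protocol.
oc_auto <- function(layout, scenario, phi, divergence = "jsd",
                    enum_limit = 3e6, n_mc = 1000, seed = 1) {
  if (prod(layout$sample_sizes + 1) <= enum_limit) {
    exact_oc(layout, scenario, phi, divergence, enum_limit)
  } else {
    mc_oc(layout, scenario, phi, divergence, n_mc, seed)
  }
}

#' Single-scenario utility functions
#'
#' The four single-scenario utilities of the framework, all to be
#' maximized over the tuning vector \eqn{\phi}:
#' * `u_ewp()`: discontinuous family-wise power-error function — the
#'   experiment-wise power under `p1` if the family-wise error rate under
#'   `p2` stays strictly below `eta1`, else the penalty
#'   \eqn{-\xi_1 \cdot fwer(p_2)};
#' * `u_ecd()`: as `u_ewp()` with the expected number of correct decisions
#'   in the pass branch;
#' * `u_2ewp()`: two-level family-wise power-error function
#'   \eqn{ewp - (\xi_1 fwer + \xi_2 (fwer - \eta_2)^+)};
#' * `u_2pow()`: its stratum-wise analogue, summing power over active
#'   strata and subtracting the two-level penalty of each inactive
#'   stratum's type-I error rate.
#'
#' `p2` is conventionally the global null scenario.
#'
#' @param layout A [basket_layout()].
#' @param phi A [tuning_params()] vector.
#' @param p1,p2 [scenario()] objects (`p2` typically the global null).
#' @param p A single [scenario()] for the two-level utilities.
#' @param cfg A [utility_config()].
#' @param divergence `"jsd"` or `"hellinger"`.
#' @param ... Passed to the operating-characteristics backend
#'   (`enum_limit`, `n_mc`, `seed`).
#' @return The utility value.
#' @name single_scenario_utilities
NULL

#' @rdname single_scenario_utilities
#' @export
u_ewp <- function(layout, phi, p1, p2, cfg = utility_config(),
                  divergence = "jsd", ...) {
  oc1 <- oc_auto(layout, p1, phi, divergence, ...)
  oc2 <- oc_auto(layout, p2, phi, divergence, ...)
  u_ewp_formula(oc1$ewp, oc2$fwer, cfg)
}

#' @rdname single_scenario_utilities
#' @export
u_ecd <- function(layout, phi, p1, p2, cfg = utility_config(),
                  divergence = "jsd", ...) {
  oc1 <- oc_auto(layout, p1, phi, divergence, ...)
  oc2 <- oc_auto(layout, p2, phi, divergence, ...)
  u_ecd_formula(oc1$ecd, oc2$fwer, cfg)
}

#' @rdname single_scenario_utilities
#' @export
u_2ewp <- function(layout, phi, p, cfg = utility_config(),
                   divergence = "jsd", ...) {
  oc <- oc_auto(layout, p, phi, divergence, ...)
  u_2ewp_formula(oc$ewp, oc$fwer, cfg)
}

#' @rdname single_scenario_utilities
#' @export
u_2pow <- function(layout, phi, p, cfg = utility_config(),
                   divergence = "jsd", ...) {
  oc <- oc_auto(layout, p, phi, divergence, ...)
  u_2pow_formula(oc, p$active_set, layout$n_strata, cfg)
}

# utility value for one family from per-scenario measures
single_family_value <- function(family, meas, scenario, gn_fwer, n_strata,
                                cfg) {
  switch(family,
         ewp = u_ewp_formula(meas$ewp, gn_fwer, cfg),
         ecd = u_ecd_formula(meas$ecd, gn_fwer, cfg),
         "2ewp" = u_2ewp_formula(meas$ewp, meas$fwer, cfg),
         "2pow" = u_2pow_formula(meas, scenario$active_set, n_strata, cfg),
         stop("unknown utility family: ", family))
}

#' Scenario-averaged utility functions
#'
#' `u_averaged()` is the weighted mean \eqn{\sum_p w_p u_l(\phi, p)} of a
#' single-scenario utility over all scenarios of a set; for the `ewp` and
#' `ecd` families the error scenario `p2` is the set's global null.
#' `u_averaged_penalized()` returns the scenario-averaged value as long as
#' the largest type-I error rate over every scenario of the set and every
#' inactive stratum stays strictly below `eta3`, and the harsh penalty
#' \eqn{-\xi_3 \cdot \max toer} otherwise.
#'
#' @param family One of `"ewp"`, `"ecd"`, `"2ewp"`, `"2pow"`.
#' @param phi A [tuning_params()] vector.
#' @param set A [scenario_set()].
#' @param cfg A [utility_config()]; `cfg$weights` (default uniform) must
#'   match the number of scenarios in the set.
#' @param divergence `"jsd"` or `"hellinger"`.
#' @param ... Passed to the operating-characteristics backend.
#' @return The utility value.
#' @export
u_averaged <- function(family, phi, set, cfg = utility_config(),
                       divergence = "jsd", ...) {
  f <- build_utility_objective(family, "averaged", set, cfg, divergence, ...)
  f(phi)
}

#' @rdname u_averaged
#' @export
u_averaged_penalized <- function(family, phi, set, cfg = utility_config(),
                                 divergence = "jsd", ...) {
  f <- build_utility_objective(family, "averaged_penalized", set, cfg,
                               divergence, ...)
  f(phi)
}

#' The registry of the twelve utility functions
#'
#' Four families (`ewp`, `ecd`, `2ewp`, `2pow`) crossed with three modes:
#' single-scenario, scenario-averaged, and scenario-averaged with the
#' maximal-TOER penalty. Names are stable for reporting.
#'
#' @param cfg A [utility_config()].
#' @return A list of 12 `utility_spec` objects (fields `name`, `family`,
#'   `averaging`, `cfg`).
#' @examples
#' length(utility_registry())  # 12
#' @export
utility_registry <- function(cfg = utility_config()) {
  families <- c("ewp", "ecd", "2ewp", "2pow")
  specs <- list()
  for (avg in c("single", "averaged", "averaged_penalized")) {
    for (fam in families) {
      nm <- switch(avg, single = paste0("u_", fam),
                   averaged = paste0("u_avg_", fam),
                   averaged_penalized = paste0("u_avg_pen_", fam))
      specs[[nm]] <- structure(
        list(name = nm, family = fam, averaging = avg, cfg = cfg),
        class = "utility_spec")
    }
  }
  specs
}

# Default single-scenario binding: the "about half active" scenario
# (2 of 3, 2 of 4, 4 of 8, ...).
default_single_scenario <- function(set) {
  I <- set$layout$n_strata
  paste0(ceiling(I / 2), " of ", I, " active")
}

find_scenario <- function(set, label) {
  idx <- which(vapply(set$scenarios, function(s) s$label, "") == label)
  if (!length(idx)) stop("scenario not found in set: ", label)
  idx[1]
}

#' Build a fast objective function for one utility on one scenario set
#'
#' Returns `function(phi) -> value` suitable for the optimizers. Per
#' evaluation, the borrowing design's decision rule is applied once to
#' the relevant outcome space and reused across all scenarios of the set
#' (exact backend: all outcome vectors with per-scenario binomial masses;
#' Monte Carlo backend: common random numbers — outcome draws fixed per
#' scenario when the objective is built, so repeated evaluations are
#' smooth in phi and reproducible).
#'
#' @inheritParams u_averaged
#' @param averaging `"single"`, `"averaged"` or `"averaged_penalized"`.
#' @param single_scenario Scenario label bound by single-scenario
#'   utilities (default: the "half active" scenario of the set).
#' @param enum_limit Outcome-space bound for the exact backend.
#' @param n_mc,seed Monte Carlo settings when enumeration is infeasible.
#' @return A function mapping a tuning vector to the utility value.
#' @export
build_utility_objective <- function(family, averaging, set,
                                    cfg = utility_config(),
                                    divergence = "jsd",
                                    single_scenario = NULL,
                                    enum_limit = 3e6, n_mc = 1000,
                                    seed = 1) {
  layout <- set$layout
  I <- layout$n_strata
  gn_idx <- find_scenario(set, global_null(set)$label)
  scen_idx <- if (averaging == "single") {
    lab <- single_scenario %||% default_single_scenario(set)
    unique(c(find_scenario(set, lab), gn_idx))
  } else {
    seq_along(set$scenarios)
  }
  scenarios <- set$scenarios[scen_idx]
  gn_pos <- match(gn_idx, scen_idx)
  exact <- prod(layout$sample_sizes + 1) <= enum_limit
  if (exact) {
    outcomes <- enumerate_outcomes(layout)
    masses <- lapply(scenarios, function(s)
      outcome_mass(layout, outcomes, s$true_rates))
  } else {
    # common random numbers: one fixed draw per scenario
    set.seed(seed)
    outcomes <- do.call(rbind, lapply(scenarios, function(s) {
      draws <- vapply(seq_len(I), function(i)
        rbinom(n_mc, layout$sample_sizes[i], s$true_rates[i]),
        integer(n_mc))
      matrix(draws, nrow = n_mc)
    }))
    masses <- lapply(seq_along(scenarios), function(k) {
      m <- numeric(nrow(outcomes))
      m[seq((k - 1) * n_mc + 1, k * n_mc)] <- 1 / n_mc
      m
    })
  }
  w <- if (averaging == "single") NULL else set_weights(cfg, length(scenarios))
  function(phi) {
    decisions <- decision_matrix(layout, outcomes, phi, divergence)
    meas <- lapply(seq_along(scenarios), function(k)
      oc_from_decisions(decisions, masses[[k]], scenarios[[k]]$active_set))
    gn_fwer <- meas[[gn_pos]]$fwer
    if (averaging == "single") {
      p1_pos <- 1L
      return(single_family_value(family, meas[[p1_pos]], scenarios[[p1_pos]],
                                 gn_fwer, I, cfg))
    }
    vals <- vapply(seq_along(scenarios), function(k)
      single_family_value(family, meas[[k]], scenarios[[k]], gn_fwer, I, cfg),
      0)
    avg <- sum(w * vals)
    if (averaging == "averaged") return(avg)
    max_toer <- max(c(0, unlist(lapply(seq_along(scenarios), function(k) {
      meas[[k]]$rejection_rates[scenarios[[k]]$inactive_set]
    }))))
    if (max_toer < cfg$eta3) avg else -cfg$xi3 * max_toer
  }
}
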