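#' A single outcome scenario
#'
#' A scenario fixes the true response rate of every stratum. Strata whose
#' true rate exceeds the target rate are classified active; the rest are
#' inactive. The target rate is the null response rate the design tests
#' against, so "active" means exactly "the null is false in this stratum".
#'
#' @param true_rates Numeric vector of true response rates in (0, 1\].
#' @param target_rates Target rates \eqn{p^*_i}; scalar recycled.
#' @param label Optional scenario label.
#' @return A `scenario` object with `true_rates`, `active_set`,
#'   `inactive_set`, `label`.
#' @examples
#' scenario(c(0.2, 0.5, 0.5), target_rates = 0.2, label = "2 of 3 active")
#' @export
scenario <- function(true_rates, target_rates, label = NULL) {
  I <- length(true_rates)
  if (length(target_rates) == 1L) target_rates <- rep(target_rates, I)
  stopifnot(length(target_rates) == I,
            all(true_rates > 0), all(true_rates <= 1))
  active <- which(true_rates > target_rates)
  structure(
    list(true_rates = as.numeric(true_rates),
         active_set = active,
         inactive_set = setdiff(seq_len(I), active),
         label = label %||% paste0("(", paste(true_rates, collapse = ","), ")")),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s | active: {%s}\n", x$label,
              paste(x$active_set, collapse = ",")))
  invisible(x)
}

#' A pre-specified set of outcome scenarios sharing one layout
#'
#' @param layout A [basket_layout()].
#' @param scenarios List of [scenario()] objects (global null first).
#' @param label Set label.
#' @param p0,p1 The inactive and active response rates the set is built
#'   from.
#' @return A `scenario_set` object.
#' @export
scenario_set <- function(layout, scenarios, label, p0, p1) {
  stopifnot(all(vapply(scenarios, inherits, TRUE, "scenario")),
            all(vapply(scenarios, function(s) length(s$true_rates), 0L) ==
                  layout$n_strata))
  structure(list(layout = layout, scenarios = scenarios, label = label,
                 p0 = p0, p1 = p1),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("<scenario_set> %s | I = %d, n_i = %d, %d scenarios\n",
              x$label, x$layout$n_strata, x$layout$sample_sizes[1],
              length(x$scenarios)))
  invisible(x)
}

# One "a of I active" set: rates (p0,...,p0, p1,...,p1) with a active
# strata at the end, for each a in `actives`. Target rate p* = p0 for
# every stratum, so active strata are exactly those at rate p1 > p0.
stepped_scenario_set <- function(I, p0, p1, n, actives = 0:I,
                                 extra = list(), label = NULL) {
  layout <- basket_layout(rep(n, I), target_rates = p0)
  scen <- lapply(actives, function(a) {
    scenario(c(rep(p0, I - a), rep(p1, a)), target_rates = p0,
             label = paste0(a, " of ", I, " active"))
  })
  scen <- c(scen, lapply(extra, function(e)
    scenario(e$rates, target_rates = p0, label = e$label)))
  label <- label %||% sprintf("I=%d, p0=%.2f, p1=%.2f, n=%d", I, p0, p1, n)
  scenario_set(layout, scen, label, p0, p1)
}

#' Build the seven pre-specified outcome scenario sets
#'
#' The comparison study fixes seven scenario sets spanning 3 to 20 strata,
#' inactive rates 0.01 to 0.20, active rates 0.10 to 0.50 and total sample
#' sizes 72 to 480. Each set contains the "a of I active" scenarios
#' \eqn{p = (p_0, \ldots, p_0, p_1, \ldots, p_1)} (inactive strata first),
#' starting with the global null (a = 0); the four-stratum set with
#' \eqn{n_i = 20} additionally carries the mixed "one in the middle"
#' scenario (0.4, 0.4, 0.3, 0.5) and the "linear" scenario
#' (0.15, 0.25, 0.35, 0.45), ordered after the stepped scenarios. The
#' target rate of every stratum is the set's inactive rate \eqn{p_0}.
#'
#' @return Named list of 7 [scenario_set()] objects, in the pre-specified
#'   table order.
#' @examples
#' sets <- build_all_scenario_sets()
#' vapply(sets, function(s) length(s$scenarios), 0L)
#' @export
build_all_scenario_sets <- function() {
  sets <- list(
    stepped_scenario_set(3, 0.20, 0.50, 24),
    stepped_scenario_set(3, 0.15, 0.30, 53),
    stepped_scenario_set(4, 0.15, 0.40, 20, extra = list(
      list(rates = c(0.4, 0.4, 0.3, 0.5), label = "one in the middle"),
      list(rates = c(0.15, 0.25, 0.35, 0.45), label = "linear"))),
    stepped_scenario_set(4, 0.10, 0.35, 36),
    stepped_scenario_set(8, 0.15, 0.45, 15),
    stepped_scenario_set(9, 0.01, 0.10, 23),
    stepped_scenario_set(20, 0.10, 0.35, 24, actives = seq(0, 20, by = 2))
  )
  names(sets) <- vapply(sets, function(s) s$label, "")
  sets
}

#' Global null scenario of a set
#'
#' The scenario in which every stratum sits at the inactive rate; its
#' active set is empty.
#'
#' @param set A [scenario_set()].
#' @return The `scenario` with zero active strata.
#' @export
global_null <- function(set) {
  stopifnot(inherits(set, "scenario_set"))
  idx <- which(vapply(set$scenarios, function(s) length(s$active_set), 0L) == 0)
  stopifnot(length(idx) >= 1)
  set$scenarios[[idx[1]]]
}

#' Tabulate a scenario set for audit
#'
#' @param x A [scenario_set()].
#' @param ... Unused.
#' @return A tibble with one row per (scenario, stratum): set label,
#'   scenario label, stratum, true rate and active flag.
#' @export
as_tibble.scenario_set <- function(x, ...) {
  purrr::map_dfr(x$scenarios, function(s) {
    tibble::tibble(
      set = x$label, scenario = s$label,
      stratum = seq_along(s$true_rates),
      true_rate = s$true_rates,
      active = seq_along(s$true_rates) %in% s$active_set
    )
  })
}
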