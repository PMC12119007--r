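#' Standard error of a sample standard deviation
#'
#' Unbiased estimator of the standard error of the sample standard
#' deviation of a normal sample,
#' \deqn{\widehat{SD}(s) = s \cdot \frac{\Gamma((n-1)/2)}{\Gamma(n/2)}
#'   \sqrt{\frac{n-1}{2} -
#'   \Big(\frac{\Gamma(n/2)}{\Gamma((n-1)/2)}\Big)^2},}
#' with the gamma-function ratios evaluated in log space. The coefficient
#' multiplying `s` depends only on `n`; at n = 50 it is 0.10127, and it
#' behaves like \eqn{1/\sqrt{2(n-1)}} for large `n`.
#'
#' @param s Sample standard deviation (nonnegative).
#' @param n Sample size, at least 2.
#' @return The standard error estimate.
#' @examples
#' se_of_sd(1, 50)  # 0.10127
#' @export
se_of_sd <- function(s, n) {
  stopifnot(n >= 2, s >= 0)
  log_ratio <- lgamma((n - 1) / 2) - lgamma(n / 2)
  s * exp(log_ratio) * sqrt((n - 1) / 2 - exp(-2 * log_ratio))
}

#' Internal reliability of a set of optimizer runs
#'
#' The fraction of runs whose best value lies within `tol` of the best
#' value over all runs — the repeatability statistic used to filter
#' algorithms before comparing them against the grid benchmark.
#'
#' @param results List of `opt_result` objects (at least one).
#' @param tol Tolerance below the per-problem best (default 1e-4).
#' @return A fraction in \[0, 1\].
#' @export
internal_reliability <- function(results, tol = 1e-4) {
  stopifnot(length(results) >= 1)
  vals <- vapply(results, function(r) r$best_value, 0)
  mean(vals >= max(vals) - tol)
}

#' Configuration of the comparison study
#'
#' Bundles the pre-specified constants of the algorithm and utility
#' comparison: number of repeated stochastic runs, evaluation budget,
#' the fixed seeds of the algorithm-comparison and utility-comparison
#' parts, the common start vector for simulated annealing and COBYLA,
#' Monte Carlo size, and the reliability thresholds of the three-stage
#' selection filter.
#'
#' @param n_runs Repeated runs per stochastic algorithm (default 50).
#' @param budget Objective evaluations per run (default 1000).
#' @param seed_part1 Seed of the first algorithm-comparison run
#'   (default 1856); run k uses `seed_part1 + k - 1`.
#' @param seed_part2 Seed of the utility-comparison optimizations
#'   (default 899).
#' @param start Start vector (default (0.2, 0.5, 0): a mostly positive
#'   test decision with borrowing almost always on — deliberately
#'   suboptimal).
#' @param n_mc Monte Carlo size when enumeration is infeasible
#'   (default 1000).
#' @param reliability_threshold,success_threshold Filter thresholds
#'   (default 0.99 each).
#' @param tol Numeric tolerance for reliability and grid comparisons.
#' @param enum_limit Outcome-space bound for the exact backend.
#' @param divergence `"jsd"` or `"hellinger"`.
#' @return A `study_config` list.
#' @export
study_config <- function(n_runs = 50, budget = 1000, seed_part1 = 1856,
                         seed_part2 = 899, start = c(0.2, 0.5, 0),
                         n_mc = 1000, reliability_threshold = 0.99,
                         success_threshold = 0.99, tol = 1e-4,
                         enum_limit = 3e6, divergence = "jsd") {
  stopifnot(n_runs >= 1, budget >= 1,
            reliability_threshold > 0, reliability_threshold < 1,
            success_threshold > 0, success_threshold < 1)
  structure(list(n_runs = n_runs, budget = budget, seed_part1 = seed_part1,
                 seed_part2 = seed_part2, start = start, n_mc = n_mc,
                 reliability_threshold = reliability_threshold,
                 success_threshold = success_threshold, tol = tol,
                 enum_limit = enum_limit, divergence = divergence),
            class = "study_config")
}

ci_normal <- function(x) {
  m <- mean(x)
  half <- qnorm(0.975) * stats::sd(x) / sqrt(length(x))
  c(lower = m - half, upper = m + half)
}

# Summaries of one algorithm's runs on one test problem.
summarize_runs <- function(runs, grid_value, tol) {
  vals <- vapply(runs, function(r) r$best_value, 0)
  phis <- t(vapply(runs, function(r) as.numeric(r$best_phi), numeric(3)))
  colnames(phis) <- c("lambda", "epsilon", "tau")
  evals <- vapply(runs, function(r) r$n_evals, 0L)
  times <- vapply(runs, function(r) r$elapsed, 0)
  diffs <- vals - grid_value
  n <- length(runs)
  sds <- if (n > 1) apply(phis, 2, stats::sd) else c(lambda = 0, epsilon = 0, tau = 0)
  val_sd <- if (n > 1) stats::sd(vals) else 0
  ci_val <- if (n > 1) ci_normal(vals) else c(lower = vals[1], upper = vals[1])
  ci_diff <- if (n > 1) ci_normal(diffs) else c(lower = diffs[1], upper = diffs[1])
  tibble::tibble(
    n_runs = n,
    mean_evals = mean(evals), mean_elapsed = mean(times),
    mean_value = mean(vals), sd_value = val_sd,
    se_sd_value = if (n > 1) se_of_sd(val_sd, n) else NA_real_,
    min_value = min(vals), max_value = max(vals),
    value_ci_lower = ci_val[["lower"]], value_ci_upper = ci_val[["upper"]],
    mean_lambda = mean(phis[, "lambda"]), sd_lambda = sds[["lambda"]],
    mean_epsilon = mean(phis[, "epsilon"]), sd_epsilon = sds[["epsilon"]],
    mean_tau = mean(phis[, "tau"]), sd_tau = sds[["tau"]],
    internal_reliability = internal_reliability(runs, tol),
    success_rate = mean(vals >= grid_value - 1e-9),
    mean_diff_to_grid = mean(diffs),
    diff_ci_lower = ci_diff[["lower"]], diff_ci_upper = ci_diff[["upper"]],
    min_diff = min(diffs), max_diff = max(diffs)
  )
}

#' Part I: compare the eight optimizer configurations
#'
#' Runs the eight algorithm configurations on the two test problems (the
#' scenario-averaged two-level family-wise power-error utility and the
#' scenario-averaged expected-number-of-correct-decisions utility, both
#' over `set`). Stochastic algorithms are repeated `cfg$n_runs` times
#' with seeds `cfg$seed_part1 + run - 1`; COBYLA and grid search run
#' once. Per algorithm and test problem the report carries efficiency
#' (evaluations, wall time), internal consistency (mean/SD/normal 95% CI
#' and range of the best value and of each tuning-parameter component),
#' internal reliability, and external reliability against the grid
#' benchmark (success rate of reaching at least the grid value, CI and
#' range of the difference). The best algorithm is the fastest one whose
#' mean internal reliability and mean success rate both exceed the
#' configured thresholds.
#'
#' @param cfg A [study_config()].
#' @param set Scenario set of the test problems (default: the
#'   four-stratum set with n = 20 from [build_all_scenario_sets()]).
#' @param ucfg A [utility_config()].
#' @return A list with `report` (tibble, one row per algorithm x test
#'   problem), `summary` (per-algorithm means across problems),
#'   `best_algorithm` (name, or `NA` with `none_reliable = TRUE`), and
#'   `runs` (all `opt_result` objects).
#' @export
run_part1 <- function(cfg = study_config(),
                      set = build_all_scenario_sets()[[3]],
                      ucfg = utility_config()) {
  problems <- list(
    u_avg_2ewp = build_utility_objective("2ewp", "averaged", set, ucfg,
                                         cfg$divergence,
                                         enum_limit = cfg$enum_limit,
                                         n_mc = cfg$n_mc,
                                         seed = cfg$seed_part1),
    u_avg_ecd = build_utility_objective("ecd", "averaged", set, ucfg,
                                        cfg$divergence,
                                        enum_limit = cfg$enum_limit,
                                        n_mc = cfg$n_mc,
                                        seed = cfg$seed_part1)
  )
  algs <- algorithm_registry()
  stochastic <- attr(algs, "stochastic")
  all_runs <- list()
  report <- list()
  for (prob_name in names(problems)) {
    objective <- problems[[prob_name]]
    grid_prob <- opt_problem(objective, budget = 1000, seed = cfg$seed_part1,
                             start = cfg$start)
    grid_res <- algs$grid_search(grid_prob)
    grid_value <- grid_res$best_value
    for (alg_name in names(algs)) {
      runs <- if (alg_name == "grid_search") {
        list(grid_res)
      } else if (alg_name %in% stochastic) {
        lapply(seq_len(cfg$n_runs), function(k) {
          algs[[alg_name]](opt_problem(objective, budget = cfg$budget,
                                       seed = cfg$seed_part1 + k - 1,
                                       start = cfg$start))
        })
      } else {
        list(algs[[alg_name]](opt_problem(objective, budget = cfg$budget,
                                          seed = cfg$seed_part1,
                                          start = cfg$start)))
      }
      all_runs[[paste(prob_name, alg_name, sep = ".")]] <- runs
      report[[length(report) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(problem = prob_name, algorithm = alg_name),
        summarize_runs(runs, grid_value, cfg$tol))
    }
  }
  report <- dplyr::bind_rows(report)
  summary <- report |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(
      internal_reliability = mean(.data$internal_reliability),
      success_rate = mean(.data$success_rate),
      mean_elapsed = mean(.data$mean_elapsed),
      mean_value = mean(.data$mean_value),
      .groups = "drop")
  eligible <- summary |>
    dplyr::filter(.data$internal_reliability > cfg$reliability_threshold) |>
    dplyr::filter(.data$success_rate > cfg$success_threshold) |>
    dplyr::arrange(.data$mean_elapsed)
  none <- nrow(eligible) == 0
  list(report = report, summary = summary,
       best_algorithm = if (none) NA_character_ else eligible$algorithm[1],
       none_reliable = none, runs = all_runs)
}

#' Full performance table of one tuning vector on one scenario set
#'
#' Evaluates, for every scenario of the set, the marginal rejection rate
#' of each stratum (type-I error if inactive, power if active), the
#' family-wise error rate, the experiment-wise power and the expected
#' number of correct decisions, using exact enumeration when the outcome
#' space permits and Monte Carlo otherwise.
#'
#' @param set A [scenario_set()].
#' @param phi A [tuning_params()] vector.
#' @param cfg A [study_config()] (backend settings).
#' @param label Optional label column for the emitted table.
#' @return A tibble, one row per (scenario, stratum) with the per-set
#'   measures repeated.
#' @export
performance_table <- function(set, phi, cfg = study_config(),
                              label = NULL) {
  purrr::map_dfr(set$scenarios, function(s) {
    oc <- oc_auto(set$layout, s, phi, cfg$divergence,
                  enum_limit = cfg$enum_limit, n_mc = cfg$n_mc,
                  seed = cfg$seed_part2)
    dplyr::mutate(tidy(oc),
                  set = set$label, scenario = s$label,
                  n_active = length(s$active_set),
                  ewp = oc$ewp, fwer = oc$fwer, ecd = oc$ecd,
                  method = oc$method,
                  lambda = phi[[1]], epsilon = phi[[2]], tau = phi[[3]],
                  label = label %||% NA_character_,
                  .before = 1)
  })
}

#' Part II: optimize the twelve utility functions
#'
#' For each utility in [utility_registry()] and each supplied scenario
#' set, optimizes the tuning vector with the selected algorithm (seeded
#' with `cfg$seed_part2`), then tabulates all performance measures for
#' every scenario of the set at the optimum and cross-evaluates every
#' utility function at every found optimum.
#'
#' @param cfg A [study_config()].
#' @param algorithm Name of the algorithm to use (from
#'   [algorithm_registry()]), typically Part I's selection.
#' @param sets List of [scenario_set()]s (default: the exactly
#'   enumerable three-stratum set).
#' @param ucfg A [utility_config()].
#' @return A list with `optima` (tibble: utility, set, best phi, best
#'   value), `performance` (tibble of all measures at each optimum) and
#'   `cross_utilities` (every utility evaluated at every optimum).
#' @export
run_part2 <- function(cfg = study_config(), algorithm = "grid_search",
                      sets = build_all_scenario_sets()[1],
                      ucfg = utility_config()) {
  algs <- algorithm_registry()
  stopifnot(algorithm %in% names(algs))
  specs <- utility_registry(ucfg)
  optima <- list()
  perf <- list()
  cross <- list()
  for (set in sets) {
    objectives <- lapply(specs, function(sp)
      build_utility_objective(sp$family, sp$averaging, set, ucfg,
                              cfg$divergence, enum_limit = cfg$enum_limit,
                              n_mc = cfg$n_mc, seed = cfg$seed_part2))
    for (nm in names(specs)) {
      prob <- opt_problem(objectives[[nm]], budget = cfg$budget,
                          seed = cfg$seed_part2, start = cfg$start)
      res <- algs[[algorithm]](prob)
      optima[[length(optima) + 1L]] <- tibble::tibble(
        set = set$label, utility = nm,
        lambda = res$best_phi[["lambda"]],
        epsilon = res$best_phi[["epsilon"]],
        tau = res$best_phi[["tau"]],
        best_value = res$best_value, n_evals = res$n_evals,
        algorithm = algorithm)
      phi <- as.numeric(res$best_phi)
      perf[[length(perf) + 1L]] <-
        performance_table(set, phi, cfg, label = nm)
      cross[[length(cross) + 1L]] <- tibble::tibble(
        set = set$label, optimized_for = nm,
        utility = names(specs),
        value = unname(vapply(names(specs), function(other)
          objectives[[other]](phi), 0)))
    }
  }
  list(optima = dplyr::bind_rows(optima),
       performance = dplyr::bind_rows(perf),
       cross_utilities = dplyr::bind_rows(cross))
}

#' Part III: performance of the two heuristic tuning suggestions
#'
#' Tabulates the same performance measures as Part II at the two
#' literature-suggested tuning vectors \eqn{(0.99, 2, 0)} and
#' \eqn{(0.99, 2, 0.5)} for each supplied scenario set.
#'
#' @inheritParams run_part2
#' @return A tibble of performance measures, one block per (set, tuning
#'   vector).
#' @export
run_part3 <- function(cfg = study_config(),
                      sets = build_all_scenario_sets()[1]) {
  vectors <- list(fujikawa_i = c(0.99, 2, 0), fujikawa_ii = c(0.99, 2, 0.5))
  purrr::map_dfr(sets, function(set) {
    purrr::map_dfr(names(vectors), function(nm) {
      performance_table(set, vectors[[nm]], cfg, label = nm)
    })
  })
}

#' Exploratory extras: Hellinger variant and two-stratum borrowing curves
#'
#' Two exploratory views of the borrowing design:
#' (a) matched exact operating characteristics of the Jensen-Shannon and
#' Hellinger similarity variants on a scenario set, with wall time per
#' variant reported; (b) the type-I error rate of an inactive basket
#' (true and target rate `p_star`) in a two-stratum trial, as the second
#' basket's true response rate sweeps `p2_grid`, for a list of
#' (epsilon, tau) combinations — a direct picture of how borrowing
#' inflates the error of a null basket next to an increasingly active
#' neighbour.
#'
#' @param cfg A [study_config()].
#' @param set Scenario set for the divergence comparison.
#' @param phi Tuning vector for the divergence comparison.
#' @param n Two-stratum per-basket sample size for the curves.
#' @param p_star Inactive/target rate of basket 1 (default 0.2).
#' @param p2_grid True rates of basket 2 (default 0.2 to 1 by 0.05).
#' @param eps_tau List of `c(epsilon, tau)` combinations for the curves.
#' @param lambda Detection threshold for the curves.
#' @return A list with `divergence_comparison` (tibble incl. an
#'   `elapsed` column per variant) and `toer_curves` (tibble: p2,
#'   epsilon, tau, toer of basket 1).
#' @export
run_extras <- function(cfg = study_config(),
                       set = build_all_scenario_sets()[[1]],
                       phi = c(0.99, 2, 0),
                       n = 24, p_star = 0.2,
                       p2_grid = seq(0.2, 1, by = 0.05),
                       eps_tau = list(c(2, 0), c(2, 0.5), c(1, 0),
                                      c(5, 0), c(2, 1)),
                       lambda = 0.99) {
  comparison <- purrr::map_dfr(c("jsd", "hellinger"), function(dv) {
    t0 <- proc.time()
    tab <- purrr::map_dfr(set$scenarios, function(s) {
      glance(exact_oc(set$layout, s, phi, divergence = dv,
                      enum_limit = cfg$enum_limit))
    })
    dplyr::mutate(tab, divergence = dv,
                  elapsed = unname((proc.time() - t0)["elapsed"]))
  })
  layout2 <- basket_layout(rep(n, 2), target_rates = p_star)
  curves <- purrr::map_dfr(eps_tau, function(et) {
    purrr::map_dfr(p2_grid, function(p2) {
      sc <- scenario(c(p_star, p2), target_rates = p_star)
      oc <- exact_oc(layout2, sc, c(lambda, et[1], et[2]),
                     divergence = cfg$divergence,
                     enum_limit = cfg$enum_limit)
      tibble::tibble(p2 = p2, epsilon = et[1], tau = et[2],
                     lambda = lambda, toer_basket1 = oc$rejection_rates[1])
    })
  })
  list(divergence_comparison = comparison, toer_curves = curves)
}
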