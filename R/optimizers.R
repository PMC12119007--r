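#' Search space of the tuning parameters
#'
#' The optimization hypercube: \eqn{\lambda \in [0,1]},
#' \eqn{\epsilon \in} \[`eps_lo`, `eps_hi`\] and \eqn{\tau \in [0,1]}. The
#' shape exponent is unbounded in principle, but above the extreme
#' borrowing boundary larger values no longer change the design, so the
#' bounded algorithms search \[0, 25\] by default (the range also covered
#' by the grid).
#'
#' @param eps_lo,eps_hi Bounds of the shape exponent.
#' @return A `search_space` list with `lower` and `upper` length-3
#'   vectors, in (lambda, epsilon, tau) order.
#' @export
search_space <- function(eps_lo = 0, eps_hi = 25) {
  stopifnot(eps_hi > eps_lo, eps_lo >= 0)
  structure(list(lower = c(lambda = 0, epsilon = eps_lo, tau = 0),
                 upper = c(lambda = 1, epsilon = eps_hi, tau = 1)),
            class = "search_space")
}

#' An optimization problem over the tuning parameters
#'
#' @param objective Function mapping a length-3 tuning vector to the
#'   utility value to be maximized.
#' @param space A [search_space()].
#' @param budget Maximum number of objective evaluations (default 1000).
#' @param seed Integer seed used by the stochastic algorithms.
#' @param start Optional start vector for simulated annealing and COBYLA.
#' @return An `opt_problem` list.
#' @export
opt_problem <- function(objective, space = search_space(), budget = 1000,
                        seed = 1, start = NULL) {
  stopifnot(is.function(objective), budget >= 1)
  if (!is.null(start)) {
    start <- as.numeric(start)
    stopifnot(length(start) == 3)
  }
  structure(list(objective = objective, space = space,
                 budget = as.integer(budget), seed = as.integer(seed),
                 start = start),
            class = "opt_problem")
}

in_bounds <- function(x, space) {
  all(x >= space$lower) && all(x <= space$upper)
}

clip <- function(x, space) pmin(pmax(x, space$lower), space$upper)

#' Reflect a coordinate into an interval
#'
#' Folds `x` into \[`lo`, `hi`\] by repeated reflection at the
#' boundaries, computed in closed form as an affine transformation plus
#' division with remainder (period `2 * (hi - lo)`). In-range values are
#' returned unchanged.
#'
#' @param x Numeric (vectorized).
#' @param lo,hi Interval bounds, `hi > lo`.
#' @return Value(s) in \[`lo`, `hi`\].
#' @examples
#' reflect(1.2, 0, 1)   # 0.8
#' reflect(-0.3, 0, 1)  # 0.3
#' @export
reflect <- function(x, lo, hi) {
  stopifnot(hi > lo)
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

# Shared evaluation counter. Every algorithm evaluates the objective only
# through rec$eval(), which enforces the budget, records the trajectory
# and tracks the best point (ties kept at first occurrence).
new_recorder <- function(problem) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$traj <- matrix(NA_real_, problem$budget, 5L)
  env$best_value <- -Inf
  env$best_phi <- NULL
  env$exhausted <- function() env$n >= problem$budget
  env$eval <- function(phi, value = NULL) {
    if (env$exhausted()) stop(budget_exhausted_condition())
    phi <- unname(phi)
    val <- unname(if (is.null(value)) problem$objective(phi) else value)
    env$n <- env$n + 1L
    env$traj[env$n, ] <- c(env$n, phi, val)
    if (val > env$best_value) {
      env$best_value <- val
      env$best_phi <- phi
    }
    val
  }
  env
}

budget_exhausted_condition <- function() {
  structure(class = c("basketopt_budget_exhausted", "error", "condition"),
            list(message = "evaluation budget exhausted", call = NULL))
}

# Run `body(rec)` and package the recorder state into an opt_result,
# swallowing the budget-exhausted signal.
with_recorder <- function(problem, algorithm, body, extra = list()) {
  rec <- new_recorder(problem)
  t0 <- proc.time()
  status <- tryCatch({
    body(rec)
    "ok"
  }, basketopt_budget_exhausted = function(e) "budget_exhausted")
  elapsed <- unname((proc.time() - t0)["elapsed"])
  traj <- rec$traj[seq_len(rec$n), , drop = FALSE]
  colnames(traj) <- c("eval", "lambda", "epsilon", "tau", "value")
  structure(
    c(list(algorithm = algorithm,
           best_phi = tuning_params(rec$best_phi[1], rec$best_phi[2],
                                    rec$best_phi[3]),
           best_value = rec$best_value,
           n_evals = rec$n,
           trajectory = tibble::as_tibble(as.data.frame(traj)),
           elapsed = elapsed,
           status = status,
           seed = problem$seed),
      extra),
    class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf(
    "<opt_result> %s | best value %.6g at (%.4g, %.4g, %.4g) | %d evals (%s)\n",
    x$algorithm, x$best_value, x$best_phi[["lambda"]],
    x$best_phi[["epsilon"]], x$best_phi[["tau"]], x$n_evals, x$status))
  invisible(x)
}

#' Tidy an optimizer result
#'
#' @param x An `opt_result`.
#' @param ... Unused.
#' @return The evaluation trajectory as a tibble (`eval`, `lambda`,
#'   `epsilon`, `tau`, `value`).
#' @export
tidy.opt_result <- function(x, ...) x$trajectory

#' One-row summary of an optimizer result
#'
#' @param x An `opt_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.opt_result <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm, best_value = x$best_value,
    lambda = x$best_phi[["lambda"]], epsilon = x$best_phi[["epsilon"]],
    tau = x$best_phi[["tau"]], n_evals = x$n_evals,
    elapsed = x$elapsed, status = x$status, seed = x$seed
  )
}

random_start <- function(space) {
  space$lower + runif(3) * (space$upper - space$lower)
}

#' Simulated annealing over the tuning parameters
#'
#' Metropolis search with geometric cooling: one objective evaluation per
#' temperature step, Gaussian proposals with scale `prop_scale` times the
#' box width per dimension, acceptance of worse moves with probability
#' \eqn{\exp(\Delta u / T)}. The temperature decays from `t_start` to
#' `t_final` over the evaluation budget. Two boundary policies are
#' offered: `optimize_sa_bounded()` folds proposals back into the box by
#' [reflect()]; `optimize_sa_unbounded()` leaves proposals free and
#' assigns out-of-bounds points an invalid (\eqn{-\infty}) objective
#' value, so they are never accepted (the "return NA" policy). The
#' unbounded variant rejects an out-of-bounds start.
#'
#' @param problem An [opt_problem()].
#' @param t_start Start temperature (the study uses 100, 10 and 1 for the
#'   bounded variant and 10 for the unbounded one).
#' @param t_final Final temperature of the geometric schedule.
#' @param prop_scale Proposal standard deviation as a fraction of each
#'   dimension's width.
#' @return An `opt_result`.
#' @export
optimize_sa_bounded <- function(problem, t_start = 10, t_final = 1e-10,
                                prop_scale = 0.1) {
  sa_engine(problem, t_start, t_final, prop_scale, bounded = TRUE)
}

#' @rdname optimize_sa_bounded
#' @export
optimize_sa_unbounded <- function(problem, t_start = 10, t_final = 1e-10,
                                  prop_scale = 0.1) {
  sa_engine(problem, t_start, t_final, prop_scale, bounded = FALSE)
}

sa_engine <- function(problem, t_start, t_final, prop_scale, bounded) {
  space <- problem$space
  widths <- space$upper - space$lower
  cool <- (t_final / t_start)^(1 / problem$budget)
  name <- if (bounded) sprintf("sa_bounded_t%g", t_start) else
    sprintf("sa_unbounded_t%g", t_start)
  with_recorder(problem, name, function(rec) {
    set.seed(problem$seed)
    x <- problem$start %||% random_start(space)
    if (!in_bounds(x, space))
      stop("start vector outside the search space", call. = FALSE)
    ux <- rec$eval(x)
    temp <- t_start
    while (!rec$exhausted()) {
      # proposal width decays geometrically over the budget (to 2% of the
      # initial scale) so early steps explore and late steps refine
      step_sd <- prop_scale * widths * 0.02^(rec$n / problem$budget)
      prop <- x + rnorm(3, 0, step_sd)
      if (bounded) {
        prop <- vapply(1:3, function(d)
          reflect(prop[d], space$lower[d], space$upper[d]), 0)
        uprop <- rec$eval(prop)
      } else if (in_bounds(prop, space)) {
        uprop <- rec$eval(prop)
      } else {
        uprop <- rec$eval(prop, value = -Inf)
      }
      if (uprop >= ux || runif(1) < exp((uprop - ux) / temp)) {
        x <- prop
        ux <- uprop
      }
      temp <- temp * cool
    }
  })
}

#' Differential evolution over the tuning parameters
#'
#' Canonical rand/1/bin scheme: donor vectors
#' \eqn{v = x_a + F (x_b - x_c)} from three distinct random population
#' members, binomial crossover at rate `crossover` with one guaranteed
#' donor component, greedy selection (an offspring replaces its parent
#' when its utility is at least as good). Out-of-box donor components are
#' clipped. The initial population evaluation counts against the budget;
#' a final generation that does not fit is truncated.
#'
#' @param problem An [opt_problem()] with `budget >= pop_size`.
#' @param pop_size Population size (default 40).
#' @param scale Mutation scale factor F (default 0.8).
#' @param crossover Crossover rate (default 0.5).
#' @return An `opt_result`.
#' @export
optimize_de <- function(problem, pop_size = 40, scale = 0.8,
                        crossover = 0.5) {
  stopifnot(problem$budget >= pop_size, pop_size >= 4)
  space <- problem$space
  with_recorder(problem, "de", function(rec) {
    set.seed(problem$seed)
    pop <- t(vapply(seq_len(pop_size), function(k) random_start(space), numeric(3)))
    vals <- vapply(seq_len(pop_size), function(k) rec$eval(pop[k, ]), 0)
    while (!rec$exhausted()) {
      for (k in seq_len(pop_size)) {
        others <- sample(setdiff(seq_len(pop_size), k), 3)
        donor <- clip(pop[others[1], ] +
                        scale * (pop[others[2], ] - pop[others[3], ]), space)
        jrand <- sample(3, 1)
        cross <- runif(3) < crossover
        cross[jrand] <- TRUE
        trial <- ifelse(cross, donor, pop[k, ])
        utrial <- rec$eval(trial)
        if (utrial >= vals[k]) {
          pop[k, ] <- trial
          vals[k] <- utrial
        }
      }
    }
  })
}

#' Grey wolf optimizer over the tuning parameters
#'
#' Original grey wolf scheme: the pack follows the three best candidates
#' (alpha, beta, delta); each wolf moves to the mean of three
#' leader-guided points with exploration coefficient `a` decaying
#' linearly from 2 to 0 over the generation budget, so the pack contracts
#' toward the leaders in the final phase. Positions are clipped to the
#' box. The initial pack evaluation counts against the budget.
#'
#' @param problem An [opt_problem()] with `budget >= pop_size`.
#' @param pop_size Pack size (default 40).
#' @return An `opt_result`.
#' @export
optimize_gwo <- function(problem, pop_size = 40) {
  stopifnot(problem$budget >= pop_size, pop_size >= 3)
  space <- problem$space
  n_gen <- max(floor(problem$budget / pop_size) - 1L, 1L)
  with_recorder(problem, "gwo", function(rec) {
    set.seed(problem$seed)
    pop <- t(vapply(seq_len(pop_size), function(k) random_start(space), numeric(3)))
    vals <- vapply(seq_len(pop_size), function(k) rec$eval(pop[k, ]), 0)
    for (gen in seq_len(n_gen)) {
      if (rec$exhausted()) break
      a <- 2 * (1 - gen / n_gen)
      ord <- order(vals, decreasing = TRUE)
      leaders <- pop[ord[1:3], , drop = FALSE]
      for (k in seq_len(pop_size)) {
        guided <- vapply(1:3, function(l) {
          r1 <- runif(3); r2 <- runif(3)
          coefA <- 2 * a * r1 - a
          coefC <- 2 * r2
          dist <- abs(coefC * leaders[l, ] - pop[k, ])
          leaders[l, ] - coefA * dist
        }, numeric(3))
        newpos <- clip(rowMeans(guided), space)
        newval <- rec$eval(newpos)
        pop[k, ] <- newpos
        vals[k] <- newval
      }
    }
  })
}

#' COBYLA over the tuning parameters
#'
#' Derivative-free constrained optimization by linear approximations,
#' backed by the nloptr implementation wrapped in the shared
#' evaluation counter (the box bounds are passed as constraints; the
#' maximization is run as minimization of the negated utility). Stopping:
#' tolerance `xtol` in the parameter space, `ftol` (default 0, i.e.
#' disabled) in the value space, or the evaluation budget.
#' Non-convergence is reported in the result status, never raised.
#'
#' @param problem An [opt_problem()]; `start` is required.
#' @param xtol Parameter-space stopping tolerance (default 1e-6).
#' @param ftol Value-space stopping tolerance (default 0).
#' @return An `opt_result`.
#' @export
optimize_cobyla <- function(problem, xtol = 1e-6, ftol = 0) {
  space <- problem$space
  start <- problem$start
  if (is.null(start)) stop("COBYLA requires a start vector")
  if (!in_bounds(start, space)) stop("start vector outside the search space")
  with_recorder(problem, "cobyla", function(rec) {
    neg <- function(phi) -rec$eval(phi)
    res <- tryCatch(
      nloptr::cobyla(x0 = start, fn = neg,
                     lower = space$lower, upper = space$upper,
                     control = list(xtol_rel = xtol, ftol_abs = ftol,
                                    maxeval = problem$budget)),
      basketopt_budget_exhausted = function(e) NULL)
    invisible(res)
  })
}

#' Grid values of the pre-specified 10 x 10 x 10 search grid
#'
#' \eqn{\lambda \in \{0.2, \ldots, 0.9\} \cup \{0.99, 0.999\}},
#' \eqn{\epsilon \in \{0, 0.5, 1, 1.5, 2\} \cup \{5, 10, 15, 20, 25\}},
#' \eqn{\tau \in \{0, 0.1, \ldots, 0.8\} \cup \{1.0\}} — 1000
#' combinations, matching the 1000-evaluation budget of the other
#' algorithms.
#'
#' @return A list with `lambda`, `epsilon`, `tau` value vectors.
#' @export
default_grid <- function() {
  list(lambda = c(seq(0.2, 0.9, by = 0.1), 0.99, 0.999),
       epsilon = c(0, 0.5, 1, 1.5, 2, 5, 10, 15, 20, 25),
       tau = c(seq(0, 0.8, by = 0.1), 1))
}

#' Exhaustive grid search over the tuning parameters
#'
#' Evaluates every grid combination exactly once, in lexicographic
#' (lambda, epsilon, tau) order with tau varying fastest; ties are broken
#' by first occurrence in that order. Fully deterministic. If the
#' problem's budget is smaller than the grid, evaluation stops at the
#' budget (with the truncation flagged in the result status).
#'
#' @param problem An [opt_problem()].
#' @param grid Per-dimension value lists as from [default_grid()].
#' @return An `opt_result`.
#' @export
grid_search <- function(problem, grid = default_grid()) {
  combos <- expand.grid(tau = grid$tau, epsilon = grid$epsilon,
                        lambda = grid$lambda, KEEP.OUT.ATTRS = FALSE)
  combos <- combos[, c("lambda", "epsilon", "tau")]
  res <- with_recorder(problem, "grid_search", function(rec) {
    for (k in seq_len(nrow(combos))) {
      rec$eval(as.numeric(combos[k, ]))
    }
  }, extra = list(grid_size = nrow(combos)))
  res
}

#' The eight optimizer configurations of the algorithm comparison
#'
#' Three bounded simulated annealing runs (start temperatures 100, 10,
#' 1), unbounded simulated annealing (start temperature 10), differential
#' evolution, the grey wolf optimizer, COBYLA and grid search.
#'
#' @return Named list of functions, each taking an [opt_problem()] and
#'   returning an `opt_result`, with attributes `stochastic` marking the
#'   seed-dependent entries.
#' @examples
#' length(algorithm_registry())  # 8
#' @export
algorithm_registry <- function() {
  algs <- list(
    sa_bounded_t100 = function(problem) optimize_sa_bounded(problem, t_start = 100),
    sa_bounded_t10 = function(problem) optimize_sa_bounded(problem, t_start = 10),
    sa_bounded_t1 = function(problem) optimize_sa_bounded(problem, t_start = 1),
    sa_unbounded_t10 = function(problem) optimize_sa_unbounded(problem, t_start = 10),
    de = optimize_de,
    gwo = optimize_gwo,
    cobyla = optimize_cobyla,
    grid_search = grid_search
  )
  attr(algs, "stochastic") <- c("sa_bounded_t100", "sa_bounded_t10",
                                "sa_bounded_t1", "sa_unbounded_t10",
                                "de", "gwo")
  algs
}
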