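test_that("standard error of the sample SD follows the gamma formula", {
  expect_equal(se_of_sd(1, 50), 0.10127, tolerance = 5e-5)
  expect_equal(se_of_sd(0, 17), 0)
  expect_equal(se_of_sd(2.5, 50), 2.5 * se_of_sd(1, 50))
  # n = 2: gamma(1/2) = sqrt(pi), gamma(1) = 1
  expect_equal(se_of_sd(1, 2), sqrt(pi / 2 - 1), tolerance = 1e-12)
  # asymptotics: coefficient ~ 1 / sqrt(2 (n - 1))
  expect_lt(abs(se_of_sd(1, 200) / (1 / sqrt(2 * 199)) - 1), 0.01)
  expect_error(se_of_sd(1, 1))
})

test_that("internal reliability counts runs near the per-problem best", {
  fake <- function(v) structure(list(best_value = v), class = "opt_result")
  same <- lapply(rep(0.7, 8), fake)
  expect_equal(internal_reliability(same), 1)
  mixed <- lapply(c(rep(0.7, 9), 0.5), fake)
  expect_equal(internal_reliability(mixed), 0.9)
  expect_equal(internal_reliability(list(fake(0.3))), 1)
  # values within tolerance still count
  close <- lapply(c(0.7, 0.7 - 5e-5), fake)
  expect_equal(internal_reliability(close, tol = 1e-4), 1)
})

test_that("the algorithm comparison runs end-to-end at rehearsal scale", {
  cfg <- study_config(n_runs = 3, budget = 100, seed_part1 = 1856)
  out <- run_part1(cfg, set = rehearsal_set())
  expect_setequal(unique(out$report$algorithm), names(algorithm_registry()))
  expect_equal(nrow(out$report), 16)  # 8 algorithms x 2 test problems
  # deterministic algorithms show zero spread
  det <- dplyr::filter(out$report, algorithm %in%
                         c("cobyla", "grid_search"))
  expect_true(all(det$sd_value == 0))
  expect_true(all(det$sd_lambda == 0))
  # grid search always succeeds against itself
  grid_rows <- dplyr::filter(out$report, algorithm == "grid_search")
  expect_true(all(grid_rows$success_rate == 1))
  expect_true(all(grid_rows$internal_reliability == 1))
  # all success rates computable
  expect_false(any(is.na(out$report$success_rate)))
  expect_true(is.character(out$best_algorithm) || out$none_reliable)
  # summary averages across the two problems
  expect_equal(nrow(out$summary), 8)
})

test_that("the utility comparison optimizes, tabulates and cross-evaluates", {
  cfg <- study_config(budget = 1000, seed_part2 = 899)
  sets <- list(rehearsal_set())
  out <- run_part2(cfg, algorithm = "grid_search", sets = sets)
  expect_equal(nrow(out$optima), 12)
  # every optimum lies inside the search space
  sp <- search_space()
  expect_true(all(out$optima$lambda >= 0 & out$optima$lambda <= 1))
  expect_true(all(out$optima$epsilon >= sp$lower[2] &
                    out$optima$epsilon <= sp$upper[2]))
  expect_true(all(out$optima$tau >= 0 & out$optima$tau <= 1))
  # the commonly suggested vector (0.99, 2, 0) is a grid point, so the
  # grid optimum can never fall below it
  for (nm in out$optima$utility) {
    sp_row <- dplyr::filter(out$optima, utility == nm)
    fuji_val <- dplyr::filter(out$cross_utilities,
                              optimized_for == nm,
                              utility == nm)$value
    expect_equal(sp_row$best_value, fuji_val, tolerance = 1e-9)
  }
  fuji <- c(0.99, 2, 0)
  for (nm in c("u_avg_ecd", "u_avg_2ewp")) {
    spec <- utility_registry()[[nm]]
    f <- build_utility_objective(spec$family, spec$averaging, sets[[1]])
    best <- dplyr::filter(out$optima, utility == nm)$best_value
    expect_gte(best, f(fuji) - 1e-9)
  }
  # performance table carries all measures for every scenario
  expect_equal(sort(unique(out$performance$label)), sort(out$optima$utility))
  expect_true(all(c("rejection_rate", "ewp", "fwer", "ecd") %in%
                    names(out$performance)))
})

test_that("the fixed-vector comparison evaluates both suggested tunings", {
  cfg <- study_config()
  out <- run_part3(cfg, sets = list(rehearsal_set()))
  expect_setequal(unique(out$label), c("fujikawa_i", "fujikawa_ii"))
  expect_true(all(out$method == "exact"))
  # same raw similarities, different thresholding only
  lay <- rehearsal_set()$layout
  w0 <- similarity_matrix(lay, c(1, 2, 4), c(0.99, 2, 0))
  w5 <- similarity_matrix(lay, c(1, 2, 4), c(0.99, 2, 0.5))
  expect_equal(w0$raw, w5$raw)
  changed <- w5$weighted != w0$weighted
  expect_true(all(w5$weighted[changed] == 0))
})

test_that("the exploratory extras behave consistently", {
  cfg <- study_config()
  small_set <- rehearsal_set()
  out <- run_extras(cfg, set = small_set, n = 6,
                    p2_grid = seq(0.2, 1, by = 0.2),
                    eps_tau = list(c(2, 0), c(2, 1)))
  cmp <- out$divergence_comparison
  expect_setequal(unique(cmp$divergence), c("jsd", "hellinger"))
  expect_equal(nrow(cmp), 2 * length(small_set$scenarios))
  expect_true(all(is.finite(cmp$elapsed)))
  curves <- out$toer_curves
  # with borrowing off (tau = 1) the null basket's error ignores basket 2
  flat <- dplyr::filter(curves, tau == 1)
  expect_equal(length(unique(round(flat$toer_basket1, 12))), 1)
  # at p2 = p0 both settings describe the same global null configuration
  base <- dplyr::filter(curves, p2 == 0.2)
  expect_true(all(base$toer_basket1 >= 0 & base$toer_basket1 <= 1))
  # borrowing from an active neighbour inflates the null basket's error
  on <- dplyr::filter(curves, tau == 0)
  expect_gte(max(on$toer_basket1), max(flat$toer_basket1))
})
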