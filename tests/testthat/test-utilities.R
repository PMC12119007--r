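make_small <- function() {
  layout <- basket_layout(rep(4, 3), 0.2)
  scen <- lapply(0:3, function(a)
    scenario(c(rep(0.2, 3 - a), rep(0.5, a)), 0.2,
             label = paste0(a, " of 3 active")))
  scenario_set(layout, scen, "small I=3 n=4", p0 = 0.2, p1 = 0.5)
}

test_that("discontinuous utilities branch on the error constraint", {
  set <- make_small()
  lay <- set$layout
  p1 <- set$scenarios[[3]]
  gn <- global_null(set)
  # lambda = 1: nothing detected, fwer = 0 < eta1, pass branch with ewp 0
  expect_equal(u_ewp(lay, c(1, 2, 0), p1, gn), 0)
  # ecd pass branch at lambda = 1 equals the number of inactive strata
  expect_equal(u_ecd(lay, c(1, 2, 0), p1, gn), 1)
  # force the penalty branch: eta1 set exactly to the achieved fwer
  phi <- c(0.9, 2, 0)
  fw <- exact_oc(lay, gn, phi)$fwer
  cfg_pen <- utility_config(eta1 = fw)   # fwer >= eta1 (boundary, strict <)
  expect_equal(u_ewp(lay, phi, p1, gn, cfg_pen), -fw)
  expect_equal(u_ecd(lay, phi, p1, gn, cfg_pen), -fw)
  # pass branch reproduces the raw measures
  cfg_pass <- utility_config(eta1 = fw + 1e-9)
  expect_equal(u_ewp(lay, phi, p1, gn, cfg_pass),
               exact_oc(lay, p1, phi)$ewp)
})

test_that("two-level utilities apply the hinge penalty as written", {
  set <- make_small()
  lay <- set$layout
  p <- set$scenarios[[3]]   # 2 of 3 active
  phi <- c(0.9, 2, 0)
  oc <- exact_oc(lay, p, phi)
  # default config: ewp - (fwer + (fwer - 0.1)^+)
  expected <- oc$ewp - (oc$fwer + max(oc$fwer - 0.1, 0))
  expect_equal(u_2ewp(lay, phi, p), expected)
  # at eta2 exactly equal to fwer the second-level penalty is off
  cfg_edge <- utility_config(eta2 = oc$fwer)
  expect_equal(u_2ewp(lay, phi, p, cfg_edge), oc$ewp - oc$fwer)
  # u_2ewp <= ewp with equality iff fwer = 0
  expect_lte(u_2ewp(lay, phi, p), oc$ewp)
  expect_equal(u_2ewp(lay, c(1, 2, 0), p), 0)
  # stratum-wise version at lambda = 0: |R| - |Rc| (1 + xi2 (1 - eta2))
  expect_equal(u_2pow(lay, c(0, 2, 0), p), 2 - 1 * (1 + 0.9))
  # and the generic value against hand-assembled rates
  toer <- oc$rejection_rates[1]
  pows <- oc$rejection_rates[2:3]
  expect_equal(u_2pow(lay, phi, p),
               sum(pows) - (toer + max(toer - 0.1, 0)))
})

test_that("scenario averaging is a weighted mean with global-null error scenario", {
  set <- make_small()
  lay <- set$layout
  phi <- c(0.99, 2, 0)
  gn <- global_null(set)
  singles <- vapply(set$scenarios, function(p)
    u_ewp(lay, phi, p, gn), 0)
  expect_equal(u_averaged("ewp", phi, set), mean(singles))
  # custom weights: linear in the weights, invariant under permutation
  w <- c(0.4, 0.3, 0.2, 0.1)
  cfg_w <- utility_config(weights = w)
  expect_equal(u_averaged("ewp", phi, set, cfg_w), sum(w * singles))
  perm <- c(3, 1, 4, 2)
  set_perm <- scenario_set(lay, set$scenarios[perm], set$label,
                           set$p0, set$p1)
  cfg_perm <- utility_config(weights = w[perm])
  expect_equal(u_averaged("ewp", phi, set_perm, cfg_perm),
               u_averaged("ewp", phi, set, cfg_w), tolerance = 1e-12)
  # a one-scenario set with weight 1 collapses to the single utility
  one <- scenario_set(lay, list(gn, set$scenarios[[3]]), "two", 0.2, 0.5)
  cfg_one <- utility_config(weights = c(0, 1))
  expect_equal(u_averaged("2ewp", phi, one, cfg_one),
               u_2ewp(lay, phi, set$scenarios[[3]]))
})

test_that("penalized averaging switches at the maximal type-I error", {
  set <- make_small()
  phi_none <- c(1, 2, 0)   # nothing detected: max toer 0 < eta3
  expect_equal(u_averaged_penalized("ecd", phi_none, set),
               u_averaged("ecd", phi_none, set))
  phi_all <- c(0, 2, 0)    # everything detected: max toer 1 >= 0.2
  expect_equal(u_averaged_penalized("ecd", phi_all, set), -1000)
  # mid case consistency with a directly computed maximum
  phi <- c(0.9, 2, 0)
  toers <- unlist(lapply(set$scenarios, function(p) {
    oc <- exact_oc(set$layout, p, phi)
    oc$rejection_rates[p$inactive_set]
  }))
  if (max(toers) < 0.2) {
    expect_equal(u_averaged_penalized("2pow", phi, set),
                 u_averaged("2pow", phi, set))
  } else {
    expect_equal(u_averaged_penalized("2pow", phi, set), -1000 * max(toers))
  }
})

test_that("the registry holds the twelve utility specifications", {
  specs <- utility_registry()
  expect_length(specs, 12)
  fams <- vapply(specs, function(s) s$family, "")
  avgs <- vapply(specs, function(s) s$averaging, "")
  expect_true(all(table(fams) == 3L) && length(unique(fams)) == 4)
  expect_equal(sort(unique(avgs)),
               c("averaged", "averaged_penalized", "single"))
  # every spec is evaluable on the three-stratum reference set
  set3 <- build_all_scenario_sets()[[1]]
  for (sp in specs) {
    f <- build_utility_objective(sp$family, sp$averaging, set3)
    v <- f(c(0.99, 2, 0))
    expect_true(is.finite(v))
  }
})

test_that("objective closures agree with the direct utility evaluations", {
  set <- make_small()
  phi <- c(0.8, 1.5, 0.3)
  f_avg <- build_utility_objective("ecd", "averaged", set)
  expect_equal(f_avg(phi), u_averaged("ecd", phi, set))
  f_single <- build_utility_objective("ewp", "single", set,
                                      single_scenario = "2 of 3 active")
  expect_equal(f_single(phi),
               u_ewp(set$layout, phi, set$scenarios[[3]], global_null(set)))
})
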