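test_that("posterior shapes follow beta-binomial conjugacy", {
  lay <- basket_layout(rep(24, 3), 0.2)
  expect_equal(posterior_params(lay, c(0, 0, 0), 1),
               c(shape1 = 1, shape2 = 25))
  expect_equal(posterior_params(lay, c(10, 0, 0), 1),
               c(shape1 = 11, shape2 = 15))
  lay2 <- basket_layout(c(10, 10), 0.2, prior_shape1 = 2, prior_shape2 = 3)
  expect_equal(posterior_params(lay2, c(4, 0), 1), c(shape1 = 6, shape2 = 9))
  expect_error(posterior_params(lay, c(10, 0, 0), 4))
})

test_that("KL divergence vanishes on identical pairs and matches quadrature", {
  d22 <- function(x) dbeta(x, 2, 2)
  expect_equal(kld(d22, d22), 0)
  mix_same <- function(x) 0.5 * (dbeta(x, 2, 2) + dbeta(x, 2, 2))
  expect_equal(kld(d22, mix_same), 0, tolerance = 1e-10)
  # frozen high-resolution composite-quadrature value
  mix <- function(x) 0.5 * (dbeta(x, 1, 1) + dbeta(x, 5, 1))
  expect_equal(kld(function(x) dbeta(x, 1, 1), mix), 0.1766026219,
               tolerance = 1e-8)
})

test_that("Jensen-Shannon divergence is symmetric, bounded and matches the oracle", {
  expect_equal(jsd(11, 15, 11, 15), 0)
  expect_equal(jsd(3, 21, 9, 13), jsd(9, 13, 3, 21), tolerance = 1e-10)
  expect_equal(jsd(1, 1, 5, 1), 0.2161926318, tolerance = 1e-8)
  set.seed(42)
  for (k in 1:20) {
    sh <- 1 + 29 * runif(4)
    v <- jsd(sh[1], sh[2], sh[3], sh[4])
    expect_gte(v, 0)
    expect_lte(v, log(2))
    expect_equal(v, jsd(sh[3], sh[4], sh[1], sh[2]), tolerance = 1e-9)
  }
})

test_that("Hellinger closed form matches its quadrature definition", {
  expect_equal(hellinger(3, 7, 3, 7), 0)
  expect_equal(hellinger(1, 1, 2, 2), 1 - (pi / 8) / sqrt(1 / 6),
               tolerance = 1e-12)
  expect_equal(hellinger(1, 1, 2, 2), oracle_hellinger(1, 1, 2, 2),
               tolerance = 1e-8)
  expect_equal(hellinger(3, 7, 7, 3), hellinger(7, 3, 3, 7))
})

test_that("similarity weighting follows the exponent/cutoff rules", {
  lay <- basket_layout(rep(24, 3), 0.2)
  r <- c(5, 9, 20)
  # epsilon = 0: all raised similarities are 1 > tau
  w0 <- similarity_matrix(lay, r, tuning_params(0.9, 0, 0.5))
  expect_true(all(w0$weighted == 1))
  # epsilon = 2, tau = 0: squared raw similarities off-diagonal
  w2 <- similarity_matrix(lay, r, tuning_params(0.99, 2, 0))
  off <- row(w2$raw) != col(w2$raw)
  expect_equal(w2$weighted[off], w2$raw[off]^2)
  expect_equal(diag(w2$weighted), rep(1, 3))
  expect_equal(w2$raw, t(w2$raw))
  # above the extreme borrowing boundary: equal-responses indicator
  tau <- 0.7
  eps_star <- extreme_borrowing_boundary(lay, tau) + 0.5
  weq <- similarity_matrix(lay, c(5, 5, 12), tuning_params(0.9, eps_star, tau))
  expect_equal(weq$weighted[1, 2], 1)
  expect_equal(weq$weighted[1, 3], 0)
  expect_equal(weq$weighted[2, 3], 0)
})

test_that("borrowing posterior pools weighted shape sums", {
  lay2 <- basket_layout(rep(24, 2), 0.2)
  # tau = 1 switches all cross-borrowing off
  w_off <- similarity_matrix(lay2, c(10, 3), tuning_params(0.9, 2, 1))
  expect_equal(borrowed_posterior(lay2, c(10, 3), w_off, 1),
               posterior_params(lay2, c(10, 3), 1))
  # identical outcomes: full borrowing doubles the shape sums
  w_on <- similarity_matrix(lay2, c(10, 10), tuning_params(0.9, 0, 0))
  expect_equal(borrowed_posterior(lay2, c(10, 10), w_on, 1),
               c(shape1 = 22, shape2 = 30))
  # three strata at a commonly suggested tuning, against the quadrature oracle
  lay3 <- basket_layout(rep(24, 3), 0.2)
  r <- c(5, 5, 12)
  w <- similarity_matrix(lay3, r, tuning_params(0.99, 2, 0))
  om12 <- (1 - oracle_jsd(6, 20, 6, 20))^2
  om13 <- (1 - oracle_jsd(6, 20, 13, 13))^2
  om23 <- (1 - oracle_jsd(6, 20, 13, 13))^2
  exp_shape1 <- 6 + om12 * 6 + om13 * 13
  exp_shape2 <- 20 + om12 * 20 + om13 * 13
  got <- borrowed_posterior(lay3, r, w, 1)
  expect_equal(unname(got["shape1"]), exp_shape1, tolerance = 1e-6)
  expect_equal(unname(got["shape2"]), exp_shape2, tolerance = 1e-6)
})

test_that("test decision is the posterior upper tail against lambda", {
  lay <- basket_layout(rep(24, 3), 0.2)
  expect_true(all(decide(lay, c(0, 5, 24), tuning_params(0, 2, 0))))
  expect_false(any(decide(lay, c(0, 5, 24), tuning_params(1, 2, 0))))
  # single stratum: no borrowing possible, plain incomplete-beta tail
  lay1 <- basket_layout(24, 0.2)
  expected <- pbeta(0.2, 11, 15, lower.tail = FALSE) >= 0.9
  expect_equal(decide(lay1, 10, tuning_params(0.9, 2, 0)), expected)
  # monotone in lambda: raising lambda never creates a detection
  set.seed(7)
  for (k in 1:10) {
    r <- rbinom(3, 24, 0.3)
    phi_lo <- c(runif(1, 0, 0.5), runif(1, 0, 5), runif(1, 0, 0.9))
    phi_hi <- phi_lo + c(runif(1, 0, 0.5), 0, 0)
    d_lo <- decide(lay, r, phi_lo)
    d_hi <- decide(lay, r, phi_hi)
    expect_true(all(d_hi <= d_lo))
  }
})

test_that("extreme borrowing boundary matches its defining construction", {
  lay <- basket_layout(rep(24, 3), 0.2)
  # frozen oracle: max unequal-response raw similarity at n = 24 and the
  # resulting boundary at tau = 0.7
  expect_equal(extreme_borrowing_boundary(lay, 0.7), 17.98999787,
               tolerance = 1e-4)
  om_star <- exp(log(0.7) / extreme_borrowing_boundary(lay, 0.7))
  expect_equal(extreme_borrowing_boundary(lay, om_star), 1, tolerance = 1e-9)
  expect_gt(extreme_borrowing_boundary(lay, 0.3),
            extreme_borrowing_boundary(lay, 0.7))
  expect_error(extreme_borrowing_boundary(lay, 0))
  expect_error(extreme_borrowing_boundary(lay, 1))
})

test_that("weights above the boundary equal the equal-responses indicator (exhaustive)", {
  lay <- basket_layout(rep(4, 2), 0.2)
  tau <- 0.5
  eps <- extreme_borrowing_boundary(lay, tau) * 1.01
  for (r1 in 0:4) {
    for (r2 in 0:4) {
      w <- similarity_matrix(lay, c(r1, r2), c(0.9, eps, tau))
      expect_equal(w$weighted[1, 2], as.numeric(r1 == r2))
    }
  }
})
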