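# Independent numerical oracles, deliberately not sharing code with the
# package: composite Simpson quadrature on a fixed fine grid.

simpson_quad <- function(f, n = 20000L, eps = 1e-12) {
  # n must be even
  x <- seq(eps, 1 - eps, length.out = n + 1L)
  h <- x[2] - x[1]
  y <- f(x)
  w <- rep(c(4, 2), length.out = n - 1L)
  h / 3 * (y[1] + sum(w * y[2:n]) + y[n + 1L])
}

oracle_kld <- function(p, q, n = 20000L) {
  simpson_quad(function(x) {
    px <- p(x)
    qx <- q(x)
    ifelse(px > 0, px * log(px / qx), 0)
  }, n = n)
}

oracle_jsd <- function(a1, b1, a2, b2, n = 20000L) {
  p <- function(x) dbeta(x, a1, b1)
  q <- function(x) dbeta(x, a2, b2)
  m <- function(x) 0.5 * (p(x) + q(x))
  0.5 * (oracle_kld(p, m, n) + oracle_kld(q, m, n))
}

oracle_hellinger <- function(a1, b1, a2, b2, n = 200000L) {
  # x = sin^2(theta) substitution tames the endpoint derivative
  # singularities of the root-density integrand
  theta <- seq(0, pi / 2, length.out = n + 1L)
  x <- sin(theta)^2
  f <- sqrt(dbeta(x, a1, b1) * dbeta(x, a2, b2)) * 2 * sin(theta) * cos(theta)
  f[!is.finite(f)] <- 0
  h <- theta[2] - theta[1]
  w <- rep(c(4, 2), length.out = n - 1L)
  bc <- h / 3 * (f[1] + sum(w * f[2:n]) + f[n + 1L])
  1 - bc
}

# concave quadratic toy objective with unique maximum at (0.5, 1, 0.5)
toy_objective <- function(phi) {
  -(phi[1] - 0.5)^2 - (phi[2] - 1)^2 - (phi[3] - 0.5)^2
}
toy_optimum <- c(0.5, 1, 0.5)

# small rehearsal scenario set: 3 strata of 5 patients, p0 = 0.2, p1 = 0.5
rehearsal_set <- function() {
  layout <- basket_layout(rep(5, 3), target_rates = 0.2)
  scen <- lapply(0:3, function(a)
    scenario(c(rep(0.2, 3 - a), rep(0.5, a)), target_rates = 0.2,
             label = paste0(a, " of 3 active")))
  scenario_set(layout, scen, "rehearsal I=3 n=5", p0 = 0.2, p1 = 0.5)
}
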