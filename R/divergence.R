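#' Kullback-Leibler divergence between densities on (0, 1)
#'
#' Computes \eqn{KLD(P, Q) = \int_0^1 P(x) \log(P(x)/Q(x)) dx} by adaptive
#' quadrature, with the natural logarithm. The integrand is taken as 0
#' wherever \eqn{P(x) = 0}. `P` and `Q` are density functions; the pairs
#' used by the borrowing design (beta posteriors and their equal mixtures,
#' with all shapes \eqn{\ge 1}) are bounded on (0, 1), so no endpoint
#' singularities arise.
#'
#' @param p,q Vectorized density functions on (0, 1).
#' @param abs_tol Absolute quadrature tolerance.
#' @return Nonnegative divergence value (natural-log scale).
#' @examples
#' kld(function(x) dbeta(x, 2, 2), function(x) dbeta(x, 2, 2))  # 0
#' @export
kld <- function(p, q, abs_tol = 1e-9) {
  integrand <- function(x) {
    px <- p(x)
    qx <- q(x)
    out <- numeric(length(x))
    pos <- px > 0
    out[pos] <- px[pos] * (log(px[pos]) - log(qx[pos]))
    if (any(!is.finite(out)))
      stop("non-finite KLD integrand: invalid density pair")
    out
  }
  val <- stats::integrate(integrand, 0, 1, abs.tol = abs_tol,
                          rel.tol = 1e-10, subdivisions = 500L)$value
  max(val, 0)
}

#' Jensen-Shannon divergence between two beta distributions
#'
#' \eqn{JSD(P, Q) = \frac12 KLD(P, M) + \frac12 KLD(Q, M)} with
#' \eqn{M = \frac12 (P + Q)} the equal mixture. Under the natural logarithm
#' the value lies in \eqn{[0, \log 2]}; it is symmetric and 0 iff the two
#' distributions coincide.
#'
#' @param shape1_p,shape2_p Shapes of the first beta distribution.
#' @param shape1_q,shape2_q Shapes of the second beta distribution.
#' @return Divergence in \eqn{[0, \log 2]}.
#' @examples
#' jsd(11, 15, 11, 15)  # 0
#' jsd(1, 1, 5, 1)
#' @export
jsd <- function(shape1_p, shape2_p, shape1_q, shape2_q) {
  if (shape1_p == shape1_q && shape2_p == shape2_q) return(0)
  p <- function(x) dbeta(x, shape1_p, shape2_p)
  q <- function(x) dbeta(x, shape1_q, shape2_q)
  m <- function(x) 0.5 * (p(x) + q(x))
  val <- 0.5 * (kld(p, m) + kld(q, m))
  min(max(val, 0), log(2))
}

#' Hellinger distance between two beta distributions (closed form)
#'
#' \eqn{HLD(P, Q) = 1 - \int_0^1 \sqrt{P(x) Q(x)} dx}. For two beta
#' distributions the integral is a ratio of beta functions,
#' \deqn{HLD = 1 - \frac{B((a_1+a_2)/2, (b_1+b_2)/2)}
#'                      {\sqrt{B(a_1,b_1)\,B(a_2,b_2)}},}
#' evaluated here in log space so extreme shapes do not overflow.
#'
#' @param shape1_p,shape2_p,shape1_q,shape2_q Beta shape parameters.
#' @return Distance in \[0, 1\].
#' @examples
#' hellinger(1, 1, 2, 2)  # about 0.0381
#' @export
hellinger <- function(shape1_p, shape2_p, shape1_q, shape2_q) {
  log_bc <- lbeta((shape1_p + shape1_q) / 2, (shape2_p + shape2_q) / 2) -
    0.5 * (lbeta(shape1_p, shape2_p) + lbeta(shape1_q, shape2_q))
  min(max(1 - exp(log_bc), 0), 1)
}

# Divergence between the stratum-wise posteriors of two (r, n, a, b)
# configurations, dispatching on the divergence name.
posterior_divergence <- function(divergence, a1, b1, a2, b2) {
  switch(divergence,
         jsd = jsd(a1, b1, a2, b2),
         hellinger = hellinger(a1, b1, a2, b2),
         stop("unknown divergence: ", divergence))
}
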