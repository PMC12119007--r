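# Raw similarity table for a pair of stratum configurations.
#
# The raw similarity between strata i and j depends only on the pairs
# (r_i, n_i, a_i, b_i) and (r_j, n_j, a_j, b_j), so for a given layout and
# divergence the full (n_i + 1) x (n_j + 1) table over all response pairs
# can be computed once and reused. Caching it makes exact enumeration over
# all outcome vectors cost O(prod(n_i + 1)) decisions but only
# O(max(n_i + 1)^2) integrals. The cache lives for the R session and is
# shared across calls with identical (n, prior, divergence).
raw_similarity_table <- function(n1, a1, b1, n2, a2, b2, divergence) {
  key <- paste(divergence, n1, a1, b1, n2, a2, b2, sep = "|")
  hit <- get0(key, envir = .basketopt_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  # symmetric: reuse the transposed table if present
  key_t <- paste(divergence, n2, a2, b2, n1, a1, b1, sep = "|")
  hit_t <- get0(key_t, envir = .basketopt_cache, inherits = FALSE)
  if (!is.null(hit_t)) {
    tab <- t(hit_t)
    assign(key, tab, envir = .basketopt_cache)
    return(tab)
  }
  tab <- matrix(NA_real_, n1 + 1L, n2 + 1L)
  for (r1 in 0:n1) {
    for (r2 in 0:n2) {
      same_cfg <- n1 == n2 && a1 == a2 && b1 == b2
      if (same_cfg && r2 < r1) {
        tab[r1 + 1L, r2 + 1L] <- tab[r2 + 1L, r1 + 1L]
      } else {
        d <- posterior_divergence(divergence,
                                  a1 + r1, b1 + n1 - r1,
                                  a2 + r2, b2 + n2 - r2)
        tab[r1 + 1L, r2 + 1L] <- 1 - d
      }
    }
  }
  assign(key, tab, envir = .basketopt_cache)
  tab
}

# List-of-lists of raw similarity tables for all ordered stratum pairs.
pairwise_tables <- function(layout, divergence) {
  I <- layout$n_strata
  lapply(seq_len(I), function(i) {
    lapply(seq_len(I), function(j) {
      if (i == j) return(NULL)
      raw_similarity_table(layout$sample_sizes[i], layout$prior_shape1[i],
                           layout$prior_shape2[i],
                           layout$sample_sizes[j], layout$prior_shape1[j],
                           layout$prior_shape2[j], divergence)
    })
  })
}

#' Drop the session-wide similarity cache
#'
#' Pairwise raw-similarity tables are memoized per (sample size, prior,
#' divergence). This clears them; mainly useful in benchmarks.
#' @return Invisibly, the number of cached tables removed.
#' @export
clear_similarity_cache <- function() {
  keys <- ls(envir = .basketopt_cache)
  rm(list = keys, envir = .basketopt_cache)
  invisible(length(keys))
}

#' Similarity weight matrix for an observed outcome
#'
#' The raw similarity between strata i and j is
#' \eqn{\tilde\omega_{ij} = 1 - D(\mathrm{post}_i, \mathrm{post}_j)} where D
#' is the Jensen-Shannon divergence (default) or the Hellinger distance of
#' the unborrowed stratum-wise posteriors. The borrowing weight is
#' \eqn{\omega_{ij} = \tilde\omega_{ij}^\epsilon} if
#' \eqn{\tilde\omega_{ij}^\epsilon > \tau} (strictly), else 0. The
#' self-weight \eqn{\omega_{ii}} is always 1, so a stratum never discards
#' its own data (a strict reading at \eqn{\tau = 1} would zero the diagonal
#' and leave an undefined Beta(0, 0) posterior).
#'
#' @param layout A [basket_layout()].
#' @param responses Responder counts per stratum.
#' @param phi A [tuning_params()] vector (or bare length-3 numeric).
#' @param divergence `"jsd"` or `"hellinger"`.
#' @return Object of class `similarity_matrix`: list with `raw` (matrix of
#'   \eqn{\tilde\omega_{ij}}, diagonal 1) and `weighted` (matrix of
#'   \eqn{\omega_{ij}}).
#' @examples
#' lay <- basket_layout(rep(24, 3), 0.2)
#' similarity_matrix(lay, c(5, 5, 12), tuning_params(0.99, 2, 0))
#' @export
similarity_matrix <- function(layout, responses, phi, divergence = "jsd") {
  phi <- as_tuning(phi)
  responses <- validate_outcome(layout, responses)
  I <- layout$n_strata
  tabs <- pairwise_tables(layout, divergence)
  raw <- diag(1, I)
  for (i in seq_len(I)) {
    for (j in seq_len(I)) {
      if (i != j)
        raw[i, j] <- tabs[[i]][[j]][responses[i] + 1L, responses[j] + 1L]
    }
  }
  weighted <- apply_weighting(raw, phi[["epsilon"]], phi[["tau"]])
  structure(list(raw = raw, weighted = weighted), class = "similarity_matrix")
}

# omega = raw^eps thresholded strictly at tau; diagonal forced to 1.
apply_weighting <- function(raw, epsilon, tau) {
  w <- raw^epsilon
  w[w <= tau] <- 0
  diag(w) <- 1
  w
}

#' Borrowing posterior of one stratum
#'
#' The borrowing mechanism replaces the stratum-wise posterior by
#' \deqn{\mathrm{Beta}\Big(\sum_j \omega_{ij} (a_j + r_j),\;
#'       \sum_j \omega_{ij} (b_j + n_j - r_j)\Big),}
#' pooling the posterior shape parameters of all strata with the
#' similarity weights of [similarity_matrix()].
#'
#' @inheritParams similarity_matrix
#' @param weights A `similarity_matrix` computed for this outcome.
#' @param stratum Stratum index.
#' @return Named numeric `c(shape1, shape2)`; both strictly positive.
#' @export
borrowed_posterior <- function(layout, responses, weights, stratum) {
  responses <- validate_outcome(layout, responses)
  stopifnot(inherits(weights, "similarity_matrix"),
            stratum >= 1, stratum <= layout$n_strata)
  w <- weights$weighted[as.integer(stratum), ]
  shape1 <- sum(w * (layout$prior_shape1 + responses))
  shape2 <- sum(w * (layout$prior_shape2 + layout$sample_sizes - responses))
  if (shape1 <= 0 || shape2 <= 0)
    stop("nonpositive borrowing posterior shape: broken weight convention")
  c(shape1 = shape1, shape2 = shape2)
}

#' Per-stratum test decision of the borrowing design
#'
#' Stratum i is detected as active when the borrowing posterior puts mass
#' at least \eqn{\lambda} above the target rate:
#' \eqn{P(p_i > p^*_i \mid r) \ge \lambda}, the upper tail of the borrowing
#' beta posterior at \eqn{p^*_i}.
#'
#' @inheritParams similarity_matrix
#' @return Logical vector, one detection flag per stratum.
#' @examples
#' lay <- basket_layout(rep(24, 3), 0.2)
#' decide(lay, c(10, 9, 2), tuning_params(0.99, 2, 0))
#' @export
decide <- function(layout, responses, phi, divergence = "jsd") {
  phi <- as_tuning(phi)
  responses <- validate_outcome(layout, responses)
  drop(decision_matrix(layout, matrix(responses, nrow = 1), phi, divergence))
}

#' Extreme borrowing boundary in the shape exponent
#'
#' Let \eqn{\tilde\omega^*} be the largest raw similarity attainable by two
#' strata with unequal responder counts, over all response pairs the layout
#' allows. For \eqn{\epsilon} above
#' \eqn{\epsilon_{extreme}(\tau) = \log(\tau) / \log(\tilde\omega^*)} the
#' thresholded weight matrix collapses to the equal-responses indicator:
#' strata borrow fully from strata with identical counts and not at all
#' otherwise, so raising \eqn{\epsilon} or \eqn{\tau} further cannot change
#' the design. The boundary is decreasing in \eqn{\tau}.
#'
#' @param layout A [basket_layout()].
#' @param tau Similarity cutoff strictly inside (0, 1).
#' @param divergence `"jsd"` or `"hellinger"`.
#' @return The boundary value \eqn{\epsilon_{extreme}(\tau)}.
#' @export
extreme_borrowing_boundary <- function(layout, tau, divergence = "jsd") {
  stopifnot(length(tau) == 1, tau > 0, tau < 1)
  log(tau) / log(max_unequal_similarity(layout, divergence))
}

# Largest raw similarity over all stratum pairs and response pairs with
# r_k != r_l.
max_unequal_similarity <- function(layout, divergence = "jsd") {
  I <- layout$n_strata
  stopifnot(I >= 2)
  tabs <- pairwise_tables(layout, divergence)
  best <- -Inf
  for (i in seq_len(I - 1)) {
    for (j in seq(i + 1, I)) {
      tab <- tabs[[i]][[j]]
      uneq <- outer(0:layout$sample_sizes[i], 0:layout$sample_sizes[j], "!=")
      best <- max(best, tab[uneq])
    }
  }
  best
}
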