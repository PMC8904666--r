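#' Quadrature grid over the latent trait
#'
#' Equally spaced nodes used for marginal integration over theta. The default
#' (61 nodes on [-6, 6]) is the package-wide working grid; oracle computations
#' in the test-suite use much denser grids.
#'
#' @param n Number of nodes.
#' @param from,to Grid end points (latent-trait units).
#' @return Numeric vector of strictly increasing nodes.
#' @export
quad_grid <- function(n = 61L, from = -6, to = 6) {
  stopifnot(n >= 2L, from < to)
  seq(from, to, length.out = n)
}

#' Latent-trait population density
#'
#' Either a normal density (the default assumption of the graded response
#' model) or an empirical set of normalized weights on a quadrature grid.
#' During fixed-parameter calibration the normal mean and sd are freed so the
#' target items land on the anchor metric.
#'
#' @param mean,sd Normal parameters (sd > 0).
#' @param weights Optional non-negative weights (one per grid node); when
#'   supplied the density is empirical and `mean`/`sd` are ignored.
#' @return An object of class `latent_density`.
#' @export
latent_density <- function(mean = 0, sd = 1, weights = NULL) {
  if (is.null(weights)) {
    if (!is.finite(mean) || !is.finite(sd) || sd <= 0)
      stop("latent density requires finite mean and positive sd")
    structure(list(type = "normal", mean = mean, sd = sd),
              class = "latent_density")
  } else {
    if (any(weights < 0) || sum(weights) <= 0)
      stop("empirical weights must be non-negative with positive sum")
    structure(list(type = "empirical", weights = weights / sum(weights)),
              class = "latent_density")
  }
}

# Normalized prior weights on a grid.
density_weights <- function(density, grid) {
  if (density$type == "empirical") {
    if (length(density$weights) != length(grid))
      stop("empirical weights do not match the grid")
    return(density$weights)
  }
  w <- stats::dnorm(grid, density$mean, density$sd)
  w / sum(w)
}

#' Graded-response-model category probabilities
#'
#' Boundary curves are two-parameter logistics \eqn{P^*_k(\theta) =
#' [1 + \exp(-a(\theta - b_k))]^{-1}} and the probability of category k is the
#' adjacent difference of boundaries. No 1.7 scaling constant is used; the
#' t-metric transform is invariant to this convention as long as simulation
#' and estimation share it.
#'
#' @param a Discrimination (> 0).
#' @param b Strictly increasing thresholds (length m - 1 for m categories).
#' @param theta Numeric vector of latent-trait values.
#' @return Matrix `length(theta)` x m of category probabilities (rows sum to 1).
#' @examples
#' grm_category_probs(1, 0, 0)          # 0.5 / 0.5
#' grm_category_probs(2, c(-1, 1), 0)   # 0.1192 / 0.7616 / 0.1192
#' @export
grm_category_probs <- function(a, b, theta) {
  if (a <= 0) stop("discrimination must be positive")
  if (length(b) > 1L && is.unsorted(b, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  bstar <- grm_boundaries(a, b, theta)           # n x (m-1)
  p <- cbind(1, bstar) - cbind(bstar, 0)
  rownames(p) <- NULL
  p
}

# P(X >= k | theta) for k = 1..m-1; n x (m-1) matrix.
grm_boundaries <- function(a, b, theta) {
  matrix(stats::plogis(a * (rep(theta, times = length(b)) -
                              rep(b, each = length(theta)))),
         nrow = length(theta))
}

# Category probability matrices for a list of item_params: list of (m_j x Q).
item_prob_list <- function(params, grid) {
  lapply(params, function(p) t(grm_category_probs(p$a, p$b, grid)))
}

#' Item and test information
#'
#' Fisher information of the graded response model,
#' \eqn{I_j(\theta) = \sum_k (P'_{k})^2 / P_k} with
#' \eqn{P'_k = P^{*\prime}_{k-1} - P^{*\prime}_k}; test information is the sum
#' over items.
#'
#' @param params List of [item_params()].
#' @param theta Numeric vector of trait values.
#' @return Numeric vector, one value per `theta`.
#' @export
test_information <- function(params, theta) {
  out <- numeric(length(theta))
  for (p in params) out <- out + item_information(p$a, p$b, theta)
  out
}

#' @rdname test_information
#' @param a,b Single-item parameters as in [grm_category_probs()].
#' @export
item_information <- function(a, b, theta) {
  bstar <- grm_boundaries(a, b, theta)
  dstar <- a * bstar * (1 - bstar)               # derivative of boundaries
  dP <- cbind(0, dstar) - cbind(dstar, 0)        # derivative per category
  P <- cbind(1, bstar) - cbind(bstar, 0)
  rowSums(dP^2 / pmax(P, 1e-300))
}

#' Test characteristic curve (expected raw score)
#'
#' Expected summed score \eqn{\sum_j E[X_j | \theta]} with item codes
#' `lowest_code + 0:(m-1)`. Strictly increasing in theta; used to map anchor
#' t-scores back to expected anchor raw scores.
#'
#' @inheritParams test_information
#' @param lowest_code Integer code of the lowest category (scalar, applied to
#'   every item).
#' @return Numeric vector of expected raw scores.
#' @export
tcc <- function(params, theta, lowest_code = 0L) {
  out <- numeric(length(theta))
  for (p in params) {
    m <- length(p$b) + 1L
    codes <- lowest_code + 0:(m - 1L)
    out <- out + drop(grm_category_probs(p$a, p$b, theta) %*% codes)
  }
  out
}

#' Summed-score likelihoods (Lord-Wingersky recursion)
#'
#' Distribution of the raw (total) score conditional on theta, built by the
#' Lord-Wingersky convolution over items. Row s of the result is
#' \eqn{P(\mathrm{raw} = s \mid \theta)} for every achievable raw score.
#'
#' @inheritParams tcc
#' @return Matrix with one row per achievable raw score (rownames are the raw
#'   scores) and one column per `theta` value; columns sum to 1.
#' @export
summed_score_likelihoods <- function(params, theta, lowest_code = 0L) {
  stopifnot(length(params) >= 1L)
  nq <- length(theta)
  min_raw <- length(params) * lowest_code
  f <- NULL  # rows: scores from current min; cols: theta
  lo <- 0L
  for (p in params) {
    m <- length(p$b) + 1L
    pr <- t(grm_category_probs(p$a, p$b, theta))   # m x nq
    if (is.null(f)) {
      f <- pr
      lo <- lowest_code
    } else {
      new_n <- nrow(f) + m - 1L
      g <- matrix(0, new_n, nq)
      for (k in seq_len(m)) {
        idx <- (k - 1L) + seq_len(nrow(f))
        g[idx, ] <- g[idx, ] + f * rep(pr[k, ], each = nrow(f))
      }
      f <- g
      lo <- lo + lowest_code
    }
  }
  rownames(f) <- seq(from = lo, length.out = nrow(f))
  f
}
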