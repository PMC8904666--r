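# Marginal maximum likelihood calibration of the graded response model, with
# optional fixed (anchor) items. Estimation is EM over a fixed quadrature
# grid: the E-step computes posterior node weights per respondent, the M-step
# maximizes each free item's expected complete-data log-likelihood (Newton
# via optim on a reparameterized scale that keeps thresholds ordered:
# b_k = b_1 + cumsum(exp(gamma))), and, when anchors are present, updates the
# free normal latent density from posterior moments.

# Build dense one-hot indicator matrices (n x m) per item; NA rows are all 0.
onehot_list <- function(cats, scales_items_m) {
  lapply(seq_along(scales_items_m), function(j) {
    m <- scales_items_m[j]
    x <- cats[, j]
    oh <- matrix(0, length(x), m)
    ok <- which(!is.na(x))
    oh[cbind(ok, x[ok])] <- 1
    oh
  })
}

# n x Q log-likelihood matrix of observed patterns at each node.
pattern_loglik_matrix <- function(onehots, probs) {
  n <- nrow(onehots[[1]]); Q <- ncol(probs[[1]])
  ll <- matrix(0, n, Q)
  for (j in seq_along(onehots)) {
    ll <- ll + onehots[[j]] %*% log(pmax(probs[[j]], 1e-300))
  }
  ll
}

#' Marginal log-likelihood of a response matrix
#'
#' Log of the pattern likelihood integrated over the latent density on the
#' quadrature grid, summed over respondents. Missing responses are skipped;
#' a respondent with no observed items contributes zero (with a message).
#'
#' @param responses Data frame containing the scales' item columns (integer
#'   codes, `NA` = missing).
#' @param scales A [scale_def()] or list of them.
#' @param params List of [item_params()] covering all items of `scales`.
#' @param density A [latent_density()].
#' @param grid Quadrature nodes from [quad_grid()].
#' @return A single finite number.
#' @export
grm_loglikelihood <- function(responses, scales, params,
                              density = latent_density(),
                              grid = quad_grid()) {
  sc <- if (inherits(scales, "scale_def")) list(scales) else scales
  cats <- do.call(cbind, lapply(sc, codes_to_cats, responses = responses))
  items <- unlist(lapply(sc, `[[`, "items"))
  mvec <- unlist(lapply(sc, `[[`, "n_categories"))
  ids <- vapply(params, `[[`, character(1), "item")
  params <- params[match(items, ids)]
  if (anyNA(match(items, ids))) stop("parameters missing for some items")
  empty <- rowSums(!is.na(cats)) == 0L
  if (any(empty)) {
    message(sum(empty), " respondent(s) with no observed items contribute no terms")
    cats <- cats[!empty, , drop = FALSE]
  }
  w <- density_weights(density, grid)
  probs <- item_prob_list(params, grid)
  oh <- onehot_list(cats, mvec)
  ll <- pattern_loglik_matrix(oh, probs)
  a <- apply(ll, 1, max)
  sum(a + log(drop(exp(ll - a) %*% w)))
}

# Transform item_params <-> unconstrained vector (log a, b1, log diffs).
par_to_vec <- function(p) {
  d <- diff(p$b)
  c(log(p$a), p$b[1], if (length(d)) log(pmax(d, 1e-6)))
}
vec_to_par <- function(v, item) {
  a <- exp(min(v[1], 3)); b1 <- v[2]
  b <- b1
  if (length(v) > 2) b <- b1 + c(0, cumsum(pmax(exp(v[-(1:2)]), 1e-6)))
  # repair floating-point ties from extreme transient iterates
  for (k in seq_along(b)[-1]) if (b[k] <= b[k - 1]) b[k] <- b[k - 1] + 1e-6
  item_params(item, a, b)
}

# Expected complete-data negative log-likelihood for one item. Computes
# probabilities directly (no validation) so that transient line-search
# iterates with saturated thresholds do not abort.
item_obj <- function(v, item, r, grid) {
  a <- exp(min(v[1], 3))
  b <- v[2]
  if (length(v) > 2) b <- b + c(0, cumsum(pmax(exp(v[-(1:2)]), 1e-6)))
  bstar <- grm_boundaries(a, b, grid)
  pr <- t(cbind(1, bstar) - cbind(bstar, 0))    # m x Q
  -sum(r * log(pmax(pr, 1e-300)))
}

# Start values: a = 1; thresholds from inverse-logistic cumulative proportions.
start_values <- function(cats, mvec, items) {
  lapply(seq_along(items), function(j) {
    x <- cats[, j]
    m <- mvec[j]
    tab <- tabulate(x[!is.na(x)], nbins = m) + 0.5   # smoothed counts
    pge <- rev(cumsum(rev(tab)))[-1] / sum(tab)      # P(X >= k), k = 2..m
    b <- -stats::qlogis(pmin(pmax(pge, 1e-3), 1 - 1e-3))
    # enforce strict increase
    for (k in seq_along(b)[-1]) if (b[k] <= b[k - 1]) b[k] <- b[k - 1] + 0.05
    item_params(items[j], 1, b)
  })
}

# Merge empty categories into their lower neighbour (first category merges
# upward). Returns recoded categories, new m, and the recode map.
collapse_empty <- function(x, m) {
  counts <- tabulate(x[!is.na(x)], nbins = m)
  if (all(counts > 0)) return(list(x = x, m = m, map = NULL))
  keep <- which(counts > 0)
  if (length(keep) < 2L) stop("item has fewer than 2 observed categories")
  # each original category maps to the nearest kept category at or below it,
  # or the lowest kept category.
  map <- integer(m)
  for (k in seq_len(m)) {
    lower <- keep[keep <= k]
    map[k] <- if (length(lower)) max(lower) else min(keep)
  }
  map <- match(map, keep)  # re-index 1..m'
  list(x = map[x], m = length(keep), map = map)
}

#' Calibrate graded-response-model items, optionally with fixed anchors
#'
#' EM marginal maximum likelihood. With no fixed items the latent density is
#' pinned to N(0, 1) for identification. With fixed (anchor) items the normal
#' latent mean and sd are freed, which places the freely estimated (target)
#' item parameters on the anchor metric - the fixed-parameter calibration
#' step of the linking pipeline.
#'
#' @inheritParams grm_loglikelihood
#' @param fixed Optional list of [item_params()] to hold fixed (anchor items).
#' @param control List: `tol` (max absolute parameter change, default 1e-4),
#'   `max_cycles` (default 500), `strict` (logical; when `TRUE`, empty
#'   response categories abort instead of being collapsed into a neighbour).
#' @return Object of class `grm_calibration`: `params` (all items, fixed ones
#'   echoed unchanged), `free` (ids of estimated items), `density`
#'   ([latent_density()]), `loglik` (trace), `converged`, `cycles`,
#'   `collapsed` (recode maps for any collapsed items).
#' @export
grm_calibrate <- function(responses, scales, fixed = NULL,
                          grid = quad_grid(), control = list()) {
  ctl <- utils::modifyList(list(tol = 1e-4, max_cycles = 500L, strict = FALSE),
                           control)
  sc <- if (inherits(scales, "scale_def")) list(scales) else scales
  items <- unlist(lapply(sc, `[[`, "items"))
  mvec <- unlist(lapply(sc, `[[`, "n_categories"))
  cats <- do.call(cbind, lapply(sc, codes_to_cats, responses = responses))
  keep <- rowSums(!is.na(cats)) > 0L
  cats <- cats[keep, , drop = FALSE]
  n <- nrow(cats)
  if (n < 2L) stop("too few respondents with data to calibrate")

  fixed_ids <- vapply(fixed %||% list(), `[[`, character(1), "item")
  free_idx <- which(!(items %in% fixed_ids))
  free_ids <- items[free_idx]

  # empty-category handling for free items only
  collapsed <- list()
  for (j in free_idx) {
    cc <- collapse_empty(cats[, j], mvec[j])
    if (!is.null(cc$map)) {
      if (ctl$strict)
        stop("empty response category for item '", items[j],
             "' (strict mode); observed categories: ",
             paste(sort(unique(stats::na.omit(cats[, j]))), collapse = ", "))
      warning("collapsing empty categories for item '", items[j], "'")
      collapsed[[items[j]]] <- cc$map
      cats[, j] <- cc$x
      mvec[j] <- cc$m
    }
  }

  params <- start_values(cats, mvec, items)
  if (length(fixed_ids)) {
    fx <- match(items[items %in% fixed_ids], fixed_ids)
    params[items %in% fixed_ids] <- fixed[fx]
    params <- lapply(seq_along(params), function(j) {
      p <- params[[j]]
      if (length(p$b) + 1L != mvec[j])
        stop("fixed parameters for item '", items[j],
             "' do not match its category count")
      p
    })
  }
  free_density <- length(fixed_ids) > 0L
  dens <- latent_density(0, 1)
  oh <- onehot_list(cats, mvec)
  Q <- length(grid)
  ll_trace <- numeric(0)
  vecs <- lapply(params, par_to_vec)
  converged <- FALSE

  for (cycle in seq_len(ctl$max_cycles)) {
    w <- density_weights(dens, grid)
    probs <- item_prob_list(params, grid)
    ll <- pattern_loglik_matrix(oh, probs)
    lmax <- apply(ll, 1, max)
    lik <- exp(ll - lmax)                       # n x Q
    post <- lik * rep(w, each = n)
    marg <- rowSums(post)
    ll_trace <- c(ll_trace, sum(lmax + log(marg)))
    post <- post / marg                          # posterior node weights

    delta <- 0
    if (free_density) {
      mu <- sum(post %*% grid) / n
      sigma2 <- sum(post %*% outer(grid, mu, "-")^2) / n
      delta <- max(delta, abs(mu - dens$mean), abs(sqrt(sigma2) - dens$sd))
      dens <- latent_density(mu, sqrt(sigma2))
    }
    for (j in free_idx) {
      r <- crossprod(oh[[j]], post)              # m x Q expected counts
      opt <- stats::optim(vecs[[j]], item_obj, item = items[j], r = r,
                          grid = grid, method = "BFGS",
                          control = list(maxit = 50, reltol = 1e-10))
      newp <- vec_to_par(opt$par, items[j])
      delta <- max(delta, abs(newp$a - params[[j]]$a),
                   max(abs(newp$b - params[[j]]$b)))
      params[[j]] <- newp
      vecs[[j]] <- opt$par
    }
    if (delta < ctl$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not reach tol = ", ctl$tol, " within ",
            ctl$max_cycles, " cycles (last max change ", signif(delta, 3), ")")
  structure(
    list(params = stats::setNames(params, items), free = free_ids,
         density = dens, loglik = ll_trace, converged = converged,
         cycles = length(ll_trace), collapsed = collapsed),
    class = "grm_calibration"
  )
}

#' @export
print.grm_calibration <- function(x, ...) {
  cat(sprintf("<grm_calibration> %d item(s) (%d free), %d EM cycle(s), %s\n",
              length(x$params), length(x$free), x$cycles,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  latent density: N(%.3f, %.3f^2)\n", x$density$mean, x$density$sd))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' EAP trait estimate for one response pattern
#'
#' Posterior mean and SD of theta given an observed pattern, integrating the
#' likelihood against the latent density on the grid. Missing items are
#' omitted from the likelihood.
#'
#' @param pattern Named numeric vector of item codes (names = item ids;
#'   `NA` = missing), or codes aligned with `params`.
#' @param params List of [item_params()].
#' @param density A [latent_density()] prior.
#' @param grid Quadrature nodes.
#' @param lowest_code Integer code of the lowest category.
#' @return Named vector `c(theta, se)`.
#' @export
eap_theta <- function(pattern, params, density = latent_density(),
                      grid = quad_grid(), lowest_code = 0L) {
  ids <- vapply(params, `[[`, character(1), "item")
  if (!is.null(names(pattern))) pattern <- pattern[ids]
  cats <- as.numeric(pattern) - lowest_code + 1
  if (all(is.na(cats))) stop("all responses missing: no information for EAP")
  w <- density_weights(density, grid)
  loglik <- numeric(length(grid))
  for (j in seq_along(params)) {
    if (is.na(cats[j])) next
    pr <- grm_category_probs(params[[j]]$a, params[[j]]$b, grid)
    loglik <- loglik + log(pmax(pr[, cats[j]], 1e-300))
  }
  post <- w * exp(loglik - max(loglik))
  post <- post / sum(post)
  mu <- sum(post * grid)
  se <- sqrt(max(sum(post * (grid - mu)^2), 0))
  c(theta = mu, se = se)
}

#' Score all respondents by pattern-level EAP
#'
#' @param responses Data frame with an `id` column (optional) and the scale's
#'   item columns.
#' @param scale A [scale_def()].
#' @inheritParams eap_theta
#' @return Data frame `id, theta, se, t, se_t` (t = 50 + 10 theta).
#'   Respondents with no observed items are dropped with a warning.
#' @export
score_respondents <- function(responses, scale, params,
                              density = latent_density(), grid = quad_grid()) {
  params <- params_for_scale(params, scale)
  cats <- codes_to_cats(responses, scale)
  ids <- if ("id" %in% names(responses)) responses$id else seq_len(nrow(cats))
  ok <- rowSums(!is.na(cats)) > 0L
  if (any(!ok)) warning(sum(!ok), " respondent(s) with all items missing dropped")
  cats <- cats[ok, , drop = FALSE]
  w <- density_weights(density, grid)
  probs <- item_prob_list(params, grid)
  oh <- onehot_list(cats, scale$n_categories)
  ll <- pattern_loglik_matrix(oh, probs)
  post <- exp(ll - apply(ll, 1, max)) * rep(w, each = nrow(cats))
  post <- post / rowSums(post)
  theta <- drop(post %*% grid)
  se <- sqrt(pmax(drop(post %*% grid^2) - theta^2, 0))
  data.frame(id = ids[ok], theta = theta, se = se,
             t = 50 + 10 * theta, se_t = 10 * se)
}

#' Summed-score EAP conversion table
#'
#' For every achievable raw score s, the posterior mean and SD of theta given
#' raw = s (Bayes over the grid using the Lord-Wingersky likelihoods), plus
#' the t-metric transform t = 50 + 10 theta. This is the engine behind the
#' raw-score to t-score columns of a crosswalk.
#'
#' @inheritParams eap_theta
#' @return Data frame `raw, theta, se, t, se_t, prob` (marginal probability
#'   of each raw score). Rows whose marginal probability underflows are
#'   flagged in the logical `flagged` column.
#' @export
summed_score_eap <- function(params, density = latent_density(),
                             grid = quad_grid(), lowest_code = 0L) {
  w <- density_weights(density, grid)
  L <- summed_score_likelihoods(params, grid, lowest_code)  # S x Q
  joint <- L * rep(w, each = nrow(L))
  ps <- rowSums(joint)
  flagged <- ps < 1e-12
  if (any(flagged))
    warning(sum(flagged), " raw score(s) have vanishing marginal probability")
  psafe <- pmax(ps, 1e-300)
  theta <- drop(joint %*% grid) / psafe
  se <- sqrt(pmax(drop(joint %*% grid^2) / psafe - theta^2, 0))
  data.frame(raw = as.integer(rownames(L)), theta = theta, se = se,
             t = 50 + 10 * theta, se_t = 10 * se, prob = ps,
             flagged = flagged)
}
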