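# Linking accuracy by k-fold cross-validation, the quantitative linking
# assumption checks (inter-scale correlation and a polychoric-eigenvalue
# unidimensionality screen), conditional reliability, and subgroup
# invariance of crosswalks.

#' K-fold cross-validated linking accuracy
#'
#' Respondents (after the <=1-missing inclusion rule) are split into k seeded
#' folds, stratified on target raw-score quintiles. For each fold the
#' crosswalk is rebuilt on the remaining folds; held-out respondents'
#' predicted t-scores (crosswalk at their target raw score) are pooled
#' against their actual t-scores (EAP from their anchor responses under the
#' fixed anchor parameters) and the correlation, mean difference
#' (predicted - actual) and SD of the difference are computed on the pool.
#'
#' @param iset An [item_set()].
#' @param k Number of folds (>= 2; k = n gives leave-one-out).
#' @param method `"irt"` or `"equipercentile"`.
#' @param seed Integer seed for the fold split.
#' @param grid Quadrature nodes.
#' @param control Passed to [grm_calibrate()] for IRT folds.
#' @param actual `"pattern"` (pattern-level EAP on anchor items, the stricter
#'   comparator and the default) or `"summed"` (summed-score EAP at the
#'   prorated anchor raw total).
#' @return Object of class `linking_accuracy`: `r`, `mean_diff`, `sd_diff`,
#'   `n`, `method`, plus the pooled predictions.
#' @export
kfold_cv <- function(iset, k = 5L, method = c("irt", "equipercentile"),
                     seed = 1L, grid = quad_grid(), control = list(),
                     actual = c("pattern", "summed")) {
  method <- match.arg(method); actual <- match.arg(actual)
  stopifnot(k >= 2L)
  flt <- filter_missingness(iset$responses,
                            list(iset$target, iset$anchor))
  resp <- flt$responses
  n <- nrow(resp)
  if (k > n) stop("k exceeds the number of retained respondents")
  t_raw <- flt$totals[[iset$target$name]]
  a_raw <- flt$totals[[iset$anchor$name]]

  # actual anchor t-scores under the fixed anchor parameters
  if (actual == "pattern") {
    sc <- score_respondents(resp, iset$anchor, iset$anchor_params,
                            latent_density(0, 1), grid)
    actual_t <- sc$t
  } else {
    tab <- summed_score_eap(iset$anchor_params, latent_density(0, 1), grid,
                            iset$anchor$lowest_code)
    actual_t <- tab$t[match(a_raw, tab$raw)]
  }

  # anchor raw->t table for the equipercentile t lookup
  anchor_tab <- summed_score_eap(iset$anchor_params, latent_density(0, 1),
                                 grid, iset$anchor$lowest_code)

  folds <- stratified_folds(t_raw, k, seed)
  pred_t <- rep(NA_real_, n)
  dropped <- integer(0)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- folds == f
    if (!any(te)) next
    xw <- tryCatch({
      if (method == "irt") {
        iset_f <- item_set(iset$target, iset$anchor,
                           resp[tr, , drop = FALSE], iset$anchor_params,
                           target_params = iset$target_params,
                           anchor_metric = iset$anchor_metric)
        irt_link(iset_f, grid = grid, control = control)
      } else {
        equipercentile_link(t_raw[tr], a_raw[tr], anchor_tab,
                            target_range = c(iset$target$min_raw,
                                             iset$target$max_raw),
                            anchor_range = c(iset$anchor$min_raw,
                                             iset$anchor$max_raw),
                            target = iset$target$name,
                            anchor = iset$anchor$name,
                            anchor_metric = iset$anchor_metric)
      }
    }, error = function(e) e)
    if (inherits(xw, "error")) {
      warning("fold ", f, " dropped: ", conditionMessage(xw))
      dropped <- c(dropped, f)
      next
    }
    pred_t[te] <- xw$t[match(t_raw[te], xw$raw)]
  }
  ok <- !is.na(pred_t)
  d <- pred_t[ok] - actual_t[ok]
  structure(list(r = stats::cor(pred_t[ok], actual_t[ok]),
                 mean_diff = mean(d), sd_diff = stats::sd(d), n = sum(ok),
                 method = method, k = k, dropped_folds = dropped,
                 predicted = pred_t[ok], actual = actual_t[ok]),
            class = "linking_accuracy")
}

#' @export
print.linking_accuracy <- function(x, ...) {
  cat(sprintf("<linking_accuracy> %s, %d-fold: r = %.3f, mean diff = %.3f, SD diff = %.3f (n = %d)\n",
              x$method, x$k, x$r, x$mean_diff, x$sd_diff, x$n))
  invisible(x)
}

# Seeded fold assignment stratified on raw-score quintiles.
stratified_folds <- function(raw, k, seed) {
  qs <- stats::quantile(raw, probs = seq(0, 1, 0.2), type = 1)
  strata <- cut(raw, breaks = unique(qs), include.lowest = TRUE,
                labels = FALSE)
  folds <- integer(length(raw))
  withr_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Select the better linking method by triple dominance
#'
#' The winning method must have the highest correlation, the lowest absolute
#' mean difference, and the lowest SD of difference, for every item set. If
#' no method dominates, the status is `"indeterminate"` and a ranked report
#' is returned instead of a winner.
#'
#' @param accuracies Data frame with columns `method`, `item_set`, `r`,
#'   `mean_diff`, `sd_diff` (one row per method x item set).
#' @return List: `method` (winner or `NA`), `status` (`"dominant"`,
#'   `"uncontested"`, or `"indeterminate"`), `table` (ranked summary).
#' @export
select_method <- function(accuracies) {
  stopifnot(all(c("method", "item_set", "r", "mean_diff", "sd_diff") %in%
                  names(accuracies)))
  methods <- unique(accuracies$method)
  summ <- do.call(rbind, lapply(methods, function(m) {
    a <- accuracies[accuracies$method == m, ]
    data.frame(method = m, mean_r = mean(a$r),
               mean_abs_diff = mean(abs(a$mean_diff)),
               mean_sd_diff = mean(a$sd_diff))
  }))
  summ <- summ[order(-summ$mean_r, summ$mean_abs_diff, summ$mean_sd_diff), ]
  if (length(methods) == 1L)
    return(list(method = methods, status = "uncontested", table = summ))
  dominates <- function(m1, m2) {
    a1 <- accuracies[accuracies$method == m1, ]
    a2 <- accuracies[accuracies$method == m2, ]
    a2 <- a2[match(a1$item_set, a2$item_set), ]
    all(a1$r >= a2$r & abs(a1$mean_diff) <= abs(a2$mean_diff) &
          a1$sd_diff <= a2$sd_diff) &&
      any(a1$r > a2$r | abs(a1$mean_diff) < abs(a2$mean_diff) |
            a1$sd_diff < a2$sd_diff)
  }
  for (m in methods) {
    if (all(vapply(setdiff(methods, m), function(o) dominates(m, o),
                   logical(1))))
      return(list(method = m, status = "dominant", table = summ))
  }
  list(method = NA_character_, status = "indeterminate", table = summ)
}

#' Quantitative linking-assumption checks
#'
#' Inter-scale Pearson correlation of (prorated) raw totals, and a
#' unidimensionality screen on the pooled target + anchor items: the ratio
#' of the first to second eigenvalue of the polychoric correlation matrix.
#'
#' @param iset An [item_set()].
#' @param r_threshold Pass threshold for the inter-scale correlation
#'   (default 0.75).
#' @param ratio_threshold Pass threshold for the eigenvalue ratio (default 3).
#' @return Object of class `assumption_report`: `pearson_r`, `eigenvalues`,
#'   `eigen_ratio`, `prop_first`, and logical flags `pass_r`, `pass_unidim`.
#' @export
assumption_check <- function(iset, r_threshold = 0.75, ratio_threshold = 3) {
  flt <- filter_missingness(iset$responses, list(iset$target, iset$anchor))
  r <- stats::cor(flt$totals[[iset$target$name]],
                  flt$totals[[iset$anchor$name]])
  items <- unique(c(iset$target$items, iset$anchor$items))
  R <- polychoric_matrix(flt$responses[, items, drop = FALSE])
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ratio <- ev[1] / ev[2]
  structure(list(pearson_r = r, eigenvalues = ev, eigen_ratio = ratio,
                 prop_first = ev[1] / sum(ev),
                 r_threshold = r_threshold,
                 ratio_threshold = ratio_threshold,
                 pass_r = r >= r_threshold,
                 pass_unidim = ratio >= ratio_threshold),
            class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("<assumption_report> inter-scale r = %.3f (>= %.2f: %s); eigen ratio = %.2f (>= %.1f: %s)\n",
              x$pearson_r, x$r_threshold, if (x$pass_r) "pass" else "FAIL",
              x$eigen_ratio, x$ratio_threshold,
              if (x$pass_unidim) "pass" else "FAIL"))
  invisible(x)
}

# Vectorized bivariate normal CDF via Gauss-Legendre integration of
# phi(x) * Phi((b - rho x)/sqrt(1-rho^2)) over (-8, a].
bvn_cdf <- function(a, b, rho, gl = gauss_legendre(48)) {
  s <- sqrt(max(1 - rho^2, 1e-12))
  a <- pmin(pmax(a, -8), 8); b <- pmin(pmax(b, -8), 8)
  lo <- -8
  half <- (a - lo) / 2; mid <- (a + lo) / 2
  # nodes: length(a) x ngl
  x <- outer(half, gl$nodes) + mid
  f <- stats::dnorm(x) * stats::pnorm((b - rho * x) / s)
  drop(f %*% gl$weights) * half
}

gauss_legendre <- function(n) {
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix on [-1, 1]
  i <- seq_len(n - 1)
  bb <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- bb; J[cbind(i + 1, i)] <- bb
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1, idx]^2)
}

#' Two-step maximum likelihood polychoric correlation
#'
#' Thresholds are fixed at the inverse-normal transforms of the univariate
#' cumulative margins; the correlation maximizes the bivariate-normal
#' contingency-table likelihood.
#'
#' @param x,y Integer ordinal vectors (pairwise-complete cases are used).
#' @return The estimated correlation, or `NA` if either margin is constant.
#' @export
polychoric_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(x, y)
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  tx <- stats::qnorm(cumsum(rowSums(tab))[-nrow(tab)] / sum(tab))
  ty <- stats::qnorm(cumsum(colSums(tab))[-ncol(tab)] / sum(tab))
  ax <- c(-Inf, tx, Inf); ay <- c(-Inf, ty, Inf)
  gl <- gauss_legendre(48)
  # grid of upper-corner CDF values at all threshold pairs
  nr <- nrow(tab); nc <- ncol(tab)
  negll <- function(rho) {
    cd <- matrix(0, nr + 1L, nc + 1L)
    cd[nr + 1L, ] <- stats::pnorm(pmin(pmax(ay, -8), 8))
    cd[, nc + 1L] <- stats::pnorm(pmin(pmax(ax, -8), 8))
    cd[nr + 1L, nc + 1L] <- 1
    inner <- expand.grid(i = seq_len(nr - 1L) + 1L, j = seq_len(nc - 1L) + 1L)
    cd[cbind(inner$i, inner$j)] <-
      bvn_cdf(ax[inner$i], ay[inner$j], rho, gl)
    cd[1, ] <- 0; cd[, 1] <- 0
    pr <- cd[-1, -1] - cd[-(nr + 1L), -1] - cd[-1, -(nc + 1L)] +
      cd[-(nr + 1L), -(nc + 1L)]
    -sum(tab * log(pmax(pr, 1e-300)))
  }
  stats::optimize(negll, c(-0.999, 0.999))$minimum
}

#' Polychoric correlation matrix
#'
#' @param responses Data frame of ordinal item columns.
#' @return Symmetric correlation matrix; pairs whose polychoric estimate
#'   fails (constant margins) are dropped to 0 with a warning.
#' @export
polychoric_matrix <- function(responses) {
  p <- ncol(responses)
  R <- diag(p)
  dimnames(R) <- list(names(responses), names(responses))
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    r <- polychoric_corr(responses[[i]], responses[[j]])
    if (is.na(r)) {
      warning("polychoric failed for pair (", names(responses)[i], ", ",
              names(responses)[j], "); set to 0")
      r <- 0
    }
    R[i, j] <- R[j, i] <- r
  }
  R
}

#' Conditional reliability across the anchor t-metric
#'
#' Reliability at trait level theta = (t - 50)/10 is 1 - 1/I(theta) (one
#' minus the squared standard error against unit population variance),
#' floored at 0. Conventional adequacy thresholds are 0.70 for group-level
#' and 0.90 for individual-level assessment.
#'
#' @param params List of [item_params()] on the anchor metric.
#' @param t_grid Grid of t-scores (default 20 to 80 by 0.5).
#' @param scale_name Label recorded on the curve.
#' @return Object of class `reliability_curve`: data frame `t, reliability`.
#' @export
reliability_curve <- function(params, t_grid = seq(20, 80, by = 0.5),
                              scale_name = "scale") {
  theta <- (t_grid - 50) / 10
  info <- test_information(params, theta)
  rel <- pmax(1 - 1 / info, 0)
  structure(data.frame(t = t_grid, reliability = rel),
            scale_name = scale_name,
            class = c("reliability_curve", "data.frame"))
}

#' T-score intervals of adequate reliability
#'
#' @param curve A [reliability_curve()].
#' @param threshold Reliability threshold in (0, 1).
#' @return Data frame `t_min, t_max`, one row per maximal interval on the
#'   grid where reliability >= threshold (possibly zero rows).
#' @export
reliable_range <- function(curve, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  ok <- curve$reliability >= threshold
  if (!any(ok)) return(data.frame(t_min = numeric(0), t_max = numeric(0)))
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(t_min = curve$t[starts[keep]], t_max = curve$t[ends[keep]])
}

#' Subgroup invariance of a crosswalk
#'
#' Runs the full linking separately in each subgroup and compares the
#' resulting t columns row by row. Under a correctly specified model the
#' crosswalk is a population-invariant property of the item parameters, so
#' even subgroups with shifted trait means should agree; a max |delta t|
#' above `margin` flags non-invariance.
#'
#' @param iset An [item_set()] whose responses carry a binary `subgroup`
#'   column.
#' @param method `"irt"` or `"equipercentile"`.
#' @param floor Minimum respondents per subgroup (default 100).
#' @param margin Flag threshold on max |delta t| (default 3 t-units).
#' @param grid Quadrature nodes.
#' @param control Passed to [grm_calibrate()].
#' @return List: per-group crosswalks, `delta_t` per raw score, `max_abs_dt`,
#'   `mean_abs_dt`, `flag`.
#' @export
subgroup_invariance <- function(iset, method = c("irt", "equipercentile"),
                                floor = 100L, margin = 3,
                                grid = quad_grid(), control = list()) {
  method <- match.arg(method)
  if (!"subgroup" %in% names(iset$responses))
    stop("responses have no 'subgroup' column")
  groups <- sort(unique(iset$responses$subgroup))
  if (length(groups) != 2L) stop("subgroup must be binary")
  sizes <- table(iset$responses$subgroup)
  if (any(sizes < floor))
    stop("subgroup(s) below the size floor of ", floor, ": ",
         paste(names(sizes)[sizes < floor], collapse = ", "))
  xws <- lapply(groups, function(g) {
    sub <- iset$responses[iset$responses$subgroup == g, , drop = FALSE]
    is_g <- item_set(iset$target, iset$anchor, sub, iset$anchor_params,
                     anchor_metric = iset$anchor_metric)
    if (method == "irt") {
      irt_link(is_g, grid = grid, control = control)
    } else {
      flt <- filter_missingness(sub, list(iset$target, iset$anchor))
      tab <- summed_score_eap(iset$anchor_params, latent_density(0, 1),
                              grid, iset$anchor$lowest_code)
      equipercentile_link(flt$totals[[iset$target$name]],
                          flt$totals[[iset$anchor$name]], tab,
                          target_range = c(iset$target$min_raw,
                                           iset$target$max_raw),
                          anchor_range = c(iset$anchor$min_raw,
                                           iset$anchor$max_raw),
                          target = iset$target$name, anchor = iset$anchor$name,
                          anchor_metric = iset$anchor_metric)
    }
  })
  dt <- xws[[2]]$t - xws[[1]]$t
  list(crosswalks = stats::setNames(xws, paste0("group", groups)),
       delta_t = data.frame(raw = xws[[1]]$raw, delta_t = dt),
       max_abs_dt = max(abs(dt)), mean_abs_dt = mean(abs(dt)),
       margin = margin, flag = max(abs(dt)) > margin)
}
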