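# Crosswalk construction: fixed-calibration IRT linking and equipercentile
# equating, plus the cut-point and group-rate tools built on crosswalks.

#' Bundle a target scale, an anchor scale, and their shared responses
#'
#' The single-group linking design: both scales answered by the same
#' respondents. Item sets must be disjoint unless the target *is* the anchor
#' (a self item set, useful as a null check).
#'
#' @param target,anchor [scale_def()] objects.
#' @param responses Data frame holding both scales' item columns (plus
#'   optional `id` and `subgroup` columns).
#' @param anchor_params List of [item_params()] for the anchor items (the
#'   fixed calibration); mandatory.
#' @param target_params Optional known target parameters (skip calibration).
#' @param anchor_metric Label of the metric the anchor parameters define;
#'   recorded in crosswalk provenance so cross-metric comparisons can be
#'   refused. Defaults to the anchor scale name.
#' @return Object of class `item_set`.
#' @export
item_set <- function(target, anchor, responses, anchor_params,
                     target_params = NULL, anchor_metric = anchor$name) {
  stopifnot(inherits(target, "scale_def"), inherits(anchor, "scale_def"))
  self <- identical(target$items, anchor$items)
  if (!self && length(intersect(target$items, anchor$items)))
    stop("target and anchor item sets must be disjoint")
  miss <- setdiff(unique(c(target$items, anchor$items)), names(responses))
  if (length(miss))
    stop("responses lack item column(s): ", paste(miss, collapse = ", "))
  anchor_params <- params_for_scale(anchor_params, anchor)
  if (!is.null(target_params))
    target_params <- params_for_scale(target_params, target)
  structure(list(target = target, anchor = anchor, responses = responses,
                 anchor_params = anchor_params, target_params = target_params,
                 anchor_metric = anchor_metric, self = self),
            class = "item_set")
}

new_crosswalk <- function(df, method, target, anchor, anchor_metric,
                          extra = list()) {
  stopifnot(all(c("raw", "t", "se_t", "anchor_raw") %in% names(df)))
  if (is.unsorted(df$t)) stop("crosswalk t column must be non-decreasing")
  structure(df[c("raw", "t", "se_t", "anchor_raw")],
            method = method, target = target, anchor = anchor,
            anchor_metric = anchor_metric, extra = extra,
            class = c("crosswalk", "data.frame"))
}

#' @export
print.crosswalk <- function(x, ...) {
  cat(sprintf("<crosswalk> %s -> %s [%s linking, metric: %s]\n",
              attr(x, "target"), attr(x, "anchor"), attr(x, "method"),
              attr(x, "anchor_metric")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' IRT fixed-calibration linking
#'
#' Calibrates the target items with the anchor parameters held fixed (latent
#' mean/sd freed), converts target raw scores to t-scores by summed-score
#' EAP, and maps each t-score to an expected anchor raw score through the
#' anchor test characteristic curve.
#'
#' @param iset An [item_set()].
#' @param grid Quadrature nodes.
#' @param prior `"standard"` (N(0,1) on the anchor metric, the default used
#'   for conversion tables) or `"estimated"` (the latent density recovered in
#'   fixed calibration).
#' @param control Passed to [grm_calibrate()].
#' @return A `crosswalk`: one row per achievable target raw score with
#'   `t`, `se_t`, and `anchor_raw` (expected anchor raw score).
#' @export
irt_link <- function(iset, grid = quad_grid(), prior = c("standard", "estimated"),
                     control = list()) {
  stopifnot(inherits(iset, "item_set"))
  prior <- match.arg(prior)
  flagged <- character(0)
  if (iset$self) {
    tpar <- iset$anchor_params
    dens <- latent_density(0, 1)
  } else if (!is.null(iset$target_params)) {
    tpar <- iset$target_params
    dens <- latent_density(0, 1)
  } else {
    cal <- grm_calibrate(iset$responses, list(iset$anchor, iset$target),
                         fixed = iset$anchor_params, grid = grid,
                         control = control)
    if (!cal$converged) flagged <- "calibration did not converge"
    tpar <- cal$params[iset$target$items]
    dens <- cal$density
  }
  tab <- summed_score_eap(tpar,
                          density = if (prior == "standard")
                            latent_density(0, 1) else dens,
                          grid = grid, lowest_code = iset$target$lowest_code)
  tab$anchor_raw <- tcc(iset$anchor_params, tab$theta,
                        lowest_code = iset$anchor$lowest_code)
  new_crosswalk(tab, "irt", iset$target$name, iset$anchor$name,
                iset$anchor_metric,
                extra = list(prior = prior, density = dens, flagged = flagged,
                             target_params = tpar))
}

# --- equipercentile machinery (Kolen-Brennan mid-point continuization) ------

# Percentile ranks (0-100) of the integer scores in `support` given counts.
percentile_ranks <- function(counts) {
  p <- counts / sum(counts)
  FF <- cumsum(p)
  100 * (c(0, FF[-length(FF)]) + p / 2)
}

# Inverse of the continuized CDF of Y at probability pr (0-1): the K-B
# upper-score formula, with flat (zero-frequency) segments resolved at their
# midpoint.
inv_continuized <- function(pr, support, counts) {
  p <- counts / sum(counts)
  FF <- cumsum(p)
  Flo <- c(0, FF[-length(FF)])
  sapply(pr, function(q) {
    if (q <= 0) return(support[1] - 0.5)
    if (q >= 1) return(support[length(support)] + 0.5)
    u <- which(FF > q)[1]
    if (is.na(u)) return(support[length(support)] + 0.5)
    l <- which(FF >= q)[1]
    if (l < u && FF[l] == q) {
      # continuized CDF is flat at level q between score intervals l and u:
      # take the midpoint of the flat stretch
      return(((support[l] + 0.5) + (support[u] - 0.5)) / 2)
    }
    support[u] - 0.5 + (q - Flo[u]) / p[u]
  })
}

# Optional log-linear presmoothing of a frequency distribution.
loglinear_smooth <- function(support, counts, degree) {
  df <- data.frame(y = counts, s = support)
  X <- stats::poly(df$s, degree = degree, raw = TRUE)
  fit <- stats::glm(y ~ X, family = stats::poisson(), data = df)
  stats::fitted(fit)
}

#' Equipercentile linking
#'
#' Links target raw scores to the anchor raw metric by matching mid-point
#' continuized percentile ranks (Kolen-Brennan), then attaches anchor-metric
#' t-scores by linear interpolation in an anchor raw-to-t table.
#'
#' @param target_raw,anchor_raw Paired integer raw scores from the same
#'   respondents (those passing the missingness rule).
#' @param anchor_table Data frame `raw, t` (e.g. from [summed_score_eap()] of
#'   the fixed anchor parameters) used for the t lookup.
#' @param target_range,anchor_range Integer `c(min, max)` achievable raw
#'   ranges; default to the observed ranges.
#' @param smooth Optional integer degree for log-linear presmoothing of both
#'   score distributions (default `NULL` = none).
#' @param target,anchor,anchor_metric Provenance labels.
#' @return A `crosswalk`; `anchor_raw` is the continuized equated score
#'   \eqn{e_Y(s)} and `se_t` is `NA` (equipercentile equating does not yield
#'   model-based SEs here).
#' @export
equipercentile_link <- function(target_raw, anchor_raw, anchor_table,
                                target_range = range(target_raw),
                                anchor_range = range(anchor_raw),
                                smooth = NULL,
                                target = "target", anchor = "anchor",
                                anchor_metric = anchor) {
  target_raw <- target_raw[!is.na(target_raw)]
  anchor_raw <- anchor_raw[!is.na(anchor_raw)]
  if (length(unique(target_raw)) < 2L || length(unique(anchor_raw)) < 2L)
    stop("degenerate (constant) score distribution: linking undefined")
  xs <- seq(target_range[1], target_range[2])
  ys <- seq(anchor_range[1], anchor_range[2])
  fx <- tabulate(target_raw - target_range[1] + 1L, nbins = length(xs))
  fy <- tabulate(anchor_raw - anchor_range[1] + 1L, nbins = length(ys))
  if (!is.null(smooth)) {
    fx <- loglinear_smooth(xs, fx, smooth)
    fy <- loglinear_smooth(ys, fy, smooth)
  }
  pr <- percentile_ranks(fx) / 100
  ey <- inv_continuized(pr, ys, fy)
  tt <- stats::approx(anchor_table$raw, anchor_table$t, xout = ey,
                      rule = 2)$y
  df <- data.frame(raw = xs, t = tt, se_t = NA_real_, anchor_raw = ey)
  # guard: monotone non-decreasing by construction; enforce against fp noise
  df$t <- cummax(df$t)
  df$anchor_raw <- cummax(df$anchor_raw)
  new_crosswalk(df, "equipercentile", target, anchor, anchor_metric)
}

#' Closest cut-point equivalency
#'
#' Finds the target raw score whose crosswalk row lies closest to an anchor
#' cut-point. Anchor cut-points are defined on the anchor raw-score metric
#' (e.g. emotional-exhaustion raw >= 27) with an associated t-score, so by
#' default the match is on the predicted anchor raw-score column when
#' `cut_raw` is supplied, and on the t column otherwise. Ties break toward
#' the lower raw score.
#'
#' @param xw A `crosswalk`.
#' @param cut_t Anchor cut t-score.
#' @param cut_raw Anchor cut raw score (optional).
#' @param match `"anchor_raw"` or `"t"`; default follows the supplied cut.
#' @return Object of class `cutpoint_equivalence`: the matched target raw
#'   cut, the |t| and |anchor raw| distances at the match, and the cut used.
#' @export
closest_cutpoint <- function(xw, cut_t = NULL, cut_raw = NULL, match = NULL) {
  stopifnot(inherits(xw, "crosswalk"), nrow(xw) >= 1L)
  if (is.null(cut_t) && is.null(cut_raw))
    stop("supply cut_t and/or cut_raw")
  if (is.null(match)) match <- if (!is.null(cut_raw)) "anchor_raw" else "t"
  match <- match.arg(match, c("anchor_raw", "t"))
  d <- if (match == "anchor_raw") abs(xw$anchor_raw - cut_raw)
       else abs(xw$t - cut_t)
  i <- which.min(d)  # which.min returns the first (lowest raw) minimum
  structure(list(target = attr(xw, "target"),
                 anchor = attr(xw, "anchor"),
                 anchor_metric = attr(xw, "anchor_metric"),
                 cut_t = cut_t, cut_raw = cut_raw, match = match,
                 raw_cut = xw$raw[i],
                 t_at_match = xw$t[i],
                 anchor_raw_at_match = xw$anchor_raw[i],
                 delta_t = if (!is.null(cut_t)) abs(xw$t[i] - cut_t) else NA_real_,
                 delta_raw = if (!is.null(cut_raw))
                   abs(xw$anchor_raw[i] - cut_raw) else NA_real_),
            class = "cutpoint_equivalence")
}

#' @export
print.cutpoint_equivalence <- function(x, ...) {
  cat(sprintf("<cutpoint_equivalence> %s raw >= %d matches anchor cut (%s%s) on %s\n",
              x$target, x$raw_cut,
              if (!is.null(x$cut_raw)) paste0("raw ", x$cut_raw) else "",
              if (!is.null(x$cut_t)) paste0(" t ", x$cut_t) else "",
              x$anchor_metric))
  invisible(x)
}

#' Cut-point mapping between two targets linked to the same anchor metric
#'
#' Looks up the crosswalk row of `raw_cut_a` on scale A and finds the closest
#' row on scale B. Refuses crosswalks whose anchor metrics differ (scores on
#' different anchor metrics are not comparable).
#'
#' @param xw_a,xw_b `crosswalk` objects sharing the anchor metric.
#' @param raw_cut_a Raw cut on scale A.
#' @param match Matching column, as in [closest_cutpoint()] (default
#'   `"anchor_raw"`).
#' @return A `cutpoint_equivalence` on scale B.
#' @export
cross_target_cutpoint <- function(xw_a, raw_cut_a, xw_b, match = "anchor_raw") {
  if (!identical(attr(xw_a, "anchor_metric"), attr(xw_b, "anchor_metric")))
    stop("incompatible crosswalks: anchor metrics differ (",
         attr(xw_a, "anchor_metric"), " vs ", attr(xw_b, "anchor_metric"), ")")
  i <- match(raw_cut_a, xw_a$raw)
  if (is.na(i)) stop("raw_cut_a = ", raw_cut_a, " is not a row of crosswalk A")
  closest_cutpoint(xw_b, cut_t = xw_a$t[i], cut_raw = xw_a$anchor_raw[i],
                   match = match)
}

#' Substitute raw scores with anchor-metric t-scores and compute a group rate
#'
#' Group-level use of a crosswalk: each respondent's target raw score is
#' replaced by the crosswalk t-score and the proportion at or above an anchor
#' cut t-score is reported. Individual substituted scores are intermediates
#' for the group statistics, not individual-level translations.
#'
#' @param raw Integer vector of target raw scores (no `NA`).
#' @param xw A `crosswalk`.
#' @param cut_t Anchor cut t-score.
#' @return List: `t` (per-respondent substituted t-scores), `proportion`
#'   (share with t >= `cut_t`), `mean_t`, `n`.
#' @export
apply_crosswalk <- function(raw, xw, cut_t) {
  if (length(raw) == 0L) stop("empty input: no scores to substitute")
  if (anyNA(raw)) stop("raw scores contain NA; apply the missingness filter first")
  i <- match(raw, xw$raw)
  if (anyNA(i))
    stop("raw score(s) outside the crosswalk: ",
         paste(sort(unique(raw[is.na(i)])), collapse = ", "))
  tt <- xw$t[i]
  list(t = tt, proportion = mean(tt >= cut_t), mean_t = mean(tt),
       n = length(tt))
}

#' Group rate from an aggregated frequency table
#'
#' The aggregated-data route: given only a frequency table of raw scores, the
#' proportion at or above an anchor cut t-score is the share of counts whose
#' crosswalk t-score meets the cut.
#'
#' @param freq Data frame `raw, count` (counts non-negative).
#' @param xw A `crosswalk`.
#' @param cut_t Anchor cut t-score.
#' @return The proportion (single number).
#' @export
rates_from_frequency_table <- function(freq, xw, cut_t) {
  stopifnot(all(c("raw", "count") %in% names(freq)))
  if (any(freq$count < 0)) stop("counts must be non-negative")
  tot <- sum(freq$count)
  if (tot <= 0) stop("zero total count: rate undefined")
  i <- match(freq$raw, xw$raw)
  if (anyNA(i))
    stop("raw score(s) outside the crosswalk: ",
         paste(freq$raw[is.na(i)], collapse = ", "))
  sum(freq$count[xw$t[i] >= cut_t]) / tot
}

#' Missing-response inclusion rule and prorated raw totals
#'
#' Keeps respondents with at most one missing item response per scale, for
#' every listed scale (and at least one observed item per scale). Raw totals
#' for retained respondents with one missing item are prorated:
#' round-half-up of observed mean times the item count.
#'
#' @param responses Data frame with the scales' item columns (and optional
#'   `id`, `subgroup`).
#' @param scales List of [scale_def()].
#' @return List: `responses` (retained rows), `totals` (data frame `id`,
#'   `subgroup` if present, one prorated raw-total column per scale, named by
#'   scale name), `excluded_ids`, `n_excluded`.
#' @export
filter_missingness <- function(responses, scales) {
  if (inherits(scales, "scale_def")) scales <- list(scales)
  n <- nrow(responses)
  ids <- if ("id" %in% names(responses)) responses$id else seq_len(n)
  keep <- rep(TRUE, n)
  for (sc in scales) {
    nmiss <- rowSums(is.na(responses[, sc$items, drop = FALSE]))
    keep <- keep & nmiss <= 1L & nmiss < length(sc$items)
  }
  kept <- responses[keep, , drop = FALSE]
  totals <- data.frame(id = ids[keep])
  if ("subgroup" %in% names(responses)) totals$subgroup <- kept$subgroup
  for (sc in scales) {
    x <- as.matrix(kept[, sc$items, drop = FALSE])
    nobs <- rowSums(!is.na(x))
    tot <- rowSums(x, na.rm = TRUE)
    prorated <- round_half_up(tot / nobs * length(sc$items))
    totals[[sc$name]] <- as.integer(ifelse(nobs == length(sc$items),
                                           tot, prorated))
  }
  list(responses = kept, totals = totals,
       excluded_ids = ids[!keep], n_excluded = sum(!keep))
}
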