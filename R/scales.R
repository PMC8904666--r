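#' Define an ordinal scale
#'
#' A scale is an ordered set of polytomous items scored by integer category
#' codes. Raw (total) scores are sums of item codes, so the achievable raw
#' range is determined by the number of categories per item and the lowest
#' code (0 for MBI/PFI-style items, 1 for the single-item screening scale).
#'
#' @param name Scale label, e.g. `"MBI-EE"`.
#' @param items Character vector of item ids (column names in response data).
#' @param n_categories Integer: number of ordered response categories per
#'   item. A scalar is recycled; otherwise one value per item.
#' @param lowest_code Integer code of the lowest category (default 0).
#' @param role `"anchor"` or `"target"`; the anchor is the scale whose metric
#'   is held fixed during linking.
#' @return An object of class `scale_def` with the raw-score range attached.
#' @examples
#' scale_def("MZSIB", "mz1", n_categories = 5, lowest_code = 1, role = "target")
#' @export
scale_def <- function(name, items, n_categories, lowest_code = 0L,
                      role = c("target", "anchor")) {
  role <- match.arg(role)
  items <- as.character(items)
  if (anyDuplicated(items)) stop("duplicate item ids in scale '", name, "'")
  n_categories <- as.integer(rep_len(n_categories, length(items)))
  if (any(n_categories < 2L)) stop("each item needs at least 2 categories")
  lowest_code <- as.integer(lowest_code)
  min_raw <- length(items) * lowest_code
  max_raw <- sum(n_categories - 1L) + min_raw
  structure(
    list(name = name, items = items, n_categories = n_categories,
         lowest_code = lowest_code, role = role,
         min_raw = min_raw, max_raw = max_raw),
    class = "scale_def"
  )
}

#' @export
print.scale_def <- function(x, ...) {
  cat(sprintf("<scale_def> %s (%s): %d item(s), codes %d-%d per item, raw %d-%d\n",
              x$name, x$role, length(x$items), x$lowest_code,
              x$lowest_code + max(x$n_categories) - 1L, x$min_raw, x$max_raw))
  invisible(x)
}

#' Graded-response-model parameters for one item
#'
#' @param item Item id.
#' @param a Discrimination (positive, logistic metric).
#' @param b Numeric vector of strictly increasing category thresholds; its
#'   length is one less than the number of response categories.
#' @return An object of class `item_params`.
#' @export
item_params <- function(item, a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 1L || !is.finite(a) || a <= 0)
    stop("discrimination 'a' must be a single positive number")
  if (length(b) < 1L || any(!is.finite(b)))
    stop("thresholds 'b' must be finite and non-empty")
  if (is.unsorted(b, strictly = TRUE))
    stop("thresholds 'b' must be strictly increasing")
  structure(list(item = as.character(item), a = a, b = b),
            class = "item_params")
}

#' @export
print.item_params <- function(x, ...) {
  cat(sprintf("<item_params> %s: a = %.3f, b = [%s]\n", x$item, x$a,
              paste(sprintf("%.3f", x$b), collapse = ", ")))
  invisible(x)
}

# Align a list of item_params with a scale; errors on mismatch.
params_for_scale <- function(params, scale) {
  stopifnot(inherits(scale, "scale_def"))
  ids <- vapply(params, function(p) p$item, character(1))
  miss <- setdiff(scale$items, ids)
  if (length(miss))
    stop("missing item parameters for: ", paste(miss, collapse = ", "))
  params <- params[match(scale$items, ids)]
  m <- vapply(params, function(p) length(p$b) + 1L, integer(1))
  bad <- which(m != scale$n_categories)
  if (length(bad))
    stop("category-count mismatch between parameters and scale for item(s): ",
         paste(scale$items[bad], collapse = ", "))
  params
}

# Convert codes to 1-based category indices for a scale (NA preserved).
codes_to_cats <- function(responses, scale) {
  x <- as.matrix(responses[, scale$items, drop = FALSE])
  storage.mode(x) <- "double"
  check_codes(x, scale)
  x - scale$lowest_code + 1
}

# Validate that all non-missing codes lie in the scale's code range.
check_codes <- function(x, scale) {
  for (j in seq_along(scale$items)) {
    hi <- scale$lowest_code + scale$n_categories[j] - 1L
    v <- x[, j]
    bad <- which(!is.na(v) & (v < scale$lowest_code | v > hi | v != round(v)))
    if (length(bad))
      stop(sprintf("invalid code(s) for item '%s' (allowed %d-%d) at row(s) %s",
                   scale$items[j], scale$lowest_code, hi,
                   paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

round_half_up <- function(x) floor(x + 0.5)
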