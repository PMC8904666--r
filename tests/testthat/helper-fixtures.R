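# Small reusable fixtures; everything built in code.

toy_params_3x3 <- function() {
  list(item_params("i1", 1.2, c(-1, 0.5)),
       item_params("i2", 0.8, c(-0.3, 1)),
       item_params("i3", 1.5, c(0, 0.7)))
}
toy_scale_3x3 <- function(role = "target") {
  scale_def("toy3", c("i1", "i2", "i3"), 3, 0, role)
}

# mirror-symmetric two-item dichotomous scale
sym_params <- function() {
  list(item_params("s1", 1.3, -1), item_params("s2", 1.3, 1))
}
sym_scale <- function() scale_def("sym", c("s1", "s2"), 2, 0, "target")

dense_grid <- function() quad_grid(2001L, -8, 8)

# independent posterior-mean oracle: plain sums over a grid
eap_oracle <- function(pattern, params, grid, mean = 0, sd = 1,
                       lowest_code = 0) {
  w <- dnorm(grid, mean, sd)
  lik <- rep(1, length(grid))
  for (j in seq_along(params)) {
    code <- pattern[j]
    if (is.na(code)) next
    p <- params[[j]]
    k <- code - lowest_code + 1
    pr <- grm_category_probs(p$a, p$b, grid)[, k]
    lik <- lik * pr
  }
  post <- w * lik
  post <- post / sum(post)
  sum(post * grid)
}

# brute-force summed-score distribution by pattern enumeration
enumerate_summed <- function(params, theta, lowest_code = 0) {
  ms <- vapply(params, function(p) length(p$b) + 1L, integer(1))
  grids <- lapply(ms, function(m) seq_len(m))
  pats <- expand.grid(grids)
  probs <- lapply(params, function(p)
    as.numeric(grm_category_probs(p$a, p$b, theta)))
  min_raw <- length(params) * lowest_code
  max_raw <- sum(ms - 1) + min_raw
  out <- setNames(numeric(max_raw - min_raw + 1), min_raw:max_raw)
  for (r in seq_len(nrow(pats))) {
    pp <- prod(vapply(seq_along(params),
                      function(j) probs[[j]][pats[r, j]], numeric(1)))
    s <- sum(pats[r, ] - 1) + min_raw
    out[as.character(s)] <- out[as.character(s)] + pp
  }
  out
}

tmp_path <- function(name) file.path(tempdir(), name)
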