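test_that("method selection requires dominance on all three criteria", {
  acc <- data.frame(method = rep(c("irt", "equipercentile"), each = 2),
                    item_set = rep(c("s1", "s2"), 2),
                    r = c(0.9, 0.88, 0.85, 0.84),
                    mean_diff = c(0.01, -0.02, 0.1, 0.12),
                    sd_diff = c(3.1, 3.3, 4.0, 4.2))
  sel <- select_method(acc)
  expect_equal(sel$method, "irt")
  expect_equal(sel$status, "dominant")
  # permutation invariance of the input order
  sel2 <- select_method(acc[sample(nrow(acc)), ])
  expect_equal(sel2$method, "irt")

  # A better on r, B better on SD: no dominator
  acc2 <- acc
  acc2$sd_diff <- c(4.5, 4.6, 4.0, 4.2)
  sel3 <- select_method(acc2)
  expect_equal(sel3$status, "indeterminate")
  expect_true(is.na(sel3$method))

  sel4 <- select_method(acc[acc$method == "irt", ])
  expect_equal(sel4$status, "uncontested")
  expect_equal(sel4$method, "irt")
})

test_that("polychoric correlation recovers the generating correlation", {
  set.seed(37)
  n <- 10000; rho <- 0.6
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  x <- cut(z1, c(-Inf, -1, 0, 1, Inf), labels = FALSE)
  y <- cut(z2, c(-Inf, -0.5, 0.5, 1.5, Inf), labels = FALSE)
  expect_lt(abs(polychoric_corr(x, y) - rho), 0.05)
  # matrix form is symmetric with unit diagonal
  R <- polychoric_matrix(data.frame(x = x, y = y))
  expect_equal(diag(R), c(x = 1, y = 1))
  expect_equal(R[1, 2], R[2, 1])
})

test_that("assumption checks pass on a shared trait and fail on independent traits", {
  fx <- default_study_fixture(seed = 19, n = 900, construct_correlation = 1,
                              missing_rate = 0)
  iset <- item_set(fx$scales$we, fx$scales$ee, fx$responses, fx$params$ee)
  rep1 <- assumption_check(iset)
  expect_true(rep1$pass_r)
  expect_true(rep1$pass_unidim)
  expect_gte(rep1$pearson_r, 0.75)

  fx0 <- default_study_fixture(seed = 19, n = 900, construct_correlation = 0,
                               missing_rate = 0)
  iset0 <- item_set(fx0$scales$we, fx0$scales$ee, fx0$responses,
                    fx0$params$ee)
  rep0 <- assumption_check(iset0)
  expect_false(rep0$pass_r)
})

test_that("conditional reliability follows 1 - 1/I with a floor at zero", {
  fx <- default_study_fixture(seed = 2, n = 10)
  curve <- reliability_curve(fx$params$ee, scale_name = "EE")
  theta <- (curve$t - 50) / 10
  expect_equal(curve$reliability,
               pmax(1 - 1 / test_information(fx$params$ee, theta), 0))
  expect_true(all(curve$reliability >= 0 & curve$reliability <= 1))
  # a near-uninformative single item is floored at zero
  weak <- reliability_curve(list(item_params("w", 0.1, 0)))
  expect_true(all(weak$reliability == 0))
  # information additivity: combined item set dominates each subset pointwise
  sub <- reliability_curve(fx$params$ee[1:4])
  expect_true(all(curve$reliability >= sub$reliability))
})

test_that("reliable ranges are maximal intervals on the grid", {
  const <- function(v) structure(
    data.frame(t = seq(20, 80, 0.5), reliability = v),
    class = c("reliability_curve", "data.frame"))
  expect_equal(reliable_range(const(0.8), 0.7),
               data.frame(t_min = 20, t_max = 80))
  expect_equal(nrow(reliable_range(const(0.5), 0.7)), 0)
  # unimodal curve: a single interval bracketing the mode
  fx <- default_study_fixture(seed = 2, n = 10)
  curve <- reliability_curve(fx$params$we)
  rr <- reliable_range(curve, 0.7)
  expect_equal(nrow(rr), 1)
  mode_t <- curve$t[which.max(curve$reliability)]
  expect_true(rr$t_min <= mode_t && mode_t <= rr$t_max)
})

test_that("cross-validation is reproducible under a seed and works at k = n", {
  fx <- default_study_fixture(seed = 12, n = 50, missing_rate = 0)
  iset <- item_set(fx$scales$we, fx$scales$ee, fx$responses, fx$params$ee,
                   target_params = fx$params$we)
  loo <- kfold_cv(iset, k = nrow(fx$responses), method = "irt", seed = 1)
  expect_true(is.finite(loo$r) && is.finite(loo$mean_diff) &&
                is.finite(loo$sd_diff))
  cv1 <- kfold_cv(iset, k = 5, method = "irt", seed = 3)
  cv2 <- kfold_cv(iset, k = 5, method = "irt", seed = 3)
  expect_identical(cv1$r, cv2$r)
  expect_error(kfold_cv(iset, k = 1), "k >= 2")
})

test_that("a shared trait links more accurately than a weakly shared one", {
  cvs <- lapply(c(1, 0.5), function(rho) {
    fx <- default_study_fixture(seed = 22, n = 1200,
                                construct_correlation = rho,
                                missing_rate = 0)
    iset <- item_set(fx$scales$we, fx$scales$ee, fx$responses, fx$params$ee)
    kfold_cv(iset, k = 5, method = "irt", seed = 4)
  })
  expect_gt(cvs[[1]]$r, cvs[[2]]$r)
  expect_lt(cvs[[1]]$sd_diff, cvs[[2]]$sd_diff)
})

test_that("subgroup invariance holds under random labels and a pure trait shift, and fails under parameter drift", {
  fx <- default_study_fixture(seed = 31, n = 2400, missing_rate = 0)
  iset <- item_set(fx$scales$we, fx$scales$ee, fx$responses, fx$params$ee)
  null_run <- subgroup_invariance(iset)
  expect_false(null_run$flag)

  # trait mean shift in group 2: linking is invariant to population shift
  fx_sh <- default_study_fixture(seed = 31, n = 2400, missing_rate = 0,
                                 subgroup_shift = 1)
  iset_sh <- item_set(fx_sh$scales$we, fx_sh$scales$ee, fx_sh$responses,
                      fx_sh$params$ee)
  shift_run <- subgroup_invariance(iset_sh)
  expect_false(shift_run$flag)

  # different target thresholds in group 2: designed non-invariance
  fx2 <- default_study_fixture(seed = 31, n = 1200, missing_rate = 0)
  drift <- lapply(fx2$params$we, function(p)
    item_params(p$item, p$a, p$b + 1.6))
  g2 <- simulate_responses(fx2$thetas$ee_target, fx2$scales$we, drift,
                           seed = 99)
  resp2 <- fx2$responses
  resp2$subgroup <- 1L
  g2full <- resp2
  g2full$subgroup <- 2L
  g2full[fx2$scales$we$items] <- g2[fx2$scales$we$items]
  both <- rbind(resp2, g2full)
  both$id <- seq_len(nrow(both))
  iset2 <- item_set(fx2$scales$we, fx2$scales$ee, both, fx2$params$ee)
  drift_run <- subgroup_invariance(iset2)
  expect_true(drift_run$flag)

  small <- fx$responses[1:150, ]
  iset_small <- item_set(fx$scales$we, fx$scales$ee, small, fx$params$ee)
  expect_error(subgroup_invariance(iset_small), "floor")
})
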