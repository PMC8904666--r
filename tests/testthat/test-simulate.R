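test_that("latent trait pairs honor the specified correlation structure", {
  sp <- latent_spec(200, 0, 1, 1, seed = 9)
  th <- simulate_thetas(sp)
  expect_equal(th$theta_target, th$theta_anchor, tolerance = 1e-12)

  sp2 <- latent_spec(1e5, 0, 1, 0.8, seed = 10)
  th2 <- simulate_thetas(sp2)
  expect_lt(abs(cor(th2$theta_target, th2$theta_anchor) - 0.8), 0.02)
  expect_lt(abs(sd(th2$theta_target) - 1), 0.02)

  one <- simulate_thetas(latent_spec(1, seed = 3))
  expect_identical(one, simulate_thetas(latent_spec(1, seed = 3)))

  expect_error(latent_spec(0), "positive")
  expect_error(latent_spec(10, theta_sd = -1), "positive")
  expect_error(latent_spec(10, construct_correlation = 1.2), "\\[-1, 1\\]")
})

test_that("simulated responses follow the GRM category distribution", {
  sc <- scale_def("one", "x1", 2)
  p <- list(item_params("x1", 1, 0))
  r <- simulate_responses(rep(0, 50000), sc, p, seed = 5)
  expect_lt(abs(mean(r$x1 == 1) - 0.5), 0.02)

  # saturation: very high trait puts everyone in the top category
  r2 <- simulate_responses(rep(10, 500), sc, p, seed = 6)
  expect_true(all(r2$x1 == 1))

  # codes respect the lowest_code offset
  mz <- scale_def("mz", "mz1", 5, lowest_code = 1)
  pm <- list(item_params("mz1", 2, c(-1.5, -0.3, 0.7, 1.8)))
  rm_ <- simulate_responses(rnorm(2000), mz, pm, seed = 7)
  expect_true(all(rm_$mz1 %in% 1:5))

  th <- rnorm(20)
  expect_identical(simulate_responses(th, sc, p, seed = 8),
                   simulate_responses(th, sc, p, seed = 8))
})

test_that("generated category frequencies pass a goodness-of-fit check against the model", {
  sc <- scale_def("g", "g1", 3)
  p <- list(item_params("g1", 1.4, c(-0.6, 0.9)))
  th0 <- 0.25
  r <- simulate_responses(rep(th0, 50000), sc, p, seed = 13)
  obs <- tabulate(r$g1 + 1, nbins = 3)
  expected_p <- as.numeric(grm_category_probs(1.4, c(-0.6, 0.9), th0))
  gof <- chisq.test(obs, p = expected_p)
  expect_gt(gof$p.value, 0.001)
})

test_that("missingness injection is MCAR at the requested rate and reproducible", {
  sc <- scale_def("m", paste0("m", 1:9), 7)
  p <- lapply(sc$items, function(it)
    item_params(it, 1.5, seq(-2, 2, length.out = 6)))
  r <- simulate_responses(rnorm(1000), sc, p, seed = 14)
  expect_identical(inject_missingness(r, 0, seed = 1), r)
  rm5 <- inject_missingness(r, 0.05, seed = 15)
  frac <- mean(is.na(as.matrix(rm5[, sc$items])))
  expect_lt(abs(frac - 0.05), 0.01)
  expect_identical(rm5, inject_missingness(r, 0.05, seed = 15))
  expect_error(inject_missingness(r, 1), "rate")
})

test_that("the packaged study fixture has the documented structure", {
  fx <- default_study_fixture(seed = 4, n = 700)
  expect_named(fx$scales, c("ee", "we", "mz", "dp", "id"))
  expect_equal(fx$scales$ee$max_raw, 54)
  expect_equal(fx$scales$we$max_raw, 16)
  expect_equal(fx$scales$id$max_raw, 24)
  expect_equal(fx$scales$mz$min_raw, 1)
  ee <- as.matrix(fx$responses[, fx$scales$ee$items])
  expect_true(all(is.na(ee) | (ee >= 0 & ee <= 6)))
  expect_true(all(fx$responses$subgroup %in% 1:2))
  # inter-scale correlation of the EE item set
  flt <- filter_missingness(fx$responses, fx$scales[c("we", "ee")])
  expect_gte(cor(flt$totals[["PFI-WE-like"]], flt$totals[["MBI-EE-like"]]), 0.7)
  # determinism
  fx2 <- default_study_fixture(seed = 4, n = 700)
  expect_identical(fx$responses, fx2$responses)
})
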