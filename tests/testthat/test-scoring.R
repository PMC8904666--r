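test_that("EAP respects symmetry, matches a dense-grid oracle, and shrinks to the prior", {
  # mirror-symmetric scale, middle raw score
  est <- eap_theta(c(s1 = 1, s2 = 0), sym_params())
  expect_equal(unname(est["theta"]), 0, tolerance = 1e-6)

  params <- toy_params_3x3()
  pat <- c(i1 = 2, i2 = 0, i3 = 1)
  dg <- dense_grid()
  got <- eap_theta(pat, params, grid = dg)
  expect_equal(unname(got["theta"]), eap_oracle(pat, params, dg),
               tolerance = 1e-10)
  # working grid close to dense oracle
  got61 <- eap_theta(pat, params)
  expect_equal(unname(got61["theta"]), eap_oracle(pat, params, dg),
               tolerance = 1e-4)

  # uninformative items: posterior = prior
  upar <- list(item_params("u1", 1e-6, 0), item_params("u2", 1e-6, 0))
  est <- eap_theta(c(u1 = 1, u2 = 0), upar, latent_density(0.3, 0.9))
  expect_equal(unname(est["theta"]), 0.3, tolerance = 1e-3)
  expect_equal(unname(est["se"]), 0.9, tolerance = 1e-2)

  expect_error(eap_theta(c(i1 = NA, i2 = NA, i3 = NA), params), "missing")
})

test_that("missing items are omitted from the EAP likelihood", {
  params <- toy_params_3x3()
  with_na <- eap_theta(c(i1 = 2, i2 = NA, i3 = 1), params)
  subset_only <- eap_theta(c(i1 = 2, i3 = 1), params[c(1, 3)])
  expect_equal(with_na, subset_only, tolerance = 1e-12)
})

test_that("summed-score EAP table is symmetric, monotone, and matches simulation", {
  tab <- summed_score_eap(sym_params())
  expect_equal(tab$theta[tab$raw == 1], 0, tolerance = 1e-8)
  expect_equal(tab$t, 50 + 10 * tab$theta)

  fx <- default_study_fixture(seed = 2, n = 50, missing_rate = 0)
  for (nm in c("ee", "we", "mz")) {
    tt <- summed_score_eap(fx$params[[nm]],
                           lowest_code = fx$scales[[nm]]$lowest_code)
    expect_true(all(diff(tt$theta) > 0))
    expect_equal(tt$raw, fx$scales[[nm]]$min_raw:fx$scales[[nm]]$max_raw)
  }

  # Monte-Carlo oracle: mean theta within each raw-score group
  params <- toy_params_3x3()
  sc <- toy_scale_3x3()
  set.seed(31)
  th <- rnorm(2e5)
  resp <- simulate_responses(th, sc, params, seed = 32)
  raw <- rowSums(resp[, sc$items])
  mc <- tapply(th, raw, mean)
  tab <- summed_score_eap(params)
  common <- intersect(names(mc), as.character(tab$raw))
  expect_lt(max(abs(mc[common] - tab$theta[match(as.integer(common), tab$raw)])),
            0.02)
})

test_that("group mean of EAP-from-raw t-scores recovers the population t mean", {
  fx <- default_study_fixture(seed = 5, n = 10, missing_rate = 0)
  sc <- fx$scales$ee; params <- fx$params$ee
  set.seed(41)
  th <- rnorm(5000)
  resp <- simulate_responses(th, sc, params, seed = 42)
  raw <- rowSums(resp[, sc$items])
  tab <- summed_score_eap(params)
  tvals <- tab$t[match(raw, tab$raw)]
  expect_lt(abs(mean(tvals) - 50), 0.5)
})

test_that("pattern scoring returns one row per respondent with positive SEs", {
  sc <- toy_scale_3x3()
  params <- toy_params_3x3()
  resp <- data.frame(id = 1:4, i1 = c(0, 2, 1, NA), i2 = c(1, 1, 0, NA),
                     i3 = c(2, 0, 1, NA))
  expect_warning(out <- score_respondents(resp, sc, params), "dropped")
  expect_equal(out$id, 1:3)
  expect_true(all(out$se > 0))
  expect_equal(out$t, 50 + 10 * out$theta)
})
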