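ee_fixture <- function(n = 1500, rho = 1, seed = 8) {
  fx <- default_study_fixture(seed = seed, n = n, construct_correlation = rho,
                              missing_rate = 0)
  list(fx = fx,
       iset = item_set(fx$scales$we, fx$scales$ee, fx$responses,
                       fx$params$ee))
}

test_that("IRT self-link reproduces the anchor's own raw-to-t table", {
  fx <- default_study_fixture(seed = 6, n = 300, missing_rate = 0)
  iset <- item_set(fx$scales$ee, fx$scales$ee, fx$responses, fx$params$ee)
  xw <- irt_link(iset)
  tab <- summed_score_eap(fx$params$ee)
  expect_lt(max(abs(xw$t - tab$t)), 1e-10)
  expect_lt(max(abs(xw$se_t - tab$se_t)), 1e-10)
})

test_that("fixed-calibration linking yields a monotone crosswalk spanning the anchor range", {
  ef <- ee_fixture()
  xw <- irt_link(ef$iset)
  expect_s3_class(xw, "crosswalk")
  expect_equal(xw$raw, 0:16)
  expect_true(all(diff(xw$t) > 0))
  expect_true(all(diff(xw$anchor_raw) > 0))
  span <- diff(range(xw$anchor_raw)) / 54
  expect_gt(span, 0.8)
  expect_true(all(xw$anchor_raw >= 0 & xw$anchor_raw <= 54))
})

test_that("a single-item target produces one crosswalk row per category code", {
  fx <- default_study_fixture(seed = 6, n = 1200, missing_rate = 0)
  iset <- item_set(fx$scales$mz, fx$scales$ee, fx$responses, fx$params$ee)
  xw <- irt_link(iset)
  expect_equal(nrow(xw), 5)
  expect_equal(xw$raw, 1:5)
})

test_that("target and anchor item sets must be disjoint and share respondents", {
  fx <- default_study_fixture(seed = 6, n = 50, missing_rate = 0)
  overlap <- scale_def("bad", c("we1", "ee1"), 5)
  expect_error(item_set(overlap, fx$scales$ee, fx$responses, fx$params$ee),
               "disjoint")
  expect_error(item_set(fx$scales$we, fx$scales$ee,
                        fx$responses[, c("id", fx$scales$we$items)],
                        fx$params$ee),
               "lack item column")
})

test_that("closest cut-point matching breaks ties toward the lower raw score", {
  df <- data.frame(raw = 0:4, t = c(40, 45, 50, 55, 60), se_t = 1,
                   anchor_raw = c(5, 10, 15, 20, 25))
  xw <- burnoutlink:::new_crosswalk(df, "irt", "A", "B", "M")
  # cut halfway between two rows: tie goes to the lower raw score
  expect_equal(closest_cutpoint(xw, cut_t = 47.5, match = "t")$raw_cut, 1)
  # all rows above the cut: the minimum raw score is returned
  expect_equal(closest_cutpoint(xw, cut_t = 10, match = "t")$raw_cut, 0)
  expect_error(closest_cutpoint(xw), "cut_t")
})

test_that("cross-target mapping refuses different anchor metrics and is self-consistent", {
  xw1 <- published_crosswalk("pfi_we")
  xw2 <- published_crosswalk("pfi_id")
  xw3 <- published_crosswalk("mzsib")
  expect_error(cross_target_cutpoint(xw2, 9, xw1), "incompatible")
  expect_equal(cross_target_cutpoint(xw1, 7, xw1)$raw_cut, 7)
  expect_equal(cross_target_cutpoint(xw3, 3, xw1)$raw_cut, 8)
})

test_that("crosswalk substitution and the frequency-table route agree on group rates", {
  xw <- published_crosswalk("pfi_we")
  raw <- c(5, 5, 7, 8, 10, 12, 7, 3)
  res <- apply_crosswalk(raw, xw, cut_t = 50.70)
  expect_equal(res$n, 8)
  freq <- as.data.frame(table(raw))
  freq <- data.frame(raw = as.integer(as.character(freq$raw)),
                     count = freq$Freq)
  expect_equal(res$proportion,
               rates_from_frequency_table(freq, xw, cut_t = 50.70))
  # all respondents exactly at a raw score above the cut
  expect_equal(apply_crosswalk(rep(8, 3), xw, 50.70)$proportion, 1)
  expect_error(apply_crosswalk(numeric(0), xw, 50.70), "empty")
  expect_error(apply_crosswalk(c(5, 99), xw, 50.70), "99")
})

test_that("frequency-table rates behave like proportions", {
  xw <- published_crosswalk("pfi_we")
  expect_equal(rates_from_frequency_table(
    data.frame(raw = c(5, 8), count = c(10, 10)), xw, 50.70), 0.5)
  pm <- rates_from_frequency_table(data.frame(raw = 4, count = 7), xw, 50.70)
  expect_true(pm %in% c(0, 1))
  f <- data.frame(raw = c(2, 6, 9, 14), count = c(3, 5, 2, 1))
  expect_equal(rates_from_frequency_table(f, xw, 50.70),
               rates_from_frequency_table(transform(f, count = count * 10),
                                          xw, 50.70))
  expect_error(rates_from_frequency_table(
    data.frame(raw = 5, count = 0), xw, 50.70), "zero total")
})

test_that("the missingness rule keeps <=1 missing per scale and prorates totals", {
  sc9 <- scale_def("nine", paste0("n", 1:9), 3)
  sc1 <- scale_def("single", "s1", 5, lowest_code = 1)
  resp <- data.frame(id = 1:4)
  resp[paste0("n", 1:9)] <- 2
  resp$s1 <- 3
  resp[2, c("n1", "n2")] <- NA          # 2 missing on one scale: excluded
  resp[3, "n1"] <- NA                   # 1 missing: retained, prorated
  resp[4, "s1"] <- NA                   # single-item scale fully missing
  flt <- filter_missingness(resp, list(sc9, sc1))
  expect_equal(flt$responses$id, c(1, 3))
  expect_equal(flt$n_excluded, 2)
  expect_equal(flt$excluded_ids, c(2, 4))
  # 8 observed items summing to 16 -> round(16/8*9) = 18
  expect_equal(flt$totals$nine, c(18L, 18L))
  # complete matrix is a no-op
  full <- resp[1, ]
  expect_equal(filter_missingness(full, list(sc9, sc1))$n_excluded, 0)
})
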