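test_that("cohort configuration validates and reports offending fields", {
  cfg <- cohort_config()
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$groups$sizes, c(80, 40, 80, 40))
  expect_equal(cfg$thresholds$hads_cutoff, 9)
  expect_equal(cfg$thresholds$apathy_cutoff, 16)
  expect_true("jpss" %in% names(cfg$continuous))
  expect_true(all(c("ataxia", "aphasia") %in% names(cfg$binary)))

  bad <- unclass(cfg)
  bad$continuous$jpss$sd <- c(-1, 6.6, 6.4, 6.9)
  expect_error(llgmn:::validate_cohort_config(bad), "jpss")
  bad2 <- unclass(cfg)
  bad2$binary$ataxia$prob <- c(2, 0, 0, 0)
  expect_error(llgmn:::validate_cohort_config(bad2), "ataxia")
  bad3 <- unclass(cfg)
  bad3$continuous$mmse$bounds <- c(30, 0)
  expect_error(llgmn:::validate_cohort_config(bad3), "mmse")
})

test_that("cohort generation is seed-reproducible and respects group structure", {
  a <- generate_cohort(seed = 5)
  b <- generate_cohort(seed = 5)
  expect_identical(a$features, b$features)
  expect_identical(a$labels, b$labels)
  c2 <- generate_cohort(seed = 6)
  expect_false(identical(a$features, c2$features))

  expect_equal(nrow(a$features), 240)
  expect_equal(table(a$group)[["control"]], 80)
  expect_true(all(is.finite(a$features)))
  # bounds respected
  cfg <- a$config
  for (nm in names(cfg$continuous)) {
    expect_gte(min(a$features[, nm]), cfg$continuous[[nm]]$bounds[1])
    expect_lte(max(a$features[, nm]), cfg$continuous[[nm]]$bounds[2])
  }
  expect_true(all(a$features[, names(cfg$binary)] %in% 0:1))

  empty <- generate_cohort(cohort_config(groups = list(names = "control",
                                                       sizes = 0)), seed = 1)
  expect_equal(nrow(empty$features), 0)
})

test_that("large-sample index means match the configured group statistics", {
  cb <- generate_cohort(cohort_config(groups = list(names = "control",
                                                    sizes = 5000)), seed = 2)
  expect_equal(mean(cb$features[, "jpss"]), 16.1, tolerance = 0.3 / 16.1)
  expect_equal(mean(cb$features[, "cancellation_kana_time"]), 136.8,
               tolerance = 0.02)
  # marginal SD preserved under the variance-preserving factor mixing
  expect_equal(sd(cb$features[, "jpss"]), 6.5, tolerance = 0.06)
})

test_that("mood labels use strict score thresholds and validate ranges", {
  lab <- assign_mood_labels(10, 9, 17)
  expect_true(lab$psd)
  expect_false(lab$anxiety)
  expect_true(lab$apathy)
  lab2 <- assign_mood_labels(9, 10, 16)
  expect_false(lab2$psd)
  expect_true(lab2$anxiety)
  expect_false(lab2$apathy)
  expect_error(assign_mood_labels(22, 0, 0), "hads_depression")
  expect_error(assign_mood_labels(3, -1, 0), "hads_anxiety")
  expect_error(assign_mood_labels(3, 0, 43), "apathy_score")
  expect_error(assign_mood_labels(3.5, 0, 1), "hads_depression")
})

test_that("FIM improvement rate follows the printed formula", {
  expect_equal(fim_improvement_rate(62, 82, 10), 2.0)
  expect_equal(fim_improvement_rate(75, 75, 4), 0.0)
  expect_error(fim_improvement_rate(62, 82, 0), "weeks")
  expect_error(fim_improvement_rate(200, 82, 4), "range")
})

test_that("planted cohorts expose ground truth and the quadratic mode hides linear signal", {
  pc <- planted_cohort(400, 2, 3, effect = 2, seed = 61)
  expect_identical(attr(pc$features, "informative"), c("signal_1", "signal_2"))
  expect_equal(sum(pc$labels), 200)
  expect_gt(abs(mean(pc$features[pc$labels == 1, "signal_1"]) -
                mean(pc$features[pc$labels == 0, "signal_1"])), 1.5)

  pq <- planted_cohort(2000, 2, 1, boundary = "quadratic", label_noise = 0,
                       seed = 62)
  expect_lt(abs(cor(pq$features[, "signal_1"], pq$labels)), 0.08)
  expect_lt(abs(cor(pq$features[, "signal_2"], pq$labels)), 0.08)
  expect_equal(unique(as.integer(pq$features[, 1] * pq$features[, 2] > 0) ==
                        pq$labels), TRUE)
})

test_that("disorder prevalence rises monotonically with additive stress loading", {
  base_scores <- list(
    hads_depression = list(mean = rep(7, 1), sd = rep(2.5, 1), bounds = c(0, 21),
                           factor = "stress"),
    hads_anxiety = list(mean = rep(7, 1), sd = rep(2.5, 1), bounds = c(0, 21),
                        factor = "stress"),
    apathy_score = list(mean = rep(13, 1), sd = rep(3, 1), bounds = c(0, 42),
                        factor = "stress")
  )
  prevalence <- sapply(c(0, 1, 2.5), function(lambda) {
    cfg <- list(
      groups = list(names = "g", sizes = 2000),
      thresholds = list(hads_cutoff = 9, apathy_cutoff = 16),
      factors = list(stress_loading = lambda, speed_loading = 0,
                     mode = "additive"),
      continuous = list(filler = list(mean = 0, sd = 1, bounds = c(-10, 10))),
      binary = list(),
      scores = base_scores
    )
    mean(colMeans(generate_cohort(cfg, seed = 71)$labels))
  })
  expect_true(all(diff(prevalence) > 0))
})

test_that("cohorts round-trip through CSV", {
  co <- generate_cohort(cohort_config(groups = list(
    names = c("control", "depression"), sizes = c(30, 20))), seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(unname(back$features), unname(co$features), tolerance = 1e-6)
  expect_equal(back$labels$psd, co$labels$psd)
  expect_equal(as.character(back$group), as.character(co$group))
})
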