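test_that("KL information matches hand arithmetic and is nonnegative, zero iff perfect", {
  expect_equal(kl_information(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)),
               log(2), tolerance = 1e-12)
  q2 <- rbind(c(1, 0), c(0, 1))
  y2 <- rbind(c(0.5, 0.5), c(0.75, 0.25))
  expect_equal(kl_information(q2, y2), log(2) + log(4), tolerance = 1e-12)

  # perfect posteriors: zero up to the clipping guard
  q <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(kl_information(q, q), 0, tolerance = 1e-9)

  set.seed(21)
  for (rep in 1:200) {
    n <- sample(1:20, 1)
    lab <- sample(0:1, n, replace = TRUE)
    q <- cbind(1 - lab, lab)
    y <- rand_simplex2(n)
    kl <- kl_information(q, y)
    expect_gte(kl, 0)
    # oracle: sum of -log true-class posteriors
    expect_equal(kl, sum(-log(y[cbind(1:n, lab + 1)])), tolerance = 1e-9)
    if (kl < 1e-6) expect_equal(q, y, tolerance = 1e-3)
  }
  expect_error(kl_information(rbind(c(1, 0)), rand_simplex2(2)), "rows")
})

test_that("partial KL ratio divides with an epsilon guard and rejects negatives", {
  expect_equal(partial_kl_ratio(1.5, 1.5), 1.0)
  expect_equal(partial_kl_ratio(2.0, 0.5), 4.0)
  guarded <- partial_kl_ratio(2.0, 0)
  expect_true(is.finite(guarded))
  expect_equal(guarded, 2.0 / 1e-12)
  expect_error(partial_kl_ratio(-1, 1), ">= 0")
  expect_error(partial_kl_ratio(1, -1), ">= 0")
})

test_that("greedy elimination runs P-1 strictly nested steps and records the criteria", {
  pc <- planted_cohort(160, 2, 2, effect = 2, seed = 31)
  tr <- 1:120
  va <- 121:160
  trace <- greedy_eliminate(pc$features[tr, ], pc$labels[tr],
                            pc$features[va, ], pc$labels[va],
                            max_epochs = 150, learning_rate = 0.1, seed = 2)
  p <- ncol(pc$features)
  expect_s3_class(trace, "reduction_trace")
  expect_equal(nrow(trace$steps), p - 1)
  expect_equal(anyDuplicated(trace$steps$removed), 0L)
  expect_true(all(trace$steps$removed %in% colnames(pc$features)))
  expect_true(all(trace$steps$E > 0))
  expect_true(all(trace$steps$kl_numerator >= 0 & trace$steps$kl_denominator >= 0))
  # successive numerators chain to the previous denominator (nested models)
  expect_equal(trace$steps$kl_numerator[-1],
               trace$steps$kl_denominator[-(p - 1)], tolerance = 1e-12)

  best <- select_best(trace)
  expect_gte(length(best$dims), 1)
  expect_true(all(best$dims %in% colnames(pc$features)))
  expect_s3_class(best$model, "llgmn")

  # P = 2 gives exactly one step
  trace2 <- greedy_eliminate(pc$features[tr, 1:2], pc$labels[tr],
                             pc$features[va, 1:2], pc$labels[va],
                             max_epochs = 100, learning_rate = 0.1, seed = 2)
  expect_equal(nrow(trace2$steps), 1L)

  expect_error(greedy_eliminate(pc$features[tr, 1, drop = FALSE], pc$labels[tr],
                                pc$features[va, 1, drop = FALSE], pc$labels[va]),
               "2 input dimensions")
})

test_that("a constant column is eliminated before any informative dimension", {
  hits <- 0L
  n_runs <- 20L
  for (s in seq_len(n_runs)) {
    pc <- planted_cohort(120, 2, 0, effect = 2, seed = 200 + s)
    x <- cbind(pc$features, constant = 1)
    tr <- 1:90
    va <- 91:120
    trace <- greedy_eliminate(x[tr, ], pc$labels[tr], x[va, ], pc$labels[va],
                              max_epochs = 120, learning_rate = 0.1, seed = s)
    if (trace$steps$removed[1] == "constant") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("select_best maximizes validation AUC with ties broken toward fewer dimensions", {
  fake <- structure(list(
    initial_dims = c("a", "b", "c", "d"),
    initial = list(kl = 5, auc = 0.80, model = NULL),
    steps = data.frame(step = 1:3, removed = c("d", "c", "b"),
                       E = 1, kl_numerator = 1, kl_denominator = 1,
                       auc = c(0.85, 0.83, 0.80),
                       denominator_guarded = FALSE),
    models = NULL
  ), class = "reduction_trace")
  best <- select_best(fake)
  expect_equal(best$dims, c("a", "b", "c"))
  expect_equal(best$auc, 0.85)

  fake$steps$auc <- c(0.78, 0.75, 0.70)   # strictly decreasing: keep all dims
  expect_equal(select_best(fake)$dims, c("a", "b", "c", "d"))

  fake$steps$auc <- c(0.85, 0.80, 0.85)   # tie: later step = fewer dims wins
  expect_equal(select_best(fake)$dims, "a")

  fake$steps <- fake$steps[0, ]
  expect_error(select_best(fake), "empty")
})

test_that("reduction traces export as TSV and JSON", {
  pc <- planted_cohort(80, 2, 0, effect = 2, seed = 77)
  trace <- greedy_eliminate(pc$features[1:60, ], pc$labels[1:60],
                            pc$features[61:80, ], pc$labels[61:80],
                            max_epochs = 60, learning_rate = 0.1, seed = 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_trace(trace, tsv, "tsv")
  write_trace(trace, js, "json")
  tab <- read.delim(tsv)
  expect_equal(tab$removed, trace$steps$removed)
  doc <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(doc$initial_auc, trace$initial$auc, tolerance = 1e-12)
})
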