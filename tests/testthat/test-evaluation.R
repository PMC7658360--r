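test_that("AUC equals Mann-Whitney pair counting, with invariances", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_equal(auc(c(0.8, 0.4, 0.6, 0.2), c(1, 0, 0, 1)), 0.5)

  set.seed(41)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    lab <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # induces ties
    a <- auc(sc, lab)
    expect_equal(a, pair_count_auc(sc, lab), tolerance = 1e-12)
    expect_equal(auc(sc, 1 - lab), 1 - a, tolerance = 1e-12)
    expect_equal(auc(exp(3 * sc), lab), a, tolerance = 1e-12)  # monotone map
  }
  expect_error(auc(c(1, 2), c(1, 1)), "both classes")

  # agreement with an established ROC implementation
  set.seed(42)
  sc <- rnorm(60)
  lab <- rbinom(60, 1, 0.5)
  expect_equal(auc(sc, lab),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("ROC curves are monotone from (0,0) to (1,1) with trapezoid area equal to AUC", {
  rc <- roc_points(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_true(any(rc$points$fpr == 0 & rc$points$tpr == 1))
  expect_equal(rc$auc, 1.0)

  anti <- roc_points(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(anti$auc, 0.0)

  set.seed(43)
  sc <- rnorm(50)
  lab <- rep(0:1, 25)
  rc2 <- roc_points(sc, lab)
  expect_equal(rc2$points$fpr[1], 0)
  expect_equal(rc2$points$tpr[1], 0)
  expect_equal(rc2$points$fpr[nrow(rc2$points)], 1)
  expect_equal(rc2$points$tpr[nrow(rc2$points)], 1)
  expect_true(all(diff(rc2$points$fpr) >= 0))
  expect_true(all(diff(rc2$points$tpr) >= 0))
  expect_equal(rc2$auc, pair_count_auc(sc, lab), tolerance = 1e-12)
  expect_equal(rc2$auc, auc(sc, lab), tolerance = 1e-12)
})

test_that("operating metrics sit at the Youden-optimal point with sensitivity-favoring ties", {
  om <- operating_metrics(c(0.99, 0.9, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(om$sensitivity, 1)
  expect_equal(om$specificity, 1)
  expect_equal(om$ppv, 1)
  expect_equal(om$npv, 1)

  om2 <- operating_metrics(c(0.9, 0.6, 0.8, 0.1), c(1, 1, 0, 0))
  expect_equal(om2$threshold, 0.6)
  expect_equal(om2$sensitivity, 1.0)
  expect_equal(om2$specificity, 0.5)
  expect_equal(om2$ppv, 2 / 3)
  expect_equal(om2$npv, 1.0)

  om3 <- operating_metrics(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(om3$sensitivity, 1)
  expect_equal(om3$specificity, 0)
})

test_that("k-fold plans partition samples with near-equal, stratified folds", {
  f <- kfold_split(20, 10, seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 2))

  f274 <- kfold_split(274, 10, seed = 2)
  expect_true(all(table(f274) %in% c(27, 28)))
  expect_equal(sum(table(f274)), 274)

  expect_error(kfold_split(9, 10), "at least")

  lab <- rep(c(0, 1), each = 50)
  fs <- kfold_split(100, 10, seed = 3, labels = lab)
  per_fold <- table(fs, lab)
  expect_true(all(per_fold == 5))          # perfect stratification possible here
  expect_identical(fs, kfold_split(100, 10, seed = 3, labels = lab))
  expect_false(identical(fs, kfold_split(100, 10, seed = 4, labels = lab)))
})

test_that("class balancing undersamples the majority to minority count, seeded", {
  lab <- c(rep(0, 80), rep(1, 40))
  keep <- balance_classes(lab, seed = 1)
  expect_equal(sum(lab[keep] == 0), 40)
  expect_equal(sum(lab[keep] == 1), 40)
  expect_identical(keep, sort(keep))

  bal <- rep(0:1, 30)
  expect_identical(balance_classes(bal, seed = 9), seq_along(bal))

  k1 <- balance_classes(lab, seed = 1)
  k2 <- balance_classes(lab, seed = 2)
  expect_false(identical(k1, k2))
  expect_equal(length(k1), length(k2))
  expect_error(balance_classes(rep(1, 5)), "both classes")
})

test_that("DeLong test matches the reference implementation and its conventions", {
  s <- rnorm(100)
  lab <- rep(0:1, 50)
  same <- delong_test(s, s, lab)
  expect_equal(same$p_value, 1)
  expect_equal(same$auc_a, same$auc_b)

  set.seed(45)
  for (rep in 1:10) {
    lab <- c(0, 1, rbinom(78, 1, 0.5))
    sa <- rnorm(80) + lab
    sb <- rnorm(80) + 0.3 * lab
    ours <- delong_test(sa, sb, lab)
    ra <- pROC::roc(lab, sa, quiet = TRUE, levels = c(0, 1), direction = "<")
    rb <- pROC::roc(lab, sb, quiet = TRUE, levels = c(0, 1), direction = "<")
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    # invariance to common monotone transforms
    trans <- delong_test(exp(sa), exp(sb), lab)
    expect_equal(trans$p_value, ours$p_value, tolerance = 1e-9)
  }
})

test_that("Holm adjustment is step-down, monotone, and permutation-equivariant", {
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(c(0.05, 0.05, 0.05)), c(0.15, 0.15, 0.15))

  set.seed(46)
  for (rep in 1:50) {
    p <- runif(sample(1:8, 1))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    perm <- sample(seq_along(p))
    expect_equal(holm_adjust(p[perm]), adj[perm])
  }
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(holm_adjust(c(-0.1, 0.5)), "\\[0, 1\\]")
})
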