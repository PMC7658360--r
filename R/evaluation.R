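#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability: the fraction of
#' (positive, negative) pairs in which the positive sample outscores the
#' negative one, ties counting 1/2. Equivalent to the trapezoidal area under
#' the empirical ROC curve.
#'
#' @param scores Numeric vector of classifier scores (higher = more positive).
#' @param labels Binary labels (0/1 vector or two-level factor), same length.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))  # 1
#' @export
auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (any(!labels %in% c(0, 1))) stop("labels must be binary 0/1")
  as.integer(labels)
}

#' Empirical ROC curve
#'
#' Operating points are generated at every distinct score value (classifying
#' `score >= threshold` as positive), bracketed by the degenerate points
#' (0, 0) at threshold `Inf` and (1, 1) at `-Inf`. The stored `auc` is the
#' trapezoidal area of the curve, identical to [auc()].
#'
#' @inheritParams auc
#' @return An object of class `"roc_curve"`: a list with a `points` data frame
#'   (`fpr`, `tpr`, `threshold`) and the scalar `auc`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)            # last duplicate of each score block
  tp <- cumsum(l)[keep]
  fp <- cumsum(1L - l)[keep]
  pts <- data.frame(
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos),
    threshold = c(Inf, s[keep])
  )
  area <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = area, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, AUC = %.4f (%d pos / %d neg)\n",
              nrow(x$points), x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Export an ROC curve as TSV
#'
#' @param curve A `"roc_curve"` object.
#' @param path Output file path.
#' @export
write_roc_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "roc_curve"))
  utils::write.table(curve$points, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Operating-point metrics at the Youden-optimal threshold
#'
#' Chooses the ROC operating point maximizing Youden's
#' J = sensitivity + specificity - 1, ties broken toward higher sensitivity,
#' and reports sensitivity, specificity, positive and negative predictive
#' values there. Predictive values with empty denominators (degenerate
#' all-positive / all-negative calls) are `NA`.
#'
#' @inheritParams auc
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`, `threshold`,
#'   and `youden_j`.
#' @export
operating_metrics <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  rc <- roc_points(scores, labels)
  pts <- rc$points[-1L, , drop = FALSE]     # drop (0,0,Inf): no calls made
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  best <- best[which.max(pts$tpr[best])]    # tie toward sensitivity
  thr <- pts$threshold[best]
  pred <- as.integer(scores >= thr)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = safe_div(tp, tp + fp),
       npv = safe_div(tn, tn + fn),
       threshold = thr,
       youden_j = max(j))
}

#' Stratified k-fold cross-validation plan
#'
#' Assigns each sample to exactly one validation fold. Fold sizes differ by
#' at most one; when `labels` are supplied the folds are stratified so each
#' class is spread across folds as evenly as possible. The shuffle is seeded.
#'
#' @param n Number of samples.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @param labels Optional binary labels for stratification.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
kfold_split <- function(n, k = 10L, seed = 1L, labels = NULL) {
  if (n < k) stop("n (", n, ") must be at least the fold count k (", k, ")")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  if (is.null(labels)) {
    ord <- sample.int(n)
  } else {
    labels <- as_binary_labels(labels)
    if (length(labels) != n) stop("labels length must equal n")
    # shuffle within class, then concatenate classes: cycling fold ids over
    # this ordering balances fold sizes globally and per class
    ord <- unlist(lapply(split(seq_len(n), labels),
                         function(ix) ix[sample.int(length(ix))]),
                  use.names = FALSE)
  }
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  folds
}

#' Balance classes by seeded undersampling
#'
#' Randomly undersamples the majority class without replacement down to the
#' minority-class count, so that downstream fitting sees equal numbers of
#' positives and negatives. Retained indices keep their original order.
#'
#' @param labels Binary labels (0/1).
#' @param seed Integer seed for the subsample.
#' @return Sorted integer vector of retained sample indices.
#' @export
balance_classes <- function(labels, seed = 1L) {
  labels <- as_binary_labels(labels)
  idx_pos <- which(labels == 1L)
  idx_neg <- which(labels == 0L)
  if (!length(idx_pos) || !length(idx_neg)) stop("both classes must be present")
  n_keep <- min(length(idx_pos), length(idx_neg))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  keep <- c(
    if (length(idx_pos) > n_keep) sample(idx_pos, n_keep) else idx_pos,
    if (length(idx_neg) > n_keep) sample(idx_neg, n_keep) else idx_neg
  )
  sort(keep)
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric paired comparison of the AUCs of two scorers evaluated on
#' the same samples, using the asymptotic normal distribution of the AUC
#' difference with variance estimated from placement values (structural
#' components). When the estimated variance of the difference is zero and the
#' AUCs are equal (e.g. identical scorers) the p-value is 1 by convention.
#'
#' @param scores_a,scores_b Paired score vectors from the two methods.
#' @param labels Shared binary labels.
#' @return List with `auc_a`, `auc_b`, `statistic` (z), and `p_value`
#'   (two-sided).
#' @references DeLong, DeLong and Clarke-Pearson (1988), Biometrics 44:837-845.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stop("scores and labels differ in length")
  pos <- labels == 1L
  m <- sum(pos)
  n <- sum(!pos)
  if (m == 0L || n == 0L) stop("both classes must be present")

  placements <- function(s) {
    sp <- s[pos]
    sn <- s[!pos]
    # v10[i]: fraction of negatives the i-th positive beats (ties 1/2)
    v10 <- vapply(sp, function(x) (sum(x > sn) + 0.5 * sum(x == sn)) / n, 0)
    v01 <- vapply(sn, function(x) (sum(sp > x) + 0.5 * sum(sp == x)) / m, 0)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (var_diff <= 0 || !is.finite(var_diff)) {
    if (abs(d) < 1e-12) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, statistic = 0, p_value = 1))
    }
    stop("zero variance of the AUC difference with unequal AUCs: inconsistent input")
  }
  z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, statistic = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Holm step-down multiple-testing adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "holm")`:
#' ascending p-values are multiplied by (m - rank + 1), a cumulative maximum
#' enforces monotonicity, values are capped at 1, and the input order is
#' restored.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # c(0.03, 0.06, 0.06)
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}
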