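#' Training-control settings for the LLGMN
#'
#' Bundles the hyperparameters of [llgmn_train()] used throughout the
#' pipeline. Defaults: one mixture component per class, learning rate 0.01,
#' at most 5000 epochs, convergence tolerance 1e-6 on the mean
#' cross-entropy.
#'
#' @param n_components Mixture components per class.
#' @param learning_rate Gradient step size.
#' @param max_epochs Epoch cap.
#' @param tol Convergence tolerance.
#' @return Named list of class `"llgmn_control"`.
#' @export
llgmn_control <- function(n_components = 1L, learning_rate = 0.01,
                          max_epochs = 5000L, tol = 1e-6) {
  stopifnot(n_components >= 1, learning_rate > 0, max_epochs >= 1, tol > 0)
  structure(list(n_components = as.integer(n_components),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), tol = tol),
            class = "llgmn_control")
}

stratified_holdout <- function(labels, frac = 0.2, seed = 1L) {
  labels <- as_binary_labels(labels)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  hold <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
    ix[sample.int(length(ix), max(1L, round(frac * length(ix))))]
  }), use.names = FALSE)
  sort(hold)
}

#' Full per-disorder mood-disorder identification analysis
#'
#' For each disorder label column: balances positives and negatives by
#' seeded undersampling, lays a stratified k-fold plan shared by all
#' methods, and in each fold (a) runs the greedy partial-KL backward
#' elimination on the fold's training split scored against the fold's
#' validation split (or an inner holdout of the training split when
#' `nested = TRUE`), adopts the subset with the largest validation AUC and
#' collects its validation posteriors, and (b) fits the three linear
#' reference classifiers (stepwise linear, ridge logistic, PLS) on the
#' identical training split. Validation scores are pooled across folds into
#' one ROC per method; operating metrics are taken at the Youden-optimal
#' threshold; the proposed model is compared with each baseline by the
#' DeLong test with Holm adjustment; and, when requested, a single-index
#' ablation ranking is computed on the modal selected index set.
#'
#' @param features N x P numeric matrix/data frame of evaluation indices.
#' @param labels Data frame (or named list) of binary label columns, one per
#'   disorder; or a single binary vector.
#' @param k Folds (default 10).
#' @param seed Master seed; every random stage derives from it.
#' @param control [llgmn_control()] settings for every LLGMN training.
#' @param reduction `"per_fold"` (default) greedy elimination inside each
#'   fold; `"none"` trains on all indices.
#' @param nested Score the elimination on an inner 20% holdout of the
#'   training split instead of the fold's validation split (slower, avoids
#'   selection-evaluation leakage; the selected model is then refitted on
#'   the whole training split).
#' @param ablation Compute the ablation ranking (needs `reduction !=
#'   "none"` and a modal set of >= 2 indices).
#' @param ablation_denominator `"relative"` reduction in percent of the
#'   selected model's AUC, or `"absolute"` percentage points.
#' @return Named list of `"disorder_report"` objects (one per label column).
#' @export
run_full_analysis <- function(features, labels, k = 10L, seed = 1L,
                              control = llgmn_control(),
                              reduction = c("per_fold", "none"),
                              nested = FALSE, ablation = TRUE,
                              ablation_denominator = c("relative", "absolute")) {
  reduction <- match.arg(reduction)
  ablation_denominator <- match.arg(ablation_denominator)
  features <- validate_feature_matrix(features)
  if (is.atomic(labels) && !is.list(labels)) labels <- list(disorder = labels)
  labels <- as.data.frame(labels)
  if (nrow(labels) != nrow(features))
    stop("features and labels disagree on the number of patients")

  reports <- list()
  for (d in seq_along(labels)) {
    disorder <- names(labels)[d]
    reports[[disorder]] <- tryCatch(
      analyze_disorder(features, as_binary_labels(labels[[d]]), disorder,
                       k = k, seed = seed + (d - 1L) * 1000L,
                       control = control, reduction = reduction,
                       nested = nested, ablation = ablation,
                       ablation_denominator = ablation_denominator),
      error = function(e) stop("disorder '", disorder, "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  reports
}

analyze_disorder <- function(features, y, disorder, k, seed, control,
                             reduction, nested, ablation,
                             ablation_denominator) {
  keep <- balance_classes(y, seed = seed)
  x_b <- features[keep, , drop = FALSE]
  y_b <- y[keep]
  n <- length(y_b)
  folds <- kfold_split(n, k = k, seed = seed + 1L, labels = y_b)

  methods <- c("proposed", "stepwise_linear", "logistic", "pls")
  scores <- matrix(NA_real_, nrow = n, ncol = length(methods),
                   dimnames = list(NULL, methods))
  fold_dims <- vector("list", k)

  for (f in seq_len(k)) {
    stage <- "fold setup"
    tr <- which(folds != f)
    va <- which(folds == f)
    res <- tryCatch({
      stage <- "proposed model"
      if (reduction == "per_fold") {
        if (nested) {
          inner <- stratified_holdout(y_b[tr], frac = 0.2, seed = seed + 10L + f)
          trace <- greedy_eliminate(
            x_b[tr[-inner], , drop = FALSE], y_b[tr[-inner]],
            x_b[tr[inner], , drop = FALSE], y_b[tr[inner]],
            n_components = control$n_components,
            learning_rate = control$learning_rate,
            max_epochs = control$max_epochs, tol = control$tol,
            seed = seed + 2L)
          best <- select_best(trace)
          model <- llgmn_train(x_b[tr, best$dims, drop = FALSE], y_b[tr],
                               n_components = control$n_components,
                               learning_rate = control$learning_rate,
                               max_epochs = control$max_epochs,
                               tol = control$tol, seed = seed + 2L)
        } else {
          trace <- greedy_eliminate(
            x_b[tr, , drop = FALSE], y_b[tr],
            x_b[va, , drop = FALSE], y_b[va],
            n_components = control$n_components,
            learning_rate = control$learning_rate,
            max_epochs = control$max_epochs, tol = control$tol,
            seed = seed + 2L)
          best <- select_best(trace)
          model <- best$model
        }
        dims <- best$dims
      } else {
        dims <- colnames(x_b)
        model <- llgmn_train(x_b[tr, , drop = FALSE], y_b[tr],
                             n_components = control$n_components,
                             learning_rate = control$learning_rate,
                             max_epochs = control$max_epochs,
                             tol = control$tol, seed = seed + 2L)
      }
      prop <- predict(model, x_b[va, dims, drop = FALSE])[, "present"]
      stage <- "baselines"
      base <- fit_baselines(x_b[tr, , drop = FALSE], y_b[tr])
      list(dims = dims, prop = prop,
           base = lapply(base, predict, newdata = x_b[va, , drop = FALSE]))
    }, error = function(e) {
      stop("disorder '", disorder, "', fold ", f, ", stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
    fold_dims[[f]] <- res$dims
    scores[va, "proposed"] <- res$prop
    for (b in names(res$base)) scores[va, b] <- res$base[[b]]
  }

  rocs <- lapply(methods, function(m) roc_points(scores[, m], y_b))
  names(rocs) <- methods
  metrics <- lapply(methods, function(m) operating_metrics(scores[, m], y_b))
  names(metrics) <- methods

  comparisons <- lapply(methods[-1L], function(m)
    delong_test(scores[, "proposed"], scores[, m], y_b))
  p_raw <- vapply(comparisons, `[[`, 0, "p_value")
  p_holm <- holm_adjust(p_raw)
  delong <- data.frame(
    method = methods[-1L],
    auc_proposed = vapply(comparisons, `[[`, 0, "auc_a"),
    auc_baseline = vapply(comparisons, `[[`, 0, "auc_b"),
    p_raw = p_raw, p_holm = p_holm,
    stringsAsFactors = FALSE
  )

  sel <- summarize_selection(fold_dims, colnames(x_b))
  abl <- NULL
  if (isTRUE(ablation) && reduction == "per_fold" && length(sel$modal) >= 2L) {
    abl <- ablation_ranking(x_b, y_b, sel$modal, k = k, seed = seed,
                            control = control,
                            denominator = ablation_denominator)
  }

  structure(list(
    disorder = disorder,
    n_balanced = n,
    n_positive = sum(y_b == 1L),
    k = k,
    seed = seed,
    reduction = reduction,
    nested = nested,
    pooled_scores = scores,
    labels = y_b,
    roc = rocs,
    auc = vapply(rocs, `[[`, 0, "auc"),
    operating_metrics = metrics,
    delong = delong,
    selection = sel,
    ablation = abl
  ), class = "disorder_report")
}

summarize_selection <- function(fold_dims, all_dims) {
  freq <- table(factor(unlist(fold_dims), levels = all_dims))
  freq <- freq[freq > 0]
  sets <- vapply(fold_dims, function(d) paste(sort(d), collapse = "|"), "")
  modal_key <- names(sort(table(sets), decreasing = TRUE))[1L]
  modal <- intersect(all_dims, strsplit(modal_key, "|", fixed = TRUE)[[1L]])
  list(per_fold = fold_dims,
       union_freq = data.frame(index = names(freq),
                               folds_selected = as.integer(freq),
                               stringsAsFactors = FALSE),
       modal = modal,
       size_range = range(lengths(fold_dims)))
}

#' Single-index ablation ranking
#'
#' Quantifies each retained index's contribution: under one shared
#' stratified CV plan, the cross-validated pooled AUC of the LLGMN trained
#' on `selected_dims` is compared with the AUC obtained after disregarding
#' one index at a time. The reduction is reported in percent, either
#' relative to the selected model's AUC (default) or in absolute percentage
#' points, and the ranking is sorted descending.
#'
#' @param features Balanced feature matrix.
#' @param labels Balanced binary labels.
#' @param selected_dims Index names retained by the reduction (>= 2).
#' @param k,seed,control As in [run_full_analysis()].
#' @param denominator `"relative"` or `"absolute"`.
#' @return Data frame `index`, `auc_ablated`, `auc_selected`,
#'   `reduction_pct`, sorted by decreasing reduction.
#' @export
ablation_ranking <- function(features, labels, selected_dims, k = 10L,
                             seed = 1L, control = llgmn_control(),
                             denominator = c("relative", "absolute")) {
  denominator <- match.arg(denominator)
  features <- validate_feature_matrix(features)
  labels <- as_binary_labels(labels)
  if (length(selected_dims) < 2L) stop("need at least 2 selected indices")
  if (!all(selected_dims %in% colnames(features)))
    stop("selected_dims not all present in features")
  folds <- kfold_split(length(labels), k = k, seed = seed + 1L, labels = labels)

  cv_auc <- function(dims) {
    sc <- rep(NA_real_, length(labels))
    for (f in seq_len(k)) {
      tr <- which(folds != f)
      va <- which(folds == f)
      model <- llgmn_train(features[tr, dims, drop = FALSE], labels[tr],
                           n_components = control$n_components,
                           learning_rate = control$learning_rate,
                           max_epochs = control$max_epochs, tol = control$tol,
                           seed = seed + 2L)
      sc[va] <- predict(model, features[va, dims, drop = FALSE])[, "present"]
    }
    auc(sc, labels)
  }

  auc_sel <- cv_auc(selected_dims)
  auc_abl <- vapply(selected_dims,
                    function(i) cv_auc(setdiff(selected_dims, i)), 0)
  reduction <- if (denominator == "relative") {
    100 * (auc_sel - auc_abl) / auc_sel
  } else {
    100 * (auc_sel - auc_abl)
  }
  out <- data.frame(index = selected_dims,
                    auc_selected = auc_sel,
                    auc_ablated = auc_abl,
                    reduction_pct = reduction,
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(-out$reduction_pct), , drop = FALSE]
}

#' @export
print.disorder_report <- function(x, ...) {
  cat(sprintf("Disorder report: %s (n = %d balanced, %d-fold CV)\n",
              x$disorder, x$n_balanced, x$k))
  cat("  pooled AUC:",
      paste(sprintf("%s %.3f", names(x$auc), x$auc), collapse = ", "), "\n")
  m <- x$operating_metrics$proposed
  cat(sprintf("  proposed @ Youden: sens %.3f spec %.3f ppv %.3f npv %.3f\n",
              m$sensitivity, m$specificity, m$ppv, m$npv))
  cat(sprintf("  selected indices (modal set, %d): %s\n",
              length(x$selection$modal),
              paste(x$selection$modal, collapse = ", ")))
  if (!is.null(x$ablation)) {
    top <- utils::head(x$ablation, 3L)
    cat("  top ablation:",
        paste(sprintf("%s %.2f%%", top$index, top$reduction_pct),
              collapse = ", "), "\n")
  }
  invisible(x)
}

report_to_list <- function(report) {
  stopifnot(inherits(report, "disorder_report"))
  list(
    disorder = report$disorder,
    n_balanced = report$n_balanced,
    n_positive = report$n_positive,
    k = report$k,
    seed = report$seed,
    reduction = report$reduction,
    nested = report$nested,
    auc = as.list(report$auc),
    operating_metrics = report$operating_metrics,
    delong = report$delong,
    selection = list(union_freq = report$selection$union_freq,
                     modal = report$selection$modal,
                     per_fold = report$selection$per_fold),
    ablation = report$ablation
  )
}

#' Serialize a disorder report to JSON
#'
#' Writes the report's scalar and tabular content (AUCs, operating metrics,
#' DeLong comparisons, selection summary, ablation ranking) as JSON;
#' [read_report_json()] restores the same structure.
#'
#' @param report A `"disorder_report"`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
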