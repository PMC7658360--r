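#' Kullback-Leibler information between targets and predicted posteriors
#'
#' Sums, over validation samples, the KL divergence from the predicted
#' two-class posterior to the one-hot target:
#' `sum_n sum_k Q_k log(Q_k / Y_k)` with natural logarithm and the
#' convention `0 log 0 = 0`. For one-hot targets this reduces to
#' `-sum_n log Y_true`. Posteriors are clipped to `[clip_eps, 1 - clip_eps]`
#' before the logarithm.
#'
#' @param targets N x 2 one-hot matrix (or 0/1 label vector).
#' @param posteriors N x 2 matrix of class posteriors.
#' @param clip_eps Posterior clipping bound.
#' @return Nonnegative scalar; 0 iff the posterior equals the target on
#'   every sample.
#' @export
kl_information <- function(targets, posteriors, clip_eps = 1e-12) {
  q <- as_onehot(targets)
  y <- as.matrix(posteriors)
  if (nrow(q) != nrow(y) || ncol(y) != 2L)
    stop("targets and posteriors must both have N rows and 2 columns")
  y <- pmin(pmax(y, clip_eps), 1 - clip_eps)
  truth <- max.col(q)
  sum(-log(y[cbind(seq_len(nrow(y)), truth)]))
}

#' Partial KL information ratio
#'
#' Ratio `E = KL_current / KL_candidate` comparing the validation KL
#' information of the current reduced model (numerator) with that of a
#' candidate model from which one more dimension has been removed
#' (denominator). A larger `E` means removing the candidate dimension harms
#' the fit less. A zero denominator is guarded by `eps`.
#'
#' @param kl_current Nonnegative KL information of the current model.
#' @param kl_candidate Nonnegative KL information of the candidate model.
#' @param eps Denominator guard.
#' @return Positive ratio.
#' @export
partial_kl_ratio <- function(kl_current, kl_candidate, eps = 1e-12) {
  if (kl_current < 0 || kl_candidate < 0) stop("KL information must be >= 0")
  kl_current / max(kl_candidate, eps)
}

#' Greedy backward input-dimensionality reduction by partial KL information
#'
#' Starting from the full index set, repeatedly removes the dimension whose
#' removal maximizes the partial KL information ratio `E` (i.e. least
#' degrades the validation fit), retraining a fresh LLGMN for every
#' candidate subset because the quadratic expansion changes with the input
#' dimension. The loop runs exactly P - 1 steps, leaving one dimension. The
#' trace records, for every adopted removal, the ratio `E`, both KL terms
#' and the validation AUC of the reduced model; [select_best()] then picks
#' the subset with the largest validation AUC.
#'
#' @param train_x,train_y Training split (features x binary labels).
#' @param val_x,val_y Validation split used for the KL and AUC criteria.
#' @param n_components,learning_rate,max_epochs,tol,seed Passed to
#'   [llgmn_train()]; each candidate model is trained with the same seed.
#' @param store_models Keep the adopted model at each step (needed by
#'   [select_best()] to return a model without retraining).
#' @return An object of class `"reduction_trace"` with elements
#'   `initial_dims`, `initial` (KL/AUC/model of the full-input state) and a
#'   `steps` data frame (`step`, `removed`, `E`, `kl_numerator`,
#'   `kl_denominator`, `auc`, `denominator_guarded`).
#' @export
greedy_eliminate <- function(train_x, train_y, val_x, val_y,
                             n_components = 1L, learning_rate = 0.01,
                             max_epochs = 5000L, tol = 1e-6, seed = 1L,
                             store_models = TRUE) {
  train_x <- validate_feature_matrix(train_x)
  val_x <- validate_feature_matrix(val_x)
  if (!identical(colnames(train_x), colnames(val_x)))
    stop("training and validation index names differ")
  p <- ncol(train_x)
  if (p < 2L) stop("at least 2 input dimensions are required")
  val_lab <- as_binary_labels_from_targets(val_y)

  fit_eval <- function(dims) {
    model <- llgmn_train(train_x[, dims, drop = FALSE], train_y,
                         n_components = n_components,
                         learning_rate = learning_rate,
                         max_epochs = max_epochs, tol = tol, seed = seed)
    post <- predict(model, val_x[, dims, drop = FALSE])
    list(model = model,
         kl = kl_information(val_y, post),
         auc = auc(post[, "present"], val_lab))
  }

  all_dims <- colnames(train_x)
  current <- fit_eval(all_dims)
  initial <- list(kl = current$kl, auc = current$auc,
                  model = if (store_models) current$model else NULL)
  remaining <- all_dims
  kl_now <- current$kl

  steps <- vector("list", p - 1L)
  models <- vector("list", p - 1L)
  for (step in seq_len(p - 1L)) {
    cand <- lapply(remaining, function(dim_out) {
      tryCatch(fit_eval(setdiff(remaining, dim_out)),
               error = function(e) NULL)
    })
    ok <- !vapply(cand, is.null, TRUE)
    if (!any(ok)) stop("all candidate trainings failed at step ", step)
    e_vals <- rep(-Inf, length(remaining))
    e_vals[ok] <- vapply(cand[ok], function(cc) partial_kl_ratio(kl_now, cc$kl), 0)
    best <- which.max(e_vals)            # first max = lowest dim index tie-break
    chosen <- cand[[best]]
    steps[[step]] <- data.frame(
      step = step,
      removed = remaining[best],
      E = e_vals[best],
      kl_numerator = kl_now,
      kl_denominator = chosen$kl,
      auc = chosen$auc,
      denominator_guarded = chosen$kl < 1e-12,
      stringsAsFactors = FALSE
    )
    if (store_models) models[[step]] <- chosen$model
    remaining <- setdiff(remaining, remaining[best])
    kl_now <- chosen$kl
  }

  structure(list(
    initial_dims = all_dims,
    initial = initial,
    steps = do.call(rbind, steps),
    models = if (store_models) models else NULL
  ), class = "reduction_trace")
}

as_binary_labels_from_targets <- function(y) {
  if (is.matrix(y)) max.col(as_onehot(y)) - 1L else as_binary_labels(y)
}

#' @export
print.reduction_trace <- function(x, ...) {
  cat(sprintf("Backward elimination trace: P = %d, %d steps\n",
              length(x$initial_dims), nrow(x$steps)))
  cat(sprintf("  full-input validation AUC = %.4f\n", x$initial$auc))
  best <- select_best(x)
  cat(sprintf("  best state: %d dims, AUC = %.4f\n",
              length(best$dims), best$auc))
  invisible(x)
}

#' Select the reduced model with the largest validation AUC
#'
#' Scans the full-input state and every reduction step of a trace and
#' returns the state with the maximal validation AUC; ties are broken
#' toward fewer dimensions.
#'
#' @param trace A `"reduction_trace"` from [greedy_eliminate()].
#' @return List with `dims` (retained index names), `auc`, `step` (0 = full
#'   input), and `model` (when the trace stored models).
#' @export
select_best <- function(trace) {
  stopifnot(inherits(trace, "reduction_trace"))
  if (is.null(trace$steps) || nrow(trace$steps) == 0L) stop("empty trace")
  aucs <- c(trace$initial$auc, trace$steps$auc)
  best <- max(which(aucs == max(aucs))) - 1L   # latest max = fewest dims
  dims <- trace$initial_dims
  if (best > 0L) dims <- setdiff(dims, trace$steps$removed[seq_len(best)])
  model <- if (best == 0L) trace$initial$model else
    if (!is.null(trace$models)) trace$models[[best]] else NULL
  list(dims = dims, auc = aucs[best + 1L], step = best, model = model)
}

#' Export a reduction trace
#'
#' @param trace A `"reduction_trace"`.
#' @param path Output path (`.tsv` or `.json` by `format`).
#' @param format `"tsv"` or `"json"`.
#' @export
write_trace <- function(trace, path, format = c("tsv", "json")) {
  stopifnot(inherits(trace, "reduction_trace"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(trace$steps, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    jsonlite::write_json(list(initial_dims = trace$initial_dims,
                              initial_auc = trace$initial$auc,
                              initial_kl = trace$initial$kl,
                              steps = trace$steps),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
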