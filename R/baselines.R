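#' Stepwise multiple linear regression baseline
#'
#' Regresses the 0/1 disorder label on the evaluation indices with classical
#' forward-backward stepwise selection on partial-F p-values: a variable
#' enters when its addition p-value is <= `p_enter` (default 0.05) and is
#' removed when its retention p-value exceeds `p_remove` (default 0.10).
#' When no variable meets the entry criterion the intercept-only model is
#' returned (a valid scorer with AUC 0.5). The classification score is the
#' fitted linear predictor.
#'
#' @param x Feature matrix / data frame (raw scales; selection p-values are
#'   scale-invariant).
#' @param y Binary 0/1 labels.
#' @param p_enter Entry threshold for the partial-F p-value.
#' @param p_remove Removal threshold.
#' @return Object of class `"baseline_model"` with `method = "stepwise_linear"`
#'   and the selected variable set.
#' @export
fit_stepwise_linear <- function(x, y, p_enter = 0.05, p_remove = 0.10) {
  x <- validate_feature_matrix(x)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  dat <- data.frame(.y = y, x, check.names = FALSE)
  vars <- colnames(x)
  selected <- character(0)
  seen <- character(0)                    # visited sets; guards add/drop cycles

  repeat {
    state <- paste(sort(selected), collapse = "\r")
    if (state %in% seen) break
    seen <- c(seen, state)
    changed <- FALSE
    # forward: best addition by partial-F p-value
    candidates <- setdiff(vars, selected)
    if (length(candidates) && length(selected) + 2L < nrow(dat)) {
      fit0 <- stats::lm(make_formula(selected), data = dat)
      a1 <- suppressWarnings(stats::add1(fit0, scope = make_formula(vars),
                                         test = "F"))
      pvals <- a1[["Pr(>F)"]][-1L]
      names(pvals) <- rownames(a1)[-1L]
      pvals <- pvals[is.finite(pvals)]
      if (length(pvals) && min(pvals) <= p_enter) {
        selected <- c(selected, names(pvals)[which.min(pvals)])
        changed <- TRUE
      }
    }
    # backward: drop any retained variable whose p-value exceeds p_remove
    if (length(selected)) {
      fit1 <- stats::lm(make_formula(selected), data = dat)
      d1 <- suppressWarnings(stats::drop1(fit1, test = "F"))
      pvals <- d1[["Pr(>F)"]][-1L]
      names(pvals) <- rownames(d1)[-1L]
      if (length(pvals) && max(pvals, na.rm = TRUE) > p_remove) {
        selected <- setdiff(selected, names(pvals)[which.max(pvals)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  fit <- stats::lm(make_formula(selected), data = dat)
  structure(list(method = "stepwise_linear", fit = fit, selected = selected,
                 index_names = colnames(x)),
            class = "baseline_model")
}

# env must be where `dat` lives: add1/drop1 re-evaluate the lm call there
make_formula <- function(vars, env = parent.frame()) {
  rhs <- if (!length(vars)) "1" else paste(sprintf("`%s`", vars), collapse = " + ")
  stats::as.formula(paste(".y ~", rhs), env = env)
}

#' Ridge-regularised logistic regression baseline
#'
#' Maximum-likelihood logistic regression on all standardized indices with a
#' small ridge penalty so that separable data still yield a finite fit. The
#' classification score is the linear predictor.
#'
#' @inheritParams fit_stepwise_linear
#' @param lambda Ridge penalty passed to `glmnet` (small; near-ML).
#' @return `"baseline_model"` with `method = "logistic"`.
#' @export
fit_logistic <- function(x, y, lambda = 1e-4) {
  x <- validate_feature_matrix(x)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  padded <- ncol(x) == 1L           # glmnet needs >= 2 columns; pad inertly
  xg <- if (padded) cbind(x, `.pad` = 0) else x
  fit <- glmnet::glmnet(xg, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  structure(list(method = "logistic", fit = fit, lambda = lambda,
                 padded = padded, index_names = colnames(x)),
            class = "baseline_model")
}

#' Partial least squares regression baseline
#'
#' PLS1 regression of the 0/1 label on the standardized indices with
#' `n_factors` latent factors (default 3); the classification score is the
#' predicted response.
#'
#' @inheritParams fit_stepwise_linear
#' @param n_factors Number of latent factors.
#' @return `"baseline_model"` with `method = "pls"`.
#' @export
fit_pls <- function(x, y, n_factors = 3L) {
  x <- validate_feature_matrix(x)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (n_factors > min(nrow(x) - 1L, ncol(x)))
    stop("n_factors exceeds min(N - 1, P)")
  fit <- mixOmics::pls(x, y, ncomp = n_factors, scale = TRUE, mode = "regression")
  structure(list(method = "pls", fit = fit, n_factors = n_factors,
                 index_names = colnames(x)),
            class = "baseline_model")
}

#' Predict classification scores from a baseline model
#'
#' @param object A `"baseline_model"`.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return Numeric score vector (one per row); higher = more likely positive.
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (!is.null(colnames(x))) x <- x[, object$index_names, drop = FALSE]
  switch(object$method,
    stepwise_linear = {
      dat <- as.data.frame(x, check.names = FALSE)
      as.numeric(stats::predict(object$fit, newdata = dat))
    },
    logistic = {
      if (isTRUE(object$padded)) x <- cbind(x, `.pad` = 0)
      as.numeric(stats::predict(object$fit, newx = x, type = "link"))
    },
    pls = {
      pr <- stats::predict(object$fit, newdata = x)
      as.numeric(pr$predict[, 1L, object$n_factors])
    },
    stop("unknown baseline method: ", object$method)
  )
}

#' @export
print.baseline_model <- function(x, ...) {
  cat("Baseline classifier:", x$method, "\n")
  if (x$method == "stepwise_linear")
    cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
        else "(intercept only)", "\n")
  if (x$method == "pls") cat("  latent factors:", x$n_factors, "\n")
  invisible(x)
}

# Fit all three reference classifiers on one training split.
fit_baselines <- function(x, y) {
  list(stepwise_linear = fit_stepwise_linear(x, y),
       logistic = fit_logistic(x, y),
       pls = fit_pls(x, y, n_factors = min(3L, nrow(as.matrix(x)) - 1L, ncol(as.matrix(x)))))
}
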