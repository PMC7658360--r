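#' Quadratic input expansion for the log-linearized Gaussian mixture network
#'
#' Maps a D-dimensional input vector `z` to the nonlinear feature vector
#' `[1, z_1, ..., z_D, z_1 z_1, z_1 z_2, ..., z_D z_D]` in which every
#' unordered quadratic pair appears exactly once, ordered
#' (1,1), (1,2), ..., (1,D), (2,2), ..., (D,D). The expanded length is
#' `H = 1 + D (D + 3) / 2`. Under this expansion a single linear
#' (log-linear) layer can represent the log of a Gaussian mixture component
#' density up to its normalizing constant, which is what lets the network
#' parameterize a Gaussian mixture classifier.
#'
#' @param z Numeric vector of finite values (length D >= 1).
#' @return Numeric vector of length `1 + D * (D + 3) / 2`.
#' @examples
#' expand_input(c(1, 2))  # c(1, 1, 2, 1, 2, 4)
#' @export
expand_input <- function(z) {
  if (!is.numeric(z) || length(z) < 1L) {
    stop("`z` must be a numeric vector of length >= 1")
  }
  bad <- which(!is.finite(z))
  if (length(bad)) {
    nm <- if (!is.null(names(z))) names(z)[bad] else as.character(bad)
    stop("non-finite input at index: ", paste(nm, collapse = ", "))
  }
  drop(expand_matrix(matrix(z, nrow = 1L)))
}

#' @return Expanded dimension H for an input dimension D.
#' @rdname expand_input
#' @param d Input dimension D.
#' @export
expansion_dim <- function(d) as.integer(1 + (d * (d + 3)) %/% 2)

# Row-wise quadratic expansion of an N x D matrix -> N x H matrix.
expand_matrix <- function(x) {
  d <- ncol(x)
  quad <- matrix(0, nrow = nrow(x), ncol = (d * (d + 1L)) %/% 2L)
  col <- 1L
  for (i in seq_len(d)) {
    for (j in i:d) {
      quad[, col] <- x[, i] * x[, j]
      col <- col + 1L
    }
  }
  cbind(1, x, quad)
}

# Component-unit memberships: the first M1 columns belong to class 1
# (absence), the next M2 to class 2 (presence); a scalar M means M per
# class. The very last unit's weights stay fixed at zero for
# identifiability (softmax is invariant to a common shift).
component_class <- function(m_per_class) {
  m <- rep_len(as.integer(m_per_class), 2L)
  rep(1:2, times = m)
}

# Forward pass on an already expanded matrix; returns list(post = N x 2 class
# posteriors, comp = N x K component activations).
llgmn_forward_expanded <- function(xh, weights, m_per_class) {
  a <- xh %*% weights
  a <- a - apply(a, 1L, max)          # overflow guard; softmax shift-invariant
  e <- exp(a)
  p <- e / rowSums(e)
  cls <- component_class(m_per_class)
  post <- cbind(rowSums(p[, cls == 1L, drop = FALSE]),
                rowSums(p[, cls == 2L, drop = FALSE]))
  colnames(post) <- c("absent", "present")
  list(post = post, comp = p)
}

as_onehot <- function(y) {
  if (is.matrix(y)) {
    if (ncol(y) != 2L || any(!y %in% c(0, 1)) || any(rowSums(y) != 1))
      stop("one-hot targets must be an N x 2 matrix of 0/1 with unit row sums")
    return(y)
  }
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (any(!y %in% c(0, 1))) stop("labels must be binary (0 = absent, 1 = present)")
  cbind(absent = 1 - y, present = y)
}

validate_feature_matrix <- function(x, impute = FALSE, medians = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("z", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop("index names must be unique")
  if (anyNA(x) || any(!is.finite(x))) {
    if (!impute) {
      bad <- colnames(x)[apply(x, 2L, function(v) any(!is.finite(v)))]
      stop("non-finite values in index: ", paste(bad, collapse = ", "),
           " (set impute = TRUE for training-split median imputation)")
    }
    if (is.null(medians)) {
      medians <- apply(x, 2L, function(v) stats::median(v[is.finite(v)]))
    }
    for (j in seq_len(ncol(x))) {
      x[!is.finite(x[, j]), j] <- medians[j]
    }
  }
  attr(x, "medians") <- medians
  x
}

#' Train a log-linearized Gaussian mixture network
#'
#' Fits a two-class LLGMN by full-batch gradient descent (error
#' backpropagation) on the cross-entropy between one-hot targets and the
#' class posteriors. Inputs are z-score standardized with training-set
#' statistics before the quadratic expansion; each class owns
#' `n_components` Gaussian-mixture component units whose softmax activations
#' are summed into the class posterior. The last component unit's weights are
#' fixed at zero for identifiability.
#'
#' @param x Numeric matrix or data frame, N patients x D evaluation indices.
#' @param y Binary labels: 0/1 vector, two-level factor, or N x 2 one-hot
#'   matrix (column order absent, present).
#' @param n_components Mixture components per class: a scalar M shared by
#'   both classes or a length-2 vector (absent, present).
#' @param learning_rate Gradient-descent step size on the mean gradient.
#' @param max_epochs Epoch cap.
#' @param tol Convergence tolerance on the change in mean cross-entropy.
#' @param seed Integer seed controlling weight initialization.
#' @param clip_eps Posterior clipping bound used before logarithms.
#' @param impute Impute non-finite values with training medians instead of
#'   rejecting them.
#' @return An object of class `"llgmn"` with the fitted weights, the
#'   standardization parameters, and the loss trace.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(80), ncol = 2)
#' y <- as.integer(x[, 1] + x[, 2] > 0)
#' fit <- llgmn_train(x, y, max_epochs = 200)
#' head(predict(fit, x))
#' @export
llgmn_train <- function(x, y, n_components = 1L, learning_rate = 0.01,
                        max_epochs = 5000L, tol = 1e-6, seed = 1L,
                        clip_eps = 1e-12, impute = FALSE) {
  stopifnot(learning_rate > 0, max_epochs >= 1, tol > 0, all(n_components >= 1),
            length(n_components) %in% 1:2, clip_eps > 0)
  x <- validate_feature_matrix(x, impute = impute)
  q <- as_onehot(y)
  if (nrow(x) != nrow(q)) stop("row counts of features and targets differ")
  if (any(colSums(q) == 0)) stop("training set must contain both classes")

  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  xh <- expand_matrix(xs)
  h <- ncol(xh)
  m <- rep_len(as.integer(n_components), 2L)
  k <- sum(m)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  w <- matrix(stats::runif(h * k, -0.01, 0.01), nrow = h, ncol = k)
  w[, k] <- 0                                 # fixed reference unit

  n <- nrow(xh)
  truth <- max.col(q)                         # 1 = absent, 2 = present
  cls <- component_class(m)
  in_truth <- outer(truth, cls, "==")         # N x K membership of true class
  loss_trace <- numeric(0)
  prev_loss <- Inf
  converged <- FALSE

  for (epoch in seq_len(max_epochs)) {
    fw <- llgmn_forward_expanded(xh, w, m)
    y_true <- pmin(pmax(fw$post[cbind(seq_len(n), truth)], clip_eps), 1 - clip_eps)
    loss <- -mean(log(y_true))
    if (!is.finite(loss)) {
      stop("training diverged (non-finite loss); reduce `learning_rate`")
    }
    loss_trace[epoch] <- loss
    if (abs(prev_loss - loss) < tol) {
      converged <- TRUE
      break
    }
    prev_loss <- loss
    # dL/da_k = p_k - p_k * 1{k in true class} / Y_true
    delta <- fw$comp - fw$comp * in_truth / y_true
    grad <- crossprod(xh, delta) / n
    grad[, k] <- 0
    w <- w - learning_rate * grad
  }

  structure(list(
    weights = w,
    n_components = m,
    input_dim = ncol(x),
    expansion_dim = h,
    index_names = colnames(x),
    center = center,
    scale = scale,
    medians = attr(x, "medians"),
    impute = impute,
    clip_eps = clip_eps,
    loss_trace = loss_trace,
    final_loss = loss_trace[length(loss_trace)],
    converged = converged,
    config = list(n_components = m, learning_rate = learning_rate,
                  max_epochs = max_epochs, tol = tol, seed = seed)
  ), class = "llgmn")
}

#' Posterior prediction from a fitted LLGMN
#'
#' Standardizes `newdata` with the training-set statistics stored in the
#' model, applies the quadratic expansion, and returns the two-class
#' posterior probabilities (columns `absent`, `present`); every row sums
#' to 1.
#'
#' @param object A fitted `"llgmn"` model.
#' @param newdata Matrix or data frame with the model's input columns. When
#'   column names are present they must contain the training index names;
#'   columns are reordered by name.
#' @param ... Unused.
#' @return N x 2 matrix of posterior probabilities.
#' @export
predict.llgmn <- function(object, newdata, ...) {
  x <- newdata
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(colnames(x)) && !is.null(object$index_names)) {
    missing_cols <- setdiff(object$index_names, colnames(x))
    if (length(missing_cols)) {
      stop("newdata lacks model indices: ", paste(missing_cols, collapse = ", "))
    }
    x <- x[, object$index_names, drop = FALSE]
  } else if (ncol(x) != object$input_dim) {
    stop("newdata has ", ncol(x), " columns; model expects ", object$input_dim)
  }
  if (any(!is.finite(x))) {
    if (!object$impute || is.null(object$medians)) {
      stop("non-finite values in prediction input")
    }
    for (j in seq_len(ncol(x))) x[!is.finite(x[, j]), j] <- object$medians[j]
  }
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  xh <- expand_matrix(xs)
  llgmn_forward_expanded(xh, object$weights, object$n_components)$post
}

#' @export
print.llgmn <- function(x, ...) {
  cat("Log-linearized Gaussian mixture network (two-class)\n")
  cat(sprintf("  input dim D = %d, expansion dim H = %d, components/class M = %s\n",
              x$input_dim, x$expansion_dim,
              paste(x$n_components, collapse = "/")))
  cat(sprintf("  epochs run = %d (%s), final cross-entropy = %.6f\n",
              length(x$loss_trace),
              if (x$converged) "converged" else "epoch cap reached",
              x$final_loss))
  invisible(x)
}

#' Serialize / restore an LLGMN model as JSON
#'
#' Writes the fitted weights, dimensions, index names and standardization
#' parameters to a JSON document so a model can be reloaded without
#' retraining.
#'
#' @param model A fitted `"llgmn"` model.
#' @param path File path for the JSON document.
#' @return `write_llgmn` returns `path` invisibly; `read_llgmn` returns the
#'   restored `"llgmn"` object.
#' @export
write_llgmn <- function(model, path) {
  stopifnot(inherits(model, "llgmn"))
  doc <- list(
    class = "llgmn",
    n_components = model$n_components,
    input_dim = model$input_dim,
    expansion_dim = model$expansion_dim,
    index_names = model$index_names,
    center = as.numeric(model$center),
    scale = as.numeric(model$scale),
    clip_eps = model$clip_eps,
    impute = model$impute,
    medians = if (is.null(model$medians)) NULL else as.numeric(model$medians),
    weights = model$weights,
    final_loss = model$final_loss,
    converged = model$converged,
    config = model$config
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_llgmn
#' @param path File path of a JSON document written by [write_llgmn()].
#' @export
read_llgmn <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$class, "llgmn")) stop("not an LLGMN JSON document")
  w <- doc$weights
  if (!is.matrix(w)) w <- do.call(rbind, lapply(doc$weights, unlist))
  dimnames(w) <- NULL
  structure(list(
    weights = w,
    n_components = as.integer(doc$n_components),
    input_dim = as.integer(doc$input_dim),
    expansion_dim = as.integer(doc$expansion_dim),
    index_names = doc$index_names,
    center = stats::setNames(doc$center, doc$index_names),
    scale = stats::setNames(doc$scale, doc$index_names),
    medians = doc$medians,
    impute = isTRUE(doc$impute),
    clip_eps = doc$clip_eps,
    loss_trace = numeric(0),
    final_loss = doc$final_loss,
    converged = isTRUE(doc$converged),
    config = doc$config
  ), class = "llgmn")
}
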