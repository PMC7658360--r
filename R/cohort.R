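#' Synthetic post-stroke cohort configuration
#'
#' Loads and validates a cohort-generator configuration. The packaged
#' default (`system.file("extdata", "cohort_defaults.yaml", package =
#' "llgmn")`) encodes group-conditional means/SDs for the continuous
#' evaluation indices, occurrence probabilities for the binary indices,
#' the psychological-score distributions from which disorder labels are
#' thresholded, group sizes, labeling cutoffs and latent-factor loadings.
#' Any element can be overridden via `...` (e.g. `groups = list(...)`).
#'
#' @param path YAML configuration path; defaults to the packaged file.
#' @param ... Named top-level overrides merged over the file contents.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(path = NULL, ...) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_defaults.yaml", package = "llgmn")
  }
  cfg <- yaml::read_yaml(path)
  orig_names <- cfg$groups$names
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  # overriding groups with a subset / reordering of the configured group
  # names subsets every per-group parameter vector accordingly
  new_names <- cfg$groups$names
  if (!identical(new_names, orig_names) && all(new_names %in% orig_names)) {
    ix <- match(new_names, orig_names)
    for (block in c("continuous", "binary", "scores")) {
      cfg[[block]] <- lapply(cfg[[block]], function(item) {
        for (f in intersect(c("mean", "sd", "prob"), names(item))) {
          if (length(item[[f]]) == length(orig_names)) item[[f]] <- item[[f]][ix]
        }
        item
      })
    }
  }
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  problems <- character(0)
  g <- cfg$groups
  if (is.null(g$names) || is.null(g$sizes) || length(g$names) != length(g$sizes))
    problems <- c(problems, "groups$names/sizes missing or of unequal length")
  if (any(g$sizes < 0)) problems <- c(problems, "groups$sizes must be >= 0")
  n_groups <- length(g$names)
  check_block <- function(block, block_name, fields) {
    for (nm in names(block)) {
      item <- block[[nm]]
      for (f in fields) {
        if (length(item[[f]]) != n_groups)
          problems <<- c(problems, sprintf("%s$%s$%s must have %d entries",
                                           block_name, nm, f, n_groups))
      }
      if (!is.null(item$sd) && any(item$sd < 0))
        problems <<- c(problems, sprintf("%s$%s$sd must be >= 0", block_name, nm))
      if (!is.null(item$prob) && any(item$prob < 0 | item$prob > 1))
        problems <<- c(problems, sprintf("%s$%s$prob must lie in [0,1]", block_name, nm))
      if (!is.null(item$bounds) && item$bounds[1] >= item$bounds[2])
        problems <<- c(problems, sprintf("%s$%s$bounds must be ordered", block_name, nm))
    }
  }
  check_block(cfg$continuous, "continuous", c("mean", "sd"))
  check_block(cfg$binary, "binary", "prob")
  check_block(cfg$scores, "scores", c("mean", "sd"))
  mix_mode <- is.null(cfg$factors$mode) || identical(cfg$factors$mode, "mix")
  for (f in c("stress_loading", "speed_loading")) {
    v <- cfg$factors[[f]]
    if (!is.null(v) && (!is.finite(v) || (mix_mode && abs(v) > 1)))
      problems <- c(problems, paste0("factors$", f,
                                     " must be finite (and in [-1,1] in 'mix' mode)"))
  }
  if (length(problems)) {
    stop("invalid cohort configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  structure(cfg, class = "cohort_config")
}

# Truncated-Gaussian draws with a shared latent-factor contribution. In
# "mix" mode value = mean + sd * (loading * factor + sqrt(1-loading^2) * eps),
# preserving the marginal SD; in "additive" mode value = mean +
# sd * (loading * factor + eps), so a larger loading adds shared variance.
# The idiosyncratic noise is re-drawn for out-of-bounds values (rejection),
# keeping the latent-factor contribution.
rtrunc_factor <- function(n, mean, sd, bounds, factor_values, loading,
                          mode = "mix") {
  stopifnot(length(factor_values) == n)
  base <- mean + sd * loading * factor_values
  resid_sd <- if (mode == "mix") sd * sqrt(1 - loading^2) else sd
  x <- base + resid_sd * stats::rnorm(n)
  for (iter in 1:200) {
    bad <- which(x < bounds[1] | x > bounds[2])
    if (!length(bad)) break
    x[bad] <- base[bad] + resid_sd * stats::rnorm(length(bad))
  }
  pmin(pmax(x, bounds[1]), bounds[2])   # clamp pathological stragglers
}

#' Generate a synthetic post-stroke cohort
#'
#' Draws, per configured group, continuous evaluation indices as truncated
#' Gaussians around the group means with two shared patient-level latent
#' factors (a "perceived stress" factor loading on the psychological scores
#' and JPSS, and a "processing speed" factor loading on the timing indices),
#' binary indices as Bernoulli draws, and integer psychological scores from
#' which the three mood-disorder labels are thresholded (HADS subscales
#' strictly above `hads_cutoff`, apathy score strictly above
#' `apathy_cutoff`). Fully reproducible by `seed`.
#'
#' @param config A `"cohort_config"`, e.g. from [cohort_config()].
#' @param seed Integer seed.
#' @return An object of class `"cohort"`: list with `features` (N x P numeric
#'   matrix, patient ids as row names), `scores` (data frame of the three
#'   psychological scores), `labels` (data frame with logical `psd`,
#'   `apathy`, `anxiety`), and `group` (factor).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  config <- validate_cohort_config(unclass(config))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  sizes <- config$groups$sizes
  gnames <- config$groups$names
  n <- sum(sizes)
  group_id <- rep(seq_along(sizes), sizes)
  feat_names <- c(names(config$continuous), names(config$binary))
  features <- matrix(NA_real_, nrow = n, ncol = length(feat_names),
                     dimnames = list(NULL, feat_names))
  score_names <- names(config$scores)
  scores <- matrix(NA_real_, nrow = n, ncol = length(score_names),
                   dimnames = list(NULL, score_names))

  stress <- stats::rnorm(n)
  speed <- stats::rnorm(n)
  factor_mode <- config$factors$mode %||% "mix"
  if (!factor_mode %in% c("mix", "additive"))
    stop("factors$mode must be 'mix' or 'additive'")
  loading_of <- function(item) {
    f <- item$factor
    if (is.null(f)) return(list(values = numeric(0), loading = 0))
    switch(f,
           stress = list(values = stress, loading = config$factors$stress_loading %||% 0),
           speed = list(values = speed, loading = config$factors$speed_loading %||% 0),
           stop("unknown factor tag: ", f))
  }

  for (g in seq_along(sizes)) {
    rows <- which(group_id == g)
    if (!length(rows)) next
    for (nm in names(config$continuous)) {
      item <- config$continuous[[nm]]
      lf <- loading_of(item)
      fv <- if (length(lf$values)) lf$values[rows] else numeric(length(rows))
      features[rows, nm] <- rtrunc_factor(length(rows), item$mean[g], item$sd[g],
                                          item$bounds, fv, lf$loading,
                                          mode = factor_mode)
    }
    for (nm in names(config$binary)) {
      features[rows, nm] <- stats::rbinom(length(rows), 1L, config$binary[[nm]]$prob[g])
    }
    for (nm in score_names) {
      item <- config$scores[[nm]]
      lf <- loading_of(item)
      fv <- if (length(lf$values)) lf$values[rows] else numeric(length(rows))
      raw <- rtrunc_factor(length(rows), item$mean[g], item$sd[g],
                           item$bounds, fv, lf$loading, mode = factor_mode)
      scores[rows, nm] <- pmin(pmax(round(raw), item$bounds[1]), item$bounds[2])
    }
  }

  rownames(features) <- sprintf("patient_%03d", seq_len(max(n, 1L))[seq_len(n)])
  scores <- as.data.frame(scores)
  labels <- assign_mood_labels(scores$hads_depression, scores$hads_anxiety,
                               scores$apathy_score)
  structure(list(
    features = features,
    scores = scores,
    labels = labels,
    group = factor(gnames[group_id], levels = gnames),
    config = config,
    seed = seed
  ), class = "cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients x %d indices\n",
              nrow(x$features), ncol(x$features)))
  print(table(group = x$group))
  cat("disorder prevalence:",
      sprintf("%s %.2f", names(x$labels), colMeans(x$labels)), "\n")
  invisible(x)
}

#' Threshold psychological scores into mood-disorder labels
#'
#' Post-stroke depression is labeled when HADS-Depression is strictly above
#' 9, anxiety when HADS-Anxiety is strictly above 9, and apathy when the
#' apathy score is strictly above 16.
#'
#' @param hads_depression,hads_anxiety Integer HADS subscale scores (0-21).
#' @param apathy_score Integer apathy scores (0-42).
#' @param hads_cutoff,apathy_cutoff Label cutoffs (strict inequality).
#' @return Data frame with logical columns `psd`, `apathy`, `anxiety`.
#' @examples
#' assign_mood_labels(10, 9, 17)  # psd TRUE, anxiety FALSE, apathy TRUE
#' @export
assign_mood_labels <- function(hads_depression, hads_anxiety, apathy_score,
                               hads_cutoff = 9, apathy_cutoff = 16) {
  check_scores <- function(v, lo, hi, nm) {
    if (any(!is.finite(v)) || any(v < lo) || any(v > hi) || any(v != round(v)))
      stop(nm, " must be integers in [", lo, ", ", hi, "]")
  }
  check_scores(hads_depression, 0, 21, "hads_depression")
  check_scores(hads_anxiety, 0, 21, "hads_anxiety")
  check_scores(apathy_score, 0, 42, "apathy_score")
  data.frame(psd = hads_depression > hads_cutoff,
             apathy = apathy_score > apathy_cutoff,
             anxiety = hads_anxiety > hads_cutoff)
}

#' FIM improvement rate
#'
#' Score gain of the Functional Independence Measure per week of
#' hospitalisation: `(discharge - admission) / weeks`.
#'
#' @param fim_admission,fim_discharge FIM scores (total 18-126; motor
#'   subscale 13-91; cognitive subscale 5-35).
#' @param weeks Hospitalisation period in weeks (> 0).
#' @return Improvement rate in FIM points per week.
#' @examples
#' fim_improvement_rate(62, 82, 10)  # 2
#' @export
fim_improvement_rate <- function(fim_admission, fim_discharge, weeks) {
  if (any(weeks <= 0)) stop("hospitalisation period must be > 0 weeks")
  for (v in list(fim_admission, fim_discharge)) {
    if (any(!is.finite(v)) || any(v < 5) || any(v > 126))
      stop("FIM scores must lie within the instrument range (5-126)")
  }
  (fim_discharge - fim_admission) / weeks
}

#' Planted-signal synthetic cohort
#'
#' Small, fully controlled generator used for power/recovery experiments:
#' `n_informative` informative indices plus `n_noise` pure-noise indices,
#' all unit-variance Gaussian. With `boundary = "linear"` the informative
#' indices get a between-class mean shift of `effect` SD; with
#' `boundary = "quadratic"` the class is the sign of the product of the
#' first two informative indices (an XOR-like boundary carrying no linear
#' signal), corrupted by `label_noise`. The attribute `informative` on the
#' feature matrix names the ground-truth informative columns.
#'
#' @param n Total number of samples (classes balanced).
#' @param n_informative Number of informative indices (>= 2 for quadratic).
#' @param n_noise Number of pure-noise indices.
#' @param effect Between-class mean shift in SD units (linear boundary).
#' @param boundary `"linear"` or `"quadratic"`.
#' @param label_noise Label-flip probability (quadratic boundary).
#' @param seed Integer seed.
#' @return List with `features` (matrix; attribute `"informative"`),
#'   `labels` (0/1 integer vector).
#' @export
planted_cohort <- function(n, n_informative = 2L, n_noise = 3L, effect = 2,
                           boundary = c("linear", "quadratic"),
                           label_noise = 0.05, seed = 1L) {
  boundary <- match.arg(boundary)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  p <- n_informative + n_noise
  x <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  info_names <- if (n_informative) paste0("signal_", seq_len(n_informative)) else character(0)
  colnames(x) <- c(info_names,
                   if (n_noise) paste0("noise_", seq_len(n_noise)) else character(0))
  if (boundary == "linear") {
    y <- rep_len(c(0L, 1L), n)[sample.int(n)]
    if (n_informative) {
      x[y == 1L, seq_len(n_informative)] <-
        x[y == 1L, seq_len(n_informative)] + effect
    }
  } else {
    if (n_informative < 2L) stop("quadratic boundary needs >= 2 informative indices")
    y <- as.integer(x[, 1L] * x[, 2L] > 0)
    flip <- stats::runif(n) < label_noise
    y[flip] <- 1L - y[flip]
  }
  attr(x, "informative") <- info_names
  list(features = x, labels = y)
}

#' Write a cohort as CSV (features + one label column per disorder)
#'
#' @param cohort A `"cohort"` object.
#' @param path Output CSV path.
#' @param include_scores Also write the raw psychological scores.
#' @export
write_cohort_csv <- function(cohort, path, include_scores = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  df <- data.frame(patient_id = rownames(cohort$features),
                   cohort$features,
                   group = as.character(cohort$group),
                   lapply(cohort$labels, as.integer),
                   check.names = FALSE)
  if (include_scores) df <- cbind(df, cohort$scores)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort_csv()] (or any feature CSV
#' with `psd`/`apathy`/`anxiety` 0-1 label columns)
#'
#' @param path CSV path with a header row.
#' @return A `"cohort"`-like list with `features`, `labels` and, when
#'   present, `group`.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  label_cols <- intersect(c("psd", "apathy", "anxiety"), names(df))
  if (!length(label_cols)) stop("no disorder label columns found in ", path)
  meta_cols <- intersect(c("patient_id", "group"), names(df))
  feat <- as.matrix(df[, setdiff(names(df), c(label_cols, meta_cols)), drop = FALSE])
  storage.mode(feat) <- "double"
  if ("patient_id" %in% meta_cols) rownames(feat) <- df$patient_id
  structure(list(
    features = feat,
    labels = as.data.frame(lapply(df[label_cols], function(v) v == 1)),
    group = if ("group" %in% meta_cols) factor(df$group) else NULL
  ), class = "cohort")
}
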