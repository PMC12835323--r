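# Threshold calibration against expert annotations: exhaustive grid search
# minimising the mean squared BS-duration error, evaluated under stratified
# k-fold cross-validation with per-recording absolute error metrics.

#' Default detection parameter grid
#'
#' Suppression thresholds 1–10 uV crossed with envelope windows
#' 0.25/0.5/1.0 s; the remaining detection parameters are held at their
#' defaults. The grid brackets the 5 uV literature threshold.
#'
#' @param theta_supp numeric vector of thresholds (uV).
#' @param w_env numeric vector of envelope windows (s).
#' @return A data frame with columns `theta_supp` and `w_env`, ordered by
#'   increasing `theta_supp` then `w_env` (the tie-break order).
#' @export
default_param_grid <- function(theta_supp = 1:10,
                               w_env = c(0.25, 0.5, 1.0)) {
  g <- expand.grid(w_env = sort(w_env), theta_supp = sort(theta_supp),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$theta_supp, g$w_env), c("theta_supp", "w_env")]
  rownames(g) <- NULL
  g
}

#' Detector error against an annotated ground truth
#'
#' Absolute error of the detected total suppressed time against the
#' annotated total (channel-`"all"` suppression intervals), in seconds and
#' as a BSR percentage-point error; both use the analysed recording length
#' as the denominator.
#'
#' @param pred a [bs_summary] from [detect_bs()], or a single number giving
#'   the detected total suppressed time in seconds (then `analyzed_s` is
#'   required).
#' @param truth a [bs_annotations] track of expert suppressions.
#' @param analyzed_s recording length in seconds (taken from `pred` when it
#'   is a [bs_summary]).
#' @return Named numeric vector `c(duration_error = , bsr_error = )`.
#' @examples
#' truth <- bs_annotations(onset = 0, duration = 20.64, label = "suppression")
#' duration_error(0, truth, analyzed_s = 3600)  # 20.64 s, 0.573 %
#' @export
duration_error <- function(pred, truth, analyzed_s = NULL) {
  if (inherits(pred, "bs_summary")) {
    analyzed_s <- pred$analyzed_s
    pred <- pred$bs_duration
  }
  if (is.null(analyzed_s))
    stop("analyzed_s is required when pred is a plain duration")
  truth <- validate_annotations(truth)
  if (nrow(truth) && any(truth$onset + truth$duration > analyzed_s + 1e-6))
    stop("ground-truth interval extends beyond the analysed span")
  true_dur <- interval_total(truth, "suppression", channel = "all")
  derr <- abs(pred - true_dur)
  c(duration_error = derr, bsr_error = 100 * derr / analyzed_s)
}

# Detected total suppressed time for one labelled recording at every grid
# point, reproducing the detect_bs() chain (per-channel minimum-duration
# filter, all-channel AND, consensus re-filter) with the envelope computed
# once per window length. Returns a vector over grid rows.
filter_short_runs <- function(mask, min_len) {
  r <- rle(mask)
  r$values[r$values & r$lengths < min_len] <- FALSE
  inverse.rle(r)
}

grid_durations_one <- function(lr, grid, base = detection_params()) {
  rec <- lr$recording
  fs <- rec_fs(rec)
  n <- nrow(rec)
  out <- numeric(nrow(grid))
  for (w in unique(grid$w_env)) {
    envs <- lapply(seq_len(ncol(rec)), function(j)
      amplitude_envelope(rec[, j], fs, w))
    min_len <- ceiling(base$d_supp_min * fs - 1e-9)
    for (r in which(grid$w_env == w)) {
      th <- grid$theta_supp[r]
      mask <- rep(TRUE, n)
      for (e in envs) mask <- mask & filter_short_runs(e < th, min_len)
      out[r] <- sum(filter_short_runs(mask, min_len)) / fs
    }
  }
  out
}

# n_recordings x n_grid matrix of detected durations, plus truth totals and
# analysed lengths. The per-recording computation is independent of every
# other recording, so precomputing it once for all CV folds cannot leak
# held-out information into training.
grid_durations <- function(data, grid, base = detection_params()) {
  det <- vapply(data, grid_durations_one, numeric(nrow(grid)),
                grid = grid, base = base)
  det <- t(matrix(det, nrow = nrow(grid)))   # recordings x grid points
  truth <- vapply(data, function(l)
    interval_total(l$truth, "suppression", channel = "all"), numeric(1L))
  len <- vapply(data, function(l) rec_duration(l$recording), numeric(1L))
  list(detected = det, truth = truth, analyzed = len)
}

pick_best <- function(gd, rows, grid, objective) {
  err <- gd$detected[rows, , drop = FALSE] - gd$truth[rows]
  if (objective == "bsr")
    err <- 100 * err / gd$analyzed[rows]
  mse <- colMeans(err^2)
  # exhaustive argmin; grid rows are pre-ordered by (theta_supp, w_env) so
  # which.min on the minimal values applies the documented tie-break
  best <- which(mse <= min(mse) + 1e-12)[1L]
  best
}

#' Optimise detection parameters on annotated recordings
#'
#' Exhaustive grid search minimising the mean squared error of the detected
#' total BS duration (or BSR, with `objective = "bsr"`) over the training
#' recordings. Ties are broken in favour of the smaller suppression
#' threshold, then the smaller envelope window.
#'
#' @param train non-empty list of [labeled_recording] objects.
#' @param grid data frame with columns `theta_supp` and `w_env` (see
#'   [default_param_grid()]).
#' @param objective `"duration"` (default) or `"bsr"`.
#' @param base a [detection_params] supplying the non-searched parameters.
#' @return A [detection_params] object at the selected grid point, with the
#'   attained training MSE in attribute `"mse"`.
#' @export
optimize_params <- function(train, grid = default_param_grid(),
                            objective = c("duration", "bsr"),
                            base = detection_params()) {
  objective <- match.arg(objective)
  if (!length(train)) stop("empty training set")
  if (!is.data.frame(grid) || nrow(grid) == 0L ||
      !all(c("theta_supp", "w_env") %in% names(grid)))
    stop("grid must be a non-empty data frame with theta_supp and w_env")
  grid <- grid[order(grid$theta_supp, grid$w_env), , drop = FALSE]
  gd <- grid_durations(train, grid, base)
  best <- pick_best(gd, seq_along(train), grid, objective)
  p <- detection_params(theta_supp = grid$theta_supp[best],
                        w_env = grid$w_env[best],
                        d_supp_min = base$d_supp_min,
                        d_burst_min = base$d_burst_min,
                        n_phases_min = base$n_phases_min,
                        g_max = base$g_max)
  err <- gd$detected[, best] - gd$truth
  if (objective == "bsr") err <- 100 * err / gd$analyzed
  attr(p, "mse") <- mean(err^2)
  p
}

# Stratified fold assignment: within each group, a seeded shuffle followed
# by cyclic fold labels, so fold sizes differ by at most one per stratum.
stratified_folds <- function(groups, k, seed) {
  n <- length(groups)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("more folds (", k, ") than recordings (", n, ")")
  fold <- integer(n)
  withr::with_seed(seed, {
    for (g in unique(groups)) {
      idx <- which(groups == g)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k) - 1L, length(idx))
    }
  })
  fold
}

#' Calibrate the detector by stratified k-fold cross-validation
#'
#' Folds are stratified by anesthetic group. For each fold, detection
#' parameters are fitted on the other k−1 folds by [optimize_params()] and
#' the per-recording absolute errors (BS duration in seconds, BSR in
#' percentage points) are computed on the held-out recordings, so every
#' recording is scored exactly once, by parameters its own annotations never
#' influenced. With `per_group = TRUE` the two anesthetic groups are
#' calibrated by two fully independent cross-validations.
#'
#' @param data list of [labeled_recording] objects (or a `bs_corpus`).
#' @param k number of folds (default 10).
#' @param grid parameter grid, see [default_param_grid()].
#' @param seed integer seed for the fold shuffle (required: results are
#'   deterministic given the seed).
#' @param objective `"duration"` or `"bsr"` MSE, passed to
#'   [optimize_params()].
#' @param per_group calibrate each anesthetic group independently.
#' @param base non-searched detection parameters.
#' @return An object of class `"bs_cv"`: `fold_assignments` (named integer
#'   vector, 0..k−1), `per_fold_params`, `errors` (data frame with
#'   `recording_id`, `group`, `fold`, `duration_error`, `bsr_error`),
#'   `median_duration_error`, `median_bsr_error`, `iqr_duration_error`,
#'   and the call settings.
#' @export
bs_calibrate <- function(data, k = 10, grid = default_param_grid(),
                         seed, objective = c("duration", "bsr"),
                         per_group = FALSE, base = detection_params()) {
  objective <- match.arg(objective)
  if (missing(seed)) stop("a seed is required for reproducible folds")
  data <- unclass(data)
  if (!length(data)) stop("empty recording list")
  groups <- vapply(data, `[[`, character(1L), "group")
  ids <- vapply(data, `[[`, character(1L), "recording_id")
  if (anyDuplicated(ids)) stop("duplicate recording_id in data")
  if (per_group) {
    parts <- lapply(unique(groups), function(g) {
      bs_calibrate(data[groups == g], k = k, grid = grid,
                   seed = seed, objective = objective, per_group = FALSE,
                   base = base)
    })
    errors <- do.call(rbind, lapply(parts, `[[`, "errors"))
    res <- list(
      fold_assignments = unlist(lapply(parts, `[[`, "fold_assignments")),
      per_fold_params = setNames(lapply(parts, `[[`, "per_fold_params"),
                                 unique(groups)),
      errors = errors,
      median_duration_error = median(errors$duration_error),
      median_bsr_error = median(errors$bsr_error),
      iqr_duration_error = unname(quantile(errors$duration_error,
                                           c(0.25, 0.75), type = 7)),
      k = k, seed = seed, objective = objective, per_group = TRUE)
    class(res) <- "bs_cv"
    return(res)
  }
  grid <- grid[order(grid$theta_supp, grid$w_env), , drop = FALSE]
  fold <- stratified_folds(groups, k, seed)
  gd <- grid_durations(data, grid, base)
  per_fold <- vector("list", k)
  derr <- numeric(length(data))
  berr <- numeric(length(data))
  for (f in seq_len(k) - 1L) {
    train_rows <- which(fold != f)
    test_rows <- which(fold == f)
    best <- pick_best(gd, train_rows, grid, objective)
    p <- detection_params(theta_supp = grid$theta_supp[best],
                          w_env = grid$w_env[best],
                          d_supp_min = base$d_supp_min,
                          d_burst_min = base$d_burst_min,
                          n_phases_min = base$n_phases_min,
                          g_max = base$g_max)
    per_fold[[f + 1L]] <- p
    derr[test_rows] <- abs(gd$detected[test_rows, best] -
                             gd$truth[test_rows])
    berr[test_rows] <- 100 * derr[test_rows] / gd$analyzed[test_rows]
  }
  errors <- data.frame(recording_id = ids, group = groups, fold = fold,
                       duration_error = derr, bsr_error = berr,
                       stringsAsFactors = FALSE)
  res <- list(
    fold_assignments = setNames(fold, ids),
    per_fold_params = per_fold,
    errors = errors,
    median_duration_error = median(derr),
    median_bsr_error = median(berr),
    iqr_duration_error = unname(quantile(derr, c(0.25, 0.75), type = 7)),
    k = k, seed = seed, objective = objective, per_group = FALSE)
  class(res) <- "bs_cv"
  res
}

#' @export
print.bs_cv <- function(x, ...) {
  cat("<bs_cv> ", x$k, "-fold stratified cross-validation (",
      nrow(x$errors), " recordings", if (x$per_group) ", per-group", ")\n",
      "  median |BS duration error|: ",
      format(x$median_duration_error, digits = 4), " s  [IQR ",
      format(x$iqr_duration_error[1L], digits = 4), "-",
      format(x$iqr_duration_error[2L], digits = 4), "]\n",
      "  median |BSR error|: ", format(x$median_bsr_error, digits = 4),
      " %\n", sep = "")
  invisible(x)
}

#' Summarise cross-validated detector errors
#'
#' Median and inter-quartile range (linear-interpolation quartiles) of the
#' per-recording absolute BS-duration error (s) and BSR error (%), overall
#' and per anesthetic group.
#'
#' @param object a [bs_cv] result from [bs_calibrate()].
#' @param ... unused.
#' @return A data frame with one row per stratum (`overall` plus each
#'   group).
#' @export
summary.bs_cv <- function(object, ...) {
  err <- object$errors
  strata <- c(list(overall = err),
              split(err, err$group))
  out <- do.call(rbind, lapply(names(strata), function(nm) {
    e <- strata[[nm]]
    qd <- quantile(e$duration_error, c(0.25, 0.5, 0.75), type = 7)
    qb <- quantile(e$bsr_error, c(0.25, 0.5, 0.75), type = 7)
    data.frame(stratum = nm, n = nrow(e),
               median_duration_error = qd[[2L]],
               iqr_lo_duration = qd[[1L]], iqr_hi_duration = qd[[3L]],
               median_bsr_error = qb[[2L]],
               iqr_lo_bsr = qb[[1L]], iqr_hi_bsr = qb[[3L]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
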