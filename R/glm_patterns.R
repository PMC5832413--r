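# Object-evoked pattern estimation: double-gamma HRF, event-to-design
# convolution, per-run OLS with nuisance covariates, beta -> t, run averaging.
# OLS stands in for prewhitened GLS: the synthetic data carry white noise, for
# which prewhitening is a no-op (see the methods vignette).

#' Double-gamma hemodynamic response function
#'
#' Canonical HRF: a gamma density peaking near `peak_delay` seconds minus a
#' scaled gamma undershoot peaking near `undershoot_delay` seconds, normalized
#' to peak amplitude 1.
#'
#' @param t uniform time grid in seconds, starting at 0
#' @param peak_delay peak delay in s (default 6)
#' @param undershoot_delay undershoot delay in s (default 16)
#' @param ratio undershoot-to-peak amplitude ratio (default 1/6)
#' @param peak_disp,undershoot_disp dispersions in s (default 1)
#' @return numeric vector, the HRF sampled on `t`, peak value 1
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             ratio = 1 / 6, peak_disp = 1, undershoot_disp = 1) {
  if (length(t) < 2) stop("time grid needs at least two points")
  dt <- diff(t)
  if (t[1] != 0 || max(abs(dt - dt[1])) > 1e-8 * dt[1])
    stop("time grid must be uniform and start at 0")
  h <- dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * dgamma(t, shape = undershoot_delay / undershoot_disp,
                   scale = undershoot_disp)
  h / max(h)
}

#' Construct an event table
#'
#' One row per stimulus presentation within a run: onset and duration in
#' seconds, the object concept shown, and the task context of the run.
#'
#' @param run run index
#' @param context task context, `"visual"` or `"conceptual"`
#' @param object object concept label
#' @param onset onset in seconds (nonnegative, strictly increasing per run)
#' @param duration stimulus duration in seconds (study value 2)
#' @return a `data.frame` of class `event_table`
#' @export
event_table <- function(run, context, object, onset, duration = 2) {
  n <- length(object)
  df <- data.frame(run = as.integer(rep_len(run, n)),
                   context = as.character(rep_len(context, n)),
                   object = as.character(object), onset = as.numeric(onset),
                   duration = as.numeric(rep_len(duration, n)),
                   stringsAsFactors = FALSE)
  if (any(!df$context %in% c("visual", "conceptual")))
    stop("context must be 'visual' or 'conceptual'")
  if (any(df$onset < 0)) stop("onsets must be nonnegative")
  for (rn in unique(df$run)) {
    o <- df$onset[df$run == rn]
    if (is.unsorted(o, strictly = TRUE)) stop("onsets must be strictly increasing within run ", rn)
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' Build a single-run GLM design matrix
#'
#' One regressor per object: a delta (stick) function at each event onset,
#' convolved with the double-gamma HRF on an oversampled grid and sampled at
#' volume acquisition times, plus an intercept column.
#'
#' @param events an `event_table` for one run
#' @param tr repetition time in seconds
#' @param n_volumes number of volumes in the run
#' @param oversample microtime resolution: grid step is `tr / oversample`
#' @param hrf_fun HRF generator taking a time grid (default
#'   [hrf_double_gamma()])
#' @return numeric matrix `n_volumes` x (n_objects + 1); object columns named
#'   by object, last column `"(intercept)"`
#' @export
build_design <- function(events, tr, n_volumes, oversample = 16L,
                         hrf_fun = hrf_double_gamma) {
  if (length(unique(events$run)) > 1) stop("build_design expects a single run")
  if (nrow(events) > 0 && any(events$onset >= n_volumes * tr))
    stop("event onset beyond the end of the run")
  objects <- unique(events$object)
  for (ob in objects) {
    o <- sort(events$onset[events$object == ob])
    d <- events$duration[events$object == ob][1]
    if (length(o) > 1 && any(diff(o) < d))
      stop("overlapping events for object ", ob)
  }
  dt <- tr / oversample
  grid_n <- n_volumes * oversample + 32L * oversample  # pad for HRF tail
  hrf <- hrf_fun(seq(0, by = dt, length.out = 32L * oversample))
  vol_idx <- 1L + (seq_len(n_volumes) - 1L) * oversample
  X <- matrix(0, n_volumes, length(objects) + 1L,
              dimnames = list(NULL, c(objects, "(intercept)")))
  for (j in seq_along(objects)) {
    stick <- numeric(grid_n)
    ons <- events$onset[events$object == objects[j]]
    stick[pmin(grid_n, 1L + round(ons / dt))] <- 1
    reg <- convolve(stick, rev(hrf), type = "open")[seq_len(grid_n)]
    X[, j] <- reg[vol_idx]
  }
  X[, length(objects) + 1L] <- 1
  X
}

#' Construct a time-series container
#'
#' @param data volumes x voxels numeric matrix
#' @param tr repetition time in seconds (study value 2)
#' @param run run index
#' @param nuisance volumes x k matrix of nuisance covariates (e.g. motion
#'   parameters), or NULL
#' @return a list of class `timeseries`
#' @export
timeseries <- function(data, tr = 2, run = 1L, nuisance = NULL) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("time series contains non-finite values")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nrow(data)) stop("nuisance rows must match volumes")
    if (any(!is.finite(nuisance))) stop("nuisance covariates must be finite")
  }
  structure(list(data = data, tr = tr, run = as.integer(run),
                 nuisance = nuisance), class = "timeseries")
}

#' Estimate object betas and t-statistics by per-voxel OLS
#'
#' Fits `y = [design, nuisance] b + e` by ordinary least squares at every
#' voxel and converts object-regressor betas to t-statistics,
#' `t = beta / SE(beta)` with residual degrees of freedom
#' `volumes - rank(design)`.
#'
#' @param ts a `timeseries`
#' @param design design matrix from [build_design()] (object columns + intercept)
#' @return list with `beta` and `t` (objects x voxels matrices), `df`, and
#'   `objects`
#' @export
estimate_patterns <- function(ts, design) {
  X <- design
  if (!is.null(ts$nuisance)) {
    nz <- ts$nuisance
    colnames(nz) <- paste0("nuisance", seq_len(ncol(nz)))
    X <- cbind(design, nz)
  }
  y <- ts$data
  if (nrow(X) != nrow(y)) stop("design rows must match volumes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- nrow(X) - qrX$rank
  if (df <= 0) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  xtx_inv_piv <- chol2inv(qr.R(qrX))          # (X'X)^-1 in pivoted column order
  diag_inv <- numeric(ncol(X))
  diag_inv[qrX$pivot] <- diag(xtx_inv_piv)
  se <- sqrt(outer(diag_inv, sigma2))         # regressors x voxels
  tval <- beta / se
  objects <- setdiff(colnames(design), "(intercept)")
  bo <- beta[objects, , drop = FALSE]
  to <- tval[objects, , drop = FALSE]
  colnames(bo) <- colnames(to) <- colnames(y)
  list(beta = bo, t = to, df = df, objects = objects)
}

#' Average per-run t-patterns into a pattern set
#'
#' @param per_run_patterns list of objects x voxels t matrices with identical
#'   dimnames
#' @param context task context
#' @param subject subject id
#' @param roi ROI/mask id
#' @return a `pattern_set`
#' @export
average_runs <- function(per_run_patterns, context = "visual",
                         subject = "s01", roi = "roi") {
  stopifnot(length(per_run_patterns) >= 1)
  ref <- per_run_patterns[[1]]
  for (m in per_run_patterns) {
    if (!identical(dim(m), dim(ref)) || !identical(rownames(m), rownames(ref)))
      stop("mismatched pattern shapes or object labels across runs")
  }
  avg <- Reduce(`+`, per_run_patterns) / length(per_run_patterns)
  pattern_set(avg, subject = subject, context = context, roi = roi)
}

#' Construct a pattern set
#'
#' Objects x voxels matrix of run-averaged t-values for one subject, task
#' context, and ROI/mask.
#'
#' @param data objects x voxels numeric matrix with object rownames
#' @param subject subject id
#' @param context task context
#' @param roi ROI/mask id
#' @return a list of class `pattern_set`
#' @export
pattern_set <- function(data, subject = "s01", context = "visual", roi = "roi") {
  data <- as.matrix(data)
  if (is.null(rownames(data))) rownames(data) <- paste0("obj", seq_len(nrow(data)))
  if (anyDuplicated(rownames(data))) stop("object labels must be unique")
  if (any(!is.finite(data))) stop("pattern values must be finite")
  structure(list(data = data, subject = subject, context = context, roi = roi),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set: %d objects x %d voxels (subject %s, context %s, roi %s)\n",
              nrow(x$data), ncol(x$data), x$subject, x$context, x$roi))
  invisible(x)
}
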