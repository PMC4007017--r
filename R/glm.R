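#' Canonical double-gamma haemodynamic response function
#'
#' The conventional BOLD impulse response: a gamma density peaking at
#' `peak_s` minus an undershoot gamma peaking at `undershoot_s`, scaled
#' by `undershoot_ratio`. With unit rate parameters the peak of a
#' gamma density with shape a is at a - 1, so the defaults (6 s peak,
#' 16 s undershoot, ratio 1/6) use shapes 7 and 17.
#'
#' @param t time in seconds (vector); values < 0 return 0.
#' @param peak_s,undershoot_s peak times of response and undershoot (s).
#' @param undershoot_ratio relative undershoot amplitude.
#' @return numeric vector of the HRF evaluated at `t`.
#' @export
canonical_hrf <- function(t, peak_s = 6, undershoot_s = 16,
                          undershoot_ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
  h[t < 0] <- 0
  h
}

# Boxcar for one mode's task blocks convolved with the HRF, evaluated on
# a fine grid and returned at the volume acquisition times. Shared by
# build_design() and simulate_bold() so the GLM matches the generator by
# construction.
convolved_regressor <- function(schedule, mode, hrf_params = list(),
                                dt = 0.1) {
  dur <- schedule_duration(schedule)
  grid <- seq(0, dur, by = dt)
  box <- numeric(length(grid))
  blocks <- task_blocks(schedule)
  blocks <- blocks[blocks$mode == mode, , drop = FALSE]
  for (i in seq_len(nrow(blocks)))
    box[grid >= blocks$onset_s[i] & grid < blocks$offset_s[i]] <- 1
  hrf <- do.call(canonical_hrf, c(list(t = seq(0, 32, by = dt)), hrf_params))
  conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(grid)] * dt
  vol_t <- (seq_len(schedule$n_volumes) - 1L) * schedule$tr_s
  stats::approx(grid, conv, xout = vol_t, rule = 2)$y
}

#' Build a first-level design matrix for one run
#'
#' One HRF-convolved boxcar regressor per coupling mode present in the
#' run, each with its temporal derivative (finite difference of the
#' convolved regressor), plus an intercept and polynomial drift terms.
#'
#' @param schedule a [task_schedule()].
#' @param hrf_params named list passed to [canonical_hrf()]
#'   (e.g. `list(peak_s = 5)`).
#' @param drift_order polynomial drift order (0 = intercept only;
#'   default 1 adds a linear trend).
#' @return An object of class `design_matrix`: a list with `X` (matrix,
#'   n_volumes x columns, named), `times` (volume times, s) and
#'   `task_cols` (names of the HRF columns per mode).
#' @export
build_design <- function(schedule, hrf_params = list(), drift_order = 1) {
  stopifnot(inherits(schedule, "task_schedule"))
  vol_t <- (seq_len(schedule$n_volumes) - 1L) * schedule$tr_s
  modes <- unique(schedule$mode_sequence)
  cols <- list(intercept = rep(1, schedule$n_volumes))
  for (k in seq_len(drift_order)) {
    z <- scale(vol_t^k)  # centred/scaled polynomial drift
    cols[[paste0("drift", k)]] <- as.numeric(z)
  }
  task_cols <- character(0)
  for (m in modes) {
    reg <- convolved_regressor(schedule, m, hrf_params)
    dreg <- c(0, diff(reg)) / schedule$tr_s
    if (all(abs(reg) < 1e-12))
      stop("all-zero task regressor for mode ", m)
    cols[[paste0("task_", m)]] <- reg
    cols[[paste0("deriv_", m)]] <- dreg
    task_cols <- c(task_cols, paste0("task_", m))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = X, times = vol_t, task_cols = task_cols),
            class = "design_matrix")
}

#' Simulate block-design BOLD-like ROI time series
#'
#' Each ROI series is the sum over modes of an amplitude times the
#' HRF-convolved mode boxcar, plus AR(1) Gaussian noise, sampled at the
#' TR for `n_volumes` volumes.
#'
#' @param schedule a [task_schedule()].
#' @param amplitudes matrix of task amplitudes, one row per mode in
#'   `schedule$mode_sequence` (rownames = modes), one column per ROI.
#' @param noise_sd innovation-scaled marginal SD of the AR(1) noise
#'   (0 for noiseless series).
#' @param ar_rho AR(1) autocorrelation of the noise (default 0.2).
#' @param hrf_params named list passed to [canonical_hrf()].
#' @param seed integer seed.
#' @return numeric matrix, n_volumes x ROIs (column names from
#'   `amplitudes`).
#' @export
simulate_bold <- function(schedule, amplitudes, noise_sd = 1,
                          ar_rho = 0.2, hrf_params = list(), seed = NULL) {
  stopifnot(inherits(schedule, "task_schedule"), is.matrix(amplitudes))
  modes <- unique(schedule$mode_sequence)
  if (!all(modes %in% rownames(amplitudes)))
    stop_validation("amplitudes must have one row per mode: ",
                    paste(modes, collapse = ", "))
  if (noise_sd < 0 || abs(ar_rho) >= 1)
    stop_validation("need noise_sd >= 0 and |ar_rho| < 1")
  n <- schedule$n_volumes
  regs <- vapply(modes, function(m)
    convolved_regressor(schedule, m, hrf_params), numeric(n))
  signal <- regs %*% amplitudes[modes, , drop = FALSE]
  with_seed(seed, {
    noise <- 0
    if (noise_sd > 0) {
      innov_sd <- noise_sd * sqrt(1 - ar_rho^2)  # marginal sd = noise_sd
      eps <- matrix(stats::rnorm(n * ncol(signal), 0, innov_sd),
                    n, ncol(signal))
      noise <- apply(eps, 2L, function(e)
        as.numeric(stats::filter(e, ar_rho, method = "recursive")))
    }
    out <- signal + noise
    colnames(out) <- colnames(amplitudes)
    out
  })
}

#' Fit an ordinary least-squares GLM to ROI time series
#'
#' @param series numeric matrix or vector, n_volumes x ROIs.
#' @param design a [build_design()] result.
#' @return An object of class `glm_fit`: list with `coef` (columns x
#'   ROIs), `sigma2` (residual variance per ROI, df = n - rank),
#'   `df_resid`, `XtX_inv`, `design`.
#' @export
fit_glm <- function(series, design) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- as.matrix(series)
  if (nrow(Y) != nrow(design$X))
    stop_validation("series length ", nrow(Y),
                    " does not match design rows ", nrow(design$X))
  if (anyNA(Y)) stop("NaN/NA in series")
  X <- design$X
  qrX <- qr(X)
  coef <- qr.coef(qrX, Y)
  resid <- Y - X %*% coef
  df_resid <- nrow(X) - qrX$rank
  sigma2 <- colSums(resid^2) / df_resid
  structure(list(coef = coef, sigma2 = sigma2, df_resid = df_resid,
                 XtX_inv = chol2inv(chol(crossprod(X))), resid = resid,
                 design = design),
            class = "glm_fit")
}

#' Linear contrast of GLM coefficients
#'
#' @param fit a [fit_glm()] result.
#' @param weights numeric contrast vector over design columns, or a
#'   named vector/list giving nonzero weights by column name.
#' @return data.frame with one row per ROI: `roi`, `estimate`, `se`,
#'   `t`, `df`.
#' @export
glm_contrast <- function(fit, weights) {
  stopifnot(inherits(fit, "glm_fit"))
  cn <- colnames(fit$design$X)
  if (!is.null(names(weights))) {
    w <- stats::setNames(numeric(length(cn)), cn)
    unknown <- setdiff(names(weights), cn)
    if (length(unknown))
      stop_validation("unknown design columns: ",
                      paste(unknown, collapse = ", "))
    w[names(weights)] <- unlist(weights)
  } else w <- as.numeric(weights)
  if (length(w) != length(cn))
    stop_validation("weights length must equal design column count")
  if (all(w == 0)) stop_validation("contrast weights are all zero")
  est <- drop(t(w) %*% fit$coef)
  se <- sqrt(fit$sigma2 * drop(t(w) %*% fit$XtX_inv %*% w))
  data.frame(roi = colnames(fit$coef) %||% seq_along(est),
             estimate = est, se = se, t = est / se, df = fit$df_resid,
             row.names = NULL)
}

#' Task-vs-rest contrast for one mode
#'
#' Convenience wrapper extracting the HRF-column estimate for a mode
#' (the temporal derivative is excluded from the contrast by default,
#' following common practice for block designs).
#'
#' @param fit a [fit_glm()] result.
#' @param mode `"in_phase"` or `"anti_phase"`.
#' @param include_derivative if `TRUE`, report the amplitude-weighted
#'   combination `sign(b) * sqrt(b^2 + d^2)` of the HRF and derivative
#'   coefficients instead of the HRF coefficient alone (no se/t).
#' @return as [glm_contrast()].
#' @export
mode_contrast <- function(fit, mode, include_derivative = FALSE) {
  col <- paste0("task_", mode)
  if (!col %in% colnames(fit$design$X))
    stop_validation("mode ", mode, " has no regressor in this design")
  if (!include_derivative)
    return(glm_contrast(fit, stats::setNames(1, col)))
  b <- fit$coef[col, ]
  d <- fit$coef[paste0("deriv_", mode), ]
  data.frame(roi = colnames(fit$coef) %||% seq_along(b),
             estimate = sign(b) * sqrt(b^2 + d^2), se = NA_real_,
             t = NA_real_, df = fit$df_resid, row.names = NULL)
}

#' Read/write ROI time-series tables as TSV (volume x ROI)
#' @param series numeric matrix, volumes x ROIs.
#' @param path file path.
#' @export
write_series_tsv <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE))
}
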