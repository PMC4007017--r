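#' Draw multivariate ROI observations from a known path model
#'
#' Each observation (row) is generated as `x = solve(I - A) %*% zeta`
#' with `zeta ~ N(0, Psi)` (independent components, Psi diagonal), so
#' the population covariance is the model-implied
#' `(I - A)^-1 Psi (I - A)^-T` and the sample covariance converges to
#' it as n grows. An optional mean is added; it does not affect the
#' covariance structure.
#'
#' @param truth a [connectivity_truth()].
#' @param n_subjects number of observations (rows), at least 2.
#' @param seed integer seed for reproducibility.
#' @param mean scalar or per-variable mean added to every draw
#'   (default 0).
#' @return numeric matrix, `n_subjects` x p, columns named by variable.
#' @export
simulate_roi_observations <- function(truth, n_subjects, seed = NULL,
                                      mean = 0) {
  stopifnot(inherits(truth, "connectivity_truth"))
  if (n_subjects < 2) stop_validation("n_subjects must be >= 2")
  mats <- truth_matrices(truth)
  p <- length(truth$variables)
  IA <- diag(p) - mats$A
  if (abs(det(IA)) < 1e-12)
    stop("model error: (I - A) is singular")
  with_seed(seed, {
    zeta <- matrix(stats::rnorm(n_subjects * p), n_subjects, p)
    zeta <- sweep(zeta, 2L, sqrt(diag(mats$Psi)), `*`)
    x <- zeta %*% t(solve(IA))  # x' = (I-A)^-1 zeta'
    colnames(x) <- truth$variables
    sweep(x, 2L, rep_len(mean, p), `+`)
  })
}

#' Model-implied covariance of a path model
#'
#' `Sigma(theta) = (I - A)^-1 Psi (I - A)^-T`, the covariance of
#' observations generated by the structural system `x = A x + zeta`.
#'
#' @param model a [connectivity_truth()] (no `params` needed) or a bare
#'   [path_model()] with a free-parameter vector `params` (paths first,
#'   then disturbance variances, then any free disturbance covariances).
#' @param params numeric parameter vector for a bare [path_model()].
#' @return symmetric p x p matrix with variable dimnames.
#' @export
implied_covariance <- function(model, params = NULL) {
  stopifnot(inherits(model, "path_model"))
  mats <- if (inherits(model, "connectivity_truth") && is.null(params))
    truth_matrices(model)
  else
    model_matrices(model, params)
  p <- nrow(mats$A)
  IA <- diag(p) - mats$A
  d <- det(IA)
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("model error: (I - A) is singular; a feedback loop has unit gain")
  B <- solve(IA)
  S <- B %*% mats$Psi %*% t(B)
  dimnames(S) <- dimnames(mats$A)
  (S + t(S)) / 2
}

#' Read/write subject-by-ROI observation tables as CSV
#'
#' One row per subject, one column per variable, plus a leading
#' `subject_id` column on disk.
#' @param x numeric matrix (subjects x variables).
#' @param path file path.
#' @export
write_betas_csv <- function(x, path) {
  df <- data.frame(subject_id = rownames(x) %||% seq_len(nrow(x)), x,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_betas_csv
#' @export
read_betas_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[setdiff(names(df), "subject_id")])
  rownames(m) <- df$subject_id
  m
}
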