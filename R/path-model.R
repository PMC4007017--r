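#' Default ROI variable set
#'
#' The ten bilateral motor-association regions used throughout: primary
#' motor (M1), primary somatosensory (S1), dorsal premotor (PMd),
#' supplementary motor area (SMA) and superior parietal lobule (SPL),
#' left and right.
#' @export
default_rois <- function() {
  as.vector(outer(c("L", "R"), c("M1", "S1", "PMd", "SMA", "SPL"),
                  function(h, r) paste(h, r, sep = ".")))
}

#' Directed path-model topology over observed variables
#'
#' Describes which directed paths (regression coefficients of the
#' structural matrix A, column variable -> row variable) are free, and
#' which disturbance (co)variances of the diagonal-or-sparse matrix Psi
#' are free. Every variable always has a free disturbance variance;
#' disturbance covariances are off by default.
#'
#' @param variables ordered character vector of variable names.
#' @param paths data.frame with character columns `from`, `to`; one row
#'   per free directed path. Self-paths are rejected; reciprocal pairs
#'   (nonrecursive models) are allowed.
#' @param psi_pairs optional data.frame with columns `var1`, `var2`
#'   naming free disturbance covariances (default none).
#' @return An object of class `path_model`.
#' @examples
#' m <- path_model(c("x", "y"), data.frame(from = "x", to = "y"))
#' model_df(m) # 3 moments - 3 parameters = 0
#' @export
path_model <- function(variables, paths, psi_pairs = NULL) {
  variables <- as.character(variables)
  p <- length(variables)
  if (p < 1L || anyDuplicated(variables))
    stop_validation("variables must be distinct names")
  paths <- as.data.frame(paths)
  if (!nrow(paths)) paths <- data.frame(from = character(), to = character())
  if (nrow(paths)) {
    if (!all(c("from", "to") %in% names(paths)))
      stop_validation("paths needs columns from, to")
    paths$from <- as.character(paths$from)
    paths$to <- as.character(paths$to)
    unknown <- setdiff(c(paths$from, paths$to), variables)
    if (length(unknown))
      stop_validation("paths mention unknown variables: ",
                      paste(unknown, collapse = ", "))
    if (any(paths$from == paths$to))
      stop_validation("self-paths are not allowed")
    if (anyDuplicated(paths[c("from", "to")]))
      stop_validation("duplicate paths")
  }
  if (!is.null(psi_pairs) && nrow(psi_pairs)) {
    psi_pairs <- as.data.frame(psi_pairs)
    psi_pairs$var1 <- as.character(psi_pairs$var1)
    psi_pairs$var2 <- as.character(psi_pairs$var2)
    if (!all(c(psi_pairs$var1, psi_pairs$var2) %in% variables) ||
        any(psi_pairs$var1 == psi_pairs$var2))
      stop_validation("psi_pairs must name two distinct known variables")
  } else psi_pairs <- NULL
  t_free <- nrow(paths) + p + if (is.null(psi_pairs)) 0L else nrow(psi_pairs)
  if (t_free > p * (p + 1) / 2)
    stop_validation("model has more free parameters (", t_free,
                    ") than covariance moments (", p * (p + 1) / 2, ")")
  structure(list(variables = variables,
                 paths = paths[c("from", "to")],
                 psi_pairs = psi_pairs),
            class = "path_model")
}

#' Free-parameter count and model degrees of freedom
#'
#' `model_n_free()` counts free parameters t (paths + disturbance
#' variances + free disturbance covariances); `model_df()` returns
#' p(p+1)/2 - t, the degrees of freedom of the chi-square fit test.
#'
#' @param model a [path_model()].
#' @export
model_n_free <- function(model) {
  stopifnot(inherits(model, "path_model"))
  nrow(model$paths) + length(model$variables) +
    if (is.null(model$psi_pairs)) 0L else nrow(model$psi_pairs)
}

#' @rdname model_n_free
#' @export
model_df <- function(model) {
  p <- length(model$variables)
  as.integer(p * (p + 1) / 2 - model_n_free(model))
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("path_model: %d variables, %d paths, t = %d free parameters, df = %d\n",
              length(x$variables), nrow(x$paths), model_n_free(x),
              model_df(x)))
  invisible(x)
}

# parameter vector layout: paths, then log/plain disturbance variances,
# then disturbance covariances (if any)
param_names <- function(model) {
  c(if (nrow(model$paths)) paste0(model$paths$from, "->", model$paths$to),
    paste0("var(", model$variables, ")"),
    if (!is.null(model$psi_pairs))
      paste0("cov(", model$psi_pairs$var1, ",", model$psi_pairs$var2, ")"))
}

# Build A and Psi matrices from a parameter vector in the layout above.
model_matrices <- function(model, params) {
  p <- length(model$variables)
  n_a <- nrow(model$paths)
  n_c <- if (is.null(model$psi_pairs)) 0L else nrow(model$psi_pairs)
  stopifnot(length(params) == n_a + p + n_c)
  A <- matrix(0, p, p, dimnames = list(model$variables, model$variables))
  if (n_a) {
    idx <- cbind(match(model$paths$to, model$variables),
                 match(model$paths$from, model$variables))
    A[idx] <- params[seq_len(n_a)]
  }
  Psi <- diag(params[n_a + seq_len(p)], p)
  dimnames(Psi) <- dimnames(A)
  if (n_c) {
    i <- match(model$psi_pairs$var1, model$variables)
    j <- match(model$psi_pairs$var2, model$variables)
    Psi[cbind(i, j)] <- Psi[cbind(j, i)] <- params[n_a + p + seq_len(n_c)]
  }
  list(A = A, Psi = Psi)
}

#' A known data-generating path model (truth for simulation)
#'
#' A [path_model()] together with numeric path coefficients and
#' disturbance variances; observations are generated as
#' `x = solve(I - A, zeta)` with `zeta ~ N(0, Psi)`.
#'
#' @param variables ordered variable names.
#' @param paths data.frame with columns `from`, `to`, `coef`.
#' @param disturbance_vars positive variances, one per variable
#'   (recycled if scalar).
#' @return An object of class `connectivity_truth` (also a `path_model`).
#' @export
connectivity_truth <- function(variables, paths,
                               disturbance_vars = 1) {
  if (nrow(paths) && !("coef" %in% names(paths)))
    stop_validation("truth paths need a coef column")
  base <- path_model(variables, paths)
  psi <- rep_len(disturbance_vars, length(variables))
  if (any(!is.finite(psi)) || any(psi <= 0))
    stop_validation("disturbance variances must be positive")
  base$paths$coef <- if (nrow(paths)) as.numeric(paths$coef) else numeric()
  base$disturbance_vars <- psi
  mats <- truth_matrices(base)
  if (abs(det(diag(length(variables)) - mats$A)) < 1e-12)
    stop("model error: (I - A) is singular; a feedback loop has unit gain")
  class(base) <- c("connectivity_truth", "path_model")
  base
}

truth_matrices <- function(truth) {
  model_matrices(truth, c(truth$paths$coef, truth$disturbance_vars))
}

#' @export
print.connectivity_truth <- function(x, ...) {
  cat(sprintf("connectivity_truth: %d variables, %d paths (|coef| in [%.2f, %.2f])\n",
              length(x$variables), nrow(x$paths),
              if (nrow(x$paths)) min(abs(x$paths$coef)) else 0,
              if (nrow(x$paths)) max(abs(x$paths$coef)) else 0))
  invisible(x)
}

#' Drop coefficients from a truth, keeping the topology
#' @param truth a [connectivity_truth()].
#' @return the corresponding free-parameter [path_model()].
#' @export
as_path_model <- function(truth) {
  stopifnot(inherits(truth, "path_model"))
  path_model(truth$variables, truth$paths[c("from", "to")],
             psi_pairs = truth$psi_pairs)
}

#' Read/write path models as JSON
#'
#' Dialect: `{"variables": [...], "paths": [{"from":, "to":, "coef":}],
#' "disturbance_vars": [...]}`. `coef` and `disturbance_vars` are
#' optional; with them the file round-trips a [connectivity_truth()],
#' without them a bare [path_model()].
#'
#' @param model a [path_model()] or [connectivity_truth()].
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(variables = model$variables, paths = model$paths)
  if (inherits(model, "connectivity_truth"))
    obj$disturbance_vars <- model$disturbance_vars
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  paths <- as.data.frame(obj$paths)
  if (!is.null(obj$disturbance_vars) && "coef" %in% names(paths))
    connectivity_truth(obj$variables, paths, obj$disturbance_vars)
  else
    path_model(obj$variables, paths[intersect(c("from", "to"), names(paths))])
}
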