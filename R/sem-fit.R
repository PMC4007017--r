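#' Sample moments for covariance-structure fitting
#'
#' @param x numeric matrix of observations (rows) by variables
#'   (columns), or `NULL` if `S` is given directly.
#' @param S sample covariance (denominator N - 1), used with `N` when
#'   raw data are not available.
#' @param N number of observations.
#' @return An object of class `sample_moments` with elements `S`, `N`,
#'   `variables`.
#' @export
sample_moments <- function(x = NULL, S = NULL, N = NULL) {
  if (!is.null(x)) {
    x <- as.matrix(x)
    if (nrow(x) < 2) stop_validation("need N >= 2 observations")
    S <- stats::cov(x)  # denominator N - 1
    N <- nrow(x)
  }
  if (is.null(S) || is.null(N)) stop_validation("supply x, or S and N")
  S <- as.matrix(S)
  if (!isSymmetric(unname(S), tol = 1e-8))
    stop_validation("S must be symmetric")
  S <- (S + t(S)) / 2
  if (N < 2) stop_validation("N must be >= 2")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("S is not positive definite (smallest eigenvalue ",
         format(min(ev)), "); maximum-likelihood fitting requires PD S")
  structure(list(S = S, N = as.integer(N),
                 variables = colnames(S) %||% paste0("v", seq_len(ncol(S)))),
            class = "sample_moments")
}

#' Maximum-likelihood discrepancy between covariance matrices
#'
#' `F = log det(Sigma) + tr(S Sigma^-1) - log det(S) - p`, the
#' discrepancy minimized by ML covariance-structure estimation. It is
#' nonnegative and zero iff `Sigma == S` (it equals twice the
#' Kullback-Leibler divergence between the two centred Gaussians).
#'
#' @param S sample covariance (positive definite).
#' @param Sigma model-implied covariance (positive definite, same size).
#' @return scalar discrepancy.
#' @export
ml_discrepancy <- function(S, Sigma) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  if (!all(dim(S) == dim(Sigma)))
    stop_validation("S and Sigma must have the same dimensions")
  for (M in list(S = S, Sigma = Sigma)) {
    ev <- min(eigen((M + t(M)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev <= 0)
      stop("matrix not positive definite (smallest eigenvalue ",
           format(ev), ")")
  }
  p <- ncol(S)
  cS <- chol(S); cSig <- chol(Sigma)
  ld_S <- 2 * sum(log(diag(cS)))
  ld_Sig <- 2 * sum(log(diag(cSig)))
  ld_Sig + sum(S * chol2inv(cSig)) - ld_S - p
}

# --- internal objective machinery -----------------------------------------
# Parameter vector (optimization scale): path coefficients as-is,
# log disturbance variances, disturbance covariances as-is.

theta_to_natural <- function(model, theta) {
  n_a <- nrow(model$paths)
  p <- length(model$variables)
  nat <- theta
  nat[n_a + seq_len(p)] <- exp(theta[n_a + seq_len(p)])
  nat
}

natural_to_theta <- function(model, nat) {
  n_a <- nrow(model$paths)
  p <- length(model$variables)
  th <- nat
  th[n_a + seq_len(p)] <- log(nat[n_a + seq_len(p)])
  th
}

# F and its analytic gradient w.r.t. NATURAL parameters; returns NULL
# on an inadmissible point.
sem_objective <- function(model, nat, S, want_grad = FALSE) {
  mats <- model_matrices(model, nat)
  p <- ncol(S)
  IA <- diag(p) - mats$A
  d <- det(IA)
  if (!is.finite(d) || abs(d) < 1e-12) return(NULL)
  B <- solve(IA)
  Sigma <- B %*% mats$Psi %*% t(B)
  Sigma <- (Sigma + t(Sigma)) / 2
  cSig <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cSig)) return(NULL)
  Sig_inv <- chol2inv(cSig)
  f <- 2 * sum(log(diag(cSig))) + sum(S * Sig_inv) -
    attr(S, "logdet") - p
  if (!is.finite(f)) return(NULL)
  out <- list(f = f, Sigma = Sigma)
  if (want_grad) {
    G <- Sig_inv - Sig_inv %*% S %*% Sig_inv        # dF/dSigma
    n_a <- nrow(model$paths)
    grad <- numeric(length(nat))
    if (n_a) {
      M <- 2 * (Sigma %*% G %*% B)                  # dF/dA[i,j] = M[j,i]
      idx <- cbind(match(model$paths$from, model$variables),
                   match(model$paths$to, model$variables))
      grad[seq_len(n_a)] <- M[idx]
    }
    H <- t(B) %*% G %*% B                           # dF/dPsi
    grad[n_a + seq_len(p)] <- diag(H)
    if (!is.null(model$psi_pairs)) {
      i <- match(model$psi_pairs$var1, model$variables)
      j <- match(model$psi_pairs$var2, model$variables)
      grad[n_a + p + seq_along(i)] <- 2 * H[cbind(i, j)]
    }
    out$grad <- grad
  }
  out
}

# Per-equation OLS starting values computed from S alone.
start_values <- function(model, S) {
  p <- length(model$variables)
  n_a <- nrow(model$paths)
  a <- numeric(n_a)
  psi <- diag(S)
  for (i in seq_len(p)) {
    rows <- which(model$paths$to == model$variables[i])
    if (!length(rows)) next
    J <- match(model$paths$from[rows], model$variables)
    b <- tryCatch(solve(S[J, J, drop = FALSE], S[J, i]),
                  error = function(e) NULL)
    if (is.null(b)) { a[rows] <- 0; next }
    a[rows] <- b
    rv <- S[i, i] - sum(S[i, J] * b)
    psi[i] <- max(rv, 0.05 * S[i, i])
  }
  c(a, psi, numeric(if (is.null(model$psi_pairs)) 0 else nrow(model$psi_pairs)))
}

#' Fit a path model by maximum likelihood
#'
#' Minimizes the ML discrepancy between the sample covariance and the
#' model-implied covariance `(I - A)^-1 Psi (I - A)^-T` over the free
#' path coefficients and disturbance (co)variances, by quasi-Newton
#' (BFGS) iteration on an unconstrained parameterization (log
#' disturbance variances), with analytic gradients. Starting values are
#' per-equation least-squares regressions derived from S. Standard
#' errors come from the inverse of the observed information of the
#' `(N - 1)/2`-scaled discrepancy at the solution; z statistics and
#' two-sided normal p-values are attached per path, along with
#' standardized coefficients (`beta_ij = a_ij * sigma_j / sigma_i`,
#' sigmas from the fitted Sigma diagonal) and the full fit battery
#' (chi-square, GFI, CFI, RMSEA, AIC, BIC).
#'
#' @param model a [path_model()] (or [connectivity_truth()], whose
#'   coefficient values are ignored).
#' @param moments a [sample_moments()] object, or a raw observation
#'   matrix (rows = observations).
#' @param se compute standard errors (default `TRUE`; turned off
#'   internally during specification search for speed).
#' @param max_iter,grad_tol,f_tol convergence controls: BFGS restarts
#'   until the gradient infinity-norm is below `grad_tol` and the
#'   discrepancy change below `f_tol`, up to `max_iter` total
#'   iterations.
#' @param warn_low_n warn when N is small relative to the free
#'   parameter count (default `TRUE`).
#' @return An object of class `sem_fit`; see Details. Key elements:
#'   `paths` (data.frame from/to/estimate/se/z/p_value/beta),
#'   `disturbances`, `F_min`, `chisq`, `df`, `p_chi`, `GFI`, `CFI`,
#'   `RMSEA`, `AIC`, `BIC`, `Sigma_hat`, `converged`, `n_iter`.
#' @export
fit_ml <- function(model, moments, se = TRUE, max_iter = 500,
                   grad_tol = 1e-6, f_tol = 1e-10, warn_low_n = TRUE) {
  stopifnot(inherits(model, "path_model"))
  if (!inherits(moments, "sample_moments")) moments <- sample_moments(moments)
  if (!setequal(model$variables, moments$variables))
    stop_validation("model variables and data variables differ")
  ord <- match(model$variables, moments$variables)
  S <- moments$S[ord, ord, drop = FALSE]
  N <- moments$N
  p <- ncol(S)
  t_free <- model_n_free(model)
  if (warn_low_n && N < 2 * t_free)
    warning(sprintf(paste0("N = %d is small relative to the %d free ",
                           "parameters; estimates, standard errors and ",
                           "fit indices are of limited reliability"),
                    N, t_free), call. = FALSE)
  attr(S, "logdet") <- 2 * sum(log(diag(chol(S))))

  nat0 <- start_values(model, S)
  if (is.null(sem_objective(model, nat0, S)))
    nat0 <- c(numeric(nrow(model$paths)), diag(S),
              numeric(t_free - nrow(model$paths) - p))
  theta <- natural_to_theta(model, nat0)

  fn <- function(th) {
    o <- sem_objective(model, theta_to_natural(model, th), S)
    if (is.null(o)) 1e10 else o$f
  }
  gr <- function(th) {
    nat <- theta_to_natural(model, th)
    o <- sem_objective(model, nat, S, want_grad = TRUE)
    if (is.null(o)) return(numeric(length(th)))
    g <- o$grad
    n_a <- nrow(model$paths)
    g[n_a + seq_len(p)] <- g[n_a + seq_len(p)] * nat[n_a + seq_len(p)]
    g
  }

  run_bfgs <- function(theta0) {
    n_iter_loc <- 0L
    f_prev <- Inf
    th <- theta0
    conv <- FALSE
    for (round in 1:10) {
      opt <- stats::optim(th, fn, gr, method = "BFGS",
                          control = list(maxit = max_iter,
                                         reltol = 1e-15))
      n_iter_loc <- n_iter_loc + opt$counts[["function"]]
      th <- opt$par
      g_norm <- max(abs(gr(th)))
      if (g_norm < grad_tol && abs(f_prev - opt$value) < f_tol) {
        conv <- TRUE
        break
      }
      f_prev <- opt$value
    }
    list(theta = th, f = fn(th), converged = conv, n_iter = n_iter_loc)
  }
  best <- run_bfgs(theta)
  if (!best$converged) {
    # deterministic alternative starts: shrink the regression starting
    # values towards zero-path / diagonal-Psi configurations
    n_a <- nrow(model$paths)
    for (shrink in c(0.5, 0.1, 0)) {
      nat_alt <- nat0
      nat_alt[seq_len(n_a)] <- shrink * nat0[seq_len(n_a)]
      nat_alt[n_a + seq_len(p)] <- (1 - shrink) * diag(S) +
        shrink * nat0[n_a + seq_len(p)]
      cand <- run_bfgs(natural_to_theta(model, nat_alt))
      if (cand$converged && cand$f <= best$f + 1e-8) {
        best <- cand
        break
      }
      if (cand$f < best$f) best <- cand
    }
  }
  theta <- best$theta
  converged <- best$converged
  n_iter <- best$n_iter
  nat <- theta_to_natural(model, theta)
  obj <- sem_objective(model, nat, S, want_grad = TRUE)
  if (is.null(obj))
    stop("optimizer left the admissible region; model may be misspecified")
  F_min <- obj$f
  Sigma_hat <- obj$Sigma
  dimnames(Sigma_hat) <- list(model$variables, model$variables)

  df <- model_df(model)
  chisq <- max((N - 1) * F_min, 0)
  p_chi <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_

  # baseline independence model: free variances only; ML solution is
  # Psi = diag(S), so F_B has closed form
  F_base <- sum(log(diag(S))) - attr(S, "logdet")
  chisq_base <- max((N - 1) * F_base, 0)
  df_base <- p * (p + 1) / 2 - p

  names(nat) <- param_names(model)
  se_vec <- rep(NA_real_, length(nat))
  info_ok <- TRUE
  if (se) {
    info <- observed_information(model, nat, S, N)
    eg <- eigen((info + t(info)) / 2, symmetric = TRUE)
    tol <- max(eg$values) * 1e-10
    if (min(eg$values) < tol) {
      info_ok <- FALSE
      null_dim <- which(eg$values < tol)
      culprits <- unique(unlist(lapply(null_dim, function(k)
        names(nat)[order(-abs(eg$vectors[, k]))[1:2]])))
      warning("information matrix is rank deficient; model is empirically ",
              "unidentified in the direction of: ",
              paste(culprits, collapse = ", "), call. = FALSE)
    } else {
      se_vec <- sqrt(diag(solve(info)))
    }
  }

  n_a <- nrow(model$paths)
  sig <- sqrt(diag(Sigma_hat))
  paths <- model$paths[c("from", "to")]
  if (n_a) {
    paths$estimate <- nat[seq_len(n_a)]
    paths$se <- se_vec[seq_len(n_a)]
    paths$z <- paths$estimate / paths$se
    paths$p_value <- 2 * stats::pnorm(-abs(paths$z))
    paths$beta <- paths$estimate *
      sig[match(paths$from, model$variables)] /
      sig[match(paths$to, model$variables)]
  } else {
    paths$estimate <- paths$se <- paths$z <- paths$p_value <-
      paths$beta <- numeric(0)
  }

  if (max(nat[n_a + seq_len(p)]) > 100 * max(diag(S)))
    warning("improper solution: a disturbance variance diverged far ",
            "beyond the observed variances; interpret this fit with ",
            "caution (typical of small N relative to model size)",
            call. = FALSE)

  A_hat <- model_matrices(model, nat)$A
  if (n_a && max(Mod(eigen(A_hat, only.values = TRUE)$values)) >= 1)
    warning("fitted structural matrix is unstable (spectral radius >= 1); ",
            "a feedback loop amplifies without bound", call. = FALSE)

  structure(list(
    model = model, N = N, S = S,
    estimates = nat, se = se_vec, paths = paths,
    disturbances = stats::setNames(nat[n_a + seq_len(p)], model$variables),
    F_min = F_min, chisq = chisq, df = df, p_chi = p_chi,
    GFI = gfi(S, Sigma_hat),
    CFI = cfi(chisq, df, chisq_base, df_base),
    RMSEA = rmsea(chisq, df, N),
    AIC = chisq + 2 * t_free,
    BIC = chisq + t_free * log(N),
    chisq_base = chisq_base, df_base = df_base,
    Sigma_hat = Sigma_hat,
    converged = converged, identified = info_ok, n_iter = n_iter
  ), class = "sem_fit")
}

# Observed information of the (N-1)/2-scaled discrepancy, by central
# finite differences of the analytic gradient in natural parameters.
observed_information <- function(model, nat, S, N) {
  t_free <- length(nat)
  H <- matrix(0, t_free, t_free)
  h <- pmax(abs(nat), 1) * 1e-5
  for (k in seq_len(t_free)) {
    up <- nat; up[k] <- up[k] + h[k]
    dn <- nat; dn[k] <- dn[k] - h[k]
    gu <- sem_objective(model, up, S, want_grad = TRUE)
    gd <- sem_objective(model, dn, S, want_grad = TRUE)
    if (is.null(gu) || is.null(gd))
      stop("information matrix evaluation left the admissible region")
    H[, k] <- (gu$grad - gd$grad) / (2 * h[k])
  }
  (N - 1) / 2 * (H + t(H)) / 2
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat(sprintf("sem_fit: %d variables, %d paths, N = %d%s\n",
              length(x$model$variables), nrow(x$model$paths), x$N,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  chisq(%d) = %.3f, p = %s | GFI %.3f CFI %.3f RMSEA %.3f | AIC %.1f BIC %.1f\n",
              x$df, x$chisq,
              ifelse(is.na(x$p_chi), "NA", format(round(x$p_chi, 3))),
              x$GFI, x$CFI, x$RMSEA, x$AIC, x$BIC))
  if (nrow(x$paths)) {
    tab <- x$paths
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], round, digits)
    print(utils::head(tab, 40), row.names = FALSE)
    if (nrow(tab) > 40) cat("  ...\n")
  }
  invisible(x)
}
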