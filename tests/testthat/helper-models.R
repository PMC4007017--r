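# shared fixtures built in code

# tiny 2-variable truth: single path x -> y with coefficient a
truth2 <- function(a = 0.5, psi = c(1, 1)) {
  connectivity_truth(c("x", "y"),
                     data.frame(from = "x", to = "y", coef = a),
                     disturbance_vars = psi)
}

# recursive chain x1 -> x2 -> x3 -> x4
truth_chain4 <- function(coefs = c(0.8, -0.5, 0.3)) {
  connectivity_truth(paste0("x", 1:4),
                     data.frame(from = paste0("x", 1:3),
                                to = paste0("x", 2:4),
                                coef = coefs),
                     disturbance_vars = c(1, 0.5, 2, 1))
}

# just-identified recursive model over p variables: complete DAG in the
# given causal order (p(p-1)/2 paths + p variances = p(p+1)/2)
complete_dag_model <- function(vars) {
  p <- length(vars)
  pairs <- do.call(rbind, lapply(2:p, function(i)
    data.frame(from = vars[seq_len(i - 1)], to = vars[i])))
  path_model(vars, pairs)
}

# independent multivariate normal log-likelihood oracle (centred data,
# covariance Sigma), via the Cholesky factor
loglik_gauss <- function(x, Sigma) {
  p <- ncol(x)
  ch <- chol(Sigma)
  z <- x %*% backsolve(ch, diag(p))   # rows ~ N(0, I) under Sigma
  -0.5 * nrow(x) * (p * log(2 * pi) + 2 * sum(log(diag(ch)))) -
    0.5 * sum(z^2)
}

expect_no_warning_fit <- function(model, x) {
  suppressWarnings(fit_ml(model, sample_moments(x)))
}
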