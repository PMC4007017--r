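test_that("ml_discrepancy matches closed forms and the KL oracle", {
  S <- matrix(c(2, 0.3, 0.3, 1), 2)
  expect_equal(ml_discrepancy(S, S), 0, tolerance = 1e-12)
  # scalar case: ln(1) + 2 - ln(2) - 1
  expect_equal(ml_discrepancy(matrix(2), matrix(1)), 1 - log(2))
  # F(S, Sigma) = 2 * KL( N(0,S) || N(0,Sigma) )
  set.seed(44)
  for (rep in 1:10) {
    A <- matrix(rnorm(9), 3); S1 <- crossprod(A) + diag(3)
    B <- matrix(rnorm(9), 3); S2 <- crossprod(B) + diag(3)
    kl <- 0.5 * (sum(diag(solve(S2, S1))) - 3 +
                   determinant(S2)$modulus - determinant(S1)$modulus)
    expect_equal(ml_discrepancy(S1, S2), 2 * as.numeric(kl),
                 tolerance = 1e-10)
    expect_gte(ml_discrepancy(S1, S2), 0)
  }
  expect_error(ml_discrepancy(diag(2), diag(3)),
               class = "bimansem_validation_error")
  expect_error(ml_discrepancy(matrix(c(1, 2, 2, 1), 2), diag(2)),
               "positive definite")
})

test_that("just-identified recursive models reproduce per-equation OLS with chisq 0", {
  set.seed(52)
  for (rep in 1:5) {
    vars <- paste0("x", 1:4)
    tr <- truth_chain4(runif(3, -0.7, 0.7))
    x <- simulate_roi_observations(tr, 150, seed = 52 + rep)
    model <- complete_dag_model(vars)
    expect_equal(model_df(model), 0L)
    fit <- suppressWarnings(fit_ml(model, sample_moments(x)))
    expect_true(fit$converged)
    expect_lt(abs(fit$F_min), 1e-8)
    expect_equal(fit$chisq, 0, tolerance = 1e-6)
    expect_equal(fit$GFI, 1, tolerance = 1e-6)
    # independent oracle: per-equation normal equations from S
    S <- cov(x)
    for (i in 2:4) {
      J <- seq_len(i - 1)
      b_ols <- solve(S[J, J], S[J, i])
      got <- fit$paths$estimate[fit$paths$to == vars[i]]
      names(got) <- fit$paths$from[fit$paths$to == vars[i]]
      expect_equal(unname(got[vars[J]]), unname(b_ols), tolerance = 1e-6)
    }
  }
})

test_that("saturated fit reproduces S; estimates recover the generating truth", {
  tr <- truth_chain4()
  x <- simulate_roi_observations(tr, 5000, seed = 77)
  fit <- suppressWarnings(fit_ml(as_path_model(tr), sample_moments(x)))
  expect_true(fit$converged)
  key <- paste(fit$paths$from, fit$paths$to)
  truth_coef <- tr$paths$coef[match(key, paste(tr$paths$from, tr$paths$to))]
  expect_true(all(abs(fit$paths$estimate - truth_coef) <
                    3 * fit$paths$se))
  expect_true(all(fit$paths$p_value[abs(truth_coef) > 0.2] < 0.001))
})

test_that("freeing a parameter never increases chisq (nesting monotonicity)", {
  tr <- connectivity_fixture("elderly", "in_phase")
  x <- simulate_roi_observations(tr, 300, seed = 88)
  mom <- sample_moments(x)
  m1 <- as_path_model(tr)
  f1 <- suppressWarnings(fit_ml(m1, mom, se = FALSE))
  # drop one path, then re-add it: nested pair
  m0 <- path_model(m1$variables, m1$paths[-1, ])
  f0 <- suppressWarnings(fit_ml(m0, mom, se = FALSE))
  expect_gte(f0$chisq, f1$chisq - 1e-6)
  # freeing yet another edge can only keep improving
  m2 <- path_model(m1$variables,
                   rbind(m1$paths, data.frame(from = "L.M1", to = "L.SPL")))
  f2 <- suppressWarnings(fit_ml(m2, mom, se = FALSE))
  expect_gte(f1$chisq, f2$chisq - 1e-6)
})

test_that("standardized coefficients equal a refit on the correlation scale", {
  tr <- truth_chain4(c(0.6, -0.4, 0.5))
  x <- simulate_roi_observations(tr, 400, seed = 91)
  fit <- suppressWarnings(fit_ml(as_path_model(tr), sample_moments(x)))
  xs <- scale(x)
  fit_s <- suppressWarnings(fit_ml(as_path_model(tr), sample_moments(xs)))
  expect_equal(fit$paths$beta, fit_s$paths$estimate, tolerance = 1e-4)
})

test_that("standard errors approximate the sampling spread", {
  tr <- truth2(0.5)
  m <- as_path_model(tr)
  ests <- ses <- numeric(200)
  for (r in 1:200) {
    x <- simulate_roi_observations(tr, 200, seed = 3000 + r)
    f <- suppressWarnings(fit_ml(m, sample_moments(x)))
    ests[r] <- f$paths$estimate[1]
    ses[r] <- f$paths$se[1]
  }
  expect_equal(sd(ests), mean(ses), tolerance = 0.15)
  covered <- abs(ests - 0.5) < 1.96 * ses
  expect_gt(mean(covered), 0.90)
})

test_that("misfit is detected and low-N / improper fits warn", {
  # data from a chain, fitted with a single wrong edge only
  tr <- truth_chain4(c(0.8, 0.8, 0.8))
  x <- simulate_roi_observations(tr, 1000, seed = 13)
  wrong <- path_model(paste0("x", 1:4),
                      data.frame(from = "x1", to = "x4"))
  f <- suppressWarnings(fit_ml(wrong, sample_moments(x)))
  expect_lt(f$p_chi, 1e-6)
  expect_lt(f$CFI, 0.95)
  expect_gt(f$RMSEA, 0.05)
  # low-N warning fires in the paper-sized regime
  big <- connectivity_fixture("elderly", "in_phase")
  xx <- simulate_roi_observations(big, 20, seed = 2)
  expect_warning(fit_ml(as_path_model(big), sample_moments(xx)),
                 "small relative to")
})

test_that("variable order in the data does not matter", {
  tr <- truth_chain4()
  x <- simulate_roi_observations(tr, 500, seed = 6)
  f1 <- suppressWarnings(fit_ml(as_path_model(tr), sample_moments(x)))
  f2 <- suppressWarnings(fit_ml(as_path_model(tr),
                                sample_moments(x[, c(3, 1, 4, 2)])))
  expect_equal(f1$paths$estimate, f2$paths$estimate, tolerance = 1e-6)
  expect_equal(f1$chisq, f2$chisq, tolerance = 1e-6)
})
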