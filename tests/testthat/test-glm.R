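sch <- task_schedule(1.5)

test_that("design matrix has the expected shape and columns", {
  d <- build_design(sch)
  expect_equal(nrow(d$X), 113L)
  expect_setequal(colnames(d$X),
                  c("intercept", "drift1", "task_in_phase",
                    "deriv_in_phase", "task_anti_phase",
                    "deriv_anti_phase"))
  # no task blocks -> intercept + drift only
  rest <- generate_schedule(1.0, list(n_rest_blocks = 1, n_task_blocks = 0,
                                      n_volumes = 6))
  d0 <- build_design(rest)
  expect_setequal(colnames(d0$X), c("intercept", "drift1"))
})

test_that("a long unit boxcar convolved with the HRF plateaus at the HRF area", {
  long <- task_schedule(1.0, rest_block_s = 60, n_rest_blocks = 2,
                        n_task_blocks = 1, mode_sequence = "in_phase",
                        n_volumes = 60)
  reg <- bimansem:::convolved_regressor(long, "in_phase")
  area <- integrate(canonical_hrf, 0, 32)$value
  plateau <- reg[long$tr_s * seq_len(60) > 95 &
                   long$tr_s * seq_len(60) < 115]
  expect_equal(mean(plateau), area, tolerance = 0.01)
})

test_that("noiseless series are recovered exactly", {
  d <- build_design(sch)
  beta <- c(intercept = 5, drift1 = -1, task_in_phase = 2,
            deriv_in_phase = 0.3, task_anti_phase = -1.5,
            deriv_anti_phase = 0)
  y <- d$X %*% beta[colnames(d$X)]
  fit <- fit_glm(y, d)
  expect_equal(unname(fit$coef[, 1]), unname(beta[colnames(d$X)]),
               tolerance = 1e-8)
  # simulate_bold with zero noise recovers amplitudes via the contrast
  amp <- rbind(in_phase = c(r1 = 2, r2 = -1), anti_phase = c(r1 = 0.5, r2 = 3))
  y2 <- simulate_bold(sch, amp, noise_sd = 0)
  f2 <- fit_glm(y2, d)
  expect_equal(mode_contrast(f2, "in_phase")$estimate, c(2, -1),
               tolerance = 1e-8)
  expect_equal(mode_contrast(f2, "anti_phase")$estimate, c(0.5, 3),
               tolerance = 1e-8)
})

test_that("null signal yields near-nominal z statistics", {
  d <- build_design(sch)
  amp <- matrix(0, 2, 1000,
                dimnames = list(c("in_phase", "anti_phase"), NULL))
  y <- simulate_bold(sch, amp, noise_sd = 1, ar_rho = 0, seed = 21)
  fit <- fit_glm(y, d)
  z <- mode_contrast(fit, "in_phase")$t
  expect_gte(mean(abs(z) < 3), 0.99)
})

test_that("OLS residuals are orthogonal to every design column", {
  d <- build_design(sch)
  amp <- rbind(in_phase = c(a = 1, b = 2), anti_phase = c(a = 2, b = 0))
  y <- simulate_bold(sch, amp, noise_sd = 0.7, seed = 5)
  fit <- fit_glm(y, d)
  dots <- crossprod(d$X, fit$resid)
  norms <- outer(sqrt(colSums(d$X^2)), sqrt(colSums(fit$resid^2)))
  expect_lt(max(abs(dots) / norms), 1e-6)
})

test_that("an orthogonalized drift column leaves task betas unchanged", {
  d <- build_design(sch)
  amp <- rbind(in_phase = c(a = 1.5), anti_phase = c(a = -0.5))
  y <- simulate_bold(sch, amp, noise_sd = 0.5, seed = 6)
  f1 <- fit_glm(y, d)
  extra <- sin(2 * pi * d$times / 170)
  # orthogonalize against the whole design
  extra <- extra - d$X %*% qr.coef(qr(d$X), extra)
  d2 <- d
  d2$X <- cbind(d$X, ortho = extra)
  f2 <- fit_glm(y, d2)
  expect_equal(f2$coef["task_in_phase", ], f1$coef["task_in_phase", ],
               tolerance = 1e-8)
})

test_that("contrasts are linear and validated", {
  d <- build_design(sch)
  amp <- rbind(in_phase = c(a = 2), anti_phase = c(a = 0.5))
  y <- simulate_bold(sch, amp, noise_sd = 0.4, seed = 12)
  fit <- fit_glm(y, d)
  anti_vs_in <- glm_contrast(fit, list(task_anti_phase = 1,
                                       task_in_phase = -1))
  expect_equal(anti_vs_in$estimate,
               mode_contrast(fit, "anti_phase")$estimate -
                 mode_contrast(fit, "in_phase")$estimate,
               tolerance = 1e-10)
  expect_error(glm_contrast(fit, numeric(ncol(d$X))),
               class = "bimansem_validation_error")
  expect_error(glm_contrast(fit, list(no_such_col = 1)),
               class = "bimansem_validation_error")
  expect_error(fit_glm(y[1:50, , drop = FALSE], d),
               class = "bimansem_validation_error")
})

test_that("betas recovered from generator amplitudes track the truth", {
  d <- build_design(sch)
  tr <- truth_chain4()
  amps <- simulate_roi_observations(tr, 30, seed = 14, mean = 1)
  est <- matrix(NA_real_, 30, 4)
  for (s in 1:30) {
    a <- rbind(in_phase = amps[s, ], anti_phase = 0)
    colnames(a) <- colnames(amps)
    y <- simulate_bold(sch, a, noise_sd = 0.1, seed = 1000 + s)
    est[s, ] <- mode_contrast(fit_glm(y, d), "in_phase")$estimate
  }
  expect_gt(cor(as.vector(est), as.vector(amps)), 0.95)
})

test_that("series TSV round-trips", {
  amp <- rbind(in_phase = c(x = 1, y = 2), anti_phase = c(x = 0, y = 1))
  y <- simulate_bold(sch, amp, noise_sd = 0.3, seed = 2)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_series_tsv(y, p)
  expect_equal(read_series_tsv(p), y, tolerance = 1e-6)
})
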