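test_that("implied covariance matches closed forms", {
  # no paths: Sigma = Psi
  t0 <- connectivity_truth(c("a", "b"),
                           data.frame(from = character(),
                                      to = character(),
                                      coef = numeric()),
                           disturbance_vars = c(2, 3))
  expect_equal(unname(implied_covariance(t0)), diag(c(2, 3)))
  # single path a = 0.5, Psi = I: [[1, .5], [.5, 1.25]]
  expect_equal(unname(implied_covariance(truth2(0.5))),
               matrix(c(1, 0.5, 0.5, 1.25), 2), tolerance = 1e-12)
  # bare model + explicit params gives the same answer
  m <- path_model(c("x", "y"), data.frame(from = "x", to = "y"))
  expect_equal(implied_covariance(m, c(0.5, 1, 1)),
               implied_covariance(truth2(0.5)))
})

test_that("a unit-gain feedback loop is rejected as singular", {
  # reciprocal pair with product 1: det(I - A) = 0
  expect_error(
    implied_covariance(
      connectivity_truth(c("x", "y", "z"),
                         data.frame(from = c("x", "y"), to = c("y", "x"),
                                    coef = c(2, 0.5)))),
    "singular")
})

test_that("analytic covariance is symmetric positive definite for random stable truths", {
  set.seed(31)
  for (rep in 1:20) {
    p <- sample(3:8, 1)
    vars <- paste0("v", seq_len(p))
    # random DAG in a random order, coefficients |a| <= 0.8
    ord <- sample(vars)
    pairs <- do.call(rbind, lapply(2:p, function(i) {
      k <- sample(seq_len(i - 1), sample(seq_len(i - 1), 1))
      data.frame(from = ord[k], to = ord[i])
    }))
    pairs$coef <- runif(nrow(pairs), -0.8, 0.8)
    tr <- connectivity_truth(vars, pairs,
                             disturbance_vars = runif(p, 0.5, 2))
    S <- implied_covariance(tr)
    expect_equal(S, t(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("Monte-Carlo covariance converges to the implied covariance", {
  n <- 1e6
  # independent unit-variance case
  t0 <- connectivity_truth(c("a", "b"),
                           data.frame(from = character(),
                                      to = character(),
                                      coef = numeric()))
  x <- simulate_roi_observations(t0, n, seed = 8)
  expect_lt(max(abs(cov(x) - diag(2))), 0.01)
  # 2-variable closed form
  x2 <- simulate_roi_observations(truth2(0.5), n, seed = 9)
  expect_lt(max(abs(cov(x2) - implied_covariance(truth2(0.5)))), 0.01)
  # 4-variable chain vs the SEM module's implied covariance
  tr <- truth_chain4()
  x4 <- simulate_roi_observations(tr, n, seed = 10)
  expect_lt(max(abs(cov(x4) - implied_covariance(tr))), 0.01)
})

test_that("draws are reproducible, mean-shiftable, and validated", {
  tr <- truth_chain4()
  a <- simulate_roi_observations(tr, 50, seed = 3)
  b <- simulate_roi_observations(tr, 50, seed = 3)
  expect_identical(a, b)
  shifted <- simulate_roi_observations(tr, 2000, seed = 3, mean = 5)
  expect_equal(unname(colMeans(shifted)), rep(5, 4), tolerance = 0.2)
  expect_equal(cov(shifted),
               cov(simulate_roi_observations(tr, 2000, seed = 3)))
  expect_error(simulate_roi_observations(tr, 1),
               class = "bimansem_validation_error")
})

test_that("betas CSV and model JSON round-trip", {
  tr <- truth_chain4()
  x <- simulate_roi_observations(tr, 10, seed = 1)
  rownames(x) <- paste0("s", 1:10)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_betas_csv(x, p1)
  expect_equal(read_betas_csv(p1), x, tolerance = 1e-12)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_model_json(tr, p2)
  back <- read_model_json(p2)
  expect_s3_class(back, "connectivity_truth")
  expect_equal(back$paths, tr$paths)
  expect_equal(back$disturbance_vars, tr$disturbance_vars)
  # topology-only round trip
  m <- as_path_model(tr)
  p3 <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, p3)
  expect_equal(model_df(read_model_json(p3)), model_df(m))
})
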