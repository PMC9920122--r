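test_that("log-likelihood matches closed forms for trivial models", {
  x1 <- matrix(1, 1, 1, dimnames = list("R1", NULL))
  expect_equal(log_likelihood(x1, pmem_params(0, matrix(0, 1, 1))),
               log(0.5))
  set.seed(2)
  x2 <- rand_series(2, 4)
  expect_equal(log_likelihood(x2, pmem_params(c(0, 0), matrix(0, 2, 2))),
               4 * log(1 / 4))
})

test_that("exact model moments match closed forms", {
  mm0 <- model_moments(pmem_params(rep(0, 3), matrix(0, 3, 3)))
  expect_equal(unname(mm0$mean_activity), rep(0, 3))
  expect_equal(unname(mm0$pairwise_products), diag(3))

  mm1 <- model_moments(pmem_params(0.5, matrix(0, 1, 1)))
  expect_equal(unname(mm1$mean_activity), tanh(0.5), tolerance = 1e-12)

  # <sigma1 sigma2> increases monotonically with the coupling
  corrs <- vapply(c(0, 1, 2, 4), function(j) {
    model_moments(pmem_params(c(0, 0),
                              matrix(c(0, j, j, 0), 2)))$pairwise_products[1, 2]
  }, numeric(1))
  expect_true(all(diff(corrs) > 0))
})

test_that("fitting a uniform empirical distribution returns zero parameters", {
  x <- t(all_states(2))
  rownames(x) <- c("R1", "R2")
  fit <- pmem(x)
  expect_true(fit$converged)
  expect_lt(max(abs(coef(fit)$h)), 1e-4)
  expect_lt(max(abs(coef(fit)$J)), 1e-4)
})

test_that("single-region fit inverts the tanh link", {
  x <- matrix(c(rep(1, 75), rep(-1, 25)), 1, dimnames = list("R1", NULL))
  fit <- pmem(x, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)$h), atanh(0.5), tolerance = 1e-6)
})

test_that("moment matching holds at convergence (MLE stationarity)", {
  set.seed(21)
  for (n in 2:4) {
    x <- rand_series(n, 300)
    fit <- pmem(x)
    expect_true(fit$converged)
    mm <- model_moments(fit$params)
    emp <- empirical_stats(x)
    d2 <- emp$pairwise_products - mm$pairwise_products
    diag(d2) <- 0
    expect_lte(max(abs(emp$mean_activity - mm$mean_activity)), 1e-5)
    expect_lte(max(abs(d2)), 1e-5)
    # fitted parameters beat the uniform competitor
    expect_gte(log_likelihood(x, fit$params),
               log_likelihood(x, pmem_params(rep(0, n), matrix(0, n, n))))
  }
})

test_that("fixed-step gradient ascent never decreases the likelihood", {
  set.seed(31)
  for (r in 1:20) {
    n <- sample(2:4, 1)
    x <- rand_series(n, 100)
    fit <- pmem(x, learning_rate = 0.05, adapt = FALSE, max_iter = 400,
                trace = TRUE)
    expect_true(all(diff(fit$trace$log_likelihood) > -1e-9))
  }
})

test_that("fitted couplings stay symmetric with a zero diagonal", {
  set.seed(41)
  x <- rand_series(4, 500)
  J <- coef(pmem(x))$J
  expect_identical(unname(J), unname(t(J)))
  expect_identical(unname(diag(J)), rep(0, 4))
})

test_that("generating parameters are recovered from a large exact sample", {
  set.seed(51)
  n <- 5
  J <- matrix(runif(n * n, -0.5, 0.5), n, n); J <- (J + t(J)) / 2; diag(J) <- 0
  truth <- pmem_params(runif(n, -0.5, 0.5), J)
  x <- sample_patterns(truth, 20000, seed = 52)
  est <- coef(pmem(x))
  expect_gt(cor(truth$h, est$h), 0.9)
  expect_gt(cor(truth$J[upper.tri(J)], est$J[upper.tri(J)]), 0.9)
})

test_that("non-convergence is reported honestly, not as an error", {
  set.seed(61)
  x <- rand_series(3, 200)
  fit <- pmem(x, max_iter = 2)
  expect_false(fit$converged)
  expect_identical(fit$iterations, 2L)
  expect_gt(fit$final_mismatch, 1e-5)
})

test_that("model methods are coherent with the fit", {
  set.seed(71)
  x <- rand_series(3, 400)
  fit <- pmem(x)
  expect_equal(as.numeric(logLik(fit)), log_likelihood(x, fit$params))
  expect_identical(attr(logLik(fit), "df"), 3 + 3)
  r <- residuals(fit)
  expect_lt(max(abs(r$mean_activity)), 1e-5)
  p_all <- predict(fit, type = "probability")
  expect_equal(sum(p_all), 1)
  expect_equal(predict(fit, decode_state(5, 3)),
               enumerate_energies(fit$params)[5])
  expect_equal(exp(predict(fit, type = "log_probability")), p_all)
  sim <- simulate(fit, nsim = 10, seed = 1)
  expect_identical(dim(sim), c(3L, 10L))
  expect_output(print(fit), "converged")
  expect_output(print(summary(fit)), "Couplings")
  grDevices::pdf(NULL)
  plot(fit)
  grDevices::dev.off()
})
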