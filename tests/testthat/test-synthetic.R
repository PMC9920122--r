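test_that("exact sampler reproduces the Boltzmann law", {
  # uniform model: all four states near 1/4
  u <- pmem_params(c(0, 0), matrix(0, 2, 2))
  x <- sample_patterns(u, 40000, seed = 401)
  freq <- tabulate(encode_state(x), 4) / 40000
  expect_true(all(abs(freq - 0.25) < 0.01))

  # single-region marginal matches the logistic closed form
  x1 <- sample_patterns(pmem_params(0.5, matrix(0, 1, 1)), 100000,
                        seed = 402)
  expect_lt(abs(mean(x1 == 1) - 1 / (1 + exp(-1))), 0.01)

  # determinism
  p <- rand_params(3)
  expect_identical(sample_patterns(p, 500, seed = 403),
                   sample_patterns(p, 500, seed = 403))
})

test_that("empirical distribution converges to the exact one (TV distance)", {
  set.seed(405)
  p <- rand_params(4)
  x <- sample_patterns(p, 200000, seed = 406)
  emp <- tabulate(encode_state(x), 16) / 200000
  tv <- 0.5 * sum(abs(emp - boltzmann_distribution(p)))
  expect_lt(tv, 0.01)
})

test_that("continuous surrogates re-binarize to the source series", {
  set.seed(411)
  x <- sample_patterns(pmem_params(rep(0, 3), matrix(0, 3, 3)), 500,
                       seed = 412)
  y0 <- make_continuous_surrogate(x, noise_scale = 0, seed = 413)
  expect_identical(unname(binarize(y0)), unname(x))
  y1 <- make_continuous_surrogate(x, noise_scale = 0.1, seed = 414)
  expect_identical(unname(binarize(y1)), unname(x))
  expect_identical(dimnames(y1), dimnames(x))
  # overwhelming noise cannot guarantee recovery
  expect_warning(make_continuous_surrogate(x, noise_scale = 50, seed = 415),
                 "recover")
})

test_that("two-group generator reproduces the study design", {
  pp <- ferromagnetic_params(4, 0.1, 0.05, seed = 421)
  ds <- make_two_group_dataset(list(young = pp, old = pp),
                               subjects_per_group = c(23, 47),
                               t_max = 20, seed = 422)
  expect_identical(nrow(ds$manifest), 70L)
  expect_identical(as.vector(table(ds$manifest$group)[c("young", "old")]),
                   c(23L, 47L))
  expect_identical(names(ds$series), ds$manifest$subject_id)

  # reproducible byte-for-byte; subjects mutually distinct
  ds2 <- make_two_group_dataset(list(young = pp, old = pp),
                                subjects_per_group = c(23, 47),
                                t_max = 20, seed = 422)
  expect_identical(ds$series, ds2$series)
  expect_false(identical(ds$series[[1]], ds$series[[2]]))

  # coupling-scaled group raises the energy of the all-active state
  dse <- make_two_group_dataset(
    list(young = pp, old = scale_couplings(pp, 0.5)),
    subjects_per_group = c(4, 4), t_max = 400, seed = 423)
  e_young <- mean(vapply(dse$series[dse$manifest$group == "young"],
                         function(x) subject_state_energy(x, 16L), 1))
  e_old <- mean(vapply(dse$series[dse$manifest$group == "old"],
                       function(x) subject_state_energy(x, 16L), 1))
  expect_lt(e_young, e_old)
})

test_that("fit-sample-fit closes on the generating parameters", {
  set.seed(431)
  truth <- rand_params(4, h_sd = 0.25, j_sd = 0.25)
  est <- coef(pmem(sample_patterns(truth, 30000, seed = 432)))
  expect_gt(cor(truth$h, est$h), 0.9)
  expect_gt(cor(truth$J[upper.tri(truth$J)], est$J[upper.tri(est$J)]), 0.9)
})
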