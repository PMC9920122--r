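test_that("two-sample t-test matches the hand-computed pooled formula", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- two_sample_t(a, b, "pooled")
  # pooled formula: s_p^2 = 1, t = -3 / sqrt(2/3), df = 4
  t_exp <- -3 / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_exp, tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * stats::pt(t_exp, 4), tolerance = 1e-10)

  # antisymmetry
  swapped <- two_sample_t(b, a, "pooled")
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)

  # identical samples carry no evidence
  same <- two_sample_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("pooled and Welch flavors agree for balanced designs", {
  a <- c(0, 1, 2, 3); b <- c(5, 6, 7, 8)  # equal sizes, equal variances
  p <- two_sample_t(a, b, "pooled")
  w <- two_sample_t(a, b, "welch")
  expect_equal(p$t, w$t, tolerance = 1e-10)
  expect_equal(p$df, w$df, tolerance = 1e-10)
  expect_equal(p$p, w$p, tolerance = 1e-10)
})

test_that("degenerate samples are rejected", {
  expect_error(two_sample_t(1, c(1, 2)), "degenerate")
  expect_error(two_sample_t(c(1, 1), c(2, 2)), "degenerate")
})

test_that("Bonferroni threshold divides alpha by the comparison count", {
  expect_equal(bonferroni_threshold(0.05, 125), 0.0004, tolerance = 1e-15)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_equal(bonferroni_threshold(0.05, 125) * 125, 0.05, tolerance = 1e-15)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("subject state energies come from the subject's own fit", {
  x <- matrix(c(rep(1, 75), rep(-1, 25)), 1, dimnames = list("R1", NULL))
  e <- subject_state_energy(x, states = 2, tolerance = 1e-8)
  expect_equal(unname(e), -atanh(0.5), tolerance = 1e-6)

  set.seed(301)
  y <- rand_series(3, 200)
  e1 <- subject_state_energy(y, 1:8)
  e2 <- subject_state_energy(y, 1:8)
  expect_identical(e1, e2)  # determinism

  # uniform subject: every state at zero energy
  u <- t(all_states(2)); rownames(u) <- c("R1", "R2")
  expect_equal(max(abs(subject_state_energy(u, 1:4))), 0, tolerance = 1e-4)

  bad <- matrix(1, 2, 5, dimnames = list(c("A", "B"), NULL))
  expect_error(subject_state_energy(bad, 1, subject_id = "s7",
                                    max_iter = 5),
               NA)  # constant-but-valid binary series still fits
})

test_that("signature extraction flags only Bonferroni-surviving states", {
  set.seed(311)
  n_sub <- 8
  truth <- ferromagnetic_params(4, 0.4, 0.05, seed = 312)
  weak <- scale_couplings(truth, 0.5)
  energies <- t(vapply(seq_len(2 * n_sub), function(i) {
    p <- if (i <= n_sub) truth else weak
    subject_state_energy(sample_patterns(p, 600), states = c(1L, 16L))
  }, numeric(2)))
  colnames(energies) <- c("1", "16")
  groups <- rep(c("strong", "weak"), each = n_sub)

  res <- extract_signatures(energies, groups, m = 4, alpha = 0.05,
                            n_regions = 4, network = "SIM")
  expect_identical(nrow(res), 2L)
  expect_true(all(res$significant == (res$p < 0.05 / 4)))
  expect_true(all(diff(res$p) >= 0))
  expect_identical(res$pattern[res$state == 16], "++++")
  # stronger couplings give the lower energy at the all-active state
  row16 <- res[res$state == 16, ]
  expect_lt(row16$mean_strong, row16$mean_weak)

  # same-params groups at a harsh threshold: no false positives expected
  null_en <- energies
  null_groups <- rep(c("g1", "g2"), n_sub)  # interleave same-mix groups
  res0 <- extract_signatures(null_en, null_groups, m = 125)
  expect_equal(res0$corrected_alpha, rep(0.05 / 125, 2))
})
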