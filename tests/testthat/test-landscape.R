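test_that("analytic models yield the expected minima", {
  # 3-region ferromagnet: exactly the all-inactive and all-active states
  J <- matrix(0.5, 3, 3); diag(J) <- 0
  ferro <- energy_landscape(pmem_params(rep(0, 3), J))
  expect_identical(ferro$local_minima, c(1L, 8L))
  expect_equal(ferro$energies[1], ferro$energies[8])

  # factorized model: single minimum at the sign pattern of h
  fac <- energy_landscape(pmem_params(c(1, -2, 3), matrix(0, 3, 3)))
  expect_identical(fac$local_minima, encode_state(c(1, -1, 1)))
})

test_that("local minima match the brute-force neighbor check", {
  set.seed(101)
  for (r in 1:20) {
    n <- sample(2:4, 1)
    e <- rnorm(2^n)
    expect_identical(find_local_minima(e, n), brute_minima(e, n))
  }
  expect_error(find_local_minima(rnorm(7), 3), "length")
})

test_that("steepest-descent basins terminate at local minima", {
  J <- matrix(0.5, 3, 3); diag(J) <- 0
  ferro <- energy_landscape(pmem_params(rep(0, 3), J))
  b <- ferro$basins
  # minima are fixed points
  expect_identical(b[c(1, 8)], c(1L, 8L))
  # majority-active states drain to all-active, majority-inactive to all-off
  for (s in seq_len(8)) {
    n_up <- sum(decode_state(s, 3) == 1)
    expect_identical(b[s], if (n_up > 1) 8L else 1L)
  }
  set.seed(103)
  for (r in 1:10) {
    n <- sample(2:4, 1)
    e <- rnorm(2^n)
    bas <- assign_basins(e, n)
    expect_true(all(bas %in% find_local_minima(e, n)))
    # each descent step target has energy <= own energy
    expect_true(all(e[bas] <= e))
  }
})

test_that("basin ties resolve to the lowest state index", {
  # state 2 and 3 are equal-energy lowest neighbors of state 4 (N=2)
  e <- c(5, 0, 0, 1)
  expect_identical(assign_basins(e, 2)[4], 2L)
})

test_that("minimax barriers match exhaustive path enumeration", {
  # degenerate and hand-checked square cases
  e_sq <- c(-2, 1, 0.5, -2)
  expect_equal(minimax_barrier(e_sq, 2, 1, 1), -2)
  expect_equal(minimax_barrier(e_sq, 2, 1, 4), 0.5)

  set.seed(107)
  for (r in 1:15) {
    e <- rnorm(8)
    mins <- find_local_minima(e, 3)
    pairs <- which(upper.tri(diag(length(mins))), arr.ind = TRUE)
    for (k in seq_len(nrow(pairs))) {
      a <- mins[pairs[k, 1]]; b <- mins[pairs[k, 2]]
      expect_equal(minimax_barrier(e, 3, a, b), brute_minimax_dfs(e, 3, a, b))
      expect_equal(minimax_barrier(e, 3, a, b), minimax_barrier(e, 3, b, a))
    }
  }
  for (r in 1:15) {
    e <- rnorm(16)
    mins <- find_local_minima(e, 4)
    pairs <- which(upper.tri(diag(length(mins))), arr.ind = TRUE)
    for (k in seq_len(nrow(pairs))) {
      a <- mins[pairs[k, 1]]; b <- mins[pairs[k, 2]]
      expect_equal(minimax_barrier(e, 4, a, b),
                   brute_minimax_threshold(e, 4, a, b))
    }
  }
})

test_that("the global minimum is the mode of the Boltzmann distribution", {
  set.seed(109)
  for (r in 1:10) {
    land <- energy_landscape(rand_params(4))
    expect_identical(which.min(land$energies), which.max(land$probabilities))
    expect_true(which.min(land$energies) %in% land$local_minima)
  }
})

test_that("with h = 0 the minima set is closed under global sign flip", {
  set.seed(113)
  for (r in 1:10) {
    n <- sample(2:6, 1)
    J <- matrix(rnorm(n * n, 0, 0.5), n, n); J <- (J + t(J)) / 2; diag(J) <- 0
    land <- energy_landscape(pmem_params(rep(0, n), J))
    flipped <- sort(as.integer(2^n + 1 - land$local_minima))
    expect_identical(land$local_minima, flipped)
    expect_equal(land$energies[land$local_minima],
                 land$energies[rev(flipped)])
  }
})
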