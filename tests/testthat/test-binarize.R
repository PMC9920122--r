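test_that("binarization thresholds each region at its own time mean", {
  x <- matrix(c(1, 2, 3), 1, dimnames = list("ROI1", NULL))
  expect_equal(unname(binarize(x))[1, ], c(-1, -1, 1))

  x2 <- matrix(c(5, 1, 5, 1), 1, dimnames = list("ROI1", NULL))
  expect_equal(unname(binarize(x2))[1, ], c(1, -1, 1, -1))

  x3 <- rbind(A = c(2, 2, 2), B = c(1, 2, 3))
  expect_error(binarize(x3), "degenerate region.*A")
})

test_that("binarization preserves shape and is idempotent on sign structure", {
  set.seed(5)
  for (r in 1:10) {
    x <- rand_series(4, 50)
    # skip regions pinned at one level (mean on the boundary)
    if (any(abs(rowMeans(x)) == 1)) next
    b <- binarize(x * 1.0)
    expect_identical(dim(b), dim(x))
    expect_true(all(b == 1 | b == -1))
    expect_equal(unname(b), unname(x))
  }
})

test_that("bilateral reduction averages pairs before binarization", {
  mk <- function(n_pairs) {
    nm <- c(paste0("Reg", seq_len(n_pairs), "-L"),
            paste0("Reg", seq_len(n_pairs), "-R"))
    x <- matrix(rnorm(2 * n_pairs * 30), 2 * n_pairs, 30,
                dimnames = list(nm, NULL))
    pairs <- data.frame(left = paste0("Reg", seq_len(n_pairs), "-L"),
                        right = paste0("Reg", seq_len(n_pairs), "-R"),
                        merged = paste0("Reg", seq_len(n_pairs)))
    list(x = x, pairs = pairs)
  }
  set.seed(9)
  dmn <- mk(9)   # 18-region default-mode-sized set
  expect_identical(nrow(reduce_bilateral(dmn$x, dmn$pairs)), 9L)
  vis <- mk(7)   # 14-region visual-sized set
  expect_identical(nrow(reduce_bilateral(vis$x, vis$pairs)), 7L)

  x <- rbind("F-L" = c(1, 3), "F-R" = c(3, 5))
  red <- reduce_bilateral(x, data.frame(left = "F-L", right = "F-R",
                                        merged = "F"))
  expect_equal(red["F", ], c(2, 4))

  expect_error(reduce_bilateral(x, data.frame(left = "F-L", right = "G-R",
                                              merged = "F")), "absent")
  xx <- rbind(x, "G-L" = c(0, 0))
  expect_error(reduce_bilateral(
    xx, data.frame(left = c("F-L", "F-R"), right = c("F-R", "G-L"),
                   merged = c("F", "G"))), "disjoint")
})

test_that("bilateral reduction commutes with time cropping", {
  set.seed(13)
  x <- matrix(rnorm(4 * 40), 4, 40,
              dimnames = list(c("A-L", "A-R", "B-L", "B-R"), NULL))
  pairs <- data.frame(left = c("A-L", "B-L"), right = c("A-R", "B-R"),
                      merged = c("A", "B"))
  expect_equal(reduce_bilateral(x, pairs)[, 1:10],
               reduce_bilateral(x[, 1:10], pairs))
})

test_that("group concatenation joins subjects without re-binarizing", {
  set.seed(17)
  a <- rand_series(3, 100)
  b <- sample_patterns(rand_params(3), 120)
  rownames(b) <- rownames(a)
  cc <- concatenate_group(list(a, b))
  expect_identical(ncol(cc), 220L)
  expect_identical(concatenate_group(list(a)), a)

  # concatenated stats are the duration-weighted average of per-subject stats
  sa <- empirical_stats(a); sb <- empirical_stats(b)
  sc <- empirical_stats(cc)
  w <- c(100, 120) / 220
  expect_equal(sc$mean_activity,
               w[1] * sa$mean_activity + w[2] * sb$mean_activity)
  expect_equal(sc$pairwise_products,
               w[1] * sa$pairwise_products + w[2] * sb$pairwise_products)

  b2 <- b; rownames(b2) <- c("X", "Y", "Z")
  expect_error(concatenate_group(list(a, b2)), "region names")
})
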