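test_that("min-max standardisation anchors benefit and cost columns", {
  d <- indicator_data(cbind(b = c(0, 5, 10), c = c(0, 5, 10)),
                      orientations = c("benefit", "cost"))
  r <- standardize_indicators(d)
  expect_equal(unname(r[, "b"]), c(0, 0.5, 1))
  expect_equal(unname(r[, "c"]), c(1, 0.5, 0))

  const <- indicator_data(cbind(x = c(7, 7, 7), y = 1:3))
  expect_warning(rc <- standardize_indicators(const),
                 class = "ohindex_constant_column_warning")
  expect_equal(unname(rc[, "x"]), rep(0.5, 3))

  expect_error(indicator_data(matrix(1:3, 1)),
               class = "ohindex_domain_error")
  expect_error(indicator_data(matrix(c(1, NA, 3, 4), 2)),
               class = "ohindex_domain_error")
})

test_that("entropies hit the stated anchors and the hand-computed case", {
  # uniform column -> maximal entropy 1
  u <- matrix(rep(0.4, 5), ncol = 1)
  expect_equal(unname(indicator_entropy(u)$entropy), 1)
  # single positive entity -> entropy 0
  one <- matrix(c(1, 0, 0, 0), ncol = 1)
  expect_equal(unname(indicator_entropy(one)$entropy), 0)
  # share column (0.4, 0.3, 0.2, 0.1), m = 4: direct evaluation oracle
  p <- c(0.4, 0.3, 0.2, 0.1)
  oracle <- -sum(p * log(p)) / log(4)
  got <- indicator_entropy(matrix(p, ncol = 1))
  expect_equal(unname(got$entropy), oracle, tolerance = 1e-12)
  expect_equal(unname(got$entropy), 0.9232, tolerance = 1e-4)
  expect_equal(colSums(got$P), 1, ignore_attr = TRUE)
  # all-zero column: uniform with warning
  expect_warning(z <- indicator_entropy(cbind(a = c(0, 0, 0), b = p[1:3])),
                 class = "ohindex_uniform_column_warning")
  expect_equal(unname(z$entropy["a"]), 1)
})

test_that("entropy weights follow (1 - e) shares with degenerate guards", {
  expect_equal(unname(entropy_weight_vector(c(0.9, 0.8, 0.7))),
               c(1 / 6, 1 / 3, 1 / 2))
  expect_equal(unname(entropy_weight_vector(rep(0.4, 5))), rep(0.2, 5))
  expect_warning(w1 <- entropy_weight_vector(rep(1, 3)),
                 class = "ohindex_degenerate_entropy_warning")
  expect_equal(unname(w1), rep(1 / 3, 3))
})

test_that("published per-group entropies reproduce the published weights", {
  tab <- gohidi_weight_table()
  # the quoted human-health example holds at 0.2 percentage points
  hh <- tab[tab$group_code == "1", ]
  expect_lt(max(abs(100 * entropy_weight_vector(hh$entropy) -
                      hh$ewm_weight)), 0.2)
  # every group agrees within the worst case that 2-d.p. rounding of its
  # printed entropies can propagate (enumerated bound, per indicator)
  for (g in unique(tab$group_code)) {
    sub <- tab[tab$group_code == g, ]
    w <- 100 * entropy_weight_vector(sub$entropy)
    expect_true(all(abs(w - sub$ewm_weight) <=
                      ewm_rounding_bound(sub$entropy)))
  }
})

test_that("entropy bounds, conservation and scale invariance hold for random data", {
  set.seed(7)
  for (rep in 1:10) {
    m <- sample(5:40, 1); n <- sample(2:6, 1)
    d <- indicator_data(matrix(stats::rlnorm(m * n), m, n),
                        orientations = sample(c("benefit", "cost"), n,
                                              replace = TRUE))
    res <- ewm_weights(d)
    expect_true(all(res$entropy >= 0 & res$entropy <= 1))
    expect_equal(sum(res$weights), 1, tolerance = 1e-12)
    expect_equal(unname(colSums(res$P)), rep(1, n), tolerance = 1e-12)
    expect_true(all(res$standardized >= 0 & res$standardized <= 1))

    # positive affine transforms of raw columns change nothing
    scaled <- indicator_data(sweep(d$values, 2, stats::runif(n, 0.5, 5),
                                   "*") + 3,
                             orientations = d$orientations)
    expect_equal(ewm_weights(scaled)$weights, res$weights,
                 tolerance = 1e-9)
  }
})

test_that("a mean-preserving spread earns the larger entropy weight", {
  m <- 50
  b <- seq(0.35, 0.65, length.out = m)     # narrow standardised profile
  a <- 0.5 + 2.5 * (b - 0.5)               # strict spread of b, same mean
  ent <- indicator_entropy(cbind(a = a, b = b))
  w <- entropy_weight_vector(ent$entropy)
  expect_lt(ent$entropy[["a"]], ent$entropy[["b"]])
  expect_gt(w[["a"]], w[["b"]])
})

test_that("epsilon mode changes nothing materially for positive data", {
  d <- indicator_data(matrix(stats::runif(60, 1, 9), 20, 3))
  plain <- ewm_weights(d)$weights
  eps <- ewm_weights(d, epsilon = TRUE)$weights
  expect_equal(plain, eps, tolerance = 1e-6)
})
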