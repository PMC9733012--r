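test_that("judgment matrices are built and mirrored from questionnaire rows", {
  m <- consistent_matrix(c(0.5, 0.3, 0.2))
  expect_equal(m$values["i1", "i2"], 5 / 3)
  expect_equal(m$values["i1", "i3"], 2.5)
  expect_equal(m$values["i2", "i3"], 1.5)

  resp <- responses_from_matrix(m)
  built <- build_judgment_matrix(resp, scale = "reciprocal",
                                 indicators = m$indicators)
  expect_equal(built$values, m$values)

  # all pairs judged equally important -> all-ones matrix
  neutral <- responses_from_matrix(consistent_matrix(rep(1, 6)))
  expect_true(all(build_judgment_matrix(neutral)$values == 1))

  # completeness and scale violations
  expect_error(build_judgment_matrix(resp[-2, ], indicators = m$indicators),
               class = "ohindex_completeness_error")
  expect_error(build_judgment_matrix(rbind(resp, resp[1, ])),
               class = "ohindex_completeness_error")
  bad <- resp; bad$value[1] <- -2
  expect_error(build_judgment_matrix(bad), class = "ohindex_domain_error")
})

test_that("complementary-scale matrices obey their own mirror law", {
  resp <- data.frame(expert_id = "e1", group_code = "g",
                     indicator_i = c("a", "a", "b"),
                     indicator_e = c("b", "c", "c"),
                     value = c(0.7, 0.9, 0.6))
  m <- build_judgment_matrix(resp, scale = "complementary")
  expect_equal(diag(m$values), rep(0.5, 3), ignore_attr = TRUE)
  expect_equal(m$values + t(m$values), matrix(1, 3, 3),
               ignore_attr = TRUE)
  w <- fahp_weights(m)$weights
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_gt(w[["a"]], w[["b"]])  # a preferred to both others
})

test_that("consensus pooling preserves the scale law and known means", {
  m2 <- function(v) judgment_matrix(matrix(c(1, 1 / v, v, 1), 2),
                                    indicators = c("x", "y"))
  cons <- aggregate_judgments(list(m2(2), m2(8)))
  expect_equal(cons$values["x", "y"], 4)  # geometric mean sqrt(2 * 8)
  expect_equal(cons$values["y", "x"], 1 / 4)

  # idempotence on identical matrices
  m <- consistent_matrix(c(0.4, 0.35, 0.25))
  expect_equal(aggregate_judgments(list(m, m, m))$values, m$values)

  # consensus of consistent matrices sharing w stays consistent with w
  w <- c(0.5, 0.3, 0.2)
  cons2 <- aggregate_judgments(list(consistent_matrix(w),
                                    consistent_matrix(w)))
  expect_equal(unname(fahp_weights(cons2)$weights), w, tolerance = 1e-12)

  expect_error(aggregate_judgments(list()),
               class = "ohindex_aggregation_error")
  expect_error(
    aggregate_judgments(list(consistent_matrix(c(0.6, 0.4)),
                             consistent_matrix(c(0.5, 0.3, 0.2)))),
    class = "ohindex_aggregation_error")
})

test_that("row geometric means recover weights from judgment matrices", {
  # consistent-matrix recovery oracle
  expect_equal(unname(fahp_weights(consistent_matrix(c(0.5, 0.3, 0.2)))$weights),
               c(0.5, 0.3, 0.2), tolerance = 1e-12)
  # 2x2 with r12 = 4: row geometric means (2, 0.5) normalise to (0.8, 0.2)
  m <- judgment_matrix(matrix(c(1, 0.25, 4, 1), 2),
                       indicators = c("x", "y"))
  expect_equal(unname(fahp_weights(m)$weights), c(0.8, 0.2))
  # neutral matrix -> uniform weights
  expect_equal(unname(fahp_weights(consistent_matrix(rep(1, 5)))$weights),
               rep(0.2, 5))
})

test_that("weight recovery is exact and permutation-equivariant for random w", {
  set.seed(42)
  for (rep in 1:10) {
    a <- sample(3:8, 1)
    w <- stats::runif(a, 0.05, 1); w <- w / sum(w)
    got <- fahp_weights(consistent_matrix(w))$weights
    expect_equal(unname(got), w, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)

    p <- sample(a)
    mp <- judgment_matrix(outer(w[p], w[p], "/"),
                          indicators = paste0("i", p))
    expect_equal(unname(fahp_weights(mp)$weights), w[p],
                 tolerance = 1e-12)
  }
})

test_that("consistency ratio is 0 for consistent and 2x2 matrices", {
  expect_lt(consistency_ratio(consistent_matrix(c(0.4, 0.3, 0.2, 0.1))),
            1e-9)
  any2 <- judgment_matrix(matrix(c(1, 1 / 7, 7, 1), 2),
                          indicators = c("x", "y"))
  expect_identical(consistency_ratio(any2), 0)
})

test_that("consistency ratio matches the characteristic-polynomial root", {
  vals <- matrix(c(1, 1 / 2, 1 / 4,
                   2, 1, 1 / 4,
                   4, 4, 1), 3, 3)  # r12 = 2, r13 = 4, r23 = 4
  m <- judgment_matrix(vals, indicators = c("a", "b", "c"))
  # independent oracle: lambda_max as largest real root of det(A - x I) = 0
  A <- m$values
  minors <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1] +
    A[1, 1] * A[3, 3] - A[1, 3] * A[3, 1] +
    A[2, 2] * A[3, 3] - A[2, 3] * A[3, 2]
  roots <- polyroot(c(det(A), -minors, sum(diag(A)), -1))
  lambda <- max(Re(roots[abs(Im(roots)) < 1e-8]))
  cr_oracle <- ((lambda - 3) / 2) / 0.58
  expect_gt(cr_oracle, 0)
  expect_equal(consistency_ratio(m), cr_oracle, tolerance = 1e-8)
  expect_error(
    consistency_ratio(judgment_matrix(matrix(c(0.5, 0.3, 0.7, 0.5), 2),
                                      indicators = c("x", "y"),
                                      scale = "complementary")),
    class = "ohindex_scale_error")
})
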