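test_that("panel specs validate their stated world and reject bad values", {
  spec <- expert_panel_spec()
  expect_identical(unname(spec$group_sizes), c(6L, 4L, 5L))
  expect_identical(spec$n_experts, 42L)
  expect_equal(vapply(spec$priorities, sum, numeric(1)),
               c(`1` = 1, `2` = 1, `3` = 1))
  expect_error(expert_panel_spec(n_experts = 0),
               class = "ohindex_domain_error")
  expect_error(expert_panel_spec(group_sizes = c(1L, 4L)),
               class = "ohindex_domain_error")
  expect_error(expert_panel_spec(noise_sd = -0.1),
               class = "ohindex_domain_error")
  expect_error(indicator_data_spec(n_entities = 1),
               class = "ohindex_domain_error")
  expect_error(indicator_data_spec(dispersion = -1),
               class = "ohindex_domain_error")
})

test_that("simulated questionnaires are reciprocal, complete and seed-stable", {
  spec <- expert_panel_spec(n_experts = 3L, noise_sd = 0.2, seed = 99L)
  r1 <- simulate_expert_responses(spec)
  r2 <- simulate_expert_responses(spec)
  expect_identical(r1, r2)
  # one row per expert, group, unordered pair
  expect_identical(nrow(r1), 3L * (15L + 6L + 10L))
  # a different seed moves the values
  r3 <- simulate_expert_responses(expert_panel_spec(n_experts = 3L,
                                                    noise_sd = 0.2,
                                                    seed = 100L))
  expect_false(isTRUE(all.equal(r1$value, r3$value)))
  # the generator leaves the global RNG stream untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(simulate_expert_responses(spec))
  expect_identical(stats::runif(1), before)
})

test_that("noise-free panels recover the true priorities to machine precision", {
  spec <- expert_panel_spec(noise_sd = 0, seed = 4L)
  ws <- panel_weights(simulate_expert_responses(spec))
  for (g in names(ws)) {
    expect_equal(unname(ws[[g]]$weights), unname(spec$priorities[[g]]),
                 tolerance = 1e-12)
  }
})

test_that("a 42-expert panel at log-noise 0.1 recovers weights within RMSE 0.05", {
  for (seed in c(1L, 2L)) {
    spec <- expert_panel_spec(noise_sd = 0.1, seed = seed)
    ws <- panel_weights(simulate_expert_responses(spec))
    sq <- unlist(lapply(names(ws), function(g) {
      (unname(ws[[g]]$weights) - unname(spec$priorities[[g]]))^2
    }))
    expect_lt(sqrt(mean(sq)), 0.05)
  }
})

test_that("per-expert-then-average pooling agrees closely at modest noise", {
  spec <- expert_panel_spec(n_experts = 10L, noise_sd = 0.1, seed = 21L)
  resp <- simulate_expert_responses(spec)
  wa <- panel_weights(resp, pool = "judgments")
  wb <- panel_weights(resp, pool = "weights")
  for (g in names(wa)) {
    expect_lt(max(abs(wa[[g]]$weights - wb[[g]]$weights)), 0.01)
  }
})

test_that("simulated indicator data respects seed, families and conventions", {
  spec <- indicator_data_spec(n_entities = 40L, seed = 8L)
  d1 <- simulate_indicator_data(spec)
  d2 <- simulate_indicator_data(spec)
  expect_identical(d1$values, d2$values)
  expect_identical(dim(d1$values), c(40L, 4L))

  # zero-dispersion indicator earns entropy weight 0
  dz <- simulate_indicator_data(
    indicator_data_spec(n_entities = 30L, indicators = c("a", "b", "flat"),
                        dispersion = c(0.5, 0.5, 0), seed = 3L))
  suppressWarnings(w <- ewm_weights(dz)$weights)
  expect_equal(unname(w[["flat"]]), 0)
  expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("the higher-dispersion indicator gets the larger entropy weight across seeds", {
  wins <- vapply(1:20, function(seed) {
    d <- simulate_indicator_data(
      indicator_data_spec(n_entities = 200L, indicators = c("wide", "narrow"),
                          dispersion = c(1, 0.5), seed = seed))
    w <- ewm_weights(d)$weights
    w[["wide"]] > w[["narrow"]]
  }, logical(1))
  expect_true(all(wins))
})

test_that("end-to-end: simulated experts and data integrate near the blended truth", {
  spec <- expert_panel_spec(group_sizes = c(g = 4L), n_experts = 42L,
                            priorities = list(g = c(0.4, 0.3, 0.2, 0.1)),
                            noise_sd = 0.1, seed = 17L)
  subj <- panel_weights(simulate_expert_responses(spec))$g$weights

  dspec <- indicator_data_spec(n_entities = 300L,
                               indicators = paste0("g.", 1:4),
                               dispersion = c(1.2, 0.8, 0.5, 0.3),
                               seed = 18L)
  obj <- ewm_weights(simulate_indicator_data(dspec))$weights
  integrated <- integrate_weights(unname(subj), unname(obj),
                                  beta = 0.5)$weights

  # truth_subjective known exactly; truth_objective taken as the weights a
  # 20x larger sample of the same generator yields (stochastic target)
  big <- ewm_weights(simulate_indicator_data(
    indicator_data_spec(n_entities = 6000L, indicators = paste0("g.", 1:4),
                        dispersion = c(1.2, 0.8, 0.5, 0.3), seed = 19L)))
  blend <- 0.5 * (spec$priorities$g + unname(big$weights))
  expect_lt(sqrt(mean((integrated - blend)^2)), 0.05)
})
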