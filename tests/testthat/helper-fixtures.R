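# tiny frameworks and matrices built in code for unit tests

# one domain, one group, leaves with given weights
toy_framework <- function(leaf_weights = c(0.75, 0.25)) {
  n <- length(leaf_weights)
  nodes <- data.frame(
    code = c("1", "1.1", paste0("1.1.", seq_len(n))),
    name = c("Domain", "Group", paste("Leaf", seq_len(n))),
    level = c(1L, 2L, rep(3L, n)),
    category = "none",
    weight = c(1, 1, leaf_weights),
    stringsAsFactors = FALSE)
  indicator_framework(nodes, metadata = list(name = "toy", version = "1"))
}

# perfectly consistent reciprocal matrix from a positive weight vector
consistent_matrix <- function(w, group = "g", expert = "e1") {
  judgment_matrix(outer(w, w, "/"), indicators = paste0("i", seq_along(w)),
                  group_code = group, expert_id = expert)
}

# worst-case effect of 2-d.p. rounding of printed entropies on the entropy
# weights: enumerate +/- half-ulp perturbations of every e and record, per
# indicator, the largest resulting weight shift (percent scale)
ewm_rounding_bound <- function(e, delta = 0.005) {
  grid <- expand.grid(rep(list(c(-delta, 0, delta)), length(e)))
  base <- 100 * (1 - e) / sum(1 - e)
  dev <- apply(grid, 1, function(d) {
    ee <- e + as.numeric(d)
    abs(100 * (1 - ee) / sum(1 - ee) - base)
  })
  apply(dev, 1, max)
}

# long-format responses for one expert from a full matrix
responses_from_matrix <- function(m, expert = "e1", group = "g") {
  codes <- m$indicators
  pairs <- utils::combn(length(codes), 2L)
  data.frame(expert_id = expert, group_code = group,
             indicator_i = codes[pairs[1, ]],
             indicator_e = codes[pairs[2, ]],
             value = m$values[cbind(pairs[1, ], pairs[2, ])],
             stringsAsFactors = FALSE)
}
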