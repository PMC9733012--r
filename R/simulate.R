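#' Specification of a simulated expert panel
#'
#' Describes a pairwise-comparison questionnaire study with known ground
#' truth: the indicator groups (default three groups of 6, 4 and 5
#' second-level indicators, the geometry of the published One Health panel),
#' the number of experts (default 42, as in the published study), the true
#' priority vector of each group, and the log-scale noise of individual
#' judgments. By default the true priorities are the published subjective
#' (FAHP) weight columns, normalised — i.e. the generator's stated world is
#' the published panel.
#'
#' @param group_sizes named or unnamed integer vector of indicators per
#'   group (each >= 2).
#' @param n_experts number of simulated experts (>= 1).
#' @param priorities list of positive weight vectors, one per group, each
#'   summing to 1 (normalised on input); `NULL` takes the published
#'   second-level FAHP weights per first-level group.
#' @param noise_sd standard deviation of the Normal noise added to
#'   log-judgments (>= 0); 0 gives perfectly consistent experts.
#' @param seed integer seed driving all randomness.
#' @return An `expert_panel_spec` list.
#' @export
expert_panel_spec <- function(group_sizes = c(6L, 4L, 5L), n_experts = 42L,
                              priorities = NULL, noise_sd = 0.1,
                              seed = 1L) {
  if (any(group_sizes < 2L)) {
    abort_ohx("every group needs at least 2 indicators",
              "ohindex_domain_error")
  }
  if (!is.numeric(n_experts) || length(n_experts) != 1L || n_experts < 1) {
    abort_ohx("n_experts must be >= 1", "ohindex_domain_error")
  }
  if (noise_sd < 0) abort_ohx("noise_sd must be >= 0",
                              "ohindex_domain_error")
  groups <- names(group_sizes) %||% as.character(seq_along(group_sizes))
  if (is.null(priorities)) {
    tab <- gohidi_weight_table()
    pubs <- split(tab$fahp_weight, tab$group_code)
    if (all(groups %in% names(pubs)) &&
        identical(as.integer(unname(group_sizes)),
                  as.integer(unname(lengths(pubs)[groups])))) {
      priorities <- lapply(groups, function(g) pubs[[g]] / sum(pubs[[g]]))
    } else {
      priorities <- lapply(group_sizes, function(n) rep(1 / n, n))
    }
  }
  if (length(priorities) != length(group_sizes) ||
      !all(lengths(priorities) == group_sizes)) {
    abort_ohx("priorities must give one weight per indicator per group",
              "ohindex_domain_error")
  }
  priorities <- lapply(priorities, function(w) {
    if (any(w <= 0)) abort_ohx("priorities must be positive",
                               "ohindex_domain_error")
    w / sum(w)
  })
  names(priorities) <- groups
  structure(list(group_sizes = stats::setNames(as.integer(group_sizes),
                                               groups),
                 groups = groups, n_experts = as.integer(n_experts),
                 priorities = priorities, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "expert_panel_spec")
}

#' Simulate expert pairwise-comparison responses
#'
#' Each expert judges every unordered pair (i, e) within every group; the
#' stated value is the true ratio `w_i / w_e` perturbed by multiplicative
#' log-normal noise, `value = (w_i / w_e) * exp(rnorm(1, 0, noise_sd))`.
#' Multiplicative noise keeps the implied matrix exactly reciprocal — the
#' standard perturbation model for ratio-scale judgment studies. With
#' `noise_sd = 0` the consensus pipeline recovers the true priorities to
#' machine precision. Output is deterministic given the spec's seed, and the
#' global RNG state is left untouched.
#'
#' @param spec an [expert_panel_spec()].
#' @return Long data frame with columns `expert_id`, `group_code`,
#'   `indicator_i`, `indicator_e`, `value` (one row per expert, group and
#'   unordered pair).
#' @export
simulate_expert_responses <- function(spec) {
  stopifnot(inherits(spec, "expert_panel_spec"))
  with_seed(spec$seed, {
    out <- vector("list", spec$n_experts * length(spec$groups))
    k <- 0L
    for (b in seq_len(spec$n_experts)) {
      for (g in spec$groups) {
        w <- spec$priorities[[g]]
        a <- length(w)
        codes <- paste(g, seq_len(a), sep = ".")
        pairs <- utils::combn(a, 2L)
        eps <- stats::rnorm(ncol(pairs), 0, spec$noise_sd)
        k <- k + 1L
        out[[k]] <- data.frame(
          expert_id = sprintf("expert_%02d", b),
          group_code = g,
          indicator_i = codes[pairs[1, ]],
          indicator_e = codes[pairs[2, ]],
          value = w[pairs[1, ]] / w[pairs[2, ]] * exp(eps),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Recover group weights from questionnaire responses
#'
#' Convenience wrapper over the subjective-weighting pipeline: for each
#' group, every expert's responses are assembled into a reciprocal judgment
#' matrix, the matrices are pooled by element-wise geometric mean, and
#' weights are taken as the consensus row geometric means. A
#' per-expert-then-average mode (arithmetic mean of per-expert weight
#' vectors, renormalised) is available for sensitivity checks.
#'
#' @param responses long questionnaire data frame as produced by
#'   [simulate_expert_responses()] or read from CSV.
#' @param pool `"judgments"` (default: aggregate matrices, then weight) or
#'   `"weights"` (weight each expert, then average).
#' @return Named list of [fahp_weights()]-style weight vectors per group.
#' @export
panel_weights <- function(responses, pool = c("judgments", "weights")) {
  pool <- match.arg(pool)
  lapply(split(responses, responses$group_code), function(gr) {
    order_codes <- sort(unique(c(gr$indicator_i, gr$indicator_e)))
    mats <- lapply(split(gr, gr$expert_id), build_judgment_matrix,
                   scale = "reciprocal", indicators = order_codes)
    if (pool == "judgments") {
      fahp_weights(aggregate_judgments(unname(mats)))
    } else {
      ws <- vapply(mats, function(m) fahp_weights(m)$weights,
                   numeric(length(order_codes)))
      w <- rowMeans(ws)
      structure(list(group_code = gr$group_code[1],
                     indicators = order_codes,
                     omega = w, weights = w / sum(w)),
                class = "weight_vector")
    }
  })
}

#' Specification of a simulated entity-by-indicator dataset
#'
#' Stand-in for the unpublished country-level data behind objective
#' (entropy) weighting: per-indicator distribution family, location,
#' dispersion and orientation. The default family is log-normal — for
#' location-scale (affine) families, min-max standardisation is invariant to
#' dispersion, so dispersion differences would be invisible to the entropy
#' method by construction; log-normal dispersion changes distributional
#' shape, as skewed real-world country indicators do.
#'
#' @param n_entities number of entities m (>= 2); default 150, a realistic
#'   country-panel size.
#' @param indicators character vector of indicator codes.
#' @param family per-indicator family, `"lognormal"`, `"normal"` or
#'   `"uniform"` (recycled).
#' @param location per-indicator location (meanlog / mean / midpoint;
#'   recycled).
#' @param dispersion per-indicator dispersion, >= 0 (sdlog / sd /
#'   half-width; recycled).
#' @param orientations `"benefit"` or `"cost"` per indicator (recycled).
#' @param seed integer seed.
#' @return An `indicator_data_spec` list.
#' @export
indicator_data_spec <- function(n_entities = 150L,
                                indicators = paste0("I", 1:4),
                                family = "lognormal", location = 0,
                                dispersion = 0.5,
                                orientations = "benefit", seed = 1L) {
  if (!is.numeric(n_entities) || length(n_entities) != 1L ||
      n_entities < 2) {
    abort_ohx("n_entities must be >= 2", "ohindex_domain_error")
  }
  n <- length(indicators)
  rec <- function(x) if (length(x) == 1L) rep(x, n) else x
  family <- rec(family); location <- rec(location)
  dispersion <- rec(dispersion); orientations <- rec(orientations)
  if (any(lengths(list(family, location, dispersion, orientations)) != n)) {
    abort_ohx("per-indicator fields must have length 1 or n",
              "ohindex_domain_error")
  }
  if (!all(family %in% c("lognormal", "normal", "uniform"))) {
    abort_ohx("family must be lognormal, normal or uniform",
              "ohindex_domain_error")
  }
  if (any(dispersion < 0)) abort_ohx("dispersion must be >= 0",
                                     "ohindex_domain_error")
  structure(list(n_entities = as.integer(n_entities),
                 indicators = indicators, family = family,
                 location = location, dispersion = dispersion,
                 orientations = orientations, seed = as.integer(seed)),
            class = "indicator_data_spec")
}

#' Simulate an entity-by-indicator data matrix
#'
#' Draws each indicator column independently from its specified family and
#' attaches orientations, producing an [indicator_data()] object.
#' Deterministic given the spec's seed; the global RNG state is left
#' untouched.
#'
#' @param spec an [indicator_data_spec()].
#' @return An `indicator_data` object with `m = n_entities` rows.
#' @export
simulate_indicator_data <- function(spec) {
  stopifnot(inherits(spec, "indicator_data_spec"))
  with_seed(spec$seed, {
    m <- spec$n_entities
    cols <- lapply(seq_along(spec$indicators), function(j) {
      mu <- spec$location[j]; s <- spec$dispersion[j]
      switch(spec$family[j],
             lognormal = stats::rlnorm(m, meanlog = mu, sdlog = s),
             normal = stats::rnorm(m, mean = mu, sd = s),
             uniform = stats::runif(m, min = mu - s, max = mu + s))
    })
    values <- do.call(cbind, cols)
    colnames(values) <- spec$indicators
    indicator_data(values, orientations = spec$orientations)
  })
}
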