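#' Entity-by-indicator data matrices
#'
#' Raw values of `n` indicators observed on `m` entities (typically
#' countries), together with each indicator's orientation: `"benefit"` if
#' larger raw values are better, `"cost"` if smaller values are better.
#' Orientation is required input — it cannot be inferred from the data.
#'
#' @param values numeric matrix or data frame, one row per entity, one
#'   column per indicator.
#' @param orientations character vector (`"benefit"`/`"cost"`), one per
#'   indicator; a single value is recycled.
#' @param entities optional entity ids (default rownames or E1..Em).
#' @param indicators optional indicator codes (default colnames).
#' @return An `indicator_data` object.
#' @export
indicator_data <- function(values, orientations = "benefit",
                           entities = NULL, indicators = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    abort_ohx("indicator values must be numeric", "ohindex_format_error")
  }
  if (nrow(values) < 2L) {
    abort_ohx("at least two entities are required (m >= 2)",
              "ohindex_domain_error")
  }
  if (anyNA(values)) {
    abort_ohx("missing values must be resolved before weighting",
              "ohindex_domain_error")
  }
  m <- nrow(values); n <- ncol(values)
  entities <- entities %||% rownames(values) %||% paste0("E", seq_len(m))
  indicators <- indicators %||% colnames(values) %||% paste0("I", seq_len(n))
  if (length(orientations) == 1L) orientations <- rep(orientations, n)
  if (length(orientations) != n ||
      !all(orientations %in% c("benefit", "cost"))) {
    abort_ohx("orientations must be 'benefit' or 'cost', one per indicator",
              "ohindex_domain_error")
  }
  dimnames(values) <- list(entities, indicators)
  structure(list(values = values, entities = entities,
                 indicators = indicators,
                 orientations = stats::setNames(orientations, indicators)),
            class = "indicator_data")
}

#' @export
print.indicator_data <- function(x, ...) {
  cat(sprintf("<indicator_data> %d entities x %d indicators (%d cost-type)\n",
              nrow(x$values), ncol(x$values),
              sum(x$orientations == "cost")))
  invisible(x)
}

#' Min-max standardisation of an indicator data matrix
#'
#' Each benefit column j is rescaled to `(x - min_j) / (max_j - min_j)` and
#' each cost column to `(max_j - x) / (max_j - min_j)`, so 1 always marks
#' the best-performing entity. A constant column carries no ranking
#' information; it is mapped to 0.5 everywhere (with a warning), which
#' yields a uniform share vector, entropy 1 and hence entropy weight 0.
#'
#' @param data an `indicator_data` object.
#' @return Numeric matrix of standardised values in `[0, 1]`, same dimnames
#'   as the input.
#' @export
standardize_indicators <- function(data) {
  stopifnot(inherits(data, "indicator_data"))
  x <- data$values
  out <- x
  constant <- character(0)
  for (j in seq_len(ncol(x))) {
    rng <- range(x[, j])
    if (diff(rng) == 0) {
      out[, j] <- 0.5
      constant <- c(constant, data$indicators[j])
      next
    }
    out[, j] <- if (data$orientations[j] == "benefit") {
      (x[, j] - rng[1]) / diff(rng)
    } else {
      (rng[2] - x[, j]) / diff(rng)
    }
  }
  if (length(constant)) {
    warn_ohx(sprintf("constant column(s) standardised to 0.5: %s",
                     paste(constant, collapse = ", ")),
             "ohindex_constant_column_warning")
  }
  out
}

#' Shannon entropy of each indicator's cross-entity profile
#'
#' For standardised values r (in `[0, 1]`), each column is turned into
#' shares `P[i, j] = r[i, j] / sum_i r[i, j]` and scored by the normalised
#' Shannon entropy `e_j = -(1/log(m)) * sum_i P[i, j] * log(P[i, j])`, with
#' the `0 * log(0) = 0` convention. An all-zero column provides no
#' information and is treated as uniform (`e_j = 1`) with a warning. An
#' optional epsilon mode adds 1e-12 to every standardised value before the
#' shares, for comparison with implementations that avoid exact zeros that
#' way.
#'
#' @param r standardised matrix from [standardize_indicators()] (values in
#'   `[0, 1]`).
#' @param epsilon logical; add 1e-12 before forming shares.
#' @return List with `P` (share matrix, columns summing to 1) and `entropy`
#'   (named vector, each value in `[0, 1]`).
#' @export
indicator_entropy <- function(r, epsilon = FALSE) {
  r <- as.matrix(r)
  if (anyNA(r) || any(r < 0 | r > 1)) {
    abort_ohx("standardised values must lie in [0, 1]",
              "ohindex_domain_error")
  }
  m <- nrow(r)
  if (m < 2L) abort_ohx("m >= 2 required", "ohindex_domain_error")
  if (epsilon) r <- r + 1e-12
  csum <- colSums(r)
  zero_cols <- csum == 0
  if (any(zero_cols)) {
    warn_ohx(sprintf("all-zero column(s) treated as uniform: %s",
                     paste(colnames(r)[zero_cols] %||%
                             which(zero_cols), collapse = ", ")),
             "ohindex_uniform_column_warning")
  }
  P <- sweep(r, 2, ifelse(zero_cols, 1, csum), "/")
  P[, zero_cols] <- 1 / m
  plogp <- P * log(P)
  plogp[P == 0] <- 0                      # 0 * log(0) := 0
  e <- -colSums(plogp) / log(m)
  e <- pmin(pmax(e, 0), 1)                # guard FP drift at the bounds
  list(P = P, entropy = stats::setNames(e, colnames(r)))
}

#' Entropy weights from entropy values
#'
#' Converts per-indicator entropies into weights
#' `W_j = (1 - e_j) / sum_k (1 - e_k)`: the less even an indicator's
#' cross-entity profile (lower entropy), the more discriminating it is and
#' the larger its weight. If every entropy equals 1 the formula degenerates;
#' uniform weights are returned with a warning. Entropies above 1 (as found
#' in some published tables, where the printed scale exceeds the Shannon
#' bound) are accepted: all `1 - e_j` then share a sign and the formula
#' still yields positive normalised weights.
#'
#' @param entropy numeric vector of entropies.
#' @return Named weight vector summing to 1.
#' @export
entropy_weight_vector <- function(entropy) {
  if (!is.numeric(entropy) || length(entropy) < 1L || anyNA(entropy)) {
    abort_ohx("entropy must be a numeric vector", "ohindex_domain_error")
  }
  d <- 1 - entropy
  if (all(abs(d) < 1e-12)) {
    warn_ohx("all entropies equal 1; returning uniform weights",
             "ohindex_degenerate_entropy_warning")
    w <- rep(1 / length(entropy), length(entropy))
  } else {
    w <- d / sum(d)
    if (any(w < 0)) {
      warn_ohx("mixed entropy signs around 1 produced negative weights",
               "ohindex_degenerate_entropy_warning")
    }
  }
  stats::setNames(w, names(entropy))
}

#' Objective weights for one indicator group by the entropy weight method
#'
#' Convenience wrapper running the full chain on one sibling group:
#' min-max standardisation, cross-entity shares, normalised Shannon
#' entropies and entropy weights. Weights are computed independently within
#' each group, matching how per-group weight columns each sum to ~100%.
#'
#' @param data an `indicator_data` object holding the group's indicators.
#' @param epsilon passed to [indicator_entropy()].
#' @return An `ewm_result`: list with `standardized`, `P`, `entropy`,
#'   `weights`.
#' @export
ewm_weights <- function(data, epsilon = FALSE) {
  r <- standardize_indicators(data)
  ent <- indicator_entropy(r, epsilon = epsilon)
  w <- entropy_weight_vector(ent$entropy)
  structure(list(standardized = r, P = ent$P, entropy = ent$entropy,
                 weights = w),
            class = "ewm_result")
}

#' @export
print.ewm_result <- function(x, ...) {
  cat("<ewm_result>\n")
  print(round(rbind(entropy = x$entropy, weight = x$weights), 4))
  invisible(x)
}
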