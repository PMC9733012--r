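#' Pairwise-comparison judgment matrices
#'
#' A `judgment_matrix` records one expert's (or a panel consensus) pairwise
#' relative-importance judgments over the `a` indicators of one sibling
#' group. Two scale conventions are supported: `"reciprocal"` ratio
#' judgments (Saaty-style 1-9), where `r[i, e] * r[e, i] == 1` with unit
#' diagonal, and `"complementary"` 0.1-0.9 fuzzy preference, where
#' `r[i, e] + r[e, i] == 1` with 0.5 diagonal.
#'
#' @param values square numeric matrix of judgments.
#' @param indicators character vector of indicator codes (column order).
#' @param group_code code of the parent group whose children are compared.
#' @param scale `"reciprocal"` or `"complementary"`.
#' @param expert_id identifier of the judge; `"consensus"` for a pooled
#'   matrix.
#' @return A `judgment_matrix`.
#' @export
judgment_matrix <- function(values, indicators = colnames(values),
                            group_code = "group",
                            scale = c("reciprocal", "complementary"),
                            expert_id = "expert") {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  a <- nrow(values)
  if (a < 2L || ncol(values) != a || anyNA(values)) {
    abort_ohx("values must be a complete square matrix of order >= 2",
              "ohindex_domain_error")
  }
  if (is.null(indicators)) indicators <- as.character(seq_len(a))
  if (length(indicators) != a) {
    abort_ohx("indicators must match matrix order", "ohindex_domain_error")
  }
  tol <- 1e-8
  if (scale == "reciprocal") {
    if (any(values <= 0)) {
      abort_ohx("reciprocal-scale entries must be positive",
                "ohindex_domain_error")
    }
    if (max(abs(values * t(values) - 1)) > tol) {
      abort_ohx("reciprocal scale requires r[i,e] * r[e,i] == 1",
                "ohindex_domain_error")
    }
  } else {
    if (any(values < 0.1 - tol | values > 0.9 + tol)) {
      abort_ohx("complementary-scale entries must lie in [0.1, 0.9]",
                "ohindex_domain_error")
    }
    if (max(abs(values + t(values) - 1)) > tol) {
      abort_ohx("complementary scale requires r[i,e] + r[e,i] == 1",
                "ohindex_domain_error")
    }
  }
  dimnames(values) <- list(indicators, indicators)
  structure(list(values = values, indicators = indicators,
                 group_code = group_code, scale = scale,
                 expert_id = expert_id),
            class = "judgment_matrix")
}

#' @export
print.judgment_matrix <- function(x, ...) {
  cat(sprintf("<judgment_matrix> group %s, %s scale, judge %s\n",
              x$group_code, x$scale, x$expert_id))
  print(round(x$values, 3))
  invisible(x)
}

#' Build a judgment matrix from questionnaire responses
#'
#' Long-format questionnaire rows (one expert, one group) are assembled into
#' a complete judgment matrix: each stated value fills `r[i, e]`, the mirror
#' cell follows the scale law (reciprocal `1/v` or complement `1 - v`), and
#' the diagonal is 1 (reciprocal) or 0.5 (complementary). Every unordered
#' pair must appear exactly once.
#'
#' @param responses data frame with columns `expert_id`, `group_code`,
#'   `indicator_i`, `indicator_e`, `value`, all rows from one expert and one
#'   group.
#' @param scale `"reciprocal"` or `"complementary"`.
#' @param indicators optional explicit indicator order; defaults to sorted
#'   codes appearing in the responses.
#' @return A `judgment_matrix`.
#' @export
build_judgment_matrix <- function(responses,
                                  scale = c("reciprocal", "complementary"),
                                  indicators = NULL) {
  scale <- match.arg(scale)
  need <- c("expert_id", "group_code", "indicator_i", "indicator_e", "value")
  if (!is.data.frame(responses) || !all(need %in% names(responses))) {
    abort_ohx(sprintf("responses must have columns %s",
                      paste(need, collapse = ", ")),
              "ohindex_format_error")
  }
  if (nrow(responses) == 0L) {
    abort_ohx("no responses supplied", "ohindex_completeness_error")
  }
  if (length(unique(responses$expert_id)) != 1L ||
      length(unique(responses$group_code)) != 1L) {
    abort_ohx("responses must come from a single expert and group",
              "ohindex_domain_error")
  }
  if (any(responses$indicator_i == responses$indicator_e)) {
    abort_ohx("self-comparisons are not allowed", "ohindex_domain_error")
  }
  if (is.null(indicators)) {
    indicators <- sort(unique(c(responses$indicator_i,
                                responses$indicator_e)))
  }
  a <- length(indicators)
  unknown <- setdiff(c(responses$indicator_i, responses$indicator_e),
                     indicators)
  if (length(unknown)) {
    abort_ohx(sprintf("responses mention unknown indicators: %s",
                      paste(unique(unknown), collapse = ", ")),
              "ohindex_domain_error")
  }
  key <- function(i, e) paste(pmin(i, e), pmax(i, e))
  seen <- key(responses$indicator_i, responses$indicator_e)
  if (anyDuplicated(seen)) {
    abort_ohx(sprintf("duplicate judgments for pair(s): %s",
                      paste(unique(seen[duplicated(seen)]), collapse = "; ")),
              "ohindex_completeness_error")
  }
  all_pairs <- utils::combn(indicators, 2L)
  missing <- setdiff(key(all_pairs[1, ], all_pairs[2, ]), seen)
  if (length(missing)) {
    abort_ohx(sprintf("missing judgments for pair(s): %s",
                      paste(missing, collapse = "; ")),
              "ohindex_completeness_error")
  }
  v <- responses$value
  if (!is.numeric(v) || anyNA(v)) {
    abort_ohx("values must be numeric", "ohindex_format_error")
  }
  if (scale == "reciprocal" && any(v <= 0)) {
    abort_ohx("reciprocal-scale values must be positive",
              "ohindex_domain_error")
  }
  if (scale == "complementary" && any(v < 0.1 | v > 0.9)) {
    abort_ohx("complementary-scale values must lie in [0.1, 0.9]",
              "ohindex_domain_error")
  }
  m <- diag(if (scale == "reciprocal") 1 else 0.5, a)
  dimnames(m) <- list(indicators, indicators)
  for (r in seq_len(nrow(responses))) {
    i <- responses$indicator_i[r]; e <- responses$indicator_e[r]
    m[i, e] <- v[r]
    m[e, i] <- if (scale == "reciprocal") 1 / v[r] else 1 - v[r]
  }
  judgment_matrix(m, indicators, responses$group_code[1], scale,
                  as.character(responses$expert_id[1]))
}

#' Pool expert judgment matrices into a consensus matrix
#'
#' Element-wise geometric mean for reciprocal matrices (the only mean that
#' preserves reciprocity, and standard group-AHP practice) and element-wise
#' arithmetic mean for complementary matrices (preserves complementarity).
#'
#' @param matrices list of `judgment_matrix` objects sharing group,
#'   indicator order and scale.
#' @return A consensus `judgment_matrix` with `expert_id = "consensus"`.
#' @export
aggregate_judgments <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L ||
      !all(vapply(matrices, inherits, logical(1), "judgment_matrix"))) {
    abort_ohx("matrices must be a non-empty list of judgment matrices",
              "ohindex_aggregation_error")
  }
  first <- matrices[[1]]
  same <- vapply(matrices, function(m) {
    identical(m$indicators, first$indicators) &&
      identical(m$group_code, first$group_code) &&
      identical(m$scale, first$scale)
  }, logical(1))
  if (!all(same)) {
    abort_ohx("matrices differ in group, indicator order or scale",
              "ohindex_aggregation_error")
  }
  arr <- vapply(matrices, function(m) m$values,
                matrix(0, length(first$indicators),
                       length(first$indicators)))
  cons <- if (first$scale == "reciprocal") {
    exp(apply(log(arr), c(1, 2), mean))
  } else {
    apply(arr, c(1, 2), mean)
  }
  judgment_matrix(cons, first$indicators, first$group_code, first$scale,
                  expert_id = "consensus")
}

#' Subjective weights from a judgment matrix (row geometric means)
#'
#' The priority vector of a judgment matrix: the unnormalised weight of
#' indicator i is the geometric mean of row i,
#' `omega_i = (prod_e r[i, e])^(1/a)`, normalised over the group, followed by
#' the (idempotent) renormalisation `W_i = omega_i / sum(omega)`. For a
#' perfectly consistent ratio matrix `r[i, e] = w_i / w_e` this recovers `w`
#' exactly. Complementary-scale matrices are first transformed to ratio form
#' by `b[i, e] = r[i, e] / r[e, i]` before the row geometric means.
#'
#' @param matrix a `judgment_matrix`.
#' @param clip entries are clipped to `[1e-6, 1e6]` before logs as a zero /
#'   overflow guard; a warning is raised if clipping occurs.
#' @return A `weight_vector`: list with `group_code`, `indicators`, raw
#'   `omega` and normalised `weights` (summing to 1 within 1e-12).
#' @export
fahp_weights <- function(matrix, clip = TRUE) {
  stopifnot(inherits(matrix, "judgment_matrix"))
  v <- matrix$values
  if (matrix$scale == "complementary") v <- v / t(v)
  if (any(v <= 0)) {
    abort_ohx("judgment entries must be positive", "ohindex_domain_error")
  }
  if (clip && (any(v < 1e-6) || any(v > 1e6))) {
    warn_ohx("judgment entries clipped to [1e-6, 1e6]",
             "ohindex_clip_warning")
    v <- pmin(pmax(v, 1e-6), 1e6)
  }
  a <- nrow(v)
  gm <- exp(rowMeans(log(v)))      # (prod_e r_ie)^(1/a)
  omega <- gm / sum(gm)
  w <- omega / sum(omega)
  structure(list(group_code = matrix$group_code,
                 indicators = matrix$indicators,
                 omega = stats::setNames(omega, matrix$indicators),
                 weights = stats::setNames(w, matrix$indicators)),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector> group %s\n", x$group_code))
  print(round(x$weights, 4))
  invisible(x)
}

# Saaty random consistency indices for orders 1..10
.saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Consistency ratio of a reciprocal judgment matrix
#'
#' Standard eigenvalue diagnostic: the consistency index
#' `CI = (lambda_max - a) / (a - 1)` divided by the Saaty random index for
#' order `a`. Zero for perfectly consistent matrices (and for any matrix of
#' order 2, which is always consistent). Defined for the reciprocal scale
#' only.
#'
#' @param matrix a reciprocal-scale `judgment_matrix`.
#' @return Nonnegative consistency ratio; values below ~0.1 are
#'   conventionally regarded as acceptable.
#' @export
consistency_ratio <- function(matrix) {
  stopifnot(inherits(matrix, "judgment_matrix"))
  if (matrix$scale != "reciprocal") {
    abort_ohx("consistency ratio is defined for reciprocal matrices only",
              "ohindex_scale_error")
  }
  a <- nrow(matrix$values)
  if (a <= 2L) return(0)
  lambda_max <- max(Re(eigen(matrix$values, only.values = TRUE)$values))
  ci <- (lambda_max - a) / (a - 1)
  ri <- if (a <= length(.saaty_ri)) .saaty_ri[a] else 1.49
  max(ci / ri, 0)
}
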