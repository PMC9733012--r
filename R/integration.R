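#' Integrate subjective and objective weights
#'
#' The integrated weight of each indicator is the convex combination
#' `W_int = beta * W_subj + (1 - beta) * W_obj` of the expert-derived
#' (FAHP) weight and the data-derived (entropy) weight, where `beta` is the
#' subjective preference coefficient. With the squared-deviation-optimal
#' `beta = 0.5` (see [optimal_beta()]) this is the plain arithmetic mean of
#' the two weight vectors.
#'
#' @param subjective numeric weight vector (sums to 1), or a
#'   `weight_vector` from [fahp_weights()].
#' @param objective numeric weight vector (sums to 1), same indicator order.
#'   Named vectors are checked for name agreement.
#' @param beta subjective preference coefficient in `[0, 1]`.
#' @return An `integrated_weights` object: list with `indicators`,
#'   `subjective`, `objective`, `beta`, `weights`.
#' @export
integrate_weights <- function(subjective, objective, beta = 0.5) {
  if (inherits(subjective, "weight_vector")) subjective <- subjective$weights
  if (inherits(objective, "ewm_result")) objective <- objective$weights
  if (length(subjective) != length(objective)) {
    abort_ohx("subjective and objective weights differ in length",
              "ohindex_alignment_error")
  }
  if (!is.null(names(subjective)) && !is.null(names(objective)) &&
      !identical(names(subjective), names(objective))) {
    abort_ohx("subjective and objective weights are ordered differently",
              "ohindex_alignment_error")
  }
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < 0 || beta > 1) {
    abort_ohx("beta must be a single value in [0, 1]",
              "ohindex_domain_error")
  }
  stopifnot_prob_vector(subjective, "subjective weights", tol = 1e-6)
  stopifnot_prob_vector(objective, "objective weights", tol = 1e-6)
  w <- beta * subjective + (1 - beta) * objective
  structure(list(indicators = names(subjective) %||%
                   as.character(seq_along(subjective)),
                 subjective = subjective, objective = objective,
                 beta = beta, weights = w),
            class = "integrated_weights")
}

#' @export
print.integrated_weights <- function(x, ...) {
  cat(sprintf("<integrated_weights> beta = %.3f\n", x$beta))
  print(round(rbind(subjective = x$subjective, objective = x$objective,
                    integrated = x$weights), 4))
  invisible(x)
}

#' Optimal subjective preference coefficient
#'
#' Chooses `beta` by minimising the sum of squared deviations of the
#' integrated weights from both source vectors,
#' `Z(beta) = sum_i (W_int_i - W_subj_i)^2 + (W_int_i - W_obj_i)^2` with
#' `W_int = beta * W_subj + (1 - beta) * W_obj`. Since
#' `Z(beta) = sum_i (W_subj_i - W_obj_i)^2 * ((1 - beta)^2 + beta^2)`, the
#' minimiser is `beta = 0.5` for any pair of distinct weight vectors; the
#' default numerical method recovers this by one-dimensional minimisation of
#' `Z` so the result is computed, not assumed. When the two vectors are
#' identical the objective is flat and 0.5 is returned by convention with a
#' `flat` flag.
#'
#' @param subjective,objective weight vectors of equal length summing to 1.
#' @param method `"optimize"` (golden-section search on `Z` over `[0, 1]`),
#'   `"grid"` (fine grid search, step 1e-3), or `"analytic"` (vertex of the
#'   quadratic assembled from evaluations of `Z`).
#' @return Numeric `beta` in `[0, 1]`, with attribute `flat = TRUE` when the
#'   objective does not depend on `beta`.
#' @export
optimal_beta <- function(subjective, objective,
                         method = c("optimize", "grid", "analytic")) {
  method <- match.arg(method)
  if (inherits(subjective, "weight_vector")) subjective <- subjective$weights
  if (inherits(objective, "ewm_result")) objective <- objective$weights
  if (length(subjective) != length(objective)) {
    abort_ohx("weight vectors differ in length", "ohindex_alignment_error")
  }
  stopifnot_prob_vector(subjective, "subjective weights", tol = 1e-6)
  stopifnot_prob_vector(objective, "objective weights", tol = 1e-6)

  z <- function(beta) {
    w <- beta * subjective + (1 - beta) * objective
    sum((w - subjective)^2 + (w - objective)^2)
  }
  if (z(0) < .Machine$double.eps^0.75) {     # identical vectors: flat Z
    return(structure(0.5, flat = TRUE))
  }
  beta <- switch(method,
    optimize = stats::optimize(z, c(0, 1), tol = 1e-10)$minimum,
    grid = {
      grid <- seq(0, 1, by = 1e-3)
      grid[which.min(vapply(grid, z, numeric(1)))]
    },
    analytic = {
      # Z(b) = A*b^2 + B*b + C is quadratic; vertex from three evaluations
      z0 <- z(0); z1 <- z(1); zh <- z(0.5)
      A <- 2 * (z0 + z1 - 2 * zh)
      B <- z1 - z0 - A
      min(max(-B / (2 * A), 0), 1)
    })
  structure(beta, flat = FALSE)
}

#' Reproduce a published weight table's integration column
#'
#' Applies [integrate_weights()] within each first-level group of a weight
#' table shaped like [gohidi_weight_table()] (percent columns
#' `fahp_weight`, `ewm_weight`), returning the table with a recomputed
#' `integrated_recomputed` percent column for comparison against the printed
#' `integrated_weight`.
#'
#' @param table data frame with columns `code`, `group_code`,
#'   `fahp_weight`, `ewm_weight` (percentages per group).
#' @param beta subjective preference coefficient.
#' @return The input table with an `integrated_recomputed` column.
#' @export
integrate_weight_table <- function(table, beta = 0.5) {
  need <- c("code", "group_code", "fahp_weight", "ewm_weight")
  if (!all(need %in% names(table))) {
    abort_ohx(sprintf("table must have columns %s",
                      paste(need, collapse = ", ")),
              "ohindex_format_error")
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta > 1) {
    abort_ohx("beta must be a single value in [0, 1]",
              "ohindex_domain_error")
  }
  out <- table
  # printed percent columns are combined verbatim: two-decimal rounding
  # makes each group sum 99.9x-100.0x, so renormalising before combining
  # would distort the comparison against the printed integrated column
  out$integrated_recomputed <-
    beta * table$fahp_weight + (1 - beta) * table$ewm_weight
  out
}
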