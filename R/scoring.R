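#' Hierarchical composite scores for entities
#'
#' Scores each entity against a three-level indicator framework: leaf
#' indicator values are min-max standardised across the entity pool (cost
#' indicators reversed, so 1 is always best), then aggregated bottom-up by
#' linear weighted means — each second-level score is the weighted mean of
#' its leaves, each first-level score the weighted mean of its groups, and
#' the composite the weighted mean over first-level domains. Linear
#' aggregation matches the additive semantics of the framework's weights
#' and anchors the scale: an entity best on every indicator scores 1
#' (reported as 100), an entity worst on every indicator scores 0.
#'
#' Anchors are relative to the supplied entity pool by default; fixed
#' external anchors can be supplied to score against absolute benchmarks.
#'
#' @param fw an `indicator_framework` whose third-level codes are all
#'   present as columns of `data`.
#' @param data an `indicator_data` object (columns named by third-level
#'   codes, orientations attached).
#' @param anchors optional list with numeric vectors `min` and `max` (named
#'   by indicator code) overriding the pool min/max per indicator.
#' @return A `score_report`: list with `standardized` (entity x leaf
#'   matrix), `scores` (long data frame: entity, code, level, score) and
#'   `composite` (data frame: entity, score in `[0, 1]`, score_100).
#' @export
score_entities <- function(fw, data, anchors = NULL) {
  stopifnot(inherits(fw, "indicator_framework"),
            inherits(data, "indicator_data"))
  leaves <- fw$nodes[fw$nodes$level == 3L, , drop = FALSE]
  missing <- setdiff(leaves$code, data$indicators)
  if (length(missing)) {
    abort_ohx(sprintf("data lacks columns for indicator code(s): %s",
                      paste(missing, collapse = ", ")),
              "ohindex_coverage_error")
  }

  if (!is.null(anchors)) {
    vals <- data$values
    r <- vals
    for (code in leaves$code) {
      lo <- anchors$min[[code]]; hi <- anchors$max[[code]]
      if (is.null(lo) || is.null(hi) || hi <= lo) {
        abort_ohx(sprintf("invalid anchors for indicator %s", code),
                  "ohindex_domain_error")
      }
      z <- pmin(pmax((vals[, code] - lo) / (hi - lo), 0), 1)
      r[, code] <- if (data$orientations[code] == "benefit") z else 1 - z
    }
    r <- r[, leaves$code, drop = FALSE]
  } else {
    r <- standardize_indicators(data)[, leaves$code, drop = FALSE]
  }

  entities <- data$entities
  weighted_mean_children <- function(scores_by_code, parent) {
    kids <- framework_children(fw, parent)
    w <- kids$weight / sum(kids$weight)
    as.numeric(scores_by_code[, kids$code, drop = FALSE] %*% w)
  }

  lvl2 <- fw$nodes$code[fw$nodes$level == 2L]
  s2 <- vapply(lvl2, function(code) weighted_mean_children(r, code),
               numeric(length(entities)))
  s2 <- matrix(s2, nrow = length(entities),
               dimnames = list(entities, lvl2))
  lvl1 <- fw$nodes$code[fw$nodes$level == 1L]
  s1 <- vapply(lvl1, function(code) weighted_mean_children(s2, code),
               numeric(length(entities)))
  s1 <- matrix(s1, nrow = length(entities),
               dimnames = list(entities, lvl1))
  w1 <- fw$nodes$weight[fw$nodes$level == 1L]
  composite <- as.numeric(s1 %*% (w1 / sum(w1)))

  long <- rbind(
    data.frame(entity = rep(entities, ncol(r)),
               code = rep(colnames(r), each = length(entities)),
               level = 3L, score = as.numeric(r)),
    data.frame(entity = rep(entities, ncol(s2)),
               code = rep(colnames(s2), each = length(entities)),
               level = 2L, score = as.numeric(s2)),
    data.frame(entity = rep(entities, ncol(s1)),
               code = rep(colnames(s1), each = length(entities)),
               level = 1L, score = as.numeric(s1)))

  structure(list(standardized = r,
                 level2 = s2, level1 = s1,
                 scores = long,
                 composite = data.frame(entity = entities,
                                        score = composite,
                                        score_100 = 100 * composite)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("<score_report>\n")
  print(x$composite[order(-x$composite$score), ], row.names = FALSE)
  invisible(x)
}
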