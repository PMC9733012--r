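#' Packaged One Health intrinsic-drivers index frameworks
#'
#' Ships the published three-level evaluation framework of the global One
#' Health intrinsic-drivers index: `"final"` is the post-review framework (3
#' first-level, 15 second-level, 61 third-level indicators) with its
#' published weights — equal weights at levels 1 and 3, integrated
#' FAHP-entropy weights at level 2. `"initial"` is the pre-review framework
#' (3/19/79). The published record names the 19 deleted leaves and the
#' revised groups but not which group each deleted leaf belonged to, so the
#' initial fixture reconstructs plausible placements and equal provisional
#' weights; it is a documented reconstruction, not a published table.
#'
#' @param which `"final"` or `"initial"`.
#' @return An `indicator_framework`.
#' @seealso [gohidi_revision_log()], [gohidi_weight_table()]
#' @export
gohidi_framework <- function(which = c("final", "initial")) {
  which <- match.arg(which)
  file <- switch(which,
                 final = "gohidi_final.csv",
                 initial = "gohidi_initial_reconstructed.csv")
  fw <- load_framework(system.file("extdata", file, package = "ohindex",
                                   mustWork = TRUE))
  fw$metadata$name <- paste0("GOH-IDI (", which, ")")
  fw
}

#' Packaged expert-review revision log
#'
#' The sequence of add/delete/merge/rename operations that turns the initial
#' (3/19/79) framework into the final (3/15/61) one: one added leaf
#' (COVID-19), 19 deleted leaves, the merge of the air-quality and
#' climate-change groups, three deleted second-level groups, and three
#' renames. Leaf placements follow the reconstruction documented in
#' [gohidi_framework()].
#'
#' @return List of [revision_op()] objects.
#' @export
gohidi_revision_log <- function() {
  load_revisions(system.file("extdata", "gohidi_revisions.json",
                             package = "ohindex", mustWork = TRUE))
}

#' Published second-level weight table
#'
#' The published per-group weighting of the 15 second-level indicators:
#' subjective FAHP weight (percent), printed entropy value, entropy-method
#' weight (percent) and integrated weight (percent). `group_code` identifies
#' the first-level sibling group within which each weight column sums to
#' ~100.
#'
#' Note the printed entropy values lie in \[1.13, 2.01\], above the
#' theoretical upper bound of 1 for a Shannon entropy normalised by
#' `log(m)`; they are retained verbatim because the published entropy-weight
#' column is reproduced by applying the weight formula to them as printed.
#'
#' @return Data frame with columns `code`, `name`, `group_code`,
#'   `fahp_weight`, `entropy`, `ewm_weight`, `integrated_weight`.
#' @export
gohidi_weight_table <- function() {
  utils::read.csv(system.file("extdata", "gohidi_weights_level2.csv",
                              package = "ohindex", mustWork = TRUE),
                  stringsAsFactors = FALSE, encoding = "UTF-8",
                  colClasses = c(code = "character",
                                 group_code = "character"))
}
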