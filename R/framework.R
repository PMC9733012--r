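#' Three-level indicator frameworks
#'
#' An `indicator_framework` holds a three-level hierarchy of evaluation
#' indicators: first-level domains (e.g. human, animal and environmental
#' health), second-level indicator groups, and third-level leaf indicators.
#' Nodes carry a dotted hierarchical code (`"2.1.3"` is the third leaf of the
#' first group of domain 2), a display name, a structure/process/outcome
#' category tag (inert metadata), and a weight expressed as a fraction
#' relative to the node's sibling group, so every sibling group sums to 1.
#'
#' @param nodes data frame with columns `code`, `name`, `level`, `category`
#'   and `weight` (fractions in `[0, 1]`).
#' @param metadata list with at least `name` and `version`.
#' @param sum_tol tolerance used when checking that sibling weights sum to 1.
#'   Frameworks loaded from two-decimal percentage tables use 5e-4; exact
#'   constructions use 1e-9.
#' @return An object of class `indicator_framework`.
#' @export
indicator_framework <- function(nodes,
                                metadata = list(name = "framework",
                                                version = "1"),
                                sum_tol = 1e-9) {
  required <- c("code", "name", "level", "category", "weight")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes))) {
    abort_ohx(sprintf("nodes must be a data frame with columns %s",
                      paste(required, collapse = ", ")),
              "ohindex_format_error")
  }
  nodes <- as.data.frame(nodes)[required]
  nodes$code <- as.character(nodes$code)
  nodes$name <- as.character(nodes$name)
  nodes$level <- as.integer(nodes$level)
  nodes$category <- as.character(nodes$category)
  nodes$weight <- as.numeric(nodes$weight)
  rownames(nodes) <- NULL
  fw <- structure(list(nodes = nodes, metadata = metadata),
                  class = "indicator_framework", sum_tol = sum_tol)
  rep <- validate_framework(fw)
  if (!rep$pass) {
    abort_ohx(paste0("invalid framework:\n  ",
                     paste(rep$problems, collapse = "\n  ")),
              "ohindex_validation_error")
  }
  fw
}

#' @export
print.indicator_framework <- function(x, ...) {
  n <- framework_counts(x)
  cat(sprintf("<indicator_framework> %s (v%s)\n",
              x$metadata$name %||% "framework",
              x$metadata$version %||% "?"))
  cat(sprintf("  levels: %d first / %d second / %d third\n",
              n[[1]], n[[2]], n[[3]]))
  invisible(x)
}

#' Count nodes per hierarchy level
#'
#' @param fw an `indicator_framework`.
#' @return Named integer vector of length 3 (`"1"`, `"2"`, `"3"`).
#' @export
framework_counts <- function(fw) {
  stopifnot(inherits(fw, "indicator_framework"))
  cnt <- table(factor(fw$nodes$level, levels = 1:3))
  stats::setNames(as.integer(cnt), names(cnt))
}

#' Children of a framework node
#'
#' @param fw an `indicator_framework`.
#' @param code parent code; `""` returns the first-level nodes.
#' @return Data frame of child nodes in framework order.
#' @export
framework_children <- function(fw, code = "") {
  stopifnot(inherits(fw, "indicator_framework"))
  fw$nodes[parent_code(fw$nodes$code) == code, , drop = FALSE]
}

#' Validate a three-level indicator framework
#'
#' Checks the structural invariants: unique codes, code depth equal to the
#' declared level, weights in `[0, 1]` with every sibling group summing to 1
#' within tolerance, every second-level node carrying at least one leaf, and
#' third-level nodes being leaves. Always returns a report rather than
#' raising.
#'
#' @param fw an `indicator_framework` (or a bare list with a `nodes` data
#'   frame, so partially built objects can be inspected).
#' @param sum_tol tolerance on sibling-group weight sums; defaults to the
#'   tolerance recorded when the framework was built or loaded.
#' @return A `framework_validation` list: `counts` (nodes per level),
#'   `group_sums` (one row per sibling group: parent code, number of
#'   children, weight sum), `problems` (character vector) and `pass`.
#' @export
validate_framework <- function(fw, sum_tol = NULL) {
  nodes <- fw$nodes
  sum_tol <- sum_tol %||% attr(fw, "sum_tol") %||% 1e-9
  problems <- character(0)

  if (anyDuplicated(nodes$code)) {
    problems <- c(problems, sprintf("duplicate codes: %s",
      paste(unique(nodes$code[duplicated(nodes$code)]), collapse = ", ")))
  }
  bad_depth <- nodes$code[code_depth(nodes$code) != nodes$level]
  if (length(bad_depth)) {
    problems <- c(problems, sprintf("code depth != level for: %s",
                                    paste(bad_depth, collapse = ", ")))
  }
  if (!all(nodes$level %in% 1:3)) {
    problems <- c(problems, "levels must be 1, 2 or 3")
  }
  if (anyNA(nodes$weight) || any(nodes$weight < 0 | nodes$weight > 1)) {
    problems <- c(problems, "weights must lie in [0, 1]")
  }
  orphan <- setdiff(unique(parent_code(nodes$code)), c("", nodes$code))
  if (length(orphan)) {
    problems <- c(problems, sprintf("missing parent codes: %s",
                                    paste(orphan, collapse = ", ")))
  }

  parent <- parent_code(nodes$code)
  sums <- tapply(nodes$weight, parent, sum)
  group_sums <- data.frame(parent = names(sums),
                           n_children = as.integer(table(parent)[names(sums)]),
                           weight_sum = as.numeric(sums),
                           row.names = NULL, stringsAsFactors = FALSE)
  off <- group_sums[abs(group_sums$weight_sum - 1) > sum_tol, , drop = FALSE]
  if (nrow(off)) {
    problems <- c(problems, sprintf(
      "sibling weights of group '%s' sum to %.4f, not 1",
      ifelse(off$parent == "", "<root>", off$parent), off$weight_sum))
  }

  lvl2 <- nodes$code[nodes$level == 2L]
  childless <- lvl2[!(lvl2 %in% parent)]
  if (length(childless)) {
    problems <- c(problems, sprintf("second-level nodes without leaves: %s",
                                    paste(childless, collapse = ", ")))
  }

  structure(list(counts = framework_counts_raw(nodes),
                 group_sums = group_sums,
                 problems = problems,
                 pass = length(problems) == 0L),
            class = "framework_validation")
}

framework_counts_raw <- function(nodes) {
  cnt <- table(factor(nodes$level, levels = 1:3))
  stats::setNames(as.integer(cnt), names(cnt))
}

#' @export
print.framework_validation <- function(x, ...) {
  cat(sprintf("framework validation: %s\n",
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  counts: %d/%d/%d (first/second/third level)\n",
              x$counts[[1]], x$counts[[2]], x$counts[[3]]))
  if (!x$pass) cat(paste0("  - ", x$problems, collapse = "\n"), "\n")
  invisible(x)
}

#' Read an indicator framework from JSON or CSV
#'
#' Two serialisations are supported. JSON: an object with `metadata`
#' (`name`, `version`) and `nodes`, a flat array of objects with fields
#' `code`, `name`, `level`, `category`, `weight_percent`. CSV: columns
#' `code,name,level,category,weight_percent`, UTF-8, one row per node.
#' Percentages are converted to fractions on load; because published tables
#' print two decimals (so equal sevenths appear as 14.28 and groups sum to
#' 99.96-100.02), loaded frameworks are validated with a sibling-sum
#' tolerance of 5e-4.
#'
#' @param source path to a `.json` or `.csv` file, or a character scalar of
#'   JSON text.
#' @return An `indicator_framework`.
#' @export
load_framework <- function(source) {
  if (!is.character(source) || length(source) != 1L) {
    abort_ohx("source must be a single path or JSON string",
              "ohindex_format_error")
  }
  is_path <- file.exists(source)
  if (is_path && grepl("\\.csv$", source, ignore.case = TRUE)) {
    raw <- tryCatch(
      utils::read.csv(source, stringsAsFactors = FALSE, encoding = "UTF-8"),
      error = function(e) abort_ohx(
        sprintf("cannot parse CSV framework '%s': %s", source,
                conditionMessage(e)), "ohindex_format_error"))
    meta <- list(name = sub("\\.csv$", "", basename(source),
                            ignore.case = TRUE), version = "1")
    nodes <- raw
  } else {
    txt <- if (is_path) paste(readLines(source, warn = FALSE,
                                        encoding = "UTF-8"),
                              collapse = "\n") else source
    if (!nzchar(trimws(txt))) {
      abort_ohx("empty framework source", "ohindex_format_error")
    }
    parsed <- tryCatch(jsonlite::fromJSON(txt, simplifyDataFrame = TRUE),
                       error = function(e) abort_ohx(
                         sprintf("cannot parse JSON framework: %s",
                                 conditionMessage(e)),
                         "ohindex_format_error"))
    if (is.null(parsed$nodes)) {
      abort_ohx("JSON framework must contain a 'nodes' array",
                "ohindex_format_error")
    }
    meta <- as.list(parsed$metadata %||%
                      list(name = "framework", version = "1"))
    nodes <- as.data.frame(parsed$nodes)
  }
  if (!all(c("code", "name", "level", "weight_percent") %in% names(nodes))) {
    abort_ohx("framework source needs columns code, name, level, weight_percent",
              "ohindex_format_error")
  }
  if (is.null(nodes$category)) nodes$category <- "none"
  if (!is.numeric(nodes$weight_percent)) {
    abort_ohx("weight_percent must be numeric", "ohindex_format_error")
  }
  nodes$weight <- nodes$weight_percent / 100
  indicator_framework(nodes, metadata = meta, sum_tol = 5e-4)
}

#' Write an indicator framework to JSON or CSV
#'
#' Inverse of [load_framework()]: weights are written as percentages in
#' `weight_percent` at full precision, so `load_framework(write_framework(fw))`
#' reproduces `fw` node for node.
#'
#' @param fw an `indicator_framework`.
#' @param path output file; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_framework <- function(fw, path) {
  stopifnot(inherits(fw, "indicator_framework"))
  out <- fw$nodes[c("code", "name", "level", "category")]
  out$weight_percent <- fw$nodes$weight * 100
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(list(schema_version = "1",
                              metadata = fw$metadata, nodes = out),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Revision operations on a framework
#'
#' Constructs one revision step of the kind applied when expert review
#' streamlines an indicator framework: `add` inserts a leaf under an existing
#' second-level node, `delete` removes a node and its subtree, `merge`
#' replaces two or more sibling second-level nodes by one destination that
#' inherits (and re-codes) all their leaves, and `rename` changes a node's
#' display name only.
#'
#' @param kind one of `"add"`, `"delete"`, `"merge"`, `"rename"`.
#' @param target code of the node acted on (`delete`, `rename`).
#' @param sources two or more codes to merge (`merge`).
#' @param parent parent code for an added leaf (`add`).
#' @param code code of the added leaf or of the merge destination.
#' @param name display name for `add`, `merge` destination, or `rename`.
#' @param level,category leaf metadata for `add`.
#' @return A `revision_op` list.
#' @export
revision_op <- function(kind, target = NULL, sources = NULL, parent = NULL,
                        code = NULL, name = NULL, level = 3L,
                        category = "none") {
  kind <- match.arg(kind, c("add", "delete", "merge", "rename"))
  ok <- switch(kind,
    add = !is.null(parent) && !is.null(code) && !is.null(name),
    delete = !is.null(target),
    merge = length(sources) >= 2L && !is.null(code) && !is.null(name),
    rename = !is.null(target) && !is.null(name))
  if (!ok) {
    abort_ohx(sprintf("incomplete fields for revision kind '%s'", kind),
              "ohindex_revision_error")
  }
  structure(list(kind = kind, target = target, sources = sources,
                 parent = parent, code = code, name = name,
                 level = as.integer(level), category = category),
            class = "revision_op")
}

#' Read a revision log from JSON
#'
#' @param path JSON file with an `ops` array of revision objects.
#' @return List of [revision_op()] objects.
#' @export
load_revisions <- function(path) {
  parsed <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(parsed$ops, function(o) do.call(revision_op, o))
}

#' Apply a revision log to a framework
#'
#' Operations are applied in order against the running framework state; an
#' operation whose target does not resolve raises a revision error naming the
#' operation. Deleting or merging nodes breaks the sum-to-one invariant of
#' the affected sibling groups, so after all operations the weights of every
#' group whose membership changed are re-assigned: `"equal"` (default) resets
#' them to 1/n — the natural state before re-weighting, which is recomputed
#' downstream anyway — `"renormalize"` rescales surviving weights
#' proportionally, and `"none"` leaves weights untouched (the result may then
#' fail validation).
#'
#' @param fw an `indicator_framework`.
#' @param ops list of [revision_op()] objects (or a path accepted by
#'   [load_revisions()]).
#' @param reweight `"equal"`, `"renormalize"` or `"none"`.
#' @return The revised `indicator_framework`.
#' @export
apply_revisions <- function(fw, ops, reweight = c("equal", "renormalize",
                                                  "none")) {
  stopifnot(inherits(fw, "indicator_framework"))
  reweight <- match.arg(reweight)
  if (is.character(ops)) ops <- load_revisions(ops)
  if (inherits(ops, "revision_op")) ops <- list(ops)
  nodes <- fw$nodes
  touched <- character(0)

  resolve <- function(codes, op) {
    missing <- setdiff(codes, nodes$code)
    if (length(missing)) {
      abort_ohx(sprintf("revision '%s' targets unknown code(s): %s",
                        op$kind, paste(missing, collapse = ", ")),
                "ohindex_revision_error")
    }
  }

  for (op in ops) {
    if (!inherits(op, "revision_op")) op <- do.call(revision_op, op)
    if (op$kind == "add") {
      resolve(op$parent, op)
      if (op$code %in% nodes$code) {
        abort_ohx(sprintf("revision 'add': code %s already exists", op$code),
                  "ohindex_revision_error")
      }
      nodes <- rbind(nodes, data.frame(
        code = op$code, name = op$name, level = op$level,
        category = op$category, weight = 0, stringsAsFactors = FALSE))
      touched <- c(touched, op$parent)
    } else if (op$kind == "delete") {
      resolve(op$target, op)
      sub <- nodes$code == op$target |
        startsWith(nodes$code, paste0(op$target, "."))
      touched <- c(touched, parent_code(op$target))
      nodes <- nodes[!sub, , drop = FALSE]
    } else if (op$kind == "merge") {
      resolve(op$sources, op)
      par <- unique(parent_code(op$sources))
      if (length(par) != 1L) {
        abort_ohx("revision 'merge': sources must share one parent",
                  "ohindex_revision_error")
      }
      is_leaf_of <- parent_code(nodes$code) %in% op$sources
      leaves <- nodes[is_leaf_of, , drop = FALSE]
      keep <- !(nodes$code %in% op$sources) & !is_leaf_of
      dest <- data.frame(code = op$code, name = op$name,
                         level = unique(nodes$level[nodes$code %in% op$sources]),
                         category = nodes$category[nodes$code == op$sources[1]],
                         weight = sum(nodes$weight[nodes$code %in% op$sources]),
                         stringsAsFactors = FALSE)
      if (nrow(leaves)) {
        leaves$code <- paste(op$code, seq_len(nrow(leaves)), sep = ".")
      }
      nodes <- rbind(nodes[keep, , drop = FALSE], dest, leaves)
      touched <- c(touched, par, op$code)
    } else { # rename
      resolve(op$target, op)
      nodes$name[nodes$code == op$target] <- op$name
    }
  }

  # restore sibling-sum invariant in membership-changed groups
  parent <- parent_code(nodes$code)
  for (grp in intersect(unique(touched), c("", nodes$code))) {
    idx <- parent == grp
    if (!any(idx)) next
    if (reweight == "equal") {
      nodes$weight[idx] <- 1 / sum(idx)
    } else if (reweight == "renormalize") {
      s <- sum(nodes$weight[idx])
      nodes$weight[idx] <- if (s > 0) nodes$weight[idx] / s else 1 / sum(idx)
    }
  }

  ord <- order(vapply(strsplit(nodes$code, ".", fixed = TRUE), function(p)
    paste(formatC(suppressWarnings(as.integer(p)), width = 6, flag = "0"),
          collapse = "."), character(1)))
  nodes <- nodes[ord, , drop = FALSE]
  indicator_framework(nodes, metadata = fw$metadata,
                      sum_tol = if (reweight == "none") Inf
                                else attr(fw, "sum_tol"))
}

#' Equal weights for a sibling group
#'
#' First- and third-level indicators of the index are weighted equally within
#' their sibling group; this returns those weights as exact fractions 1/n.
#' Printed tables truncate to two decimals (1/7 appears as 14.28%, 1/3 as
#' 33.33%), so presentation layers, not this function, own any rounding
#' adjustment.
#'
#' @param n number of siblings (>= 1).
#' @return Numeric vector of `n` fractions summing to 1 exactly.
#' @export
equal_weight_allocation <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      n != floor(n)) {
    abort_ohx("n must be a positive integer", "ohindex_domain_error")
  }
  rep(1 / n, n)
}
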