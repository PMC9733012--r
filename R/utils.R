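#' @keywords internal
"_PACKAGE"

# classed conditions so callers can distinguish failure modes
abort_ohx <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "ohindex_error"),
                      call = call))
}

warn_ohx <- function(message, class) {
  warning(warningCondition(message, class = c(class, "ohindex_warning")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# depth of a dotted hierarchical code ("2.1.3" -> 3)
code_depth <- function(code) {
  lengths(strsplit(as.character(code), ".", fixed = TRUE))
}

# parent of a dotted code ("2.1.3" -> "2.1"; top level -> "")
parent_code <- function(code) {
  vapply(strsplit(as.character(code), ".", fixed = TRUE), function(p) {
    if (length(p) <= 1L) "" else paste(p[-length(p)], collapse = ".")
  }, character(1))
}

# evaluate expr with a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

stopifnot_prob_vector <- function(w, what = "weights", tol = 1e-8) {
  if (!is.numeric(w) || length(w) < 1L || anyNA(w)) {
    abort_ohx(sprintf("%s must be a numeric vector with no missing values", what),
              "ohindex_domain_error")
  }
  if (any(w < 0)) {
    abort_ohx(sprintf("%s must be nonnegative", what), "ohindex_domain_error")
  }
  if (abs(sum(w) - 1) > tol) {
    abort_ohx(sprintf("%s must sum to 1 (got %.10f)", what, sum(w)),
              "ohindex_domain_error")
  }
  invisible(w)
}
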