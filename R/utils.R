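# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that generators never leak
#' hidden state between calls. All randomized operations in the package go
#' through this; seeds are mandatory arguments, never implicit.
#'
#' @param seed integer scalar
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "Mersenne-Twister")
  expr
}

# derive a sub-seed for a pipeline stage, kept inside 32-bit integer range
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && all(!is.na(x)) && all(x == floor(x)) &&
    all(x >= if (positive) 1 else 0)
  if (!ok) {
    stop(sprintf("%s must be %s integer count(s)", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

# group membership as logical vectors from a two-column design
design_groups <- function(design) {
  stopifnot(is.data.frame(design), all(c("sample", "group") %in% names(design)))
  grp <- as.character(design$group)
  bad <- setdiff(unique(grp), c("case", "control"))
  if (length(bad)) {
    stop("design groups must be 'case'/'control', found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(samples = as.character(design$sample),
       is_case = grp == "case",
       n_case = sum(grp == "case"),
       n_control = sum(grp == "control"))
}
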