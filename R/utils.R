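#' @keywords internal
"_PACKAGE"

#' Class labels used throughout the package
#'
#' Segment classes, in canonical order. The order matters: argmax ties are
#' broken toward the earlier class, and confusion matrices / one-vs-rest
#' curves use this order.
#'
#' @return Character vector `c("physiological", "pathological", "artifact")`.
#' @export
ieeg_classes <- function() c("physiological", "pathological", "artifact")

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
# seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Parameter-naming validation helper: all errors mention the offending argument.
check_that <- function(ok, what) {
  if (!isTRUE(ok)) stop(what, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Empty event table in the package's 0-based, half-open sample convention.
empty_events <- function() {
  data.frame(onset_sample = integer(0), offset_sample = integer(0),
             kind = character(0), stringsAsFactors = FALSE)
}
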