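#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Classed conditions used across the package:
#   ivm_format_error  - malformed input file / table layout
#   ivm_data_error    - structurally valid input with inconsistent content
#   ivm_usage_error   - caller violated a precondition
#   ivm_metric_undefined - a metric has no defined value for this input
stop_format <- function(msg, ...) abort(msg, class = "ivm_format_error", ...)
stop_data <- function(msg, ...) abort(msg, class = "ivm_data_error", ...)
stop_usage <- function(msg, ...) abort(msg, class = "ivm_usage_error", ...)
stop_undefined <- function(msg, ...) abort(msg, class = "ivm_metric_undefined", ...)

#' Run code with a private, seeded RNG stream
#'
#' Saves and restores `.Random.seed` so that package randomness (the
#' simulator, the permutation test) never perturbs, and is never perturbed
#' by, the caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
with_private_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_usage("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# format a numeric to 6 significant digits, round-trip safe through as.numeric
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", trimws(formatC(signif(x, 6), digits = 6, format = "g")))
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

CELL_LABELS <- c("t_cell_resident", "t_cell_peripheral", "tumor")
T_CELL_LABELS <- c("t_cell_resident", "t_cell_peripheral")
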