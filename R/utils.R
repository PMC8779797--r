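#' @keywords internal
"_PACKAGE"

#' Derive reproducible child seeds from a master seed
#'
#' Each pipeline stage draws its own seed from the master seed so that stages
#' are independently reproducible: rerunning one stage with its child seed
#' gives the same output regardless of which other stages ran before it.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds to derive.
#' @return integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @export
fan_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# number of unordered pairs, vectorised; c may be a matrix
choose2 <- function(c) c * (c - 1) / 2

stop_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}
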