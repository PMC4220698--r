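#' @keywords internal
"_PACKAGE"

utils::globalVariables(c("x", "y", "density"))

## Internal validation helpers. All user-facing errors are classed so tests
## can assert on condition classes rather than message text.

abort <- function(message, class) {
  stop(structure(
    class = c(class, "synmorph_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

check_that <- function(ok, message, class = "synmorph_validation_error") {
  if (!isTRUE(ok)) abort(message, class)
  invisible(TRUE)
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x),
             sprintf("`%s` must be a single finite number", name))
  if (positive) check_that(x > 0, sprintf("`%s` must be > 0", name))
  if (nonneg) check_that(x >= 0, sprintf("`%s` must be >= 0", name))
  invisible(x)
}

check_count <- function(x, name) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x) &&
               x >= 0 && x == floor(x),
             sprintf("`%s` must be a non-negative integer", name))
  invisible(as.integer(x))
}

#' Convert between nanometre and micrometre length units
#'
#' Physical coordinates in this package are always tagged with a unit
#' (`"nm"` for electron microscopy, `"um"` for confocal data). Mixing the
#' two without explicit conversion is an error in every sampling routine,
#' so this helper is the only sanctioned bridge.
#'
#' @param x numeric vector of lengths.
#' @param from,to `"nm"` or `"um"`.
#' @return `x` expressed in the `to` unit.
#' @examples
#' convert_unit(1500, "nm", "um")
#' @export
convert_unit <- function(x, from, to) {
  from <- match.arg(from, c("nm", "um"))
  to <- match.arg(to, c("nm", "um"))
  if (from == to) return(x)
  if (from == "nm") x / 1000 else x * 1000
}

check_same_unit <- function(a, b, what = "inputs") {
  check_that(identical(a, b),
             sprintf("%s use different length units (%s vs %s); convert explicitly with convert_unit()",
                     what, a, b),
             class = "synmorph_unit_error")
}

## Seeded evaluation that does not disturb the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
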