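#' @keywords internal
"_PACKAGE"

## Avogadro constant (exact SI definition), 1/mol
N_AVOGADRO <- 6.02214076e23

## default detector saturation threshold, Hz (count rate per pixel)
DEFAULT_SATURATION_HZ <- 2e6

#' Stop unless a condition holds
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Scalar positive number check
#' @noRd
assert_positive <- function(x, name) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0,
              sprintf("`%s` must be a single positive finite number", name))
}

#' Scalar non-negative number check
#' @noRd
assert_nonneg <- function(x, name) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0,
              sprintf("`%s` must be a single non-negative finite number", name))
}

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "`seed` must be a single number")
  withr::with_seed(as.integer(seed), code)
}

#' Parse a physical quantity that may carry a unit suffix
#'
#' Accepts a bare number or a string such as `"7 pN"` or `"50 us"`. If a unit
#' is present it must match `unit` (a character vector of accepted spellings).
#' Returns the numeric value.
#' @noRd
parse_quantity <- function(x, unit, name = "value") {
  if (is.numeric(x)) {
    assert_that(length(x) == 1L && is.finite(x), sprintf("`%s` must be scalar", name))
    return(as.numeric(x))
  }
  if (is.character(x) && length(x) == 1L) {
    m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*([A-Za-zμ/²^0-9]*)\\s*$", x))[[1]]
    assert_that(length(m) == 3L && nzchar(m[2]),
                sprintf("cannot parse quantity `%s` for `%s`", x, name))
    val <- suppressWarnings(as.numeric(m[2]))
    assert_that(is.finite(val), sprintf("cannot parse numeric part of `%s`", x))
    if (nzchar(m[3])) {
      assert_that(m[3] %in% unit,
                  sprintf("`%s`: unit `%s` not accepted (expected one of: %s)",
                          name, m[3], paste(unit, collapse = ", ")))
    }
    return(val)
  }
  stop(sprintf("`%s` must be a number or a 'value unit' string", name), call. = FALSE)
}
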