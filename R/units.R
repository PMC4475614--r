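#' Parse a concentration unit string
#'
#' Recognized units are `nM`, `uM` (also the Unicode micro variants
#' `µM` and `μM`), `mM` and `M`. Parsing is case-tolerant in the
#' prefix except where case distinguishes units (`mM` vs `M`).
#'
#' @param unit Character scalar, e.g. `"uM"`.
#' @return A list with `canonical` (one of `"nM"`, `"uM"`, `"mM"`, `"M"`)
#'   and `scale`, the multiplier that converts a value in this unit to molar.
#' @examples
#' parse_conc_unit("uM")$scale    # 1e-6
#' parse_conc_unit("µM")$canonical  # "uM"
#' @export
parse_conc_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || is.na(unit))
    stop("`unit` must be a single character string", call. = FALSE)
  u <- trimws(unit)
  # normalize micro sign (U+00B5) and Greek mu (U+03BC) to ASCII 'u'
  u <- chartr("µμ", "uu", u)
  scale <- switch(u,
    "nM" = 1e-9, "NM" = 1e-9,
    "uM" = 1e-6, "UM" = 1e-6,
    "mM" = 1e-3,
    "M"  = 1,
    stop(sprintf("unknown concentration unit: '%s'", unit), call. = FALSE)
  )
  canonical <- c(`1e-09` = "nM", `1e-06` = "uM", `0.001` = "mM", `1` = "M")[[as.character(scale)]]
  list(canonical = canonical, scale = scale)
}

#' Convert a dose between concentration units
#'
#' @param value Numeric vector of concentrations.
#' @param from,to Unit strings accepted by [parse_conc_unit()].
#' @return `value` expressed in the `to` unit.
#' @examples
#' convert_dose(1.8, "mM", "uM")  # 1800
#' @export
convert_dose <- function(value, from, to) {
  value * parse_conc_unit(from)$scale / parse_conc_unit(to)$scale
}

#' Round half away from zero
#'
#' Display convention for report tables (base `round()` is
#' half-to-even); computation always precedes rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return `x` rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` with a private RNG stream; the caller's .Random.seed is
# untouched. Used by every generator and bootstrap so results depend only
# on the `seed` argument.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
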