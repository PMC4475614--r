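#' Express a combination dose as a fraction of the single-agent IC50
#'
#' The IC50-equivalent dose is `dose / single_agent_ic50`, computed on
#' unrounded values. It equals 1 exactly when the combination dose
#' matches the drug's own IC50. When units are supplied the dose is
#' converted to the IC50's unit first, so equivalents are dimensionless
#' regardless of input units.
#'
#' @param dose Combination dose(s), > 0.
#' @param single_agent_ic50 The drug's single-agent IC50, > 0.
#' @param unit_dose,unit_ic50 Optional unit strings; both or neither.
#' @return Numeric vector of dimensionless equivalents.
#' @examples
#' ic50_equivalent(54.360, 133.1)           # 0.408 at 3 decimals
#' ic50_equivalent(1.8, 5.79)               # 0.311 at 3 decimals
#' ic50_equivalent(1800, 5.79, "uM", "mM")  # unit-aware
#' @export
ic50_equivalent <- function(dose, single_agent_ic50, unit_dose = NULL, unit_ic50 = NULL) {
  if (xor(is.null(unit_dose), is.null(unit_ic50)))
    stop("supply both `unit_dose` and `unit_ic50`, or neither", call. = FALSE)
  if (!is.null(unit_dose)) dose <- convert_dose(dose, unit_dose, unit_ic50)
  if (any(!is.finite(dose)) || any(dose <= 0))
    stop("`dose` must be positive", call. = FALSE)
  if (length(single_agent_ic50) != 1L || !is.finite(single_agent_ic50) ||
      single_agent_ic50 <= 0)
    stop("`single_agent_ic50` must be a single positive number", call. = FALSE)
  dose / single_agent_ic50
}

#' Synergy classification bands for the combination index
#'
#' The default bands refine the basic CI interpretation (below 1
#' synergy, 1 additive, above 1 antagonism) into seven named classes.
#' Bands are lower-closed/upper-open except at 1.3, which belongs to
#' moderate antagonism (only CI strictly above 1.3 is antagonism).
#' The scale starts at 0.2; values below it are reported as
#' `"below-scale"` rather than assigned an unnamed stronger class.
#'
#' @return A data frame with columns `lower`, `upper`, `class`; each
#'   band is `[lower, upper)` except the final antagonism band, which
#'   is `(1.3, Inf)`.
#' @export
ci_bands <- function() {
  data.frame(
    lower = c(0, 0.2, 0.4, 0.6, 0.8, 0.9, 1.1, 1.3),
    upper = c(0.2, 0.4, 0.6, 0.8, 0.9, 1.1, 1.3, Inf),
    class = c("below-scale", "strong synergism", "synergism",
              "moderate synergism", "slight synergism", "additive",
              "moderate antagonism", "antagonism"),
    stringsAsFactors = FALSE
  )
}

#' Classify a combination index into a synergy band
#'
#' Classification always uses the unrounded CI; display rounding is a
#' reporting concern only (see [write_synergy_report()]).
#'
#' @param ci Numeric vector of combination indices, each >= 0.
#' @param bands Band table as returned by [ci_bands()]; bands are
#'   `[lower, upper)` except the last, which is upper-closed at its
#'   lower end being open: the default table makes 1.3 moderate
#'   antagonism and only CI > 1.3 antagonism.
#' @return Character vector of class labels.
#' @examples
#' classify_ci(c(0.211, 0.837, 1.0, 1.3, 1.595))
#' @export
classify_ci <- function(ci, bands = ci_bands()) {
  if (any(!is.finite(ci)) || any(ci < 0))
    stop("`ci` must be finite and non-negative", call. = FALSE)
  vapply(ci, function(v) {
    # last band is (lower, Inf): lower-open so that the boundary value
    # stays with the preceding band, matching an "> lower" legend; the
    # preceding band is therefore closed at its upper end.
    k <- nrow(bands)
    if (v > bands$lower[k]) return(bands$class[k])
    if (v >= bands$lower[k - 1]) return(bands$class[k - 1])
    i <- which(v >= bands$lower & v < bands$upper)
    bands$class[i[1]]
  }, character(1))
}

#' Combination index at a fixed effect level
#'
#' The combination index is the sum of the two drugs' IC50-equivalent
#' doses, `CI = e_a + e_b`, evaluated here at the 50% effect level.
#' CI below 1 indicates synergy (the combination reaches the effect at
#' a sub-additive total equivalent dose), 1 additivity, above 1
#' antagonism; [classify_ci()] refines this into bands. Sums are taken
#' on unrounded equivalents.
#'
#' @param e_a,e_b Numeric vectors of IC50-equivalent doses (>= 0),
#'   recycled to a common length.
#' @param effect_level Percent effect at which the equivalents were
#'   measured (fixed design field; default 50).
#' @param bands Band table for classification.
#' @return A `combination_index_result` data frame with columns `e_a`,
#'   `e_b`, `ci`, `effect_level`, `synergy_class`.
#' @examples
#' combination_index(1.207 / 337.2, 1.200 / 5.79)  # CI 0.211, strong synergism
#' @export
combination_index <- function(e_a, e_b, effect_level = 50, bands = ci_bands()) {
  if (any(!is.finite(e_a)) || any(e_a < 0) || any(!is.finite(e_b)) || any(e_b < 0))
    stop("equivalent doses must be finite and non-negative", call. = FALSE)
  n <- max(length(e_a), length(e_b))
  e_a <- rep_len(e_a, n); e_b <- rep_len(e_b, n)
  ci <- e_a + e_b
  structure(data.frame(e_a = e_a, e_b = e_b, ci = ci,
                       effect_level = effect_level,
                       synergy_class = classify_ci(ci, bands),
                       stringsAsFactors = FALSE),
            class = c("combination_index_result", "data.frame"))
}

#' Isobologram coordinates for a set of combinations
#'
#' Maps each combination design point to IC50-equivalent axes. The line
#' of additivity connects (1, 0) and (0, 1); a point below the line
#' (`e_a + e_b < 1`) indicates synergy, on the line additivity, above
#' it antagonism.
#'
#' @param records Data frame with columns `dose_a`, `dose_b` (and
#'   optionally `cell_line`); doses in the same units as the
#'   corresponding IC50s, or supply `unit_a`/`unit_b` columns matching
#'   `unit_ic50_a`/`unit_ic50_b`.
#' @param ic50_a,ic50_b Single-agent IC50s of drugs A and B.
#' @param labels Axis labels, e.g. `c("SSZ (IC50 eq)", "DFMO (IC50 eq)")`.
#' @return An `isobologram` list: `additivity_line` (two endpoints),
#'   `points` (with `e_a`, `e_b`, `ci`, `position` in
#'   below/on/above), `labels`.
#' @export
isobologram <- function(records, ic50_a, ic50_b,
                        labels = c("drug A (IC50 equivalents)",
                                   "drug B (IC50 equivalents)")) {
  e_a <- ic50_equivalent(records$dose_a, ic50_a)
  e_b <- ic50_equivalent(records$dose_b, ic50_b)
  ci <- e_a + e_b
  position <- ifelse(ci < 1, "below", ifelse(ci > 1, "above", "on"))
  pts <- data.frame(e_a = e_a, e_b = e_b, ci = ci, position = position,
                    stringsAsFactors = FALSE)
  if (!is.null(records$cell_line)) pts$cell_line <- records$cell_line
  structure(list(
    additivity_line = data.frame(e_a = c(1, 0), e_b = c(0, 1)),
    points = pts, labels = labels),
    class = "isobologram")
}

#' @export
print.isobologram <- function(x, ...) {
  cat(sprintf("Isobologram: %d combination points (%d below, %d on, %d above the additivity line)\n",
              nrow(x$points), sum(x$points$position == "below"),
              sum(x$points$position == "on"), sum(x$points$position == "above")))
  print(x$points, ...)
  invisible(x)
}

#' Plot an isobologram
#'
#' @param x An `isobologram`.
#' @param ... Passed to [plot()].
#' @export
plot.isobologram <- function(x, ...) {
  lim <- c(0, max(1, x$points$e_a, x$points$e_b) * 1.05)
  plot(x$points$e_a, x$points$e_b, xlim = lim, ylim = lim,
       xlab = x$labels[1], ylab = x$labels[2], pch = 19, ...)
  lines(x$additivity_line$e_a, x$additivity_line$e_b, lty = 2)
  invisible(x)
}

#' Build a combination-index table from per-B-dose dose-response plates
#'
#' Encodes the fixed-B/varying-A combination design: for every fixed
#' drug-B dose there is a full drug-A dose-response plate measured in
#' the presence of that B dose. Each plate is normalized and fit to
#' obtain drug A's combination IC50 at that B dose; equivalents, CI and
#' class follow. A plate whose fit fails yields a row flagged unfit
#' rather than aborting the table.
#'
#' @param plates List of [viability_plate()] objects (or pre-normalized
#'   `normalized_response` data frames), one per fixed B dose.
#' @param b_doses Numeric vector of the fixed drug-B doses, same length
#'   and order as `plates`, in the unit of `ic50_b`.
#' @param ic50_a,ic50_b Single-agent IC50s (A in the plates' unit, B in
#'   `b_doses`' unit). A `b_dose` of 0 contributes `e_b = 0`, so CI
#'   reduces to `e_a` alone.
#' @param cell_line Optional label carried into the table.
#' @param effect_level,bands,variable_slope See [combination_index()]
#'   and [fit_normalized_logistic()].
#' @return A `combination_index_result` data frame with one row per B
#'   dose: `e_a`, `e_b`, `ci`, `effect_level`, `synergy_class`,
#'   `dose_a` (fitted combination IC50 of A), `dose_b`, `cell_line`,
#'   `fit_ok`.
#' @export
synergy_table <- function(plates, b_doses, ic50_a, ic50_b, cell_line = NA_character_,
                          effect_level = 50, bands = ci_bands(),
                          variable_slope = TRUE) {
  stopifnot(length(plates) == length(b_doses))
  rows <- lapply(seq_along(plates), function(i) {
    pts <- if (inherits(plates[[i]], "viability_plate"))
      normalize_plate(plates[[i]]) else plates[[i]]
    fit <- tryCatch(fit_normalized_logistic(pts, variable_slope = variable_slope),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      return(data.frame(e_a = NA_real_, e_b = NA_real_, ci = NA_real_,
                        effect_level = effect_level,
                        synergy_class = "unfit", dose_a = NA_real_,
                        dose_b = b_doses[i], cell_line = cell_line,
                        fit_ok = FALSE, stringsAsFactors = FALSE))
    }
    dose_a <- 10^fit$log_ic50
    e_a <- ic50_equivalent(dose_a, ic50_a)
    e_b <- if (b_doses[i] == 0) 0 else ic50_equivalent(b_doses[i], ic50_b)
    ci <- e_a + e_b
    data.frame(e_a = e_a, e_b = e_b, ci = ci, effect_level = effect_level,
               synergy_class = classify_ci(ci, bands), dose_a = dose_a,
               dose_b = b_doses[i], cell_line = cell_line, fit_ok = TRUE,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("combination_index_result", "data.frame"))
}

#' Combination-index table from measured combination doses
#'
#' The direct route when combination IC50s are already known (for
#' example from a published table): computes equivalents, CI and class
#' for each (dose A, dose B) pair.
#'
#' @param dose_a Drug A's combination IC50 at each design point, in the
#'   unit of `ic50_a`.
#' @param dose_b The fixed drug-B dose per design point, in the unit of
#'   `ic50_b`.
#' @param ic50_a,ic50_b Single-agent IC50s.
#' @param cell_line,effect_level,bands See [synergy_table()].
#' @return A `combination_index_result` data frame with `dose_a`,
#'   `dose_b` columns appended.
#' @examples
#' ci_from_doses(c(1.207, 58.25), c(1.2, 1.8), ic50_a = 337.2, ic50_b = 5.79)
#' @export
ci_from_doses <- function(dose_a, dose_b, ic50_a, ic50_b,
                          cell_line = NA_character_, effect_level = 50,
                          bands = ci_bands()) {
  e_a <- ic50_equivalent(dose_a, ic50_a)
  e_b <- ic50_equivalent(dose_b, ic50_b)
  res <- combination_index(e_a, e_b, effect_level = effect_level, bands = bands)
  res$dose_a <- dose_a
  res$dose_b <- dose_b
  res$cell_line <- cell_line
  res$fit_ok <- TRUE
  res
}
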