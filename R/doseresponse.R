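#' Construct a viability plate
#'
#' A viability plate holds raw per-well optical densities (OD, read at
#' 490 nm in an MTS/formazan assay) together with the dose, replicate
#' index and well role. Treated wells at dose 0 are re-labelled as
#' vehicle wells: with no inhibitor they measure the same quantity as
#' the vehicle control.
#'
#' @param dose Numeric vector of concentrations, one per well. Must be
#'   non-negative; all wells share `unit`.
#' @param od Numeric vector of optical densities.
#' @param replicate Integer replicate index per well.
#' @param role Character vector, each element one of `"treated"`,
#'   `"vehicle"`, `"blank"`.
#' @param drug Drug label.
#' @param unit Concentration unit for every well (see [parse_conc_unit()]).
#' @return An object of class `viability_plate`: a data frame of wells
#'   with attributes `drug` and `unit`.
#' @examples
#' p <- viability_plate(dose = c(0, 10, 10), od = c(1.0, 0.6, 0.62),
#'                      replicate = c(1, 1, 2),
#'                      role = c("vehicle", "treated", "treated"))
#' normalize_plate(p)
#' @export
viability_plate <- function(dose, od, replicate = seq_along(dose),
                            role = "treated", drug = "drug", unit = "uM") {
  n <- length(dose)
  role <- rep_len(as.character(role), n)
  replicate <- rep_len(as.integer(replicate), n)
  stopifnot(length(od) == n)
  if (!all(role %in% c("treated", "vehicle", "blank")))
    stop("well roles must be 'treated', 'vehicle' or 'blank'", call. = FALSE)
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("doses must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(od)))
    stop("optical densities must be finite", call. = FALSE)
  parse_conc_unit(unit)  # validates
  role[role == "treated" & dose == 0] <- "vehicle"
  if (!any(role == "vehicle"))
    stop("plate has no vehicle wells; cannot normalize", call. = FALSE)
  wells <- data.frame(dose = as.numeric(dose), od = as.numeric(od),
                      replicate = replicate, role = role,
                      stringsAsFactors = FALSE)
  structure(wells, drug = drug, unit = unit, class = c("viability_plate", "data.frame"))
}

#' @export
print.viability_plate <- function(x, ...) {
  cat(sprintf("Viability plate: %s (%s), %d wells (%d treated, %d vehicle, %d blank)\n",
              attr(x, "drug"), attr(x, "unit"), nrow(x),
              sum(x$role == "treated"), sum(x$role == "vehicle"), sum(x$role == "blank")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Normalize a viability plate to percent of vehicle control
#'
#' Converts raw ODs to percent viability:
#' `100 * (mean OD_treated(d) - mean OD_blank) / (mean OD_vehicle - mean OD_blank)`,
#' with the blank term taken as 0 when the plate has no blank wells.
#' Values above 100 are retained (clipping would bias the top plateau).
#'
#' @param plate A [viability_plate()].
#' @param aggregate If `TRUE` (default) treated wells are averaged per
#'   dose; if `FALSE` every treated well keeps its own row (the
#'   replicate-level form used for residual-bootstrap intervals, where
#'   per-well residuals carry the plate noise).
#' @return A `normalized_response` data frame with columns `dose`,
#'   `response` (percent of vehicle), `n_replicates` and `sem`
#'   (standard error of the per-well percent values over replicates;
#'   `NA` for a single replicate). The dose-0 row is the vehicle
#'   condition and has `response` exactly 100 by construction.
#' @export
normalize_plate <- function(plate, aggregate = TRUE) {
  if (!inherits(plate, "viability_plate"))
    stop("`plate` must be a viability_plate", call. = FALSE)
  blank <- if (any(plate$role == "blank")) mean(plate$od[plate$role == "blank"]) else 0
  veh <- mean(plate$od[plate$role == "vehicle"])
  denom <- veh - blank
  if (denom <= 0)
    stop("degenerate plate: vehicle mean OD must exceed blank mean OD", call. = FALSE)
  pct <- function(od) 100 * (od - blank) / denom
  treated <- plate[plate$role == "treated", , drop = FALSE]
  out_dose <- sort(unique(treated$dose))
  rows <- if (aggregate) {
    lapply(out_dose, function(d) {
      v <- pct(treated$od[treated$dose == d])
      data.frame(dose = d, response = mean(v), n_replicates = length(v),
                 sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
    })
  } else {
    o <- order(treated$dose, treated$replicate)
    list(data.frame(dose = treated$dose[o], response = pct(treated$od[o]),
                    n_replicates = 1L, sem = NA_real_))
  }
  if (!aggregate) {
    # keep the individual vehicle wells: their spread is the anchor
    # uncertainty the bootstrap needs (their mean is exactly 100)
    veh_row <- data.frame(dose = 0, response = pct(plate$od[plate$role == "vehicle"]),
                          n_replicates = 1L, sem = NA_real_)
    res <- rbind(veh_row, do.call(rbind, rows))
    rownames(res) <- NULL
    return(structure(res, drug = attr(plate, "drug"), unit = attr(plate, "unit"),
                     class = c("normalized_response", "data.frame")))
  }
  veh_row <- {
    v <- pct(plate$od[plate$role == "vehicle"])
    data.frame(dose = 0, response = 100,  # exactly 100 by construction
               n_replicates = length(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }
  res <- rbind(veh_row, do.call(rbind, rows))
  rownames(res) <- NULL
  structure(res, drug = attr(plate, "drug"), unit = attr(plate, "unit"),
            class = c("normalized_response", "data.frame"))
}

# model: percent response at log10-dose x
.logistic_response <- function(x, log_ic50, hill) {
  100 / (1 + 10^((x - log_ic50) * hill))
}

#' Fit the log(inhibitor) versus normalized response model
#'
#' Least-squares fit of `Y = 100 / (1 + 10^((X - LogIC50) * HillSlope))`
#' with `X = log10(dose)`, the two-parameter normalized dose-response
#' family (Top fixed at 100, Bottom at 0). Dose-0 points are the
#' normalization anchor and do not enter the fit, since the model is
#' defined on log dose.
#'
#' Initialization is deterministic: LogIC50 starts at the log10 dose
#' whose response is nearest 50; the Hill slope is started at 1, 0.5
#' and 2 (Levenberg-Marquardt from each start); the lowest-SSE solution
#' wins, ties broken toward the slope nearest 1. No RNG is used.
#'
#' @param points A `normalized_response` data frame (or any data frame
#'   with `dose` and `response` columns).
#' @param variable_slope If `TRUE` (default) the Hill slope is a free
#'   parameter; if `FALSE` it is fixed at 1.
#' @return A `logistic_fit` list: `log_ic50`, `hill_slope`, `top`
#'   (100), `bottom` (0), `sse`, `converged`, `n_points`.
#' @export
fit_normalized_logistic <- function(points, variable_slope = TRUE) {
  pts <- points[points$dose > 0, , drop = FALSE]
  x <- log10(pts$dose)
  y <- pts$response
  n_par <- if (variable_slope) 2L else 1L
  n_dose <- length(unique(pts$dose))
  if (n_dose < n_par + 2L)
    stop(sprintf("need at least %d distinct nonzero doses, got %d",
                 n_par + 2L, n_dose), call. = FALSE)
  unit <- attr(points, "unit")
  fail <- structure(list(log_ic50 = NA_real_, hill_slope = NA_real_,
                         top = 100, bottom = 0, sse = NA_real_,
                         converged = FALSE, n_points = length(x), unit = unit),
                    class = "logistic_fit")
  if (stats::sd(y) == 0) return(fail)
  l0 <- x[which.min(abs(y - 50))]
  starts <- if (variable_slope) {
    list(c(l0, 1), c(l0, 0.5), c(l0, 2))
  } else list(c(l0))
  resid_fn <- if (variable_slope) {
    function(p) y - .logistic_response(x, p[1], p[2])
  } else {
    function(p) y - .logistic_response(x, p[1], 1)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    hill <- if (variable_slope) fit$par[2] else 1
    if (!is.finite(sse) || !is.finite(hill) || hill == 0) next
    better <- is.null(best) || sse < best$sse - 1e-12 ||
      (abs(sse - best$sse) <= 1e-12 && abs(hill - 1) < abs(best$hill - 1))
    if (better) best <- list(log_ic50 = fit$par[1], hill = hill, sse = sse)
  }
  if (is.null(best)) return(fail)
  structure(list(log_ic50 = best$log_ic50, hill_slope = best$hill,
                 top = 100, bottom = 0, sse = best$sse,
                 converged = TRUE, n_points = length(x), unit = unit),
            class = "logistic_fit")
}

#' Evaluate a fitted dose-response model
#'
#' @param object A `logistic_fit`.
#' @param dose Doses (same unit as the fitted plate).
#' @param ... Unused.
#' @return Predicted percent responses.
#' @export
predict.logistic_fit <- function(object, dose, ...) {
  .logistic_response(log10(dose), object$log_ic50, object$hill_slope)
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Normalized logistic fit: NOT converged\n")
  } else {
    cat(sprintf(
      "Normalized logistic fit: IC50 = %.4g %s (logIC50 = %.4f), Hill = %.3f, SSE = %.4g\n",
      10^x$log_ic50, if (is.null(x$unit)) "" else x$unit, x$log_ic50, x$hill_slope, x$sse))
  }
  invisible(x)
}

#' Estimate an IC50 with a residual-bootstrap confidence interval
#'
#' The point estimate is `10^LogIC50` from the full-data fit. The
#' interval comes from residual resampling: fitted values plus
#' resampled residuals are refit `n_boot` times. Residual (not case)
#' resampling is used because plates have few distinct doses; residuals
#' are inflated by `sqrt(n / (n - p))` before resampling to undo the
#' variance absorbed by the `p` fitted parameters. Refits that fail to
#' converge are dropped and counted; a warning is issued when more than
#' 10% fail.
#'
#' Two interval constructions are offered. The default,
#' `"bootstrap-t"`, studentizes each replicate's `LogIC50*` by its
#' delta-method standard error and applies the resulting t-quantiles to
#' the full-data estimate; this self-calibrates against the
#' plate-to-plate variability of the interval width and holds close to
#' nominal coverage at typical plate sizes. `"percentile"` reports
#' (expanded) percentile bounds of the resampled IC50s; it is simpler
#' but runs a few points below nominal coverage on single plates.
#'
#' Pass replicate-level points (`normalize_plate(plate, aggregate =
#' FALSE)`) so the residual pool reflects per-well noise; on per-dose
#' means the pool has very few members and the interval narrows. When
#' the points carry several dose-0 (vehicle) rows, each bootstrap
#' replicate also resamples the vehicle wells and rescales the curve,
#' propagating the normalization-anchor uncertainty that all wells of
#' a plate share.
#'
#' @param points A `normalized_response` data frame.
#' @param n_boot Number of bootstrap replicates; 0 gives a degenerate
#'   interval equal to the point estimate.
#' @param seed Integer seed making the bootstrap reproducible.
#' @param variable_slope Passed to [fit_normalized_logistic()].
#' @param level Confidence level (default 0.95).
#' @param interval Interval construction, `"bootstrap-t"` (default) or
#'   `"percentile"`.
#' @return An `ic50_estimate` list: `ic50`, `ci_low`, `ci_high`,
#'   `n_boot`, `n_failed`, `seed`, `fit` (the full-data `logistic_fit`).
#' @export
estimate_ic50 <- function(points, n_boot = 0, seed = NULL,
                          variable_slope = TRUE, level = 0.95,
                          interval = c("bootstrap-t", "percentile")) {
  interval <- match.arg(interval)
  if (n_boot < 0) stop("`n_boot` must be non-negative", call. = FALSE)
  fit <- fit_normalized_logistic(points, variable_slope = variable_slope)
  if (!fit$converged)
    stop("full-data fit did not converge; cannot estimate IC50", call. = FALSE)
  ic50 <- 10^fit$log_ic50
  if (n_boot == 0) {
    return(structure(list(ic50 = ic50, ci_low = ic50, ci_high = ic50,
                          n_boot = 0L, n_failed = 0L, seed = seed, fit = fit,
                          unit = fit$unit),
                     class = "ic50_estimate"))
  }
  pts <- points[points$dose > 0, , drop = FALSE]
  veh <- points$response[points$dose == 0]
  resample_vehicle <- length(veh) >= 2
  x <- log10(pts$dose)
  fitted_y <- .logistic_response(x, fit$log_ic50, fit$hill_slope)
  n_par <- if (variable_slope) 2 else 1
  n_res <- length(fitted_y)
  resid <- (pts$response - fitted_y) * sqrt(n_res / (n_res - n_par))
  se_hat <- .se_log_ic50(x, pts$response, fit$log_ic50, fit$hill_slope,
                         variable_slope)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ystar <- fitted_y + sample(resid, n_res, replace = TRUE)
      if (resample_vehicle) {
        # inflate the resampled anchor deviation by sqrt(n/(n-1)) so its
        # variance is an unbiased image of the vehicle-mean variance
        dev <- (mean(sample(veh, length(veh), replace = TRUE)) - 100) *
          sqrt(length(veh) / (length(veh) - 1))
        ystar <- ystar * 100 / (100 + dev)
      }
      bp <- data.frame(dose = pts$dose, response = ystar)
      f <- tryCatch(fit_normalized_logistic(bp, variable_slope = variable_slope),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) return(c(NA_real_, NA_real_))
      c(f$log_ic50,
        .se_log_ic50(x, ystar, f$log_ic50, f$hill_slope, variable_slope))
    }, numeric(2))
  })
  n_failed <- sum(!is.finite(boots[1, ]) | !is.finite(boots[2, ]))
  if (n_failed > 0.1 * n_boot)
    warning(sprintf("%d of %d bootstrap refits failed", n_failed, n_boot))
  keep <- is.finite(boots[1, ]) & is.finite(boots[2, ])
  if (interval == "bootstrap-t" && is.finite(se_hat) && se_hat > 0) {
    tstar <- (boots[1, keep] - fit$log_ic50) / boots[2, keep]
    tq <- stats::quantile(tstar, c(1 - (1 - level) / 2, (1 - level) / 2),
                          names = FALSE, type = 7)
    qs <- 10^(fit$log_ic50 - tq * se_hat)
  } else {
    # expanded percentile levels (Hesterberg): map the normal quantile to
    # the t scale at the residual df, undoing the usual small-sample
    # narrowness of plain percentile intervals
    z <- stats::qt(1 - (1 - level) / 2, df = max(n_res - n_par, 1)) *
      sqrt(n_res / max(n_res - 1, 1))
    alpha <- stats::pnorm(-z)
    qs <- stats::quantile(10^boots[1, keep], c(alpha, 1 - alpha),
                          names = FALSE, type = 7)
  }
  structure(list(ic50 = ic50, ci_low = min(qs[1], ic50),
                 ci_high = max(qs[2], ic50),
                 n_boot = as.integer(n_boot), n_failed = as.integer(n_failed),
                 seed = seed, fit = fit, unit = fit$unit),
            class = "ic50_estimate")
}

# Delta-method standard error of LogIC50 from the model Jacobian at the
# fitted parameters.
.se_log_ic50 <- function(x, y, log_ic50, hill, variable_slope) {
  u <- 10^((x - log_ic50) * hill)
  denom <- (1 + u)^2
  dl <- 100 * log(10) * hill * u / denom
  J <- if (variable_slope)
    cbind(dl, -100 * log(10) * (x - log_ic50) * u / denom) else cbind(dl)
  r <- y - 100 / (1 + u)
  df <- length(x) - ncol(J)
  if (df < 1) return(NA_real_)
  s2 <- sum(r^2) / df
  V <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
  if (is.null(V)) return(NA_real_)
  sqrt(V[1, 1])
}

#' @export
print.ic50_estimate <- function(x, ...) {
  u <- if (is.null(x$unit)) "" else x$unit
  cat(sprintf("IC50 = %.4g %s", x$ic50, u))
  if (x$n_boot > 0)
    cat(sprintf(" [%.4g, %.4g] (%d bootstrap replicates, %d failed)",
                x$ci_low, x$ci_high, x$n_boot, x$n_failed))
  cat("\n")
  invisible(x)
}
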