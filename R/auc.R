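#' Fit an evaluable curve to a 365-day window of a daily series
#'
#' `"trapezoid"` mode keeps the piecewise-linear daily series unchanged;
#' `"polynomial"` mode fits a least-squares polynomial of the given degree
#' (default 7) to the window's daily values, with time scaled to \[0, 1\]
#' over the window for numerical conditioning.
#'
#' @param series numeric vector of daily values covering the window.
#' @param window length-2 integer vector of day offsets `(first, last)`
#'   (0-based, inclusive) into `series`; spans 365 days, e.g. `c(0, 365)`.
#' @param mode `"trapezoid"` or `"polynomial"`.
#' @param degree polynomial degree (polynomial mode only).
#' @return object of class `auc_curve`: list with `mode`, `days` (window
#'   grid), `values` (daily values on the grid), and for polynomial mode
#'   `coef` (coefficients on the scaled time axis, increasing powers).
#' @export
fit_curve <- function(series, window, mode = c("trapezoid", "polynomial"),
                      degree = 7) {
  mode <- match.arg(mode)
  stopifnot(length(window) == 2L, window[1] >= 0,
            window[2] <= length(series) - 1)
  days <- window[1]:window[2]
  y <- series[days + 1]
  out <- list(mode = mode, days = days, values = y)
  if (mode == "polynomial") {
    if (degree >= length(days)) stop("degree must be below window length")
    u <- (days - window[1]) / (window[2] - window[1])
    # pracma::polyfit returns decreasing powers; store increasing
    out$coef <- rev(pracma::polyfit(u, y, degree))
    out$values <- pracma::polyval(rev(out$coef), u)
  }
  class(out) <- "auc_curve"
  out
}

#' Area under a fitted curve over its window
#'
#' Trapezoid mode integrates the piecewise-linear daily curve over the
#' window's daily grid. Polynomial mode integrates the fitted polynomial
#' analytically over the window, after flooring negative excursions at 0
#' (done on a fine sub-daily grid).
#'
#' @param curve an `auc_curve` from [fit_curve()].
#' @return area in abundance x days.
#' @export
auc_window <- function(curve) {
  stopifnot(inherits(curve, "auc_curve"))
  span <- max(curve$days) - min(curve$days)
  if (curve$mode == "trapezoid")
    return(pracma::trapz(curve$days, curve$values))
  u <- seq(0, 1, length.out = 20 * span + 1)
  v <- pmax(pracma::polyval(rev(curve$coef), u), 0)
  span * pracma::trapz(u, v)
}

#' Year-to-year AUC ratios
#'
#' @param auc_y1,auc_y2 areas for the two 365-day windows (vectorized).
#' @return data frame with `ratio_12 = auc_y1/auc_y2` and
#'   `ratio_21 = auc_y2/auc_y1`; a zero denominator yields `NA` (flagged in
#'   column `undefined`).
#' @export
auc_ratio <- function(auc_y1, auc_y2) {
  if (any(auc_y1 < 0) || any(auc_y2 < 0)) stop("negative area")
  r12 <- ifelse(auc_y2 > 0, auc_y1 / auc_y2, NA_real_)
  r21 <- ifelse(auc_y1 > 0, auc_y2 / auc_y1, NA_real_)
  data.frame(ratio_12 = r12, ratio_21 = r21,
             undefined = auc_y1 == 0 | auc_y2 == 0)
}

#' Per-entity AUC comparison between two year windows
#'
#' Computes the AUC of each daily series over both 365-day windows and the
#' ratios between them.
#'
#' @param daily numeric matrix of daily series (rows = entities), e.g. from
#'   [interpolate_daily()].
#' @param window_y1,window_y2 length-2 day-offset windows (default the two
#'   calendar years of a 730-day window, sharing the boundary day).
#' @param mode,degree passed to [fit_curve()].
#' @return data frame `entity_id`, `auc_y1`, `auc_y2`, `ratio_12`,
#'   `ratio_21`, `fit_mode`.
#' @export
auc_crosscondition <- function(daily, window_y1 = c(0, 365),
                               window_y2 = c(365, 730),
                               mode = c("trapezoid", "polynomial"),
                               degree = 7) {
  mode <- match.arg(mode)
  a1 <- apply(daily, 1, function(x)
    auc_window(fit_curve(x, window_y1, mode, degree)))
  a2 <- apply(daily, 1, function(x)
    auc_window(fit_curve(x, window_y2, mode, degree)))
  r <- auc_ratio(a1, a2)
  data.frame(entity_id = rownames(daily), auc_y1 = a1, auc_y2 = a2,
             ratio_12 = r$ratio_12, ratio_21 = r$ratio_21,
             fit_mode = if (mode == "polynomial")
               paste0("polynomial-", degree) else mode,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster-level AUC comparison
#'
#' The cluster curve is the sum of its members' daily series (the cluster's
#' total relative abundance); AUCs and ratios are computed on that summed
#' curve.
#'
#' @param model a named `cluster_model`.
#' @param daily daily matrix covering all members.
#' @inheritParams auc_crosscondition
#' @return data frame as in [auc_crosscondition()], one row per cluster.
#' @export
cluster_auc <- function(model, daily, window_y1 = c(0, 365),
                        window_y2 = c(365, 730),
                        mode = c("trapezoid", "polynomial"), degree = 7) {
  stopifnot(!is.null(model$names))
  mode <- match.arg(mode)
  rows <- t(vapply(seq_along(model$names), function(j) {
    members <- names(model$assignments)[model$assignments == j]
    colSums(daily[members, , drop = FALSE])
  }, numeric(ncol(daily))))
  rownames(rows) <- model$names
  auc_crosscondition(rows, window_y1, window_y2, mode, degree)
}
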