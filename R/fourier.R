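#' Interpolate station samples to daily resolution
#'
#' Each ASV's biweekly (possibly gappy) series is linearly interpolated onto
#' an integer daily grid spanning the analysis window. Values at sampling
#' dates are preserved exactly; before the first and after the last sample
#' the nearest observed value is extended as a constant.
#'
#' @param table a [sample_table()].
#' @param window length-2 vector of dates (start, end), inclusive.
#' @return numeric matrix, one row per ASV, one column per day
#'   (`T = end - start + 1` columns), with attributes `start_date` and
#'   `station_id`. ASVs with all-missing values come back as all-zero rows
#'   with a warning.
#' @export
interpolate_daily <- function(table, window) {
  stopifnot(inherits(table, "sample_table"), length(window) == 2L)
  window <- as.Date(window)
  if (window[2] <= window[1]) stop("window end must be after start")
  days <- as.numeric(table$dates - window[1])
  tlen <- as.numeric(window[2] - window[1]) + 1
  grid <- seq(0, tlen - 1)
  out <- matrix(0, nrow = length(table$asv_ids), ncol = tlen,
                dimnames = list(table$asv_ids, NULL))
  allna <- character(0)
  for (i in seq_along(table$asv_ids)) {
    y <- table$values[i, ]
    ok <- is.finite(y)
    if (sum(ok) == 0L) { allna <- c(allna, table$asv_ids[i]); next }
    if (sum(ok) == 1L) { out[i, ] <- y[ok]; next }
    out[i, ] <- stats::approx(days[ok], y[ok], xout = grid, method = "linear",
                              rule = 2)$y
  }
  if (length(allna))
    warning("ASV(s) with no observed values emitted as zero series: ",
            paste(allna, collapse = ", "))
  attr(out, "start_date") <- window[1]
  attr(out, "station_id") <- table$station_id
  out
}

#' Discrete Fourier components and seasonality of daily series
#'
#' Computes the unnormalized forward DFT coefficients
#' `c_k = sum_d x_d exp(-2*pi*i*k*d/T)` for `k = 0..K` of each daily series,
#' the seasonality score `s = |c_m| / |c_0|` (with `m` the index of the
#' annual component, i.e. the number of whole years in the window), the
#' day-of-year of the annual-component maximum, and the annual amplitude
#' `|c_m|`. A series with `|c_0| = 0` is flagged degenerate and gets `s = 0`.
#'
#' @param daily numeric matrix (rows = ASVs) or a single numeric vector of
#'   daily values.
#' @param K highest retained component index (default 4).
#' @param m index of the annual component; defaults to `floor(T / 365)`.
#' @return object of class `fourier_profiles`: list with `asv_ids`,
#'   complex matrix `components` (columns `c0..cK`), numeric vectors
#'   `seasonality`, `annual_phase_day`, `annual_amplitude`, logical
#'   `degenerate`, and scalars `T`, `K`, `m`.
#' @export
dft_components <- function(daily, K = 4, m = NULL) {
  if (is.null(dim(daily))) daily <- matrix(daily, nrow = 1,
                                           dimnames = list("series1", NULL))
  tlen <- ncol(daily)
  if (is.null(m)) m <- max(1L, floor(tlen / 365))
  K <- max(K, m)
  if (tlen < 2 * K)
    stop("series length ", tlen, " too short for K = ", K,
         " (components beyond T/2 exceed the Nyquist limit)")
  # fft over rows gives exactly the unnormalized forward transform
  co <- t(apply(daily, 1, function(x) stats::fft(x)[seq_len(K + 1)]))
  if (nrow(daily) == 1L) co <- matrix(co, nrow = 1)
  colnames(co) <- paste0("c", 0:K)
  rownames(co) <- rownames(daily)
  c0 <- Mod(co[, 1])
  cm <- co[, m + 1]
  degenerate <- c0 == 0
  s <- ifelse(degenerate, 0, Mod(cm) / ifelse(degenerate, 1, c0))
  phase_day <- ((-Arg(cm)) * tlen / (2 * pi * m)) %% 365
  phase_day[degenerate] <- NA_real_
  structure(list(asv_ids = rownames(daily), components = co,
                 seasonality = unname(s),
                 annual_phase_day = unname(phase_day),
                 annual_amplitude = unname(Mod(cm)),
                 degenerate = unname(degenerate),
                 T = tlen, K = K, m = m),
            class = "fourier_profiles")
}

#' @export
print.fourier_profiles <- function(x, ...) {
  cat(sprintf("fourier_profiles: %d series, T = %d days, K = %d, annual m = %d\n",
              length(x$asv_ids), x$T, x$K, x$m))
  invisible(x)
}

#' Seasonality score of a profile
#'
#' The ratio `|c_m| / |c_0|` of the annual Fourier component modulus to the
#' DC (mean) component modulus. Scale-invariant: multiplying a series by any
#' positive constant leaves the score unchanged. Degenerate profiles
#' (`|c_0| = 0`) score 0.
#'
#' @param profiles a `fourier_profiles` object.
#' @param m annual component index; defaults to the profile's own.
#' @return numeric vector of scores, with attribute `degenerate`.
#' @export
seasonality_score <- function(profiles, m = NULL) {
  stopifnot(inherits(profiles, "fourier_profiles"))
  if (is.null(m) || m == profiles$m) {
    s <- profiles$seasonality
  } else {
    if (m + 1 > ncol(profiles$components))
      stop("profile has no component ", m)
    c0 <- Mod(profiles$components[, 1])
    s <- ifelse(profiles$degenerate, 0,
                Mod(profiles$components[, m + 1]) / ifelse(c0 == 0, 1, c0))
  }
  s <- unname(s)
  attr(s, "degenerate") <- profiles$degenerate
  s
}

#' Reconstruct a smooth series from selected Fourier components
#'
#' Partial inverse transform
#' `x_hat_d = (1/T) * sum_{k in set} w_k * Re(c_k exp(+2*pi*i*k*d/T))`
#' with real-signal weights `w_0 = 1`, `w_k = 2` for `k >= 1`. With the full
#' component set `0..T/2` this is the exact inverse for a real series.
#'
#' @param profiles a `fourier_profiles` object.
#' @param component_set integer vector of component indices (subset of 0..K).
#' @param asv id or row index of the series; default all.
#' @return numeric matrix of reconstructed series (rows = selected ASVs).
#' @export
reconstruct_profile <- function(profiles, component_set = 0:profiles$K,
                                asv = NULL) {
  stopifnot(inherits(profiles, "fourier_profiles"))
  if (any(component_set < 0 | component_set > profiles$K))
    stop("component_set outside 0..K")
  rows <- if (is.null(asv)) seq_along(profiles$asv_ids) else asv
  co <- profiles$components[rows, , drop = FALSE]
  tlen <- profiles$T
  d <- 0:(tlen - 1)
  out <- matrix(0, nrow = nrow(co), ncol = tlen,
                dimnames = list(rownames(co), NULL))
  for (k in unique(component_set)) {
    w <- if (k == 0) 1 else 2
    basis <- exp(2i * pi * k * d / tlen)
    out <- out + w * Re(co[, k + 1] %o% basis)
  }
  out / tlen
}

#' Correlation between two ASVs' temporal profiles
#'
#' Pearson correlation of the reconstructed smooth series of two profiles
#' over a common component set. Centering removes the DC component, so only
#' the shape of the seasonal signal matters; this avoids the compositional
#' bias of correlating raw relative abundances directly.
#'
#' @param profiles a `fourier_profiles` object.
#' @param a,b ids or row indices of the two series.
#' @param component_set component indices used in the reconstruction
#'   (default `1..K`; including 0 changes nothing since series are centered).
#' @return correlation in \[-1, 1\]; a zero-variance reconstruction yields 0
#'   with attribute `undefined = TRUE`.
#' @export
profile_correlation <- function(profiles, a, b,
                                component_set = seq_len(profiles$K)) {
  ra <- drop(reconstruct_profile(profiles, component_set, a))
  rb <- drop(reconstruct_profile(profiles, component_set, b))
  ra <- ra - mean(ra); rb <- rb - mean(rb)
  va <- sum(ra^2); vb <- sum(rb^2)
  if (va == 0 || vb == 0) {
    r <- 0
    attr(r, "undefined") <- TRUE
    return(r)
  }
  sum(ra * rb) / sqrt(va * vb)
}

#' Export Fourier profiles as a flat table
#'
#' @param profiles a `fourier_profiles` object.
#' @return data frame with seasonality, phase, amplitude and the modulus and
#'   argument of every retained component.
#' @export
profiles_table <- function(profiles) {
  stopifnot(inherits(profiles, "fourier_profiles"))
  df <- data.frame(asv_id = profiles$asv_ids,
                   s_score = profiles$seasonality,
                   annual_phase_day = profiles$annual_phase_day,
                   annual_amplitude = profiles$annual_amplitude,
                   degenerate = profiles$degenerate,
                   stringsAsFactors = FALSE)
  for (k in 0:profiles$K) {
    df[[paste0("c", k, "_mod")]] <- Mod(profiles$components[, k + 1])
    df[[paste0("c", k, "_arg")]] <- Arg(profiles$components[, k + 1])
  }
  df
}
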