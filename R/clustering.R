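#' Build clustering features from Fourier profiles
#'
#' The feature row for an ASV is the concatenated real and imaginary parts
#' of its Fourier coefficients `c_k` for `k` in `component_range`, after
#' per-series scaling. The default `unit-mean` scaling divides the series by
#' its mean (equivalently, coefficients by `c_0 / T`), so clustering groups
#' temporal shapes irrespective of absolute abundance. `z-score` scales by
#' the standard deviation implied by the retained spectrum; `none` leaves
#' coefficients raw.
#'
#' @param profiles a `fourier_profiles` object.
#' @param component_range component indices to use (default `1..K`).
#' @param scale_mode one of `"unit-mean"`, `"z-score"`, `"none"`.
#' @return numeric matrix with `2 * length(component_range)` columns and one
#'   row per non-degenerate ASV; excluded (all-zero) ASV ids are attached as
#'   attribute `excluded` and reported with a warning.
#' @export
build_features <- function(profiles, component_range = seq_len(profiles$K),
                           scale_mode = c("unit-mean", "z-score", "none")) {
  stopifnot(inherits(profiles, "fourier_profiles"))
  scale_mode <- match.arg(scale_mode)
  if (any(component_range < 0 | component_range > profiles$K))
    stop("component_range outside 0..K")
  keep <- !profiles$degenerate
  if (scale_mode %in% c("unit-mean", "z-score") && any(!keep))
    warning("excluding degenerate all-zero series: ",
            paste(profiles$asv_ids[!keep], collapse = ", "))
  if (scale_mode == "none") keep <- rep(TRUE, length(profiles$asv_ids))
  co <- profiles$components[keep, , drop = FALSE]
  tlen <- profiles$T
  scl <- switch(scale_mode,
    "unit-mean" = tlen / Re(co[, 1]),
    "z-score" = {
      # sd of the K-band-limited reconstruction, via Parseval on k >= 1
      ss <- rowSums(2 * Mod(co[, -1, drop = FALSE])^2) / tlen^2
      ifelse(ss == 0, 1, 1 / sqrt(ss))
    },
    "none" = rep(1, nrow(co)))
  cols <- lapply(component_range, function(k) {
    ck <- co[, k + 1] * scl
    cbind(Re(ck), Im(ck))
  })
  f <- do.call(cbind, cols)
  colnames(f) <- as.vector(rbind(paste0("re_c", component_range),
                                 paste0("im_c", component_range)))
  rownames(f) <- profiles$asv_ids[keep]
  attr(f, "excluded") <- profiles$asv_ids[!keep]
  f
}

#' Cluster ASVs by Fourier features
#'
#' k-means with `n_restarts` random initializations; the run with the
#' smallest within-cluster sum of squares wins. Deterministic given `seed`
#' (the caller's RNG state is left untouched).
#'
#' @param features feature matrix from [build_features()].
#' @param N number of clusters.
#' @param n_restarts random restarts (default 50).
#' @param seed integer seed.
#' @return object of class `cluster_model`: list with `assignments` (named
#'   integer vector asv -> cluster), `centers`, `wcss`, `N`, `station_id`.
#' @export
cluster_asvs <- function(features, N, n_restarts = 50, seed = 1) {
  if (N < 1) stop("N must be >= 1")
  if (N > nrow(features)) stop("N exceeds number of ASVs")
  fit <- withr::with_seed(as.integer(seed), {
    if (N == nrow(features)) {
      # degenerate limit: every point its own cluster
      list(cluster = seq_len(nrow(features)), centers = features,
           tot.withinss = 0)
    } else {
      # an occasional restart drops a cluster; nstart keeps the best fit
      withCallingHandlers(
        stats::kmeans(features, centers = N, nstart = n_restarts,
                      iter.max = 100),
        warning = function(w) {
          if (grepl("empty cluster", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    }
  })
  assignments <- stats::setNames(as.integer(fit$cluster), rownames(features))
  structure(list(assignments = assignments, centers = fit$centers,
                 wcss = fit$tot.withinss, N = N,
                 station_id = attr(features, "station_id")),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: %d ASVs in %d clusters (WCSS %.4g)\n",
              length(x$assignments), x$N, x$wcss))
  invisible(x)
}

#' Choose the number of clusters by BIC
#'
#' Fits k-means for every `k` in `k_range` and scores each fit with the BIC
#' of the corresponding spherical-Gaussian mixture: the log-likelihood uses
#' the pooled within-cluster variance, and the parameter count is
#' `k*d + k` (centers, mixing weights, one shared variance). The chosen `k`
#' minimizes BIC.
#'
#' @param features feature matrix.
#' @param k_range integer vector of candidate cluster numbers.
#' @param seed integer seed.
#' @param n_restarts restarts per `k`.
#' @return list with `table` (data frame of `k`, `wcss`, `bic`,
#'   `degenerate`) and `chosen_k`.
#' @export
select_n_clusters <- function(features, k_range, seed = 1, n_restarts = 20) {
  n <- nrow(features); d <- ncol(features)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1) || any(k_range > n))
    stop("k_range must lie within [1, rows]")
  rows <- lapply(seq_along(k_range), function(i) {
    k <- k_range[i]
    fit <- cluster_asvs(features, k, n_restarts, seed + i)
    w <- fit$wcss
    nj <- tabulate(fit$assignments, nbins = k)
    degen <- w <= 0 || n <= k
    if (degen) {
      bic <- -Inf
    } else {
      sigma2 <- w / (d * (n - k))
      ll <- sum(nj[nj > 0] * log(nj[nj > 0] / n)) -
        n * d / 2 * log(2 * pi * sigma2) - d * (n - k) / 2
      bic <- -2 * ll + (k * d + k) * log(n)
    }
    data.frame(k = k, wcss = w, bic = bic, degenerate = degen)
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$degenerate
  chosen <- if (any(ok)) tab$k[ok][which.min(tab$bic[ok])] else min(tab$k)
  if (any(tab$degenerate))
    warning("zero-variance fit at k = ",
            paste(tab$k[tab$degenerate], collapse = ", "),
            " (BIC = -Inf, excluded from selection)")
  list(table = tab, chosen_k = chosen)
}

#' Order clusters by phase and assign station-prefixed names
#'
#' The phase of a cluster is the annual phase of its mean member profile
#' (complex Fourier coefficients averaged over members, then the phase of
#' the annual component extracted). Clusters are sorted by ascending phase
#' day and named `<prefix>-01 ... <prefix>-NN`, so the numbering follows the
#' order of occurrence within the year. Phase ties are broken by descending
#' size, then by the lexically first member id.
#'
#' @param model a `cluster_model`.
#' @param profiles the `fourier_profiles` the model was built from.
#' @param station_prefix single-letter station prefix (e.g. `"H"` or `"F"`).
#' @return the model with added `names` (cluster index -> name),
#'   `phase_day`, `mean_components` (complex matrix of per-cluster mean
#'   coefficients) and `order` fields; `assignments` are renumbered to the
#'   phase order.
#' @export
order_and_name_clusters <- function(model, profiles, station_prefix) {
  stopifnot(inherits(model, "cluster_model"),
            inherits(profiles, "fourier_profiles"))
  idx <- match(names(model$assignments), profiles$asv_ids)
  if (anyNA(idx)) stop("model members missing from profiles")
  ks <- sort(unique(model$assignments))
  mean_co <- t(vapply(ks, function(k) {
    members <- idx[model$assignments == k]
    colMeans(profiles$components[members, , drop = FALSE])
  }, complex(ncol(profiles$components))))
  cm <- mean_co[, profiles$m + 1]
  phase <- ((-Arg(cm)) * profiles$T / (2 * pi * profiles$m)) %% 365
  size <- as.integer(table(factor(model$assignments, levels = ks)))
  first_member <- vapply(ks, function(k)
    min(names(model$assignments)[model$assignments == k]), character(1))
  o <- order(phase, -size, first_member)
  new_index <- stats::setNames(seq_along(ks), ks[o])
  renum <- new_index[as.character(model$assignments)]
  model$assignments <- stats::setNames(as.integer(renum),
                                       names(model$assignments))
  model$phase_day <- phase[o]
  model$mean_components <- mean_co[o, , drop = FALSE]
  model$names <- sprintf("%s-%02d", station_prefix, seq_along(ks))
  model$station_prefix <- station_prefix
  model$profiles_T <- profiles$T
  model$profiles_m <- profiles$m
  model
}

#' Count abundance peaks of a smooth seasonal curve
#'
#' Counts local maxima of the (periodic) reconstructed cluster curve whose
#' prominence is at least `prominence_frac` of the series range. The curve
#' is treated as circular — a Fourier partial sum is periodic over the
#' window, so a maximum on the window boundary is one peak, not two — and a
#' peak's prominence is its height above the higher of the two adjacent
#' valleys. Flat series have no peaks.
#'
#' @param x numeric vector, one value per day.
#' @param prominence_frac minimum prominence as a fraction of
#'   `max(x) - min(x)` (default 0.1).
#' @return integer peak count.
#' @export
count_peaks <- function(x, prominence_frac = 0.1) {
  n <- length(x)
  rng <- max(x) - min(x)
  if (n < 3 || rng <= 0) return(0L)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  # circular local maxima; strict on one side to count plateaus once
  is_peak <- x > x[prv] & x >= x[nxt]
  peaks <- which(is_peak)
  if (!length(peaks)) return(0L)
  if (length(peaks) == 1L) return(1L)
  # valley between consecutive peaks (circular)
  peaks <- sort(peaks)
  np <- length(peaks)
  valley <- numeric(np)
  for (i in seq_len(np)) {
    a <- peaks[i]; b <- peaks[ifelse(i == np, 1, i + 1)]
    seg <- if (b > a) x[a:b] else c(x[a:n], x[1:b])
    valley[i] <- min(seg)
  }
  left_valley <- valley[c(np, seq_len(np - 1))]
  prom <- x[peaks] - pmax(left_valley, valley)
  sum(prom >= prominence_frac * rng)
}

#' Hours of daylight at a given latitude and day of year
#'
#' Standard solar-declination day-length formula with polar clamping: 0 h
#' in polar night, 24 h in polar day. Declination is approximated as
#' `-23.44 * cos(2*pi*(doy + 10)/365)` degrees.
#'
#' @param doy day of year (0-based, 0 = Jan 1); vectorized.
#' @param latitude_deg latitude in degrees (default 79, the Fram Strait
#'   mooring latitude).
#' @return daylight hours in \[0, 24\].
#' @export
daylight_hours <- function(doy, latitude_deg = 79) {
  if (any(latitude_deg < -90 | latitude_deg > 90))
    stop("latitude outside [-90, 90]")
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  lat <- latitude_deg * pi / 180
  cos_h <- -tan(lat) * tan(decl)
  cos_h <- pmin(1, pmax(-1, cos_h))
  24 * acos(cos_h) / pi
}

#' Assign a light class to a cluster phase
#'
#' Clusters are classified by the light conditions at their abundance
#' maximum: low-light (`LL`, at most 2 h daylight) or high-light (`HL`, more
#' than 2 h). A cluster whose peak count differs from the expected annual
#' count (one maximum per year, i.e. 2 peaks over a two-year window) is an
#' anomalous/mixed-light cluster and gets `NA`. The alternative
#' `mode = "months"` uses fixed seasonal windows instead of the day-length
#' formula: October through the March equinox is LL, the rest HL.
#'
#' @param phase_day day-of-year of the abundance maximum in \[0, 365).
#' @param n_peaks observed peak count over the window.
#' @param latitude_deg latitude for the day-length formula.
#' @param expected_peaks annual peak count expected over the window
#'   (2 for a two-year window).
#' @param mode `"daylight"` or `"months"`.
#' @return `"LL"`, `"HL"`, or `NA_character_`.
#' @export
assign_light_class <- function(phase_day, n_peaks, latitude_deg = 79,
                               expected_peaks = 2,
                               mode = c("daylight", "months")) {
  mode <- match.arg(mode)
  if (!is.na(n_peaks) && n_peaks != expected_peaks) return(NA_character_)
  if (is.na(phase_day)) return(NA_character_)
  if (mode == "daylight") {
    if (daylight_hours(phase_day, latitude_deg) <= 2) "LL" else "HL"
  } else {
    # day 79 ~ spring equinox; HL runs to end of September (day 273)
    if (phase_day >= 79 && phase_day < 273) "HL" else "LL"
  }
}

#' Annotate a named cluster model with peaks and light classes
#'
#' Reconstructs each cluster's mean seasonal curve from components
#' `1..K` (plus DC for positivity), counts its peaks, and assigns light
#' classes. A cluster whose peaks fall in different light classes is set to
#' `NA` (mixed light), as is a cluster with an anomalous peak count.
#'
#' @param model a named `cluster_model` (see [order_and_name_clusters()]).
#' @param latitude_deg latitude for light classification.
#' @param prominence_frac passed to [count_peaks()].
#' @param light_mode `"daylight"` or `"months"`.
#' @return model with `n_peaks` and `light_class` vectors added.
#' @export
annotate_clusters <- function(model, latitude_deg = 79,
                              prominence_frac = 0.1,
                              light_mode = c("daylight", "months")) {
  light_mode <- match.arg(light_mode)
  stopifnot(!is.null(model$names), !is.null(model$mean_components))
  tlen <- model$profiles_T
  m <- model$profiles_m
  expected <- m  # one annual maximum per whole year in the window
  d <- 0:(tlen - 1)
  nk <- ncol(model$mean_components) - 1
  n_peaks <- integer(length(model$names))
  light <- character(length(model$names))
  for (j in seq_along(model$names)) {
    co <- model$mean_components[j, ]
    curve <- Re(co[1]) / tlen
    for (k in seq_len(nk))
      curve <- curve + 2 * Re(co[k + 1] * exp(2i * pi * k * d / tlen)) / tlen
    n_peaks[j] <- count_peaks(curve, prominence_frac)
    if (n_peaks[j] != expected) { light[j] <- NA_character_; next }
    peak_pos <- peak_days(curve, prominence_frac)
    classes <- vapply(peak_pos %% 365, function(p)
      assign_light_class(p, expected, latitude_deg, expected, light_mode),
      character(1))
    light[j] <- if (length(unique(classes)) == 1L) classes[1] else
      NA_character_
  }
  model$n_peaks <- n_peaks
  model$light_class <- light
  model
}

# day positions (0-based) of the prominent circular peaks of x
peak_days <- function(x, prominence_frac = 0.1) {
  n <- length(x)
  rng <- max(x) - min(x)
  if (n < 3 || rng <= 0) return(integer(0))
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  peaks <- which(x > x[prv] & x >= x[nxt])
  if (!length(peaks)) return(integer(0))
  if (length(peaks) == 1L) return(peaks - 1L)
  peaks <- sort(peaks); np <- length(peaks)
  valley <- numeric(np)
  for (i in seq_len(np)) {
    a <- peaks[i]; b <- peaks[ifelse(i == np, 1, i + 1)]
    seg <- if (b > a) x[a:b] else c(x[a:n], x[1:b])
    valley[i] <- min(seg)
  }
  left_valley <- valley[c(np, seq_len(np - 1))]
  prom <- x[peaks] - pmax(left_valley, valley)
  peaks[prom >= prominence_frac * rng] - 1L
}

#' Per-cluster summary table
#'
#' One row per cluster: name, light class, peak count, size, size as a
#' percentage of the station total (rounded to integer for display), mean
#' member seasonality score, and the mooring-specific member counts
#' `ms_abs` (members not shared with the partner station) and
#' `ms_rel = 100 * ms_abs / size` (2 decimals).
#'
#' @param model an annotated, named `cluster_model`.
#' @param profiles the station's `fourier_profiles`.
#' @param partner_asv_set character vector of ASV ids present at the partner
#'   station.
#' @return data frame with columns `name`, `light_class`, `n_peaks`,
#'   `phase_day`, `cl_size`, `cl_size_pct`, `s_score`, `ms_abs`, `ms_rel`.
#' @export
cluster_summary <- function(model, profiles, partner_asv_set) {
  stopifnot(!is.null(model$names))
  total <- length(model$assignments)
  idx <- match(names(model$assignments), profiles$asv_ids)
  rows <- lapply(seq_along(model$names), function(j) {
    members <- names(model$assignments)[model$assignments == j]
    size <- length(members)
    ms_abs <- sum(!(members %in% partner_asv_set))
    data.frame(
      name = model$names[j],
      light_class = if (is.null(model$light_class)) NA_character_ else
        model$light_class[j],
      n_peaks = if (is.null(model$n_peaks)) NA_integer_ else model$n_peaks[j],
      phase_day = model$phase_day[j],
      cl_size = size,
      cl_size_pct = as.integer(round(100 * size / total)),
      s_score = mean(profiles$seasonality[idx[model$assignments == j]]),
      ms_abs = ms_abs,
      ms_rel = round(100 * ms_abs / size, 2),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
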