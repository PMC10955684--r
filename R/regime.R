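#' Yearly abundance sums per ASV
#'
#' Sums relative abundances over the raw sampling events falling in a given
#' calendar year (interpolated days are never used here).
#'
#' @param table a [sample_table()].
#' @param year calendar year (integer).
#' @return named numeric vector, one sum per ASV.
#' @export
yearly_abundance <- function(table, year) {
  stopifnot(inherits(table, "sample_table"))
  sel <- as.integer(format(table$dates, "%Y")) == year
  if (!any(sel)) stop("no samples in year ", year)
  rowSums(table$values[, sel, drop = FALSE])
}

#' Classify regime preference from two yearly sums
#'
#' An ASV at the contrast station is a meltwater-regime (MWR) taxon if it
#' was at least twice as abundant in the meltwater year
#' (`log2(sum_y1/sum_y2) >= 1`), a mixed-layer-regime (MLR) taxon if at
#' least twice as abundant in the mixed-layer year (`log2 <= -1`), and
#' unspecified otherwise; both thresholds are inclusive. ASVs with a zero
#' sum in either year are excluded to avoid division by zero.
#'
#' @param sum_y1 yearly sum in the meltwater year (vectorized).
#' @param sum_y2 yearly sum in the mixed-layer year.
#' @return data frame with `sum_y1`, `sum_y2`, `log2_quotient`,
#'   `regime_class` (one of `"MWR"`, `"MLR"`, `"unspecified"`,
#'   `"excluded-zero"`).
#' @export
classify_regime <- function(sum_y1, sum_y2) {
  if (any(sum_y1 < 0) || any(sum_y2 < 0)) stop("negative yearly sum")
  lq <- ifelse(sum_y1 > 0 & sum_y2 > 0, log2(sum_y1 / sum_y2), NA_real_)
  cls <- ifelse(sum_y1 == 0 | sum_y2 == 0, "excluded-zero",
         ifelse(lq >= 1, "MWR", ifelse(lq <= -1, "MLR", "unspecified")))
  df <- data.frame(sum_y1 = sum_y1, sum_y2 = sum_y2, log2_quotient = lq,
                   regime_class = cls, stringsAsFactors = FALSE)
  nm <- names(sum_y1)
  if (!is.null(nm)) df <- cbind(asv_id = nm, df, row.names = NULL)
  df
}

#' Regime preference table for a station
#'
#' Runs [yearly_abundance()] for both years and [classify_regime()] on the
#' result, optionally restricted to a set of ASVs (normally the core
#' community).
#'
#' @param table a [sample_table()] for the contrast station.
#' @param year1 meltwater year (e.g. 2017).
#' @param year2 mixed-layer year (e.g. 2018).
#' @param restrict optional character vector of ASV ids.
#' @return data frame as from [classify_regime()], with `asv_id`.
#' @export
regime_preference <- function(table, year1, year2, restrict = NULL) {
  s1 <- yearly_abundance(table, year1)
  s2 <- yearly_abundance(table, year2)
  if (!is.null(restrict)) {
    keep <- names(s1) %in% restrict
    s1 <- s1[keep]; s2 <- s2[keep]
  }
  classify_regime(s1, s2)
}

#' Cross-location abundance ratio for one regime group
#'
#' Aggregate (median by default) of the group members' abundances at one
#' station-year divided by the same aggregate at another.
#'
#' @param x_abund,y_abund numeric vectors of the group members' abundances
#'   at the two station-years.
#' @param aggregate `"median"` or `"mean"`.
#' @return the ratio; `NA` with attribute `undefined = TRUE` if either group
#'   is empty.
#' @export
location_ratio <- function(x_abund, y_abund,
                           aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!length(x_abund) || !length(y_abund)) {
    r <- NA_real_; attr(r, "undefined") <- TRUE; return(r)
  }
  f <- if (aggregate == "median") stats::median else mean
  f(x_abund) / f(y_abund)
}

#' Within-site meltwater-over-mixed-layer preference
#'
#' `q(z)`: mean abundance of the MWR group at site-year `z` divided by the
#' mean abundance of the MLR group at `z`.
#'
#' @param mwr_abund,mlr_abund numeric vectors of group member abundances at
#'   the site-year.
#' @return the ratio of means; `NA` flagged `undefined` on an empty group.
#' @export
within_site_preference <- function(mwr_abund, mlr_abund) {
  if (!length(mwr_abund) || !length(mlr_abund)) {
    r <- NA_real_; attr(r, "undefined") <- TRUE; return(r)
  }
  mean(mwr_abund) / mean(mlr_abund)
}

#' Full cross-location / within-site ratio report
#'
#' For two stations and two years, computes the cross-location quotients
#' `p(x, y)` (MWR group) and `t(x, y)` (MLR group) for every pair of a
#' reference-station year `x` and a contrast-station year `y`, and the
#' within-site preference `q(z)` for all four station-years. Group
#' membership comes from a regime classification at the contrast station;
#' the abundance entering the ratios is the member's yearly sum at the given
#' station-year.
#'
#' @param tables named list of two [sample_table()]s (names = station
#'   labels).
#' @param classes named character vector asv_id -> regime class (from
#'   [regime_preference()]).
#' @param years length-2 integer vector (meltwater year, mixed-layer year).
#' @param ref_station,contrast_station station labels; `x` ranges over
#'   `ref_station` years, `y` over `contrast_station` years.
#' @param aggregate `"median"` (default) or `"mean"` for `p` and `t`
#'   (`q` always uses means).
#' @return list with data frames `p_ratios`, `t_ratios` (`x`, `y`, `value`)
#'   and `q_values` (`z`, `value`), plus `aggregate`.
#' @export
ratio_report <- function(tables, classes, years, ref_station,
                         contrast_station,
                         aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c(ref_station, contrast_station) %in% names(tables)),
            length(years) == 2L)
  mwr_ids <- names(classes)[classes == "MWR"]
  mlr_ids <- names(classes)[classes == "MLR"]
  abund <- function(st, yr, ids) {
    s <- yearly_abundance(tables[[st]], yr)
    s[names(s) %in% ids]
  }
  key <- function(st, yr) paste0(st, "-", yr)
  grid <- expand.grid(x_year = years, y_year = years)
  mk <- function(ids) {
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      xa <- abund(ref_station, grid$x_year[i], ids)
      ya <- abund(contrast_station, grid$y_year[i], ids)
      data.frame(x = key(ref_station, grid$x_year[i]),
                 y = key(contrast_station, grid$y_year[i]),
                 value = as.numeric(location_ratio(xa, ya, aggregate)),
                 stringsAsFactors = FALSE)
    }))
  }
  q_rows <- do.call(rbind, lapply(names(tables), function(st) {
    do.call(rbind, lapply(years, function(yr) {
      data.frame(z = key(st, yr),
                 value = as.numeric(within_site_preference(
                   abund(st, yr, mwr_ids), abund(st, yr, mlr_ids))),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(p_ratios = mk(mwr_ids), t_ratios = mk(mlr_ids), q_values = q_rows,
       aggregate = aggregate)
}

#' One-sided two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper around [stats::ks.test()] for comparing the abundance
#' distributions of two groups. `alternative = "greater"` tests whether the
#' empirical CDF of `a` lies above that of `b` (i.e. `a` stochastically
#' smaller); the statistic is the corresponding one-sided supremum
#' `D+ = max(ecdf_a - ecdf_b)`. The exact small-sample p-value is used when
#' both samples have at most 25 observations (and no ties); the asymptotic
#' approximation otherwise.
#'
#' @param a,b numeric vectors, non-empty.
#' @param alternative `"greater"` or `"less"`.
#' @return list with `statistic` and `p_value`.
#' @export
ks_compare <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("empty sample")
  exact <- length(a) <= 25 && length(b) <= 25
  res <- suppressWarnings(
    stats::ks.test(a, b, alternative = alternative, exact = exact))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}
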