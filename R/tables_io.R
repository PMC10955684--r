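#' Construct a validated sample table
#'
#' A `sample_table` holds the ASV x sampling-date relative-abundance matrix
#' for one mooring station, together with optional taxonomy annotations.
#' Abundances are unitless fractions; every sampling-date column must sum to
#' at most 1 (compositional data may sum below 1 when ASVs were filtered).
#'
#' @param station_id single character label for the station (e.g. "HG-IV").
#' @param values numeric matrix, rows = ASVs, columns = sampling dates.
#' @param dates `Date` vector, one per column, strictly increasing.
#' @param asv_ids character vector of unique ASV identifiers, one per row.
#' @param taxonomy optional character vector of lineage strings, same length
#'   as `asv_ids`.
#' @return an object of class `sample_table`: a list with elements
#'   `station_id`, `asv_ids`, `taxonomy`, `dates`, `values`.
#' @export
sample_table <- function(station_id, values, dates, asv_ids, taxonomy = NULL) {
  values <- as.matrix(values)
  dates <- as.Date(dates)
  asv_ids <- as.character(asv_ids)
  if (length(station_id) != 1L) stop("station_id must be a single label")
  if (nrow(values) != length(asv_ids))
    stop("values must have one row per ASV id")
  if (ncol(values) != length(dates))
    stop("values must have one column per date")
  if (anyDuplicated(asv_ids))
    stop("duplicate ASV ids: ", paste(unique(asv_ids[duplicated(asv_ids)]),
                                      collapse = ", "))
  if (any(is.na(dates))) stop("unparseable date in header")
  if (is.unsorted(dates, strictly = TRUE)) {
    o <- order(dates)
    if (anyDuplicated(dates)) stop("duplicate sampling dates")
    dates <- dates[o]
    values <- values[, o, drop = FALSE]
  }
  if (any(!is.finite(values))) stop("non-finite abundance value")
  if (any(values < 0)) stop("negative abundance value")
  csum <- colSums(values)
  if (any(csum > 1 + 1e-9))
    stop("column sum exceeds 1 for date(s): ",
         paste(format(dates[csum > 1 + 1e-9]), collapse = ", "))
  if (!is.null(taxonomy) && length(taxonomy) != length(asv_ids))
    stop("taxonomy must match asv_ids in length")
  dimnames(values) <- list(asv_ids, format(dates))
  structure(list(station_id = as.character(station_id), asv_ids = asv_ids,
                 taxonomy = taxonomy, dates = dates, values = values),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("sample_table: station %s, %d ASVs x %d dates (%s .. %s)\n",
              x$station_id, length(x$asv_ids), length(x$dates),
              format(min(x$dates)), format(max(x$dates))))
  invisible(x)
}

#' Read an ASV relative-abundance table
#'
#' The expected format is TSV (or CSV) with first column `asv_id`, an
#' optional `taxonomy` column, and one column per sampling date with an
#' ISO-8601 (`YYYY-MM-DD`) header. Values are fractions in \[0, 1\];
#' percentage-scale input is accepted with `percent = TRUE`.
#'
#' @param path path to the file.
#' @param station_id label attached to the returned table.
#' @param sep field separator, `"\t"` by default.
#' @param percent if `TRUE`, values are divided by 100 on read.
#' @return a [sample_table()].
#' @export
read_abundance_table <- function(path, station_id, sep = "\t",
                                 percent = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (nrow(df) == 0L) stop("no rows in ", path)
  cn <- names(df)
  if (cn[1] != "asv_id") stop("first column must be 'asv_id'")
  taxonomy <- NULL
  date_from <- 2L
  if (length(cn) >= 2L && cn[2] == "taxonomy") {
    taxonomy <- as.character(df$taxonomy)
    date_from <- 3L
  }
  date_names <- cn[date_from:length(cn)]
  dates <- as.Date(date_names, format = "%Y-%m-%d")
  if (any(is.na(dates)))
    stop("malformed date header(s): ",
         paste(date_names[is.na(dates)], collapse = ", "))
  vals <- as.matrix(df[, date_from:length(cn), drop = FALSE])
  storage.mode(vals) <- "double"
  if (percent) vals <- vals / 100
  sample_table(station_id, vals, dates, df$asv_id, taxonomy)
}

#' Write an ASV relative-abundance table
#'
#' Inverse of [read_abundance_table()]; values are written with 12
#' significant digits so that write-then-read round-trips within float
#' formatting.
#'
#' @param table a [sample_table()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, sep = "\t") {
  stopifnot(inherits(table, "sample_table"))
  df <- data.frame(asv_id = table$asv_ids, stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy)) df$taxonomy <- table$taxonomy
  vals <- signif(table$values, 12)
  colnames(vals) <- format(table$dates)
  df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# canonical environmental covariates measured at/around the moorings
ENV_VARIABLES <- c("temp", "chl_sens", "daylight", "depth", "iceConc",
                   "iceDist", "MLD", "pCO2_conc", "O2_conc", "PW_frac")

#' Read an environmental covariate table
#'
#' CSV with a `date` column and any subset of the ten canonical variables:
#' `temp` (deg C), `chl_sens` (ug/l), `daylight` (h), `depth` (m),
#' `iceConc` (%), `iceDist` (km), `MLD` (m), `pCO2_conc` (uatm),
#' `O2_conc` (umol/l), `PW_frac` (%). Unknown columns are carried through
#' with a warning; missing variables are simply absent (never imputed).
#'
#' @param path path to the CSV file.
#' @return an object of class `env_series`: list with `dates` (Date) and
#'   `variables` (named list of numeric vectors).
#' @export
read_env_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no rows in ", path)
  if (!"date" %in% names(df)) stop("missing 'date' column")
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (any(is.na(dates))) stop("unparseable date in 'date' column")
  extra <- setdiff(names(df), c("date", ENV_VARIABLES))
  if (length(extra))
    warning("unknown column(s) carried through: ", paste(extra, collapse = ", "))
  vars <- df[setdiff(names(df), "date")]
  vars <- lapply(vars, as.numeric)
  env_series(dates, vars)
}

#' @rdname read_env_table
#' @param dates `Date` vector.
#' @param variables named list of numeric vectors, one per covariate.
#' @export
env_series <- function(dates, variables) {
  dates <- as.Date(dates)
  stopifnot(is.list(variables), all(nzchar(names(variables))))
  for (v in names(variables)) {
    if (length(variables[[v]]) != length(dates))
      stop("variable ", v, " length does not match dates")
  }
  chk <- function(name, lo, hi) {
    x <- variables[[name]]
    if (!is.null(x) && any(x < lo - 1e-9 | x > hi + 1e-9, na.rm = TRUE))
      stop(name, " outside [", lo, ",", hi, "]")
  }
  chk("iceConc", 0, 100); chk("PW_frac", 0, 100); chk("daylight", 0, 24)
  structure(list(dates = dates, variables = variables), class = "env_series")
}

#' @export
print.env_series <- function(x, ...) {
  cat(sprintf("env_series: %d dates, variables: %s\n", length(x$dates),
              paste(names(x$variables), collapse = ", ")))
  invisible(x)
}

#' Write an environmental covariate table
#' @param env an [env_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_env_table <- function(env, path) {
  stopifnot(inherits(env, "env_series"))
  df <- data.frame(date = format(env$dates), stringsAsFactors = FALSE)
  for (v in names(env$variables)) df[[v]] <- signif(env$variables[[v]], 12)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pipeline result tables
#'
#' Writes one TSV per result type and returns a manifest of paths and row
#' counts. Result names become file names (`<name>.tsv`).
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if absent).
#' @return data frame manifest with columns `name`, `path`, `n_rows`.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory ", out_dir)
  paths <- character(0); nrows <- integer(0)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    stopifnot(is.data.frame(df))
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], signif, digits = 12)
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p); nrows <- c(nrows, nrow(df))
  }
  data.frame(name = names(tables), path = paths, n_rows = nrows,
             stringsAsFactors = FALSE)
}
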