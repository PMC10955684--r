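#' Partition ASVs into core and station-unique sets
#'
#' The core community is the set of ASVs detected at both stations; the
#' remainder are unique to one station.
#'
#' @param table_a,table_b [sample_table()] objects (or character vectors of
#'   ASV ids).
#' @return list with `core`, `unique_a`, `unique_b` (character vectors) and
#'   `pct` (named vector of percentages of the union, rounded to integer).
#' @export
partition_asvs <- function(table_a, table_b) {
  ids_a <- if (inherits(table_a, "sample_table")) table_a$asv_ids else
    as.character(table_a)
  ids_b <- if (inherits(table_b, "sample_table")) table_b$asv_ids else
    as.character(table_b)
  core <- intersect(ids_a, ids_b)
  ua <- setdiff(ids_a, ids_b)
  ub <- setdiff(ids_b, ids_a)
  if (!length(core)) warning("stations share no ASVs")
  u <- length(core) + length(ua) + length(ub)
  pct <- round(100 * c(core = length(core), unique_a = length(ua),
                       unique_b = length(ub)) / u)
  list(core = core, unique_a = ua, unique_b = ub, pct = pct)
}

#' Shared-member counts between two stations' clusters
#'
#' Entry (i, j) is the number of universe ASVs assigned both to cluster i of
#' station A and cluster j of station B.
#'
#' @param model_a,model_b named `cluster_model` objects.
#' @param universe character vector of ASV ids over which overlap is counted
#'   (normally the core community).
#' @return integer matrix with A cluster names as rows, B as columns.
#' @export
overlap_counts <- function(model_a, model_b, universe) {
  stopifnot(!is.null(model_a$names), !is.null(model_b$names))
  mem_a <- lapply(seq_along(model_a$names), function(j)
    intersect(names(model_a$assignments)[model_a$assignments == j], universe))
  mem_b <- lapply(seq_along(model_b$names), function(j)
    intersect(names(model_b$assignments)[model_b$assignments == j], universe))
  m <- matrix(0L, length(mem_a), length(mem_b),
              dimnames = list(model_a$names, model_b$names))
  for (i in seq_along(mem_a))
    for (j in seq_along(mem_b))
      m[i, j] <- length(intersect(mem_a[[i]], mem_b[[j]]))
  m
}

#' Hypergeometric significance of a cluster overlap
#'
#' Upper-tail hypergeometric probability of observing at least `k` shared
#' members between a cluster of `nA` and a cluster of `nB` universe members
#' drawn from a common universe of size `U`.
#'
#' @param k observed shared count.
#' @param nA,nB universe-restricted cluster sizes.
#' @param U universe size.
#' @param log_base base of the reported negative logarithm (default 10).
#' @return list with `p` (P(X >= k)) and `neglog_p`.
#' @export
overlap_significance <- function(k, nA, nB, U, log_base = 10) {
  if (k > min(nA, nB) || min(nA, nB) > U || k < 0)
    stop("inconsistent counts: need k <= min(nA, nB) <= U")
  p <- stats::phyper(k - 1, nA, U - nA, nB, lower.tail = FALSE)
  list(p = p, neglog_p = -log(p, base = log_base))
}

#' Cross-station cluster overlap matrices
#'
#' Combines [overlap_counts()] and [overlap_significance()] over all cluster
#' pairs of two stations.
#'
#' @inheritParams overlap_counts
#' @param adjust if `TRUE`, Benjamini-Hochberg adjust the p-values across
#'   all cluster pairs before taking logs.
#' @param log_base base for the negative logarithm.
#' @return object of class `overlap_result`: list with `universe_size`,
#'   `counts`, `p`, `neglog_p` matrices and a long-format data frame
#'   `table` (`cluster_a`, `cluster_b`, `shared`, `p`, `neglog10_p`).
#' @export
station_overlap <- function(model_a, model_b, universe, adjust = FALSE,
                            log_base = 10) {
  counts <- overlap_counts(model_a, model_b, universe)
  U <- length(universe)
  in_universe <- function(model, j)
    sum(names(model$assignments)[model$assignments == j] %in% universe)
  na <- vapply(seq_len(nrow(counts)), function(j) in_universe(model_a, j),
               integer(1))
  nb <- vapply(seq_len(ncol(counts)), function(j) in_universe(model_b, j),
               integer(1))
  p <- matrix(1, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts)))
      p[i, j] <- overlap_significance(counts[i, j], na[i], nb[j], U)$p
  if (adjust) p[] <- stats::p.adjust(p, method = "BH")
  neglog <- -log(p, base = log_base)
  long <- data.frame(
    cluster_a = rep(rownames(counts), times = ncol(counts)),
    cluster_b = rep(colnames(counts), each = nrow(counts)),
    shared = as.vector(counts), p = as.vector(p),
    neglog10_p = as.vector(neglog), stringsAsFactors = FALSE)
  structure(list(universe_size = U, counts = counts, p = p,
                 neglog_p = neglog, table = long),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: %d x %d clusters over universe of %d ASVs\n",
              nrow(x$counts), ncol(x$counts), x$universe_size))
  invisible(x)
}
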