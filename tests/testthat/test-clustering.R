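test_that("feature matrix has two columns per component and is scale-invariant", {
  tlen <- 730
  d <- 0:(tlen - 1)
  pr <- dft_components(rbind(a = 2 + cos(2 * pi * 2 * d / tlen),
                             b = 3 + sin(2 * pi * 4 * d / tlen)), K = 4)
  f <- build_features(pr, component_range = c(1, 2))
  expect_equal(dim(f), c(2L, 4L))

  pr10 <- dft_components(rbind(a = 2 + cos(2 * pi * 2 * d / tlen),
                               b = 10 * (2 + cos(2 * pi * 2 * d / tlen))),
                         K = 4)
  f10 <- build_features(pr10)
  expect_equal(f10["a", ], f10["b", ], tolerance = 1e-12)

  # antiphase annual sinusoids give negated annual feature columns
  anti <- dft_components(rbind(a = 2 + cos(2 * pi * 2 * d / tlen),
                               b = 2 + cos(2 * pi * 2 * (d - 182.5) / tlen)),
                         K = 4)
  fa <- build_features(anti, component_range = 2)
  expect_equal(fa["a", ], -fa["b", ], tolerance = 1e-9)

  # degenerate all-zero series excluded with warning
  dg <- dft_components(rbind(a = 2 + cos(2 * pi * 2 * d / tlen),
                             z = rep(0, tlen)), K = 4)
  expect_warning(fd <- build_features(dg), "degenerate")
  expect_equal(rownames(fd), "a")
  expect_equal(attr(fd, "excluded"), "z")
})

test_that("k-means recovers well-separated phase groups and is deterministic", {
  cf <- synth_config(seed = 21, n_core = 45, n_unique_a = 0, n_unique_b = 0,
                     n_phase_groups = 3, noise_sigma = 0.1,
                     zero_inflation_p = 0, n_mwr = 0, n_mlr = 0)
  sim <- generate_community(cf)
  pr <- dft_components(interpolate_daily(sim$table_b, cf$window), K = 4)
  f <- build_features(pr, component_range = c(2, 4))
  km <- cluster_asvs(f, 3, n_restarts = 30, seed = 8)
  grp <- sim$truth$phase_group[match(names(km$assignments),
                                     sim$truth$asv_id)]
  expect_equal(mclust::adjustedRandIndex(km$assignments, grp), 1.0)

  km2 <- cluster_asvs(f, 3, n_restarts = 30, seed = 8)
  expect_identical(km$assignments, km2$assignments)

  # degenerate limit: as many clusters as points
  kmn <- cluster_asvs(f, nrow(f), seed = 1)
  expect_equal(kmn$wcss, 0)
  expect_equal(sort(unique(kmn$assignments)), seq_len(nrow(f)))
  expect_error(cluster_asvs(f, nrow(f) + 1, seed = 1), "exceeds")
})

test_that("BIC selects the true group number on separable phase groups", {
  f <- ring_features(n_groups = 4, seed = 11)
  sel <- select_n_clusters(f, 2:8, seed = 5)
  expect_equal(sel$chosen_k, 4L)
  expect_equal(sel$table$k, 2:8)
  expect_true(all(is.finite(sel$table$bic)))
})

test_that("BIC never chooses k_max for a single Gaussian blob", {
  for (r in 1:20) {
    y <- withr::with_seed(100 + r, matrix(stats::rnorm(300), ncol = 2))
    sel <- select_n_clusters(y, 2:8, seed = r)
    expect_lt(sel$chosen_k, 8L)
  }
})

test_that("a forced single-value k range returns that k", {
  f <- ring_features(n_groups = 3, seed = 2)
  expect_equal(select_n_clusters(f, 3, seed = 1)$chosen_k, 3L)
})

test_that("clusters are ordered and named by phase with documented tie-breaks", {
  daily <- cosine_daily(c(rep(50, 10), rep(200, 5)))
  rownames(daily) <- sprintf("asv%03d", 1:15)
  pr <- dft_components(daily, K = 4)
  km <- structure(list(
    assignments = stats::setNames(c(rep(2L, 10), rep(1L, 5)),
                                  rownames(daily)),
    N = 2L), class = "cluster_model")
  named <- order_and_name_clusters(km, pr, "H")
  expect_equal(named$names, c("H-01", "H-02"))
  expect_equal(named$phase_day, c(50, 200), tolerance = 1e-6)
  # phase-50 members now carry cluster index 1
  expect_true(all(named$assignments[1:10] == 1L))

  # equal phases: larger cluster gets the lower number
  tie <- cosine_daily(rep(100, 15))
  rownames(tie) <- sprintf("asv%03d", 1:15)
  prt <- dft_components(tie, K = 4)
  kmt <- structure(list(
    assignments = stats::setNames(c(rep(1L, 5), rep(2L, 10)),
                                  rownames(tie)),
    N = 2L), class = "cluster_model")
  namedt <- order_and_name_clusters(kmt, prt, "F")
  expect_true(all(namedt$assignments[6:15] == 1L))

  # permuting input cluster indices leaves the named output unchanged
  kmp <- km
  kmp$assignments <- stats::setNames(3L - km$assignments,
                                     names(km$assignments))
  namedp <- order_and_name_clusters(kmp, pr, "H")
  expect_identical(named$assignments, namedp$assignments)
  expect_identical(named$names, namedp$names)
  expect_equal(named$phase_day, namedp$phase_day)
})

test_that("peak counting is circular with a prominence threshold", {
  d <- 0:729
  expect_equal(count_peaks(2 + cos(2 * pi * 2 * d / 730)), 2L)
  expect_equal(count_peaks(rep(1, 730)), 0L)
  expect_equal(count_peaks(2 + cos(2 * pi * 4 * d / 730)), 4L)  # semiannual
  # low-prominence ripple on one annual peak is not counted
  x <- 2 + cos(2 * pi * 2 * d / 730) + 0.02 * cos(2 * pi * 8 * d / 730)
  expect_equal(count_peaks(x), 2L)
})

test_that("light classes follow polar day length and flag anomalous peaks", {
  expect_equal(daylight_hours(172), 24)
  expect_equal(daylight_hours(354), 0)
  expect_equal(assign_light_class(172, 2), "HL")
  expect_equal(assign_light_class(354, 2), "LL")
  expect_true(is.na(assign_light_class(100, 4)))   # anomalous peak count
  # partition of the year: every day is LL or HL, never both
  classes <- vapply(0:364, assign_light_class, character(1), n_peaks = 2)
  expect_true(all(classes %in% c("LL", "HL")))
  # month mode boundaries: equinox day opens HL, October returns to LL
  expect_equal(assign_light_class(79, 2, mode = "months"), "HL")
  expect_equal(assign_light_class(78, 2, mode = "months"), "LL")
  expect_equal(assign_light_class(280, 2, mode = "months"), "LL")
  expect_error(assign_light_class(100, 2, latitude_deg = 99), "latitude")
})

test_that("cluster summary reproduces size and mooring-specific percentages", {
  sizes <- c(68L, 27L, 151L, 591L)
  total <- sum(sizes)  # 837 ASVs at the station
  ids <- sprintf("asv%04d", seq_len(total))
  daily <- withr::with_seed(31, matrix(runif(total * 40, 0.1, 1), total,
                                       dimnames = list(ids, NULL)))
  pr <- dft_components(daily, K = 2, m = 1)
  assign <- rep(seq_along(sizes), sizes)
  model <- structure(list(
    assignments = stats::setNames(assign, ids),
    names = sprintf("H-%02d", seq_along(sizes)),
    phase_day = c(10, 50, 120, 300),
    N = length(sizes)), class = "cluster_model")
  # partner station lacks 52 of cluster 1, 26 of cluster 2, none elsewhere
  unshared <- c(ids[1:52], ids[69:94])
  summ <- cluster_summary(model, pr, setdiff(ids, unshared))
  expect_equal(summ$ms_abs, c(52L, 26L, 0L, 0L))
  expect_equal(summ$ms_rel[1], 76.47)
  expect_equal(summ$ms_rel[2], 96.3)
  expect_equal(summ$cl_size_pct[3], 18L)
  expect_equal(sum(summ$cl_size), total)
})
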