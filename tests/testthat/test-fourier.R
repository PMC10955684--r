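test_that("daily interpolation is linear, exact at samples, constant at edges", {
  dates <- as.Date("2017-01-01") + c(0, 14)
  tab <- sample_table("X", matrix(c(0, 0.14), 1), dates, "a")
  daily <- interpolate_daily(tab, as.Date(c("2017-01-01", "2017-02-01")))
  expect_equal(unname(daily[1, 8]), 0.07)          # midpoint of 0 .. 0.14
  expect_equal(unname(daily[1, 1]), 0)
  expect_equal(unname(daily[1, 15]), 0.14)
  expect_equal(unname(daily[1, 32]), 0.14)         # constant extension past last sample

  const <- sample_table("X", matrix(0.2, 1, 2), dates, "a")
  expect_equal(unique(as.vector(
    interpolate_daily(const, as.Date(c("2017-01-01", "2017-03-01"))))), 0.2)
})

test_that("interpolation reproduces random biweekly samples exactly and is monotone", {
  tab <- withr::with_seed(7, {
    dates <- seq(as.Date("2017-01-01"), by = 14, length.out = 20)
    sample_table("X", matrix(runif(3 * 20, 0, 0.3), 3), dates,
                 c("a", "b", "c"))
  })
  win <- as.Date(c("2017-01-01", "2017-09-20"))
  daily <- interpolate_daily(tab, win)
  offs <- as.numeric(tab$dates - win[1]) + 1
  offs <- offs[offs <= ncol(daily)]
  expect_equal(daily[, offs], tab$values[, seq_along(offs)],
               ignore_attr = TRUE)
  # monotone input yields monotone daily output between samples
  mono <- sample_table("X", matrix(seq(0.01, 0.2, length.out = 20), 1),
                       tab$dates, "a")
  dm <- interpolate_daily(mono, win)
  expect_true(all(diff(dm[1, ]) >= 0))
})

test_that("DFT of a constant-plus-annual-cosine matches the closed form", {
  tlen <- 730
  x <- 2 + cos(2 * pi * 2 * (0:(tlen - 1)) / tlen)
  pr <- dft_components(x, K = 4)
  expect_equal(Mod(pr$components[1, "c0"]), 1460)
  expect_equal(Mod(pr$components[1, "c2"]), 365)
  expect_equal(pr$seasonality, 0.25)
  expect_equal(pr$annual_phase_day, 0)
  # band-limited signal: components {0, 2} reconstruct the input exactly
  rec <- reconstruct_profile(pr, c(0, 2))
  expect_equal(drop(rec), x, tolerance = 1e-12)
})

test_that("DFT components equal the brute-force summation oracle", {
  withr::with_seed(11, {
    for (i in 1:20) {
      x <- runif(64, 0, 1)
      pr <- dft_components(x, K = 5, m = 1)
      expect_equal(pr$components[1, ], dft_oracle(x, 5),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  })
})

test_that("Parseval holds over the full spectrum on small series", {
  withr::with_seed(3, {
    for (i in 1:5) {
      tlen <- 52
      x <- runif(tlen)
      pr <- dft_components(x, K = tlen / 2, m = 1)
      mods2 <- Mod(pr$components[1, ])^2
      # real series: |c_k| = |c_{T-k}|; spectrum energy from k = 0..T/2
      energy <- unname(mods2[1] + mods2[tlen / 2 + 1] +
                   2 * sum(mods2[2:(tlen / 2)])) / tlen
      expect_equal(sum(x^2), energy, tolerance = 1e-9)
    }
  })
})

test_that("full inverse transform recovers a real series", {
  withr::with_seed(5, {
    # odd length: components 0..(T-1)/2 carry the whole spectrum
    tlen <- 61
    x <- runif(tlen)
    pr <- dft_components(x, K = (tlen - 1) / 2, m = 1)
    rec <- reconstruct_profile(pr, 0:((tlen - 1) / 2))
    expect_equal(drop(rec), x, tolerance = 1e-9)
    # reconstruct {0} of a constant is the constant
    pc <- dft_components(rep(5, 30), K = 2, m = 1)
    expect_equal(unique(round(drop(reconstruct_profile(pc, 0)), 12)), 5)
  })
})

test_that("seasonality is scale- and shift-invariant; degenerate flagged", {
  withr::with_seed(13, {
    for (i in 1:20) {
      x <- runif(146, 0.01, 1)
      s1 <- dft_components(x, K = 4, m = 1)$seasonality
      s3 <- dft_components(3 * x, K = 4, m = 1)$seasonality
      expect_equal(s1, s3, tolerance = 1e-12)
      sh <- dft_components(x[c(38:146, 1:37)], K = 4, m = 1)$seasonality
      expect_equal(s1, sh, tolerance = 1e-9)
    }
  })
  z <- dft_components(rep(0, 40), K = 3, m = 1)
  expect_equal(z$seasonality, 0)
  expect_true(z$degenerate)
  expect_equal(seasonality_score(z), 0, ignore_attr = TRUE)
})

test_that("profile correlation matches a textbook Pearson oracle", {
  tlen <- 730
  d <- 0:(tlen - 1)
  ident <- dft_components(rbind(a = 2 + cos(2 * pi * 2 * d / tlen),
                                b = 2 + cos(2 * pi * 2 * d / tlen)), K = 4)
  expect_equal(profile_correlation(ident, "a", "b"), 1.0)
  anti <- dft_components(rbind(
    a = 2 + cos(2 * pi * 2 * d / tlen),
    b = 2 + cos(2 * pi * 2 * (d - 182.5) / tlen)), K = 4)
  expect_equal(profile_correlation(anti, "a", "b", component_set = 2), -1.0)

  withr::with_seed(17, {
    for (i in 1:10) {
      m <- matrix(runif(2 * 146, 0, 1), 2,
                  dimnames = list(c("a", "b"), NULL))
      pr <- dft_components(m, K = 4, m = 2)
      got <- profile_correlation(pr, "a", "b")
      ra <- reconstruct_oracle(pr$components[1, ], 1:4, 146)
      rb <- reconstruct_oracle(pr$components[2, ], 1:4, 146)
      num <- sum((ra - mean(ra)) * (rb - mean(rb)))
      den <- sqrt(sum((ra - mean(ra))^2)) * sqrt(sum((rb - mean(rb))^2))
      expect_equal(as.numeric(got), num / den, tolerance = 1e-9)
    }
  })
  # zero-variance reconstruction is flagged
  z <- dft_components(rbind(a = rep(1, 40), b = rep(2, 40)), K = 3, m = 1)
  r <- profile_correlation(z, "a", "b")
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "undefined"))
})

test_that("over-Nyquist component requests are rejected", {
  expect_error(dft_components(runif(10), K = 6, m = 1), "too short")
})
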