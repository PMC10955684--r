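# shared fixtures and independent oracles

# small abundance table: values chosen to be exact at 12 significant digits
toy_table <- function(station = "HG-IV", n_asv = 3, n_dates = 4,
                      start = as.Date("2017-01-01"), by = 14, seed = 42) {
  vals <- withr::with_seed(seed, {
    m <- matrix(stats::runif(n_asv * n_dates, 0.01, 0.2), n_asv)
    signif(m, 6)
  })
  sample_table(station, vals, seq(start, by = by, length.out = n_dates),
               sprintf("asv%03d", seq_len(n_asv)),
               taxonomy = rep("Eukaryota;Alveolata", n_asv))
}

# brute-force double-loop DFT, the independent oracle for dft_components
dft_oracle <- function(x, K) {
  tlen <- length(x)
  vapply(0:K, function(k)
    sum(x * exp(-2i * pi * k * (0:(tlen - 1)) / tlen)), complex(1))
}

# independent partial inverse transform (loop formula, no vectorized reuse)
reconstruct_oracle <- function(coefs, component_set, tlen) {
  out <- numeric(tlen)
  for (d in 0:(tlen - 1)) {
    acc <- 0
    for (k in component_set) {
      w <- if (k == 0) 1 else 2
      acc <- acc + w * Re(coefs[k + 1] * exp(2i * pi * k * d / tlen))
    }
    out[d + 1] <- acc / tlen
  }
  out
}

# circular distance between day-of-year phases
phase_error_days <- function(est, truth) {
  abs(((est - truth + 182.5) %% 365) - 182.5)
}

# daily series matrix whose rows are cosines with given phase days
cosine_daily <- function(phases, tlen = 730, m = 2, amp = 1, base = 2) {
  t(vapply(phases, function(p)
    base + amp * cos(2 * pi * m * ((0:(tlen - 1)) - p) / tlen),
    numeric(tlen)))
}

# 10-phase-group ring in feature space (annual + harmonic dims)
ring_features <- function(n_groups = 4, n_per = 20, radius = 500, sd = 25,
                          seed = 1) {
  withr::with_seed(seed, {
    ph <- rep(seq(0, 2 * pi, length.out = n_groups + 1)[1:n_groups],
              each = n_per)
    f <- cbind(radius * cos(ph) + stats::rnorm(n_groups * n_per, 0, sd),
               radius * sin(ph) + stats::rnorm(n_groups * n_per, 0, sd),
               stats::rnorm(n_groups * n_per, 0, sd),
               stats::rnorm(n_groups * n_per, 0, sd))
    rownames(f) <- sprintf("asv%03d", seq_len(nrow(f)))
    attr(f, "group") <- rep(seq_len(n_groups), each = n_per)
    f
  })
}

# one-sided two-sample KS permutation p-value (independent of stats::ks.test)
ks_perm_p <- function(a, b, B = 10000, seed = 1) {
  m <- length(a); n <- length(b)
  o <- order(c(a, b))
  g0 <- c(rep(1L, m), rep(0L, n))[o]
  dplus <- function(g) max(cumsum(g) / m - cumsum(1L - g) / n)
  obs <- dplus(g0)
  withr::with_seed(seed, {
    hits <- 0L
    for (i in seq_len(B)) if (dplus(sample(g0)) >= obs - 1e-12) hits <- hits + 1L
    hits / B
  })
}
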