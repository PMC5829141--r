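## Independent oracles used across the suite. These deliberately re-derive
## quantities by a different route than the package code.

## Direct time-domain complex Morlet convolution (O(n * support) loop),
## mirroring the wavelet definition but not the FFT path.
direct_morlet <- function(x, fs, f, nCycles = 7) {
  n <- length(x)
  sigma <- nCycles / (2 * pi * f) * fs
  h <- as.integer(ceiling(3.5 * sigma))
  k <- -h:h
  g <- exp(-k^2 / (2 * sigma^2))
  w <- (2 / sum(g)) * g * exp(2i * pi * f * k / fs)
  xp <- c(rep(0, h), x, rep(0, h))
  vapply(seq_len(n), function(t0) sum(xp[t0 + h - k] * w), complex(1))
}

## PSD slope by periodogram regression (smoothed, log-log), 2-100 Hz.
psd_slope <- function(x, fs, f_lo = 2, f_hi = 100) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 31,
                          taper = 0, plot = FALSE)
  sel <- sp$freq > f_lo & sp$freq < f_hi
  unname(stats::coef(stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2])
}

## Closed-form one-way ANOVA (textbook sums of squares) + Tukey HSD p-values
## from the studentized range distribution. Balanced groups as a list.
anova_oracle <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  msw <- ssw / df2
  F <- (ssb / df1) / msw
  pairs <- utils::combn(k, 2)
  tukey_p <- apply(pairs, 2, function(ij) {
    se <- sqrt(msw / 2 * (1 / n[ij[1]] + 1 / n[ij[2]]))
    stats::ptukey(abs(means[ij[1]] - means[ij[2]]) / se, k, df2,
                  lower.tail = FALSE)
  })
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE),
       tukey_p = tukey_p)
}

## Brute-force epoch slicing by integer indexing (1-based recording,
## sample i at time (i-1)/fs), nearest sample with ties toward earlier.
slice_oracle <- function(trace, fs, onsets, span) {
  npre <- round(-span[1] * fs); npost <- round(span[2] * fs)
  t(vapply(onsets, function(on) {
    i0 <- ceiling(on * fs - 0.5) + 1L
    trace[(i0 - npre):(i0 + npost)]
  }, numeric(npre + npost + 1L)))
}
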