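# Independent oracles and small fixture builders used across tests.

# brute-force double-loop Gaussian convolution (oracle for smooth_counts)
brute_smooth <- function(counts, cfg) {
  cfg <- nucpatterns:::.as_smoothing_config(cfg)
  h <- cfg$half_width
  k <- stats::dnorm((-h:h) - 0.5, sd = cfg$sigma)
  k <- k / sum(k)
  out <- numeric(length(counts))
  for (x in seq_along(counts)) {
    s <- 0
    for (m in -h:h) {
      xi <- x - m
      if (xi >= 1 && xi <= length(counts)) s <- s + counts[xi] * k[m + h + 1]
    }
    out[x] <- s
  }
  out
}

# Moore-Penrose pseudo-inverse via SVD (oracle for lambda = 0 ridge)
pinv <- function(M, tol = 1e-10) {
  sv <- svd(M)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

# zero-padded FFT peak period (oracle for dominant_period)
fft_peak_period <- function(signal, pad = 8192) {
  signal <- signal - mean(signal)
  sp <- Mod(stats::fft(c(signal, rep(0, pad - length(signal)))))^2
  half <- 2:(pad %/% 2)
  pad / (which.max(sp[half]) + 1 - 1)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

.normalize2 <- function(v) {
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

# small deterministic midpoint track + anchors for profile tests
toy_track <- function(mids, chrom = "chr1", total = length(mids)) {
  midpoint_track(rep(chrom, length(mids)), mids, total = total)
}
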