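# Shape analysis: Morlet-wavelet scalograms of pattern shapes and
# nucleosome co-positioning (cosine-similarity) matrices.

#' Wavelet configuration
#'
#' Morlet continuous-wavelet grid: log-spaced scales over a range and
#' unit-step positions across the profile window.
#'
#' @param n_scales Number of log-spaced scales (default 64).
#' @param scale_range Scale range in bp-domain units, default `c(64, 1024)`
#'   which brackets pseudo-periods from sub-nucleosomal (~66 bp) to
#'   multi-nucleosomal (~1060 bp) at `omega0 = 6`.
#' @param omega0 Morlet center-frequency parameter; 6 is the conventional
#'   admissibility choice.
#' @param window Half-window of the profiles analyzed (positions
#'   `-window..window`).
#' @return A `WaveletConfig` list.
#' @export
wavelet_config <- function(n_scales = 64, scale_range = c(64, 1024),
                           omega0 = 6, window = 500) {
  if (any(scale_range <= 0) || scale_range[2] <= scale_range[1]) {
    stop("scale_range must be positive and ascending")
  }
  scales <- exp(seq(log(scale_range[1]), log(scale_range[2]),
                    length.out = n_scales))
  structure(list(scales = scales, positions = -window:window,
                 omega0 = omega0, window = window),
            class = "WaveletConfig")
}

#' Morlet wavelet evaluated on a grid
#'
#' `psi_{a,b}(x) = pi^(-1/4) a^(-1/2) exp(i omega0 (x-b)/a)
#'  exp(-((x-b)/a)^2 / 2)`.
#'
#' @param x Positions (bp).
#' @param a Scale (> 0).
#' @param b Localized position.
#' @param omega0 Center-frequency parameter.
#' @return Complex vector.
#' @export
morlet_wavelet <- function(x, a, b = 0, omega0 = 6) {
  if (a <= 0) stop("scale a must be positive")
  z <- (x - b) / a
  pi^(-0.25) / sqrt(a) * exp(1i * omega0 * z) * exp(-z^2 / 2)
}

#' Single Morlet wavelet coefficient
#'
#' Inner product of a pattern with the conjugated scaled/translated Morlet
#' wavelet, summed over the integer positions of the window.
#'
#' @param pattern Real series over `positions`.
#' @param a Scale.
#' @param b Position.
#' @param omega0 Center-frequency parameter.
#' @param positions Position grid; defaults to a symmetric window.
#' @return Complex coefficient.
#' @export
morlet_coefficient <- function(pattern, a, b, omega0 = 6, positions = NULL) {
  if (is.null(positions)) {
    w <- (length(pattern) - 1) / 2
    positions <- -w:w
  }
  sum(pattern * Conj(morlet_wavelet(positions, a, b, omega0)))
}

#' Morlet scalogram of a pattern
#'
#' Full coefficient table over the scale/position grid plus per-scale
#' total power (`sum_b Re^2 + Im^2`). The real part is the display view
#' (it carries both periodicity and peak localization); the power sums
#' real and imaginary parts. The pattern's mean is removed first: inside
#' a finite window the truncated Morlet does not integrate to zero at
#' large scales, so without centering a constant offset would leak
#' spurious large-scale power (a flat pattern then has exactly zero
#' power, as it should).
#'
#' @param pattern Real vector matching the config's position grid.
#' @param cfg A [wavelet_config()].
#' @return A `Scalogram`: list with `coef` (complex, scales x positions),
#'   `scales`, `positions`, `power` (per scale), `omega0`.
#' @export
scalogram <- function(pattern, cfg = wavelet_config()) {
  x <- cfg$positions
  if (length(pattern) != length(x)) {
    stop("pattern length must match the config position grid (",
         length(x), ")")
  }
  pattern <- pattern - mean(pattern)
  D <- outer(x, x, `-`)                # x minus b, positions = b grid
  nS <- length(cfg$scales)
  coef <- matrix(complex(real = 0), nS, length(x))
  power <- numeric(nS)
  amp <- pi^(-0.25)
  for (si in seq_len(nS)) {
    a <- cfg$scales[si]
    Z <- D / a
    E <- (amp / sqrt(a)) * exp(-Z^2 / 2)
    re <- colSums(pattern * (E * cos(cfg$omega0 * Z)))
    im <- -colSums(pattern * (E * sin(cfg$omega0 * Z)))   # conjugate
    coef[si, ] <- complex(real = re, imaginary = im)
    power[si] <- sum(re^2 + im^2)
  }
  dimnames(coef) <- list(format(cfg$scales, digits = 6), as.character(x))
  structure(list(coef = coef, scales = cfg$scales, positions = x,
                 power = power, omega0 = cfg$omega0),
            class = "Scalogram")
}

#' Morlet scale to pseudo-period conversion
#'
#' `period = a * 4 * pi / (omega0 + sqrt(2 + omega0^2))`, the standard
#' relation placing the wavelet's Fourier-energy peak at that period.
#'
#' @param a Scale(s).
#' @param omega0 Center-frequency parameter.
#' @export
scale_to_period <- function(a, omega0 = 6) {
  a * 4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' @rdname scale_to_period
#' @param period Pseudo-period(s) in bp.
#' @export
period_to_scale <- function(period, omega0 = 6) {
  period * (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
}

#' Dominant pseudo-period(s) of a scalogram
#'
#' The pseudo-period of the maximum-power scale; with `n_peaks > 1`, the
#' pseudo-periods of local power maxima ordered by decreasing power.
#'
#' @param s A `Scalogram`.
#' @param n_peaks Number of local power maxima to report.
#' @return Pseudo-period(s) in bp.
#' @export
dominant_period <- function(s, n_peaks = 1) {
  p <- s$power
  if (all(p <= 0) || max(p) < .Machine$double.eps) {
    stop("scalogram has no power; dominant period undefined")
  }
  if (n_peaks == 1) {
    return(scale_to_period(s$scales[which.max(p)], s$omega0))
  }
  n <- length(p)
  is_peak <- c(p[1] > p[2],
               p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] > p[3:n],
               p[n] > p[n - 1])
  idx <- which(is_peak)
  idx <- idx[order(p[idx], decreasing = TRUE)]
  scale_to_period(s$scales[utils::head(idx, n_peaks)], s$omega0)
}

#' Nucleosome co-positioning matrix
#'
#' Cosine similarity between every pair of offset columns of a per-locus
#' density matrix: entry `(i, j)` is high when loci that carry density at
#' offset i tend to carry density at offset j as well, i.e. the two
#' nucleosome positions co-occur at single loci rather than in different
#' subsets of loci.
#'
#' @param S A [per_locus_matrix()] result (M loci x N offsets), M >= 2.
#' @param label Optional anchor-class label.
#' @return A `CopositionMatrix`: N x N symmetric matrix in `[-1, 1]` with
#'   unit diagonal for nonzero columns; zero-norm columns give 0 rows and
#'   are flagged in the `"zero_columns"` attribute.
#' @export
coposition_matrix <- function(S, label = NULL) {
  S <- unclass(S)
  if (!is.matrix(S) || nrow(S) < 2) {
    stop("need a per-locus matrix with M >= 2 loci")
  }
  norms <- sqrt(colSums(S^2))
  G <- crossprod(S)
  denom <- outer(norms, norms)
  A <- matrix(0, ncol(S), ncol(S))
  nz <- norms > 0
  A[nz, nz] <- G[nz, nz] / denom[nz, nz]
  A <- (A + t(A)) / 2                   # enforce exact symmetry
  A[A > 1] <- 1; A[A < -1] <- -1
  diag(A)[nz] <- 1
  dimnames(A) <- list(colnames(S), colnames(S))
  attr(A, "zero_columns") <- which(!nz)
  attr(A, "label") <- label
  class(A) <- c("CopositionMatrix", class(A))
  A
}

#' Write a scalogram as TSV
#'
#' Real-part table (scales x positions) preceded by metadata and followed
#' by the per-scale power column.
#'
#' @param s A `Scalogram`.
#' @param path Output file.
#' @export
write_scalogram <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# omega0: %s", format(s$omega0)),
               sprintf("# scales: %s",
                       paste(format(s$scales, digits = 10), collapse = "\t")),
               paste(c("scale", "power", as.character(s$positions)),
                     collapse = "\t")), con)
  body <- cbind(format(s$scales, digits = 10),
                format(s$power, digits = 10),
                format(Re(s$coef), digits = 10))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a co-positioning matrix as TSV with offset labels
#' @param A A `CopositionMatrix`.
#' @param path Output file.
#' @export
write_coposition <- function(A, path) {
  df <- data.frame(offset = rownames(A) %||% seq_len(nrow(A)),
                   format(unclass(A), digits = 10), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
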