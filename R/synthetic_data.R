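# Synthetic data: fragment sets, anchors and expression tables with
# planted positioning-pattern structure, so every pipeline stage is
# testable without sequencing data.

.pattern_families <- c("occupancy_trend", "on_motif_single", "asymmetric",
                       "holding", "phased_array")

#' Planted pattern specification
#'
#' One of five shape families emulating the recurring positioning motifs
#' around regulatory elements: a broad occupancy trend, a single
#' on-motif nucleosome (central dip/peak), a strand-oriented asymmetric
#' array, a mixed short-period/long-period "holding" shape, and a
#' regularly phased array.
#'
#' @param family One of `"occupancy_trend"`, `"on_motif_single"`,
#'   `"asymmetric"`, `"holding"`, `"phased_array"`.
#' @param sign `"+"` or `"-"`; flips the shape vertically (asymmetric:
#'   mirrors it left/right).
#' @param amplitude Relative modulation depth `A` in `[0, 1]` (keeps the
#'   intensity nonnegative).
#' @param nrl Nucleosome repeat length in bp (default 186).
#' @param tau Central dip/peak width in bp for `on_motif_single`.
#' @param trend_width Gaussian width of the occupancy trend in bp.
#' @param outer_period Long period (bp) of the `holding` family's broad
#'   cyclic component (default 400).
#' @return A `PatternSpec` list.
#' @export
pattern_spec <- function(family, sign = "+", amplitude = 0.6, nrl = 186,
                         tau = 100, trend_width = 250, outer_period = 400) {
  family <- match.arg(family, .pattern_families)
  if (!sign %in% c("+", "-")) stop("sign must be '+' or '-'")
  if (amplitude < 0 || amplitude > 1) stop("amplitude must be in [0, 1]")
  if (nrl <= 0) stop("nrl must be positive")
  structure(list(family = family, sign = sign, amplitude = amplitude,
                 nrl = nrl, tau = tau, trend_width = trend_width,
                 outer_period = outer_period),
            class = "PatternSpec")
}

#' Relative midpoint intensity of a planted pattern
#'
#' Deterministic nonnegative intensity (baseline 1) at offset `x` bp from
#' the anchor center:
#' * `occupancy_trend`: `1 +/- A exp(-x^2 / (2 trend_width^2))`
#' * `on_motif_single`: `1 -/+ A exp(-x^2 / (2 tau^2))` (`+` = central dip)
#' * `asymmetric`: `1 + A cos(2 pi x / nrl)` on `x > 0` only (`-` mirrors
#'   to `x < 0`), so `f_plus(x) = f_minus(-x)`
#' * `holding`: `1 +/- [A/2 cos(2 pi x / 160) exp(-x^2 / (2 * 250^2)) +
#'    A/2 cos(2 pi x / outer_period)]`
#' * `phased_array`: `1 -/+ A cos(2 pi x / nrl)`
#'
#' @param spec A [pattern_spec()].
#' @param x Offsets in bp (any integers; the simulator evaluates slightly
#'   beyond the +/-500 bp window).
#' @return Nonnegative intensities, same length as `x`.
#' @export
pattern_intensity <- function(spec, x) {
  s <- if (spec$sign == "+") 1 else -1
  A <- spec$amplitude
  v <- switch(spec$family,
    occupancy_trend = 1 + s * A * exp(-x^2 / (2 * spec$trend_width^2)),
    on_motif_single = 1 - s * A * exp(-x^2 / (2 * spec$tau^2)),
    asymmetric = if (spec$sign == "+") {
      1 + A * cos(2 * pi * x / spec$nrl) * (x > 0)
    } else {
      1 + A * cos(2 * pi * x / spec$nrl) * (x < 0)
    },
    holding = 1 + s * (A / 2 * cos(2 * pi * x / 160) *
                         exp(-x^2 / (2 * 250^2)) +
                       A / 2 * cos(2 * pi * x / spec$outer_period)),
    phased_array = 1 - s * A * cos(2 * pi * x / spec$nrl))
  pmax(v, 0)
}

#' Planted orthonormal pattern basis
#'
#' The five family shapes (plus sign, amplitude-independent direction)
#' evaluated on the window, centered, and orthonormalized in fixed family
#' order by Gram-Schmidt (QR). Ground truth for basis-recovery tests.
#'
#' @param window Half-window (default 500).
#' @param nrl,tau,trend_width,outer_period Shape parameters as in
#'   [pattern_spec()].
#' @return A `PatternBasis` with orthonormal `vectors` (W x 5) and no
#'   eigenvalue spectrum (`NA`).
#' @export
planted_basis <- function(window = 500, nrl = 186, tau = 100,
                          trend_width = 250, outer_period = 400) {
  x <- -window:window
  shapes <- vapply(.pattern_families, function(fam) {
    sp <- pattern_spec(fam, "+", amplitude = 0.5, nrl = nrl, tau = tau,
                       trend_width = trend_width,
                       outer_period = outer_period)
    v <- pattern_intensity(sp, x) - 1
    v - mean(v)
  }, numeric(length(x)))
  qrd <- qr(shapes)
  Q <- qr.Q(qrd)
  for (k in seq_len(ncol(Q))) {      # orient along the raw family shape
    if (sum(Q[, k] * shapes[, k]) < 0) Q[, k] <- -Q[, k]
  }
  colnames(Q) <- sprintf("pattern_%d", seq_len(ncol(Q)))
  structure(list(vectors = Q, eigenvalues = rep(NA_real_, 5),
                 contrib = NULL, cum_contrib = NULL, K = 5L,
                 W = length(x), flips = rep(1, 5), signs_fixed = NA),
            class = "PatternBasis")
}

#' Simulate a matrix of profiles as noisy planted-pattern mixtures
#'
#' Each profile is `B w + e` with `B` the planted basis, mixture weights
#' drawn `N(0, weight_sd_k^2)` per pattern, and isotropic noise scaled so
#' `||e|| = noise_frac * ||B w||` per profile. Distinct weight variances
#' (default decreasing) make the extracted principal components align
#' with the planted patterns in order, which mirrors the decreasing
#' contribution ratios seen in real profile collections.
#'
#' @param n_profiles Number of profiles (default 516).
#' @param noise_frac Noise norm as a fraction of signal norm (default 0.10).
#' @param weight_sd Per-pattern weight standard deviations.
#' @param seed RNG seed.
#' @param window Half-window.
#' @param basis Planted basis; defaults to [planted_basis()].
#' @return List with `profiles` (W x C raw matrix), `weights` (5 x C true
#'   mixture weights), `basis`, `seed`.
#' @export
simulate_profile_matrix <- function(n_profiles = 516, noise_frac = 0.10,
                                    weight_sd = c(1, 0.8, 0.65, 0.5, 0.4),
                                    seed = 1, window = 500,
                                    basis = planted_basis(window)) {
  set.seed(seed)
  B <- basis$vectors
  K <- ncol(B); W <- nrow(B)
  Wt <- matrix(stats::rnorm(K * n_profiles), K, n_profiles) * weight_sd
  Sg <- B %*% Wt
  E <- matrix(stats::rnorm(W * n_profiles), W, n_profiles)
  sc <- noise_frac * sqrt(colSums(Sg^2)) / sqrt(colSums(E^2))
  X <- Sg + sweep(E, 2, sc, `*`)
  colnames(X) <- sprintf("profile_%d", seq_len(n_profiles))
  list(profiles = X, weights = Wt, basis = basis, seed = seed)
}

#' Simulate expression linearly linked to planted pattern scores
#'
#' `y = b1 * s_1 + b5 * s_5 + noise` where `s_k` is a profile's score on
#' planted pattern k (projection of the centered, unit-normalized profile
#' on the planted basis): the generative claim that broad occupancy
#' (pattern 1) and regular phasing (pattern 5) drive neighbouring
#' expression. Noise sd is set from the signal sd and the requested
#' signal-to-noise (variance) ratio. Returned centered.
#'
#' @param sim A [simulate_profile_matrix()] result (uses `profiles` and
#'   `basis`).
#' @param b1,b5 Linkage coefficients.
#' @param snr Signal-to-noise variance ratio (default 10).
#' @param seed RNG seed.
#' @return List with `y` (centered), `signal`, `scores` (C x K), `noise_sd`.
#' @export
simulate_expression <- function(sim, b1 = 1, b5 = 1, snr = 10,
                                seed = 1) {
  set.seed(seed)
  Xn <- apply(sim$profiles, 2, .normalize_column)
  scores <- crossprod(Xn, sim$basis$vectors)
  signal <- b1 * scores[, 1] + b5 * scores[, 5]
  noise_sd <- stats::sd(signal) / sqrt(snr)
  y <- signal + stats::rnorm(length(signal), 0, noise_sd)
  list(y = y - mean(y), signal = signal, scores = scores,
       noise_sd = noise_sd)
}

#' Synthetic dataset configuration
#'
#' Defaults state the emulated world: a 2 Mb toy genome, ~520 anchors
#' (104 per pattern family), ~100 midpoints per anchor window, mono-
#' nucleosome fragment lengths 164 +/- 12 bp, 30% background fragments,
#' and expression log-linearly linked to the planted occupancy-trend and
#' phasing coefficients.
#'
#' @param genome_size Total genome size in bp.
#' @param n_chrom Number of equal-sized chromosomes.
#' @param elements_per_class Anchors per pattern family.
#' @param strand_prob Probability an anchor is minus-strand.
#' @param depth Expected midpoints per anchor window.
#' @param frag_mean,frag_sd Fragment length distribution (bp); lengths
#'   are rounded and clipped at >= 50.
#' @param background_frac Fraction of all fragments that are uniform
#'   background.
#' @param amplitude,nrl,tau,trend_width,outer_period Planted shape
#'   parameters, see [pattern_spec()].
#' @param b0,b1,b5,expr_noise_sd Expression model on the log2 scale:
#'   `log2(expr + 1) = b0 + b1*c1 + b5*c5 + N(0, expr_noise_sd)` where
#'   `c1`/`c5` are the anchor's signed trend/phasing coefficients.
#' @param sigma Smoothing bandwidth the window slack is derived from.
#' @param window Profile half-window.
#' @param seed RNG seed; all outputs are a pure function of (config, seed).
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(genome_size = 2e6, n_chrom = 1,
                             elements_per_class = 104, strand_prob = 0.5,
                             depth = 100, frag_mean = 164, frag_sd = 12,
                             background_frac = 0.30, amplitude = 0.6,
                             nrl = 186, tau = 100, trend_width = 250,
                             outer_period = 400, b0 = 8, b1 = 2, b5 = 2,
                             expr_noise_sd = 0.5, sigma = 30,
                             window = 500, seed = 1) {
  cfg <- list(genome_size = genome_size, n_chrom = n_chrom,
              elements_per_class = elements_per_class,
              strand_prob = strand_prob, depth = depth,
              frag_mean = frag_mean, frag_sd = frag_sd,
              background_frac = background_frac, amplitude = amplitude,
              nrl = nrl, tau = tau, trend_width = trend_width,
              outer_period = outer_period, b0 = b0, b1 = b1, b5 = b5,
              expr_noise_sd = expr_noise_sd, sigma = sigma,
              window = window, seed = seed)
  if (any(unlist(cfg[c("genome_size", "n_chrom", "elements_per_class",
                       "depth", "frag_mean")]) <= 0)) {
    stop("counts and sizes must be positive")
  }
  if (background_frac < 0 || background_frac >= 1) {
    stop("background_frac must be in [0, 1)")
  }
  structure(cfg, class = "SyntheticConfig")
}

#' Simulate a full fragment-level dataset
#'
#' Places non-overlapping anchors with random strands and pattern
#' families; draws per-anchor midpoints from an inhomogeneous Poisson
#' process with rate proportional to the (strand-oriented) planted
#' intensity over `+/-(window + 4 sigma)`; adds uniform background
#' midpoints; expands every midpoint to a fragment of length
#' `round(N(frag_mean, frag_sd))` clipped at >= 50; places one gene near
#' each anchor and assigns expression from the planted coefficients.
#' Identical config + seed reproduces byte-identical outputs.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `genome` (GenomeTable), `anchors` (AnchorSet),
#'   `fragments` (FragmentSet), `expression` (ExpressionTable), `truth`
#'   (per-anchor planted parameters), `config`.
#' @export
simulate_dataset <- function(cfg = synthetic_config()) {
  set.seed(cfg$seed)
  h <- ceiling(4 * cfg$sigma)
  span <- cfg$window + h
  pitch <- 2 * span + 1
  n_anchors <- 5 * cfg$elements_per_class
  chrom_len <- floor(cfg$genome_size / cfg$n_chrom)
  chrom_names <- sprintf("chrS%d", seq_len(cfg$n_chrom))
  genome <- genome_table(chrom_names, rep(chrom_len, cfg$n_chrom))

  # spread anchors over chromosomes, non-overlapping padded windows
  per_chrom <- diff(floor(seq(0, n_anchors, length.out = cfg$n_chrom + 1)))
  anchor_chrom <- rep(chrom_names, per_chrom)
  centers <- numeric(0)
  for (ci in seq_len(cfg$n_chrom)) {
    nc <- per_chrom[ci]
    if (nc == 0) next
    free <- (chrom_len - 2 * span) - nc * pitch
    if (free < 0) {
      stop("overcrowded genome: cannot place ", nc,
           " non-overlapping anchor windows on a ", chrom_len,
           " bp chromosome")
    }
    u <- sort(stats::runif(nc, 0, free))
    centers <- c(centers, floor(span + u + (seq_len(nc) - 1) * pitch))
  }
  family <- sample(rep(.pattern_families, cfg$elements_per_class))
  psign <- sample(c("+", "-"), n_anchors, replace = TRUE)
  strand <- sample(c("+", "-"), n_anchors, replace = TRUE,
                   prob = c(1 - cfg$strand_prob, cfg$strand_prob))
  anchors <- anchor_set(anchor_chrom, centers, strand,
                        id = sprintf("el_%03d", seq_len(n_anchors)),
                        group = family, genome = genome)

  xs <- -span:span
  frag_chrom <- character(0); mids <- numeric(0)
  n_mid <- integer(n_anchors)
  for (i in seq_len(n_anchors)) {
    sp <- pattern_spec(family[i], psign[i], cfg$amplitude, cfg$nrl,
                       cfg$tau, cfg$trend_width, cfg$outer_period)
    rate <- pattern_intensity(sp, xs)
    n_i <- stats::rpois(1, cfg$depth)
    n_mid[i] <- n_i
    if (n_i == 0) next
    off <- sample(xs, n_i, replace = TRUE, prob = rate)
    if (strand[i] == "-") off <- -off        # pattern rides the strand
    frag_chrom <- c(frag_chrom, rep(anchor_chrom[i], n_i))
    mids <- c(mids, centers[i] + off)
  }
  bg_expect <- n_anchors * cfg$depth *
    cfg$background_frac / (1 - cfg$background_frac)
  n_bg <- stats::rpois(1, bg_expect)
  if (n_bg > 0) {
    bg_chrom <- sample(chrom_names, n_bg, replace = TRUE)
    frag_chrom <- c(frag_chrom, bg_chrom)
    mids <- c(mids, floor(stats::runif(n_bg, 0, chrom_len)))
  }
  len <- pmax(50, round(stats::rnorm(length(mids), cfg$frag_mean,
                                     cfg$frag_sd)))
  fstart <- mids - len %/% 2
  fend <- fstart + len
  ok <- fstart >= 0 & fend <= chrom_len
  fragments <- fragment_set(frag_chrom[ok], fstart[ok], fend[ok])

  # planted expression linkage: signed coefficients of the trend (c1) and
  # phasing (c5) families, zero elsewhere
  sgn <- ifelse(psign == "+", 1, -1)
  c1 <- ifelse(family == "occupancy_trend", sgn * cfg$amplitude, 0)
  c5 <- ifelse(family == "phased_array", sgn * cfg$amplitude, 0)
  g <- cfg$b0 + cfg$b1 * c1 + cfg$b5 * c5 +
    stats::rnorm(n_anchors, 0, cfg$expr_noise_sd)
  g <- pmax(g, 0)
  gstart <- ifelse(centers + 1200 <= chrom_len, centers + 200,
                   centers - 1200)
  genes <- expression_table(sprintf("gene_%03d", seq_len(n_anchors)),
                            anchor_chrom, gstart, gstart + 1000,
                            sample(c("+", "-"), n_anchors, replace = TRUE),
                            2^g - 1)
  truth <- data.frame(id = anchors$id, chrom = anchor_chrom,
                      center = centers, strand = strand, family = family,
                      sign = psign, amplitude = cfg$amplitude, c1 = c1,
                      c5 = c5, n_midpoints = n_mid, log2_expression = g,
                      seed = cfg$seed, stringsAsFactors = FALSE)
  list(genome = genome, anchors = anchors, fragments = fragments,
       expression = genes, truth = truth, config = cfg)
}

#' Write a simulated dataset to a directory
#'
#' Emits `genome.tsv`, `anchors.bed`, `fragments.bed`, `expression.tsv`,
#' `truth.tsv` (all plain text; the seed is recorded in the truth table).
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_table(sim$genome, file.path(dir, "genome.tsv"))
  write_anchors_bed(sim$anchors, file.path(dir, "anchors.bed"))
  write_fragments_bed(sim$fragments, file.path(dir, "fragments.bed"))
  write_expression_table(sim$expression, file.path(dir, "expression.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
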