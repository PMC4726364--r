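test_that("fragment midpoints use the integer interval midpoint", {
  fs <- fragment_set(c("chr1", "chr1"), c(100, 0), c(264, 1))
  trk <- fragment_midpoints(fs)
  expect_equal(trk$positions$chr1, c(0, 182))
  expect_equal(trk$total, 2)
})

test_that("midpoint histogram of planted dyads peaks at the dyads", {
  set.seed(3)
  dyads <- c(5000, 5200, 5400)
  st <- rep(dyads, each = 400) - 82 + sample(-3:3, 1200, TRUE)
  fs <- fragment_set("chr1", st, st + 164)
  trk <- fragment_midpoints(fs)
  # direct histogram oracle
  mids <- floor((st + st + 164) / 2)
  expect_equal(sort(trk$positions$chr1), sort(mids))
  h <- tabulate(trk$positions$chr1, nbins = 6000)
  for (d in dyads) {   # local histogram mode sits on the planted dyad
    expect_lte(abs(which.max(h[(d - 10):(d + 10)]) - 11), 3)
    expect_equal(sum(h[(d - 10):(d + 10)]), 400)
  }
})

test_that("smooth_counts matches the brute-force convolution oracle", {
  cfg <- smoothing_config(5)
  expect_equal(smooth_counts(rep(0, 50), cfg), rep(0, 50))
  set.seed(11)
  for (sigma in c(3, 7.5, 12)) {
    cfg <- smoothing_config(sigma)
    counts <- rpois(120, 3)
    expect_lt(max(abs(smooth_counts(counts, cfg) - brute_smooth(counts, cfg))),
              1e-10)
  }
  expect_error(smoothing_config(0), "positive")
  expect_error(smooth_counts(c(1, NA), smoothing_config(2)), "finite")
})

test_that("kernel mass is conserved and the half-integer shift shows", {
  cfg <- smoothing_config(30)
  imp <- c(rep(0, 200), 1, rep(0, 200))
  out <- smooth_counts(imp, cfg)
  expect_equal(sum(out), 1, tolerance = 1e-12)     # unit kernel mass
  # kernel evaluated at m - 0.5: offsets 0 and +1 are equidistant maxima
  expect_equal(out[201], out[202])
  expect_equal(which.max(out), 201)
  # mass conservation for interior signal, with RPM scaling
  set.seed(2)
  counts <- c(rep(0, 130), rpois(100, 4), rep(0, 130))
  expect_equal(sum(smooth_counts(counts * 2.5, cfg)), sum(counts) * 2.5,
               tolerance = 1e-8)
})

test_that("single-midpoint anchor reproduces the smoothed impulse x RPM", {
  trk <- toy_track(5000, total = 2e6)
  a <- anchor_set("chr1", 5000, "+")
  cfg <- smoothing_config(30)
  prof <- aggregate_profile(trk, a, cfg)
  h <- cfg$half_width
  imp <- c(rep(0, 620), 1, rep(0, 620)) * 1e6 / 2e6
  expect_equal(prof$values,
               smooth_counts(imp, cfg)[(h + 1):(h + 1001)],
               tolerance = 1e-12)
  expect_equal(prof$n_anchors, 1L)
})

test_that("strand-aware flipping merges opposite-strand peaks", {
  # midpoints at +100 in the oriented frame of each anchor
  trk <- toy_track(c(rep(5100, 30), rep(19900, 30)), total = 60)
  a <- anchor_set("chr1", c(5000, 20000), c("+", "-"))
  on <- aggregate_profile(trk, a, smoothing_config(20), strand_aware = TRUE,
                          rpm = FALSE)
  off <- aggregate_profile(trk, a, smoothing_config(20), strand_aware = FALSE,
                           rpm = FALSE)
  peak_on <- on$offsets[which.max(on$values)]
  expect_lte(abs(peak_on - 100), 1)                # single merged peak
  expect_gt(max(on$values), max(off$values))       # aligned asymmetry sharper
  # unstranded anchors behave as plus strand
  a_dot <- anchor_set("chr1", c(5000, 20000), c("+", "."))
  expect_equal(aggregate_profile(trk, a_dot, smoothing_config(20),
                                 strand_aware = TRUE, rpm = FALSE)$values,
               off$values)
})

test_that("per-locus matrix rows average to the aggregate profile", {
  set.seed(9)
  mids <- c(5000 + sample(-400:400, 150, TRUE),
            30000 + sample(-400:400, 130, TRUE),
            70000 + sample(-400:400, 170, TRUE))
  trk <- toy_track(mids)
  a <- anchor_set("chr1", c(5000, 30000, 70000), c("+", "-", "+"),
                  id = c("a", "b", "c"))
  cfg <- smoothing_config(25)
  S <- per_locus_matrix(trk, a, cfg)
  expect_equal(dim(S), c(3, 1001))
  expect_equal(rownames(S), c("a", "b", "c"))
  prof <- aggregate_profile(trk, a, cfg)
  expect_lt(max(abs(colMeans(S) - prof$values)), 1e-10)
  # M = 1: the single row is the aggregate
  S1 <- per_locus_matrix(trk, a[1, ], cfg)
  expect_equal(drop(unclass(S1)),
               aggregate_profile(trk, a[1, ], cfg)$values,
               ignore_attr = TRUE)
})

test_that("aggregate_profile is anchor-order invariant and flip is involutive", {
  set.seed(4)
  mids <- sample(2000:98000, 800, TRUE)
  trk <- toy_track(mids)
  a <- anchor_set("chr1", c(5000, 30000, 70000, 50000),
                  c("+", "-", "+", "-"))
  p1 <- aggregate_profile(trk, a, smoothing_config(30))
  p2 <- aggregate_profile(trk, a[c(3, 1, 4, 2), ], smoothing_config(30))
  expect_equal(p1$values, p2$values)
  expect_equal(rev(rev(p1$values)), p1$values)     # involution, exact
})

test_that("anchors whose padded window leaves the chromosome are skipped", {
  g <- genome_table("chr1", 10000)
  trk <- toy_track(c(500, 5000, 9800))
  cfg <- smoothing_config(30)                      # span 620
  a <- anchor_set("chr1", c(500, 5000, 9800), genome = g)
  prof <- aggregate_profile(trk, a, cfg, genome = g)
  expect_equal(prof$n_anchors, 1L)
  expect_equal(prof$n_skipped, 2L)
  a_edge <- anchor_set("chr1", c(500, 9800), genome = g)
  expect_error(aggregate_profile(trk, a_edge, cfg, genome = g),
               "zero usable")
})

test_that("coverage probability matches closed form and guards bounds", {
  # deep-sequencing remark: ~77% chance of >= 1 read per 200 bp window
  expect_equal(coverage_probability(2e7, 2.7e9, 200), 0.77, tolerance = 0.01)
  expect_equal(coverage_probability(1, 100, 50), 0.5)
  expect_equal(coverage_probability(5, 100, 100), 1)
  expect_error(coverage_probability(10, 100, 200), "exceed")
  expect_error(coverage_probability(0, 100, 10), "positive")
})

test_that("profiles round-trip through the TSV format", {
  set.seed(6)
  prof <- density_profile(abs(rnorm(1001)), n_anchors = 7, sigma = 30,
                          rpm = TRUE, label = "MYOD_Q6")
  f <- tempfile(fileext = ".tsv")
  write_profile(prof, f)
  back <- read_profile(f)
  expect_equal(back$values, prof$values)
  expect_equal(back$n_anchors, prof$n_anchors)
  expect_equal(back$label, prof$label)
})
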