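test_that("gene association respects the 2 kbp bound strictly", {
  genes <- expression_table(c("up", "far", "in", "down", "pt"),
                            "chr1",
                            start = c(11500, 16001, 9800, 5000, 13000),
                            end = c(12500, 17000, 10200, 6000, 13000),
                            strand = "+",
                            expression = c(3, 7, 1, 15, 2))
  a <- anchor_set("chr1", 10000, "+", id = "el")
  ee <- associate_expression(a, genes, center = FALSE, transform = "raw")
  # 'up' starts 1500 bp away: in; 'far' starts 6001 bp away: out;
  # 'in' overlaps: in; 'down' ends 4000 bp before: out;
  # 'pt' zero-length at 3000 bp: out
  expect_equal(ee$n_genes, 2L)
  expect_equal(unname(ee$y), mean(c(3, 1)))
  # exact boundary: last covered base 2000 bp away is in, 2001 bp is out
  g2 <- expression_table("b", "chr1", 6000, 8001, "+", 4)
  expect_equal(associate_expression(a, g2, center = FALSE)$n_genes, 1L)
  g3 <- expression_table("b", "chr1", 5999, 8000, "+", 4)
  expect_error(associate_expression(a, g3), "no anchor")
})

test_that("association matches the all-pairs distance oracle", {
  set.seed(41)
  n_g <- 60
  gs <- sample.int(2e5, n_g)
  genes <- expression_table(sprintf("g%d", 1:n_g), "chr1", gs,
                            gs + sample(0:3000, n_g, TRUE), "+",
                            rexp(n_g, 0.1))
  anchors <- anchor_set("chr1", sample.int(2e5, 25), "+")
  ee <- associate_expression(anchors, genes, transform = "log2")
  # oracle: explicit all-pairs distance check
  counts <- integer(25); means <- numeric(25)
  for (i in 1:25) {
    ctr <- anchors$center[i]
    d <- sapply(1:n_g, function(j) {
      if (genes$start[j] == genes$end[j]) return(abs(ctr - genes$start[j]))
      if (ctr >= genes$start[j] && ctr < genes$end[j]) 0
      else min(abs(ctr - genes$start[j]), abs(ctr - (genes$end[j] - 1)))
    })
    hit <- d <= 2000
    counts[i] <- sum(hit)
    if (any(hit)) means[i] <- mean(log2(genes$expression[hit] + 1))
  }
  expect_equal(ee$n_genes, counts[counts > 0])
  expect_equal(unname(ee$y), means[counts > 0] - mean(means[counts > 0]))
  expect_equal(ee$n_excluded, sum(counts == 0))
})

make_fixture <- function(seed = 42, W = 80, C = 40, K = 4) {
  set.seed(seed)
  X <- build_profile_matrix(matrix(rnorm(W * C), W, C))
  basis <- fix_basis_signs(extract_basis(X, K))
  S <- crossprod(X, basis$vectors)
  list(X = X, basis = basis, S = S,
       Sc = scale(S, center = TRUE, scale = FALSE))  # model's score matrix
}

test_that("PCR recovers noiseless coefficients and degenerate cases", {
  fx <- make_fixture()
  beta0 <- c(2, -1, 0.5, 3)
  y <- drop(fx$Sc %*% beta0)          # centered y, exactly in model space
  fit <- pcr_fit(fx$X, fx$basis, y)
  expect_equal(unname(fit$beta), beta0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$ideal, drop(fx$basis$vectors %*% beta0), tolerance = 1e-8)
  # y orthogonal to the score columns (and centered) -> beta = 0, R^2 = 0
  set.seed(43)
  y2 <- rnorm(ncol(fx$X))
  M <- cbind(fx$S, 1)
  y2 <- drop(y2 - M %*% solve(crossprod(M), crossprod(M, y2)))
  fit2 <- pcr_fit(fx$X, fx$basis, y2)
  expect_lt(max(abs(fit2$beta)), 1e-10)
  expect_equal(fit2$r_squared, 0, tolerance = 1e-10)
})

test_that("PCR estimates fall within 3 closed-form standard errors", {
  fx <- make_fixture(seed = 44, W = 120, C = 90)
  beta0 <- c(1.5, -2, 0.8, 0.3)
  mu <- drop(fx$Sc %*% beta0)
  sig <- 0.1 * sqrt(sum(mu^2)) / sqrt(length(mu))
  set.seed(45)
  y <- mu + rnorm(length(mu), 0, sig)
  fit <- pcr_fit(fx$X, fx$basis, y)
  se <- sig * sqrt(diag(solve(crossprod(fx$Sc))))  # LS sampling oracle
  expect_true(all(abs(fit$beta - beta0) <= 3 * se))
  # LS identity: R^2 equals squared Pearson on centered y
  yc <- y - mean(y)
  fitc <- pcr_fit(fx$X, fx$basis, yc)
  expect_equal(fitc$r_squared, fitc$pearson^2, tolerance = 1e-10)
  expect_error(pcr_fit(fx$X[, 1:3], fx$basis, rnorm(3)), "singular")
})

test_that("ridge: shrinkage limit, lambda = 0 vs pseudo-inverse, duplication", {
  set.seed(46)
  W <- 6; C <- 25
  X <- matrix(rnorm(W * C), W, C)
  y <- rnorm(C); y <- y - mean(y)
  norms <- sapply(10^seq(-2, 5), function(l) ridge_fit(X, y, l)$beta_norm)
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], 1e-3 * norms[1])
  # lambda = 0 on a full-row-rank instance equals pseudo-inverse LS
  b0 <- ridge_fit(X, y, 0)$beta
  expect_equal(b0, drop(pinv(t(X)) %*% y), tolerance = 1e-8)
  # duplicating columns and y entries: unchanged at lambda = 0,
  # and beta(X', y', 2*lambda) == beta(X, y, lambda) in general
  Xd <- cbind(X, X); yd <- c(y, y)
  expect_equal(ridge_fit(Xd, yd, 0)$beta, b0, tolerance = 1e-8)
  expect_equal(ridge_fit(Xd, yd, 2 * 0.7)$beta,
               ridge_fit(X, y, 0.7)$beta, tolerance = 1e-8)
  # under-determined at lambda = 0 is refused with guidance
  expect_error(ridge_fit(matrix(rnorm(40), 10, 4), rnorm(4), 0),
               "lambda > 0")
})

test_that("ridge primal and dual forms agree on random instances", {
  for (seed in 1:3) {
    set.seed(seed)
    W <- sample(10:60, 1); C <- sample(10:60, 1)
    X <- matrix(rnorm(W * C), W, C)
    y <- rnorm(C)
    for (l in c(0.05, 1, 50)) {
      expect_lt(max(abs(ridge_fit(X, y, l, method = "primal")$beta -
                        ridge_fit(X, y, l, method = "dual")$beta)), 1e-8)
    }
  }
})

test_that("ridge path sweeps lambdas in order with planted dominance", {
  sim <- simulate_profile_matrix(300, 0.10, seed = 47)
  X <- build_profile_matrix(sim$profiles)
  ex <- simulate_expression(sim, snr = 10, seed = 48)
  basis <- fix_basis_signs(extract_basis(X, 5))
  rp <- ridge_path(X, ex$y, basis = basis)
  expect_equal(rp$lambdas, 10^seq(-2, 3))
  norms <- sapply(rp$results, `[[`, "beta_norm")
  expect_true(all(diff(norms) <= 0))
  # expression planted on patterns 1 and 5: their weights dominate 2-4
  for (r in rp$results) {
    w <- abs(r$weights)
    expect_gt(min(w[c(1, 5)]), max(w[2:4]))
  }
  # singleton path equals ridge_fit
  rp1 <- ridge_path(X, ex$y, lambdas = 3, basis = basis)
  expect_equal(rp1$results[[1]]$beta, ridge_fit(X, ex$y, 3)$beta)
})

test_that("regression reports serialize with summary blocks", {
  fx <- make_fixture(seed = 49, W = 60, C = 20)
  set.seed(50)
  y <- drop(fx$Sc %*% c(1, 0, 0, -1)) + 0.01 * rnorm(20)
  fit <- pcr_fit(fx$X, fx$basis, y)
  f <- tempfile(fileext = ".tsv"); fi <- tempfile(fileext = ".tsv")
  write_regression_report(fit, y, f, ideal_path = fi)
  lines <- readLines(f)
  expect_match(lines[1], "pcr")
  expect_match(lines[2], "r_squared")
  body <- read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(body), 20)
  expect_equal(body$fitted, unname(fit$fitted), tolerance = 1e-12)
  ideal <- read.table(fi, header = TRUE, sep = "\t")
  expect_equal(ideal$value, fit$ideal, tolerance = 1e-12)
})
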