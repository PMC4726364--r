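# Expression regression: associate gene expression to anchors, then
# recover the positioning shape predictive of expression by principal-
# component regression (pattern space) and ridge regression (position
# space).

#' Associate gene expression with anchors
#'
#' A gene is associated with an anchor when the anchor center lies within
#' `max_dist` bp of the gene body (distance 0 inside the body; zero-length
#' gene loci are treated as the point `start`). Each anchor's expression
#' value is the arithmetic mean of its associated genes' (optionally
#' log-transformed) expression; values are then centered across anchors
#' so downstream regressions need no intercept.
#'
#' @param anchors An [anchor_set()].
#' @param genes An [expression_table()].
#' @param max_dist Association distance in bp (default 2000). The bound
#'   is inclusive: a gene exactly `max_dist` away is associated, one at
#'   `max_dist + 1` is not.
#' @param transform `"log2"` (default, `log2(level + 1)` before
#'   averaging) or `"raw"`.
#' @param center Center the per-anchor means across anchors.
#' @return An `ElementExpression`: list with `y` (named by anchor id),
#'   `n_genes` per anchor, `keep` (indices of anchors retained),
#'   `n_excluded` (anchors with zero associated genes), `transform`,
#'   `centered`.
#' @export
associate_expression <- function(anchors, genes, max_dist = 2000,
                                 transform = c("log2", "raw"),
                                 center = TRUE) {
  transform <- match.arg(transform)
  if (!nrow(anchors) || !nrow(genes)) stop("empty anchors or gene table")
  e <- if (transform == "log2") log2(genes$expression + 1) else
    genes$expression
  y <- numeric(nrow(anchors))
  ng <- integer(nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    same <- genes$chrom == anchors$chrom[i]
    if (!any(same)) next
    ctr <- anchors$center[i]
    gs <- genes$start[same]; ge <- genes$end[same]
    zero_len <- ge == gs
    d <- pmax(0, gs - ctr, ctr - ge + 1)
    d[zero_len] <- abs(ctr - gs[zero_len])
    assoc <- d <= max_dist
    ng[i] <- sum(assoc)
    if (ng[i] > 0) y[i] <- mean(e[same][assoc])
  }
  keep <- which(ng > 0)
  if (!length(keep)) stop("no anchor has an associated gene within ",
                          max_dist, " bp")
  y <- y[keep]
  names(y) <- anchors$id[keep]
  if (center) y <- y - mean(y)
  structure(list(y = y, n_genes = ng[keep], keep = keep,
                 n_excluded = nrow(anchors) - length(keep),
                 transform = transform, centered = center),
            class = "ElementExpression")
}

.as_y <- function(y) {
  if (inherits(y, "ElementExpression")) y$y else as.numeric(y)
}

#' Principal-component regression of expression on pattern scores
#'
#' With score matrix `S = X^T P` (elements x patterns), the least-squares
#' estimator is `beta = (S^T S)^{-1} S^T y`; the fitted "ideal" shape in
#' position space is `P beta`. Expression `y` should be centered (see
#' [associate_expression()]) and no intercept is fitted; to keep that
#' model internally consistent the score columns are centered across
#' elements as well (equivalent to fitting and absorbing an intercept),
#' which makes `R^2` equal the squared Pearson correlation exactly.
#'
#' @param X A [build_profile_matrix()] result whose columns align 1:1
#'   with the entries of `y`.
#' @param basis A `PatternBasis`.
#' @param y An `ElementExpression` or centered numeric vector.
#' @return A `PCRResult`: list with `beta` (pattern weights), `fitted`,
#'   `r_squared`, `pearson`, `spearman`, `ideal` (length-W shape).
#' @export
pcr_fit <- function(X, basis, y) {
  y <- .as_y(y)
  P <- .basis_vectors(basis)
  if (ncol(X) != length(y)) stop("ncol(X) must equal length(y)")
  S <- crossprod(X, P)                        # C x K scores
  S <- scale(S, center = TRUE, scale = FALSE)
  StS <- crossprod(S)
  if (rcond(StS) < 1e-12) {
    stop("score matrix S^T S is numerically singular; reduce K")
  }
  beta <- drop(solve(StS, crossprod(S, y)))
  names(beta) <- colnames(P)
  fitted <- drop(S %*% beta)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - sum((y - fitted)^2) / ss_tot
  pearson <- if (stats::sd(fitted) > 0) stats::cor(fitted, y) else NA_real_
  spearman <- if (stats::sd(fitted) > 0) {
    stats::cor(fitted, y, method = "spearman")   # average ranks on ties
  } else NA_real_
  structure(list(beta = beta, fitted = fitted, r_squared = r2,
                 pearson = pearson, spearman = spearman,
                 ideal = drop(P %*% beta), scores = S),
            class = "PCRResult")
}

#' @export
print.PCRResult <- function(x, ...) {
  cat(sprintf("PCRResult: R^2 = %.3f, Pearson = %.3f, Spearman = %.3f\n",
              x$r_squared, x$pearson, x$spearman))
  cat("  pattern weights:", paste(sprintf("%+.3f", x$beta), collapse = " "),
      "\n")
  invisible(x)
}

#' Ridge regression of expression on per-position densities
#'
#' Solves `beta = (X X^T + lambda I)^{-1} X y` over the W positions; the
#' resulting `beta` is the "ideal" positioning shape for expression. When
#' there are fewer elements than positions (C < W, the usual
#' under-determined case) the equivalent dual form
#' `beta = X (X^T X + lambda I)^{-1} y` is solved in C x C instead.
#'
#' @param X Profile matrix (`W x C`), columns aligned with `y`.
#' @param y An `ElementExpression` or centered numeric vector.
#' @param lambda Nonnegative ridge penalty. `lambda = 0` requires
#'   `X X^T` to be invertible (needs C >= W and full row rank), else an
#'   error directs to `lambda > 0`.
#' @param basis Optional `PatternBasis`; when supplied, pattern weights
#'   `beta . P_i` are reported.
#' @param method `"auto"` picks primal/dual by dimensions; `"primal"` or
#'   `"dual"` force a form (they agree to numerical precision).
#' @return A `RidgeResult`: list with `lambda`, `beta` (length W),
#'   `fitted`, `weights` (or NULL), `beta_norm`.
#' @export
ridge_fit <- function(X, y, lambda, basis = NULL,
                      method = c("auto", "primal", "dual")) {
  method <- match.arg(method)
  y <- .as_y(y)
  W <- nrow(X); C <- ncol(X)
  if (C != length(y)) stop("ncol(X) must equal length(y)")
  if (lambda < 0) stop("lambda must be >= 0")
  if (lambda == 0) {
    XXt <- tcrossprod(X)
    if (C < W || rcond(XXt) < 1e-12) {
      stop("X X^T is rank-deficient at lambda = 0; use lambda > 0")
    }
    beta <- drop(solve(XXt, X %*% y))
  } else if (method == "dual" || (method == "auto" && C < W)) {
    beta <- drop(X %*% solve(crossprod(X) + diag(lambda, C), y))
  } else {
    beta <- drop(solve(tcrossprod(X) + diag(lambda, W), X %*% y))
  }
  weights <- if (!is.null(basis)) {
    drop(crossprod(.basis_vectors(basis), beta))
  }
  structure(list(lambda = lambda, beta = beta,
                 fitted = drop(crossprod(X, beta)),
                 weights = weights, beta_norm = sqrt(sum(beta^2))),
            class = "RidgeResult")
}

#' Ridge path over a lambda sweep
#'
#' One [ridge_fit()] per penalty, default sweep `10^-2 .. 10^3`; pattern
#' weights across the path are collected into a table when a basis is
#' supplied.
#'
#' @inheritParams ridge_fit
#' @param lambdas Penalty grid, in order.
#' @return A `RidgePath`: list with `results` (list of `RidgeResult`),
#'   `lambdas`, and `weight_table` (lambdas x patterns, or NULL).
#' @export
ridge_path <- function(X, y, lambdas = 10^seq(-2, 3), basis = NULL) {
  results <- lapply(lambdas, function(l) ridge_fit(X, y, l, basis = basis))
  wt <- if (!is.null(basis)) {
    t(vapply(results, function(r) r$weights,
             numeric(ncol(.basis_vectors(basis)))))
  }
  if (!is.null(wt)) {
    dimnames(wt) <- list(format(lambdas), colnames(.basis_vectors(basis)))
  }
  structure(list(results = results, lambdas = lambdas, weight_table = wt),
            class = "RidgePath")
}

#' Write a regression report
#'
#' Tab-delimited per-element observed/fitted table after a `#` summary
#' block (R^2, Pearson, Spearman); the ideal profile is written alongside
#' in [write_profile()] format so it can be fed to shape analysis.
#'
#' @param fit A `PCRResult` or `RidgeResult`.
#' @param y The `ElementExpression` (or numeric vector) used in the fit.
#' @param path Output report file.
#' @param ideal_path Optional path for the ideal-profile vector.
#' @export
write_regression_report <- function(fit, y, path, ideal_path = NULL) {
  yv <- .as_y(y)
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(fit, "PCRResult")) {
    writeLines(c("# model: pcr",
                 sprintf("# r_squared: %s", format(fit$r_squared, digits = 17)),
                 sprintf("# pearson: %s", format(fit$pearson, digits = 17)),
                 sprintf("# spearman: %s", format(fit$spearman, digits = 17)),
                 sprintf("# beta: %s",
                         paste(format(fit$beta, digits = 17), collapse = "\t"))),
               con)
    ideal <- fit$ideal
  } else {
    writeLines(c("# model: ridge",
                 sprintf("# lambda: %s", format(fit$lambda, digits = 17)),
                 sprintf("# beta_norm: %s", format(fit$beta_norm, digits = 17)),
                 if (!is.null(fit$weights))
                   sprintf("# pattern_weights: %s",
                           paste(format(fit$weights, digits = 17),
                                 collapse = "\t"))),
               con)
    ideal <- fit$beta
  }
  writeLines("element\ty\tfitted", con)
  labs <- names(yv) %||% sprintf("element_%d", seq_along(yv))
  utils::write.table(data.frame(labs, format(yv, digits = 17),
                                format(fit$fitted, digits = 17)),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(ideal_path)) {
    w <- (length(ideal) - 1) / 2
    # ideal shapes may dip negative: store shifted-to-zero with an offset note
    utils::write.table(data.frame(offset = -w:w,
                                  value = format(ideal, digits = 17)),
                       ideal_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
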