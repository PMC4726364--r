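# Pattern basis: normalized profile matrix, principal-component pattern
# extraction, sign fixing, weight decomposition, cross-dataset comparison.

# center to mean 0 / scale to unit Euclidean norm; error on constant input
.normalize_column <- function(v, what = "profile") {
  v <- v - mean(v)
  n2 <- sqrt(sum(v^2))
  if (n2 < .Machine$double.eps * length(v)) {
    stop("constant (zero-variance) ", what, " cannot be normalized")
  }
  v / n2
}

#' Build the normalized profile matrix
#'
#' Assembles density profiles as columns of a `W x C` matrix, each column
#' centered to mean 0 and scaled to unit Euclidean norm. With this
#' normalization the squared scores of a column on the full principal-
#' component spectrum sum to 1, so squared weights read directly as
#' composition fractions.
#'
#' @param profiles A list of `DensityProfile`s (or numeric vectors of a
#'   common length), or a numeric matrix with one profile per column.
#' @return A `ProfileMatrix` (numeric matrix, columns normalized; labels
#'   as column names).
#' @export
build_profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) {
    X <- profiles
  } else {
    vals <- lapply(profiles, function(p) {
      if (inherits(p, "DensityProfile")) p$values else as.numeric(p)
    })
    lens <- lengths(vals)
    if (length(unique(lens)) != 1) stop("profiles have differing lengths")
    X <- do.call(cbind, vals)
    labs <- vapply(seq_along(profiles), function(i) {
      p <- profiles[[i]]
      if (inherits(p, "DensityProfile") && !is.null(p$label)) p$label
      else sprintf("profile_%d", i)
    }, character(1))
    colnames(X) <- labs
  }
  if (ncol(X) < 2) stop("need at least 2 profiles")
  labs <- colnames(X)
  if (is.null(labs)) labs <- sprintf("profile_%d", seq_len(ncol(X)))
  for (j in seq_len(ncol(X))) {
    X[, j] <- tryCatch(.normalize_column(X[, j]),
                       error = function(e) stop("column '", labs[j], "': ",
                                                conditionMessage(e)))
  }
  colnames(X) <- labs
  class(X) <- c("ProfileMatrix", class(X))
  X
}

#' Extract the principal-component pattern basis
#'
#' Principal components of the offset-by-offset covariance
#' `1/(C-1) X X^T` of the normalized profile matrix, computed via the SVD
#' of `X` for numerical stability (a test asserts equivalence with the
#' explicit eigenproblem). Eigenvalues and contribution ratios are
#' reported for the full spectrum; the basis keeps the top `K` patterns.
#'
#' @param X A [build_profile_matrix()] result (`W x C`).
#' @param K Number of patterns to keep, `1 <= K <= min(W, C)`; default 5.
#' @return A `PatternBasis`: list with `vectors` (`W x K`, orthonormal
#'   columns), `eigenvalues` (full spectrum, nonincreasing), `contrib`,
#'   `cum_contrib`, `K`, `flips`, `signs_fixed`.
#' @export
extract_basis <- function(X, K = 5) {
  W <- nrow(X); C <- ncol(X)
  if (K < 1 || K > min(W, C)) {
    stop("K must be between 1 and min(W, C) = ", min(W, C))
  }
  sv <- svd(X, nu = min(W, C), nv = 0)
  ev <- sv$d^2 / (C - 1)
  if (any(diff(ev) == 0)) {
    message("tied eigenvalues; component order follows first occurrence")
  }
  contrib <- ev / sum(ev)
  vectors <- sv$u[, seq_len(K), drop = FALSE]
  colnames(vectors) <- sprintf("pattern_%d", seq_len(K))
  structure(list(vectors = vectors, eigenvalues = ev, contrib = contrib,
                 cum_contrib = cumsum(contrib), K = as.integer(K),
                 W = W, flips = rep(1, K), signs_fixed = FALSE),
            class = "PatternBasis")
}

#' @export
print.PatternBasis <- function(x, ...) {
  cat(sprintf("PatternBasis: K=%d patterns over %d offsets; signs %s\n",
              x$K, x$W, if (isTRUE(x$signs_fixed)) "fixed" else "raw"))
  if (!all(is.na(x$eigenvalues))) {
    cat(sprintf("  top-%d cumulative contribution ratio: %.3f\n",
                x$K, x$cum_contrib[x$K]))
  }
  invisible(x)
}

#' Fix pattern signs
#'
#' PCA eigenvector signs are arbitrary; this pins each pattern so that its
#' largest-magnitude element is positive (i.e. the pattern's dominant
#' feature reads as high nucleosome density). Idempotent; applied flips
#' are recorded in `flips` so downstream scores stay consistent.
#'
#' @param basis A `PatternBasis`.
#' @return The basis with adjusted `vectors`, updated `flips`, and
#'   `signs_fixed = TRUE`.
#' @export
fix_basis_signs <- function(basis) {
  V <- basis$vectors
  flips <- vapply(seq_len(ncol(V)), function(i) {
    v <- V[, i]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  basis$vectors <- sweep(V, 2, flips, `*`)
  basis$flips <- basis$flips * flips
  basis$signs_fixed <- TRUE
  basis
}

.basis_vectors <- function(b) {
  if (inherits(b, "PatternBasis")) b$vectors
  else if (is.matrix(b)) b
  else stop("expected a PatternBasis or a matrix of pattern columns")
}

#' Decompose a profile into pattern weights
#'
#' The profile is centered and unit-normalized, then projected on each
#' pattern: `w_i = <profile, pattern_i>`. Squared weights are composition
#' ratios; `1 - sum(w_i^2)` is the share unexplained by the K patterns.
#'
#' @param profile A `DensityProfile` or numeric vector of length `W`.
#' @param basis A `PatternBasis`.
#' @param label Label for the decomposition (defaults to the profile's).
#' @return A `Decomposition`: list with `label`, `weights`, `ratios`,
#'   `remainder`.
#' @export
decompose_profile <- function(profile, basis, label = NULL) {
  v <- if (inherits(profile, "DensityProfile")) profile$values else
    as.numeric(profile)
  P <- .basis_vectors(basis)
  if (length(v) != nrow(P)) stop("profile length does not match basis")
  if (is.null(label) && inherits(profile, "DensityProfile")) {
    label <- profile$label
  }
  v <- .normalize_column(v)
  w <- drop(crossprod(P, v))
  names(w) <- colnames(P)
  structure(list(label = label, weights = w, ratios = w^2,
                 remainder = max(0, 1 - sum(w^2))),
            class = "Decomposition")
}

#' @export
print.Decomposition <- function(x, ...) {
  cat(sprintf("Decomposition%s:\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'")))
  cat("  weights:", paste(sprintf("%+.3f", x$weights), collapse = " "), "\n")
  cat(sprintf("  reconstructed: %.1f%%, remainder: %.1f%%\n",
              100 * sum(x$ratios), 100 * x$remainder))
  invisible(x)
}

#' Fraction of a normalized profile reconstructed by the pattern weights
#'
#' Sum of squared weights; because profiles are unit-normalized this is
#' the fraction of the profile's (centered) energy captured by the basis.
#'
#' @param d A `Decomposition`, or a bare numeric vector of weights.
#' @return A fraction in `[0, 1]` (up to rounding of supplied weights).
#' @export
reconstruction_fraction <- function(d) {
  w <- if (inherits(d, "Decomposition")) d$weights else as.numeric(d)
  sum(w^2)
}

#' Compare two pattern bases
#'
#' Entry `(i, j)` of the table is the squared inner product
#' `(P_i . Q_j)^2`; the containment of pattern `P_i` in the span of `Q`
#' is the row sum, in `[0, 1]` when `Q` is orthonormal.
#'
#' @param P,Q `PatternBasis` objects (or pattern matrices) over the same
#'   number of offsets.
#' @return A `BasisSimilarity`: list with `table` (`K_P x K_Q`) and
#'   `containment` (length `K_P`).
#' @export
basis_similarity <- function(P, Q) {
  Pv <- .basis_vectors(P); Qv <- .basis_vectors(Q)
  if (nrow(Pv) != nrow(Qv)) stop("bases are over different offset grids")
  tab <- crossprod(Pv, Qv)^2
  rownames(tab) <- colnames(Pv); colnames(tab) <- colnames(Qv)
  structure(list(table = tab, containment = rowSums(tab)),
            class = "BasisSimilarity")
}

#' Write a pattern basis as TSV
#'
#' Header lines carry eigenvalues, contribution ratios and the sign
#' convention; body is the `W x K` pattern matrix with an offset column.
#'
#' @param basis A `PatternBasis`.
#' @param path Output file.
#' @param window Half-window for offset labels.
#' @export
write_basis <- function(basis, path, window = (basis$W - 1) / 2) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) paste(format(x, digits = 17), collapse = "\t")
  writeLines(c(sprintf("# K: %d", basis$K),
               sprintf("# signs_fixed: %s", isTRUE(basis$signs_fixed)),
               sprintf("# flips: %s", paste(basis$flips, collapse = "\t")),
               sprintf("# eigenvalues: %s", fmt(basis$eigenvalues[seq_len(basis$K)])),
               sprintf("# contrib: %s", fmt(basis$contrib[seq_len(basis$K)])),
               sprintf("# cum_contrib_K: %s",
                       format(basis$cum_contrib[basis$K], digits = 17)),
               paste(c("offset", colnames(basis$vectors)), collapse = "\t")),
             con)
  utils::write.table(cbind(-window:window,
                           format(basis$vectors, digits = 17)),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  get <- function(key) {
    m <- grep(sprintf("^# %s:", key), meta, value = TRUE)
    if (!length(m)) return(NULL)
    strsplit(trimws(sub(sprintf("^# %s:", key), "", m[1])), "\t")[[1]]
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t", check.names = FALSE)
  V <- as.matrix(df[, -1, drop = FALSE])
  ev <- as.numeric(get("eigenvalues"))
  contrib <- as.numeric(get("contrib"))
  structure(list(vectors = V, eigenvalues = ev, contrib = contrib,
                 cum_contrib = cumsum(contrib), K = ncol(V), W = nrow(V),
                 flips = as.numeric(get("flips")),
                 signs_fixed = identical(get("signs_fixed"), "TRUE")),
            class = "PatternBasis")
}

#' Write decompositions as a TSV table
#'
#' One row per profile: label, weights, composition ratios, remainder —
#' the machine-readable form of per-element pattern pie charts.
#'
#' @param decomps A list of `Decomposition`s.
#' @param path Output file.
#' @export
write_decompositions <- function(decomps, path) {
  K <- length(decomps[[1]]$weights)
  rows <- lapply(decomps, function(d) {
    c(label = if (is.null(d$label)) "NA" else d$label,
      stats::setNames(format(d$weights, digits = 17), sprintf("w%d", 1:K)),
      stats::setNames(format(d$ratios, digits = 17), sprintf("ratio%d", 1:K)),
      remainder = format(d$remainder, digits = 17))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
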