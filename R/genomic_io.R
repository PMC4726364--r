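# Genomic I/O: containers and plain-text readers/writers.
#
# All coordinates are 0-based, half-open [start, end) internally (BED-native).
# Inputs in other conventions are converted at the boundary.

#' Genome table
#'
#' Chromosome names and lengths. Used to skip anchors whose aggregation
#' window would leave the chromosome.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param len Positive chromosome lengths in bp.
#' @return A `GenomeTable`: data frame with columns `chrom`, `length`.
#' @export
genome_table <- function(chrom, len) {
  chrom <- as.character(chrom)
  len <- as.numeric(len)
  if (length(chrom) != length(len)) {
    stop("`chrom` and `len` must have the same length")
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("chromosome lengths must be positive and finite")
  }
  structure(data.frame(chrom = chrom, length = len,
                       stringsAsFactors = FALSE),
            class = c("GenomeTable", "data.frame"))
}

.chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) {
    stop("chromosome not in genome table: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  genome$length[i]
}

#' Anchor set
#'
#' Point anchors (e.g. cis-regulatory element centers, ChIP-seq peak
#' summits, TSSs) around which density profiles are aggregated.
#'
#' @param chrom Chromosome names.
#' @param center 0-based center positions (bp).
#' @param strand One of `"+"`, `"-"`, `"."` per anchor.
#' @param id Anchor labels; generated when missing.
#' @param group Optional group label (element name / condition) per anchor.
#' @param genome Optional [genome_table()] used to bound-check centers.
#' @return An `AnchorSet` data frame with columns
#'   `chrom`, `center`, `strand`, `id`, `group`.
#' @export
anchor_set <- function(chrom, center, strand = ".", id = NULL,
                       group = NA_character_, genome = NULL) {
  n <- length(center)
  chrom <- rep_len(as.character(chrom), n)
  center <- as.numeric(center)
  strand <- rep_len(as.character(strand), n)
  if (is.null(id)) id <- sprintf("anchor_%d", seq_len(n))
  id <- rep_len(as.character(id), n)
  group <- rep_len(as.character(group), n)
  if (any(!is.finite(center)) || any(center < 0)) {
    stop("anchor centers must be finite and >= 0")
  }
  if (any(center != floor(center))) stop("anchor centers must be integral")
  bad <- !strand %in% c("+", "-", ".")
  if (any(bad)) {
    stop("invalid strand symbol(s): ", paste(unique(strand[bad]), collapse = ", "))
  }
  if (!is.null(genome)) {
    if (any(center >= .chrom_length(genome, chrom))) {
      stop("anchor center beyond chromosome end")
    }
  }
  structure(data.frame(chrom = chrom, center = center, strand = strand,
                       id = id, group = group, stringsAsFactors = FALSE),
            class = c("AnchorSet", "data.frame"))
}

#' Fragment set
#'
#' Sequenced fragments as half-open intervals; for MNase-seq these are
#' (approximately) mono-nucleosome fragments whose midpoints estimate dyads.
#'
#' @param chrom,start,end Fragment coordinates (0-based, half-open).
#' @return A `FragmentSet` data frame (`chrom`, `start`, `end`) whose row
#'   count is the total fragment count used for RPM normalization.
#' @export
fragment_set <- function(chrom, start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  chrom <- rep_len(as.character(chrom), length(start))
  if (length(start) != length(end)) {
    stop("start and end must have equal length")
  }
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    stop("fragment coordinates must be finite")
  }
  if (any(start < 0)) stop("fragment start must be >= 0")
  if (any(end <= start)) stop("fragment end must be > start")
  structure(data.frame(chrom = chrom, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("FragmentSet", "data.frame"))
}

#' Expression table
#'
#' Gene models plus a nonnegative expression level on a normalized scale.
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom,start,end Gene body coordinates, 0-based half-open.
#'   `start == end` is accepted as a degenerate zero-length locus (treated
#'   as the point `start` for distance computations).
#' @param strand Gene strand.
#' @param expression Nonnegative finite expression levels.
#' @return An `ExpressionTable` data frame.
#' @export
expression_table <- function(gene_id, chrom, start, end, strand, expression) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  start <- as.numeric(start); end <- as.numeric(end)
  expression <- as.numeric(expression)
  if (any(!is.finite(expression)) || any(expression < 0)) {
    stop("expression levels must be finite and >= 0")
  }
  if (any(end < start)) stop("gene end must be >= start")
  strand <- as.character(strand)
  if (any(!strand %in% c("+", "-", "."))) stop("invalid gene strand symbol")
  structure(data.frame(gene_id = gene_id, chrom = as.character(chrom),
                       start = start, end = end, strand = strand,
                       expression = expression, stringsAsFactors = FALSE),
            class = c("ExpressionTable", "data.frame"))
}

# split a text file into whitespace-delimited fields, skipping BED headers
.read_table_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(fields = strsplit(trimws(lines[keep]), "[ \t]+"),
       lineno = which(keep))
}

.num_or_stop <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    stop(sprintf("malformed %s at line %d: '%s' is not numeric",
                 what, lineno, x[which(is.na(v))[1]]))
  }
  v
}

#' Integer midpoint of a half-open interval
#'
#' Ties on even-length intervals break toward the lower coordinate:
#' `floor((start + end) / 2)`.
#'
#' @param start,end 0-based half-open interval bounds.
#' @export
interval_center <- function(start, end) floor((start + end) / 2)

#' Read anchors from a BED file
#'
#' Reduces each BED interval to a single anchor point. BED3 or better;
#' column 4 supplies the id and column 6 the strand when present.
#'
#' @param path BED3+ file.
#' @param center_rule `"midpoint"` (default, `floor((start+end)/2)`),
#'   `"start"`, or `"end"` (last covered base, `end - 1`).
#' @param group Optional group label applied to every anchor.
#' @param genome Optional [genome_table()] for bound checks.
#' @return An [anchor_set()].
#' @export
read_bed_anchors <- function(path, center_rule = c("midpoint", "start", "end"),
                             group = NA_character_, genome = NULL) {
  center_rule <- match.arg(center_rule)
  tl <- .read_table_lines(path)
  if (!length(tl$fields)) stop("no records in BED file: ", path)
  n <- length(tl$fields)
  chrom <- character(n); ctr <- numeric(n)
  strand <- character(n); id <- character(n)
  for (i in seq_len(n)) {
    f <- tl$fields[[i]]; ln <- tl$lineno[i]
    if (length(f) < 3) stop(sprintf("malformed BED at line %d: fewer than 3 columns", ln))
    s <- .num_or_stop(f[2], "BED start", ln)
    e <- .num_or_stop(f[3], "BED end", ln)
    if (e <= s || s < 0) {
      stop(sprintf("malformed BED at line %d: invalid interval [%s, %s)", ln, f[2], f[3]))
    }
    chrom[i] <- f[1]
    ctr[i] <- switch(center_rule,
                     midpoint = interval_center(s, e),
                     start = s,
                     end = e - 1)
    id[i] <- if (length(f) >= 4) f[4] else sprintf("anchor_%d", i)
    strand[i] <- if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "."
  }
  anchor_set(chrom, ctr, strand, id, group = group, genome = genome)
}

#' Read anchors from an ENCODE narrowPeak file
#'
#' Anchor center is `start + summit_offset` (column 10) when the summit
#' offset is nonnegative, else the interval midpoint.
#'
#' @param path 10-column narrowPeak file.
#' @param group,genome As in [read_bed_anchors()].
#' @return An [anchor_set()], record order preserved.
#' @export
read_narrowpeak <- function(path, group = NA_character_, genome = NULL) {
  tl <- .read_table_lines(path)
  if (!length(tl$fields)) stop("no records in narrowPeak file: ", path)
  n <- length(tl$fields)
  chrom <- character(n); ctr <- numeric(n)
  strand <- character(n); id <- character(n)
  for (i in seq_len(n)) {
    f <- tl$fields[[i]]; ln <- tl$lineno[i]
    if (length(f) != 10) {
      stop(sprintf("malformed narrowPeak at line %d: expected 10 columns, got %d",
                   ln, length(f)))
    }
    s <- .num_or_stop(f[2], "narrowPeak start", ln)
    e <- .num_or_stop(f[3], "narrowPeak end", ln)
    summit <- .num_or_stop(f[10], "narrowPeak summit", ln)
    if (e <= s || s < 0) {
      stop(sprintf("malformed narrowPeak at line %d: invalid interval", ln))
    }
    chrom[i] <- f[1]
    ctr[i] <- if (summit >= 0) s + summit else interval_center(s, e)
    id[i] <- if (f[4] != ".") f[4] else sprintf("peak_%d", i)
    strand[i] <- if (f[6] %in% c("+", "-")) f[6] else "."
  }
  anchor_set(chrom, ctr, strand, id, group = group, genome = genome)
}

#' Read fragments
#'
#' @param path BED3+ file of fragment intervals, or a SAM text file.
#' @param format `"bed"` or `"sam"`. SAM support is minimal: properly
#'   paired records with positive TLEN yield one fragment per pair
#'   (template span); unpaired mapped reads are extended to
#'   `fragment_length` from their 5' end.
#' @param fragment_length Extension length for unpaired SAM reads.
#' @return A [fragment_set()]. Records with `end <= start` are skipped and
#'   their count reported via a message and the `"n_skipped"` attribute.
#' @export
read_fragments <- function(path, format = c("bed", "sam"),
                           fragment_length = 164) {
  format <- match.arg(format)
  if (format == "bed") {
    tl <- .read_table_lines(path)
    if (!length(tl$fields)) stop("no fragment records in: ", path)
    n <- length(tl$fields)
    chrom <- character(n); s <- numeric(n); e <- numeric(n)
    for (i in seq_len(n)) {
      f <- tl$fields[[i]]; ln <- tl$lineno[i]
      if (length(f) < 3) stop(sprintf("malformed BED at line %d: fewer than 3 columns", ln))
      chrom[i] <- f[1]
      s[i] <- .num_or_stop(f[2], "fragment start", ln)
      e[i] <- .num_or_stop(f[3], "fragment end", ln)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    if (!length(lines)) stop("no alignment records in: ", path)
    fields <- strsplit(lines, "\t")
    chrom <- character(0); s <- numeric(0); e <- numeric(0)
    for (f in fields) {
      flag <- as.integer(f[2])
      if (is.na(flag) || bitwAnd(flag, 4L) > 0L) next   # unmapped
      pos <- as.numeric(f[4]) - 1                        # SAM is 1-based
      if (bitwAnd(flag, 1L) > 0L) {                      # paired
        tlen <- as.numeric(f[9])
        if (bitwAnd(flag, 2L) > 0L && !is.na(tlen) && tlen > 0) {
          chrom <- c(chrom, f[3]); s <- c(s, pos); e <- c(e, pos + tlen)
        }
      } else {                                           # single-end: extend
        rl <- nchar(f[10])
        if (bitwAnd(flag, 16L) > 0L) {
          e2 <- pos + rl; chrom <- c(chrom, f[3])
          s <- c(s, e2 - fragment_length); e <- c(e, e2)
        } else {
          chrom <- c(chrom, f[3]); s <- c(s, pos); e <- c(e, pos + fragment_length)
        }
      }
    }
  }
  ok <- is.finite(s) & is.finite(e) & e > s & s >= 0
  if (any(!ok)) {
    message(sum(!ok), " invalid fragment record(s) skipped")
  }
  if (!any(ok)) stop("zero valid fragments in: ", path)
  fs <- fragment_set(chrom[ok], s[ok], e[ok])
  attr(fs, "n_skipped") <- sum(!ok)
  fs
}

#' Filter fragments by length
#'
#' @param fragments A [fragment_set()].
#' @param min_len,max_len Inclusive length bounds in bp.
#' @export
filter_fragments <- function(fragments, min_len = 0, max_len = Inf) {
  len <- fragments$end - fragments$start
  keep <- len >= min_len & len <= max_len
  if (!any(keep)) stop("no fragments left after length filtering")
  fragment_set(fragments$chrom[keep], fragments$start[keep], fragments$end[keep])
}

#' Read a gene expression table
#'
#' Tab-delimited with a header naming at least
#' `gene_id`, `chrom`, `start`, `end`, `strand`, `expression`.
#'
#' @param path File path.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  need <- c("gene_id", "chrom", "start", "end", "strand", "expression")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("expression table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!nrow(df)) stop("no records in expression table: ", path)
  expression_table(df$gene_id, df$chrom, df$start, df$end, df$strand,
                   df$expression)
}

#' @rdname read_expression_table
#' @param x An `ExpressionTable`.
#' @export
write_expression_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write anchors as BED6 (1 bp intervals at the center)
#' @param x An `AnchorSet`.
#' @param path Output file.
#' @export
write_anchors_bed <- function(x, path) {
  bed <- data.frame(x$chrom, format(x$center, scientific = FALSE, trim = TRUE),
                    format(x$center + 1, scientific = FALSE, trim = TRUE),
                    x$id, 0L, x$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write fragments as BED3
#' @param x A `FragmentSet`.
#' @param path Output file.
#' @export
write_fragments_bed <- function(x, path) {
  bed <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                    format(x$end, scientific = FALSE, trim = TRUE))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a genome table (two-column TSV)
#' @param x A `GenomeTable`.
#' @param path File path.
#' @export
write_genome_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_table
#' @export
read_genome_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  genome_table(df$chrom, df$length)
}
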