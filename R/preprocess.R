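#' Rarefy a count table to the minimum sample depth
#'
#' Depth normalization "to the sample with the lowest number of reads":
#' each sample's reads are subsampled without replacement down to the minimum
#' observed column sum, preserving integer counts (needed downstream for
#' Good's coverage). Samples already at the minimum are returned unchanged.
#'
#' @param x a [count_table()] with integer reads (not protozoa percentages).
#' @param seed integer seed; the draw is fully reproducible.
#' @return a [count_table()] whose column sums all equal the minimum depth.
#' @export
rarefy_to_min <- function(x, seed = 1L) {
  stopifnot(inherits(x, "count_table"))
  if (x$kingdom == "protozoa")
    stopf("protozoa tables hold percentage compositions and are not rarefied")
  depths <- colSums(x$counts)
  empty <- names(depths)[depths < 1]
  if (length(empty))
    stopf("sample(s) with no reads cannot be rarefied: %s",
          paste(empty, collapse = ", "))
  m <- min(depths)
  out <- x$counts
  with_seed(seed, {
    for (j in seq_along(depths)) {
      if (depths[j] > m) {
        reads <- rep.int(seq_len(nrow(out)), out[, j])
        keep <- sample(reads, m)
        out[, j] <- tabulate(keep, nbins = nrow(out))
      }
    }
  })
  count_table(out, x$kingdom, x$lineage)
}

#' Elementwise log10(x + 1)
#'
#' The abundance transform used throughout: base-10 logarithm with a
#' pseudocount of one, so a zero count maps to 0 and 9 reads map to 1.
#'
#' @param x non-negative numeric vector or matrix.
#' @param pseudocount added before taking logs (default 1).
#' @return transformed object of the same shape.
#' @export
log10_p1 <- function(x, pseudocount = 1) {
  if (any(x < 0)) stopf("log10_p1 requires non-negative input")
  log10(x + pseudocount)
}

#' Relative abundances (columns sum to one)
#' @param x a [count_table()] or non-negative matrix (taxa x samples).
#' @return matrix of per-sample proportions.
#' @export
to_relative <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else x
  if (any(m < 0)) stopf("to_relative requires non-negative input")
  cs <- colSums(m)
  if (any(cs == 0)) stopf("sample(s) with zero total abundance")
  sweep(m, 2, cs, "/")
}

#' Per-taxon prevalence
#'
#' Fraction of (a subset of) samples in which a taxon is present, with strict
#' presence defined as count > 0.
#'
#' @param x a [count_table()] or matrix.
#' @param samples optional character vector restricting the computation.
#' @return named numeric vector in \[0, 1\].
#' @export
prevalence <- function(x, samples = NULL) {
  m <- if (inherits(x, "count_table")) x$counts else x
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(m))
    if (length(miss)) stopf("unknown sample(s): %s", paste(miss, collapse = ", "))
    m <- m[, samples, drop = FALSE]
  }
  rowMeans(m > 0)
}

#' Normalize a count table for downstream analysis
#'
#' Bundles the shared preprocessing substrate: depth normalization (seeded
#' rarefaction by default, or proportional scaling), the log10(x+1)
#' transform, and per-sample relative abundances. Protozoa percentage tables
#' are passed through with depth 100 (they are already compositions).
#'
#' @param x a [count_table()].
#' @param seed rarefaction seed.
#' @param method `"subsample"` (default; without-replacement rarefaction) or
#'   `"scale"` (proportional scaling to the minimum depth).
#' @return an object of class `normalized_table` with fields `counts`,
#'   `depth`, `log_abundance`, `rel_abundance`, plus the `count_table`
#'   annotations.
#' @export
normalize_table <- function(x, seed = 1L, method = c("subsample", "scale")) {
  stopifnot(inherits(x, "count_table"))
  method <- match.arg(method)
  if (x$kingdom == "protozoa") {
    counts <- x$counts
    depth <- 100
  } else if (method == "subsample") {
    counts <- rarefy_to_min(x, seed)$counts
    depth <- min(colSums(x$counts))
  } else {
    depth <- min(colSums(x$counts))
    counts <- sweep(x$counts, 2, colSums(x$counts), "/") * depth
  }
  structure(
    list(counts = counts, depth = depth,
         log_abundance = log10_p1(counts),
         rel_abundance = to_relative(counts),
         kingdom = x$kingdom, lineage = x$lineage,
         taxa = x$taxa, samples = x$samples),
    class = "normalized_table")
}

#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("normalized_table [%s]: %d taxa x %d samples at depth %s\n",
              x$kingdom, length(x$taxa), length(x$samples),
              format_num(x$depth)))
  invisible(x)
}
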