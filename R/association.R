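#' Spearman correlation with t-approximation p-values
#'
#' Average-rank (tie-corrected) Spearman rho between the rows of `x` and the
#' rows of `y`, with two-sided p from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)). Constant rows yield NA cells.
#'
#' @param x,y numeric matrices with variables in rows and the same sample
#'   columns (`y` defaults to `x`).
#' @return list with matrices `rho` and `p`, and the sample size `n`.
#' @keywords internal
spearman_matrix <- function(x, y = x) {
  stopifnot(ncol(x) == ncol(y))
  n <- ncol(x)
  rho <- suppressWarnings(cor(t(x), t(y), method = "spearman"))
  const_x <- apply(x, 1, function(r) length(unique(r)) == 1)
  const_y <- apply(y, 1, function(r) length(unique(r)) == 1)
  rho[const_x, ] <- NA_real_
  rho[, const_y] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[!is.na(rho) & abs(rho) >= 1] <- 0
  list(rho = rho, p = p, n = n)
}

#' Paired per-taxon diet test
#'
#' Tests, for every sufficiently abundant taxon, whether its log10 abundance
#' differs between diets. In this complete two-period crossover the
#' repeated-measures mixed model's diet contrast (diet fixed, animal random)
#' is exactly the paired t-test on per-animal differences, which is what is
#' computed: SED = sd(differences) / sqrt(n_pairs), two-sided p, and
#' Bonferroni control at the number of taxa tested within the kingdom.
#'
#' Taxa are gated on mean relative abundance before testing (default
#' > 0.05%), mirroring the convention of reporting only non-marginal taxa.
#'
#' @param x a [normalize_table()] result.
#' @param metadata a [sample_metadata()] frame.
#' @param min_rel_abund abundance gate on the mean relative abundance
#'   (default `5e-4`, i.e. 0.05%).
#' @param alpha significance threshold for the `significant` flag (applied
#'   to the Bonferroni-adjusted p).
#' @return data.frame of class `taxon_diet_result`: `taxon`, `mean_log_CON`,
#'   `mean_log_PAS`, `SED`, `p_raw`, `p_bonferroni`, `significant`,
#'   `degenerate`.
#' @export
paired_diet_test <- function(x, metadata, min_rel_abund = 5e-4,
                             alpha = 0.05) {
  stopifnot(inherits(x, "normalized_table"))
  pairs <- paired_animals(metadata)
  if (length(pairs) < 3)
    stopf("paired test needs at least 3 animals sampled under both diets")
  md <- metadata[metadata$animal %in% pairs, ]
  con <- md$sample[md$diet == "CON"][order(md$animal[md$diet == "CON"])]
  pas <- md$sample[md$diet == "PAS"][order(md$animal[md$diet == "PAS"])]
  keep <- rowMeans(x$rel_abundance) > min_rel_abund
  taxa <- x$taxa[keep]
  m <- length(taxa)
  la <- x$log_abundance
  rows <- lapply(taxa, function(tx) {
    a <- la[tx, con]
    b <- la[tx, pas]
    d <- b - a
    sed <- sd(d) / sqrt(length(d))
    if (sed <= 1e-12 * max(1, abs(mean(d)))) {
      p <- if (abs(mean(d)) <= 1e-12) 1 else .Machine$double.xmin
      degenerate <- abs(mean(d)) > 1e-12
      sed <- 0
    } else {
      p <- t.test(d)$p.value
      degenerate <- FALSE
    }
    data.frame(taxon = tx, mean_log_CON = mean(a), mean_log_PAS = mean(b),
               SED = sed, p_raw = p, stringsAsFactors = FALSE,
               degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * m)
  out$significant <- out$p_bonferroni < alpha
  out <- out[, c("taxon", "mean_log_CON", "mean_log_PAS", "SED",
                 "p_raw", "p_bonferroni", "significant", "degenerate")]
  class(out) <- c("taxon_diet_result", "data.frame")
  attr(out, "n_tested") <- m
  out
}

#' Within-diet Spearman screen of taxa against fermentation variables
#'
#' Rank correlations between taxon log10 abundances and rumen chemistry,
#' computed within one diet (correlation structure differs between diets, so
#' diets are never pooled). Cells with |rho| below the display threshold are
#' masked, matching the sparsity convention of published screens where only
#' correlations of at least ~0.30 are shown.
#'
#' @param x a [normalize_table()] result (or taxa-by-samples log matrix).
#' @param fermentation a [fermentation_profile()] frame.
#' @param metadata a [sample_metadata()] frame.
#' @param diet `"CON"` or `"PAS"`.
#' @param threshold display threshold on |rho| (default 0.30).
#' @param min_n minimum within-diet sample count (default 5).
#' @return object of class `correlation_screen`: matrices `rho`, `p`,
#'   logical `mask` (TRUE where reportable), `diet`, `n`.
#' @export
spearman_screen <- function(x, fermentation, metadata, diet = c("CON", "PAS"),
                            threshold = 0.30, min_n = 5) {
  diet <- match.arg(diet)
  la <- if (inherits(x, "normalized_table")) x$log_abundance else x
  samples <- intersect(metadata$sample[metadata$diet == diet],
                       intersect(colnames(la), fermentation$sample))
  if (length(samples) < min_n)
    stopf("only %d samples on diet %s (need >= %d)", length(samples), diet,
          min_n)
  ferm <- as.data.frame(fermentation)
  rownames(ferm) <- ferm$sample
  fm <- t(as.matrix(ferm[samples, fermentation_variables()]))
  sp <- spearman_matrix(la[, samples, drop = FALSE], fm)
  mask <- !is.na(sp$rho) & abs(sp$rho) >= threshold
  structure(list(rho = sp$rho, p = sp$p, mask = mask, diet = diet,
                 n = sp$n, threshold = threshold),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("Spearman screen (%s, n = %d): %d of %d cells at |rho| >= %.2f\n",
              x$diet, x$n, sum(x$mask), length(x$mask), x$threshold))
  invisible(x)
}
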