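#' Alpha-diversity panel for one sample
#'
#' Computes the five per-sample indices reported for each kingdom:
#' \describe{
#'   \item{richness}{number of taxa with count > 0 (observed OTUs).}
#'   \item{shannon}{H = -sum p_i ln p_i, in nats.}
#'   \item{evenness}{Pielou's J = H / ln(richness); undefined (NA) when only
#'     one taxon is present.}
#'   \item{simpson}{Gini-Simpson index 1 - sum p_i^2.}
#'   \item{goods}{Good's coverage 1 - F1/N, F1 = number of singleton taxa,
#'     N = reads. Depth-dependent, so it is computed on the rarefied table.}
#' }
#' Proportions p_i use the sample's own total.
#'
#' @param counts non-negative integer vector of per-taxon reads for one
#'   sample, with at least one positive entry.
#' @return named list with the five indices.
#' @examples
#' alpha_panel(c(10, 10, 10, 10))  # richness 4, evenness 1, simpson 0.75
#' @export
alpha_panel <- function(counts) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stopf("all-zero sample has no diversity")
  pos <- counts[counts > 0]
  p <- pos / n
  richness <- length(pos)
  shannon <- -sum(p * log(p))
  list(richness = richness,
       shannon = shannon,
       evenness = if (richness > 1) shannon / log(richness) else NA_real_,
       simpson = 1 - sum(p^2),
       goods = 1 - sum(pos == 1) / n)
}

#' Alpha diversity for every sample of a normalized table
#' @param x a [normalize_table()] result (integer counts at common depth).
#' @return data.frame: one row per sample, columns `sample`, `richness`,
#'   `shannon`, `evenness`, `simpson`, `goods`.
#' @export
alpha_table <- function(x) {
  stopifnot(inherits(x, "normalized_table"))
  rows <- lapply(x$samples, function(s) {
    c(list(sample = s), alpha_panel(x$counts[, s]))
  })
  do.call(rbind.data.frame, rows)
}

#' Paired per-diet summary of sample-level variables
#'
#' For each numeric column: the CON and PAS group means, the standard error
#' of the per-animal differences (SED = sd(PAS - CON) / sqrt(n_pairs)), and
#' the two-sided paired t-test p-value for the diet effect. In this complete
#' two-level crossover the mixed model's diet contrast (diet fixed, animal
#' random) is exactly the paired t-test on per-animal differences, which is
#' what is computed here.
#'
#' Degenerate case: when every difference is zero the diet clearly has no
#' effect and p = 1 is reported; zero variance with a nonzero mean difference
#' is reported as p below the double-precision floor with `degenerate = TRUE`.
#'
#' @param values data.frame with a `sample` column plus numeric columns.
#' @param metadata a [sample_metadata()] frame covering the samples.
#' @return data.frame: `variable`, `mean_CON`, `mean_PAS`, `SED`, `p_value`,
#'   `degenerate`.
#' @export
group_summary <- function(values, metadata) {
  stopifnot(is.data.frame(values), "sample" %in% names(values))
  orphan <- setdiff(values$sample, metadata$sample)
  if (length(orphan))
    stopf("sample(s) absent from metadata: %s", paste(orphan, collapse = ", "))
  pairs <- paired_animals(metadata)
  if (length(pairs) < 3)
    stopf("paired summary needs at least 3 animals sampled under both diets")
  md <- metadata[metadata$animal %in% pairs, ]
  con_samples <- md$sample[md$diet == "CON"][order(md$animal[md$diet == "CON"])]
  pas_samples <- md$sample[md$diet == "PAS"][order(md$animal[md$diet == "PAS"])]
  rownames(values) <- values$sample
  vars <- setdiff(names(values), "sample")
  rows <- lapply(vars, function(v) {
    a <- values[con_samples, v]
    b <- values[pas_samples, v]
    ok <- !is.na(a) & !is.na(b)
    d <- b[ok] - a[ok]
    n <- length(d)
    sed <- sd(d) / sqrt(n)
    if (sed <= 1e-12 * max(1, abs(mean(d)))) {
      p <- if (abs(mean(d)) <= 1e-12) 1 else .Machine$double.xmin
      degenerate <- abs(mean(d)) > 1e-12
      sed <- 0
    } else {
      p <- t.test(d)$p.value
      degenerate <- FALSE
    }
    data.frame(variable = v, mean_CON = mean(a[ok]), mean_PAS = mean(b[ok]),
               SED = sed, p_value = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-diet alpha-diversity summary
#'
#' Convenience wrapper: [alpha_table()] followed by [group_summary()],
#' yielding one row per index with CON/PAS means, SED and paired p-value.
#'
#' @param x a [normalize_table()] result.
#' @param metadata a [sample_metadata()] frame.
#' @return data.frame as in [group_summary()].
#' @export
diversity_summary <- function(x, metadata) {
  group_summary(alpha_table(x), metadata)
}
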