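# Shared fixtures, all generated in code.

toy_counts <- function() {
  m <- matrix(c(10L, 0L, 3L,
                2L, 8L, 0L,
                5L, 5L, 5L), nrow = 3, byrow = FALSE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("A01_CON", "A01_PAS", "A02_CON")))
  count_table(m, "bacteria")
}

# minimal single-kingdom truth without diet effects, modules or covariates
flat_truth <- function(n_taxa = 20, depth = c(2000L, 3000L),
                       baseline = NULL) {
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  if (is.null(baseline)) baseline <- stats::setNames(rep(1, n_taxa), taxa)
  synthetic_truth(kingdoms = list(bacteria = kingdom_spec(
    taxa, baseline, core = taxa[baseline >= 1], depth_range = depth)))
}

# null version of the full study conditions: abundant taxa only, no effects
null_truth_40 <- function() {
  taxa <- sprintf("t%02d", 1:40)
  base <- stats::setNames(c(rep(1, 30), seq(-2, -1.6, length.out = 10)), taxa)
  synthetic_truth(kingdoms = list(bacteria = kingdom_spec(
    taxa, base, core = taxa[1:30], depth_range = c(10000L, 15000L))))
}

# metadata for n paired animals
paired_md <- function(n) {
  an <- sprintf("A%02d", seq_len(n))
  sample_metadata(c(paste0(an, "_CON"), paste0(an, "_PAS")),
                  rep(an, 2), rep(c("CON", "PAS"), each = n))
}

# hand-built multi_kingdom object from a log-abundance matrix
fake_multi_kingdom <- function(la, kingdom = "bacteria", rel = NULL) {
  structure(list(
    log_abundance = la,
    kingdom = stats::setNames(rep(kingdom, nrow(la)), rownames(la)),
    mean_rel_abundance = rel %||%
      stats::setNames(rep(1 / nrow(la), nrow(la)), rownames(la)),
    samples = colnames(la)), class = "multi_kingdom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
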