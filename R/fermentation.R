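#' Reducing-equivalent coefficients for stoichiometric H2 estimation
#'
#' Metabolic hydrogen implied by a VFA profile is computed from per-acid
#' net reducing-equivalent coefficients (mol H2-equivalents released or
#' consumed per mol VFA formed), after the classical fermentation balance of
#' Marty & Demeyer: acetate and butyrate formation release 2 and 4 mol H2
#' per mol respectively, propionate consumes 1 (net coefficient +1 in the
#' production sense used here), and the 5- and 6-carbon straight-chain acids
#' (valerate, caproate) carry 2 each; branched-chain iso-acids, which arise
#' from amino-acid skeletons rather than carbohydrate fermentation, carry 0.
#'
#' @param acetate,propionate,butyrate,valerate,caproate,iso per-acid
#'   coefficients; the defaults \{2, 1, 4, 2, 2, 0\} reproduce the hydrogen
#'   balance used in sheep grazing studies.
#' @return named numeric vector of class `stoich_coefficients`.
#' @export
stoich_coefficients <- function(acetate = 2, propionate = 1, butyrate = 4,
                                valerate = 2, caproate = 2, iso = 0) {
  x <- c(acetate = acetate, propionate = propionate, butyrate = butyrate,
         valerate = valerate, caproate = caproate, iso = iso)
  if (any(!is.finite(x))) stopf("coefficients must be finite")
  class(x) <- c("stoich_coefficients", class(x))
  x
}

#' Stoichiometric H2 production from a VFA profile
#'
#' Converts total VFA (mM) and molar proportions (%) to per-acid molar
#' concentrations c_k = total_VFA * proportion_k / 100 and returns
#' H2 = sum coeff_k * c_k (mM). Linear in every VFA concentration. Accepts a
#' [fermentation_profile()] (one value per row), a single named vector, or
#' group means.
#'
#' @param profile a [fermentation_profile()] frame or a named numeric vector
#'   with `total_VFA` and the molar-proportion entries.
#' @param coeffs a [stoich_coefficients()] vector.
#' @return numeric vector of H2 production in mM.
#' @examples
#' con <- c(total_VFA = 87.7, acetate = 71.4, propionate = 15.4,
#'          butyrate = 9.39, iso_butyrate = 1.70, valerate = 0.69,
#'          iso_valerate = 1.14, caproate = 0.25, iso_caproate = 0.01)
#' h2_production(con)  # ~173 mM
#' @export
h2_production <- function(profile, coeffs = stoich_coefficients()) {
  if (is.numeric(profile) && !is.null(names(profile)))
    profile <- as.data.frame(as.list(profile))
  need <- c("total_VFA", MOLAR_PROPORTIONS)
  miss <- setdiff(need, names(profile))
  if (length(miss))
    stopf("profile missing: %s", paste(miss, collapse = ", "))
  props <- as.matrix(profile[, MOLAR_PROPORTIONS, drop = FALSE])
  s <- rowSums(props)
  bad <- which(s < 95 | s > 105)
  if (length(bad))
    stopf("molar proportions sum to %.2f (must be in [95, 105])", s[bad[1]])
  per_acid <- c(acetate = unname(coeffs["acetate"]),
                propionate = unname(coeffs["propionate"]),
                butyrate = unname(coeffs["butyrate"]),
                iso_butyrate = unname(coeffs["iso"]),
                valerate = unname(coeffs["valerate"]),
                iso_valerate = unname(coeffs["iso"]),
                caproate = unname(coeffs["caproate"]),
                iso_caproate = unname(coeffs["iso"]))
  conc <- sweep(props, 1, profile$total_VFA / 100, "*")
  as.numeric(conc[, names(per_acid)] %*% per_acid)
}

#' Percent change and fold change between group means
#'
#' `percent_change(a, b)` = 100 * (a - b) / b, i.e. `a` relative to the
#' reference `b`; `fold_change(a, b)` = a / b. They satisfy
#' fold = 1 + pct/100 exactly. Rounding happens only at serialization.
#'
#' @param a value of interest.
#' @param b reference value (must be > 0).
#' @return numeric.
#' @export
percent_change <- function(a, b) {
  if (any(b <= 0)) stopf("reference must be positive")
  100 * (a - b) / b
}

#' @rdname percent_change
#' @export
fold_change <- function(a, b) {
  if (any(b <= 0)) stopf("reference must be positive")
  a / b
}

#' Per-diet fermentation summary
#'
#' CON/PAS means, SED and paired p-value for every fermentation variable
#' (see [group_summary()] for the paired-test convention).
#'
#' @param profile a [fermentation_profile()] frame.
#' @param metadata a [sample_metadata()] frame.
#' @return data.frame as in [group_summary()].
#' @export
fermentation_summary <- function(profile, metadata) {
  stopifnot(inherits(profile, "fermentation_profile"))
  group_summary(as.data.frame(profile), metadata)
}

#' Published-style reference group means
#'
#' The bundled reference table of per-diet group means (fermentation
#' chemistry and per-kingdom alpha diversity) from a 24-ewe hay/concentrate
#' versus pasture crossover study. Serves as the default centre of the
#' synthetic generator's fermentation model and as input for the headline
#' derived quantities (H2 stoichiometry, percent/fold changes, richness
#' deltas).
#'
#' @return data.frame with columns `block`, `variable`, `CON`, `PAS`, `SED`.
#' @export
reference_group_means <- function() {
  path <- system.file("extdata", "grazing_reference_means.tsv",
                      package = "rumenshift", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
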