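#' Specify one kingdom of a synthetic community
#'
#' @param taxa character vector of taxon IDs.
#' @param baseline named log10 unnormalized abundance scores under CON; the
#'   softmax of (baseline + effects + noise) is the sampled composition.
#' @param core taxa planted at 100% prevalence under both diets.
#' @param con_specific,pas_specific taxa planted as present under one diet
#'   and largely absent under the other (their diet effects live in
#'   `diet_log_effects` of the truth object).
#' @param depth_range integer c(min, max) sequencing depth per sample.
#' @return list describing the kingdom.
#' @export
kingdom_spec <- function(taxa, baseline, core = character(),
                         con_specific = character(),
                         pas_specific = character(),
                         depth_range = c(10000L, 15000L)) {
  stopifnot(all(names(baseline) == taxa),
            all(core %in% taxa), all(con_specific %in% taxa),
            all(pas_specific %in% taxa),
            depth_range[1] >= 1, depth_range[2] >= depth_range[1])
  list(taxa = taxa, baseline = baseline, core = core,
       con_specific = con_specific, pas_specific = pas_specific,
       depth_range = depth_range)
}

#' Construct a synthetic-study ground truth
#'
#' Bundles everything the generator needs and the recovery tests assert
#' against: per-kingdom taxa with planted cores and diet-specific taxa,
#' correlation modules (taxon sets sharing a latent factor), per-taxon diet
#' effects on log10 abundance, per-taxon noise standard deviations, the
#' coupling of fermentation covariates to the module factors, and the
#' fermentation means per diet.
#'
#' Module loadings are derived from the requested correlation strength: for
#' target rho and member noise sd sigma, loading = sigma * sqrt(rho/(1-rho))
#' against a unit-variance factor, so the latent pairwise correlation among
#' members is rho (compositional closure attenuates it slightly).
#'
#' @param kingdoms named list of [kingdom_spec()] entries (names are the
#'   kingdom labels `bacteria`, `methanogen`, `fungus`).
#' @param modules list of `list(taxa = c(...), rho_target = ...)`; taxa may
#'   span kingdoms. rho_target must lie in (0.5, 1].
#' @param diet_log_effects named vector: additive shift of a taxon's log10
#'   score under PAS (empty = no diet effects).
#' @param animal_sd,resid_sd named per-taxon standard deviations (log10) of
#'   the animal random intercept and the residual; scalars are recycled.
#' @param protozoa list with `groups`, `mean_pct` (group x diet matrix) and
#'   `noise_sd`, or `NULL` to skip the protozoa table.
#' @param ferm data.frame `variable`, `CON`, `PAS`, `resid_sd` for the
#'   fermentation covariates, or `NULL` to skip the fermentation profile.
#' @param coupling matrix (fermentation variable x module) of coefficients
#'   linking module factors to covariates; `NULL` for no coupling.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(kingdoms, modules = list(),
                            diet_log_effects = numeric(),
                            animal_sd = 0.2, resid_sd = 0.2,
                            protozoa = NULL, ferm = NULL, coupling = NULL) {
  all_taxa <- unlist(lapply(kingdoms, `[[`, "taxa"))
  if (anyDuplicated(all_taxa)) stopf("taxon IDs must be unique across kingdoms")
  expand <- function(x) {
    if (length(x) == 1 && is.null(names(x)))
      return(stats::setNames(rep(x, length(all_taxa)), all_taxa))
    out <- stats::setNames(rep(0.2, length(all_taxa)), all_taxa)
    out[names(x)] <- x
    out
  }
  animal_sd <- expand(animal_sd)
  resid_sd <- expand(resid_sd)
  for (m in modules) {
    if (!all(m$taxa %in% all_taxa))
      stopf("module taxa missing from kingdoms")
    if (m$rho_target <= 0.5 || m$rho_target > 1)
      stopf("rho_target must be in (0.5, 1]")
  }
  modules <- lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    m$name <- m$name %||% paste0("module", i)
    sigma <- sqrt(animal_sd[m$taxa]^2 + resid_sd[m$taxa]^2)
    m$loading <- stats::setNames(
      sigma * sqrt(m$rho_target / (1 - m$rho_target)), m$taxa)
    m
  })
  bad <- setdiff(names(diet_log_effects), all_taxa)
  if (length(bad)) stopf("diet effects for unknown taxa: %s",
                         paste(bad, collapse = ", "))
  if (!is.null(coupling) && length(modules) > 0) {
    stopifnot(ncol(coupling) == length(modules))
  }
  structure(list(kingdoms = kingdoms, modules = modules,
                 diet_log_effects = diet_log_effects,
                 animal_sd = animal_sd, resid_sd = resid_sd,
                 protozoa = protozoa, ferm = ferm, coupling = coupling),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:\n")
  for (k in names(x$kingdoms)) {
    kk <- x$kingdoms[[k]]
    cat(sprintf("  %s: %d taxa (%d core, %d/%d diet-specific), depth %d-%d\n",
                k, length(kk$taxa), length(kk$core),
                length(kk$con_specific), length(kk$pas_specific),
                kk$depth_range[1], kk$depth_range[2]))
  }
  cat(sprintf("  %d correlation modules; %d planted diet effects\n",
              length(x$modules), length(x$diet_log_effects)))
  invisible(x)
}

#' Default synthetic ground truth
#'
#' The generator's reference condition, emulating a 24-ewe two-diet grazing
#' study: 70 bacterial, 20 methanogen and 40 fungal genera with planted
#' shared cores of 34, 9 and 13 taxa; 8 CON-specific and 10 PAS-specific
#' bacterial taxa; a tail of rare taxa driving uneven prevalence; three
#' 5-taxon correlation modules at rho_target 0.9 (the third spans bacteria,
#' methanogens and fungi); moderate diet effects on a subset of core taxa;
#' per-kingdom sequencing depths centred near 12,500 / 1,100 / 8,900 reads;
#' protozoa as four optically counted groups in percent; and fermentation
#' covariates centred on the bundled reference group means, with lactate,
#' ammonia and total VFA coupled to the module factors.
#'
#' @param diet_effects logical; `FALSE` zeroes every planted diet effect
#'   (including the diet-specific prevalence planting) for null calibration.
#' @param modules logical; `FALSE` drops the correlation modules.
#' @return a [synthetic_truth()] object. Two calls return identical objects.
#' @export
default_truth <- function(diet_effects = TRUE, modules = TRUE) {
  bac <- sprintf("bac_g%02d", 1:70)
  met <- sprintf("met_s%02d", 1:20)
  fun <- sprintf("fun_g%02d", 1:40)

  bac_base <- stats::setNames(c(rep(1.0, 34),            # core
                                rep(0.9, 8),             # CON-specific
                                rep(0.9 - 3.0, 10),      # PAS-specific
                                seq(-2.0, -1.6, length.out = 18)), bac)
  met_base <- stats::setNames(c(rep(1.0, 9),
                                seq(-1.7, -1.2, length.out = 11)), met)
  fun_base <- stats::setNames(c(rep(1.0, 13),
                                seq(-2.5, -1.95, length.out = 27)), fun)

  kingdoms <- list(
    bacteria = kingdom_spec(bac, bac_base, core = bac[1:34],
                            con_specific = bac[35:42],
                            pas_specific = bac[43:52],
                            depth_range = c(10000L, 15000L)),
    methanogen = kingdom_spec(met, met_base, core = met[1:9],
                              depth_range = c(900L, 1300L)),
    fungus = kingdom_spec(fun, fun_base, core = fun[1:13],
                          depth_range = c(7100L, 10700L)))

  effects <- numeric(0)
  if (diet_effects) {
    effects <- c(
      stats::setNames(rep(-3.0, 8), bac[35:42]),   # CON-specific vanish on PAS
      stats::setNames(rep(+3.0, 10), bac[43:52]),  # PAS-specific appear on PAS
      stats::setNames(c(0.4, -0.4, 0.3, -0.3, 0.5, -0.5, 0.25, -0.25,
                        0.35, -0.35), bac[14:23]),
      stats::setNames(c(0.3, -0.3, 0.4), met[2:4]),
      stats::setNames(c(0.5, -0.4, 0.3, -0.3), fun[2:5]))
  }

  mod_list <- list()
  if (modules) {
    mod_list <- list(
      list(name = "module1", taxa = bac[1:5], rho_target = 0.9),
      list(name = "module2", taxa = bac[6:10], rho_target = 0.9),
      list(name = "module3", taxa = c(bac[11:13], met[1], fun[1]),
           rho_target = 0.9))
  }
  module_taxa <- unlist(lapply(mod_list, `[[`, "taxa"))
  animal_sd <- stats::setNames(rep(0.2, 130), c(bac, met, fun))
  resid_sd <- animal_sd
  # module members: low idiosyncratic noise (tightly co-varying guilds)
  animal_sd[module_taxa] <- 0.1
  resid_sd[module_taxa] <- 0.1

  ref <- reference_group_means()
  fref <- ref[ref$block == "fermentation" & ref$variable != "H2_production", ]
  ferm <- data.frame(variable = fref$variable, CON = fref$CON,
                     PAS = fref$PAS,
                     resid_sd = fref$SED * sqrt(24) / sqrt(2),
                     stringsAsFactors = FALSE)

  coupling <- NULL
  if (modules) {
    coupling <- matrix(0, nrow = nrow(ferm), ncol = 3,
                       dimnames = list(ferm$variable,
                                       c("module1", "module2", "module3")))
    coupling["lactate", "module1"] <- 3.0
    coupling["butyrate", "module1"] <- 0.5
    coupling["ammonia_N", "module2"] <- 12.0
    coupling["propionate", "module2"] <- -2.0
    coupling["total_VFA", "module3"] <- 6.0
    coupling["acetate", "module3"] <- 2.0
    # residual sd excludes the coupled share so total spread stays realistic
    coupled_var <- rowSums(coupling^2)
    ferm$resid_sd <- sqrt(pmax(ferm$resid_sd^2 - coupled_var,
                               (ferm$resid_sd / 2)^2))
  }

  pref <- ref[ref$block == "protozoa_pct", ]
  protozoa <- list(groups = pref$variable,
                   mean_pct = matrix(c(pref$CON, pref$PAS), ncol = 2,
                                     dimnames = list(pref$variable, DIETS)),
                   noise_sd = 0.15)

  synthetic_truth(kingdoms, mod_list, effects, animal_sd, resid_sd,
                  protozoa, ferm, coupling)
}

#' Expected (noise-free) planted composition
#'
#' Softmax of baseline + diet effect, i.e. the composition the generator
#' targets before animal, module and residual variation. Useful for
#' monotonicity and symmetry checks.
#'
#' @param truth a [synthetic_truth()].
#' @param kingdom kingdom name.
#' @param diet `"CON"` or `"PAS"`.
#' @return named proportions summing to 1.
#' @export
planted_composition <- function(truth, kingdom, diet = c("CON", "PAS")) {
  diet <- match.arg(diet)
  kk <- truth$kingdoms[[kingdom]]
  if (is.null(kk)) stopf("unknown kingdom '%s'", kingdom)
  score <- kk$baseline
  if (diet == "PAS") {
    eff <- truth$diet_log_effects
    hit <- intersect(names(eff), kk$taxa)
    score[hit] <- score[hit] + eff[hit]
  }
  w <- 10^(score - max(score))
  w / sum(w)
}

#' Simulate a complete two-diet multi-kingdom study
#'
#' For every animal and diet, draws per-module latent factors and per-animal
#' random intercepts, forms log10 abundance scores
#' baseline + diet effect + loading x factor + animal intercept + residual,
#' converts each sample's scores to a composition by softmax, and samples
#' reads multinomially at a depth drawn uniformly from the kingdom's depth
#' range. Fermentation covariates are diet means + coupling x factors +
#' Gaussian noise, clipped to physiological ranges (molar proportions are
#' renormalized to sum to 100). Protozoa are generated as percentage
#' compositions of the four counted groups. Identical seeds give identical
#' output; one global seed streams per-component sub-seeds.
#'
#' @param n_animals number of animals (>= 4), each sampled under both diets.
#' @param truth a [synthetic_truth()]; default [default_truth()].
#' @param seed integer master seed.
#' @return object of class `synthetic_study`: `tables` (named list of
#'   [count_table()]s), `metadata`, `fermentation` (or NULL), `truth`,
#'   `factors` (module factor draws, samples in columns).
#' @export
simulate_study <- function(n_animals = 24, truth = default_truth(),
                           seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_animals < 4) stopf("n_animals must be >= 4")
  animals <- sprintf("A%02d", seq_len(n_animals))
  metadata <- sample_metadata(
    sample = c(paste0(animals, "_CON"), paste0(animals, "_PAS")),
    animal = rep(animals, 2),
    diet = rep(DIETS, each = n_animals))
  samples <- metadata$sample
  n_s <- length(samples)

  seeds <- derive_seeds(seed, 3 + length(truth$kingdoms))

  n_mod <- length(truth$modules)
  factors <- with_seed(seeds[1], {
    matrix(rnorm(n_mod * n_s), nrow = n_mod, ncol = n_s,
           dimnames = list(vapply(truth$modules, `[[`, "", "name"),
                           samples))
  })

  tables <- list()
  for (ki in seq_along(truth$kingdoms)) {
    kname <- names(truth$kingdoms)[ki]
    kk <- truth$kingdoms[[ki]]
    taxa <- kk$taxa
    nt <- length(taxa)
    counts <- with_seed(seeds[3 + ki], {
      animal_eff <- matrix(rnorm(nt * n_animals, 0,
                                 truth$animal_sd[taxa]),
                           nrow = nt, dimnames = list(taxa, animals))
      score <- matrix(kk$baseline, nrow = nt, ncol = n_s,
                      dimnames = list(taxa, samples))
      eff <- truth$diet_log_effects
      hit <- intersect(names(eff), taxa)
      pas_cols <- metadata$diet == "PAS"
      if (length(hit)) score[hit, pas_cols] <- score[hit, pas_cols] + eff[hit]
      score <- score + animal_eff[, metadata$animal]
      if (n_mod) for (m in truth$modules) {
        in_k <- intersect(m$taxa, taxa)
        if (length(in_k))
          score[in_k, ] <- score[in_k, ] +
            outer(unname(m$loading[in_k]), factors[m$name, ])
      }
      score <- score + matrix(rnorm(nt * n_s, 0, truth$resid_sd[taxa]),
                              nrow = nt)
      depths <- round(runif(n_s, kk$depth_range[1], kk$depth_range[2]))
      out <- matrix(0L, nrow = nt, ncol = n_s,
                    dimnames = list(taxa, samples))
      for (j in seq_len(n_s)) {
        w <- 10^(score[, j] - max(score[, j]))
        p <- w / sum(w)
        if (max(p) > 0.999)
          stopf("degenerate composition in sample '%s' (%s): one taxon holds %.1f%%",
                samples[j], kname, 100 * max(p))
        out[, j] <- rmultinom(1, depths[j], p)
      }
      out
    })
    tables[[kname]] <- count_table(counts, kname)
  }

  if (!is.null(truth$protozoa)) {
    pz <- truth$protozoa
    tables$protozoa <- with_seed(seeds[2], {
      sc <- log10(pz$mean_pct[, metadata$diet]) +
        matrix(rnorm(length(pz$groups) * n_s, 0, pz$noise_sd),
               nrow = length(pz$groups))
      pct <- apply(sc, 2, function(v) {
        w <- 10^(v - max(v)); 100 * w / sum(w)
      })
      dimnames(pct) <- list(pz$groups, samples)
      count_table(signif(pct, 6), "protozoa")
    })
  }

  fermentation <- NULL
  if (!is.null(truth$ferm)) {
    fermentation <- with_seed(seeds[3], {
      fm <- truth$ferm
      vals <- matrix(NA_real_, nrow = n_s, ncol = nrow(fm),
                     dimnames = list(samples, fm$variable))
      for (vi in seq_len(nrow(fm))) {
        mu <- ifelse(metadata$diet == "CON", fm$CON[vi], fm$PAS[vi])
        x <- mu + rnorm(n_s, 0, fm$resid_sd[vi])
        if (!is.null(truth$coupling) && n_mod)
          x <- x + as.numeric(truth$coupling[fm$variable[vi], ] %*% factors)
        vals[, vi] <- x
      }
      df <- as.data.frame(vals)
      df$pH <- pmin(pmax(df$pH, 5.0), 7.8)
      df$ammonia_N <- pmax(df$ammonia_N, 0.5)
      df$total_VFA <- pmax(df$total_VFA, 5)
      props <- as.matrix(df[, MOLAR_PROPORTIONS])
      props <- pmax(props, 0.005)
      props <- 100 * props / rowSums(props)
      df[, MOLAR_PROPORTIONS] <- props
      df$lactate <- pmax(df$lactate, 0.05)
      df$DL_lactate_ratio <- pmax(df$DL_lactate_ratio, 0.01)
      df$protozoa_log <- pmin(pmax(df$protozoa_log, 3), 10)
      df <- cbind(sample = samples, df)
      rownames(df) <- NULL
      for (v in fermentation_variables()) df[[v]] <- signif(df[[v]], 6)
      fermentation_profile(df)
    })
  }

  structure(list(tables = tables, metadata = metadata,
                 fermentation = fermentation, truth = truth,
                 factors = factors),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d samples (%d animals x 2 diets), kingdoms: %s\n",
              nrow(x$metadata), nrow(x$metadata) / 2,
              paste(names(x$tables), collapse = ", ")))
  invisible(x)
}
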