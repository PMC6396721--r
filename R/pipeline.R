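READ_KINGDOMS <- c("bacteria", "methanogen", "fungus")

#' Build / validate a run configuration
#'
#' A run is driven either by a `simulate` block (n_animals, truth defaults)
#' or by `inputs` paths (per-kingdom count TSVs, metadata CSV, optional
#' fermentation CSV). One global `seed` is fanned out to the simulation,
#' rarefaction and permutation stages. `params` holds the per-stage
#' thresholds.
#'
#' @param config named list, or path to a YAML file with the same structure.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stopf("config needs an out_dir")
  if (is.null(config$simulate) && is.null(config$inputs))
    stopf("config needs either a simulate block or an inputs block")
  config$seed <- as.integer(config$seed %||% 1L)
  p <- config$params %||% list()
  p$n_perm <- p$n_perm %||% 999
  p$r_min <- p$r_min %||% 0.5
  p$alpha <- p$alpha %||% 0.05
  p$adjust <- p$adjust %||% "BH"
  p$prevalence_min <- p$prevalence_min %||% 0.5
  p$core_threshold <- p$core_threshold %||% 0.95
  p$cca_vars <- p$cca_vars %||% c("pH", "ammonia_N", "total_VFA", "acetate",
                                  "propionate", "butyrate", "lactate",
                                  "DL_lactate_ratio", "protozoa_log")
  p$min_rel_abund <- p$min_rel_abund %||% 5e-4
  config$params <- p
  if (!is.null(config$simulate))
    config$simulate$n_animals <- config$simulate$n_animals %||% 24
  class(config) <- c("run_config", "list")
  config
}

write_tsv <- function(df, path) {
  out <- df
  for (v in names(out)) if (is.numeric(out[[v]])) out[[v]] <- format_num(out[[v]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order - input/simulation, depth
#' normalization, alpha diversity, Bray-Curtis PERMANOVA, CCA against
#' fermentation covariates, paired per-taxon diet tests, taxon-fermentation
#' Spearman screens, core partitioning, per-diet co-occurrence networks and
#' their comparison, and the fermentation summary with stoichiometric H2 -
#' writing one TSV per result surface into `out_dir`, plus the serialized
#' configuration and a manifest of output files with MD5 checksums. When no
#' fermentation table is available the CCA and correlation screens are
#' skipped with a logged warning; everything else still runs. Given the same
#' config and seed the report directory is byte-identical.
#'
#' @param config a [run_config()] (or list / YAML path accepted by it).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results and `out_dir`.
#' @export
run_all <- function(config, quiet = FALSE) {
  config <- run_config(config)
  p <- config$params
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  files <- character()
  emit <- function(path) files <<- c(files, path)
  seeds <- derive_seeds(config$seed, 8)

  # ---- inputs ----------------------------------------------------------
  res <- stage("input", {
    if (!is.null(config$simulate)) {
      say("simulate: %d animals, seed %d [seed fingerprint %d]",
          config$simulate$n_animals, config$seed, seeds[1])
      study <- simulate_study(config$simulate$n_animals,
                              truth = default_truth(), seed = seeds[1])
      list(tables = study$tables, metadata = study$metadata,
           fermentation = study$fermentation)
    } else {
      inp <- config$inputs
      tables <- list()
      for (k in names(inp$counts))
        tables[[k]] <- read_count_table(inp$counts[[k]], k)
      md <- read_metadata(inp$metadata)
      for (tb in tables) validate_samples(tb, md)
      ferm <- if (!is.null(inp$fermentation))
        read_fermentation(inp$fermentation) else NULL
      list(tables = tables, metadata = md, fermentation = ferm)
    }
  })
  tables <- res$tables
  metadata <- res$metadata
  ferm <- res$fermentation
  emit(write_tsv(as.data.frame(metadata), file.path(out_dir, "metadata.tsv")))

  # ---- preprocess ------------------------------------------------------
  norm <- stage("preprocess", {
    out <- list()
    for (k in names(tables)) {
      say("preprocess: normalizing %s [rarefaction seed %d]", k, seeds[2])
      out[[k]] <- normalize_table(tables[[k]], seed = seeds[2])
    }
    out
  })

  results <- list()
  for (k in intersect(READ_KINGDOMS, names(norm))) {
    nk <- norm[[k]]
    # diversity
    stage(paste0("diversity/", k), {
      at <- alpha_table(nk)
      emit(write_tsv(at, file.path(out_dir, paste0("alpha_", k, ".tsv"))))
      ds <- diversity_summary(nk, metadata)
      emit(write_tsv(ds, file.path(out_dir,
                                   paste0("alpha_summary_", k, ".tsv"))))
      results$diversity[[k]] <- ds
    })
    # community structure
    stage(paste0("ordination/", k), {
      d <- bray_curtis(nk)
      dd <- data.frame(sample = rownames(d), d, check.names = FALSE)
      emit(write_tsv(dd, file.path(out_dir, paste0("braycurtis_", k, ".tsv"))))
      pm <- permanova(d, metadata, n_perm = p$n_perm, seed = seeds[3])
      say("ordination: %s pseudo-F %.2f p %.4g [%d perms]", k, pm$pseudo_F,
          pm$p_perm, pm$n_permutations)
      emit(write_tsv(
        data.frame(kingdom = k, pseudo_F = pm$pseudo_F, p = pm$p_perm,
                   df_between = pm$df_between, df_within = pm$df_within,
                   similarity_CON = pm$group_similarity[["CON"]],
                   similarity_PAS = pm$group_similarity[["PAS"]]),
        file.path(out_dir, paste0("permanova_", k, ".tsv"))))
      results$permanova[[k]] <- pm
      if (!is.null(ferm)) {
        fr <- as.data.frame(ferm)
        rownames(fr) <- fr$sample
        cons <- fr[nk$samples, p$cca_vars, drop = FALSE]
        cc <- cca_fermentation(nk, cons, n_perm = p$n_perm, seed = seeds[4])
        emit(write_tsv(
          data.frame(sample = rownames(cc$site_scores), cc$site_scores,
                     check.names = FALSE),
          file.path(out_dir, paste0("cca_sites_", k, ".tsv"))))
        emit(write_tsv(
          data.frame(variable = names(cc$var_p), p = unname(cc$var_p)),
          file.path(out_dir, paste0("cca_varp_", k, ".tsv"))))
        results$cca[[k]] <- cc
      }
    })
    # association
    stage(paste0("association/", k), {
      dt <- paired_diet_test(nk, metadata, min_rel_abund = p$min_rel_abund)
      emit(write_tsv(as.data.frame(dt),
                     file.path(out_dir, paste0("diet_test_", k, ".tsv"))))
      results$diet_test[[k]] <- dt
      if (!is.null(ferm)) {
        for (d in DIETS) {
          sc <- spearman_screen(nk, ferm, metadata, d)
          rep_df <- data.frame(taxon = rownames(sc$rho)[row(sc$rho)[sc$mask]],
                               variable = colnames(sc$rho)[col(sc$rho)[sc$mask]],
                               rho = sc$rho[sc$mask], p = sc$p[sc$mask])
          rep_df <- rep_df[order(rep_df$taxon, rep_df$variable), ]
          emit(write_tsv(rep_df, file.path(
            out_dir, paste0("correlations_", k, "_", d, ".tsv"))))
        }
      }
    })
    # core
    stage(paste0("core/", k), {
      cp <- core_partition(nk, metadata, threshold = p$core_threshold)
      core_df <- data.frame(
        taxon = c(cp$shared_core, cp$diet_specific_core$CON,
                  cp$diet_specific_core$PAS),
        set = c(rep("shared", length(cp$shared_core)),
                rep("CON_specific", length(cp$diet_specific_core$CON)),
                rep("PAS_specific", length(cp$diet_specific_core$PAS))))
      emit(write_tsv(core_df, file.path(out_dir, paste0("core_", k, ".tsv"))))
      results$core[[k]] <- cp
    })
  }

  if (is.null(ferm))
    say("warning: no fermentation table; CCA and correlation screens skipped")

  # ---- network ---------------------------------------------------------
  stage("network", {
    mk <- combine_kingdoms(norm, ferm)
    nets <- list()
    for (d in DIETS) {
      nets[[d]] <- build_network(mk, metadata, d, r_min = p$r_min,
                                 alpha = p$alpha, adjust = p$adjust,
                                 prevalence_min = p$prevalence_min)
      say("network %s: %d nodes, %d edges", d, nets[[d]]$metrics$n_nodes,
          nets[[d]]$metrics$n_edges)
      emit(write_edge_list(nets[[d]],
                           file.path(out_dir, paste0("network_", d, ".tsv"))))
      emit(write_tsv(nets[[d]]$nodes,
                     file.path(out_dir, paste0("network_nodes_", d, ".tsv"))))
    }
    cmp <- compare_networks(nets$CON, nets$PAS)
    emit(write_tsv(
      data.frame(delta_nodes = cmp$delta_nodes, delta_edges = cmp$delta_edges,
                 delta_pct_positive = cmp$delta_pct_positive,
                 delta_contribution = cmp$delta_contribution),
      file.path(out_dir, "network_comparison.tsv")))
    results$networks <- nets
    results$network_comparison <- cmp
  })

  # ---- fermentation ----------------------------------------------------
  if (!is.null(ferm)) stage("fermentation", {
    fs <- fermentation_summary(ferm, metadata)
    h2 <- vapply(DIETS, function(d) {
      mu <- fs$mean_CON
      means <- stats::setNames(
        if (d == "CON") fs$mean_CON else fs$mean_PAS, fs$variable)
      h2_production(means)
    }, numeric(1))
    fs <- rbind(fs, data.frame(variable = "H2_production",
                               mean_CON = h2[["CON"]], mean_PAS = h2[["PAS"]],
                               SED = NA_real_, p_value = NA_real_,
                               degenerate = FALSE))
    emit(write_tsv(fs, file.path(out_dir, "fermentation_summary.tsv")))
    results$fermentation <- fs
  })

  # ---- provenance ------------------------------------------------------
  stage("manifest", {
    cfg_path <- file.path(out_dir, "config.yaml")
    cfg <- unclass(config)
    yaml::write_yaml(cfg, cfg_path)
    emit(cfg_path)
    sums <- tools::md5sum(sort(unique(files)))
    manifest <- data.frame(file = basename(names(sums)), md5 = unname(sums))
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  say("run complete: %d output files in %s", length(unique(files)) + 1,
      out_dir)
  invisible(c(results, list(out_dir = out_dir)))
}
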