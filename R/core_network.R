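#' Prevalence-based core microbiota partition
#'
#' Partitions the taxa of one kingdom by prevalence across animals within
#' each diet: the shared core (prevalence >= threshold under BOTH diets),
#' and per-diet specific cores (>= threshold under one diet, below it under
#' the other). For each set and diet the summed mean relative abundance (%)
#' is reported, i.e. how much of the community the set represents.
#'
#' @param x a [normalize_table()] or [count_table()].
#' @param metadata a [sample_metadata()] frame.
#' @param threshold prevalence cut in (0, 1\]; default 0.95 ("present in at
#'   least 95% of animals").
#' @return object of class `core_partition`: `shared_core`,
#'   `diet_specific_core` (list CON/PAS), `abundance_fraction` (matrix,
#'   set x diet, in %), `prevalence` (taxon x diet), `threshold`, `kingdom`.
#' @export
core_partition <- function(x, metadata, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1)
    stopf("threshold must be in (0, 1]")
  counts <- x$counts
  rel <- to_relative(counts)
  for (d in DIETS)
    if (!any(metadata$diet == d)) stopf("diet %s absent from metadata", d)
  prev <- sapply(DIETS, function(d) {
    prevalence(counts, metadata$sample[metadata$diet == d])
  })
  shared <- rownames(prev)[prev[, "CON"] >= threshold &
                           prev[, "PAS"] >= threshold]
  con_only <- rownames(prev)[prev[, "CON"] >= threshold &
                             prev[, "PAS"] < threshold]
  pas_only <- rownames(prev)[prev[, "PAS"] >= threshold &
                             prev[, "CON"] < threshold]
  sets <- list(shared = shared, CON_specific = con_only,
               PAS_specific = pas_only)
  frac <- sapply(DIETS, function(d) {
    samp <- metadata$sample[metadata$diet == d]
    mr <- rowMeans(rel[, samp, drop = FALSE])
    vapply(sets, function(s) 100 * sum(mr[s]), numeric(1))
  })
  structure(list(shared_core = shared,
                 diet_specific_core = list(CON = con_only, PAS = pas_only),
                 abundance_fraction = frac,
                 prevalence = prev,
                 threshold = threshold,
                 kingdom = x$kingdom %||% NA_character_),
            class = "core_partition")
}

#' @export
print.core_partition <- function(x, ...) {
  cat(sprintf("core partition [%s] at prevalence >= %.2f\n",
              x$kingdom, x$threshold))
  cat(sprintf("  shared core: %d taxa (%.1f%% CON / %.1f%% PAS of community)\n",
              length(x$shared_core), x$abundance_fraction["shared", "CON"],
              x$abundance_fraction["shared", "PAS"]))
  cat(sprintf("  CON-specific: %d taxa; PAS-specific: %d taxa\n",
              length(x$diet_specific_core$CON),
              length(x$diet_specific_core$PAS)))
  invisible(x)
}

#' Pool kingdoms into one multi-kingdom abundance object
#'
#' Stacks the log10 abundance matrices of several kingdoms over their common
#' samples for cross-kingdom correlation and network analysis. Protozoa,
#' recorded as percentage compositions, are converted to log10 cells/mL via
#' the total protozoal concentration from the fermentation profile when one
#' is supplied (log abundance of a group = log10 of its cell concentration),
#' otherwise log10(percent + 1) is used.
#'
#' @param tables named list of [normalize_table()] results (names ignored;
#'   kingdoms are read from the tables).
#' @param fermentation optional [fermentation_profile()] providing
#'   `protozoa_log` totals.
#' @return object of class `multi_kingdom`: `log_abundance` (taxa x
#'   samples), `kingdom` (per taxon), `mean_rel_abundance` (per taxon,
#'   within its own kingdom), `samples`.
#' @export
combine_kingdoms <- function(tables, fermentation = NULL) {
  stopifnot(length(tables) >= 1)
  samples <- Reduce(intersect, lapply(tables, `[[`, "samples"))
  if (length(samples) == 0) stopf("tables share no samples")
  taxa_all <- unlist(lapply(tables, `[[`, "taxa"))
  if (anyDuplicated(taxa_all))
    stopf("taxon IDs must be unique across kingdoms")
  mats <- lapply(tables, function(tb) {
    if (tb$kingdom == "protozoa" && !is.null(fermentation)) {
      ferm <- as.data.frame(fermentation)
      rownames(ferm) <- ferm$sample
      tot <- 10^ferm[samples, "protozoa_log"]
      cells <- sweep(tb$counts[, samples, drop = FALSE] / 100, 2, tot, "*")
      log10_p1(cells)
    } else {
      tb$log_abundance[, samples, drop = FALSE]
    }
  })
  structure(list(
    log_abundance = do.call(rbind, mats),
    kingdom = stats::setNames(
      unlist(lapply(tables, function(tb) rep(tb$kingdom, length(tb$taxa))),
             use.names = FALSE), taxa_all),
    mean_rel_abundance = stats::setNames(
      unlist(lapply(tables, function(tb) rowMeans(tb$rel_abundance)),
             use.names = FALSE), taxa_all),
    samples = samples), class = "multi_kingdom")
}

#' Thresholded multi-kingdom co-occurrence network
#'
#' All-pairs Spearman correlation of log10 taxon abundances within one diet,
#' filtered to strong, significant associations: taxa must be present in
#' more than `prevalence_min` of the diet's samples (strict inequality),
#' and an edge requires |rho| > `r_min` together with a multiplicity-adjusted
#' p below `alpha`. Adjustment spans all tested pairs
#' (Benjamini-Hochberg by default; Bonferroni available). Nodes are the taxa
#' incident to at least one retained edge.
#'
#' Complexity metrics: node/edge counts, positive/negative edge counts,
#' mean neighbors 2E/N, unnormalized shortest-path betweenness per node
#' (unit edge weights, via \pkg{igraph}), and the contribution of the node
#' taxa to the total community (summed mean relative abundance within each
#' kingdom, %).
#'
#' @param x a [combine_kingdoms()] object (or single [normalize_table()]).
#' @param metadata a [sample_metadata()] frame.
#' @param diet `"CON"` or `"PAS"`.
#' @param r_min correlation threshold; edge needs |rho| > r_min (default 0.5).
#' @param alpha threshold on adjusted p (default 0.05).
#' @param adjust p-adjustment method across all tested pairs (default "BH").
#' @param prevalence_min prevalence gate, strict (default 0.5).
#' @param min_n minimum within-diet sample count (default 5).
#' @return object of class `cooccurrence_network`: `nodes` (data.frame with
#'   taxon, kingdom, mean_rel_abundance, betweenness), `edges` (source,
#'   target, rho, sign, p_adj), `metrics`, `params`, `warning` flag.
#' @export
build_network <- function(x, metadata, diet = c("CON", "PAS"), r_min = 0.5,
                          alpha = 0.05, adjust = "BH", prevalence_min = 0.5,
                          min_n = 5) {
  diet <- match.arg(diet)
  if (inherits(x, "normalized_table")) {
    x <- combine_kingdoms(list(x))
  }
  stopifnot(inherits(x, "multi_kingdom"))
  samples <- intersect(metadata$sample[metadata$diet == diet], x$samples)
  if (length(samples) < min_n)
    stopf("only %d samples on diet %s (need >= %d)", length(samples), diet,
          min_n)
  la <- x$log_abundance[, samples, drop = FALSE]
  prev <- rowMeans(la > 0)
  gated <- rownames(la)[prev > prevalence_min]
  params <- list(diet = diet, r_min = r_min, alpha = alpha, adjust = adjust,
                 prevalence_min = prevalence_min)
  empty <- function(warn) {
    nodes <- data.frame(taxon = character(), kingdom = character(),
                        mean_rel_abundance = numeric(),
                        betweenness = numeric(), stringsAsFactors = FALSE)
    edges <- data.frame(source = character(), target = character(),
                        rho = numeric(), sign = character(),
                        p_adj = numeric(), stringsAsFactors = FALSE)
    structure(list(nodes = nodes, edges = edges,
                   metrics = list(n_nodes = 0L, n_edges = 0L,
                                  n_positive = 0L, n_negative = 0L,
                                  mean_neighbors = NA_real_,
                                  community_contribution = numeric()),
                   n_tested_pairs = 0L, params = params, warning = warn),
              class = "cooccurrence_network")
  }
  if (length(gated) < 2) {
    w <- empty(TRUE)
    warning("fewer than 2 taxa pass the prevalence gate; empty network")
    return(w)
  }
  sp <- spearman_matrix(la[gated, , drop = FALSE])
  ut <- which(upper.tri(sp$rho), arr.ind = TRUE)
  rho <- sp$rho[ut]
  p <- sp$p[ut]
  ok <- !is.na(rho)
  ut <- ut[ok, , drop = FALSE]; rho <- rho[ok]; p <- p[ok]
  p_adj <- p.adjust(p, method = adjust)
  keep <- abs(rho) > r_min & p_adj < alpha
  edges <- data.frame(source = gated[ut[keep, 1]],
                      target = gated[ut[keep, 2]],
                      rho = rho[keep],
                      sign = ifelse(rho[keep] > 0, "+", "-"),
                      p_adj = p_adj[keep], stringsAsFactors = FALSE)
  # canonical edge orientation for deterministic output
  flip <- edges$source > edges$target
  tmp <- edges$source[flip]
  edges$source[flip] <- edges$target[flip]
  edges$target[flip] <- tmp
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0) {
    out <- empty(TRUE)
    out$n_tested_pairs <- length(rho)
    warning("no edges pass the correlation/significance filter")
    return(out)
  }
  node_taxa <- sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = node_taxa)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  nodes <- data.frame(taxon = node_taxa,
                      kingdom = unname(x$kingdom[node_taxa]),
                      mean_rel_abundance = unname(
                        x$mean_rel_abundance[node_taxa]),
                      betweenness = unname(btw[node_taxa]),
                      stringsAsFactors = FALSE)
  contrib <- tapply(nodes$mean_rel_abundance, nodes$kingdom, sum) * 100
  metrics <- list(n_nodes = nrow(nodes), n_edges = nrow(edges),
                  n_positive = sum(edges$sign == "+"),
                  n_negative = sum(edges$sign == "-"),
                  mean_neighbors = 2 * nrow(edges) / nrow(nodes),
                  community_contribution = contrib)
  structure(list(nodes = nodes, edges = edges, metrics = metrics,
                 n_tested_pairs = length(rho), params = params,
                 warning = FALSE),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("co-occurrence network (%s): %d nodes, %d edges (%d+/%d-)\n",
              x$params$diet, m$n_nodes, m$n_edges, m$n_positive,
              m$n_negative))
  if (m$n_nodes > 0)
    cat(sprintf("  mean neighbors %.2f; kingdom contribution (%%): %s\n",
                m$mean_neighbors,
                paste(sprintf("%s %.1f", names(m$community_contribution),
                              m$community_contribution), collapse = ", ")))
  invisible(x)
}

#' Compare two co-occurrence networks
#'
#' Differences in complexity between networks built under identical
#' thresholds (typically CON vs PAS): delta nodes, delta edges, delta in the
#' percentage of positive edges, delta community contribution, and the
#' kingdom composition of each network's nodes (%).
#'
#' @param net_a,net_b [build_network()] results with identical `params`
#'   (apart from diet).
#' @return object of class `network_comparison`.
#' @export
compare_networks <- function(net_a, net_b) {
  pa <- net_a$params; pb <- net_b$params
  same <- identical(pa[setdiff(names(pa), "diet")],
                    pb[setdiff(names(pb), "diet")])
  if (!same) stopf("networks were built with different thresholds")
  pct_pos <- function(n) {
    if (n$metrics$n_edges == 0) return(NA_real_)
    100 * n$metrics$n_positive / n$metrics$n_edges
  }
  kingdom_pct <- function(n) {
    if (n$metrics$n_nodes == 0) return(numeric())
    100 * table(n$nodes$kingdom) / n$metrics$n_nodes
  }
  contrib_total <- function(n) {
    cc <- n$metrics$community_contribution
    if (length(cc) == 0) 0 else mean(cc)
  }
  structure(list(
    delta_nodes = net_b$metrics$n_nodes - net_a$metrics$n_nodes,
    delta_edges = net_b$metrics$n_edges - net_a$metrics$n_edges,
    delta_pct_positive = pct_pos(net_b) - pct_pos(net_a),
    delta_contribution = contrib_total(net_b) - contrib_total(net_a),
    kingdom_pct = list(a = kingdom_pct(net_a), b = kingdom_pct(net_b)),
    diets = c(pa$diet, pb$diet)), class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("network comparison (%s -> %s): %+d nodes, %+d edges\n",
              x$diets[1], x$diets[2], x$delta_nodes, x$delta_edges))
  invisible(x)
}
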