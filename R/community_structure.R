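#' Bray-Curtis dissimilarity matrix
#'
#' d(i, j) = sum |x_i - x_j| / sum (x_i + x_j) over taxa, computed between
#' all sample pairs (via \pkg{vegan}). Input should be depth-normalized
#' counts or relative abundances so that samples are comparable.
#'
#' @param x a [normalize_table()] result, a [count_table()], or a numeric
#'   taxa-by-samples matrix.
#' @return symmetric samples-by-samples matrix in \[0, 1\] with zero diagonal.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, c("normalized_table", "count_table"))) x$counts else x
  if (any(colSums(m) == 0))
    stopf("zero-sum sample(s): %s",
          paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

permanova_F <- function(d2, groups) {
  # d2: squared distance matrix; SS via Anderson's partition
  n <- nrow(d2)
  lev <- unique(groups)
  a <- length(lev)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in lev) {
    idx <- which(groups == g)
    dg <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dg[upper.tri(dg)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

#' PERMANOVA for the diet effect with design-respecting permutations
#'
#' Permutational multivariate analysis of variance on a (Bray-Curtis)
#' dissimilarity matrix. Sums of squares follow the standard distance-based
#' partition: SS_total = sum of squared dissimilarities / N over all pairs,
#' SS_within from within-group pairs, and
#' pseudo-F = (SS_between / (a - 1)) / (SS_within / (N - a)).
#'
#' Because the design is repeated measures (every animal sampled under both
#' diets), free label shuffling would break the animal stratification.
#' Permutations therefore swap the two diet labels *within* each paired
#' animal; in this one-factor paired design that restricted scheme is the
#' reduced-model residual permutation. With n paired animals there are 2^n
#' distinct relabellings; when `n_perm >= 2^n - 1` (or `exhaustive = TRUE`)
#' they are enumerated exactly and p = #\{F* >= F\} / 2^n, otherwise random
#' swaps give the Monte-Carlo estimate p = (1 + #\{F* >= F\}) / (n_perm + 1).
#'
#' Also reports, per diet, the descriptive group similarity
#' 100 x (1 - mean within-diet dissimilarity).
#'
#' @param d symmetric dissimilarity matrix with sample dimnames.
#' @param metadata a [sample_metadata()] frame.
#' @param n_perm number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param exhaustive force (or forbid, `FALSE`) complete enumeration;
#'   default `NULL` enumerates whenever cheaper than `n_perm` draws.
#' @return object of class `rumen_permanova`: `pseudo_F`, `p_perm`,
#'   `n_permutations`, `df_between`, `df_within`, `group_similarity`,
#'   `method`.
#' @export
permanova <- function(d, metadata, n_perm = 999, seed = 1L,
                      exhaustive = NULL) {
  d <- as.matrix(d)
  samples <- rownames(d)
  md <- metadata[match(samples, metadata$sample), ]
  if (anyNA(md$sample)) stopf("distance matrix samples missing from metadata")
  groups <- md$diet
  if (length(unique(groups)) < 2)
    stopf("diet factor is constant; PERMANOVA needs two groups")
  if (min(table(groups)) < 2)
    stopf("each diet needs at least two samples")
  n <- length(samples)
  a <- length(unique(groups))
  d2 <- d^2
  f_obs <- permanova_F(d2, groups)

  pairs <- paired_animals(md)
  if (length(pairs) == 0)
    stopf("no paired animals; the restricted permutation scheme needs pairs")
  pair_idx <- lapply(pairs, function(an) which(md$animal == an))
  np <- length(pairs)

  do_exhaustive <- exhaustive %||% (2^np - 1 <= n_perm)
  if (do_exhaustive && np > 20)
    stopf("exhaustive enumeration of 2^%d swaps is not feasible", np)

  swap_groups <- function(flips) {
    g <- groups
    for (k in which(flips)) g[pair_idx[[k]]] <- rev(g[pair_idx[[k]]])
    g
  }

  if (do_exhaustive) {
    total <- 2^np
    f_all <- numeric(total)
    for (i in seq_len(total) - 1L) {
      flips <- as.logical(bitwAnd(i, 2^(seq_len(np) - 1L)))
      f_all[i + 1L] <- permanova_F(d2, swap_groups(flips))
    }
    p <- mean(f_all >= f_obs - 1e-12)
    n_used <- total
    method <- "exhaustive"
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        permanova_F(d2, swap_groups(runif(np) < 0.5))
      }, numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
    method <- "monte-carlo"
  }

  sim <- vapply(unique(groups), function(g) {
    idx <- which(groups == g)
    dg <- d[idx, idx]
    100 * (1 - mean(dg[upper.tri(dg)]))
  }, numeric(1))
  names(sim) <- unique(groups)

  structure(list(pseudo_F = f_obs, p_perm = p, n_permutations = n_used,
                 df_between = a - 1, df_within = n - a,
                 group_similarity = sim, method = method),
            class = "rumen_permanova")
}

#' @export
print.rumen_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (within-animal %s permutations, n = %d)\n",
              x$method, x$n_permutations))
  cat(sprintf("  pseudo-F = %.3f (df %d, %d), p = %.4g\n",
              x$pseudo_F, x$df_between, x$df_within, x$p_perm))
  cat("  group similarity (%):",
      paste(sprintf("%s %.1f", names(x$group_similarity),
                    x$group_similarity), collapse = ", "), "\n")
  invisible(x)
}

#' Canonical correspondence analysis against fermentation covariates
#'
#' Constrained ordination of the chi-square standardized community matrix on
#' rumen chemistry covariates (fitted with \pkg{vegan}). The community matrix
#' is samples x taxa counts; taxa with zero total are dropped. Covariates
#' must be complete and linearly independent - collinear columns raise an
#' error naming the dependent ones rather than being silently dropped.
#' Per-variable significance comes from marginal permutation tests
#' (`anova.cca`, `by = "margin"`), seeded for reproducibility. Reported
#' scores use taxon-focused scaling (scaling 2).
#'
#' @param x a [normalize_table()] result (or count matrix, taxa x samples).
#' @param constraints data.frame of numeric covariates, one row per sample in
#'   the order of the community samples.
#' @param n_perm permutations for the per-variable tests (default 999).
#' @param seed RNG seed.
#' @return object of class `rumen_cca`: `eigenvalues` (constrained),
#'   `total_inertia`, `constrained_inertia`, `site_scores`, `taxon_scores`,
#'   `biplot_scores`, `var_p`, and the underlying vegan `model`.
#' @export
cca_fermentation <- function(x, constraints, n_perm = 999, seed = 1L) {
  m <- if (inherits(x, c("normalized_table", "count_table"))) x$counts else x
  m <- m[rowSums(m) > 0, , drop = FALSE]
  comm <- t(m)
  constraints <- as.data.frame(constraints)
  if (anyNA(constraints)) stopf("constraints contain missing values")
  if (nrow(constraints) != nrow(comm))
    stopf("constraints must have one row per sample")
  cm <- scale(as.matrix(constraints))
  qrd <- qr(cm)
  if (qrd$rank < ncol(cm)) {
    dep <- colnames(cm)[setdiff(seq_len(ncol(cm)),
                                qrd$pivot[seq_len(qrd$rank)])]
    stopf("collinear constraint column(s): %s", paste(dep, collapse = ", "))
  }
  mod <- vegan::cca(comm ~ ., data = constraints)
  var_p <- with_seed(seed, {
    # vegan chats about complete enumeration on tiny designs
    an <- suppressMessages(
      vegan::anova.cca(mod, by = "margin", permutations = n_perm))
    p <- an[["Pr(>F)"]]
    names(p) <- rownames(an)
    p[names(constraints)]
  })
  structure(list(
    eigenvalues = mod$CCA$eig,
    total_inertia = mod$tot.chi,
    constrained_inertia = sum(mod$CCA$eig),
    site_scores = vegan::scores(mod, display = "sites", scaling = 2),
    taxon_scores = vegan::scores(mod, display = "species", scaling = 2),
    biplot_scores = vegan::scores(mod, display = "bp", scaling = 2),
    var_p = var_p,
    model = mod), class = "rumen_cca")
}

#' @export
print.rumen_cca <- function(x, ...) {
  cat(sprintf("CCA: %d constrained axes, inertia %.4f of %.4f (%.1f%%)\n",
              length(x$eigenvalues), x$constrained_inertia, x$total_inertia,
              100 * x$constrained_inertia / x$total_inertia))
  cat("  per-variable permutation p:\n")
  print(round(x$var_p, 4))
  invisible(x)
}
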