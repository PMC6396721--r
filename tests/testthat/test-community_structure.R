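test_that("Bray-Curtis matches the hand formula", {
  m <- matrix(c(6, 2, 0, 2, 2, 0, 6, 2, 0, 0, 0, 5), nrow = 3,
              dimnames = list(c("a", "b", "c"),
                              c("x", "y", "same_x", "disjoint")))
  # x=[6,2,0] vs y=[2,2,0]: (4+0+0)/(8+4+0) = 1/3
  d <- bray_curtis(m)
  expect_equal(d["x", "y"], 1 / 3)
  expect_equal(d["x", "same_x"], 0)
  expect_equal(d["y", "disjoint"], 1)  # disjoint supports
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  m0 <- m; m0[, 2] <- 0
  expect_error(bray_curtis(m0), "zero-sum")
})

test_that("pseudo-F agrees with vegan::adonis2", {
  st <- simulate_study(6, flat_truth(), seed = 3)
  d <- bray_curtis(normalize_table(st$tables$bacteria, seed = 3))
  pm <- permanova(d, st$metadata, n_perm = 49, seed = 1, exhaustive = FALSE)
  a2 <- vegan::adonis2(stats::as.dist(d) ~ diet,
                       data = as.data.frame(st$metadata), permutations = 9)
  expect_equal(pm$pseudo_F, a2$F[1], tolerance = 1e-10)
  expect_equal(pm$df_between, 1)
  expect_equal(pm$df_within, 10)
})

test_that("exhaustive permutation p matches brute-force enumeration (n = 6)", {
  st <- simulate_study(4, flat_truth(n_taxa = 10, depth = c(500L, 800L)),
                       seed = 5)
  md <- st$metadata[st$metadata$animal != "A04", ]  # 3 animals, 6 samples
  nb <- normalize_table(st$tables$bacteria, seed = 5)
  d <- bray_curtis(nb)[md$sample, md$sample]
  pm <- permanova(d, md, exhaustive = TRUE)
  expect_equal(pm$n_permutations, 8)

  # independent oracle: adonis2 F on every within-animal relabelling
  animals <- unique(md$animal)
  f_all <- vapply(0:7, function(i) {
    g <- md$diet
    flips <- as.logical(bitwAnd(i, 2^(0:2)))
    for (k in which(flips)) {
      idx <- which(md$animal == animals[k])
      g[idx] <- rev(g[idx])
    }
    vegan::adonis2(stats::as.dist(d) ~ g, data = data.frame(g = g),
                   permutations = 2)$F[1]
  }, numeric(1))
  expect_equal(pm$p_perm, mean(f_all >= pm$pseudo_F - 1e-12))
})

test_that("extreme separation yields the minimal permutation p", {
  n <- 12
  md <- paired_md(n)
  m <- matrix(0, nrow = 2, ncol = 2 * n,
              dimnames = list(c("a", "b"), md$sample))
  m["a", md$diet == "CON"] <- 10 + seq_len(n) / 100
  m["b", md$diet == "PAS"] <- 10 + seq_len(n) / 100
  m[m == 0] <- 0.01
  d <- bray_curtis(m)
  pm <- permanova(d, md, n_perm = 199, seed = 7)
  expect_equal(pm$p_perm, 1 / 200)
  expect_gte(min(pm$group_similarity), 90)  # tight within-diet similarity
})

test_that("pseudo-F is invariant to sample order", {
  st <- simulate_study(5, flat_truth(), seed = 8)
  d <- bray_curtis(normalize_table(st$tables$bacteria, seed = 8))
  perm <- sample(rownames(d))
  pm1 <- permanova(d, st$metadata, exhaustive = TRUE)
  pm2 <- permanova(d[perm, perm], st$metadata, exhaustive = TRUE)
  expect_equal(pm1$pseudo_F, pm2$pseudo_F)
  expect_equal(pm1$p_perm, pm2$p_perm)
})

test_that("CCA total inertia equals the direct chi-square computation", {
  X <- matrix(c(10, 2, 0, 3, 1, 8, 2, 0, 0, 3, 9, 1, 2, 0, 4, 7,
                5, 5, 5, 5), nrow = 4,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:5)))
  P <- X / sum(X)
  E <- rowSums(P) %o% colSums(P)
  direct <- sum((P - E)^2 / E)
  set.seed(1)
  cons <- data.frame(a = rnorm(4), b = rnorm(4))
  m <- cca_fermentation(t(X), cons, n_perm = 99, seed = 1)
  expect_equal(m$total_inertia, direct, tolerance = 1e-10)
  expect_lte(m$constrained_inertia, m$total_inertia + 1e-12)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))  # non-increasing
})

test_that("a constraint equal to the first CA axis recovers its eigenvalue", {
  X <- matrix(c(10, 2, 0, 3, 1, 8, 2, 0, 0, 3, 9, 1, 2, 0, 4, 7,
                5, 5, 5, 5), nrow = 4,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:5)))
  ca <- vegan::cca(X)
  ax1 <- as.numeric(vegan::scores(ca, display = "sites", choices = 1,
                                  scaling = 1))
  m <- cca_fermentation(t(X), data.frame(ax1 = ax1), n_perm = 99, seed = 1)
  expect_equal(unname(m$eigenvalues[1]), unname(ca$CA$eig[1]),
               tolerance = 1e-8)
})

test_that("collinear constraints raise an informative error", {
  st <- simulate_study(6, flat_truth(), seed = 2)
  nb <- normalize_table(st$tables$bacteria, seed = 2)
  set.seed(3)
  cons <- data.frame(u = rnorm(12), v = rnorm(12))
  cons$w <- cons$u + 2 * cons$v
  expect_error(cca_fermentation(nb, cons, n_perm = 9), "collinear.*w")
})

test_that("a pure-noise constraint is mostly non-significant", {
  st <- simulate_study(10, flat_truth(n_taxa = 15), seed = 31)
  nb <- normalize_table(st$tables$bacteria, seed = 31)
  ps <- vapply(1:20, function(s) {
    set.seed(s)
    cons <- data.frame(noise = rnorm(20))
    cca_fermentation(nb, cons, n_perm = 199, seed = s)$var_p[["noise"]]
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})
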