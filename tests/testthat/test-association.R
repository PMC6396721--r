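test_that("paired diet test handles degenerate differences", {
  st <- simulate_study(6, flat_truth(), seed = 13)
  nb <- normalize_table(st$tables$bacteria, seed = 13)
  # force identical diets: copy CON values onto PAS samples
  md <- st$metadata
  nb$log_abundance[, md$sample[md$diet == "PAS"]] <-
    nb$log_abundance[, md$sample[md$diet == "CON"]]
  res <- paired_diet_test(nb, md)
  expect_true(all(res$p_raw == 1))
  expect_true(all(res$SED == 0))
  expect_false(any(res$degenerate))

  # constant nonzero shift: below machine floor, flagged
  nb$log_abundance[1, md$sample[md$diet == "PAS"]] <-
    nb$log_abundance[1, md$sample[md$diet == "CON"]] + 0.5
  res2 <- paired_diet_test(nb, md)
  r1 <- res2[res2$taxon == nb$taxa[1], ]
  expect_true(r1$degenerate)
  expect_lte(r1$p_raw, .Machine$double.xmin)
})

test_that("Bonferroni-significant taxa are a subset of raw-significant taxa", {
  st <- simulate_study(12, default_truth(), seed = 17)
  nb <- normalize_table(st$tables$bacteria, seed = 17)
  res <- paired_diet_test(nb, st$metadata)
  expect_equal(res$p_bonferroni,
               pmin(1, res$p_raw * attr(res, "n_tested")))
  expect_true(all(res$taxon[res$p_bonferroni < 0.05] %in%
                  res$taxon[res$p_raw < 0.05]))
  # planted strong effects are detected
  planted <- names(st$truth$diet_log_effects)
  planted <- intersect(planted[abs(st$truth$diet_log_effects) >= 0.4],
                       res$taxon)
  expect_gt(mean(res$significant[match(planted, res$taxon)]), 0.8)
})

test_that("paired test absorbs animal-specific constants", {
  st <- simulate_study(8, flat_truth(), seed = 23)
  nb <- normalize_table(st$tables$bacteria, seed = 23)
  res1 <- paired_diet_test(nb, st$metadata)
  # add a per-animal offset to both diets: the diet contrast is unchanged
  md <- st$metadata
  offs <- stats::setNames(rnorm(8, sd = 2), unique(md$animal))
  nb2 <- nb
  nb2$log_abundance <- sweep(nb$log_abundance, 2, offs[md$animal[
    match(colnames(nb$log_abundance), md$sample)]], "+")
  res2 <- paired_diet_test(nb2, md)
  expect_equal(res2$p_raw, res1$p_raw, tolerance = 1e-9)
  expect_equal(res2$SED, res1$SED, tolerance = 1e-9)
})

test_that("planted paired effects are detected with near-certain power", {
  # +0.5 log10 shift against sd 0.3 differences, n = 24 pairs
  closed_form <- power.t.test(n = 24, delta = 0.5, sd = 0.3 * sqrt(2),
                              sig.level = 0.05, type = "paired")$power
  expect_gte(closed_form, 0.9)
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    d <- rnorm(24, mean = 0.5, sd = 0.3 * sqrt(2))
    t.test(d)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Spearman rho matches hand-computed tie-corrected value", {
  x <- matrix(c(1, 2, 3, 4, 5), nrow = 1, dimnames = list("x", NULL))
  y <- matrix(c(5, 6, 7, 8, 7), nrow = 1, dimnames = list("y", NULL))
  sp <- rumenshift:::spearman_matrix(x, y)
  # average ranks of y: 1, 2, 3.5, 5, 3.5 -> r = 8 / sqrt(10 * 9.5)
  expect_equal(sp$rho[1, 1], 8 / sqrt(10 * 9.5), tolerance = 1e-12)
  expect_equal(round(sp$rho[1, 1], 3), 0.821)
})

test_that("the screen is invariant to monotone transforms and masks weak cells", {
  st <- simulate_study(8, default_truth(), seed = 29)
  nb <- normalize_table(st$tables$bacteria, seed = 29)
  sc1 <- spearman_screen(nb, st$fermentation, st$metadata, "CON")
  # monotone transform of the abundances: identical rank correlations
  nb2 <- nb
  nb2$log_abundance <- exp(nb$log_abundance)
  sc2 <- spearman_screen(nb2, st$fermentation, st$metadata, "CON")
  expect_equal(sc1$rho, sc2$rho, tolerance = 1e-12)
  expect_true(all(abs(sc1$rho[sc1$mask]) >= 0.30))
  expect_true(all(is.na(sc1$rho) | abs(sc1$rho) <= 1))
  # self-correlation of a monotone pair is exactly 1
  la <- nb$log_abundance[1:2, , drop = FALSE]
  la[2, ] <- la[1, ]^3 + 5
  sp <- rumenshift:::spearman_matrix(la)
  expect_equal(sp$rho[1, 2], 1)
  expect_equal(sp$p[1, 2], 0)
})

test_that("independent vectors rarely reach the network correlation gate", {
  set.seed(101)
  n <- 24
  hits <- replicate(2000, {
    abs(cor(rnorm(n), rnorm(n), method = "spearman")) >= 0.5
  })
  expect_lt(mean(hits), 0.02)
})

test_that("constant vectors yield missing correlation cells", {
  st <- simulate_study(6, flat_truth(), seed = 37)
  nb <- normalize_table(st$tables$bacteria, seed = 37)
  nb$log_abundance[1, ] <- 2  # constant taxon
  sc <- spearman_screen(nb, st$fermentation %||%
                          simulate_study(6, default_truth(), seed = 37)$fermentation,
                        st$metadata, "CON")
  expect_true(all(is.na(sc$rho[1, ])))
  expect_false(any(sc$mask[1, ]))
})
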