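test_that("a full simulation yields a complete paired design per kingdom", {
  st <- simulate_study(24, default_truth(), seed = 1)
  for (k in c("bacteria", "methanogen", "fungus", "protozoa")) {
    expect_equal(length(st$tables[[k]]$samples), 48)
  }
  expect_equal(length(paired_animals(st$metadata)), 24)
  expect_equal(nrow(st$fermentation), 48)
})

test_that("identical seeds give identical studies; truth is deterministic", {
  expect_identical(default_truth(), default_truth())
  a <- simulate_study(6, default_truth(), seed = 99)
  b <- simulate_study(6, default_truth(), seed = 99)
  expect_identical(a$tables, b$tables)
  expect_identical(as.data.frame(a$fermentation),
                   as.data.frame(b$fermentation))
  c <- simulate_study(6, default_truth(), seed = 100)
  expect_false(identical(a$tables$bacteria$counts, c$tables$bacteria$counts))
})

test_that("default truth matches its documented study conditions", {
  tr <- default_truth()
  expect_equal(length(tr$kingdoms$bacteria$core), 34)
  expect_equal(length(tr$kingdoms$methanogen$core), 9)
  expect_equal(length(tr$kingdoms$fungus$core), 13)
  expect_equal(length(tr$kingdoms$bacteria$con_specific), 8)
  expect_equal(length(tr$kingdoms$bacteria$pas_specific), 10)
  expect_equal(length(tr$modules), 3)
  # depth midpoints within 20% of the emulated platform depths
  mids <- vapply(tr$kingdoms, function(k) mean(k$depth_range), numeric(1))
  ref <- c(bacteria = 12500, methanogen = 1098, fungus = 8901)
  expect_true(all(abs(mids - ref) / ref < 0.2))
})

test_that("multinomial sampling conserves the drawn depth exactly", {
  st <- simulate_study(8, default_truth(), seed = 12)
  for (k in c("bacteria", "methanogen", "fungus")) {
    depths <- colSums(st$tables[[k]]$counts)
    rng <- st$truth$kingdoms[[k]]$depth_range
    expect_true(all(depths >= rng[1] & depths <= rng[2]))
  }
  # protozoa are percentage compositions
  expect_equal(unname(colSums(st$tables$protozoa$counts)), rep(100, 16),
               tolerance = 1e-4)
})

test_that("equal baselines with no effects give a uniform expected composition", {
  taxa <- paste0("t", 1:7)
  tr <- synthetic_truth(kingdoms = list(bacteria = kingdom_spec(
    taxa, stats::setNames(rep(0.3, 7), taxa), depth_range = c(100L, 100L))))
  for (d in c("CON", "PAS"))
    expect_equal(unname(planted_composition(tr, "bacteria", d)),
                 rep(1 / 7, 7), tolerance = 1e-12)
})

test_that("raising a diet effect strictly raises expected PAS abundance", {
  taxa <- paste0("t", 1:5)
  base <- stats::setNames(rep(0, 5), taxa)
  comp <- function(eff) {
    tr <- synthetic_truth(
      kingdoms = list(bacteria = kingdom_spec(taxa, base,
                                              depth_range = c(100L, 100L))),
      diet_log_effects = c(t1 = eff))
    planted_composition(tr, "bacteria", "PAS")[["t1"]]
  }
  effs <- seq(-1, 1, by = 0.25)
  vals <- vapply(effs, comp, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("planted modules express strong within-diet rank correlation", {
  tr <- default_truth()
  frac_high <- vapply(1:20, function(s) {
    st <- simulate_study(24, tr, seed = 400 + s)
    nb <- normalize_table(st$tables$bacteria, seed = s)
    con <- st$metadata$sample[st$metadata$diet == "CON"]
    unlist(lapply(tr$modules[1:2], function(m) {
      r <- cor(t(nb$log_abundance[m$taxa, con]), method = "spearman")
      r[upper.tri(r)] > 0.5
    }))
  }, logical(20))
  expect_gte(mean(frac_high), 0.8)
})

test_that("degenerate compositions are rejected", {
  taxa <- c("dominant", "rare")
  tr <- synthetic_truth(kingdoms = list(bacteria = kingdom_spec(
    taxa, stats::setNames(c(8, 0), taxa), depth_range = c(100L, 100L))))
  expect_error(simulate_study(4, tr, seed = 1), "degenerate composition")
})

test_that("truth construction validates module strength and taxa", {
  taxa <- paste0("t", 1:6)
  kd <- list(bacteria = kingdom_spec(taxa, stats::setNames(rep(1, 6), taxa)))
  expect_error(synthetic_truth(kd, modules = list(
    list(taxa = taxa[1:3], rho_target = 0.4))), "rho_target")
  expect_error(synthetic_truth(kd, modules = list(
    list(taxa = c("t1", "zz"), rho_target = 0.9))), "missing")
  expect_error(synthetic_truth(kd, diet_log_effects = c(zz = 1)), "unknown")
})
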