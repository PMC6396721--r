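test_that("core partition applies the prevalence threshold per diet", {
  md <- paired_md(24)
  con <- md$sample[md$diet == "CON"]
  pas <- md$sample[md$diet == "PAS"]
  m <- matrix(0L, nrow = 3, ncol = 48,
              dimnames = list(c("everywhere", "pas_core", "rare"), md$sample))
  m["everywhere", ] <- 5L
  m["pas_core", pas[1:23]] <- 5L       # 23/24 = 0.958 on PAS
  m["pas_core", con[1:9]] <- 5L        # 9/24 on CON
  m["rare", c(con[1:3], pas[1:3])] <- 2L
  ct <- count_table(m, "bacteria")
  cp <- core_partition(ct, md)
  expect_equal(cp$shared_core, "everywhere")
  expect_equal(cp$diet_specific_core$PAS, "pas_core")
  expect_equal(cp$diet_specific_core$CON, character(0))
  expect_true(all(cp$abundance_fraction >= 0 & cp$abundance_fraction <= 100))
  # shared and diet-specific sets are disjoint
  expect_length(intersect(cp$shared_core,
                          unlist(cp$diet_specific_core)), 0)
  expect_error(core_partition(ct, md, threshold = 1.2), "threshold")
})

test_that("a single planted correlation yields exactly one unit edge", {
  set.seed(5)
  n <- 100
  md <- paired_md(n / 2)
  con <- md$sample[md$diet == "CON"]
  la <- matrix(rnorm(6 * n), nrow = 6,
               dimnames = list(paste0("t", 1:6), md$sample))
  la["t2", ] <- la["t1", ] * 2 + 7  # perfect monotone pair
  la <- la + 5  # keep everything "present"
  net <- build_network(fake_multi_kingdom(la), md, "CON", min_n = 5)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$source, "t1")
  expect_equal(net$edges$target, "t2")
  expect_equal(net$edges$rho, 1)
  expect_equal(net$edges$sign, "+")
  expect_equal(net$metrics$n_nodes, 2)
  expect_equal(net$metrics$mean_neighbors, 1)
})

test_that("betweenness follows unnormalized shortest-path counting", {
  # construct a path A - B - C: strong links via B, weak A-C correlation
  set.seed(11)
  n <- 200
  md <- paired_md(n / 2)
  b <- rnorm(n)
  la <- rbind(A = b + rnorm(n, sd = 1.18),
              B = b,
              C = b + rnorm(n, sd = 1.18))
  la <- la + 10
  colnames(la) <- md$sample
  net <- build_network(fake_multi_kingdom(la), md, "CON", min_n = 5)
  e <- paste(net$edges$source, net$edges$target)
  expect_setequal(e, c("A B", "B C"))
  btw <- stats::setNames(net$nodes$betweenness, net$nodes$taxon)
  expect_equal(unname(btw["B"]), 1)
  expect_equal(unname(btw[c("A", "C")]), c(0, 0))
})

test_that("tightening the edge filters never adds edges", {
  st <- simulate_study(16, default_truth(), seed = 61)
  norm <- lapply(st$tables, normalize_table, seed = 61)
  mk <- combine_kingdoms(norm, st$fermentation)
  edge_key <- function(net) paste(net$edges$source, net$edges$target)
  base <- build_network(mk, st$metadata, "CON", r_min = 0.4, alpha = 0.10)
  for (r in c(0.5, 0.6, 0.7)) {
    tighter <- build_network(mk, st$metadata, "CON", r_min = r, alpha = 0.10)
    expect_true(all(edge_key(tighter) %in% edge_key(base)))
    expect_lte(tighter$metrics$n_edges, base$metrics$n_edges)
  }
  for (a in c(0.05, 0.01, 0.001)) {
    tighter <- build_network(mk, st$metadata, "CON", r_min = 0.4, alpha = a)
    expect_true(all(edge_key(tighter) %in% edge_key(base)))
  }
  # raising the prevalence gate cannot add nodes
  high_prev <- build_network(mk, st$metadata, "CON", r_min = 0.4,
                             alpha = 0.10, prevalence_min = 0.9)
  expect_true(all(high_prev$nodes$taxon %in% base$nodes$taxon))
})

test_that("network metrics are internally consistent", {
  st <- simulate_study(12, default_truth(), seed = 71)
  norm <- lapply(st$tables, normalize_table, seed = 71)
  mk <- combine_kingdoms(norm, st$fermentation)
  net <- build_network(mk, st$metadata, "PAS")
  m <- net$metrics
  expect_equal(m$n_edges, m$n_positive + m$n_negative)
  expect_equal(m$mean_neighbors, 2 * m$n_edges / m$n_nodes)
  expect_true(all(abs(net$edges$rho) > 0.5))
  expect_true(all(net$edges$p_adj < 0.05))
  expect_false(any(net$edges$source == net$edges$target))
  expect_false(anyDuplicated(paste(net$edges$source, net$edges$target)) > 0)
})

test_that("an all-noise input returns an empty flagged network, not an error", {
  set.seed(3)
  md <- paired_md(6)
  la <- matrix(rnorm(8 * 12), nrow = 8,
               dimnames = list(paste0("t", 1:8), md$sample)) + 10
  net <- suppressWarnings(build_network(fake_multi_kingdom(la), md, "CON"))
  expect_true(net$warning)
  expect_equal(net$metrics$n_edges, 0)
})

test_that("network comparison reports deltas and kingdom percentages", {
  st <- simulate_study(16, default_truth(), seed = 81)
  norm <- lapply(st$tables, normalize_table, seed = 81)
  mk <- combine_kingdoms(norm, st$fermentation)
  con <- build_network(mk, st$metadata, "CON")
  pas <- build_network(mk, st$metadata, "PAS")
  same <- compare_networks(con, con)
  expect_equal(same$delta_nodes, 0)
  expect_equal(same$delta_edges, 0)
  expect_equal(same$delta_pct_positive, 0)
  cmp <- compare_networks(con, pas)
  expect_equal(cmp$delta_nodes,
               pas$metrics$n_nodes - con$metrics$n_nodes)
  for (side in cmp$kingdom_pct)
    if (length(side)) expect_equal(sum(side), 100, tolerance = 0.1)
  loose <- build_network(mk, st$metadata, "PAS", r_min = 0.3)
  expect_error(compare_networks(con, loose), "different thresholds")
})
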