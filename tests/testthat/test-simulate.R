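test_that("generators are pure functions of their seed", {
  e1 <- simulate_expression(n_genes = 50, seed = 11)
  e2 <- simulate_expression(n_genes = 50, seed = 11)
  expect_identical(e1, e2)
  n1 <- simulate_network(n_background_nodes = 30, p = 0.1,
                         clique_sizes = 4, hub_spokes = 5, seed = 11)
  n2 <- simulate_network(n_background_nodes = 30, p = 0.1,
                         clique_sizes = 4, hub_spokes = 5, seed = 11)
  expect_identical(n1, n2)
  s1 <- simulate_survival(n_subjects = 30, gene_list = "A", seed = 11)
  s2 <- simulate_survival(n_subjects = 30, gene_list = "A", seed = 11)
  expect_identical(s1, s2)
  a1 <- simulate_annotation(paste0("G", 1:100), n_sets = 5, seed = 11)
  a2 <- simulate_annotation(paste0("G", 1:100), n_sets = 5, seed = 11)
  expect_identical(a1, a2)
})

test_that("generator calls do not disturb the session RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_expression(n_genes = 10, seed = 5))
  expect_identical(runif(1), before)
})

test_that("zero-noise expression reproduces planted logFC exactly", {
  sim <- simulate_expression(n_genes = 200, frac_up = 0.1, frac_down = 0.1,
                             effect_logfc = 2, noise_sd = 0,
                             frac_discordant = 0, seed = 4)
  st <- test_differential(sim$expr, 1)
  lf <- setNames(st$logfc, st$gene)
  up <- rownames(sim$truth$labels)[sim$truth$labels[, 1] == "up"]
  null <- rownames(sim$truth$labels)[sim$truth$labels[, 1] == "null"]
  expect_true(all(lf[up] == 2))
  expect_true(all(lf[null] == 0))
})

test_that("planted label counts match the requested fractions", {
  sim <- simulate_expression(n_genes = 1000, frac_up = 0.1,
                             frac_down = 0.05, frac_discordant = 0,
                             seed = 8)
  for (j in 1:3) {
    expect_equal(sum(sim$truth$labels[, j] == "up"), 100)
    expect_equal(sum(sim$truth$labels[, j] == "down"), 50)
  }
  expect_error(simulate_expression(n_genes = 10, n_replicates = 1),
               "n_replicates")
})

test_that("discordant planting flips signs only in the last generation", {
  sim <- simulate_expression(n_genes = 500, frac_up = 0.1, frac_down = 0.1,
                             frac_discordant = 0.2, seed = 8)
  lab <- sim$truth$labels
  planted <- rownames(lab)[lab[, 1] != "null"]
  expect_true(all(lab[planted, 1] == lab[planted, 2]))
  flipped <- planted[lab[planted, 1] != lab[planted, 3]]
  expect_equal(length(flipped), round(0.2 * 100))
})

test_that("planted cliques are complete and bridge once into the background", {
  sim <- simulate_network(n_background_nodes = 20, p = 0,
                          clique_sizes = 6, hub_spokes = 0, seed = 5)
  clique <- sim$truth$modules[[1]]
  A <- oracle_adjacency(sim$edges)
  internal <- A[clique, clique]
  expect_equal(sum(internal), 6 * 5)  # density 1 inside the clique
  # p = 0 background: all edges are the clique plus exactly one bridge
  expect_equal(nrow(sim$edges), choose(6, 2) + 1)
})

test_that("a 50-spoke planted hub dominates an ER(200, 0.02) background", {
  for (seed in 1:5) {
    sim <- simulate_network(n_background_nodes = 200, p = 0.02,
                            clique_sizes = integer(), hub_spokes = 50,
                            seed = seed)
    A <- oracle_adjacency(sim$edges)
    deg <- rowSums(A)
    expect_equal(names(which.max(deg)), sim$truth$hub)
    expect_gte(max(deg), 50)
  }
})

test_that("network constraints are enforced", {
  expect_error(simulate_network(clique_sizes = 2), "clique sizes")
  expect_error(simulate_network(n_background_nodes = 10, hub_spokes = 11),
               "budget")
  expect_error(simulate_network(n_background_nodes = 10, clique_sizes = 4,
                                hub_spokes = 2,
                                node_names = paste0("X", 1:5), seed = 1),
               "node_names")
})

test_that("all simulated edge confidences clear the 0.4 filter by default", {
  sim <- simulate_network(n_background_nodes = 50, p = 0.05,
                          clique_sizes = 4, hub_spokes = 5, seed = 9)
  expect_true(all(sim$edges$confidence > 0.4))
  noisy <- simulate_network(n_background_nodes = 50, p = 0.05,
                            clique_sizes = 4, hub_spokes = 5,
                            noise_edge_frac = 0.3, seed = 9)
  expect_true(any(noisy$edges$confidence < 0.4))
})

test_that("zero censoring yields an event for every subject", {
  sim <- simulate_survival(n_subjects = 40, gene_list = "A",
                           censor_rate = 0, seed = 3)
  expect_true(all(sim$table$event == 1))
})

test_that("prognostic planting separates the high/low hazard groups", {
  sim <- simulate_survival(n_subjects = 400, gene_list = c("A", "B"),
                           prognostic_genes = "A", hazard_ratio = 3,
                           baseline_rate = 0.02, censor_rate = 0.005,
                           seed = 6)
  grp <- sim$truth$groups[, "A"]
  expect_equal(sort(unique(as.vector(grp))), c("high", "low"))
  # high-hazard group accumulates events faster
  mean_hi <- mean(sim$table$time_months[grp == "high"])
  mean_lo <- mean(sim$table$time_months[grp == "low"])
  expect_lt(mean_hi, mean_lo)
  expect_equal(unname(sim$truth$hazard_ratio), c(3, 1))
})

test_that("planted annotation sets contain the requested query overlap", {
  uni <- paste0("G", 1:500)
  query <- paste0("G", 1:50)
  sim <- simulate_annotation(uni, n_sets = 10, set_size_range = c(20, 30),
                             target_query = query, n_enriched = 3,
                             overlap_count = 15, seed = 2)
  for (id in sim$truth$enriched)
    expect_equal(sum(sim$collection$sets[[id]] %in% query), 15)
  nulls <- setdiff(names(sim$collection$sets), sim$truth$enriched)
  expect_length(nulls, 7)
  expect_error(
    simulate_annotation(uni, set_size_range = c(10, 600)),
    "universe smaller")
  expect_error(
    simulate_annotation(uni, n_sets = 5, set_size_range = c(5, 10),
                        target_query = query, n_enriched = 1,
                        overlap_count = 8),
    "overlap_count")
})

test_that("a fully-overlapping planted set attains the minimum p-value", {
  uni <- paste0("G", 1:60)
  query <- paste0("G", 1:10)
  sim <- simulate_annotation(uni, n_sets = 4, set_size_range = c(10, 10),
                             target_query = query, n_enriched = 1,
                             overlap_count = 10, seed = 3)
  res <- enrich(query, sim$collection, universe = uni, min_count = 1,
                p_threshold = 1.01)
  p_planted <- res$p_value[res$set_id == sim$truth$enriched]
  expect_equal(p_planted, 1 / choose(60, 10) * choose(50, 0) * choose(10, 10),
               tolerance = 1e-12)
  expect_equal(min(res$p_value), p_planted)
})

test_that("the bundle writes every dialect and truth sufficient to score", {
  dir <- withr::local_tempdir()
  b <- simulate_bundle(seed = 3, out_dir = dir)
  expect_setequal(list.files(dir),
                  c("expression.tsv", "edges.tsv", "sets.gmt",
                    "survival.tsv", "truth.json"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_true(all(c("expression", "network", "survival", "annotation")
                  %in% names(truth)))
  back <- read_expression_table(file.path(dir, "expression.tsv"))
  expect_equal(back$values, b$expr$values, tolerance = 1e-12)
})
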