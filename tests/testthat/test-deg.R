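make_two_group <- function(ctrl, trt) {
  vals <- rbind(gene1 = c(ctrl, trt))
  colnames(vals) <- c(paste0("c", seq_along(ctrl)),
                      paste0("t", seq_along(trt)))
  expr_matrix(vals, rep(c("control", "treated"),
                        c(length(ctrl), length(trt))),
              c(rep(NA, length(ctrl)), rep(1, length(trt))))
}

test_that("logFC is treated minus control on the log2 scale", {
  x <- make_two_group(c(1, 1.01, 0.99), c(1, 1.01, 0.99))
  expect_equal(test_differential(x, 1)$logfc, 0)
  x2 <- make_two_group(c(1, 1.001, 0.999), c(3, 3.001, 2.999))
  expect_equal(test_differential(x2, 1)$logfc, 2, tolerance = 1e-9)
})

test_that("the Welch statistic matches stats::t.test", {
  ctrl <- c(5.1, 4.9, 5.0)
  trt <- c(7.0, 7.2, 6.8)
  st <- test_differential(make_two_group(ctrl, trt), 1)
  ref <- stats::t.test(trt, ctrl, var.equal = FALSE)
  expect_equal(st$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(st$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(st$logfc, mean(trt) - mean(ctrl), tolerance = 1e-12)
})

test_that("Welch results match t.test across random fixtures", {
  set.seed(21)
  for (i in 1:20) {
    ctrl <- rnorm(sample(3:6, 1), sd = runif(1, 0.2, 2))
    trt <- rnorm(sample(3:6, 1), mean = runif(1, -2, 2),
                 sd = runif(1, 0.2, 2))
    st <- test_differential(make_two_group(ctrl, trt), 1)
    ref <- stats::t.test(trt, ctrl, var.equal = FALSE)
    expect_equal(st$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate zero-variance genes get the documented p-values", {
  same <- make_two_group(c(2, 2, 2), c(2, 2, 2))
  st <- test_differential(same, 1)
  expect_equal(st$p_value, 1)
  diff <- make_two_group(c(2, 2, 2), c(4, 4, 4))
  st2 <- test_differential(diff, 1)
  expect_equal(st2$p_value, 0)
  expect_equal(st2$logfc, 2)
})

test_that("genes with missing values are excluded from the comparison", {
  vals <- matrix(c(1, 2, NA, 4, 5, 6,
                   1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE,
                 dimnames = list(c("gNA", "gOK"), paste0("s", 1:6)))
  x <- expr_matrix(vals, rep(c("control", "treated"), each = 3),
                   c(NA, NA, NA, 1, 1, 1))
  expect_message(st <- test_differential(x, 1), "1 gene")
  expect_equal(st$gene, "gOK")
})

test_that("fewer than two replicates in a group is a hard error", {
  vals <- matrix(1:6, 2, 3,
                 dimnames = list(c("a", "b"), c("c1", "t1", "t2")))
  x <- expr_matrix(vals, c("control", "treated", "treated"), c(NA, 1, 1))
  expect_error(test_differential(x, 1), ">= 2")
})

test_that("DEG calls use strict thresholds on both axes", {
  st <- data.frame(gene = c("a", "b", "c", "d", "e"),
                   logfc = c(1.5, -1.2, 1.0, 2.0, 0.5),
                   t_stat = 0,
                   p_value = c(0.01, 0.04, 0.001, 0.05, 0.001))
  called <- call_degs(st)
  dirs <- setNames(called$direction, called$gene)
  expect_equal(unname(dirs[c("a", "b")]), c("up", "down"))
  expect_equal(unname(dirs["c"]), "none")  # logfc exactly 1
  expect_equal(unname(dirs["d"]), "none")  # p exactly 0.05
  expect_equal(unname(dirs["e"]), "none")
})

test_that("raising the logFC threshold never adds a DEG", {
  sim <- simulate_expression(n_genes = 300, frac_up = 0.2, frac_down = 0.2,
                             seed = 14)
  st <- test_differential(sim$expr, 4)
  prev <- NULL
  for (th in c(0.5, 1, 1.5, 2, 2.5)) {
    cur <- call_degs(st, logfc_threshold = th)
    cur_set <- cur$gene[cur$direction != "none"]
    if (!is.null(prev)) expect_true(all(cur_set %in% prev))
    prev <- cur_set
  }
})

test_that("BH adjustment is available and more conservative", {
  sim <- simulate_expression(n_genes = 500, frac_up = 0.05,
                             frac_down = 0.05, seed = 15)
  st <- test_differential(sim$expr, 1)
  raw <- call_degs(st)
  adj <- call_degs(st, adjust = "BH")
  expect_true(all(adj$adjusted_p >= adj$p_value))
  called_adj <- adj$gene[adj$direction != "none"]
  called_raw <- raw$gene[raw$direction != "none"]
  expect_true(all(called_adj %in% called_raw))
})

test_that("moderated mode keeps logFC and returns finite statistics", {
  sim <- simulate_expression(n_genes = 100, seed = 16)
  w <- test_differential(sim$expr, 1, method = "welch")
  m <- test_differential(sim$expr, 1, method = "moderated")
  expect_equal(m$logfc, w$logfc)
  expect_true(all(is.finite(m$t_stat)))
  expect_true(all(m$p_value >= 0 & m$p_value <= 1))
})

partition_fixture <- function(dir1, dir4, dir9) {
  mk <- function(d) data.frame(
    gene = names(d),
    logfc = ifelse(d == "up", 2, ifelse(d == "down", -2, 0)),
    t_stat = 0, p_value = ifelse(d == "none", 0.5, 0.001),
    direction = unname(d), stringsAsFactors = FALSE)
  list(gen1 = mk(dir1), gen4 = mk(dir4), gen9 = mk(dir9))
}

test_that("the common-DEG partition assigns up/down/both correctly", {
  d <- c(gA = "up", gB = "down", gC = "up", gD = "none")
  tabs <- partition_fixture(
    d, d, c(gA = "up", gB = "down", gC = "down", gD = "up"))
  part <- partition_common(tabs)
  expect_equal(part$up, "gA")
  expect_equal(part$down, "gB")
  expect_equal(part$both, "gC")   # discordant across generations
  expect_equal(part$common, sort(c("gA", "gB", "gC")))
})

test_that("the partition is invariant under generation order", {
  d1 <- c(gA = "up", gB = "down", gC = "up")
  d4 <- c(gA = "up", gB = "down", gC = "none")
  d9 <- c(gA = "up", gB = "up", gC = "up")
  tabs <- partition_fixture(d1, d4, d9)
  p1 <- partition_common(tabs)
  p2 <- partition_common(tabs[c(3, 1, 2)])
  expect_equal(p1[c("up", "down", "both", "common")],
               p2[c("up", "down", "both", "common")])
})

test_that("identical single-generation input repeated gives both = empty", {
  d <- c(gA = "up", gB = "down", gC = "none")
  tabs <- partition_fixture(d, d, d)
  part <- partition_common(tabs)
  expect_equal(part$up, "gA")
  expect_equal(part$down, "gB")
  expect_length(part$both, 0)
  expect_error(partition_common(tabs[1]), ">= 2")
})

test_that("up/down/both are disjoint and exhaustive over the common set", {
  sim <- simulate_expression(n_genes = 400, frac_up = 0.15,
                             frac_down = 0.15, frac_discordant = 0.3,
                             seed = 17)
  tabs <- lapply(c(1, 4, 9), function(g)
    call_degs(test_differential(sim$expr, g)))
  part <- partition_common(tabs)
  expect_length(intersect(part$up, part$down), 0)
  expect_length(intersect(part$up, part$both), 0)
  expect_length(intersect(part$down, part$both), 0)
  expect_setequal(c(part$up, part$down, part$both), part$common)
  expect_gt(length(part$both), 0)  # discordant planting shows up
})

test_that("annotation classes intersect the query and tally directions", {
  classes <- list(gf = c("A", "B", "Z"), empty = c("Q1", "Q2"))
  deg <- data.frame(gene = c("A", "B", "C"),
                    direction = c("up", "down", "up"))
  out <- classify_by_annotation(c("A", "B", "C"), classes, deg)
  gf <- out[out$class == "gf", ]
  expect_equal(gf$n_members, 2)
  expect_equal(gf$n_up, 1)
  expect_equal(gf$n_down, 1)
  expect_equal(out[out$class == "empty", ]$n_members, 0)
  # class equal to the full query returns the query
  out2 <- classify_by_annotation(c("A", "B"), list(all = c("A", "B")))
  expect_equal(out2$members[[1]], c("A", "B"))
})
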