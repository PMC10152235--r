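icells <- function(x, y, class) {
  data.frame(cell_id = seq_along(x), x_um = x, y_um = y, class = class)
}

test_that("a small triangle yields 3 Delaunay edges; long edges are pruned", {
  g <- build_graph(icells(c(0, 100, 50), c(0, 0, 80),
                          c("CD8", "CD8", "CD79b")))
  expect_equal(nrow(g$edges), 3)
  expect_false(g$degenerate)
  # stretch one side beyond 250 um
  g2 <- build_graph(icells(c(0, 300, 150), c(0, 0, 80),
                           c("CD8", "CD8", "CD79b")))
  expect_equal(nrow(g2$edges), 2)
  expect_true(all(g2$edges$length_um <= 250))
  # fewer than 3 usable cells: flagged, no edges
  g3 <- build_graph(icells(c(0, 10), c(0, 0), c("CD8", "CD8")))
  expect_true(g3$degenerate)
  expect_equal(nrow(g3$edges), 0)
  # collinear points: no triangulation
  g4 <- build_graph(icells(c(0, 10, 20, 30), c(0, 0, 0, 0), rep("CD8", 4)))
  expect_true(g4$degenerate)
})

test_that("P40 cells and duplicates are handled before triangulation", {
  g <- build_graph(icells(c(0, 100, 50, 50, 60), c(0, 0, 80, 80, 200),
                          c("CD8", "CD8", "CD79b", "CD79b", "P40")))
  expect_equal(nrow(g$vertices), 3)        # P40 dropped, duplicate collapsed
  expect_equal(g$n_duplicates_collapsed, 1)
  expect_equal(sum(g$vertices$multiplicity), 4)
})

test_that("Delaunay edges match the empty-circumcircle oracle", {
  set.seed(42)
  for (r in 1:20) {
    n <- sample(5:25, 1)
    x <- runif(n) * 1000; y <- runif(n) * 1000
    tri <- delaunay_triangulate(x, y)
    expect_identical(sorted_edges(triangulation_edges(tri)),
                     delaunay_oracle_edges(x, y))
  }
})

test_that("removing the edge-length pruning never decreases the edge count", {
  set.seed(3)
  cls <- sample(immune_subsets(), 60, replace = TRUE)
  cells <- icells(runif(60) * 1500, runif(60) * 1500, cls)
  gp <- build_graph(cells, max_edge_um = 250)
  gu <- build_graph(cells, max_edge_um = Inf)
  expect_gte(nrow(gu$edges), nrow(gp$edges))
  expect_true(all(gp$edges$length_um <= 250))
})

test_that("interaction fractions enumerate labeled edges", {
  g <- build_graph(icells(c(0, 100, 50), c(0, 0, 80),
                          c("CD8", "CD8", "CD79b")))
  prof <- interaction_fractions(g)
  expect_equal(unname(prof$fractions[["CD8|CD8"]]), 1 / 3)
  expect_equal(unname(prof$fractions[["CD8|CD79b"]]), 2 / 3)
  expect_equal(sum(prof$fractions), 1)
  expect_equal(sum(prof$fractions > 0), 2)
  # all vertices one subset
  g2 <- build_graph(icells(c(0, 100, 50), c(0, 0, 80), rep("CD8", 3)))
  expect_equal(unname(interaction_fractions(g2)$fractions[["CD8|CD8"]]), 1)
  # zero edges: fractions undefined, composition still computed
  g3 <- build_graph(icells(c(0, 10), c(0, 0), c("CD8", "CD4_FOXP3pos")))
  prof3 <- interaction_fractions(g3)
  expect_true(all(is.na(prof3$fractions)))
  expect_equal(unname(prof3$counts[["CD8"]]), 1)
  expect_equal(prof3$cd8_treg_ratio, 1)
})

test_that("composition metrics: percentages, CD8/Treg ratio, B-cell fraction", {
  cls <- c(rep("CD8", 4), rep("CD4_FOXP3pos", 2), rep("CD20_CXCR5pos", 2),
           rep("CD79b", 2))
  set.seed(10)
  cells <- icells(runif(10) * 100, runif(10) * 100, cls)
  prof <- interaction_fractions(build_graph(cells))
  expect_equal(sum(prof$percentages), 1)
  expect_equal(unname(prof$percentages[["CD8"]]), 0.4)
  expect_equal(prof$cd8_treg_ratio, 2)
  expect_equal(prof$b_cell_pct, 0.4)
  expect_lte(prof$h_composition, log(6))
  expect_lte(prof$h_interaction, log(21))
  # Treg count 0 -> undefined ratio
  cells2 <- icells(c(0, 100, 50), c(0, 0, 80), c("CD8", "CD8", "CD79b"))
  expect_true(is.na(interaction_fractions(build_graph(cells2))$cd8_treg_ratio))
})

test_that("Shannon index has its closed-form values", {
  expect_equal(shannon(rep(1, 21)), log(21))
  expect_equal(shannon(c(0, 0, 7, 0)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(shannon(rep(1, 4), base = 2), 2)
  expect_error(shannon(c(0, 0)), "positive sum")
  expect_error(shannon(c(-1, 2)), "non-negative")
})

test_that("permuted labels drive fractions to the CSR expectation", {
  set.seed(31)
  n <- 250
  cls <- sample(immune_subsets(), n, replace = TRUE,
                prob = c(0.3, 0.25, 0.15, 0.12, 0.1, 0.08))
  cells <- icells(runif(n) * 2000, runif(n) * 2000, cls)
  g <- build_graph(cells, max_edge_um = Inf)
  v <- g$vertices
  e <- g$edges
  acc <- setNames(numeric(21), subset_pairs())
  nperm <- 1000
  for (p in seq_len(nperm)) {
    lab <- sample(v$class)
    keys <- hotspotr:::pair_key(lab[e$i], lab[e$j])
    tab <- table(factor(keys, levels = subset_pairs()))
    acc <- acc + as.numeric(tab) / nrow(e)
  }
  acc <- acc / nperm
  p_a <- table(factor(v$class, immune_subsets())) / nrow(v)
  for (a in 1:6) for (b in a:6) {
    nm <- paste(immune_subsets()[a], immune_subsets()[b], sep = "|")
    # finite-population (permutation without replacement) expectation
    expected <- if (a == b) {
      nrow(v) * p_a[a] * (nrow(v) * p_a[a] - 1) / (nrow(v) * (nrow(v) - 1))
    } else {
      2 * nrow(v)^2 * p_a[a] * p_a[b] / (nrow(v) * (nrow(v) - 1))
    }
    expect_lt(abs(acc[[nm]] - expected), 0.01)
  }
})

test_that("compare_groups runs rank-sum and signed-rank tests with BH", {
  set.seed(6)
  df <- data.frame(v1 = c(rnorm(20), rnorm(20)), v2 = c(rnorm(20), rnorm(20) + 3),
                   g = rep(c("a", "b"), each = 20), block = rep(1:20, 2))
  res <- compare_groups(df, c("v1", "v2"), "g")
  expect_false(res$significant[res$variable == "v1"])
  expect_true(res$significant[res$variable == "v2"])
  # identical groups -> p = 1 under rank-sum with tie handling
  df2 <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(compare_groups(df2, "v", "g")$p, 1)
  # paired signed-rank detects a consistent within-pair shift
  resp <- compare_groups(df, c("v1", "v2"), "g", paired = TRUE, block = "block")
  expect_true(resp$significant[resp$variable == "v2"])
  # group too small: variable skipped with reason
  df3 <- data.frame(v = c(1, 2, 3), g = c("a", "a", "b"))
  res3 <- compare_groups(df3, "v", "g")
  expect_true(res3$skipped)
  expect_match(res3$reason, "fewer than 2")
})

test_that("BH adjustment matches the hand-computed step-up procedure", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # step-up: p_(i) * m / i, cumulative minimum from the largest
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  df <- data.frame(v1 = 1:20, v2 = 1:20, v3 = 1:20,
                   g = rep(c("a", "b"), each = 10))
  df$v1[11:20] <- df$v1[11:20] + 100
  res <- compare_groups(df, c("v1", "v2", "v3"), "g")
  m <- sum(!res$skipped)
  o <- order(res$p)
  manual <- rev(cummin(rev(res$p[o] * m / seq_len(m))))[order(o)]
  expect_equal(res$p_adj, pmin(1, manual))
})

test_that("classify_by_median stratifies within compartments", {
  expect_equal(classify_by_median(c(1, 2, 3, 4), rep("a", 4)),
               c("low", "low", "high", "high"))
  expect_equal(classify_by_median(c(1, 1, 1, 5), rep("a", 4)),
               c("low", "low", "low", "high"))
  # compartment-stratified medians differ from a pooled median
  v <- c(1, 2, 3, 100, 200, 300)
  cp <- rep(c("IH_peri", "IH_intra"), each = 3)
  out <- classify_by_median(v, cp)
  expect_equal(out, c("low", "low", "high", "low", "low", "high"))
  pooled <- ifelse(v > median(v), "high", "low")
  expect_false(identical(out, pooled))
  expect_warning(classify_by_median(c(2, 2), c("a", "a")), "constant")
  suppressWarnings(
    expect_error(classify_by_median(c(2, 2, 1), c("a", "a", "b")),
                 "fewer than 2"))
})

test_that("interaction_logistic signs follow enrichment and flags apply", {
  set.seed(17)
  n <- 120
  compartment <- rep(c("IH_peri", "IH_intra"), each = n / 2)
  # enriched in peritumoral IH, with enough overlap to avoid separation
  f1 <- ifelse(compartment == "IH_peri", 0.31, 0.25) + rnorm(n, 0, 0.08)
  prof <- data.frame(compartment = compartment, f_a = f1,
                     f_b = rnorm(n, 0.3, 0.05), f_c = 0.5)
  res <- interaction_logistic(prof, c("f_a", "f_b", "f_c"))
  # enriched in peritumoral IH -> negative coefficient
  expect_lt(res$coefficient[res$variable == "f_a"], 0)
  expect_lt(res$p_adj[res$variable == "f_a"], 0.05)
  expect_gt(res$p_adj[res$variable == "f_b"], 0.05)
  expect_true(res$skipped[res$variable == "f_c"])   # constant predictor
  # class floor
  res2 <- interaction_logistic(prof[1:35, ], "f_a", min_per_class = 10)
  expect_true(res2$skipped)
})

test_that("logistic fit agrees with a likelihood grid-search oracle", {
  set.seed(23)
  x <- runif(40)
  y <- rbinom(40, 1, plogis(-1 + 2.5 * x))
  prof <- data.frame(compartment = ifelse(y == 1, "IH_intra", "IH_peri"),
                     f_x = x)
  res <- interaction_logistic(prof, "f_x")
  best <- logistic_grid_oracle(x, y)
  expect_equal(res$coefficient, best[2], tolerance = 1e-3)
})

test_that("type-I error of the logistic screen is nominal under permutation", {
  set.seed(41)
  n <- 80
  rej <- vapply(1:200, function(r) {
    prof <- data.frame(compartment = sample(rep(c("IH_peri", "IH_intra"),
                                                each = n / 2)),
                       f_a = rnorm(n, 0.3, 0.1))
    interaction_logistic(prof, "f_a")$p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.10)
  expect_gte(mean(rej), 0.01)
})
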