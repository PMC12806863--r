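test_that("simulation is reproducible and edge-free specs give independent
           genes", {
  spec <- synthetic_spec(n_tfs = 3, n_tgs = 7, n_edges = 0, n_samples = 500,
                         seed = 6)
  s1 <- simulate_grn(spec)
  s2 <- simulate_grn(spec)
  expect_identical(s1$expression, s2$expression)
  expect_equal(nrow(s1$edges), 0)
  r <- pearson_matrix(s1$expression)
  expect_lt(max(abs(r[upper.tri(r)])), 0.2)
})

test_that("planted graphs respect roster semantics and requested size", {
  sim <- simulate_grn(synthetic_spec(n_tfs = 5, n_tgs = 10, n_edges = 25,
                                     n_samples = 50, seed = 3))
  expect_equal(nrow(sim$edges), 25)
  expect_true(all(sim$edges$regulator %in% sim$roster$tfs))
  expect_false(any(sim$edges$regulator == sim$edges$target))
  expect_equal(sim$gold$P, 25L)
  expect_equal(dim(sim$expression), c(50, 15))
  # TF-TF edges are acyclic: igraph-free check via repeated leaf-stripping
  tf_edges <- sim$edges[sim$edges$target %in% sim$roster$tfs, ]
  nodes <- unique(c(tf_edges$regulator, tf_edges$target))
  while (length(nodes)) {
    leaves <- setdiff(nodes, tf_edges$regulator)
    expect_gt(length(leaves), 0)               # a DAG always has a sink
    nodes <- setdiff(nodes, leaves)
    tf_edges <- tf_edges[!tf_edges$target %in% leaves, ]
  }
})

test_that("bipartite specs plant no TF-TF edges", {
  sim <- simulate_grn(synthetic_spec(n_tfs = 4, n_tgs = 8, n_edges = 20,
                                     n_samples = 30, tf_tf = FALSE,
                                     seed = 9))
  expect_false(any(sim$edges$target %in% sim$roster$tfs))
})

test_that("edge oversubscription errors", {
  expect_error(simulate_grn(synthetic_spec(n_tfs = 2, n_tgs = 2,
                                           n_edges = 100, n_samples = 20)),
               "admissible")
})

test_that("root TFs are plausibly normal across seeds", {
  pvals <- vapply(1:20, function(s) {
    sim <- simulate_grn(synthetic_spec(n_tfs = 2, n_tgs = 2, n_edges = 2,
                                       n_samples = 200, seed = s))
    roots <- setdiff(sim$roster$tfs, sim$edges$target)
    if (!length(roots)) return(NA_real_)
    stats::shapiro.test(sim$expression[, roots[1]])$p.value
  }, 0)
  pvals <- pvals[!is.na(pvals)]
  expect_lte(mean(pvals < 0.01), 0.15)
})

test_that("a single planted quadratic edge is directionally recoverable", {
  spec <- synthetic_spec(n_tfs = 1, n_tgs = 1, n_edges = 1, n_samples = 200,
                         noise_sd = 0.1, function_family = "quadratic",
                         seed = 12)
  sim <- simulate_grn(spec)
  u <- sim$expression[, sim$edges$regulator]
  v <- sim$expression[, sim$edges$target]
  s <- anm_score(u, v)
  expect_identical(s$direction, "forward")
})

test_that("stage series are seed-deterministic with recorded monotone sets", {
  spec <- synthetic_spec(n_tfs = 3, n_tgs = 6, n_edges = 5, n_samples = 40,
                         tf_tf = FALSE, seed = 4)
  ser1 <- simulate_stage_series(spec, n_stages = 4, drift = 2, n_drift = 2)
  ser2 <- simulate_stage_series(spec, n_stages = 4, drift = 2, n_drift = 2)
  expect_identical(ser1$stages, ser2$stages)
  expect_equal(nrow(ser1$monotone), 2)
  expect_setequal(ser1$monotone$direction, c("increasing", "decreasing"))
  # drifting edges sit on single-parent targets
  counts <- table(ser1$gold$edges$target)
  expect_true(all(counts[ser1$monotone$target] == 1))

  ser0 <- simulate_stage_series(spec, n_stages = 3, drift = 0)
  expect_equal(nrow(ser0$monotone), 0)
  expect_length(ser0$stages, 3)
})

test_that("drifting amplitudes shift the target's variance stage by stage", {
  spec <- synthetic_spec(n_tfs = 2, n_tgs = 4, n_edges = 2, n_samples = 2000,
                         noise_sd = 0.1, function_family = "quadratic",
                         tf_tf = FALSE, seed = 21)
  ser <- simulate_stage_series(spec, n_stages = 4, drift = 3, n_drift = 2)
  inc <- ser$monotone[ser$monotone$direction == "increasing", ]
  vars <- vapply(ser$stages, function(m) var(m[, inc$target[1]]), 0)
  # the regulator's contribution grows, so so does the target's variance
  expect_true(all(diff(vars) > 0))
})

test_that("synthetic bundles round-trip through the standard files", {
  sim <- simulate_grn(synthetic_spec(n_tfs = 3, n_tgs = 4, n_edges = 6,
                                     n_samples = 15, seed = 8))
  dir <- withr::local_tempdir()
  write_synthetic(sim, dir)
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(unname(expr), unname(sim$expression), tolerance = 1e-12)
  tfs <- read_tf_list(file.path(dir, "tfs.txt"))
  expect_identical(tfs, sim$roster$tfs)
  roster <- gene_roster(tfs, colnames(expr))
  gold <- read_gold_standard(file.path(dir, "gold.tsv"), roster)
  expect_setequal(gold$positives, sim$gold$positives)
  manifest <- readLines(file.path(dir, "manifest.json"))
  expect_match(manifest, "\"n_tfs\": 3")
})
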