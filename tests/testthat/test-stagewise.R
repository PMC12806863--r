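# Build stage_scores directly from small matrices so the screen's rule can
# be tested in isolation from the inference machinery.
manual_stages <- function(seqs, roster) {
  # seqs: named list pair-key -> numeric vector over stages
  n_stages <- length(seqs[[1]])
  pairs <- grncausal:::admissible_pairs(roster)
  lapply(seq_len(n_stages), function(s) {
    v <- matrix(0, length(roster$tfs), length(roster$all),
                dimnames = list(roster$tfs, roster$all))
    for (key in names(seqs)) {
      rt <- strsplit(key, " ", fixed = TRUE)[[1]]
      v[rt[1], rt[2]] <- seqs[[key]][s]
    }
    structure(list(values = v, roster = roster),
              class = "propensity_matrix")
  })
}

test_that("the monotonicity rule flags exactly the hand-worked cases", {
  roster <- toy_roster()
  w <- manual_stages(list(
    "TF001 G0001" = c(0.1, 0.2, 0.3, 0.4),    # increasing, total 0.3
    "TF001 G0002" = c(0.1, 0.3, 0.2, 0.4),    # dip: not monotone
    "TF002 G0001" = c(0.4, 0.3, 0.2, 0.1),    # decreasing, total 0.3
    "TF002 G0002" = c(0.2, 0.2, 0.2, 0.2),    # constant
    "TF001 TF002" = c(0.1, 0.15, 0.2, 0.22),  # increasing, total 0.12
    "TF002 TF001" = c(0, 0, 0, 0.05)), roster)
  sc <- stage_scores(w)
  rel <- monotone_screen(sc, threshold = 0.15, scale = "raw")
  keys <- paste(rel$regulator, rel$target, rel$direction)
  expect_setequal(keys, c("TF001 G0001 increasing",
                          "TF002 G0001 decreasing"))
  expect_equal(sort(rel$magnitude), c(0.3, 0.3), tolerance = 1e-12)

  # lowering the threshold admits the weak riser
  rel2 <- monotone_screen(sc, threshold = 0.1, scale = "raw")
  expect_true("TF001 TF002 increasing" %in%
                paste(rel2$regulator, rel2$target, rel2$direction))
})

test_that("increasing and decreasing sets are disjoint and swap exactly
           under stage reversal", {
  set.seed(30)
  roster <- toy_roster()
  pairs <- grncausal:::admissible_pairs(roster)
  keys <- paste(pairs$regulator, pairs$target)
  seqs <- setNames(lapply(keys, function(k) cumsum(runif(4, -0.2, 0.3))),
                   keys)
  w <- manual_stages(seqs, roster)
  sc <- stage_scores(w)
  rel <- monotone_screen(sc, threshold = 0.05, scale = "raw")
  expect_identical(anyDuplicated(paste(rel$regulator, rel$target)), 0L)

  sc_rev <- stage_scores(rev(w))
  rel_rev <- monotone_screen(sc_rev, threshold = 0.05, scale = "raw")
  flip <- c(increasing = "decreasing", decreasing = "increasing")
  expect_setequal(paste(rel$regulator, rel$target, flip[rel$direction]),
                  paste(rel_rev$regulator, rel_rev$target,
                        rel_rev$direction))
})

test_that("normalized scales are comparable across stages of different
           magnitude", {
  roster <- toy_roster()
  # later stages are global rescalings of stage 1: raw screening flags the
  # proportional growth, normalized screening sees no relative change
  vals <- c("TF001 G0001" = 0.5, "TF001 G0002" = 1.0,
            "TF002 G0001" = 0.75, "TF002 G0002" = 1.5,
            "TF001 TF002" = 0.25, "TF002 TF001" = -0.25)
  mult <- c(1, 1.2, 1.5, 2)
  base <- lapply(vals, function(v) v * mult)
  w <- manual_stages(base, roster)
  sc <- stage_scores(w)
  expect_equal(nrow(monotone_screen(sc, 0.15, scale = "minmax")), 0)
  expect_gt(nrow(monotone_screen(sc, 0.15, scale = "raw")), 0)
})

test_that("stage_scores validates rosters and stage counts", {
  roster <- toy_roster()
  w <- manual_stages(list("TF001 G0001" = c(0, 0.5)), roster)
  other <- gene_roster("TFX", c("TFX", "GX"))
  wo <- manual_stages(list("TFX GX" = c(0, 0.5)), other)
  expect_error(stage_scores(c(w[1], wo[1])), "non-matching")
  expect_error(monotone_screen(stage_scores(w), 0.15), "3 stages")
})

test_that("driver ranking counts relations with lexicographic ties", {
  rel <- structure(data.frame(
    regulator = c("TFB", "TFA", "TFB", "TFB", "TFC", "TFA"),
    target = paste0("G", 1:6),
    direction = rep(c("increasing", "decreasing"), 3),
    magnitude = runif(6)), class = c("monotone_relations", "data.frame"))
  drv <- driver_tf_ranking(rel)
  expect_identical(drv$tf, c("TFB", "TFA", "TFC"))
  expect_identical(drv$n_relations, c(3L, 2L, 1L))
  empty <- rel[0, ]
  expect_error(driver_tf_ranking(empty), "no monotone")
})

test_that("the planted driver TF tops the end-to-end stage analysis", {
  spec <- synthetic_spec(n_tfs = 3, n_tgs = 9, n_edges = 6, n_samples = 600,
                         noise_sd = 0.15, function_family = "quadratic",
                         tf_tf = FALSE, seed = 31)
  ser <- simulate_stage_series(spec, n_stages = 4, drift = 3, n_drift = 4)
  ana <- stagewise_analysis(ser$stages, ser$roster$tfs, threshold = 0.15,
                            grn_config(pipeline = "anm-only",
                                       anm_bags = 2L, seed = 3))
  planted_counts <- sort(table(ser$monotone$regulator), decreasing = TRUE)
  expect_gt(nrow(ana$relations), 0)
  # the TF carrying the most drifting edges leads the driver ranking
  top_planted <- names(planted_counts)[planted_counts == max(planted_counts)]
  expect_true(ana$drivers$tf[1] %in% top_planted)
})
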