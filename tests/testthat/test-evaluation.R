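# Brute-force oracle: confusion counts computed by direct set operations at
# every cutoff, no cumulative tricks.
oracle_curve <- function(edges, gold) {
  key <- paste(edges$regulator, edges$target, sep = "\r")
  L <- length(key)
  t(vapply(seq_len(L), function(k) {
    tp <- sum(key[1:k] %in% gold$positives)
    c(TP = tp, FP = k - tp)
  }, c(TP = 0, FP = 0)))
}

test_that("exact-branch curve points match the brute-force confusion
           counts and textbook formulas", {
  gr <- random_gold(nf = 4, ng = 10, P = 12, seed = 5)
  el <- random_ranking(gr$roster, seed = 6)
  pts <- curve_points(el, gr$gold)
  orc <- oracle_curve(el, gr$gold)
  L <- nrow(el)
  expect_equal(pts$TP[1:L], unname(orc[, "TP"]))
  expect_equal(pts$FP[1:L], unname(orc[, "FP"]))
  expect_equal(pts$TPR, pts$recall)
  expect_equal(pts$TPR[1:L], orc[, "TP"] / gr$gold$P, ignore_attr = TRUE)
  expect_equal(pts$precision[1:L], orc[, "TP"] / seq_len(L),
               ignore_attr = TRUE)
})

test_that("perfect and anti-perfect rankings hit the AUROC/AUPR extremes", {
  gr <- random_gold(nf = 4, ng = 10, P = 12, seed = 1)
  pos_keys <- gr$gold$positives
  key <- paste(gr$pairs$regulator, gr$pairs$target, sep = "\r")
  score <- ifelse(key %in% pos_keys, 2, 1)
  perfect <- ranked_edges(gr$pairs$regulator, gr$pairs$target, score)
  a <- auroc_aupr(curve_points(perfect, gr$gold))
  expect_equal(unname(a["auroc"]), 1)
  expect_equal(unname(a["aupr"]), 1)
  reversed <- ranked_edges(gr$pairs$regulator, gr$pairs$target, -score)
  ar <- auroc_aupr(curve_points(reversed, gr$gold))
  expect_equal(unname(ar["auroc"]), 0)
})

test_that("the hand-worked filling example evaluates as printed", {
  # universe T = 10, P = 4, list L = 5 with TP_L = 3; at k = 8 the filled
  # true positives are 3 + 0.6 and recall 0.9
  roster <- gene_roster(c("TF1", "TF2"), c("TF1", "TF2", "G1", "G2", "G3",
                                           "G4"))
  expect_equal(n_admissible_pairs(roster), 10)
  gold <- gold_standard(data.frame(regulator = c("TF1", "TF1", "TF2", "TF2"),
                                   target = c("G1", "G2", "G1", "TF1")),
                        roster)
  el <- ranked_edges(c("TF1", "TF1", "TF2", "TF1", "TF2"),
                     c("G1", "G2", "G1", "G3", "G2"),
                     c(5, 4, 3, 2, 1))
  pts <- curve_points(el, gold)
  expect_equal(pts$TP[5], 3)
  expect_equal(pts$TP[8], 3 + (8 - 5) * (4 - 3) / (10 - 5))
  expect_equal(pts$recall[8], 0.9)
  expect_equal(pts$FP[8], 8 - 3.6)
})

test_that("filled recall is monotone and the fill stays within bounds", {
  gr <- random_gold(nf = 5, ng = 10, P = 15, seed = 3)
  full <- random_ranking(gr$roster, seed = 4)
  el <- full[1:20, ]
  pts <- curve_points(el, gr$gold)
  expect_true(all(diff(pts$recall) >= -1e-12))
  fill <- pts$TP[21:nrow(pts)] - pts$TP[20]
  expect_true(all(fill >= 0 & fill <= gr$gold$P - pts$TP[20] + 1e-12))
  expect_equal(pts$TP[nrow(pts)], gr$gold$P)     # end of fill hits P
})

test_that("full-list AUROC matches pROC and AUPR matches average
           precision on random rankings", {
  skip_if_not_installed("pROC")
  gr <- random_gold(nf = 5, ng = 15, P = 40, seed = 7)
  for (s in 1:10) {
    el <- random_ranking(gr$roster, seed = s)
    a <- auroc_aupr(curve_points(el, gr$gold))
    labels <- as.integer(paste(el$regulator, el$target, sep = "\r") %in%
                           gr$gold$positives)
    roc <- pROC::roc(response = labels, predictor = el$score,
                     direction = "<", quiet = TRUE)
    expect_equal(unname(a["auroc"]), as.numeric(pROC::auc(roc)),
                 tolerance = 1e-9)
    ap <- mean(cumsum(labels)[labels == 1] / which(labels == 1))
    expect_equal(unname(a["aupr"]), ap, tolerance = 1e-9)
  }
})

test_that("rankings with out-of-universe pairs are rejected by name", {
  gr <- random_gold(nf = 3, ng = 5, P = 5, seed = 2)
  el <- ranked_edges(c("TF001", "G0001"), c("G0001", "G0002"), c(2, 1))
  expect_error(curve_points(el, gr$gold), "G0001 G0002")
})

test_that("random-ranking nulls have the expected means and are
           seed-reproducible", {
  gr <- random_gold(nf = 5, ng = 15, P = 20, seed = 9)
  null <- random_null(gr$gold, n = 2000, seed = 11)
  se <- sd(null$auroc) / sqrt(null$n)
  expect_lt(abs(mean(null$auroc) - 0.5), 3 * se)
  se_pr <- sd(null$aupr) / sqrt(null$n)
  density <- gr$gold$P / gr$gold$T
  # AP of a random ranking is slightly above P/T at finite T; allow the
  # documented bias margin plus Monte-Carlo error
  expect_lt(abs(mean(null$aupr) - density), 0.05 + 3 * se_pr)
  null2 <- random_null(gr$gold, n = 2000, seed = 11)
  expect_identical(null$auroc, null2$auroc)
})

test_that("null AUROC sampling agrees with the full curve machinery", {
  gr <- random_gold(nf = 4, ng = 8, P = 8, seed = 13)
  null <- random_null(gr$gold, n = 5, seed = 21)
  set.seed(21)
  for (r in 1:5) {
    pos <- sort.int(sample.int(gr$gold$T, gr$gold$P))
    # rebuild the corresponding explicit ranking: positives at `pos`
    scores <- numeric(gr$gold$T)
    perm <- order(c(pos, setdiff(seq_len(gr$gold$T), pos)))
    ord_keys <- c(gr$gold$positives,
                  setdiff(paste(gr$pairs$regulator, gr$pairs$target,
                                sep = "\r"), gr$gold$positives))[perm]
    parts <- strsplit(ord_keys, "\r", fixed = TRUE)
    el <- ranked_edges(vapply(parts, `[[`, "", 1),
                       vapply(parts, `[[`, "", 2),
                       rev(seq_len(gr$gold$T)))
    a <- auroc_aupr(curve_points(el, gr$gold))
    expect_equal(unname(a["auroc"]), null$auroc[r], tolerance = 1e-12)
    expect_equal(unname(a["aupr"]), null$aupr[r], tolerance = 1e-12)
  }
})

test_that("confidence score calibrates at the null median, caps at 100,
           and is monotone", {
  set.seed(15)
  null <- rnorm(5000, mean = 0.5, sd = 0.03)
  med <- median(null)
  expect_lt(abs(confidence_score(med, null) - (-log10(0.5))), 0.05)
  expect_equal(confidence_score(1.5, null), 100)
  expect_lt(confidence_score(0.3, null), 0.05)
  vals <- seq(0.4, 0.7, by = 0.02)
  scores <- vapply(vals, confidence_score, 0, null_samples = null)
  expect_true(all(diff(scores) >= 0))
  expect_error(confidence_score(0.5, rnorm(50)), "100 null samples")
})

test_that("EPR is 1-ish for random rankings, T/P for perfect, 1 under
           saturation", {
  gr <- random_gold(nf = 5, ng = 15, P = 20, seed = 17)
  eprs <- vapply(1:200, function(s)
    epr(random_ranking(gr$roster, seed = s), gr$gold), 0)
  expect_gte(mean(eprs), 0.9)
  expect_lte(mean(eprs), 1.1)

  key <- paste(gr$pairs$regulator, gr$pairs$target, sep = "\r")
  perfect <- ranked_edges(gr$pairs$regulator, gr$pairs$target,
                          ifelse(key %in% gr$gold$positives, 2, 1))
  expect_equal(epr(perfect, gr$gold), gr$gold$T / gr$gold$P)

  all_pos <- gold_standard(gr$pairs[, c("regulator", "target")], gr$roster)
  expect_equal(epr(random_ranking(gr$roster, seed = 1), all_pos), 1)
})

test_that("evaluate_ranking assembles the full report", {
  gr <- random_gold(nf = 4, ng = 8, P = 10, seed = 19)
  el <- random_ranking(gr$roster, seed = 20)
  null <- random_null(gr$gold, n = 300, seed = 2)
  rep <- evaluate_ranking(el, gr$gold, null)
  expect_true(all(c("auroc", "aupr", "epr", "confidence_auroc",
                    "confidence_aupr", "confidence") %in% names(rep)))
  expect_true(rep$auroc >= 0 && rep$auroc <= 1)
  expect_true(rep$confidence >= 0 && rep$confidence <= 100)
})

test_that("TF-TF restriction rebuilds the universe consistently", {
  gr <- random_gold(nf = 5, ng = 10, P = 20, seed = 23)
  g2 <- restrict_gold_tf_tf(gr$gold)
  expect_equal(g2$T, 5 * 4)
  expect_true(all(g2$edges$target %in% gr$roster$tfs))
  expect_equal(g2$P, sum(gr$gold$edges$target %in% gr$roster$tfs))

  el <- random_ranking(gr$roster, seed = 24)
  el2 <- restrict_ranking_tf_tf(el, gr$roster$tfs)
  expect_equal(nrow(el2), g2$T)
  expect_true(!is.unsorted(rev(el2$score)))
  if (g2$P > 0) {
    a <- auroc_aupr(curve_points(el2, g2))
    expect_true(a["auroc"] >= 0 && a["auroc"] <= 1)
  }
})
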