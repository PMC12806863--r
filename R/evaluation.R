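# DREAM-style evaluation of ranked edge lists: AUROC/AUPR with the
# sampling-and-filling correction for truncated lists, a confidence score
# against a random-ranking null (Gaussian KDE upper tail, capped at 100),
# and the early precision ratio.

#' Confusion-curve points for a ranked list against a gold standard
#'
#' For every cutoff `k` in `1..T` (the admissible-pair universe size)
#' computes TP, FP, TPR (= recall), FPR and precision. For `k` up to the
#' list length `L` the counts are exact; beyond the list the true positives
#' are filled linearly, `TP(k) = TP_L + (k - L) * (P - TP_L) / (T - L)`,
#' the expected count if the unlisted pairs were appended in random order.
#'
#' @param edges a `ranked_edges` data frame whose pairs all lie inside the
#'   admissible universe of `gold`.
#' @param gold a `gold_standard`.
#' @return data.frame with columns `k`, `TP`, `FP`, `TPR`, `FPR`,
#'   `precision`, `recall` for `k = 1..T`.
#' @export
curve_points <- function(edges, gold) {
  pos_flags <- positive_flags(edges, gold)
  L <- length(pos_flags)
  P <- gold$P; N <- gold$N; T_all <- gold$T
  if (L > T_all) stop("list is longer than the admissible universe")
  tp <- cumsum(pos_flags)
  if (L < T_all) {
    tp_l <- tp[L]
    k_fill <- seq.int(L + 1L, T_all)
    tp <- c(tp, tp_l + (k_fill - L) * (P - tp_l) / (T_all - L))
  }
  k <- seq_len(T_all)
  fp <- k - tp
  data.frame(k = k, TP = tp, FP = fp,
             TPR = tp / P, FPR = fp / N,
             precision = tp / k, recall = tp / P)
}

positive_flags <- function(edges, gold) {
  roster <- gold$roster
  bad_reg <- setdiff(edges$regulator, roster$tfs)
  bad_tgt <- setdiff(edges$target, roster$all)
  offending <- character()
  if (length(bad_reg) || length(bad_tgt) || any(edges$regulator == edges$target)) {
    self <- edges$regulator == edges$target
    offending <- unique(c(
      if (length(bad_reg))
        paste(edges$regulator, edges$target)[edges$regulator %in% bad_reg],
      if (length(bad_tgt))
        paste(edges$regulator, edges$target)[edges$target %in% bad_tgt],
      paste(edges$regulator, edges$target)[self]))
    stop("pairs outside the gold universe: ",
         paste(utils::head(offending, 10L), collapse = "; "))
  }
  key <- paste(edges$regulator, edges$target, sep = "\r")
  as.integer(key %in% gold$positives)
}

#' Areas under the ROC and precision-recall curves
#'
#' Trapezoidal area over (FPR, TPR) and step-wise area over
#' (recall, precision) — the latter equals average precision on a full,
#' tie-free list.
#'
#' @param points output of [curve_points()].
#' @return named numeric vector `c(auroc = , aupr = )`.
#' @export
auroc_aupr <- function(points) {
  if (!all(c("TPR", "FPR", "precision", "recall") %in% names(points)))
    stop("points must come from curve_points()")
  tpr <- c(0, points$TPR); fpr <- c(0, points$FPR)
  if (!is.finite(tpr[length(tpr)]) || !is.finite(fpr[length(fpr)]))
    stop("undefined curves: the gold standard needs both positives and negatives")
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  drec <- diff(c(0, points$recall))
  aupr <- sum(drec * points$precision)
  c(auroc = auroc, aupr = aupr)
}

#' Random-ranking null distribution of AUROC and AUPR
#'
#' Evaluates `n` uniformly random orderings of the full admissible pair
#' universe against the gold standard. Each random ranking is a permutation;
#' its AUROC is computed from the positive positions by the rank
#' (Mann-Whitney) identity and its AUPR as average precision, both exactly
#' equal to running the full curve machinery.
#'
#' @param gold a `gold_standard`.
#' @param n number of random networks (the headline analysis uses 100,000;
#'   tests use far fewer).
#' @param seed integer seed.
#' @return object of class `null_distribution`: list with numeric vectors
#'   `auroc` and `aupr` of length `n`, and `n`.
#' @export
random_null <- function(gold, n = 100000L, seed = 1L) {
  if (n < 1L) stop("n must be positive")
  P <- gold$P; T_all <- gold$T; N <- gold$N
  if (P == 0L || N == 0L)
    stop("gold standard needs both positives and negatives")
  set.seed(seed)
  auroc <- numeric(n); aupr <- numeric(n)
  ip <- seq_len(P)
  for (r in seq_len(n)) {
    pos <- sort.int(sample.int(T_all, P))
    # negatives before positive i: pos_i - i ; Mann-Whitney count
    auroc[r] <- 1 - sum(pos - ip) / (P * N)
    aupr[r] <- mean(ip / pos)
  }
  structure(list(auroc = auroc, aupr = aupr, n = n),
            class = "null_distribution")
}

#' Confidence score of a metric value against a null sample
#'
#' Fits a Gaussian kernel density (Scott's bandwidth) to the null sample and
#' returns `min(-log10(p), 100)` where `p` is the KDE's upper-tail
#' probability beyond `value` (computed exactly as the mean Gaussian tail
#' over the kernels, floored at 1e-100).
#'
#' @param value observed metric value (e.g. an AUROC).
#' @param null_samples numeric vector of >= 100 null metric values, or a
#'   `null_distribution` together with `metric`.
#' @param metric which null to use when a `null_distribution` is supplied.
#' @return confidence score in `[0, 100]`.
#' @export
confidence_score <- function(value, null_samples,
                             metric = c("auroc", "aupr")) {
  if (inherits(null_samples, "null_distribution")) {
    metric <- match.arg(metric)
    null_samples <- null_samples[[metric]]
  }
  if (length(null_samples) < 100L)
    stop("need at least 100 null samples, got ", length(null_samples))
  h <- stats::bw.nrd(null_samples)
  if (!is.finite(h) || h <= 0) h <- 1e-6
  p <- mean(stats::pnorm(value, mean = null_samples, sd = h,
                         lower.tail = FALSE))
  p <- max(p, 1e-100)
  min(-log10(p), 100)
}

#' Early precision ratio
#'
#' Early precision is the fraction of true positives among the top-`q`
#' predictions, with `q` the number of gold-standard edges; the EPR divides
#' it by a random predictor's expected precision `P / T`.
#'
#' @param edges a `ranked_edges` data frame of length >= `q`.
#' @param gold a `gold_standard`.
#' @return non-negative scalar; 1 is random-level, `T / P` is perfect.
#' @export
epr <- function(edges, gold) {
  q <- gold$P
  if (q == 0L) stop("gold standard has no positive edges")
  if (nrow(edges) < q)
    stop("ranked list (", nrow(edges), ") shorter than q = ", q)
  flags <- positive_flags(edges, gold)
  tp_q <- sum(flags[seq_len(q)])
  (tp_q / q) / (gold$P / gold$T)
}

#' Restrict evaluation to TF-TF pairs
#'
#' Rebuilds a gold standard over the TF-only universe (all ordered TF
#' pairs, `T = |F| * (|F| - 1)`), keeping the positives whose targets are
#' TFs. Use together with [restrict_ranking_tf_tf()] to evaluate how well
#' a method resolves regulation *among* regulators, which association
#' methods cannot orient; nulls must be re-sampled on the restricted gold.
#'
#' @param gold a `gold_standard`.
#' @return a `gold_standard` over the TF-only roster.
#' @export
restrict_gold_tf_tf <- function(gold) {
  roster <- gold$roster
  r2 <- gene_roster(roster$tfs, roster$tfs)
  pos <- gold$edges[gold$edges$target %in% roster$tfs,
                    c("regulator", "target"), drop = FALSE]
  gold_standard(pos, r2)
}

#' @rdname restrict_gold_tf_tf
#' @param edges a `ranked_edges` data frame.
#' @param tfs character vector of TF ids.
#' @return for `restrict_ranking_tf_tf`: the rows whose target is a TF,
#'   order preserved.
#' @export
restrict_ranking_tf_tf <- function(edges, tfs) {
  out <- edges[edges$target %in% tfs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full evaluation report for a ranked list
#'
#' @param edges a `ranked_edges` data frame.
#' @param gold a `gold_standard`.
#' @param null optional `null_distribution` (see [random_null()]); when
#'   given, per-metric confidence scores and their mean are reported.
#' @return list of class `eval_report`: `auroc`, `aupr`, `epr`, and (with a
#'   null) `confidence_auroc`, `confidence_aupr`, `confidence`.
#' @export
evaluate_ranking <- function(edges, gold, null = NULL) {
  pts <- curve_points(edges, gold)
  areas <- auroc_aupr(pts)
  report <- list(auroc = unname(areas["auroc"]), aupr = unname(areas["aupr"]),
              epr = if (nrow(edges) >= gold$P) epr(edges, gold) else NA_real_)
  if (!is.null(null)) {
    report$confidence_auroc <- confidence_score(report$auroc, null, "auroc")
    report$confidence_aupr <- confidence_score(report$aupr, null, "aupr")
    report$confidence <- mean(c(report$confidence_auroc,
                                report$confidence_aupr))
  }
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report: AUROC", round(x$auroc, 4), " AUPR", round(x$aupr, 4),
      " EPR", round(x$epr, 3), "\n")
  if (!is.null(x$confidence))
    cat("  confidence:", round(x$confidence_auroc, 2), "(AUROC),",
        round(x$confidence_aupr, 2), "(AUPR), mean",
        round(x$confidence, 2), "\n")
  invisible(x)
}
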