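# Stage-wise analysis: infer a propensity matrix per ordered disease stage,
# flag regulator-target pairs whose regulation strength changes
# monotonically across the stages, and rank driver TFs by how many such
# relations they regulate.

#' Bundle per-stage propensity matrices
#'
#' @param w_list list of `propensity_matrix` objects, one per stage, in
#'   stage order, sharing one roster.
#' @param stage_labels character labels (e.g. normal, IBD, adenoma, CRC).
#' @return object of class `stage_scores`.
#' @export
stage_scores <- function(w_list, stage_labels = NULL) {
  if (length(w_list) < 2L) stop("need at least 2 stages")
  ref <- w_list[[1L]]$roster
  for (w in w_list[-1L])
    if (!identical(w$roster$tfs, ref$tfs) ||
        !identical(w$roster$all, ref$all))
      stop("stages have non-matching rosters")
  if (is.null(stage_labels))
    stage_labels <- paste0("stage_", seq_along(w_list))
  stopifnot(length(stage_labels) == length(w_list))
  structure(list(w = w_list, roster = ref, stage_labels = stage_labels),
            class = "stage_scores")
}

#' Screen for monotonically changing regulatory relations
#'
#' Each stage's propensity scores are first normalized to a common `[0, 1]`
#' scale over the admissible pairs so stages of different sample sizes are
#' comparable: `scale = "minmax"` (the default) rescales linearly,
#' `"rank"` replaces scores by their normalized ranks (robust to score
#' scale but unstable when many null pairs are nearly tied, since tiny
#' estimate fluctuations then move ranks a lot), and `"raw"` screens the
#' scores as-is. A relation is flagged *increasing* when every
#' consecutive stage difference is >= 0 and the total change from first to
#' last stage is at least `threshold`; *decreasing* symmetrically.
#'
#' @param scores a [stage_scores()] with >= 3 stages.
#' @param threshold minimum total change on the normalized scale;
#'   default 0.15.
#' @param scale `"minmax"`, `"rank"` or `"raw"`.
#' @return data.frame of class `monotone_relations`: columns `regulator`,
#'   `target`, `direction` (`"increasing"`/`"decreasing"`), `magnitude`
#'   (absolute total change), sorted by decreasing magnitude.
#' @export
monotone_screen <- function(scores, threshold = 0.15,
                            scale = c("minmax", "rank", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(scores, "stage_scores"))
  if (length(scores$w) < 3L) stop("need at least 3 stages to screen")
  pairs <- admissible_pairs(scores$roster)
  idx <- cbind(pairs$row, pairs$col)
  seqs <- vapply(scores$w, function(w) {
    v <- w$values[idx]
    switch(scale,
           rank = (rank(v, ties.method = "average") - 1) / (length(v) - 1),
           minmax = {
             rng <- range(v)
             if (rng[1] == rng[2]) rep(0.5, length(v))
             else (v - rng[1]) / (rng[2] - rng[1])
           },
           raw = v)
  }, numeric(nrow(pairs)))
  diffs <- t(apply(seqs, 1L, diff))
  total <- seqs[, ncol(seqs)] - seqs[, 1L]
  inc <- apply(diffs >= 0, 1L, all) & total >= threshold
  dec <- apply(diffs <= 0, 1L, all) & (-total) >= threshold
  out <- data.frame(
    regulator = c(pairs$regulator[inc], pairs$regulator[dec]),
    target = c(pairs$target[inc], pairs$target[dec]),
    direction = rep(c("increasing", "decreasing"), c(sum(inc), sum(dec))),
    magnitude = abs(c(total[inc], total[dec])),
    stringsAsFactors = FALSE)
  out <- out[order(-out$magnitude, out$regulator, out$target), ]
  rownames(out) <- NULL
  structure(out, class = c("monotone_relations", "data.frame"))
}

#' Rank driver TFs by monotone-relation participation
#'
#' TFs regulating more monotonically changing relations are ranked higher;
#' ties break lexicographically.
#'
#' @param relations a `monotone_relations` data frame (non-empty).
#' @return data.frame with columns `tf`, `n_relations`, sorted.
#' @export
driver_tf_ranking <- function(relations) {
  if (!nrow(relations))
    stop("no monotone relations to rank drivers from")
  counts <- table(relations$regulator)
  df <- data.frame(tf = names(counts), n_relations = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n_relations, df$tf), ]
  rownames(df) <- NULL
  df
}

#' Infer per-stage propensity matrices and screen them
#'
#' Convenience wrapper for the stage-wise analysis: z-scores each stage's
#' expression, scores all admissible pairs with the expression-profile ANM
#' scorer (per-stage graph embedding is configurable via `config`), then
#' runs [monotone_screen()] and [driver_tf_ranking()].
#'
#' @param stage_exprs ordered list of samples x genes expression matrices
#'   sharing gene columns.
#' @param tfs character vector of TF ids.
#' @param threshold monotonicity threshold (total rank-scale change).
#' @param config a [grn_config()]; its `pipeline` selects how each stage's
#'   propensity matrix is produced (default `"anm-only"` keeps the stage
#'   analysis light).
#' @param stage_labels optional labels.
#' @return list with `relations`, `drivers`, `scores`.
#' @export
stagewise_analysis <- function(stage_exprs, tfs, threshold = 0.15,
                               config = grn_config(pipeline = "anm-only"),
                               stage_labels = NULL) {
  w_list <- lapply(seq_along(stage_exprs), function(s) {
    res <- infer_grn(stage_exprs[[s]], tfs, config)
    res$W
  })
  sc <- stage_scores(w_list, stage_labels)
  rel <- monotone_screen(sc, threshold = threshold)
  drv <- if (nrow(rel)) driver_tf_ranking(rel) else
    data.frame(tf = character(), n_relations = integer())
  list(relations = rel, drivers = drv, scores = sc)
}
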