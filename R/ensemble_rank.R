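# Weighted Borda combination of the linear- and nonlinear-pipeline
# propensity matrices, and conversion of a propensity matrix into the final
# ranked edge list.

#' Combine two propensity matrices with a lambda-weighted vote
#'
#' `W = lambda * norm(W_li) + (1 - lambda) * norm(W_nonli)` over the
#' admissible entries. The default normalization `"rank"` replaces each
#' matrix's admissible entries by their centered ranks (a true Borda count,
#' invariant to any strictly monotone rescaling of either input); `"minmax"`
#' rescales to `[0, 1]`; `"none"` combines the raw values (the literal
#' weighted sum, sensible only when both matrices share a scale).
#'
#' @param w_li,w_nonli `propensity_matrix` objects over the same roster.
#' @param lambda weight of the linear pipeline, strictly inside (0, 1);
#'   default 0.5.
#' @param normalization `"rank"`, `"minmax"` or `"none"`.
#' @return a `propensity_matrix` with the combined scores (inadmissible
#'   entries zero).
#' @export
ensemble_propensity <- function(w_li, w_nonli, lambda = 0.5,
                                normalization = c("rank", "minmax", "none")) {
  normalization <- match.arg(normalization)
  if (!(lambda > 0 && lambda < 1))
    stop("lambda must lie strictly inside (0, 1)")
  if (!identical(dim(w_li$values), dim(w_nonli$values)) ||
      !identical(w_li$roster$all, w_nonli$roster$all) ||
      !identical(w_li$roster$tfs, w_nonli$roster$tfs))
    stop("propensity matrices have mismatched rosters or shapes")
  pairs <- admissible_pairs(w_li$roster)
  idx <- cbind(pairs$row, pairs$col)
  a <- normalize_scores(w_li$values[idx], normalization)
  b <- normalize_scores(w_nonli$values[idx], normalization)
  out <- w_li$values * 0
  out[idx] <- lambda * a + (1 - lambda) * b
  structure(list(values = out, roster = w_li$roster),
            class = "propensity_matrix")
}

normalize_scores <- function(v, normalization) {
  switch(normalization,
         rank = {
           n <- length(v)
           (rank(v, ties.method = "average") - (n + 1) / 2) / n
         },
         minmax = {
           rng <- range(v)
           if (rng[1] == rng[2]) rep(0.5, length(v))
           else (v - rng[1]) / (rng[2] - rng[1])
         },
         none = v)
}

#' Rank all admissible edges of a propensity matrix
#'
#' @param w a `propensity_matrix`.
#' @return a [ranked_edges()] data frame of length `|F| * (|F| + |G| - 1)`,
#'   descending by score with deterministic lexicographic
#'   `(regulator, target)` tie-break.
#' @export
rank_edges <- function(w) {
  pairs <- admissible_pairs(w$roster)
  ranked_edges(pairs$regulator, pairs$target,
               w$values[cbind(pairs$row, pairs$col)])
}

#' Size of the top-k intersection of two ranked edge lists
#'
#' @param list_a,list_b `ranked_edges` data frames.
#' @param k how many top edges of each list to compare; must be positive and
#'   at most the shorter list's length.
#' @return integer: number of directed pairs present in both top-k sets.
#' @export
topk_intersection <- function(list_a, list_b, k) {
  if (k <= 0) stop("k must be positive")
  if (k > min(nrow(list_a), nrow(list_b)))
    stop("k exceeds the length of a list")
  ka <- paste(list_a$regulator[seq_len(k)], list_a$target[seq_len(k)],
              sep = "\r")
  kb <- paste(list_b$regulator[seq_len(k)], list_b$target[seq_len(k)],
              sep = "\r")
  length(intersect(ka, kb))
}
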