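# Co-expression "potential" networks: undirected, thresholded association
# graphs used only to guide representation learning, never as the output.

#' Pearson correlation matrix between genes
#'
#' @param m standardized samples x genes matrix (see [zscore_normalize()]).
#' @return symmetric genes x genes correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(m) {
  validate_expression(m)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds <= 0))
    stop("zero-variance column(s): ",
         paste(colnames(m)[sds <= 0], collapse = ", "))
  r <- stats::cor(m)
  # enforce exact symmetry against floating asymmetries
  (r + t(r)) / 2
}

#' Pairwise mutual information between genes
#'
#' Plug-in (histogram) estimator: each gene is discretized into `n_bins`
#' equal-width bins over its own range, and MI is computed in nats from the
#' joint and marginal bin frequencies. The diagonal holds each gene's
#' marginal entropy (its self-MI); thresholding ignores it.
#'
#' @param m samples x genes matrix (standardized or raw; MI is invariant to
#'   the per-gene affine rescaling that z-scoring applies).
#' @param n_bins number of equal-width bins per gene; default
#'   `ceiling(sqrt(m))` over the sample count.
#' @return symmetric genes x genes matrix of MI values in nats (>= 0).
#' @export
mutual_information_matrix <- function(m, n_bins = NULL) {
  validate_expression(m)
  ns <- nrow(m)
  if (is.null(n_bins)) n_bins <- ceiling(sqrt(ns))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (n_bins > ns) stop("n_bins (", n_bins, ") exceeds sample count (", ns, ")")
  ng <- ncol(m)
  bins <- matrix(0L, ns, ng)
  for (j in seq_len(ng)) bins[, j] <- equal_width_bins(m[, j], n_bins)
  marg <- lapply(seq_len(ng), function(j) tabulate(bins[, j], n_bins) / ns)
  ent <- vapply(marg, function(p) -sum(p[p > 0] * log(p[p > 0])), 0)
  mi <- matrix(0, ng, ng, dimnames = list(colnames(m), colnames(m)))
  diag(mi) <- ent
  for (i in seq_len(ng - 1L)) {
    bi <- bins[, i]
    for (j in seq.int(i + 1L, ng)) {
      joint <- tabulate(bi + n_bins * (bins[, j] - 1L), n_bins * n_bins) / ns
      hj <- -sum(joint[joint > 0] * log(joint[joint > 0]))
      mi[i, j] <- mi[j, i] <- max(ent[i] + ent[j] - hj, 0)
    }
  }
  mi
}

equal_width_bins <- function(x, n_bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  idx <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
  pmin(idx, n_bins)
}

#' Threshold an association matrix into a potential network
#'
#' Keeps an undirected edge i-j when the association score is at least
#' `threshold` (and i != j). For the linear flavor the score is `|R_ij|`
#' by default (co-expression strength is sign-agnostic; set `absolute =
#' FALSE` to threshold the signed correlation); for the nonlinear flavor the
#' raw MI in nats.
#'
#' On the DREAM-challenge benchmarks, cutoffs of 0.35-0.70 for `|r|` and
#' 0.15-0.65 for MI produce networks whose sparsity is close to the
#' respective gold standards, which is the regime where downstream
#' inference works best; when the expected edge density is known, derive
#' the cutoff with [threshold_for_edges()] instead of fixing it.
#'
#' @param r symmetric association matrix ([pearson_matrix()] or
#'   [mutual_information_matrix()]).
#' @param threshold real cutoff.
#' @param flavor `"linear"` or `"nonlinear"`; recorded on the result.
#' @param absolute threshold `|r|` instead of `r` (default `TRUE`; only
#'   meaningful for the linear flavor).
#' @return object of class `potential_network`: list with `adjacency`
#'   (symmetric 0/1 matrix, zero diagonal), `threshold`, `flavor`,
#'   `n_edges`.
#' @export
threshold_network <- function(r, threshold, flavor = c("linear", "nonlinear"),
                              absolute = TRUE) {
  flavor <- match.arg(flavor)
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8)))
    stop("association matrix must be symmetric")
  score <- if (flavor == "linear" && absolute) abs(r) else r
  adj <- (score >= threshold) * 1L
  diag(adj) <- 0L
  adj <- pmax(adj, t(adj))  # exact symmetry
  n_edges <- sum(adj) / 2
  if (n_edges == 0)
    stop("threshold ", threshold, " leaves an empty network; lower it ",
         "(max off-diagonal score: ",
         signif(max(score[upper.tri(score)]), 4), ")")
  structure(list(adjacency = adj, threshold = threshold, flavor = flavor,
                 n_edges = n_edges),
            class = "potential_network")
}

#' @export
print.potential_network <- function(x, ...) {
  cat("potential_network (", x$flavor, "): ", nrow(x$adjacency), " genes, ",
      x$n_edges, " edges at threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Choose a threshold that matches a target edge count
#'
#' The framework performs best when the potential network's sparsity is close
#' to the expected gold-standard sparsity, so rather than fixing an absolute
#' cutoff one can pick the threshold whose network has (at most) a target
#' number of edges.
#'
#' @param r association matrix.
#' @param n_edges desired number of undirected edges.
#' @param flavor,absolute as in [threshold_network()].
#' @return the score of the `n_edges`-th strongest gene pair; passing it to
#'   [threshold_network()] yields at least `n_edges` edges (more under ties).
#' @export
threshold_for_edges <- function(r, n_edges, flavor = c("linear", "nonlinear"),
                                absolute = TRUE) {
  flavor <- match.arg(flavor)
  score <- if (flavor == "linear" && absolute) abs(r) else r
  vals <- sort(score[upper.tri(score)], decreasing = TRUE)
  n_edges <- min(max(as.integer(n_edges), 1L), length(vals))
  vals[n_edges]
}

#' Export a potential network as an undirected edge list
#'
#' TSV rows `geneA<TAB>geneB` with `geneA < geneB` lexicographically.
#'
#' @param net a `potential_network`.
#' @param path output path.
#' @export
write_potential_network <- function(net, path) {
  adj <- net$adjacency
  idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  g <- colnames(adj)
  a <- g[idx[, 1L]]; b <- g[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ord <- order(a, b)
  writeLines(paste(a[ord], b[ord], sep = "\t"), path)
  invisible(NULL)
}
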