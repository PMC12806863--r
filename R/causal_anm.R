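# Pairwise causal direction scoring under the additive noise model (ANM):
# regress each gene on the other with Gaussian-process regression, then
# measure dependence between the residual and the putative cause with the
# Hilbert-Schmidt independence criterion. The direction whose residual is
# more independent of its input (smaller HSIC) is the better causal fit.

#' Gaussian-process regression residuals
#'
#' Fits a zero-mean GP with squared-exponential kernel plus i.i.d. noise to
#' `y ~ x` and returns `y` minus the posterior-mean prediction at the
#' training inputs. The kernel lengthscale is set by the median
#' pairwise-distance heuristic on standardized `x`; the signal and noise
#' variances are chosen by maximizing the log marginal likelihood (two
#' optimizer restarts) in the eigenbasis of the kernel matrix, which keeps
#' each likelihood evaluation linear in the sample count.
#'
#' @param x,y numeric vectors of equal length (>= 10).
#' @return numeric vector of residuals (the estimated noise).
#' @export
gpr_residuals <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  m <- length(x)
  if (m < 10L) stop("GPR needs at least 10 observations, got ", m)
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("x and y must be finite")

  sy <- stats::sd(y)
  if (sy == 0) return(rep(0, m))
  my <- mean(y)
  yc <- (y - my) / sy

  sx <- stats::sd(x)
  if (sx == 0) return(y - my)          # constant input: fit the mean
  xs <- (x - mean(x)) / sx

  d2 <- outer(xs, xs, `-`)^2
  med <- stats::median(sqrt(d2[d2 > 0]))
  ell <- if (is.finite(med) && med > 0) med else 1
  K0 <- exp(-d2 / (2 * ell^2))
  e <- eigen(K0, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  g <- drop(crossprod(e$vectors, yc))
  g2 <- g^2

  nll <- function(par) {
    sf2 <- exp(par[1L]); sn2 <- exp(par[2L])
    ev <- sf2 * lam + sn2
    0.5 * (sum(log(ev)) + sum(g2 / ev))
  }
  starts <- list(c(log(0.9), log(0.1)), c(log(0.1), log(0.9)))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, nll, method = "L-BFGS-B",
                        lower = log(1e-9), upper = log(1e4))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  sf2 <- exp(best$par[1L]); sn2 <- exp(best$par[2L])
  shrink <- sf2 * lam / (sf2 * lam + sn2)
  fitted <- drop(e$vectors %*% (shrink * g))
  (yc - fitted) * sy
}

#' Hilbert-Schmidt independence criterion (biased statistic)
#'
#' `HSIC = trace(K H L H) / m^2` with Gaussian kernels on both arguments
#' (bandwidth by the median pairwise-distance heuristic) and `H` the
#' centering matrix. Zero for any constant argument; grows with dependence.
#'
#' @param a,b numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
hsic <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  m <- length(a)
  K <- gaussian_gram(a)
  L <- gaussian_gram(b)
  if (is.null(K) || is.null(L)) return(0)
  Kc <- center_gram(K)
  Lc <- center_gram(L)
  max(sum(Kc * Lc) / m^2, 0)
}

gaussian_gram <- function(x) {
  d2 <- outer(x, x, `-`)^2
  med2 <- stats::median(d2[d2 > 0])
  if (!is.finite(med2) || med2 <= 0) return(NULL)   # constant vector
  exp(-d2 / (2 * med2))
}

center_gram <- function(K) {
  K <- K - rowMeans(K)
  sweep(K, 2L, colMeans(K))
}

#' ANM asymmetry score for an ordered gene pair
#'
#' `forward` is the HSIC between the residual of regressing `v` on `u` and
#' `u` (the fit quality of direction `u -> v`: smaller means the residual is
#' more independent of the cause, i.e. better ANM fit); `backward` is the
#' reverse direction. The direction `u -> v` is supported when
#' `forward < backward`.
#'
#' @param u,v numeric vectors of equal length (>= 10).
#' @return list of class `pair_score` with elements `forward`, `backward`
#'   and `direction` (`"forward"`, `"backward"` or `"tie"`).
#' @export
anm_score <- function(u, v) {
  ru <- gpr_residuals(u, v)   # residual of v ~ u
  rv <- gpr_residuals(v, u)   # residual of u ~ v
  fwd <- hsic(ru, u)
  bwd <- hsic(rv, v)
  structure(list(forward = fwd, backward = bwd,
                 direction = if (fwd < bwd) "forward"
                 else if (bwd < fwd) "backward" else "tie"),
            class = "pair_score")
}

#' @export
print.pair_score <- function(x, ...) {
  cat("pair_score: forward", signif(x$forward, 4), "backward",
      signif(x$backward, 4), "->", x$direction, "\n")
  invisible(x)
}

#' Directional propensity matrix over all admissible pairs
#'
#' Scores every admissible directed pair (TF -> TF and TF -> TG, no
#' self-pairs, never TG -> TG) by the ANM asymmetry of the two genes'
#' profile vectors. The stored entry is `W[i, j] = backward - forward`
#' (reverse-direction HSIC minus forward-direction HSIC), so larger values
#' mean stronger evidence for regulation i -> j and a descending sort ranks
#' likely causal edges first. The diagonal of the TF block is zero (no
#' self-regulation) and the TF-TF block is exactly antisymmetric.
#'
#' @param profiles numeric matrix with one column per gene (named), rows
#'   being the per-gene observation series: either the standardized
#'   expression samples or the learned embedding dimensions (genes as
#'   columns of the transposed embedding matrix).
#' @param roster a [gene_roster()]; every roster gene must have a profile
#'   column.
#' @param subsample_cap rows are subsampled (without replacement, using the
#'   current RNG) to this cap to bound the cubic GPR cost; default 500.
#' @param n_bags average the scores over this many disjoint row subsets
#'   (default 1, no bagging). Bagging reduces the variance of every pair's
#'   score at fixed total sample cost, which matters when scores are
#'   compared across independently sampled datasets, as in the stage-wise
#'   screen.
#' @param progress print a dot every 200 pairs.
#' @return object of class `propensity_matrix`: list with `values`
#'   (`|F| x |F|+|G|` matrix with TF rows and roster-ordered columns) and
#'   `roster`.
#' @export
propensity_matrix <- function(profiles, roster, subsample_cap = 500L,
                              n_bags = 1L, progress = FALSE) {
  stopifnot(inherits(roster, "gene_roster"))
  missing <- setdiff(roster$all, colnames(profiles))
  if (length(missing))
    stop("no profile for gene(s): ", paste(missing, collapse = ", "))
  profiles <- profiles[, roster$all, drop = FALSE]
  n_bags <- max(1L, as.integer(n_bags))
  if (n_bags > 1L) {
    groups <- split(sample.int(nrow(profiles)),
                    rep_len(seq_len(n_bags), nrow(profiles)))
    ws <- lapply(groups, function(rows)
      propensity_matrix(profiles[rows, , drop = FALSE], roster,
                        subsample_cap = subsample_cap, progress = progress))
    avg <- Reduce(`+`, lapply(ws, `[[`, "values")) / n_bags
    return(structure(list(values = avg, roster = roster),
                     class = "propensity_matrix"))
  }
  if (nrow(profiles) > subsample_cap)
    profiles <- profiles[sample.int(nrow(profiles), subsample_cap), ,
                         drop = FALSE]

  nf <- length(roster$tfs)
  ng <- length(roster$all)
  W <- matrix(0, nf, ng, dimnames = list(roster$tfs, roster$all))
  done <- 0L
  for (i in seq_len(nf)) {
    xi <- profiles[, i]
    for (j in seq_len(ng)) {
      if (j <= nf && j <= i) next          # TF block: fill upper, mirror
      sc <- anm_score(xi, profiles[, j])
      W[i, j] <- sc$backward - sc$forward
      if (j <= nf) W[j, i] <- -W[i, j]
      done <- done + 1L
      if (progress && done %% 200L == 0L) cat(".")
    }
  }
  if (progress) cat("\n")
  structure(list(values = W, roster = roster), class = "propensity_matrix")
}

#' @export
print.propensity_matrix <- function(x, ...) {
  cat("propensity_matrix:", nrow(x$values), "TFs x", ncol(x$values),
      "genes\n")
  invisible(x)
}

#' Dump pairwise scores as TSV
#'
#' @param w a `propensity_matrix`.
#' @param path output path; rows `regulator<TAB>target<TAB>W`.
#' @export
write_propensity <- function(w, path) {
  el <- admissible_pairs(w$roster)
  utils::write.table(
    data.frame(el$regulator, el$target,
               w$values[cbind(el$row, el$col)]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

# All admissible (regulator, target) pairs with matrix indices.
admissible_pairs <- function(roster) {
  nf <- length(roster$tfs)
  ng <- length(roster$all)
  row <- rep(seq_len(nf), each = ng)
  col <- rep(seq_len(ng), nf)
  keep <- !(col <= nf & col == row)     # drop TF self-pairs
  row <- row[keep]; col <- col[keep]
  data.frame(row = row, col = col,
             regulator = roster$tfs[row], target = roster$all[col],
             stringsAsFactors = FALSE)
}
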