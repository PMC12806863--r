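# Synthetic regulatory networks with ANM-consistent expression: a planted
# directed TF -> gene graph (acyclic over TFs via a random topological
# order) where every non-root gene is a sum of nonlinear functions of its
# regulators plus additive Gaussian noise. Root genes are standard normal.

#' Specification for a synthetic regulatory network
#'
#' @param n_tfs,n_tgs numbers of transcription factors and target genes.
#' @param n_edges number of planted directed edges (TF -> TF respecting a
#'   random topological order, or TF -> TG).
#' @param n_samples samples to draw.
#' @param function_family `"quadratic"` (`a * (x - b)^2`), `"sigmoid"`
#'   (`a * tanh(c * x)`) or `"mixed"` (each edge picks one at random).
#'   Amplitudes satisfy `0.5 <= |a| <= 1.5` so planted edges stay detectable.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   every regulated gene.
#' @param tf_tf allow TF -> TF edges (default `TRUE`). With `FALSE` the
#'   planted graph is bipartite (TF -> TG only), so every TF is an
#'   independent root; useful when planted effects must be attributable to
#'   a single regulator, as in the stage-wise screen fixtures.
#' @param seed integer seed; fixes graph, coefficients and samples.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_tfs = 20L, n_tgs = 80L, n_edges = 150L,
                           n_samples = 300L,
                           function_family = c("mixed", "quadratic",
                                               "sigmoid"),
                           noise_sd = 0.3, tf_tf = TRUE, seed = 1L) {
  function_family <- match.arg(function_family)
  stopifnot(n_tfs >= 1L, n_tgs >= 0L, n_edges >= 0L, n_samples >= 2L,
            noise_sd > 0)
  structure(list(n_tfs = as.integer(n_tfs), n_tgs = as.integer(n_tgs),
                 n_edges = as.integer(n_edges),
                 n_samples = as.integer(n_samples),
                 function_family = function_family, noise_sd = noise_sd,
                 tf_tf = isTRUE(tf_tf), seed = as.integer(seed)),
            class = "synthetic_spec")
}

draw_edge_function <- function(family) {
  fam <- if (family == "mixed")
    sample(c("quadratic", "sigmoid"), 1L) else family
  a <- sample(c(-1, 1), 1L) * stats::runif(1L, 0.5, 1.5)
  if (fam == "quadratic") {
    b <- stats::runif(1L, -1, 1)
    list(family = "quadratic", a = a, b = b,
         f = function(x) a * (x - b)^2)
  } else {
    cc <- stats::runif(1L, 1, 3)
    list(family = "sigmoid", a = a, c = cc,
         f = function(x) a * tanh(cc * x))
  }
}

plant_edges <- function(n_tfs, n_tgs, n_edges, tf_ids, tg_ids,
                        tf_tf = TRUE) {
  topo <- sample.int(n_tfs)                      # random topological order
  cand_reg <- integer(); cand_tgt <- integer()
  if (tf_tf && n_tfs > 1L) {
    idx <- which(outer(topo, topo, `<`), arr.ind = TRUE)
    cand_reg <- idx[, 1L]; cand_tgt <- idx[, 2L]
  }
  if (n_tgs > 0L) {
    cand_reg <- c(cand_reg, rep(seq_len(n_tfs), each = n_tgs))
    cand_tgt <- c(cand_tgt, rep(n_tfs + seq_len(n_tgs), n_tfs))
  }
  if (n_edges > length(cand_reg))
    stop("requested ", n_edges, " edges but only ", length(cand_reg),
         " admissible DAG-consistent pairs exist")
  pick <- if (n_edges > 0L) sample.int(length(cand_reg), n_edges) else
    integer()
  list(reg = cand_reg[pick], tgt = cand_tgt[pick], topo = topo)
}

#' Simulate a planted regulatory network with ANM expression
#'
#' Draws the planted graph, per-edge nonlinear functions and an expression
#' matrix in which every regulated gene is the sum of its regulators'
#' transformed (standardized) values plus Gaussian noise; unregulated genes
#' are standard normal. Regulator values are population-standardized before
#' entering the edge functions so scales stay bounded along TF chains; this
#' affine step preserves the additive-noise mechanism.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_grn`: `expression` (samples x genes),
#'   `roster`, `gold` (the planted edges as a `gold_standard`), `edges`
#'   (data.frame with per-edge function metadata), `spec`.
#' @export
simulate_grn <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  tf_ids <- sprintf("TF%03d", seq_len(spec$n_tfs))
  tg_ids <- if (spec$n_tgs > 0L) sprintf("G%04d", seq_len(spec$n_tgs))
    else character()
  ids <- c(tf_ids, tg_ids)
  n_genes <- length(ids)
  planted <- plant_edges(spec$n_tfs, spec$n_tgs, spec$n_edges, tf_ids,
                         tg_ids, spec$tf_tf)
  funs <- lapply(seq_along(planted$reg), function(i)
    draw_edge_function(spec$function_family))

  expr <- sample_expression(spec, planted, funs, n_genes)
  dimnames(expr) <- list(sprintf("S%04d", seq_len(spec$n_samples)), ids)

  roster <- gene_roster(tf_ids, ids)
  edges_df <- data.frame(
    regulator = ids[planted$reg], target = ids[planted$tgt],
    family = vapply(funs, `[[`, "", "family"),
    amplitude = vapply(funs, `[[`, 0, "a"),
    stringsAsFactors = FALSE)
  gold <- if (nrow(edges_df))
    gold_standard(edges_df, roster)
  else structure(list(edges = edges_df, positives = character(),
                      P = 0L, N = n_admissible_pairs(roster),
                      T = n_admissible_pairs(roster), roster = roster),
                 class = "gold_standard")
  structure(list(expression = expr, roster = roster, gold = gold,
                 edges = edges_df, spec = spec),
            class = "synthetic_grn")
}

# Draw one expression matrix for a planted graph, with optional per-edge
# amplitude multipliers (used by the stage series).
sample_expression <- function(spec, planted, funs, n_genes,
                              amp_scale = NULL) {
  ns <- spec$n_samples
  expr <- matrix(0, ns, n_genes)
  parents <- split(seq_along(planted$reg), planted$tgt)
  # generation order: TFs by topological order, then TGs
  tf_order <- order(planted$topo)
  gen_order <- c(tf_order, setdiff(seq_len(n_genes), seq_along(planted$topo)))
  for (g in gen_order) {
    eidx <- parents[[as.character(g)]]
    if (is.null(eidx)) {
      expr[, g] <- stats::rnorm(ns)
    } else {
      val <- stats::rnorm(ns, sd = spec$noise_sd)
      for (e in eidx) {
        pvals <- expr[, planted$reg[e]]
        pstd <- (pvals - mean(pvals)) / pop_sd(pvals)
        scale_e <- if (is.null(amp_scale)) 1 else amp_scale[e]
        val <- val + scale_e * funs[[e]]$f(pstd)
      }
      expr[, g] <- val
    }
  }
  expr
}

pop_sd <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) 1 else s
}

#' @export
print.synthetic_grn <- function(x, ...) {
  cat("synthetic_grn:", x$spec$n_tfs, "TFs,", x$spec$n_tgs, "TGs,",
      nrow(x$edges), "planted edges,", x$spec$n_samples, "samples\n")
  invisible(x)
}

#' Simulate an ordered series of disease-stage expression matrices
#'
#' Re-draws the same planted network's expression once per stage. A
#' designated subset of edges drifts between a weak and a full-strength
#' regime: amplitudes are scaled geometrically across stages between
#' `weak = 1 / (1 + drift * (S - 1))` and 1 (increasing edges start weak
#' and end at full strength, decreasing edges mirror that). The geometric
#' spacing compensates for the saturating response of causal-asymmetry
#' scores to signal-to-noise, giving roughly even per-stage steps in the
#' detectable score. `drift = 0` plants nothing: stages are i.i.d.
#' re-draws.
#'
#' @param spec a [synthetic_spec()].
#' @param n_stages number of ordered stages (>= 2).
#' @param drift per-stage relative amplitude change (>= 0).
#' @param n_drift number of drifting edges (half increasing, half
#'   decreasing; ignored when `drift = 0`).
#' @return list of class `stage_series`: `stages` (list of expression
#'   matrices), `roster`, `gold`, `monotone` (data.frame regulator /
#'   target / direction of the planted drifting edges), `spec`.
#' @export
simulate_stage_series <- function(spec = synthetic_spec(), n_stages = 4L,
                                  drift = 0.5, n_drift = 4L) {
  if (n_stages < 2L) stop("need at least 2 stages")
  if (drift < 0) stop("drift must be non-negative")
  set.seed(spec$seed)
  tf_ids <- sprintf("TF%03d", seq_len(spec$n_tfs))
  tg_ids <- if (spec$n_tgs > 0L) sprintf("G%04d", seq_len(spec$n_tgs))
    else character()
  ids <- c(tf_ids, tg_ids)
  n_genes <- length(ids)
  planted <- plant_edges(spec$n_tfs, spec$n_tgs, spec$n_edges, tf_ids,
                         tg_ids, spec$tf_tf)
  funs <- lapply(seq_along(planted$reg), function(i)
    draw_edge_function(spec$function_family))

  n_edges <- length(planted$reg)
  monotone <- data.frame(regulator = character(), target = character(),
                         direction = character(), stringsAsFactors = FALSE)
  drift_dir <- numeric(n_edges)                  # 0 fixed, +1 up, -1 down
  if (drift > 0 && n_drift > 0L && n_edges > 0L) {
    # designate drifting edges on single-parent targets so each planted
    # monotone relation is identifiable by a pairwise screen (two drifting
    # edges into one target would confound each other)
    parent_counts <- table(planted$tgt)
    cand <- which(parent_counts[as.character(planted$tgt)] == 1L)
    if (!length(cand)) cand <- seq_len(n_edges)
    n_drift <- min(n_drift, length(cand))
    chosen <- cand[sample.int(length(cand), n_drift)]
    dirs <- rep(c(1, -1), length.out = n_drift)
    drift_dir[chosen] <- dirs
    monotone <- data.frame(
      regulator = ids[planted$reg[chosen]],
      target = ids[planted$tgt[chosen]],
      direction = ifelse(dirs > 0, "increasing", "decreasing"),
      stringsAsFactors = FALSE)
  }

  stages <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    weak <- 1 / (1 + drift * (n_stages - 1))
    frac <- (s - 1) / (n_stages - 1)
    amp <- ifelse(drift_dir > 0, weak^(1 - frac),
                  ifelse(drift_dir < 0, weak^frac, 1))
    m <- sample_expression(spec, planted, funs, n_genes, amp_scale = amp)
    dimnames(m) <- list(sprintf("S%04d", seq_len(spec$n_samples)), ids)
    stages[[s]] <- m
  }
  roster <- gene_roster(tf_ids, ids)
  edges_df <- data.frame(regulator = ids[planted$reg],
                         target = ids[planted$tgt],
                         stringsAsFactors = FALSE)
  gold <- if (nrow(edges_df)) gold_standard(edges_df, roster) else NULL
  structure(list(stages = stages, roster = roster, gold = gold,
                 monotone = monotone, spec = spec,
                 stage_labels = paste0("stage_", seq_len(n_stages))),
            class = "stage_series")
}

#' Write the three standard files plus a manifest for a synthetic network
#'
#' Emits `expression.tsv`, `tfs.txt`, `gold.tsv` and `manifest.json`
#' (spec parameters) into a directory.
#'
#' @param sim a `synthetic_grn`.
#' @param dir output directory (created if needed).
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  writeLines(sim$roster$tfs, file.path(dir, "tfs.txt"))
  write_gold_standard(sim$gold, file.path(dir, "gold.tsv"))
  sp <- sim$spec
  json <- sprintf(
    paste0('{"n_tfs": %d, "n_tgs": %d, "n_edges": %d, "n_samples": %d, ',
           '"function_family": "%s", "noise_sd": %g, "seed": %d}'),
    sp$n_tfs, sp$n_tgs, sp$n_edges, sp$n_samples, sp$function_family,
    sp$noise_sd, sp$seed)
  writeLines(json, file.path(dir, "manifest.json"))
  invisible(NULL)
}
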