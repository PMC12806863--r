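# End-to-end orchestration: z-score -> linear + nonlinear potential
# networks -> per-flavor gene embeddings -> per-flavor propensity matrices
# -> lambda ensemble -> ranked edge list. A single master seed fans out to
# fixed per-stage seeds so every stage is independently re-runnable.

#' Pipeline configuration
#'
#' @param linear_threshold cutoff on `|Pearson r|` for the linear potential
#'   network (`NULL` to match `target_edges`).
#' @param nonlinear_threshold cutoff on mutual information in nats for the
#'   nonlinear potential network (`NULL` to match `target_edges`).
#' @param target_edges undirected edge count the potential networks should
#'   approximate when a threshold is `NULL`; the framework performs best
#'   when this matches the expected gold-standard sparsity. Defaults to
#'   `5 * n_genes`.
#' @param mi_bins bins for the MI estimator (`NULL`: `ceiling(sqrt(m))`).
#' @param sage a [sage_config()]; its seed is overridden by per-flavor
#'   seeds derived from `seed`.
#' @param lambda ensemble weight of the linear pipeline (default 0.5).
#' @param normalization ensemble normalization (see
#'   [ensemble_propensity()]).
#' @param anm_input `"expression"` (default): pairwise causal scoring runs
#'   on the standardized expression profiles, the scale on which the
#'   additive-noise mechanism acts (the two flavors then share one
#'   propensity computation and differ only through the ensemble's inputs);
#'   `"embedding"`: scoring runs on the genes' learned embedding vectors,
#'   so each pipeline's propensity matrix reflects its own representation.
#' @param subsample_cap per-pair observation cap for GPR (default 500).
#' @param anm_bags disjoint-subsample bags for the propensity scores
#'   (default 1; see [propensity_matrix()]). Raise for stage-wise analyses
#'   where scores are compared across datasets.
#' @param pipeline `"full"`, `"linear-only"`, `"nonlinear-only"`, or
#'   `"anm-only"` (no potential network or embedding; genes are represented
#'   by raw standardized expression).
#' @param seed master seed.
#' @param verbose print stage progress.
#' @return list of class `grn_config`.
#' @export
grn_config <- function(linear_threshold = NULL, nonlinear_threshold = NULL,
                       target_edges = NULL, mi_bins = NULL,
                       sage = sage_config(), lambda = 0.5,
                       normalization = "rank",
                       anm_input = c("expression", "embedding"),
                       subsample_cap = 500L, anm_bags = 1L,
                       pipeline = c("full", "linear-only", "nonlinear-only",
                                    "anm-only"),
                       seed = 1L, verbose = FALSE) {
  structure(list(linear_threshold = linear_threshold,
                 nonlinear_threshold = nonlinear_threshold,
                 target_edges = target_edges, mi_bins = mi_bins,
                 sage = sage, lambda = lambda,
                 normalization = normalization,
                 anm_input = match.arg(anm_input),
                 subsample_cap = as.integer(subsample_cap),
                 anm_bags = as.integer(anm_bags),
                 pipeline = match.arg(pipeline),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "grn_config")
}

stage_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 97 + offset) %% .Machine$integer.max)
}

#' Infer a ranked regulatory network from expression data
#'
#' Runs the configured pipeline and returns the ranked edge list over all
#' admissible TF -> gene pairs together with every intermediate artifact.
#' Deterministic under the master seed.
#'
#' @param expression samples x genes numeric matrix (raw; z-scored
#'   internally) with gene column names.
#' @param tfs character vector of TF identifiers (must appear among the
#'   gene columns).
#' @param config a [grn_config()].
#' @return list of class `grn_result`: `ranking` (a `ranked_edges` data
#'   frame), `W` (final `propensity_matrix`), `W_linear`, `W_nonlinear`
#'   (when computed), `networks`, `embeddings`, `roster`, `config`.
#' @export
infer_grn <- function(expression, tfs, config = grn_config()) {
  validate_expression(expression)
  roster <- gene_roster(tfs, colnames(expression))
  say <- function(...) if (config$verbose) message(...)
  mz <- zscore_normalize(expression)
  mz <- mz[, roster$all, drop = FALSE]          # roster order everywhere
  n_genes <- ncol(mz)
  target_edges <- if (is.null(config$target_edges)) 5L * n_genes else
    config$target_edges

  networks <- list(); embeddings <- list()
  w_li <- w_nonli <- NULL

  shared_w <- NULL   # expression-profile W is flavor-independent
  run_flavor <- function(flavor, offset) {
    say("building ", flavor, " potential network")
    if (flavor == "linear") {
      r <- pearson_matrix(mz)
      thr <- config$linear_threshold
      if (is.null(thr)) thr <- threshold_for_edges(r, target_edges, flavor)
    } else {
      r <- mutual_information_matrix(mz, config$mi_bins)
      thr <- config$nonlinear_threshold
      if (is.null(thr)) thr <- threshold_for_edges(r, target_edges, flavor)
    }
    net <- threshold_network(r, thr, flavor)
    say("  ", net$n_edges, " edges at threshold ", signif(thr, 4))
    cfg <- config$sage
    cfg$seed <- stage_seed(config$seed, offset)
    emb <- train_embedding(net, mz, cfg)
    say("  embedding trained; link accuracy ", round(emb$accuracy, 3))
    if (config$anm_input == "embedding") {
      set.seed(stage_seed(config$seed, offset + 7L))
      w <- propensity_matrix(t(emb$values), roster,
                             subsample_cap = config$subsample_cap,
                             n_bags = config$anm_bags)
    } else if (!is.null(shared_w)) {
      w <- shared_w
    } else {
      set.seed(stage_seed(config$seed, 31L))
      w <- propensity_matrix(mz, roster,
                             subsample_cap = config$subsample_cap,
                             n_bags = config$anm_bags)
      shared_w <<- w
    }
    list(net = net, emb = emb, w = w)
  }

  ranking <- NULL
  if (config$pipeline == "anm-only") {
    say("ANM on standardized expression (no embedding)")
    set.seed(stage_seed(config$seed, 31L))
    w <- propensity_matrix(mz, roster, subsample_cap = config$subsample_cap,
                           n_bags = config$anm_bags)
    final_w <- w
  } else if (config$pipeline == "linear-only") {
    res <- run_flavor("linear", 11L)
    networks$linear <- res$net; embeddings$linear <- res$emb
    w_li <- res$w; final_w <- res$w
  } else if (config$pipeline == "nonlinear-only") {
    res <- run_flavor("nonlinear", 21L)
    networks$nonlinear <- res$net; embeddings$nonlinear <- res$emb
    w_nonli <- res$w; final_w <- res$w
  } else {
    res_l <- run_flavor("linear", 11L)
    res_n <- run_flavor("nonlinear", 21L)
    networks <- list(linear = res_l$net, nonlinear = res_n$net)
    embeddings <- list(linear = res_l$emb, nonlinear = res_n$emb)
    w_li <- res_l$w; w_nonli <- res_n$w
    final_w <- ensemble_propensity(w_li, w_nonli, lambda = config$lambda,
                                   normalization = config$normalization)
  }
  ranking <- rank_edges(final_w)
  structure(list(ranking = ranking, W = final_w,
                 W_linear = w_li, W_nonlinear = w_nonli,
                 networks = networks, embeddings = embeddings,
                 roster = roster, config = config),
            class = "grn_result")
}

#' @export
print.grn_result <- function(x, ...) {
  cat("grn_result (", x$config$pipeline, " pipeline): ",
      nrow(x$ranking), " ranked edges over ", length(x$roster$tfs),
      " TFs\n", sep = "")
  invisible(x)
}
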