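# Fixtures are built in code; nothing is read from disk.

# Small expression matrix with named genes.
toy_expression <- function(m = 20, genes = c("TF001", "TF002", "G0001",
                                             "G0002"), seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(m * length(genes)), m,
              dimnames = list(paste0("s", seq_len(m)), genes))
  x
}

toy_roster <- function() gene_roster(c("TF001", "TF002"),
                                     c("TF001", "TF002", "G0001", "G0002"))

# A gold standard over a roster of nf TFs / ng TGs with P random positives.
random_gold <- function(nf = 5, ng = 15, P = 20, seed = 1) {
  roster <- gene_roster(sprintf("TF%03d", 1:nf),
                        c(sprintf("TF%03d", 1:nf), sprintf("G%04d", 1:ng)))
  pairs <- grncausal:::admissible_pairs(roster)
  set.seed(seed)
  pick <- sample.int(nrow(pairs), P)
  gold <- gold_standard(data.frame(regulator = pairs$regulator[pick],
                                   target = pairs$target[pick]), roster)
  list(roster = roster, gold = gold, pairs = pairs)
}

# A ranked list assigning random scores to every admissible pair.
random_ranking <- function(roster, seed = 1) {
  pairs <- grncausal:::admissible_pairs(roster)
  set.seed(seed)
  ranked_edges(pairs$regulator, pairs$target, runif(nrow(pairs)))
}

# Two disconnected dense communities whose genes share a community latent
# factor; links are perfectly predictable from features.
two_community_net <- function(size = 15, m = 60, p_within = 0.6, seed = 1) {
  set.seed(seed)
  n <- 2 * size
  adj <- matrix(0L, n, n)
  for (block in 0:1) {
    idx <- block * size + seq_len(size)
    for (i in idx) for (j in idx) if (i < j && runif(1) < p_within)
      adj[i, j] <- adj[j, i] <- 1L
  }
  genes <- sprintf("g%03d", seq_len(n))
  dimnames(adj) <- list(genes, genes)
  f1 <- rnorm(m); f2 <- rnorm(m)
  expr <- sapply(seq_len(n), function(g) {
    base <- if (g <= size) f1 else f2
    base + rnorm(m, sd = 0.4)
  })
  colnames(expr) <- genes
  rownames(expr) <- paste0("s", seq_len(m))
  net <- structure(list(adjacency = adj, threshold = NA, flavor = "linear",
                        n_edges = sum(adj) / 2),
                   class = "potential_network")
  list(net = net, expr = expr, size = size)
}
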