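# Gene representation learning: sample positive links by uniform random
# walks over the potential network and negative links from its degree
# distribution, then train a two-layer mean-aggregating graph encoder
# (GraphSAGE-style) with a logistic link classifier. Implemented directly in
# base matrix algebra with Adam; every stochastic draw goes through R's RNG
# so a single seed fixes the whole run.

#' Configuration for the graph encoder
#'
#' @param hidden_dims integer pair: output dimensions of the two layers.
#' @param neighbor_samples integer pair: neighbors sampled per node at each
#'   layer (bootstrap resampling when a node has fewer neighbors).
#' @param walk_length steps per random walk for positive-link sampling.
#' @param walks_per_node walks started from each node.
#' @param epochs full-batch training epochs.
#' @param learning_rate Adam step size.
#' @param holdout fraction of sampled links held out to report
#'   link-classification accuracy.
#' @param seed integer seed fixing sampling, initialization and training.
#' @return list of class `sage_config`.
#' @export
sage_config <- function(hidden_dims = c(64L, 32L),
                        neighbor_samples = c(10L, 5L),
                        walk_length = 5L, walks_per_node = 10L,
                        epochs = 100L, learning_rate = 1e-3,
                        holdout = 0.2, seed = 1L) {
  stopifnot(length(hidden_dims) == 2L, all(hidden_dims >= 1L),
            length(neighbor_samples) == 2L, all(neighbor_samples >= 1L),
            walk_length >= 1L, walks_per_node >= 1L, epochs >= 0L,
            learning_rate > 0, holdout >= 0, holdout < 1)
  structure(list(hidden_dims = as.integer(hidden_dims),
                 neighbor_samples = as.integer(neighbor_samples),
                 walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 holdout = holdout,
                 seed = as.integer(seed)),
            class = "sage_config")
}

adjacency_list <- function(adj) {
  lapply(seq_len(nrow(adj)), function(i) which(adj[i, ] == 1L))
}

#' Sample positive links by uniform random walks
#'
#' Starts `walks_per_node` uniform random walks of `walk_length` steps from
#' every non-isolated node and returns the distinct undirected edges the
#' walks traverse. Uses the current RNG state; seed with `set.seed()` for
#' reproducibility.
#'
#' @param net a `potential_network`.
#' @param cfg a [sage_config()] (walk parameters).
#' @return integer matrix with two columns (node indices, smaller first),
#'   one row per distinct traversed edge.
#' @export
sample_positive_links <- function(net, cfg = sage_config()) {
  adj <- net$adjacency
  nbrs <- adjacency_list(adj)
  starts <- which(lengths(nbrs) > 0L)
  if (!length(starts))
    stop("potential network has only isolated nodes; cannot sample links")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- vector("list", length(starts) * cfg$walks_per_node)
  k <- 0L
  for (s in starts) {
    for (w in seq_len(cfg$walks_per_node)) {
      cur <- s
      path <- integer(cfg$walk_length * 2L)
      np <- 0L
      for (step in seq_len(cfg$walk_length)) {
        nb <- nbrs[[cur]]
        if (!length(nb)) break
        nxt <- nb[sample.int(length(nb), 1L)]
        path[np + 1L] <- min(cur, nxt); path[np + 2L] <- max(cur, nxt)
        np <- np + 2L
        cur <- nxt
      }
      if (np) { k <- k + 1L; out[[k]] <- path[seq_len(np)] }
    }
  }
  pairs <- matrix(unlist(out[seq_len(k)]), ncol = 2L, byrow = TRUE)
  keys <- paste(pairs[, 1L], pairs[, 2L])
  pairs[!duplicated(keys), , drop = FALSE]
}

#' Sample negative links from the degree distribution
#'
#' Draws endpoint pairs with probability proportional to node degree
#' (unigram distribution) and keeps those that are neither self-pairs nor
#' edges of the network; sampling is with replacement.
#'
#' @param net a `potential_network`.
#' @param count number of negative pairs to return.
#' @param cfg a [sage_config()] (unused fields reserved).
#' @return integer matrix with two columns (smaller index first).
#' @export
sample_negative_links <- function(net, count, cfg = sage_config()) {
  adj <- net$adjacency
  n <- nrow(adj)
  deg <- rowSums(adj)
  n_non_edges <- n * (n - 1) / 2 - net$n_edges
  if (n_non_edges <= 0)
    stop("potential network is complete; no negative links exist")
  if (count > n_non_edges)
    stop("requested ", count, " negative links but only ", n_non_edges,
         " distinct non-edges exist")
  prob <- deg / sum(deg)
  got <- matrix(0L, count, 2L)
  filled <- 0L
  guard <- 0L
  while (filled < count) {
    guard <- guard + 1L
    if (guard > 10000L) stop("negative-link rejection sampling stalled")
    need <- (count - filled) * 2L + 8L
    a <- sample.int(n, need, replace = TRUE, prob = prob)
    b <- sample.int(n, need, replace = TRUE, prob = prob)
    ok <- a != b & adj[cbind(a, b)] == 0L
    a <- a[ok]; b <- b[ok]
    take <- min(length(a), count - filled)
    if (take) {
      idx <- seq_len(take)
      got[filled + idx, 1L] <- pmin(a[idx], b[idx])
      got[filled + idx, 2L] <- pmax(a[idx], b[idx])
      filled <- filled + take
    }
  }
  got
}

#' One mean-aggregation layer
#'
#' Computes `act((h_g, mean of sampled neighbor features) %*% theta)` for
#' every node. With `sample_size = NULL` the full neighborhood is averaged
#' (the deterministic form used at inference); otherwise `sample_size`
#' neighbors are drawn per node, with bootstrap resampling when a node has
#' fewer. A node without neighbors aggregates over itself.
#'
#' @param h_prev n x d_in feature matrix (rows follow the network's genes).
#' @param net a `potential_network`.
#' @param theta (2 d_in) x d_out weight matrix.
#' @param activation vectorized activation function (default identity).
#' @param sample_size neighbors sampled per node, or `NULL` for all.
#' @return n x d_out feature matrix.
#' @export
sage_layer <- function(h_prev, net, theta, activation = identity,
                       sample_size = NULL) {
  stopifnot(nrow(h_prev) == nrow(net$adjacency),
            nrow(theta) == 2L * ncol(h_prev))
  agg <- neighbor_mean_matrix(net$adjacency, sample_size)
  activation(cbind(h_prev, agg %*% h_prev) %*% theta)
}

# Row-stochastic aggregation matrix over (sampled) neighborhoods.
neighbor_mean_matrix <- function(adj, sample_size = NULL) {
  n <- nrow(adj)
  if (is.null(sample_size)) {
    deg <- rowSums(adj)
    a <- adj / pmax(deg, 1)
    iso <- deg == 0
    if (any(iso)) a[cbind(which(iso), which(iso))] <- 1
    return(a)
  }
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1L)
    if (!length(nb)) { a[i, i] <- 1; next }
    picked <- if (length(nb) >= sample_size)
      nb[sample.int(length(nb), sample_size)]
    else nb[sample.int(length(nb), sample_size, replace = TRUE)]
    tab <- tabulate(picked, n)
    a[i, ] <- tab / sample_size
  }
  a
}

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))),
         n_in, n_out)
}

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$par <- state$par - lr * mhat / (sqrt(vhat) + eps)
  state
}

adam_init <- function(par) list(par = par, m = par * 0, v = par * 0, t = 0)

#' Train gene embeddings on a potential network
#'
#' Samples balanced positive/negative links, then trains the two-layer
#' mean-aggregating encoder plus a logistic link classifier (Hadamard
#' product of the endpoint embeddings followed by an affine map) by
#' full-batch Adam on the binary cross-entropy. Neighborhoods are resampled
#' every epoch. The returned embedding is the encoder's deterministic
#' forward pass with full-neighborhood aggregation.
#'
#' @param net a `potential_network`.
#' @param expr standardized samples x genes matrix; each gene's expression
#'   vector is its input feature.
#' @param cfg a [sage_config()].
#' @return object of class `embedding_matrix`: list with `values` (genes x
#'   d2 matrix, rows named by gene), `flavor`, `accuracy` (held-out
#'   link-classification accuracy; training-set accuracy when
#'   `holdout = 0`), `loss` (per-epoch training loss), `config`.
#' @export
train_embedding <- function(net, expr, cfg = sage_config()) {
  validate_expression(expr)
  adj <- net$adjacency
  n <- nrow(adj)
  if (ncol(expr) != n || !identical(colnames(expr), colnames(adj)))
    stop("expression genes and network genes must match in order")
  set.seed(cfg$seed)

  pos <- sample_positive_links(net, cfg)
  neg <- sample_negative_links(net, nrow(pos), cfg)
  pairs <- rbind(pos, neg)
  labels <- rep(c(1, 0), c(nrow(pos), nrow(neg)))

  n_links <- nrow(pairs)
  n_hold <- floor(cfg$holdout * n_links)
  hold_idx <- if (n_hold > 0) sample.int(n_links, n_hold) else integer()
  train_idx <- setdiff(seq_len(n_links), hold_idx)
  if (!length(train_idx)) stop("no training links left after holdout split")

  h0 <- t(expr)                      # genes x samples features
  d0 <- ncol(h0); d1 <- cfg$hidden_dims[1L]; d2 <- cfg$hidden_dims[2L]
  W1 <- adam_init(glorot(2L * d0, d1))
  W2 <- adam_init(glorot(2L * d1, d2))
  wc <- adam_init(matrix(stats::rnorm(d2, sd = 0.1), d2, 1L))
  bc <- adam_init(0)

  u <- pairs[train_idx, 1L]; v <- pairs[train_idx, 2L]
  y <- labels[train_idx]
  loss_hist <- numeric(cfg$epochs)

  forward <- function(a1, a2) {
    c1 <- cbind(h0, a1 %*% h0)
    z1 <- c1 %*% W1$par
    hh1 <- relu(z1)
    c2 <- cbind(hh1, a2 %*% hh1)
    h2 <- c2 %*% W2$par
    list(c1 = c1, z1 = z1, h1 = hh1, c2 = c2, h2 = h2, a2 = a2)
  }

  for (ep in seq_len(cfg$epochs)) {
    a1 <- neighbor_mean_matrix(adj, cfg$neighbor_samples[1L])
    a2 <- neighbor_mean_matrix(adj, cfg$neighbor_samples[2L])
    fw <- forward(a1, a2)
    e <- fw$h2[u, , drop = FALSE] * fw$h2[v, , drop = FALSE]
    logit <- drop(e %*% wc$par) + bc$par
    p <- sigmoid(logit)
    eps <- 1e-12
    loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
    if (!is.finite(loss))
      stop("non-finite training loss at epoch ", ep,
           " (lr = ", cfg$learning_rate, "); inspect input scaling")
    loss_hist[ep] <- loss

    dlogit <- (p - y) / length(y)
    g_wc <- crossprod(e, dlogit)
    g_bc <- sum(dlogit)
    de <- dlogit %*% t(wc$par)                     # L x d2
    dh2 <- matrix(0, n, d2)
    du <- de * fw$h2[v, , drop = FALSE]
    dv <- de * fw$h2[u, , drop = FALSE]
    for (col in seq_len(d2)) {
      dh2[, col] <- dh2[, col] +
        unname(rowsum_vec(du[, col], u, n)) + rowsum_vec(dv[, col], v, n)
    }
    g_W2 <- crossprod(fw$c2, dh2)
    dc2 <- dh2 %*% t(W2$par)
    dh1 <- dc2[, seq_len(d1), drop = FALSE] +
      crossprod(fw$a2, dc2[, d1 + seq_len(d1), drop = FALSE])
    dz1 <- dh1 * (fw$z1 > 0)
    g_W1 <- crossprod(fw$c1, dz1)

    lr <- cfg$learning_rate
    W1 <- adam_step(W1, g_W1, lr)
    W2 <- adam_step(W2, g_W2, lr)
    wc <- adam_step(wc, g_wc, lr)
    bc <- adam_step(bc, g_bc, lr)
  }

  a_full <- neighbor_mean_matrix(adj, NULL)
  fw <- forward(a_full, a_full)
  emb <- fw$h2
  rownames(emb) <- colnames(adj)

  acc_idx <- if (length(hold_idx)) hold_idx else train_idx
  eh <- emb[pairs[acc_idx, 1L], , drop = FALSE] *
    emb[pairs[acc_idx, 2L], , drop = FALSE]
  ph <- sigmoid(drop(eh %*% wc$par) + bc$par)
  acc <- mean((ph > 0.5) == (labels[acc_idx] == 1))

  structure(list(values = emb, flavor = net$flavor, accuracy = acc,
                 loss = loss_hist, config = cfg),
            class = "embedding_matrix")
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat("embedding_matrix (", x$flavor, "): ", nrow(x$values), " genes x ",
      ncol(x$values), " dims; link accuracy ", round(x$accuracy, 3), "\n",
      sep = "")
  invisible(x)
}

#' Export an embedding as TSV
#'
#' @param emb an `embedding_matrix`.
#' @param path output path; rows are `gene<TAB>dim1<TAB>...`.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(gene = rownames(emb$values), emb$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
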