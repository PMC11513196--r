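# Build a network_model directly from a precision matrix, bypassing
# estimation, so measure computations can be tested on known structures.
model_from_theta <- function(theta, labels = NULL) {
  p <- nrow(theta)
  if (is.null(labels)) labels <- colnames(theta)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  dimnames(theta) <- list(labels, labels)
  pc <- precision_to_pcor(theta)
  supp <- (abs(pc) > 1e-10) * 1L
  diag(supp) <- 0L
  structure(list(labels = labels, theta = theta, partial_corr = pc,
                 support = supp, config = estimation_config(B = 1),
                 provenance = list()),
            class = "network_model")
}

# Build a network_model from prescribed signed edge weights (for centrality
# and spanning-tree tests where only the graph matters). The precision is a
# placeholder consistent with the weights' support.
model_from_weights <- function(W, labels = NULL) {
  p <- nrow(W)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  W <- (W + t(W)) / 2
  diag(W) <- 1
  dimnames(W) <- list(labels, labels)
  supp <- (abs(W) > 1e-12) * 1L
  diag(supp) <- 0L
  theta <- diag(p)
  dimnames(theta) <- dimnames(W)
  structure(list(labels = labels, theta = theta, partial_corr = W,
                 support = supp, config = estimation_config(B = 1),
                 provenance = list()),
            class = "network_model")
}

# Random connected symmetric weight matrix on p nodes (strictly positive
# distinct weights so spanning trees are unique).
random_connected_weights <- function(p, seed) {
  withr::with_seed(seed, {
    repeat {
      W <- matrix(0, p, p)
      n_pairs <- p * (p - 1) / 2
      keep <- runif(n_pairs) < 0.6
      w <- runif(n_pairs, 0.05, 0.95) * keep
      W[upper.tri(W)] <- w
      W <- W + t(W)
      g <- igraph::graph_from_adjacency_matrix((W != 0) * 1,
                                               mode = "undirected")
      if (igraph::is_connected(g)) break
    }
    W
  })
}

# Exhaustive maximum-spanning-tree total weight: enumerate all spanning
# trees by choosing p-1 edges and checking connectivity/acyclicity.
brute_force_mst_weight <- function(W) {
  p <- nrow(W)
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  best <- -Inf
  for (sel in utils::combn(nrow(idx), p - 1, simplify = FALSE)) {
    e <- idx[sel, , drop = FALSE]
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (igraph::vcount(g) < p) next
    if (!igraph::is_connected(g) || igraph::ecount(g) != p - 1) next
    best <- max(best, sum(W[e]))
  }
  best
}

# Pairwise current-flow oracle: effective resistance by solving one linear
# system per node pair (grounding the target node).
brute_force_cfc <- function(C) {
  p <- nrow(C)
  L <- diag(rowSums(C)) - C
  vals <- numeric(p)
  for (v in seq_len(p)) {
    rsum <- 0
    for (t in seq_len(p)[-v]) {
      keep <- setdiff(seq_len(p), t)
      b <- numeric(p - 1)
      b[match(v, keep)] <- 1
      phi <- solve(L[keep, keep], b)
      rsum <- rsum + phi[match(v, keep)]
    }
    vals[v] <- (p - 1) / rsum
  }
  vals
}

# Brute-force weighted betweenness on distances 1/|w|: enumerate all simple
# paths per pair, find the shortest, and accredit interior nodes of all
# ties equally.
brute_force_betweenness <- function(W) {
  p <- nrow(W)
  D <- ifelse(W != 0, 1 / abs(W), Inf)
  all_paths <- function(s, t, visited) {
    if (s == t) return(list(t))
    out <- list()
    for (nxt in seq_len(p)[-visited]) {
      if (!is.finite(D[s, nxt])) next
      for (tail in all_paths(nxt, t, c(visited, nxt)))
        out[[length(out) + 1L]] <- c(s, tail)
    }
    out
  }
  bt <- numeric(p)
  for (s in seq_len(p - 1)) for (t in seq((s + 1), p)) {
    paths <- all_paths(s, t, s)
    if (!length(paths)) next
    lens <- vapply(paths, function(pa)
      sum(D[cbind(pa[-length(pa)], pa[-1])]), numeric(1))
    sp <- paths[abs(lens - min(lens)) < 1e-12]
    for (pa in sp) {
      interior <- pa[-c(1, length(pa))]
      bt[interior] <- bt[interior] + 1 / length(sp)
    }
  }
  bt / ((p - 1) * (p - 2) / 2)
}
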