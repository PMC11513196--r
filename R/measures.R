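#' Node predictability (variance explained by neighbors)
#'
#' On standardized (unit-variance) data the residual variance of node i
#' given all others is `1 / theta[i,i]`, so `R2_i = 1 - 1/theta[i,i]`,
#' identical to the R-squared of the node-wise regression with coefficients
#' `beta_ij = -theta[i,j] / theta[i,i]`. Reported as a percentage.
#'
#' @param model a `network_model` estimated on standardized data.
#' @return Named numeric vector of percentages; 0 for isolated nodes.
#' @export
predictability <- function(model) {
  r2 <- 1 - 1 / diag(model$theta)
  stats::setNames(100 * pmax(r2, 0), model$labels)
}

#' Hold-out predictability on an independent sample
#'
#' Applies the training model's implied node-wise regression coefficients to
#' a test table (standardized with the training transform) and reports
#' `R2 = 1 - SSE/SST` per node, as a percentage. Values can be negative
#' when the model predicts worse than the test mean.
#'
#' @param model a `network_model`.
#' @param test a [data_table()] or matrix with the model's columns.
#' @return Named numeric vector of percentages.
#' @export
holdout_predictability <- function(model, test) {
  x <- if (is.matrix(test)) test else as_matrix(test)
  if (!all(model$labels %in% colnames(x)))
    stop("test table lacks model columns")
  x <- x[, model$labels, drop = FALSE]
  p <- length(model$labels)
  out <- numeric(p)
  for (i in seq_len(p)) {
    beta <- -model$theta[i, ] / model$theta[i, i]
    beta[i] <- 0
    pred <- as.vector(x %*% beta)
    y <- x[, i]
    sse <- sum((y - pred)^2)
    sst <- sum((y - mean(y))^2)
    out[i] <- 100 * (1 - sse / sst)
  }
  stats::setNames(out, model$labels)
}

#' Degree centrality
#'
#' Fraction of the other nodes each node is connected to:
#' `degree_i / (p - 1)`.
#'
#' @param model a `network_model`.
#' @return Named numeric vector in [0, 1].
#' @export
degree_centrality <- function(model) {
  stats::setNames(rowSums(model$support) / (length(model$labels) - 1),
                  model$labels)
}

# Laplacian pseudoinverse of a conductance matrix (single component)
laplacian_pinv <- function(C) {
  L <- diag(rowSums(C)) - C
  n <- nrow(L)
  J <- matrix(1 / n, n, n)
  solve(L + J) - J
}

#' Current-flow closeness (information) centrality
#'
#' Treats absolute partial correlations as conductances and measures how
#' close a node is to all others in terms of effective electrical
#' resistance: `(p_c - 1) / sum_t R_eff(v, t)` within each connected
#' component (`p_c` the component size), with
#' `R_eff(v,t) = L+[v,v] + L+[t,t] - 2 L+[v,t]` from the Laplacian
#' pseudoinverse. Unlike shortest-path closeness, all paths contribute.
#'
#' @param model a `network_model`.
#' @return Named numeric vector; isolated nodes get 0.
#' @export
current_flow_closeness <- function(model) {
  C <- abs(model$partial_corr) * model$support
  p <- nrow(C)
  out <- numeric(p)
  comp <- graph_components(C)
  for (nodes in comp) {
    if (length(nodes) == 1L) next
    Lp <- laplacian_pinv(C[nodes, nodes, drop = FALSE])
    d <- diag(Lp)
    reff <- outer(d, d, "+") - 2 * Lp
    out[nodes] <- (length(nodes) - 1) / rowSums(reff)
  }
  stats::setNames(out, model$labels)
}

# connected components of an adjacency matrix, as lists of node indices
graph_components <- function(A) {
  g <- igraph::graph_from_adjacency_matrix((A != 0) * 1, mode = "undirected",
                                           diag = FALSE)
  m <- igraph::components(g)$membership
  split(seq_len(nrow(A)), m)
}

#' Current-flow betweenness centrality
#'
#' For each source/target pair a unit current is injected and extracted;
#' node throughput is half the absolute current through its incident edges.
#' A node's centrality is its mean throughput over all pairs it is not an
#' endpoint of, computed per connected component with absolute partial
#' correlations as conductances.
#'
#' @param model a `network_model`.
#' @return Named numeric vector; isolated and degree-limited nodes get 0.
#' @export
current_flow_betweenness <- function(model) {
  C <- abs(model$partial_corr) * model$support
  p <- nrow(C)
  out <- numeric(p)
  for (nodes in graph_components(C)) {
    nc <- length(nodes)
    if (nc < 3L) next
    Cc <- C[nodes, nodes, drop = FALSE]
    Lp <- laplacian_pinv(Cc)
    acc <- numeric(nc)
    for (s in seq_len(nc - 1)) for (t in seq((s + 1), nc)) {
      v <- Lp[, s] - Lp[, t]
      thr <- 0.5 * rowSums(Cc * abs(outer(v, v, "-")))
      thr[c(s, t)] <- 0
      acc <- acc + thr
    }
    out[nodes] <- acc / ((nc - 1) * (nc - 2) / 2)
  }
  stats::setNames(out, model$labels)
}

#' Shortest-path closeness and betweenness
#'
#' Edge distances are `1 / |partial correlation|` on support edges, the
#' standard convention for association networks. Closeness is normalized
#' within connected components; betweenness is normalized by
#' `(p - 1)(p - 2) / 2`.
#'
#' @param model a `network_model`.
#' @return Data frame: node, closeness, betweenness.
#' @export
classical_centralities <- function(model) {
  g <- model_graph(model)
  p <- length(model$labels)
  if (igraph::ecount(g) == 0) {
    return(data.frame(node = model$labels, closeness = 0, betweenness = 0))
  }
  d <- 1 / igraph::E(g)$weight
  cl <- suppressWarnings(
    igraph::closeness(g, weights = d, normalized = TRUE))
  cl[is.nan(cl) | is.na(cl)] <- 0
  bt <- igraph::betweenness(g, weights = d) / ((p - 1) * (p - 2) / 2)
  data.frame(node = model$labels, closeness = as.numeric(cl),
             betweenness = as.numeric(bt))
}

#' All node-level measures in tidy form
#'
#' @param model a `network_model`.
#' @param test optional hold-out [data_table()] for out-of-sample
#'   predictability.
#' @return Tidy data frame: node, measure, context, value.
#' @export
network_measures <- function(model, test = NULL) {
  cc <- classical_centralities(model)
  rows <- list(
    data.frame(node = model$labels, measure = "predictability",
               context = "training", value = unname(predictability(model))),
    data.frame(node = model$labels, measure = "degree_centrality",
               context = "training", value = unname(degree_centrality(model))),
    data.frame(node = model$labels, measure = "current_flow_closeness",
               context = "training",
               value = unname(current_flow_closeness(model))),
    data.frame(node = model$labels, measure = "current_flow_betweenness",
               context = "training",
               value = unname(current_flow_betweenness(model))),
    data.frame(node = cc$node, measure = "closeness", context = "training",
               value = cc$closeness),
    data.frame(node = cc$node, measure = "betweenness", context = "training",
               value = cc$betweenness))
  if (!is.null(test))
    rows <- c(rows, list(
      data.frame(node = model$labels, measure = "predictability",
                 context = "holdout",
                 value = unname(holdout_predictability(model, test)))))
  do.call(rbind, rows)
}

#' Maximal spanning tree by Prim's algorithm
#'
#' Grows the tree per connected component, always adding the
#' largest-|weight| edge crossing the cut; ties are broken by lexicographic
#' node-pair order so the result is deterministic. Edge weights are
#' absolute partial correlations; the signed weights are attached to the
#' returned edges. A forest is returned when the graph is disconnected.
#'
#' @param model a `network_model`.
#' @return A list of class `spanning_tree`: `edges` (node_i, node_j,
#'   weight signed, abs_weight), `total_weight` (sum of absolute weights).
#' @export
maximal_spanning_tree <- function(model) {
  W <- abs(model$partial_corr) * model$support
  p <- nrow(W)
  edges <- list()
  for (nodes in graph_components(W)) {
    if (length(nodes) == 1L) next
    in_tree <- nodes[1]
    rest <- setdiff(nodes, in_tree)
    while (length(rest)) {
      best <- NULL
      for (i in sort(in_tree)) for (j in sort(rest)) {
        if (W[i, j] == 0) next
        if (is.null(best) || W[i, j] > best$w + 1e-15 ||
            (abs(W[i, j] - best$w) <= 1e-15 &&
             (min(i, j) < best$a || (min(i, j) == best$a &&
                                     max(i, j) < best$b)))) {
          best <- list(w = W[i, j], a = min(i, j), b = max(i, j))
        }
      }
      edges[[length(edges) + 1L]] <- best
      new <- setdiff(c(best$a, best$b), in_tree)
      in_tree <- c(in_tree, new)
      rest <- setdiff(rest, new)
    }
  }
  if (length(edges)) {
    df <- data.frame(
      node_i = model$labels[vapply(edges, `[[`, numeric(1), "a")],
      node_j = model$labels[vapply(edges, `[[`, numeric(1), "b")],
      abs_weight = vapply(edges, `[[`, numeric(1), "w"))
    ij <- cbind(match(df$node_i, model$labels),
                match(df$node_j, model$labels))
    df$weight <- model$partial_corr[ij]
  } else {
    df <- data.frame(node_i = character(), node_j = character(),
                     abs_weight = numeric(), weight = numeric())
  }
  structure(list(edges = df[, c("node_i", "node_j", "weight", "abs_weight")],
                 total_weight = sum(df$abs_weight)),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree> %d edges, total |weight| %.4f\n",
              nrow(x$edges), x$total_weight))
  invisible(x)
}
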