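#' Estimation settings for the adaptive network procedure
#'
#' @param B ensemble size for stability selection (default 1000).
#' @param tau edge-inclusion threshold on the proportion matrix (default
#'   0.65; strict exceedance).
#' @param scheme a [penalty_scheme()].
#' @param tol,max_iter passed to [graphical_lasso()].
#' @param nonzero_tol magnitude above which a precision entry counts as a
#'   selected edge inside the ensemble.
#' @param seed integer seed for the ensemble.
#' @return A list of class `estimation_config`.
#' @export
estimation_config <- function(B = 1000, tau = 0.65,
                              scheme = penalty_scheme(), tol = 1e-6,
                              max_iter = 500, nonzero_tol = 1e-8,
                              seed = 1L) {
  stopifnot(B >= 1, tau > 0, tau < 1)
  structure(list(B = as.integer(B), tau = tau, scheme = scheme, tol = tol,
                 max_iter = max_iter, nonzero_tol = nonzero_tol,
                 seed = as.integer(seed)),
            class = "estimation_config")
}

#' Stability-selection ensemble of randomly penalized graphical lassos
#'
#' Runs `B` iterations; each draws a bootstrap resample of the rows (same
#' size, with replacement), computes its ML covariance, draws a random
#' penalty from the scheme, fits the graphical lasso, and records which
#' off-diagonal precision entries are nonzero. The per-edge nonzero
#' frequency over the ensemble is the proportion matrix. Failing members
#' are dropped (and counted); more than 10% failures is an error.
#'
#' @param table standardized [data_table()] or numeric matrix.
#' @param config an [estimation_config()].
#' @return A list of class `proportion_matrix`: `proportions` (symmetric,
#'   diagonal 1), `B`, `n_failed`, `labels`.
#' @export
stability_ensemble <- function(table, config = estimation_config()) {
  x <- if (is.matrix(table)) table else as_matrix(table)
  n <- nrow(x); p <- ncol(x)
  labels <- colnames(x)
  counts <- matrix(0, p, p)
  seeds <- derive_seeds(config$seed, config$B)
  n_failed <- 0L
  for (b in seq_len(config$B)) {
    res <- with_seed(seeds[b], {
      rows <- sample.int(n, n, replace = TRUE)
      S <- empirical_covariance(x[rows, , drop = FALSE])
      P <- draw_penalty(S, config$scheme, n = n)
      tryCatch(graphical_lasso(S, P, config$tol, config$max_iter),
               error = function(e) NULL)
    })
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    counts <- counts + (abs(res$theta) > config$nonzero_tol)
  }
  if (n_failed > 0.1 * config$B)
    stop(sprintf("%d of %d ensemble members failed", n_failed, config$B))
  prop <- counts / (config$B - n_failed)
  diag(prop) <- 1
  prop <- (prop + t(prop)) / 2
  dimnames(prop) <- list(labels, labels)
  structure(list(proportions = prop, B = config$B, n_failed = n_failed,
                 labels = labels),
            class = "proportion_matrix")
}

#' Threshold a proportion matrix into a binary support
#'
#' An edge enters the support only if its selection proportion strictly
#' exceeds `tau` (a proportion exactly at the threshold is zeroed).
#'
#' @param proportions a [stability_ensemble()] result or a plain symmetric
#'   matrix of proportions.
#' @param tau threshold in (0, 1); default 0.65.
#' @return Binary symmetric matrix with zero diagonal.
#' @export
threshold_support <- function(proportions, tau = 0.65) {
  stopifnot(tau > 0, tau < 1)
  m <- if (inherits(proportions, "proportion_matrix"))
    proportions$proportions else proportions
  supp <- (m > tau) * 1L
  diag(supp) <- 0L
  supp
}

#' Support-constrained maximum-likelihood refit
#'
#' Refits the precision matrix with the graphical lasso using per-entry
#' penalty 0 on supported edges and a prohibitively large penalty
#' (`1e6 * lambda_max`) elsewhere, which realizes the support-constrained
#' Gaussian MLE to within the nonzero tolerance. Off-support partial
#' correlations are then zeroed exactly.
#'
#' @param table standardized [data_table()] or numeric matrix.
#' @param support binary symmetric matrix (zero diagonal).
#' @param config an [estimation_config()] (tolerances only; no randomness).
#' @param proportions optional [stability_ensemble()] result stored for
#'   provenance.
#' @return A `network_model`: `labels`, `theta`, `partial_corr`, `support`,
#'   `config`, `provenance`.
#' @export
refit_support <- function(table, support, config = estimation_config(),
                          proportions = NULL) {
  x <- if (is.matrix(table)) table else as_matrix(table)
  S <- empirical_covariance(x)
  p <- ncol(S)
  stopifnot(dim(support) == dim(S))
  support <- (support != 0) * 1L
  diag(support) <- 0L
  if (max(abs(support - t(support))) != 0) stop("support must be symmetric")
  off <- abs(S); diag(off) <- 0
  lambda_max <- max(off)
  if (all(support == 0)) {
    warning("empty support: returning a diagonal (independence) model")
    theta <- diag(1 / diag(S))
  } else {
    P <- matrix(1e6 * lambda_max, p, p)
    P[support == 1L] <- 0
    diag(P) <- 0
    fit <- graphical_lasso(S, P, config$tol, config$max_iter)
    theta <- fit$theta
    theta[support == 0L & abs(theta) <= config$nonzero_tol &
            row(theta) != col(theta)] <- 0
  }
  dimnames(theta) <- dimnames(S)
  pc <- precision_to_pcor(theta)
  structure(list(labels = colnames(x), theta = theta, partial_corr = pc,
                 support = support, config = config,
                 provenance = list(input_hash = rlang::hash(x),
                                   n = nrow(x), p = p,
                                   timestamp = format(Sys.time(), tz = "UTC"),
                                   proportions = proportions)),
            class = "network_model")
}

#' Adaptive random-penalty network estimation
#'
#' The three-stage procedure: (1) a stability-selection ensemble of
#' bootstrap-resampled, randomly penalized graphical lassos yields the
#' proportion matrix; (2) strict thresholding at `tau` gives the support;
#' (3) a support-constrained ML refit gives the final precision and
#' partial-correlation network.
#'
#' @param table standardized [data_table()] or numeric matrix.
#' @param config an [estimation_config()].
#' @return List with `model` (a `network_model`) and `proportions` (a
#'   `proportion_matrix`).
#' @export
estimate_network <- function(table, config = estimation_config()) {
  prop <- stability_ensemble(table, config)
  supp <- threshold_support(prop, config$tau)
  model <- refit_support(table, supp, config, proportions = prop)
  list(model = model, proportions = prop)
}

#' @export
print.network_model <- function(x, ...) {
  ut <- upper.tri(x$support)
  cat(sprintf("<network_model> %d nodes, %d edges (B=%d, tau=%.2f)\n",
              length(x$labels), sum(x$support[ut]), x$config$B,
              x$config$tau))
  invisible(x)
}

#' Edge list of a network model
#'
#' @param model a `network_model`.
#' @param all include absent edges (support 0) as well.
#' @return Data frame: node_i, node_j, weight (partial correlation),
#'   support.
#' @export
edge_list <- function(model, all = FALSE) {
  ut <- which(upper.tri(model$support), arr.ind = TRUE)
  df <- data.frame(node_i = model$labels[ut[, 1]],
                   node_j = model$labels[ut[, 2]],
                   weight = model$partial_corr[ut],
                   support = model$support[ut])
  if (!all) df <- df[df$support == 1L, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a network model to disk
#'
#' Emits the precision and partial-correlation matrices (CSV), the edge
#' list (TSV), the graph (GraphML, via igraph) and config/provenance
#' (JSON) under `dir`, using `name` as the file stem.
#'
#' @param model a `network_model`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return `dir`, invisibly.
#' @export
write_network_model <- function(model, dir, name = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(model$theta, file.path(dir, paste0(name, "_precision.csv")))
  write.csv(model$partial_corr,
            file.path(dir, paste0(name, "_partial_corr.csv")))
  utils::write.table(edge_list(model, all = TRUE),
                     file.path(dir, paste0(name, "_edges.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  g <- model_graph(model)
  igraph::write_graph(g, file.path(dir, paste0(name, ".graphml")),
                      format = "graphml")
  prov <- model$provenance
  prov$proportions <- NULL
  jsonlite::write_json(
    list(config = list(B = model$config$B, tau = model$config$tau,
                       scheme = unclass(model$config$scheme),
                       seed = model$config$seed),
         provenance = prov),
    file.path(dir, paste0(name, "_config.json")), auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}

# weighted igraph graph on the support, |partial correlation| weights,
# signed weights kept as an edge attribute
model_graph <- function(model, absolute = TRUE) {
  w <- model$partial_corr * model$support
  adj <- if (absolute) abs(w) else w
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ends <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$signed_weight <- w[cbind(ends[, 1], ends[, 2])]
  g
}
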