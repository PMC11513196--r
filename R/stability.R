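measure_registry <- function() {
  list(predictability = predictability,
       degree_centrality = degree_centrality,
       current_flow_closeness = current_flow_closeness,
       current_flow_betweenness = current_flow_betweenness,
       closeness = function(m) stats::setNames(
         classical_centralities(m)$closeness, m$labels),
       betweenness = function(m) stats::setNames(
         classical_centralities(m)$betweenness, m$labels))
}

#' Bootstrap the full network estimation for edge and measure stability
#'
#' Draws `B` bootstrap resamples of the rows and re-runs the whole adaptive
#' procedure on each, with a reduced inner stability-selection ensemble
#' (`inner_B`) for tractability. Per resample it records every edge's
#' partial correlation and presence, plus the node-level measures, so the
#' same object feeds confidence intervals, sensitivity/specificity and
#' difference tests. Two bootstraps built from the same `seed` on
#' equally sized tables share resample indices and are therefore paired.
#'
#' @param table standardized [data_table()] or matrix.
#' @param config an [estimation_config()] (used for the reference model and,
#'   with `B = inner_B`, inside each resample).
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed driving the resample indices.
#' @param inner_B ensemble size inside each resample (default 100).
#' @param reference optional precomputed reference `network_model`.
#' @return A list of class `edge_bootstrap`: `weights` and `presence`
#'   (B x n-pairs matrices), `measures` (list of B x p matrices),
#'   `pairs`, `labels`, `reference`, `seed`, `n`, `B`.
#' @export
edge_bootstrap <- function(table, config = estimation_config(), B = 1000,
                           seed = 1L, inner_B = 100, reference = NULL) {
  if (B < 100) warning("fewer than 100 bootstrap samples: CIs are unstable")
  x <- if (is.matrix(table)) table else as_matrix(table)
  n <- nrow(x); p <- ncol(x)
  if (is.null(reference)) reference <- estimate_network(x, config)$model
  stopifnot(identical(reference$labels, colnames(x)))
  ut <- which(upper.tri(diag(p)), arr.ind = TRUE)
  pairs <- data.frame(node_i = colnames(x)[ut[, 1]],
                      node_j = colnames(x)[ut[, 2]])
  seeds <- derive_seeds(seed, B)
  weights <- matrix(NA_real_, B, nrow(ut))
  presence <- matrix(NA, B, nrow(ut))
  meas_names <- c("predictability", "degree_centrality",
                  "current_flow_closeness")
  measures <- lapply(meas_names, function(m)
    matrix(NA_real_, B, p, dimnames = list(NULL, colnames(x))))
  names(measures) <- meas_names
  reg <- measure_registry()
  for (b in seq_len(B)) {
    rows <- with_seed(seeds[b], sample.int(n, n, replace = TRUE))
    cfg <- config
    cfg$B <- as.integer(inner_B)
    cfg$seed <- seeds[b]
    fit <- estimate_network(x[rows, , drop = FALSE], cfg)$model
    weights[b, ] <- fit$partial_corr[upper.tri(fit$partial_corr)]
    presence[b, ] <- fit$support[upper.tri(fit$support)] == 1L
    for (m in meas_names) measures[[m]][b, ] <- reg[[m]](fit)
  }
  structure(list(weights = weights, presence = presence,
                 measures = measures, pairs = pairs,
                 labels = colnames(x), reference = reference,
                 seed = as.integer(seed), n = n, B = as.integer(B)),
            class = "edge_bootstrap")
}

#' Edge-stability summary: CIs, sensitivity, specificity
#'
#' Percentile 95% confidence intervals for every edge weight over the
#' bootstrap, plus — per edge — sensitivity (fraction of resamples in which
#' a reference-present edge is recovered) or specificity (fraction in which
#' a reference-absent edge stays absent). Exactly one of the two is defined
#' per edge, depending on its status in the reference network.
#'
#' @param boot an [edge_bootstrap()] result.
#' @return Data frame: node_i, node_j, reference_weight, mean, ci_low,
#'   ci_high, in_reference, sensitivity, specificity.
#' @export
edge_stability <- function(boot) {
  stopifnot(inherits(boot, "edge_bootstrap"))
  ref <- boot$reference
  ref_w <- ref$partial_corr[upper.tri(ref$partial_corr)]
  ref_s <- ref$support[upper.tri(ref$support)] == 1L
  ci <- apply(boot$weights, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  pres <- colMeans(boot$presence)
  mw <- colMeans(boot$weights)
  # a point-mass-at-zero edge with rare nonzero excursions can put the mean
  # just outside the percentile bounds; widen so the interval contains it
  data.frame(boot$pairs, reference_weight = ref_w,
             mean = mw, ci_low = pmin(ci[1, ], mw),
             ci_high = pmax(ci[2, ], mw), in_reference = ref_s,
             sensitivity = ifelse(ref_s, pres, NA_real_),
             specificity = ifelse(ref_s, NA_real_, 1 - pres))
}

check_paired <- function(a, b) {
  stopifnot(inherits(a, "edge_bootstrap"), inherits(b, "edge_bootstrap"))
  if (a$B != b$B || a$seed != b$seed || a$n != b$n)
    stop("bootstraps are not paired: they must share seed, B and sample size")
}

boot_p_value <- function(diff) {
  B <- length(diff)
  p <- 2 * min(mean(diff <= 0), mean(diff >= 0))
  max(min(p, 1), 1 / B)
}

#' Paired bootstrap difference test for one edge
#'
#' Two-sided p-value `2 * min(P(diff <= 0), P(diff >= 0))` over the paired
#' per-resample difference of an edge's weight in two models, floored at
#' `1/B`. The bootstraps must be paired (same seed, size and resample
#' count).
#'
#' @param boot_a,boot_b paired [edge_bootstrap()] results.
#' @param node_i,node_j edge endpoints (labels present in both).
#' @return List: `p_value`, `mean_difference`, `B`.
#' @export
edge_difference_test <- function(boot_a, boot_b, node_i, node_j) {
  check_paired(boot_a, boot_b)
  find_edge <- function(boot) {
    k <- which((boot$pairs$node_i == node_i & boot$pairs$node_j == node_j) |
                 (boot$pairs$node_i == node_j & boot$pairs$node_j == node_i))
    if (length(k) != 1L) stop("edge not found: ", node_i, "--", node_j)
    k
  }
  d <- boot_a$weights[, find_edge(boot_a)] -
    boot_b$weights[, find_edge(boot_b)]
  list(p_value = boot_p_value(d), mean_difference = mean(d), B = boot_a$B)
}

#' Paired bootstrap difference test for a node's centrality
#'
#' @param boot_a,boot_b paired [edge_bootstrap()] results.
#' @param node node label.
#' @param measure one of `"predictability"`, `"degree_centrality"`,
#'   `"current_flow_closeness"`.
#' @return List: `p_value`, `mean_difference`, `B`.
#' @export
centrality_difference_test <- function(boot_a, boot_b, node,
                                       measure = "degree_centrality") {
  check_paired(boot_a, boot_b)
  stopifnot(measure %in% names(boot_a$measures),
            node %in% boot_a$labels, node %in% boot_b$labels)
  d <- boot_a$measures[[measure]][, node] - boot_b$measures[[measure]][, node]
  list(p_value = boot_p_value(d), mean_difference = mean(d), B = boot_a$B)
}

#' Similarity of two network models (Pearson and Hamming)
#'
#' Full scope vectorizes the upper-triangle partial correlations of both
#' models and reports their Pearson correlation (with p-value) plus the
#' Hamming similarity of the binarized supports, `1 - mismatches /
#' compared-entries`. Row scope restricts the comparison to the edges
#' incident to one node (its row of the adjacency, diagonal excluded) — the
#' one-dimensional comparison used for single ERP components.
#'
#' @param model_a,model_b `network_model`s over the same node labels.
#' @param scope `"full"` or a node label for row scope.
#' @return A list of class `similarity_report`: `pearson_r`, `pearson_p`,
#'   `hamming_similarity`, `scope`, `n_compared`.
#' @export
compare_networks <- function(model_a, model_b, scope = "full") {
  if (!identical(model_a$labels, model_b$labels))
    stop("node label sets differ")
  wa <- model_a$partial_corr * model_a$support
  wb <- model_b$partial_corr * model_b$support
  if (identical(scope, "full")) {
    va <- wa[upper.tri(wa)]; vb <- wb[upper.tri(wb)]
    sa <- model_a$support[upper.tri(wa)]; sb <- model_b$support[upper.tri(wb)]
  } else {
    stopifnot(scope %in% model_a$labels)
    k <- match(scope, model_a$labels)
    va <- wa[k, -k]; vb <- wb[k, -k]
    sa <- model_a$support[k, -k]; sb <- model_b$support[k, -k]
  }
  r <- if (sd(va) == 0 || sd(vb) == 0) {
    list(estimate = NA_real_, p.value = NA_real_)
  } else {
    ct <- cor.test(va, vb)
    list(estimate = unname(ct$estimate), p.value = ct$p.value)
  }
  structure(list(pearson_r = r$estimate, pearson_p = r$p.value,
                 hamming_similarity = 1 - mean(sa != sb),
                 scope = if (identical(scope, "full")) "full" else
                   paste0("row:", scope),
                 n_compared = length(va)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report> %s: r=%.3f (p=%.3g), hamming=%.3f (m=%d)\n",
              x$scope, x$pearson_r, x$pearson_p, x$hamming_similarity,
              x$n_compared))
  invisible(x)
}

#' Case-dropping stability of a node-level network measure
#'
#' Re-estimates the network on progressively smaller subsamples (drawn
#' without replacement) and correlates the node measure with its value on
#' the full sample. The CS coefficient is the largest fraction of cases
#' that can be dropped while the correlation stays at or above
#' `cor_floor` in at least 95% of subsamples.
#'
#' @param table standardized [data_table()] or matrix.
#' @param config an [estimation_config()].
#' @param measure a measure name (see [edge_bootstrap()] plus
#'   `"closeness"`, `"betweenness"`, `"current_flow_betweenness"`).
#' @param fractions retained-case fractions, strictly decreasing.
#' @param reps subsamples per fraction.
#' @param seed integer seed.
#' @param cor_floor correlation floor for the CS coefficient (default 0.7).
#' @param reference optional precomputed reference `network_model`.
#' @return A list of class `stability_curve`: `measure`, `detail` (tidy
#'   data frame fraction/rep/correlation), `summary` (mean correlation per
#'   fraction), `cs_coefficient`.
#' @export
measure_stability <- function(table, config = estimation_config(),
                              measure = "predictability",
                              fractions = seq(0.9, 0.3, by = -0.1),
                              reps = 100, seed = 1L, cor_floor = 0.7,
                              reference = NULL) {
  reg <- measure_registry()
  stopifnot(measure %in% names(reg), all(diff(fractions) < 0))
  x <- if (is.matrix(table)) table else as_matrix(table)
  n <- nrow(x); p <- ncol(x)
  if (is.null(reference)) reference <- estimate_network(x, config)$model
  ref_vals <- reg[[measure]](reference)
  seeds <- derive_seeds(seed, length(fractions) * reps)
  rows_out <- list()
  k <- 0L
  for (f in fractions) {
    m <- round(f * n)
    if (m < p + 1) {
      warning(sprintf("fraction %.2f gives %d < p+1 cases; skipped", f, m))
      k <- k + reps
      next
    }
    for (r in seq_len(reps)) {
      k <- k + 1L
      idx <- with_seed(seeds[k], sample.int(n, m))
      cfg <- config
      cfg$seed <- seeds[k]
      fit <- estimate_network(x[idx, , drop = FALSE], cfg)$model
      vals <- reg[[measure]](fit)
      cc <- if (sd(vals) == 0 || sd(ref_vals) == 0) NA_real_
        else cor(vals, ref_vals)
      rows_out[[length(rows_out) + 1L]] <-
        data.frame(measure = measure, fraction = f, rep = r,
                   correlation = cc)
    }
  }
  detail <- do.call(rbind, rows_out)
  summ <- stats::aggregate(correlation ~ fraction, detail, mean,
                           na.action = stats::na.omit)
  ok <- stats::aggregate(correlation ~ fraction, detail,
                         function(v) mean(v >= cor_floor, na.rm = TRUE))
  good <- ok$fraction[ok$correlation >= 0.95]
  cs <- if (length(good)) 1 - min(good) else 0
  structure(list(measure = measure, detail = detail, summary = summ,
                 cs_coefficient = cs),
            class = "stability_curve")
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("<stability_curve> %s: CS = %.2f\n", x$measure,
              x$cs_coefficient))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
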