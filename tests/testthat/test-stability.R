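# small planted problem shared across stability tests
stab_fixture <- function(n = 300, seed = 201) {
  spec <- make_precision(5, 0.2, c(0.38, 0.45), seed = seed)
  xs <- standardize(sample_mvn(spec, n, seed = seed + 1))
  list(spec = spec, x = xs)
}

test_that("bootstrapped CIs bracket strong planted edges", {
  fx <- stab_fixture()
  cfg <- estimation_config(B = 60, seed = 202)
  expect_warning(
    boot <- edge_bootstrap(fx$x, cfg, B = 60, seed = 203, inner_B = 60),
    "unstable")
  es <- edge_stability(boot)
  ut <- upper.tri(fx$spec$true_support)
  true_edges <- which(fx$spec$true_support[ut] == 1L)
  for (k in true_edges) {
    if (!es$in_reference[k]) next
    expect_gte(es$sensitivity[k], 0.9)
    truth <- fx$spec$true_partial_corr[ut][k]
    expect_lte(es$ci_low[k], truth)
    expect_gte(es$ci_high[k], truth)
  }
  expect_true(all(es$ci_low <= es$mean & es$mean <= es$ci_high))
  # exactly one of sensitivity/specificity defined per edge
  expect_true(all(xor(is.na(es$sensitivity), is.na(es$specificity))))
})

test_that("null edges have high bootstrap specificity", {
  x <- withr::with_seed(204, matrix(rnorm(300 * 5), 300, 5,
                                    dimnames = list(NULL, paste0("V", 1:5))))
  cfg <- estimation_config(B = 60, seed = 205)
  boot <- suppressWarnings(
    edge_bootstrap(scale(x), cfg, B = 60, seed = 206, inner_B = 60))
  es <- edge_stability(boot)
  absent <- which(!es$in_reference)
  expect_gt(length(absent), 0)
  expect_gte(mean(es$specificity[absent]), 0.9)
})

test_that("CI width shrinks as the sample grows", {
  width_at <- function(n) {
    fx <- stab_fixture(n = n, seed = 207)
    cfg <- estimation_config(B = 50, seed = 208)
    boot <- suppressWarnings(
      edge_bootstrap(fx$x, cfg, B = 50, seed = 209, inner_B = 50))
    es <- edge_stability(boot)
    k <- which(fx$spec$true_support[upper.tri(fx$spec$true_support)] == 1L)[1]
    es$ci_high[k] - es$ci_low[k]
  }
  expect_lt(width_at(800), width_at(200))
})

test_that("paired difference tests are calibrated and symmetric", {
  fx <- stab_fixture()
  cfg <- estimation_config(B = 50, seed = 210)
  boot <- suppressWarnings(
    edge_bootstrap(fx$x, cfg, B = 50, seed = 211, inner_B = 50))
  ut <- upper.tri(fx$spec$true_support)
  k <- which(fx$spec$true_support[ut] == 1L)[1]
  ni <- boot$pairs$node_i[k]; nj <- boot$pairs$node_j[k]
  # identical models: difference distribution degenerate at 0 -> p = 1
  same <- edge_difference_test(boot, boot, ni, nj)
  expect_equal(same$p_value, 1)
  # a structurally zeroed copy of the same edge differs significantly
  x2 <- fx$x
  df <- as.data.frame(x2)
  df[[ni]] <- withr::with_seed(212, sample(df[[ni]]))  # break the edge
  x2 <- standardize(data_table(df, table_roles(fx$x)))
  boot2 <- suppressWarnings(
    edge_bootstrap(x2, cfg, B = 50, seed = 211, inner_B = 50))
  diff <- edge_difference_test(boot, boot2, ni, nj)
  expect_lt(diff$p_value, 0.05)
  # symmetric in model order
  rev <- edge_difference_test(boot2, boot, ni, nj)
  expect_equal(diff$p_value, rev$p_value)
  # unpaired bootstraps are rejected
  boot3 <- suppressWarnings(
    edge_bootstrap(fx$x, cfg, B = 50, seed = 999, inner_B = 50))
  expect_error(edge_difference_test(boot, boot3, ni, nj), "paired")
})

test_that("centrality difference tests flag removed hubs", {
  fx <- stab_fixture()
  cfg <- estimation_config(B = 50, seed = 213)
  boot <- suppressWarnings(
    edge_bootstrap(fx$x, cfg, B = 50, seed = 214, inner_B = 50))
  same <- centrality_difference_test(boot, boot, boot$labels[1])
  expect_equal(same$p_value, 1)
  # destroy the hub node's edges and compare
  deg <- degree_centrality(boot$reference)
  hub <- names(which.max(deg))
  df <- as.data.frame(fx$x)
  df[[hub]] <- withr::with_seed(215, sample(df[[hub]]))
  x2 <- standardize(data_table(df, table_roles(fx$x)))
  boot2 <- suppressWarnings(
    edge_bootstrap(x2, cfg, B = 50, seed = 214, inner_B = 50))
  res <- centrality_difference_test(boot, boot2, hub, "degree_centrality")
  expect_lt(res$p_value, 0.05)
})

test_that("network similarity has its identity and complement endpoints", {
  fx <- stab_fixture()
  model <- refit_support(fx$x, fx$spec$true_support)
  self <- compare_networks(model, model)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$hamming_similarity, 1)
  # complemented support: Hamming similarity 0
  anti <- model
  anti$support <- 1L - model$support
  diag(anti$support) <- 0L
  expect_equal(compare_networks(model, anti)$hamming_similarity, 0)
  # row scope restricts to one node's incident edges
  row_rep <- compare_networks(model, model, scope = model$labels[1])
  expect_equal(row_rep$n_compared, length(model$labels) - 1)
  expect_match(row_rep$scope, "row:")
  other <- model
  other$labels <- rev(model$labels)
  expect_error(compare_networks(model, other), "label")
})

test_that("independent replicates of one model give similar networks", {
  rs <- hs <- numeric(3)
  for (s in 1:3) {
    spec <- make_precision(8, 0.25, c(0.25, 0.45), seed = 220 + s)
    cfg <- estimation_config(B = 100, seed = s)
    m1 <- estimate_network(standardize(sample_mvn(spec, 400, seed = 230 + s)),
                           cfg)$model
    m2 <- estimate_network(standardize(sample_mvn(spec, 400, seed = 240 + s)),
                           cfg)$model
    rep <- compare_networks(m1, m2)
    rs[s] <- rep$pearson_r; hs[s] <- rep$hamming_similarity
  }
  expect_gt(mean(rs), 0.3)
  expect_gt(mean(hs), 0.7)
})

test_that("measure-stability curves behave and reproduce under a seed", {
  fx <- stab_fixture()
  cfg <- estimation_config(B = 40, seed = 250)
  curve <- measure_stability(fx$x, cfg, "predictability",
                             fractions = c(0.9, 0.6), reps = 10, seed = 251)
  expect_equal(nrow(curve$summary), 2)
  expect_true(all(curve$detail$correlation <= 1 &
                    curve$detail$correlation >= -1))
  curve2 <- measure_stability(fx$x, cfg, "predictability",
                              fractions = c(0.9, 0.6), reps = 10, seed = 251)
  expect_identical(curve$detail, curve2$detail)
  # too-small fractions are skipped with a warning
  expect_warning(
    small <- measure_stability(fx$x, cfg, "predictability",
                               fractions = c(0.9, 0.01), reps = 2,
                               seed = 252),
    "skipped")
  expect_equal(nrow(small$summary), 1)
})

test_that("predictability is more subsample-stable than betweenness", {
  spec <- make_precision(8, 0.25, c(0.25, 0.45), seed = 260)
  xs <- standardize(sample_mvn(spec, 400, seed = 261))
  cfg <- estimation_config(B = 40, seed = 262)
  ref <- estimate_network(xs, cfg)$model
  cp <- measure_stability(xs, cfg, "predictability", fractions = c(0.5),
                          reps = 15, seed = 263, reference = ref)
  cb <- measure_stability(xs, cfg, "betweenness", fractions = c(0.5),
                          reps = 15, seed = 263, reference = ref)
  expect_gt(mean(cp$detail$correlation, na.rm = TRUE),
            mean(cb$detail$correlation, na.rm = TRUE))
})
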