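test_that("predictability matches nodewise regression R-squared", {
  spec <- make_precision(3, 0.6, c(0.3, 0.4), seed = 101)
  x <- as.matrix(as.data.frame(standardize(sample_mvn(spec, 1e5, seed = 102))))
  model <- refit_support(x, spec$true_support)
  pred <- predictability(model)
  for (i in 1:3) {
    fit <- stats::lm(x[, i] ~ x[, -i])
    expect_lt(abs(pred[i] - 100 * summary(fit)$r.squared), 0.5)
  }
})

test_that("isolated nodes have zero predictability and degree", {
  theta <- diag(3)
  theta[1, 2] <- theta[2, 1] <- -0.4
  model <- model_from_theta(theta)
  expect_equal(unname(predictability(model)[3]), 0)
  expect_equal(unname(degree_centrality(model)[3]), 0)
})

test_that("degree centrality has its closed forms on stars and hubs", {
  p <- 11
  W <- matrix(0, p, p)
  W[1, 2:p] <- W[2:p, 1] <- 0.3
  star <- model_from_weights(W)
  dc <- degree_centrality(star)
  expect_equal(unname(dc[1]), 1.0)
  expect_equal(unname(dc[2:p]), rep(1 / (p - 1), p - 1))
})

test_that("hold-out predictability tracks training on matched samples", {
  spec <- make_precision(6, 0.4, c(0.25, 0.4), seed = 103)
  xs <- standardize(sample_mvn(spec, 5000, seed = 104))
  model <- refit_support(xs, spec$true_support)
  test <- standardize(sample_mvn(spec, 20000, seed = 105))
  ho <- holdout_predictability(model, test)
  tr <- predictability(model)
  expect_lt(max(abs(ho - tr)), 3)
  # permuting one column's rows destroys that node's hold-out signal
  xt <- as.matrix(as.data.frame(test))
  k <- which.max(tr)
  xt[, k] <- withr::with_seed(106, sample(xt[, k]))
  colnames(xt) <- model$labels
  ho2 <- holdout_predictability(model, xt)
  expect_lt(ho2[k], 5)
  expect_error(holdout_predictability(model, xt[, 1:3]), "columns")
})

test_that("no-edge nodes predict nothing out of sample", {
  theta <- diag(3)
  theta[1, 2] <- theta[2, 1] <- -0.4
  model <- model_from_theta(theta)
  x <- withr::with_seed(107, matrix(rnorm(600), 200, 3))
  colnames(x) <- model$labels
  expect_lte(holdout_predictability(model, x)[3], 0)
})

test_that("current-flow closeness matches its small closed forms", {
  W2 <- matrix(0, 2, 2)
  W2[1, 2] <- W2[2, 1] <- 1
  expect_equal(unname(current_flow_closeness(model_from_weights(W2))),
               c(1, 1))
  # path of three unit edges: center beats leaves
  W4 <- matrix(0, 4, 4)
  W4[1, 2] <- W4[2, 3] <- W4[3, 4] <- 1
  W4 <- W4 + t(W4)
  cfc <- current_flow_closeness(model_from_weights(W4))
  expect_true(all(cfc[2:3] > cfc[c(1, 4)]))
})

test_that("current-flow closeness matches the pairwise-current oracle", {
  for (s in 1:5) {
    W <- random_connected_weights(6, seed = 110 + s)
    model <- model_from_weights(W)
    got <- current_flow_closeness(model)
    oracle <- brute_force_cfc(abs(W) * model$support)
    expect_lt(max(abs(got - oracle)), 1e-8)
  }
})

test_that("current-flow closeness grows with an incident conductance", {
  W <- random_connected_weights(5, seed = 120)
  base <- current_flow_closeness(model_from_weights(W))
  W2 <- W
  j <- which(W[1, ] != 0)[1]
  W2[1, j] <- W2[j, 1] <- W[1, j] + 0.5
  up <- current_flow_closeness(model_from_weights(pmin(W2, 0.99)))
  expect_gt(up[1], base[1])
})

test_that("betweenness measures single out star centers", {
  p <- 6
  W <- matrix(0, p, p)
  W[1, 2:p] <- W[2:p, 1] <- 0.4
  star <- model_from_weights(W)
  cc <- classical_centralities(star)
  expect_gt(cc$betweenness[1], max(cc$betweenness[-1]))
  expect_equal(cc$betweenness[-1], rep(0, p - 1))
  cfb <- current_flow_betweenness(star)
  expect_gt(cfb[1], max(cfb[-1]))
  expect_equal(unname(cfb[-1]), rep(0, p - 1))
})

test_that("path-graph closeness decreases from center to leaves", {
  p <- 5
  W <- matrix(0, p, p)
  for (i in 1:(p - 1)) W[i, i + 1] <- W[i + 1, i] <- 0.5
  cc <- classical_centralities(model_from_weights(W))
  expect_true(cc$closeness[3] >= cc$closeness[2])
  expect_true(cc$closeness[2] >= cc$closeness[1])
})

test_that("weighted betweenness matches exhaustive path enumeration", {
  for (s in 1:4) {
    W <- random_connected_weights(5, seed = 130 + s)
    cc <- classical_centralities(model_from_weights(W))
    oracle <- brute_force_betweenness(W)
    expect_equal(cc$betweenness, oracle, tolerance = 1e-10)
  }
})

test_that("all node measures are permutation-equivariant", {
  spec <- make_precision(6, 0.4, c(0.2, 0.4), seed = 140)
  model <- model_from_theta(spec$theta)
  perm <- withr::with_seed(141, sample(6))
  theta_p <- spec$theta[perm, perm]
  model_p <- model_from_theta(theta_p)
  for (f in list(predictability, degree_centrality, current_flow_closeness,
                 current_flow_betweenness)) {
    expect_equal(unname(f(model_p)), unname(f(model)[perm]),
                 tolerance = 1e-10)
  }
})

test_that("the maximal spanning tree keeps the right triangle edges", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.4
  W[1, 3] <- W[3, 1] <- 0.3
  tree <- maximal_spanning_tree(model_from_weights(W))
  expect_equal(nrow(tree$edges), 2)
  expect_equal(tree$total_weight, 0.9)
  expect_setequal(tree$edges$abs_weight, c(0.5, 0.4))
})

test_that("a tree input passes through the MST unchanged", {
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 3] <- W[3, 4] <- W[3, 5] <- 0.3
  W <- W + t(W)
  model <- model_from_weights(W)
  tree <- maximal_spanning_tree(model)
  expect_equal(nrow(tree$edges), 4)
  expect_equal(tree$total_weight, 4 * 0.3)
})

test_that("Prim agrees with the igraph greedy cross-check", {
  for (s in 1:6) {
    W <- random_connected_weights(7, seed = 150 + s)
    model <- model_from_weights(W)
    tree <- maximal_spanning_tree(model)
    g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    ig <- igraph::mst(g, weights = -igraph::E(g)$weight)
    expect_equal(tree$total_weight, sum(igraph::E(ig)$weight),
                 tolerance = 1e-12)
  }
})

test_that("disconnected graphs yield a forest", {
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 3] <- 0.4   # component 1
  W[4, 5] <- W[5, 6] <- 0.3   # component 2
  W <- W + t(W)
  tree <- maximal_spanning_tree(model_from_weights(W))
  expect_equal(nrow(tree$edges), 4)  # (3-1) + (3-1)
})

test_that("network_measures returns a tidy stacked table", {
  spec <- make_precision(5, 0.4, seed = 160)
  xs <- standardize(sample_mvn(spec, 500, seed = 161))
  model <- refit_support(xs, spec$true_support)
  m <- network_measures(model, test = standardize(sample_mvn(spec, 500,
                                                             seed = 162)))
  expect_setequal(unique(m$measure),
                  c("predictability", "degree_centrality",
                    "current_flow_closeness", "current_flow_betweenness",
                    "closeness", "betweenness"))
  expect_true(all(c("training", "holdout") %in% m$context))
})
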