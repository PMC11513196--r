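#' Default six-network study roster
#'
#' Builds the standard recipe list from the table's roles: for each ERP
#' amplitude node a network with traits only and one adding covariates,
#' then the two combined-amplitude networks. Covariate recipes include the
#' latency column(s) whose name contains the amplitude name (both latencies
#' in the combined models).
#'
#' @param table a [data_table()] with role labels.
#' @return Named list of character vectors of column names, one per recipe.
#' @export
default_recipes <- function(table) {
  roles <- table_roles(table)
  traits <- names(roles)[roles == "trait"]
  amps <- names(roles)[roles == "erp_amplitude"]
  lats <- names(roles)[roles == "erp_latency"]
  covs <- names(roles)[roles == "covariate"]
  if (!length(amps)) stop("no erp_amplitude columns in table")
  match_lat <- function(amp) lats[grepl(amp, lats, fixed = TRUE)]
  recipes <- list()
  for (a in amps) {
    recipes[[a]] <- c(traits, a)
    recipes[[paste0(a, "_cov")]] <- c(traits, a, covs, match_lat(a))
  }
  if (length(amps) >= 2) {
    comb <- paste(amps, collapse = "_")
    recipes[[comb]] <- c(traits, amps)
    recipes[[paste0(comb, "_cov")]] <- c(traits, amps, covs, lats)
  }
  recipes
}

#' Run the full train/test network study
#'
#' For each recipe: fit the normalization pipeline (Box-Cox, screen,
#' standardize) on the training rows, apply it unchanged to the test rows,
#' estimate the network on both splits, compute node measures (training
#' and hold-out predictability, all centralities), the maximal spanning
#' tree, and the train/test similarity (full scope plus one row-scope
#' comparison per ERP amplitude node). Optionally runs the bootstrap
#' stability suite per recipe. One seed governs the whole run.
#'
#' @param train training [data_table()].
#' @param test optional hold-out [data_table()]; when `NULL` the hold-out
#'   and similarity stages are skipped.
#' @param recipes named list of column sets; default [default_recipes()].
#' @param config an [estimation_config()]; its seed is re-derived per
#'   recipe from `seed`.
#' @param seed integer master seed.
#' @param stability optional list with elements `B` and `inner_B` to run
#'   [edge_bootstrap()] per recipe (skipped when `NULL` — it dominates the
#'   runtime).
#' @param out_dir optional output directory; when given, every artifact is
#'   written under `out_dir/<recipe>/`.
#' @param skew_limit passed to [fit_transforms()].
#' @return A list of class `study_report`: per-recipe results (`model`,
#'   `proportions`, `measures`, `tree`, `similarity`, `row_similarity`,
#'   optional `edge_stability`), plus `seed` and `recipes`.
#' @export
run_study <- function(train, test = NULL, recipes = NULL,
                      config = estimation_config(), seed = 1L,
                      stability = NULL, out_dir = NULL, skew_limit = 2.0) {
  if (is.null(recipes)) recipes <- default_recipes(train)
  seeds <- derive_seeds(seed, length(recipes) * 3L)
  results <- list()
  for (k in seq_along(recipes)) {
    name <- names(recipes)[k]
    cols <- recipes[[k]]
    res <- tryCatch({
      tr <- select_roles(train, columns = cols)
      transformer <- fit_transforms(tr, skew_limit = skew_limit)
      cfg <- config
      cfg$seed <- seeds[3 * k - 2]
      est <- estimate_network(transformer$table, cfg)
      te_std <- NULL
      test_model <- NULL
      if (!is.null(test)) {
        te_std <- apply_transforms(transformer,
                                   select_roles(test, columns = cols))
        cfg_test <- cfg
        cfg_test$seed <- seeds[3 * k - 1]
        test_model <- estimate_network(te_std, cfg_test)$model
      }
      measures <- network_measures(est$model, test = te_std)
      tree <- maximal_spanning_tree(est$model)
      sim <- row_sim <- NULL
      if (!is.null(test_model)) {
        sim <- compare_networks(est$model, test_model, scope = "full")
        amps <- intersect(
          names(table_roles(train))[table_roles(train) == "erp_amplitude"],
          est$model$labels)
        row_sim <- lapply(amps, function(a)
          compare_networks(est$model, test_model, scope = a))
        names(row_sim) <- amps
      }
      stab <- NULL
      if (!is.null(stability)) {
        boot <- edge_bootstrap(transformer$table, cfg,
                               B = stability$B, seed = seeds[3 * k],
                               inner_B = stability$inner_B,
                               reference = est$model)
        stab <- edge_stability(boot)
      }
      list(model = est$model, proportions = est$proportions,
           transformer = transformer, measures = measures, tree = tree,
           similarity = sim, row_similarity = row_sim,
           edge_stability = stab, test_model = test_model,
           error = NULL)
    }, error = function(e) {
      list(error = sprintf("recipe '%s' failed: %s", name,
                           conditionMessage(e)))
    })
    results[[name]] <- res
    if (!is.null(out_dir) && is.null(res$error))
      write_recipe_outputs(res, file.path(out_dir, name), name)
  }
  structure(list(results = results, seed = as.integer(seed),
                 recipes = recipes, config = config),
            class = "study_report")
}

write_recipe_outputs <- function(res, dir, name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network_model(res$model, dir, name)
  write.csv(res$measures, file.path(dir, paste0(name, "_measures.csv")),
            row.names = FALSE)
  utils::write.table(res$tree$edges,
                     file.path(dir, paste0(name, "_mst.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(res$proportions$proportions,
            file.path(dir, paste0(name, "_proportions.csv")))
  transformer_to_json(res$transformer,
                      file.path(dir, paste0(name, "_transforms.json")))
  if (!is.null(res$similarity)) {
    sims <- c(list(full = res$similarity), res$row_similarity)
    jsonlite::write_json(lapply(sims, unclass),
                         file.path(dir, paste0(name, "_similarity.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$edge_stability))
    write.csv(res$edge_stability,
              file.path(dir, paste0(name, "_edge_stability.csv")),
              row.names = FALSE)
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d recipes, seed %d\n", length(x$results),
              x$seed))
  for (name in names(x$results)) {
    r <- x$results[[name]]
    if (!is.null(r$error)) {
      cat(sprintf("  %s: FAILED (%s)\n", name, r$error))
    } else {
      line <- sprintf("  %s: %d nodes, %d edges", name,
                      length(r$model$labels), nrow(edge_list(r$model)))
      if (!is.null(r$similarity))
        line <- sprintf("%s; train/test r=%.2f hamming=%.2f", line,
                        r$similarity$pearson_r,
                        r$similarity$hamming_similarity)
      cat(line, "\n")
    }
  }
  invisible(x)
}

#' Run a study from a YAML/JSON configuration file
#'
#' The config document holds `train` and optional `test` CSV paths (with
#' their role-map sidecars), estimation settings (`B`, `tau`,
#' `lambda_min_ratio`, `penalty_kind`), optional `recipes` (name -> column
#' list), optional `stability` (`B`, `inner_B`), `seed` and `out_dir`.
#' Omitted settings take the package defaults (B = 1000, tau = 0.65).
#'
#' @param path YAML (or JSON) config file.
#' @return The [run_study()] report.
#' @export
run_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$train))
  train <- read_data_table(cfg$train)
  test <- if (!is.null(cfg$test)) read_data_table(cfg$test)
  est <- estimation_config(
    B = cfg$B %||% 1000, tau = cfg$tau %||% 0.65,
    scheme = penalty_scheme(kind = cfg$penalty_kind %||% "scaled",
                            lambda_min_ratio = cfg$lambda_min_ratio %||% 0.01))
  recipes <- cfg$recipes
  if (!is.null(recipes)) recipes <- lapply(recipes, unlist)
  run_study(train, test, recipes = recipes, config = est,
            seed = cfg$seed %||% 1L, stability = cfg$stability,
            out_dir = cfg$out_dir, skew_limit = cfg$skew_limit %||% 2.0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
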