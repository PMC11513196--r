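#' Random sparse precision matrix with known partial correlations
#'
#' Draws an Erdos-Renyi-style support at the requested density, assigns each
#' edge a partial correlation with magnitude uniform in `weight_range` and a
#' Rademacher sign, and turns the result into a valid precision matrix.
#' Positive definiteness is enforced by boosting the diagonal until the
#' smallest eigenvalue reaches `min_eigen`; the matrix is then rescaled so
#' the implied covariance has unit diagonal (standardized-variable
#' convention). The returned ground truth (`true_partial_corr`,
#' `true_support`) is recomputed from the final matrix, so it is exact even
#' when a diagonal boost shrank the requested weights.
#'
#' @param p number of variables (>= 3).
#' @param edge_density fraction of the `p(p-1)/2` possible edges that are
#'   present; the realized count is `round(edge_density * choose(p, 2))`.
#' @param weight_range length-2 interval in (0, 1) for target partial
#'   correlation magnitudes.
#' @param seed integer seed; generation is fully deterministic given it.
#' @param labels,roles optional node names and role labels (see
#'   [data_table()]); defaults are `V1..Vp`, all `"trait"`.
#' @param min_eigen smallest admissible eigenvalue before rescaling.
#' @param max_boost upper bound on the diagonal boost; exceeding it is an
#'   error (the requested structure is then too dense/strong to be a valid
#'   precision matrix).
#' @return An object of class `precision_spec` with elements `labels`,
#'   `roles`, `theta`, `sigma`, `true_support`, `true_partial_corr`.
#' @export
make_precision <- function(p, edge_density, weight_range = c(0.1, 0.4),
                           seed = 1L, labels = NULL, roles = NULL,
                           min_eigen = 0.05, max_boost = 100) {
  stopifnot(p >= 3, edge_density >= 0, edge_density < 1,
            length(weight_range) == 2, weight_range[1] > 0,
            weight_range[2] < 1, weight_range[1] <= weight_range[2])
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  if (is.null(roles)) roles <- stats::setNames(rep("trait", p), labels)

  n_pairs <- p * (p - 1L) / 2L
  m <- round(edge_density * n_pairs)
  K <- diag(p)
  if (m > 0) {
    with_seed(seed, {
      picked <- sample.int(n_pairs, m)
      mags <- runif(m, weight_range[1], weight_range[2])
      signs <- ifelse(runif(m) < 0.5, -1, 1)
    })
    pairs <- which(upper.tri(K), arr.ind = TRUE)[picked, , drop = FALSE]
    for (e in seq_len(m)) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      # theta_ij = -rho_ij on the unit-diagonal scale
      K[i, j] <- K[j, i] <- -signs[e] * mags[e]
    }
  }

  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  boost <- 0
  while (ev < min_eigen) {
    step <- max(min_eigen - ev, 0.01)
    boost <- boost + step
    if (boost > max_boost)
      stop("cannot reach positive definiteness within the diagonal-boost limit")
    diag(K) <- diag(K) + step
    ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  }

  sigma <- solve(K)
  d <- sqrt(diag(sigma))
  # unit-diagonal covariance convention; partial correlations are unchanged
  theta <- diag(d) %*% K %*% diag(d)
  theta <- (theta + t(theta)) / 2
  dimnames(theta) <- list(labels, labels)

  pc <- precision_to_pcor(theta)
  supp <- (abs(theta) > 1e-12) * 1L
  diag(supp) <- 0L
  dimnames(supp) <- dimnames(theta)
  sigma <- solve(theta)
  sigma <- (sigma + t(sigma)) / 2
  dimnames(sigma) <- dimnames(theta)

  structure(list(labels = labels, roles = roles, theta = theta,
                 sigma = sigma, true_support = supp,
                 true_partial_corr = pc),
            class = "precision_spec")
}

#' Partial correlations implied by a precision matrix
#'
#' `pcor[i,j] = -theta[i,j] / sqrt(theta[i,i] * theta[j,j])`, with unit
#' diagonal.
#'
#' @param theta symmetric positive-definite precision matrix.
#' @return Symmetric matrix of partial correlations.
#' @export
precision_to_pcor <- function(theta) {
  d <- 1 / sqrt(diag(theta))
  pc <- -theta * tcrossprod(d)
  diag(pc) <- 1
  (pc + t(pc)) / 2
}

#' @export
print.precision_spec <- function(x, ...) {
  cat(sprintf("<precision_spec> p=%d, %d true edges\n",
              length(x$labels), sum(x$true_support[upper.tri(x$true_support)])))
  invisible(x)
}

#' Sample multivariate-normal data from a precision spec
#'
#' Rows are drawn from the zero-mean Gaussian with covariance
#' `solve(spec$theta)`. Optionally an elementwise exponential (a strictly
#' monotone transform) is applied to selected columns to induce marginal
#' skewness for exercising the Box-Cox stage; rank correlations are
#' unaffected.
#'
#' @param spec a [make_precision()] result.
#' @param n number of subjects.
#' @param seed integer seed.
#' @param skew optional character/integer vector of columns to skew via
#'   `exp()`.
#' @return A [data_table()] with roles copied from the spec.
#' @export
sample_mvn <- function(spec, n, seed = 1L, skew = NULL) {
  stopifnot(inherits(spec, "precision_spec"), n >= 2)
  p <- length(spec$labels)
  L <- chol(spec$sigma)
  z <- with_seed(seed, matrix(rnorm(n * p), n, p))
  x <- z %*% L
  colnames(x) <- spec$labels
  x <- as.data.frame(x)
  if (!is.null(skew)) {
    if (is.numeric(skew)) skew <- spec$labels[skew]
    stopifnot(all(skew %in% spec$labels))
    for (cl in skew) x[[cl]] <- exp(x[[cl]])
  }
  data_table(x, spec$roles)
}

#' Specification for synthetic trial-level ERP epochs
#'
#' Defaults mirror a response-locked ERN-style component: 256 Hz sampling on
#' a -100..600 ms axis, mean amplitude around -4 uV with between-subject SD
#' ~4.5 uV and trial-level SD ~8 uV, and a latency near 50 ms — the scale of
#' error-related activity in speeded go/no-go work.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_subject trial count, recycled to one value per subject.
#' @param sampling_rate Hz.
#' @param epoch_window length-2 ms pair for the epoch time axis.
#' @param component_window length-2 ms pair containing the component.
#' @param amp_mean,amp_sd_between,amp_sd_within component amplitude mean and
#'   SDs (uV); between-subject SD spreads subjects, within-subject SD
#'   spreads trials around the subject's latent amplitude.
#' @param latency_mean,latency_sd per-subject component latency (ms).
#' @param peak_sd width (SD, ms) of the Gaussian-shaped component peak.
#' @param noise_sd white-noise SD per sample (uV).
#' @param condition condition label (`"error"` or `"correct"`).
#' @param seed integer seed.
#' @return A list of class `epoch_spec`.
#' @export
epoch_spec <- function(n_subjects = 50, trials_per_subject = 28,
                       sampling_rate = 256, epoch_window = c(-100, 600),
                       component_window = c(0, 100), amp_mean = -4,
                       amp_sd_between = 4.5, amp_sd_within = 8,
                       latency_mean = 50, latency_sd = 15, peak_sd = 20,
                       noise_sd = 3, condition = "error", seed = 1L) {
  stopifnot(n_subjects >= 1, all(trials_per_subject >= 1),
            amp_sd_between >= 0, amp_sd_within >= 0, latency_sd >= 0,
            noise_sd >= 0, peak_sd > 0,
            component_window[1] >= epoch_window[1],
            component_window[2] <= epoch_window[2])
  trials <- rep_len(trials_per_subject, n_subjects)
  structure(list(n_subjects = n_subjects, trials_per_subject = trials,
                 sampling_rate = sampling_rate, epoch_window = epoch_window,
                 component_window = component_window, amp_mean = amp_mean,
                 amp_sd_between = amp_sd_between,
                 amp_sd_within = amp_sd_within, latency_mean = latency_mean,
                 latency_sd = latency_sd, peak_sd = peak_sd,
                 noise_sd = noise_sd, condition = condition,
                 seed = as.integer(seed)),
            class = "epoch_spec")
}

#' Generate trial-level epochs with known per-subject ground truth
#'
#' Each subject i receives a latent amplitude `a_i ~ N(amp_mean,
#' amp_sd_between^2)` and latency `l_i ~ N(latency_mean, latency_sd^2)`;
#' each trial is a Gaussian-shaped peak of amplitude `a_i + N(0,
#' amp_sd_within^2)` centered at `l_i`, plus white noise. The latent values
#' are returned alongside so recovery can be checked exactly.
#'
#' @param spec an [epoch_spec()].
#' @return An object of class `epoch_set`: `epochs` (list of trial x sample
#'   matrices), `time` (ms axis), `sampling_rate`, `condition`, `truth`
#'   (data frame: subject_id, amplitude, latency, n_trials), `spec`.
#' @export
make_epochs <- function(spec) {
  stopifnot(inherits(spec, "epoch_spec"))
  step <- 1000 / spec$sampling_rate
  time <- seq(spec$epoch_window[1], spec$epoch_window[2], by = step)
  ids <- paste0("s", seq_len(spec$n_subjects))

  out <- with_seed(spec$seed, {
    a <- rnorm(spec$n_subjects, spec$amp_mean, spec$amp_sd_between)
    l <- rnorm(spec$n_subjects, spec$latency_mean, spec$latency_sd)
    epochs <- vector("list", spec$n_subjects)
    for (i in seq_len(spec$n_subjects)) {
      nt <- spec$trials_per_subject[i]
      shape <- exp(-(time - l[i])^2 / (2 * spec$peak_sd^2))
      amp <- a[i] + rnorm(nt, 0, spec$amp_sd_within)
      m <- tcrossprod(amp, shape)
      if (spec$noise_sd > 0)
        m <- m + matrix(rnorm(nt * length(time), 0, spec$noise_sd),
                        nt, length(time))
      epochs[[i]] <- m
    }
    list(a = a, l = l, epochs = epochs)
  })
  names(out$epochs) <- ids

  structure(list(epochs = out$epochs, time = time,
                 sampling_rate = spec$sampling_rate,
                 condition = spec$condition,
                 truth = data.frame(subject_id = ids, amplitude = out$a,
                                    latency = out$l,
                                    n_trials = spec$trials_per_subject),
                 spec = spec),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d subjects, %s condition, %d samples at %g Hz\n",
              length(x$epochs), x$condition, length(x$time),
              x$sampling_rate))
  invisible(x)
}

#' Write / read an epoch set as per-subject CSV arrays plus a JSON manifest
#'
#' @param x an [make_epochs()] result.
#' @param dir directory to hold `manifest.json` and one `<subject>.csv`
#'   (trials x samples) per subject.
#' @return `write_epoch_set` returns `dir` invisibly; `read_epoch_set`
#'   returns an `epoch_set` (without the generating spec/truth).
#' @export
write_epoch_set <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(subjects = names(x$epochs), sampling_rate = x$sampling_rate,
         time = x$time, condition = x$condition),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  for (id in names(x$epochs))
    utils::write.table(x$epochs[[id]], file.path(dir, paste0(id, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  epochs <- lapply(man$subjects, function(id)
    as.matrix(read.csv(file.path(dir, paste0(id, ".csv")), header = FALSE)))
  names(epochs) <- man$subjects
  structure(list(epochs = epochs, time = man$time,
                 sampling_rate = man$sampling_rate,
                 condition = man$condition, truth = NULL, spec = NULL),
            class = "epoch_set")
}

#' Simulate a full train/test trait-ERP study
#'
#' Builds one precision spec over trait, ERP-amplitude, ERP-latency and
#' covariate nodes and draws two independent samples from the same
#' distribution — a training and a testing set — mirroring a split-sample
#' replication design (defaults: 236 training and 107 testing subjects, 29
#' trait variables, ERN and CRN amplitude nodes, age/handedness/performance
#' plus the two component latencies as covariates).
#'
#' @param p_traits number of trait variables.
#' @param n_train,n_test sample sizes.
#' @param seed integer seed (governs structure and both draws).
#' @param edge_density,weight_range passed to [make_precision()].
#' @return A list with elements `train`, `test` (both [data_table()]s) and
#'   `spec` (the shared [make_precision()] ground truth).
#' @export
make_study <- function(p_traits = 29, n_train = 236, n_test = 107,
                       seed = 1L, edge_density = 0.12,
                       weight_range = c(0.05, 0.45)) {
  stopifnot(p_traits >= 1, n_train >= 1, n_test >= 1)
  labels <- c(paste0("trait_", seq_len(p_traits)), "ERN", "CRN",
              "age", "handedness", "performance",
              "ERN_latency", "CRN_latency")
  roles <- stats::setNames(
    c(rep("trait", p_traits), rep("erp_amplitude", 2),
      rep("covariate", 3), rep("erp_latency", 2)), labels)
  seeds <- derive_seeds(seed, 3L)
  spec <- make_precision(length(labels), edge_density, weight_range,
                         seed = seeds[1], labels = labels, roles = roles)
  list(train = sample_mvn(spec, n_train, seed = seeds[2]),
       test = sample_mvn(spec, n_test, seed = seeds[3]),
       spec = spec)
}
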