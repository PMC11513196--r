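#' Maximum-likelihood covariance of a data table
#'
#' The (1/n) covariance used as input to the graphical lasso. Columns are
#' centered; no bias correction, matching the Gaussian ML estimator.
#'
#' @param table a [data_table()] or numeric matrix.
#' @return Symmetric positive semi-definite covariance matrix.
#' @export
empirical_covariance <- function(table) {
  x <- if (is.matrix(table)) table else as_matrix(table)
  if (anyNA(x)) stop("missing values are not supported")
  if (nrow(x) < 2) stop("need at least two rows")
  xc <- sweep(x, 2, colMeans(x))
  S <- crossprod(xc) / nrow(x)
  (S + t(S)) / 2
}

#' Graphical lasso with an entrywise penalty matrix
#'
#' Maximizes `log det(Theta) - tr(S Theta) - sum_{i != j} P[i,j] |Theta[i,j]|`
#' over symmetric positive-definite matrices by block coordinate descent.
#' Diagonal entries are never penalized. The recorded objective trace is the
#' (monotone non-decreasing) dual objective `log det W`; convergence is
#' declared when the maximum change of the working covariance between
#' sweeps falls below `tol`.
#'
#' @param S symmetric positive (semi-)definite covariance matrix.
#' @param penalty scalar penalty, or symmetric nonnegative matrix of
#'   per-entry penalties with arbitrary (ignored) diagonal.
#' @param tol convergence tolerance on the successive-iterate max change.
#' @param max_iter maximum number of outer sweeps.
#' @return A list of class `glasso_fit`: `theta` (precision estimate), `w`
#'   (covariance estimate), `iterations`, `objective_trace`, `dual_gap`.
#' @export
graphical_lasso <- function(S, penalty, tol = 1e-6, max_iter = 500) {
  p <- nrow(S)
  stopifnot(is.matrix(S), ncol(S) == p, max(abs(S - t(S))) < 1e-8)
  if (length(penalty) == 1L) penalty <- matrix(penalty, p, p)
  stopifnot(dim(penalty) == dim(S), all(penalty >= 0),
            max(abs(penalty - t(penalty))) < 1e-12)
  diag(penalty) <- 0
  fit <- .glasso_cpp(S, penalty, tol, as.integer(max_iter))
  if (!fit$converged)
    stop(sprintf(
      "graphical lasso did not converge in %d iterations (duality gap %.3e)",
      max_iter, fit$dual_gap))
  dimnames(fit$theta) <- dimnames(S)
  class(fit) <- "glasso_fit"
  fit
}

#' Random-penalty scheme for the stability-selection ensemble
#'
#' Each ensemble member draws its own graphical-lasso penalty. Three kinds
#' are available:
#'
#' * `"scaled"` (the default): a single lambda drawn log-uniformly over
#'   `lambda_window * sqrt(log(p) / n)`, the universal graphical-lasso
#'   regularization scale. Anchoring the draw at the noise level — rather
#'   than at the largest covariance entry, which tracks the signal — keeps
#'   the selection frequency of noise edges well below the inclusion
#'   threshold while genuine conditional dependencies are selected in most
#'   ensemble members, regardless of how strong the strongest edge happens
#'   to be.
#' * `"scalar"`: a single lambda drawn log-uniformly between
#'   `lambda_min_ratio * lambda_max` and `lambda_max`, with `lambda_max`
#'   the largest off-diagonal |S| (the smallest penalty that empties the
#'   graph).
#' * `"entrywise"`: the `"scalar"` draw with every off-diagonal entry
#'   additionally multiplied by an independent uniform factor in
#'   `[perturbation_floor, 1]`, symmetrized (randomized-lasso style).
#'
#' @param kind `"scaled"`, `"scalar"` or `"entrywise"`.
#' @param lambda_window length-2 multiplier window for the `"scaled"` draw.
#' @param lambda_min_ratio lower bound of the `"scalar"`/`"entrywise"`
#'   draw, as a fraction of `lambda_max`.
#' @param perturbation_floor lower bound of the entrywise factors.
#' @return A list of class `penalty_scheme`.
#' @export
penalty_scheme <- function(kind = c("scaled", "scalar", "entrywise"),
                           lambda_window = c(1.5, 4),
                           lambda_min_ratio = 0.01,
                           perturbation_floor = 0.5) {
  kind <- match.arg(kind)
  stopifnot(lambda_min_ratio > 0, lambda_min_ratio < 1,
            perturbation_floor > 0, perturbation_floor <= 1,
            length(lambda_window) == 2, lambda_window[1] > 0,
            lambda_window[1] <= lambda_window[2])
  structure(list(kind = kind, lambda_window = lambda_window,
                 lambda_min_ratio = lambda_min_ratio,
                 perturbation_floor = perturbation_floor),
            class = "penalty_scheme")
}

#' Draw one random penalty matrix
#'
#' Uses the current RNG state; callers seed via their own entry points so
#' ensembles are reproducible.
#'
#' @param S covariance matrix (defines `lambda_max` for the
#'   signal-anchored kinds).
#' @param scheme a [penalty_scheme()].
#' @param n number of observations behind `S`; required for the
#'   `"scaled"` kind.
#' @return Symmetric nonnegative penalty matrix with zero diagonal.
#' @export
draw_penalty <- function(S, scheme = penalty_scheme(), n = NULL) {
  stopifnot(inherits(scheme, "penalty_scheme"))
  p <- nrow(S)
  if (scheme$kind == "scaled") {
    if (is.null(n)) stop("the scaled penalty kind needs the sample size n")
    lref <- sqrt(log(p) / n)
    u <- runif(1, log(scheme$lambda_window[1] * lref),
               log(scheme$lambda_window[2] * lref))
    P <- matrix(exp(u), p, p)
    diag(P) <- 0
    return(P)
  }
  off <- abs(S)
  diag(off) <- 0
  lambda_max <- max(off)
  if (lambda_max == 0) stop("diagonal covariance: lambda_max is zero")
  u <- runif(1, log(scheme$lambda_min_ratio * lambda_max), log(lambda_max))
  P <- matrix(exp(u), p, p)
  if (scheme$kind == "entrywise") {
    f <- matrix(runif(length(S), scheme$perturbation_floor, 1), p, p)
    f[lower.tri(f)] <- t(f)[lower.tri(f)]
    P <- P * f
  }
  diag(P) <- 0
  P
}
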