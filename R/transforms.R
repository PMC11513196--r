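#' Fit a Box-Cox normalizing transform to one variable
#'
#' Non-positive inputs are shifted by `1 - min(x)` so the minimum is exactly
#' 1; the exponent lambda is then chosen by maximizing the Box-Cox profile
#' log-likelihood over `[-5, 5]` (golden-section/parabolic search, tolerance
#' 1e-4). Skewness before and after the transform is recorded so downstream
#' screening can flag variables the transform could not normalize.
#'
#' @param x numeric vector with at least 10 finite values and nonzero
#'   variance.
#' @param name variable name stored in the record.
#' @return A list of class `boxcox_record`: `name`, `shift`, `lambda`,
#'   `pre_skewness`, `post_skewness`.
#' @export
boxcox_fit <- function(x, name = deparse(substitute(x))) {
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("need >= 10 finite values")
  if (sd(x) == 0) stop("constant vector")
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  xs <- x + shift
  n <- length(xs)
  lx <- log(xs)
  slx <- sum(lx)
  profile_ll <- function(lambda) {
    y <- if (abs(lambda) < 1e-12) lx else (xs^lambda - 1) / lambda
    -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * slx
  }
  lambda <- optimize(profile_ll, c(-5, 5), maximum = TRUE, tol = 1e-4)$maximum
  rec <- structure(list(name = name, shift = shift, lambda = lambda,
                        pre_skewness = sample_skewness(x),
                        post_skewness = NA_real_),
                   class = "boxcox_record")
  rec$post_skewness <- sample_skewness(boxcox_apply(x, rec))
  rec
}

#' Apply a fitted Box-Cox transform
#'
#' `y = ((x + shift)^lambda - 1) / lambda` for `lambda != 0`, `log(x +
#' shift)` for `lambda == 0`; strictly increasing in `x` either way.
#'
#' A transform fitted on training data can meet hold-out values below the
#' training minimum, where `x + shift` is no longer positive. By default
#' this is an error; with `clamp = TRUE` (used when applying a training
#' transform to a test split) such values are floored at a small positive
#' offset, i.e. mapped to just below the training minimum's image.
#'
#' @param x numeric vector.
#' @param record a [boxcox_fit()] result.
#' @param clamp floor out-of-range shifted values at `0.01` instead of
#'   erroring.
#' @return Transformed numeric vector.
#' @export
boxcox_apply <- function(x, record, clamp = FALSE) {
  stopifnot(inherits(record, "boxcox_record"))
  xs <- x + record$shift
  if (any(xs <= 0, na.rm = TRUE)) {
    if (!clamp)
      stop("shifted values must be strictly positive; refit the shift")
    xs <- pmax(xs, 0.01)
  }
  if (abs(record$lambda) < 1e-12) log(xs)
  else (xs^record$lambda - 1) / record$lambda
}

#' Drop variables that remain non-normal after transformation
#'
#' Variables whose post-transform absolute skewness exceeds `skew_limit`
#' cannot be made approximately Gaussian by a monotone power transform
#' (e.g. heavily zero-inflated scales) and are removed before network
#' estimation.
#'
#' @param table a [data_table()] (already transformed).
#' @param skew_limit absolute skewness threshold (default 2).
#' @return List with `kept` (filtered [data_table()]) and `dropped` (data
#'   frame: variable, skewness).
#' @export
normality_screen <- function(table, skew_limit = 2.0) {
  sk <- vapply(as.data.frame(table), sample_skewness, numeric(1))
  drop <- names(sk)[abs(sk) > skew_limit]
  kept <- select_roles(table, columns = setdiff(names(table), drop))
  list(kept = kept,
       dropped = data.frame(variable = drop, skewness = sk[drop],
                            row.names = NULL))
}

#' Standardize columns to mean 0, SD 1
#'
#' @param table a [data_table()].
#' @param params optional scaling from a previous call (training fit); when
#'   supplied, its centers/scales are applied unchanged — the hold-out
#'   convention.
#' @return A `data_table` with attribute `scaling` (list of `center`,
#'   `scale`).
#' @export
standardize <- function(table, params = NULL) {
  df <- as.data.frame(table)
  if (is.null(params)) {
    center <- vapply(df, mean, numeric(1))
    scale <- vapply(df, sd, numeric(1))
    zero <- names(scale)[scale == 0]
    if (length(zero))
      stop("zero-variance column(s): ", paste(zero, collapse = ", "))
  } else {
    stopifnot(all(names(df) %in% names(params$center)))
    center <- params$center[names(df)]
    scale <- params$scale[names(df)]
  }
  for (j in names(df)) df[[j]] <- (df[[j]] - center[j]) / scale[j]
  out <- data_table(df, table_roles(table), attr(table, "subject_ids"))
  attr(out, "scaling") <- list(center = center, scale = scale)
  out
}

#' Fit the full normalization pipeline on training data
#'
#' Fixed order: Box-Cox per column, non-normality screen, standardization.
#' The fitted transformer can be applied unchanged to a hold-out table, so
#' test data never influence the transform.
#'
#' @param table training [data_table()].
#' @param skew_limit passed to [normality_screen()].
#' @return A list of class `transformer`: `records` (per-variable
#'   [boxcox_fit()] records), `dropped`, `scaling`, plus `$table`, the
#'   transformed training table.
#' @export
fit_transforms <- function(table, skew_limit = 2.0) {
  df <- as.data.frame(table)
  records <- lapply(names(df), function(cl) boxcox_fit(df[[cl]], name = cl))
  names(records) <- names(df)
  for (cl in names(df)) df[[cl]] <- boxcox_apply(df[[cl]], records[[cl]])
  tab <- data_table(df, table_roles(table), attr(table, "subject_ids"))
  scr <- normality_screen(tab, skew_limit)
  std <- standardize(scr$kept)
  structure(list(records = records, dropped = scr$dropped,
                 scaling = attr(std, "scaling"), skew_limit = skew_limit,
                 table = std),
            class = "transformer")
}

#' Apply a fitted transformer to new data
#'
#' @param transformer a [fit_transforms()] result.
#' @param table a [data_table()] with (at least) the training columns.
#' @return The transformed, screened, standardized `data_table`.
#' @export
apply_transforms <- function(transformer, table) {
  stopifnot(inherits(transformer, "transformer"))
  keep <- names(transformer$scaling$center)
  missing <- setdiff(keep, names(table))
  if (length(missing))
    stop("test table lacks column(s): ", paste(missing, collapse = ", "))
  tab <- select_roles(table, columns = keep)
  df <- as.data.frame(tab)
  for (cl in keep) df[[cl]] <- boxcox_apply(df[[cl]],
                                            transformer$records[[cl]],
                                            clamp = TRUE)
  tab <- data_table(df, table_roles(tab), attr(tab, "subject_ids"))
  standardize(tab, params = transformer$scaling)
}

#' Serialize / restore a fitted transformer as JSON
#'
#' @param transformer a [fit_transforms()] result.
#' @param path JSON file path.
#' @return `transformer_to_json` returns `path` invisibly;
#'   `transformer_from_json` returns a `transformer` (without the training
#'   table).
#' @export
transformer_to_json <- function(transformer, path) {
  obj <- list(
    records = lapply(transformer$records, function(r)
      r[c("name", "shift", "lambda", "pre_skewness", "post_skewness")]),
    dropped = transformer$dropped,
    scaling = lapply(transformer$scaling, as.list),
    skew_limit = transformer$skew_limit)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname transformer_to_json
#' @export
transformer_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  records <- lapply(obj$records, function(r)
    structure(lapply(r, function(v) if (is.null(v)) NA_real_ else v),
              class = "boxcox_record"))
  names(records) <- vapply(records, `[[`, character(1), "name")
  dropped <- if (length(obj$dropped))
    do.call(rbind, lapply(obj$dropped, as.data.frame))
  else data.frame(variable = character(), skewness = numeric())
  structure(list(records = records, dropped = dropped,
                 scaling = list(center = unlist(obj$scaling$center),
                                scale = unlist(obj$scaling$scale)),
                 skew_limit = obj$skew_limit, table = NULL),
            class = "transformer")
}
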