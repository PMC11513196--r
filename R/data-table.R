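#' Subjects-by-variables table with variable roles
#'
#' A `data_table` is a plain data frame of numeric columns plus a role label
#' per variable. Roles drive which columns enter each network recipe:
#' `"trait"` for questionnaire scores, `"erp_amplitude"` for component
#' amplitudes (e.g. ERN, CRN), `"erp_latency"` for component latencies, and
#' `"covariate"` for demographics and task performance.
#'
#' @param x data frame (or coercible) of numeric columns; row order is the
#'   subject order.
#' @param roles named character vector mapping every column to one of
#'   `"trait"`, `"erp_amplitude"`, `"erp_latency"`, `"covariate"`.
#' @param subject_ids optional character vector of subject identifiers;
#'   defaults to `"s1" ... "sn"`.
#' @return A data frame of class `data_table` with attributes `roles` and
#'   `subject_ids`.
#' @export
data_table <- function(x, roles, subject_ids = NULL) {
  x <- as.data.frame(x)
  if (anyDuplicated(names(x)))
    stop("duplicate column names: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  bad <- names(x)[!vapply(x, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric columns: ", paste(bad, collapse = ", "))
  roles <- validate_roles(roles, names(x))
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(nrow(x)))
  stopifnot(length(subject_ids) == nrow(x))
  structure(x, roles = roles, subject_ids = as.character(subject_ids),
            class = c("data_table", "data.frame"))
}

validate_roles <- function(roles, cols) {
  allowed <- c("trait", "erp_amplitude", "erp_latency", "covariate")
  if (is.null(names(roles)) || any(names(roles) == ""))
    stop("roles must be a fully named character vector")
  missing <- setdiff(cols, names(roles))
  if (length(missing))
    stop("missing role for column(s): ", paste(missing, collapse = ", "))
  roles <- roles[cols]
  bad <- setdiff(unique(roles), allowed)
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  roles
}

#' @export
print.data_table <- function(x, ...) {
  cat(sprintf("<data_table> %d subjects x %d variables\n", nrow(x), ncol(x)))
  cat("roles:", paste(sprintf("%s=%d", names(table(attr(x, "roles"))),
                              table(attr(x, "roles"))), collapse = " "), "\n")
  NextMethod()
}

table_roles <- function(x) attr(x, "roles")

#' Select columns of a data table by role
#'
#' @param x a [data_table()].
#' @param roles character vector of roles to keep.
#' @param columns optional explicit column names (applied after the role
#'   filter if both are given).
#' @return A `data_table` restricted to the requested variables.
#' @export
select_roles <- function(x, roles = NULL, columns = NULL) {
  keep <- names(x)
  if (!is.null(roles)) keep <- keep[table_roles(x)[keep] %in% roles]
  if (!is.null(columns)) {
    missing <- setdiff(columns, names(x))
    if (length(missing))
      stop("unknown column(s): ", paste(missing, collapse = ", "))
    keep <- intersect(keep, columns)
  }
  data_table(as.data.frame(x)[keep], table_roles(x)[keep],
             attr(x, "subject_ids"))
}

#' Read and write a data table as CSV plus a JSON role map
#'
#' The table is stored as a plain CSV with a header row; the roles travel in
#' a sidecar JSON file (`<path>.roles.json` by default) so the pair
#' round-trips through any CSV-aware tool.
#'
#' @param x a [data_table()].
#' @param path CSV file path.
#' @param roles_path path for the role map; default derived from `path`.
#' @return `write_data_table` returns `path` invisibly; `read_data_table`
#'   returns a [data_table()].
#' @export
write_data_table <- function(x, path, roles_path = paste0(path, ".roles.json")) {
  df <- cbind(subject_id = attr(x, "subject_ids"), as.data.frame(x))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(as.list(table_roles(x)), roles_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_data_table
#' @export
read_data_table <- function(path, roles_path = paste0(path, ".roles.json")) {
  df <- read.csv(path, check.names = FALSE)
  ids <- NULL
  if ("subject_id" %in% names(df)) {
    ids <- as.character(df$subject_id)
    df$subject_id <- NULL
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]]))
      stop(sprintf("non-numeric cells in column '%s'", names(df)[j]))
  }
  roles <- unlist(jsonlite::read_json(roles_path))
  data_table(df, roles, ids)
}

as_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x))
  storage.mode(m) <- "double"
  m
}
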