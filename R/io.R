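#' Declare the layout of a delimited DIF dataset
#'
#' @param items ordered item column names.
#' @param cluster cluster-id column name (optional: `NULL` for single-level
#'   data).
#' @param groups named character vector mapping group column names to their
#'   level, e.g. `c(gender = "within", school_type = "between")`.
#' @param n_categories number of ordered categories K (responses coded
#'   `0..K-1`).
#' @param reverse_coded item columns to recode as `K-1 - y` on read (for
#'   instruments scored so that higher raw codes mean more problems while the
#'   analysis scale wants higher = better, or vice versa).
#' @return a `dataset_schema` list.
#' @export
dataset_schema <- function(items, cluster = NULL, groups = character(),
                           n_categories = 5L, reverse_coded = character()) {
  if (length(items) < 1L) stop("'items' must name at least one column")
  if (length(groups) && (is.null(names(groups)) || any(names(groups) == "")))
    stop("'groups' must be a named vector: c(column = \"within|between\")")
  if (length(groups) && !all(groups %in% c("within", "between")))
    stop("group levels must be \"within\" or \"between\"")
  if (!all(reverse_coded %in% items))
    stop("'reverse_coded' must be a subset of 'items'")
  structure(list(items = items, cluster = cluster, groups = groups,
                 n_categories = as.integer(n_categories),
                 reverse_coded = reverse_coded),
            class = "dataset_schema")
}

#' Read and validate a delimited DIF dataset
#'
#' Reads a CSV/TSV file (delimiter chosen by extension, overridable), checks
#' it against a [dataset_schema()], recodes reverse-coded items, drops rows
#' with missing values in the declared columns (listwise deletion, count
#' messaged), and returns a `dif_data` data frame usable by [dif_scan()],
#' [olr_dif_test()], [holr_dif_test()] and [screen_clustering()].
#'
#' Validation errors name the offending column and row: missing columns,
#' non-integer or out-of-range category codes, and between-level group
#' columns that vary within a cluster are all rejected.
#'
#' @param path file path.
#' @param schema a [dataset_schema()].
#' @param sep field delimiter; default `","` unless the extension is
#'   `.tsv`/`.txt` (then tab).
#' @return a `dif_data` data frame (attributes `items`, `n_categories`,
#'   `groups`).
#' @export
read_dataset <- function(path, schema, sep = NULL) {
  stopifnot(inherits(schema, "dataset_schema"))
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path)
  need <- c(schema$items, schema$cluster, names(schema$groups))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))

  keep <- stats::complete.cases(df[need])
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped for missing values (listwise)")
    df <- df[keep, , drop = FALSE]
    if (nrow(df) == 0L) stop("all rows dropped: no complete cases")
  }

  K <- schema$n_categories
  for (it in schema$items) {
    v <- df[[it]]
    if (!is.numeric(v) || any(v != floor(v)))
      stop("item column '", it, "' is not integer-coded")
    bad <- which(v < 0 | v > K - 1L)
    if (length(bad))
      stop(sprintf("item column '%s', row %d: category value %s outside 0..%d",
                   it, bad[1], format(v[bad[1]]), K - 1L))
  }
  for (it in schema$reverse_coded) df[[it]] <- (K - 1L) - df[[it]]

  for (gcol in names(schema$groups)) {
    gv <- df[[gcol]]
    if (length(unique(gv)) != 2L)
      stop("group column '", gcol, "' is not dichotomous")
    if (schema$groups[[gcol]] == "between") {
      if (is.null(schema$cluster))
        stop("between-level group '", gcol, "' requires a cluster column")
      nuniq <- tapply(gv, df[[schema$cluster]],
                      function(v) length(unique(v)))
      if (any(nuniq > 1L))
        stop("group column '", gcol, "' varies within cluster ",
             names(nuniq)[which(nuniq > 1L)[1]],
             " but is declared between-level")
    }
  }

  structure(df, items = schema$items,
            n_categories = K, groups = schema$groups,
            class = c("dif_data", "data.frame"))
}

#' Write DIF or simulation results
#'
#' Writes a [dif_scan()] table (item, group coefficient, chi-square, p-value
#' layout) or a [run_cell()]/[run_design()] table to CSV (floats at 6
#' significant digits, rows ordered by item index then method) or JSON (full
#' precision plus metadata).
#'
#' @param results a `dif_scan` or `cell_result` data frame.
#' @param path output file.
#' @param format `"csv"` or `"json"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  df <- as.data.frame(results)
  if ("item" %in% names(df)) {
    idx <- suppressWarnings(as.integer(sub("^\\D*", "", df$item)))
    ord <- order(if (anyNA(idx)) match(df$item, unique(df$item)) else idx,
                 if ("method" %in% names(df)) df$method else seq_len(nrow(df)))
    df <- df[ord, , drop = FALSE]
  }
  if (format == "csv") {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a results file written by [write_results()]
#' @param path file path.
#' @param format `"csv"` or `"json"` (default from extension).
#' @return data frame.
#' @export
read_results <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
  else as.data.frame(jsonlite::fromJSON(path))
}

#' Write a simulated dataset with its generating truth
#'
#' Long-format CSV (`person_id`, `cluster_id`, `group`, items) plus a JSON
#' sidecar (`<path>.truth.json`) recording the item bank, ICC, DIF
#' specification and grouping level, so a simulation is fully reconstructible.
#'
#' @param data a `dif_data` object from [simulate_dif_data()] /
#'   [generate_responses()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  bank <- attr(data, "bank")
  truth <- list(level = attr(data, "level"),
                n_categories = attr(data, "n_categories"),
                items = attr(data, "items"))
  if (!is.null(bank))
    truth <- c(truth, list(
      discrimination = bank$discrimination,
      thresholds = apply(bank$thresholds, 1, identity, simplify = FALSE),
      studied_item = bank$studied_item,
      dif_magnitude = bank$dif_magnitude,
      dif_target = bank$dif_target))
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
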