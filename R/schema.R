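## Data model: indicator schemas and validated indicator tables.

.vartypes <- c("continuous", "count", "ordinal", "binary")
.families <- c("gamma", "gaussian", "poisson", "negbin", "pig", "bernoulli",
               "saturated_categorical")

## family -> admissible vartypes
.family_vartype <- list(
  bernoulli             = "binary",
  poisson               = "count",
  negbin                = "count",
  pig                   = "count",
  gamma                 = c("ordinal", "continuous"),
  gaussian              = c("count", "ordinal", "continuous"),
  saturated_categorical = c("ordinal", "binary")
)

#' Declare one severity indicator
#'
#' An indicator is a column of the subject-by-indicator table: its name, its
#' measurement type, the parametric family used for every conditional
#' regression in which it is the target, and (for ordinal/categorical
#' indicators) its number of levels. All indicators must be coded so that
#' higher values mean more of the measured construct (severity); this
#' unidirectional coding is what lets the joint-density value act as an
#' index, and it is the only admitted direction.
#'
#' @param name Column name, unique within a schema.
#' @param vartype One of `"continuous"`, `"count"`, `"ordinal"`, `"binary"`.
#' @param family Conditional-model family: `"gamma"`, `"gaussian"`,
#'   `"poisson"`, `"negbin"`, `"pig"` (Poisson-inverse-Gaussian),
#'   `"bernoulli"`, or `"saturated_categorical"`. Must be compatible with
#'   `vartype` (e.g. `bernoulli` only for binary; count families only for
#'   counts; `saturated_categorical` only for discrete columns with at most
#'   12 levels).
#' @param levels Number of levels K for ordinal columns (values `0..K-1`);
#'   ignored otherwise (binary implies 2).
#' @param direction Coding direction; only `+1` (higher = more severe) is
#'   admitted.
#' @return An object of class `"indicator_schema"`.
#' @examples
#' indicator_schema("pain_mood", "ordinal", "gamma", levels = 11)
#' @export
indicator_schema <- function(name, vartype, family, levels = NULL, direction = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  vartype <- match.arg(vartype, .vartypes)
  family <- match.arg(family, .families)
  if (!vartype %in% .family_vartype[[family]])
    stop_domain("family '%s' is incompatible with vartype '%s' (indicator '%s')",
                family, vartype, name)
  if (vartype == "binary") levels <- 2L
  if (vartype == "ordinal") {
    if (is.null(levels)) stop_domain("ordinal indicator '%s' needs 'levels'", name)
    levels <- as.integer(levels)
    if (levels < 2L) stop_domain("ordinal indicator '%s': levels must be >= 2", name)
  }
  if (family == "saturated_categorical" && (is.null(levels) || levels > 12L))
    stop_domain("saturated_categorical requires a discrete indicator with K <= 12 ('%s')", name)
  if (!identical(as.numeric(direction), 1))
    stop_domain("indicator '%s': direction must be +1 (recode so higher = more severe)", name)
  structure(list(name = name, vartype = vartype, family = family,
                 levels = levels, direction = 1),
            class = "indicator_schema")
}

#' Bundle indicator declarations into a schema
#'
#' @param ... `indicator_schema` objects (or a single list of them).
#' @return Object of class `"jpd_schema"`: a named list of indicator schemas.
#' @export
jpd_schema <- function(...) {
  items <- list(...)
  if (length(items) == 1L && is.list(items[[1]]) &&
      !inherits(items[[1]], "indicator_schema")) items <- items[[1]]
  if (!length(items)) stop_domain("schema must contain at least one indicator")
  ok <- vapply(items, inherits, logical(1), "indicator_schema")
  if (!all(ok)) stop_domain("all schema entries must be indicator_schema objects")
  nms <- vapply(items, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_domain("indicator names must be unique")
  names(items) <- nms
  structure(items, class = "jpd_schema")
}

#' @export
print.jpd_schema <- function(x, ...) {
  cat("Indicator schema (", length(x), " indicators)\n", sep = "")
  for (s in x)
    cat(sprintf("  %-16s %-10s family=%-22s%s\n", s$name, s$vartype, s$family,
                if (!is.null(s$levels)) paste0(" K=", s$levels) else ""))
  invisible(x)
}

#' Read a schema from a JSON or YAML file
#'
#' The file holds a list of indicator entries with keys `name`, `vartype`,
#' `family` and optionally `levels`.
#'
#' @param path File path; format inferred from the extension
#'   (`.json` vs `.yml`/`.yaml`).
#' @return A `jpd_schema`.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop_domain("schema file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_domain("YAML schema files need the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  jpd_schema(lapply(raw, function(e)
    indicator_schema(e$name, e$vartype, e$family, levels = e$levels %||% NULL)))
}

## Validate one column against its schema entry; returns character(0) or messages.
.validate_column <- function(x, sch) {
  bad <- character(0)
  rows <- function(w) paste(utils::head(which(w), 5), collapse = ", ")
  if (sch$vartype == "binary" && any(!x %in% c(0, 1)))
    bad <- c(bad, sprintf("column '%s': binary values must be 0/1 (rows %s)",
                          sch$name, rows(!x %in% c(0, 1))))
  if (sch$vartype == "count") {
    w <- x < 0 | x != floor(x)
    if (any(w)) bad <- c(bad, sprintf(
      "column '%s': counts must be non-negative integers (rows %s)", sch$name, rows(w)))
  }
  if (sch$vartype == "ordinal") {
    w <- x < 0 | x > sch$levels - 1 | x != floor(x)
    if (any(w)) bad <- c(bad, sprintf(
      "column '%s': ordinal values must lie in 0..%d (rows %s)",
      sch$name, sch$levels - 1L, rows(w)))
  }
  bad
}

#' Construct a validated subject-by-indicator table
#'
#' @param data A data frame or matrix whose columns match the schema names
#'   (order taken from the schema).
#' @param schema A `jpd_schema`.
#' @param subject_ids Optional subject labels (default `1..n` as character).
#' @return Object of class `"indicator_table"`: a numeric matrix with
#'   attributes `schema` and `subject_ids`. No missing values are allowed;
#'   use [load_indicator_table()] for complete-case filtering at load time.
#' @export
indicator_table <- function(data, schema, subject_ids = NULL) {
  stopifnot(inherits(schema, "jpd_schema"))
  data <- as.data.frame(data)
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols))
    stop_domain("schema error: columns absent from data: %s",
                paste(missing_cols, collapse = ", "))
  m <- as.matrix(data[names(schema)])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_domain("indicator table contains missing values")
  msgs <- unlist(lapply(names(schema), function(nm) .validate_column(m[, nm], schema[[nm]])))
  if (length(msgs)) stop_domain("validation error: %s", paste(msgs, collapse = "; "))
  ids <- as.character(subject_ids %||% seq_len(nrow(m)))
  if (length(ids) != nrow(m)) stop_domain("subject_ids length must equal row count")
  structure(m, schema = schema, subject_ids = ids, class = c("indicator_table", "matrix"))
}

#' @export
print.indicator_table <- function(x, ...) {
  cat("Indicator table: ", nrow(x), " subjects x ", ncol(x), " indicators\n", sep = "")
  print(utils::head(unclass(x)[, , drop = FALSE]), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Load an indicator table from CSV
#'
#' Reads an RFC-4180 CSV with a header row, checks the header against the
#' schema, optionally drops rows with any missing indicator (complete-case
#' rule), and validates value ranges per column type.
#'
#' @param path CSV file path.
#' @param schema A `jpd_schema`; every schema name must appear in the header.
#' @param drop_incomplete Drop rows containing missing values (default
#'   `TRUE`); the number removed is logged. With `FALSE`, any missing value
#'   is an error.
#' @param id_col Optional name of a subject-id column in the file.
#' @return An `indicator_table`.
#' @export
load_indicator_table <- function(path, schema, drop_incomplete = TRUE, id_col = NULL) {
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols))
    stop_domain("schema error: header lacks declared column(s): %s",
                paste(missing_cols, collapse = ", "))
  ids <- if (!is.null(id_col) && id_col %in% names(df)) as.character(df[[id_col]])
         else as.character(seq_len(nrow(df)))
  vals <- df[names(schema)]
  keep <- stats::complete.cases(vals)
  if (!all(keep)) {
    if (!drop_incomplete)
      stop_domain("validation error: %d row(s) with missing values (drop_incomplete = FALSE)",
                  sum(!keep))
    log_msg("%d row%s excluded (incomplete indicator data); %d retained",
            sum(!keep), if (sum(!keep) == 1) "" else "s", sum(keep))
  }
  indicator_table(vals[keep, , drop = FALSE], schema, subject_ids = ids[keep])
}

#' Write per-subject scores to CSV
#'
#' Columns: `subject_id`, `log_jpd`, `between_spec_sd`, plus `bootstrap_se`
#' and `rescaled` when present in the score object.
#'
#' @param scores A `jpd_scores` object (see [score_jpd()]).
#' @param path Output CSV path.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "jpd_scores"))
  if (!length(scores$log_jpd)) stop_domain("empty scores: nothing to write")
  df <- data.frame(subject_id = scores$subject_ids,
                   log_jpd = scores$log_jpd,
                   between_spec_sd = scores$between_spec_sd)
  if (!is.null(scores$bootstrap_se)) df$bootstrap_se <- scores$bootstrap_se
  if (!is.null(scores$rescaled)) df$rescaled <- scores$rescaled
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a score CSV written by [write_scores()]
#'
#' @param path CSV path.
#' @return A data frame with numeric score columns.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  for (nm in setdiff(names(df), "subject_id")) df[[nm]] <- as.numeric(df[[nm]])
  df$subject_id <- as.character(df$subject_id)
  df
}
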