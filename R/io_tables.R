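#' Feature table I/O
#'
#' A feature table is a plain `data.frame` with a character `subject_id` key,
#' numeric feature columns, and a small set of categorical covariate columns
#' (by default `batch`, `split`, `label`). Feature and covariate columns are
#' distinguished by the declared covariate list, not by name prefix.
#'
#' `write_feature_table()` serializes numeric cells with 17 significant
#' digits so that doubles round-trip exactly through CSV.
#'
#' @param path CSV path (comma separator, `.` decimal, header required).
#' @param covariates names of non-feature columns (besides `subject_id`);
#'   covariates present in the file are kept as-is, absent ones are ignored.
#' @return `read_feature_table()`: a validated `data.frame`.
#' @export
read_feature_table <- function(path, covariates = c("batch", "split", "label")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = NA)
  validate_feature_table(df, covariates)
}

#' @rdname read_feature_table
#' @param table a feature table `data.frame`.
#' @export
write_feature_table <- function(table, path,
                                covariates = c("batch", "split", "label")) {
  table <- validate_feature_table(table, covariates)
  out <- table
  feat <- feature_columns(table, covariates)
  for (f in feat) out[[f]] <- sprintf("%.17g", table[[f]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_feature_table <- function(df, covariates = c("batch", "split", "label")) {
  if (!"subject_id" %in% names(df))
    stop("feature table lacks a subject_id column", call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "),
         call. = FALSE)
  feat <- feature_columns(df, covariates)
  for (f in feat) {
    v <- df[[f]]
    if (!is.numeric(v))
      stop("non-numeric feature column: ", f, call. = FALSE)
    if (anyNA(v))
      stop("missing values in feature column: ", f, call. = FALSE)
  }
  df
}

feature_columns <- function(df, covariates = c("batch", "split", "label")) {
  setdiff(names(df), c("subject_id", covariates))
}
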