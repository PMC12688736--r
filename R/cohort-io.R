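# Cohort CSV schema: patient_id, age, sex, then pre_<marker>/post_<marker>
# for the 10 candidate markers (in canonical marker order), then trg.
# Leading '#' lines carry provenance metadata and are ignored on read.
# Doubles are written with 17 significant digits so that a write/read
# round-trip is value-exact.

.cohort_columns <- function() {
  c("patient_id", "age", "sex",
    as.vector(rbind(paste0("pre_", marker_names()),
                    paste0("post_", marker_names()))),
    "trg")
}

#' Write a cohort to CSV
#'
#' Writes the canonical cohort schema with a commented metadata header
#' (package version, timestamp-free audit fields passed via `metadata`).
#' Numeric columns are serialized with 17 significant digits, making
#' [read_cohort()] a lossless inverse.
#'
#' @param cohort a `cohort_table`.
#' @param path output file path.
#' @param metadata optional named list written as `# key: value` header
#'   lines (e.g. the resolved generator config and seed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, metadata = NULL) {
  cols <- .cohort_columns()
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(cohort)[, cols]
  ser <- df
  for (cn in cols) {
    if (is.double(df[[cn]])) ser[[cn]] <- formatC(df[[cn]], digits = 17, format = "g")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (key in names(metadata))
    writeLines(sprintf("# %s: %s", key,
                       paste(format(metadata[[key]]), collapse = " ")), con)
  utils::write.csv(ser, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Parses and validates the canonical cohort schema.  Schema violations
#' (missing columns, out-of-range TRG, categorical values outside their
#' level sets, non-finite continuous values) raise errors naming the
#' offending column and row numbers.
#'
#' @param path CSV file written by [write_cohort()] (or following the same
#'   schema).
#' @return a `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    stop("empty cohort file: ", path)
  cols <- .cohort_columns()
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), cols)
  if (length(extra))
    stop("unknown marker column(s): ", paste(extra, collapse = ", "))
  df <- df[, cols]
  bad_trg <- which(!(df$trg %in% 0:3))
  if (length(bad_trg))
    stop("out-of-range trg at row(s): ", paste(bad_trg, collapse = ", "))
  for (mk in marker_names("continuous")) {
    for (side in c("pre_", "post_")) {
      cn <- paste0(side, mk)
      bad <- which(!is.finite(df[[cn]]))
      if (length(bad))
        stop("non-finite values in ", cn, " at row(s): ",
             paste(bad, collapse = ", "))
    }
  }
  for (mk in names(.CAT_LEVELS)) {
    for (side in c("pre_", "post_")) {
      cn <- paste0(side, mk)
      bad <- which(!(df[[cn]] %in% .CAT_LEVELS[[mk]]))
      if (length(bad))
        stop("value outside level set in ", cn, " at row(s): ",
             paste(bad, collapse = ", "))
      df[[cn]] <- as.integer(df[[cn]])
    }
  }
  df$trg <- as.integer(df$trg)
  class(df) <- c("cohort_table", "data.frame")
  df
}

# numeric baseline feature matrix for model features `subset` (indices 1-7)
.feature_matrix <- function(cohort, subset) {
  nm <- .feature_name(subset)
  X <- as.matrix(as.data.frame(cohort)[, paste0("pre_", nm), drop = FALSE])
  colnames(X) <- nm
  storage.mode(X) <- "double"
  X
}
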