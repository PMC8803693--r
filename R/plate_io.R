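#' Read a long-format plate-reader table
#'
#' Reads a delimited text file (CSV or TSV, autodetected by extension) of
#' well-level optical-density readings with full sample provenance. Required
#' columns: `sample_id`, `reactor_id`, `treatment`, `day`, `matrix`,
#' `substrate`, `replicate`, `time_h`, `od590`. Optional: `od750` (read and
#' retained but never used in any computation -- all analysis is on the
#' 590 nm signal), `storage_flag`, `aeration_at_sampling`.
#'
#' Every substrate name must resolve against the catalog or equal the
#' reserved blank token `"BLANK"`; unresolved names abort with near-match
#' suggestions. Malformed rows (non-numeric OD, negative time, replicate
#' outside 1..3) abort with a line-numbered report.
#'
#' @param path Path to the file.
#' @param catalog Substrate catalog, default [default_catalog()].
#' @return A data frame of well readings (one row per well x time point),
#'   with `treatment` and `matrix` as factors.
#' @export
read_plate_table <- function(path, catalog = default_catalog()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = TRUE, fileEncoding = "UTF-8")
  validate_plate_table(df, catalog)
}

#' Validate an in-memory plate table
#'
#' Applies the same column, type, range and catalog checks as
#' [read_plate_table()] to a data frame already in memory.
#'
#' @inheritParams read_plate_table
#' @param df Data frame of readings.
#' @return The validated (type-coerced) data frame.
#' @export
validate_plate_table <- function(df, catalog = default_catalog()) {
  required <- c("sample_id", "reactor_id", "treatment", "day", "matrix",
                "substrate", "replicate", "time_h", "od590")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- c("reactor_id", "day", "replicate", "time_h", "od590")
  if ("od750" %in% names(df)) num_cols <- c(num_cols, "od750")
  bad_rows <- integer(0)
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad_rows <- union(bad_rows, which(is.na(v) & !is.na(df[[cc]])))
    df[[cc]] <- v
  }
  bad_rows <- sort(union(bad_rows, which(df$time_h < 0 | df$day < 0 |
                                           !(df$replicate %in% 1:3))))
  if (length(bad_rows) > 0L) {
    stop("malformed row(s) at line(s) ",
         paste(utils::head(bad_rows + 1L, 10L), collapse = ", "),
         " (line numbers include the header)", call. = FALSE)
  }
  treatments <- c("aerobic", "mixed", "anaerobic")
  if (!all(df$treatment %in% treatments)) {
    stop("treatment must be one of: ", paste(treatments, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$matrix %in% c("solid", "leachate"))) {
    stop("matrix must be 'solid' or 'leachate'", call. = FALSE)
  }
  non_blank <- setdiff(unique(df$substrate), BLANK)
  unresolved <- setdiff(non_blank, catalog$substrate)
  if (length(unresolved) > 0L) {
    stop(unknown_substrate_message(unresolved, catalog), call. = FALSE)
  }
  # at most 3 replicates per (sample, substrate, time)
  key <- paste(df$sample_id, df$substrate, df$time_h, sep = "\r")
  if (any(table(key) > 3L)) {
    stop("more than 3 replicates for some (sample, substrate, time) triple",
         call. = FALSE)
  }
  df$treatment <- factor(df$treatment, levels = treatments)
  df$matrix <- factor(df$matrix, levels = c("solid", "leachate"))
  df
}

#' Write pipeline result tables as delimited text
#'
#' Writes the standard result tables of a pipeline run as CSV files with a
#' `# schema:` comment header and deterministic column order. Numeric
#' columns are serialized at full double precision (17 significant digits)
#' so that a read/write round trip is lossless.
#'
#' @param tables Named list of data frames, e.g. the `tables` element of a
#'   [run_pipeline()] result. Recognised names map to the canonical file
#'   names (`auc_per_substrate.csv`, `group_activity.csv`,
#'   `scaled_activity.csv`, `normalized.csv`, `success_table.csv`); other
#'   names are written as `<name>.csv`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  }
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    write_table_fp(tables[[nm]], f)
    files <- c(files, f)
  }
  invisible(files)
}

# CSV writer with schema comment and full-precision numerics.
write_table_fp <- function(df, path) {
  stopifnot(is.data.frame(df))
  types <- vapply(df, function(x) class(x)[1], character(1))
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
      out[[j]][is.na(df[[j]])] <- NA
    } else if (is.factor(out[[j]])) {
      out[[j]] <- as.character(out[[j]])
    }
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# schema: ",
                    paste(names(df), types, sep = ":", collapse = ",")), con)
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to a CSV written by this package.
#' @return Data frame with column types restored from the schema header.
#' @export
read_result_table <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (grepl("^# schema: ", first)) {
    schema <- strsplit(sub("^# schema: ", "", first), ",", fixed = TRUE)[[1]]
    for (item in schema) {
      kv <- strsplit(item, ":", fixed = TRUE)[[1]]
      if (kv[1] %in% names(df)) {
        df[[kv[1]]] <- switch(kv[2],
          numeric = as.numeric(df[[kv[1]]]),
          integer = as.integer(df[[kv[1]]]),
          logical = as.logical(df[[kv[1]]]),
          factor = factor(df[[kv[1]]]),
          as.character(df[[kv[1]]])
        )
      }
    }
  }
  df
}
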