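#' Subtract the plate blank from every well
#'
#' For each (sample, time point), the mean optical density of that sample's
#' blank replicates is subtracted from every non-blank well read at the same
#' time. Blank rows are dropped from the output. Blanks are never
#' interpolated: a time point with wells but no blank replicate for the same
#' sample is a hard error.
#'
#' @param readings Validated plate table (see [read_plate_table()]).
#' @return The table restricted to non-blank wells with `od590` corrected.
#' @export
subtract_blank <- function(readings) {
  is_blank <- readings$substrate == BLANK
  blanks <- readings[is_blank, , drop = FALSE]
  wells <- readings[!is_blank, , drop = FALSE]
  key <- function(d) paste(d$sample_id, d$time_h, sep = "\r")
  blank_mean <- tapply(blanks$od590, key(blanks), mean)
  idx <- match(key(wells), names(blank_mean))
  if (anyNA(idx)) {
    miss <- unique(wells[is.na(idx), c("sample_id", "time_h")])
    stop("no blank replicate for sample/time: ",
         paste(miss$sample_id, miss$time_h, sep = "@", collapse = ", "),
         call. = FALSE)
  }
  wells$od590 <- wells$od590 - as.numeric(blank_mean[idx])
  wells
}

#' Set negative blank-corrected values to zero
#'
#' Optical density cannot be negative; values pushed below zero by blank
#' subtraction are replaced by exactly 0. The number of clipped values is
#' attached as attribute `n_clipped`.
#'
#' @param readings Blank-corrected plate table.
#' @return Same table with `od590 >= 0` everywhere.
#' @export
clip_negatives <- function(readings) {
  neg <- readings$od590 < 0
  readings$od590[neg] <- 0
  attr(readings, "n_clipped") <- sum(neg)
  readings
}

#' Average technical replicates into kinetic curves
#'
#' Averages the (up to three) technical replicates of each well at each time
#' point, yielding one blank-corrected kinetic curve per (sample, substrate).
#' The processing order is fixed: subtract blank, clip negatives, then
#' average.
#'
#' @param readings Clipped, blank-corrected plate table.
#' @return Long data frame with one row per (sample, substrate, time):
#'   columns `sample_id`, `reactor_id`, `treatment`, `day`, `matrix`,
#'   `aeration_at_sampling` (if present), `substrate`, `time_h`, `od`,
#'   `n_replicates_used`, `imputed` (FALSE here).
#' @export
average_replicates <- function(readings) {
  meta_cols <- intersect(
    c("sample_id", "reactor_id", "treatment", "day", "matrix",
      "aeration_at_sampling", "storage_flag"),
    names(readings)
  )
  key <- paste(readings$sample_id, readings$substrate, readings$time_h,
               sep = "\r")
  first <- !duplicated(key)
  out <- readings[first, c(meta_cols, "substrate", "time_h"), drop = FALSE]
  out$od <- as.numeric(tapply(readings$od590, key, mean)[key[first]])
  out$n_replicates_used <-
    as.integer(tapply(readings$od590, key, length)[key[first]])
  out$imputed <- FALSE
  rownames(out) <- NULL
  out <- out[order(out$sample_id, out$substrate, out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Impute a missing replicate reactor from the other reactors of its cell
#'
#' When one reactor of a treatment x day x matrix cell has no plate data but
#' at least two sibling reactors do, a synthetic sample is created whose
#' curve values are, per substrate and time point, the element-wise mean of
#' the siblings' values. Imputed rows carry `imputed = TRUE` and that flag
#' propagates through all downstream tables. Leachate samples are never
#' imputed: a missing leachate sample simply remains excluded.
#'
#' @param curves Curve table from [average_replicates()].
#' @param design Expected design table, default [experiment_design()]
#'   restricted to the days present in `curves`.
#' @return `curves` with imputed samples appended; attribute `missing`
#'   records cells that could not be imputed.
#' @export
impute_missing_sample <- function(curves, design = NULL) {
  if (is.null(design)) {
    design <- experiment_design()
    design <- design[design$day %in% unique(curves$day) &
                       design$matrix %in% unique(as.character(curves$matrix)), ,
                     drop = FALSE]
  }
  have <- unique(curves[, c("reactor_id", "treatment", "day", "matrix")])
  key <- function(d) paste(d$reactor_id, d$treatment, d$day, d$matrix,
                           sep = "\r")
  missing <- design[!(key(design) %in% key(have)), , drop = FALSE]
  not_imputed <- missing[0, , drop = FALSE]
  for (i in seq_len(nrow(missing))) {
    m <- missing[i, ]
    if (m$matrix != "solid") {            # leachate: remains excluded
      not_imputed <- rbind(not_imputed, m)
      next
    }
    donors <- curves[curves$treatment == m$treatment & curves$day == m$day &
                       curves$matrix == m$matrix, , drop = FALSE]
    donor_ids <- unique(donors$reactor_id)
    if (length(donor_ids) < 2L) {
      warning("cell ", m$treatment, "/day ", m$day, "/", m$matrix,
              ": fewer than 2 donor reactors; reactor ", m$reactor_id,
              " left missing", call. = FALSE)
      not_imputed <- rbind(not_imputed, m)
      next
    }
    k <- paste(donors$substrate, donors$time_h, sep = "\r")
    first <- !duplicated(k)
    imp <- donors[first, , drop = FALSE]
    imp$od <- as.numeric(tapply(donors$od, k, mean)[k[first]])
    # id follows the canonical sample-id scheme so externally measured
    # per-sample records (e.g. RI4) can still be joined to the imputed sample
    imp$sample_id <- sample_id(m$treatment, m$reactor_id, m$day, m$matrix)
    imp$reactor_id <- m$reactor_id
    imp$n_replicates_used <- NA_integer_
    imp$imputed <- TRUE
    rownames(imp) <- NULL
    curves <- rbind(curves, imp)
  }
  attr(curves, "missing") <- not_imputed
  curves
}

#' Preprocess raw well readings into kinetic curves
#'
#' Convenience wrapper running the fixed cleaning order: blank subtraction,
#' clipping of negative values, replicate averaging, then imputation of
#' missing solid replicates. A cleaning report (clipped-value count, imputed
#' and unrecoverable cells) is attached as attribute `cleaning`.
#'
#' @inheritParams subtract_blank
#' @param impute Impute missing solid replicates? Default TRUE.
#' @param design Design table for imputation (see [impute_missing_sample()]).
#' @return Curve table as from [average_replicates()].
#' @export
preprocess_plate <- function(readings, impute = TRUE, design = NULL) {
  corrected <- clip_negatives(subtract_blank(readings))
  curves <- average_replicates(corrected)
  n_imputed <- 0L
  missing <- NULL
  if (impute) {
    curves <- impute_missing_sample(curves, design)
    missing <- attr(curves, "missing")
    n_imputed <- sum(curves$imputed[!duplicated(curves$sample_id)])
  }
  attr(curves, "cleaning") <- list(
    n_clipped = attr(corrected, "n_clipped"),
    n_imputed_samples = n_imputed,
    unrecoverable = missing
  )
  curves
}
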