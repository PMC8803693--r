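#' Aggregate per-substrate activity integrals into guild activities
#'
#' Sums the 96-h activity integrals (AUC, OD·h) of each sample over the five
#' substrate guilds of the catalog. Every sample must carry all 31
#' substrates: a missing substrate is a hard error, never a silent zero.
#'
#' @param fits Fit table from [fit_curves()].
#' @param catalog Substrate catalog, default [default_catalog()].
#' @return Data frame with 5 rows per sample: sample metadata, `group`,
#'   `activity`, `imputed`.
#' @export
aggregate_groups <- function(fits, catalog = default_catalog()) {
  per_sample <- split(seq_len(nrow(fits)), fits$sample_id)
  meta_cols <- intersect(
    c("sample_id", "reactor_id", "treatment", "day", "matrix",
      "aeration_at_sampling", "imputed"), names(fits))
  rows <- lapply(per_sample, function(ii) {
    f <- fits[ii, , drop = FALSE]
    missing <- setdiff(catalog$substrate, f$substrate)
    if (length(missing) > 0L) {
      stop("sample ", f$sample_id[1], " lacks AUC for ",
           length(missing), " substrate(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    grp <- substrate_group(f$substrate, catalog)
    act <- tapply(f$auc, factor(grp, levels = substrate_groups()), sum)
    out <- f[rep(1, 5), meta_cols, drop = FALSE]
    out$group <- factor(substrate_groups(), levels = substrate_groups())
    out$activity <- as.numeric(act)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$group), , drop = FALSE]
}

#' Scale guild activities to each reactor's day-0 baseline
#'
#' Divides every reactor x guild activity series by that reactor's value at
#' the first sampling day, so the initial value is exactly 1. Series whose
#' baseline is 0 (or whose reactor has no day-0 sample) get `NA` with a
#' warning. Solid and leachate series are scaled separately against their
#' own matrix's baseline.
#'
#' @param group_table Guild activity table from [aggregate_groups()].
#' @param baseline_day Day defining the baseline, default the minimum day
#'   present.
#' @return The table with an additional `scaled` column.
#' @export
scale_to_baseline <- function(group_table, baseline_day = NULL) {
  if (is.null(baseline_day)) baseline_day <- min(group_table$day)
  base <- group_table[group_table$day == baseline_day, , drop = FALSE]
  bkey <- paste(base$reactor_id, base$matrix, base$group, sep = "\r")
  bval <- stats::setNames(base$activity, bkey)
  key <- paste(group_table$reactor_id, group_table$matrix, group_table$group,
               sep = "\r")
  denom <- as.numeric(bval[key])
  zero_base <- !is.na(denom) & denom == 0
  if (any(zero_base) || anyNA(denom)) {
    warning(sum(zero_base | is.na(denom)),
            " series with zero or missing day-", baseline_day,
            " baseline: scaled values set to NA", call. = FALSE)
  }
  denom[zero_base] <- NA_real_
  group_table$scaled <- group_table$activity / denom
  group_table
}

#' Min-max normalize variables to the unit interval
#'
#' Applies `(x - min(x)) / (max(x) - min(x))` per variable over the given
#' cohort, so the smallest value maps to exactly 0 and the largest to
#' exactly 1. A constant variable has no scale and is an error. The
#' transformation is invariant under positive affine maps of the input.
#'
#' @param x Numeric vector, or a data frame in which case `vars` names the
#'   columns to normalize (each over the full table).
#' @param vars Columns to normalize when `x` is a data frame.
#' @return Same shape as the input with normalized values.
#' @export
minmax_normalize <- function(x, vars = NULL) {
  norm1 <- function(v, label = "x") {
    r <- range(v, na.rm = TRUE)
    if (!all(is.finite(r))) stop("no finite values in ", label, call. = FALSE)
    if (r[1] == r[2]) {
      stop("variable '", label, "' is constant: min-max normalization ",
           "undefined (division by zero)", call. = FALSE)
    }
    (v - r[1]) / (r[2] - r[1])
  }
  if (is.data.frame(x)) {
    stopifnot(!is.null(vars), all(vars %in% names(x)))
    for (v in vars) x[[v]] <- norm1(x[[v]], v)
    x
  } else {
    norm1(x)
  }
}

#' Mean and standard error of scaled activities per design cell
#'
#' Summarizes scaled guild activities as mean and standard error
#' (sd / sqrt(n)). With `pool_equivalent = TRUE` (default), treatments whose
#' operational history is identical up to a given day are pooled, matching
#' the reporting convention of the experiment: at day 0 all nine reactors
#' are in the same state (n = 9), from day 57 to 358 the aerobic and mixed
#' treatments are indistinguishable (n = 6), and only at the final day are
#' the three treatments reported separately (n = 3).
#'
#' @param scaled_table Table from [scale_to_baseline()].
#' @param pool_equivalent Pool operationally equivalent treatments?
#' @param value Column to summarize, default `"scaled"`.
#' @return Data frame `day`, `treatment` (a pooled label where applicable),
#'   `group`, `n`, `mean`, `se`.
#' @export
group_summary <- function(scaled_table, pool_equivalent = TRUE,
                          value = "scaled") {
  d <- scaled_table
  lab <- as.character(d$treatment)
  if (pool_equivalent) {
    final_day <- max(d$day)
    first_day <- min(d$day)
    lab[d$day == first_day] <- "all"
    mid <- d$day > first_day & d$day < final_day
    lab[mid & lab %in% c("aerobic", "mixed")] <- "aerated"
  }
  key <- interaction(d$day, lab, d$group, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(d)), key), function(ii) {
    v <- d[[value]][ii]
    v <- v[!is.na(v)]
    data.frame(
      day = d$day[ii][1], treatment = lab[ii][1],
      group = as.character(d$group[ii][1]),
      n = length(v), mean = mean(v),
      se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$day, out$treatment, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
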