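#' Fit the biodegradability regression
#'
#' Ordinary least squares linking the four-day respiration index RI4 (the
#' standard aerobic biodegradability proxy for solid waste, mg O2 per kg dry
#' weight) to the carbohydrate and polymer guild activities:
#' `RI4_norm = b0 + b_carb * Carbohydrates + b_poly * Polymers`. All three
#' variables are min-max normalized over the modeling cohort before fitting
#' (the default; disable response normalization with
#' `normalize_response = FALSE` for sensitivity checks), so the coefficients
#' are on the unit-interval scale.
#'
#' @param group_table Guild activity table from [aggregate_groups()] (only
#'   the carbohydrate and polymer rows are used).
#' @param ri4 Data frame with columns `sample_id` and `ri4` (>= 0, finite).
#' @param normalize Normalize the covariates (min-max over the cohort)?
#'   Default TRUE.
#' @param normalize_response Normalize the response too? Default TRUE.
#' @return Object of class `"ri4_fit"`: the underlying `lm` plus `n`,
#'   `adj_r2`, `p_values`, and the modeling data.
#' @export
fit_ri4 <- function(group_table, ri4, normalize = TRUE,
                    normalize_response = TRUE) {
  stopifnot(all(c("sample_id", "ri4") %in% names(ri4)))
  if (any(!is.finite(ri4$ri4)) || any(ri4$ri4 < 0)) {
    stop("ri4 values must be finite and non-negative", call. = FALSE)
  }
  carb <- group_table[group_table$group == "carbohydrates", ]
  poly <- group_table[group_table$group == "polymers", ]
  dat <- data.frame(sample_id = carb$sample_id,
                    carbohydrates = carb$activity,
                    polymers = poly$activity[match(carb$sample_id,
                                                   poly$sample_id)],
                    stringsAsFactors = FALSE)
  dat <- merge(dat, ri4[, c("sample_id", "ri4")], by = "sample_id")
  if (nrow(dat) < 4L) {
    stop("need at least 4 samples for 2 covariates plus intercept; got ",
         nrow(dat), call. = FALSE)
  }
  if (normalize) {
    dat <- minmax_normalize(dat, c("carbohydrates", "polymers"))
  }
  if (normalize_response) dat <- minmax_normalize(dat, "ri4")
  fit <- stats::lm(ri4 ~ carbohydrates + polymers, data = dat)
  sm <- summary(fit)
  out <- list(
    lm = fit,
    n = nrow(dat),
    coefficients = stats::coef(fit),
    adj_r2 = sm$adj.r.squared,
    p_values = sm$coefficients[, "Pr(>|t|)"],
    std_errors = sm$coefficients[, "Std. Error"],
    data = dat,
    normalized = normalize,
    normalized_response = normalize_response
  )
  class(out) <- "ri4_fit"
  out
}

#' @export
print.ri4_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Biodegradability model (OLS on ",
      if (x$normalized) "min-max normalized" else "raw", " scales):\n",
      sep = "")
  cat(sprintf("  RI4 = %.3f %+.3f * Carbohydrates %+.3f * Polymers\n",
              cf[1], cf[2], cf[3]))
  cat(sprintf("  adjusted R^2 = %.3f, n = %d\n", x$adj_r2, x$n))
  stars <- vapply(x$p_values, p_stars, character(1))
  cat("  p-values:",
      paste(names(cf), "=", signif(x$p_values, 3), stars, collapse = "; "),
      "\n")
  invisible(x)
}

#' @export
summary.ri4_fit <- function(object, ...) summary(object$lm, ...)

#' @export
coef.ri4_fit <- function(object, ...) object$coefficients

#' @export
predict.ri4_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$lm, ...) else
    stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
residuals.ri4_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
plot.ri4_fit <- function(x, ...) {
  graphics::plot(stats::fitted(x$lm), x$data$ri4,
                 xlab = "fitted RI4 (normalized)",
                 ylab = "observed RI4 (normalized)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Significance stars for p-values
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, empty otherwise.
#' @param p Numeric p-value.
#' @return Character string of stars.
#' @export
p_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' ANOVA precondition checks (Levene and Shapiro)
#'
#' Runs Levene's test for homogeneity of variances across groups and the
#' Shapiro-Wilk normality test per group, the two preconditions checked
#' before a one-way ANOVA. Levene's test uses the classical mean-centered
#' statistic; `center = median` gives the more robust Brown-Forsythe
#' variant (which is conservative at small group sizes).
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor (e.g. treatment).
#' @param center Centering function for Levene's test, default `mean`.
#' @return Data frame `test`, `grouping`, `statistic`, `p_value`, `violated`
#'   (at alpha = 0.05).
#' @export
anova_prechecks <- function(values, groups, center = mean) {
  groups <- factor(groups)
  lev <- car::leveneTest(values ~ groups, center = center)
  rows <- list(data.frame(
    test = "levene", grouping = "all",
    statistic = lev[1, "F value"], p_value = lev[1, "Pr(>F)"],
    stringsAsFactors = FALSE))
  for (g in levels(groups)) {
    v <- values[groups == g]
    if (length(unique(v)) < 3L) {
      rows[[length(rows) + 1L]] <- data.frame(
        test = "shapiro", grouping = g, statistic = NA_real_,
        p_value = NA_real_, stringsAsFactors = FALSE)
    } else {
      sh <- stats::shapiro.test(v)
      rows[[length(rows) + 1L]] <- data.frame(
        test = "shapiro", grouping = g,
        statistic = unname(sh$statistic), p_value = sh$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$violated <- !is.na(out$p_value) & out$p_value < 0.05
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Tests for differences between treatments (one-way ANOVA), follows up with
#' Tukey's honestly-significant-difference pairwise comparisons, and encodes
#' the outcome as a compact letter display: treatments sharing a letter are
#' not significantly different at `alpha`.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor with >= 2 levels, >= 2 observations each.
#' @param alpha Family-wise significance level, default 0.05.
#' @return List with `anova_p`, `f_statistic`, `tukey` (pairwise table) and
#'   `letters` (named character vector per group level).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L || any(table(groups) < 2L)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pmat <- matrix(1, nlevels(groups), nlevels(groups),
                 dimnames = list(levels(groups), levels(groups)))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  letters_out <- compact_letters(pmat, alpha)
  list(
    anova_p = an[["Pr(>F)"]][1],
    f_statistic = an[["F value"]][1],
    tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL),
    letters = letters_out
  )
}

# Compact letter display by insert-and-absorb over a pairwise p-value
# matrix: maintain letter-columns (sets of mutually non-different groups);
# each significant pair splits every column containing both.
compact_letters <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  cols <- list(g)
  sig <- which(pmat < alpha & upper.tri(pmat), arr.ind = TRUE)
  for (k in seq_len(nrow(sig))) {
    a <- g[sig[k, 1]]; b <- g[sig[k, 2]]
    new_cols <- list()
    for (col in cols) {
      if (all(c(a, b) %in% col)) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i != j && keep[j] &&
            all(new_cols[[i]] %in% new_cols[[j]]) &&
            (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }
  out <- stats::setNames(rep("", length(g)), g)
  for (i in seq_along(cols)) {
    for (grp in cols[[i]]) out[grp] <- paste0(out[grp], letters[i])
  }
  out
}

#' Rank-sum comparison of solid versus leachate sampling
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) tests comparing solid-derived
#' and leachate-derived scaled guild activities at each sampling day, with
#' star encoding of significance (`***` p < 0.001, `**` p < 0.01, `*`
#' p < 0.05). Exact p-values are used for small samples without ties.
#'
#' @param scaled_table Table from [scale_to_baseline()] containing both
#'   matrices.
#' @param days Days to test; default all days after the baseline day (at the
#'   baseline both matrices are identically 1 by construction).
#' @return Data frame `day`, `group`, `n_solid`, `n_leachate`, `statistic`,
#'   `p_value`, `stars`.
#' @export
wilcoxon_solid_vs_leachate <- function(scaled_table, days = NULL) {
  d <- scaled_table
  if (is.null(days)) {
    days <- sort(unique(d$day))
    # at the baseline day both matrices are identically 1 by construction
    if (length(days) > 1L) days <- days[-1]
  }
  rows <- list()
  for (dy in days) {
    for (g in levels(factor(d$group))) {
      s <- d$scaled[d$day == dy & d$group == g & d$matrix == "solid"]
      l <- d$scaled[d$day == dy & d$group == g & d$matrix == "leachate"]
      s <- s[!is.na(s)]; l <- l[!is.na(l)]
      if (length(s) < 2L || length(l) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          day = dy, group = g, n_solid = length(s), n_leachate = length(l),
          statistic = NA_real_, p_value = NA_real_, stars = "",
          stringsAsFactors = FALSE)
        next
      }
      wt <- suppressWarnings(stats::wilcox.test(s, l))
      rows[[length(rows) + 1L]] <- data.frame(
        day = dy, group = g, n_solid = length(s), n_leachate = length(l),
        statistic = unname(wt$statistic), p_value = wt$p.value,
        stars = p_stars(wt$p.value), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(day = numeric(0), group = character(0),
                      n_solid = integer(0), n_leachate = integer(0),
                      statistic = numeric(0), p_value = numeric(0),
                      stars = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
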