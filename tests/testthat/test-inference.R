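# Build a guild-activity table + RI4 records whose carbohydrate/polymer
# activities already span [0, 1] so min-max normalization is the identity.
make_cohort <- function(n = 36, b0 = 0.26, bc = 0.68, bp = -0.5, sigma = 0,
                        seed = 1) {
  set.seed(seed)
  C <- c(0, 1, stats::runif(n - 2))
  P <- c(1, 0, stats::runif(n - 2))
  ids <- sprintf("s%02d", seq_len(n))
  g <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(sample_id = ids[i], reactor_id = i, treatment = "aerobic",
               day = 0, matrix = "solid", imputed = FALSE,
               group = substrate_groups(),
               activity = c(0.5, 0.5, C[i], 0.5, P[i]),
               stringsAsFactors = FALSE)
  }))
  y <- b0 + bc * C + bp * P + stats::rnorm(n, 0, sigma)
  list(groups = g, ri4 = data.frame(sample_id = ids, ri4 = y + 1),
       C = C, P = P, y = y)
}

test_that("a noiseless affine response is recovered to machine precision", {
  ch <- make_cohort(sigma = 0)
  fit <- suppressWarnings(   # "essentially perfect fit" is the point here
    fit_ri4(ch$groups, ch$ri4, normalize_response = FALSE))
  # response was shifted by +1; only the intercept absorbs that
  expect_equal(unname(coef(fit)), c(1.26, 0.68, -0.5), tolerance = 1e-12)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-12)
  expect_equal(fit$n, 36L)
})

test_that("OLS residuals are orthogonal to the covariates", {
  ch <- make_cohort(sigma = 0.2, seed = 7)
  fit <- fit_ri4(ch$groups, ch$ri4)
  r <- residuals(fit)
  X <- stats::model.matrix(fit$lm)
  expect_lt(max(abs(crossprod(X, r))), 1e-10)
  expect_lte(fit$adj_r2, summary(fit)$r.squared)
})

test_that("underdetermined cohorts are refused", {
  ch <- make_cohort(n = 36)
  small_ids <- ch$ri4$sample_id[1:3]
  expect_error(
    fit_ri4(ch$groups[ch$groups$sample_id %in% small_ids, ],
            ch$ri4[1:3, ]),
    "at least 4")
})

test_that("coefficient estimates are unbiased over simulated cohorts", {
  est <- sapply(1:200, function(s) {
    ch <- make_cohort(sigma = 0.2, seed = s)
    coef(fit_ri4(ch$groups, ch$ri4, normalize_response = FALSE))
  })
  mc_se <- apply(est, 1, stats::sd) / sqrt(ncol(est))
  bias <- rowMeans(est) - c(1.26, 0.68, -0.5)
  expect_true(all(abs(bias) < 4 * mc_se + 1e-8))
})

test_that("ANOVA prechecks report Levene and per-group Shapiro", {
  set.seed(21)
  v <- stats::rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  pc <- anova_prechecks(v, g)
  expect_equal(pc$test, c("levene", rep("shapiro", 3)))
  expect_true(all(pc$p_value >= 0 & pc$p_value <= 1, na.rm = TRUE))

  # two identical groups: no variance difference at all
  v2 <- rep(c(1, 2, 3), 2)
  pc2 <- anova_prechecks(v2, rep(c("a", "b"), each = 3))
  expect_equal(pc2$statistic[pc2$test == "levene"], 0)
})

test_that("Tukey letters separate only groups that differ", {
  set.seed(31)
  base <- stats::rnorm(6, sd = 0.5)
  same <- c(base, base + 0.01, base - 0.01)
  g <- rep(c("a", "b", "c"), each = 6)
  res_same <- anova_tukey(same, g)
  expect_equal(length(unique(res_same$letters)), 1L)

  shifted <- c(base, base, base + 50)
  res_diff <- anova_tukey(shifted, g)
  expect_false(res_diff$letters["c"] %in% res_diff$letters[c("a", "b")])
  expect_equal(res_diff$letters[["a"]], res_diff$letters[["b"]])
  expect_lt(res_diff$anova_p, 0.001)

  expect_error(anova_tukey(1:3, c("a", "b", "c")), ">= 2")
})

test_that("equal group means give F = 0 and one shared letter", {
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anova_tukey(v, g)
  expect_equal(res$f_statistic, 0, tolerance = 1e-12)
  expect_equal(length(unique(res$letters)), 1L)
})

test_that("rank-sum encoding matches the star thresholds", {
  expect_equal(p_stars(0.0004), "***")
  expect_equal(p_stars(0.004), "**")
  expect_equal(p_stars(0.04), "*")
  expect_equal(p_stars(0.4), "")

  # fully separated n = 6 vs 6: the minimal attainable two-sided p
  scaled <- data.frame(
    day = 57, group = "amines",
    matrix = rep(c("solid", "leachate"), each = 6),
    scaled = c(1:6, 101:106), stringsAsFactors = FALSE
  )
  w <- wilcoxon_solid_vs_leachate(scaled)
  expect_equal(w$p_value, 2 / choose(12, 6), tolerance = 1e-12)
  expect_equal(w$stars, "**")

  # identical samples: no evidence at all
  same <- scaled; same$scaled <- rep(c(1, 2, 3, 4, 5, 6), 2)
  w2 <- wilcoxon_solid_vs_leachate(same)
  expect_equal(w2$p_value, 1, tolerance = 1e-9)

  # fewer than 2 per side: missing result
  short <- scaled[c(1, 7), ]
  w3 <- wilcoxon_solid_vs_leachate(short)
  expect_true(is.na(w3$p_value))
})

test_that("treatment comparisons run on the synthetic final day", {
  run <- default_run()
  scaled <- run$tables$scaled_activity
  final <- scaled[scaled$day == 763 & scaled$matrix == "solid" &
                    scaled$group == "polymers", ]
  res <- anova_tukey(final$scaled, final$treatment)
  expect_true(all(nchar(res$letters) >= 1))
  expect_true(res$anova_p >= 0 && res$anova_p <= 1)
})
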