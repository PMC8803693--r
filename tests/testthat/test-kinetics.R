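test_that("Gompertz closed-form identities hold to machine precision", {
  A <- 1.3; mu <- 0.05; lam <- 9
  expect_equal(gompertz(lam, A, mu, lam), A * exp(-exp(1)),
               tolerance = 1e-15)
  t_inf <- lam + A / (mu * exp(1))
  expect_equal(gompertz(t_inf, A, mu, lam), A / exp(1), tolerance = 1e-15)
  # frozen independent evaluation of the closed form
  expect_equal(gompertz(96, 1, 0.05, 10), 0.9999771971, tolerance = 1e-9)
  # monotone non-decreasing everywhere, strictly rising around the lag
  tt <- seq(-20, 500, by = 0.5)
  expect_true(all(diff(gompertz(tt, A, mu, lam)) >= 0))
  rise <- seq(lam - 5, lam + 40, by = 0.5)
  expect_true(all(diff(gompertz(rise, A, mu, lam)) > 0))
  expect_equal(gompertz(1e6, A, mu, lam), A, tolerance = 1e-12)
})

test_that("the spline grid reproduces linear data and respects the cutoff", {
  times <- c(24, 48, 72, 96)
  ic <- spline_interpolate(times, 0.01 * times)
  expect_equal(length(ic$grid_h), 100L)
  expect_equal(range(ic$grid_h), c(0, 96))
  expect_equal(ic$od_hat, 0.01 * ic$grid_h, tolerance = 1e-10)

  zero <- spline_interpolate(times, rep(0, 4))
  expect_identical(zero$od_hat, rep(0, 100))

  # 144-h read supports the spline but the grid still stops at 96 h
  with144 <- spline_interpolate(c(24, 48, 72, 96, 144),
                                c(0.1, 0.4, 0.7, 0.8, 0.85))
  expect_equal(max(with144$grid_h), 96)
  expect_equal(with144$od_hat[1], 0)     # anchor
  expect_true(all(with144$od_hat >= 0))

  # a single measured point (plus the anchor) degenerates to linear
  expect_warning(two <- spline_interpolate(48, 0.4), "linear")
  expect_equal(two$od_hat[100], 0.4, tolerance = 1e-12)  # rule-2 plateau
})

test_that("the heuristic initializer lands near the truth", {
  A <- 1.2; mu <- 0.04; lam <- 12
  grid <- seq(0, 96, length.out = 100)
  ic <- list(grid_h = grid, od_hat = gompertz(grid, A, mu, lam))
  st <- heuristic_initializer(ic)
  expect_lt(abs(st$A - A) / A, 0.25)
  expect_lt(abs(st$mu - mu) / mu, 0.25)
  expect_lt(abs(st$lam - lam) / lam, 0.25)

  step <- list(grid_h = grid, od_hat = pmin(1, 0.25 * grid))
  expect_equal(heuristic_initializer(step)$A, 1.0)

  expect_error(heuristic_initializer(list(grid_h = grid,
                                          od_hat = rep(0, 100))),
               "all-zero")
})

test_that("noiseless Gompertz grids are recovered within 1 percent", {
  grid <- seq(0, 96, length.out = 100)
  set.seed(11)
  for (i in 1:25) {
    A <- stats::runif(1, 0.2, 1.5)
    mu <- A / stats::runif(1, 18, 35)
    lam <- stats::runif(1, 3, 20)
    ic <- list(grid_h = grid, od_hat = gompertz(grid, A, mu, lam))
    f <- fit_gompertz(ic)
    expect_true(f$converged)
    expect_lt(abs(f$params$A - A) / A, 0.01)
    expect_lt(abs(f$params$mu - mu) / mu, 0.01)
    expect_lt(abs(f$params$lam - lam) / max(abs(lam), 1), 0.01)
  }
})

test_that("a curve generated with a negative lag is fitted with one", {
  grid <- seq(0, 96, length.out = 100)
  ic <- list(grid_h = grid, od_hat = gompertz(grid, 1, 0.05, -5))
  f <- fit_gompertz(ic)
  expect_true(f$converged)
  expect_lt(f$params$lam, 0)
})

test_that("A is recovered within 5 percent median error under noise", {
  grid <- seq(0, 96, length.out = 100)
  A <- 0.8; mu <- 0.032; lam <- 10
  clean <- gompertz(grid, A, mu, lam)
  set.seed(101)
  rel_err <- replicate(50, {
    y <- pmax(0, clean + stats::rnorm(100, 0, 0.01))
    y[1] <- 0
    f <- fit_gompertz(list(grid_h = grid, od_hat = y))
    abs(f$params$A - A) / A
  })
  expect_lt(stats::median(rel_err), 0.05)
})

test_that("classification follows the zero / negative-lag / success rules", {
  grid <- seq(0, 96, length.out = 100)
  zero_ic <- list(grid_h = grid, od_hat = rep(0, 100))
  rz <- classify_and_integrate(zero_ic, NULL)
  expect_equal(rz$outcome, "zero")
  expect_identical(rz$auc, 0)

  ic <- list(grid_h = grid, od_hat = gompertz(grid, 1, 0.05, -5))
  cand <- fit_gompertz(ic)                # fitted lambda < 0
  rf <- classify_and_integrate(ic, cand)
  expect_equal(rf$outcome, "spline_fallback")
  expect_equal(rf$auc, sum(diff(grid) * (ic$od_hat[-1] + ic$od_hat[-100]) / 2))

  ic2 <- list(grid_h = grid, od_hat = gompertz(grid, 1, 0.05, 10))
  cand2 <- fit_gompertz(ic2)
  rg <- classify_and_integrate(ic2, cand2)
  expect_equal(rg$outcome, "gompertz")
  # oracle: adaptive quadrature of the closed form
  oracle <- stats::integrate(gompertz, 0, 96, A = 1, mu = 0.05, lam = 10,
                             rel.tol = 1e-10)$value
  expect_lt(abs(rg$auc - oracle) / oracle, 0.001)
})

test_that("gompertz_fit behaves like a model object", {
  grid <- seq(0, 96, length.out = 100)
  ic <- list(grid_h = grid, od_hat = gompertz(grid, 1.1, 0.04, 8))
  f <- fit_gompertz(ic)
  expect_s3_class(f, "gompertz_fit")
  expect_named(coef(f), c("A", "mu", "lam"))
  expect_equal(predict(f, newdata = list(t = grid)), fitted(f))
  expect_equal(residuals(f), ic$od_hat - fitted(f))
  expect_output(print(f), "Gompertz")
})

test_that("success bookkeeping matches the design arithmetic", {
  f1 <- fits_with_auc(1, sample = paste0("r", 1), reactor = 1)
  f2 <- fits_with_auc(1, sample = paste0("r", 2), reactor = 2)
  f3 <- fits_with_auc(1, sample = paste0("r", 3), reactor = 3)
  all3 <- rbind(f1, f2, f3)
  st <- success_table(all3)
  expect_equal(st$n_total, 93L)
  expect_equal(st$n_success, 93L)
  expect_equal(st$percent, 100)

  # 69 of 93 successes
  mixed <- all3
  mixed$outcome[1:24] <- "spline_fallback"
  st2 <- success_table(mixed)
  expect_equal(st2$n_success, 69L)
  expect_equal(st2$percent, 74.2)

  # one sample missing: denominator 62
  st3 <- success_table(rbind(f1, f2))
  expect_equal(st3$n_total, 62L)

  # imputed samples are not measurements and are excluded
  f3$imputed <- TRUE
  st4 <- success_table(rbind(f1, f2, f3))
  expect_equal(st4$n_total, 62L)
})
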