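#' Gompertz growth curve (Zwietering parametrization)
#'
#' `y(t) = A * exp(-exp(mu*e/A * (lambda - t) + 1))` with asymptote `A`
#' (amplitude, OD units), maximum slope `mu` (OD per hour, attained at the
#' inflection point) and lag time `lambda` (hours, the t-intercept of the
#' tangent at the inflection). Closed-form identities used by the tests:
#' `y(lambda) = A*exp(-e)` and `y(lambda + A/(mu*e)) = A/e`.
#'
#' @param t Time(s), hours.
#' @param A Asymptote, must be > 0.
#' @param mu Maximum slope, must be > 0.
#' @param lam Lag time, hours (may be negative).
#' @return Numeric vector of OD values.
#' @export
gompertz <- function(t, A, mu, lam) {
  A * exp(-exp(mu * exp(1) / A * (lam - t) + 1))
}

#' Interpolate a kinetic curve on the analysis grid
#'
#' Fits a natural cubic interpolating spline through the anchor point
#' (0 h, 0 OD) and all measured points of one curve, evaluates it on
#' `grid_points` equally spaced nodes spanning `[0, horizon_h]`, and clips
#' negative excursions to 0. Measurements beyond the horizon (e.g. 144-h
#' reads) support the spline but the grid stops at the horizon. With fewer
#' than 3 distinct points the spline degenerates to linear interpolation
#' (with a warning); with no points at all the grid is all-zero.
#'
#' @param times_h Measurement times (hours, >= 0). The 0-h anchor is added
#'   automatically if absent.
#' @param od Blank-corrected OD values (same length).
#' @param horizon_h Integration horizon, default 96 h.
#' @param grid_points Number of grid nodes, default 100.
#' @param method `"natural_cubic"` (default) or `"pchip"` (monotone
#'   shape-preserving Fritsch-Carlson spline).
#' @return List with `grid_h` and `od_hat` (clipped to >= 0, `od_hat[1] == 0`).
#' @export
spline_interpolate <- function(times_h, od, horizon_h = 96, grid_points = 100,
                               method = c("natural_cubic", "pchip")) {
  method <- match.arg(method)
  stopifnot(length(times_h) == length(od), grid_points >= 2)
  keep <- !is.na(od) & !is.na(times_h)
  times_h <- times_h[keep]; od <- od[keep]
  if (!any(times_h == 0)) {         # t = 0 anchored at OD 0
    times_h <- c(0, times_h)
    od <- c(0, od)
  }
  o <- order(times_h)
  times_h <- times_h[o]; od <- od[o]
  grid_h <- seq(0, horizon_h, length.out = grid_points)
  if (length(times_h) == 1L || all(od == 0)) {
    return(list(grid_h = grid_h, od_hat = rep(0, grid_points)))
  }
  if (length(times_h) < 3L) {
    warning("fewer than 3 time points: linear interpolation used",
            call. = FALSE)
    od_hat <- stats::approx(times_h, od, xout = grid_h, rule = 2)$y
  } else if (method == "pchip") {
    f <- stats::splinefun(times_h, od, method = "monoH.FC")
    od_hat <- f(grid_h)
  } else {
    od_hat <- stats::spline(times_h, od, xout = grid_h, method = "natural")$y
  }
  od_hat[od_hat < 0] <- 0
  od_hat[1] <- 0
  list(grid_h = grid_h, od_hat = od_hat)
}

#' Heuristic Gompertz starting values
#'
#' `A0` is the curve maximum; `mu0` the largest finite-difference slope over
#' the grid; `lambda0` the t-intercept of the tangent line at the
#' max-slope node, clamped to >= 0 (the clamp applies to the starting value
#' only -- the fit itself leaves lambda unbounded). A flat non-zero curve
#' gets a small positive slope floor.
#'
#' @param ic Interpolated curve from [spline_interpolate()].
#' @return Named list `A`, `mu`, `lam`.
#' @export
heuristic_initializer <- function(ic) {
  y <- ic$od_hat; x <- ic$grid_h
  if (all(y == 0)) stop("all-zero curve has no Gompertz start", call. = FALSE)
  A0 <- max(y)
  slopes <- diff(y) / diff(x)
  k <- which.max(slopes)
  mu0 <- slopes[k]
  if (mu0 <= 0) mu0 <- A0 / (2 * max(x))    # flat-curve floor
  xm <- (x[k] + x[k + 1]) / 2
  ym <- (y[k] + y[k + 1]) / 2
  lam0 <- max(0, xm - ym / mu0)             # tangent t-intercept
  list(A = A0, mu = mu0, lam = lam0)
}

#' Fit the Gompertz model to an interpolated curve
#'
#' Levenberg-Marquardt nonlinear least squares of the Gompertz curve against
#' the interpolated OD grid, started from [heuristic_initializer()]. No
#' bound is placed on lambda: a negative fitted lag is what routes a curve
#' to the spline fallback in [classify_and_integrate()]. On failure one
#' restart is attempted from the start values scaled by 1.5. Deterministic.
#'
#' @param ic Interpolated curve from [spline_interpolate()].
#' @param max_iter Maximum optimizer iterations, default 200.
#' @param restart Number of perturbed restarts on failure, default 1.
#' @return Object of class `"gompertz_fit"`: list with `converged`, `params`
#'   (named list A, mu, lam), `rss`, `fitted`, `grid_h`, `od_hat`, `start`.
#' @export
fit_gompertz <- function(ic, max_iter = 200, restart = 1) {
  if (all(ic$od_hat == 0)) {
    stop("all-zero curve: nothing to fit (classify as zero)", call. = FALSE)
  }
  start <- heuristic_initializer(ic)
  df <- data.frame(t = ic$grid_h, y = ic$od_hat)
  one_try <- function(st) {
    st$lam <- max(st$lam, 1e-6)  # strictly interior start; fit is unbounded
    tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-exp(mu * exp(1) / A * (lam - t) + 1)),
        data = df, start = st,
        lower = c(A = 1e-8, mu = 1e-8, lam = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = max_iter)
      ),
      error = function(e) NULL
    )
  }
  fit <- one_try(start)
  tries <- 0
  while (is.null(fit) && tries < restart) {
    tries <- tries + 1
    fit <- one_try(lapply(start, function(v) v * 1.5))
  }
  if (is.null(fit)) {
    out <- list(converged = FALSE, params = NULL, rss = NA_real_,
                fitted = NULL, grid_h = ic$grid_h, od_hat = ic$od_hat,
                start = start)
  } else {
    cf <- as.list(coef(fit))
    yhat <- gompertz(ic$grid_h, cf$A, cf$mu, cf$lam)
    out <- list(converged = TRUE, params = cf,
                rss = sum((ic$od_hat - yhat)^2),
                fitted = yhat, grid_h = ic$grid_h, od_hat = ic$od_hat,
                start = start)
  }
  class(out) <- "gompertz_fit"
  out
}

#' @export
print.gompertz_fit <- function(x, ...) {
  if (x$converged) {
    cat("Gompertz fit (Zwietering): A =", signif(x$params$A, 5),
        " mu =", signif(x$params$mu, 5),
        " lambda =", signif(x$params$lam, 5), "h\n")
    cat("RSS:", signif(x$rss, 5), "on", length(x$grid_h), "grid points\n")
  } else {
    cat("Gompertz fit: optimizer did not converge (spline fallback)\n")
  }
  invisible(x)
}

#' @export
coef.gompertz_fit <- function(object, ...) {
  if (!object$converged) return(c(A = NA_real_, mu = NA_real_, lam = NA_real_))
  unlist(object$params)
}

#' @export
predict.gompertz_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$grid_h else
    if (is.list(newdata)) newdata$t else newdata
  if (!object$converged) stop("no converged parameters to predict from")
  gompertz(t, object$params$A, object$params$mu, object$params$lam)
}

#' @export
fitted.gompertz_fit <- function(object, ...) object$fitted

#' @export
residuals.gompertz_fit <- function(object, ...) {
  if (!object$converged) return(NULL)
  object$od_hat - object$fitted
}

#' @export
plot.gompertz_fit <- function(x, ...) {
  graphics::plot(x$grid_h, x$od_hat, pch = 16, cex = 0.5,
                 xlab = "time [h]", ylab = "OD590 (blank-corrected)", ...)
  if (x$converged) graphics::lines(x$grid_h, x$fitted, col = 2, lwd = 2)
  invisible(x)
}

# Composite trapezoid on possibly non-uniform grid.
trapezoid <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Classify a curve and compute its 96-h activity integral
#'
#' Applies the outcome rules: `zero` if the interpolated curve is identically
#' 0 (AUC exactly 0); `gompertz` if the fit converged with lag `lambda >= 0`
#' (AUC = trapezoidal integral of the fitted Gompertz curve on the grid);
#' `spline_fallback` otherwise, i.e. negative fitted lag or optimizer failure
#' (AUC = trapezoidal integral of the interpolated spline itself).
#'
#' @param ic Interpolated curve from [spline_interpolate()].
#' @param candidate A `"gompertz_fit"` (or NULL for all-zero curves).
#' @return List of class `"fit_result"`: `outcome`, `params`, `auc`, `rss`.
#' @export
classify_and_integrate <- function(ic, candidate = NULL) {
  if (all(ic$od_hat == 0)) {
    out <- list(outcome = "zero", params = NULL, auc = 0, rss = 0)
  } else if (!is.null(candidate) && candidate$converged &&
             candidate$params$lam >= 0) {
    out <- list(outcome = "gompertz", params = candidate$params,
                auc = trapezoid(ic$grid_h, candidate$fitted),
                rss = candidate$rss)
  } else {
    out <- list(outcome = "spline_fallback", params = NULL,
                auc = trapezoid(ic$grid_h, ic$od_hat),
                rss = if (is.null(candidate)) NA_real_ else candidate$rss)
  }
  class(out) <- "fit_result"
  out
}

#' Fit all curves of a curve table
#'
#' Runs [spline_interpolate()], [fit_gompertz()] and
#' [classify_and_integrate()] for every (sample, substrate) curve.
#'
#' @param curves Curve table from [preprocess_plate()].
#' @param horizon_h,grid_points,method Passed to [spline_interpolate()].
#' @param max_iter,restart Passed to [fit_gompertz()].
#' @return Data frame with one row per curve: sample metadata, `substrate`,
#'   `outcome`, `A`, `mu`, `lambda`, `rss`, `auc`, `imputed`.
#' @export
fit_curves <- function(curves, horizon_h = 96, grid_points = 100,
                       method = "natural_cubic", max_iter = 200, restart = 1) {
  key <- paste(curves$sample_id, curves$substrate, sep = "\r")
  idx <- split(seq_len(nrow(curves)), key)
  meta_cols <- intersect(
    c("sample_id", "reactor_id", "treatment", "day", "matrix",
      "aeration_at_sampling", "substrate", "imputed"), names(curves))
  rows <- lapply(idx, function(ii) {
    cv <- curves[ii, , drop = FALSE]
    cv <- cv[order(cv$time_h), , drop = FALSE]
    ic <- spline_interpolate(cv$time_h, cv$od, horizon_h, grid_points, method)
    cand <- if (all(ic$od_hat == 0)) NULL else
      fit_gompertz(ic, max_iter = max_iter, restart = restart)
    res <- classify_and_integrate(ic, cand)
    p <- res$params
    out <- cv[1, meta_cols, drop = FALSE]
    out$outcome <- res$outcome
    out$A <- if (is.null(p)) NA_real_ else p$A
    out$mu <- if (is.null(p)) NA_real_ else p$mu
    out$lambda <- if (is.null(p)) NA_real_ else p$lam
    out$rss <- res$rss
    out$auc <- res$auc
    # diagnostic: spline-based integral, for fallback/Gompertz comparison
    out$auc_spline <- trapezoid(ic$grid_h, ic$od_hat)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$substrate), , drop = FALSE]
}

#' Gompertz success bookkeeping per treatment and day
#'
#' Counts, per treatment x sampling day, how many curves were integrated via
#' a successful Gompertz fit out of the total number of measured curves
#' (31 substrates per sampled reactor; imputed samples are excluded -- they
#' are not measurements).
#'
#' @param fits Fit table from [fit_curves()] (typically solids only).
#' @return Data frame `treatment`, `day`, `n_success`, `n_total`, `percent`
#'   (rounded to one decimal, as conventionally reported).
#' @export
success_table <- function(fits) {
  fits <- fits[!fits$imputed, , drop = FALSE]
  key <- interaction(fits$treatment, fits$day, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(fits)), key), function(ii) {
    f <- fits[ii, , drop = FALSE]
    data.frame(
      treatment = as.character(f$treatment[1]),
      day = f$day[1],
      n_success = sum(f$outcome == "gompertz"),
      n_total = nrow(f),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$percent <- round(100 * out$n_success / out$n_total, 1)
  out <- out[order(out$treatment, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}
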