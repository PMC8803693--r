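#' Pipeline configuration
#'
#' Assembles analysis options for [run_pipeline()]. A YAML or JSON file with
#' the same keys may be supplied instead; flags in `...` override file
#' values.
#'
#' @param path Optional path to a YAML (needs the `yaml` package) or JSON
#'   (needs `jsonlite`) config file.
#' @param ... Key overrides: `horizon_h` (default 96), `grid_points` (100),
#'   `spline` ("natural_cubic" or "pchip"), `max_iter`, `restart`,
#'   `normalize_response` (TRUE), `impute` (TRUE), `seed`.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(horizon_h = 96, grid_points = 100, spline = "natural_cubic",
              max_iter = 200, restart = 1, normalize_response = TRUE,
              impute = TRUE, seed = 1L)
  if (!is.null(path)) {
    file_cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML config requires the 'yaml' package", call. = FALSE)
      }
      yaml::read_yaml(path)
    } else {
      if (!requireNamespace("jsonlite", quietly = TRUE)) {
        stop("reading JSON config requires the 'jsonlite' package",
             call. = FALSE)
      }
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing (blank subtraction, clipping, replicate averaging,
#' imputation), kinetics (spline interpolation, Gompertz fitting, fallback
#' classification, activity integrals), profiling (guild aggregation,
#' baseline scaling, min-max normalization) and, when RI4 records are
#' supplied, the biodegradability regression. All stages are deterministic
#' given the inputs.
#'
#' @param plate Validated plate table (from [read_plate_table()],
#'   [validate_plate_table()] or a [generate_experiment()] simulation).
#' @param ri4 Optional RI4 table (`sample_id`, `ri4`); solids only.
#' @param config A [pipeline_config()].
#' @param design Optional design table for imputation.
#' @return Object of class `"clpp_run"`: list with `curves`, `fits`,
#'   `tables` (auc_per_substrate, group_activity, scaled_activity,
#'   normalized, success_table), `ri4_fit` (or NULL), `cleaning`,
#'   `manifest`.
#' @export
run_pipeline <- function(plate, ri4 = NULL, config = pipeline_config(),
                         design = NULL) {
  plate <- validate_plate_table(plate)
  curves <- preprocess_plate(plate, impute = config$impute, design = design)
  fits <- fit_curves(curves, horizon_h = config$horizon_h,
                     grid_points = config$grid_points,
                     method = config$spline, max_iter = config$max_iter,
                     restart = config$restart)
  groups <- aggregate_groups(fits)
  scaled <- scale_to_baseline(groups)
  solids <- groups[groups$matrix == "solid", , drop = FALSE]
  ri4_fit <- NULL
  normalized <- NULL
  if (!is.null(ri4)) {
    ri4_fit <- fit_ri4(solids, ri4,
                       normalize_response = config$normalize_response)
    normalized <- ri4_fit$data
  }
  success <- success_table(fits[fits$matrix == "solid", , drop = FALSE])
  tables <- list(
    auc_per_substrate = fits[, setdiff(names(fits), "aeration_at_sampling")],
    group_activity = groups,
    scaled_activity = scaled,
    success_table = success
  )
  if (!is.null(normalized)) tables$normalized <- normalized
  out <- list(
    curves = curves,
    fits = fits,
    tables = tables,
    ri4_fit = ri4_fit,
    cleaning = attr(curves, "cleaning"),
    manifest = NULL,
    config = config
  )
  out$manifest <- run_manifest(out)
  class(out) <- "clpp_run"
  out
}

#' @export
print.clpp_run <- function(x, ...) {
  cat("CLPP pipeline run\n")
  cat("  samples:", length(unique(x$fits$sample_id)),
      " curves:", nrow(x$fits), "\n")
  oc <- table(x$fits$outcome)
  cat("  outcomes:", paste(names(oc), oc, sep = "=", collapse = ", "), "\n")
  cat("  cleaning: clipped", x$cleaning$n_clipped, "values, imputed",
      x$cleaning$n_imputed_samples, "sample(s)\n")
  if (!is.null(x$ri4_fit)) print(x$ri4_fit)
  invisible(x)
}

# Manifest of a run: per-stage row counts and content digests of the result
# tables, so identical inputs provably produce identical outputs.
run_manifest <- function(run) {
  digests <- vapply(run$tables, function(df) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp))
    write_table_fp(df, tmp)
    unname(tools::md5sum(tmp))
  }, character(1))
  list(
    package_version = as.character(utils::packageVersion("ecoplateR")),
    n_curve_rows = nrow(run$curves),
    n_fit_rows = nrow(run$fits),
    table_digests = digests,
    config = unclass(run$config),
    warnings = run$cleaning
  )
}

#' Write all result tables and the manifest of a run
#'
#' @param run A `"clpp_run"` object.
#' @param out_dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_run <- function(run, out_dir) {
  files <- write_results(run$tables, out_dir)
  if (!is.null(run$ri4_fit)) {
    f <- file.path(out_dir, "ri4_model.txt")
    txt <- c(
      utils::capture.output(print(run$ri4_fit)),
      "",
      utils::capture.output(print(summary(run$ri4_fit)))
    )
    writeLines(txt, f)
    files <- c(files, f)
  }
  mf <- file.path(out_dir, "manifest.txt")
  m <- run$manifest
  writeLines(c(
    paste0("package_version: ", m$package_version),
    paste0("n_curve_rows: ", m$n_curve_rows),
    paste0("n_fit_rows: ", m$n_fit_rows),
    paste0("digest_", names(m$table_digests), ": ", m$table_digests)
  ), mf)
  invisible(c(files, mf))
}
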