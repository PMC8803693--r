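# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Default synthetic experiment + full pipeline run (the study conditions).
default_sim <- function() {
  cached("default_sim", generate_experiment(generator_config(seed = 42)))
}

default_run <- function() {
  cached("default_run", {
    sim <- default_sim()
    suppressWarnings(run_pipeline(sim$plate, sim$ri4))
  })
}

# Small hand-built plate table: one sample, `substrates` wells + blank,
# 3 replicates, times 24..96 h, constant OD per well.
tiny_plate <- function(od_by_substrate = c("D-Xylose" = 0.5),
                       blank_od = 0.1,
                       times = c(24, 48, 72, 96),
                       sample = "s1", reactor = 1, treatment = "aerobic",
                       day = 0, matrix = "solid") {
  subs <- c(names(od_by_substrate), BLANK)
  ods <- c(unname(od_by_substrate), blank_od)
  rows <- expand.grid(substrate = subs, replicate = 1:3, time_h = times,
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = sample, reactor_id = reactor, treatment = treatment,
    day = day, matrix = matrix, substrate = rows$substrate,
    replicate = rows$replicate, time_h = rows$time_h,
    od590 = ods[match(rows$substrate, subs)],
    stringsAsFactors = FALSE
  )
}

# A fits table with prescribed per-substrate AUCs for one or more samples.
fits_with_auc <- function(auc_values, sample = "s1", reactor = 1,
                          treatment = "aerobic", day = 0, matrix = "solid",
                          outcome = "gompertz") {
  catalog <- default_catalog()
  stopifnot(length(auc_values) %in% c(1L, 31L))
  data.frame(
    sample_id = sample, reactor_id = reactor, treatment = treatment,
    day = day, matrix = matrix, substrate = catalog$substrate,
    imputed = FALSE, outcome = outcome,
    A = NA_real_, mu = NA_real_, lambda = NA_real_, rss = NA_real_,
    auc = rep_len(auc_values, 31L),
    stringsAsFactors = FALSE
  )
}
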