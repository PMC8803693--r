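#' Sampling design of the landfill simulation experiment
#'
#' Nine reactors in three treatments of three: `aerobic` (aerated from day 57
#' to the end), `mixed` (aerated from day 57 for about a year, then anaerobic
#' again) and `anaerobic` (never aerated). Solid and leachate samples are
#' taken at days 0, 57, 114, 358 and 763, but anaerobic reactors cannot be
#' opened while anaerobic operation must be preserved, so they are sampled
#' only at installation (day 0) and termination (day 763). This gives 36
#' samples per matrix: 9 + 6 + 6 + 6 + 9. Day-114 samples had to be frozen
#' before processing; the flag is metadata only and never alters computation.
#'
#' @param days Sampling days, default `c(0, 57, 114, 358, 763)`.
#' @param matrices Sample matrices, default both `"solid"` and `"leachate"`.
#' @return Data frame with one row per expected sample: `reactor_id`,
#'   `treatment`, `day`, `matrix`, `aeration_at_sampling`, `storage_flag`.
#' @export
experiment_design <- function(days = c(0, 57, 114, 358, 763),
                              matrices = c("solid", "leachate")) {
  treatments <- rep(c("aerobic", "mixed", "anaerobic"), each = 3)
  first_day <- min(days)
  final_day <- max(days)
  rows <- list()
  for (m in matrices) {
    for (d in days) {
      idx <- if (d == first_day || d == final_day) {
        1:9                                  # all reactors
      } else {
        which(treatments != "anaerobic")     # aerated reactors only
      }
      aer <- vapply(treatments[idx],
                    aeration_state, character(1), day = d)
      rows[[length(rows) + 1L]] <- data.frame(
        reactor_id = (1:9)[idx],
        treatment = treatments[idx],
        day = d,
        matrix = m,
        aeration_at_sampling = aer,
        storage_flag = if (d == 114) "frozen" else "cooled",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Operational state of a treatment at a sampling day: everything is anaerobic
# up to the start of aeration (day 57 sampling happened just before aeration
# began); the mixed treatment returns to anaerobic after its ~1-year aerated
# phase (still aerated at the day-358 sampling, anaerobic at day 763).
aeration_state <- function(treatment, day) {
  if (day <= 57) return("anaerobic")
  switch(treatment,
    aerobic = "aerobic",
    mixed = if (day <= 358) "aerobic" else "anaerobic",
    anaerobic = "anaerobic"
  )
}
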