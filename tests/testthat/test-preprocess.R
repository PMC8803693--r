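test_that("blank subtraction removes the per-sample, per-time blank mean", {
  plate <- tiny_plate(c("D-Xylose" = 0.50), blank_od = 0.10)
  # blanks 0.10, 0.12, 0.08 -> mean 0.10
  plate$od590[plate$substrate == BLANK & plate$replicate == 2] <- 0.12
  plate$od590[plate$substrate == BLANK & plate$replicate == 3] <- 0.08
  out <- subtract_blank(plate)
  expect_true(all(out$substrate != BLANK))
  expect_equal(unique(out$od590), 0.40)

  eq <- subtract_blank(tiny_plate(c("D-Xylose" = 0.10), blank_od = 0.10))
  expect_equal(unique(eq$od590), 0)
})

test_that("a time point without blanks is a hard error", {
  plate <- tiny_plate()
  plate <- plate[!(plate$substrate == BLANK & plate$time_h == 48), ]
  expect_error(subtract_blank(plate), "48")
})

test_that("subtracting a zero blank is idempotent", {
  plate <- tiny_plate(c("D-Xylose" = 0.5), blank_od = 0)
  once <- subtract_blank(plate)
  # re-attach the zero blanks and subtract again
  again <- subtract_blank(rbind(once, plate[plate$substrate == BLANK, ]))
  expect_equal(again$od590, once$od590)
})

test_that("clipping maps negatives to exactly zero and counts them", {
  df <- data.frame(od590 = c(-1, 0, 1, -0.03))
  out <- clip_negatives(df)
  expect_identical(out$od590, c(0, 0, 1, 0))
  expect_equal(attr(out, "n_clipped"), 2L)
  expect_equal(clip_negatives(out)$od590, out$od590)  # fixed point
})

test_that("replicate averaging uses the replicates that are present", {
  plate <- tiny_plate(c("D-Xylose" = 0.2), blank_od = 0)
  plate$od590[plate$substrate == "D-Xylose" & plate$replicate == 2] <- 0.4
  plate$od590[plate$substrate == "D-Xylose" & plate$replicate == 3] <- 0.6
  cur <- average_replicates(clip_negatives(subtract_blank(plate)))
  expect_equal(unique(cur$od), 0.4)
  expect_equal(unique(cur$n_replicates_used), 3L)

  two <- plate[!(plate$substrate == "D-Xylose" & plate$replicate == 3), ]
  cur2 <- average_replicates(clip_negatives(subtract_blank(two)))
  expect_equal(unique(cur2$od), 0.3)
  expect_equal(unique(cur2$n_replicates_used), 2L)

  zeros <- tiny_plate(c("D-Xylose" = 0), blank_od = 0)
  cz <- average_replicates(clip_negatives(subtract_blank(zeros)))
  expect_true(all(cz$od == 0))           # all-zero curve is legal
})

test_that("missing solid replicates are imputed as the donor mean", {
  mk <- function(r, odval) {
    p <- tiny_plate(c("D-Xylose" = odval), blank_od = 0, sample = paste0("s", r),
                    reactor = r, treatment = "mixed", day = 763)
    p
  }
  plate <- rbind(mk(4, 0.2), mk(5, 0.4))
  curves <- average_replicates(clip_negatives(subtract_blank(plate)))
  design <- data.frame(reactor_id = 4:6, treatment = "mixed", day = 763,
                       matrix = "solid", stringsAsFactors = FALSE)
  out <- impute_missing_sample(curves, design)
  imp <- out[out$imputed, ]
  expect_equal(length(unique(imp$sample_id)), 1L)
  expect_equal(unique(imp$od), 0.3)      # mean of 0.2 and 0.4
  expect_equal(unique(imp$reactor_id), 6)
  # donors untouched
  expect_equal(out[!out$imputed, ]$od, curves$od)
})

test_that("leachate samples are never imputed and 1 donor refuses", {
  plate <- tiny_plate(c("D-Xylose" = 0.2), matrix = "leachate",
                      treatment = "mixed", day = 763, blank_od = 0)
  curves <- average_replicates(clip_negatives(subtract_blank(plate)))
  design <- data.frame(reactor_id = c(1, 2), treatment = "mixed", day = 763,
                       matrix = "leachate", stringsAsFactors = FALSE)
  out <- impute_missing_sample(curves, design)
  expect_false(any(out$imputed))
  expect_equal(nrow(attr(out, "missing")), 1L)

  design_s <- data.frame(reactor_id = c(1, 2), treatment = "aerobic", day = 0,
                         matrix = "solid", stringsAsFactors = FALSE)
  plate_s <- tiny_plate(c("D-Xylose" = 0.2), blank_od = 0)
  curves_s <- average_replicates(clip_negatives(subtract_blank(plate_s)))
  expect_warning(out_s <- impute_missing_sample(curves_s, design_s),
                 "fewer than 2")
  expect_false(any(out_s$imputed))
})

test_that("preprocessing a full synthetic experiment attaches a report", {
  sim <- default_sim()
  curves <- suppressWarnings(preprocess_plate(sim$plate))
  cl <- attr(curves, "cleaning")
  expect_gt(cl$n_clipped, 0)
  expect_equal(cl$n_imputed_samples, 1L)
  expect_true(all(curves$od >= 0))
  # the imputed sample is the configured missing one
  imp_ids <- unique(curves$sample_id[curves$imputed])
  expect_equal(imp_ids, "mixed_r6_d763_solid")
})
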