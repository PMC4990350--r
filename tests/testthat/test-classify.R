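mkMeta <- function() quickMeta()   # 40 frames, stim at 7 (30 s), iono at 33

test_that("the maximal-responder definition is applied to archetype traces", {
  meta <- mkMeta()
  tS <- frameTimesS(meta)
  tStim <- stimulusTimeS(meta)
  # rises 5-fold at 10 s post-stimulus, stays within +/- 5%
  fold <- ifelse(tS < tStim + 10, 1, 5)
  fold[tS >= tStim + 10] <- 5 * (1 + 0.04 * sin(seq_len(sum(tS >= tStim + 10))))
  call <- classifyWaveform(foldTrace(fold), meta)
  expect_equal(call$class, "maximal")
  expect_lte(call$time_to_threshold_s, 10)

  # flat trace at 1 +/- 2%: nonresponder
  flat <- 1 + 0.02 * sin(seq_along(tS))
  expect_equal(classifyWaveform(foldTrace(flat), meta)$class, "nonresponder")

  # rises 5-fold at 10 s then decays to 2 by 100 s: transient, not maximal
  dec <- rep(1, length(tS))
  u <- tS - tStim - 10
  dec[u >= 0] <- 2 + 3 * exp(-u[u >= 0] / 40)
  call <- classifyWaveform(foldTrace(dec), meta)
  expect_equal(call$class, "transient")
  expect_gt(call$plateau_deviation, 0.10)

  # crosses threshold only at 100 s (after the 60-s onset window): gradual
  late <- rep(1, length(tS))
  late[tS >= tStim + 100] <- 5
  expect_equal(classifyWaveform(foldTrace(late), meta)$class, "gradual")
})

test_that("classification is invariant to positive rescaling of the trace", {
  meta <- mkMeta()
  tS <- frameTimesS(meta)
  fold <- ifelse(tS < stimulusTimeS(meta) + 10, 1, 5)
  tr <- foldTrace(fold)
  for (c_ in c(0.5, 3, 40)) {
    scaled <- new("FluxTrace", label = 1L, intden = tr@intden * c_,
                  areaPx = tr@areaPx, areaUm2 = tr@areaUm2,
                  background = tr@background, ctcf = tr@ctcf * c_,
                  f0 = tr@f0 * c_, saturated = FALSE, valid = TRUE,
                  reason = "")
    expect_equal(classifyWaveform(scaled, meta)$class,
                 classifyWaveform(tr, meta)$class)
  }
})

test_that("scaling up a maximal excursion never demotes it", {
  meta <- mkMeta()
  tS <- frameTimesS(meta)
  base <- ifelse(tS < stimulusTimeS(meta) + 10, 1, 5)
  expect_equal(classifyWaveform(foldTrace(base), meta)$class, "maximal")
  for (gain in c(1.5, 2, 5)) {
    up <- 1 + (base - 1) * gain    # same shape, larger excursion
    expect_equal(classifyWaveform(foldTrace(up), meta)$class, "maximal")
  }
})

test_that("invalid traces are excluded with a reason, not classified", {
  meta <- mkMeta()
  tr <- foldTrace(rep(2, meta@nFrames))
  tr@valid <- FALSE
  tr@reason <- "non-positive baseline"
  call <- classifyWaveform(tr, meta)
  expect_true(is.na(call$class))
  expect_match(call$reason, "baseline")
})

test_that("the ionomycin viability filter removes only unresponsive cells", {
  meta <- mkMeta()
  tS <- frameTimesS(meta)
  tIono <- ionomycinTimeS(meta)
  # calcium-nonresponsive but ionomycin-responsive: retained nonresponder
  nr <- rep(1, length(tS))
  nr[tS >= tIono] <- 5
  # no response at all: nonviable
  deadF <- rep(1, length(tS))
  # maximal with ionomycin spike
  mx <- ifelse(tS < stimulusTimeS(meta) + 10, 1, 5)
  mx[tS >= tIono] <- 6
  traces <- list(foldTrace(nr, 1), foldTrace(deadF, 2), foldTrace(mx, 3))
  calls <- classifyWaveforms(traces, meta)
  filtered <- viabilityFilter(calls, meta)
  expect_equal(filtered$class, c("nonresponder", "nonviable", "maximal"))
  # all-responsive input passes through unchanged
  calls2 <- classifyWaveforms(list(foldTrace(nr, 1), foldTrace(mx, 2)), meta)
  expect_identical(viabilityFilter(calls2, meta), calls2)
  # no ionomycin frame and no stain: warning, no-op
  meta2 <- quickMeta(ionomycinFrame = NA)
  calls3 <- classifyWaveforms(list(foldTrace(mx[1:40], 1)), meta2)
  expect_warning(out <- viabilityFilter(calls3, meta2), "no-op")
  expect_identical(out, calls3)
})

test_that("waveform calls match generator latent labels on noiseless movies", {
  meta <- AcquisitionMeta(imageSizePx = 256L)   # full 132-frame acquisition
  classes <- rep(c("maximal", "transient", "gradual", "nonresponder",
                   "nonviable"), each = 5)
  sc <- classScene(classes, meta = meta)
  mv <- renderMovie(sc, seed = 31, noiseless = TRUE)
  masks <- sceneMasks(sc)
  traces <- extractTraces(mv, masks$labels)
  calls <- classifyWaveforms(traces, meta)
  via <- viabilityPositive(viabilityChannel(mv), masks$labels)
  calls <- viabilityFilter(calls, meta, viabilityPositive = via)
  truth <- sceneCells(sc)$class[calls$label]
  expect_identical(calls$class, truth)
})

test_that("per-class accuracy is at least 95% at default noise", {
  meta <- AcquisitionMeta(imageSizePx = 256L)
  classes <- rep(c("maximal", "transient", "gradual", "nonresponder",
                   "nonviable"), each = 8)
  sc <- classScene(classes, meta = meta)
  mv <- renderMovie(sc, seed = 32)
  masks <- sceneMasks(sc)
  traces <- extractTraces(mv, masks$labels)
  calls <- classifyWaveforms(traces, meta)
  via <- viabilityPositive(viabilityChannel(mv), masks$labels)
  calls <- viabilityFilter(calls, meta, viabilityPositive = via)
  truth <- sceneCells(sc)$class[calls$label]
  acc <- vapply(unique(truth), function(cl)
    mean(calls$class[truth == cl] == cl), numeric(1))
  expect_true(all(acc >= 0.95))
})
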