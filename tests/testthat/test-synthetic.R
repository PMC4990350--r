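test_that("scene sampling is deterministic and respects the field", {
  cfg <- quickConfig(nCells = 40L)
  meta <- quickMeta()
  s1 <- sampleScene(cfg, 3, seed = 11, meta = meta)
  s2 <- sampleScene(cfg, 3, seed = 11, meta = meta)
  expect_identical(sceneCells(s1), sceneCells(s2))
  s3 <- sampleScene(cfg, 3, seed = 12, meta = meta)
  expect_false(identical(sceneCells(s1), sceneCells(s3)))
  cells <- sceneCells(s1)
  expect_true(all(cells$x_um > cells$radius_um &
                    cells$x_um < meta@fieldSizeUm - cells$radius_um))
  # non-overlap by construction
  d <- as.matrix(dist(cells[, c("x_um", "y_um")]))
  diag(d) <- Inf
  rsum <- outer(cells$radius_um, cells$radius_um, "+")
  expect_true(all(d > rsum))
})

test_that("latent class frequencies follow the configured logistic", {
  # saturation: far above the EC50 with bottom 0 / top 1, every viable
  # cell is maximal
  cfg <- quickConfig(nCells = 60L, deadFraction = 0,
                     responderModel = list(bottom = 0, top = 1,
                                           ec50Mm = 3.2, hill = 4))
  sc <- sampleScene(cfg, 1e6, seed = 5, meta = quickMeta())
  expect_true(all(sceneCells(sc)$class == "maximal"))

  # at the EC50 with top 0.8 the expected maximal fraction is 0.40;
  # check the empirical fraction over 10,000 cells within 3 binomial SDs
  n <- 10000L
  cfgBig <- quickConfig(nCells = n, deadFraction = 0,
                        responderModel = list(bottom = 0, top = 0.8,
                                              ec50Mm = 3.2, hill = 4))
  metaBig <- quickMeta(imageSizePx = 128L)
  metaBig@fieldSizeUm <- 3200
  sc <- sampleScene(cfgBig, 3.2, seed = 7, meta = metaBig)
  pHat <- mean(sceneCells(sc)$class == "maximal")
  expect_lt(abs(pHat - 0.40), 3 * sqrt(0.4 * 0.6 / n))
  # the non-maximal mass splits by the configured weights (also 3 SD)
  pNR <- mean(sceneCells(sc)$class == "nonresponder")
  expect_lt(abs(pNR - 0.6 * 0.5), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("rendered traces follow the latent kinetic model exactly without noise", {
  meta <- quickMeta()
  sc <- classScene(c("maximal", "transient", "gradual", "nonresponder"),
                   meta = meta)
  mv <- renderMovie(sc, seed = 1, noiseless = TRUE)
  masks <- sceneMasks(sc)
  traces <- extractTraces(mv, masks$labels)
  tS <- frameTimesS(meta)
  kin <- defaultKinetics()
  for (i in seq_len(nrow(sceneCells(sc)))) {
    cls <- sceneCells(sc)$class[i]
    latent <- kineticFoldOracle(tS, cls, kin, stimulusTimeS(meta),
                                ionomycinTimeS(meta))
    fold <- foldSeries(traces[[as.character(i)]])
    # 8-bit rounding is the only discrepancy permitted
    expect_lt(max(abs(fold - latent)), 0.05)
  }
})

test_that("maximal cells render at their configured plateau fold", {
  meta <- quickMeta()
  sc <- classScene("maximal", meta = meta)
  mv <- renderMovie(sc, seed = 3, noiseless = TRUE)
  traces <- extractTraces(mv, sceneMasks(sc)$labels)
  fold <- foldSeries(traces[[1]])
  plateauIdx <- 25:32   # late post-stimulus, pre-ionomycin
  expect_lt(abs(mean(fold[plateauIdx]) / 6 - 1), 0.01)
})

test_that("dead cells are flux-flat through ionomycin and viability-bright", {
  meta <- quickMeta()
  sc <- classScene(c("nonviable", "maximal"), meta = meta)
  mv <- renderMovie(sc, seed = 2, noiseless = TRUE)
  traces <- extractTraces(mv, sceneMasks(sc)$labels)
  foldDead <- foldSeries(traces[["1"]])
  expect_lt(max(abs(foldDead - 1)), 0.05)
  labels <- sceneMasks(sc)$labels
  via <- viabilityPositive(viabilityChannel(mv), labels)
  expect_true(via[["1"]])
  expect_false(via[["2"]])
})

test_that("a zero-cell scene renders pure background", {
  meta <- quickMeta()
  sc <- Scene(data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                         radius_um = numeric(), class = character(),
                         f0 = numeric(), viable = logical()),
              doseMm = 1, meta = meta, config = quickConfig(nCells = 0L))
  mv <- renderMovie(sc, seed = 4, noiseless = TRUE)
  expect_true(all(fluxChannel(mv) == 10))
})

test_that("movie rendering is reproducible from the seed", {
  sc <- sampleScene(quickConfig(), 2, seed = 1, meta = quickMeta())
  m1 <- renderMovie(sc, seed = 9)
  m2 <- renderMovie(sc, seed = 9)
  expect_identical(fluxChannel(m1), fluxChannel(m2))
  expect_identical(nuclearChannel(m1), nuclearChannel(m2))
})

test_that("dose series yields one movie per dose with monotone latent fractions", {
  cfg <- quickConfig(nCells = 250L, deadFraction = 0)
  doses <- c(0.5, 0.75, 1, 1.25, 2, 3, 5, 10)
  ser <- simulateDoseSeries(cfg, doses, seed = 3, meta = quickMeta(),
                            render = FALSE)
  expect_length(ser, 8)
  fr <- vapply(ser, function(s) mean(sceneCells(s$scene)$class == "maximal"),
               numeric(1))
  # monotone in expectation; allow small-sample wiggle below binomial noise
  expect_true(all(diff(fr) > -3 * sqrt(0.25 / 250)))
  expect_gt(fr[8], fr[1])
  ser2 <- simulateDoseSeries(cfg, doses, seed = 3, meta = quickMeta(),
                             render = FALSE)
  expect_identical(sceneCells(ser2[[4]]$scene), sceneCells(ser[[4]]$scene))
  expect_error(simulateDoseSeries(cfg, numeric(0)), "empty")
  expect_error(simulateDoseSeries(cfg, c(2, 2)), "distinct")
})

test_that("simulated hormone decay obeys the half-life definition", {
  s <- simulatePTHDecay(100, 0, 4, c(0, 4, 10, 15, 20), noiseSd = 0)
  expect_equal(s$pth_pg_ml[1], 100)
  expect_equal(s$pth_pg_ml[2], 50)
  expect_error(simulatePTHDecay(100, 0, 4, c(0, 5, 5)), "increasing")
  expect_error(simulatePTHDecay(10, 20, 4, c(0, 5)), "p0 > plateau")
  s1 <- simulatePTHDecay(100, 10, 5, 0:20, noiseSd = 3, seed = 42)
  s2 <- simulatePTHDecay(100, 10, 5, 0:20, noiseSd = 3, seed = 42)
  expect_identical(s1, s2)
})

test_that("fixed-field simulation reproduces nuclei under the stated transform", {
  meta <- quickMeta()
  sc <- classScene(c("maximal", "nonresponder", "gradual", "transient"),
                   meta = meta)
  shifted <- simulateFixedField(sc, transform = RigidTransform(7, -4, 0),
                                seed = 1, noiseless = TRUE)
  base <- simulateFixedField(sc, transform = RigidTransform(0, 0, 0),
                             seed = 1, noiseless = TRUE)
  expect_equal(shifted$truth$x_px - base$truth$x_px, rep(7, 4))
  expect_equal(shifted$truth$y_px - base$truth$y_px, rep(-4, 4))
  # PTH painted on exactly the maximal cells -> perfect overlap with the
  # responders by construction
  resp <- simulateFixedField(sc, pthModel = list(
    prob = c(maximal = 1), intensityMean = 110, intensitySd = 0),
    seed = 2, noiseless = TRUE)
  expect_identical(resp$truth$pth_positive,
                   sceneCells(sc)$class == "maximal")
})
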