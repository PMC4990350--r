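test_that("nuclei counting recovers well-separated nuclei and handles empty fields", {
  meta <- quickMeta(imageSizePx = 256L)
  sc <- sampleScene(quickConfig(nCells = 25L, deadFraction = 0), 2,
                    seed = 21, meta = meta)
  mv <- renderMovie(sc, seed = 22)
  nuc <- countNuclei(nuclearChannel(mv), pixelSizeUm(meta))
  expect_equal(nrow(nuc), 25)
  # centroids land on the true cells
  truth <- sceneCells(sc)
  d <- sqrt(outer(nuc$x_um, truth$x_um, "-")^2 +
              outer(nuc$y_um, truth$y_um, "-")^2)
  expect_lt(max(apply(d, 1, min)), 3)

  flat <- matrix(8L, 256, 256)
  expect_equal(nrow(countNuclei(flat, pixelSizeUm(meta))), 0)
  set.seed(1)
  noiseOnly <- matrix(as.integer(pmax(0, round(rnorm(256^2, 8, 2)))), 256, 256)
  expect_equal(nrow(countNuclei(noiseOnly, pixelSizeUm(meta))), 0)
})

test_that("nuclei detection meets 95% recall and precision at default SNR", {
  hits <- 0; detections <- 0; truths <- 0
  for (rep in 1:3) {
    meta <- quickMeta(imageSizePx = 256L)
    sc <- sampleScene(SceneConfig(nCells = 150L), 2, seed = 30 + rep,
                      meta = meta)
    mv <- renderMovie(sc, seed = 40 + rep)
    nuc <- countNuclei(nuclearChannel(mv), pixelSizeUm(meta))
    truth <- sceneCells(sc)
    d <- sqrt(outer(nuc$x_um, truth$x_um, "-")^2 +
                outer(nuc$y_um, truth$y_um, "-")^2)
    matched <- apply(d, 1, min) < truth$radius_um[apply(d, 1, which.min)]
    hits <- hits + sum(matched)
    detections <- detections + nrow(nuc)
    truths <- truths + nrow(truth)
  }
  expect_gte(hits / detections, 0.95)   # precision
  expect_gte(hits / truths, 0.95)       # recall
})

test_that("flux-object detection finds responding cells of 12 um", {
  # grid chosen so the 5-um filter is resolvable (pixel 2.4 um)
  meta <- quickMeta(imageSizePx = 256L)
  sc <- classScene(rep("maximal", 10), meta = meta, radiusUm = 6)
  mv <- renderMovie(sc, seed = 5)
  det <- detectFluxObjects(mv)
  expect_equal(nrow(det$objects), 10)
  expect_true(all(det$objects$equiv_diameter_um > 5))
})

test_that("the 5 um minimal size filter removes small objects", {
  meta <- quickMeta(imageSizePx = 256L)
  cells <- data.frame(id = 1:2,
                      x_um = c(150, 450), y_um = c(300, 300),
                      radius_um = c(1.5, 6),   # 3 um vs 12 um diameter
                      class = "maximal", f0 = 25, viable = TRUE)
  sc <- Scene(cells, doseMm = 5, meta = meta, config = quickConfig())
  mv <- renderMovie(sc, seed = 6, noiseless = TRUE)
  det <- detectFluxObjects(mv, minDiameterUm = 5)
  expect_equal(nrow(det$objects), 1)
  expect_gt(det$objects$x_um[1], 300)   # the 12-um cell survived
  detAll <- detectFluxObjects(mv, minDiameterUm = 0)
  expect_equal(nrow(detAll$objects), 2)
})

test_that("edge objects are excluded only when requested", {
  meta <- quickMeta(imageSizePx = 256L)
  fs <- meta@fieldSizeUm
  cells <- data.frame(id = 1:2,
                      x_um = c(0, fs / 2), y_um = c(fs / 2, fs / 2),
                      radius_um = 6, class = "maximal", f0 = 25,
                      viable = TRUE)
  sc <- Scene(cells, doseMm = 5, meta = meta, config = quickConfig())
  mv <- renderMovie(sc, seed = 7, noiseless = TRUE)
  withEdges <- detectFluxObjects(mv, excludeEdges = FALSE)
  noEdges <- detectFluxObjects(mv, excludeEdges = TRUE)
  expect_equal(nrow(withEdges$objects), 2)
  expect_equal(nrow(noEdges$objects), 1)
  expect_false(any(noEdges$objects$touches_edge))
  # an object fully interior by >= 1 px is never removed by edge exclusion
  expect_true(all(withEdges$objects$touches_edge[
    withEdges$objects$x_um < 10]))
})

test_that("size-filter outcomes are stated in physical units, not pixels", {
  # the same noiseless scene at two grid resolutions yields the same
  # um-scale object decisions
  cells <- data.frame(id = 1:3,
                      x_um = c(120, 300, 480), y_um = c(300, 300, 300),
                      radius_um = c(1.5, 4, 6), class = "maximal",
                      f0 = 25, viable = TRUE)
  counts <- vapply(c(256L, 512L), function(px) {
    meta <- quickMeta(imageSizePx = px)
    sc <- Scene(cells, doseMm = 5, meta = meta, config = quickConfig())
    mv <- renderMovie(sc, seed = 8, noiseless = TRUE)
    nrow(detectFluxObjects(mv, minDiameterUm = 5)$objects)
  }, integer(1))
  expect_equal(counts[1], counts[2])
})

test_that("movies shorter than the baseline window are rejected", {
  meta <- quickMeta(imageSizePx = 32L, nFrames = 8L, ionomycinFrame = NA)
  sc <- sampleScene(quickConfig(nCells = 2L), 2, seed = 1, meta = meta)
  mv <- renderMovie(sc, seed = 2)
  short <- mv
  short@flux <- mv@flux[, , 1:5, drop = FALSE]
  short@meta@nFrames <- 5L
  expect_error(detectFluxObjects(short), "baseline")
})
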