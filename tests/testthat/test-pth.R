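test_that("field quantitation is ratio-invariant and handles empty channels", {
  set.seed(61)
  nuc <- round(matrix(pmax(rnorm(64^2, 40, 5), 0), 64, 64))
  pth <- round(matrix(pmax(rnorm(64^2, 30, 8), 0), 64, 64))
  q1 <- quantifyPTHField(pth, nuc, backgroundThreshold = 0)
  q2 <- quantifyPTHField(2 * pth, 2 * nuc, backgroundThreshold = 0)
  expect_equal(q2$normalized, q1$normalized)
  qZero <- quantifyPTHField(matrix(0, 64, 64), nuc)
  expect_equal(qZero$normalized, 0)
  qNoNuc <- quantifyPTHField(pth, matrix(0, 64, 64))
  expect_true(is.na(qNoNuc$normalized))
})

test_that("median object IntDen matches a brute-force oracle on known masks", {
  meta <- quickMeta()
  sc <- classScene(rep(c("maximal", "nonresponder"), 6), meta = meta)
  ff <- simulateFixedField(sc, pthModel = list(
    prob = c(maximal = 1, nonresponder = 1),
    intensityMean = 100, intensitySd = 20), seed = 62)
  masks <- sceneMasks(sc)
  q <- quantifyPTHField(ff$pth, ff$nuclear, backgroundThreshold = 10,
                        labels = masks$labels)
  pthAdj <- pmax(ff$pth - 10, 0)
  intdens <- vapply(sort(unique(masks$labels[masks$labels > 0])),
                    function(id) sum(pthAdj[masks$labels == id]),
                    numeric(1))
  expect_equal(q$median_intden, median(intdens))
  expect_equal(q$n_objects, 12)
})

test_that("fold suppression reflects constructed intensity reductions", {
  set.seed(63)
  nuc <- round(matrix(pmax(rnorm(128^2, 40, 4), 0), 128, 128))
  pth <- round(matrix(pmax(rnorm(128^2, 54, 5), 0), 128, 128))
  ref <- quantifyPTHField(pth, nuc)
  expect_equal(foldSuppression(ref, ref), 1)
  halfQ <- quantifyPTHField(round(pth / 2), nuc)
  expect_lt(abs(foldSuppression(ref, halfQ) - 2), 0.05)
  # a constructed 2.7-fold reduction is recovered within noise tolerance
  supp <- round(matrix(pmax(rnorm(128^2, 54 / 2.7, 5 / 2.7), 0), 128, 128))
  q27 <- quantifyPTHField(supp, nuc)
  expect_lt(abs(foldSuppression(ref, q27) - 2.7) / 2.7, 0.05)
  zero <- quantifyPTHField(matrix(0, 128, 128), nuc)
  expect_equal(foldSuppression(ref, zero), Inf)
})

test_that("noiseless decay series are recovered essentially exactly", {
  s <- simulatePTHDecay(100, 0, 4, c(0, 10, 15, 20), noiseSd = 0)
  fit <- fitDecay(s)
  expect_true(fit@converged)
  expect_lt(abs(halfLife(fit) / 4 - 1), 1e-6)
  expect_lt(abs(fit@p0 - 100), 1e-4)
  expect_equal(fit@halfLifeMin, log(2) / fit@k)
})

test_that("degenerate series are flagged, not fitted", {
  flat <- data.frame(time_min = c(0, 5, 10), pth_pg_ml = c(80, 80, 80))
  fit <- fitDecay(flat)
  expect_false(fit@converged)
  expect_match(fit@message, "constant|identifiable")
  rising <- data.frame(time_min = c(0, 5, 10), pth_pg_ml = c(50, 60, 80))
  expect_false(fitDecay(rising)@converged)
  expect_error(fitDecay(data.frame(time_min = 0, pth_pg_ml = 50)), ">= 3")
})

test_that("decay fitting is scale-equivariant and beats a grid search", {
  s <- simulatePTHDecay(120, 10, 6, c(0, 5, 10, 15, 20, 30), noiseSd = 2,
                        seed = 64)
  fit <- fitDecay(s)
  s2 <- s
  s2$pth_pg_ml <- s$pth_pg_ml * 7
  fit2 <- fitDecay(s2)
  expect_lt(abs(fit2@k / fit@k - 1), 1e-6)
  expect_lt(abs(fit2@halfLifeMin / fit@halfLifeMin - 1), 1e-6)
  # brute-force grid oracle on (p0, plateau, k)
  grid <- expand.grid(p0 = seq(100, 140, 2), plateau = seq(0, 30, 2),
                      k = seq(0.02, 0.5, 0.005))
  rssGrid <- mapply(function(p0, pl, k)
    sum((s$pth_pg_ml - (pl + (p0 - pl) * exp(-k * s$time_min)))^2),
    grid$p0, grid$plateau, grid$k)
  expect_lte(fit@rss, min(rssGrid) + 1e-8)
})

test_that("noisy half-life recovery stays within 10% median error", {
  errs <- vapply(1:50, function(rep) {
    s <- simulatePTHDecay(100, 0, 4, c(0, 2.5, 5, 7.5, 10, 15, 20),
                          noiseSd = 2, seed = 700 + rep)
    abs(halfLife(fitDecay(s)) / 4 - 1)
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})

test_that("percent decrement follows its definition with interpolation", {
  s <- data.frame(time_min = c(0, 10, 20), pth_pg_ml = c(100, 40, 30))
  expect_equal(percentDecrement(s, 10, "drop"), 60)
  expect_equal(percentDecrement(s, 10, "residual"), 40)
  expect_equal(percentDecrement(s, 0, "drop"), 0)
  expect_equal(percentDecrement(s, 0, "residual"), 100)
  expect_equal(percentDecrement(s, 15, "drop"), 65)   # interpolated
  # exact exponential with 10-min half-life sits on the 50% boundary
  e <- simulatePTHDecay(200, 0, 10, c(0, 5, 10, 15), noiseSd = 0)
  expect_equal(percentDecrement(e, 10, "drop"), 50)
  expect_error(percentDecrement(s, 25), "outside")
  z <- data.frame(time_min = c(0, 10), pth_pg_ml = c(0, 0))
  expect_error(percentDecrement(z, 5), "zero")
})
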