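test_that("dose points store exact integer ratios", {
  p <- dosePoint(NULL, nTotal = 600, caMm = 2, nMaximal = 150)
  expect_equal(p$proportion, 0.25)
  expect_equal(dosePoint(NULL, 600, 2, nMaximal = 0)$proportion, 0)
  calls <- data.frame(class = c("maximal", "maximal", "nonresponder"))
  expect_equal(dosePoint(calls, 10, 2)$n_maximal, 2L)
  expect_error(dosePoint(NULL, 0, 2, nMaximal = 0), "nTotal")
  expect_error(dosePoint(NULL, 5, 2, nMaximal = 7), "below")
})

test_that("the proportion equals a brute-force count over latent labels", {
  cfg <- quickConfig(nCells = 200L)
  sc <- sampleScene(cfg, 3, seed = 41, meta = quickMeta())
  cells <- sceneCells(sc)
  viable <- cells[cells$viable, ]
  p <- dosePoint(data.frame(class = viable$class), nrow(viable), 3)
  expect_equal(p$n_maximal, sum(viable$class == "maximal"))
  expect_equal(p$proportion,
               sum(viable$class == "maximal") / nrow(viable))
})

test_that("noiseless 4PL generative recovery is essentially exact", {
  doses <- c(0.5, 0.75, 1, 1.25, 2, 3, 5, 10)
  p <- 0 + (0.8 - 0) / (1 + 10^((log10(3.2) - log10(doses)) * 4))
  pts <- data.frame(ca_mM = doses, n_total = 600, proportion = p)
  fit <- fit4PL(pts)
  expect_true(fit@converged && fit@identifiable)
  expect_lt(abs(ec50(fit) / 3.2 - 1), 1e-6)
  expect_lt(abs(fit@hill - 4), 1e-4)
  expect_lt(abs(fit@top - 0.8), 1e-6)
})

test_that("degenerate dose tables are flagged unidentifiable, not fatal", {
  doses <- c(0.5, 1, 2, 4)
  flat <- data.frame(ca_mM = doses, n_total = 100, proportion = 0.5)
  fit <- fit4PL(flat)
  expect_false(fit@identifiable)
  expect_true(is.na(ec50(fit)))
  few <- data.frame(ca_mM = c(1, 1, 2, 2), n_total = 100,
                    proportion = c(0.1, 0.12, 0.8, 0.82))
  expect_false(fit4PL(few)@identifiable)
})

test_that("scaling the dose axis scales the fitted EC50", {
  doses <- c(0.5, 0.75, 1, 1.25, 2, 3, 5, 10)
  p <- 0.05 + 0.7 / (1 + 10^((log10(2.5) - log10(doses)) * 3))
  pts <- data.frame(ca_mM = doses, n_total = 600, proportion = p)
  e1 <- ec50(fit4PL(pts))
  for (c_ in c(0.5, 4)) {
    pts2 <- pts
    pts2$ca_mM <- pts$ca_mM * c_
    expect_lt(abs(ec50(fit4PL(pts2)) / (c_ * e1) - 1), 1e-5)
  }
})

test_that("the optimiser matches a brute-force grid search on small instances", {
  set.seed(51)
  doses <- c(0.5, 1, 2, 4, 8)
  for (rep in 1:3) {
    p <- pmin(pmax(0.1 + 0.6 / (1 + 10^((log10(2) - log10(doses)) * 2)) +
                     rnorm(5, 0, 0.03), 0), 1)
    pts <- data.frame(ca_mM = doses, proportion = p)
    fit <- fit4PL(pts, weighting = "none")
    grid <- expand.grid(bottom = seq(0, 0.4, 0.05),
                        top = seq(0.4, 1, 0.05),
                        logEc50 = seq(-0.5, 1, 0.05),
                        hill = c(0.5, 1, 2, 3, 4, 6))
    rssGrid <- mapply(function(b, t, l, h)
      sum((p - (b + (t - b) / (1 + 10^((l - log10(doses)) * h))))^2),
      grid$bottom, grid$top, grid$logEc50, grid$hill)
    expect_lte(fit@rss, min(rssGrid) + 1e-8)
  }
})

test_that("the EC50 bootstrap is seeded and honest about degeneracy", {
  doses <- c(0.5, 0.75, 1, 1.25, 2, 3, 5, 10)
  p <- 0.8 / (1 + 10^((log10(3.2) - log10(doses)) * 4))
  n <- rep(600L, 8)
  pts <- data.frame(ca_mM = doses, n_total = n,
                    n_maximal = as.integer(round(p * n)))
  pts$proportion <- pts$n_maximal / pts$n_total
  fit <- fit4PL(pts)
  ci1 <- ec50Confint(fit, nBoot = 50, seed = 9)
  ci2 <- ec50Confint(fit, nBoot = 50, seed = 9)
  expect_identical(ci1, ci2)
  expect_lt(ci1$lower, ec50(fit))
  expect_gt(ci1$upper, ec50(fit))
  # binomial noise at n = 600 keeps the interval tight around the truth
  expect_lt(ci1$upper / ci1$lower, 1.2)
  badFit <- fit4PL(data.frame(ca_mM = c(1, 2, 4), n_total = 10,
                              proportion = 0.5))
  expect_error(ec50Confint(badFit), "converge")
})

test_that("bootstrap intervals cover the generating EC50", {
  doses <- c(0.5, 0.75, 1, 1.25, 2, 3, 5, 10)
  pTrue <- 0.8 / (1 + 10^((log10(3.2) - log10(doses)) * 4))
  hits <- 0
  nRep <- 10
  for (rep in seq_len(nRep)) {
    set.seed(600 + rep)
    nm <- rbinom(8, 600, pTrue)
    pts <- data.frame(ca_mM = doses, n_total = 600, n_maximal = nm,
                      proportion = nm / 600)
    fit <- fit4PL(pts)
    ci <- ec50Confint(fit, nBoot = 100, seed = rep)
    if (ci$lower <= 3.2 && ci$upper >= 3.2) hits <- hits + 1
  }
  expect_gte(hits, 8)   # ~90% nominal coverage at this n
})
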