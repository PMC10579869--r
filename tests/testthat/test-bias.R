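test_that("pull traces join on time and report the force peak", {
  t <- seq(0, 100, by = 1)
  force <- ifelse(t <= 40, 5 * t, 200 - 2 * (t - 40))  # triangular, peak at 40
  pos <- 0.5 + 0.01 * t                                 # linear ramp
  tr <- pullAnalysis(LabeledSeries(t, force), LabeledSeries(t, pos))
  expect_equal(tr@times, t)                    # identity pairing
  expect_equal(tr@displacement, 0.01 * t)      # relative to first point
  expect_equal(tr@peakForce, 200)
  expect_equal(tr@peakTime, 40)

  # constant position: displacement all zeros
  trc <- pullAnalysis(LabeledSeries(t, force), LabeledSeries(t, rep(2, 101)))
  expect_true(all(trc@displacement == 0))

  expect_error(pullAnalysis(LabeledSeries(0:10, 0:10),
                            LabeledSeries(100:110, 100:110)),
               "overlap")
})

test_that("pull join tolerates slightly offset sampling grids", {
  tf <- seq(0, 10, by = 0.1)
  tp <- tf + 0.01   # within half the sampling interval
  tr <- pullAnalysis(LabeledSeries(tf, sin(tf)), LabeledSeries(tp, tf))
  expect_equal(length(tr@times), length(tf))
})

test_that("window selection walks the distance trace at the given spacing", {
  d <- LabeledSeries(0:100, seq(0, 1, by = 0.01))
  w <- selectWindows(d, 0.2)
  expect_equal(w$centers, seq(0, 1, by = 0.2))
  expect_equal(length(w$frames), 6L)
  expect_equal(max(w$deviation), 0)

  # spacing larger than the range: first and last frames, with a warning
  expect_warning(w2 <- selectWindows(d, 10), "exceeds")
  expect_equal(w2$frames, c(1L, 101L))
  expect_true(w2$degenerate)
})

test_that("window selection equals a brute-force nearest search on noise", {
  set.seed(61)
  dv <- cumsum(abs(rnorm(300, 0.004, 0.004))) + rnorm(300, sd = 0.002)
  w <- selectWindows(LabeledSeries(seq_along(dv) - 1, dv), 0.1)
  # independent re-walk
  sel <- 1L
  repeat {
    target <- dv[sel[length(sel)]] + 0.1
    if (target > dv[length(dv)] + 1e-12) break
    cand <- which.min(abs(dv - target))
    if (cand == sel[length(sel)]) break
    sel <- c(sel, cand)
  }
  expect_equal(w$frames, sel)
  # centers non-decreasing along a monotone trace
  mono <- selectWindows(LabeledSeries(0:50, seq(0, 2, length.out = 51)),
                        0.15)
  expect_true(all(diff(mono$centers) >= 0))
})

test_that("one unbiased window reduces WHAM to direct inversion", {
  set.seed(62)
  smp <- rnorm(20000)
  ws <- new("UmbrellaWindowSet", centers = 0, springK = 0,
            samples = list(smp))
  p <- wham(ws, nBins = 50)
  edges <- seq(min(smp), max(smp), length.out = 51)
  hb <- tabulate(findInterval(smp, edges, rightmost.closed = TRUE), 50)
  direct <- rep(Inf, 50)
  direct[hb > 0] <- -log(hb[hb > 0]) - min(-log(hb[hb > 0]))
  cov <- is.finite(pmfValues(p))
  expect_equal(pmfValues(p)[cov], direct[is.finite(direct)],
               tolerance = 1e-9)
  expect_equal(min(pmfValues(p)[cov]), 0)
})

test_that("duplicated windows do not change the PMF", {
  # a window duplicated against itself reduces to the single window
  set.seed(63)
  smp <- rnorm(3000, 0, sqrt(1 / 11))
  one <- new("UmbrellaWindowSet", centers = 0, springK = 10,
             samples = list(smp))
  two <- new("UmbrellaWindowSet", centers = c(0, 0), springK = c(10, 10),
             samples = list(smp, smp))
  p1 <- wham(one, nBins = 60)
  p2 <- wham(two, nBins = 60)
  cov <- is.finite(pmfValues(p1))
  expect_equal(pmfValues(p2)[cov], pmfValues(p1)[cov], tolerance = 1e-6)

  # duplicating the whole set is likewise a no-op
  ws <- makeUmbrellaWindows(harmonicPotential(), centers = c(-1, 0, 1),
                            springK = 10, nPerWindow = 2000, seed = 63)
  dup <- new("UmbrellaWindowSet",
             centers = rep(ws@centers, 2), springK = rep(ws@springK, 2),
             samples = c(ws@samples, ws@samples))
  p3 <- wham(ws, nBins = 60)
  p4 <- wham(dup, nBins = 60)
  cov3 <- is.finite(pmfValues(p3))
  expect_equal(pmfValues(p4)[cov3], pmfValues(p3)[cov3], tolerance = 1e-6)
})

test_that("WHAM is covariant under a uniform coordinate shift", {
  ws <- makeUmbrellaWindows(harmonicPotential(), centers = seq(-1, 1, 0.5),
                            springK = 10, nPerWindow = 1500, seed = 64)
  shift <- 7.25
  ws2 <- new("UmbrellaWindowSet", centers = ws@centers + shift,
             springK = ws@springK,
             samples = lapply(ws@samples, function(s) s + shift))
  p1 <- wham(ws, nBins = 80)
  p2 <- wham(ws2, nBins = 80)
  expect_equal(p2@binCenters, p1@binCenters + shift, tolerance = 1e-9)
  cov <- is.finite(pmfValues(p1))
  expect_equal(pmfValues(p2)[cov], pmfValues(p1)[cov], tolerance = 1e-8)
})

test_that("WHAM diagnoses gaps and non-convergence", {
  ws <- new("UmbrellaWindowSet", centers = c(0, 10),
            springK = c(50, 50),
            samples = list(rnorm(500, 0, 0.1), rnorm(500, 10, 0.1)))
  expect_warning(try(wham(ws, nBins = 50), silent = TRUE),
                 "share no occupied")
  ws2 <- makeUmbrellaWindows(harmonicPotential(), centers = c(-1, 0, 1),
                             springK = 10, nPerWindow = 500, seed = 65)
  expect_error(suppressWarnings(wham(ws2, maxIterations = 2L)),
               "did not converge")
})

test_that("binding energy averages the terminal PMF plateau", {
  # PMF rising to a flat 8 kT tail
  p <- new("PMFProfile", binCenters = seq(0, 3, length.out = 100),
           pmf = c(seq(0, 8, length.out = 50), rep(8, 50)),
           windowF = 0, iterations = 1L, residual = 0,
           residualHistory = 0, energyUnit = "kT")
  b <- bindingEnergy(p, plateauFraction = 0.1)
  s <- attr(b, "summary")
  expect_equal(s$unbindingCost, 8)
  expect_equal(s$deltaGBind, -8)

  # flat PMF: zero cost
  pf <- new("PMFProfile", binCenters = 1:10, pmf = rep(0, 10),
            windowF = 0, iterations = 1L, residual = 0,
            residualHistory = 0, energyUnit = "kT")
  expect_equal(attr(bindingEnergy(pf), "summary")$unbindingCost, 0)

  # truncated harmonic recovery: plateau equals the direct tail mean
  xc <- seq(0, 3, length.out = 120)
  ph <- new("PMFProfile", binCenters = xc, pmf = 0.5 * xc^2,
            windowF = 0, iterations = 1L, residual = 0,
            residualHistory = 0, energyUnit = "kT")
  keep <- 0.5 * xc^2 <= 4.5
  pt <- new("PMFProfile", binCenters = xc[keep], pmf = (0.5 * xc^2)[keep],
            windowF = 0, iterations = 1L, residual = 0,
            residualHistory = 0, energyUnit = "kT")
  bt <- bindingEnergy(pt, plateauFraction = 0.1)
  k <- max(1, round(0.1 * sum(keep)))
  expect_equal(attr(bt, "summary")$unbindingCost,
               mean(tail((0.5 * xc^2)[keep], k)))
})
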