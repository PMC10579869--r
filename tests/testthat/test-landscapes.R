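felOf <- function(xv, yv, nx = 2, ny = 2, ...)
  buildFEL(LabeledSeries(seq_along(xv) - 1, xv),
           LabeledSeries(seq_along(yv) - 1, yv), nx, ny, ...)

test_that("Boltzmann inversion arithmetic on a 75/25 split", {
  f <- felOf(c(rep(0.25, 75), rep(0.75, 25)), rep(0.5, 100))
  dg <- deltaG(f)
  fin <- sort(dg[is.finite(dg)])
  expect_equal(fin, c(0, log(3)), tolerance = 1e-12)
  # kJ/mol scaling: same ratio times k_B T
  fkj <- felOf(c(rep(0.25, 75), rep(0.75, 25)), rep(0.5, 100),
               temperature = 300, energyUnit = "kJ/mol")
  fin_kj <- sort(deltaG(fkj)[is.finite(deltaG(fkj))])
  expect_equal(fin_kj[2], 0.0083144626 * 300 * log(3), tolerance = 1e-9)
})

test_that("uniform occupancy gives a flat zero surface", {
  xv <- rep(c(0.25, 0.75), each = 50)
  yv <- rep(c(0.25, 0.75), times = 50)
  f <- felOf(xv, yv)
  expect_true(all(deltaG(f) == 0))
  expect_equal(sum(binCounts(f)), 100)
})

test_that("duplicating every frame leaves the surface unchanged", {
  set.seed(41)
  xv <- rnorm(400); yv <- rnorm(400)
  f1 <- felOf(xv, yv, 6, 6)
  f2 <- felOf(rep(xv, 2), rep(yv, 2), 6, 6)
  expect_equal(deltaG(f1), deltaG(f2))
})

test_that("surface invariants hold on random data", {
  set.seed(42)
  f <- felOf(rnorm(2000), rnorm(2000), 10, 10)
  dg <- deltaG(f); ct <- binCounts(f)
  expect_identical(dg[f@minBin[1], f@minBin[2]], 0)
  expect_true(all(dg[is.finite(dg)] >= 0))
  expect_true(all(is.infinite(dg[ct == 0])))
  expect_equal(sum(ct), 2000)
  # monotone: a larger count never has a larger free energy
  ord <- order(ct[ct > 0])
  expect_true(all(diff(dg[ct > 0][ord]) <= 1e-12))
  # mismatched lengths are rejected
  expect_error(felOf(rnorm(5), rnorm(6)), "aligned")
})

test_that("inversion recovers the analytic free energy of a 2D Gaussian", {
  # direct (uncorrelated) Boltzmann draws keep this unit test fast; the
  # Metropolis-sampled version runs in the acceptance suite
  set.seed(43)
  n <- 20000
  f <- felOf(rnorm(n), rnorm(n), 20, 20)
  mx <- diff(pnorm(f@xEdges)); my <- diff(pnorm(f@yEdges))
  M <- outer(mx, my)
  ref <- -log(M / max(M))
  sel <- binCounts(f) >= 50
  d <- deltaG(f)[sel] - ref[sel]
  expect_lt(sqrt(mean((d - mean(d))^2)), 0.15)
})

test_that("minimum-energy frame extraction matches a linear scan", {
  set.seed(44)
  xv <- rnorm(300); yv <- rnorm(300)
  f <- felOf(xv, yv, 5, 5)
  fr <- extractMinEnergyFrames(f, k = 10)
  scan <- which(f@frameToBin[, 1] == f@minBin[1] &
                f@frameToBin[, 2] == f@minBin[2])
  expect_equal(fr, head(sort(scan), 10))
  expect_true(all(extractMinEnergyFrames(f, k = 1e6) == sort(scan)))

  # all frames in one bin: first k indices, no padding past membership
  g <- felOf(rep(0.5, 7), rep(0.5, 7), 2, 2)
  expect_equal(extractMinEnergyFrames(g, 3), 1:3)
  expect_equal(extractMinEnergyFrames(g, 99), 1:7)
  expect_error(extractMinEnergyFrames(g, 0), "k must be")

  # arbitrary user-specified bin
  other <- which(binCounts(f) > 0 & deltaG(f) > 0, arr.ind = TRUE)[1, ]
  fr2 <- extractMinEnergyFrames(f, k = 5, bin = other)
  expect_true(all(f@frameToBin[fr2, 1] == other[1]))
})

test_that("KDE matches the kernel-sum definition exactly", {
  # single point with explicit h: density at the point is 1/(h sqrt(2 pi))
  d1 <- kdeEstimate(0, h = 2, nBins = 1, grid = 0)
  expect_equal(d1@density, 1 / (2 * sqrt(2 * pi)), tolerance = 1e-12)

  # naive double-loop evaluation of the kernel sum at every grid point
  set.seed(45)
  v <- rnorm(200, sd = 2)
  d <- kdeEstimate(v, gridSize = 101)
  h <- d@bandwidth
  naive <- numeric(101)
  for (g in seq_len(101)) {
    acc <- 0
    for (xi in v) {
      t <- (d@grid[g] - xi) / h
      acc <- acc + exp(-t^2 / 2) / sqrt(2 * pi)
    }
    naive[g] <- acc / (length(v) * h)
  }
  expect_equal(d@density, naive, tolerance = 1e-12)
})

test_that("Silverman's rule evaluates exactly as its formula", {
  set.seed(46)
  v <- rnorm(1000)
  d <- kdeEstimate(v)
  expect_equal(d@bandwidth,
               0.9 * min(sd(v), IQR(v) / 1.34) * 1000^(-1 / 5))
  expect_equal(d@bwRule, "silverman")
  expect_error(kdeEstimate(rep(1, 10)), "explicit")
})

test_that("KDE integrates to ~1 and peaks near the sample mode", {
  set.seed(47)
  v <- rnorm(1000, mean = 3)
  d <- kdeEstimate(v)
  integral <- sum(diff(d@grid) * (head(d@density, -1) + tail(d@density, -1)) / 2)
  expect_gte(integral, 0.98)
  expect_lte(integral, 1.0 + 1e-9)
  expect_true(all(d@density >= 0))
  expect_lt(abs(d@grid[which.max(d@density)] - 3), d@bandwidth + 0.2)
})

test_that("comparative KDE shares a grid and preserves each estimate", {
  set.seed(48)
  a <- rnorm(500); b <- rnorm(500, mean = 2)
  cmp <- kdeCompare(list(A = a, B = b))
  expect_named(cmp, c("A", "B"))
  expect_identical(cmp$A@grid, cmp$B@grid)

  # identical samples give identical curves
  same <- kdeCompare(list(x = a, y = a))
  expect_equal(same$x@density, same$y@density)

  # each curve equals its single-dataset estimate on the common grid
  solo <- kdeEstimate(b, grid = cmp$B@grid)
  expect_equal(cmp$B@density, solo@density)

  # translation equivariance (same bandwidth forced)
  d0 <- kdeEstimate(a, h = 0.4, gridSize = 64)
  d1 <- kdeEstimate(a + 5, h = 0.4, gridSize = 64)
  expect_equal(d1@grid, d0@grid + 5, tolerance = 1e-9)
  expect_equal(d1@density, d0@density, tolerance = 1e-9)
})
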