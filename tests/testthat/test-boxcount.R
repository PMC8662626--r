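defaultScales <- scales(scaleSchedule())

test_that("the default schedule is 20 log-spaced edges with constant ratio", {
  s <- defaultScales
  expect_length(s, 20L)
  expect_equal(s[1], 10^0.01)
  expect_equal(s[10], 10^(0.01 + 9 * 0.0495))
  expect_equal(s[20], 10^0.9505)
  # successive quotients all equal 10^0.0495
  expect_equal(s[-1] / s[-20], rep(10^0.0495, 19))
  expect_equal(epsilons(scaleSchedule()) * s, rep(1, 20))
})

test_that("schedule parameters are validated", {
  expect_error(scaleSchedule(1), ">= 2")
  expect_error(scaleSchedule(5, 0.5, 0.5), "maxExp > minExp")
  expect_error(scaleSchedule(5, 0.5, 0.2), "maxExp > minExp")
  # minExp 0 implies an edge of exactly 1 voxel, which degenerates counting
  expect_error(scaleSchedule(2, 0, 1), "> 1")
  two <- scaleSchedule(2, 0.01, 1)
  expect_equal(scales(two), c(10^0.01, 10))
  expect_error(scaleSchedule(scales = c(2, 2, 3)), "increasing")
})

test_that("countBoxes matches hand values on solids", {
  cube8 <- array(TRUE, c(8, 8, 8))
  expect_identical(countBoxes(cube8, 2), 64L)
  expect_identical(countBoxes(cube8, 8), 1L)
  one <- array(FALSE, c(9, 9, 9)); one[4, 7, 2] <- TRUE
  for (s in c(1.5, 2.7, 8))
    expect_identical(countBoxes(one, s), 1L)
})

test_that("countBoxes rejects degenerate input", {
  cube <- array(TRUE, c(4, 4, 4))
  expect_error(countBoxes(cube, 1), "> 1")
  expect_error(countBoxes(cube, 0.5), "> 1")
  expect_error(countBoxes(array(FALSE, c(4, 4, 4)), 2), "empty ROI")
  expect_error(countBoxes(matrix(TRUE, 4, 4), 2), "3D")
})

test_that("countBoxes equals the brute-force floor-triple oracle", {
  m <- randomMask(20, 0.1, seed = 123)
  expect_identical(countBoxes(m, 2.7), bruteCountBoxes(m, 2.7))
  m2 <- randomMask(12, 0.4, seed = 321)
  for (s in c(1.1, 2, 3.9, 11.5))
    expect_identical(countBoxes(m2, s), bruteCountBoxes(m2, s))
})

test_that("counts respect the occupancy and grid-cell bounds", {
  for (seed in 1:20) {
    n <- withSeed(seed, sample(5:24, 1))
    m <- randomMask(n, withSeed(seed + 100, stats::runif(1, 0.02, 0.6)),
                    seed = seed)
    if (!any(m)) next
    occ <- sum(m)
    for (s in defaultScales[c(1, 7, 14, 20)]) {
      nb <- countBoxes(m, s)
      expect_gte(nb, 1L)
      expect_lte(nb, min(occ, prod(ceiling(dim(m) / s))))
    }
  }
})

test_that("counts are non-increasing in s on well-filled masks", {
  masks <- list(array(TRUE, c(32, 32, 32)), array(TRUE, c(48, 48, 1)),
                makePhantom("random_blob", size = 24, seed = 5),
                makePhantom("random_blob", size = 20, seed = 9))
  for (m in masks) {
    N <- vapply(defaultScales, function(s) countBoxes(m, s), numeric(1))
    expect_true(all(diff(N) <= 0))
  }
  # holey structures can straddle more cells at a coarser misaligned grid:
  # the level-3 sponge is a concrete counterexample to global monotonicity
  sponge <- makePhantom("menger_sponge", level = 3)
  Ns <- vapply(defaultScales, function(s) countBoxes(sponge, s), numeric(1))
  expect_false(all(diff(Ns) <= 0))
  expect_lt(Ns[20], Ns[1])  # the overall trend still falls
})

test_that("an exact power-law series is fit exactly", {
  sched <- scaleSchedule()
  for (D in c(1, 2, 2.5, 3)) {
    n <- 10^(5 - D * log10(scales(sched)))
    fit <- fitFD(new("BoxCountSeries", schedule = sched, counts = n))
    expect_equal(fd(fit), D, tolerance = 1e-12)
    expect_lt(rmse(fit), 1e-12)
    expect_equal(rsquared(fit), 1, tolerance = 1e-12)
    expect_equal(fdIntercept(fit), 5, tolerance = 1e-10)
  }
})

test_that("constant counts give dimension zero with r2 defined as zero", {
  sched <- scaleSchedule(5, 0.1, 0.5)
  fit <- fitFD(new("BoxCountSeries", schedule = sched,
                   counts = rep(7, 5)))
  expect_equal(fd(fit), 0)
  expect_equal(rsquared(fit), 0)
  expect_equal(rmse(fit), 0)
})

test_that("fit preconditions are enforced", {
  sched <- scaleSchedule(2, 0.1, 0.5)
  expect_error(new("BoxCountSeries", schedule = sched, counts = c(0, 5)))
  expect_error(new("BoxCountSeries", schedule = sched, counts = 4))
  expect_error(fitFD(data.frame(s = 1, n = 1)))
})

test_that("estimateFD stores exactly the counted series", {
  m <- makePhantom("random_blob", size = 16, seed = 3)
  sched <- scaleSchedule(6, 0.1, 0.8)
  est <- estimateFD(m, sched)
  expect_equal(counts(countSeries(est)),
               vapply(scales(sched), function(s) countBoxes(m, s),
                      numeric(1)))
  expect_identical(nPoints(est), 6L)
  # deterministic: same mask, same result
  expect_equal(fd(estimateFD(m, sched)), fd(est))
})

test_that("sponge counts are exact at construction-aligned scales", {
  sponge <- makePhantom("menger_sponge", level = 4)
  expect_identical(countBoxes(sponge, 3), 8000L)   # 20^3
  expect_identical(countBoxes(sponge, 9), 400L)    # 20^2
  expect_identical(countBoxes(sponge, 27), 20L)    # 20^1
  # a base-3 schedule recovers the similarity dimension to float precision
  fit <- estimateFD(sponge, scaleSchedule(scales = c(3, 9, 27)))
  expect_equal(fd(fit), log(20) / log(3), tolerance = 1e-12)
  expect_lt(rmse(fit), 1e-12)
})

test_that("misaligned scales overcount the sponge and flatten the slope", {
  # boxes that straddle the base-3 holes inflate N(s) at every edge length
  # that is not a power of 3, biasing the default-schedule estimate low and
  # inflating the linearity RMSE past the multifractal-suspect threshold
  sponge <- makePhantom("menger_sponge", level = 4)
  est <- estimateFD(sponge)
  expect_gt(fd(est), 2.4)
  expect_lt(fd(est), log(20) / log(3))
  expect_identical(linearityFlag(est), "multifractal_suspect")
})

test_that("translation sensitivity is bounded", {
  cube <- makePhantom("filled_cube", size = 64)
  base <- estimateFD(cube)
  shifted <- volumeData(embedPhantom(cube, c(66, 66, 66), 1)) > 0
  shiftedFit <- estimateFD(shifted)
  expect_lt(abs(fd(shiftedFit) - fd(base)), 0.1)
  # per-scale change bounded by the cells the cube's faces occupy
  for (s in defaultScales[c(3, 10, 18)]) {
    k <- countBoxes(cube, s)
    perAxis <- floor(63 / s) + 1
    # a one-voxel shift adds at most one occupied cell layer per axis
    expect_lte(abs(countBoxes(shifted, s) - k),
               (perAxis + 1)^3 - perAxis^3)
  }
})

test_that("linearity flag splits on the RMSE threshold", {
  sched <- scaleSchedule(5, 0.1, 0.5)
  exact <- fitFD(new("BoxCountSeries", schedule = sched,
                     counts = 10^(3 - 2 * log10(scales(sched)))))
  expect_identical(linearityFlag(exact), "fractal_ok")
  expect_identical(linearityFlag(exact, 1e-9), "fractal_ok")
  noisy <- new("FDResult", fd = 2, slope = -2, intercept = 3, rmse = 0.2,
               r2 = 0.9, nPoints = 5L,
               series = new("BoxCountSeries", schedule = sched,
                            counts = rep(2, 5)))
  expect_identical(linearityFlag(noisy, 0.05), "multifractal_suspect")
  expect_error(linearityFlag(noisy, 0), "> 0")
})

test_that("FD results serialize to rows and JSON", {
  est <- estimateFD(makePhantom("slab", size = 16),
                    scaleSchedule(5, 0.1, 0.8))
  row <- fdResultRow(est, session_id = "OAS30001_MR_d0129",
                     region = "whole_volume")
  expect_identical(names(row)[1:2], c("session_id", "region"))
  expect_equal(row$fd, fd(est))
  parsed <- jsonlite::fromJSON(fdResultJSON(est))
  expect_equal(parsed$fd, fd(est))
  expect_length(parsed$scale, 5L)
  tab <- as.data.frame(countSeries(est))
  expect_identical(names(tab), c("scale", "n_boxes"))
  expect_equal(nrow(tab), 5L)
})
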