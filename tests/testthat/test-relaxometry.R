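test_that("log-linear T2 initializer handles exact and degenerate inputs", {
  te4 <- TE6[1:4]
  ## exact mono-exponential recovers T2 exactly
  expect_equal(loglinearInitT2(100 * exp(-te4 / 70), te4), 70)
  ## flat signal: formally infinite T2, clamps to the 200 ms upper bound
  expect_equal(loglinearInitT2(rep(50, 4), te4), 200)
  ## rising signal and nonpositive signals take the 70 ms fallback
  expect_equal(loglinearInitT2(c(10, 20, 30, 40), te4), 70)
  expect_equal(loglinearInitT2(c(100, 80, 0, 40), te4), 70)
  ## clamping into [20, 200]
  expect_equal(loglinearInitT2(100 * exp(-te4 / 5), te4), 20)
  expect_equal(loglinearInitT2(100 * exp(-te4 / 5000), te4), 200)
})

test_that("pool initialization follows the 10/90/last-echo amplitude rule", {
  s <- c(1000, 900, 800, 500, 200, 50)
  ini <- initPools(s, TE6)
  expect_equal(ini$a, c(100, 900, 50))
  expect_equal(ini$t2[1], 10)
  expect_equal(ini$t2[3], 2000)
  expect_false(ini$unfittable)
  ## a pure intermediate pool initializes T2_IEW at its true value
  s2 <- 500 * exp(-TE6 / 70)
  expect_equal(initPools(s2, TE6)$t2[2], 70, tolerance = 1e-6)
  ## all-zero voxel is flagged unfittable
  expect_true(initPools(rep(0, 6), TE6)$unfittable)
})

test_that("noiseless three-pool signals are recovered by the bounded fit", {
  a <- c(10, 85, 5); t2 <- c(10, 70, 1000)
  s <- threePoolOracle(a, t2, TE6)
  f <- fitVoxel(s, TE6)
  wf <- computeWF(f)
  expect_lt(max(abs(wf - c(0.10, 0.85, 0.05))), 0.01)
  expect_true(f$converged)
  ## single-pool signal: spurious pools stay near zero
  s1 <- threePoolOracle(c(0, 100, 0), c(10, 70, 1000), TE6)
  wf1 <- computeWF(fitVoxel(s1, TE6))
  expect_lte(wf1["mwf"], 0.01)
  expect_lte(wf1["csff"], 0.01)
  ## zero signal propagates the unfittable flag
  f0 <- fitVoxel(rep(0, 6), TE6)
  expect_true(f0$unfittable)
  expect_true(all(is.na(computeWF(f0))))
})

test_that("round-trip recovery holds for well-separated random truths", {
  set.seed(7)
  nOk <- 0L
  nCase <- 40L
  for (i in seq_len(nCase)) {
    t2 <- c(runif(1, 8, 15), runif(1, 50, 120), runif(1, 800, 2000))
    wfTrue <- c(runif(1, 0.05, 0.2), runif(1, 0.6, 0.9), runif(1, 0.02, 0.2))
    wfTrue <- wfTrue / sum(wfTrue)
    s <- threePoolOracle(1000 * wfTrue, t2, TE6)
    f <- fitVoxel(s, TE6)
    wf <- computeWF(f)
    if (max(abs(wf - wfTrue)) <= 0.02) nOk <- nOk + 1L
    ## bound compliance and objective decrease hold case by case
    b <- poolBounds()
    expect_true(all(f$t2 >= b[, 1] - 1e-9 & f$t2 <= b[, 2] + 1e-9))
    ini <- initPools(s, TE6)
    objInit <- sum((s - threePoolOracle(ini$a, ini$t2, TE6))^2)
    expect_lte(f$objective, objInit + 1e-9)
  }
  expect_gte(nOk / nCase, 0.95)
})

test_that("objective never increases on noisy voxels either", {
  set.seed(11)
  for (i in 1:10) {
    s <- threePoolOracle(c(100, 850, 60), c(10, 70, 1500), TE6) +
      rnorm(6, 0, 10)
    s <- pmax(s, 1)
    ini <- initPools(s, TE6)
    f <- fitVoxel(s, TE6, init = ini)
    objInit <- sum((s - threePoolOracle(ini$a, ini$t2, TE6))^2)
    expect_lte(f$objective, objInit + 1e-9)
  }
})

test_that("computeWF is the amplitude ratio with exact closure", {
  expect_equal(computeWF(c(10, 85, 5)),
               c(mwf = 0.10, iewf = 0.85, csff = 0.05))
  expect_equal(unname(computeWF(c(0, 1, 0))), c(0, 1, 0))
  expect_true(all(is.na(computeWF(c(0, 0, 0)))))
  expect_error(computeWF(c(-1, 1, 0)), "nonnegative")
  set.seed(3)
  for (i in 1:20) {
    a <- runif(3, 0, 100)
    expect_equal(sum(computeWF(a)), 1, tolerance = 1e-12)
  }
})

test_that("volume fit with lambda = 0 equals independent voxel fits", {
  dims <- c(3, 1, 1)
  sigs <- rbind(threePoolOracle(c(100, 850, 50), c(10, 60, 2000), TE6),
                threePoolOracle(c(40, 900, 60), c(12, 80, 1500), TE6),
                threePoolOracle(c(0, 0, 1000), c(10, 70, 2000), TE6))
  arr <- array(0, c(dims, 6))
  for (v in 1:3) arr[v, 1, 1, ] <- sigs[v, ]
  ev <- EchoVolume(arr, c(1.3, 1.3, 5), TE6)
  fit <- fitVolume(ev, array(TRUE, dims))
  for (v in 1:3) {
    fv <- fitVoxel(sigs[v, ], TE6)
    expect_equal(fit$params$aCSF[v, 1, 1], fv$a[3], tolerance = 1e-12)
    expect_equal(fit$params$t2IEW[v, 1, 1], fv$t2[2], tolerance = 1e-12)
  }
  expect_true(all(fit$quality[array(TRUE, dims)] == 0L))
})

test_that("uniform noiseless phantom yields spatially constant maps", {
  s <- threePoolOracle(c(100, 850, 50), c(10, 60, 2000), TE6)
  ev <- uniformEchoVolume(s, dims = c(4, 4, 2))
  for (lam in c(0, 1)) {
    fit <- fitVolume(ev, array(TRUE, c(4, 4, 2)),
                     config = fitConfig(lambda = lam, nStarts = 1))
    cs <- wfMap(fit$wf, "csff")
    expect_lt(diff(range(cs)), 1e-6)
  }
})

test_that("spatial smoothing does not degrade CSFF accuracy under noise", {
  ## piecewise-constant phantom: two tissue blocks, moderate noise; the
  ## Laplacian penalty should reduce (or at least not increase) CSFF RMSE
  dims <- c(6, 6, 3)
  arr <- array(0, c(dims, 6))
  trueCs <- array(0, dims)
  sA <- threePoolOracle(c(110, 840, 50), c(10, 60, 2000), TE6)
  sB <- threePoolOracle(c(35, 925, 40), c(10, 80, 2000), TE6)
  for (i in 1:6) for (j in 1:6) for (k in 1:3) {
    left <- i <= 3
    arr[i, j, k, ] <- if (left) sA else sB
    trueCs[i, j, k] <- if (left) 0.05 else 0.04
  }
  clean <- EchoVolume(arr, c(1.3, 1.3, 5), TE6)
  nm <- NoiseModel(10, 32L)
  tab <- buildCorrectionTable(nm)
  mask <- array(TRUE, dims)
  rmse <- function(fit) sqrt(mean((wfMap(fit$wf, "csff")[mask] -
                                   trueCs[mask])^2))
  r0 <- c(); r1 <- c()
  for (seed in 1:5) {
    corr <- correctMagnitude(addNcChiNoise(clean, nm, seed = seed), tab)
    r0 <- c(r0, rmse(fitVolume(corr, mask,
                               config = fitConfig(lambda = 0, nStarts = 1))))
    r1 <- c(r1, rmse(fitVolume(corr, mask,
                               config = fitConfig(lambda = 0.5,
                                                  nStarts = 1))))
  }
  expect_lte(mean(r1), mean(r0))
})

test_that("volume fit validates its inputs", {
  ev <- uniformEchoVolume(rep(1, 6), dims = c(3, 3, 2))
  expect_error(fitVolume(ev, array(FALSE, c(3, 3, 2))), "empty mask")
  bad <- echoData(ev); bad[2, 1, 1, 3] <- NaN
  evBad <- EchoVolume(bad, voxelSize(ev), echoTimes(ev))
  expect_error(fitVolume(evBad, array(TRUE, c(3, 3, 2))),
               "\\(2, 1, 1\\), echo 3")
})

test_that("unfittable voxels are flagged and excluded from the maps", {
  dims <- c(2, 1, 1)
  arr <- array(0, c(dims, 6))
  arr[1, 1, 1, ] <- threePoolOracle(c(100, 850, 50), c(10, 60, 2000), TE6)
  ev <- EchoVolume(arr, c(1.3, 1.3, 5), TE6)
  fit <- fitVolume(ev, array(TRUE, dims))
  expect_identical(fit$quality[1, 1, 1], 0L)
  expect_identical(fit$quality[2, 1, 1], 1L)
  expect_true(definedMask(fit$wf)[1, 1, 1])
  expect_false(definedMask(fit$wf)[2, 1, 1])
  expect_true(is.na(wfMap(fit$wf, "csff")[2, 1, 1]))
})
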