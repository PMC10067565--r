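test_that("breath segmentation recovers a pure ventilatory sinusoid", {
  fr <- 50
  t <- (0:(60 * fr - 1)) / fr
  sig <- 100 + 5 * (1 - cos(2 * pi * 0.5 * t))  # 30 cycles/min, range 10
  bt <- detectBreaths(sig, rateHint = 30, rate = fr)
  expect_equal(breathCount(bt), 30)
  expect_equal(breathTable(bt)$globalDeltaZ, rep(10, 30), tolerance = 0.01)
  expect_error(detectBreaths(rep(7, 3000), rateHint = 30, rate = fr),
               "no breaths")
  expect_warning(detectBreaths(sig, rateHint = 80, rate = fr),
                 "inconsistent")
})

test_that("detected end-expiration matches simulator truth within 2 samples", {
  hits <- 0; total <- 0
  for (sd in 1:3) {
    m <- buildLungModel(simConfig(seed = sd))
    m <- stepState(m, ventSettings(), posture("supine"), 150)$model
    set.seed(sd + 100)
    s <- renderFrames(m, ventSettings(), posture("supine"), 30)
    tb <- breathTable(detectBreaths(s, 30, defaultRoiMask()))
    truth <- seq(0, 28, by = 2) * 50 + 1  # breath boundaries every 2 s
    err <- vapply(tb$startIdx, function(i) min(abs(i - truth)), numeric(1))
    hits <- hits + sum(err <= 2); total <- total + length(err)
  }
  expect_gte(hits / total, 0.95)
})

test_that("regional deltaZ localizes and is partition-additive", {
  cfg <- simConfig(seed = 15, noise_sd = 0, cardiac_amplitude = 0,
                   injury_severity = 0)
  m <- buildLungModel(cfg)
  mask <- defaultRoiMask()
  u <- lungUnits(m)
  quad <- mask@quadrant[u$pixel + 1]
  u$compliance[quad != "lower_left"] <- 0
  m@units <- u
  s <- renderFrames(m, ventSettings(), posture("supine"), 20)
  bt <- detectBreaths(s, 30, mask)
  dzQ <- regionalDeltaZ(s, bt, mask, "quadrant")
  expect_true(all(abs(dzQ[, c("upper_right", "upper_left",
                              "lower_right")]) < 1e-9))
  expect_true(all(dzQ[, "lower_left"] > 0))

  ## additivity at machine precision on a noisy injured render
  m2 <- buildLungModel(simConfig(seed = 16))
  m2 <- stepState(m2, ventSettings(), posture("supine"), 120)$model
  set.seed(16)
  s2 <- renderFrames(m2, ventSettings(), posture("supine"), 20)
  bt2 <- detectBreaths(s2, 30, mask)
  dzQ2 <- regionalDeltaZ(s2, bt2, mask, "quadrant")
  dzH2 <- regionalDeltaZ(s2, bt2, mask, "half")
  dzL2 <- regionalDeltaZ(s2, bt2, mask, "lung")
  expect_equal(rowSums(dzQ2), rowSums(dzH2), tolerance = 1e-9)
  expect_equal(rowSums(dzQ2), drop(dzL2), tolerance = 1e-9)
  expect_error(roiPixels(mask, "upper_middle"), "unknown")
})

test_that("ventilation shares normalize, clip noise, and scale-invariate", {
  expect_equal(as.numeric(ventilationDistribution(c(a = 3, b = 1, c = 0,
                                                     d = 0))),
               c(75, 25, 0, 0))
  d <- ventilationDistribution(c(5, 5, 5, 5))
  expect_equal(as.numeric(d), rep(25, 4))
  dneg <- ventilationDistribution(c(6, -1, 2, 0))
  expect_equal(sum(dneg), 100)
  expect_equal(attr(dneg, "clipped"), -1)
  expect_error(ventilationDistribution(c(0, 0, 0)), "positive")
  ## invariance to rescaling all frames
  x <- c(4, 3, 2, 1)
  expect_equal(as.numeric(ventilationDistribution(x)),
               as.numeric(ventilationDistribution(10 * x)))
})

test_that("regional tidal volume and compliance follow their identities", {
  expect_equal(unname(regionalTidalVolume(c(r = 30), 350)), 105)
  expect_equal(unname(regionalTidalVolume(c(r = 100), 350)), 350)
  expect_equal(regionalCompliance(105, 15), 7)
  expect_error(regionalCompliance(105, 0), "positive")
  expect_error(regionalTidalVolume(c(50, 50), -1), "positive")
  set.seed(17)
  for (k in 1:100) {
    dz <- rgamma(4, 2)
    vt <- runif(1, 100, 600)
    dp <- runif(1, 5, 30)
    shares <- ventilationDistribution(dz)
    vtr <- regionalTidalVolume(shares, vt)
    expect_equal(sum(vtr), vt, tolerance = 1e-9)
    cz <- regionalCompliance(vtr, dp)
    expect_equal(sum(cz), vt / dp, tolerance = 1e-9)
    expect_equal(cz * dp, vtr, tolerance = 1e-12)
  }
})

test_that("known quadrant tidal ratios are recovered from rendered frames", {
  sc <- ventilationRecoveryScenario(c(0.4, 0.3, 0.2, 0.1), seed = 18)
  bt <- detectBreaths(sc$seq, 30, sc$mask)
  rec <- ventilationDistribution(colMeans(regionalDeltaZ(sc$seq, bt, sc$mask,
                                                         "quadrant")))
  expect_equal(as.numeric(rec) / 100, unname(sc$truth), tolerance = 0.02)
  ## a 40% dorsal-half split is recovered within 2 percentage points
  sc2 <- ventilationRecoveryScenario(c(0.30, 0.30, 0.20, 0.20), seed = 19)
  bt2 <- detectBreaths(sc2$seq, 30, sc2$mask)
  recH <- ventilationDistribution(colMeans(regionalDeltaZ(sc2$seq, bt2,
                                                          sc2$mask, "half")))
  expect_equal(unname(recH["dorsal"]), 40, tolerance = 2)
})

test_that("EELI series and deltaEELI behave under constructed offsets", {
  m <- buildLungModel(simConfig(seed = 20))
  m <- stepState(m, ventSettings(), posture("supine"), 120)$model
  mask <- defaultRoiMask()
  set.seed(20)
  s <- renderFrames(m, ventSettings(), posture("supine"), 40)
  bt <- detectBreaths(s, 30, mask)
  es <- eeliSeries(s, bt, mask, "quadrant")
  ## identical epochs give zero change
  d0 <- deltaEeli(es, c(0, 40), c(0, 40))
  expect_equal(d0$global, 0)
  expect_true(all(d0$regional == 0))
  expect_error(deltaEeli(es, c(100, 110), c(0, 40)), "epoch")

  ## a constant +K offset on one quadrant's pixels moves only that quadrant,
  ## by K x pixel count
  K <- 3
  px <- roiPixels(mask, "lower_right")
  fm <- frameMatrix(s)
  half <- frameTimes(s) >= 19
  fm[half, px] <- fm[half, px] + K
  s2 <- frameSequence(fm, frameRate(s), events = eitEvents(s),
                      metadata = seqMetadata(s))
  es2 <- eeliSeries(s2, bt, mask, "quadrant")
  d2 <- deltaEeli(es2, c(0, 18.5), c(20, 40))
  base <- deltaEeli(es, c(0, 18.5), c(20, 40))
  shift <- d2$regional - base$regional
  expect_equal(unname(shift["lower_right"]), K * length(px),
               tolerance = 1e-6)
  expect_true(all(abs(shift[c("upper_right", "upper_left",
                              "lower_left")]) < 1e-9))

  ## noise-only epochs: |deltaEELI| bounded by 3 standard errors
  set.seed(33)
  noise <- matrix(rnorm(3000 * 1024, 0, 0.05), 3000, 1024)
  carrier <- 50 + 10 * (1 - cos(2 * pi * 0.5 * (0:2999) / 50))
  lungPx <- roiPixels(mask, "lung")
  noise[, lungPx] <- noise[, lungPx] + carrier / length(lungPx)
  s3 <- frameSequence(noise, 50)
  bt3 <- detectBreaths(s3, 30, mask)
  es3 <- eeliSeries(s3, bt3, mask, "half")
  dA <- es3$global[es3$time < 30]; dB <- es3$global[es3$time >= 30]
  d3 <- deltaEeli(es3, c(0, 29.9), c(30, 60))
  se <- sqrt(var(dA) / length(dA) + var(dB) / length(dB))
  expect_lt(abs(d3$global), 3 * se + 1e-9)
})
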