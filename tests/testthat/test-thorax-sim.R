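test_that("model construction is deterministic and respects the healthy limit", {
  cfg <- simConfig(seed = 11)
  m1 <- buildLungModel(cfg)
  m2 <- buildLungModel(cfg)
  expect_identical(lungUnits(m1), lungUnits(m2))
  m3 <- buildLungModel(simConfig(seed = 12))
  expect_false(identical(lungUnits(m1)$compliance, lungUnits(m3)$compliance))

  ## healthy limit: opening pressures all <= 0, nothing ever collapses
  h <- buildLungModel(simConfig(seed = 11, injury_severity = 0))
  expect_true(all(lungUnits(h)$opening <= 0))
  for (p in c(0, 5, 10)) {
    st <- stepState(h, ventSettings(peep = p), posture("supine"), 150)
    expect_true(all(lungUnits(st$model)$open))
  }

  ## unit count equals the lung-mask size; positions inside the thorax ellipse
  mask <- defaultRoiMask(cfg$grid)
  expect_equal(nrow(lungUnits(m1)), sum(mask@lungMask))
  expect_true(validObject(m1))
  expect_true(all(lungUnits(m1)$opening >= lungUnits(m1)$closing))
})

test_that("invalid simulator configurations are rejected", {
  expect_error(simConfig(ap_span = -1), "positive")
  expect_error(simConfig(ap_span = 30, rl_span = 25), "right-left")
  expect_error(simConfig(injury_severity = 1.5), "injury_severity")
  expect_error(simConfig(noise_sd = -0.1), "amplitudes")
  expect_error(posture("supine", tilt = 20), "supine")
  expect_error(ventSettings(tidalVolume = 0), "tidalVolume")
})

test_that("transpulmonary pressure follows the rotated linear pleural gradient", {
  cfg <- simConfig(seed = 2)
  m <- buildLungModel(cfg)
  ## at gravitational depth 0 (least-dependent unit), P_L = airway pressure
  pl <- transpulmonaryPressure(m, 25, posture("supine"))
  gd <- gravitationalDepth(lungUnits(m)$depth, lungUnits(m)$lateral,
                           posture("supine"))
  expect_equal(pl[which.min(gd)], 25, tolerance = 1e-9)
  ## linear gradient: 10 cm apart along gravity differ by 10 x 0.5 cmH2O
  i <- which.min(gd)
  j <- which.min(abs(gd - (gd[i] + 10)))
  expect_equal(pl[i] - pl[j], cfg$pleural_gradient * (gd[j] - gd[i]),
               tolerance = 1e-9)
  ## lateral spread exceeds the supine spread (rl span > ap span)
  sprSup <- diff(range(pl))
  sprLat <- diff(range(transpulmonaryPressure(m, 25, posture("lateral_left"))))
  sprLatR <- diff(range(transpulmonaryPressure(m, 25,
                                               posture("lateral_right"))))
  expect_gt(sprLat, sprSup)
  expect_gt(sprLatR, sprSup)
})

test_that("emergent driving pressure is tidal volume over open compliance", {
  m <- buildLungModel(simConfig(seed = 3, injury_severity = 0))
  ## scale total compliance to exactly 20 mL/cmH2O
  u <- lungUnits(m)
  u$compliance <- u$compliance / sum(u$compliance) * 20
  m@units <- u
  st <- stepState(m, ventSettings(tidalVolume = 350), posture("supine"), 1)
  expect_equal(st$physio$drivingPressure, 17.5, tolerance = 1e-12)

  ## strictly more open units => strictly lower driving pressure
  u$open[seq_len(50)] <- FALSE
  m2 <- m; m2@units <- u
  st2 <- stepState(m2, ventSettings(tidalVolume = 350, peep = 20),
                   posture("supine"), 1)
  expect_gt(st2$physio$drivingPressure, st$physio$drivingPressure)
})

test_that("hysteresis: PEEP above every closing pressure prevents collapse", {
  cfg <- simConfig(seed = 4, pleural_gradient = 0)
  m <- buildLungModel(cfg)
  peep <- max(lungUnits(m)$closing) + 0.5
  st <- stepState(m, ventSettings(peep = peep), posture("supine"), 100)
  expect_true(all(lungUnits(st$model)$open))
})

test_that("steady-state collapse matches a unit-by-unit brute-force evaluation", {
  cfg <- simConfig(seed = 5, derecruit_damage = c(0, 0))
  m <- buildLungModel(cfg)
  v <- ventSettings(tidalVolume = 480, peep = 10)
  st <- stepState(m, v, posture("supine"), 30)
  oracle <- naiveBreathLoop(m, v, posture("supine"), 30)
  expect_identical(lungUnits(st$model)$open, oracle)
  ## P_L rule consistency at the final state
  u <- lungUnits(st$model)
  plExp <- transpulmonaryPressure(st$model, v$peep, posture("supine"))
  plInsp <- transpulmonaryPressure(
    st$model, v$peep + st$physio$drivingPressure, posture("supine"))
  expect_true(all(plExp[u$open] >= u$closing[u$open]))
  ## units that can neither open nor stay open are collapsed
  stuck <- plInsp < u$opening & plExp < u$closing
  expect_true(all(!u$open[stuck]))
})

test_that("a dependent unit recruited by lateral posture persists in supine", {
  ## hand-computed trajectory for a single test unit riding on a large
  ## always-open carrier unit (compliance 20, so deltaP = 300/20 = 15):
  ##   gravity supine: carrier depth 5, unit depth 16, gradient 1 =>
  ##     unit pleural = 11; PEEP 10: insp P_L = 25 - 11 = 14 < opening 22
  ##     -> stays closed (deficit 8)
  ##   lateral_right (unit x = +14): unit grav depth = 0.866*16 + (-0.5*14)
  ##     relative to carrier = 2.53; PEEP 15: insp P_L = 30 - 2.53 = 27.5
  ##     > 22 -> opens; exp P_L = 15 - 2.53 = 12.5 >= closing 2 -> stays
  ##   supine PEEP 14: exp P_L = 14 - 11 = 3 >= 2 -> remains open
  ##   (at PEEP 10 it would have collapsed: 10 - 11 = -1 < 2)
  cfg <- simConfig(seed = 6, pleural_gradient = 1,
                   derecruit_damage = c(0, 0))
  m <- buildLungModel(cfg)
  u <- lungUnits(m)[1:2, ]
  u$depth <- c(5, 16); u$lateral <- c(0, 14)
  u$compliance <- c(20, 0)
  u$opening <- c(-100, 22); u$closing <- c(-100, 2)
  u$open <- c(TRUE, FALSE); u$damage <- 0; u$damageThreshold <- 0
  m@units <- u
  v <- ventSettings(tidalVolume = 300, peep = 10)

  st <- stepState(m, v, posture("supine"), 5)
  expect_false(lungUnits(st$model)$open[2])

  v$peep <- 15
  st <- stepState(st$model, v, posture("lateral_right"), 5)
  expect_true(lungUnits(st$model)$open[2])

  v$peep <- 14
  st <- stepState(st$model, v, posture("supine"), 5)
  expect_true(lungUnits(st$model)$open[2])

  v$peep <- 10
  st <- stepState(st$model, v, posture("supine"), 5)
  expect_false(lungUnits(st$model)$open[2])
})

test_that("raising PEEP never increases steady-state collapse", {
  counts <- vapply(c(8, 12, 16), function(p) {
    m <- buildLungModel(simConfig(seed = 2))
    st <- stepState(m, ventSettings(peep = p), posture("supine"), 200)
    sum(!lungUnits(st$model)$open)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("all-collapsed state is a flagged degenerate error", {
  m <- buildLungModel(simConfig(seed = 7))
  u <- lungUnits(m); u$open <- FALSE; m@units <- u
  expect_error(stepState(m, ventSettings(), posture("supine"), 1),
               "degenerate")
})

test_that("perfusion fractions stay normalized under gravity and HPV factors", {
  m <- buildLungModel(simConfig(seed = 8))
  st <- stepState(m, ventSettings(), posture("supine"), 100)
  for (p in list(posture("supine"), posture("lateral_left"),
                 posture("lateral_right"))) {
    fr <- perfusionFractions(st$model, p)
    expect_true(all(fr >= 0))
    expect_equal(sum(fr), 1, tolerance = 1e-9)
  }
})

test_that("oxygenation surrogate interpolates monotonically between its limits", {
  expect_equal(oxygenationSurrogate(0), 500, tolerance = 1e-9)
  expect_equal(oxygenationSurrogate(1), 40, tolerance = 1e-9)
  expect_equal(oxygenationSurrogate(0, ceiling = 400, floor = 60), 400)
  expect_error(oxygenationSurrogate(1.2), "shunt")
  expect_error(oxygenationSurrogate(-0.1), "shunt")
  set.seed(31)
  for (k in 1:100) {
    ab <- sort(runif(2))
    expect_gt(oxygenationSurrogate(ab[1]), oxygenationSurrogate(ab[2]))
  }
})

test_that("rendered frames compose the configured signal model", {
  cfg <- simConfig(seed = 9, noise_sd = 0, cardiac_amplitude = 0)
  m <- buildLungModel(cfg)
  ## single open unit: the global signal is exactly that unit's waveform
  u <- lungUnits(m); u$open <- FALSE
  u$open[100] <- TRUE; u$compliance[100] <- 20
  m@units <- u
  s <- renderFrames(m, ventSettings(), posture("supine"), 4)
  expect_equal(rowSums(frameMatrix(s)),
               frameMatrix(s)[, u$pixel[100] + 1], tolerance = 1e-12)

  ## frame count: 60 s at 50 Hz = 3000 frames
  m2 <- buildLungModel(simConfig(seed = 9))
  expect_equal(nFrames(renderFrames(m2, ventSettings(), posture("supine"),
                                    60)), 3000)

  ## a bolus outside an apnea window is rejected
  expect_error(renderFrames(m2, ventSettings(), posture("supine"), 30,
                            apnea = c(5, 25), bolusTime = 27),
               "inside the apnea")
  expect_error(renderFrames(m2, ventSettings(), posture("supine"), 30,
                            bolusTime = 10), "apnea")

  ## bolus deflection confined to the perfused quadrant
  cfgq <- simConfig(seed = 10, noise_sd = 0, cardiac_amplitude = 0,
                    gravity_perfusion_slope = 0)
  mq <- buildLungModel(cfgq)
  uq <- lungUnits(mq)
  mask <- defaultRoiMask()
  quad <- mask@quadrant[uq$pixel + 1]
  uq$perfWeight <- ifelse(quad == "upper_left", uq$perfWeight, 0)
  mq@units <- uq
  sq <- renderFrames(mq, ventSettings(), posture("supine"), 26,
                     apnea = c(2, 24), bolusTime = 4)
  fm <- frameMatrix(sq)
  apIdx <- which(frameTimes(sq) >= 6 & frameTimes(sq) <= 20)
  base <- colMeans(fm[frameTimes(sq) >= 2 & frameTimes(sq) < 4, ])
  defl <- sweep(-fm[apIdx, ], 2, base, "+")
  outside <- setdiff(roiPixels(mask, "lung"), roiPixels(mask, "upper_left"))
  expect_lt(max(abs(defl[, outside])), 1e-9)
  expect_gt(max(defl[, roiPixels(mask, "upper_left")]), 1)
})

test_that("rendering is reproducible for a fixed seed", {
  cfg <- simConfig(seed = 13)
  m <- buildLungModel(cfg)
  set.seed(99); s1 <- renderFrames(m, ventSettings(), posture("supine"), 3)
  set.seed(99); s2 <- renderFrames(m, ventSettings(), posture("supine"), 3)
  expect_identical(frameMatrix(s1), frameMatrix(s2))
})
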