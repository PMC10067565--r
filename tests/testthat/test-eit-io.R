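test_that("FrameSequence validity enforces the container contract", {
  f <- matrix(rnorm(50 * 16), 50, 16)
  s <- frameSequence(f, 50)
  expect_s4_class(s, "FrameSequence")
  expect_equal(frameTimes(s), (0:49) / 50)

  expect_error(frameSequence(matrix(c(1, NA), 1, 2), 50), "finite")
  expect_error(frameSequence(f, -1), "frameRate|positive")
  ## wrong time spacing rejected at the class level
  expect_error(new("FrameSequence", frames = f, frameRate = 50,
                   times = seq(0, 49) * 0.1,
                   events = lungEIT:::normalizeEvents(NULL),
                   metadata = list()),
               "spacing")
  ## apnea pairing and bolus location are enforced
  ev <- data.frame(time = c(1, 2), kind = c("apnea_start", "bolus_injection"))
  expect_error(frameSequence(matrix(0, 200, 4), 50, events = ev),
               "apnea")
  ev2 <- data.frame(time = 1, kind = "bolus_injection")
  expect_error(frameSequence(matrix(0, 200, 4), 50, events = ev2),
               "apnea")
  ev3 <- data.frame(time = c(0.5, 1, 3),
                    kind = c("apnea_start", "bolus_injection", "apnea_end"))
  expect_s4_class(frameSequence(matrix(0, 200, 4), 50, events = ev3),
                  "FrameSequence")
  expect_error(frameSequence(matrix(0, 10, 4), 50,
                             events = data.frame(time = 1, kind = "party")),
               "kind")
})

test_that("write/read round-trips sequences exactly", {
  set.seed(21)
  for (k in 1:5) {
    ev <- data.frame(time = sort(runif(3, 0, 0.1)),
                     kind = c("position_change", "peep_change",
                              "step_measurement"))
    ev$payload <- list(list(posture = "supine", tilt = 0),
                       list(peep = 12), list())
    s1 <- frameSequence(matrix(rnorm(10 * 1024), 10, 1024), 50,
                        t0 = runif(1), events = ev,
                        metadata = list(subject = paste0("pig", k), w = 69))
    path <- file.path(tempdir(), paste0("fs", k))
    writeFrameSequence(s1, path)
    s2 <- readFrameSequence(path)
    expect_identical(frameMatrix(s2), frameMatrix(s1))
    expect_identical(frameTimes(s2), frameTimes(s1))
    expect_equal(frameRate(s2), frameRate(s1))
    expect_equal(eitEvents(s2)$time, eitEvents(s1)$time)
    expect_equal(eitEvents(s2)$kind, eitEvents(s1)$kind)
    expect_equal(seqMetadata(s2)$subject, paste0("pig", k))
    unlink(path, recursive = TRUE)
  }
})

test_that("a simulator sequence with a full event schedule round-trips", {
  m <- buildLungModel(simConfig(seed = 14))
  set.seed(14)
  extra <- data.frame(time = 0, kind = "position_change")
  extra$payload <- list(list(posture = "supine", tilt = 0))
  s1 <- renderFrames(m, ventSettings(), posture("supine"), 30,
                     apnea = c(6, 27), bolusTime = 8, extraEvents = extra)
  path <- file.path(tempdir(), "fsfull")
  writeFrameSequence(s1, path)
  s2 <- readFrameSequence(path)
  expect_identical(frameMatrix(s2), frameMatrix(s1))
  expect_equal(eitEvents(s2)$kind, eitEvents(s1)$kind)
  bol <- which(eitEvents(s2)$kind == "bolus_injection")
  expect_equal(eitEvents(s2)$payload[[bol]]$volume_ml, 10)
  expect_equal(eitEvents(s2)$payload[[bol]]$nacl_pct, 10)
  unlink(path, recursive = TRUE)
})

test_that("malformed containers are rejected with descriptive errors", {
  s <- frameSequence(matrix(rnorm(5 * 8), 5, 8), 50)
  path <- file.path(tempdir(), "fsbad")
  writeFrameSequence(s, path)
  ## declared frame length inconsistent with the payload
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  meta$n_pixels <- 1024
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(readFrameSequence(path), "mismatch")
  expect_error(readFrameSequence(tempdir()), "container")
  unlink(path, recursive = TRUE)
})

test_that("the default ROI mask is an exact three-scheme partition", {
  mask <- defaultRoiMask()
  lung <- which(mask@lungMask)
  expect_gt(length(lung), 100)
  ## every lung pixel carries exactly one label per scheme, none outside
  expect_true(all(!is.na(mask@half[lung])))
  expect_true(all(!is.na(mask@quadrant[lung])))
  expect_true(all(!is.na(mask@side[lung])))
  expect_true(all(is.na(mask@half[-lung])))

  quads <- roiRegions(mask, "quadrant")
  px <- lapply(quads, function(q) roiPixels(mask, q))
  ## disjoint and jointly exhaustive
  expect_equal(sort(unlist(px)), lung)
  expect_length(intersect(px[[1]], px[[3]]), 0)
  expect_length(intersect(px[[1]], px[[2]]), 0)
  ## quadrants refine halves and sides
  expect_setequal(union(px[[1]], px[[2]]), roiPixels(mask, "ventral"))
  expect_setequal(union(px[[3]], px[[4]]), roiPixels(mask, "dorsal"))
  expect_setequal(union(px[[1]], px[[3]]), roiPixels(mask, "right_lung"))
  ## mirror-symmetric quadrant counts
  expect_equal(length(px[[1]]), length(px[[2]]))
  expect_equal(length(px[[3]]), length(px[[4]]))
  expect_error(roiPixels(mask, "mediastinum"), "unknown region")
})

test_that("ROI masks round-trip through JSON", {
  mask <- defaultRoiMask()
  path <- file.path(tempdir(), "roi.json")
  writeRoiMask(mask, path)
  m2 <- readRoiMask(path)
  expect_equal(m2@lungMask, mask@lungMask)
  expect_equal(m2@quadrant, mask@quadrant)
  expect_equal(m2@side, mask@side)
  unlink(path)
})

test_that("the dependent lung maps lateral postures and rejects supine", {
  expect_equal(dependentLung(posture("lateral_left")), "left_lung")
  expect_equal(dependentLung(posture("lateral_right")), "right_lung")
  expect_error(dependentLung(posture("supine")), "supine")
})
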