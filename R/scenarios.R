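## Constructed study scenarios with known ground truth. These are first-class
## simulator configurations used for parameter-recovery and mechanism tests:
## each returns the generated data together with the truth it encodes.

#' Ventilation-recovery scenario with prescribed quadrant tidal fractions
#'
#' Builds a healthy (fully open) lung whose per-quadrant compliance sums are
#' rescaled to the requested tidal fractions, then renders a ventilation
#' epoch with the default measurement noise. Because open-unit tidal
#' amplitude is proportional to compliance, the true quadrant ventilation
#' shares equal the prescribed fractions.
#'
#' @param fractions named or positional numeric vector of 4 quadrant tidal
#'   fractions (upper_right, upper_left, lower_right, lower_left) summing
#'   to 1.
#' @param seed integer seed (model jitter and rendering noise).
#' @param duration rendered epoch length, seconds.
#' @param vent a \code{\link{ventSettings}}.
#' @return list: \code{seq} (FrameSequence), \code{truth} (fractions),
#'   \code{mask}, \code{model}, \code{vent}.
#' @export
ventilationRecoveryScenario <- function(fractions, seed = 1,
                                        duration = 20,
                                        vent = ventSettings()) {
  quads <- c("upper_right", "upper_left", "lower_right", "lower_left")
  fractions <- stats::setNames(as.numeric(fractions), quads)
  stopifnot(all(fractions >= 0), abs(sum(fractions) - 1) < 1e-9)
  cfg <- simConfig(seed = seed, injury_severity = 0)
  model <- buildLungModel(cfg)
  mask <- defaultRoiMask(cfg$grid)
  u <- model@units
  quadOf <- mask@quadrant[u$pixel + 1L]
  for (q in quads) {
    inQ <- quadOf == q
    cur <- sum(u$compliance[inQ])
    u$compliance[inQ] <- u$compliance[inQ] * fractions[q] /
      max(cur, .Machine$double.eps) * sum(model@units$compliance)
  }
  model@units <- u
  seqV <- withSeed(seed + 7L,
                   renderFrames(model, vent, posture("supine"), duration))
  list(seq = seqV, truth = fractions, mask = mask, model = model,
       vent = vent)
}

#' Bolus perfusion-recovery scenario with prescribed quadrant flow fractions
#'
#' Builds a healthy lung whose per-quadrant perfusion weights are rescaled
#' to the requested fractions (gravity slope disabled so the encoded
#' fractions are exact), then renders an expiratory breath hold of 20 s with
#' a hypertonic saline bolus and the default noise and cardiac oscillation.
#'
#' @param fractions 4 quadrant perfusion fractions summing to 1.
#' @param seed integer seed.
#' @param noiseSd measurement noise; default from \code{\link{simConfig}}.
#' @return list: \code{seq}, \code{truth}, \code{mask}, \code{model}.
#' @export
perfusionRecoveryScenario <- function(fractions, seed = 1, noiseSd = NULL) {
  quads <- c("upper_right", "upper_left", "lower_right", "lower_left")
  fractions <- stats::setNames(as.numeric(fractions), quads)
  stopifnot(all(fractions >= 0), abs(sum(fractions) - 1) < 1e-9)
  cfg <- simConfig(seed = seed, injury_severity = 0,
                   gravity_perfusion_slope = 0)
  if (!is.null(noiseSd)) cfg$noise_sd <- noiseSd
  model <- buildLungModel(cfg)
  mask <- defaultRoiMask(cfg$grid)
  u <- model@units
  quadOf <- mask@quadrant[u$pixel + 1L]
  for (q in quads) {
    inQ <- quadOf == q
    cur <- sum(u$perfWeight[inQ])
    u$perfWeight[inQ] <- u$perfWeight[inQ] * fractions[q] /
      max(cur, .Machine$double.eps)
  }
  model@units <- u
  vent <- ventSettings()
  seqV <- withSeed(seed + 11L,
                   renderFrames(model, vent, posture("supine"),
                                duration = 26, apnea = c(2, 22),
                                bolusTime = 5))
  list(seq = seqV, truth = fractions, mask = mask, model = model)
}

#' Titration scenario with a known dependent-lung maximal closing pressure
#'
#' Constructs a lateral-left scenario in which the final titrated PEEP has a
#' closed form. The pleural gradient is zeroed so end-expiratory
#' transpulmonary pressure equals PEEP exactly; a band of left-lung
#' (dependent) units receives closing pressure \code{closingMax}, and the
#' band's derecruitment damage thresholds are laid out on a grid spanning
#' the cumulative pressure-deficit exposure of every PEEP level below
#' \code{closingMax}, so derecruitment keeps progressing (and the EELI keeps
#' falling) throughout every titration window until PEEP first reaches or
#' exceeds \code{closingMax}. The correct end point is therefore the
#' smallest 10 + 2k >= \code{closingMax}. For the guarantee,
#' \code{closingMax} should sit at least ~0.5 cmH2O above an even PEEP step.
#'
#' @param closingMax dependent-lung maximal closing pressure, cmH2O
#'   (> 10).
#' @param seed integer seed (selects which pixels form the band).
#' @param bandFraction fraction of dependent-lung units in the collapsing
#'   band.
#' @return list: \code{model}, \code{vent}, \code{post}, \code{dzRef},
#'   \code{criteria}, \code{closingMax}, \code{expectedFinal}.
#' @export
titrationScenario <- function(closingMax, seed = 1, bandFraction = 0.4) {
  stopifnot(closingMax > 10)
  cfg <- simConfig(seed = seed, injury_severity = 0, pleural_gradient = 0)
  model <- buildLungModel(cfg)
  u <- model@units
  u$opening <- 0
  u$closing <- -cfg$healthy_closing_margin
  left <- u$lateral > 0
  leftIdx <- which(left)
  nBand <- max(8L, round(bandFraction * length(leftIdx)))
  bandIdx <- withSeed(seed + 3L, sample(leftIdx, nBand))
  expectedFinal <- 10 + 2 * ceiling((closingMax - 10) / 2)
  ## cumulative deficit exposure (cmH2O x breaths) across the PEEP levels
  ## below closingMax, at one 2-min window (60 breaths at 30/min) per level
  peeps <- seq(10, expectedFinal - 2, by = 2)
  totalDamage <- 60 * sum(closingMax - peeps)
  u$closing[bandIdx] <- closingMax
  u$damageThreshold[bandIdx] <- seq(10, 0.98 * totalDamage,
                                    length.out = nBand)
  u$opening[bandIdx] <- 60  # collapsed band units stay collapsed
  model@units <- u
  vent <- ventSettings(peep = 10)
  dP <- vent$tidalVolume / sum(u$compliance)
  dzRef <- cfg$tidal_gain * sum(u$compliance[left]) * dP
  list(model = model, vent = vent, post = posture("lateral_left"),
       dzRef = dzRef,
       criteria = titrationCriteria(eeliSlopeTolerance = 0.2),
       closingMax = closingMax, expectedFinal = expectedFinal)
}

#' Geometric EELI-shift scenario (lateral versus supine, no derecruitment)
#'
#' Demonstrates the paradoxical dependent-lung EELI split seen when turning
#' an open lung lateral with a PEEP increase that offsets the mean
#' dependent-lung pleural-pressure rise: both non-dependent quadrants gain
#' EELI, while within the dependent lung the ventral quadrant loses and the
#' dorsal quadrant gains. The mechanism is purely geometric: under the
#' rotated gravity axis the dependent-dorsal corner gains less pleural
#' pressure than the dependent-ventral one (its depth coordinate contributes
#' with cos(tilt) < 1), so a uniform PEEP offset splits the two quadrants
#' around zero. Injury is disabled so no recruitment or derecruitment
#' contributes.
#'
#' @param seed integer seed.
#' @param lateralLabel "lateral_left" or "lateral_right".
#' @param epochSeconds rendered epoch length per posture, seconds.
#' @return list: \code{delta} (named quadrant EELI changes, relabelled
#'   dependent / non-dependent), \code{peepSupine}, \code{peepLateral}.
#' @export
eeliShiftScenario <- function(seed = 1, lateralLabel = "lateral_left",
                              epochSeconds = 24) {
  cfg <- simConfig(seed = seed, injury_severity = 0, pleural_gradient = 0.6)
  model <- buildLungModel(cfg)
  mask <- defaultRoiMask(cfg$grid)
  post <- posture(lateralLabel)
  sup <- posture("supine")
  u <- model@units
  gdSup <- gravitationalDepth(u$depth, u$lateral, sup)
  gdLat <- gravitationalDepth(u$depth, u$lateral, post)
  depSide <- dependentLung(post)
  depPix <- if (depSide == "left_lung") u$lateral > 0 else u$lateral < 0
  peepSupine <- 16
  peepLateral <- peepSupine +
    cfg$pleural_gradient * mean(gdLat[depPix] - gdSup[depPix])
  ventSup <- ventSettings(peep = peepSupine)
  ventLat <- ventSettings(peep = peepLateral)
  measure <- function(v, p, sd) {
    seqV <- withSeed(sd, renderFrames(model, v, p, epochSeconds))
    bt <- detectBreaths(seqV, v$respRate, mask)
    colMeans(eeliSeries(seqV, bt, mask, "quadrant")$regional)
  }
  eeliSup <- measure(ventSup, sup, seed + 21L)
  eeliLat <- measure(ventLat, post, seed + 22L)
  d <- eeliLat - eeliSup
  depLbl <- if (depSide == "left_lung") "left" else "right"
  ndLbl <- if (depLbl == "left") "right" else "left"
  delta <- c(dep_ventral = unname(d[paste0("upper_", depLbl)]),
             dep_dorsal = unname(d[paste0("lower_", depLbl)]),
             nondep_ventral = unname(d[paste0("upper_", ndLbl)]),
             nondep_dorsal = unname(d[paste0("lower_", ndLbl)]))
  list(delta = delta, peepSupine = peepSupine, peepLateral = peepLateral)
}
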