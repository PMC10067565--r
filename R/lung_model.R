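#' Build a compartmental gravitational lung model
#'
#' Instantiates one lung unit per lung-mask pixel. Opening and closing
#' pressures increase ventral-to-dorsal and scale with
#' \code{injury_severity}; at severity 0 every opening pressure is 0 and
#' closing pressures sit far below any attainable end-expiratory
#' transpulmonary pressure, so the healthy lung stays open at any PEEP >= 0.
#' Per-unit compliance coefficients, perfusion weights and derecruitment
#' damage thresholds carry seeded lognormal / uniform jitter. Construction is
#' deterministic for a fixed \code{config$seed} and leaves the session RNG
#' untouched.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \code{\linkS4class{LungModel}} with every unit initially open.
#' @export
buildLungModel <- function(config) {
  validateSimConfig(config)
  mask <- defaultRoiMask(config$grid)
  px <- pixelCoords(config)
  lung <- px[mask@lungMask, , drop = FALSE]
  n <- nrow(lung)
  units <- withSeed(config$seed, {
    dfrac <- (lung$depth - min(lung$depth)) /
      (max(lung$depth) - min(lung$depth))
    comp <- stats::rlnorm(n, 0, config$compliance_cv)
    comp <- comp / sum(comp) * config$healthy_compliance
    s <- config$injury_severity
    op <- s * (config$opening_base + config$opening_slope * dfrac +
                 stats::rnorm(n, 0, config$opening_sd))
    cl <- s * (config$closing_base + config$closing_slope * dfrac +
                 stats::rnorm(n, 0, config$closing_sd)) -
      (1 - s) * config$healthy_closing_margin
    cl <- pmin(cl, op)
    perf <- stats::rlnorm(n, 0, 0.2)
    thr <- stats::runif(n, config$derecruit_damage[1],
                        config$derecruit_damage[2])
    data.frame(pixel = lung$pixel, row = lung$row, col = lung$col,
               depth = lung$depth, lateral = lung$lateral, dfrac = dfrac,
               compliance = comp, opening = op, closing = cl,
               perfWeight = perf, damageThreshold = thr, damage = 0,
               open = TRUE)
  })
  new("LungModel", units = units, config = config)
}

#' @describeIn buildLungModel accessor for the per-unit table.
#' @param model a \code{\linkS4class{LungModel}}.
#' @export
lungUnits <- function(model) model@units

#' @describeIn buildLungModel accessor for the simulator configuration.
#' @export
modelConfig <- function(model) model@config

setMethod("show", "LungModel", function(object) {
  u <- object@units
  cat("LungModel:", nrow(u), "units;",
      sum(u$open), "open /", sum(!u$open), "collapsed\n")
  cat("  open compliance:", round(sum(u$compliance[u$open]), 2),
      "mL/cmH2O; injury severity:", object@config$injury_severity, "\n")
})

#' Transpulmonary pressure of every unit
#'
#' P_L = airway pressure - pleural pressure, with pleural pressure modelled
#' as a linear, posture-independent gradient along the gravitational depth of
#' each unit under the posture's rotated gravity axis:
#' pleural = pleural_ref + pleural_gradient x gravitational depth.
#' The across-unit P_L spread is wider in lateral posture than supine because
#' the right-left thorax span exceeds the anterior-posterior one.
#'
#' @param model a \code{\linkS4class{LungModel}}.
#' @param airwayPressure airway pressure, cmH2O.
#' @param post a \code{\link{posture}}.
#' @return numeric vector, one P_L (cmH2O) per unit.
#' @export
transpulmonaryPressure <- function(model, airwayPressure, post) {
  cfg <- model@config
  gd <- gravitationalDepth(model@units$depth, model@units$lateral, post)
  airwayPressure - (cfg$pleural_ref + cfg$pleural_gradient * gd)
}

#' Per-unit perfusion fractions
#'
#' perfusion_weight x (1 + gravity_perfusion_slope x gravitational depth),
#' multiplied by \code{hpv_factor} for collapsed units (hypoxic pulmonary
#' vasoconstriction), then renormalized to sum to 1.
#'
#' @inheritParams transpulmonaryPressure
#' @return numeric vector of fractions summing to 1.
#' @export
perfusionFractions <- function(model, post) {
  cfg <- model@config
  u <- model@units
  gd <- gravitationalDepth(u$depth, u$lateral, post)
  w <- u$perfWeight * (1 + cfg$gravity_perfusion_slope * gd) *
    ifelse(u$open, 1, cfg$hpv_factor)
  w / sum(w)
}

#' Oxygenation surrogate from shunt fraction
#'
#' A monotone logistic interpolation between a healthy ceiling (shunt 0) and
#' a full-shunt floor, mimicking the qualitative PaO2/FiO2 response to
#' changes in the perfusion fraction of collapsed units. Purely a qualitative
#' surrogate: the mapping is not a gas-exchange model.
#'
#' @param shunt shunt fraction in [0, 1] (perfusion fraction of collapsed
#'   units).
#' @param ceiling value at shunt 0 (mmHg-like).
#' @param floor value at shunt 1.
#' @return numeric, strictly decreasing in \code{shunt}, equal to
#'   \code{ceiling} at 0 and \code{floor} at 1.
#' @export
oxygenationSurrogate <- function(shunt, ceiling = 500, floor = 40) {
  if (any(!is.finite(shunt)) || any(shunt < 0) || any(shunt > 1))
    stop("shunt fraction must lie in [0, 1]")
  k <- 14; s0 <- 0.05
  L <- function(s) 1 / (1 + exp(k * (s - s0)))
  floor + (ceiling - floor) * (L(shunt) - L(1)) / (L(0) - L(1))
}

#' Advance the lung model by whole breaths
#'
#' Per breath: the emergent driving pressure is recomputed as
#' tidal volume / total compliance of open units; a collapsed unit opens the
#' moment its end-inspiratory P_L exceeds its opening pressure; an open unit
#' whose end-expiratory P_L falls below its closing pressure accrues damage
#' equal to the deficit and collapses once its damage threshold is exceeded
#' (threshold 0 = instantaneous rule); otherwise state persists (hysteresis).
#' End-expiratory lung impedance (EELI) surrogates are recorded per breath,
#' globally and per lung side.
#'
#' @param model a \code{\linkS4class{LungModel}}.
#' @param vent a \code{\link{ventSettings}}.
#' @param post a \code{\link{posture}}.
#' @param nBreaths number of breaths to simulate.
#' @param t0 simulation time of the first breath, seconds.
#' @return list with elements \code{model} (updated), \code{physio}
#'   (drivingPressure cmH2O, shuntFraction, pfSurrogate, openCompliance) and
#'   \code{trace} (per-breath data.frame: time, drivingPressure, nOpen,
#'   eeliGlobal, eeliLeft, eeliRight).
#' @export
stepState <- function(model, vent, post, nBreaths = 1L, t0 = 0) {
  cfg <- model@config
  u <- model@units
  gd <- gravitationalDepth(u$depth, u$lateral, post)
  pleural <- cfg$pleural_ref + cfg$pleural_gradient * gd
  leftSide <- u$lateral > 0
  dtBreath <- 60 / vent$respRate
  nBreaths <- as.integer(nBreaths)
  tr <- data.frame(time = t0 + seq_len(nBreaths) * dtBreath,
                   drivingPressure = NA_real_, nOpen = NA_integer_,
                   eeliGlobal = NA_real_, eeliLeft = NA_real_,
                   eeliRight = NA_real_)
  dP <- NA_real_
  for (b in seq_len(nBreaths)) {
    cOpen <- sum(u$compliance[u$open])
    if (cOpen <= 0)
      stop("degenerate lung state: all units collapsed, driving pressure undefined")
    dP <- vent$tidalVolume / cOpen
    plInsp <- (vent$peep + dP) - pleural
    plExp <- vent$peep - pleural
    ## recruitment at end-inspiration
    opens <- !u$open & plInsp > u$opening
    if (any(opens)) { u$open[opens] <- TRUE; u$damage[opens] <- 0 }
    ## derecruitment pressure-deficit accumulation at end-expiration
    deficit <- pmax(u$closing - plExp, 0)
    safe <- u$open & deficit == 0
    u$damage[safe] <- 0
    viol <- u$open & deficit > 0
    u$damage[viol] <- u$damage[viol] + deficit[viol]
    closes <- viol & u$damage >= u$damageThreshold
    if (any(closes)) { u$open[closes] <- FALSE; u$damage[closes] <- 0 }
    eeliPx <- ifelse(u$open,
                     cfg$eeli_gain * u$compliance *
                       (cfg$eeli_floor + pmax(plExp, 0)), 0)
    tr$drivingPressure[b] <- dP
    tr$nOpen[b] <- sum(u$open)
    tr$eeliGlobal[b] <- sum(eeliPx)
    tr$eeliLeft[b] <- sum(eeliPx[leftSide])
    tr$eeliRight[b] <- sum(eeliPx[!leftSide])
  }
  model@units <- u
  pf <- perfusionFractions(model, post)
  shunt <- sum(pf[!u$open])
  list(model = model,
       physio = list(drivingPressure = dP, shuntFraction = shunt,
                     pfSurrogate = oxygenationSurrogate(
                       shunt, cfg$oxy_ceiling, cfg$oxy_floor),
                     openCompliance = sum(u$compliance[u$open])),
       trace = tr)
}
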