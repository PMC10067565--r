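## Forward rendering of EIT pixel-image sequences from a lung model state.

## Peak-normalized gamma-variate first-pass dilution kernel.
gammaVariateKernel <- function(t, delay, tp, shape) {
  s <- (t - delay) / tp
  out <- numeric(length(t))
  pos <- s > 0
  out[pos] <- s[pos]^shape * exp(shape * (1 - s[pos]))
  out
}

## Volume-controlled breath waveform in [0, 1]: linear constant-flow
## inspiration, exponential passive expiration (time constant Texp/3).
breathWaveform <- function(tRel, respRate, ieRatio) {
  period <- 60 / respRate
  tin <- period * ieRatio / (1 + ieRatio)
  texp <- period - tin
  phase <- tRel %% period
  ifelse(phase < tin, phase / tin, exp(-(phase - tin) / (texp / 3)))
}

#' Render an EIT frame sequence from the current lung state
#'
#' Composes the per-pixel signal of a steady-state epoch at the configured
#' frame rate: an EELI baseline (open units hold an aeration-proportional
#' offset), a tidal component (open units only, amplitude proportional to
#' compliance x driving pressure, shaped by the I:E breath waveform), a
#' cardiac oscillation (amplitude proportional to the unit's perfusion
#' fraction) and white measurement noise. During an apnea window the tidal
#' component is held at end-expiration (expiratory breath hold). After a
#' bolus event, every perfused pixel shows a transient negative deflection
#' (the hypertonic saline lowers impedance) whose amplitude is proportional
#' to its perfusion fraction, following a gamma-variate first-pass dilution
#' kernel plus a smaller delayed recirculation bump.
#'
#' The open/collapsed state is frozen during rendering; advance the model
#' with \code{\link{stepState}} first. Noise is drawn from the session RNG:
#' seed the session for reproducible frames.
#'
#' @param model a \code{\linkS4class{LungModel}}.
#' @param vent a \code{\link{ventSettings}}.
#' @param post a \code{\link{posture}}.
#' @param duration rendered length, seconds.
#' @param t0 timestamp of the first frame, seconds.
#' @param apnea optional c(start, end), seconds relative to \code{t0}, of an
#'   expiratory breath hold.
#' @param bolusTime optional saline bolus injection time, seconds relative to
#'   \code{t0}; must lie inside the apnea window.
#' @param extraEvents optional additional event data.frame to merge into the
#'   event log.
#' @return a \code{\linkS4class{FrameSequence}}.
#' @export
renderFrames <- function(model, vent, post, duration, t0 = 0,
                         apnea = NULL, bolusTime = NULL,
                         extraEvents = NULL) {
  cfg <- model@config
  u <- model@units
  rate <- cfg$frame_rate
  nT <- round(duration * rate)
  stopifnot(nT >= 1)
  tRel <- (0:(nT - 1)) / rate
  if (!is.null(bolusTime)) {
    if (is.null(apnea))
      stop("a bolus event requires an enclosing apnea window")
    if (bolusTime < apnea[1] || bolusTime > apnea[2])
      stop("the bolus event must lie inside the apnea window")
  }
  gd <- gravitationalDepth(u$depth, u$lateral, post)
  plExp <- vent$peep - (cfg$pleural_ref + cfg$pleural_gradient * gd)
  cOpen <- sum(u$compliance[u$open])
  if (cOpen <= 0) stop("degenerate lung state: all units collapsed")
  dP <- vent$tidalVolume / cOpen
  base <- ifelse(u$open,
                 cfg$eeli_gain * u$compliance *
                   (cfg$eeli_floor + pmax(plExp, 0)), 0)
  amp <- ifelse(u$open, cfg$tidal_gain * u$compliance * dP, 0)
  pf <- perfusionFractions(model, post)
  relPerf <- pf / mean(pf)
  camp <- cfg$cardiac_amplitude * relPerf
  w <- breathWaveform(tRel, vent$respRate, vent$ieRatio)
  if (!is.null(apnea)) w[tRel >= apnea[1] & tRel <= apnea[2]] <- 0
  cw <- sin(2 * pi * cfg$cardiac_rate / 60 * tRel)
  lungSig <- outer(rep(1, nT), base) + outer(w, amp) + outer(cw, camp)
  if (!is.null(bolusTime)) {
    K <- gammaVariateKernel(tRel - bolusTime, cfg$bolus_delay, cfg$bolus_tp,
                            cfg$bolus_shape) +
      cfg$recirc_fraction *
        gammaVariateKernel(tRel - bolusTime,
                           cfg$bolus_delay + cfg$recirc_delay,
                           cfg$recirc_tp, 2)
    lungSig <- lungSig - outer(K, cfg$bolus_amplitude * relPerf)
  }
  nPix <- cfg$grid^2
  frames <- matrix(stats::rnorm(nT * nPix, 0, cfg$noise_sd), nT, nPix)
  lungCols <- u$pixel + 1L
  frames[, lungCols] <- frames[, lungCols] + lungSig
  ev <- data.frame(time = numeric(0), kind = character(0))
  ev$payload <- list()
  if (!is.null(apnea))
    ev <- rbind(ev, data.frame(time = t0 + apnea,
                               kind = c("apnea_start", "apnea_end"),
                               payload = I(list(list(), list()))))
  if (!is.null(bolusTime))
    ev <- rbind(ev, data.frame(time = t0 + bolusTime,
                               kind = "bolus_injection",
                               payload = I(list(list(volume_ml = 10,
                                                     nacl_pct = 10)))))
  if (!is.null(extraEvents)) ev <- rbind(ev, extraEvents)
  ev <- ev[order(ev$time), , drop = FALSE]
  frameSequence(frames, rate, t0 = t0, events = ev,
                metadata = list(cardiacRate = cfg$cardiac_rate,
                                respRate = vent$respRate,
                                peep = vent$peep,
                                posture = post$label,
                                drivingPressure = dP))
}
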