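#' @import methods
NULL

.EVENT_KINDS <- c("position_change", "peep_change", "bolus_injection",
                  "apnea_start", "apnea_end", "step_measurement")

#' FrameSequence: a timestamped EIT pixel-image sequence
#'
#' The single exchange container between the simulator and the analysis
#' functions. Holds a T x 1024 matrix of reconstructed pixel impedance values
#' (arbitrary units), the acquisition rate, a time axis, an ordered event log
#' (posture changes, PEEP changes, apnea windows, saline bolus injections) and
#' free-form metadata.
#'
#' @slot frames numeric matrix, one row per frame, one column per pixel
#'   (row-major 32 x 32 grid, pixel 0 at row 0 / column 0).
#' @slot frameRate acquisition rate in Hz.
#' @slot times frame timestamps in seconds, strictly increasing, uniformly
#'   spaced at 1/frameRate.
#' @slot events data.frame with columns \code{time}, \code{kind},
#'   \code{payload} (list column of per-event named lists).
#' @slot metadata free-form named list (subject id, scenario parameters, ...).
#' @export
setClass("FrameSequence",
         representation(frames = "matrix", frameRate = "numeric",
                        times = "numeric", events = "data.frame",
                        metadata = "list"))

setValidity("FrameSequence", function(object) {
  msg <- character(0)
  fr <- object@frameRate
  if (length(fr) != 1L || !is.finite(fr) || fr <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (!is.numeric(object@frames) || !all(is.finite(object@frames)))
    msg <- c(msg, "frames must be finite numeric values")
  if (length(object@times) != nrow(object@frames))
    msg <- c(msg, "length(times) must equal the number of frames")
  if (length(object@times) > 1L) {
    dt <- diff(object@times)
    if (any(dt <= 0)) msg <- c(msg, "times must be strictly increasing")
    if (any(abs(dt - 1 / fr) > 1e-9))
      msg <- c(msg, "frame spacing must equal 1/frameRate within 1e-9")
  }
  ev <- object@events
  if (!all(c("time", "kind") %in% names(ev)))
    msg <- c(msg, "events must have columns 'time' and 'kind'")
  else {
    if (nrow(ev) > 1L && is.unsorted(ev$time))
      msg <- c(msg, "events must be time-sorted")
    if (!all(ev$kind %in% .EVENT_KINDS))
      msg <- c(msg, paste0("unknown event kind(s): ",
                           paste(setdiff(ev$kind, .EVENT_KINDS), collapse = ", ")))
    ap <- .apneaWindows(ev)
    if (is.character(ap)) msg <- c(msg, ap)
    else if (any(ev$kind == "bolus_injection")) {
      bt <- ev$time[ev$kind == "bolus_injection"]
      inside <- vapply(bt, function(t)
        nrow(ap) > 0 && any(t >= ap$start & t <= ap$end), logical(1))
      if (!all(inside))
        msg <- c(msg, "every bolus_injection must lie inside an apnea window")
    }
  }
  if (length(msg)) msg else TRUE
})

## Pair apnea_start / apnea_end events; returns a data.frame(start, end) or a
## character error message.
.apneaWindows <- function(events) {
  st <- events$time[events$kind == "apnea_start"]
  en <- events$time[events$kind == "apnea_end"]
  if (length(st) != length(en))
    return("every apnea_start must have a matching apnea_end")
  if (length(st) == 0L) return(data.frame(start = numeric(0), end = numeric(0)))
  st <- sort(st); en <- sort(en)
  if (any(en <= st))
    return("each apnea_end must follow its apnea_start")
  data.frame(start = st, end = en)
}

#' ROIMask: pixel-to-region assignment on the 32 x 32 EIT grid
#'
#' Assigns every lung pixel one label per scheme: ventral/dorsal half,
#' anatomical quadrant, and left/right lung. Pixel coordinates are body-fixed
#' (the electrode belt rotates with the animal), so the same mask applies in
#' every posture. Row 0 is ventral (anterior), row 31 dorsal; column 0 is the
#' animal's right side.
#'
#' @slot grid grid side length (32).
#' @slot lungMask logical vector, length grid^2, TRUE for lung pixels.
#' @slot half character vector ("ventral"/"dorsal", NA outside the lung).
#' @slot quadrant character vector ("upper_right", "upper_left",
#'   "lower_right", "lower_left", NA outside the lung).
#' @slot side character vector ("right_lung"/"left_lung", NA outside the lung).
#' @export
setClass("ROIMask",
         representation(grid = "integer", lungMask = "logical",
                        half = "character", quadrant = "character",
                        side = "character"))

setValidity("ROIMask", function(object) {
  msg <- character(0)
  n <- object@grid^2
  if (length(object@lungMask) != n || length(object@half) != n ||
      length(object@quadrant) != n || length(object@side) != n)
    return("all label vectors must have length grid^2")
  lp <- object@lungMask
  if (!all(!is.na(object@half[lp])) || !all(is.na(object@half[!lp])))
    msg <- c(msg, "half labels must cover exactly the lung pixels")
  if (!all(!is.na(object@quadrant[lp])) || !all(is.na(object@quadrant[!lp])))
    msg <- c(msg, "quadrant labels must cover exactly the lung pixels")
  if (!all(!is.na(object@side[lp])) || !all(is.na(object@side[!lp])))
    msg <- c(msg, "side labels must cover exactly the lung pixels")
  ## the quadrant partition must refine the half partition exactly
  okv <- all(object@quadrant[lp][object@half[lp] == "ventral"] %in%
               c("upper_right", "upper_left"))
  okd <- all(object@quadrant[lp][object@half[lp] == "dorsal"] %in%
               c("lower_right", "lower_left"))
  if (!okv || !okd)
    msg <- c(msg, "quadrants must refine the ventral/dorsal halves")
  if (length(msg)) msg else TRUE
})

#' LungModel: a compartmental gravitational lung
#'
#' One lung unit per lung-mask pixel, each with a compliance coefficient,
#' opening and closing pressures (recruitment hysteresis), a perfusion weight,
#' an open/collapsed state, and a body-fixed anatomical position
#' (ventral-dorsal depth and right-left offset, cm).
#'
#' @slot units data.frame with one row per unit.
#' @slot config the \code{\link{simConfig}} list the model was built from.
#' @export
setClass("LungModel", representation(units = "data.frame", config = "ANY"))

setValidity("LungModel", function(object) {
  u <- object@units
  need <- c("pixel", "depth", "lateral", "dfrac", "compliance", "opening",
            "closing", "perfWeight", "damageThreshold", "damage", "open")
  if (!all(need %in% names(u)))
    return(paste("units is missing columns:",
                 paste(setdiff(need, names(u)), collapse = ", ")))
  msg <- character(0)
  if (any(u$opening < u$closing - 1e-9))
    msg <- c(msg, "opening_pressure must be >= closing_pressure for every unit")
  if (any(u$compliance < 0)) msg <- c(msg, "compliance must be non-negative")
  if (any(u$perfWeight < 0)) msg <- c(msg, "perfusion weights must be non-negative")
  cfg <- object@config
  if (!is.null(cfg$ap_span) && !is.null(cfg$rl_span)) {
    fd <- (u$depth - cfg$ap_span / 2) / (cfg$ap_span / 2)
    fx <- u$lateral / (cfg$rl_span / 2)
    if (any(fd^2 + fx^2 > 1 + 1e-9))
      msg <- c(msg, "unit positions must lie within the thorax ellipse")
  }
  if (length(msg)) msg else TRUE
})

#' BreathTable: segmented breaths of a ventilation recording
#'
#' Per breath: end-expiration start index, end-inspiration peak index, end
#' index (all 1-based frame indices), their times, the global tidal impedance
#' variation (deltaZ, read from the raw lung-summed signal), and the global
#' end-expiratory lung impedance (EELI) at the breath start.
#'
#' @slot table the per-breath data.frame.
#' @slot frameRate acquisition rate in Hz.
#' @export
setClass("BreathTable",
         representation(table = "data.frame", frameRate = "numeric"))

setValidity("BreathTable", function(object) {
  tb <- object@table
  need <- c("startIdx", "peakIdx", "endIdx", "startTime", "peakTime",
            "globalDeltaZ", "globalEeli")
  if (!all(need %in% names(tb)))
    return(paste("table is missing columns:",
                 paste(setdiff(need, names(tb)), collapse = ", ")))
  msg <- character(0)
  if (nrow(tb)) {
    if (any(tb$peakIdx <= tb$startIdx) || any(tb$endIdx < tb$peakIdx))
      msg <- c(msg, "breath indices must be ordered start < peak <= end")
    if (nrow(tb) > 1L && any(tb$startIdx[-1] < tb$endIdx[-nrow(tb)]))
      msg <- c(msg, "breaths must be non-overlapping and time-ordered")
    if (any(tb$globalDeltaZ < 0))
      msg <- c(msg, "global deltaZ must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' TitrationTrace: record of one upward PEEP titration
#'
#' @slot records data.frame of criterion evaluations: time (s), peep (cmH2O),
#'   globalSlope and depSlope (A.U./min), cumDrop (A.U.), critA/critB/critC.
#' @slot initialPeep starting PEEP (cmH2O).
#' @slot finalPeep PEEP at termination (cmH2O).
#' @slot terminatedBy "all_criteria_met" or "max_peep_reached".
#' @slot dzRef pre-lateralization dependent-lung deltaZ reference (A.U.).
#' @export
setClass("TitrationTrace",
         representation(records = "data.frame", initialPeep = "numeric",
                        finalPeep = "numeric", terminatedBy = "character",
                        dzRef = "numeric"))

setValidity("TitrationTrace", function(object) {
  msg <- character(0)
  if (!object@terminatedBy %in% c("all_criteria_met", "max_peep_reached"))
    msg <- c(msg, "terminatedBy must be all_criteria_met or max_peep_reached")
  p <- object@records$peep
  if (length(p) > 1L && any(diff(p) < 0))
    msg <- c(msg, "PEEP must be non-decreasing along the trace")
  if (length(p) && object@finalPeep < max(p))
    msg <- c(msg, "finalPeep must be at least the last recorded PEEP")
  if (length(msg)) msg else TRUE
})
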