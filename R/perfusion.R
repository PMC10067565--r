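#' Extract per-pixel saline dilution curves from an apneic bolus recording
#'
#' Locates the bolus event and its enclosing apnea window in the event log,
#' computes each lung pixel's baseline as the mean of the pre-bolus apneic
#' segment, sign-corrects the deflection (deflection = baseline - signal, so
#' the conductive saline transit becomes a positive wave), and suppresses the
#' cardiac-frequency oscillation with a zero-phase low-pass below the cardiac
#' band.
#'
#' @param seq a \code{\linkS4class{FrameSequence}} containing an apnea window
#'   of at least 10 s with a bolus_injection event inside it.
#' @param mask a \code{\linkS4class{ROIMask}}.
#' @param cardiacHz cardiac frequency in Hz used for the low-pass cutoff
#'   (half this value); defaults to \code{metadata$cardiacRate}/60 or 1.5 Hz.
#' @return list of class \code{dilutionCurves}: \code{time} (s relative to
#'   the bolus), \code{deflection} (samples x pixels matrix, A.U.),
#'   \code{pixels} (1-based pixel columns), \code{baseline}.
#' @export
extractDilutionCurves <- function(seq, mask, cardiacHz = NULL) {
  ev <- seq@events
  bolusIdx <- which(ev$kind == "bolus_injection")
  if (!length(bolusIdx)) stop("no bolus_injection event in the sequence")
  tBolus <- ev$time[bolusIdx[1L]]
  ap <- .apneaWindows(ev)
  if (is.character(ap)) stop(ap)
  enc <- which(ap$start <= tBolus & ap$end >= tBolus)
  if (!length(enc))
    stop("the bolus event does not lie inside an apnea window")
  win <- ap[enc[1L], ]
  if (win$end - win$start < 10)
    stop("the apnea window is too short for first-pass analysis (< 10 s)")
  if (is.null(cardiacHz))
    cardiacHz <- (seq@metadata$cardiacRate %||% 90) / 60
  px <- roiPixels(mask, "lung")
  tAxis <- seq@times
  preIdx <- which(tAxis >= win$start & tAxis < tBolus)
  winIdx <- which(tAxis >= tBolus & tAxis <= win$end)
  if (length(preIdx) < 5L)
    stop("too few pre-bolus apneic samples for a baseline")
  baseline <- colMeans(seq@frames[preIdx, px, drop = FALSE])
  defl <- sweep(-seq@frames[winIdx, px, drop = FALSE], 2L, baseline, "+")
  defl <- lowpassFilter(defl, seq@frameRate, cardiacHz / 2)
  structure(list(time = tAxis[winIdx] - tBolus, deflection = defl,
                 pixels = px, baseline = baseline,
                 frameRate = seq@frameRate),
            class = "dilutionCurves")
}

## First-pass metric of one deflection curve: maximal upslope (A.U./s) up to
## the peak, or area under the curve, truncated at the first post-peak local
## minimum to exclude recirculation. The upslope is measured over a 0.25 s
## lag so single-sample noise does not bias the maximum.
.firstPassMetric <- function(y, dt, metric) {
  pk <- which.max(y)
  if (!is.finite(y[pk]) || y[pk] <= 0) return(0)
  ## truncate at the first local minimum after the peak
  trunc <- length(y)
  if (pk < length(y) - 1L) {
    post <- y[(pk + 1L):length(y)]
    d <- diff(post)
    turn <- which(d > 0)
    if (length(turn)) trunc <- pk + turn[1L]
  }
  if (metric == "slope") {
    lag <- max(1L, round(0.25 / dt))
    if (pk <= lag) lag <- max(1L, pk - 1L)
    if (pk < 2L) return(0)
    seg <- y[1:pk]
    max(seg[(lag + 1L):pk] - seg[1:(pk - lag)]) / (lag * dt)
  } else {
    sum(y[1:trunc]) * dt
  }
}

#' Regional perfusion distribution from first-pass dilution curves
#'
#' Scores every lung pixel by the maximal upslope of its first-pass
#' deflection (default, following first-pass indicator-dilution practice) or
#' by the area under the first-pass segment (\code{metric = "auc"}); curves
#' are truncated at the first post-peak local minimum so recirculation is
#' excluded. Negative pixel metrics (noise) are clipped to zero, then
#' regional shares are the region sums normalized to total 1.
#'
#' @param curves a \code{dilutionCurves} list from
#'   \code{\link{extractDilutionCurves}}.
#' @param mask a \code{\linkS4class{ROIMask}}.
#' @param scheme "quadrant", "half" or "side".
#' @param metric "slope" (maximal upslope) or "auc" (first-pass area).
#' @return named numeric vector of perfusion fractions summing to 1, with
#'   attribute \code{pixelMetric} (the per-pixel scores).
#' @export
regionalPerfusion <- function(curves, mask,
                              scheme = c("quadrant", "half", "side"),
                              metric = c("slope", "auc")) {
  scheme <- match.arg(scheme)
  metric <- match.arg(metric)
  dt <- 1 / curves$frameRate
  scores <- apply(curves$deflection, 2L, .firstPassMetric, dt = dt,
                  metric = metric)
  scores <- pmax(scores, 0)
  if (sum(scores) <= 0)
    stop("no positive dilution deflection in any region")
  names(scores) <- as.character(curves$pixels)
  regions <- roiRegions(mask, scheme)
  shares <- vapply(regions, function(r) {
    px <- roiPixels(mask, r)
    sum(scores[as.character(px)], na.rm = TRUE)
  }, numeric(1))
  shares <- shares / sum(shares)
  attr(shares, "pixelMetric") <- scores
  shares
}
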