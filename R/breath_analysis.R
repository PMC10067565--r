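#' Segment breaths from the global impedance signal
#'
#' Band-limits the lung-summed signal around the ventilatory frequency
#' (zero-phase Butterworth), finds alternating end-expiratory minima and
#' end-inspiratory maxima from the zero crossings of the band-limited curve,
#' then refines each index on a lightly smoothed copy of the raw signal so
#' that amplitudes are read without filter bias. Each breath spans one
#' end-expiratory minimum to the next (the last breath may end at the signal
#' end). Breaths overlapping an apnea window in the event log are dropped.
#'
#' @param seq a \code{\linkS4class{FrameSequence}} (or a numeric global
#'   signal, in which case \code{rate} must be given).
#' @param rateHint expected respiratory rate, breaths/min.
#' @param mask optional \code{\linkS4class{ROIMask}}; when supplied, the
#'   global signal is the sum over lung pixels (recommended).
#' @param rate sampling rate in Hz when \code{seq} is a plain vector.
#' @param cardiacHz cardiac frequency in Hz; when known, a least-squares
#'   sinusoid at that frequency is removed from the global signal before
#'   extrema are located (cardiac gating), which sharpens end-expiration
#'   timing. Defaults to \code{metadata$cardiacRate}/60 when available.
#' @return a \code{\linkS4class{BreathTable}}.
#' @export
detectBreaths <- function(seq, rateHint = 30, mask = NULL, rate = NULL,
                          cardiacHz = NULL) {
  if (is(seq, "FrameSequence")) {
    fr <- seq@frameRate
    px <- if (is.null(mask)) seq_len(ncol(seq@frames)) else
      roiPixels(mask, "lung")
    sig <- rowSums(seq@frames[, px, drop = FALSE])
    apnea <- .apneaWindows(seq@events)
    tAxis <- seq@times
    if (is.null(cardiacHz) && !is.null(seq@metadata$cardiacRate))
      cardiacHz <- seq@metadata$cardiacRate / 60
  } else {
    if (is.null(rate)) stop("rate is required for a plain numeric signal")
    fr <- rate
    sig <- as.numeric(seq)
    apnea <- data.frame(start = numeric(0), end = numeric(0))
    tAxis <- (0:(length(sig) - 1)) / fr
  }
  if (!is.null(cardiacHz) && is.finite(cardiacHz) && cardiacHz > 0) {
    ph <- 2 * pi * cardiacHz * tAxis
    X <- cbind(sin(ph), cos(ph))
    sig <- sig - X %*% stats::lm.fit(X, sig - mean(sig))$coefficients
  }
  fHint <- rateHint / 60
  n <- length(sig)
  if (n < 3 * fr / fHint)
    stop("signal shorter than three breath periods")
  filt <- bandpassFilter(sig - mean(sig), fr, 0.4 * fHint, 1.8 * fHint)
  if (stats::sd(filt) <= 1e-9 * max(stats::sd(sig), .Machine$double.eps) ||
      diff(range(sig)) == 0)
    stop("no breaths detected: no oscillation at the ventilatory frequency")
  ## alternating extrema from zero-crossing segments of the filtered curve
  s <- sign(filt); s[s == 0] <- 1
  bnd <- c(0L, which(diff(s) != 0), n)
  mins <- integer(0); maxs <- integer(0)
  for (k in seq_len(length(bnd) - 1L)) {
    idx <- (bnd[k] + 1L):bnd[k + 1L]
    if (length(idx) < 2L) next
    if (filt[idx[1L]] < 0) mins <- c(mins, idx[which.min(filt[idx])])
    else maxs <- c(maxs, idx[which.max(filt[idx])])
  }
  if (length(mins) < 2L || length(maxs) < 1L)
    stop("no breaths detected: too few respiratory extrema")
  ## refine extrema on the raw signal (the band-pass shifts amplitudes, and
  ## smoothing would bias the flat expiratory tail toward earlier samples)
  refine <- function(i, type) {
    w <- max(1L, round(0.15 * fr / fHint))
    lo <- max(1L, i - w); hi <- min(n, i + w)
    j <- if (type == "min") which.min(sig[lo:hi]) else which.max(sig[lo:hi])
    as.integer(lo + j - 1L)
  }
  mins <- vapply(mins, refine, integer(1), type = "min")
  maxs <- vapply(maxs, refine, integer(1), type = "max")
  ## assemble breaths: min -> enclosed max -> next min (or signal end)
  rows <- list()
  for (k in seq_along(mins)) {
    stIdx <- mins[k]
    enIdx <- if (k < length(mins)) mins[k + 1L] else n
    cand <- maxs[maxs > stIdx & maxs <= enIdx]
    if (!length(cand)) next
    pk <- cand[which.max(sig[cand])]
    if (pk <= stIdx || pk > enIdx) next
    rows[[length(rows) + 1L]] <-
      data.frame(startIdx = stIdx, peakIdx = pk, endIdx = enIdx)
  }
  if (!length(rows)) stop("no breaths detected")
  tb <- do.call(rbind, rows)
  ## drop breaths overlapping apnea windows
  if (nrow(apnea)) {
    keep <- vapply(seq_len(nrow(tb)), function(i) {
      t1 <- tAxis[tb$startIdx[i]]; t2 <- tAxis[tb$endIdx[i]]
      !any(t1 < apnea$end & t2 > apnea$start)
    }, logical(1))
    tb <- tb[keep, , drop = FALSE]
  }
  if (!nrow(tb)) stop("no breaths detected outside apnea windows")
  tb$startTime <- tAxis[tb$startIdx]
  tb$peakTime <- tAxis[tb$peakIdx]
  tb$globalDeltaZ <- sig[tb$peakIdx] - sig[tb$startIdx]
  tb$globalEeli <- sig[tb$startIdx]
  tb <- tb[tb$globalDeltaZ >= 0, , drop = FALSE]
  rownames(tb) <- NULL
  estRate <- nrow(tb) / (diff(range(tAxis)) / 60)
  if (estRate < 0.5 * rateHint || estRate > 2 * rateHint)
    warning("detected breath rate (", round(estRate, 1),
            "/min) is grossly inconsistent with the hint (", rateHint,
            "/min)")
  new("BreathTable", table = tb, frameRate = fr)
}

#' @describeIn detectBreaths the per-breath data.frame.
#' @param bt a \code{\linkS4class{BreathTable}}.
#' @export
breathTable <- function(bt) bt@table

#' @describeIn detectBreaths number of breaths.
#' @export
breathCount <- function(bt) nrow(bt@table)

setMethod("show", "BreathTable", function(object) {
  tb <- object@table
  cat("BreathTable:", nrow(tb), "breaths")
  if (nrow(tb))
    cat(sprintf("; mean deltaZ %.1f A.U.; mean EELI %.1f A.U.",
                mean(tb$globalDeltaZ), mean(tb$globalEeli)))
  cat("\n")
})

## Windowed mean of a signal around sample indices; backward windows look
## only into the past (used at end-expiration so the next inspiration's
## upstroke does not leak in).
.winMean <- function(sig, idx, w, backward = FALSE) {
  n <- length(sig)
  vapply(idx, function(i) {
    lo <- max(1L, i - w)
    hi <- if (backward) i else min(n, i + w)
    mean(sig[lo:hi])
  }, numeric(1))
}

#' Regional tidal impedance variation (deltaZ) per breath
#'
#' For each breath and region, the region-summed signal difference between
#' end-inspiration and end-expiration. Values are read as short window
#' averages around the detected indices (0.3 s at the default rates), which
#' attenuates the cardiac oscillation without touching regional ratios (the
#' tidal waveform is common to all pixels). Additive over disjoint regions:
#' summed over a partition of the lung it equals the "lung" scheme value.
#'
#' @param seq a \code{\linkS4class{FrameSequence}}.
#' @param bt a \code{\linkS4class{BreathTable}}.
#' @param mask a \code{\linkS4class{ROIMask}}.
#' @param scheme "quadrant", "half", "side" or "lung".
#' @param windowSeconds half-width of the read-out averaging window, seconds.
#' @return matrix (breaths x regions) of deltaZ values, A.U.
#' @export
regionalDeltaZ <- function(seq, bt, mask,
                           scheme = c("quadrant", "half", "side", "lung"),
                           windowSeconds = 0.3) {
  scheme <- match.arg(scheme)
  regions <- roiRegions(mask, scheme)
  tb <- bt@table
  out <- matrix(NA_real_, nrow(tb), length(regions),
                dimnames = list(NULL, regions))
  fm <- seq@frames
  w <- round(windowSeconds * bt@frameRate)
  for (r in regions) {
    px <- roiPixels(mask, r)
    roiSig <- rowSums(fm[, px, drop = FALSE])
    out[, r] <- .winMean(roiSig, tb$peakIdx, w) -
      .winMean(roiSig, tb$startIdx, w, backward = TRUE)
  }
  out
}

#' Ventilation distribution across regions
#'
#' share_r = 100 x deltaZ_r / deltaZ_total. Negative regional deltaZ values
#' (out-of-phase noise) are clipped to zero before normalization; the
#' clipped mass is attached as attribute \code{clipped}. Shares over a
#' partition sum to exactly 100.
#'
#' @param dz named numeric vector of per-region deltaZ (average the
#'   per-breath matrix over breaths first), or a one-row matrix.
#' @return named numeric vector of percentages summing to 100, with
#'   attribute \code{clipped}.
#' @export
ventilationDistribution <- function(dz) {
  if (is.matrix(dz)) {
    if (nrow(dz) > 1L)
      stop("pass per-region deltaZ averaged over breaths (a vector)")
    dz <- drop(dz)
  }
  clipped <- sum(pmin(dz, 0))
  dz <- pmax(dz, 0)
  tot <- sum(dz)
  if (!is.finite(tot) || tot <= 0)
    stop("total deltaZ must be positive to form a ventilation distribution")
  out <- 100 * dz / tot
  attr(out, "clipped") <- clipped
  out
}

#' Regional tidal volume
#'
#' V_Tr = (regional deltaZ / total deltaZ) x total tidal volume, expressed
#' through the percentage shares. Over a partition the regional volumes sum
#' to the tidal volume.
#'
#' @param distribution percentage shares from
#'   \code{\link{ventilationDistribution}}.
#' @param tidalVolume total tidal volume, mL.
#' @return named numeric vector of regional tidal volumes, mL.
#' @export
regionalTidalVolume <- function(distribution, tidalVolume) {
  if (!is.finite(tidalVolume) || tidalVolume <= 0)
    stop("tidalVolume must be positive")
  v <- as.numeric(distribution) / 100 * tidalVolume
  names(v) <- names(distribution)
  v
}

#' Regional compliance
#'
#' C_Z = V_Tr / driving pressure. Over a partition the regional compliances
#' sum to the respiratory-system compliance V_T / driving pressure.
#'
#' @param vtr regional tidal volume(s), mL.
#' @param drivingPressure driving pressure, cmH2O; must be positive.
#' @return regional compliance(s), mL/cmH2O.
#' @export
regionalCompliance <- function(vtr, drivingPressure) {
  if (!is.finite(drivingPressure) || drivingPressure <= 0)
    stop("driving pressure must be positive")
  vtr / drivingPressure
}

#' End-expiratory lung impedance series
#'
#' Reads raw (unfiltered) pixel values at the detected end-expiration
#' indices, globally (lung sum) and per region of the chosen scheme, as
#' backward-looking window averages over the expiratory tail (cardiac
#' suppression without inspiratory leakage).
#'
#' @inheritParams regionalDeltaZ
#' @return list of class \code{eeliSeries}: \code{time} (s), \code{global}
#'   (A.U.), \code{regional} (breaths x regions matrix).
#' @export
eeliSeries <- function(seq, bt, mask, scheme = c("quadrant", "half", "side"),
                       windowSeconds = 0.3) {
  scheme <- match.arg(scheme)
  regions <- roiRegions(mask, scheme)
  tb <- bt@table
  fm <- seq@frames
  w <- round(windowSeconds * bt@frameRate)
  roiEeli <- function(r) {
    roiSig <- rowSums(fm[, roiPixels(mask, r), drop = FALSE])
    .winMean(roiSig, tb$startIdx, w, backward = TRUE)
  }
  reg <- vapply(regions, roiEeli, numeric(nrow(tb)))
  if (nrow(tb) == 1L) reg <- matrix(reg, 1L, dimnames = list(NULL, regions))
  structure(list(time = tb$startTime, global = roiEeli("lung"),
                 regional = reg),
            class = "eeliSeries")
}

#' Change in end-expiratory lung impedance between two epochs
#'
#' deltaEELI = mean EELI over epoch B minus mean EELI over epoch A, globally
#' and per region. A slow linear drift estimated over each epoch from the
#' end-expiratory points is reported alongside (not subtracted).
#'
#' @param series an \code{eeliSeries} from \code{\link{eeliSeries}}.
#' @param epochA,epochB time windows c(start, end), seconds.
#' @return list with \code{global} (A.U.), \code{regional} (named vector),
#'   and \code{drift} (A.U./min per epoch, global signal).
#' @export
deltaEeli <- function(series, epochA, epochB) {
  inA <- series$time >= epochA[1] & series$time <= epochA[2]
  inB <- series$time >= epochB[1] & series$time <= epochB[2]
  if (!any(inA) || !any(inB))
    stop("each epoch must contain at least one end-expiration sample")
  drift <- c(A = if (sum(inA) >= 3)
    lsSlope(series$time[inA], series$global[inA]) * 60 else NA_real_,
    B = if (sum(inB) >= 3)
      lsSlope(series$time[inB], series$global[inB]) * 60 else NA_real_)
  list(global = mean(series$global[inB]) - mean(series$global[inA]),
       regional = colMeans(series$regional[inB, , drop = FALSE]) -
         colMeans(series$regional[inA, , drop = FALSE]),
       drift = drift)
}
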