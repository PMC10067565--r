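## Internal helpers: seeded evaluation, filtering, slope estimation.

## Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Zero-phase Butterworth band-pass. Frequencies in Hz.
bandpassFilter <- function(x, rate, lo, hi, order = 2L) {
  ny <- rate / 2
  hi <- min(hi, 0.95 * ny)
  stopifnot(lo > 0, hi > lo)
  bf <- signal::butter(order, c(lo, hi) / ny, type = "pass")
  signal::filtfilt(bf, x)
}

## Zero-phase Butterworth low-pass. Cutoff in Hz.
lowpassFilter <- function(x, rate, cutoff, order = 2L) {
  ny <- rate / 2
  cutoff <- min(cutoff, 0.95 * ny)
  stopifnot(cutoff > 0)
  bf <- signal::butter(order, cutoff / ny, type = "low")
  if (is.matrix(x)) apply(x, 2L, function(col) signal::filtfilt(bf, col))
  else signal::filtfilt(bf, x)
}

## Centered moving-average smoother (reflective ends).
boxcarSmooth <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width <= 1L) return(x)
  n <- length(x)
  pad <- c(rev(x[seq_len(min(width, n))]), x, rev(x[n + 1 - seq_len(min(width, n))]))
  sm <- stats::filter(pad, rep(1 / width, width), sides = 2)
  as.numeric(sm[(min(width, n) + 1):(min(width, n) + n)])
}

## Least-squares slope of value vs time (per second).
lsSlope <- function(time, value) {
  tm <- time - mean(time)
  sum(tm * (value - mean(value))) / sum(tm^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
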