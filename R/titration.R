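#' Least-squares EELI slope
#'
#' Slope of EELI versus time over a window, in A.U. per minute. This is the
#' operational meaning of "EELI stops decreasing": a slope no more negative
#' than the configured tolerance.
#'
#' @param time times, seconds.
#' @param values EELI values, A.U.
#' @return slope in A.U./minute.
#' @export
eeliSlope <- function(time, values) {
  if (length(time) != length(values)) stop("time and values lengths differ")
  if (length(time) < 3L)
    stop("at least 3 end-expiratory points are required for a slope")
  lsSlope(time, values) * 60
}

#' Real-time upward PEEP titration at a lateral-position onset
#'
#' Runs the three-criterion titration as an explicit state machine over a
#' streaming source of per-breath EELI summaries. Starting from
#' \code{initialPeep}, observations accumulate until a full window
#' (\code{criteria$dependentWindow} minutes) has elapsed at the current PEEP;
#' the criteria are then evaluated every breath: (a) the global EELI slope
#' over the window is at least \code{-tolerance}; (b) the dependent-lung
#' EELI slope over the window is at least \code{-tolerance}; (c) the
#' cumulative dependent-lung EELI drop since the lateral onset does not
#' exceed \code{dzMultiple} times the pre-lateralization dependent-lung
#' deltaZ. On any failure PEEP is raised by \code{stepSize} and the window
#' restarts (each new PEEP needs its own stabilization evidence); titration
#' terminates when all three criteria hold, or is flagged when the safety cap
#' is reached.
#'
#' @param stepFn streaming source: a function of the current PEEP returning,
#'   per call, one breath's observation as
#'   \code{list(time =, global =, dependent =)} (seconds, A.U., A.U.), or
#'   \code{NULL} when the stream is exhausted. The function doubles as the
#'   PEEP-setter callback, so the same engine drives the simulator or
#'   replayed recordings.
#' @param criteria a \code{\link{titrationCriteria}}.
#' @param initialPeep starting PEEP, cmH2O (the protocol starts from
#'   10 cmH2O).
#' @param dzRef dependent-lung deltaZ measured in the preceding supine epoch,
#'   A.U.; required.
#' @param maxMinutes safety limit on total titration time.
#' @return a \code{\linkS4class{TitrationTrace}}.
#' @export
titrate <- function(stepFn, criteria = titrationCriteria(),
                    initialPeep = 10, dzRef, maxMinutes = 60) {
  if (missing(dzRef) || is.null(dzRef) || !is.finite(dzRef) || dzRef <= 0)
    stop("a positive pre-lateralization deltaZ reference (dzRef) is required")
  tol <- criteria$eeliSlopeTolerance
  if (!is.finite(tol)) tol <- 0.01 * dzRef
  W <- criteria$dependentWindow * 60
  peep <- initialPeep
  times <- g <- d <- numeric(0)
  onsetDep <- NA_real_
  windowStart <- NA_real_
  recs <- list()
  term <- NULL
  evaluated <- FALSE
  repeat {
    ob <- stepFn(peep)
    if (is.null(ob)) {
      if (!evaluated)
        stop("stream ended before one full evaluation window")
      stop("stream ended before the titration terminated")
    }
    times <- c(times, ob$time); g <- c(g, ob$global); d <- c(d, ob$dependent)
    if (length(times) == 1L) {
      onsetDep <- d[1L]
      windowStart <- times[1L]
    }
    tNow <- times[length(times)]
    if (tNow - windowStart >= W) {
      evaluated <- TRUE
      idx <- which(times >= max(windowStart, tNow - W))
      gS <- eeliSlope(times[idx], g[idx])
      dS <- eeliSlope(times[idx], d[idx])
      drop <- onsetDep - d[length(d)]
      a <- gS >= -tol
      b <- dS >= -tol
      cc <- drop <= criteria$dzMultiple * dzRef
      recs[[length(recs) + 1L]] <-
        data.frame(time = tNow, peep = peep, globalSlope = gS,
                   depSlope = dS, cumDrop = drop, critA = a, critB = b,
                   critC = cc)
      if (a && b && cc) { term <- "all_criteria_met"; break }
      if (peep >= criteria$maxPeep) { term <- "max_peep_reached"; break }
      peep <- min(peep + criteria$stepSize, criteria$maxPeep)
      windowStart <- tNow
    }
    if (tNow - times[1L] > maxMinutes * 60) {
      term <- "max_peep_reached"
      warning("titration time limit reached before the criteria were met")
      break
    }
  }
  new("TitrationTrace", records = do.call(rbind, recs),
      initialPeep = initialPeep, finalPeep = peep, terminatedBy = term,
      dzRef = dzRef)
}

#' @describeIn titrate final PEEP of a trace.
#' @param trace a \code{\linkS4class{TitrationTrace}}.
#' @export
finalPeep <- function(trace) trace@finalPeep

#' @describeIn titrate the per-evaluation record table.
#' @export
titrationRecords <- function(trace) trace@records

setMethod("show", "TitrationTrace", function(object) {
  cat("TitrationTrace:", object@initialPeep, "->", object@finalPeep,
      "cmH2O (", object@terminatedBy, ")\n")
  cat("  ", nrow(object@records), "criterion evaluations; deltaZ reference",
      round(object@dzRef, 1), "A.U.\n")
})

#' Simulator-backed titration stream
#'
#' Builds the streaming source \code{\link{titrate}} consumes from a live
#' lung model: each call advances the model by one breath at the requested
#' PEEP and returns the global and dependent-lung EELI. The accumulated
#' model state is retrievable afterwards via \code{$getModel()}.
#'
#' @param model a \code{\linkS4class{LungModel}}.
#' @param vent a \code{\link{ventSettings}} (its PEEP is overridden by the
#'   titration engine).
#' @param post a lateral \code{\link{posture}}.
#' @param t0 stream start time, seconds.
#' @return list with \code{step} (the stream function) and \code{getModel}.
#' @export
simTitrationStream <- function(model, vent, post, t0 = 0) {
  depSide <- dependentLung(post)
  env <- new.env()
  env$model <- model
  env$t <- t0
  dtBreath <- 60 / vent$respRate
  step <- function(peep) {
    v <- vent
    v$peep <- peep
    r <- stepState(env$model, v, post, 1L, t0 = env$t)
    env$model <- r$model
    env$t <- env$t + dtBreath
    list(time = r$trace$time[1L], global = r$trace$eeliGlobal[1L],
         dependent = if (depSide == "left_lung") r$trace$eeliLeft[1L]
                     else r$trace$eeliRight[1L])
  }
  list(step = step, getModel = function() env$model)
}
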