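#' The five-step sequential lateral positioning protocol
#'
#' Fixed order: Supine 1; Lateral Left; Supine 2; Lateral Right; Supine 3.
#' Lateral steps carry a 30 degree tilt.
#'
#' @param stepMinutes simulated duration of each step, minutes. Step
#'   durations are simulated time and may be compressed; steady state, not
#'   wall clock, is what the summaries measure.
#' @return data.frame of steps with labels and posture labels.
#' @export
protocolSteps <- function(stepMinutes = 3) {
  data.frame(label = c("Supine1", "LateralLeft", "Supine2", "LateralRight",
                       "Supine3"),
             posture = c("supine", "lateral_left", "supine", "lateral_right",
                         "supine"),
             minutes = stepMinutes)
}

## Analyze the end-of-step epoch of one rendered sequence into a summary row.
.analyzeEpoch <- function(seqV, mask, vent, physio, label, peep, perfusion) {
  bt <- detectBreaths(seqV, rateHint = vent$respRate, mask = mask)
  dzQ <- regionalDeltaZ(seqV, bt, mask, "quadrant")
  dzH <- regionalDeltaZ(seqV, bt, mask, "half")
  dzS <- regionalDeltaZ(seqV, bt, mask, "side")
  distH <- ventilationDistribution(colMeans(dzH))
  distQ <- ventilationDistribution(colMeans(dzQ))
  vtrH <- regionalTidalVolume(distH, vent$tidalVolume)
  czH <- regionalCompliance(vtrH, physio$drivingPressure)
  es <- eeliSeries(seqV, bt, mask, "quadrant")
  eeliQ <- colMeans(es$regional)
  row <- data.frame(label = label, peep = peep,
                    tidalVolume = vent$tidalVolume,
                    drivingPressure = physio$drivingPressure,
                    respSystemCompliance =
                      vent$tidalVolume / physio$drivingPressure,
                    shuntFraction = physio$shuntFraction,
                    pfSurrogate = physio$pfSurrogate,
                    globalDeltaZ = mean(breathTable(bt)$globalDeltaZ),
                    globalEeli = mean(es$global))
  for (r in names(distH)) row[[paste0("vent_", r)]] <- unname(distH[r])
  for (r in names(distQ)) row[[paste0("vent_", r)]] <- unname(distQ[r])
  for (r in names(czH)) row[[paste0("cz_", r)]] <- unname(czH[r])
  for (r in colnames(dzS)) row[[paste0("dz_", r)]] <- mean(dzS[, r])
  for (r in names(eeliQ)) row[[paste0("eeli_", r)]] <- unname(eeliQ[r])
  if (perfusion) {
    curves <- extractDilutionCurves(seqV, mask)
    perfQ <- regionalPerfusion(curves, mask, "quadrant")
    perfS <- regionalPerfusion(curves, mask, "side")
    for (r in names(perfQ)) row[[paste0("perf_", r)]] <- unname(perfQ[r])
    for (r in names(perfS)) row[[paste0("perf_", r)]] <- unname(perfS[r])
  }
  row
}

#' Run the sequential lateral positioning protocol on the simulator
#'
#' Executes the five steps in their fixed order on a seeded lung model. At
#' each lateral onset the three-criterion PEEP titration runs against the
#' live simulator stream (the deltaZ reference is the dependent lung's
#' deltaZ measured in the immediately preceding supine epoch); the titrated
#' PEEP is kept for the remainder of the step and carried over into the
#' following supine step. At the end of every step a measurement epoch is
#' rendered at 50 Hz and analyzed: ventilation distribution (halves and
#' quadrants), regional tidal volumes and compliances, quadrant EELI, the
#' emergent driving pressure and oxygenation surrogate, and - when
#' \code{perfusion} is enabled - an expiratory breath hold with a saline
#' bolus scored into a perfusion distribution.
#'
#' @param config a \code{\link{simConfig}}.
#' @param vent baseline \code{\link{ventSettings}} (initial PEEP 10 cmH2O).
#' @param seed integer seed; overrides \code{config$seed} and seeds the
#'   rendering noise.
#' @param stepMinutes simulated minutes per step (compressed time).
#' @param settleMinutes supine stabilization run before Supine 1, minutes
#'   (the post-injury settling period that precedes the protocol).
#' @param epochSeconds length of the ventilation measurement epoch, seconds.
#' @param perfusion schedule an apnea + bolus once per step and report
#'   perfusion distributions.
#' @param criteria a \code{\link{titrationCriteria}}.
#' @param keepFrames keep the rendered epoch FrameSequences in the result.
#' @return list with \code{summaries} (one row per step, in protocol order),
#'   \code{titrations} (named list of \code{\linkS4class{TitrationTrace}}),
#'   \code{model} (final state), and optionally \code{frames}.
#' @export
runProtocol <- function(config = simConfig(), vent = ventSettings(),
                        seed = config$seed, stepMinutes = 3,
                        settleMinutes = 10, epochSeconds = 24,
                        perfusion = TRUE, criteria = titrationCriteria(),
                        keepFrames = FALSE) {
  config$seed <- as.integer(seed)
  model <- buildLungModel(config)
  mask <- defaultRoiMask(config$grid)
  steps <- protocolSteps(stepMinutes)
  set.seed(as.integer(seed))
  peep <- vent$peep
  if (settleMinutes > 0)
    model <- stepState(model, vent, posture("supine"),
                       nBreaths = round(settleMinutes * vent$respRate))$model
  lastSupineDz <- NULL
  rows <- list()
  titrations <- list()
  frames <- list()
  tNow <- 0
  for (i in seq_len(nrow(steps))) {
    post <- posture(steps$posture[i])
    v <- vent
    v$peep <- peep
    stepBreaths <- round(steps$minutes[i] * vent$respRate)
    if (post$label != "supine") {
      if (is.null(lastSupineDz))
        stop("a lateral step requires a preceding supine deltaZ reference")
      dzRef <- lastSupineDz[dependentLung(post)]
      stream <- simTitrationStream(model, v, post, t0 = tNow)
      tr <- titrate(stream$step, criteria, initialPeep = peep, dzRef = dzRef)
      titrations[[steps$label[i]]] <- tr
      model <- stream$getModel()
      peep <- finalPeep(tr)
      v$peep <- peep
    }
    st <- stepState(model, v, post, nBreaths = stepBreaths, t0 = tNow)
    model <- st$model
    physio <- st$physio
    tNow <- max(st$trace$time)
    dur <- epochSeconds + if (perfusion) 23 else 0
    seqV <- renderFrames(model, v, post, duration = dur, t0 = tNow,
                         apnea = if (perfusion)
                           c(epochSeconds + 1, epochSeconds + 21) else NULL,
                         bolusTime = if (perfusion) epochSeconds + 4 else NULL)
    tNow <- tNow + dur
    row <- .analyzeEpoch(seqV, mask, v, physio, steps$label[i], peep,
                         perfusion)
    row$step <- i
    rows[[i]] <- row
    if (keepFrames) frames[[steps$label[i]]] <- seqV
    if (post$label == "supine")
      lastSupineDz <- c(right_lung = row$dz_right_lung,
                        left_lung = row$dz_left_lung)
  }
  out <- list(summaries = do.call(rbind, rows), titrations = titrations,
              model = model)
  if (keepFrames) out$frames <- frames
  out
}

#' Run a simulated cohort through the protocol
#'
#' Independent subjects are independent seeds with jittered model and
#' ventilator parameters (compliance scale, injury severity, tidal volume),
#' mirroring between-animal variability. Summaries are stacked with a
#' \code{subject} column so steps can be compared pairwise across subjects.
#'
#' @param config base \code{\link{simConfig}}.
#' @param vent base \code{\link{ventSettings}}.
#' @param nSubjects cohort size.
#' @param seed master seed; subject i runs with seed + 101 * i.
#' @param perfusionSubjects subjects (indices) for which the bolus perfusion
#'   measurement is scheduled; defaults to all.
#' @param ... passed to \code{\link{runProtocol}}.
#' @return list with \code{summaries} (stacked data.frame) and
#'   \code{titrations} (per-subject list).
#' @export
runCohort <- function(config = simConfig(), vent = ventSettings(),
                      nSubjects = 7, seed = 1,
                      perfusionSubjects = seq_len(nSubjects), ...) {
  allRows <- list()
  allTitr <- list()
  for (i in seq_len(nSubjects)) {
    subjSeed <- as.integer(seed + 101L * i)
    cfg <- config
    v <- vent
    jit <- withSeed(subjSeed * 2L + 1L, stats::runif(3))
    cfg$healthy_compliance <- config$healthy_compliance * (0.85 + 0.3 * jit[1])
    cfg$injury_severity <- min(1, max(0, config$injury_severity +
                                        0.06 * (jit[2] - 0.5)))
    v$tidalVolume <- vent$tidalVolume * (0.85 + 0.3 * jit[3])
    res <- runProtocol(cfg, v, seed = subjSeed,
                       perfusion = i %in% perfusionSubjects, ...)
    res$summaries$subject <- i
    allRows[[i]] <- res$summaries
    allTitr[[i]] <- res$titrations
  }
  common <- Reduce(intersect, lapply(allRows, names))
  summaries <- do.call(rbind, lapply(allRows, function(r)
    r[, common, drop = FALSE]))
  perfCols <- grep("^perf_", unlist(lapply(allRows, names)), value = TRUE)
  if (length(perfCols) && !length(grep("^perf_", common))) {
    ## perfusion measured in a subset only: keep its columns, NA elsewhere
    perfCols <- unique(perfCols)
    for (cn in perfCols)
      summaries[[cn]] <- unlist(lapply(allRows, function(r)
        if (cn %in% names(r)) r[[cn]] else rep(NA_real_, nrow(r))))
  }
  list(summaries = summaries, titrations = allTitr)
}

#' Paired-samples t statistic
#'
#' t = mean(d) / (sd(d) / sqrt(n)) on the paired differences d = b - a, with
#' n - 1 degrees of freedom; used to test whether the mean difference
#' between paired step observations differs from zero.
#'
#' @param a,b paired observation vectors of equal length n >= 2.
#' @return list of class \code{pairedComparison}: n, meanDiff, sd, se, t,
#'   df, p (two-sided).
#' @export
pairedT <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal lengths")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2L) stop("at least 2 complete pairs are required")
  d <- b - a
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd == 0)
    stop("zero variance of the paired differences: t is undefined")
  se <- sdd / sqrt(n)
  t <- mean(d) / se
  structure(list(n = n, meanDiff = mean(d), sd = sdd, se = se, t = t,
                 df = n - 1L, p = 2 * stats::pt(-abs(t), n - 1L)),
            class = "pairedComparison")
}

#' @export
print.pairedComparison <- function(x, ...) {
  cat(sprintf("paired t: mean diff %.3f (se %.3f), t = %.3f, df = %d, p = %.4f\n",
              x$meanDiff, x$se, x$t, x$df, x$p))
  invisible(x)
}

#' Quadrant change report: lateral step versus the preceding supine
#'
#' For each subject of a cohort, computes per-quadrant EELI differences (and
#' perfusion-share differences when available) between a lateral step and
#' its immediately preceding supine step, relabels the quadrants by
#' dependent / non-dependent lung for that posture, and reports paired
#' statistics across subjects. If fewer than 2 subjects carry perfusion
#' data, the perfusion table is omitted with a notice.
#'
#' @param summaries stacked cohort summaries from \code{\link{runCohort}}.
#' @param lateralLabel "LateralLeft" or "LateralRight".
#' @return list with \code{eeli} and (possibly NULL) \code{perfusion}
#'   data.frames: one row per relabelled quadrant with meanDiff, t, df, p.
#' @export
quadrantChangeReport <- function(summaries,
                                 lateralLabel = c("LateralLeft",
                                                  "LateralRight")) {
  lateralLabel <- match.arg(lateralLabel)
  supLabel <- if (lateralLabel == "LateralLeft") "Supine1" else "Supine2"
  depSide <- if (lateralLabel == "LateralLeft") "left" else "right"
  ndSide <- if (depSide == "left") "right" else "left"
  relabel <- c(dep_ventral = paste0("upper_", depSide),
               dep_dorsal = paste0("lower_", depSide),
               nondep_ventral = paste0("upper_", ndSide),
               nondep_dorsal = paste0("lower_", ndSide))
  if (!"subject" %in% names(summaries)) summaries$subject <- 1L
  lat <- summaries[summaries$label == lateralLabel, ]
  sup <- summaries[summaries$label == supLabel, ]
  lat <- lat[order(lat$subject), ]; sup <- sup[order(sup$subject), ]
  if (!nrow(lat) || !nrow(sup) || !identical(lat$subject, sup$subject))
    stop("both steps must be present for the same subjects")
  buildTable <- function(prefix) {
    rows <- lapply(names(relabel), function(lbl) {
      col <- paste0(prefix, relabel[[lbl]])
      aVal <- sup[[col]]; bVal <- lat[[col]]
      ok <- is.finite(aVal) & is.finite(bVal)
      if (sum(ok) < 2L) return(NULL)
      pt <- tryCatch(pairedT(aVal[ok], bVal[ok]), error = function(e) NULL)
      data.frame(quadrant = lbl, n = sum(ok),
                 meanDiff = mean(bVal[ok] - aVal[ok]),
                 t = if (is.null(pt)) NA_real_ else pt$t,
                 df = if (is.null(pt)) NA_integer_ else pt$df,
                 p = if (is.null(pt)) NA_real_ else pt$p)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
  }
  eeli <- buildTable("eeli_")
  perf <- NULL
  if (any(grepl("^perf_", names(summaries)))) {
    perf <- buildTable("perf_")
    if (is.null(perf))
      message("perfusion data available for fewer than 2 subjects; ",
              "perfusion table omitted")
  } else {
    message("no perfusion data in the summaries; perfusion table omitted")
  }
  list(eeli = eeli, perfusion = perf)
}
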