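## Shared test helpers: random distributions, cached cohort run.

## Random point on the 4-simplex (quadrant fractions).
randomFractions <- function() {
  x <- stats::rgamma(4, 2)
  x / sum(x)
}

## Naive per-unit re-implementation of the breath open/close loop
## (instantaneous collapse), used as the brute-force oracle for stepState.
naiveBreathLoop <- function(model, vent, post, nBreaths) {
  u <- model@units
  cfg <- model@config
  gd <- gravitationalDepth(u$depth, u$lateral, post)
  pl <- cfg$pleural_ref + cfg$pleural_gradient * gd
  open <- u$open
  for (b in seq_len(nBreaths)) {
    dP <- vent$tidalVolume / sum(u$compliance[open])
    for (i in seq_along(open)) {
      if (!open[i] && (vent$peep + dP) - pl[i] > u$opening[i])
        open[i] <- TRUE
    }
    for (i in seq_along(open)) {
      if (open[i] && vent$peep - pl[i] < u$closing[i]) open[i] <- FALSE
    }
  }
  open
}

## The documented injured-cohort scenario (n = 7 subjects, master seed 1),
## computed once per test run and shared between acceptance blocks.
.cohortCache <- new.env(parent = emptyenv())
injuredCohort <- function() {
  if (is.null(.cohortCache$res))
    .cohortCache$res <- runCohort(simConfig(seed = 1), nSubjects = 7,
                                  seed = 1)
  .cohortCache$res
}

stepMeans <- function(summaries, col) {
  agg <- tapply(summaries[[col]], summaries$label, mean)
  agg[c("Supine1", "LateralLeft", "Supine2", "LateralRight", "Supine3")]
}
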