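#' Simulator configuration
#'
#' Builds the validated parameter list driving the compartmental thorax
#' simulator. Defaults describe a ~69 kg pig with a severe two-hit surfactant
#' depletion / ventilator injury, imaged by a 32-electrode EIT belt at 50 Hz.
#'
#' @param seed integer RNG seed for model construction.
#' @param frame_rate EIT acquisition rate, Hz.
#' @param grid pixel image side length (32 for the 1024-pixel image).
#' @param ap_span anterior-posterior (ventral-dorsal) thorax span, cm.
#' @param rl_span right-left thorax span, cm; must exceed \code{ap_span}
#'   (the thoracic right-to-left distance is the longer one, which is what
#'   makes the transpulmonary-pressure spread larger in lateral posture).
#' @param pleural_gradient pleural pressure increase per cm of gravitational
#'   depth, cmH2O/cm.
#' @param pleural_ref pleural pressure at the least-dependent lung point,
#'   cmH2O.
#' @param injury_severity dimensionless in [0, 1]; scales the opening and
#'   closing pressure distributions (0 = healthy lung).
#' @param healthy_compliance total respiratory-system compliance with every
#'   unit open, mL/cmH2O.
#' @param compliance_cv lognormal sdlog of the per-unit compliance jitter.
#' @param opening_base,opening_slope,opening_sd opening-pressure model
#'   (cmH2O): severity * (base + slope * depth_fraction + N(0, sd)).
#' @param closing_base,closing_slope,closing_sd closing-pressure model
#'   (cmH2O): severity * (base + slope * depth_fraction + N(0, sd)) minus
#'   (1 - severity) * healthy_closing_margin, capped at the opening pressure.
#' @param healthy_closing_margin how far below zero healthy closing pressures
#'   sit, cmH2O (healthy units never collapse at PEEP >= 0).
#' @param derecruit_damage length-2 range of the per-unit derecruitment
#'   damage threshold (cmH2O x breaths). Each breath spent with end-expiratory
#'   transpulmonary pressure below the closing pressure adds the deficit to a
#'   damage accumulator; the unit collapses when its threshold is exceeded.
#'   c(0, 0) makes collapse instantaneous.
#' @param cardiac_rate heart rate, beats/min.
#' @param cardiac_amplitude mean per-pixel cardiac impedance amplitude, A.U.
#' @param noise_sd white measurement noise per pixel per frame, A.U.
#' @param hpv_factor hypoxic-vasoconstriction perfusion multiplier applied to
#'   collapsed units, in [0, 1].
#' @param gravity_perfusion_slope relative perfusion change per cm of
#'   gravitational depth. The default is slightly negative: in the injured
#'   lung, vascular compression in the most dependent regions diverts flow
#'   away from them, which is what makes the posture-induced perfusion
#'   redistribution non-gravitational. Positive values give the classic
#'   gravity-dominant distribution instead.
#' @param eeli_gain,eeli_floor aeration baseline model: an open unit holds a
#'   pixel offset eeli_gain * compliance * (eeli_floor + max(P_L_exp, 0)).
#' @param tidal_gain tidal amplitude scale: open-unit tidal amplitude is
#'   tidal_gain * compliance * driving pressure.
#' @param oxy_ceiling,oxy_floor PaO2/FiO2-like oxygenation surrogate at shunt
#'   0 and 1.
#' @param bolus_delay,bolus_tp,bolus_shape gamma-variate first-pass dilution
#'   kernel: arrival delay (s), time-to-peak after arrival (s), shape.
#' @param bolus_amplitude mean per-pixel peak dilution deflection, A.U.
#' @param recirc_fraction,recirc_delay,recirc_tp recirculation bump relative
#'   amplitude, extra delay (s) and time-to-peak (s).
#' @return a validated list of class \code{simConfig}.
#' @export
simConfig <- function(seed = 1L, frame_rate = 50, grid = 32L,
                      ap_span = 24, rl_span = 34,
                      pleural_gradient = 0.5, pleural_ref = 0,
                      injury_severity = 1,
                      healthy_compliance = 32, compliance_cv = 0.25,
                      opening_base = 6, opening_slope = 26, opening_sd = 2,
                      closing_base = -2, closing_slope = 14, closing_sd = 1.5,
                      healthy_closing_margin = 30,
                      derecruit_damage = c(120, 1200),
                      cardiac_rate = 77, cardiac_amplitude = 0.15,
                      noise_sd = 0.05,
                      hpv_factor = 0.3, gravity_perfusion_slope = -0.02,
                      eeli_gain = 1, eeli_floor = 5, tidal_gain = 1,
                      oxy_ceiling = 500, oxy_floor = 40,
                      bolus_delay = 1.5, bolus_tp = 2.5, bolus_shape = 3,
                      bolus_amplitude = 3,
                      recirc_fraction = 0.2, recirc_delay = 8, recirc_tp = 4) {
  cfg <- list(seed = as.integer(seed), frame_rate = frame_rate,
              grid = as.integer(grid), ap_span = ap_span, rl_span = rl_span,
              pleural_gradient = pleural_gradient, pleural_ref = pleural_ref,
              injury_severity = injury_severity,
              healthy_compliance = healthy_compliance,
              compliance_cv = compliance_cv,
              opening_base = opening_base, opening_slope = opening_slope,
              opening_sd = opening_sd, closing_base = closing_base,
              closing_slope = closing_slope, closing_sd = closing_sd,
              healthy_closing_margin = healthy_closing_margin,
              derecruit_damage = derecruit_damage,
              cardiac_rate = cardiac_rate,
              cardiac_amplitude = cardiac_amplitude, noise_sd = noise_sd,
              hpv_factor = hpv_factor,
              gravity_perfusion_slope = gravity_perfusion_slope,
              eeli_gain = eeli_gain, eeli_floor = eeli_floor,
              tidal_gain = tidal_gain,
              oxy_ceiling = oxy_ceiling, oxy_floor = oxy_floor,
              bolus_delay = bolus_delay, bolus_tp = bolus_tp,
              bolus_shape = bolus_shape, bolus_amplitude = bolus_amplitude,
              recirc_fraction = recirc_fraction, recirc_delay = recirc_delay,
              recirc_tp = recirc_tp)
  validateSimConfig(cfg)
  class(cfg) <- c("simConfig", "list")
  cfg
}

validateSimConfig <- function(cfg) {
  stopifnot(is.finite(cfg$frame_rate), cfg$frame_rate > 0)
  if (!is.finite(cfg$ap_span) || cfg$ap_span <= 0 ||
      !is.finite(cfg$rl_span) || cfg$rl_span <= 0)
    stop("thorax spans must be positive")
  if (cfg$rl_span <= cfg$ap_span)
    stop("the right-left span must exceed the anterior-posterior span")
  if (cfg$injury_severity < 0 || cfg$injury_severity > 1)
    stop("injury_severity must lie in [0, 1]")
  if (cfg$hpv_factor < 0 || cfg$hpv_factor > 1)
    stop("hpv_factor must lie in [0, 1]")
  amps <- c(cfg$cardiac_amplitude, cfg$noise_sd, cfg$bolus_amplitude,
            cfg$tidal_gain, cfg$eeli_gain)
  if (any(amps < 0)) stop("amplitudes must be non-negative")
  if (length(cfg$derecruit_damage) != 2L || any(cfg$derecruit_damage < 0) ||
      diff(cfg$derecruit_damage) < 0)
    stop("derecruit_damage must be a non-negative, non-decreasing range")
  invisible(TRUE)
}

#' Ventilator settings
#'
#' Volume-controlled ventilation settings for one epoch.
#'
#' @param tidalVolume tidal volume, mL.
#' @param respRate respiratory rate, breaths/min.
#' @param peep positive end-expiratory pressure, cmH2O.
#' @param fio2 inspired oxygen fraction, in (0, 1].
#' @param ieRatio inspiratory:expiratory time ratio (0.5 for 1:2).
#' @return a validated list of class \code{ventSettings}.
#' @export
ventSettings <- function(tidalVolume = 350, respRate = 30, peep = 10,
                         fio2 = 1, ieRatio = 0.5) {
  if (!is.finite(tidalVolume) || tidalVolume <= 0)
    stop("tidalVolume must be positive")
  if (!is.finite(respRate) || respRate <= 0) stop("respRate must be positive")
  if (!is.finite(peep) || peep < 0) stop("peep must be non-negative")
  if (!is.finite(fio2) || fio2 <= 0 || fio2 > 1)
    stop("fio2 must lie in (0, 1]")
  if (!is.finite(ieRatio) || ieRatio <= 0) stop("ieRatio must be positive")
  structure(list(mode = "VCV", tidalVolume = tidalVolume, respRate = respRate,
                 peep = peep, fio2 = fio2, ieRatio = ieRatio),
            class = c("ventSettings", "list"))
}

#' Body posture
#'
#' "lateral_left" means the animal lies toward its LEFT side, i.e. the left
#' lung is gravitationally dependent (and symmetrically for "lateral_right").
#' Pixel coordinates are body-fixed; only the gravity axis rotates with
#' posture.
#'
#' @param label one of "supine", "lateral_left", "lateral_right".
#' @param tilt tilt angle in degrees (0 for supine, 30 for lateral).
#' @return a validated list of class \code{posture}.
#' @export
posture <- function(label = c("supine", "lateral_left", "lateral_right"),
                    tilt = if (match.arg(label) == "supine") 0 else 30) {
  label <- match.arg(label)
  if (!is.finite(tilt) || tilt < 0 || tilt > 90)
    stop("tilt must lie in [0, 90] degrees")
  if (label == "supine" && tilt != 0) stop("supine posture requires tilt 0")
  structure(list(label = label, tilt = tilt), class = c("posture", "list"))
}

#' PEEP titration criteria
#'
#' Operational parameters of the three-criterion upward PEEP titration
#' applied at each lateral-position onset: (a) global EELI stops decreasing,
#' (b) dependent-lung EELI stops decreasing over the observation window,
#' (c) the cumulative dependent-lung EELI drop since lateral onset does not
#' exceed \code{dzMultiple} times the pre-lateralization dependent-lung
#' deltaZ. "Stops decreasing" is operationalized as a least-squares slope no
#' more negative than \code{-eeliSlopeTolerance}.
#'
#' @param eeliSlopeTolerance slope tolerance, A.U. per minute; \code{NA}
#'   requests the default of 2% of the deltaZ reference per minute.
#' @param dependentWindow observation window, minutes.
#' @param dzMultiple multiple of the pre-lateralization dependent-lung deltaZ
#'   allowed as cumulative EELI drop, in [0.5, 1].
#' @param maxPeep safety cap, cmH2O.
#' @param stepSize PEEP increment, cmH2O.
#' @return a validated list of class \code{titrationCriteria}.
#' @export
titrationCriteria <- function(eeliSlopeTolerance = NA_real_,
                              dependentWindow = 2, dzMultiple = 1,
                              maxPeep = 24, stepSize = 2) {
  if (!is.finite(dependentWindow) || dependentWindow <= 0)
    stop("dependentWindow must be positive")
  if (!is.finite(dzMultiple) || dzMultiple < 0.5 || dzMultiple > 1)
    stop("dzMultiple must lie in [0.5, 1]")
  if (!is.finite(stepSize) || stepSize <= 0) stop("stepSize must be positive")
  if (!is.finite(maxPeep) || maxPeep <= 0) stop("maxPeep must be positive")
  structure(list(eeliSlopeTolerance = eeliSlopeTolerance,
                 dependentWindow = dependentWindow, dzMultiple = dzMultiple,
                 maxPeep = maxPeep, stepSize = stepSize),
            class = c("titrationCriteria", "list"))
}
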