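#' Default stimulus-ensemble configuration
#'
#' Six base classes: a square-wave grating class carrying six
#' spatial-frequency variants, plus five optical-flow patterns with one
#' variant each (11 variants total), every variant drifting in eight
#' directions: 11 x 8 = 88 unique sequences. Averaging variants within
#' class yields 6 x 8 = 48 class-direction analysis units.
#'
#' @return list with \code{classes} (named list class -> variant ids) and
#'   \code{nDirections}.
#' @export
defaultEnsembleConfig <- function() {
  list(
    classes = list(
      grating         = paste0("sf", 1:6),
      onedot_flow     = "v1",
      threedot_flow   = "v1",
      dense_flow      = "v1",
      radial_flow     = "v1",
      rotational_flow = "v1"
    ),
    nDirections = 8L
  )
}

#' Build a stimulus ensemble from a configuration
#'
#' Emits one sequence per (class, variant, direction) with directions on
#' a regular grid (degrees, counter-clockwise, 0 = rightward drift).
#'
#' @param config list with \code{classes} (named list mapping each base
#'   class to its variant ids) and \code{nDirections}. Defaults to
#'   \code{\link{defaultEnsembleConfig}}.
#' @return a \linkS4class{StimulusEnsemble}.
#' @export
#' @examples
#' ens <- makeStimulusEnsemble()
#' length(ens)  # 88
makeStimulusEnsemble <- function(config = defaultEnsembleConfig()) {
  classes <- config$classes
  nd <- config$nDirections
  if (is.null(classes) || length(classes) == 0L)
    stop("config error: at least one base class is required", call. = FALSE)
  if (is.null(nd) || nd < 1L)
    stop("config error: nDirections must be a positive integer", call. = FALSE)
  if (any(vapply(classes, length, 1L) == 0L))
    stop("config error: every class needs at least one variant", call. = FALSE)
  dirs <- directionGrid(nd)
  rows <- lapply(names(classes), function(cl) {
    do.call(rbind, lapply(classes[[cl]], function(v) {
      data.frame(
        sequence_id = sprintf("%s_%s_d%03d", cl, v, dirs),
        base_class  = cl,
        variant_id  = as.character(v),
        direction   = dirs,
        stringsAsFactors = FALSE
      )
    }))
  })
  StimulusEnsemble(do.call(rbind, rows), nDirections = nd,
                   classNames = names(classes))
}

#' Default population configuration for the response simulator
#'
#' @return list of simulator parameters; see \code{\link{simulatePopulation}}.
#' @export
defaultPopulationConfig <- function() {
  list(
    nPerClass     = 20L,          # tuned neurons planted per base class
    nNonselective = 12L,          # intensity-arm units (class/direction blind)
    kappaRange    = c(2, 6),      # von Mises concentration
    gainRange     = c(0.8, 1.2),
    offClassGain  = 0.15,         # affinity to non-preferred classes
    profiles      = c("transient", "sustained", "periodic", "ramp"),
    temporalFreq  = 2,            # Hz, periodic profile
    noiseModel    = "gaussian-truncated",
    noiseScale    = 0.05,
    nTimeBins     = 20L,
    binWidth      = 0.05,         # seconds -> 1 s trials
    sharedTuning  = FALSE,        # one (pref, kappa) per class, not per neuron
    profilesByClass = NULL        # named class -> profile, overrides sampling
  )
}

# Temporal profile value on bin centers tt (seconds); peak ~1.
temporalProfile <- function(profile, tt, temporalFreq = 2) {
  tmax <- max(tt)
  switch(profile,
    transient   = { tau <- tmax / 8
                    z <- (tt / tau) * exp(1 - tt / tau); z / max(z) },
    sustained   = 1 - exp(-4 * tt / tmax),
    periodic    = pmax(0, sin(2 * pi * temporalFreq * tt)),
    ramp        = tt / tmax,
    # intensity-arm units: class/direction blind, activity builds up over
    # the first timesteps and then sustains
    nonselective = 1 - exp(-4 * tt / tmax),
    stop(sprintf("config error: unknown temporal profile '%s'", profile),
         call. = FALSE)
  )
}

# Von Mises tuning, peak 1 at the preferred direction (degrees).
vonMisesTuning <- function(direction, preferred, kappa) {
  exp(kappa * (cos((direction - preferred) * pi / 180) - 1))
}

#' Simulate a population response tensor with planted ground truth
#'
#' Each neuron has a planted base class, a preferred direction, a von
#' Mises concentration and a temporal profile; its noiseless response to
#' a sequence of class c in direction d is
#' \code{gain * affinity(c) * vonMises(d) * profile(t)}, where affinity is
#' 1 for the planted class and \code{offClassGain} otherwise. Nonselective
#' ("intensity") units respond identically to every class and direction
#' with a sustained profile. Noise is added per entry and activity is
#' clipped at zero.
#'
#' @param ensemble a \linkS4class{StimulusEnsemble}.
#' @param popConfig list of parameters, see
#'   \code{\link{defaultPopulationConfig}}; partial lists are merged over
#'   the defaults.
#' @param seed integer; identical (config, seed) gives identical output.
#' @return list with elements \code{tensor} (\linkS4class{ResponseTensor})
#'   and \code{groundTruth} (data.frame: neuron_id, planted_class,
#'   preferred_direction, kappa, temporal_profile, gain).
#' @export
simulatePopulation <- function(ensemble, popConfig = list(), seed = 1L) {
  cfg <- modifyList(defaultPopulationConfig(), popConfig)
  if (any(cfg$kappaRange < 0))
    stop("config error: kappa must be nonnegative", call. = FALSE)
  if (cfg$noiseScale < 0)
    stop("config error: noise scale must be nonnegative", call. = FALSE)
  if (!cfg$noiseModel %in% c("gaussian-truncated", "poisson-like"))
    stop(sprintf("config error: unknown noise model '%s'", cfg$noiseModel),
         call. = FALSE)
  cls <- classNames(ensemble)
  nPerClass <- cfg$nPerClass
  if (length(nPerClass) == 1L)
    nPerClass <- stats::setNames(rep(nPerClass, length(cls)), cls)
  stopIfNot(all(cls %in% names(nPerClass) | length(names(nPerClass)) == 0),
            "config error: nPerClass must cover every class")
  if (is.null(names(nPerClass))) names(nPerClass) <- cls

  sq <- sequenceTable(ensemble)
  S <- nrow(sq)
  T <- cfg$nTimeBins
  tt <- (seq_len(T) - 0.5) * cfg$binWidth

  withSeed(seed, {
    gt <- do.call(rbind, lapply(cls, function(cl) {
      n <- nPerClass[[cl]]
      if (isTRUE(cfg$sharedTuning)) {
        pref <- rep(runif(1, 0, 360), n)
        kap <- rep(runif(1, cfg$kappaRange[1], cfg$kappaRange[2]), n)
      } else {
        pref <- runif(n, 0, 360)
        kap <- runif(n, cfg$kappaRange[1], cfg$kappaRange[2])
      }
      prof <- if (!is.null(cfg$profilesByClass))
        rep(cfg$profilesByClass[[cl]], n)
      else sample(cfg$profiles, n, replace = TRUE)
      data.frame(
        planted_class       = rep(cl, n),
        preferred_direction = pref,
        kappa               = kap,
        temporal_profile    = prof,
        gain                = runif(n, cfg$gainRange[1], cfg$gainRange[2]),
        stringsAsFactors = FALSE
      )
    }))
    if (cfg$nNonselective > 0L) {
      n <- cfg$nNonselective
      gt <- rbind(gt, data.frame(
        planted_class       = rep("none", n),
        preferred_direction = runif(n, 0, 360),
        kappa               = rep(0, n),
        temporal_profile    = rep("nonselective", n),
        gain                = runif(n, cfg$gainRange[1], cfg$gainRange[2]),
        stringsAsFactors = FALSE
      ))
    }
    N <- nrow(gt)
    gt <- cbind(data.frame(neuron_id = sprintf("n%03d", seq_len(N)),
                           stringsAsFactors = FALSE), gt)

    a <- array(0, dim = c(N, S, T))
    for (n in seq_len(N)) {
      prof <- temporalProfile(gt$temporal_profile[n], tt, cfg$temporalFreq)
      if (gt$temporal_profile[n] == "nonselective") {
        affinity <- rep(1, S)
        tuning <- rep(1, S)
      } else {
        affinity <- ifelse(sq$base_class == gt$planted_class[n], 1,
                           cfg$offClassGain)
        tuning <- vonMisesTuning(sq$direction, gt$preferred_direction[n],
                                 gt$kappa[n])
      }
      a[n, , ] <- outer(gt$gain[n] * affinity * tuning, prof)
    }
    if (cfg$noiseScale > 0) {
      noise <- switch(cfg$noiseModel,
        "gaussian-truncated" = array(rnorm(length(a), 0, cfg$noiseScale),
                                     dim = dim(a)),
        "poisson-like"       = array(rnorm(length(a), 0,
                                           sqrt(pmax(a, 0) * cfg$noiseScale)),
                                     dim = dim(a))
      )
      a <- a + noise
    }
    a[a < 0] <- 0
    tensor <- ResponseTensor(a, binWidth = cfg$binWidth, ensemble = ensemble,
                             neuronIds = gt$neuron_id)
    list(tensor = tensor, groundTruth = gt)
  })
}
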