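#' Frequency band definitions
#'
#' A band definition table with columns `name`, `lo`, `hi` (Hz). Two presets
#' are provided because the analysed bands differ between the primary
#' analysis and the narrower follow-up contrast:
#' \describe{
#'   \item{`"primary"`}{low delta 0.5-3.5 Hz, alpha 9.5-11.5 Hz, low beta
#'     16.5-19.5 Hz — the bands selected against the 1/f background for the
#'     main channel-wise analysis.}
#'   \item{`"narrow"`}{delta 0.5-3.5 Hz, theta 7-8 Hz, alpha 10-11 Hz — the
#'     narrower bands used for the "specific alpha" (alpha minus theta)
#'     contrast.}
#' }
#'
#' @param preset `"primary"` or `"narrow"`
#' @return `data.frame` with columns `name`, `lo`, `hi`
#' @examples
#' bandPresets("primary")
#' @export
bandPresets <- function(preset = c("primary", "narrow")) {
  preset <- match.arg(preset)
  switch(preset,
    primary = data.frame(name = c("delta", "alpha", "lowbeta"),
                         lo = c(0.5, 9.5, 16.5), hi = c(3.5, 11.5, 19.5)),
    narrow = data.frame(name = c("delta", "theta", "alpha"),
                        lo = c(0.5, 7, 10), hi = c(3.5, 8, 11)))
}

#' Define a single frequency band
#'
#' @param name band name
#' @param lo,hi band edges in Hz, `0 < lo < hi`
#' @return one-row `data.frame` usable wherever a band table is expected
#' @export
bandDef <- function(name, lo, hi) {
  if (!(lo > 0 && hi > lo)) stop("band edges must satisfy 0 < lo < hi")
  data.frame(name = name, lo = lo, hi = hi)
}

#' Construct a study design
#'
#' @param participants `data.frame` with columns `id`, `age`, `shss`
#' @param conditions `data.frame` with columns `state`, `memory`, `phase`,
#'   `duration_s`
#' @param samplingRate sampling rate in Hz
#' @return a [StudyDesign-class]
#' @export
studyDesign <- function(participants, conditions, samplingRate = 250) {
  participants$id <- as.character(participants$id)
  new("StudyDesign", participants = participants, conditions = conditions,
      samplingRate = samplingRate)
}

#' The emulated study design
#'
#' Five participants (ages and SHSS:C scores from the reference study's
#' participant table) each complete recall blocks crossing hypnosis state
#' (NC, HY) and recalled memory (NDE, AUTOBIO), with each 20-minute recall
#' split into two focus phases (OBE then PE for the NDE memory; KS then PE
#' for the autobiographical memory), at 250 Hz. `blockDuration` scales every
#' phase block (default 600 s = half of a 20-minute recall); tests and worked
#' examples use shorter blocks.
#'
#' @param blockDuration duration in seconds of each phase block
#' @param samplingRate sampling rate in Hz
#' @return a [StudyDesign-class]
#' @examples
#' designEmulation(blockDuration = 120)
#' @export
designEmulation <- function(blockDuration = 600, samplingRate = 250) {
  participants <- data.frame(
    id = paste0("P", 1:5),
    age = c(60, 44, 66, 71, 48),
    shss = c(6, 9, 8, 9, 4))
  grid <- expand.grid(state = c("NC", "HY"), memory = c("NDE", "AUTOBIO"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  conditions <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    first <- if (grid$memory[i] == "NDE") "OBE" else "KS"
    data.frame(state = grid$state[i], memory = grid$memory[i],
               phase = c(first, "PE"), duration_s = blockDuration)
  }))
  studyDesign(participants, conditions, samplingRate)
}

#' Construct simulation parameters
#'
#' See [SimulationParams-class] for the meaning of each field. Defaults give
#' a 1/f background, moderate participant heterogeneity and window noise on
#' the log-power scale, and an artifact load comparable to a clean seated
#' recording (about 2 s of artifact per minute, i.e. ~3%).
#'
#' @param backgroundSlope exponent of the 1/f^slope background
#' @param baseLogPower baseline log band power of oscillation-carrying bands
#' @param bandEffects effect table built with [bandEffect()] (rbind rows)
#' @param participantSd SD of the participant random intercept (log power)
#' @param windowNoiseSd SD of the per-window residual (log power)
#' @param artifactRate expected artifact seconds per minute
#' @param artifactMeanDuration mean artifact segment duration (s)
#' @param backgroundScale amplitude scale of the 1/f background signal
#' @param seed integer RNG seed
#' @return a [SimulationParams-class]
#' @export
simulationParams <- function(backgroundSlope = 1, baseLogPower = 2,
                             bandEffects = emptyBandEffects(),
                             participantSd = 0.5, windowNoiseSd = 0.5,
                             artifactRate = 2, artifactMeanDuration = 3,
                             backgroundScale = 10, seed = 1) {
  new("SimulationParams", backgroundSlope = backgroundSlope,
      baseLogPower = baseLogPower, bandEffects = bandEffects,
      participantSd = participantSd, windowNoiseSd = windowNoiseSd,
      artifactRate = artifactRate,
      artifactMeanDuration = artifactMeanDuration,
      backgroundScale = backgroundScale, seed = as.integer(seed))
}

#' Specify one injected condition effect on log band power
#'
#' @param band band name the effect applies to
#' @param shift additive shift on log band power
#' @param state,memory,phase factor levels the effect is restricted to
#'   (`NA` = applies at every level of that factor)
#' @param channels channel labels carrying the effect (`NULL` = all channels)
#' @return one-row effect table; rbind rows to combine effects
#' @examples
#' bandEffect("alpha", 0.8, memory = "NDE", channels = c("E1", "E2"))
#' @export
bandEffect <- function(band, shift, state = NA, memory = NA, phase = NA,
                       channels = NULL) {
  out <- data.frame(band = band, state = state, memory = memory,
                    phase = phase, shift = shift)
  out$channels <- list(channels)
  out
}

#' @rdname bandEffect
#' @export
emptyBandEffects <- function() {
  out <- data.frame(band = character(), state = character(),
                    memory = character(), phase = character(),
                    shift = numeric())
  out$channels <- list()
  out
}

#' Frontal channels of a layout
#'
#' Returns the `n` channel labels with the largest y coordinate (the montage
#' convention here is +y = anterior, +z = superior). Used to place injected
#' effects on a spatially contiguous frontal patch.
#'
#' @param layout a [SensorLayout-class]
#' @param n number of channels
#' @return character vector of channel labels
#' @export
frontalChannels <- function(layout, n) {
  ch <- layout@channels
  ch$label[order(ch$y, decreasing = TRUE)][seq_len(n)]
}

#' Scaled-down emulation preset
#'
#' Bundles a small version of the emulated study for fast end-to-end runs
#' and calibration simulations: 8 channels, 2-minute phase blocks, 5
#' participants, and (optionally) an alpha-band effect of `effectSize` log
#' units during NDE recall on a connected 4-channel frontal patch.
#'
#' @param effectSize injected NDE alpha shift in log-power units (0 = null)
#' @param seed integer seed stored in the parameters
#' @param nChannels number of channels in the layout
#' @param blockDuration phase-block duration in seconds
#' @param patchSize number of frontal channels carrying the effect
#' @return list with elements `design`, `layout`, `params`, `bands`,
#'   `effectChannels`
#' @export
presetEmulationSmall <- function(effectSize = 0, seed = 1, nChannels = 8,
                                 blockDuration = 120, patchSize = 4) {
  design <- designEmulation(blockDuration = blockDuration)
  layout <- buildLayout(nChannels)
  patch <- frontalChannels(layout, patchSize)
  effects <- if (effectSize != 0)
    bandEffect("alpha", effectSize, memory = "NDE", channels = patch)
  else emptyBandEffects()
  params <- simulationParams(bandEffects = effects, seed = seed)
  list(design = design, layout = layout, params = params,
       bands = bandPresets("primary"), effectChannels = patch)
}
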