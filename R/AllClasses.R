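#' @import methods
NULL

#' Sensor layout: channel identities, positions, and adjacency graph
#'
#' Holds the spatial substrate of a montage: one row per channel (integer id,
#' label, 3-D position on/near a unit hemisphere) and an undirected adjacency
#' edge set used by cluster enhancement and cluster decomposition. The edge
#' set is stored once per unordered pair (`from < to`); symmetry is implied.
#'
#' @slot channels `data.frame` with columns `id` (integer), `label`
#'   (character), `x`, `y`, `z` (numeric positions).
#' @slot edges two-column integer matrix of channel ids, one row per
#'   undirected edge, `from < to`, no self-edges.
#' @seealso [sensorLayout()], [buildLayout()]
#' @export
setClass("SensorLayout",
  representation(channels = "data.frame", edges = "matrix"))

setValidity("SensorLayout", function(object) {
  ch <- object@channels
  msgs <- character()
  if (!all(c("id", "label", "x", "y", "z") %in% names(ch)))
    msgs <- c(msgs, "channels must have columns id, label, x, y, z")
  else {
    if (anyDuplicated(ch$id)) msgs <- c(msgs, "channel ids must be unique")
    e <- object@edges
    if (ncol(e) != 2) msgs <- c(msgs, "edges must have two columns")
    else if (nrow(e) > 0) {
      if (!all(e %in% ch$id))
        msgs <- c(msgs, "every edge endpoint must be a known channel id")
      if (any(e[, 1] == e[, 2])) msgs <- c(msgs, "self-edges are not allowed")
      if (any(e[, 1] >= e[, 2]))
        msgs <- c(msgs, "edges must be stored with from < to")
      if (anyDuplicated(e)) msgs <- c(msgs, "duplicate edges")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Continuous multichannel recording
#'
#' The carrier of all signal-level stages: a channels x time matrix of
#' potentials in microvolts, the sampling rate, condition and artifact
#' annotations in seconds from recording start, a bad-channel set, and the
#' current reference scheme.
#'
#' @slot samples numeric matrix, channels x samples, rownames = channel
#'   labels.
#' @slot samplingRate sampling rate in Hz.
#' @slot conditionAnnotations `data.frame` with columns `onset_s`,
#'   `duration_s`, `state` (HY/NC), `memory` (NDE/AUTOBIO), `phase`
#'   (OBE/PE/KS).
#' @slot artifactAnnotations `data.frame` with columns `onset_s`,
#'   `duration_s`.
#' @slot badChannels character vector of channel labels marked bad.
#' @slot reference `"original"` or `"average"`.
#' @slot participant participant identifier (scalar character).
#' @seealso [recording()], [simulateRecording()]
#' @export
setClass("Recording",
  representation(samples = "matrix", samplingRate = "numeric",
                 conditionAnnotations = "data.frame",
                 artifactAnnotations = "data.frame",
                 badChannels = "character", reference = "character",
                 participant = "character"))

setValidity("Recording", function(object) {
  msgs <- character()
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msgs <- c(msgs, "samplingRate must be a single positive number")
  if (is.null(rownames(object@samples)))
    msgs <- c(msgs, "samples must have channel labels as rownames")
  if (!object@reference %in% c("original", "average"))
    msgs <- c(msgs, "reference must be 'original' or 'average'")
  if (!all(object@badChannels %in% rownames(object@samples)))
    msgs <- c(msgs, "badChannels must be a subset of channel labels")
  dur <- ncol(object@samples) / object@samplingRate
  for (nm in c("conditionAnnotations", "artifactAnnotations")) {
    ann <- slot(object, nm)
    if (nrow(ann)) {
      if (!all(c("onset_s", "duration_s") %in% names(ann)))
        msgs <- c(msgs, paste(nm, "needs onset_s and duration_s"))
      else if (any(ann$onset_s < 0) ||
               any(ann$onset_s + ann$duration_s > dur + 1e-9))
        msgs <- c(msgs, paste(nm, "must lie within the recording duration"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Within-subject study design
#'
#' Participants (with age and SHSS:C score covariates) and the ordered
#' sequence of condition blocks every participant completes. Each block
#' crosses the three within-subject factors: `state` (HY = hypnosis,
#' NC = normal consciousness), `memory` (NDE vs AUTOBIO recall) and `phase`
#' (recall focus: OBE or PE within NDE blocks, KS or PE within AUTOBIO
#' blocks).
#'
#' @slot participants `data.frame` with columns `id`, `age` (years), `shss`
#'   (integer 0-12).
#' @slot conditions `data.frame` with columns `state`, `memory`, `phase`,
#'   `duration_s`.
#' @slot samplingRate sampling rate in Hz for simulated recordings.
#' @seealso [studyDesign()], [designEmulation()]
#' @export
setClass("StudyDesign",
  representation(participants = "data.frame", conditions = "data.frame",
                 samplingRate = "numeric"))

setValidity("StudyDesign", function(object) {
  msgs <- character()
  p <- object@participants
  if (!all(c("id", "age", "shss") %in% names(p)))
    msgs <- c(msgs, "participants must have columns id, age, shss")
  else {
    if (anyDuplicated(p$id)) msgs <- c(msgs, "participant ids must be unique")
    if (any(p$shss < 0 | p$shss > 12))
      msgs <- c(msgs, "shss scores must lie in 0..12")
  }
  cn <- object@conditions
  if (!all(c("state", "memory", "phase", "duration_s") %in% names(cn)))
    msgs <- c(msgs, "conditions must have state, memory, phase, duration_s")
  else {
    if (!all(cn$state %in% c("HY", "NC")))
      msgs <- c(msgs, "state levels must be HY or NC")
    if (!all(cn$memory %in% c("NDE", "AUTOBIO")))
      msgs <- c(msgs, "memory levels must be NDE or AUTOBIO")
    if (!all(cn$phase %in% c("OBE", "PE", "KS")))
      msgs <- c(msgs, "phase levels must be OBE, PE or KS")
    if (any(cn$duration_s <= 0))
      msgs <- c(msgs, "block durations must be positive")
  }
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msgs <- c(msgs, "samplingRate must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Simulation parameters for the synthetic-data generator
#'
#' Controls the generative linear model on log band power:
#' `power = baseline(band) + participant intercept + injected effects +
#' window noise`, the 1/f background spectrum of synthesised signals, and the
#' artifact process.
#'
#' @slot backgroundSlope exponent of the 1/f^slope background spectrum.
#' @slot baseLogPower intercept of log band power for an oscillation-carrying
#'   band (log microvolt^2 units).
#' @slot bandEffects `data.frame` with columns `band`, `state`, `memory`,
#'   `phase` (NA = applies to every level), `shift` (additive shift on log
#'   power), `channels` (list column of channel labels carrying the effect;
#'   NULL/NA = all channels).
#' @slot participantSd SD of the participant random intercept on log power.
#' @slot windowNoiseSd SD of the per-window residual on log power.
#' @slot artifactRate expected seconds of artifact per minute of recording.
#' @slot artifactMeanDuration mean duration (s) of one artifact segment.
#' @slot backgroundScale overall amplitude scale of the 1/f background.
#' @slot seed integer RNG seed.
#' @seealso [simulationParams()], [simulateWindowTable()],
#'   [simulateRecording()]
#' @export
setClass("SimulationParams",
  representation(backgroundSlope = "numeric", baseLogPower = "numeric",
                 bandEffects = "data.frame", participantSd = "numeric",
                 windowNoiseSd = "numeric", artifactRate = "numeric",
                 artifactMeanDuration = "numeric",
                 backgroundScale = "numeric", seed = "integer"))

setValidity("SimulationParams", function(object) {
  msgs <- character()
  if (object@participantSd < 0 || object@windowNoiseSd < 0)
    msgs <- c(msgs, "standard deviations must be >= 0")
  if (object@artifactRate < 0) msgs <- c(msgs, "artifactRate must be >= 0")
  be <- object@bandEffects
  if (nrow(be)) {
    if (!all(c("band", "state", "memory", "phase", "shift") %in% names(be)))
      msgs <- c(msgs,
        "bandEffects needs columns band, state, memory, phase, shift")
    else {
      bad_state <- !is.na(be$state) & !be$state %in% c("HY", "NC")
      bad_mem <- !is.na(be$memory) & !be$memory %in% c("NDE", "AUTOBIO")
      bad_ph <- !is.na(be$phase) & !be$phase %in% c("OBE", "PE", "KS")
      if (any(bad_state | bad_mem | bad_ph))
        msgs <- c(msgs, "unknown factor level in bandEffects")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Fixed- and random-effect structure of the channel-wise mixed model
#'
#' The dependent variable is windowed band power; the random structure is
#' always a participant intercept. Fixed terms are drawn from the three
#' within-subject factors (`state`, `memory`, `focus`), their interactions,
#' and the covariates `age` and `shss`. Interaction terms require their
#' lower-order terms (hierarchy).
#'
#' @slot fixedTerms character vector of model terms, e.g.
#'   `c("state", "memory", "state:memory", "age")`.
#' @seealso [modelSpec()], [fitChannel()]
#' @export
setClass("ModelSpec", representation(fixedTerms = "character"))

setValidity("ModelSpec", function(object) {
  terms <- object@fixedTerms
  known_main <- c("state", "memory", "focus", "age", "shss")
  msgs <- character()
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% known_main)) {
      msgs <- c(msgs, paste0("unknown term component in '", tm, "'"))
      next
    }
    if (length(parts) > 1) {
      need <- lowerOrderTerms(tm)
      if (!all(need %in% terms))
        msgs <- c(msgs, paste0("interaction '", tm,
                               "' requires its lower-order terms"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of one channel-wise mixed-model fit
#'
#' @slot coefficients `data.frame` with columns `term`, `estimate`, `se`,
#'   `t` (one row per fixed-effect coefficient).
#' @slot logLik maximised (ML) log-likelihood.
#' @slot AIC Akaike information criterion of the fit.
#' @slot effectTests `data.frame` with columns `term`, `chisq`, `df`, `p`
#'   (likelihood-ratio test of dropping the term and, per hierarchy, its
#'   dependents).
#' @slot nWindows number of windows (rows) used.
#' @slot converged logical convergence flag.
#' @slot channel channel label.
#' @slot band band name.
#' @slot engine fitting engine used ("lmer" or "profile").
#' @seealso [fitChannel()], [effectTest()]
#' @export
setClass("FitResult",
  representation(coefficients = "data.frame", logLik = "numeric",
                 AIC = "numeric", effectTests = "data.frame",
                 nWindows = "integer", converged = "logical",
                 channel = "character", band = "character",
                 engine = "character"))

#' Per-channel statistic map for one model parameter
#'
#' @slot parameter name of the fixed-effect coefficient the map belongs to.
#' @slot statistic named numeric vector, one T-value per channel (names =
#'   channel labels). Non-converged channels carry `NA`.
#' @slot band band name the map was computed for.
#' @seealso [fitAllChannels()], [tfceTransform()]
#' @export
setClass("TopoStatMap",
  representation(parameter = "character", statistic = "numeric",
                 band = "character"))

setValidity("TopoStatMap", function(object) {
  if (is.null(names(object@statistic)))
    "statistic must be named by channel label"
  else TRUE
})

#' Max-statistic permutation inference result
#'
#' @slot parameter model parameter tested.
#' @slot band band name.
#' @slot observed named numeric vector of observed T-values per channel.
#' @slot enhanced named numeric vector of TFCE-enhanced observed values.
#' @slot nullMax numeric vector of permutation-null maxima (one per
#'   relabelling).
#' @slot pvalues named numeric per-channel p-values (add-one estimator).
#' @slot threshold significance threshold used for the summary.
#' @slot summary list: `n_significant`, `significant` (labels), `clusters`
#'   (list of label vectors), `cluster_sizes`, `peak_channel`, `peak_T`,
#'   `peak_p`, `n_permutations`, `exhaustive`.
#' @seealso [permutationTest()], [significanceSummary()]
#' @export
setClass("PermutationResult",
  representation(parameter = "character", band = "character",
                 observed = "numeric", enhanced = "numeric",
                 nullMax = "numeric", pvalues = "numeric",
                 threshold = "numeric", summary = "list"))

setValidity("PermutationResult", function(object) {
  p <- object@pvalues
  if (length(p) && (any(p <= 0) || any(p > 1)))
    "p-values must lie in (0, 1]"
  else TRUE
})
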