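#' Number of channels
#' @param x a [SensorLayout-class] or [Recording-class]
#' @return integer count of channels
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Channel labels
#' @param x a [SensorLayout-class] or [Recording-class]
#' @return character vector of channel labels
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Channel positions
#' @param x a [SensorLayout-class]
#' @return numeric matrix (channels x 3) of positions
#' @export
setGeneric("channelPositions",
           function(x) standardGeneric("channelPositions"))

#' Adjacency edge list
#' @param x a [SensorLayout-class]
#' @return two-column integer matrix of channel ids (one row per undirected
#'   edge)
#' @export
setGeneric("adjacencyEdges", function(x) standardGeneric("adjacencyEdges"))

#' Sampling rate in Hz
#' @param x a [Recording-class] or [StudyDesign-class]
#' @return sampling rate (Hz)
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @describeIn SensorLayout number of channels
#' @param x object
#' @export
setMethod("nChannels", "SensorLayout", function(x) nrow(x@channels))

#' @describeIn SensorLayout channel labels
#' @export
setMethod("channelLabels", "SensorLayout", function(x) x@channels$label)

#' @describeIn SensorLayout positions matrix (channels x 3)
#' @export
setMethod("channelPositions", "SensorLayout", function(x) {
  m <- as.matrix(x@channels[, c("x", "y", "z")])
  rownames(m) <- x@channels$label
  m
})

#' @describeIn SensorLayout undirected edge list over channel ids
#' @export
setMethod("adjacencyEdges", "SensorLayout", function(x) x@edges)

#' @describeIn Recording number of channels
#' @param x object
#' @export
setMethod("nChannels", "Recording", function(x) nrow(x@samples))

#' @describeIn Recording channel labels
#' @export
setMethod("channelLabels", "Recording", function(x) rownames(x@samples))

#' @describeIn Recording sampling rate (Hz)
#' @export
setMethod("samplingRate", "Recording", function(x) x@samplingRate)

#' @describeIn StudyDesign sampling rate (Hz)
#' @param x object
#' @export
setMethod("samplingRate", "StudyDesign", function(x) x@samplingRate)

setMethod("show", "SensorLayout", function(object) {
  cat("SensorLayout with", nChannels(object), "channels and",
      nrow(object@edges), "adjacency edges\n")
  deg <- tabulate(factor(c(object@edges), levels = object@channels$id),
                  nbins = nChannels(object))
  cat("  degree: min", min(deg), "/ median", stats::median(deg),
      "/ max", max(deg), "\n")
})

setMethod("show", "Recording", function(object) {
  dur <- ncol(object@samples) / object@samplingRate
  cat(sprintf("Recording: %d channels x %.1f s @ %g Hz (%s reference)\n",
              nChannels(object), dur, object@samplingRate,
              object@reference))
  if (nzchar(object@participant))
    cat("  participant:", object@participant, "\n")
  cat(sprintf("  %d condition block(s), %d artifact segment(s), %d bad channel(s)\n",
              nrow(object@conditionAnnotations),
              nrow(object@artifactAnnotations),
              length(object@badChannels)))
})

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", nrow(object@participants), "participants,",
      nrow(object@conditions), "condition blocks per participant @",
      object@samplingRate, "Hz\n")
  cat("  total task time per participant:",
      sum(object@conditions$duration_s) / 60, "min\n")
})

setMethod("show", "SimulationParams", function(object) {
  cat(sprintf(
    "SimulationParams: 1/f^%.2f background, participant SD %.2f, window SD %.2f\n",
    object@backgroundSlope, object@participantSd, object@windowNoiseSd))
  cat(sprintf("  %d injected effect(s), artifact rate %.2f s/min, seed %d\n",
              nrow(object@bandEffects), object@artifactRate, object@seed))
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec: power ~",
      if (length(object@fixedTerms)) paste(object@fixedTerms, collapse = " + ")
      else "1",
      "+ (1 | participant)\n")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s / %s, engine=%s, %sconverged]\n",
              object@channel, object@band, object@engine,
              if (object@converged) "" else "NOT "))
  cat(sprintf("  logLik %.3f, AIC %.3f, n = %d windows\n",
              object@logLik, object@AIC, object@nWindows))
  print(object@coefficients, row.names = FALSE, digits = 4)
  if (nrow(object@effectTests)) {
    cat("  likelihood-ratio effect tests:\n")
    print(object@effectTests, row.names = FALSE, digits = 4)
  }
})

setMethod("show", "TopoStatMap", function(object) {
  v <- object@statistic
  cat(sprintf("TopoStatMap '%s' (%s band): %d channels, T range [%.3f, %.3f]\n",
              object@parameter, object@band, length(v),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "PermutationResult", function(object) {
  s <- object@summary
  cat(sprintf("PermutationResult '%s' (%s band): %d permutations%s\n",
              object@parameter, object@band, length(object@nullMax),
              if (isTRUE(s$exhaustive)) " (exhaustive)" else ""))
  cat(sprintf("  %d significant channel(s) at p < %.4f", s$n_significant,
              object@threshold))
  if (s$n_significant > 0)
    cat(sprintf("; peak %s (T = %.3f, p = %.4f)", s$peak_channel, s$peak_T,
                s$peak_p))
  cat("\n")
})
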