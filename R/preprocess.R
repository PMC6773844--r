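#' First-order high-pass filter
#'
#' Applies a first-order Butterworth high-pass to every channel. Filtering is
#' forward-backward (zero-phase) so annotation timestamps keep their meaning;
#' annotations are never altered.
#'
#' @param rec a [Recording-class]
#' @param cutoff cutoff frequency in Hz (0 < cutoff < Nyquist)
#' @return the filtered [Recording-class]
#' @export
highpass <- function(rec, cutoff = 0.1) {
  nyq <- rec@samplingRate / 2
  if (!(cutoff > 0 && cutoff < nyq))
    stop("invalid filter: cutoff must lie in (0, Nyquist)")
  bf <- signal::butter(1, cutoff / nyq, type = "high")
  applyFilter(rec, bf)
}

#' Butterworth band-stop filter for mains noise
#'
#' Attenuates the mains component (50 Hz by default) with a second-order
#' Butterworth band-stop between `stopLo` and `stopHi`, applied
#' forward-backward (zero-phase). Passband gain is near unity away from the
#' stop band.
#'
#' @param rec a [Recording-class]
#' @param stopLo,stopHi stop-band edges in Hz (0 < stopLo < stopHi < Nyquist)
#' @param order filter order
#' @return the filtered [Recording-class]
#' @export
lineNoiseFilter <- function(rec, stopLo = 48, stopHi = 52, order = 2) {
  nyq <- rec@samplingRate / 2
  if (!(stopLo > 0 && stopHi > stopLo && stopHi < nyq))
    stop("invalid filter: need 0 < stopLo < stopHi < Nyquist")
  bf <- signal::butter(order, c(stopLo, stopHi) / nyq, type = "stop")
  applyFilter(rec, bf)
}

applyFilter <- function(rec, bf) {
  out <- rec
  for (c in seq_len(nrow(rec@samples)))
    out@samples[c, ] <- signal::filtfilt(bf, rec@samples[c, ])
  out
}

# Magnitude response |H(f)| of a designed filter at frequencies f (Hz); the
# zero-phase (filtfilt) gain is |H(f)|^2.
filterGain <- function(bf, f, samplingRate) {
  w <- 2 * pi * f / samplingRate
  z <- exp(-1i * w)
  num <- outer(z, seq_along(bf$b) - 1, `^`) %*% bf$b
  den <- outer(z, seq_along(bf$a) - 1, `^`) %*% bf$a
  as.numeric(Mod(num / den))
}

# ---- spherical-spline interpolation ------------------------------------

# g(x) kernel of the spherical spline (Perrin-style): sum over Legendre
# degrees n of (2n+1) / (n (n+1))^m * P_n(x) / (4 pi), truncated at nTerms.
sphericalSplineG <- function(x, m = 4, nTerms = 50) {
  # Legendre polynomials by upward recursion, accumulated on the fly
  out <- numeric(length(x))
  Pnm1 <- rep(1, length(x)) # P_0
  Pn <- x                   # P_1
  for (n in seq_len(nTerms)) {
    out <- out + (2 * n + 1) / (n * (n + 1))^m * Pn
    Pnp1 <- ((2 * n + 1) * x * Pn - n * Pnm1) / (n + 1)
    Pnm1 <- Pn
    Pn <- Pnp1
  }
  out / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces each bad channel's time series with a spherical-spline estimate
#' from the good channels (spline order `m`, ridge regularisation `lambda`
#' on the kernel matrix diagonal). Channel positions are radially projected
#' to the unit sphere. The bad-channel set is cleared afterwards; the labels
#' that were interpolated are recorded in the returned recording's
#' `interpolated` attribute-like log (see Details).
#'
#' Refuses to interpolate when more than half of all channels are bad.
#'
#' @param rec a [Recording-class] with `badChannels` set
#' @param layout a [SensorLayout-class] covering all channels of `rec`
#' @param m spline stiffness order
#' @param lambda ridge regularisation added to the kernel diagonal
#' @return the interpolated [Recording-class] (bad set cleared)
#' @export
interpolateBadChannels <- function(rec, layout, m = 4, lambda = 1e-5) {
  bad <- rec@badChannels
  if (length(bad) == 0) return(rec)
  labels <- channelLabels(rec)
  if (!all(labels %in% channelLabels(layout)))
    stop("layout does not cover all recording channels")
  if (length(bad) > length(labels) / 2)
    stop("more than 50% of channels are bad; interpolation refused")

  pos <- channelPositions(layout)[labels, , drop = FALSE]
  pos <- pos / sqrt(rowSums(pos^2)) # project to unit sphere
  good <- setdiff(labels, bad)
  cosang <- pos %*% t(pos) # cos(angle) between channel pairs
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1

  G <- sphericalSplineG(cosang[good, good, drop = FALSE], m = m)
  ng <- length(good)
  # solve [G + lambda I, 1; 1', 0] [c; c0] = [y; 0]
  A <- rbind(cbind(G + diag(lambda, ng), 1), c(rep(1, ng), 0))
  Gbad <- sphericalSplineG(cosang[bad, good, drop = FALSE], m = m)

  out <- rec
  Y <- rbind(rec@samples[good, , drop = FALSE], 0)
  C <- solve(A, Y)
  out@samples[bad, ] <- cbind(Gbad, 1) %*% C
  out@badChannels <- character()
  out
}

#' Re-reference to the average reference
#'
#' Subtracts the per-sample mean over all channels from every channel. When
#' the original (acquisition) reference channel is absent from the montage it
#' is first recuperated as an all-zero channel (its potential in
#' original-reference data), so the output carries the full montage.
#' Idempotent once the reference flag is `"average"`.
#'
#' @param rec a [Recording-class] with at least 2 channels
#' @param referenceLabel label of the acquisition reference channel to
#'   recuperate when absent (`NULL` = never add a channel)
#' @return the re-referenced [Recording-class] (`reference == "average"`)
#' @export
averageReference <- function(rec, referenceLabel = NULL) {
  if (nrow(rec@samples) < 2)
    stop("invalid montage: average reference needs >= 2 channels")
  out <- rec
  if (!is.null(referenceLabel) && rec@reference == "original" &&
      !referenceLabel %in% rownames(out@samples)) {
    zero <- matrix(0, 1, ncol(out@samples),
                   dimnames = list(referenceLabel, NULL))
    out@samples <- rbind(out@samples, zero)
  }
  out@samples <- sweep(out@samples, 2, colMeans(out@samples))
  out@reference <- "average"
  out
}

#' Crop a recording to its condition annotations
#'
#' Removes non-session data: keeps only samples covered by condition blocks
#' and shifts all annotations to the new time base. Artifact annotations are
#' clipped to the retained segments.
#'
#' @param rec a [Recording-class]
#' @return the cropped [Recording-class]
#' @export
cropToConditions <- function(rec) {
  ann <- rec@conditionAnnotations
  if (nrow(ann) == 0) return(rec)
  fs <- rec@samplingRate
  ann <- ann[order(ann$onset_s), , drop = FALSE]
  keepIdx <- integer()
  newCond <- ann
  newArt <- emptyArtifactAnnotations()
  cursor <- 0
  for (b in seq_len(nrow(ann))) {
    i0 <- round(ann$onset_s[b] * fs)
    nb <- round(ann$duration_s[b] * fs)
    keepIdx <- c(keepIdx, i0 + seq_len(nb))
    newCond$onset_s[b] <- cursor
    art <- rec@artifactAnnotations
    if (nrow(art)) {
      lo <- pmax(art$onset_s, ann$onset_s[b])
      hi <- pmin(art$onset_s + art$duration_s,
                 ann$onset_s[b] + ann$duration_s[b])
      keep <- hi > lo
      if (any(keep))
        newArt <- rbind(newArt, data.frame(
          onset_s = cursor + lo[keep] - ann$onset_s[b],
          duration_s = hi[keep] - lo[keep]))
    }
    cursor <- cursor + ann$duration_s[b]
  }
  out <- rec
  out@samples <- rec@samples[, keepIdx, drop = FALSE]
  out@conditionAnnotations <- newCond
  out@artifactAnnotations <- newArt
  out
}

#' Standard preprocessing pipeline
#'
#' Applies the enforced stage order: high-pass, line-noise band-stop,
#' cropping to condition blocks, bad-channel interpolation (when a layout and
#' bad channels are present), then average re-referencing.
#'
#' @param rec a [Recording-class]
#' @param layout a [SensorLayout-class] (needed when bad channels are set)
#' @param highpassCutoff high-pass cutoff in Hz
#' @param stopLo,stopHi band-stop edges in Hz
#' @param referenceLabel passed to [averageReference()]
#' @return the preprocessed [Recording-class]
#' @export
preprocessRecording <- function(rec, layout = NULL, highpassCutoff = 0.1,
                                stopLo = 48, stopHi = 52,
                                referenceLabel = NULL) {
  rec <- highpass(rec, highpassCutoff)
  rec <- lineNoiseFilter(rec, stopLo, stopHi)
  rec <- cropToConditions(rec)
  if (length(rec@badChannels)) {
    if (is.null(layout))
      stop("bad channels present but no layout supplied")
    rec <- interpolateBadChannels(rec, layout)
  }
  averageReference(rec, referenceLabel)
}
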