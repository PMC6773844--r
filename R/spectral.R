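#' Segment a recording into non-overlapping windows
#'
#' Cuts each condition block into consecutive non-overlapping windows of
#' `windowS` seconds; trailing partial windows are dropped. Every window is
#' tagged with its block's factor levels.
#'
#' @param rec a [Recording-class] with condition annotations
#' @param windowS window length in seconds
#' @return `data.frame` with columns `block`, `window_index`, `onset_s`,
#'   `duration_s`, `state`, `memory`, `phase`
#' @export
segmentWindows <- function(rec, windowS = 30) {
  ann <- rec@conditionAnnotations
  out <- data.frame(block = integer(), window_index = integer(),
                    onset_s = numeric(), duration_s = numeric(),
                    state = character(), memory = character(),
                    phase = character())
  total <- ncol(rec@samples) / rec@samplingRate
  if (total < windowS || nrow(ann) == 0) {
    warning("recording shorter than one window (or no condition blocks); ",
            "returning no windows")
    return(out)
  }
  for (b in seq_len(nrow(ann))) {
    nw <- floor(ann$duration_s[b] / windowS)
    if (nw < 1) next
    out <- rbind(out, data.frame(
      block = b, window_index = seq_len(nw),
      onset_s = ann$onset_s[b] + (seq_len(nw) - 1) * windowS,
      duration_s = windowS,
      state = ann$state[b], memory = ann$memory[b], phase = ann$phase[b]))
  }
  out
}

#' Reject windows by artifact overlap
#'
#' A window is rejected iff its total overlap with artifact annotations
#' strictly exceeds `maxArtifactS` seconds (a window with exactly
#' `maxArtifactS` seconds of artifact is retained). Returns all windows with
#' the computed overlap and a `retained` flag, so that
#' retained + rejected = segmented per block.
#'
#' @param windows window table from [segmentWindows()]
#' @param artifactAnnotations `data.frame` with `onset_s`, `duration_s`
#' @param maxArtifactS rejection threshold in seconds
#' @return the window table with added columns `artifact_s` and `retained`
#' @export
rejectArtifactWindows <- function(windows, artifactAnnotations,
                                  maxArtifactS = 5) {
  windows$artifact_s <- vapply(seq_len(nrow(windows)), function(i)
    overlapSeconds(windows$onset_s[i],
                   windows$onset_s[i] + windows$duration_s[i],
                   artifactAnnotations), numeric(1))
  windows$retained <- windows$artifact_s <= maxArtifactS
  windows
}

#' Hann taper
#' @param n taper length in samples
#' @return numeric vector of taper weights (periodic Hann)
#' @export
hannWindow <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Welch power spectral density
#'
#' Averaged modified periodogram: the signal is cut into `segS`-second
#' segments with fractional `overlap`, each segment is detrended (mean
#' removed), tapered with a Hann window, and the one-sided periodograms are
#' averaged. With `segS = 1` the frequency axis has 1 Hz spacing from 0 to
#' the Nyquist frequency. Power is returned as density (unit^2 / Hz).
#'
#' @param x numeric vector or channels x samples matrix
#' @param samplingRate sampling rate in Hz
#' @param segS segment length in seconds
#' @param overlap fractional overlap between segments (0 <= overlap < 1)
#' @return list with `freq` (Hz) and `psd` (channels x frequencies matrix;
#'   a 1 x F matrix for vector input)
#' @examples
#' fs <- 250
#' t <- seq(0, 30, by = 1 / fs)[-1]
#' w <- welchPsd(sin(2 * pi * 10 * t), fs)
#' w$freq[which.max(w$psd[1, ])] # 10
#' @export
welchPsd <- function(x, samplingRate, segS = 1, overlap = 0.5) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  nseg <- round(segS * samplingRate)
  if (nseg > ncol(x))
    stop("invalid parameter: segment longer than the window")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, ncol(x) - nseg + 1, by = step)
  w <- hannWindow(nseg)
  scale <- samplingRate * sum(w^2)
  nf <- floor(nseg / 2) + 1
  acc <- matrix(0, nrow(x), nf)
  for (s in starts) {
    seg <- x[, s + seq_len(nseg) - 1, drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2, w, `*`)
    P <- Mod(t(stats::mvfft(t(seg))))^2 / scale
    P <- P[, seq_len(nf), drop = FALSE]
    # one-sided: double all bins except DC (and Nyquist when nseg is even)
    dbl <- 2:(nf - if (nseg %% 2 == 0) 1 else 0)
    P[, dbl] <- 2 * P[, dbl]
    acc <- acc + P
  }
  psd <- acc / length(starts)
  rownames(psd) <- rownames(x)
  list(freq = (seq_len(nf) - 1) * samplingRate / nseg, psd = psd)
}

#' RMS-of-log band power
#'
#' The analysis' dependent variable: the square root of the mean of squared
#' log power values over the band's frequency bins,
#' `sqrt(mean(log(p)^2))`. A positive `floor` should be applied to silent
#' channels before taking logs; bins at or below zero raise an error.
#'
#' @param psd PSD matrix (channels x frequencies) or a `welchPsd()` result
#' @param band one-row band table (see [bandDef()])
#' @param freq frequency axis in Hz (taken from `psd` when it is a
#'   `welchPsd()` result)
#' @param floor optional positive floor applied to the PSD before the log
#' @param logBase base of the logarithm (`exp(1)` = natural log)
#' @return named numeric vector, one value per channel
#' @examples
#' bandPower(matrix(exp(c(1, 2, 2, 1)), 1), bandDef("b", 1, 4),
#'           freq = 1:4) # sqrt(10/4)
#' @export
bandPower <- function(psd, band, freq = NULL, floor = NULL,
                      logBase = exp(1)) {
  if (is.list(psd) && !is.null(psd$psd)) { freq <- psd$freq; psd <- psd$psd }
  if (is.null(freq)) stop("a frequency axis is required")
  sel <- freq >= band$lo & freq <= band$hi
  if (!any(sel)) stop("band lies outside the frequency axis")
  p <- psd[, sel, drop = FALSE]
  if (!is.null(floor)) p <- pmax(p, floor)
  if (any(p <= 0))
    stop("log power undefined: PSD contains non-positive bins ",
         "(supply a positive floor)")
  lp <- log(p, base = logBase)
  out <- sqrt(rowMeans(lp^2))
  names(out) <- rownames(psd)
  out
}

# log of total (density-integrated) band power; used as a simulation
# diagnostic because injected effects live on this scale
bandTotalLogPower <- function(psd, band, freq = NULL) {
  if (is.list(psd) && !is.null(psd$psd)) { freq <- psd$freq; psd <- psd$psd }
  sel <- freq >= band$lo & freq <= band$hi
  df <- if (length(freq) > 1) freq[2] - freq[1] else 1
  log(rowSums(psd[, sel, drop = FALSE]) * df)
}

#' Compute the power window table from a recording
#'
#' Runs segmentation, artifact-based rejection, Welch PSD and RMS-of-log
#' band power for one recording, and assembles the analysis table (one row
#' per retained window x channel x band). Participant covariates are filled
#' in from `design` when supplied.
#'
#' @param rec a preprocessed [Recording-class]
#' @param bands band table (see [bandPresets()])
#' @param design optional [StudyDesign-class] for the age/shss covariates
#' @param windowS window length in seconds
#' @param maxArtifactS artifact-overlap rejection threshold in seconds
#' @param segS,overlap Welch parameters (see [welchPsd()])
#' @param psdFloor positive floor applied to the PSD before the log
#' @return a power window table (see [simulateWindowTable()] for columns)
#'   with attributes `n_segmented`, `n_rejected`, `n_retained`
#' @export
computeWindowTable <- function(rec, bands = bandPresets("primary"),
                               design = NULL, windowS = 30,
                               maxArtifactS = 5, segS = 1, overlap = 0.5,
                               psdFloor = 1e-12) {
  windows <- segmentWindows(rec, windowS)
  windows <- rejectArtifactWindows(windows, rec@artifactAnnotations,
                                   maxArtifactS)
  kept <- windows[windows$retained, , drop = FALSE]
  labels <- channelLabels(rec)
  fs <- rec@samplingRate
  age <- shss <- NA_real_
  if (!is.null(design)) {
    j <- match(rec@participant, design@participants$id)
    if (!is.na(j)) {
      age <- design@participants$age[j]
      shss <- design@participants$shss[j]
    }
  }
  rows <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    i0 <- round(kept$onset_s[i] * fs)
    idx <- i0 + seq_len(round(kept$duration_s[i] * fs))
    w <- welchPsd(rec@samples[, idx, drop = FALSE], fs, segS, overlap)
    bp <- lapply(seq_len(nrow(bands)), function(k)
      bandPower(w$psd, bands[k, ], freq = w$freq, floor = psdFloor))
    rows[[i]] <- data.frame(
      participant = rec@participant, age = age, shss = shss,
      block = kept$block[i], state = kept$state[i],
      memory = kept$memory[i], phase = kept$phase[i],
      window_index = kept$window_index[i],
      channel = rep(labels, times = nrow(bands)),
      band = rep(bands$name, each = length(labels)),
      power = unlist(bp, use.names = FALSE))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- simulateWindowTable(
    designEmulation(blockDuration = 30), buildLayout(2),
    simulationParams())[0, ]
  attr(out, "n_segmented") <- nrow(windows)
  attr(out, "n_rejected") <- sum(!windows$retained)
  attr(out, "n_retained") <- nrow(kept)
  out
}

#' Band-difference ("specific band") table
#'
#' Appends a derived band named `"specific_<a>"` whose power is
#' `power(bandA) - power(bandB)` row-by-row (matched on participant, block,
#' window and channel). Used for the alpha-minus-theta "specific alpha"
#' contrast that isolates alpha effects from broadband shifts.
#'
#' @param table a power window table containing both bands
#' @param bandA,bandB band names present in `table$band`
#' @return the rows of the new derived band (same columns as `table`)
#' @export
bandDifference <- function(table, bandA, bandB) {
  key <- c("participant", "block", "window_index", "channel")
  a <- table[table$band == bandA, , drop = FALSE]
  b <- table[table$band == bandB, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("alignment error: both bands must be present")
  ka <- do.call(paste, c(a[key], sep = "\r"))
  kb <- do.call(paste, c(b[key], sep = "\r"))
  m <- match(ka, kb)
  if (anyNA(m) || nrow(a) != nrow(b))
    stop("alignment error: band rows do not match one-to-one")
  out <- a
  out$band <- paste0("specific_", bandA)
  out$power <- a$power - b$power[m]
  out
}

#' Propose analysis bands against the 1/f background
#'
#' Fits a robust log-log linear 1/f background to each region's average
#' spectrum and returns contiguous frequency runs whose log power exceeds the
#' fit by `margin` robust standard deviations of the fit residuals in at
#' least one region. This is a reproducible surrogate for the visual
#' "stands out over the 1/f pattern" band-selection step.
#'
#' @param psdByRegion named list of spectra, one per region (e.g. frontal /
#'   central / posterior midline), each a numeric vector over `freq`
#' @param freq frequency axis in Hz
#' @param margin threshold in robust residual SDs
#' @param minResidual absolute floor (log-power units) a bin must exceed the
#'   background by, so a numerically exact 1/f spectrum proposes nothing
#' @param fmin,fmax frequency range considered
#' @return `data.frame` of proposed bands (`name`, `lo`, `hi`)
#' @export
proposeBands <- function(psdByRegion, freq, margin = 2, minResidual = 0.1,
                         fmin = 0.5, fmax = 25) {
  sel <- freq >= fmin & freq <= fmax
  f <- freq[sel]
  standing <- rep(FALSE, length(f))
  for (p in psdByRegion) {
    p <- p[sel]
    if (any(p <= 0)) stop("non-positive spectrum")
    fit <- MASS::rlm(log(p) ~ log(f), maxit = 50)
    res <- stats::residuals(fit)
    standing <- standing |
      res > pmax(margin * stats::mad(res), minResidual)
  }
  runs <- rle(standing)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  if (!length(keep))
    return(data.frame(name = character(), lo = numeric(), hi = numeric()))
  df <- if (length(f) > 1) f[2] - f[1] else 1
  data.frame(name = paste0("band", seq_along(keep)),
             lo = f[starts[keep]] - df / 2,
             hi = f[ends[keep]] + df / 2)
}
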