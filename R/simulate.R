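#' Construct a Recording
#'
#' @param samples numeric matrix (channels x samples); rownames are channel
#'   labels (`"E1"`, ... are filled in when absent).
#' @param samplingRate sampling rate in Hz
#' @param conditionAnnotations `data.frame` (`onset_s`, `duration_s`,
#'   `state`, `memory`, `phase`)
#' @param artifactAnnotations `data.frame` (`onset_s`, `duration_s`)
#' @param badChannels character vector of bad channel labels
#' @param reference `"original"` or `"average"`
#' @param participant participant id the recording belongs to
#' @return a [Recording-class]
#' @export
recording <- function(samples, samplingRate,
                      conditionAnnotations = emptyConditionAnnotations(),
                      artifactAnnotations = emptyArtifactAnnotations(),
                      badChannels = character(), reference = "original",
                      participant = "") {
  samples <- as.matrix(samples)
  if (is.null(rownames(samples)))
    rownames(samples) <- paste0("E", seq_len(nrow(samples)))
  new("Recording", samples = samples, samplingRate = samplingRate,
      conditionAnnotations = conditionAnnotations,
      artifactAnnotations = artifactAnnotations,
      badChannels = badChannels, reference = reference,
      participant = participant)
}

#' @rdname recording
#' @export
emptyConditionAnnotations <- function()
  data.frame(onset_s = numeric(), duration_s = numeric(),
             state = character(), memory = character(), phase = character())

#' @rdname recording
#' @export
emptyArtifactAnnotations <- function()
  data.frame(onset_s = numeric(), duration_s = numeric())

# baseline log band power per band: bands that carry injected oscillations
# sit at baseLogPower; purely background bands follow the 1/f trend at the
# band centre frequency.
bandBaselines <- function(params, bands) {
  fc <- (bands$lo + bands$hi) / 2
  ifelse(bands$name %in% params@bandEffects$band,
         params@baseLogPower,
         params@baseLogPower - params@backgroundSlope * log(fc))
}

checkEffects <- function(params, layout) {
  be <- params@bandEffects
  for (k in seq_len(nrow(be))) {
    chs <- be$channels[[k]]
    if (!is.null(chs) && !all(is.na(chs)) &&
        !all(chs %in% channelLabels(layout)))
      stop("configuration error: effect channels not present in the layout")
  }
  invisible(TRUE)
}

# additive injected shift for vectors of row descriptors
effectShift <- function(be, band, state, memory, phase, channel) {
  shift <- numeric(length(band))
  for (k in seq_len(nrow(be))) {
    hit <- be$band[k] == band &
      (is.na(be$state[k]) | be$state[k] == state) &
      (is.na(be$memory[k]) | be$memory[k] == memory) &
      (is.na(be$phase[k]) | be$phase[k] == phase)
    chs <- be$channels[[k]]
    if (!is.null(chs) && !all(is.na(chs))) hit <- hit & channel %in% chs
    shift[hit] <- shift[hit] + be$shift[k]
  }
  shift
}

#' Simulate a windowed band-power table directly from the generative model
#'
#' The fast path that skips signal synthesis: rows are drawn from the linear
#' mixed model the analysis assumes,
#' `power = baseline(band) + u(participant) + injected effects + noise`,
#' with one row per 30-s window x channel x band and participant intercepts
#' `u ~ N(0, participantSd^2)`. Window counts follow block durations (trailing
#' partial windows are dropped).
#'
#' @param design a [StudyDesign-class]
#' @param layout a [SensorLayout-class]
#' @param params a [SimulationParams-class]
#' @param bands band table (see [bandPresets()])
#' @param windowS window length in seconds
#' @return a power window table: `data.frame` with columns `participant`,
#'   `age`, `shss`, `block`, `state`, `memory`, `phase`, `window_index`,
#'   `channel`, `band`, `power`
#' @examples
#' preset <- presetEmulationSmall(effectSize = 0.5, seed = 7)
#' tab <- simulateWindowTable(preset$design, preset$layout, preset$params)
#' head(tab)
#' @export
simulateWindowTable <- function(design, layout, params,
                                bands = bandPresets("primary"),
                                windowS = 30) {
  checkEffects(params, layout)
  pt <- design@participants
  cond <- design@conditions
  labels <- channelLabels(layout)
  mu <- bandBaselines(params, bands)

  set.seed(deriveSeed(params@seed, 101))
  u <- rnorm(nrow(pt), 0, params@participantSd)

  nw <- floor(cond$duration_s / windowS)
  blockRows <- lapply(seq_len(nrow(cond)), function(b) {
    if (nw[b] < 1) return(NULL)
    g <- expand.grid(window_index = seq_len(nw[b]), channel = labels,
                     band = bands$name, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
    g$block <- b
    g$state <- cond$state[b]; g$memory <- cond$memory[b]
    g$phase <- cond$phase[b]
    g
  })
  oneParticipant <- do.call(rbind, blockRows)
  tab <- do.call(rbind, lapply(seq_len(nrow(pt)), function(i) {
    g <- oneParticipant
    g$participant <- pt$id[i]
    g$age <- pt$age[i]; g$shss <- pt$shss[i]
    g$u <- u[i]
    g
  }))
  tab$power <- mu[match(tab$band, bands$name)] + tab$u +
    effectShift(params@bandEffects, tab$band, tab$state, tab$memory,
                tab$phase, tab$channel) +
    rnorm(nrow(tab), 0, params@windowNoiseSd)
  tab$u <- NULL
  tab[, c("participant", "age", "shss", "block", "state", "memory", "phase",
          "window_index", "channel", "band", "power")]
}

#' Simulate a continuous multichannel recording
#'
#' Synthesises one participant's session: per channel, coloured noise shaped
#' to a 1/f^slope spectrum, plus band-limited sinusoidal oscillations at the
#' centre frequency of every band that carries injected effects. Each 30-s
#' window's oscillation amplitude is set to `sqrt(2 * exp(L))` where `L` is
#' the generative log band power (baseline + participant intercept + injected
#' effects + window noise), so Welch band power recovers the configured
#' log-power structure. Artifact segments are contiguous high-amplitude
#' stretches with exponential inter-arrival times and durations, annotated in
#' `artifactAnnotations`.
#'
#' @inheritParams simulateWindowTable
#' @param participant participant id (one of `design@participants$id`)
#' @return a [Recording-class] with condition and artifact annotations
#' @examples
#' preset <- presetEmulationSmall(effectSize = 0.5, seed = 3,
#'                                blockDuration = 60)
#' rec <- simulateRecording(preset$design, preset$layout, preset$params,
#'                          participant = "P1")
#' rec
#' @export
simulateRecording <- function(design, layout, params,
                              participant = design@participants$id[1],
                              bands = bandPresets("primary"),
                              windowS = 30) {
  checkEffects(params, layout)
  pt <- design@participants
  i <- match(as.character(participant), pt$id)
  if (is.na(i)) stop("unknown participant id")
  cond <- design@conditions
  fs <- design@samplingRate
  labels <- channelLabels(layout)
  nCh <- length(labels)

  set.seed(deriveSeed(params@seed, 101))
  u <- rnorm(nrow(pt), 0, params@participantSd)[i]

  onsets <- cumsum(c(0, cond$duration_s))[seq_len(nrow(cond))]
  total_s <- sum(cond$duration_s)
  N <- round(total_s * fs)
  X <- matrix(0, nCh, N, dimnames = list(labels, NULL))

  set.seed(deriveSeed(params@seed, 200 + 1000 * i))
  # 1/f^slope background, shaped in the frequency domain per block
  for (b in seq_len(nrow(cond))) {
    nb <- round(cond$duration_s[b] * fs)
    idx <- round(onsets[b] * fs) + seq_len(nb)
    f <- pmin(seq_len(nb) - 1, nb - (seq_len(nb) - 1)) * fs / nb
    shape <- params@backgroundScale * pmax(f, 0.5)^(-params@backgroundSlope / 2)
    shape[1] <- 0
    for (c in seq_len(nCh)) {
      spec <- stats::fft(rnorm(nb)) * shape
      X[c, idx] <- X[c, idx] + Re(stats::fft(spec, inverse = TRUE)) / nb
    }
  }

  # band-limited oscillations encoding the log-power structure
  oscBands <- bands[bands$name %in% params@bandEffects$band, , drop = FALSE]
  tsec <- (seq_len(N) - 1) / fs
  for (k in seq_len(nrow(oscBands))) {
    fc <- (oscBands$lo[k] + oscBands$hi[k]) / 2
    for (b in seq_len(nrow(cond))) {
      nwin <- ceiling(cond$duration_s[b] / windowS)
      for (w in seq_len(nwin)) {
        w0 <- onsets[b] + (w - 1) * windowS
        w1 <- min(onsets[b] + cond$duration_s[b], w0 + windowS)
        idx <- which(tsec >= w0 & tsec < w1)
        if (!length(idx)) next
        shift <- effectShift(params@bandEffects,
                             rep(oscBands$name[k], nCh),
                             rep(cond$state[b], nCh),
                             rep(cond$memory[b], nCh),
                             rep(cond$phase[b], nCh), labels)
        L <- params@baseLogPower + u + shift +
          rnorm(nCh, 0, params@windowNoiseSd)
        amp <- sqrt(2 * exp(L))
        phase <- runif(nCh, 0, 2 * pi)
        X[, idx] <- X[, idx] +
          amp * sin(outer(rep(2 * pi * fc, nCh), tsec[idx]) + phase)
      }
    }
  }

  # artifact process: exponential inter-arrival and duration
  artifacts <- emptyArtifactAnnotations()
  if (params@artifactRate > 0) {
    set.seed(deriveSeed(params@seed, 300 + 1000 * i))
    lambda <- params@artifactRate / 60 / params@artifactMeanDuration
    t <- 0
    repeat {
      t <- t + rexp(1, rate = lambda)
      if (t >= total_s) break
      d <- min(rexp(1, rate = 1 / params@artifactMeanDuration), total_s - t)
      artifacts <- rbind(artifacts, data.frame(onset_s = t, duration_s = d))
      idx <- which(tsec >= t & tsec < t + d)
      X[, idx] <- X[, idx] + matrix(rnorm(nCh * length(idx), sd = 200),
                                    nCh, length(idx))
      t <- t + d
    }
  }

  condAnn <- data.frame(onset_s = onsets, duration_s = cond$duration_s,
                        state = cond$state, memory = cond$memory,
                        phase = cond$phase)
  recording(X, fs, conditionAnnotations = condAnn,
            artifactAnnotations = artifacts,
            participant = pt$id[i])
}

#' Simulate recordings for every participant in a design
#'
#' @inheritParams simulateRecording
#' @return named list of [Recording-class], one per participant
#' @export
simulateStudy <- function(design, layout, params,
                          bands = bandPresets("primary"), windowS = 30) {
  ids <- design@participants$id
  recs <- lapply(ids, function(p)
    simulateRecording(design, layout, params, participant = p,
                      bands = bands, windowS = windowS))
  names(recs) <- ids
  recs
}

#' Write / read a power window table as CSV
#'
#' @param table a power window table (see [simulateWindowTable()])
#' @param file path to a CSV file
#' @return `readWindowTable` returns the table `data.frame`
#' @export
writeWindowTable <- function(table, file) {
  write.csv(table, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeWindowTable
#' @export
readWindowTable <- function(file) {
  read.csv(file, stringsAsFactors = FALSE)
}
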