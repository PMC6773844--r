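# Shared fixtures: all built in code at test time.

# four channels on the corners of a unit square (flat "layout")
squareLayout <- function(radius = 1.2) {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  sensorLayout(pos, neighbourRadius = radius)
}

# minimal design: one participant, custom blocks
oneBlockDesign <- function(duration_s = 300, nParticipants = 1,
                           samplingRate = 250) {
  studyDesign(
    data.frame(id = paste0("P", seq_len(nParticipants)),
               age = seq(40, length.out = nParticipants, by = 5),
               shss = rep(6, nParticipants)),
    data.frame(state = "NC", memory = "NDE", phase = "OBE",
               duration_s = duration_s),
    samplingRate = samplingRate)
}

# two blocks (one NDE, one AUTOBIO) per participant: the smallest design on
# which the memory factor is testable
twoBlockDesign <- function(nParticipants = 5, duration_s = 120) {
  studyDesign(
    data.frame(id = paste0("P", seq_len(nParticipants)),
               age = c(60, 44, 66, 71, 48)[seq_len(nParticipants)],
               shss = c(6, 9, 8, 9, 4)[seq_len(nParticipants)]),
    data.frame(state = "NC", memory = c("NDE", "AUTOBIO"),
               phase = c("OBE", "KS"), duration_s = duration_s),
    samplingRate = 250)
}

# Independent brute-force TFCE oracle: explicit threshold loop with
# connected components found by exhaustive neighbour expansion. Mirrors the
# midpoint integration grid but shares no code with the C++ implementation.
tfceOracle <- function(v, edges, E, H, nsteps, twoSided = TRUE) {
  oneSided <- function(v) {
    out <- numeric(length(v))
    hmax <- max(c(0, v))
    if (hmax <= 0) return(out)
    dh <- hmax / nsteps
    for (k in seq_len(nsteps)) {
      h <- (k - 0.5) * dh
      active <- which(v >= h)
      remaining <- active
      while (length(remaining)) {
        comp <- remaining[1]
        repeat {
          nb1 <- edges[edges[, 1] %in% comp, 2]
          nb2 <- edges[edges[, 2] %in% comp, 1]
          grow <- union(comp, intersect(c(nb1, nb2), active))
          if (length(grow) == length(comp)) break
          comp <- grow
        }
        out[comp] <- out[comp] + length(comp)^E * h^H * dh
        remaining <- setdiff(remaining, comp)
      }
    }
    out
  }
  res <- oneSided(v)
  if (twoSided) res <- res - oneSided(-v)
  names(res) <- names(v)
  res
}

# random connected-ish graph layout with nChannels nodes
randomGraphMap <- function(nChannels, seed) {
  set.seed(seed)
  pos <- matrix(rnorm(3 * nChannels), ncol = 3)
  lay <- sensorLayout(pos, neighbourRadius = stats::quantile(
    dist(pos), 0.45))
  v <- rnorm(nChannels, sd = 2)
  names(v) <- channelLabels(lay)
  list(layout = lay, values = v)
}
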