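#' Construct a sensor layout from channel positions
#'
#' Adjacency is computed as all pairs of channels whose Euclidean distance is
#' at most `neighbourRadius`. When `neighbourRadius` is `NULL` it defaults to
#' twice the median nearest-neighbour distance, which for roughly uniform
#' montages yields a connected graph with typical degree around six.
#'
#' @param positions numeric matrix (channels x 3) of sensor positions.
#' @param labels character channel labels; defaults to `"E1"`, `"E2"`, ...
#' @param neighbourRadius neighbourhood radius in the units of `positions`.
#' @return a [SensorLayout-class]
#' @examples
#' sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' layout <- sensorLayout(sq, neighbourRadius = 1.2)
#' adjacencyEdges(layout)
#' @export
sensorLayout <- function(positions, labels = NULL, neighbourRadius = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("invalid design: a layout needs at least 2 channels")
  if (is.null(labels)) labels <- paste0("E", seq_len(n))
  if (length(labels) != n) stop("one label per channel required")
  d <- as.matrix(stats::dist(positions))
  if (is.null(neighbourRadius)) {
    nn <- apply(d + diag(Inf, n), 1, min)
    neighbourRadius <- 2 * stats::median(nn)
  }
  if (neighbourRadius <= 0) stop("neighbourRadius must be positive")
  pairs <- which(upper.tri(d) & d <= neighbourRadius, arr.ind = TRUE)
  edges <- cbind(from = unname(pairs[, 1]), to = unname(pairs[, 2]))
  dimnames(edges) <- list(NULL, c("from", "to"))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  new("SensorLayout",
      channels = data.frame(id = seq_len(n), label = labels,
                            x = positions[, 1], y = positions[, 2],
                            z = positions[, 3]),
      edges = edges)
}

#' Build a hemispherical sensor layout
#'
#' Places `nChannels` sensors on the upper unit hemisphere using a Fibonacci
#' spiral (deterministic, approximately uniform) and connects channels within
#' `neighbourRadius` of each other. This emulates a high-density EEG cap such
#' as a 257-channel geodesic net.
#'
#' @param nChannels number of channels (>= 2).
#' @param neighbourRadius neighbourhood radius on the unit sphere; `NULL`
#'   (default) picks twice the median nearest-neighbour spacing.
#' @param seed optional integer; when given, adds a small reproducible jitter
#'   to the grid positions.
#' @return a [SensorLayout-class]
#' @examples
#' layout <- buildLayout(64)
#' layout
#' @export
buildLayout <- function(nChannels, neighbourRadius = NULL, seed = NULL) {
  if (nChannels < 2) stop("invalid design: nChannels must be >= 2")
  i <- seq_len(nChannels) - 0.5
  golden <- pi * (3 - sqrt(5))
  # upper hemisphere: z from just above equator to pole
  z <- i / nChannels
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * (seq_len(nChannels) - 1)
  pos <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    pos <- pos + matrix(rnorm(3 * nChannels, sd = 1e-3), ncol = 3)
  }
  sensorLayout(pos, neighbourRadius = neighbourRadius)
}

# adjacency as a per-channel list of integer neighbours (by channel id)
neighbourList <- function(layout) {
  n <- nChannels(layout)
  nb <- vector("list", n)
  e <- layout@edges
  for (k in seq_len(nrow(e))) {
    nb[[e[k, 1]]] <- c(nb[[e[k, 1]]], e[k, 2])
    nb[[e[k, 2]]] <- c(nb[[e[k, 2]]], e[k, 1])
  }
  nb
}

#' Is the adjacency graph connected?
#'
#' @param layout a [SensorLayout-class]
#' @return `TRUE` if every channel is reachable from every other through
#'   adjacency edges
#' @export
isConnectedLayout <- function(layout) {
  g <- igraph::graph_from_edgelist(layout@edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nChannels(layout) - igraph::vcount(g)))
  igraph::is_connected(g)
}

# Connected components of an induced subgraph over the given channel ids.
# Returns a list of integer vectors of channel ids.
componentsOf <- function(layout, ids) {
  if (length(ids) == 0) return(list())
  e <- layout@edges
  keep <- e[, 1] %in% ids & e[, 2] %in% ids
  g <- igraph::graph_from_data_frame(
    as.data.frame(e[keep, , drop = FALSE]),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids)))
  comp <- igraph::components(g)
  split(as.integer(igraph::V(g)$name), comp$membership)
}

#' Write / read a sensor layout as plain-text files
#'
#' The channel table is a CSV of `id,label,x,y,z`; adjacency is a two-column
#' CSV edge list of channel ids.
#'
#' @param layout a [SensorLayout-class]
#' @param channelsFile path for the channel CSV
#' @param edgesFile path for the edge-list CSV
#' @return `writeLayout` returns the paths invisibly; `readLayout` returns a
#'   [SensorLayout-class].
#' @export
writeLayout <- function(layout, channelsFile, edgesFile) {
  write.csv(layout@channels, channelsFile, row.names = FALSE)
  write.csv(as.data.frame(layout@edges), edgesFile, row.names = FALSE)
  invisible(c(channelsFile, edgesFile))
}

#' @rdname writeLayout
#' @export
readLayout <- function(channelsFile, edgesFile) {
  ch <- read.csv(channelsFile, stringsAsFactors = FALSE)
  e <- as.matrix(read.csv(edgesFile))
  colnames(e) <- c("from", "to")
  storage.mode(e) <- "integer"
  flip <- e[, 1] > e[, 2]
  e[flip, ] <- e[flip, c(2, 1)]
  e <- unique(e[order(e[, 1], e[, 2]), , drop = FALSE])
  new("SensorLayout", channels = ch, edges = e)
}
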