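#' TFCE parameters
#'
#' Threshold-free cluster enhancement integrates, over all thresholds `h`,
#' `extent^E * h^H * dh`, where extent is the size of the connected
#' suprathreshold component containing the channel. Defaults follow the
#' established sensor-space EEG practice (E = 0.666, H = 2) with 100
#' integration steps and two-sided enhancement (negative statistics are
#' enhanced on the negated map and re-signed).
#'
#' @param E extent exponent (>= 0)
#' @param H height exponent (>= 0)
#' @param nSteps number of threshold integration steps (>= 10)
#' @param twoSided enhance both signs
#' @return list of class `"tfceParams"`
#' @export
tfceParams <- function(E = 0.666, H = 2, nSteps = 100, twoSided = TRUE) {
  if (E < 0 || H < 0) stop("E and H must be >= 0")
  if (nSteps < 10) stop("nSteps must be >= 10")
  structure(list(E = E, H = H, nSteps = as.integer(nSteps),
                 twoSided = twoSided), class = "tfceParams")
}

#' Threshold-free cluster enhancement of a channel statistic map
#'
#' @param map a [TopoStatMap-class] or a named numeric vector of per-channel
#'   statistics (names = channel labels)
#' @param layout a [SensorLayout-class] whose channels match the map
#' @param params a [tfceParams()] list
#' @return named numeric vector of enhanced values in layout channel order
#' @examples
#' layout <- buildLayout(6)
#' v <- stats::setNames(c(3, 3, 0, 0, 0, 0), channelLabels(layout))
#' tfceTransform(v, layout, tfceParams(nSteps = 50))
#' @export
tfceTransform <- function(map, layout, params = tfceParams()) {
  v <- if (is(map, "TopoStatMap")) map@statistic else map
  labels <- channelLabels(layout)
  if (is.null(names(v)) || !setequal(names(v), labels))
    stop("alignment error: map channels do not match the layout")
  v <- v[labels]
  if (anyNA(v)) {
    warning("masking ", sum(is.na(v)), " non-finite channel(s) as 0")
    v[is.na(v)] <- 0
  }
  .tfce_enhance(v, layout@edges, params$E, params$H, params$nSteps,
                params$twoSided)
}

#' Permutation scheme for the max-statistic null
#'
#' The exchange unit is the whole condition block within a participant: all
#' windows of a block keep a common relabel, because windows within a block
#' are autocorrelated and relabelling them individually would break
#' exchangeability. The relabelled factor is the memory factor
#' (NDE vs AUTOBIO) by default; relabellings permute each participant's
#' block-level labels, preserving per-participant label counts. Covariates
#' are held fixed under permutation.
#'
#' @param factor factor to relabel (`"memory"`, `"state"` or `"focus"`)
#' @param nPermutations number of relabelled datasets (>= 100)
#' @param seed integer RNG seed
#' @return list of class `"permutationScheme"`
#' @export
permutationScheme <- function(factor = "memory", nPermutations = 2200,
                              seed = 1) {
  if (!factor %in% c("memory", "state", "focus"))
    stop("factor must be one of memory, state, focus")
  if (nPermutations < 100) stop("nPermutations must be >= 100")
  structure(list(factor = factor,
                 nPermutations = as.integer(nPermutations),
                 seed = as.integer(seed)), class = "permutationScheme")
}

# distinct block-label assignments per participant and in total
countRelabelings <- function(blocks, factorName) {
  per <- vapply(split(blocks[[factorName]], blocks$participant),
                function(lab) {
                  n <- length(lab)
                  counts <- table(lab)
                  exp(lgamma(n + 1) - sum(lgamma(counts + 1)))
                }, numeric(1))
  prod(per)
}

# all distinct permutations of a small label multiset
distinctPermutations <- function(labels) {
  n <- length(labels)
  if (n == 1) return(list(labels))
  out <- list()
  for (u in unique(labels)) {
    rest <- labels[-match(u, labels)]
    for (p in distinctPermutations(rest)) out <- c(out, list(c(u, p)))
  }
  out
}

#' Build the max-statistic permutation null
#'
#' For each relabelled dataset: permute the chosen factor's block labels
#' within each participant, refit the mixed model at every channel, apply
#' TFCE, and record the maximum enhanced statistic over all channels (per
#' model parameter involving the relabelled factor). When fewer distinct
#' relabellings exist than `nPermutations` (tiny designs) the null is
#' enumerated exhaustively instead, with a warning.
#'
#' @param table a power window table
#' @param band band name
#' @param spec a [ModelSpec-class]
#' @param layout a [SensorLayout-class]
#' @param tfce a [tfceParams()] list
#' @param scheme a [permutationScheme()] list
#' @param parameters coefficient names to track; default = all coefficients
#'   involving the relabelled factor
#' @return numeric matrix (permutations x parameters) of null maxima, with
#'   attribute `exhaustive`
#' @export
buildNull <- function(table, band, spec, layout, tfce = tfceParams(),
                      scheme = permutationScheme(), parameters = NULL) {
  if (!scheme$factor %in% unlist(strsplit(spec@fixedTerms, ":")))
    stop("the relabelled factor is not part of the model")
  cm <- channelResponseMatrix(table, band)
  if (is.null(cm))
    stop("the window table is unbalanced across channels")
  meta <- prepareModelData(cm$meta, standardizeCovariates = TRUE)
  ord <- order(meta$participant)
  meta <- meta[ord, , drop = FALSE]
  Y <- cm$Y[ord, , drop = FALSE]
  sizes <- as.integer(table(meta$participant))
  fml <- as.formula(paste("~", modelFormulaRHS(spec)))

  labels <- channelLabels(layout)
  if (!setequal(colnames(Y), labels))
    stop("alignment error: table channels do not match the layout")
  Y <- Y[, labels, drop = FALSE]

  # block-level label bookkeeping
  blocks <- unique(meta[, c("participant", "block")])
  blocks$key <- paste(blocks$participant, blocks$block)
  rowBlock <- match(paste(meta$participant, meta$block), blocks$key)
  origLabels <- as.character(meta[[scheme$factor]][
    match(blocks$key, paste(meta$participant, meta$block))])
  blocks[[scheme$factor]] <- origLabels
  levelsOf <- levels(meta[[scheme$factor]])

  nDistinct <- countRelabelings(blocks, scheme$factor)
  exhaustive <- nDistinct <= scheme$nPermutations
  byP <- split(seq_len(nrow(blocks)), blocks$participant)

  relabelings <- if (exhaustive) {
    warning("only ", round(nDistinct), " distinct relabelings exist; ",
            "enumerating the null exhaustively")
    perP <- lapply(byP, function(idx)
      unique(distinctPermutations(origLabels[idx])))
    grid <- do.call(expand.grid, lapply(perP, seq_along))
    lapply(seq_len(nrow(grid)), function(r) {
      lab <- origLabels
      for (j in seq_along(byP)) lab[byP[[j]]] <- perP[[j]][[grid[r, j]]]
      lab
    })
  } else {
    set.seed(deriveSeed(scheme$seed, 7))
    lapply(seq_len(scheme$nPermutations), function(r) {
      lab <- origLabels
      for (idx in byP) lab[idx] <- sample(lab[idx])
      lab
    })
  }

  fitT <- function(lab) {
    m <- meta
    m[[scheme$factor]] <- factor(lab[rowBlock], levels = levelsOf)
    X <- stats::model.matrix(fml, m)
    fit <- .fit_ri_ml(X, Y, sizes)
    t <- fit$t
    rownames(t) <- colnames(X)
    colnames(t) <- colnames(Y)
    t[, !fit$converged] <- 0
    t
  }

  t0 <- fitT(origLabels)
  if (is.null(parameters))
    parameters <- rownames(t0)[grepl(scheme$factor, rownames(t0),
                                     fixed = TRUE)]
  if (!length(parameters)) stop("no model parameter involves the factor")

  nullMax <- matrix(NA_real_, length(relabelings), length(parameters),
                    dimnames = list(NULL, parameters))
  for (r in seq_along(relabelings)) {
    t <- fitT(relabelings[[r]])
    for (pm in parameters) {
      enh <- .tfce_enhance(t[pm, ], layout@edges, tfce$E, tfce$H,
                           tfce$nSteps, tfce$twoSided)
      nullMax[r, pm] <- if (tfce$twoSided) max(abs(enh)) else max(enh)
    }
  }
  attr(nullMax, "exhaustive") <- exhaustive
  nullMax
}

#' Per-channel permutation p-values
#'
#' Add-one estimator against the max-statistic null:
#' `p(c) = (1 + #\{null maxima >= observed(c)\}) / (1 + n_permutations)`.
#' Monotone non-increasing in the observed value and never zero.
#'
#' @param observed named numeric vector of observed (enhanced) statistics
#' @param nullMax numeric vector of null maxima
#' @return named numeric vector of p-values in (0, 1]
#' @export
channelPvalues <- function(observed, nullMax) {
  vapply(observed, function(o)
    (1 + sum(nullMax >= o)) / (1 + length(nullMax)), numeric(1))
}

#' Per-band significance threshold
#'
#' Bonferroni division of the family-wise alpha across the number of bands
#' tested (e.g. alpha 0.05 over 3 bands gives a per-band cut-off of 0.016,
#' truncated at the third decimal as conventionally printed).
#'
#' @param alpha family-wise significance level
#' @param nBands number of frequency bands tested
#' @return per-band threshold `alpha / nBands`
#' @export
bandThreshold <- function(alpha = 0.05, nBands = 3) alpha / nBands

#' Summarise significant channels and clusters
#'
#' @param pvalues named per-channel p-values (see [channelPvalues()])
#' @param map a [TopoStatMap-class] or named numeric vector of the observed
#'   (unenhanced) T-values used for peak reporting
#' @param layout a [SensorLayout-class]
#' @param threshold significance threshold in (0, 1)
#' @return list: `n_significant`, `significant` (labels), `clusters` (list
#'   of label vectors, connected components over adjacency),
#'   `cluster_sizes`, `peak_channel`, `peak_T`, `peak_p`, `threshold`
#' @export
significanceSummary <- function(pvalues, map, layout, threshold = 0.05) {
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie in (0, 1)")
  tvals <- if (is(map, "TopoStatMap")) map@statistic else map
  sig <- names(pvalues)[pvalues < threshold]
  ch <- layout@channels
  comps <- componentsOf(layout, ch$id[match(sig, ch$label)])
  clusters <- lapply(comps, function(ids) ch$label[match(ids, ch$id)])
  out <- list(n_significant = length(sig), significant = sig,
              clusters = unname(clusters),
              cluster_sizes = unname(vapply(clusters, length, integer(1))),
              peak_channel = NA_character_, peak_T = NA_real_,
              peak_p = NA_real_, threshold = threshold)
  if (length(sig)) {
    peak <- sig[which.max(abs(tvals[sig]))]
    out$peak_channel <- peak
    out$peak_T <- unname(tvals[peak])
    out$peak_p <- unname(pvalues[peak])
  }
  out
}

#' Max-statistic permutation test of one model parameter
#'
#' End-to-end inference for one band and parameter: fit all channels,
#' enhance the observed T map with TFCE, build the permutation null
#' ([buildNull()]), compute per-channel p-values and the significance
#' summary.
#'
#' @inheritParams buildNull
#' @param threshold significance threshold (see [bandThreshold()])
#' @param parameter coefficient name to test; default = the first
#'   coefficient involving the relabelled factor
#' @return a [PermutationResult-class]
#' @export
permutationTest <- function(table, band, spec, layout,
                            tfce = tfceParams(),
                            scheme = permutationScheme(),
                            threshold = 0.05, parameter = NULL) {
  maps <- fitAllChannels(table, band, spec, engine = "profile")
  if (is.null(parameter)) {
    cand <- names(maps)[grepl(scheme$factor, names(maps), fixed = TRUE)]
    if (!length(cand)) stop("no model parameter involves the factor")
    parameter <- cand[1]
  }
  observed <- maps[[parameter]]@statistic[channelLabels(layout)]
  enhanced <- tfceTransform(maps[[parameter]], layout, tfce)
  nullMax <- buildNull(table, band, spec, layout, tfce, scheme,
                       parameters = parameter)
  obsStat <- if (tfce$twoSided) abs(enhanced) else enhanced
  pvals <- channelPvalues(obsStat, nullMax[, parameter])
  summ <- significanceSummary(pvals, observed, layout, threshold)
  summ$n_permutations <- nrow(nullMax)
  summ$exhaustive <- isTRUE(attr(nullMax, "exhaustive"))
  new("PermutationResult", parameter = parameter, band = band,
      observed = observed, enhanced = enhanced,
      nullMax = as.numeric(nullMax[, parameter]), pvalues = pvals,
      threshold = threshold, summary = summ)
}
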