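#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate/load, preprocess, spectral, channel-wise model
#' fitting, TFCE permutation inference and (optionally) the phenomenology
#' statistics, writing all artifacts plus a machine-readable report under
#' the configured output directory. A single global `seed` drives every
#' stochastic stage through deterministically derived stage seeds, so one
#' seed reproduces the whole run.
#'
#' The configuration is a nested list (or the path of a YAML file with the
#' same structure):
#' \preformatted{
#' seed: 1
#' outdir: "out"            # optional; no files written when absent
#' simulate:
#'   n_channels: 8
#'   block_duration: 120    # seconds per phase block
#'   effect_size: 0.8       # alpha shift (log units) during NDE recall
#'   patch_size: 4
#'   mode: "recording"      # or "table" (skip signal synthesis)
#' bands: "primary"         # band preset name
#' analysis_band: "alpha"
#' model:
#'   terms: ["state", "memory", "focus", "age", "shss"]
#'   select: false          # AIC ladder selection at reference_channel
#'   reference_channel: null
#' tfce: \{e: 0.666, h: 2, n_steps: 100\}
#' permutation: \{factor: "memory", n: 200\}
#' alpha: 0.05
#' n_bands_tested: 3        # Bonferroni divisor for the threshold
#' phenom: "phenom.csv"     # optional paired-measures CSV
#' }
#'
#' The phenomenology CSV needs columns `measure`, `participant`, `x`, `y`
#' (paired values per measure); each measure gets a Wilcoxon signed-rank
#' test.
#'
#' @param config nested list or path to a YAML file
#' @return the run report (list), written as `report.json` when `outdir` is
#'   set
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  if (is.null(cfg$seed)) stop("config validation: a seed is required")
  seed <- as.integer(cfg$seed)

  alpha <- cfg$alpha %||% 0.05
  nBandsTested <- cfg$n_bands_tested %||% 3
  threshold <- cfg$threshold %||% bandThreshold(alpha, nBandsTested)
  if (!(threshold > 0 && threshold < 1))
    stop("config validation: threshold must lie in (0, 1)")
  if (!is.null(cfg$phenom) && !file.exists(cfg$phenom))
    stop("config validation: phenomenology file not found: ", cfg$phenom)
  if (!is.null(cfg$layout_channels) && !file.exists(cfg$layout_channels))
    stop("config validation: layout file not found: ", cfg$layout_channels)

  outdir <- cfg$outdir
  if (!is.null(outdir))
    for (d in c("", "recordings", "tables", "maps", "null"))
      dir.create(file.path(outdir, d), showWarnings = FALSE,
                 recursive = TRUE)

  bands <- bandPresets(cfg$bands %||% "primary")
  analysisBand <- cfg$analysis_band %||% "alpha"
  report <- list(software = "eegperm",
                 version = as.character(utils::packageVersion("eegperm")),
                 seed = seed, threshold = threshold, stages = list())

  # ---- simulate / load ---------------------------------------------------
  sim <- cfg$simulate
  if (is.null(sim)) stop("config validation: only simulate inputs are ",
                         "supported in this release (set a simulate block)")
  preset <- presetEmulationSmall(
    effectSize = sim$effect_size %||% 0,
    seed = deriveSeed(seed, 11),
    nChannels = sim$n_channels %||% 8,
    blockDuration = sim$block_duration %||% 120,
    patchSize = sim$patch_size %||% 4)
  design <- preset$design; layout <- preset$layout
  mode <- sim$mode %||% "recording"
  report$stages$simulate <- list(
    mode = mode, n_channels = nChannels(layout),
    n_participants = nrow(design@participants),
    block_duration_s = sim$block_duration %||% 120,
    effect_size = sim$effect_size %||% 0,
    effect_channels = preset$effectChannels)
  if (!is.null(outdir))
    writeLayout(layout, file.path(outdir, "layout_channels.csv"),
                file.path(outdir, "layout_edges.csv"))

  # ---- preprocess + spectral --------------------------------------------
  counts <- list()
  if (mode == "table") {
    tab <- simulateWindowTable(design, layout, preset$params, bands)
    counts <- list(segmented = nrow(unique(tab[, c("participant", "block",
                                                   "window_index")])),
                   rejected = 0)
    counts$retained <- counts$segmented
  } else {
    tabs <- lapply(design@participants$id, function(p) {
      rec <- simulateRecording(design, layout, preset$params,
                               participant = p, bands = bands)
      if (!is.null(outdir)) {
        writeEdf(rec, file.path(outdir, "recordings",
                                paste0(p, ".edf")))
        writeAnnotations(rec, file.path(outdir, "recordings",
                                        paste0(p, "_annotations.csv")))
      }
      rec <- preprocessRecording(rec, layout)
      computeWindowTable(rec, bands, design = design)
    })
    counts <- list(
      segmented = sum(vapply(tabs, attr, numeric(1), "n_segmented")),
      rejected = sum(vapply(tabs, attr, numeric(1), "n_rejected")),
      retained = sum(vapply(tabs, attr, numeric(1), "n_retained")))
    tab <- do.call(rbind, tabs)
  }
  report$stages$spectral <- counts
  if (!is.null(outdir))
    writeWindowTable(tab, file.path(outdir, "tables", "window_table.csv"))

  # ---- model -------------------------------------------------------------
  mcfg <- cfg$model %||% list()
  spec <- if (isTRUE(mcfg$select)) {
    ref <- mcfg$reference_channel %||% channelLabels(layout)[1]
    selectModel(tab, ref, analysisBand)
  } else {
    modelSpec(unlist(mcfg$terms %||%
                       list("state", "memory", "focus", "age", "shss")))
  }
  maps <- fitAllChannels(tab, analysisBand, spec, engine = "profile")
  report$stages$model <- list(
    terms = spec@fixedTerms,
    n_channels_fit = nChannels(layout),
    n_non_converged = length(attr(maps, "nonConverged")))
  if (!is.null(outdir))
    for (pm in names(maps))
      writeTopoStatMap(maps[[pm]], file.path(
        outdir, "maps", paste0(gsub("[^A-Za-z0-9]", "_", pm), ".csv")))

  # ---- permutation inference --------------------------------------------
  pcfg <- cfg$permutation %||% list()
  tcfg <- cfg$tfce %||% list()
  tf <- tfceParams(E = tcfg$e %||% 0.666, H = tcfg$h %||% 2,
                   nSteps = tcfg$n_steps %||% 100,
                   twoSided = tcfg$two_sided %||% TRUE)
  scheme <- permutationScheme(factor = pcfg$factor %||% "memory",
                              nPermutations = pcfg$n %||% 200,
                              seed = deriveSeed(seed, 13))
  perm <- suppressWarnings(
    permutationTest(tab, analysisBand, spec, layout, tf, scheme,
                    threshold = threshold))
  report$stages$permutation <- perm@summary
  report$stages$permutation$parameter <- perm@parameter
  report$stages$permutation$band <- perm@band
  if (!is.null(outdir)) {
    write.csv(data.frame(null_max = perm@nullMax),
              file.path(outdir, "null", "null_maxima.csv"),
              row.names = FALSE)
    write.csv(data.frame(channel = names(perm@pvalues),
                         T = unname(perm@observed[names(perm@pvalues)]),
                         tfce = unname(perm@enhanced[names(perm@pvalues)]),
                         p = unname(perm@pvalues)),
              file.path(outdir, "null", "channel_pvalues.csv"),
              row.names = FALSE)
  }

  # ---- phenomenology -----------------------------------------------------
  if (!is.null(cfg$phenom)) {
    ph <- read.csv(cfg$phenom, stringsAsFactors = FALSE)
    tests <- lapply(split(ph, ph$measure), function(d) {
      w <- wilcoxonSignedRank(d$x, d$y)
      list(test = "wilcoxon_signed_rank", measure = d$measure[1],
           W = w$W, Z = w$Z, p = w$p, r = w$r, n = w$n_pairs)
    })
    report$stages$phenom <- unname(tests)
  }

  if (!is.null(outdir))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
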