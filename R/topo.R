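#' Construct a model specification
#'
#' Fixed terms are built from the factors `state` (NC/HY), `memory`
#' (AUTOBIO/NDE), `focus` (recall focus, PE vs OBE/KS) and the covariates
#' `age` and `shss`; the random structure is always a participant intercept.
#' Interactions are written with `:` and require their lower-order terms.
#'
#' @param fixedTerms character vector of terms, e.g.
#'   `c("state", "memory", "state:memory")`
#' @return a [ModelSpec-class]
#' @export
modelSpec <- function(fixedTerms = character()) {
  new("ModelSpec", fixedTerms = fixedTerms)
}

#' The candidate model ladder
#'
#' Hierarchy-respecting candidates ordered from simplest to fullest:
#' random-intercept-only baseline; three factor main effects; main effects
#' plus covariates; all two-way interactions; the full three-way interaction
#' model.
#'
#' @return list of [ModelSpec-class] objects
#' @export
defaultModelLadder <- function() {
  mains <- c("state", "memory", "focus")
  two <- c("state:memory", "state:focus", "memory:focus")
  list(
    modelSpec(character()),
    modelSpec(mains),
    modelSpec(c(mains, "age", "shss")),
    modelSpec(c(mains, "age", "shss", two)),
    modelSpec(c(mains, "age", "shss", two, "state:memory:focus")))
}

modelFormulaRHS <- function(spec) {
  if (length(spec@fixedTerms) == 0) "1"
  else paste(spec@fixedTerms, collapse = " + ")
}

# factor coding + covariate standardisation for one channel/band subset
prepareModelData <- function(d, standardizeCovariates = TRUE) {
  d$participant <- factor(d$participant)
  d$state <- factor(d$state, levels = c("NC", "HY"))
  d$memory <- factor(d$memory, levels = c("AUTOBIO", "NDE"))
  # recall-focus factor crossing the memory factor: PE vs first phase
  d$focus <- factor(ifelse(d$phase == "PE", "PE", "OBE_KS"),
                    levels = c("OBE_KS", "PE"))
  for (cv in c("age", "shss")) {
    v <- d[[cv]]
    if (standardizeCovariates) {
      s <- sd(v)
      d[[cv]] <- if (is.na(s) || s == 0) v - mean(v) else (v - mean(v)) / s
    }
  }
  d
}

checkModelData <- function(d, spec) {
  if (nrow(d) == 0) stop("no rows for this channel/band")
  if (length(unique(d$participant)) < 2)
    stop("degenerate design: the participant random intercept needs >= 2 ",
         "participants")
  if (sd(d$power) == 0)
    stop("degenerate input: zero-variance dependent variable")
  comps <- unique(unlist(strsplit(spec@fixedTerms, ":", fixed = TRUE)))
  for (f in intersect(comps, c("state", "memory", "focus")))
    if (length(unique(d[[f]])) < 2)
      stop("fixed term '", f, "' has fewer than 2 represented levels")
  invisible(TRUE)
}

# terms to drop alongside `term` to preserve hierarchy (term + dependents)
termWithDependents <- function(spec, term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  dep <- vapply(spec@fixedTerms, function(tm) {
    tparts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    all(parts %in% tparts)
  }, logical(1))
  spec@fixedTerms[dep]
}

profileFitOne <- function(d, spec) {
  d <- d[order(d$participant), , drop = FALSE]
  X <- stats::model.matrix(
    as.formula(paste("~", modelFormulaRHS(spec))), d)
  sizes <- as.integer(table(d$participant))
  fit <- .fit_ri_ml(X, matrix(d$power, ncol = 1), sizes)
  list(X = X, fit = fit, ll = fit$logLik[1],
       npar = ncol(X) + 2, converged = fit$converged[1])
}

lmerFitOne <- function(d, spec) {
  fml <- as.formula(paste("power ~", modelFormulaRHS(spec),
                          "+ (1 | participant)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = d, REML = FALSE)))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  list(model = fit, ll = as.numeric(logLik(fit)),
       npar = attr(logLik(fit), "df"), converged = conv)
}

#' Fit the channel-wise linear mixed model
#'
#' Fits `power ~ fixed terms + (1 | participant)` by maximum likelihood for
#' one channel and band, and computes a likelihood-ratio test for each fixed
#' term (dropping the term together with its hierarchy dependents against
#' the nested model). ML (not REML) is used throughout so that
#' likelihood-ratio comparisons across fixed-effect structures are valid.
#'
#' Two engines produce the same model: `"lmer"` ([lme4::lmer]) and
#' `"profile"`, an in-package profiled-likelihood solver specialised to the
#' single-random-intercept structure (used by the permutation engine, where
#' hundreds of thousands of refits are needed).
#'
#' @param table a power window table
#' @param channel channel label
#' @param band band name
#' @param spec a [ModelSpec-class]
#' @param engine `"profile"` or `"lmer"`
#' @param standardizeCovariates z-score `age` and `shss` before fitting
#' @param effectTests compute per-term likelihood-ratio tests
#' @return a [FitResult-class]
#' @examples
#' preset <- presetEmulationSmall(effectSize = 0.8, seed = 2)
#' tab <- simulateWindowTable(preset$design, preset$layout, preset$params)
#' fitChannel(tab, preset$effectChannels[1], "alpha", modelSpec("memory"))
#' @export
fitChannel <- function(table, channel, band, spec,
                       engine = c("profile", "lmer"),
                       standardizeCovariates = TRUE, effectTests = TRUE) {
  engine <- match.arg(engine)
  d <- table[table$channel == channel & table$band == band, , drop = FALSE]
  d <- prepareModelData(d, standardizeCovariates)
  checkModelData(d, spec)

  if (engine == "profile") {
    full <- profileFitOne(d, spec)
    co <- data.frame(term = colnames(full$X),
                     estimate = full$fit$beta[, 1],
                     se = full$fit$se[, 1], t = full$fit$t[, 1])
    ll <- full$ll; npar <- full$npar; converged <- full$converged
  } else {
    full <- lmerFitOne(d, spec)
    sm <- summary(full$model)$coefficients
    co <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                     se = sm[, "Std. Error"], t = sm[, "t value"])
    ll <- full$ll; npar <- full$npar; converged <- full$converged
  }
  rownames(co) <- NULL

  et <- data.frame(term = character(), chisq = numeric(), df = integer(),
                   p = numeric())
  if (effectTests && length(spec@fixedTerms)) {
    for (tm in spec@fixedTerms) {
      dropSet <- termWithDependents(spec, tm)
      red <- modelSpec(setdiff(spec@fixedTerms, dropSet))
      redFit <- if (engine == "profile") profileFitOne(d, red)
                else lmerFitOne(d, red)
      chisq <- max(0, 2 * (ll - redFit$ll))
      df <- npar - redFit$npar
      et <- rbind(et, data.frame(
        term = tm, chisq = chisq, df = df,
        p = chisqPValue(chisq, df)))
    }
  }
  new("FitResult", coefficients = co, logLik = ll,
      AIC = -2 * ll + 2 * npar, effectTests = et,
      nWindows = nrow(d), converged = converged,
      channel = as.character(channel), band = band, engine = engine)
}

#' Upper-tail chi-squared p-value
#'
#' The p-value attached to a likelihood-ratio chi-squared statistic at the
#' given degrees of freedom (e.g. a chi-squared of 8.318 at 1 df gives
#' p = 0.004 to three decimals).
#'
#' @param chisq chi-squared statistic (>= 0)
#' @param df degrees of freedom (>= 1)
#' @return upper-tail probability
#' @export
chisqPValue <- function(chisq, df) {
  if (any(chisq < 0) || any(df < 1)) stop("need chisq >= 0 and df >= 1")
  pchisq(chisq, df, lower.tail = FALSE)
}

#' Likelihood-ratio test of one model term
#'
#' Extracts the chi-squared likelihood-ratio test (term dropped together
#' with its hierarchy dependents against the nested model) from a
#' [FitResult-class]. Degrees of freedom equal the parameter-count
#' difference of the nested pair; the p-value is the chi-squared upper tail.
#'
#' @param fit a [FitResult-class] from [fitChannel()]
#' @param term fixed term name present in the fitted model
#' @return list with `chisq`, `df`, `p`
#' @export
effectTest <- function(fit, term) {
  i <- match(term, fit@effectTests$term)
  if (is.na(i))
    stop("invalid request: term '", term, "' is not in the fitted model")
  as.list(fit@effectTests[i, c("chisq", "df", "p")])
}

#' Select the channel-wise model at a reference channel by AIC
#'
#' Fits every candidate of a simplest-to-fullest model ladder at one
#' a-priori reference channel and returns the simplest candidate whose AIC
#' is within `margin` units of the minimum ("simplest, but significantly
#' lowest"); exact AIC ties therefore resolve to the simpler model.
#'
#' @param table a power window table
#' @param referenceChannel channel label (a central channel by convention)
#' @param band band name
#' @param ladder list of [ModelSpec-class], simplest first
#' @param margin AIC margin in units of AIC
#' @param engine fitting engine (see [fitChannel()])
#' @return the selected [ModelSpec-class], with an `aicTable` attribute
#'   (`data.frame` of candidate AICs)
#' @export
selectModel <- function(table, referenceChannel, band,
                        ladder = defaultModelLadder(), margin = 2,
                        engine = c("profile", "lmer")) {
  engine <- match.arg(engine)
  aics <- rep(NA_real_, length(ladder))
  for (k in seq_along(ladder)) {
    fit <- tryCatch(
      fitChannel(table, referenceChannel, band, ladder[[k]],
                 engine = engine, effectTests = FALSE),
      error = function(e) NULL)
    if (!is.null(fit) && fit@converged) aics[k] <- fit@AIC
  }
  if (all(is.na(aics))) stop("all candidate models failed to converge")
  best <- min(aics, na.rm = TRUE)
  sel <- which(!is.na(aics) & aics <= best + margin)[1]
  out <- ladder[[sel]]
  attr(out, "aicTable") <- data.frame(
    candidate = seq_along(ladder),
    terms = vapply(ladder, modelFormulaRHS, character(1)),
    AIC = aics, selected = seq_along(ladder) == sel)
  out
}

# Pivot a window table into a per-channel response matrix sharing one design
# matrix (requires each channel to carry the identical row keys).
channelResponseMatrix <- function(table, band) {
  d <- table[table$band == band, , drop = FALSE]
  channels <- unique(d$channel)
  d$key <- paste(d$participant, d$block, d$window_index, sep = "\r")
  keys <- sort(unique(d$key))
  Y <- matrix(NA_real_, length(keys), length(channels),
              dimnames = list(NULL, channels))
  for (ch in channels) {
    dc <- d[d$channel == ch, , drop = FALSE]
    m <- match(dc$key, keys)
    if (anyNA(m) || nrow(dc) != length(keys)) return(NULL) # unbalanced
    Y[m, ch] <- dc$power
  }
  meta <- d[d$channel == channels[1], , drop = FALSE]
  meta <- meta[match(keys, meta$key), , drop = FALSE]
  list(Y = Y, meta = meta)
}

#' Fit the mixed model independently at every channel
#'
#' Repeats the channel-wise fit over all channels with a fixed model (no
#' per-channel model selection) and returns one T-statistic map per
#' fixed-effect coefficient. Non-converged channels carry `NA` in the maps
#' and are listed in the `nonConverged` attribute; if more than
#' `maxNonConverged` of channels fail, a hard error is raised.
#'
#' @param table a power window table
#' @param band band name
#' @param spec a [ModelSpec-class]
#' @param engine fitting engine (see [fitChannel()])
#' @param standardizeCovariates z-score `age` and `shss`
#' @param maxNonConverged tolerated fraction of non-converged channels
#' @return named list of [TopoStatMap-class], one per coefficient
#' @export
fitAllChannels <- function(table, band, spec,
                           engine = c("profile", "lmer"),
                           standardizeCovariates = TRUE,
                           maxNonConverged = 0.1) {
  engine <- match.arg(engine)
  channels <- unique(table$channel)
  if (engine == "profile") {
    cm <- channelResponseMatrix(table, band)
    if (!is.null(cm)) {
      meta <- prepareModelData(cm$meta, standardizeCovariates)
      if (any(apply(cm$Y, 2, sd) == 0))
        stop("degenerate input: zero-variance dependent variable")
      checkModelData(transform(meta, power = cm$Y[, 1]), spec)
      ord <- order(meta$participant)
      meta <- meta[ord, , drop = FALSE]
      Y <- cm$Y[ord, , drop = FALSE]
      X <- stats::model.matrix(
        as.formula(paste("~", modelFormulaRHS(spec))), meta)
      sizes <- as.integer(table(meta$participant))
      fit <- .fit_ri_ml(X, Y, sizes)
      tmat <- fit$t
      conv <- fit$converged
      params <- colnames(X)
      maps <- lapply(seq_along(params), function(j) {
        v <- tmat[j, ]
        v[!conv] <- NA_real_
        names(v) <- channels
        new("TopoStatMap", parameter = params[j], statistic = v,
            band = band)
      })
      names(maps) <- params
      nonConv <- channels[!conv]
      if (length(nonConv) > maxNonConverged * length(channels))
        stop("data pathology: more than ", round(100 * maxNonConverged),
             "% of channels failed to converge")
      attr(maps, "nonConverged") <- nonConv
      return(maps)
    }
  }
  # general path: per-channel fits
  fits <- lapply(channels, function(ch) tryCatch(
    fitChannel(table, ch, band, spec, engine = engine,
               standardizeCovariates = standardizeCovariates,
               effectTests = FALSE),
    error = function(e) e))
  errs <- vapply(fits, inherits, logical(1), "error")
  if (all(errs)) stop("every channel failed: ",
                      conditionMessage(fits[[1]]))
  okFit <- which(!errs)[1]
  params <- fits[[okFit]]@coefficients$term
  maps <- lapply(params, function(pm) {
    v <- vapply(seq_along(channels), function(i) {
      f <- fits[[i]]
      if (inherits(f, "error") || !f@converged) return(NA_real_)
      f@coefficients$t[match(pm, f@coefficients$term)]
    }, numeric(1))
    names(v) <- channels
    new("TopoStatMap", parameter = pm, statistic = v, band = band)
  })
  names(maps) <- params
  nonConv <- channels[vapply(fits, function(f)
    inherits(f, "error") || !f@converged, logical(1))]
  if (length(nonConv) > maxNonConverged * length(channels))
    stop("data pathology: more than ", round(100 * maxNonConverged),
         "% of channels failed to converge")
  attr(maps, "nonConverged") <- nonConv
  maps
}

#' Write a statistic map as CSV
#' @param map a [TopoStatMap-class]
#' @param file output path
#' @return the path, invisibly
#' @export
writeTopoStatMap <- function(map, file) {
  write.csv(data.frame(channel = names(map@statistic),
                       T = unname(map@statistic)), file, row.names = FALSE)
  invisible(file)
}
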