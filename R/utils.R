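#' @importFrom stats rnorm runif rexp sd median quantile aggregate pchisq
#'   pnorm qnorm optimize lm mad coef logLik AIC as.formula anova
#' @importFrom utils read.csv write.csv head modifyList
#' @useDynLib eegperm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Derive a stage seed from a global seed; keeps results < 2^31 and decorrelates
# stages that share one user-facing seed.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 9973 * as.numeric(offset)) %%
               2147483629)
}

# Total overlap (seconds) of the interval [lo, hi) with a set of annotation
# intervals given as onset_s/duration_s columns.
overlapSeconds <- function(lo, hi, annotations) {
  if (is.null(annotations) || nrow(annotations) == 0) return(0)
  a <- pmax(lo, annotations$onset_s)
  b <- pmin(hi, annotations$onset_s + annotations$duration_s)
  sum(pmax(0, b - a))
}

# Expand an interaction term string to all its lower-order terms
# ("a:b:c" -> a, b, c, a:b, a:c, b:c).
lowerOrderTerms <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  k <- length(parts)
  if (k == 1) return(character())
  out <- character()
  for (m in seq_len(k - 1))
    out <- c(out, utils::combn(parts, m, paste, collapse = ":"))
  out
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x))
    stop(name, " must be a finite scalar", call. = FALSE)
  invisible(x)
}
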