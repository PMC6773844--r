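#' Wilcoxon signed-rank test with normal approximation and effect size
#'
#' Paired two-sided test for small within-subject samples. Zero differences
#' are dropped before ranking (`zeros = "drop"`, the classic treatment) or
#' kept and ranked with sign zero (`zeros = "pratt"`). The standardised
#' statistic uses the tie-corrected normal approximation
#' `Z = (W - mu_W) / sigma_W` without continuity correction, the two-sided
#' p-value is `2 * (1 - Phi(|Z|))`, and the effect size r equals
#' `Z / sqrt(N)` with `N` the total observation count (2 x pairs). An exact two-sided
#' p-value by full enumeration of sign assignments is reported alongside for
#' small samples (`n <= exactLimit` non-zero pairs, no ties); note that with
#' five pairs the exact two-sided p cannot fall below 1/16, so small
#' printed p-values from such designs are necessarily normal-approximation
#' values.
#'
#' @param x,y paired numeric samples of equal length (>= 3)
#' @param zeros `"drop"` or `"pratt"`
#' @param exactLimit largest number of non-zero pairs for which the exact
#'   enumeration p-value is also computed
#' @return list: `W` (signed-rank statistic, sum of positive-difference
#'   ranks), `Z`, `p` (two-sided, normal approximation), `p_exact` (or `NA`),
#'   `r` (signed effect size `Z/sqrt(2*pairs)`), `n_pairs`, `n_used`,
#'   `degenerate` (all differences zero)
#' @examples
#' wilcoxonSignedRank(c(5, 6, 7, 8, 9), c(3, 5, 6, 9, 4))
#' @export
wilcoxonSignedRank <- function(x, y, zeros = c("drop", "pratt"),
                               exactLimit = 12) {
  zeros <- match.arg(zeros)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 pairs are required")
  d <- x - y
  nPairs <- length(d)
  keep <- if (zeros == "drop") d != 0 else rep(TRUE, nPairs)
  dk <- d[keep]
  out <- list(W = 0, Z = 0, p = 1, p_exact = NA_real_, r = 0,
              n_pairs = nPairs, n_used = sum(dk != 0), degenerate = FALSE)
  if (all(d == 0) || length(dk) == 0) {
    out$degenerate <- TRUE
    return(out)
  }
  rk <- rank(abs(dk))
  n <- length(dk)
  W <- sum(rk[dk > 0])
  if (zeros == "pratt") { # zeros keep ranks but contribute to neither sign
    mu <- (n * (n + 1) / 2 - sum(rk[dk == 0])) / 2
  } else {
    mu <- n * (n + 1) / 4
  }
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (zeros == "pratt") {
    nz <- sum(dk == 0)
    sigma2 <- sigma2 - nz * (nz + 1) * (2 * nz + 1) / 24
  }
  Z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  out$W <- W
  out$Z <- Z
  out$p <- zToPTwoSided(Z)
  out$r <- effectSizeR(Z, nPairs)
  nz <- sum(dk != 0)
  if (zeros == "drop" && nz <= exactLimit && !any(duplicated(abs(dk)))) {
    # exact null: all 2^n sign assignments of the ranks are equally likely
    rks <- rank(abs(dk[dk != 0]))
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), nz)))
    Ws <- signs %*% rks
    pLe <- mean(Ws <= W); pGe <- mean(Ws >= W)
    out$p_exact <- min(1, 2 * min(pLe, pGe))
  }
  out
}

#' Two-sided normal p-value for a standardised statistic
#' @param z standardised statistic
#' @return `2 * (1 - Phi(|z|))`
#' @examples
#' zToPTwoSided(2.03) # 0.0424
#' @export
zToPTwoSided <- function(z) 2 * pnorm(abs(z), lower.tail = FALSE)

#' Matched-pairs rank-biserial-style effect size r = Z / sqrt(N)
#'
#' `N` is the total observation count, i.e. twice the number of pairs, which
#' is the convention under which `Z = 2.02` with 5 pairs gives
#' `|r| = 2.02 / sqrt(10) = 0.64`.
#'
#' @param z standardised Wilcoxon statistic
#' @param nPairs number of pairs
#' @return signed effect size
#' @export
effectSizeR <- function(z, nPairs) z / sqrt(2 * nPairs)

#' Greyson NDE scale total and classification
#'
#' Sixteen items, each scored 0 (not present), 1 (mildly or ambiguously
#' present) or 2 (definitively present); the total ranges 0-32 and a total
#' of at least 7 classifies the experience as an NDE.
#'
#' @param items numeric vector of 16 item scores in \{0, 1, 2\}
#' @param cutoff NDE classification cut-off
#' @return list: `total`, `is_nde`
#' @examples
#' greysonTotal(rep(2, 16)) # total 32
#' @export
greysonTotal <- function(items, cutoff = 7) {
  if (length(items) != 16)
    stop("validation error: exactly 16 items required")
  if (!all(items %in% 0:2))
    stop("validation error: items must be 0, 1 or 2")
  total <- sum(items)
  list(total = total, is_nde = total >= cutoff)
}

#' SHSS:C hypnotisability category
#'
#' Scores of at most 4 are low, 5-7 medium, and 8 or more high
#' hypnotisability (scale range 0-12).
#'
#' @param score integer SHSS:C total in 0..12
#' @return `"low"`, `"medium"` or `"high"` (vectorised)
#' @examples
#' shssCategory(c(4, 5, 7, 8))
#' @export
shssCategory <- function(score) {
  if (any(score < 0 | score > 12))
    stop("validation error: SHSS:C scores lie in 0..12")
  ifelse(score <= 4, "low", ifelse(score <= 7, "medium", "high"))
}

#' Memory Characteristics Questionnaire total
#'
#' @param items numeric vector of 16 Likert scores, each in 1..7
#' @return total score in 16..112
#' @export
mcqTotal <- function(items) {
  if (length(items) != 16)
    stop("validation error: exactly 16 items required")
  if (!all(items >= 1 & items <= 7))
    stop("validation error: items must lie in 1..7")
  sum(items)
}

#' Years elapsed since the remembered event
#'
#' @param age current ages in years
#' @param ageAtEvent ages at the remembered event in years
#' @return list: `years` (per participant), `median`, `range` (min, max)
#' @examples
#' elapsedYears(c(60, 44, 66, 71, 48), c(21, 12, 57, 8, 18))
#' @export
elapsedYears <- function(age, ageAtEvent) {
  if (length(age) != length(ageAtEvent))
    stop("validation error: unequal lengths")
  if (any(ageAtEvent > age))
    stop("validation error: age at event exceeds current age")
  years <- age - ageAtEvent
  list(years = years, median = median(years), range = range(years))
}

#' Visual analogue scale score from a millimetre reading
#'
#' A 100-mm line maps linearly to 0 ("not at all") .. 10 ("fully").
#'
#' @param positionMm cursor position in millimetres, 0..100 (vectorised)
#' @return score in 0..10
#' @export
vasFromMm <- function(positionMm) {
  if (any(positionMm < 0 | positionMm > 100))
    stop("validation error: positions lie in 0..100 mm")
  positionMm / 10
}
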