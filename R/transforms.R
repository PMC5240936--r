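#' Logit (M-value) transform of methylation beta values
#'
#' Natural-log logit: `log(beta / (1 - beta))`. Values are clipped to
#' `[eps, 1 - eps]` before the transform so boundary betas stay finite;
#' `eps = 1e-6` by default. `mToBeta()` is the exact inverse on the
#' unclipped range.
#'
#' @param beta numeric vector/matrix of beta values in [0, 1]
#' @param m numeric vector/matrix of logit-scale values
#' @param eps clipping constant
#' @return transformed object of the same shape
#' @examples
#' betaToM(0.5)            # 0
#' mToBeta(betaToM(0.8))   # 0.8
#' @export
betaToM <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  qlogis(pmin(pmax(beta, eps), 1 - eps))
}

#' @rdname betaToM
#' @export
mToBeta <- function(m) plogis(m)

#' Rank-based inverse-normal transform
#'
#' Maps values to standard-normal scores `qnorm((rank - 0.5) / n)` using
#' average ranks for ties — the symmetric convention, so a two-way tie
#' maps to 0. Missing values are preserved in place; ranks are computed
#' over the non-missing entries.
#'
#' @param values numeric vector with at least 2 non-missing entries
#' @return numeric vector of the same length, mean approximately 0
#' @examples
#' inverseNormalTransform(c(10, 20, 30))  # -0.9674, 0, 0.9674
#' @export
inverseNormalTransform <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2L) stop("need >= 2 non-missing values")
  x <- values[ok]
  if (length(unique(x)) == 1L) {
    warning("all values identical; inverse-normal transform returns zeros")
    values[ok] <- 0
    return(values)
  }
  values[ok] <- qnorm((rank(x, ties.method = "average") - 0.5) / n)
  values
}
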