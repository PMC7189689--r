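#' Beta/M-value transforms
#'
#' \code{betaToM} maps methylation beta values to M values with the base-2
#' logit, \eqn{M = \log_2(\beta / (1 - \beta))}; \code{mToBeta} is its
#' inverse, \eqn{\beta = 2^M / (1 + 2^M)}. Beta values within machine reach
#' of 0 or 1 are clipped to \code{[1e-6, 1 - 1e-6]} before the transform so
#' M stays finite. Values outside \eqn{[0,1]} are a domain error; NAs pass
#' through.
#'
#' @param beta numeric vector/matrix of beta values in \eqn{[0,1]}.
#' @param m numeric vector/matrix of M values.
#' @return numeric object of the same shape.
#' @examples
#' betaToM(c(0.5, 0.8, 0.2))   # 0, 2, -2
#' mToBeta(betaToM(0.3))
#' @export
betaToM <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dimnames(out) <- dimnames(beta)
  out
}

#' @rdname betaToM
#' @export
mToBeta <- function(m) {
  ## 1/(1+2^-M) is stable for large |M|
  out <- 1 / (1 + 2^(-m))
  if (is.matrix(m)) dimnames(out) <- dimnames(m)
  out
}
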