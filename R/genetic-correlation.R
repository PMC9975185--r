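# Genetic correlation implied by the fitted mixture parameters.

#' Genetic correlation between the two phenotypes
#'
#' Ratio of the model-implied genetic covariance to the geometric mean of
#' the two genetic variances:
#' numerator `pi1*delta21*sigma1^2 + pi2*delta12*sigma2^2 +
#' piC*[delta21*sigmaC1^2 + delta12*sigmaC2^2 + (1+delta12*delta21)*rhoC1C2]`;
#' denominator `sqrt((pi1*sigma1^2 + pi2*delta12^2*sigma2^2 +
#' piC*[sigmaC1^2 + delta12^2*sigmaC2^2]) * (pi1*delta21^2*sigma1^2 +
#' pi2*sigma2^2 + piC*[delta21^2*sigmaC1^2 + sigmaC2^2]))`.
#' The result is clamped to `[-1, 1]` (attribute `clamped` flags it).
#'
#' @param params an [mrci_params()] vector.
#' @return the genetic correlation; `NA` with a warning if either trait has
#'   zero genetic variance.
#' @export
genetic_correlation <- function(params) {
  p <- as_mrci_params(params)
  pi1 <- p[["pi1"]]; pi2 <- p[["pi2"]]; piC <- p[["piC"]]
  s1 <- p[["sigma1_sq"]]; s2 <- p[["sigma2_sq"]]
  c1 <- p[["sigmaC1_sq"]]; c2 <- p[["sigmaC2_sq"]]
  rc <- p[["rhoC1C2"]]; d12 <- p[["delta12"]]; d21 <- p[["delta21"]]
  num <- pi1 * d21 * s1 + pi2 * d12 * s2 +
    piC * (d21 * c1 + d12 * c2 + (1 + d12 * d21) * rc)
  g1 <- pi1 * s1 + pi2 * d12^2 * s2 + piC * (c1 + d12^2 * c2)
  g2 <- pi1 * d21^2 * s1 + pi2 * s2 + piC * (d21^2 * c1 + c2)
  if (g1 <= 0 || g2 <= 0) {
    warn("genetic variance is zero for at least one trait; rg undefined")
    return(NA_real_)
  }
  rg <- num / sqrt(g1 * g2)
  clamped <- abs(rg) > 1
  if (clamped) rg <- sign(rg)
  structure(rg, clamped = clamped)
}

#' Variance of the genetic correlation (numerical delta method)
#'
#' `g' Sigma g` with `g` the central-difference gradient of
#' [genetic_correlation()] with respect to the parameters covered by
#' `param_covariance`.
#'
#' @param params an [mrci_params()] vector.
#' @param param_covariance covariance matrix of the estimates with parameter
#'   names as dimnames (e.g. from [sandwich_covariance()]).
#' @param h relative central-difference step.
#' @return the delta-method variance of the genetic correlation.
#' @export
rg_variance <- function(params, param_covariance, h = 1e-5) {
  p <- as_mrci_params(params)
  nms <- colnames(param_covariance)
  stopifnot(!is.null(nms), all(nms %in% .PARAM_NAMES))
  g <- vapply(nms, function(nm) {
    hh <- h * max(1, abs(p[[nm]]))
    pp <- p; pp[nm] <- p[[nm]] + hh
    pm <- p; pm[nm] <- p[[nm]] - hh
    (as.numeric(genetic_correlation(pp)) - as.numeric(genetic_correlation(pm))) / (2 * hh)
  }, numeric(1))
  if (any(!is.finite(g))) abort("non-finite gradient in rg variance")
  S <- param_covariance
  S[is.na(S)] <- 0
  drop(t(g) %*% S %*% g)
}
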