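# Bivariate mixture density of marginal effect estimates and the composite
# log-likelihood.

#' Analysis-ready summary dataset
#'
#' Construct the per-SNP container used by all estimation functions: one row
#' per SNP with standardized marginal effect estimates for both phenotypes,
#' LD score, tagging-set size and the tagging set itself (indices into the
#' dataset rows). GWAS sample sizes are carried as attributes.
#'
#' @param snp_id character SNP identifiers.
#' @param tau1,tau2 standardized marginal effect estimates (z / sqrt(n)).
#' @param ld_score LD scores (>= 1, self r^2 = 1 included).
#' @param n_tagged tagging-set sizes (>= 1, self included).
#' @param tag_idx list of integer vectors: indices of tagged SNPs (self
#'   included) within this dataset.
#' @param n1,n2 GWAS sample sizes for the two phenotypes.
#' @return A tibble of class `mrci_data`.
#' @export
mrci_data <- function(snp_id, tau1, tau2, ld_score, n_tagged, tag_idx, n1, n2) {
  stopifnot(length(tau1) == length(snp_id), length(tau2) == length(snp_id),
            length(ld_score) == length(snp_id), length(n_tagged) == length(snp_id),
            length(tag_idx) == length(snp_id), n1 > 0, n2 > 0)
  if (any(ld_score < 1) || any(n_tagged < 1))
    abort("ld_score and n_tagged must be >= 1 (the tagging set includes the SNP itself)")
  if (any(ld_score > n_tagged + 1e-8))
    abort("ld_score cannot exceed n_tagged")
  d <- tibble(snp_id = as.character(snp_id), tau1 = as.numeric(tau1),
              tau2 = as.numeric(tau2), ld_score = as.numeric(ld_score),
              n_tagged = as.integer(n_tagged), tag_idx = tag_idx)
  attr(d, "n1") <- as.numeric(n1)
  attr(d, "n2") <- as.numeric(n2)
  class(d) <- c("mrci_data", class(d))
  d
}

sample_sizes <- function(data) c(attr(data, "n1"), attr(data, "n2"))

# group SNPs by distinct (n_tagged, ld_score/n_tagged); cached on the object
with_groups <- function(data) {
  if (!is.null(attr(data, "g_nstar"))) return(data)
  s <- data$ld_score / data$n_tagged
  key <- paste0(data$n_tagged, "_", signif(s, 12))
  u <- !duplicated(key)
  g <- match(key, key[u])
  attr(data, "group") <- g
  attr(data, "g_nstar") <- as.integer(data$n_tagged[u])
  attr(data, "g_s") <- s[u]
  data
}

#' Enumeration plan for latent tagging-set compositions
#'
#' The mixture density sums over the latent composition of each SNP's tagging
#' set across the four components. The sum is truncated: per-component causal
#' counts are capped at `c_max` (null counts are unrestricted), and the
#' multinomial prior is renormalized over the truncated set. With
#' `c_max >= n_tagged` the enumeration is exhaustive.
#'
#' @param active character vector of active non-null components
#'   (subset of `c("G1","G2","GC")`).
#' @param c_max per-component cap on causal counts.
#' @param max_nstar largest tagging-set size that the plan must cover.
#' @param t_max optional additional cap on the total causal count of a
#'   composition (default none); with mixing proportions of order 1e-3 and
#'   tagging sets of tens of SNPs the prior mass beyond 3 causal tags is
#'   negligible, so fitting functions use a finite cap for speed.
#' @return list with the composition count matrix (`comps`, columns
#'   `n_g1`, `n_g2`, `n_gc`), `c_max`, `t_max` and `active`.
#' @export
enumeration_plan <- function(active = c("G1", "G2", "GC"), c_max = 4,
                             max_nstar = Inf, t_max = Inf) {
  stopifnot(c_max >= 0, t_max >= 0)
  cap <- min(c_max, max_nstar)
  rng <- function(comp) if (comp %in% active) 0:cap else 0L
  grid <- expand.grid(n_g1 = rng("G1"), n_g2 = rng("G2"), n_gc = rng("GC"))
  grid <- grid[rowSums(grid) <= min(max_nstar, t_max), , drop = FALSE]
  comps <- as.matrix(grid)
  storage.mode(comps) <- "integer"
  list(comps = comps, c_max = c_max, t_max = t_max, active = active)
}

plan_for <- function(params, c_max, max_nstar = Inf, t_max = Inf) {
  p <- as_mrci_params(params)
  active <- c("G1", "G2", "GC")[c(p["pi1"] > 0, p["pi2"] > 0, p["piC"] > 0)]
  enumeration_plan(active, c_max, max_nstar, t_max)
}

#' Prior probability of a tagging-set composition
#'
#' Multinomial probability of observing the given counts of the four
#' components among `total` tagged SNPs, with cell probabilities
#' `(pi1, pi2, piC, pi0)`.
#'
#' @param counts numeric vector `(n_g1, n_g2, n_gc, n_g0)`.
#' @param params an [mrci_params()] vector.
#' @return the multinomial pmf value.
#' @export
#' @examples
#' component_count_prob(c(1, 1, 1, 0), mrci_params(pi1 = .1, pi2 = .2, piC = .3))
component_count_prob <- function(counts, params) {
  p <- as_mrci_params(params)
  if (any(counts < 0)) abort("composition counts must be non-negative")
  pis <- c(p["pi1"], p["pi2"], p["piC"], 1 - p["pi1"] - p["pi2"] - p["piC"])
  dmultinom(counts, prob = pis)
}

#' Renormalized composition priors for one tagging-set size
#'
#' Enumerates the (truncated) composition set for a tagging set of size
#' `nstar` and returns the multinomial priors renormalized to sum to one.
#'
#' @param plan an [enumeration_plan()].
#' @param nstar tagging-set size.
#' @param params an [mrci_params()] vector.
#' @return tibble with columns `n_g1`, `n_g2`, `n_gc`, `n_g0`, `prior`.
#' @export
plan_priors <- function(plan, nstar, params) {
  p <- as_mrci_params(params)
  cm <- plan$comps
  keep <- rowSums(cm) <= nstar
  cm <- cm[keep, , drop = FALSE]
  pis <- c(p["pi1"], p["pi2"], p["piC"], 1 - sum(p[c("pi1", "pi2", "piC")]))
  pr <- apply(cm, 1, function(cnt) dmultinom(c(cnt, nstar - sum(cnt)), prob = pis))
  tibble(n_g1 = cm[, 1], n_g2 = cm[, 2], n_gc = cm[, 3],
         n_g0 = nstar - rowSums(cm), prior = pr / sum(pr))
}

# nine per-count covariance coefficients + three bases (see kernel.cpp)
cov_coefficients <- function(params, n1, n2) {
  p <- as_mrci_params(params)
  d12 <- unname(p["delta12"]); d21 <- unname(p["delta21"])
  den <- (1 - d12 * d21)^2
  s1 <- unname(p["sigma1_sq"]); s2 <- unname(p["sigma2_sq"])
  c1 <- unname(p["sigmaC1_sq"]); c2 <- unname(p["sigmaC2_sq"])
  rc <- unname(p["rhoC1C2"])
  list(
    coef = c(s1 / den, d12^2 * s2 / den, (c1 + d12^2 * c2 + 2 * d12 * rc) / den,
             d21^2 * s1 / den, s2 / den, (c2 + d21^2 * c1 + 2 * d21 * rc) / den,
             d21 * s1 / den, d12 * s2 / den,
             (d21 * c1 + d12 * c2 + (1 + d12 * d21) * rc) / den),
    base = c(unname(p["a1"]) + 1 / n1, unname(p["a2"]) + 1 / n2, unname(p["rho0"])))
}

#' Covariance of marginal effect estimates given a tagging-set composition
#'
#' Implements the three covariance approximations of the model: each non-null
#' component contributes its per-count term weighted by
#' `(count / n_tagged) * ld_score` and divided by `(1 - delta12*delta21)^2`,
#' plus the sampling-noise and bias terms `a + 1/n` (variances) and `rho0`
#' (covariance). If the implied correlation leaves the admissible region the
#' covariance is clamped to 0.999 of the bound and flagged.
#'
#' @param counts vector `(n_g1, n_g2, n_gc)` or `(n_g1, n_g2, n_gc, n_g0)`.
#' @param ld_score,n_tagged LD score and tagging-set size of the SNP.
#' @param n1,n2 GWAS sample sizes.
#' @param params an [mrci_params()] vector.
#' @return tibble with `var1`, `var2`, `cov`, `clamped`.
#' @export
marginal_covariance <- function(counts, ld_score, n_tagged, n1, n2, params) {
  stopifnot(n_tagged >= 1, length(counts) %in% c(3L, 4L))
  cnt <- as.numeric(counts[1:3])
  cf <- cov_coefficients(params, n1, n2)
  s <- ld_score / n_tagged
  v1 <- s * sum(cnt * cf$coef[1:3]) + cf$base[1]
  v2 <- s * sum(cnt * cf$coef[4:6]) + cf$base[2]
  cv <- s * sum(cnt * cf$coef[7:9]) + cf$base[3]
  lim <- 0.999 * sqrt(v1 * v2)
  clamped <- abs(cv) >= lim
  if (clamped) cv <- sign(cv) * lim
  tibble(var1 = v1, var2 = v2, cov = cv, clamped = clamped)
}

# single entry point to the C++ kernel
cl_eval <- function(data, params, plan = NULL,
                    want_loglik = FALSE, want_counts = FALSE, want_post = FALSE) {
  p <- as_mrci_params(params)
  data <- with_groups(data)
  if (is.null(plan)) plan <- plan_for(p, c_max = 4, max_nstar = max(data$n_tagged))
  ns <- sample_sizes(data)
  cf <- cov_coefficients(p, ns[1], ns[2])
  pis <- c(unname(p[c("pi1", "pi2", "piC")]), 1 - sum(p[c("pi1", "pi2", "piC")]))
  pis[4] <- max(pis[4], 0)
  res <- cl_kernel(data$tau1, data$tau2, attr(data, "group"),
                   attr(data, "g_nstar"), attr(data, "g_s"),
                   plan$comps, pis, cf$coef, cf$base,
                   want_loglik, want_counts, want_post)
  if (isTRUE(res$bad))
    abort(paste0("non-finite likelihood term at SNP ", data$snp_id[res$bad_snp]))
  res
}

#' Per-SNP mixture log-likelihood
#'
#' Log of the prior-weighted sum of bivariate normal densities over the
#' enumerated tagging-set compositions, computed with a log-sum-exp contract
#' (no underflow for densities down to exp(-700)).
#'
#' @param data an [mrci_data()] dataset.
#' @param params an [mrci_params()] vector.
#' @param plan optional [enumeration_plan()]; defaults to the active
#'   components of `params` with `c_max = 4`.
#' @return numeric vector of per-SNP log densities.
#' @export
snp_log_likelihood <- function(data, params, plan = NULL) {
  cl_eval(data, params, plan, want_loglik = TRUE)$loglik
}

#' Composite log-likelihood
#'
#' Sum of the per-SNP mixture log-likelihoods over all SNPs in the dataset.
#' SNPs are treated as if independent (the LD correlation between them is
#' accounted for at the inference stage by the sandwich variance).
#'
#' @inheritParams snp_log_likelihood
#' @return scalar composite log-likelihood (finite, or an error naming the
#'   offending SNP).
#' @export
composite_log_likelihood <- function(data, params, plan = NULL) {
  cl_eval(data, params, plan)$cl
}
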