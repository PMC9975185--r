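# Independent reference implementations used as oracles. These deliberately
# avoid the package's kernel: enumeration by expand.grid, multinomial priors
# via dmultinom, bivariate normal densities in closed form.

# all compositions (n_g1, n_g2, n_gc) with total <= nstar
oracle_compositions <- function(nstar) {
  g <- expand.grid(n_g1 = 0:nstar, n_g2 = 0:nstar, n_gc = 0:nstar)
  as.matrix(g[rowSums(g) <= nstar, , drop = FALSE])
}

oracle_bvn_logdens <- function(x1, x2, v1, v2, cv) {
  det <- v1 * v2 - cv^2
  q <- (v2 * x1^2 - 2 * cv * x1 * x2 + v1 * x2^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

# covariance of the marginal estimate pair for one composition, straight
# from the three displayed approximations
oracle_covariance <- function(cnt, ld_score, nstar, n1, n2, p) {
  d12 <- p[["delta12"]]; d21 <- p[["delta21"]]
  den <- (1 - d12 * d21)^2
  w <- (cnt / nstar) * ld_score
  v1 <- (p[["sigma1_sq"]] * w[1] + d12^2 * p[["sigma2_sq"]] * w[2] +
         (p[["sigmaC1_sq"]] + d12^2 * p[["sigmaC2_sq"]] +
            2 * d12 * p[["rhoC1C2"]]) * w[3]) / den + p[["a1"]] + 1 / n1
  v2 <- (d21^2 * p[["sigma1_sq"]] * w[1] + p[["sigma2_sq"]] * w[2] +
         (p[["sigmaC2_sq"]] + d21^2 * p[["sigmaC1_sq"]] +
            2 * d21 * p[["rhoC1C2"]]) * w[3]) / den + p[["a2"]] + 1 / n2
  cv <- (d21 * p[["sigma1_sq"]] * w[1] + d12 * p[["sigma2_sq"]] * w[2] +
         (d21 * p[["sigmaC1_sq"]] + d12 * p[["sigmaC2_sq"]] +
            (1 + d12 * d21) * p[["rhoC1C2"]]) * w[3]) / den + p[["rho0"]]
  c(v1, v2, cv)
}

# exhaustive-enumeration mixture log density for one SNP
oracle_snp_loglik <- function(tau1, tau2, ld_score, nstar, n1, n2, p) {
  cm <- oracle_compositions(nstar)
  pis <- c(p[["pi1"]], p[["pi2"]], p[["piC"]],
           1 - p[["pi1"]] - p[["pi2"]] - p[["piC"]])
  terms <- vapply(seq_len(nrow(cm)), function(i) {
    cnt <- cm[i, ]
    pr <- dmultinom(c(cnt, nstar - sum(cnt)), prob = pis)
    v <- oracle_covariance(cnt, ld_score, nstar, n1, n2, p)
    pr * exp(oracle_bvn_logdens(tau1, tau2, v[1] + 1e-12, v[2] + 1e-12, v[3]))
  }, numeric(1))
  log(sum(terms))
}

# small synthetic dataset with hand-set LD fields
toy_dataset <- function(K = 6, nstar = 3, ld_score = 2.0, n1 = 5e4, n2 = 5e4,
                        seed = 42) {
  set.seed(seed)
  tag_idx <- lapply(seq_len(K), function(i) {
    lo <- max(1, i - (nstar - 1) %/% 2)
    sort(unique(pmin(K, lo + 0:(nstar - 1))))
  })
  ntag <- vapply(tag_idx, length, integer(1))
  mrci_data(snp_id = paste0("rs", seq_len(K)),
            tau1 = rnorm(K, 0, 0.01), tau2 = rnorm(K, 0, 0.01),
            ld_score = pmin(ld_score, ntag), n_tagged = ntag,
            tag_idx = tag_idx, n1 = n1, n2 = n2)
}

toy_params <- function() {
  mrci_params(pi1 = 2e-3, pi2 = 1.5e-3, piC = 1e-3,
              sigma1_sq = 8e-3, sigma2_sq = 6e-3,
              sigmaC1_sq = 5e-3, sigmaC2_sq = 4e-3, rhoC1C2 = 1.5e-3,
              delta12 = 0.1, delta21 = 0.05,
              a1 = 1e-6, a2 = 2e-6, rho0 = 4e-6)
}

# swap phenotype labels in a dataset and in a parameter vector
swap_dataset <- function(d) {
  ns <- mrci:::sample_sizes(d)
  mrci_data(d$snp_id, d$tau2, d$tau1, d$ld_score, d$n_tagged, d$tag_idx,
            n1 = ns[2], n2 = ns[1])
}

swap_params <- function(p) {
  mrci_params(pi1 = p[["pi2"]], pi2 = p[["pi1"]], piC = p[["piC"]],
              sigma1_sq = p[["sigma2_sq"]], sigma2_sq = p[["sigma1_sq"]],
              sigmaC1_sq = p[["sigmaC2_sq"]], sigmaC2_sq = p[["sigmaC1_sq"]],
              rhoC1C2 = p[["rhoC1C2"]],
              delta12 = p[["delta21"]], delta21 = p[["delta12"]],
              a1 = p[["a2"]], a2 = p[["a1"]], rho0 = p[["rho0"]])
}
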