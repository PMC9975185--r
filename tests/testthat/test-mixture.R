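test_that("composition prior is the multinomial pmf", {
  # all mass on the null component
  expect_equal(component_count_prob(c(0, 0, 0, 5), mrci_params()), 1.0)
  # single draw
  expect_equal(component_count_prob(c(1, 0, 0, 0), mrci_params(pi1 = 0.3)), 0.3)
  # N* = 3, one SNP in each non-null component: 3! * 0.1 * 0.2 * 0.3
  p <- mrci_params(pi1 = 0.1, pi2 = 0.2, piC = 0.3)
  expect_equal(component_count_prob(c(1, 1, 1, 0), p), 0.036)
  expect_error(component_count_prob(c(-1, 0, 0, 2), p), "non-negative")
})

test_that("enumerated priors renormalize to one and gain mass with c_max", {
  p <- toy_params()
  for (nstar in c(1, 3, 7)) {
    masses <- vapply(1:4, function(cm) {
      pl <- enumeration_plan(c_max = cm, max_nstar = nstar)
      pri <- plan_priors(pl, nstar, p)
      expect_equal(sum(pri$prior), 1)
      # raw (unrenormalized) captured mass
      sum(vapply(seq_len(nrow(pri)), function(i)
        component_count_prob(as.numeric(pri[i, 1:4]), p), numeric(1)))
    }, numeric(1))
    expect_true(all(diff(masses) >= -1e-12))
  }
})

test_that("marginal covariance matches the displayed formulas case by case", {
  p <- toy_params()
  n1 <- 5e4; n2 <- 6e4
  # null-only tagging set: noise and bias terms only
  v <- marginal_covariance(c(0, 0, 0), ld_score = 3, n_tagged = 5, n1, n2, p)
  expect_equal(v$var1, p[["a1"]] + 1 / n1)
  expect_equal(v$var2, p[["a2"]] + 1 / n2)
  expect_equal(v$cov, p[["rho0"]])
  # no causation: formulas collapse, cross-covariance is rho0 only
  p0 <- toy_params(); p0["delta12"] <- 0; p0["delta21"] <- 0
  v <- marginal_covariance(c(2, 0, 0), ld_score = 3, n_tagged = 5, n1, n2, p0)
  expect_equal(v$var1, p0[["sigma1_sq"]] * (2 / 5) * 3 + p0[["a1"]] + 1 / n1)
  expect_equal(v$cov, p0[["rho0"]])
  # general case against the independently coded oracle
  for (cnt in list(c(1, 0, 0), c(0, 2, 1), c(1, 1, 1))) {
    v <- marginal_covariance(cnt, ld_score = 2.6, n_tagged = 7, n1, n2, p)
    o <- oracle_covariance(cnt, 2.6, 7, n1, n2, p)
    expect_equal(c(v$var1, v$var2, v$cov), o, tolerance = 1e-12)
  }
})

test_that("marginal covariance matches Monte-Carlo simulation of the generative model", {
  # one SNP with an equicorrelated tagging set; fixed composition, random
  # placement of causal tags, fresh effect draws each replicate
  set.seed(31)
  nstar <- 5; r <- 0.45
  rho <- c(1, rep(r, nstar - 1))
  ld <- sum(rho^2)
  n1 <- n2 <- 5e4
  p <- toy_params()
  p["delta12"] <- 0.1; p["delta21"] <- 0.05
  cnt <- c(1, 1, 1)
  nsim <- 40000
  tau <- matrix(0, nsim, 2)
  Sc <- matrix(c(p[["sigmaC1_sq"]], p[["rhoC1C2"]],
                 p[["rhoC1C2"]], p[["sigmaC2_sq"]]), 2)
  Lc <- chol(Sc)
  for (i in seq_len(nsim)) {
    slots <- sample(nstar, sum(cnt))
    g <- matrix(0, nstar, 2)
    g[slots[1], 1] <- rnorm(1, 0, sqrt(p[["sigma1_sq"]]))
    g[slots[2], 2] <- rnorm(1, 0, sqrt(p[["sigma2_sq"]]))
    g[slots[3], ] <- rnorm(2) %*% Lc
    b <- direct_to_joint(g, p[["delta12"]], p[["delta21"]])
    tau[i, ] <- colSums(rho * b)
  }
  noise <- cbind(rnorm(nsim, 0, sqrt(p[["a1"]] + 1 / n1)),
                 rnorm(nsim, 0, sqrt(p[["a2"]] + 1 / n2)))
  tau <- tau + noise  # rho0 omitted from the draw, added to the reference below
  x <- sweep(tau, 2, colMeans(tau))
  emp <- crossprod(x) / (nsim - 1)
  v <- marginal_covariance(cnt, ld, nstar, n1, n2, p)
  # empirical Monte-Carlo SEs (the position mixture is heavy-tailed)
  expect_lt(abs(emp[1, 1] - v$var1), 3 * sd(x[, 1]^2) / sqrt(nsim))
  expect_lt(abs(emp[2, 2] - v$var2), 3 * sd(x[, 2]^2) / sqrt(nsim))
  expect_lt(abs(emp[1, 2] - (v$cov - p[["rho0"]])),
            3 * sd(x[, 1] * x[, 2]) / sqrt(nsim))
})

test_that("per-SNP log-likelihood equals exhaustive enumeration", {
  p <- toy_params()
  for (nstar in c(1, 3, 5)) {
    d <- toy_dataset(K = 8, nstar = nstar, ld_score = 1 + 0.4 * nstar,
                     seed = nstar)
    # make two SNPs strongly non-null so causal compositions dominate
    d$tau1[1] <- 0.03; d$tau2[2] <- -0.025
    plan <- enumeration_plan(c_max = nstar, max_nstar = nstar)
    got <- snp_log_likelihood(d, p, plan)
    ns <- mrci:::sample_sizes(d)
    want <- vapply(seq_len(nrow(d)), function(k)
      oracle_snp_loglik(d$tau1[k], d$tau2[k], d$ld_score[k], d$n_tagged[k],
                        ns[1], ns[2], p), numeric(1))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("log-sum-exp contract survives extreme densities", {
  d <- toy_dataset(K = 3, nstar = 1)
  d$tau1 <- c(0, 0.09, -0.09)   # z of +-20 on n = 5e4: density ~ exp(-200)
  d$tau2 <- c(0, 0.09, -0.09)
  ll <- snp_log_likelihood(d, mrci_params())  # null-only mixture
  expect_true(all(is.finite(ll)))
  ns <- mrci:::sample_sizes(d)
  expect_equal(ll[2], oracle_bvn_logdens(0.09, 0.09, 1e-12 + 1 / ns[1],
                                         1e-12 + 1 / ns[2], 0), tolerance = 1e-9)
})

test_that("composite likelihood is additive and label-swap symmetric", {
  p <- toy_params()
  d <- toy_dataset(K = 10, nstar = 3)
  cl1 <- composite_log_likelihood(d, p)
  # duplicating every SNP doubles the composite likelihood
  d2 <- mrci_data(c(d$snp_id, paste0(d$snp_id, "b")),
                  rep(d$tau1, 2), rep(d$tau2, 2), rep(d$ld_score, 2),
                  rep(d$n_tagged, 2),
                  c(d$tag_idx, lapply(d$tag_idx, `+`, nrow(d))),
                  n1 = mrci:::sample_sizes(d)[1], n2 = mrci:::sample_sizes(d)[2])
  expect_equal(composite_log_likelihood(d2, p), 2 * cl1, tolerance = 1e-10)
  # exchanging phenotype labels and swapping parameters leaves CL unchanged
  expect_equal(composite_log_likelihood(swap_dataset(d), swap_params(p)), cl1,
               tolerance = 1e-10)
  # K = 1 reduces to the per-SNP log-likelihood
  d1 <- mrci_data(d$snp_id[1], d$tau1[1], d$tau2[1], d$ld_score[1],
                  d$n_tagged[1], list(1L), 5e4, 5e4)
  expect_equal(composite_log_likelihood(d1, p), snp_log_likelihood(d1, p)[1])
})

test_that("composite likelihood prefers the truth to a no-causation model", {
  sc <- mrci_scenario("HiS-bi", M = 4000L)
  truth <- scenario_params(sc)
  p0 <- truth; p0["delta12"] <- 0; p0["delta21"] <- 0
  wins <- 0
  for (s in 1:10) {
    d <- mrci_simulate(sc, seed = 300 + s)
    wins <- wins + (composite_log_likelihood(d, truth) >
                      composite_log_likelihood(d, p0))
  }
  expect_gte(wins, 9)
})

test_that("genetic correlation limits and delta-method variance", {
  # no causation, independent pleiotropy: rg = 0
  p <- mrci_params(pi1 = 1e-3, pi2 = 1e-3, piC = 1e-3,
                   sigma1_sq = 0.01, sigma2_sq = 0.01,
                   sigmaC1_sq = 0.005, sigmaC2_sq = 0.005)
  expect_equal(as.numeric(genetic_correlation(p)), 0)
  # perfectly correlated pleiotropy only: rg = 1
  p1 <- mrci_params(piC = 1e-3, sigmaC1_sq = 3e-3, sigmaC2_sq = 3e-3,
                    rhoC1C2 = 3e-3)
  expect_equal(as.numeric(genetic_correlation(p1)), 1)
  # degenerate: no genetic variance
  expect_warning(rg0 <- genetic_correlation(mrci_params()), "undefined")
  expect_true(is.na(rg0))
  # |rg| <= 1 across random admissible parameter vectors
  set.seed(11)
  for (i in 1:25) {
    pr <- mrci_params(pi1 = runif(1, 1e-4, 5e-3), pi2 = runif(1, 1e-4, 5e-3),
                      piC = runif(1, 1e-4, 5e-3),
                      sigma1_sq = runif(1, 1e-4, 2e-2),
                      sigma2_sq = runif(1, 1e-4, 2e-2),
                      sigmaC1_sq = runif(1, 1e-4, 2e-2),
                      sigmaC2_sq = runif(1, 1e-4, 2e-2),
                      delta12 = runif(1, -0.9, 0.9), delta21 = runif(1, -0.9, 0.9))
    pr["rhoC1C2"] <- runif(1, -1, 1) * sqrt(pr[["sigmaC1_sq"]] * pr[["sigmaC2_sq"]])
    expect_lte(abs(as.numeric(genetic_correlation(pr))), 1)
  }

  # zero parameter covariance gives zero variance
  p <- toy_params()
  S <- matrix(0, 13, 13, dimnames = list(names(p), names(p)))
  expect_equal(rg_variance(p, S), 0)
  # single free parameter: matches the scalar delta method by hand
  S1 <- matrix(4e-4, 1, 1, dimnames = list("delta12", "delta12"))
  h <- 1e-6
  pp <- p; pp["delta12"] <- p[["delta12"]] + h
  pm <- p; pm["delta12"] <- p[["delta12"]] - h
  g <- (as.numeric(genetic_correlation(pp)) -
        as.numeric(genetic_correlation(pm))) / (2 * h)
  expect_equal(rg_variance(p, S1), g^2 * 4e-4, tolerance = 1e-6)
  # central differences: halving the step changes the result at O(h^2)
  v1 <- rg_variance(p, S1, h = 1e-3)
  v2 <- rg_variance(p, S1, h = 5e-4)
  v3 <- rg_variance(p, S1, h = 1e-5)
  expect_lt(abs(v2 - v3), abs(v1 - v3) + 1e-12)
})
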