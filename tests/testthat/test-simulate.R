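test_that("block LD structure: scores, tagging sets and symmetry", {
  # no LD: every SNP tags only itself
  ld0 <- build_ld_structure(5, block_size = 1)
  expect_true(all(ld0$ld$ld_score == 1))
  expect_true(all(ld0$ld$n_tagged == 1))
  # middle SNP of a 3-block with r = 0.9: l = 0.81 + 1 + 0.81
  ld3 <- build_ld_structure(3, block_size = 3, r = 0.9, tag_r2 = 0.01)
  expect_equal(ld3$ld$ld_score[2], 0.81 + 1 + 0.81)
  # l_k <= N_k*, self-inclusion, symmetry of tagging
  ld <- build_ld_structure(120, block_size = 50, r = 0.5, tag_r2 = 0.01)
  expect_true(all(ld$ld$ld_score <= ld$ld$n_tagged + 1e-12))
  expect_true(all(vapply(seq_len(120), function(i) i %in% ld$tag_idx[[i]],
                         logical(1))))
  for (i in c(1, 26, 50, 51, 120))
    for (j in ld$tag_idx[[i]])
      expect_true(i %in% ld$tag_idx[[j]])
})

test_that("component assignment draws exact counts and calibrated effects", {
  sc <- mrci_scenario("HiS-bi", M = 20000L)
  set.seed(2)
  ae <- assign_components_and_effects(sc)
  expect_equal(sum(ae$component == "G1"), round(sc$pi1 * sc$M))
  expect_equal(sum(ae$component == "GC"), round(sc$piC * sc$M))
  expect_true(all(ae$gamma[ae$component == "G0", ] == 0))
  # all components absent
  sc0 <- mrci_scenario("HiS-null", pi1 = 0, pi2 = 0, piC = 0, h2_1 = 0,
                       h2_2 = 0, h2_C = 0, rho_cor = 0)
  ae0 <- assign_components_and_effects(sc0)
  expect_true(all(ae0$component == "G0"))
  # law of large numbers on the effect-size variance
  sc2 <- mrci_scenario("HiS-bi", M = 20000L, pi1 = 0.5)
  set.seed(3)
  ae2 <- assign_components_and_effects(sc2)
  p2 <- scenario_params(sc2)
  v <- var(ae2$gamma[ae2$component == "G1", 1])
  expect_lt(abs(v - p2[["sigma1_sq"]]) / p2[["sigma1_sq"]], 0.05)
  # degenerate pleiotropy: correlation ~ 1
  sc3 <- mrci_scenario("HiS-bi", M = 2000L, piC = 0.05, rho_cor = 1)
  set.seed(4)
  ae3 <- assign_components_and_effects(sc3)
  g <- ae3$gamma[ae3$component == "GC", ]
  expect_gt(cor(g[, 1], g[, 2]), 0.999)
})

test_that("direct-to-joint conversion solves the reciprocal system", {
  expect_equal(direct_to_joint(cbind(1, 0), 0, 0), cbind(1, 0))
  expect_equal(direct_to_joint(cbind(1, 0), 0, 0.5), cbind(1, 0.5))
  # a Y2-specific SNP has no path to Y1 when delta12 = 0
  b <- direct_to_joint(cbind(0, 2), 0, 0.3)
  expect_equal(b[1, 1], 0)
  # hand solve of the 2x2 system
  b2 <- direct_to_joint(cbind(1, 1), 0.1, 0.05)
  expect_equal(b2[1, 1], (1 + 0.1) / (1 - 0.005))
  expect_equal(b2[1, 2], (1 + 0.05) / (1 - 0.005))
  expect_error(direct_to_joint(cbind(1, 1), 2, 0.5), "delta12")
})

test_that("summary-level generator: noise scale, overlap and determinism", {
  # pure noise, no LD: empirical variance ~ 1/n
  sc <- mrci_scenario("HiS-null", M = 20000L, pi1 = 0, pi2 = 0, piC = 0,
                      h2_1 = 0, h2_2 = 0, h2_C = 0, rho_cor = 0,
                      block_size = 1L, overlap = 0)
  d <- mrci_simulate(sc, seed = 12)
  expect_lt(abs(var(d$tau1) * sc$n1 - 1), 0.05)
  expect_lt(abs(cor(d$tau1, d$tau2)), 0.03)
  # full overlap: cross-trait correlation of null taus ~ rho0 * n
  sc2 <- mrci_scenario("HiS-null", M = 20000L, pi1 = 0, pi2 = 0, piC = 0,
                       h2_1 = 0, h2_2 = 0, h2_C = 0, rho_cor = 0,
                       block_size = 1L, overlap = 1, delta12 = 0.3)
  # delta12 shapes the residual phenotypic covariance even with no genetics
  p2 <- scenario_params(sc2)
  expect_gt(p2[["rho0"]], 0)
  d2 <- mrci_simulate(sc2, seed = 13)
  expect_lt(abs(cor(d2$tau1, d2$tau2) - p2[["rho0"]] * sc2$n1),
            3 / sqrt(sc2$M))
  # byte-identical under a fixed seed
  d3 <- mrci_simulate("HiS-bi", seed = 99, ld = NULL)
  d4 <- mrci_simulate("HiS-bi", seed = 99, ld = NULL)
  expect_identical(d3$tau1, d4$tau1)
  expect_identical(attr(d3, "component"), attr(d4, "component"))
})

test_that("heritability bookkeeping matches the scenario targets", {
  sc <- mrci_scenario("HiS-bi", M = 30000L)
  h1 <- h2 <- hC <- numeric(12)
  for (s in 1:12) {
    set.seed(s)
    ae <- assign_components_and_effects(sc)
    h1[s] <- sum(ae$gamma[ae$component == "G1", 1]^2)
    h2[s] <- sum(ae$gamma[ae$component == "G2", 2]^2)
    hC[s] <- sum(ae$gamma[ae$component == "GC", 1]^2)
  }
  n_causal <- round(sc$pi1 * sc$M)
  se_h <- sc$h2_1 * sqrt(2 / n_causal) / sqrt(12)
  expect_lt(abs(mean(h1) - sc$h2_1), 3 * se_h)
  expect_lt(abs(mean(h2) - sc$h2_2), 3 * se_h)
  expect_lt(abs(mean(hC) - sc$h2_C), 3 * sc$h2_C * sqrt(2 / n_causal) / sqrt(12))
})

test_that("generator and likelihood agree: truth beats perturbed parameters", {
  # no-LD setting: the per-composition covariance is exact there, so the
  # composite likelihood at the truth dominates perturbed parameter vectors;
  # 600 causal SNPs per component keep the realized per-SNP variance close
  # enough to its target that +-50% perturbations are distinguishable
  sc <- mrci_scenario("HiS-bi", block_size = 1L,
                      pi1 = 0.02, pi2 = 0.02, piC = 0.02)
  truth <- scenario_params(sc)
  wins <- setNames(numeric(4), c("sigma1_sq", "delta12", "piC", "sigma2_sq"))
  nrep <- 10
  for (s in seq_len(nrep)) {
    d <- mrci_simulate(sc, seed = 500 + s)
    cl_t <- composite_log_likelihood(d, truth)
    for (nm in names(wins)) {
      up <- truth; up[nm] <- truth[[nm]] * 1.5
      dn <- truth; dn[nm] <- truth[[nm]] * 0.5
      if (nm == "piC") { up <- validate_params(up) }
      wins[nm] <- wins[nm] +
        (cl_t > max(composite_log_likelihood(d, up),
                    composite_log_likelihood(d, dn)))
    }
  }
  for (nm in names(wins)) expect_gte(wins[[nm]], 0.9 * nrep)
})

test_that("individual-level oracle agrees with the summary-level model", {
  sc <- mrci_scenario("HiS-bi", M = 500L, n1 = 2000, n2 = 2000,
                      pi1 = 0.02, pi2 = 0.02, piC = 0.02)
  # zero effects: per-SNP regression estimates have variance ~ 1/n
  sc0 <- mrci_scenario("HiS-null", M = 400L, n1 = 2000, n2 = 2000,
                       pi1 = 0, pi2 = 0, piC = 0, h2_1 = 0, h2_2 = 0,
                       h2_C = 0, rho_cor = 0)
  iv0 <- simulate_individual_level(sc0, seed = 21)
  expect_lt(abs(var(iv0$tau_hat[, 1]) * 2000 - 1), 0.2)
  # single causal SNP, no LD: the regression estimate recovers beta
  sc1 <- mrci_scenario("HiS-uni", M = 300L, n1 = 4000, n2 = 4000,
                       pi1 = 1 / 300, pi2 = 0, piC = 0, h2_2 = 0, h2_C = 0,
                       rho_cor = 0, h2_1 = 0.05, block_size = 1L)
  iv1 <- simulate_individual_level(sc1, seed = 22)
  k <- which(iv1$component == "G1")
  expect_lt(abs(iv1$tau_hat[k, 1] - iv1$beta[k, 1]), 3 / sqrt(4000))
  # matched scenario: mean and variance of tau_hat agree across generators
  set.seed(23)
  iv <- simulate_individual_level(sc, seed = 23)
  ld <- build_ld_structure(sc$M, sc$block_size, sc$r, sc$tag_r2)
  sl <- mrci_simulate(sc, seed = 23, ld = ld)
  expect_lt(abs(mean(iv$tau_hat[, 1]) - mean(sl$tau1)), 3e-3)
  expect_lt(abs(var(iv$tau_hat[, 1]) / var(sl$tau1) - 1), 0.35)
  # oracle scale limits enforced
  expect_error(simulate_individual_level(
    mrci_scenario("HiS-bi", M = 10000L, n1 = 2000, n2 = 2000)), "restricted")
})

test_that("scenario registry round-trips through files", {
  reg <- mrci_scenarios()
  expect_true(all(c("LoS-bi-cor", "HiS-bi", "s2C-uni", "sC-null",
                    "small-bi") %in% reg$name))
  expect_error(mrci_scenario("nope"), "available")
  d <- mrci_simulate(mrci_scenario("HiS-bi", M = 500L, pi1 = 4e-3,
                                   pi2 = 4e-3, piC = 4e-3), seed = 31)
  pre <- withr::local_tempfile()
  write_dataset(d, pre)
  d2 <- read_dataset(pre)
  expect_equal(d2$tau1, d$tau1, tolerance = 1e-9)
  expect_equal(d2$tag_idx, d$tag_idx)
  expect_equal(mrci:::sample_sizes(d2), mrci:::sample_sizes(d))
  tr <- read_params(paste0(pre, "_truth.json"))
  expect_equal(as.numeric(tr), as.numeric(attr(d, "truth")))
})
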