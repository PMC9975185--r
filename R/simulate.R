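# Synthetic bivariate GWAS generator: block LD, four-component genetic
# architecture, reciprocal causal mixing, LD-induced marginal effects,
# sampling noise and sample-overlap covariance.

#' Simulation scenario registry
#'
#' Named presets for the simulation study conditions: low-polygenicity
#' (`LoS-*`, mixing proportions 1e-4) and high-polygenicity (`HiS-*`, 1e-3)
#' full-model scenarios with independent (`-ind`) or correlated (`-cor`,
#' pleiotropy correlation 0.1) pleiotropy; null / uni-directional /
#' bi-directional causation (`delta12`, `delta21` of (0,0), (0.1,0) and
#' (0.1,0.05)); sub-model scenarios `s2C-*` (no Y1-specific SNPs), `s12-*`
#' (no pleiotropic SNPs), `sC-*` (pleiotropic SNPs only); and a small-sample
#' preset (`small-bi`, n = 20,000). Heritability targets for present
#' components are 0.3 (trait-specific) and 0.1 (pleiotropic); per-SNP
#' direct-effect variances are derived as `h2 / (pi * M)`. High-polygenicity
#' presets carry correlated pleiotropy. Defaults are `M` = 30,000 SNPs and
#' n = 50,000 fully overlapping samples.
#'
#' @return tibble of scenario presets, one row per named scenario.
#' @export
mrci_scenarios <- function() {
  base <- function(name, pi, rho_cor, d12, d21, g1 = TRUE, g2 = TRUE, gc = TRUE,
                   n = 50000) {
    tibble(name = name,
           pi1 = if (g1) pi else 0, pi2 = if (g2) pi else 0,
           piC = if (gc) pi else 0,
           h2_1 = if (g1) 0.3 else 0, h2_2 = if (g2) 0.3 else 0,
           h2_C = if (gc) 0.1 else 0,
           rho_cor = if (gc) rho_cor else 0,
           delta12 = d12, delta21 = d21,
           M = 30000L, n1 = n, n2 = n, overlap = 1,
           a1 = 0, a2 = 0, block_size = 50L, r = 0.5, tag_r2 = 0.01)
  }
  dd <- list(null = c(0, 0), uni = c(0.1, 0), bi = c(0.1, 0.05))
  rows <- list()
  for (cz in names(dd)) {
    d <- dd[[cz]]
    rows <- c(rows, list(
      base(paste0("LoS-", cz, "-ind"), 1e-4, 0.0, d[1], d[2]),
      base(paste0("LoS-", cz, "-cor"), 1e-4, 0.1, d[1], d[2]),
      base(paste0("HiS-", cz), 1e-3, 0.1, d[1], d[2]),
      base(paste0("s2C-", cz), 1e-3, 0.1, d[1], d[2], g1 = FALSE),
      base(paste0("s12-", cz), 1e-3, 0.1, d[1], d[2], gc = FALSE),
      base(paste0("sC-", cz), 1e-3, 0.1, d[1], d[2], g1 = FALSE, g2 = FALSE)))
  }
  rows <- c(rows, list(base("small-bi", 1e-3, 0.1, 0.1, 0.05, n = 20000)))
  dplyr::bind_rows(rows)
}

#' Retrieve (and optionally override) a scenario preset
#'
#' @param name scenario name from [mrci_scenarios()].
#' @param ... named overrides of scenario fields (e.g. `M`, `n1`, `n2`).
#' @return a one-row scenario (list) with derived true parameters available
#'   through [scenario_params()].
#' @export
mrci_scenario <- function(name, ...) {
  reg <- mrci_scenarios()
  if (!name %in% reg$name)
    abort(paste0("unknown scenario '", name, "'; available: ",
                 paste(reg$name, collapse = ", ")))
  sc <- as.list(reg[reg$name == name, ])
  ov <- list(...)
  bad <- setdiff(names(ov), names(sc))
  if (length(bad)) abort(paste0("unknown scenario field(s): ", paste(bad, collapse = ", ")))
  sc[names(ov)] <- ov
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  for (h in c("pi1", "pi2", "piC"))
    if (sc[[h]] > 0 && sc[[h]] * sc$M < 1)
      abort(paste0("scenario invalid: ", h, " * M < 1"))
  if (abs(sc$delta12 * sc$delta21) >= 1) abort("|delta12 * delta21| must be < 1")
  sc
}

#' True model parameters implied by a scenario
#'
#' Converts heritability targets to per-SNP direct-effect variances
#' (`h2 / (pi * M)`), the pleiotropy correlation to a covariance, and the
#' overlap fraction to the error-covariance bias `rho0` (the total phenotypic
#' covariance implied by the structural model, scaled by
#' `overlap / sqrt(n1 * n2)`).
#'
#' @param scenario a scenario from [mrci_scenario()].
#' @return an [mrci_params()] vector of ground-truth parameters.
#' @export
scenario_params <- function(scenario) {
  sc <- scenario
  s1 <- if (sc$pi1 > 0) sc$h2_1 / (sc$pi1 * sc$M) else 0
  s2 <- if (sc$pi2 > 0) sc$h2_2 / (sc$pi2 * sc$M) else 0
  sC1 <- if (sc$piC > 0) sc$h2_C / (sc$piC * sc$M) else 0
  sC2 <- sC1
  rc <- sc$rho_cor * sqrt(sC1 * sC2)
  p <- mrci_params(pi1 = sc$pi1, pi2 = sc$pi2, piC = sc$piC,
                   sigma1_sq = s1, sigma2_sq = s2,
                   sigmaC1_sq = sC1, sigmaC2_sq = sC2, rhoC1C2 = rc,
                   delta12 = sc$delta12, delta21 = sc$delta21,
                   a1 = sc$a1, a2 = sc$a2)
  vy <- phenotype_covariance(sc)
  p["rho0"] <- sc$overlap * vy$cov12 / sqrt(sc$n1 * sc$n2)
  validate_params(p)
}

# Residual variances that standardize both phenotypes to unit variance under
# the structural equations, and the implied total phenotypic covariance.
phenotype_covariance <- function(scenario) {
  sc <- scenario
  d12 <- sc$delta12; d21 <- sc$delta21
  vD1 <- sc$h2_1 + sc$h2_C
  vD2 <- sc$h2_2 + sc$h2_C
  c12 <- sc$h2_C * sc$rho_cor
  q <- (1 - d12 * d21)^2
  A <- matrix(c(1, d21^2, d12^2, 1), 2, 2)
  u <- solve(A, c(q - 2 * d12 * c12, q - 2 * d21 * c12))
  ve <- u - c(vD1, vD2)
  if (any(ve <= 0))
    abort("scenario implies non-positive residual variance; reduce heritabilities")
  cov12 <- (d21 * u[1] + d12 * u[2] + (1 + d12 * d21) * c12) / q
  list(ve1 = ve[1], ve2 = ve[2], cov12 = cov12, vD1 = vD1, vD2 = vD2, c12 = c12)
}

#' Synthetic block LD structure
#'
#' Partitions `M` SNPs into blocks with within-block AR-1 correlation
#' `rho_ki = r^|i-k|` and no correlation across blocks. The LD score is
#' `l_k = sum_i rho_ki^2` over the block; the tagging set is all SNPs with
#' `rho_ki^2 >= tag_r2` (symmetric, self-inclusive).
#'
#' @param M number of SNPs.
#' @param block_size SNPs per block.
#' @param r AR-1 correlation between adjacent SNPs (0 <= r < 1).
#' @param tag_r2 squared-correlation threshold defining the tagging set.
#' @return list with `ld` (tibble `snp_id`, `ld_score`, `n_tagged`),
#'   `tag_idx` (list of index vectors), and the block settings.
#' @export
build_ld_structure <- function(M, block_size = 50, r = 0.5, tag_r2 = 0.01) {
  stopifnot(M >= 1, block_size >= 1, r >= 0, r < 1, tag_r2 > 0, tag_r2 <= 1)
  B <- as.integer(block_size)
  dmax <- if (r == 0) 0L else max(0L, as.integer(floor(log(tag_r2) / (2 * log(r)))))
  block <- (seq_len(M) - 1L) %/% B
  pos <- (seq_len(M) - 1L) %% B + 1L
  blen <- as.integer(pmin((block + 1L) * B, M) - block * B)
  # ld score within the (possibly partial) block
  r2pow <- r^(2 * (0:(B - 1)))
  ld_score <- vapply(seq_len(M), function(i) {
    sum(r2pow[abs(seq_len(blen[i]) - pos[i]) + 1L])
  }, numeric(1))
  lo <- pmax(1L, pos - dmax)
  hi <- pmin(blen, pos + dmax)
  n_tagged <- hi - lo + 1L
  offs <- block * B
  tag_idx <- lapply(seq_len(M), function(i) (offs[i] + lo[i]):(offs[i] + hi[i]))
  list(ld = tibble(snp_id = paste0("snp", seq_len(M)),
                   ld_score = ld_score, n_tagged = as.integer(n_tagged)),
       tag_idx = tag_idx, block = block, pos = pos, blen = blen,
       block_size = B, r = r, tag_r2 = tag_r2, M = as.integer(M))
}

#' Assign SNP components and draw direct effects
#'
#' Exactly `round(pi_h * M)` SNPs are sampled without replacement for each
#' active component; trait-specific direct effects are drawn from
#' `N(0, sigma^2)` and pleiotropic pairs from the bivariate normal with
#' covariance `rhoC1C2`. Null SNPs get (0, 0).
#'
#' @param scenario a scenario from [mrci_scenario()].
#' @return list with `component` (factor of `G0`,`G1`,`G2`,`GC`) and
#'   `gamma` (M x 2 matrix of direct effects). Uses the current RNG stream.
#' @export
assign_components_and_effects <- function(scenario) {
  sc <- scenario
  p <- scenario_params(sc)
  M <- sc$M
  k1 <- round(sc$pi1 * M); k2 <- round(sc$pi2 * M); kC <- round(sc$piC * M)
  idx <- sample.int(M, k1 + k2 + kC)
  component <- rep("G0", M)
  i1 <- idx[seq_len(k1)]
  i2 <- idx[k1 + seq_len(k2)]
  iC <- idx[k1 + k2 + seq_len(kC)]
  component[i1] <- "G1"; component[i2] <- "G2"; component[iC] <- "GC"
  gamma <- matrix(0, M, 2)
  if (k1 > 0) gamma[i1, 1] <- rnorm(k1, 0, sqrt(p["sigma1_sq"]))
  if (k2 > 0) gamma[i2, 2] <- rnorm(k2, 0, sqrt(p["sigma2_sq"]))
  if (kC > 0) {
    S <- matrix(c(p["sigmaC1_sq"], p["rhoC1C2"], p["rhoC1C2"], p["sigmaC2_sq"]), 2, 2)
    L <- chol(S + diag(1e-14, 2))
    gamma[iC, ] <- matrix(rnorm(2 * kC), kC, 2) %*% L
  }
  list(component = factor(component, levels = c("G0", "G1", "G2", "GC")),
       gamma = gamma)
}

#' Direct to joint effect sizes
#'
#' Applies the reciprocal-causation mixing `beta = [I - Delta]^{-1} gamma`:
#' `beta1 = (gamma1 + delta12 * gamma2) / (1 - delta12*delta21)` and
#' symmetrically for `beta2`.
#'
#' @param gamma M x 2 matrix of direct effects.
#' @param delta12,delta21 reciprocal causal effects, `|delta12*delta21| < 1`.
#' @return M x 2 matrix of joint effects.
#' @export
direct_to_joint <- function(gamma, delta12, delta21) {
  if (abs(delta12 * delta21) >= 1) abort("|delta12 * delta21| must be < 1")
  den <- 1 - delta12 * delta21
  cbind((gamma[, 1] + delta12 * gamma[, 2]) / den,
        (gamma[, 2] + delta21 * gamma[, 1]) / den)
}

block_correlation <- function(bl, r) {
  outer(seq_len(bl), seq_len(bl), function(i, j) r^abs(i - j))
}

#' Simulate marginal effect estimates
#'
#' True marginal effects are `tau = R beta` per phenotype, with `R` the
#' block LD correlation; estimates add bivariate sampling noise with
#' variances `1/n + a` and covariance `rho0`, correlated across SNPs within
#' a block through `R` (matrix-normal noise with row covariance `R`).
#'
#' @param scenario a scenario from [mrci_scenario()].
#' @param ld LD structure from [build_ld_structure()].
#' @param beta M x 2 matrix of joint effects.
#' @return an [mrci_data()] dataset. Uses the current RNG stream.
#' @export
simulate_marginal_estimates <- function(scenario, ld, beta) {
  sc <- scenario
  p <- scenario_params(sc)
  M <- ld$M
  stopifnot(nrow(beta) == M)
  Se <- matrix(c(1 / sc$n1 + sc$a1, p["rho0"], p["rho0"], 1 / sc$n2 + sc$a2), 2, 2)
  Ls <- chol(Se)
  tau <- matrix(0, M, 2)
  noise <- matrix(rnorm(2 * M), M, 2) %*% Ls
  ublen <- unique(ld$blen)
  Rb <- lapply(setNames(ublen, ublen), function(b) {
    R <- block_correlation(b, ld$r)
    list(R = R, L = t(chol(R)))
  })
  starts <- which(ld$pos == 1L)
  for (s in starts) {
    b <- ld$blen[s]
    rows <- s:(s + b - 1L)
    Rl <- Rb[[as.character(b)]]
    tau[rows, ] <- Rl$R %*% beta[rows, , drop = FALSE]
    noise[rows, ] <- Rl$L %*% noise[rows, , drop = FALSE]
  }
  tau_hat <- tau + noise
  mrci_data(snp_id = ld$ld$snp_id, tau1 = tau_hat[, 1], tau2 = tau_hat[, 2],
            ld_score = ld$ld$ld_score, n_tagged = ld$ld$n_tagged,
            tag_idx = ld$tag_idx, n1 = sc$n1, n2 = sc$n2)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: builds the LD structure, assigns components, draws
#' direct effects, converts them to joint effects and simulates marginal
#' effect estimates. Deterministic given `seed`.
#'
#' @param scenario a scenario name or a scenario from [mrci_scenario()].
#' @param seed integer seed.
#' @param ld optional prebuilt LD structure (reused across replicates).
#' @return an [mrci_data()] dataset with attributes `truth` (true
#'   [mrci_params()]), `component`, `beta` and `scenario`.
#' @export
mrci_simulate <- function(scenario, seed = 1, ld = NULL) {
  if (is.character(scenario)) scenario <- mrci_scenario(scenario)
  sc <- scenario
  set.seed(seed)
  if (is.null(ld)) ld <- build_ld_structure(sc$M, sc$block_size, sc$r, sc$tag_r2)
  ae <- assign_components_and_effects(sc)
  beta <- direct_to_joint(ae$gamma, sc$delta12, sc$delta21)
  d <- simulate_marginal_estimates(sc, ld, beta)
  attr(d, "truth") <- scenario_params(sc)
  attr(d, "component") <- ae$component
  attr(d, "beta") <- beta
  attr(d, "scenario") <- sc
  d
}

#' Small-scale individual-level simulator (oracle)
#'
#' Generates genotypes from a block-multivariate-normal liability thresholded
#' to {0, 1, 2} under Hardy-Weinberg with uniform MAF in [0.05, 0.5],
#' standardizes them, builds the phenotypes from the structural equations
#' (direct effects plus residuals scaled so each phenotype has unit
#' variance), and computes per-SNP least-squares marginal estimates. Serves
#' as the ground-truth oracle for the summary-level generator; restricted to
#' `M <= 5000` SNPs and `n <= 5000` individuals.
#'
#' @param scenario a scenario from [mrci_scenario()] with small `M`, `n1 = n2`.
#' @param seed integer seed.
#' @return list with `tau_hat` (M x 2), `beta`, `gamma`, `component`,
#'   `genetic` (n x 2 total genetic values), `Y` (n x 2) and the LD structure.
#' @export
simulate_individual_level <- function(scenario, seed = 1) {
  sc <- scenario
  n <- sc$n1
  if (sc$n1 != sc$n2) abort("individual-level oracle requires n1 == n2")
  if (sc$M > 5000 || n > 5000)
    abort("individual-level oracle is restricted to M <= 5000 and n <= 5000")
  set.seed(seed)
  ld <- build_ld_structure(sc$M, sc$block_size, sc$r, sc$tag_r2)
  ae <- assign_components_and_effects(sc)
  beta <- direct_to_joint(ae$gamma, sc$delta12, sc$delta21)
  maf <- runif(sc$M, 0.05, 0.5)
  X <- matrix(0, n, sc$M)
  starts <- which(ld$pos == 1L)
  for (s in starts) {
    b <- ld$blen[s]
    rows <- s:(s + b - 1L)
    L <- t(chol(block_correlation(b, ld$r)))
    thr <- qnorm(1 - maf[rows])
    hap1 <- t(L %*% matrix(rnorm(b * n), b, n)) > rep(thr, each = n)
    hap2 <- t(L %*% matrix(rnorm(b * n), b, n)) > rep(thr, each = n)
    X[, rows] <- hap1 + hap2
  }
  X <- scale(X)
  X[is.nan(X)] <- 0
  vy <- phenotype_covariance(sc)
  D <- X %*% ae$gamma
  e <- cbind(rnorm(n, 0, sqrt(vy$ve1)), rnorm(n, 0, sqrt(vy$ve2)))
  Ainv <- solve(matrix(c(1, -sc$delta21, -sc$delta12, 1), 2, 2))
  Y <- (D + e) %*% t(Ainv)
  genetic <- X %*% beta
  tau_hat <- crossprod(X, Y) / n
  list(tau_hat = tau_hat, beta = beta, gamma = ae$gamma,
       component = ae$component, genetic = genetic, Y = Y, ld = ld, maf = maf)
}
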