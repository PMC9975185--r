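# Five-model fitting, composite-likelihood AIC, weight optimization,
# averaged estimates and final-model selection.

#' Composite-likelihood AIC
#'
#' `-2 CL + 2 trace(I^-1 J)`: the effective number of parameters replaces
#' the free-parameter count because the composite likelihood is not a true
#' likelihood under LD. Falls back to the free-parameter count (with a
#' warning) when the trace is not finite.
#'
#' @param fit an `mrci_fit`.
#' @param sandwich the matching `mrci_sandwich`.
#' @return the information-criterion score (smaller is better).
#' @export
cl_aic <- function(fit, sandwich) {
  keep <- sandwich$kept
  pen <- tryCatch({
    Ik <- sandwich$I[keep, keep, drop = FALSE]
    Jk <- sandwich$J[keep, keep, drop = FALSE]
    sum(diag(solve(Ik, Jk)))
  }, error = function(e) NA_real_)
  if (!is.finite(pen)) {
    warn("effective-dof trace not finite; using free-parameter count")
    pen <- length(sandwich$free)
  }
  -2 * fit$cl + 2 * pen
}

#' Akaike weights from composite-likelihood AIC scores
#'
#' @param cl_aics numeric vector of [cl_aic()] scores.
#' @return weights `exp(-Delta/2) / sum(exp(-Delta/2))`.
#' @export
initial_weights <- function(cl_aics) {
  stopifnot(all(is.finite(cl_aics)))
  d <- cl_aics - min(cl_aics)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Weighted-average estimates across the model set
#'
#' `theta_ma_j = sum_s w_s theta_j_s`, with `theta_j_s = 0` when parameter j
#' is absent from model s; the averaged variance is
#' `(sum_s w_s sqrt(var_j_s + (theta_j_s - theta_ma_j)^2))^2`, with
#' `var_j_s = 0` for absent parameters.
#'
#' @param fits list of `mrci_fit` objects.
#' @param weights simplex weights, one per fit.
#' @param sandwiches optional list of matching `mrci_sandwich` objects; if
#'   omitted the averaged variances are not computed.
#' @return list with `params` (averaged [mrci_params()]) and `variance`
#'   (named vector, `NA` when no sandwich provided).
#' @export
averaged_estimates <- function(fits, weights, sandwiches = NULL) {
  stopifnot(length(fits) == length(weights),
            abs(sum(weights) - 1) < 1e-6, all(weights >= -1e-12))
  th <- vapply(fits, function(f) as.numeric(f$params), numeric(length(.PARAM_NAMES)))
  rownames(th) <- .PARAM_NAMES
  th_ma <- drop(th %*% weights)
  vr <- matrix(0, length(.PARAM_NAMES), length(fits),
               dimnames = list(.PARAM_NAMES, NULL))
  if (!is.null(sandwiches)) {
    for (s in seq_along(fits)) {
      sw <- sandwiches[[s]]
      v <- setNames(sw$se^2, sw$free)
      v[is.na(v)] <- 0
      vr[names(v), s] <- v
    }
  }
  var_ma <- vapply(seq_along(.PARAM_NAMES), function(j) {
    sum(weights * sqrt(vr[j, ] + (th[j, ] - th_ma[j])^2))^2
  }, numeric(1))
  p <- do.call(mrci_params, as.list(th_ma))
  bound <- sqrt(p[["sigmaC1_sq"]] * p[["sigmaC2_sq"]])
  if (abs(p[["rhoC1C2"]]) > bound) p["rhoC1C2"] <- sign(p[["rhoC1C2"]]) * bound
  list(params = p, variance = setNames(var_ma, .PARAM_NAMES))
}

#' Optimize model-averaging weights on the composite likelihood
#'
#' Nelder-Mead over softmax-parameterized weights maximizing the composite
#' likelihood of the averaged parameter vector, initialized from the Akaike
#' weights (plus perturbed restarts). Never returns a weight vector whose
#' averaged likelihood is below the initialization.
#'
#' @param data an [mrci_data()] dataset.
#' @param fits list of `mrci_fit` objects.
#' @param init_weights starting simplex weights.
#' @param config a [fit_config()].
#' @return list with `weights`, the attained `cl` and the initial `cl0`.
#' @export
optimize_weights <- function(data, fits, init_weights, config = fit_config()) {
  data <- with_groups(data)
  plan <- enumeration_plan(c("G1", "G2", "GC"), config$c_max,
                           max(data$n_tagged), config$t_max)
  softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  cl_of <- function(w) {
    p <- averaged_estimates(fits, w)$params
    res <- tryCatch(cl_eval(data, p, plan), error = function(e) NULL)
    if (is.null(res) || !is.finite(res$cl)) return(-1e10)
    res$cl
  }
  z0 <- log(pmax(init_weights, 1e-8))
  z0 <- z0 - mean(z0)
  cl0 <- cl_of(init_weights)
  best <- list(z = z0, cl = cl0)
  set.seed(config$seed + 211L)
  for (rs in seq_len(max(1, config$weights_restarts))) {
    z <- if (rs == 1) z0 else z0 + rnorm(length(z0), 0, 0.5)
    opt <- optim(z, function(z) -cl_of(softmax(z)), method = "Nelder-Mead",
                 control = list(maxit = config$weights_max_eval, reltol = 1e-12))
    if (-opt$value > best$cl) best <- list(z = opt$par, cl = -opt$value)
  }
  w <- softmax(best$z)
  if (best$cl < cl0 - config$nm_fatol) {
    warn("weight optimization failed to improve; returning initial weights")
    w <- init_weights
    best$cl <- cl0
  }
  list(weights = w / sum(w), cl = best$cl, cl0 = cl0)
}

#' Final-model selection
#'
#' The averaged model is selected if (1) its composite likelihood exceeds
#' the full model's, or (2) for either trait the full-model trait-specific
#' heritability estimate (`K * pi_t * sigma_t^2`) is below 0.05 while the
#' corresponding mixing proportion is not significant (sandwich Wald p >=
#' 0.05). Otherwise the full model is kept.
#'
#' @param full_fit the full-model `mrci_fit`.
#' @param full_sandwich its `mrci_sandwich`.
#' @param averaged_cl composite likelihood of the averaged parameters.
#' @param K number of analysis SNPs.
#' @return list with `choice` (`"averaged"` or `"full"`) and `reasons`.
#' @export
select_final_model <- function(full_fit, full_sandwich, averaged_cl, K) {
  reasons <- character(0)
  if (averaged_cl > full_fit$cl)
    reasons <- c(reasons, "averaged CL exceeds full-model CL")
  p <- full_fit$params
  pv <- setNames(full_sandwich$p, full_sandwich$free)
  for (t in 1:2) {
    pit <- p[[paste0("pi", t)]]
    st <- p[[paste0("sigma", t, "_sq")]]
    h2 <- K * pit * st
    pp <- pv[[paste0("pi", t)]]
    insig <- is.na(pp) || pp >= 0.05
    if (h2 < 0.05 && insig)
      reasons <- c(reasons, paste0("trait ", t, " specific heritability ",
                                   signif(h2, 3), " < 0.05 with non-significant pi", t))
  }
  list(choice = if (length(reasons)) "averaged" else "full", reasons = reasons)
}

#' Full reciprocal-causation analysis
#'
#' Fits the full model and the four sub-models, computes sandwich variances
#' and composite-likelihood AIC for each, optimizes averaging weights,
#' forms the averaged estimates, applies the final-model selection rule, and
#' reports the final reciprocal causal effects with standard errors, Wald
#' tests and the genetic correlation.
#'
#' @param data an [mrci_data()] dataset.
#' @param config a [fit_config()].
#' @return object of class `mrci_result`.
#' @export
mrci_analyze <- function(data, config = fit_config()) {
  data <- with_groups(data)
  models <- names(.SUBMODELS)
  fits <- vector("list", length(models))
  names(fits) <- models
  fits$s_12C <- fit_model(data, "s_12C", config)
  for (m in setdiff(models, "s_12C")) {
    # warm start each sub-model from the full-model estimates with the
    # absent components pinned at zero
    cfg <- config
    cfg$init <- pin_inactive(fits$s_12C$params, submodel_spec(m))
    fits[[m]] <- fit_model(data, m, cfg)
  }
  sws <- lapply(fits, function(f) sandwich_covariance(data, f, h = config$h))
  aics <- vapply(seq_along(fits), function(i) cl_aic(fits[[i]], sws[[i]]), numeric(1))
  names(aics) <- models
  w0 <- initial_weights(aics)
  wopt <- optimize_weights(data, fits, w0, config)
  avg <- averaged_estimates(fits, wopt$weights, sws)
  sel <- select_final_model(fits$s_12C, sws$s_12C, wopt$cl, nrow(data))

  if (sel$choice == "averaged") {
    fin_par <- avg$params
    fin_se <- sqrt(pmax(avg$variance, 0))
    fin_cov <- diag(avg$variance)
    dimnames(fin_cov) <- list(.PARAM_NAMES, .PARAM_NAMES)
    fin_cl <- wopt$cl
  } else {
    fin_par <- fits$s_12C$params
    fin_se <- setNames(rep(NA_real_, length(.PARAM_NAMES)), .PARAM_NAMES)
    fin_se[sws$s_12C$free] <- sws$s_12C$se
    fin_cov <- matrix(0, length(.PARAM_NAMES), length(.PARAM_NAMES),
                      dimnames = list(.PARAM_NAMES, .PARAM_NAMES))
    fin_cov[sws$s_12C$free, sws$s_12C$free] <- sws$s_12C$cov
    fin_cov[is.na(fin_cov)] <- 0
    fin_cl <- fits$s_12C$cl
  }
  est <- setNames(as.numeric(fin_par), .PARAM_NAMES)
  chi2 <- ifelse(is.na(fin_se) | fin_se <= 0, NA_real_, (est / fin_se)^2)
  pval <- pchisq(chi2, df = 1, lower.tail = FALSE)
  final <- tibble(term = .PARAM_NAMES, estimate = est, se = unname(fin_se),
                  chi2 = unname(chi2), p = unname(pval))
  rg <- genetic_correlation(fin_par)
  rg_var <- tryCatch(rg_variance(fin_par, fin_cov), error = function(e) NA_real_)

  structure(list(fits = fits, sandwiches = sws, cl_aic = aics,
                 weights_init = w0, weights = setNames(wopt$weights, models),
                 averaged = avg, averaged_cl = wopt$cl,
                 selection = sel, final = final, final_cl = fin_cl,
                 rg = as.numeric(rg), rg_se = sqrt(max(rg_var, 0)),
                 K = nrow(data), n1 = attr(data, "n1"), n2 = attr(data, "n2"),
                 config = config),
            class = "mrci_result")
}

#' @export
print.mrci_result <- function(x, ...) {
  cat("<mrci_result>", x$K, "SNPs | final model:", x$selection$choice, "\n")
  d <- x$final[x$final$term %in% c("delta12", "delta21"), ]
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %s = %+0.4f (se %0.4f, p = %0.3g)\n",
                d$term[i], d$estimate[i], d$se[i], d$p[i]))
  cat(sprintf("  rg = %+0.3f (se %0.3f)\n", x$rg, x$rg_se))
  invisible(x)
}
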