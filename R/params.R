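# Parameter vector, sub-model definitions and coordinate transforms.

.PARAM_NAMES <- c("pi1", "pi2", "piC",
                  "sigma1_sq", "sigma2_sq", "sigmaC1_sq", "sigmaC2_sq",
                  "rhoC1C2", "delta12", "delta21", "a1", "a2", "rho0")

# parameters attached to each mixture component; the remainder
# (deltas, inflation, overlap) are always free
.COMPONENT_PARAMS <- list(
  G1 = c("pi1", "sigma1_sq"),
  G2 = c("pi2", "sigma2_sq"),
  GC = c("piC", "sigmaC1_sq", "sigmaC2_sq", "rhoC1C2"))

.SUBMODELS <- list(
  s_12C = c("G1", "G2", "GC"),
  s_2C  = c("G2", "GC"),
  s_1C  = c("G1", "GC"),
  s_12  = c("G1", "G2"),
  s_C   = c("GC"))

#' Model parameter vector
#'
#' Builds the full parameter vector of the reciprocal-causation mixture model:
#' mixing proportions of the trait-specific and pleiotropic SNP components
#' (`pi1`, `pi2`, `piC`; the null proportion `pi0 = 1 - pi1 - pi2 - piC` is
#' implied), per-SNP direct-effect variances (`sigma1_sq`, `sigma2_sq`,
#' `sigmaC1_sq`, `sigmaC2_sq`), the covariance of the two pleiotropic direct
#' effects (`rhoC1C2`), the reciprocal causal effects (`delta12`: Y2 -> Y1,
#' `delta21`: Y1 -> Y2, both constrained to (-1, 1)), variance inflation
#' terms (`a1`, `a2`, e.g. residual population stratification) and the
#' covariance bias from sample overlap (`rho0`).
#'
#' @param ... named parameter values; unnamed parameters default to 0.
#' @return A named numeric vector of class `mrci_params`.
#' @export
#' @examples
#' mrci_params(pi1 = 1e-3, sigma1_sq = 1e-2, delta12 = 0.1)
mrci_params <- function(...) {
  vals <- c(...)
  p <- setNames(numeric(length(.PARAM_NAMES)), .PARAM_NAMES)
  if (length(vals)) {
    bad <- setdiff(names(vals), .PARAM_NAMES)
    if (length(bad)) abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    p[names(vals)] <- vals
  }
  structure(p, class = c("mrci_params", "numeric"))
}

#' @export
print.mrci_params <- function(x, ...) {
  cat("<mrci_params>\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

as_mrci_params <- function(x) {
  if (inherits(x, "mrci_params")) return(x)
  stopifnot(is.numeric(x), all(.PARAM_NAMES %in% names(x)))
  structure(x[.PARAM_NAMES], class = c("mrci_params", "numeric"))
}

#' Validate a parameter vector
#'
#' Checks the admissibility constraints: proportions in the simplex
#' (implied `pi0 >= 0`), non-negative variances and inflation terms,
#' `|rhoC1C2| <= sqrt(sigmaC1_sq * sigmaC2_sq)` and `|delta12 * delta21| < 1`.
#'
#' @param params an [mrci_params()] vector.
#' @return `params`, invisibly; errors if inadmissible.
#' @export
validate_params <- function(params) {
  p <- as_mrci_params(params)
  pis <- p[c("pi1", "pi2", "piC")]
  if (any(pis < 0) || sum(pis) > 1 + 1e-12)
    abort("mixing proportions must be non-negative with pi0 = 1 - sum(pi) >= 0")
  if (any(p[c("sigma1_sq", "sigma2_sq", "sigmaC1_sq", "sigmaC2_sq", "a1", "a2")] < 0))
    abort("variances and inflation terms must be non-negative")
  bound <- sqrt(p["sigmaC1_sq"] * p["sigmaC2_sq"])
  if (abs(p["rhoC1C2"]) > bound + 1e-12)
    abort("|rhoC1C2| must not exceed sqrt(sigmaC1_sq * sigmaC2_sq)")
  if (abs(p["delta12"] * p["delta21"]) >= 1)
    abort("|delta12 * delta21| must be < 1")
  invisible(p)
}

#' Sub-model specification
#'
#' The model set comprises the full model `s_12C` and four sub-models in
#' which one or two SNP components are absent: `s_2C` (no Y1-specific SNPs),
#' `s_1C` (no Y2-specific SNPs), `s_12` (no pleiotropic SNPs) and `s_C`
#' (pleiotropic SNPs only). Parameters of absent components are pinned at
#' zero and excluded from the free-parameter count.
#'
#' @param id one of `"s_12C"`, `"s_2C"`, `"s_1C"`, `"s_12"`, `"s_C"`.
#' @return list with the id, active components, and free parameter names.
#' @export
submodel_spec <- function(id = names(.SUBMODELS)) {
  id <- match.arg(id)
  active <- .SUBMODELS[[id]]
  free <- c(unlist(.COMPONENT_PARAMS[active], use.names = FALSE),
            "delta12", "delta21", "a1", "a2", "rho0")
  free <- .PARAM_NAMES[.PARAM_NAMES %in% free]
  list(id = id, active = active, free = free)
}

pin_inactive <- function(params, spec) {
  p <- as_mrci_params(params)
  p[setdiff(.PARAM_NAMES, spec$free)] <- 0
  p
}

# ---- unconstrained coordinates ------------------------------------------
# Variances, inflation terms and mixing proportions are log-transformed;
# causal effects are atanh-transformed onto (-1, 1); the pleiotropy
# covariance is parameterised through its correlation (atanh) so the
# admissibility bound holds by construction; rho0 is rescaled by
# sqrt(n1 * n2) so its unconstrained coordinate is O(1).

.LOG_PARAMS <- c("pi1", "pi2", "piC", "sigma1_sq", "sigma2_sq",
                 "sigmaC1_sq", "sigmaC2_sq", "a1", "a2")
.TANH_PARAMS <- c("delta12", "delta21")

theta_to_x <- function(params, free, nscale) {
  p <- as_mrci_params(params)
  x <- setNames(numeric(length(free)), free)
  for (nm in free) {
    v <- unname(p[nm])
    x[nm] <- switch(nm,
      rhoC1C2 = {
        b <- sqrt(p["sigmaC1_sq"] * p["sigmaC2_sq"])
        r <- if (b > 0) max(-0.999, min(0.999, v / b)) else 0
        atanh(r)
      },
      rho0 = v * nscale,
      if (nm %in% .LOG_PARAMS) log(max(v, 1e-12))
      else atanh(max(-1 + 1e-10, min(1 - 1e-10, v))))
  }
  x
}

x_to_theta <- function(x, free, base_params, nscale) {
  p <- as_mrci_params(base_params)
  for (nm in setdiff(free, "rhoC1C2")) {
    v <- unname(x[nm])
    p[nm] <- switch(nm,
      rho0 = v / nscale,
      if (nm %in% .LOG_PARAMS) exp(v) else tanh(v))
  }
  if ("rhoC1C2" %in% free) {
    b <- sqrt(p["sigmaC1_sq"] * p["sigmaC2_sq"])
    p["rhoC1C2"] <- tanh(unname(x["rhoC1C2"])) * b
  }
  p
}

# Jacobian d theta / d x at x (p x p, rows/cols ordered as `free`).
# Diagonal except the rhoC1C2 row, which picks up the dependence of the
# admissibility bound on the two pleiotropic variances.
transform_jacobian <- function(params, free, nscale) {
  p <- as_mrci_params(params)
  J <- matrix(0, length(free), length(free), dimnames = list(free, free))
  for (nm in free) {
    J[nm, nm] <- switch(nm,
      rhoC1C2 = {
        b <- sqrt(p["sigmaC1_sq"] * p["sigmaC2_sq"])
        r <- if (b > 0) p["rhoC1C2"] / b else 0
        (1 - r^2) * b
      },
      rho0 = 1 / nscale,
      if (nm %in% .LOG_PARAMS) max(unname(p[nm]), 1e-12)
      else 1 - unname(p[nm])^2)
  }
  if ("rhoC1C2" %in% free) {
    for (snm in intersect(c("sigmaC1_sq", "sigmaC2_sq"), free))
      J["rhoC1C2", snm] <- unname(p["rhoC1C2"]) / 2
  }
  J
}

#' Serialize / deserialize parameters
#'
#' Flat key-value JSON with fixed key names, plus the sub-model mask.
#'
#' @param params an [mrci_params()] vector.
#' @param submodel sub-model id (see [submodel_spec()]).
#' @param path file path; if `NULL`, the JSON string is returned.
#' @export
write_params <- function(params, submodel = "s_12C", path = NULL) {
  p <- as_mrci_params(params)
  obj <- c(as.list(setNames(as.numeric(p), names(p))), list(submodel = submodel))
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(mrci_params, obj[.PARAM_NAMES])
}
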