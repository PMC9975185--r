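# broom-style tidiers and ggplot2 autoplot methods.

#' @export
tidy.mrci_fit <- function(x, sandwich = NULL, ...) {
  out <- tibble(term = x$spec$free,
                estimate = as.numeric(x$params[x$spec$free]))
  if (!is.null(sandwich)) {
    out$std.error <- unname(sandwich$se)
    out$statistic <- unname(sandwich$chi2)
    out$p.value <- unname(sandwich$p)
  }
  out
}

#' @export
glance.mrci_fit <- function(x, ...) {
  tibble(submodel = x$submodel, cl = x$cl, n_iter = x$n_iter,
         converged = x$converged, clamp_count = x$clamp_count, K = x$K)
}

#' @export
tidy.mrci_result <- function(x, ...) {
  rename(x$final, std.error = "se", statistic = "chi2", p.value = "p")
}

#' @export
glance.mrci_result <- function(x, ...) {
  tibble(final_model = x$selection$choice, cl = x$final_cl,
         rg = x$rg, rg_se = x$rg_se, K = x$K, n1 = x$n1, n2 = x$n2)
}

#' Scatterplot of standardized effect estimates
#'
#' Bivariate scatter of the per-SNP standardized marginal effect estimates,
#' coloured by the simulated component labels when present.
#'
#' @param object an [mrci_data()] dataset.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mrci_data <- function(object, ...) {
  df <- tibble(tau1 = object$tau1, tau2 = object$tau2)
  comp <- attr(object, "component")
  if (!is.null(comp)) {
    df$component <- comp
    df <- df[order(df$component != "G0"), ]  # draw null SNPs underneath
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$tau1, .data$tau2,
                                          colour = .data$component)) +
      ggplot2::scale_colour_manual(values = c(G0 = "grey70", G1 = "#d73027",
                                              G2 = "#fc8d59", GC = "#1a9850"))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$tau1, .data$tau2))
  }
  p + ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "standardized effect, phenotype 1",
                  y = "standardized effect, phenotype 2") +
    ggplot2::theme_minimal()
}

#' Forest-style plot of the final causal estimates
#'
#' Point estimates with 95% Wald intervals for the reciprocal causal
#' effects, alongside the per-model estimates of the model set.
#'
#' @param object an `mrci_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mrci_result <- function(object, ...) {
  per_model <- bind_rows(lapply(names(object$fits), function(m) {
    f <- object$fits[[m]]
    tibble(model = m, term = c("delta12", "delta21"),
           estimate = as.numeric(f$params[c("delta12", "delta21")]),
           se = NA_real_)
  }))
  fin <- object$final[object$final$term %in% c("delta12", "delta21"), ]
  fin <- tibble(model = "final", term = fin$term, estimate = fin$estimate,
                se = fin$se)
  df <- bind_rows(per_model, fin)
  df$model <- factor(df$model, levels = c(names(object$fits), "final"))
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                   xmax = .data$estimate + 1.96 * .data$se),
      height = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~term) +
    ggplot2::labs(x = "causal effect estimate", y = NULL) +
    ggplot2::theme_minimal()
}
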