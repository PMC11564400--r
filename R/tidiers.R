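# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_pointrange geom_col geom_hline
#'   coord_flip labs facet_wrap
#' @export
ggplot2::autoplot

#' Tidy a fitted twin model
#'
#' One row per free parameter with its estimate, Wald standard error,
#' z statistic, two-sided p value and 95% confidence interval.
#'
#' @param x a `twin_fit` object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.twin_fit <- function(x, ...) {
  wald_tests(x)
}

#' One-row summary of a fitted twin model
#'
#' @param x a `twin_fit` object.
#' @param ... unused.
#' @return a tibble with the deviance, parameter count, AIC, convergence and
#'   identification flags and per-group pair counts.
#' @export
glance.twin_fit <- function(x, ...) {
  tibble::tibble(family = x$spec$family, minus2ll = x$minus2ll, k = x$k,
                 AIC = x$AIC, converged = x$converged,
                 identified = x$identified,
                 n_mz = unname(x$n_pairs["MZ"]), n_dz = unname(x$n_pairs["DZ"]))
}

#' Plot parameter estimates of a fitted twin model
#'
#' Point estimates with 95% Wald intervals, grouped by parameter class.
#'
#' @param object a `twin_fit` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.twin_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$term, y = .data$estimate,
                ymin = .data$conf.low, ymax = .data$conf.high)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_pointrange() +
    coord_flip() +
    facet_wrap(~class, scales = "free_y") +
    labs(x = NULL, y = "estimate (95% Wald CI)",
         title = paste0(object$spec$family, " fit"))
}

#' Plot standardized variance components
#'
#' @param object a `twin_varcomp` tibble from [standardized_ace()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.twin_varcomp <- function(object, ...) {
  ggplot(object, aes(x = .data$variable, y = .data$estimate,
                     fill = .data$component)) +
    geom_col(position = "stack") +
    labs(x = NULL, y = "share of variance",
         title = "Standardized ACE variance components")
}

#' Plot a trek decomposition of a cross covariance
#'
#' @param object a `twin_decomposition` from [decompose_cross_covariance()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.twin_decomposition <- function(object, ...) {
  ggplot(object, aes(x = .data$group, y = .data$percent)) +
    geom_col() +
    geom_hline(yintercept = 0) +
    coord_flip() +
    labs(x = NULL, y = "% of model-implied covariance",
         title = paste0("Treks from ", attr(object, "from"), " to ",
                        attr(object, "to")))
}

#' @export
print.twin_decomposition <- function(x, ...) {
  cat("Trek decomposition of cov(", attr(x, "from"), ", ", attr(x, "to"),
      ") = ", format(attr(x, "implied"), digits = 6), "\n", sep = "")
  NextMethod()
}
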