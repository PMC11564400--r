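# Model comparison, Wald-based pruning, standardized variance components and
# bivariate covariance shares.

#' Chi-square difference and AIC comparison of nested fits
#'
#' Compares a restricted model against the full model it nests in:
#' \eqn{\Delta\chi^2 = (-2\ln L)_{restricted} - (-2\ln L)_{full}} referred to
#' a chi-square distribution on the difference in free parameters, plus the
#' AIC preference. Nesting is checked by parameter-name subset.
#'
#' @param restricted,full `twin_fit` objects (see [fit_twin_model()]).
#' @return a one-row tibble with `delta_chisq`, `delta_df`, `p_value`,
#'   `aic_restricted`, `aic_full`, `delta_aic` and `preferred`.
#' @examples
#' # arithmetic of the chi-square reference distribution
#' pchisq(6.95, df = 4, lower.tail = FALSE)  # ~0.14
#' @export
compare_models <- function(restricted, full) {
  stopifnot(inherits(restricted, "twin_fit"), inherits(full, "twin_fit"))
  extra <- setdiff(restricted$spec$params$param, full$spec$params$param)
  if (length(extra)) {
    abort(paste0("restricted model has parameters absent from the full ",
                 "model (not nested): ", paste(extra, collapse = ", ")))
  }
  dchi <- restricted$minus2ll - full$minus2ll
  ddf <- full$k - restricted$k
  if (ddf < 0) abort("delta df is negative; models passed in wrong order?")
  if (dchi < -1e-6) {
    abort(paste0("restricted deviance is below the full model's (",
                 format(dchi), "); suspected non-convergence"))
  }
  dchi <- max(dchi, 0)
  p <- if (ddf == 0) {
    if (dchi > 1e-8) abort("identical parameter sets but different deviances")
    1
  } else {
    stats::pchisq(dchi, df = ddf, lower.tail = FALSE)
  }
  aic_r <- restricted$AIC
  aic_f <- full$AIC
  tibble::tibble(
    restricted = restricted$spec$family, full = full$spec$family,
    delta_chisq = dchi, delta_df = ddf, p_value = p,
    aic_restricted = aic_r, aic_full = aic_f, delta_aic = aic_r - aic_f,
    preferred = if (aic_r <= aic_f) "restricted" else "full")
}

#' Wald z-tests for free parameters
#'
#' @param fit a `twin_fit` object.
#' @return tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high` and the parameter `class`.
#' @export
wald_tests <- function(fit) {
  est <- fit$estimates
  se <- fit$se
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se), statistic = unname(z),
                 p.value = unname(p),
                 conf.low = unname(est - stats::qnorm(0.975) * se),
                 conf.high = unname(est + stats::qnorm(0.975) * se),
                 class = fit$spec$params$class)
}

#' Prune non-significant structural paths and refit
#'
#' Fixes to zero, simultaneously, every free structural path or correlation
#' (parameter classes in `classes`; factor loadings, variances and
#' measurement parameters are never pruned) whose two-sided Wald test in the
#' full model has `p >= alpha`, refits the pruned model, and returns the
#' chi-square comparison against the full model. Pruning is simultaneous
#' rather than stepwise, matching the practice of reporting a single
#' restricted model.
#'
#' @param fit a converged `twin_fit` from [fit_twin_model()].
#' @param cohort the cohort the fit was computed on.
#' @param alpha Wald significance level (default 0.05, two-sided).
#' @param classes parameter classes eligible for pruning.
#' @return list with `fit` (the parsimonious refit), `comparison` (tibble
#'   from [compare_models()]) and `pruned` (character vector of fixed
#'   parameters).
#' @export
prune_nonsignificant <- function(fit, cohort, alpha = 0.05,
                                 classes = c("path", "cor")) {
  stopifnot(inherits(fit, "twin_fit"))
  if (!fit$converged) abort("full model did not converge; refusing to prune")
  if (!fit$se_ok) abort("standard errors unavailable; cannot Wald-test paths")
  w <- wald_tests(fit)
  drop <- w$term[w$class %in% classes & !is.na(w$p.value) & w$p.value >= alpha]
  if (!length(drop)) {
    comp <- tibble::tibble(
      restricted = fit$spec$family, full = fit$spec$family,
      delta_chisq = 0, delta_df = 0L, p_value = 1,
      aic_restricted = fit$AIC, aic_full = fit$AIC, delta_aic = 0,
      preferred = "restricted")
    return(list(fit = fit, comparison = comp, pruned = character()))
  }
  pruned_spec <- fix_params(fit$spec, drop, 0)
  start <- fit$estimates[pruned_spec$params$param]
  refit <- fit_twin_model(cohort, pruned_spec, start = start, se = fit$se_ok)
  if (!refit$identified) {
    abort(paste0("pruned model fails identification; offending constraints ",
                 "involve: ",
                 paste(unique(unlist(refit$identification$deficient)),
                       collapse = ", ")))
  }
  list(fit = refit, comparison = compare_models(refit, fit), pruned = drop)
}

#' Falconer moment estimates of standardized variance components
#'
#' The classical moment estimator from cross-twin correlations:
#' `h2 = 2(rMZ - rDZ)`, `c2 = 2 rDZ - rMZ`, `e2 = 1 - rMZ`. For standardized
#' data whose three moments the ACE model fits perfectly, this coincides
#' with the maximum-likelihood solution.
#'
#' @param rmz,rdz MZ and DZ cross-twin correlations.
#' @return tibble with `h2`, `c2`, `e2`.
#' @export
falconer <- function(rmz, rdz) {
  tibble::tibble(h2 = 2 * (rmz - rdz), c2 = 2 * rdz - rmz, e2 = 1 - rmz)
}

# Sum of squared loading parameters for one component of one variable,
# treating parameters pruned out of the fit as zero.
component_variance <- function(theta, pnames) {
  sum(theta[intersect(pnames, names(theta))]^2)
}

#' Standardized ACE variance components from a fitted model
#'
#' Computes `h2 = A / (A + C + E)` (and `c2`, `e2` analogously) from the
#' fitted loading parameters of an ACE-bearing model, with delta-method
#' standard errors from the fit's parameter covariance and Wald 95%
#' confidence intervals. Components lie in `[0, 1]` and sum to 1 by
#' construction.
#'
#' @param fit a `twin_fit` whose spec declares ACE loadings (all model
#'   constructors except the saturated correlation model do).
#' @param variable which phenotype to decompose; defaults to all declared.
#' @return a tibble of class `twin_varcomp` with `variable`, `component`
#'   (`h2`, `c2`, `e2`), `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @export
standardized_ace <- function(fit, variable = NULL) {
  stopifnot(inherits(fit, "twin_fit"))
  map <- fit$spec$meta$std_ace
  if (is.null(map)) abort("this model family declares no ACE decomposition")
  vars <- variable %||% names(map)
  bad <- setdiff(vars, names(map))
  if (length(bad)) {
    abort(paste0("no ACE decomposition declared for: ",
                 paste(bad, collapse = ", ")))
  }
  theta <- fit$estimates
  rows <- lapply(vars, function(v) {
    comp <- map[[v]]
    shares <- function(th) {
      va <- component_variance(th, comp$A)
      vc <- component_variance(th, comp$C)
      ve <- component_variance(th, comp$E)
      tot <- va + vc + ve
      if (tot <= 0) abort(paste0("total variance is not positive for ", v))
      c(h2 = va / tot, c2 = vc / tot, e2 = ve / tot)
    }
    est <- shares(theta)
    se <- rep(NA_real_, 3)
    if (fit$se_ok && !is.null(fit$vcov)) {
      J <- vapply(seq_along(theta), function(i) {
        h <- 1e-6
        tp <- theta; tm <- theta
        tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
        (shares(tp) - shares(tm)) / (2 * h)
      }, numeric(3))
      V <- J %*% fit$vcov %*% t(J)
      se <- sqrt(pmax(diag(V), 0))
    }
    tibble::tibble(variable = v, component = c("h2", "c2", "e2"),
                   estimate = unname(est), std.error = se,
                   conf.low = unname(est) - stats::qnorm(0.975) * se,
                   conf.high = unname(est) + stats::qnorm(0.975) * se)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("twin_varcomp", class(out))
  out
}

#' Bivariate covariance shares through A, C and E
#'
#' Decomposes the model-implied cross-trait covariance between two variables
#' into the percentage travelling through additive-genetic, shared- and
#' non-shared-environmental routes, by grouping Wright path-tracing treks by
#' the biometric kind of their two-headed arc. The polygenic score, when
#' present, counts as a genetic route.
#'
#' @param fit a `twin_fit` object.
#' @param from,to variable names (per-twin suffix optional; twin 1 is used).
#' @return tibble with `component`, `contribution`, `percent`.
#' @export
ace_covariance_shares <- function(fit, from, to) {
  dec <- trek_table(fit, from, to)
  kind <- arc_kind(dec$arc_v1, dec$arc_v2)
  agg <- tapply(dec$value, factor(kind, levels = c("A", "C", "E")),
                sum, default = 0)
  total <- sum(dec$value)
  tibble::tibble(component = c("A", "C", "E"),
                 contribution = as.numeric(agg),
                 percent = 100 * as.numeric(agg) / total)
}

arc_kind <- function(v1, v2) {
  k <- function(v) {
    dplyr::case_when(
      grepl("^A", v) | grepl("^pgs", v) ~ "A",
      grepl("^C", v) ~ "C",
      grepl("^E", v) ~ "E",
      TRUE ~ "other")
  }
  k1 <- k(v1); k2 <- k(v2)
  ifelse(k1 == k2, k1, "other")
}
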