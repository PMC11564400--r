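# Fitting machinery: FIML and covariance-matrix maximum likelihood, Hessian
# standard errors, and local identification checking by Jacobian rank.

# Fast implied observed-variable covariances from a precompiled spec.
implied_cov_groups <- function(cm, theta) {
  out <- vector("list", 2)
  for (k in 1:2) {
    g <- ZYGOSITY_LEVELS[k]
    m <- group_matrices(cm, g, theta)
    B <- solve(diag(cm$nv) - m$A)
    full <- B %*% m$S %*% t(B)
    cov <- full[cm$obs_idx, cm$obs_idx, drop = FALSE]
    out[[k]] <- (cov + t(cov)) / 2
  }
  names(out) <- ZYGOSITY_LEVELS
  out
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Dense central-difference Hessian, step 1e-5 * max(|x|, 1) per coordinate.
num_hessian <- function(f, x, step = NULL) {
  k <- length(x)
  h <- step %||% (1e-5 * pmax(abs(x), 1))
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    fpp <- f(x + 2 * ei); fmm <- f(x - 2 * ei)
    H[i, i] <- (fpp - 2 * f0 + fmm) / (4 * h[i]^2)
    if (i < k) for (j in (i + 1):k) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

num_gradient <- function(f, x, step = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, step)
    (f(x + e) - f(x - e)) / (2 * step)
  }, numeric(1))
}

PENALTY <- 1e12

new_twin_fit <- function(spec, res, objective, se, fit_type, n_pairs) {
  theta <- setNames(res$par, spec$params$param)
  k <- length(theta)
  grad <- num_gradient(objective, res$par)
  # gradient tolerance relative to the deviance scale: a residual gradient
  # this small moves the deviance far less than the ~1 unit that matters for
  # a likelihood-ratio test
  grad_tol <- 1e-4 * max(100, abs(res$objective))
  converged <- res$convergence == 0 || max(abs(grad)) < grad_tol
  at_lower <- abs(res$par - spec$params$lower) < 1e-6
  at_upper <- abs(res$par - spec$params$upper) < 1e-6
  boundary <- spec$params$param[at_lower | at_upper]
  se_vec <- setNames(rep(NA_real_, k), names(theta))
  vcov <- NULL
  se_ok <- FALSE
  if (se) {
    H <- num_hessian(objective, res$par)
    V <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > -1e-8)) {
      vcov <- V
      dimnames(vcov) <- list(names(theta), names(theta))
      se_vec <- sqrt(pmax(diag(V), 0))
      names(se_vec) <- names(theta)
      se_ok <- TRUE
    }
  }
  id <- check_identification(spec, theta)
  structure(
    list(spec = spec, estimates = theta, se = se_vec, vcov = vcov,
         se_ok = se_ok, minus2ll = res$objective, k = k,
         AIC = res$objective + 2 * k, converged = converged,
         conv_code = res$convergence, gradient_norm = max(abs(grad)),
         boundary = boundary, identified = id$identified, identification = id,
         implied = implied_moments(spec, theta), fit_type = fit_type,
         n_pairs = n_pairs),
    class = "twin_fit")
}

run_optim <- function(spec, objective, start, restarts, restart_seed) {
  lower <- spec$params$lower; upper <- spec$params$upper
  ctrl <- list(eval.max = 20000, iter.max = 5000, rel.tol = 1e-10)
  res <- stats::nlminb(start, objective, lower = lower, upper = upper,
                       control = ctrl)
  attempt <- 0
  best <- res
  # restart on penalty-stuck runs always; on unconverged codes a few times
  # (code 1, "false convergence", is usually a solution with a negligible
  # gradient and is resolved by the gradient check downstream)
  needs_restart <- function(r, attempt) {
    r$objective >= PENALTY / 2 ||
      (!r$convergence %in% c(0L, 1L) && attempt < min(3, restarts))
  }
  while (needs_restart(best, attempt) && attempt < restarts) {
    attempt <- attempt + 1
    jitter <- with_seed(restart_seed + attempt,
                        stats::runif(length(start), -0.25, 0.25))
    st <- pmin(pmax(start + jitter, lower + 1e-6), upper - 1e-6)
    st[!is.finite(st)] <- (start + jitter)[!is.finite(st)]
    cand <- stats::nlminb(st, objective, lower = lower, upper = upper,
                          control = ctrl)
    if (cand$objective < best$objective ||
        (cand$convergence == 0 && best$convergence != 0 &&
         cand$objective <= best$objective + 1e-6)) {
      best <- cand
    }
  }
  best
}

#' Fit a twin model to a cohort by full-information maximum likelihood
#'
#' Minimizes [fiml_minus2ll()] over the spec's free parameters by
#' box-constrained quasi-Newton optimization, restarting from jittered start
#' values (seeded, reproducible) if the first run fails to converge. Standard
#' errors are delta-method Wald errors from a central-difference Hessian of
#' the deviance at the optimum; local identification is checked at the
#' optimum and recorded.
#'
#' @param cohort a twin cohort tibble (see [read_cohort()] /
#'   [simulate_structural()]); must contain `zygosity` plus the spec's
#'   observed columns, standardized and residualized upstream since all model
#'   means are fixed at zero.
#' @param spec a [new_twin_spec()] object.
#' @param start optional named start values overriding the spec defaults.
#' @param se logical; compute Hessian standard errors (skippable to speed up
#'   replicate simulations).
#' @param restarts maximum number of jittered restarts on non-convergence.
#' @param restart_seed integer seed driving the restart jitter.
#' @return a `twin_fit` object; see [tidy.twin_fit()] and
#'   [glance.twin_fit()] for tabular views.
#' @export
fit_twin_model <- function(cohort, spec, start = NULL, se = TRUE,
                           restarts = 10, restart_seed = 1L) {
  mats <- cohort_matrices(spec, cohort)
  stats_by_group <- lapply(mats, pattern_stats)
  n_pairs <- vapply(mats, nrow, integer(1))
  cm <- compile_spec(spec)
  objective <- function(theta) {
    tryCatch({
      covs <- implied_cov_groups(cm, theta)
      group_m2ll(covs$MZ, stats_by_group$MZ, "MZ") +
        group_m2ll(covs$DZ, stats_by_group$DZ, "DZ")
    }, error = function(e) PENALTY)
  }
  st <- if (is.null(start)) start_values(spec) else as_theta(spec, start)
  res <- run_optim(spec, objective, st, restarts, restart_seed)
  new_twin_fit(spec, res, objective, se, "fiml", n_pairs)
}

#' Fit a twin model to per-group covariance matrices
#'
#' Maximum-likelihood fit to observed MZ and DZ pair covariance matrices using
#' the normal-theory discrepancy
#' \eqn{F = \sum_g n_g (\log|\Sigma_g| + tr(S_g \Sigma_g^{-1}) - \log|S_g| - p)},
#' which is zero iff the model reproduces the observed matrices exactly and
#' differs from the FIML deviance only by the saturated constant, so
#' chi-square differences are preserved. Useful for worked examples whose
#' inputs are printed correlation matrices rather than raw data.
#'
#' @param mz_cov,dz_cov observed covariance matrices over the spec's observed
#'   variables (in spec order).
#' @param spec a [new_twin_spec()] object.
#' @param n_mz,n_dz pair counts used to weight the two groups.
#' @inheritParams fit_twin_model
#' @return a `twin_fit` object whose `minus2ll` holds the discrepancy `F`.
#' @export
fit_twin_moments <- function(spec, mz_cov, dz_cov, n_mz = 1000, n_dz = 1000,
                             start = NULL, se = TRUE, restarts = 10,
                             restart_seed = 1L) {
  p <- length(spec$obs)
  obs <- list(MZ = as.matrix(mz_cov), DZ = as.matrix(dz_cov))
  for (g in ZYGOSITY_LEVELS) {
    if (!all(dim(obs[[g]]) == c(p, p))) {
      abort(paste0(g, " covariance matrix must be ", p, "x", p,
                   " to match the spec's observed variables"))
    }
  }
  n <- c(MZ = n_mz, DZ = n_dz)
  logdet_obs <- vapply(obs, function(S) determinant(S)$modulus[1], numeric(1))
  cm <- compile_spec(spec)
  objective <- function(theta) {
    tryCatch({
      covs <- implied_cov_groups(cm, theta)
      total <- 0
      for (g in ZYGOSITY_LEVELS) {
        R <- chol(covs[[g]])
        total <- total + n[[g]] *
          (2 * sum(log(diag(R))) + sum(chol2inv(R) * obs[[g]]) -
             logdet_obs[[g]] - p)
      }
      total
    }, error = function(e) PENALTY)
  }
  st <- if (is.null(start)) start_values(spec) else as_theta(spec, start)
  res <- run_optim(spec, objective, st, restarts, restart_seed)
  new_twin_fit(spec, res, objective, se, "moments", n)
}

#' Check local identification of a twin model
#'
#' Computes the Jacobian of the stacked, vectorized unique implied-covariance
#' entries of both zygosity groups with respect to the free parameters by
#' central differences, and declares the model locally identified iff the
#' Jacobian has full column rank. Singular values below `tol` times the
#' largest are treated as zero. When rank-deficient, the right null-space
#' basis is reported with the parameter names loading on each deficient
#' combination.
#'
#' @inheritParams implied_moments
#' @param step central-difference step.
#' @param tol relative singular-value tolerance for the rank decision.
#' @return a list of class `twin_identification` with elements `identified`,
#'   `rank`, `n_params`, `deficient` (list of character vectors naming the
#'   parameters in each null direction) and `null_basis`.
#' @export
check_identification <- function(spec, params = start_values(spec),
                                 step = 1e-6, tol = 1e-8) {
  theta <- as_theta(spec, params)
  cm <- compile_spec(spec)
  stack <- function(th) {
    covs <- implied_cov_groups(cm, th)
    c(covs$MZ[lower.tri(covs$MZ, diag = TRUE)],
      covs$DZ[lower.tri(covs$DZ, diag = TRUE)])
  }
  k <- length(theta)
  base <- stack(theta)
  J <- matrix(0, length(base), k)
  for (i in seq_len(k)) {
    e <- replace(numeric(k), i, step)
    J[, i] <- (stack(theta + e) - stack(theta - e)) / (2 * step)
  }
  sv <- svd(J)
  rank <- sum(sv$d > tol * max(sv$d, .Machine$double.eps))
  identified <- rank == k
  deficient <- list()
  null_basis <- NULL
  if (!identified) {
    null_basis <- sv$v[, (rank + 1):k, drop = FALSE]
    rownames(null_basis) <- names(theta)
    deficient <- apply(null_basis, 2, function(v) {
      names(theta)[abs(v) > 0.1 * max(abs(v))]
    }, simplify = FALSE)
  }
  structure(list(identified = identified, rank = rank, n_params = k,
                 deficient = deficient, null_basis = null_basis),
            class = "twin_identification")
}

#' @export
print.twin_identification <- function(x, ...) {
  cat("<twin_identification> ",
      if (x$identified) "locally identified" else "NOT identified",
      ": rank ", x$rank, " / ", x$n_params, " parameters\n", sep = "")
  for (d in x$deficient) {
    cat("  deficient combination: ", paste(d, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.twin_fit <- function(x, ...) {
  cat("<twin_fit> family:", x$spec$family, "(", x$fit_type, ")\n")
  cat("  -2lnL:", format(x$minus2ll, digits = 8),
      " k:", x$k, " AIC:", format(x$AIC, digits = 8), "\n")
  cat("  converged:", x$converged, " identified:", x$identified, "\n")
  if (length(x$boundary)) {
    cat("  parameters at bounds:", paste(x$boundary, collapse = ", "), "\n")
  }
  print(tidy(x), n = 15)
  invisible(x)
}

#' Refit a spec with selected parameters fixed
#'
#' Returns a copy of the spec in which the named free parameters are replaced
#' by fixed constants (default 0); matrix cells scale the constant by their
#' stored multiplier. Used by [prune_nonsignificant()] and for building
#' restricted models in chi-square difference tests.
#'
#' @inheritParams implied_moments
#' @param names character vector of parameter names to fix.
#' @param value fixed value (scalar or named vector).
#' @return a [new_twin_spec()] object.
#' @export
fix_params <- function(spec, names, value = 0) {
  unknown <- setdiff(names, spec$params$param)
  if (length(unknown)) {
    abort(paste0("cannot fix unknown parameters: ",
                 paste(unknown, collapse = ", ")))
  }
  vals <- if (length(value) == 1) setNames(rep(value, length(names)), names)
          else as_theta_subset(value, names)
  entries <- spec$entries
  sel <- entries$param %in% names
  entries$value[sel] <- entries$value[sel] * vals[entries$param[sel]]
  entries$param[sel] <- NA_character_
  entries <- entries[!(entries$matrix == "A" & is.na(entries$param) &
                         entries$value == 0), , drop = FALSE]
  params <- spec$params[!spec$params$param %in% names, , drop = FALSE]
  # drop S cells fixed to zero except variances (keep diagonal explicit)
  drop_s <- entries$matrix == "S" & is.na(entries$param) & entries$value == 0 &
    entries$from != entries$to
  entries <- entries[!drop_s, , drop = FALSE]
  out <- new_twin_spec(spec$family, spec$vars, spec$obs, params, entries,
                       spec$meta)
  out
}

as_theta_subset <- function(value, names) {
  if (is.null(names(value))) abort("value must be scalar or named")
  miss <- setdiff(names, names(value))
  if (length(miss)) abort("value lacks entries for some fixed parameters")
  value[names]
}
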