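# Shared fixtures and independent oracles, built in code at test time.

# Published cross-twin correlations and standardized components for the four
# univariate factors (cognitive development and three stimulation domains).
table2_cases <- tibble::tibble(
  factor = c("pb", "tr", "pg", "cd"),
  rmz = c(0.96, 0.94, 0.95, 0.99),
  rdz = c(0.76, 0.79, 0.78, 0.86))

unit_cov <- function(r) matrix(c(1, r, r, 1), 2, 2)

# ML fit of the univariate ACE model to unit-variance correlation input.
fit_ace_to_correlations <- function(rmz, rdz, ...) {
  spec <- build_ace_univariate("x")
  fit_twin_moments(spec, unit_cov(rmz), unit_cov(rdz), n_mz = 1000,
                   n_dz = 1000, ...)
}

# Independent FIML oracle: explicit per-row mean/covariance subsetting with
# textbook multivariate-normal density algebra (no shared code with the
# pattern-grouped implementation).
brute_force_m2ll <- function(spec, params, cohort) {
  mom <- implied_moments(spec, params)
  total <- 0
  for (i in seq_len(nrow(cohort))) {
    g <- cohort$zygosity[i]
    x <- as.numeric(cohort[i, spec$obs])
    obs <- which(!is.na(x))
    if (!length(obs)) next
    S <- mom[[g]]$cov[obs, obs, drop = FALSE]
    xi <- x[obs]
    total <- total + length(obs) * log(2 * pi) +
      as.numeric(determinant(S, logarithm = TRUE)$modulus) +
      drop(t(xi) %*% solve(S) %*% xi)
  }
  total
}

# Grid-search oracle for the standardized ACE solution on correlation input:
# minimizes the two-group ML discrepancy over (h2, c2) on a fine simplex grid.
grid_ace_shares <- function(rmz, rdz, step = 0.002) {
  smz <- unit_cov(rmz); sdz <- unit_cov(rdz)
  ldo <- log(det(smz)) + log(det(sdz))
  best <- c(NA, NA, NA); best_f <- Inf
  for (h2 in seq(0, 1, by = step)) {
    for (c2 in seq(0, 1 - h2, by = step)) {
      e2 <- 1 - h2 - c2
      imz <- unit_cov(h2 + c2)
      idz <- unit_cov(0.5 * h2 + c2)
      f <- tryCatch(
        log(det(imz)) + sum(solve(imz) * smz) +
          log(det(idz)) + sum(solve(idz) * sdz) - ldo - 4,
        error = function(e) Inf)
      if (is.finite(f) && f < best_f) {
        best_f <- f
        best <- c(h2, c2, e2)
      }
    }
  }
  setNames(best, c("h2", "c2", "e2"))
}

# Small complete cohort for likelihood fixtures, deterministic values.
tiny_cohort <- function() {
  tibble::tibble(
    pair_id = paste0("p", 1:5),
    zygosity = c("MZ", "MZ", "DZ", "DZ", "MZ"),
    x_1 = c(0.5, -1.2, 0.3, NA, 1.1),
    x_2 = c(0.4, NA, -0.2, 0.8, 1.0),
    y_1 = c(-0.3, 0.6, NA, 0.2, -1.5),
    y_2 = c(0.1, 0.9, 0.7, NA, NA))
}

expect_within_3se <- function(est, se, truth, label = "parameter") {
  expect_true(is.finite(se) && se > 0,
              label = paste(label, "has a positive standard error"))
  expect_lt(abs(est - truth), 3 * se + 1e-12,
            label = paste(label, "within 3 SE of truth"))
}
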