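# Reticular moment engine: implied moments, FIML with missingness, fitting,
# identification.

test_that("univariate ACE implied moments match hand algebra", {
  spec <- build_ace_univariate("x")
  s <- sqrt(1 / 3)
  mom <- implied_moments(spec, c(a = s, c = s, e = s))
  expect_equal(unname(diag(mom$MZ$cov)), c(1, 1), tolerance = 1e-12)
  expect_equal(mom$MZ$cov[1, 2], 2 / 3, tolerance = 1e-12)
  expect_equal(mom$DZ$cov[1, 2], 1 / 2, tolerance = 1e-12)
  expect_equal(mom$MZ$cov, t(mom$MZ$cov), tolerance = 1e-12)
})

test_that("DoC with causal paths at zero reduces to the matched no-cause model", {
  doc <- build_doc("x", "y", direction = "both", latent = FALSE)
  th <- start_values(doc)
  th[c("causal_xtoy", "causal_ytox")] <- 0
  none <- build_doc("x", "y", direction = "none", latent = FALSE)
  mom_doc <- implied_moments(doc, th)
  mom_none <- implied_moments(none, th[start_values(none) |> names()])
  for (g in c("MZ", "DZ")) {
    expect_equal(mom_doc[[g]]$cov, mom_none[[g]]$cov, tolerance = 1e-12)
  }
})

test_that("MZ and DZ implied covariances differ only through genetic cells", {
  spec <- build_extended_crosslag("x", "y")
  th <- start_values(spec)
  th[grep("^a_", names(th))] <- 0   # remove all A loadings
  mom <- implied_moments(spec, th)
  expect_equal(mom$MZ$cov, mom$DZ$cov, tolerance = 1e-12)
})

test_that("FIML equals closed-form density sums on complete and missing data", {
  spec <- build_cholesky_bivariate("x", "y")
  co <- tiny_cohort()
  th <- start_values(spec)
  # brute-force oracle subsets mean/covariance per row
  expect_equal(fiml_minus2ll(spec, th, co), brute_force_m2ll(spec, th, co),
               tolerance = 1e-8)
  complete <- co
  complete[3:6] <- lapply(complete[3:6], function(x) replace(x, is.na(x), 0.25))
  expect_equal(fiml_minus2ll(spec, th, complete),
               brute_force_m2ll(spec, th, complete), tolerance = 1e-8)
})

test_that("a single observed value under a unit-variance model contributes log(2pi)+x^2", {
  spec <- build_saturated_correlation_model("x")
  co <- tibble::tibble(pair_id = "p1", zygosity = "MZ", x_1 = 0.7,
                       x_2 = NA_real_)
  m2 <- fiml_minus2ll(spec, c(r_mz_x = 0.5, r_dz_x = 0.3), co)
  expect_equal(m2, log(2 * pi) + 0.7^2, tolerance = 1e-10)
  # a pair with nothing observed contributes zero
  co2 <- dplyr::bind_rows(co, tibble::tibble(pair_id = "p2", zygosity = "DZ",
                                             x_1 = NA_real_, x_2 = NA_real_))
  expect_equal(fiml_minus2ll(spec, c(r_mz_x = 0.5, r_dz_x = 0.3), co2), m2,
               tolerance = 1e-12)
})

test_that("univariate ACE fit recovers generating shares within 3 SE", {
  spec <- build_ace_univariate("x")
  truth <- c(h2 = 0.4, c2 = 0.4, e2 = 0.2)
  co <- simulate_from_model(spec, c(a = sqrt(0.4), c = sqrt(0.4),
                                    e = sqrt(0.2)),
                            n_mz = 4000, n_dz = 4000, seed = 21)
  fit <- fit_twin_model(co, spec)
  expect_true(fit$converged)
  expect_true(fit$identified)
  vc <- standardized_ace(fit)
  for (i in 1:3) {
    expect_within_3se(vc$estimate[i], vc$std.error[i], truth[[vc$component[i]]],
                      vc$component[i])
  }
})

test_that("refitting from the optimum reproduces the deviance", {
  spec <- build_ace_univariate("x")
  co <- simulate_from_model(spec, c(a = 0.6, c = 0.6, e = 0.5),
                            n_mz = 500, n_dz = 500, seed = 22)
  fit <- fit_twin_model(co, spec, se = FALSE)
  refit <- fit_twin_model(co, spec, start = fit$estimates, se = FALSE)
  expect_equal(refit$minus2ll, fit$minus2ll, tolerance = 1e-8)
})

test_that("deviance is invariant to swapping twin order under symmetry constraints", {
  spec <- build_ace_univariate("x")
  co <- simulate_from_model(spec, c(a = 0.6, c = 0.5, e = 0.4),
                            n_mz = 200, n_dz = 200, seed = 23)
  swapped <- co
  swap_rows <- seq(1, nrow(co), by = 3)
  swapped$x_1[swap_rows] <- co$x_2[swap_rows]
  swapped$x_2[swap_rows] <- co$x_1[swap_rows]
  th <- c(a = 0.55, c = 0.5, e = 0.45)
  expect_equal(fiml_minus2ll(spec, th, swapped), fiml_minus2ll(spec, th, co),
               tolerance = 1e-10)
})

test_that("nested restricted fits never beat the full model", {
  cfg <- sim_config(n_mz = 400, n_dz = 400, crosslag = c(f = 0.1, g = 0),
                    missing_rate = 0, seed = 24)
  co <- simulate_structural(cfg)
  full <- fit_twin_model(co, build_crosslag("cd", "cs"), se = FALSE)
  restricted_spec <- fix_params(full$spec, c("f", "g"), 0)
  restricted <- fit_twin_model(co, restricted_spec, se = FALSE)
  expect_gte(restricted$minus2ll, full$minus2ll - 1e-6)
})

test_that("a loading/variance trade-off is flagged with both parameters named", {
  # only the product loading^2 * variance reaches the observed moments
  spec <- new_twin_spec(
    family = "BROKEN", vars = c("L", "v_1", "v_2"), obs = c("v_1", "v_2"),
    params = tibble::tibble(param = c("load", "vvar", "res"),
                            start = c(0.8, 1, 0.5), lower = -Inf, upper = Inf,
                            class = c("load", "var", "var")),
    entries = tibble::tibble(
      group = "all",
      matrix = c("A", "S", "S", "S"),
      from = c("L", "L", "v_1", "v_2"),
      to = c("v_1", "L", "v_1", "v_2"),
      param = c("load", "vvar", NA, "res"),
      value = c(1, 1, 0.2, 1)))
  id <- check_identification(spec)
  expect_false(id$identified)
  expect_setequal(id$deficient[[1]], c("load", "vvar"))
})

test_that("identification verdicts match the cross-lagged design's constraints", {
  id_ok <- check_identification(build_extended_crosslag("x", "y"))
  expect_true(id_ok$identified)
  id_free_e <- check_identification(
    build_extended_crosslag("x", "y", free_e_crosstime = TRUE))
  expect_false(id_free_e$identified)
  expect_true(any(grepl("e_ct", unlist(id_free_e$deficient))))
})
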