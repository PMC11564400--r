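# Model constructors: parameter counts, scaling constraints, nesting
# relations and direction recovery.

test_that("saturated correlation model frees the documented parameter count", {
  expect_equal(n_free_params(build_saturated_correlation_model("x")), 2)
  # two traits: 1 within-person + per-group (2 within-trait + 1 cross-trait)
  expect_equal(n_free_params(build_saturated_correlation_model(c("x", "y"))), 7)
})

test_that("saturated model recovers generating cross-twin correlations", {
  spec <- build_saturated_correlation_model("x")
  co <- simulate_from_model(spec, c(r_mz_x = 0.9, r_dz_x = 0.6),
                            n_mz = 5000, n_dz = 5000, seed = 31)
  fit <- fit_twin_model(co, spec)
  expect_within_3se(fit$estimates["r_mz_x"], fit$se["r_mz_x"], 0.9, "rMZ")
  expect_within_3se(fit$estimates["r_dz_x"], fit$se["r_dz_x"], 0.6, "rDZ")
})

test_that("ACE ML solution on correlation input matches the grid-search oracle", {
  for (case in c(1, 3)) {
    rmz <- table2_cases$rmz[case]; rdz <- table2_cases$rdz[case]
    fit <- fit_ace_to_correlations(rmz, rdz)
    got <- standardized_ace(fit)
    oracle <- grid_ace_shares(rmz, rdz)
    expect_equal(setNames(got$estimate, got$component), oracle,
                 tolerance = 2e-3)
    # exact three-moment solution: ML coincides with Falconer's formulas
    falc <- falconer(rmz, rdz)
    expect_equal(got$estimate[got$component == "h2"], falc$h2,
                 tolerance = 1e-4)
    expect_equal(got$estimate[got$component == "e2"], falc$e2,
                 tolerance = 1e-4)
  }
})

test_that("no MZ excess implies a zero genetic share", {
  fit <- fit_ace_to_correlations(0.5, 0.5)
  got <- standardized_ace(fit)
  expect_equal(setNames(got$estimate, got$component),
               c(h2 = 0, c2 = 0.5, e2 = 0.5), tolerance = 1e-4)
})

test_that("latent ACE model applies the stated scaling constraints", {
  spec <- build_ace_univariate("cd", latent = TRUE)
  # free: lambda, shared residual variance, a, c, e
  expect_equal(n_free_params(spec), 5)
  e <- spec$entries
  # first-indicator loading fixed at 1 for both twins
  fixed1 <- e[e$matrix == "A" & e$from == "F_cd_1" & e$to == "cd_t1_1", ]
  expect_true(is.na(fixed1$param) && fixed1$value == 1)
  # both indicator residual variances share one parameter
  res <- e[!is.na(e$param) & e$param == "res_cd" & e$matrix == "S", ]
  expect_equal(nrow(res), 4)
  expect_true(check_identification(spec)$identified)
})

test_that("Cholesky cross-loadings carry the cross-trait covariance", {
  spec <- build_cholesky_bivariate("x", "y")
  th <- start_values(spec)
  th[c("a21", "c21", "e21")] <- 0
  mom <- implied_moments(spec, th)
  expect_equal(mom$MZ$cov["x_1", "y_1"], 0, tolerance = 1e-12)
  # covariance shares sum to one when cross-loadings are present
  th2 <- start_values(spec)
  fit_stub <- structure(list(spec = spec, estimates = th2), class = "twin_fit")
  sh <- ace_covariance_shares(fit_stub, "x", "y")
  expect_equal(sum(sh$percent), 100, tolerance = 1e-8)
})

test_that("DoC direction is recovered when modes of inheritance differ", {
  # X strongly genetic, Y strongly shared-environmental; true direction X->Y
  gen <- build_doc("x", "y", direction = "XtoY", latent = FALSE)
  true <- start_values(gen)
  true[c("a_x", "c_x", "e_x")] <- sqrt(c(0.7, 0.1, 0.2))
  true[c("a_y", "c_y", "e_y")] <- sqrt(c(0.1, 0.7, 0.2))
  true["causal_xtoy"] <- 0.4
  wins <- 0; reps <- 12
  for (r in seq_len(reps)) {
    co <- simulate_from_model(gen, true, n_mz = 2500, n_dz = 2500,
                              seed = 310 + r)
    fxy <- fit_twin_model(co, build_doc("x", "y", "XtoY", latent = FALSE),
                          se = FALSE)
    fyx <- fit_twin_model(co, build_doc("x", "y", "YtoX", latent = FALSE),
                          se = FALSE)
    wins <- wins + (fxy$AIC < fyx$AIC)
  }
  expect_gte(wins, ceiling(0.9 * reps))
})

test_that("identical modes of inheritance leave the DoC directions indistinguishable", {
  gen <- build_doc("x", "y", direction = "XtoY", latent = FALSE)
  true <- start_values(gen)
  true[c("a_x", "c_x", "e_x")] <- sqrt(c(0.4, 0.4, 0.2))
  true[c("a_y", "c_y", "e_y")] <- sqrt(c(0.4, 0.4, 0.2))
  true["causal_xtoy"] <- 0.3
  daic <- vapply(1:6, function(r) {
    co <- simulate_from_model(gen, true, n_mz = 1500, n_dz = 1500,
                              seed = 500 + r)
    fxy <- fit_twin_model(co, build_doc("x", "y", "XtoY", latent = FALSE),
                          se = FALSE)
    fyx <- fit_twin_model(co, build_doc("x", "y", "YtoX", latent = FALSE),
                          se = FALSE)
    abs(fxy$AIC - fyx$AIC)
  }, numeric(1))
  expect_lt(median(daic), 2)
})

test_that("MRDoC identification hinges on the instrument as documented", {
  # pleiotropy-free variant: instrument is the sole source of identification
  spec <- build_mrdoc("x", "y", free_pleiotropy = FALSE)
  th <- start_values(spec)
  expect_true(check_identification(spec, th)$identified)
  th["p1"] <- 0
  id0 <- check_identification(spec, th)
  expect_false(id0$identified)
  expect_true("d" %in% unlist(id0$deficient))
  # default variant: pleiotropy free, E confound fixed
  spec2 <- build_mrdoc("x", "y")
  expect_true(check_identification(spec2)$identified)
  expect_false("re" %in% spec2$params$param)
})

test_that("cross-lagged model nests in the extended model exactly", {
  ext <- build_extended_crosslag("x", "y")
  reduced <- fix_params(ext, c("h1", "h2", "j1", "j2"), 0)
  naive <- build_crosslag("x", "y")
  th <- start_values(naive)
  mom_r <- implied_moments(reduced, th)
  mom_n <- implied_moments(naive, th)
  for (g in c("MZ", "DZ")) {
    expect_equal(mom_r[[g]]$cov, mom_n[[g]]$cov, tolerance = 1e-12)
  }
})

test_that("every constructor is identified at its default start values", {
  specs <- list(
    build_saturated_correlation_model(c("x", "y")),
    build_ace_univariate("x"),
    build_ace_univariate("cd", latent = TRUE),
    build_cholesky_bivariate("x", "y"),
    build_doc("x", "y", "both", latent = FALSE),
    build_doc("cd", "pb", "both", latent = TRUE),
    build_mrdoc("x", "y"),
    build_mrdoc("x", "y", free_pleiotropy = FALSE),
    build_crosslag("x", "y"),
    build_extended_crosslag("x", "y"))
  for (sp in specs) {
    expect_true(check_identification(sp)$identified, label = sp$family)
  }
})
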