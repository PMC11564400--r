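# Chi-square comparison arithmetic, pruning, standardized components and
# trek decomposition.

# Build twin_fit stubs with prescribed deviances for arithmetic tests.
fit_stub <- function(spec, m2ll) {
  k <- n_free_params(spec)
  structure(list(spec = spec, estimates = start_values(spec),
                 minus2ll = m2ll, k = k, AIC = m2ll + 2 * k,
                 converged = TRUE, identified = TRUE),
            class = "twin_fit")
}

test_that("chi-square difference arithmetic matches the reference distribution", {
  full <- build_extended_crosslag("x", "y")
  r4 <- fix_params(full, c("h1", "h2", "j1", "j2"), 0)
  r5 <- fix_params(full, c("h1", "h2", "j1", "j2", "f"), 0)
  base <- 10000
  cmp4 <- compare_models(fit_stub(r4, base + 6.95), fit_stub(full, base))
  expect_equal(cmp4$delta_chisq, 6.95, tolerance = 1e-12)
  expect_equal(cmp4$delta_df, 4)
  expect_equal(cmp4$p_value, pchisq(6.95, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(cmp4$p_value, 2), 0.14)
  cmp5 <- compare_models(fit_stub(r5, base + 8.75), fit_stub(full, base))
  expect_equal(cmp5$delta_df, 5)
  expect_equal(round(cmp5$p_value, 2), 0.12)
  # identical fits: zero difference, p = 1
  same <- compare_models(fit_stub(full, base), fit_stub(full, base))
  expect_equal(same$delta_chisq, 0)
  expect_equal(same$p_value, 1)
  # error paths: wrong order and negative deviance difference
  expect_error(compare_models(fit_stub(full, base), fit_stub(r4, base)),
               "not nested")
  expect_error(compare_models(fit_stub(r4, base - 1), fit_stub(full, base)),
               "non-convergence")
})

test_that("p-value is monotone decreasing in the chi-square difference", {
  full <- build_extended_crosslag("x", "y")
  r <- fix_params(full, c("h1", "h2", "j1", "j2"), 0)
  ps <- vapply(c(0.5, 2, 5, 9, 20), function(d) {
    compare_models(fit_stub(r, 1000 + d), fit_stub(full, 1000))$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("pruning removes true zeros and keeps the comparison non-significant", {
  cfg <- sim_config(n_mz = 1200, n_dz = 1200, crosslag = c(f = 0, g = 0),
                    crosstime = c(h1 = 0.25, h2 = 0.25, j1 = 0.35, j2 = 0.35),
                    missing_rate = 0, seed = 41)
  co <- simulate_structural(cfg)
  fit <- fit_twin_model(co, build_extended_crosslag("cd", "cs"))
  pr <- prune_nonsignificant(fit, co)
  expect_true(all(c("f", "g") %in% pr$pruned))
  expect_gt(pr$comparison$p_value, 0.05)
  expect_true(pr$fit$identified)
  # AIC sanity bound: pruning k paths can cost at most 2k AIC units... and
  # here should improve AIC
  expect_lte(pr$comparison$aic_restricted,
             pr$comparison$aic_full + 2 * length(pr$pruned))
})

test_that("a strong true path survives pruning", {
  cfg <- sim_config(n_mz = 1500, n_dz = 1500, crosslag = c(f = 0.3, g = 0.1),
                    crosstime = c(h1 = 0, h2 = 0, j1 = 0, j2 = 0),
                    missing_rate = 0, seed = 42)
  co <- simulate_structural(cfg)
  fit <- fit_twin_model(co, build_extended_crosslag("cd", "cs"))
  pr <- prune_nonsignificant(fit, co)
  expect_false("f" %in% pr$pruned)
  expect_within_3se(pr$fit$estimates["f"], pr$fit$se["f"], 0.3, "f")
})

test_that("all-significant fits are returned unchanged", {
  cfg <- sim_config(n_mz = 1500, n_dz = 1500, crosslag = c(f = 0.25, g = 0.25),
                    crosstime = c(h1 = 0.3, h2 = 0.3, j1 = 0.4, j2 = 0.4),
                    missing_rate = 0, seed = 43)
  co <- simulate_structural(cfg)
  fit <- fit_twin_model(co, build_crosslag("cd", "cs"))
  pr <- prune_nonsignificant(fit, co, alpha = 0.999999)
  expect_identical(pr$pruned, character())
  expect_equal(pr$comparison$delta_chisq, 0)
  expect_equal(pr$comparison$p_value, 1)
})

test_that("standardized components normalize, bound and sum correctly", {
  fit <- fit_ace_to_correlations(0.9, 0.6)
  vc <- standardized_ace(fit)
  expect_true(all(vc$estimate >= 0 & vc$estimate <= 1))
  expect_equal(sum(vc$estimate), 1, tolerance = 1e-10)
  # equal paths give equal thirds
  spec <- build_ace_univariate("x")
  stub <- structure(list(spec = spec,
                         estimates = c(a = 0.5, c = 0.5, e = 0.5),
                         se_ok = FALSE, vcov = NULL),
                    class = "twin_fit")
  vc2 <- standardized_ace(stub)
  expect_equal(vc2$estimate, rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("trek groups partition the implied covariance", {
  spec <- build_extended_crosslag("x", "y")
  set.seed(44)
  for (r in 1:8) {
    th <- start_values(spec)
    th[] <- th + runif(length(th), -0.08, 0.08)
    stub <- structure(list(spec = spec, estimates = th), class = "twin_fit")
    for (pair in list(c("x_t1", "y_t2"), c("y_t1", "x_t2"),
                      c("x_t1", "y_t1"))) {
      dec <- decompose_cross_covariance(stub, pair[1], pair[2])
      expect_equal(attr(dec, "total"), attr(dec, "implied"),
                   tolerance = 1e-10)
      expect_equal(sum(dec$contribution), attr(dec, "implied"),
                   tolerance = 1e-10)
      if (attr(dec, "implied") != 0) {
        expect_equal(sum(dec$percent), 100, tolerance = 1e-8)
      }
    }
  }
})

test_that("degenerate trek routes isolate single groups", {
  spec <- build_extended_crosslag("x", "y")
  # only the direct cross-lag connects x_t1 to y_t2
  th <- start_values(spec)
  th[c("ra_t1", "rc_t1", "re_t1", "ra_t2", "rc_t2", "re_t2",
       "h1", "h2", "j1", "j2")] <- 0
  stub <- structure(list(spec = spec, estimates = th), class = "twin_fit")
  dec <- decompose_cross_covariance(stub, "x_t1", "y_t2")
  expect_equal(dec$percent[dec$group == "direct"], 100, tolerance = 1e-8)
  # only one cross-time shared-environment route
  th2 <- th
  th2[c("f", "g")] <- 0
  th2["j1"] <- 0.4
  stub2 <- structure(list(spec = spec, estimates = th2), class = "twin_fit")
  dec2 <- decompose_cross_covariance(stub2, "x_t1", "y_t2")
  expect_equal(dec2$percent[dec2$group == "cross_time_rC"], 100,
               tolerance = 1e-8)
})

test_that("cyclic models are rejected by the trek decomposition", {
  spec <- build_doc("x", "y", direction = "both", latent = FALSE)
  stub <- structure(list(spec = spec, estimates = start_values(spec)),
                    class = "twin_fit")
  expect_error(decompose_cross_covariance(stub, "x", "y"), "acyclic")
})

test_that("Falconer formulas agree with their definition", {
  f <- falconer(0.96, 0.76)
  expect_equal(unlist(f), c(h2 = 0.4, c2 = 0.56, e2 = 0.04),
               tolerance = 1e-12)
})
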