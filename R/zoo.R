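#' Saturated correlation model for twin-pair data
#'
#' Free within-person cross-trait correlations constrained equal across birth
#' order and zygosity, plus cross-twin correlations (within-trait and
#' cross-trait) estimated separately for MZ and DZ pairs. Variances are fixed
#' at 1, so the model is expressed on the correlation scale and expects
#' standardized input.
#'
#' @param traits character vector of phenotype column stems; the cohort must
#'   contain columns `<trait>_1` and `<trait>_2`.
#' @return a [new_twin_spec()] object.
#' @examples
#' spec <- build_saturated_correlation_model("cd_t1")
#' n_free_params(spec)  # rMZ and rDZ
#' @export
build_saturated_correlation_model <- function(traits) {
  stopifnot(length(traits) >= 1)
  sb <- sb_new("SATURATED_CORR")
  for (tr in traits) {
    for (t in 1:2) sb_var(sb, tw(tr, t), observed = TRUE)
    for (t in 1:2) sb_cov(sb, tw(tr, t), tw(tr, t), value = 1)
    for (g in c("MZ", "DZ")) {
      p <- paste0("r_", tolower(g), "_", tr)
      sb_par(sb, p, start = 0.5, lower = -0.99, upper = 0.99, class = "cor")
      sb_cov(sb, tw(tr, 1), tw(tr, 2), param = p, group = g)
    }
  }
  if (length(traits) > 1) {
    for (i in seq_along(traits)[-length(traits)]) {
      for (j in (i + 1):length(traits)) {
        ti <- traits[i]; tj <- traits[j]
        pw <- paste0("r_wp_", ti, "_", tj)
        sb_par(sb, pw, start = 0.3, lower = -0.99, upper = 0.99, class = "cor")
        for (t in 1:2) sb_cov(sb, tw(ti, t), tw(tj, t), param = pw)
        for (g in c("MZ", "DZ")) {
          p <- paste0("r_ct_", tolower(g), "_", ti, "_", tj)
          sb_par(sb, p, start = 0.2, lower = -0.99, upper = 0.99, class = "cor")
          sb_cov(sb, tw(ti, 1), tw(tj, 2), param = p, group = g)
          sb_cov(sb, tw(ti, 2), tw(tj, 1), param = p, group = g)
        }
      }
    }
  }
  sb_build(sb)
}

#' Univariate ACE model
#'
#' Decomposes the variance of one phenotype (observed score or a latent factor
#' with two indicators) into additive-genetic (A), shared-environmental (C)
#' and non-shared-environmental (E) components. DZ additive-genetic cross-twin
#' covariance is scaled by 0.5. Path coefficients `a`, `c`, `e` are estimated
#' unconstrained; standardized shares are derived afterwards with
#' [standardized_ace()].
#'
#' With `latent = TRUE` the phenotype is a latent factor measured by two
#' indicators (by default `<trait>_t1` and `<trait>_t2`): the first loading is
#' fixed at 1, the second is free, and the two residual variances are
#' constrained equal.
#'
#' @param trait phenotype column stem (columns `<trait>_1`, `<trait>_2`), or
#'   the factor name when `latent = TRUE`.
#' @param latent logical; build the two-indicator latent-factor version.
#' @param indicators length-2 character vector of indicator stems for the
#'   latent version.
#' @return a [new_twin_spec()] object.
#' @export
build_ace_univariate <- function(trait, latent = FALSE,
                                 indicators = paste0(trait, c("_t1", "_t2"))) {
  sb <- sb_new("ACE_UNIVARIATE")
  if (latent) {
    if (length(indicators) != 2) {
      abort("latent ACE model requires exactly two indicators")
    }
    fac <- paste0("F_", trait)
    for (t in 1:2) sb_var(sb, tw(fac, t))
    sb_measurement(sb, fac, indicators, trait)
    sb_ace_on(sb, fac, trait, pnames = c("a", "c", "e"))
    sb$meta$std_ace <- setNames(list(list(A = "a", C = "c", E = "e")), fac)
  } else {
    for (t in 1:2) sb_var(sb, tw(trait, t), observed = TRUE)
    sb_ace_on(sb, trait, trait, pnames = c("a", "c", "e"))
    sb$meta$std_ace <- setNames(list(list(A = "a", C = "c", E = "e")), trait)
  }
  sb_build(sb)
}

#' Bivariate Cholesky ACE decomposition
#'
#' Triangular A, C and E factorization of two phenotypes: the first factor of
#' each component loads on both traits, the second only on the second trait,
#' partitioning all variances and covariances into ACE components without
#' causal paths. Serves as the comparison model that Direction-of-Causation
#' specifications are nested in.
#'
#' @param x,y phenotype column stems (or factor names when `latent = TRUE`).
#' @param latent logical; measure each trait by a two-indicator latent factor.
#' @param indicators_x,indicators_y indicator stems for the latent version.
#' @return a [new_twin_spec()] object.
#' @export
build_cholesky_bivariate <- function(x, y, latent = FALSE,
                                     indicators_x = paste0(x, c("_t1", "_t2")),
                                     indicators_y = paste0(y, c("_t1", "_t2"))) {
  sb <- sb_new("CHOLESKY_BIVARIATE")
  px <- x; py <- y
  if (latent) {
    px <- paste0("F_", x); py <- paste0("F_", y)
    for (t in 1:2) sb_var(sb, c(tw(px, t), tw(py, t)))
    sb_measurement(sb, px, indicators_x, x)
    sb_measurement(sb, py, indicators_y, y)
  } else {
    for (t in 1:2) sb_var(sb, c(tw(x, t), tw(y, t)), observed = TRUE)
  }
  for (kind in c("A", "C", "E")) {
    k <- tolower(kind)
    f1 <- paste0(kind, "1"); f2 <- paste0(kind, "2")
    sb_ace_factor(sb, f1, kind)
    sb_ace_factor(sb, f2, kind)
    p11 <- paste0(k, "11"); p21 <- paste0(k, "21"); p22 <- paste0(k, "22")
    sb_par(sb, p11, start = if (kind == "E") 0.4 else 0.55, class = "load")
    sb_par(sb, p21, start = 0.15, class = "load")
    sb_par(sb, p22, start = if (kind == "E") 0.4 else 0.5, class = "load")
    for (t in 1:2) {
      sb_path(sb, tw(f1, t), tw(px, t), param = p11)
      sb_path(sb, tw(f1, t), tw(py, t), param = p21)
      sb_path(sb, tw(f2, t), tw(py, t), param = p22)
    }
  }
  sb$meta$std_ace <- setNames(list(
    list(A = "a11", C = "c11", E = "e11"),
    list(A = c("a21", "a22"), C = c("c21", "c22"), E = c("e21", "e22"))),
    c(px, py))
  sb_build(sb)
}

#' Direction-of-Causation model
#'
#' ACE decomposition on each phenotype plus causal path(s) between them; the
#' cross-trait covariance is carried entirely by the causal path(s), with
#' cross-trait factor correlations fixed at zero. Direction `"both"` frees the
#' reciprocal pair (Y→X and X→Y), `"XtoY"`/`"YtoX"` free one path, `"none"`
#' reduces to two independent ACE models. Defaults to latent phenotype factors
#' with two indicators each, mirroring common practice of removing measurement
#' error before DoC comparison.
#'
#' @inheritParams build_cholesky_bivariate
#' @param direction one of `"both"`, `"XtoY"`, `"YtoX"`, `"none"`.
#' @return a [new_twin_spec()] object. Causal parameters are named
#'   `causal_xtoy` and `causal_ytox`.
#' @export
build_doc <- function(x, y, direction = c("both", "XtoY", "YtoX", "none"),
                      latent = TRUE,
                      indicators_x = paste0(x, c("_t1", "_t2")),
                      indicators_y = paste0(y, c("_t1", "_t2"))) {
  direction <- match.arg(direction)
  sb <- sb_new(paste0("DOC_", direction))
  px <- x; py <- y
  if (latent) {
    px <- paste0("F_", x); py <- paste0("F_", y)
    for (t in 1:2) sb_var(sb, c(tw(px, t), tw(py, t)))
    sb_measurement(sb, px, indicators_x, x)
    sb_measurement(sb, py, indicators_y, y)
  } else {
    for (t in 1:2) sb_var(sb, c(tw(x, t), tw(y, t)), observed = TRUE)
  }
  # deliberately asymmetric starts: DoC identification requires the two
  # traits' modes of inheritance to differ, so a symmetric start would sit on
  # a rank-deficient point
  sb_ace_on(sb, px, x, a_start = 0.65)
  sb_ace_on(sb, py, y, a_start = 0.35)
  if (direction %in% c("both", "XtoY")) {
    sb_par(sb, "causal_xtoy", start = 0.1, class = "path")
    for (t in 1:2) sb_path(sb, tw(px, t), tw(py, t), param = "causal_xtoy")
  }
  if (direction %in% c("both", "YtoX")) {
    sb_par(sb, "causal_ytox", start = 0.1, class = "path")
    for (t in 1:2) sb_path(sb, tw(py, t), tw(px, t), param = "causal_ytox")
  }
  sb$meta$std_ace <- setNames(list(
    list(A = paste0("a_", x), C = paste0("c_", x), E = paste0("e_", x)),
    list(A = paste0("a_", y), C = paste0("c_", y), E = paste0("e_", y))),
    c(px, py))
  sb$meta$causal <- intersect(c("causal_xtoy", "causal_ytox"),
                              names(sb$params))
  sb_build(sb)
}

#' Mendelian-randomization Direction-of-Causation (MRDoC) model
#'
#' Tests a unidirectional causal path `d` from an exposure to an outcome using
#' a polygenic score as instrument: paths `p1` (instrument → exposure) and
#' `p2` (instrument → outcome, direct pleiotropy), with ACE decomposition of
#' both phenotypes and cross-trait confound correlations `ra`, `rc`, `re`.
#' The instrument's cross-twin covariance is fixed at its full variance in MZ
#' pairs and half in DZ pairs.
#'
#' Pleiotropy and the non-shared-environment confound correlation cannot both
#' be estimated: with `p2` free the single instrument's moments only pin the
#' combination `p2 + d*p1`, and the local rank falls short by one when `re`
#' is also free. The constructor therefore exposes the documented trade-off:
#' with `free_pleiotropy = TRUE` (default) `p2` is free and `re` is fixed at
#' zero, the common restriction in causal twin modelling; with
#' `free_pleiotropy = FALSE` the pleiotropic path is fixed at zero and `re`
#' is free, in which case the polygenic score is the sole source of
#' identification of `d` — at `p1 = 0` the model is rank-deficient with the
#' causal path in the null space, the structural counterpart of "the score is
#' not a valid instrument".
#'
#' @param x exposure column stem (columns `<x>_1`, `<x>_2`).
#' @param y outcome column stem.
#' @param instrument polygenic-score column stem (default `"pgs"`).
#' @param free_pleiotropy logical; see Details.
#' @return a [new_twin_spec()] object.
#' @export
build_mrdoc <- function(x, y, instrument = "pgs", free_pleiotropy = TRUE) {
  sb <- sb_new("MRDOC")
  for (t in 1:2) sb_var(sb, c(tw(x, t), tw(y, t), tw(instrument, t)),
                        observed = TRUE)
  sb_par(sb, "v_pgs", start = 1, lower = 1e-8, class = "var")
  for (t in 1:2) sb_cov(sb, tw(instrument, t), tw(instrument, t), param = "v_pgs")
  sb_cov(sb, tw(instrument, 1), tw(instrument, 2), param = "v_pgs",
         value = 1, group = "MZ")
  sb_cov(sb, tw(instrument, 1), tw(instrument, 2), param = "v_pgs",
         value = 0.5, group = "DZ")
  sb_par(sb, "p1", start = 0.2, class = "path")
  sb_par(sb, "d", start = 0.1, class = "path")
  for (t in 1:2) {
    sb_path(sb, tw(instrument, t), tw(x, t), param = "p1")
    sb_path(sb, tw(x, t), tw(y, t), param = "d")
  }
  if (free_pleiotropy) {
    sb_par(sb, "p2", start = 0.1, class = "path")
    for (t in 1:2) sb_path(sb, tw(instrument, t), tw(y, t), param = "p2")
  }
  sb_ace_on(sb, x, x, a_start = 0.6)
  sb_ace_on(sb, y, y, a_start = 0.5)
  sb_factor_cor(sb, paste0("A_", x), paste0("A_", y), "A", "ra")
  sb_factor_cor(sb, paste0("C_", x), paste0("C_", y), "C", "rc")
  if (!free_pleiotropy) {
    sb_factor_cor(sb, paste0("E_", x), paste0("E_", y), "E", "re")
  }
  sb$meta$std_ace <- setNames(list(
    list(A = paste0("a_", x), C = paste0("c_", x), E = paste0("e_", x)),
    list(A = paste0("a_", y), C = paste0("c_", y), E = paste0("e_", y))),
    c(x, y))
  sb$meta$instrument <- list(strength = "p1", pleiotropy = "p2", causal = "d")
  sb_build(sb)
}

# Shared construction for the cross-lagged family. x and y are trait stems;
# observed columns are <trait>_t1_<twin> and <trait>_t2_<twin>.
build_crosslag_family <- function(x, y, crosstime, free_e_crosstime = FALSE) {
  sb <- sb_new(if (crosstime) "CROSSLAG_EXTENDED" else "CROSSLAG")
  x1 <- paste0(x, "_t1"); x2 <- paste0(x, "_t2")
  y1 <- paste0(y, "_t1"); y2 <- paste0(y, "_t2")
  for (t in 1:2) sb_var(sb, c(tw(x1, t), tw(y1, t), tw(x2, t), tw(y2, t)),
                        observed = TRUE)
  # time-1 ACE per trait with within-time cross-trait correlations
  sb_ace_on(sb, x1, paste0(x, "_t1"), a_start = 0.5)
  sb_ace_on(sb, y1, paste0(y, "_t1"), a_start = 0.5)
  for (k in c("A", "C", "E")) {
    sb_factor_cor(sb, paste0(k, "_", x, "_t1"), paste0(k, "_", y, "_t1"), k,
                  paste0("r", tolower(k), "_t1"))
  }
  # time-2 residual ACE per trait with residual within-time correlations
  sb_ace_on(sb, x2, paste0(x, "_t2r"), a_start = 0.5)
  sb_ace_on(sb, y2, paste0(y, "_t2r"), a_start = 0.5)
  for (k in c("A", "C", "E")) {
    sb_factor_cor(sb, paste0(k, "_", x, "_t2r"), paste0(k, "_", y, "_t2r"), k,
                  paste0("r", tolower(k), "_t2"))
  }
  # stability and cross-lagged regressions on the observed time-1 scores
  sb_par(sb, paste0("stab_", x), start = 0.3, class = "path")
  sb_par(sb, paste0("stab_", y), start = 0.3, class = "path")
  sb_par(sb, "f", start = 0.05, class = "path")  # y_t1 -> x_t2
  sb_par(sb, "g", start = 0.05, class = "path")  # x_t1 -> y_t2
  for (t in 1:2) {
    sb_path(sb, tw(x1, t), tw(x2, t), param = paste0("stab_", x))
    sb_path(sb, tw(y1, t), tw(y2, t), param = paste0("stab_", y))
    sb_path(sb, tw(y1, t), tw(x2, t), param = "f")
    sb_path(sb, tw(x1, t), tw(y2, t), param = "g")
  }
  if (crosstime) {
    # cross-time confound correlations: T1 common factors with T2 residual
    # factors of the *other* trait; E cross-time fixed 0 for identification
    sb_factor_cor(sb, paste0("A_", x, "_t1"), paste0("A_", y, "_t2r"), "A", "h1")
    sb_factor_cor(sb, paste0("A_", y, "_t1"), paste0("A_", x, "_t2r"), "A", "h2")
    sb_factor_cor(sb, paste0("C_", x, "_t1"), paste0("C_", y, "_t2r"), "C", "j1")
    sb_factor_cor(sb, paste0("C_", y, "_t1"), paste0("C_", x, "_t2r"), "C", "j2")
  }
  if (free_e_crosstime) {
    sb_factor_cor(sb, paste0("E_", x, "_t1"), paste0("E_", y, "_t2r"), "E", "e_ct1")
    sb_factor_cor(sb, paste0("E_", y, "_t1"), paste0("E_", x, "_t2r"), "E", "e_ct2")
  }
  sb$meta$std_ace <- setNames(list(
    list(A = paste0("a_", x, "_t1"), C = paste0("c_", x, "_t1"),
         E = paste0("e_", x, "_t1")),
    list(A = paste0("a_", y, "_t1"), C = paste0("c_", y, "_t1"),
         E = paste0("e_", y, "_t1"))),
    c(x1, y1))
  sb$meta$crosslag <- c(f = "f", g = "g")
  sb$meta$trek_groups <- list(direct = c("f", "g"),
                              rA = if (crosstime) c("h1", "h2") else character(),
                              rC = if (crosstime) c("j1", "j2") else character())
  sb_build(sb)
}

#' Cross-lagged twin model (two traits, two timepoints)
#'
#' Observed scores of two traits at two ages with per-trait ACE structure at
#' time 1, residual ACE structure at time 2, free within-time cross-trait
#' A/C/E correlations at each timepoint, autoregressive stability paths and
#' cross-lagged paths `f` (trait Y at T1 → trait X at T2) and `g` (trait X at
#' T1 → trait Y at T2).
#'
#' @param x,y trait stems; the cohort must contain columns
#'   `<trait>_t1_<twin>` and `<trait>_t2_<twin>`.
#' @return a [new_twin_spec()] object.
#' @export
build_crosslag <- function(x, y) build_crosslag_family(x, y, crosstime = FALSE)

#' Extended cross-lagged twin model with cross-time confound correlations
#'
#' The [build_crosslag()] model plus four free cross-time correlations that
#' allow genetic and shared-environmental factors to confound the cross-lagged
#' paths: `h1` (A of X at T1 with residual A of Y at T2), `h2` (A of Y at T1
#' with residual A of X at T2), `j1` and `j2` (the analogous C correlations).
#' Non-shared-environment cross-time correlations are fixed at zero; freeing
#' them (`free_e_crosstime = TRUE`) renders the model locally unidentified,
#' which is why causal twin models conventionally restrict them.
#'
#' @inheritParams build_crosslag
#' @param free_e_crosstime logical; free the E cross-time correlations
#'   (useful only to demonstrate the identification failure).
#' @return a [new_twin_spec()] object.
#' @export
build_extended_crosslag <- function(x, y, free_e_crosstime = FALSE) {
  build_crosslag_family(x, y, crosstime = TRUE,
                        free_e_crosstime = free_e_crosstime)
}
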