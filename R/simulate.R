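# Synthetic twin-cohort generation: direct structural simulation of the
# two-trait, two-timepoint twin design with a polygenic-score instrument, and
# sampling from any spec's implied moments.

#' Configuration for the structural twin-cohort simulator
#'
#' Defines the generative conditions of a two-trait (default `cd` = cognitive
#' development, `cs` = cognitive stimulation), two-timepoint MZ/DZ twin
#' cohort: per-trait variance shares at time 1 and for the time-2 residual,
#' within-time cross-trait A/C/E correlations, autoregressive stability,
#' cross-lagged effects `f` (trait 2 at T1 → trait 1 at T2) and `g` (trait 1
#' at T1 → trait 2 at T2), cross-time confound correlations between T1 common
#' factors and T2 residual factors (`h1`, `h2` genetic; `j1`, `j2` shared
#' environment), a polygenic score feeding trait 1 via `p1` and trait 2 via
#' `p2`, completely-at-random missingness, and group sizes.
#'
#' Default variance shares (a2 = 0.3, c2 = 0.6, e2 = 0.1) follow the pattern
#' of strong shared-environment and modest genetic influence typical of
#' parent-reported early-childhood measures; within-time correlations default
#' to values under which roughly three quarters of the cross-trait covariance
#' travels through C. These defaults are illustrative study conditions, not
#' fitted values.
#'
#' @param traits length-2 character vector of trait stems.
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param shares_t1,shares_t2 named lists with per-trait `c(a2, c2, e2)`
#'   (each non-negative, summing to 1); `shares_t2` applies to the time-2
#'   residual, which has unit variance before stability/cross-lag inputs.
#' @param cors_t1,cors_t2 named vectors `c(ra, rc, re)` of within-time
#'   cross-trait factor correlations.
#' @param stability named vector of autoregressive paths, one per trait.
#' @param crosslag named vector `c(f, g)`.
#' @param crosstime named vector `c(h1, h2, j1, j2)` of cross-time confound
#'   correlations (T1 common factor of one trait with T2 residual factor of
#'   the other).
#' @param pgs named vector `c(p1, p2)` of instrument paths; the polygenic
#'   score is a standardized genetic variable shared fully by MZ and half by
#'   DZ co-twins, and its contribution is carved out of the trait's
#'   additive-genetic share so `p1`/`p2` act as direct path coefficients.
#' @param missing_rate completely-at-random missingness rate in `[0, 1)`
#'   applied to phenotype and score cells.
#' @param seed integer seed making generation reproducible.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(traits = c("cd", "cs"),
                       n_mz = 2000, n_dz = 2000,
                       shares_t1 = list(c(a2 = 0.3, c2 = 0.6, e2 = 0.1),
                                        c(a2 = 0.3, c2 = 0.6, e2 = 0.1)),
                       shares_t2 = shares_t1,
                       cors_t1 = c(ra = 0.35, rc = 0.60, re = 0.20),
                       cors_t2 = c(ra = 0.25, rc = 0.40, re = 0.10),
                       stability = c(0.45, 0.45),
                       crosslag = c(f = 0, g = 0),
                       crosstime = c(h1 = 0.25, h2 = 0.25, j1 = 0.35, j2 = 0.35),
                       pgs = c(p1 = 0, p2 = 0),
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(traits = as.character(traits), n_mz = n_mz, n_dz = n_dz,
              shares_t1 = lapply(shares_t1, unlist),
              shares_t2 = lapply(shares_t2, unlist),
              cors_t1 = unlist(cors_t1), cors_t2 = unlist(cors_t2),
              stability = setNames(as.numeric(unlist(stability)), traits),
              crosslag = unlist(crosslag), crosstime = unlist(crosstime),
              pgs = unlist(pgs),
              missing_rate = missing_rate, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$traits) == 2, cfg$n_mz >= 0, cfg$n_dz >= 0)
  for (sh in c(cfg$shares_t1, cfg$shares_t2)) {
    if (any(sh < 0)) abort("variance shares must be non-negative")
    if (abs(sum(sh) - 1) > 1e-10) {
      abort("variance shares must sum to 1 per trait-time")
    }
  }
  cors <- c(cfg$cors_t1, cfg$cors_t2, cfg$crosstime)
  if (any(abs(cors) > 1)) abort("correlation parameters must lie in [-1, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("missing_rate must be in [0, 1)")
  }
  # implied latent covariance must be PSD before any sampling
  for (g in ZYGOSITY_LEVELS) {
    ev <- eigen(pair_latent_cov(cfg, g), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      abort(paste0("implied ", g,
                   " latent covariance is not positive semi-definite; ",
                   "reduce the correlation parameters"))
    }
  }
  invisible(cfg)
}

# Latent factor order (per twin): A_x1 A_y1 A_x2r A_y2r, C..., E..., PGS.
latent_block <- function(cors1, cors2, ct12, ct21, kind) {
  B <- diag(4)
  r1 <- switch(kind, A = cors1[["ra"]], C = cors1[["rc"]], E = cors1[["re"]])
  r2 <- switch(kind, A = cors2[["ra"]], C = cors2[["rc"]], E = cors2[["re"]])
  B[1, 2] <- B[2, 1] <- r1
  B[3, 4] <- B[4, 3] <- r2
  if (kind != "E") {
    B[1, 4] <- B[4, 1] <- ct12   # trait1 T1 factor with trait2 T2 residual
    B[2, 3] <- B[3, 2] <- ct21
  }
  B
}

pair_latent_cov <- function(cfg, group) {
  hA <- if (identical(group, "MZ")) 1 else 0.5
  blkA <- latent_block(cfg$cors_t1, cfg$cors_t2,
                       cfg$crosstime[["h1"]], cfg$crosstime[["h2"]], "A")
  blkC <- latent_block(cfg$cors_t1, cfg$cors_t2,
                       cfg$crosstime[["j1"]], cfg$crosstime[["j2"]], "C")
  blkE <- latent_block(cfg$cors_t1, cfg$cors_t2, 0, 0, "E")
  W <- as.matrix(Matrix_bdiag(list(blkA, blkC, blkE, matrix(1))))
  Xt <- as.matrix(Matrix_bdiag(list(hA * blkA, blkC, 0 * blkE,
                                    matrix(hA))))
  rbind(cbind(W, Xt), cbind(Xt, W))
}

# small block-diagonal helper (avoids a Matrix dependency)
Matrix_bdiag <- function(blocks) {
  sizes <- vapply(blocks, nrow, integer(1))
  n <- sum(sizes)
  M <- matrix(0, n, n)
  at <- 0
  for (b in blocks) {
    ix <- at + seq_len(nrow(b))
    M[ix, ix] <- b
    at <- at + nrow(b)
  }
  M
}

# path loadings implied by a config: additive-genetic loading is reduced so
# that the instrument's contribution keeps the trait's total genetic share
sim_loadings <- function(cfg) {
  p <- c(cfg$pgs[["p1"]], cfg$pgs[["p2"]])
  lapply(1:2, function(i) {
    s1 <- cfg$shares_t1[[i]]; s2 <- cfg$shares_t2[[i]]
    list(t1 = c(a = sqrt(max(s1[["a2"]] - p[i]^2, 0)), c = sqrt(s1[["c2"]]),
                e = sqrt(s1[["e2"]]), p = p[i]),
         t2 = c(a = sqrt(s2[["a2"]]), c = sqrt(s2[["c2"]]),
                e = sqrt(s2[["e2"]])))
  })
}

#' Simulate a twin cohort by direct structural simulation
#'
#' Draws latent A, C and E factors with the classical twin sharing structure
#' (additive-genetic cross-twin correlation 1.0 in MZ and 0.5 in DZ pairs;
#' shared environment identical within pair; non-shared environment
#' independent), plus a standardized polygenic score (cross-twin correlation
#' 1.0 / 0.5), then builds time-1 phenotypes from factor loadings and time-2
#' phenotypes by the cross-lagged recursion
#' `T2 = stability * T1_same + crosslag * T1_other + residual A/C/E`, where
#' the time-2 residual factors carry the configured cross-time correlations
#' with the time-1 common factors. Missingness is applied completely at
#' random. One integer seed drives a single generator stream: latent factors
#' first (pair by pair ordering within one matrix draw), then the missingness
#' mask.
#'
#' @param config a [sim_config()] object.
#' @return a twin cohort tibble with columns `pair_id`, `zygosity`,
#'   `<trait>_<time>_<twin>` and `pgs_<twin>`.
#' @export
simulate_structural <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    parts <- lapply(ZYGOSITY_LEVELS, function(g) {
      n <- if (g == "MZ") config$n_mz else config$n_dz
      simulate_group(config, g, n)
    })
    cohort <- dplyr::bind_rows(parts)
    cohort$pair_id <- sprintf("p%05d", seq_len(nrow(cohort)))
    cohort <- dplyr::relocate(cohort, "pair_id", "zygosity")
    if (config$missing_rate > 0) {
      pheno <- setdiff(names(cohort), c("pair_id", "zygosity"))
      for (cl in pheno) {
        drop <- stats::runif(nrow(cohort)) < config$missing_rate
        cohort[[cl]][drop] <- NA_real_
      }
    }
    cohort
  })
}

simulate_group <- function(cfg, group, n) {
  Sigma <- pair_latent_cov(cfg, group)
  d <- ncol(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d)
  Z <- matrix(stats::rnorm(n * d), n, d) %*% t(L)
  lds <- sim_loadings(cfg)
  tr <- cfg$traits
  out <- tibble::tibble(zygosity = rep(group, n))
  for (t in 1:2) {
    off <- (t - 1) * (d / 2)
    A <- Z[, off + 1:4, drop = FALSE]
    C <- Z[, off + 5:8, drop = FALSE]
    E <- Z[, off + 9:12, drop = FALSE]
    P <- Z[, off + 13]
    x1 <- lds[[1]]$t1[["p"]] * P + lds[[1]]$t1[["a"]] * A[, 1] +
      lds[[1]]$t1[["c"]] * C[, 1] + lds[[1]]$t1[["e"]] * E[, 1]
    y1 <- lds[[2]]$t1[["p"]] * P + lds[[2]]$t1[["a"]] * A[, 2] +
      lds[[2]]$t1[["c"]] * C[, 2] + lds[[2]]$t1[["e"]] * E[, 2]
    x2 <- cfg$stability[[1]] * x1 + cfg$crosslag[["f"]] * y1 +
      lds[[1]]$t2[["a"]] * A[, 3] + lds[[1]]$t2[["c"]] * C[, 3] +
      lds[[1]]$t2[["e"]] * E[, 3]
    y2 <- cfg$stability[[2]] * y1 + cfg$crosslag[["g"]] * x1 +
      lds[[2]]$t2[["a"]] * A[, 4] + lds[[2]]$t2[["c"]] * C[, 4] +
      lds[[2]]$t2[["e"]] * E[, 4]
    out[[paste0(tr[1], "_t1_", t)]] <- x1
    out[[paste0(tr[2], "_t1_", t)]] <- y1
    out[[paste0(tr[1], "_t2_", t)]] <- x2
    out[[paste0(tr[2], "_t2_", t)]] <- y2
    out[[paste0("pgs_", t)]] <- P
  }
  out
}

#' Translate a simulation config into an equivalent fixed-parameter spec
#'
#' Builds the structural model that [simulate_structural()] draws from — the
#' extended cross-lagged model with a polygenic-score instrument — with every
#' matrix cell fixed at its config-implied value, so [implied_moments()]
#' returns the exact per-group covariance of the generator. Used to verify
#' that the structural simulator and the reticular moment engine agree.
#'
#' @param config a [sim_config()] object.
#' @return a [new_twin_spec()] object with no free parameters.
#' @export
config_to_spec <- function(config) {
  validate_sim_config(config)
  cfg <- config
  tr <- cfg$traits
  lds <- sim_loadings(cfg)
  sb <- sb_new("SIM_STRUCTURAL")
  stems <- c(paste0(tr[1], "_t1"), paste0(tr[2], "_t1"),
             paste0(tr[1], "_t2"), paste0(tr[2], "_t2"))
  for (t in 1:2) sb_var(sb, c(tw(stems[1], t), tw(stems[2], t),
                              tw(stems[3], t), tw(stems[4], t),
                              tw("pgs", t)), observed = TRUE)
  fac <- function(kind, i, time) paste0(kind, "_", tr[i], "_", time)
  for (kind in c("A", "C", "E")) {
    for (i in 1:2) {
      sb_ace_factor(sb, fac(kind, i, "t1"), kind)
      sb_ace_factor(sb, fac(kind, i, "t2r"), kind)
    }
  }
  fixed_cor <- function(f1, f2, kind, r) {
    if (r == 0) return()
    for (t in 1:2) sb_cov(sb, tw(f1, t), tw(f2, t), value = r)
    if (kind == "A") {
      sb_cov(sb, tw(f1, 1), tw(f2, 2), value = r, group = "MZ")
      sb_cov(sb, tw(f1, 2), tw(f2, 1), value = r, group = "MZ")
      sb_cov(sb, tw(f1, 1), tw(f2, 2), value = 0.5 * r, group = "DZ")
      sb_cov(sb, tw(f1, 2), tw(f2, 1), value = 0.5 * r, group = "DZ")
    } else if (kind == "C") {
      sb_cov(sb, tw(f1, 1), tw(f2, 2), value = r)
      sb_cov(sb, tw(f1, 2), tw(f2, 1), value = r)
    }
  }
  for (kind in c("A", "C", "E")) {
    key <- switch(kind, A = "ra", C = "rc", E = "re")
    fixed_cor(fac(kind, 1, "t1"), fac(kind, 2, "t1"), kind, cfg$cors_t1[[key]])
    fixed_cor(fac(kind, 1, "t2r"), fac(kind, 2, "t2r"), kind, cfg$cors_t2[[key]])
  }
  fixed_cor(fac("A", 1, "t1"), fac("A", 2, "t2r"), "A", cfg$crosstime[["h1"]])
  fixed_cor(fac("A", 2, "t1"), fac("A", 1, "t2r"), "A", cfg$crosstime[["h2"]])
  fixed_cor(fac("C", 1, "t1"), fac("C", 2, "t2r"), "C", cfg$crosstime[["j1"]])
  fixed_cor(fac("C", 2, "t1"), fac("C", 1, "t2r"), "C", cfg$crosstime[["j2"]])
  # polygenic score: unit variance, genetic cross-twin sharing
  for (t in 1:2) sb_cov(sb, tw("pgs", t), tw("pgs", t), value = 1)
  sb_cov(sb, tw("pgs", 1), tw("pgs", 2), value = 1, group = "MZ")
  sb_cov(sb, tw("pgs", 1), tw("pgs", 2), value = 0.5, group = "DZ")
  for (t in 1:2) {
    for (i in 1:2) {
      t1v <- tw(stems[i], t); t2v <- tw(stems[i + 2], t)
      l1 <- lds[[i]]$t1; l2 <- lds[[i]]$t2
      for (kind in c("A", "C", "E")) {
        sb_path(sb, tw(fac(kind, i, "t1"), t), t1v,
                value = l1[[tolower(kind)]])
        sb_path(sb, tw(fac(kind, i, "t2r"), t), t2v,
                value = l2[[tolower(kind)]])
      }
      if (l1[["p"]] != 0) sb_path(sb, tw("pgs", t), t1v, value = l1[["p"]])
      sb_path(sb, t1v, t2v, value = cfg$stability[[i]])
    }
    if (cfg$crosslag[["f"]] != 0) {
      sb_path(sb, tw(stems[2], t), tw(stems[3], t),
              value = cfg$crosslag[["f"]])
    }
    if (cfg$crosslag[["g"]] != 0) {
      sb_path(sb, tw(stems[1], t), tw(stems[4], t),
              value = cfg$crosslag[["g"]])
    }
  }
  sb_build(sb)
}

#' Simulate a twin cohort from a model's implied moments
#'
#' Samples pair rows from the zygosity-group multivariate normal distributions
#' implied by a spec at given parameter values. Positive semi-definiteness is
#' checked before any sampling; generation is reproducible given the seed.
#'
#' @inheritParams implied_moments
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param seed integer seed.
#' @return a twin cohort tibble with `pair_id`, `zygosity` and the spec's
#'   observed columns.
#' @export
simulate_from_model <- function(spec, params = start_values(spec),
                                n_mz = 1000, n_dz = 1000, seed = 1L) {
  mom <- implied_moments(spec, params)
  for (g in ZYGOSITY_LEVELS) {
    ev <- eigen(mom[[g]]$cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      abort(paste0("implied ", g, " covariance is not positive semi-definite"))
    }
  }
  with_seed(seed, {
    parts <- lapply(ZYGOSITY_LEVELS, function(g) {
      n <- if (g == "MZ") n_mz else n_dz
      S <- mom[[g]]$cov
      ev <- eigen(S, symmetric = TRUE)
      L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), ncol(S))
      X <- matrix(stats::rnorm(n * ncol(S)), n, ncol(S)) %*% t(L)
      colnames(X) <- spec$obs
      dplyr::bind_cols(tibble::tibble(zygosity = rep(g, n)),
                       tibble::as_tibble(X))
    })
    cohort <- dplyr::bind_rows(parts)
    cohort$pair_id <- sprintf("p%05d", seq_len(nrow(cohort)))
    dplyr::relocate(cohort, "pair_id", "zygosity")
  })
}
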