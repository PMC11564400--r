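# End-to-end analysis pipeline: read or simulate -> preprocess -> saturated
# correlations -> univariate ACE -> causal models -> compare/prune/decompose,
# emitting one JSON-able report.

#' Run the full twin analysis pipeline from a configuration
#'
#' Executes the standard analysis ladder on a cohort: data loading (from a
#' delimited file or the structural simulator), exclusion filtering,
#' residualization and standardization, saturated cross-twin correlations,
#' univariate ACE decompositions, then any requested causal models
#' (Direction-of-Causation, MRDoC, cross-lagged, extended cross-lagged) with
#' chi-square/AIC comparison, Wald pruning and trek decomposition of the
#' cross-lagged covariances. Identical configuration and seed yield an
#' identical report.
#'
#' Two diagnostic gates echo standard practice: a DoC request is flagged with
#' a warning when the univariate h2 confidence intervals of the two traits
#' overlap (DoC requires the modes of inheritance to differ sufficiently),
#' and an MRDoC causal path is not interpreted when the instrument–exposure
#' path is not significant (weak instrument).
#'
#' @param config a named list or the path of a YAML file. Blocks: `seed`;
#'   `data` (either `path` + optional `schema`, or `simulate` with
#'   [sim_config()] fields); `preprocess` (optional `exclusions` as named
#'   predicate strings, `residualize` with `targets`/`covariates`,
#'   `standardize` targets); `models` (optional `saturated` traits, `ace`
#'   traits, `doc`, `mrdoc`, `crosslag` blocks); `inference` (`alpha`).
#' @param out optional path; when given the report is written there as JSON.
#' @return the report, a nested list, invisibly when `out` is given.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$inference$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) abort("inference alpha must be in (0, 1)")
  report <- list(
    package = "twinpath",
    version = as.character(utils::packageVersion("twinpath")),
    seed = seed,
    config_hash = rlang::hash(config),
    stages = list(), warnings = character())
  note <- function(msg) report$warnings <<- c(report$warnings, msg)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  cohort <- stage("data", {
    dat <- config$data %||% abort("config lacks a data block")
    if (!is.null(dat$path)) {
      sch <- if (is.null(dat$schema)) twin_schema()
             else do.call(twin_schema, dat$schema)
      read_cohort(dat$path, sch)
    } else if (!is.null(dat$simulate)) {
      sim <- dat$simulate
      sim$seed <- sim$seed %||% seed
      do.call(sim_config, sim) |> simulate_structural()
    } else {
      abort("data block needs either 'path' or 'simulate'")
    }
  })
  report$stages$data <- list(n_pairs = nrow(cohort),
                             n_mz = sum(cohort$zygosity == "MZ"),
                             n_dz = sum(cohort$zygosity == "DZ"))

  pp <- config$preprocess %||% list()
  if (!is.null(pp$exclusions)) {
    res <- stage("exclusions", {
      crit <- lapply(pp$exclusions, function(s) {
        if (inherits(s, "formula")) s
        else stats::as.formula(paste("~", s))
      })
      apply_exclusions(cohort, crit)
    })
    cohort <- res$cohort
    report$stages$exclusions <- as.list(setNames(res$report$n_removed,
                                                 res$report$criterion))
  }
  if (!is.null(pp$residualize)) {
    cohort <- stage("residualize",
                    residualize(cohort, pp$residualize$targets,
                                pp$residualize$covariates))
    report$stages$residualize <- pp$residualize
  }
  if (!is.null(pp$standardize)) {
    cohort <- stage("standardize", standardize(cohort, unlist(pp$standardize)))
    report$stages$standardize <- pp$standardize
  }

  mods <- config$models %||% list()
  # accept either x/y fields or a traits: [x, y] pair; YAML 1.1 readers turn
  # a bare `y` key into `TRUE`, so map that back
  norm_xy <- function(block) {
    names(block)[names(block) %in% c("TRUE", "yes")] <- "y"
    if (!is.null(block$traits)) {
      block$x <- block$traits[[1]]
      block$y <- block$traits[[2]]
    }
    if (is.null(block$x) || is.null(block$y)) {
      abort("model block needs fields x and y (or traits: [x, y])")
    }
    block
  }
  fits <- list()

  if (!is.null(mods$saturated)) {
    f <- stage("saturated", {
      fit_twin_model(cohort, build_saturated_correlation_model(
        unlist(mods$saturated)))
    })
    fits$saturated <- f
    report$stages$saturated <- c(as.list(glance(f)),
                                 list(estimates = as.list(f$estimates)))
  }

  ace_h2 <- list()
  if (!is.null(mods$ace)) {
    report$stages$ace <- list()
    for (trv in unlist(mods$ace)) {
      f <- stage(paste0("ace_", trv),
                 fit_twin_model(cohort, build_ace_univariate(trv)))
      vc <- standardized_ace(f)
      ace_h2[[trv]] <- vc[vc$component == "h2", , drop = FALSE]
      fits[[paste0("ace_", trv)]] <- f
      report$stages$ace[[trv]] <- list(
        minus2ll = f$minus2ll, AIC = f$AIC, converged = f$converged,
        components = as.data.frame(vc))
    }
  }

  if (!is.null(mods$doc)) {
    d <- norm_xy(mods$doc)
    if (length(ace_h2) >= 2) {
      h <- dplyr::bind_rows(ace_h2[1:2])
      overlap <- h$conf.low[1] <= h$conf.high[2] &&
        h$conf.low[2] <= h$conf.high[1]
      if (isTRUE(overlap)) {
        note(paste0("DoC caveat: univariate h2 intervals of the two traits ",
                    "overlap; DoC models require the ACE influences on the ",
                    "phenotypes to differ sufficiently"))
      }
    }
    doc_stage <- stage("doc", {
      latent <- d$latent %||% TRUE
      chol <- fit_twin_model(cohort, build_cholesky_bivariate(
        d$x, d$y, latent = latent))
      variants <- lapply(c("both", "XtoY", "YtoX"), function(dir) {
        fit_twin_model(cohort, build_doc(d$x, d$y, direction = dir,
                                         latent = latent))
      })
      names(variants) <- c("both", "XtoY", "YtoX")
      list(cholesky = chol, variants = variants)
    })
    fits$doc <- doc_stage
    report$stages$doc <- lapply(
      c(list(cholesky = doc_stage$cholesky), doc_stage$variants),
      function(f) as.list(glance(f)))
  }

  if (!is.null(mods$mrdoc)) {
    m <- norm_xy(mods$mrdoc)
    f <- stage("mrdoc", {
      inst <- m$instrument %||% "pgs"
      fit_twin_model(dedupe_mz_instrument(cohort, inst),
                     build_mrdoc(m$x, m$y, instrument = inst))
    })
    fits$mrdoc <- f
    w <- wald_tests(f)
    p1p <- w$p.value[w$term == "p1"]
    weak <- is.na(p1p) || p1p >= alpha
    if (weak) {
      note(paste0("MRDoC: the instrument-exposure association is not ",
                  "significant (weak instrument); the causal path is not ",
                  "interpreted"))
    }
    report$stages$mrdoc <- c(as.list(glance(f)), list(
      p1 = unname(f$estimates["p1"]), p1_p_value = unname(p1p),
      d = unname(f$estimates["d"]),
      causal_interpreted = !weak))
  }

  if (!is.null(mods$crosslag)) {
    cl <- norm_xy(mods$crosslag)
    res <- stage("crosslag", {
      naive_fit <- fit_twin_model(cohort, build_crosslag(cl$x, cl$y))
      ext_fit <- fit_twin_model(cohort, build_extended_crosslag(cl$x, cl$y))
      cmp <- compare_models(naive_fit, ext_fit)
      pr <- prune_nonsignificant(ext_fit, cohort, alpha = alpha)
      dec <- list(
        xy = decompose_cross_covariance(
          ext_fit, paste0(cl$x, "_t1"), paste0(cl$y, "_t2")),
        yx = decompose_cross_covariance(
          ext_fit, paste0(cl$y, "_t1"), paste0(cl$x, "_t2")))
      list(naive = naive_fit, extended = ext_fit, comparison = cmp,
           pruned = pr, decomposition = dec)
    })
    fits$crosslag <- res
    report$stages$crosslag <- list(
      naive = as.list(glance(res$naive)),
      extended = as.list(glance(res$extended)),
      naive_vs_extended = as.list(res$comparison),
      pruned_parameters = res$pruned$pruned,
      pruned_vs_full = as.list(res$pruned$comparison),
      decomposition = lapply(res$decomposition, as.data.frame))
  }

  report$fits <- NULL  # keep the report JSON-serializable
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
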