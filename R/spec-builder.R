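# Internal builder DSL used by the model constructors. Collects parameters and
# matrix entries imperatively, then materializes a twin_spec.

sb_new <- function(family) {
  env <- new.env(parent = emptyenv())
  env$family <- family
  env$vars <- character()
  env$obs <- character()
  env$params <- list()
  env$entries <- list()
  env$meta <- list()
  env
}

sb_var <- function(sb, name, observed = FALSE) {
  new <- setdiff(name, sb$vars)
  sb$vars <- c(sb$vars, new)
  if (observed) sb$obs <- c(sb$obs, setdiff(name, sb$obs))
  invisible(sb)
}

sb_par <- function(sb, name, start, lower = -Inf, upper = Inf, class = "path") {
  if (!name %in% names(sb$params)) {
    sb$params[[name]] <- tibble::tibble(param = name, start = start,
                                        lower = lower, upper = upper,
                                        class = class)
  }
  invisible(sb)
}

sb_path <- function(sb, from, to, param = NA_character_, value = 1, group = "all") {
  sb$entries[[length(sb$entries) + 1L]] <-
    tibble::tibble(group = group, matrix = "A", from = from, to = to,
                   param = param, value = value)
  invisible(sb)
}

sb_cov <- function(sb, v1, v2, param = NA_character_, value = 1, group = "all") {
  sb$entries[[length(sb$entries) + 1L]] <-
    tibble::tibble(group = group, matrix = "S", from = v1, to = v2,
                   param = param, value = value)
  invisible(sb)
}

sb_build <- function(sb) {
  params <- dplyr::bind_rows(sb$params)
  if (!nrow(params)) {
    params <- tibble::tibble(param = character(), start = numeric(),
                             lower = numeric(), upper = numeric(),
                             class = character())
  }
  new_twin_spec(sb$family, sb$vars, sb$obs, params,
                dplyr::bind_rows(sb$entries), sb$meta)
}

tw <- function(base, twin) paste0(base, "_", twin)

# Unit-variance biometric factor pair (one per twin) with the classical
# cross-twin covariance: A shared 1.0 (MZ) / 0.5 (DZ), C shared 1.0 in both
# groups, E uncorrelated across twins.
sb_ace_factor <- function(sb, base, kind) {
  for (t in 1:2) {
    sb_var(sb, tw(base, t))
    sb_cov(sb, tw(base, t), tw(base, t), value = 1)
  }
  if (kind == "A") {
    sb_cov(sb, tw(base, 1), tw(base, 2), value = 1, group = "MZ")
    sb_cov(sb, tw(base, 1), tw(base, 2), value = 0.5, group = "DZ")
  } else if (kind == "C") {
    sb_cov(sb, tw(base, 1), tw(base, 2), value = 1)
  } else if (kind != "E") {
    abort("kind must be A, C or E")
  }
  invisible(sb)
}

# Correlation between two unit-variance factors of the same biometric kind,
# applied within each twin and across twins with the kind's sharing rule.
sb_factor_cor <- function(sb, f1, f2, kind, param) {
  sb_par(sb, param, start = 0.2, lower = -0.99, upper = 0.99, class = "cor")
  for (t in 1:2) sb_cov(sb, tw(f1, t), tw(f2, t), param = param)
  if (kind == "A") {
    sb_cov(sb, tw(f1, 1), tw(f2, 2), param = param, value = 1, group = "MZ")
    sb_cov(sb, tw(f1, 2), tw(f2, 1), param = param, value = 1, group = "MZ")
    sb_cov(sb, tw(f1, 1), tw(f2, 2), param = param, value = 0.5, group = "DZ")
    sb_cov(sb, tw(f1, 2), tw(f2, 1), param = param, value = 0.5, group = "DZ")
  } else if (kind == "C") {
    sb_cov(sb, tw(f1, 1), tw(f2, 2), param = param)
    sb_cov(sb, tw(f1, 2), tw(f2, 1), param = param)
  }
  invisible(sb)
}

# ACE decomposition of one phenotype variable (already present in the spec):
# adds unit A/C/E factors and loading paths, duplicated across twins.
sb_ace_on <- function(sb, pheno_base, suffix, a_start = 0.55,
                      pnames = paste0(c("a", "c", "e"), "_", suffix)) {
  for (i in seq_along(c("A", "C", "E"))) {
    kind <- c("A", "C", "E")[i]
    base <- paste0(kind, "_", suffix)
    sb_ace_factor(sb, base, kind)
    p <- pnames[i]
    sb_par(sb, p, start = if (kind == "E") 0.4 else a_start, class = "load")
    for (t in 1:2) sb_path(sb, tw(base, t), tw(pheno_base, t), param = p)
  }
  invisible(sb)
}

# Latent phenotype factor measured by two indicators; scaling fixes the first
# loading at 1, frees the second, and constrains both residual variances equal.
sb_measurement <- function(sb, factor_base, indicators, suffix) {
  lam <- paste0("lam_", suffix)
  th <- paste0("res_", suffix)
  sb_par(sb, lam, start = 1, class = "meas")
  sb_par(sb, th, start = 0.2, lower = 0, class = "var")
  for (t in 1:2) {
    sb_var(sb, tw(indicators, t), observed = TRUE)
    sb_path(sb, tw(factor_base, t), tw(indicators[1], t), value = 1)
    sb_path(sb, tw(factor_base, t), tw(indicators[2], t), param = lam)
    sb_cov(sb, tw(indicators[1], t), tw(indicators[1], t), param = th)
    sb_cov(sb, tw(indicators[2], t), tw(indicators[2], t), param = th)
  }
  invisible(sb)
}
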