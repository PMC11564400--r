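#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats pchisq qnorm pnorm rnorm lm resid sd var setNames
#' @importFrom utils head modifyList
NULL

ZYGOSITY_LEVELS <- c("MZ", "DZ")

#' Construct a twin model specification
#'
#' A `twin_spec` holds the reticular (RAM) representation of a biometric twin
#' model: one-headed paths (matrix `A`, regressions and loadings), two-headed
#' arcs (matrix `S`, variances and covariances) and a filter selecting the
#' observed variables, with separate matrices per zygosity group. Each matrix
#' cell is either a fixed constant or `multiplier * parameter`, so MZ/DZ
#' structural constants (e.g. the 0.5 scaling of DZ additive-genetic sharing)
#' are encoded as multipliers on shared parameter objects, which imposes
#' cross-group equality constraints by construction. Means are fixed at zero:
#' phenotypes are expected to be residualized and standardized upstream.
#'
#' Model constructors in the package (e.g. [build_ace_univariate()],
#' [build_extended_crosslag()]) return objects of this class; users rarely
#' call `new_twin_spec()` directly.
#'
#' @param family character tag for the model family.
#' @param vars character vector of all variable names (latent and observed).
#' @param obs character vector of observed variable names; these must match
#'   cohort column names when the spec is fitted to data.
#' @param params tibble with columns `param`, `start`, `lower`, `upper`,
#'   `class` (one of `"load"`, `"path"`, `"cor"`, `"var"`, `"meas"`).
#' @param entries tibble with columns `group` (`"MZ"`, `"DZ"` or `"all"`),
#'   `matrix` (`"A"` or `"S"`), `from`, `to`, `param` (name or `NA` for fixed
#'   cells) and `value` (the constant, or the multiplier on the parameter).
#'   `A` entries are directed `from -> to`; `S` entries are symmetric and
#'   specified once.
#' @param meta named list of family-specific metadata (e.g. which parameters
#'   are cross-lags or cross-time correlations, used by the trek
#'   decomposition and by [standardized_ace()]).
#' @return an object of class `twin_spec`.
#' @export
new_twin_spec <- function(family, vars, obs, params, entries, meta = list()) {
  stopifnot(is.character(vars), is.character(obs), all(obs %in% vars))
  params <- tibble::as_tibble(params)
  entries <- tibble::as_tibble(entries)
  if (anyDuplicated(vars)) abort("duplicate variable names in spec")
  if (anyDuplicated(params$param)) abort("duplicate parameter names in spec")
  bad <- setdiff(stats::na.omit(entries$param), params$param)
  if (length(bad)) abort(paste0("entries reference unknown parameters: ",
                                paste(bad, collapse = ", ")))
  unused <- setdiff(params$param, entries$param)
  if (length(unused)) abort(paste0("free parameters appear in no matrix cell: ",
                                   paste(unused, collapse = ", ")))
  bad_v <- setdiff(c(entries$from, entries$to), vars)
  if (length(bad_v)) abort(paste0("entries reference unknown variables: ",
                                  paste(bad_v, collapse = ", ")))
  structure(
    list(family = family, vars = vars, obs = obs,
         params = params, entries = entries, meta = meta),
    class = "twin_spec")
}

#' @export
print.twin_spec <- function(x, ...) {
  cat("<twin_spec> family:", x$family, "\n")
  cat("  variables:", length(x$vars), "(", length(x$obs), "observed )\n")
  cat("  free parameters:", nrow(x$params), "\n")
  invisible(x)
}

#' Number of free parameters of a spec
#' @param spec a [new_twin_spec()] object.
#' @return integer count of free parameters.
#' @export
n_free_params <- function(spec) nrow(spec$params)

#' Default start values of a spec
#' @param spec a [new_twin_spec()] object.
#' @return named numeric vector of start values.
#' @export
start_values <- function(spec) setNames(spec$params$start, spec$params$param)

# Compile the entry table into index vectors for fast matrix assembly.
# Cached on the spec via attribute so repeated likelihood evaluations are cheap.
compile_spec <- function(spec) {
  cached <- attr(spec, "compiled")
  if (!is.null(cached)) return(cached)
  nv <- length(spec$vars)
  vidx <- setNames(seq_len(nv), spec$vars)
  pidx <- setNames(seq_len(nrow(spec$params)), spec$params$param)
  groups <- lapply(ZYGOSITY_LEVELS, function(g) {
    e <- spec$entries[spec$entries$group %in% c(g, "all"), , drop = FALSE]
    dup <- paste(e$matrix, e$from, e$to)
    if (anyDuplicated(dup)) {
      abort(paste0("duplicate matrix cell in group ", g, ": ",
                   paste(unique(dup[duplicated(dup)]), collapse = "; ")))
    }
    i <- vidx[e$from]; j <- vidx[e$to]
    # A[to, from] convention: column = source, row = destination
    a_sel <- e$matrix == "A"
    s_sel <- !a_sel
    lin_a <- vidx[e$to[a_sel]] + (vidx[e$from[a_sel]] - 1L) * nv
    # S symmetric: duplicate off-diagonal cells
    si <- vidx[e$from[s_sel]]; sj <- vidx[e$to[s_sel]]
    off <- si != sj
    lin_s <- c(si + (sj - 1L) * nv, si[off] * nv + sj[off] - nv)
    s_par <- c(e$param[s_sel], e$param[s_sel][off])
    s_val <- c(e$value[s_sel], e$value[s_sel][off])
    a_par <- e$param[a_sel]; a_val <- e$value[a_sel]
    A0 <- matrix(0, nv, nv); S0 <- matrix(0, nv, nv)
    a_fix <- is.na(a_par); s_fix <- is.na(s_par)
    A0[lin_a[a_fix]] <- a_val[a_fix]
    S0[lin_s[s_fix]] <- s_val[s_fix]
    list(
      A0 = A0, S0 = S0,
      a_idx = lin_a[!a_fix], a_par = pidx[a_par[!a_fix]], a_mult = a_val[!a_fix],
      s_idx = lin_s[!s_fix], s_par = pidx[s_par[!s_fix]], s_mult = s_val[!s_fix],
      # edge list used by the trek decomposition
      edges = tibble::tibble(from = e$from[a_sel], to = e$to[a_sel],
                             param = e$param[a_sel], value = e$value[a_sel]),
      arcs  = tibble::tibble(v1 = e$from[s_sel], v2 = e$to[s_sel],
                             param = e$param[s_sel], value = e$value[s_sel]))
  })
  names(groups) <- ZYGOSITY_LEVELS
  compiled <- list(nv = nv, vidx = vidx, obs_idx = vidx[spec$obs],
                   groups = groups)
  compiled
}

# Returns list(A=..., S=...) full matrices for one group at parameter values.
group_matrices <- function(compiled, g, theta) {
  gr <- compiled$groups[[g]]
  A <- gr$A0; S <- gr$S0
  if (length(gr$a_idx)) A[gr$a_idx] <- theta[gr$a_par] * gr$a_mult
  if (length(gr$s_idx)) S[gr$s_idx] <- theta[gr$s_par] * gr$s_mult
  list(A = A, S = S)
}

as_theta <- function(spec, params) {
  nm <- spec$params$param
  if (is.null(names(params))) {
    if (length(params) != length(nm)) abort("parameter vector has wrong length")
    return(setNames(as.numeric(params), nm))
  }
  miss <- setdiff(nm, names(params))
  if (length(miss)) abort(paste0("missing parameter values: ",
                                 paste(miss, collapse = ", ")))
  setNames(as.numeric(params[nm]), nm)
}

#' Model-implied moments per zygosity group
#'
#' Evaluates the reticular covariance formula
#' \eqn{\Sigma = F (I - A)^{-1} S (I - A)^{-\top} F^\top} for each zygosity
#' group at the given parameter values. Means are zero by construction.
#'
#' @param spec a [new_twin_spec()] object.
#' @param params named numeric vector of free-parameter values (defaults to
#'   the spec's start values).
#' @return list with elements `MZ` and `DZ`, each a list holding `mean`
#'   (zero vector) and `cov` (symmetric covariance over observed variables).
#' @examples
#' spec <- build_ace_univariate("x")
#' implied_moments(spec, c(a = sqrt(1/3), c = sqrt(1/3), e = sqrt(1/3)))
#' @export
implied_moments <- function(spec, params = start_values(spec)) {
  theta <- as_theta(spec, params)
  cm <- compile_spec(spec)
  out <- lapply(ZYGOSITY_LEVELS, function(g) {
    m <- group_matrices(cm, g, theta)
    IA <- diag(cm$nv) - m$A
    B <- tryCatch(solve(IA), error = function(e) {
      abort(paste0("(I - A) is singular in group ", g,
                   "; reciprocal causal paths form a non-invertible loop"))
    })
    # guard against explosive reciprocal loops (spectral radius >= 1)
    full <- B %*% m$S %*% t(B)
    cov <- full[cm$obs_idx, cm$obs_idx, drop = FALSE]
    cov <- (cov + t(cov)) / 2
    dimnames(cov) <- list(spec$obs, spec$obs)
    list(mean = setNames(rep(0, length(spec$obs)), spec$obs), cov = cov)
  })
  names(out) <- ZYGOSITY_LEVELS
  out
}

# ---- data preparation for FIML ------------------------------------------

# Extract per-group observed-data matrices from a cohort tibble.
cohort_matrices <- function(spec, cohort) {
  miss <- setdiff(spec$obs, names(cohort))
  if (length(miss)) {
    abort(paste0("cohort lacks columns required by the model: ",
                 paste(miss, collapse = ", ")))
  }
  if (!"zygosity" %in% names(cohort)) abort("cohort lacks a zygosity column")
  lapply(setNames(ZYGOSITY_LEVELS, ZYGOSITY_LEVELS), function(g) {
    rows <- cohort$zygosity == g
    as.matrix(cohort[rows, spec$obs, drop = FALSE])
  })
}

# Group rows by missingness pattern and precompute per-pattern sufficient
# statistics (count + scatter matrix), making each likelihood evaluation
# O(#patterns * p^3) rather than O(n * p^3).
pattern_stats <- function(X) {
  if (nrow(X) == 0) return(list())
  obs <- !is.na(X)
  key <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  keep <- key != ""          # rows with nothing observed contribute 0
  X <- X[keep, , drop = FALSE]; key <- key[keep]
  split_idx <- split(seq_len(nrow(X)), key)
  lapply(split_idx, function(ix) {
    cols <- as.integer(strsplit(key[ix[1]], ",")[[1]])
    Xi <- X[ix, cols, drop = FALSE]
    list(cols = cols, n = length(ix), scatter = crossprod(Xi))
  })
}

# -2 log likelihood for one group given implied covariance and pattern stats.
group_m2ll <- function(Sigma, stats_list, g) {
  total <- 0
  for (st in stats_list) {
    S_sub <- Sigma[st$cols, st$cols, drop = FALSE]
    R <- tryCatch(chol(S_sub), error = function(e) NULL)
    if (is.null(R)) {
      abort(paste0("implied covariance not positive definite in group ", g,
                   " on missingness pattern {",
                   paste(st$cols, collapse = ","), "}"))
    }
    logdet <- 2 * sum(log(diag(R)))
    quad <- sum(chol2inv(R) * st$scatter)
    total <- total + st$n * (length(st$cols) * log(2 * pi) + logdet) + quad
  }
  total
}

#' Full-information maximum-likelihood deviance of a cohort under a spec
#'
#' Computes \eqn{-2 \log L} summed over twin pairs: each pair contributes the
#' multivariate-normal log density of its *observed* subvector under its
#' zygosity group's implied moments, with missing entries marginalized by
#' dropping the corresponding rows/columns of the implied mean and
#' covariance. Pairs with no observed entries contribute zero.
#'
#' @inheritParams implied_moments
#' @param cohort a twin cohort tibble whose columns include `zygosity` and
#'   the spec's observed variables.
#' @return the deviance (a single number).
#' @export
fiml_minus2ll <- function(spec, params, cohort) {
  mats <- cohort_matrices(spec, cohort)
  stats_by_group <- lapply(mats, pattern_stats)
  mom <- implied_moments(spec, params)
  sum(vapply(ZYGOSITY_LEVELS, function(g) {
    group_m2ll(mom[[g]]$cov, stats_by_group[[g]], g)
  }, numeric(1)))
}
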