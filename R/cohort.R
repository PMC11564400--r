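# Twin-pair data model: wide one-row-per-pair tables, delimited-text IO,
# exclusion filtering, covariate residualization and standardization.

#' Variable schema for a wide twin-pair table
#'
#' Describes which columns a cohort file must contain: per-twin phenotype
#' columns `<trait>_<time>_<twin>` for every trait/timepoint combination,
#' per-twin instrument columns `<instrument>_<twin>`, covariates (per twin
#' when listed in `twin_covariates`, per pair otherwise) and the mandatory
#' `pair_id` and `zygosity` columns.
#'
#' @param traits character vector of trait stems (e.g. `c("cd", "tr", "pb",
#'   "pg")`).
#' @param times character vector of timepoint suffixes (default `t1`, `t2`,
#'   ages 3 and 4 years).
#' @param twin_covariates covariate stems measured per twin (expand to
#'   `<stem>_1`, `<stem>_2`).
#' @param pair_covariates covariate columns measured once per pair.
#' @param instrument instrument stem measured per twin, or `NULL`.
#' @return a list of class `twin_schema` with the expanded column sets.
#' @export
twin_schema <- function(traits = c("cd", "tr", "pb", "pg"),
                        times = c("t1", "t2"),
                        twin_covariates = "sex",
                        pair_covariates = c("age_t1", "age_t2"),
                        instrument = "pgs") {
  grid <- tidyr::expand_grid(trait = traits, time = times, twin = 1:2)
  grid$column <- paste(grid$trait, grid$time, grid$twin, sep = "_")
  pheno <- grid$column
  inst <- if (is.null(instrument)) character() else paste0(instrument, "_", 1:2)
  cov_twin <- if (length(twin_covariates)) {
    as.vector(outer(twin_covariates, 1:2, paste, sep = "_"))
  } else character()
  cols <- c("pair_id", "zygosity", cov_twin, pair_covariates, pheno, inst)
  if (anyDuplicated(cols)) {
    abort(paste0("schema produces duplicate column labels: ",
                 paste(unique(cols[duplicated(cols)]), collapse = ", ")))
  }
  structure(list(traits = traits, times = times,
                 phenotypes = tibble::as_tibble(grid),
                 instrument = instrument, instrument_cols = inst,
                 twin_covariates = twin_covariates,
                 pair_covariates = pair_covariates,
                 numeric_cols = c(cov_twin, pair_covariates, pheno, inst),
                 columns = cols),
            class = "twin_schema")
}

#' @export
print.twin_schema <- function(x, ...) {
  cat("<twin_schema>", length(x$traits), "traits x", length(x$times),
      "timepoints;", length(x$columns), "columns\n")
  invisible(x)
}

#' Read a wide twin-pair cohort from a delimited text file
#'
#' Comma-separated wide format, one row per pair, missing values as empty
#' fields. Columns are validated against the schema: a missing required
#' column raises a schema error naming the column; a non-numeric phenotype
#' cell raises a parse error with its row and column.
#'
#' @param path file path.
#' @param schema a [twin_schema()]; extra columns in the file are kept.
#' @return a twin cohort tibble.
#' @export
read_cohort <- function(path, schema = twin_schema()) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  missing_cols <- setdiff(schema$columns, names(raw))
  if (length(missing_cols)) {
    abort(paste0("cohort file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (cl in intersect(schema$numeric_cols, names(raw))) {
    v <- raw[[cl]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      abort(paste0("non-numeric value '", v[bad[1]], "' in column ", cl,
                   ", row ", bad[1]))
    }
    raw[[cl]] <- num
  }
  validate_cohort(raw, schema)
  raw
}

#' Write a cohort back to delimited text
#'
#' Inverse of [read_cohort()]: comma-separated, missing cells as empty
#' fields, so a write/read round trip preserves values and missingness
#' patterns exactly (to numeric print precision).
#'
#' @param cohort a twin cohort tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Validate a cohort against a schema
#'
#' Checks zygosity codes, pair-identifier uniqueness and numeric phenotype
#' types. Called by [read_cohort()]; exported for cohorts built in memory.
#'
#' @inheritParams write_cohort
#' @param schema a [twin_schema()].
#' @return the cohort, invisibly.
#' @export
validate_cohort <- function(cohort, schema = NULL) {
  if (!"zygosity" %in% names(cohort)) abort("cohort lacks a zygosity column")
  zy <- cohort$zygosity
  bad <- setdiff(unique(zy[!is.na(zy)]), ZYGOSITY_LEVELS)
  if (length(bad)) {
    abort(paste0("zygosity must be one of MZ/DZ; found: ",
                 paste(bad, collapse = ", ")))
  }
  if ("pair_id" %in% names(cohort) && anyDuplicated(cohort$pair_id)) {
    abort("pair identifiers are not unique")
  }
  if (!is.null(schema)) {
    for (cl in intersect(schema$numeric_cols, names(cohort))) {
      if (!is.numeric(cohort[[cl]])) {
        abort(paste0("phenotype column ", cl, " is not numeric"))
      }
    }
  }
  invisible(cohort)
}

#' Apply pair-wise exclusion criteria
#'
#' Each criterion is a named one-sided formula (or function of the cohort)
#' evaluating to one logical per pair; pairs matching *any* criterion are
#' dropped (if either twin matches, the whole pair goes, so twin-level flags
#' should be combined as e.g. `~ flag_1 | flag_2`). `NA` predicate values are
#' treated as non-matching.
#'
#' @param cohort a twin cohort tibble.
#' @param criteria named list of one-sided formulas or functions.
#' @return a list with `cohort` (retained pairs) and `report` (tibble of
#'   per-criterion removal counts; overlapping criteria both count a pair).
#' @examples
#' cohort <- simulate_structural(sim_config(n_mz = 5, n_dz = 5))
#' apply_exclusions(cohort, list(missing_zygosity = ~ is.na(zygosity)))$report
#' @export
apply_exclusions <- function(cohort, criteria = list()) {
  if (length(criteria) && is.null(names(criteria))) {
    abort("criteria must be a named list")
  }
  flags <- matrix(FALSE, nrow(cohort), length(criteria))
  for (i in seq_along(criteria)) {
    cr <- criteria[[i]]
    nm <- names(criteria)[i]
    v <- tryCatch({
      if (inherits(cr, "formula")) {
        rlang::eval_tidy(rlang::f_rhs(cr), data = cohort)
      } else if (is.function(cr)) {
        cr(cohort)
      } else {
        abort("each criterion must be a formula or a function")
      }
    }, error = function(e) {
      abort(paste0("criterion '", nm, "' failed to evaluate: ",
                   conditionMessage(e)))
    })
    if (!is.logical(v) || length(v) != nrow(cohort)) {
      abort(paste0("criterion '", nm, "' must yield one logical per pair"))
    }
    flags[, i] <- !is.na(v) & v
  }
  drop <- if (ncol(flags)) rowSums(flags) > 0 else rep(FALSE, nrow(cohort))
  report <- tibble::tibble(
    criterion = names(criteria) %||% character(),
    n_removed = if (ncol(flags)) colSums(flags) else integer())
  list(cohort = cohort[!drop, , drop = FALSE], report = report)
}

# Expand a variable stem to its two per-twin columns if present, else keep
# the name as a pair-level column.
twin_cols <- function(cohort, stem) {
  cand <- paste0(stem, "_", 1:2)
  if (all(cand %in% names(cohort))) return(cand)
  if (stem %in% names(cohort)) return(c(stem, stem))
  abort(paste0("variable '", stem, "' not found (looked for ",
               paste(cand, collapse = ", "), " or ", stem, ")"))
}

#' Drop the duplicate polygenic score of MZ co-twins
#'
#' MZ co-twins carry identical polygenic scores, so a model that fixes their
#' cross-twin score covariance at the full score variance implies a singular
#' MZ covariance matrix and the pair density does not exist. Setting the
#' second twin's score to missing for MZ pairs lets full-information maximum
#' likelihood marginalize the redundant column without losing information.
#' Call this before fitting an MRDoC model.
#'
#' @param cohort a twin cohort tibble.
#' @param instrument instrument column stem (default `"pgs"`).
#' @return the cohort with `<instrument>_2` set missing for MZ pairs.
#' @export
dedupe_mz_instrument <- function(cohort, instrument = "pgs") {
  col <- paste0(instrument, "_2")
  if (!col %in% names(cohort)) {
    abort(paste0("cohort lacks column ", col))
  }
  cohort[[col]][cohort$zygosity == "MZ"] <- NA_real_
  cohort
}

#' Residualize phenotypes for covariates
#'
#' Replaces each target by its residual from an ordinary least-squares
#' regression on the covariates (plus intercept), fitted over all non-missing
#' twin-level observations pooled across both twins — the same coefficient
#' vector is applied to either twin's scores. Covariates may be per-twin
#' stems (columns `<stem>_1`, `<stem>_2`, e.g. sex) or pair-level columns
#' applied to both twins (e.g. assessment age). Rows with missing covariate
#' values keep the target missing; a zero-variance covariate is dropped with
#' a warning.
#'
#' @param cohort a twin cohort tibble.
#' @param targets character vector of phenotype stems (per-twin columns
#'   `<stem>_1`, `<stem>_2`).
#' @param covariates character vector of covariate stems or column names.
#' @return the cohort with targets replaced by residuals.
#' @export
residualize <- function(cohort, targets, covariates) {
  for (tgt in targets) {
    tcols <- paste0(tgt, "_", 1:2)
    miss <- setdiff(tcols, names(cohort))
    if (length(miss)) {
      abort(paste0("target '", tgt, "' lacks columns: ",
                   paste(miss, collapse = ", ")))
    }
    covs <- lapply(covariates, function(cv) twin_cols(cohort, cv))
    names(covs) <- covariates
    keep <- vapply(covariates, function(cv) {
      x <- c(cohort[[covs[[cv]][1]]], cohort[[covs[[cv]][2]]])
      ok <- stats::var(x, na.rm = TRUE)
      if (!is.na(ok) && ok == 0) {
        warn(paste0("covariate '", cv, "' has zero variance; dropped"))
        FALSE
      } else TRUE
    }, logical(1))
    covariates_kept <- covariates[keep]
    y <- c(cohort[[tcols[1]]], cohort[[tcols[2]]])
    df <- data.frame(.y = y)
    if (length(covariates_kept)) {
      X <- vapply(covariates_kept, function(cv) {
        c(cohort[[covs[[cv]][1]]], cohort[[covs[[cv]][2]]])
      }, numeric(2 * nrow(cohort)))
      df <- cbind(df, as.data.frame(X))
    }
    fit <- stats::lm(.y ~ ., data = df, na.action = stats::na.exclude)
    r <- stats::resid(fit)
    n <- nrow(cohort)
    cohort[[tcols[1]]] <- r[seq_len(n)]
    cohort[[tcols[2]]] <- r[n + seq_len(n)]
  }
  cohort
}

#' Standardize phenotypes over pooled twin observations
#'
#' Z-scores each target using the mean and standard deviation of the pooled
#' non-missing observations of both twins, so co-twins share one scale.
#'
#' @inheritParams residualize
#' @return the cohort with standardized targets.
#' @export
standardize <- function(cohort, targets) {
  for (tgt in targets) {
    tcols <- paste0(tgt, "_", 1:2)
    miss <- setdiff(tcols, names(cohort))
    if (length(miss)) {
      abort(paste0("target '", tgt, "' lacks columns: ",
                   paste(miss, collapse = ", ")))
    }
    x <- c(cohort[[tcols[1]]], cohort[[tcols[2]]])
    if (sum(!is.na(x)) < 2) {
      abort(paste0("target '", tgt, "' has fewer than 2 non-missing values"))
    }
    s <- stats::sd(x, na.rm = TRUE)
    if (s == 0) abort(paste0("target '", tgt, "' has zero variance"))
    m <- mean(x, na.rm = TRUE)
    cohort[[tcols[1]]] <- (cohort[[tcols[1]]] - m) / s
    cohort[[tcols[2]]] <- (cohort[[tcols[2]]] - m) / s
  }
  cohort
}
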