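# Wright path-tracing: enumerate the treks connecting two variables of an
# acyclic model and group their contributions to the implied covariance.

# All directed paths ending at `v` (followed backwards through one-headed
# edges): returns a data frame of (top variable, coefficient product, edge
# parameter names concatenated). Includes the empty path (top = v, prod = 1).
paths_into <- function(v, edges, memo) {
  if (!is.null(memo[[v]])) return(memo[[v]])
  res <- list(list(top = v, prod = 1, pars = character()))
  inc <- which(edges$to == v)
  for (k in inc) {
    sub <- paths_into(edges$from[k], edges, memo)
    for (p in sub) {
      res[[length(res) + 1]] <- list(
        top = p$top, prod = p$prod * edges$value[k],
        pars = c(p$pars, edges$param[k]))
    }
  }
  memo[[v]] <- res
  res
}

has_cycle <- function(edges, vars) {
  colour <- setNames(rep(0L, length(vars)), vars)
  visit <- function(v) {
    colour[[v]] <<- 1L
    for (w in edges$from[edges$to == v]) {
      if (colour[[w]] == 1L) return(TRUE)
      if (colour[[w]] == 0L && visit(w)) return(TRUE)
    }
    colour[[v]] <<- 2L
    FALSE
  }
  any(vapply(vars, function(v) colour[[v]] == 0L && visit(v), logical(1)))
}

resolve_var <- function(spec, v) {
  if (v %in% spec$vars) return(v)
  if (tw(v, 1) %in% spec$vars) return(tw(v, 1))
  abort(paste0("variable '", v, "' not in the model"))
}

# Edge and arc tables of one group at the fitted parameter values.
group_graph <- function(spec, theta, group) {
  cm <- compile_spec(spec)
  gr <- cm$groups[[group]]
  ed <- gr$edges
  ed$value <- ifelse(is.na(ed$param), ed$value,
                     ed$value * theta[ed$param])
  ar <- gr$arcs
  ar$value <- ifelse(is.na(ar$param), ar$value,
                     ar$value * theta[ar$param])
  list(edges = ed, arcs = ar)
}

# Enumerate all treks from `from` to `to` in one group: a backward one-headed
# chain, exactly one two-headed arc (a variance or covariance), and a forward
# one-headed chain. Returns one row per trek with its value, the arc
# endpoints and the union of parameter names on its one-headed edges.
trek_table <- function(fit, from, to, group = "MZ") {
  spec <- fit$spec
  theta <- fit$estimates
  from <- resolve_var(spec, from)
  to <- resolve_var(spec, to)
  gg <- group_graph(spec, theta, group)
  if (has_cycle(gg$edges, spec$vars)) {
    abort("trek decomposition is defined only for recursive (acyclic) models")
  }
  memo_b <- new.env(parent = emptyenv())
  back <- paths_into(from, gg$edges, memo_b)
  fwd <- paths_into(to, gg$edges, memo_b)
  back_by_top <- split(back, vapply(back, `[[`, "", "top"))
  fwd_by_top <- split(fwd, vapply(fwd, `[[`, "", "top"))
  rows <- list()
  ar <- gg$arcs
  for (k in seq_len(nrow(ar))) {
    ends <- unique(c(ar$v1[k], ar$v2[k]))
    combos <- if (length(ends) == 1) {
      list(c(ends, ends))
    } else {
      list(c(ar$v1[k], ar$v2[k]), c(ar$v2[k], ar$v1[k]))
    }
    for (cc in combos) {
      bs <- back_by_top[[cc[1]]]
      fs <- fwd_by_top[[cc[2]]]
      if (is.null(bs) || is.null(fs)) next
      for (b in bs) for (f in fs) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          value = b$prod * ar$value[k] * f$prod,
          arc_v1 = cc[1], arc_v2 = cc[2],
          arc_param = ar$param[k],
          edge_params = list(unique(c(b$pars, f$pars))))
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(value = numeric(), arc_v1 = character(),
                          arc_v2 = character(), arc_param = character(),
                          edge_params = list()))
  }
  dplyr::bind_rows(rows)
}

#' Decompose a model-implied cross covariance into trek groups
#'
#' Enumerates every Wright path-tracing trek connecting two variables (within
#' twin 1) and partitions the model-implied covariance into four groups:
#' treks through a direct cross-lagged path, treks whose two-headed arc is a
#' cross-time genetic correlation, treks whose arc is a cross-time
#' shared-environment correlation, and the remainder (within-time
#' correlations combined with stability paths). Group contributions sum to
#' the implied covariance exactly; percentages are signed, so one group may
#' exceed 100% when another is negative.
#'
#' @param fit a `twin_fit` of an acyclic model (cross-lagged families).
#' @param from,to variable names, e.g. `"cd_t1"` and `"pb_t2"`.
#' @param group zygosity group to trace in; within-person covariances are
#'   identical across groups.
#' @return a tibble of class `twin_decomposition` with `group`,
#'   `contribution` and `percent`, plus attributes `total` (trek sum) and
#'   `implied` (the matching entry of [implied_moments()]).
#' @export
decompose_cross_covariance <- function(fit, from, to, group = "MZ") {
  spec <- fit$spec
  tg <- spec$meta$trek_groups %||%
    list(direct = unname(spec$meta$crosslag %||% character()),
         rA = character(), rC = character())
  tt <- trek_table(fit, from, to, group)
  cls <- vapply(seq_len(nrow(tt)), function(i) {
    direct <- any(tt$edge_params[[i]] %in% tg$direct)
    arcp <- tt$arc_param[i]
    in_rA <- !is.na(arcp) && arcp %in% tg$rA
    in_rC <- !is.na(arcp) && arcp %in% tg$rC
    if (direct && (in_rA || in_rC)) {
      abort("trek grouping is not a partition: a direct-path trek carries a cross-time arc")
    }
    if (direct) "direct" else if (in_rA) "cross_time_rA"
    else if (in_rC) "cross_time_rC" else "within_time_stability"
  }, character(1))
  lev <- c("direct", "cross_time_rA", "cross_time_rC", "within_time_stability")
  agg <- tapply(tt$value, factor(cls, levels = lev), sum, default = 0)
  total <- sum(tt$value)
  mom <- implied_moments(spec, fit$estimates)
  fv <- resolve_var(spec, from); tv <- resolve_var(spec, to)
  implied <- mom[[group]]$cov[fv, tv]
  if (abs(total - implied) > 1e-6 * max(1, abs(implied))) {
    abort("internal error: trek total does not match the implied covariance")
  }
  out <- tibble::tibble(group = lev, contribution = as.numeric(agg),
                        percent = if (total != 0) 100 * as.numeric(agg) / total
                                  else rep(NA_real_, 4))
  attr(out, "total") <- total
  attr(out, "implied") <- implied
  attr(out, "from") <- fv
  attr(out, "to") <- tv
  class(out) <- c("twin_decomposition", class(out))
  out
}
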