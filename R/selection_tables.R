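# Ego-alter selection tables: the tie-formation log-odds of an (ego level,
# alter level) pair relative to a dyad at the school-mean level, built from
# the fitted ego / alter / similarity parameters, pooled across schools.

.beh_category_labels <- list(
  alcohol = c("never", "infrequent", "monthly", "weekly_plus"),
  control = c("low", "moderate", "high"),
  secrecy = c("secretive", "moderate", "disclosive")
)

#' Per-school ego-alter log-odds table
#'
#' Cell (e, a) is the linear combination
#' `b_ego (v_e - vbar) + b_alt (v_a - vbar) + b_sim (sim(v_e, v_a) - sbar)`
#' minus the same combination for two actors at the school mean `vbar`, i.e.
#' the log-odds of a tie between an ego at level `v_e` and an alter at level
#' `v_a` relative to a mean-mean dyad. The variance of each cell is
#' `g' Sigma g` with `g` the coefficient-difference vector and `Sigma` the
#' fitted covariance of (ego, alter, similarity).
#'
#' @param fit a `saom_fit` whose model contains the behavior's ego, alter and
#'   similarity tie effects.
#' @param behavior `"alcohol"`, `"control"` or `"secrecy"`.
#' @param categories level grid (default: the behavior's full range).
#' @param school_mean,mean_similarity,range centering constants; default from
#'   the fit's model spec.
#' @return List with `log_odds` and `variance` (K x K matrices, ego in rows),
#'   plus the category grid and behavior name.
#' @export
school_log_odds_table <- function(fit, behavior,
                                  categories = NULL,
                                  school_mean = NULL,
                                  mean_similarity = NULL,
                                  range = NULL) {
  behavior <- match.arg(behavior, .beh_dims)
  categories <- categories %||% .beh_levels[[behavior]]
  cc <- fit$spec$centering
  school_mean <- school_mean %||% unname(cc$zbar[[behavior]])
  mean_similarity <- mean_similarity %||% unname(cc$sbar[[behavior]])
  range <- range %||% unname(cc$range[[behavior]])

  terms <- paste0(behavior, c("_ego", "_alter", "_similarity"))
  if (!all(terms %in% names(fit$par)))
    abort(sprintf("fit lacks free ego/alter/similarity effects for %s", behavior))
  beta <- fit$par[terms]
  Sigma <- fit$covariance[terms, terms]
  if (anyNA(Sigma)) abort("missing covariance entries for the selection terms")

  K <- length(categories)
  # contrast vs the mean-mean dyad: sim(vbar, vbar) = 1
  gvec <- function(ve, va)
    c(ve - school_mean, va - school_mean,
      dyadic_similarity(ve, va, range) - 1)
  lo <- va <- matrix(0, K, K, dimnames = list(ego = categories, alter = categories))
  for (e in seq_len(K)) for (a in seq_len(K)) {
    g <- gvec(categories[e], categories[a])
    lo[e, a] <- sum(beta * g)
    va[e, a] <- drop(t(g) %*% Sigma %*% g)
  }
  list(behavior = behavior, categories = categories,
       log_odds = lo, variance = va, school_id = fit$school_id)
}

#' Pool per-school selection tables across schools
#'
#' Cellwise random-effects pooling (via [pool_random_effects()]) of the
#' per-school log-odds, exponentiated to odds ratios with Wald 95% CIs. A
#' cell is flagged when the CI of its pooled log-odds excludes zero
#' (equivalently, the OR interval excludes 1).
#'
#' @param tables list of [school_log_odds_table()] results.
#' @param stratum label for the pooled table (`"all"`, `"coed"`, `"girls"`,
#'   `"boys"`).
#' @return An object of class `selection_table` with matrices `log_odds`,
#'   `variance`, `or`, `or_low`, `or_high`, `flagged`.
#' @export
pool_selection_tables <- function(tables, stratum = "all") {
  if (!length(tables)) abort("no tables to pool")
  cats <- tables[[1]]$categories
  behavior <- tables[[1]]$behavior
  for (tb in tables) {
    if (!identical(tb$categories, cats) || !identical(tb$behavior, behavior))
      abort("tables have mismatched behaviors or category grids")
  }
  K <- length(cats)
  lo <- va <- or <- lw <- hi <- matrix(0, K, K,
    dimnames = list(ego = cats, alter = cats))
  single <- length(tables) == 1L
  for (e in seq_len(K)) for (a in seq_len(K)) {
    est <- vapply(tables, function(tb) tb$log_odds[e, a], numeric(1))
    sds <- sqrt(vapply(tables, function(tb) tb$variance[e, a], numeric(1)))
    if (all(sds == 0)) {
      # the reference contrast is identically zero in every school
      lo[e, a] <- mean(est); va[e, a] <- 0
    } else {
      pooled <- pool_random_effects(est, sds)
      lo[e, a] <- pooled$estimate; va[e, a] <- pooled$std.error^2
    }
  }
  or <- exp(lo)
  lw <- exp(lo - 1.96 * sqrt(va))
  hi <- exp(lo + 1.96 * sqrt(va))
  flagged <- (lo - 1.96 * sqrt(va) > 0) | (lo + 1.96 * sqrt(va) < 0)
  structure(
    list(behavior = behavior, categories = cats,
         labels = .beh_category_labels[[behavior]][seq_len(K)],
         stratum = stratum, n_schools = length(tables), single_school = single,
         log_odds = lo, variance = va, or = or, or_low = lw, or_high = hi,
         flagged = flagged),
    class = "selection_table")
}

#' @export
print.selection_table <- function(x, digits = 2, ...) {
  cat(sprintf("<selection_table> %s, stratum %s (%d schools)\n",
              x$behavior, x$stratum, x$n_schools))
  cat("odds ratios (ego rows, alter columns); * = 95% CI excludes 1\n")
  m <- matrix(sprintf(paste0("%.", digits, "f%s"), x$or,
                      ifelse(x$flagged, "*", " ")),
              nrow(x$or), dimnames = dimnames(x$or))
  print(m, quote = FALSE)
  invisible(x)
}

#' Tidy a pooled selection table
#'
#' @param x a `selection_table`.
#' @param ... unused.
#' @return A tibble with one row per (ego, alter) cell: log-odds, OR, CI,
#'   flag, stratum.
#' @export
tidy.selection_table <- function(x, ...) {
  K <- length(x$categories)
  grid <- expand.grid(ego = seq_len(K), alter = seq_len(K))
  tibble::tibble(
    stratum = x$stratum, behavior = x$behavior,
    ego_category = x$labels[grid$ego], alter_category = x$labels[grid$alter],
    ego_level = x$categories[grid$ego], alter_level = x$categories[grid$alter],
    log_odds = x$log_odds[cbind(grid$ego, grid$alter)],
    or = x$or[cbind(grid$ego, grid$alter)],
    or_low = x$or_low[cbind(grid$ego, grid$alter)],
    or_high = x$or_high[cbind(grid$ego, grid$alter)],
    flagged = x$flagged[cbind(grid$ego, grid$alter)])
}

#' Asymmetry contrast between mirrored cells of a pooled table
#'
#' `log_odds(e, a) - log_odds(a, e)`, the "opportunity hoarding" contrast:
#' whether ties from group e to group a form more readily than the reverse.
#' The variance treats the two pooled cells as independent, a documented
#' approximation; [school_asymmetry_contrast()] gives the exact per-school
#' version using the full parameter covariance.
#'
#' @param table a `selection_table`.
#' @param e,a ego and alter category levels (values from `table$categories`,
#'   `e != a`).
#' @return One-row tibble: `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @export
asymmetry_contrast <- function(table, e, a) {
  if (e == a) abort("asymmetry contrast needs two distinct categories")
  ie <- match(e, table$categories); ia <- match(a, table$categories)
  if (is.na(ie) || is.na(ia)) abort("categories not in the table grid")
  est <- table$log_odds[ie, ia] - table$log_odds[ia, ie]
  se <- sqrt(table$variance[ie, ia] + table$variance[ia, ie])
  tibble::tibble(ego = e, alter = a, estimate = est, std.error = se,
                 conf.low = est - 1.96 * se, conf.high = est + 1.96 * se)
}

#' Exact per-school asymmetry contrast
#'
#' Computed before pooling from the fitted parameters:
#' `cell(e, a) - cell(a, e) = (b_ego - b_alt) (v_e - v_a)` (the similarity
#' term cancels), with variance from the full covariance of (ego, alter).
#'
#' @param fit a `saom_fit`.
#' @param behavior behavior dimension name.
#' @param e,a distinct category levels.
#' @return One-row tibble as in [asymmetry_contrast()].
#' @export
school_asymmetry_contrast <- function(fit, behavior, e, a) {
  if (e == a) abort("asymmetry contrast needs two distinct categories")
  terms <- paste0(behavior, c("_ego", "_alter"))
  beta <- fit$par[terms]
  Sigma <- fit$covariance[terms, terms]
  d <- e - a
  est <- (beta[1] - beta[2]) * d
  g <- c(d, -d)
  se <- sqrt(drop(t(g) %*% Sigma %*% g))
  tibble::tibble(ego = e, alter = a, estimate = unname(est), std.error = se,
                 conf.low = unname(est) - 1.96 * se,
                 conf.high = unname(est) + 1.96 * se)
}

#' Build and pool selection tables for a set of fitted schools
#'
#' Convenience wrapper reproducing the published table layout: per-school
#' tables from [school_log_odds_table()], pooled over all schools and
#' optionally within school-type strata.
#'
#' @param fits list of converged `saom_fit` objects.
#' @param behavior behavior dimension.
#' @param by_type also return per-school-type strata.
#' @return A list of `selection_table` objects keyed by stratum.
#' @export
selection_tables <- function(fits, behavior, by_type = TRUE) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(fits)) abort("no converged fits")
  tabs <- lapply(fits, school_log_odds_table, behavior = behavior)
  types <- vapply(fits, function(f) f$school_type, character(1))
  out <- list(all = pool_selection_tables(tabs, "all"))
  if (by_type) {
    for (tp in unique(types)) {
      sel <- tabs[types == tp]
      out[[tp]] <- pool_selection_tables(sel, tp)
    }
  }
  out
}
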