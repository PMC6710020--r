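# Multi-school pooling: empirical-Bayes (Paule-Mandel) random-effects
# meta-analysis per effect and weighted meta-regression on school context
# (gender status and centered drinking prevalence).

#' Paule-Mandel between-school heterogeneity variance
#'
#' Iterates tau^2 until the weighted residual sum of squares
#' `sum_s w_s r_s^2`, with `w_s = 1 / (se_s^2 + tau^2)` and residuals from
#' the weighted fit on `design`, equals its degrees of freedom (S - rank).
#' The empirical-Bayes / Paule-Mandel estimator; floored at zero.
#'
#' @param estimates per-school estimates (length >= 2).
#' @param ses per-school standard errors (positive).
#' @param design design matrix (default intercept-only), full column rank.
#' @param tol convergence tolerance on the residual identity.
#' @param max_iter iteration cap (error if exceeded).
#' @return Nonnegative scalar tau^2.
#' @export
#' @examples
#' estimate_tau2(c(0, 2), c(1, 1))   # solves 2 / (1 + tau2) = 1
estimate_tau2 <- function(estimates, ses, design = NULL, tol = 1e-8,
                          max_iter = 200) {
  y <- as.numeric(estimates); se <- as.numeric(ses)
  S <- length(y)
  if (S < 2) abort("need at least 2 schools")
  if (any(se <= 0)) abort("standard errors must be positive")
  X <- design %||% matrix(1, S, 1)
  X <- as.matrix(X)
  r <- qr(X)$rank
  if (r < ncol(X)) abort("design matrix is rank deficient")
  df <- S - r
  if (df <= 0) abort("no residual degrees of freedom")

  qfun <- function(tau2) {
    w <- 1 / (se^2 + tau2)
    W <- diag(w, S)
    beta <- solve(crossprod(X, W %*% X), crossprod(X, w * y))
    res <- y - drop(X %*% beta)
    sum(w * res^2) - df
  }
  if (qfun(0) <= tol) return(0)
  # Q is decreasing in tau2; expand the bracket then root-find
  upper <- max(se)^2
  it <- 0
  while (qfun(upper) > 0) {
    upper <- upper * 2
    it <- it + 1
    if (it > max_iter)
      abort(sprintf("Paule-Mandel iteration did not converge; last tau2 = %g", upper))
  }
  uniroot(qfun, c(0, upper), tol = tol, maxiter = max_iter)$root
}

#' Random-effects pooling of per-school estimates
#'
#' Inverse-variance pooling with Paule-Mandel tau^2:
#' `mu = sum(w_s theta_s) / sum(w_s)` with `w_s = 1 / (se_s^2 + tau^2)`,
#' `se(mu) = 1 / sqrt(sum w_s)`, Wald 95% CI and two-sided normal p-value.
#' When tau^2 = 0 this reduces exactly to fixed-effect inverse-variance
#' pooling. A single school is passed through with `pooled = FALSE`.
#'
#' @param estimates,ses per-school estimates and standard errors.
#' @param tau2 optionally override the heterogeneity variance.
#' @return One-row tibble: `estimate`, `std.error`, `conf.low`, `conf.high`,
#'   `p.value`, `tau2`, `n_schools`, `pooled`.
#' @export
pool_random_effects <- function(estimates, ses, tau2 = NULL) {
  y <- as.numeric(estimates); se <- as.numeric(ses)
  keep <- !is.na(y) & !is.na(se) & se > 0
  y <- y[keep]; se <- se[keep]
  if (length(y) == 0) abort("no usable school estimates")
  if (length(y) == 1) {
    return(tibble::tibble(
      estimate = y, std.error = se, conf.low = y - 1.96 * se,
      conf.high = y + 1.96 * se,
      p.value = 2 * pnorm(-abs(y / se)), tau2 = NA_real_,
      n_schools = 1L, pooled = FALSE))
  }
  if (is.null(tau2)) tau2 <- estimate_tau2(y, se)
  w <- 1 / (se^2 + tau2)
  mu <- sum(w * y) / sum(w)
  se_mu <- 1 / sqrt(sum(w))
  tibble::tibble(
    estimate = mu, std.error = se_mu,
    conf.low = mu - 1.96 * se_mu, conf.high = mu + 1.96 * se_mu,
    p.value = 2 * pnorm(-abs(mu / se_mu)), tau2 = tau2,
    n_schools = length(y), pooled = TRUE)
}

#' School-context design matrix for meta-regression
#'
#' Rows `(1, boys_s, girls_s, prevalence_s - mean(prevalence))`:
#' coeducational schools are the reference and drinking prevalence is
#' centered on the study-sample mean, so the intercept is the parameter value
#' for a coeducational school at mean prevalence.
#'
#' @param metadata data frame with `school_type` (coed/girls/boys) and
#'   `year3_weekly_prevalence` in `[0, 1]`.
#' @return Numeric design matrix with columns `intercept`, `boys`, `girls`,
#'   `prevalence_c`.
#' @export
encode_moderators <- function(metadata) {
  st <- as.character(metadata$school_type)
  bad <- setdiff(unique(st), c("coed", "girls", "boys"))
  if (length(bad)) abort(sprintf("unknown school type: %s", paste(bad, collapse = ", ")))
  prev <- as.numeric(metadata$year3_weekly_prevalence)
  if (any(is.na(prev)) || any(prev < 0 | prev > 1))
    abort("year3_weekly_prevalence must be in [0, 1]")
  X <- cbind(intercept = 1, boys = as.numeric(st == "boys"),
             girls = as.numeric(st == "girls"),
             prevalence_c = prev - mean(prev))
  rownames(X) <- if ("school_id" %in% names(metadata))
    as.character(metadata$school_id) else as.character(seq_along(st))
  X
}

#' Weighted meta-regression of per-school estimates on school context
#'
#' Weighted least squares with weights `1 / (se_s^2 + tau2)` where tau^2 is
#' the Paule-Mandel estimate under the same design; coefficient covariance
#' `(X' W X)^-1`, Wald CIs and p-values. Moderator columns with zero variance
#' are dropped (down to the intercept, where the coefficient equals the
#' pooled random-effects estimate exactly).
#'
#' @param estimates,ses per-school estimates and standard errors.
#' @param design design matrix (see [encode_moderators()]).
#' @param tau2 optionally override the heterogeneity variance (otherwise
#'   Paule-Mandel under the same design).
#' @return Tibble with one row per retained column: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`, `p.value`, plus `tau2` and
#'   `n_schools`.
#' @export
meta_regression <- function(estimates, ses, design, tau2 = NULL) {
  y <- as.numeric(estimates); se <- as.numeric(ses)
  X <- as.matrix(design)
  keep <- !is.na(y) & !is.na(se) & se > 0
  y <- y[keep]; se <- se[keep]; X <- X[keep, , drop = FALSE]
  S <- length(y)
  # drop constant non-intercept columns (e.g. no boys schools in stratum)
  is_int <- apply(X, 2, function(c) all(c == c[1]) && c[1] == 1)
  varying <- apply(X, 2, function(c) length(unique(c)) > 1)
  X <- X[, is_int | varying, drop = FALSE]
  r <- qr(X)$rank
  if (r < ncol(X)) {
    bad <- colnames(X)[qr(X)$pivot[(r + 1):ncol(X)]]
    abort(sprintf("collinear moderator columns: %s", paste(bad, collapse = ", ")))
  }
  if (S <= r) abort("more design columns than schools")

  if (is.null(tau2)) tau2 <- estimate_tau2(y, se, X)
  w <- 1 / (se^2 + tau2)
  XtWX <- crossprod(X, w * X)
  beta <- solve(XtWX, crossprod(X, w * y))
  V <- solve(XtWX)
  est <- unname(drop(beta)); sed <- unname(sqrt(diag(V)))
  tibble::tibble(
    term = colnames(X), estimate = est, std.error = sed,
    conf.low = est - 1.96 * sed, conf.high = est + 1.96 * sed,
    p.value = 2 * pnorm(-abs(est / sed)),
    tau2 = tau2, n_schools = S)
}

#' Pool fitted schools effect-by-effect with context meta-regression
#'
#' For each free evaluation effect: random-effects pooled estimate (log-odds
#' scale), then a meta-regression on school gender status and centered
#' drinking prevalence. Schools whose fit did not converge are excluded (with
#' a message); effects fixed in a school's model are excluded for that
#' school.
#'
#' @param fits list of `saom_fit` objects.
#' @param metadata data frame with one row per school: `school_id`,
#'   `school_type`, `year3_weekly_prevalence`.
#' @param effects which effect names to pool (default: all free evaluation
#'   effects present in the first fit).
#' @return An object of class `coevo_meta`: a tibble with one row per effect
#'   and column blocks for the pooled estimate and each moderator
#'   coefficient.
#' @export
meta_analyze <- function(fits, metadata, effects = NULL) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv))
    inform(sprintf("excluding %d non-converged school fits", sum(!conv)))
  fits <- fits[conv]
  if (length(fits) < 2) abort("need at least 2 converged schools")

  effects <- effects %||% {
    f1 <- fits[[1]]
    setdiff(names(f1$par), grep("^rate_", names(f1$par), value = TRUE))
  }
  ids <- vapply(fits, function(f) f$school_id, character(1))
  md <- metadata[match(ids, as.character(metadata$school_id)), , drop = FALSE]
  if (anyNA(md$school_type)) abort("metadata missing for some fitted schools")
  X <- encode_moderators(md)

  rows <- purrr::map_dfr(effects, function(e) {
    est <- vapply(fits, function(f)
      if (e %in% names(f$par)) unname(f$par[e]) else NA_real_, numeric(1))
    se <- vapply(fits, function(f)
      if (e %in% names(f$se)) unname(f$se[e]) else NA_real_, numeric(1))
    ok <- !is.na(est) & !is.na(se) & se > 0
    pooled <- pool_random_effects(est[ok], se[ok])
    reg <- tryCatch(meta_regression(est[ok], se[ok], X[ok, , drop = FALSE]),
                    error = function(err) NULL)
    out <- tibble::tibble(
      effect = e, estimate = pooled$estimate, std.error = pooled$std.error,
      conf.low = pooled$conf.low, conf.high = pooled$conf.high,
      p.value = pooled$p.value, tau2 = pooled$tau2,
      n_schools = pooled$n_schools)
    if (!is.null(reg)) {
      for (k in seq_len(nrow(reg))) {
        pre <- paste0("mr_", reg$term[k])
        out[[paste0(pre, "_estimate")]] <- reg$estimate[k]
        out[[paste0(pre, "_conf.low")]] <- reg$conf.low[k]
        out[[paste0(pre, "_conf.high")]] <- reg$conf.high[k]
        out[[paste0(pre, "_p.value")]] <- reg$p.value[k]
      }
    }
    out
  })
  structure(rows, class = c("coevo_meta", class(rows)))
}

#' @export
tidy.coevo_meta <- function(x, ...) tibble::as_tibble(x)
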