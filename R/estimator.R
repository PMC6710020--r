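# Unconditional method-of-moments estimation: parameters (rates included as
# free parameters) are tuned by Robbins-Monro stochastic approximation until
# the expected simulated statistics match the observed targets, then a final
# batch of simulations gives convergence t-ratios and the parameter
# covariance D^-1 Sigma_S D^-T.

#' Estimation control settings
#'
#' @param n1 derivative-estimation replicates (common-random-number pairs per
#'   parameter column); default scales as ~50 simulations per parameter.
#' @param delta finite-difference step.
#' @param subphases number of Robbins-Monro subphases (gain halved each).
#' @param n2 iterations per subphase.
#' @param gain initial gain.
#' @param n3 phase-3 simulations for diagnostics and covariance.
#' @param max_restarts automatic restarts from the last iterate when the
#'   convergence thresholds (max |t| < .1, overall < .25) are not met.
#' @param rate_floor lower bound kept on rate parameters during updates.
#' @return A list of settings for [estimate_school()].
#' @export
estimate_options <- function(n1 = NULL, delta = 0.25, subphases = 4, n2 = 40,
                             gain = 0.25, n3 = 500, max_restarts = 3,
                             rate_floor = 0.05) {
  list(n1 = n1, delta = delta, subphases = subphases, n2 = n2, gain = gain,
       n3 = n3, max_restarts = max_restarts, rate_floor = rate_floor)
}

# ---- internal estimation state ----------------------------------------------

.prepare_school <- function(panel, spec) {
  prep <- impute_panel(panel)
  M <- panel$n_waves
  dims <- c("network", spec$behaviors)
  free <- spec$effects$name[!spec$effects$fixed]
  rate_names <- as.vector(t(outer(seq_len(M - 1), dims,
                                  function(m, d) sprintf("rate_%s_p%d", d, m))))
  s_obs <- target_statistics(panel, spec)
  stopifnot(identical(names(s_obs), c(rate_names, free)))

  states <- lapply(seq_len(M), function(m)
    list(adjacency = prep$adjacency[[m]], behavior = prep$behavior[[m]],
         gender = as.integer(panel$gender), fsm = as.integer(panel$fsm)))
  masks <- lapply(seq_len(M - 1), function(m) list(
    net = prep$row_observed[, m] & prep$row_observed[, m + 1],
    beh = lapply(.beh_dims, function(b)
      prep$beh_observed[[b]][, m] & prep$beh_observed[[b]][, m + 1]) |>
      setNames(.beh_dims)))
  # actors unobserved at a period's end: their simulated out-row / behavior
  # is reset to the imputed observed value before statistics are computed, so
  # imputed entries contribute identically to both sides of every moment
  end_miss <- lapply(seq_len(M - 1), function(m) list(
    net = which(!prep$row_observed[, m + 1]),
    beh = lapply(.beh_dims, function(b)
      which(!prep$beh_observed[[b]][, m + 1])) |> setNames(.beh_dims)))

  lay <- .spec_layout(spec)
  stat_names <- c(lay$net$name, lay$alc$name, lay$con$name, lay$sec$name)
  rate_name <- outer(seq_len(M - 1), dims,
                     function(m, d) sprintf("rate_%s_p%d", d, m))
  dimnames(rate_name) <- list(NULL, dims)

  list(panel = panel, spec = spec, states = states, masks = masks,
       s_obs = s_obs, dims = dims, free = free, rate_names = rate_names,
       n_periods = M - 1,
       par_names = c(rate_names, free),
       rate_idx = seq_along(rate_names),
       lay = lay, stat_names = stat_names,
       free_idx = match(free, stat_names),
       cs0 = .cpp_spec(spec, .zero_theta(spec)),
       rate_name = rate_name,
       beh_dcol = match(spec$behaviors, .beh_dims),
       end_miss = end_miss)
}

# reset simulated values that were unobserved at the period's end wave to the
# imputed observed end state (so imputation never drives the moments)
.freeze_unobserved <- function(res, prep, m) {
  em <- prep$end_miss[[m]]
  end_obs <- prep$states[[m + 1]]
  if (length(em$net))
    res$adjacency[em$net, ] <- end_obs$adjacency[em$net, ]
  for (b in prep$spec$behaviors) {
    idx <- em$beh[[b]]
    if (length(idx)) {
      dcol <- match(b, .beh_dims)
      res$behavior[idx, dcol] <- end_obs$behavior[idx, dcol]
    }
  }
  res
}

# initial parameter vector: rates from observed change volume, outdegree -1
.init_par <- function(prep) {
  par <- setNames(numeric(length(prep$par_names)), prep$par_names)
  n <- prep$panel$n
  for (m in seq_len(prep$n_periods)) {
    for (d in prep$dims) {
      nm <- sprintf("rate_%s_p%d", d, m)
      par[nm] <- max(0.5, 1.4 * prep$s_obs[nm] / n)
    }
  }
  if ("outdegree" %in% prep$free) par["outdegree"] <- -1
  par
}

# one simulation of all periods at `par`; returns the target-statistic vector
.sim_targets <- function(par, prep) {
  spec <- prep$spec
  lay <- prep$lay
  theta <- .full_theta(spec, par[prep$free])
  cs <- prep$cs0
  cs$net_theta <- unname(theta[lay$net$name])
  cs$alc_theta <- unname(theta[lay$alc$name])
  cs$con_theta <- unname(theta[lay$con$name])
  cs$sec_theta <- unname(theta[lay$sec$name])
  ev <- setNames(numeric(length(prep$free)), prep$free)
  rates <- setNames(numeric(length(prep$rate_names)), prep$rate_names)
  cap <- as.integer(spec$cap)
  r4 <- numeric(4)
  dim_slot <- match(prep$dims, c("network", .beh_dims))
  for (m in seq_len(prep$n_periods)) {
    r4[] <- 0
    r4[dim_slot] <- par[prep$rate_name[m, ]]
    st <- prep$states[[m]]
    res <- sim_period_cpp(st$adjacency, st$behavior, st$gender, st$fsm,
                          cs, r4, 1.0, cap, FALSE)
    res <- .freeze_unobserved(res, prep, m)
    sv <- .period_target_stats(st$adjacency, st$behavior,
                               res$adjacency, res$behavior,
                               st$gender, st$fsm, cs, lay)
    ev <- ev + sv[prep$free_idx]
    msk <- prep$masks[[m]]
    rates[prep$rate_name[m, "network"]] <-
      sum(abs(res$adjacency[msk$net, , drop = FALSE] -
                st$adjacency[msk$net, , drop = FALSE]))
    for (b in spec$behaviors) {
      dcol <- match(b, .beh_dims)
      rates[prep$rate_name[m, b]] <-
        sum(abs(res$behavior[msk$beh[[b]], dcol] -
                  st$behavior[msk$beh[[b]], dcol]))
    }
  }
  c(rates[prep$rate_names], ev)
}

.deriv_matrix <- function(par, prep, n1, delta) {
  p <- length(par)
  deltas <- rep(delta, p)
  deltas[prep$rate_idx] <- delta * pmax(1, par[prep$rate_idx])
  D <- matrix(0, p, p, dimnames = list(prep$par_names, prep$par_names))
  seeds <- sample.int(.Machine$integer.max - 1L, n1)
  for (r in seq_len(n1)) {
    set.seed(seeds[r])
    s0 <- .sim_targets(par, prep)
    for (k in seq_len(p)) {
      pk <- par
      pk[k] <- pk[k] + deltas[k]
      set.seed(seeds[r])                       # common random numbers
      D[, k] <- D[, k] + (.sim_targets(pk, prep) - s0) / deltas[k]
    }
  }
  D / n1
}

.solve_deriv <- function(D) {
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    abort(sprintf("derivative matrix is singular; collinear targets: %s",
                  paste(bad, collapse = ", ")))
  }
  solve(qrD)
}

# ---- exported operations -----------------------------------------------------

#' Finite-difference derivative of expected statistics
#'
#' Estimates the Jacobian of the expected target statistics with respect to
#' the parameters by forward finite differences with common random numbers
#' across each base/perturbed pair: column k is
#' `(mean S(theta + delta e_k) - mean S(theta)) / delta` over `n1` replicate
#' pairs.
#'
#' @param theta named parameter vector over the estimation layout (rates then
#'   free effects); see [target_statistics()] for the ordering.
#' @param spec a [model_spec].
#' @param panel a [school_panel].
#' @param n1 number of replicates (at least 20 for a usable estimate).
#' @param delta finite-difference step.
#' @param seed optional integer seed.
#' @return A p x p matrix (rows: statistics, columns: parameters).
#' @export
derivative_matrix <- function(theta, spec, panel, n1 = 20, delta = 0.25,
                              seed = NULL) {
  if (n1 < 1) abort("n1 must be positive")
  if (delta <= 0) abort("delta must be positive")
  if (!is.null(seed)) set.seed(seed)
  prep <- .prepare_school(panel, spec)
  par <- .init_par(prep)
  keep <- intersect(names(theta), names(par))
  par[keep] <- theta[keep]
  .deriv_matrix(par, prep, n1, delta)
}

#' Convergence diagnostics from phase-3 simulations
#'
#' Per-target t-ratios `(mean S_k - s_obs_k) / sd(S_k)` and the overall
#' maximum-convergence ratio `sqrt((Sbar - s)' Sigma^-1 (Sbar - s))`, with a
#' pseudo-inverse (and a warning) when the simulated covariance is
#' rank-deficient. A zero-variance statistic gets t-ratio 0 when its mean
#' deviation is zero and `Inf` otherwise.
#'
#' @param simulated_stats N x p matrix of simulated target statistics.
#' @param observed length-p vector of observed targets.
#' @return A list with `t_ratios` and `overall_ratio`.
#' @export
convergence_diagnostics <- function(simulated_stats, observed) {
  S <- as.matrix(simulated_stats)
  p <- ncol(S)
  if (nrow(S) < p + 2) abort("need at least p + 2 phase-3 simulations")
  dev <- colMeans(S) - observed
  sds <- apply(S, 2, sd)
  t_ratios <- ifelse(sds > 0, dev / sds, ifelse(abs(dev) < 1e-12, 0, Inf))
  names(t_ratios) <- colnames(S) %||% names(observed)
  Sig <- cov(S)
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(abs(ev), 1)) {
    warn("simulated statistic covariance is rank-deficient; using pseudo-inverse")
    Sinv <- MASS::ginv(Sig)
  } else {
    Sinv <- solve(Sig)
  }
  overall <- sqrt(max(0, drop(t(dev) %*% Sinv %*% dev)))
  list(t_ratios = t_ratios, overall_ratio = overall)
}

#' Fit the co-evolution model to one school
#'
#' Unconditional method-of-moments estimation. Phase 1 estimates the
#' derivative matrix at the initial parameters by common-random-number
#' forward differences; phase 2 runs Robbins-Monro subphases
#' `theta <- theta - a_k D^-1 (S(theta) - s_obs)` with the gain halved per
#' subphase and the parameter averaged over the second half of each subphase;
#' phase 3 simulates independently at the estimate to compute t-ratios, the
#' overall convergence ratio, and the covariance `D^-1 Sigma_S D^-T`. The fit
#' converged when every |t-ratio| is below .1 and the overall ratio below
#' .25; otherwise estimation restarts from the last iterate, up to
#' `options$max_restarts` times, and a non-converged fit is returned rather
#' than an error. Fixed effects keep their fixed value exactly and report no
#' standard error.
#'
#' @param panel a [school_panel] with at least two waves.
#' @param spec a [model_spec] with at least one free parameter.
#' @param options see [estimate_options()].
#' @param seed integer seed; the fit is fully reproducible from
#'   (panel, spec, options, seed).
#' @return An object of class `saom_fit`; see [tidy.saom_fit()].
#' @export
estimate_school <- function(panel, spec, options = estimate_options(),
                            seed = NULL) {
  if (panel$n_waves < 2) abort("estimation needs at least 2 waves")
  if (!any(!spec$effects$fixed)) abort("no free parameters to estimate")
  if (is.null(seed)) seed <- sample.int(1e7, 1)
  set.seed(seed)

  prep <- .prepare_school(panel, spec)
  p <- length(prep$par_names)
  n1 <- options$n1 %||% max(20L, ceiling(50 * p / (p + 1)))
  par <- .init_par(prep)

  D <- .deriv_matrix(par, prep, n1, options$delta)
  Dinv <- .solve_deriv(D)

  run_phase2 <- function(par, Dinv, gain0) {
    for (sub in seq_len(options$subphases)) {
      a_k <- gain0 / 2^(sub - 1)
      iter <- matrix(0, options$n2, p)
      for (it in seq_len(options$n2)) {
        dev <- .sim_targets(par, prep) - prep$s_obs
        step <- a_k * drop(Dinv %*% dev)
        clamp <- rep(0.5, p)
        clamp[prep$rate_idx] <- 0.5 * pmax(1, par[prep$rate_idx])
        step <- pmin(pmax(step, -clamp), clamp)
        par <- par - step
        par[prep$rate_idx] <- pmax(par[prep$rate_idx], options$rate_floor)
        iter[it, ] <- par
      }
      par <- colMeans(iter[ceiling(options$n2 / 2):options$n2, , drop = FALSE])
      names(par) <- prep$par_names
    }
    par
  }

  par <- run_phase2(par, Dinv, options$gain)

  attempt <- 0L
  repeat {
    Smat <- t(vapply(seq_len(options$n3), function(r) .sim_targets(par, prep),
                     numeric(p)))
    colnames(Smat) <- prep$par_names
    # derivative at the current estimate: used for the covariance and, on a
    # restart, for a Newton polish from the low-noise phase-3 mean deviation
    D_hat <- .deriv_matrix(par, prep, n1, options$delta)
    Dinv_hat <- tryCatch(.solve_deriv(D_hat), error = function(e) Dinv)
    diag_ <- convergence_diagnostics(Smat, prep$s_obs)
    converged <- max(abs(diag_$t_ratios)) < 0.1 && diag_$overall_ratio < 0.25
    if (converged || attempt >= options$max_restarts) break
    dev <- colMeans(Smat) - prep$s_obs
    step <- drop(Dinv_hat %*% dev)
    clamp <- rep(1, p)
    clamp[prep$rate_idx] <- pmax(1, 0.5 * par[prep$rate_idx])
    step <- pmin(pmax(step, -clamp), clamp)
    par <- par - step
    par[prep$rate_idx] <- pmax(par[prep$rate_idx], options$rate_floor)
    attempt <- attempt + 1L
  }

  covar <- Dinv_hat %*% cov(Smat) %*% t(Dinv_hat)
  covar <- (covar + t(covar)) / 2
  dimnames(covar) <- list(prep$par_names, prep$par_names)
  se <- setNames(sqrt(pmax(0, diag(covar))), prep$par_names)

  theta_full <- .full_theta(spec, par[prep$free])
  rates <- matrix(par[prep$rate_idx], nrow = prep$n_periods,
                  ncol = length(prep$dims), byrow = TRUE,
                  dimnames = list(paste0("p", seq_len(prep$n_periods)),
                                  prep$dims))

  structure(
    list(school_id = panel$school_id, school_type = panel$school_type,
         theta = theta_full, par = par, rates = rates, se = se,
         covariance = covar, t_ratios = diag_$t_ratios,
         overall_ratio = diag_$overall_ratio, converged = converged,
         n_phase3 = options$n3, n_restarts = attempt, seed = seed,
         spec = spec, s_obs = prep$s_obs,
         n_actors = panel$n, n_waves = panel$n_waves),
    class = "saom_fit"
  )
}

#' @export
print.saom_fit <- function(x, ...) {
  cat(sprintf("<saom_fit> school %s: %d free parameters, %s\n",
              x$school_id, length(x$par),
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  max |t-ratio| %.3f, overall ratio %.3f\n",
              max(abs(x$t_ratios)), x$overall_ratio))
  print(tidy(x), n = 20)
  invisible(x)
}

#' Tidy a fitted school model
#'
#' @param x a `saom_fit`.
#' @param ... unused.
#' @return A tibble with one row per parameter (rates, free and fixed
#'   effects): `term`, `estimate`, `std.error`, `conv_t_ratio`, `fixed`.
#' @export
tidy.saom_fit <- function(x, ...) {
  free <- tibble::tibble(
    term = names(x$par), estimate = unname(x$par),
    std.error = unname(x$se), conv_t_ratio = unname(x$t_ratios),
    fixed = FALSE)
  fx <- x$spec$effects[x$spec$effects$fixed, ]
  if (nrow(fx)) {
    free <- dplyr::bind_rows(free, tibble::tibble(
      term = fx$name, estimate = fx$fixed_value, std.error = NA_real_,
      conv_t_ratio = NA_real_, fixed = TRUE))
  }
  free
}

#' One-row fit summary
#'
#' @param x a `saom_fit`.
#' @param ... unused.
#' @return A one-row tibble: convergence flag, diagnostics, sizes, seed.
#' @export
glance.saom_fit <- function(x, ...) {
  tibble::tibble(
    school_id = x$school_id, converged = x$converged,
    max_t_ratio = max(abs(x$t_ratios)), overall_ratio = x$overall_ratio,
    n_parameters = length(x$par), n_actors = x$n_actors,
    n_waves = x$n_waves, n_restarts = x$n_restarts, seed = x$seed)
}

#' Serialize a fit to JSON
#'
#' @param fit a `saom_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    school_id = fit$school_id, school_type = fit$school_type,
    parameters = as.list(fit$par), se = as.list(fit$se),
    covariance = as.vector(t(fit$covariance)),
    covariance_dim = ncol(fit$covariance),
    theta = as.list(fit$theta),
    t_ratios = as.list(fit$t_ratios), overall_ratio = fit$overall_ratio,
    converged = fit$converged, n_phase3 = fit$n_phase3, seed = fit$seed,
    effects = fit$spec$effects$name)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
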