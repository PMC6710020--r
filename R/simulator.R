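# Continuous-time actor-oriented microstep simulation.
#
# Actors get change opportunities at exponential waiting times; at each
# opportunity one actor either toggles one outgoing tie (respecting the
# nomination cap) or shifts one behavior by -1/0/+1, choosing by a
# multinomial logit over the objective function. The heavy lifting is in
# src/saom.cpp; the R functions here define the user surface and the small
# reference pieces used in tests.

#' Multinomial-logit choice probabilities
#'
#' Log-sum-exp stabilized softmax of objective values:
#' `p_k = exp(f_k - max f) / sum_j exp(f_j - max f)`. Invariant under adding
#' a constant to all values.
#'
#' @param objective_values numeric vector (finite).
#' @return Probability vector summing to 1.
#' @export
#' @examples
#' choice_probabilities(c(log(2), 0))
choice_probabilities <- function(objective_values) {
  if (!length(objective_values)) abort("empty choice set")
  if (anyNA(objective_values) || any(!is.finite(objective_values)))
    abort("objective values must be finite")
  w <- exp(objective_values - max(objective_values))
  w / sum(w)
}

#' Candidate states for one network microstep
#'
#' The no-change state plus one state per permissible single-tie toggle for
#' actor `i`: self-ties are never candidates and additions are excluded when
#' the actor is at the nomination cap.
#'
#' @param i actor index.
#' @param state list with at least `adjacency`; see [network_evaluation()].
#' @param cap maximum outdegree (default `r .nomination_cap`).
#' @return A list of candidate states; the first is the unchanged state.
#'   Each carries attributes `actor` and `toggled` (0 for no change).
#' @export
network_choice_set <- function(i, state, cap = .nomination_cap) {
  st <- .as_state(state)
  x <- st$adjacency
  n <- nrow(x)
  outdeg <- sum(x[i, ])
  keep <- state
  attr(keep, "toggled") <- 0L
  out <- list(keep)
  for (a in seq_len(n)) {
    if (a == i) next
    if (x[i, a] == 0L && outdeg >= cap) next
    cand <- state
    x2 <- x
    x2[i, a] <- 1L - x2[i, a]
    cand$adjacency <- x2
    attr(cand, "toggled") <- a
    out <- c(out, list(cand))
  }
  for (k in seq_along(out)) attr(out[[k]], "actor") <- i
  out
}

# normalize a rates argument to the internal length-4 vector
.rates4 <- function(rates, behaviors) {
  out <- c(network = 0, alcohol = 0, control = 0, secrecy = 0)
  if (is.null(names(rates))) {
    active <- c("network", behaviors)
    if (length(rates) != length(active))
      abort("unnamed rates must match c(network, behaviors) in length")
    out[active] <- rates
  } else {
    keep <- intersect(names(rates), names(out))
    out[keep] <- rates[keep]
  }
  if (any(out < 0) || all(out == 0)) abort("rates must be nonnegative, with at least one positive")
  out
}

#' Simulate one observation period
#'
#' Runs the continuous-time microstep chain from `state` until the clock
#' reaches `horizon` (fixed at 1.0 by convention; the rate parameters carry
#' the timescale). Each actor receives network / behavior change
#' opportunities at rates `rates["network"]`, `rates["alcohol"]`, ... per
#' unit time. Output is fully determined by `seed` and the inputs.
#'
#' @param state list with `adjacency`, `behavior`, `gender`, `fsm`.
#' @param theta named numeric vector of evaluation parameters (missing names
#'   are zero; fixed effects take their fixed values).
#' @param rates named nonnegative vector (per-actor opportunity rates); a
#'   zero rate freezes that dimension.
#' @param spec a [model_spec].
#' @param horizon period length (default 1).
#' @param seed optional integer seed.
#' @param keep_log if `TRUE`, attach a microstep log (actor, dimension, move,
#'   clock) as attribute `"log"` for diagnostics.
#' @return The end-of-period state (same shape as `state`), with attribute
#'   `n_steps` and optionally `"log"`.
#' @export
simulate_period <- function(state, theta, rates, spec, horizon = 1.0,
                            seed = NULL, keep_log = FALSE) {
  st <- .as_state(state)
  if (anyNA(st$adjacency) || anyNA(st$behavior))
    abort("simulate_period needs a complete (imputed) state")
  if (!is.null(seed)) set.seed(seed)
  full <- .full_theta(spec, theta)
  if (anyNA(full) || any(!is.finite(full))) abort("theta must be finite")
  r4 <- .rates4(rates, spec$behaviors)
  res <- sim_period_cpp(st$adjacency, st$behavior, st$gender, st$fsm,
                        .cpp_spec(spec, full), unname(r4), horizon,
                        as.integer(spec$cap), keep_log)
  out <- state
  out$adjacency <- res$adjacency
  out$behavior <- res$behavior
  colnames(out$behavior) <- .beh_dims
  out$gender <- st$gender
  out$fsm <- st$fsm
  attr(out, "n_steps") <- res$n_steps
  if (keep_log) attr(out, "log") <- tibble::as_tibble(res$log)
  out
}

#' Simulate a multi-wave school panel from a first wave
#'
#' Chains [simulate_period()] over `n_periods`, recording the state at each
#' period end as an observation wave; wave 1 equals the input state.
#'
#' @param wave1 starting state (see [simulate_period()]).
#' @param theta named evaluation parameter vector.
#' @param rates either a single rate vector reused every period or a list /
#'   matrix (periods in rows) of per-period rates.
#' @param spec a [model_spec].
#' @param n_periods number of periods (waves - 1).
#' @param seed optional integer seed.
#' @param school_id,school_type metadata for the returned panel.
#' @return A [school_panel] with `n_periods + 1` fully observed waves.
#' @export
simulate_panel <- function(wave1, theta, rates, spec, n_periods,
                           seed = NULL, school_id = "sim",
                           school_type = "coed") {
  stopifnot(n_periods >= 1)
  if (!is.null(seed)) set.seed(seed)
  st <- .as_state(wave1)
  n <- nrow(st$adjacency)
  per_period <- if (is.matrix(rates)) {
    lapply(seq_len(nrow(rates)), function(m) rates[m, ])
  } else if (is.list(rates)) rates else rep(list(rates), n_periods)
  if (length(per_period) != n_periods)
    abort("need one rate set per period")

  adjacency <- list(st$adjacency)
  beh <- list(st$behavior)
  cur <- list(adjacency = st$adjacency, behavior = st$behavior,
              gender = st$gender, fsm = st$fsm)
  for (m in seq_len(n_periods)) {
    cur <- simulate_period(cur, theta, per_period[[m]], spec)
    adjacency[[m + 1]] <- cur$adjacency
    beh[[m + 1]] <- cur$behavior
  }
  ids <- sprintf("a%03d", seq_len(n))
  school_panel(
    school_id = school_id, school_type = school_type, actor_ids = ids,
    adjacency = adjacency,
    alcohol = vapply(beh, function(b) b[, 1], integer(n)),
    control = vapply(beh, function(b) b[, 2], integer(n)),
    secrecy = vapply(beh, function(b) b[, 3], integer(n)),
    gender = st$gender, fsm = st$fsm,
    present = matrix(TRUE, n, n_periods + 1),
    year3_weekly_prevalence = {
      w3 <- min(3, n_periods + 1)
      mean(sapply(beh, function(b) b[, 1])[, w3] == 4L)
    }
  )
}
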