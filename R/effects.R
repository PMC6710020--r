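# Effect catalog, model specification, and reference implementations of the
# actor objective functions and observed target statistics.
#
# The integer codes must stay in sync with the enums in src/saom.cpp; the C++
# side is the simulation hot path, the R functions below are the readable
# reference definitions and the two are pinned to each other by tests.

.net_catalog <- tibble::tribble(
  ~name,                                ~code, ~kind,
  "outdegree",                           1L,   "structural",
  "reciprocity",                         2L,   "structural",
  "transitive_triplets",                 3L,   "structural",
  "indegree_popularity_sqrt",            4L,   "structural",
  "same_gender",                         5L,   "covariate",
  "fsm_similarity",                      6L,   "covariate",
  "alcohol_alter",                       7L,   "behavior_linked",
  "alcohol_ego",                         8L,   "behavior_linked",
  "alcohol_similarity",                  9L,   "behavior_linked",
  "control_alter",                      10L,   "behavior_linked",
  "control_ego",                        11L,   "behavior_linked",
  "control_similarity",                 12L,   "behavior_linked",
  "secrecy_alter",                      13L,   "behavior_linked",
  "secrecy_ego",                        14L,   "behavior_linked",
  "secrecy_similarity",                 15L,   "behavior_linked",
  "control_ego_x_alcohol_similarity",   16L,   "interaction"
)

.beh_catalog <- tibble::tribble(
  ~name,                                  ~dependent, ~code, ~kind,
  "alcohol_linear",                       "alcohol",   1L,   "shape",
  "alcohol_quadratic",                    "alcohol",   2L,   "shape",
  "alcohol_total_similarity",             "alcohol",   3L,   "behavior_linked",
  "alcohol_control_x_total_similarity",   "alcohol",   4L,   "interaction",
  "alcohol_secrecy_x_total_similarity",   "alcohol",   5L,   "interaction",
  "alcohol_gender",                       "alcohol",   6L,   "covariate",
  "alcohol_fsm",                          "alcohol",   7L,   "covariate",
  "control_linear",                       "control",   1L,   "shape",
  "control_quadratic",                    "control",   2L,   "shape",
  "control_from_alcohol",                 "control",   3L,   "behavior_linked",
  "control_gender",                       "control",   4L,   "covariate",
  "control_fsm",                          "control",   5L,   "covariate",
  "secrecy_linear",                       "secrecy",   1L,   "shape",
  "secrecy_quadratic",                    "secrecy",   2L,   "shape",
  "secrecy_average_similarity",           "secrecy",   3L,   "behavior_linked",
  "secrecy_alter_average_drinking",       "secrecy",   4L,   "behavior_linked",
  "secrecy_gender",                       "secrecy",   5L,   "covariate",
  "secrecy_fsm",                          "secrecy",   6L,   "covariate"
)

# which behavior each network behavior-linked effect reads
.net_behavior_of <- c(
  alcohol_alter = "alcohol", alcohol_ego = "alcohol",
  alcohol_similarity = "alcohol",
  control_alter = "control", control_ego = "control",
  control_similarity = "control",
  secrecy_alter = "secrecy", secrecy_ego = "secrecy",
  secrecy_similarity = "secrecy",
  control_ego_x_alcohol_similarity = "alcohol"
)

#' The full effect catalog
#'
#' All tie-formation (network) and behavior-dynamics effects the package
#' knows, as a tibble with one row per effect: `name`, `dependent` (network,
#' alcohol, control or secrecy), `kind` and the internal `code`.
#'
#' @return A tibble.
#' @export
effect_catalog <- function() {
  dplyr::bind_rows(
    dplyr::mutate(.net_catalog, dependent = "network"),
    .beh_catalog
  )[, c("name", "dependent", "kind", "code")]
}

#' Dyadic similarity kernel
#'
#' `1 - |v_i - v_j| / range`, the standard similarity score underlying all
#' homophily ("befriend those drinking similarly") and influence effects.
#'
#' @param v_i,v_j attribute values (numeric, recyclable).
#' @param range positive theoretical range of the attribute (3 for the 1--4
#'   alcohol scale, 2 for tertiles).
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' dyadic_similarity(2, 3, range = 3)
dyadic_similarity <- function(v_i, v_j, range) {
  if (any(range <= 0)) abort("range must be positive")
  if (any(abs(v_i - v_j) > range, na.rm = TRUE))
    abort("|v_i - v_j| exceeds the declared range")
  1 - abs(v_i - v_j) / range
}

#' Build a model specification for one school
#'
#' Selects the evaluation effects, computes the school's centering constants
#' (behavior means, mean similarities and theoretical ranges used by every
#' centered statistic) from the observed actor-waves, and records fixed
#' parameters. In a single-sex school the `same_gender` effect is
#' automatically fixed at zero (zero-variance covariate).
#'
#' @param panel a [school_panel] (used for centering constants and the
#'   single-sex rule).
#' @param effects character vector of effect names from [effect_catalog()];
#'   default is the full catalog restricted to `behaviors`.
#' @param behaviors which behavior dimensions co-evolve; network-only models
#'   use `behaviors = character(0)`.
#' @param fixed named numeric vector: effects constrained to a value and not
#'   estimated (e.g. `c(same_gender = 0)`).
#' @return An object of class `model_spec`: the effect table plus centering
#'   constants.
#' @export
model_spec <- function(panel, effects = NULL,
                       behaviors = c("alcohol", "control", "secrecy"),
                       fixed = NULL) {
  behaviors <- intersect(.beh_dims, behaviors)
  cat_all <- effect_catalog()
  if (is.null(effects)) {
    keep <- cat_all$dependent == "network" | cat_all$dependent %in% behaviors
    # drop network effects that read an excluded behavior
    nb <- .net_behavior_of[cat_all$name]
    keep <- keep & (is.na(nb) | nb %in% behaviors)
    # the control x alcohol-similarity tie interaction also reads control
    if (!("control" %in% behaviors))
      keep <- keep & cat_all$name != "control_ego_x_alcohol_similarity"
    if (!("secrecy" %in% behaviors))
      keep <- keep & !(cat_all$name %in% "alcohol_secrecy_x_total_similarity")
    if (!("control" %in% behaviors))
      keep <- keep & !(cat_all$name %in% "alcohol_control_x_total_similarity")
    effects <- cat_all$name[keep]
  }
  unknown <- setdiff(effects, cat_all$name)
  if (length(unknown))
    abort(sprintf("unknown effects: %s", paste(unknown, collapse = ", ")))
  tab <- cat_all[match(effects, cat_all$name), ]
  # only behaviors with behavior-side effects get their own dynamics; a
  # network effect that merely reads a behavior treats it as a covariate
  beh_used <- unique(tab$dependent[tab$dependent != "network"])

  fixed <- fixed %||% numeric(0)
  if (length(unique(panel$gender)) == 1L) {
    # zero-variance covariate in single-sex schools: the same-gender tie
    # effect and the behavior gender main effects are degenerate
    for (nm in intersect(c("same_gender", "alcohol_gender", "control_gender",
                           "secrecy_gender"), tab$name))
      if (!(nm %in% names(fixed))) fixed[nm] <- 0
  }
  tab$fixed <- tab$name %in% names(fixed)
  tab$fixed_value <- ifelse(tab$fixed, fixed[tab$name], NA_real_)

  structure(
    list(effects = tab,
         behaviors = intersect(.beh_dims, unique(c(behaviors, beh_used))),
         centering = .centering_constants(panel),
         cap = .nomination_cap),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %d effects (%d fixed), behaviors: %s\n",
              nrow(x$effects), sum(x$effects$fixed),
              paste(x$behaviors, collapse = ", ")))
  cat(sprintf("  behavior means: %s\n",
              paste(sprintf("%s=%.3f", names(x$centering$zbar),
                            x$centering$zbar), collapse = ", ")))
  invisible(x)
}

# school-level centering constants: behavior means over observed actor-waves,
# mean similarities over observed ordered pairs pooled over waves; ranges are
# theoretical (alcohol 3, tertiles 2, binary fsm 1)
.centering_constants <- function(panel) {
  zbar <- sbar <- numeric(0)
  for (b in .beh_dims) {
    v <- panel[[b]]
    obs <- v[!is.na(v)]
    zbar[b] <- if (length(obs)) mean(obs) else mean(.beh_levels[[b]])
    sims <- c()
    for (m in seq_len(panel$n_waves)) {
      w <- v[, m]; w <- w[!is.na(w)]
      if (length(w) >= 2) {
        d <- abs(outer(w, w, "-")) / .beh_range[[b]]
        sims <- c(sims, mean(1 - d[row(d) != col(d)]))
      }
    }
    sbar[b] <- if (length(sims)) mean(sims) else 1
  }
  f <- panel$fsm[!is.na(panel$fsm)]
  if (length(f) >= 2) {
    d <- abs(outer(f, f, "-"))
    sbar["fsm"] <- mean(1 - d[row(d) != col(d)])
  } else sbar["fsm"] <- 1
  list(zbar = zbar, sbar = sbar, range = .beh_range)
}

# ---- internal: bridge to the C++ encoding ----------------------------------

# split a spec's effects into the per-dimension code/name lists
.spec_layout <- function(spec) {
  tab <- spec$effects
  net <- tab[tab$dependent == "network", ]
  list(
    net = net,
    alc = tab[tab$dependent == "alcohol", ],
    con = tab[tab$dependent == "control", ],
    sec = tab[tab$dependent == "secrecy", ]
  )
}

# build the C++ spec list; theta is a full named vector over spec effects
.cpp_spec <- function(spec, theta) {
  lay <- .spec_layout(spec)
  th <- function(part) {
    if (!nrow(part)) return(numeric(0))
    v <- theta[part$name]
    v[part$fixed] <- part$fixed_value[part$fixed]
    unname(v)
  }
  list(
    net_eff = lay$net$code, net_theta = th(lay$net),
    alc_eff = lay$alc$code, alc_theta = th(lay$alc),
    con_eff = lay$con$code, con_theta = th(lay$con),
    sec_eff = lay$sec$code, sec_theta = th(lay$sec),
    zbar = unname(spec$centering$zbar[.beh_dims]),
    sbar = unname(spec$centering$sbar[c(.beh_dims, "fsm")])
  )
}

# full named theta with all entries zero (fixed values substituted downstream)
.zero_theta <- function(spec) {
  setNames(numeric(nrow(spec$effects)), spec$effects$name)
}

# merge a user theta (possibly partial) into a full vector, applying fixed values
.full_theta <- function(spec, theta) {
  full <- .zero_theta(spec)
  if (length(theta)) {
    if (is.null(names(theta)) && length(theta) == length(full)) {
      full[] <- theta
    } else {
      keep <- intersect(names(theta), names(full))
      full[keep] <- theta[keep]
    }
  }
  fx <- spec$effects$fixed
  full[spec$effects$name[fx]] <- spec$effects$fixed_value[fx]
  full
}

# normalize a user-supplied state list
.as_state <- function(state) {
  adj <- as.matrix(state$adjacency)
  storage.mode(adj) <- "integer"
  beh <- state$behavior
  if (is.list(beh) && !is.matrix(beh))
    beh <- cbind(alcohol = beh$alcohol, control = beh$control,
                 secrecy = beh$secrecy)
  if (is.null(beh)) beh <- matrix(1L, nrow(adj), 3)
  beh <- as.matrix(beh)
  if (ncol(beh) != 3) abort("behavior must have columns alcohol, control, secrecy")
  storage.mode(beh) <- "integer"
  colnames(beh) <- .beh_dims
  gender <- state$gender %||% rep(0L, nrow(adj))
  fsm <- state$fsm %||% rep(0L, nrow(adj))
  list(adjacency = adj, behavior = beh,
       gender = as.integer(gender), fsm = as.integer(fsm))
}

# ---- reference statistic implementations -----------------------------------

# per-actor network statistic, one effect
.net_stat_actor <- function(name, i, x, beh, gender, fsm, cc) {
  zb <- cc$zbar; sb <- cc$sbar; rg <- cc$range
  row <- x[i, ]
  simto <- function(b) dyadic_similarity(beh[i, b], beh[, b], rg[[b]]) - sb[[b]]
  switch(name,
    outdegree = sum(row),
    reciprocity = sum(row * x[, i]),
    transitive_triplets = as.numeric(row %*% x %*% row),
    indegree_popularity_sqrt = sum(row * sqrt(colSums(x))),
    same_gender = sum(row * (gender == gender[i])),
    fsm_similarity = sum(row * (1 - abs(fsm[i] - fsm) - sb[["fsm"]])),
    alcohol_alter = sum(row * (beh[, "alcohol"] - zb[["alcohol"]])),
    alcohol_ego = (beh[i, "alcohol"] - zb[["alcohol"]]) * sum(row),
    alcohol_similarity = sum(row * simto("alcohol")),
    control_alter = sum(row * (beh[, "control"] - zb[["control"]])),
    control_ego = (beh[i, "control"] - zb[["control"]]) * sum(row),
    control_similarity = sum(row * simto("control")),
    secrecy_alter = sum(row * (beh[, "secrecy"] - zb[["secrecy"]])),
    secrecy_ego = (beh[i, "secrecy"] - zb[["secrecy"]]) * sum(row),
    secrecy_similarity = sum(row * simto("secrecy")),
    control_ego_x_alcohol_similarity =
      (beh[i, "control"] - zb[["control"]]) * sum(row * simto("alcohol")),
    abort(sprintf("unknown network effect %s", name))
  )
}

# per-actor behavior statistic at candidate level z, one effect
.beh_stat_actor <- function(name, dep, i, z, x, beh, gender, fsm, cc) {
  zb <- cc$zbar; sb <- cc$sbar; rg <- cc$range
  row <- x[i, ]
  outdeg <- sum(row)
  zc <- z - zb[[dep]]
  totsim <- function(b, zi) sum(row * (dyadic_similarity(zi, beh[, b], rg[[b]]) - sb[[b]]))
  switch(name,
    alcohol_linear = , control_linear = , secrecy_linear = zc,
    alcohol_quadratic = , control_quadratic = , secrecy_quadratic = zc^2,
    alcohol_total_similarity = totsim("alcohol", z),
    alcohol_control_x_total_similarity =
      (beh[i, "control"] - zb[["control"]]) * totsim("alcohol", z),
    alcohol_secrecy_x_total_similarity =
      (beh[i, "secrecy"] - zb[["secrecy"]]) * totsim("alcohol", z),
    control_from_alcohol = zc * (beh[i, "alcohol"] - zb[["alcohol"]]),
    secrecy_average_similarity = totsim("secrecy", z) / max(1, outdeg),
    secrecy_alter_average_drinking =
      zc * sum(row * (beh[, "alcohol"] - zb[["alcohol"]])) / max(1, outdeg),
    alcohol_gender = , control_gender = , secrecy_gender = zc * gender[i],
    alcohol_fsm = , control_fsm = , secrecy_fsm = zc * fsm[i],
    abort(sprintf("unknown behavior effect %s", name))
  )
}

#' Actor objective function for tie changes
#'
#' The network evaluation function of actor `i`: the weighted sum
#' `sum_k theta_k s_ik(x, z, v)` over the network-dependent effects of the
#' model, evaluated at the given state. Statistics follow the fixed
#' conventions documented in the package vignette (transitive triplets count
#' the orientation i->j, j->h, i->h; average-style terms are zero for
#' isolates).
#'
#' @param i actor index (1-based).
#' @param state list with `adjacency` (n x n binary), `behavior` (n x 3
#'   integer matrix or named list), `gender`, `fsm`.
#' @param theta named numeric vector over the spec's network effects (missing
#'   names default to 0).
#' @param spec a [model_spec].
#' @return The objective value (scalar).
#' @export
network_evaluation <- function(i, state, theta, spec) {
  st <- .as_state(state)
  if (anyNA(st$behavior)) abort("missing behavior values: impute upstream")
  lay <- .spec_layout(spec)
  full <- .full_theta(spec, theta)
  s <- vapply(lay$net$name, .net_stat_actor, numeric(1), i = i,
              x = st$adjacency, beh = st$behavior, gender = st$gender,
              fsm = st$fsm, cc = spec$centering)
  sum(full[lay$net$name] * s)
}

#' Actor objective function for behavior changes
#'
#' The behavior evaluation function of actor `i` on dimension `behavior` at a
#' candidate level `z_i`: linear and quadratic shape terms plus the
#' influence, interaction and covariate effects of the model.
#'
#' @param i actor index.
#' @param behavior `"alcohol"`, `"control"` or `"secrecy"`.
#' @param z_i candidate level (within the behavior's range).
#' @param state as in [network_evaluation()].
#' @param theta named numeric vector over the spec's effects for this
#'   behavior.
#' @param spec a [model_spec].
#' @return The objective value (scalar).
#' @export
behavior_evaluation <- function(i, behavior, z_i, state, theta, spec) {
  behavior <- match.arg(behavior, .beh_dims)
  if (!(z_i %in% .beh_levels[[behavior]]))
    abort(sprintf("candidate level %s out of range for %s", z_i, behavior))
  st <- .as_state(state)
  if (anyNA(st$behavior)) abort("missing behavior values: impute upstream")
  tab <- spec$effects[spec$effects$dependent == behavior, ]
  full <- .full_theta(spec, theta)
  s <- vapply(tab$name, .beh_stat_actor, numeric(1), dep = behavior, i = i,
              z = z_i, x = st$adjacency, beh = st$behavior,
              gender = st$gender, fsm = st$fsm, cc = spec$centering)
  sum(full[tab$name] * s)
}

# summed (over actors) evaluation statistics of one complete state, via the
# reference R formulas; same ordering as the C++ fast path
.state_stats_r <- function(state, spec) {
  st <- .as_state(state)
  n <- nrow(st$adjacency)
  lay <- .spec_layout(spec)
  out <- c()
  for (nm in lay$net$name)
    out[nm] <- sum(vapply(seq_len(n), function(i)
      .net_stat_actor(nm, i, st$adjacency, st$behavior, st$gender, st$fsm,
                      spec$centering), numeric(1)))
  for (part in list(lay$alc, lay$con, lay$sec)) {
    if (!nrow(part)) next
    dep <- part$dependent[1]
    dcol <- match(dep, .beh_dims)
    for (nm in part$name)
      out[nm] <- sum(vapply(seq_len(n), function(i)
        .beh_stat_actor(nm, dep, i, st$behavior[i, dcol], st$adjacency,
                        st$behavior, st$gender, st$fsm, spec$centering),
        numeric(1)))
  }
  out
}

# fast path: same vector via C++
.state_stats_cpp <- function(state, spec) {
  st <- .as_state(state)
  cs <- .cpp_spec(spec, .zero_theta(spec))
  v <- saom_stats_cpp(st$adjacency, st$behavior, st$gender, st$fsm, cs)
  lay <- .spec_layout(spec)
  setNames(v, c(lay$net$name, lay$alc$name, lay$con$name, lay$sec$name))
}

# cross-lagged target statistics of one period: network-effect statistics
# pair the end-of-period network with start-of-period behavior, and each
# behavior's statistics pair the start-of-period network (and the other
# behaviors at the start) with that behavior at the period end.  Without the
# cross-lag the tie-similarity and total-similarity targets would be the same
# function of one state and the moment system singular; the lag is also what
# lets the moments separate selection from influence.
.period_target_stats <- function(adj_start, beh_start, adj_end, beh_end,
                                 gender, fsm, cs, lay) {
  stat_names <- c(lay$net$name, lay$alc$name, lay$con$name, lay$sec$name)
  out <- setNames(numeric(length(stat_names)), stat_names)
  pn <- nrow(lay$net)
  if (pn > 0) {
    v <- saom_stats_cpp(adj_end, beh_start, gender, fsm, cs)
    out[lay$net$name] <- v[seq_len(pn)]
  }
  offset <- pn
  for (part in list(lay$alc, lay$con, lay$sec)) {
    pk <- nrow(part)
    if (pk > 0) {
      dcol <- match(part$dependent[1], .beh_dims)
      beh_hyb <- beh_start
      beh_hyb[, dcol] <- beh_end[, dcol]
      v <- saom_stats_cpp(adj_start, beh_hyb, gender, fsm, cs)
      out[part$name] <- v[offset + seq_len(pk)]
    }
    offset <- offset + pk
  }
  out
}

#' Observed target statistics of a panel
#'
#' The method-of-moments targets: for every rate parameter the observed
#' amount of change in its period (network: Hamming distance between
#' consecutive adjacency matrices over jointly observed out-rows; behavior:
#' summed absolute level change over jointly observed actors), and for every
#' free evaluation effect its statistic summed over actors and over the
#' end-of-period waves 2..M of the imputed panel.
#'
#' Evaluation targets are cross-lagged, the standard moment construction for
#' co-evolving networks and behavior: a network effect's statistic is
#' evaluated on the end-of-period network with behaviors at the period start,
#' and a behavior effect's statistic on the end-of-period behavior with the
#' network (and the other behaviors) at the period start. This is what allows
#' the moments to distinguish selection (ties moving toward behavior) from
#' influence (behavior moving toward ties).
#'
#' @param panel a [school_panel].
#' @param spec a [model_spec].
#' @return Named numeric vector: rate targets first (period-major), then
#'   evaluation-effect targets in spec order.
#' @export
target_statistics <- function(panel, spec) {
  prep <- impute_panel(panel)
  M <- panel$n_waves
  dims <- c("network", spec$behaviors)

  rates <- c()
  for (m in seq_len(M - 1)) {
    for (d in dims) {
      nm <- sprintf("rate_%s_p%d", d, m)
      if (d == "network") {
        obs <- prep$row_observed[, m] & prep$row_observed[, m + 1]
        a0 <- panel$adjacency[[m]][obs, , drop = FALSE]
        a1 <- panel$adjacency[[m + 1]][obs, , drop = FALSE]
        dd <- abs(a1 - a0)
        rates[nm] <- sum(dd, na.rm = TRUE)
      } else {
        obs <- prep$beh_observed[[d]][, m] & prep$beh_observed[[d]][, m + 1]
        rates[nm] <- sum(abs(panel[[d]][obs, m + 1] - panel[[d]][obs, m]))
      }
    }
  }

  free <- spec$effects$name[!spec$effects$fixed]
  lay <- .spec_layout(spec)
  cs <- .cpp_spec(spec, .zero_theta(spec))
  gender <- as.integer(panel$gender); fsm <- as.integer(panel$fsm)
  ev <- setNames(numeric(length(free)), free)
  for (m in 2:M) {
    sv <- .period_target_stats(prep$adjacency[[m - 1]], prep$behavior[[m - 1]],
                               prep$adjacency[[m]], prep$behavior[[m]],
                               gender, fsm, cs, lay)
    ev <- ev + sv[free]
  }
  c(rates, ev)
}
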