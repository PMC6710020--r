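# Independent brute-force oracles and fixture builders. Everything here is
# written from the statistic definitions with explicit loops, deliberately
# not sharing code with the package implementation.

# random complete state (adjacency + behaviors + covariates)
rand_state <- function(n, density = 0.3, coed = TRUE) {
  x <- matrix(rbinom(n * n, 1, density), n, n)
  diag(x) <- 0L
  storage.mode(x) <- "integer"
  list(
    adjacency = x,
    behavior = cbind(alcohol = sample(1:4, n, TRUE),
                     control = sample(1:3, n, TRUE),
                     secrecy = sample(1:3, n, TRUE)),
    gender = if (coed) rbinom(n, 1, 0.5) else rep(1L, n),
    fsm = rbinom(n, 1, 0.3)
  )
}

# two-wave panel wrapping a pair of states (for centering constants / specs)
panel_from_states <- function(s1, s2, school_id = "t1",
                              school_type = "coed") {
  n <- nrow(s1$adjacency)
  school_panel(
    school_id = school_id, school_type = school_type,
    actor_ids = sprintf("p%02d", seq_len(n)),
    adjacency = list(s1$adjacency, s2$adjacency),
    alcohol = cbind(s1$behavior[, 1], s2$behavior[, 1]),
    control = cbind(s1$behavior[, 2], s2$behavior[, 2]),
    secrecy = cbind(s1$behavior[, 3], s2$behavior[, 3]),
    gender = s1$gender, fsm = s1$fsm,
    present = matrix(TRUE, n, 2))
}

# ---- brute-force per-actor statistics (triple loops, no vectorization) ----

oracle_sim <- function(a, b, range) 1 - abs(a - b) / range

oracle_net_stat <- function(name, i, st, cc) {
  x <- st$adjacency; n <- nrow(x)
  z <- st$behavior; g <- st$gender; f <- st$fsm
  rng <- c(alcohol = 3, control = 2, secrecy = 2)
  total <- 0
  if (name == "transitive_triplets") {
    for (j in seq_len(n)) for (h in seq_len(n))
      total <- total + x[i, j] * x[j, h] * x[i, h]
    return(total)
  }
  if (name == "indegree_popularity_sqrt") {
    for (j in seq_len(n)) {
      indeg_j <- 0
      for (k in seq_len(n)) indeg_j <- indeg_j + x[k, j]
      total <- total + x[i, j] * sqrt(indeg_j)
    }
    return(total)
  }
  for (j in seq_len(n)) {
    if (x[i, j] == 0) next
    total <- total + switch(name,
      outdegree = 1,
      reciprocity = x[j, i],
      same_gender = as.numeric(g[i] == g[j]),
      fsm_similarity = oracle_sim(f[i], f[j], 1) - cc$sbar[["fsm"]],
      alcohol_alter = z[j, 1] - cc$zbar[["alcohol"]],
      alcohol_ego = z[i, 1] - cc$zbar[["alcohol"]],
      alcohol_similarity = oracle_sim(z[i, 1], z[j, 1], 3) - cc$sbar[["alcohol"]],
      control_alter = z[j, 2] - cc$zbar[["control"]],
      control_ego = z[i, 2] - cc$zbar[["control"]],
      control_similarity = oracle_sim(z[i, 2], z[j, 2], 2) - cc$sbar[["control"]],
      secrecy_alter = z[j, 3] - cc$zbar[["secrecy"]],
      secrecy_ego = z[i, 3] - cc$zbar[["secrecy"]],
      secrecy_similarity = oracle_sim(z[i, 3], z[j, 3], 2) - cc$sbar[["secrecy"]],
      control_ego_x_alcohol_similarity =
        (z[i, 2] - cc$zbar[["control"]]) *
          (oracle_sim(z[i, 1], z[j, 1], 3) - cc$sbar[["alcohol"]]),
      stop("unknown effect ", name))
  }
  total
}

oracle_beh_stat <- function(name, i, zi, st, cc) {
  x <- st$adjacency; n <- nrow(x)
  z <- st$behavior; g <- st$gender; f <- st$fsm
  outdeg <- sum(x[i, ])
  dep <- strsplit(name, "_")[[1]][1]
  zbar <- cc$zbar[[dep]]
  zc <- zi - zbar
  tot_alcsim <- 0; tot_secsim <- 0; tot_alc <- 0
  for (j in seq_len(n)) {
    if (x[i, j] == 0) next
    tot_alcsim <- tot_alcsim + oracle_sim(zi, z[j, 1], 3) - cc$sbar[["alcohol"]]
    tot_secsim <- tot_secsim + oracle_sim(zi, z[j, 3], 2) - cc$sbar[["secrecy"]]
    tot_alc <- tot_alc + z[j, 1] - cc$zbar[["alcohol"]]
  }
  switch(name,
    alcohol_linear = , control_linear = , secrecy_linear = zc,
    alcohol_quadratic = , control_quadratic = , secrecy_quadratic = zc^2,
    alcohol_total_similarity = tot_alcsim,
    alcohol_control_x_total_similarity =
      (z[i, 2] - cc$zbar[["control"]]) * tot_alcsim,
    alcohol_secrecy_x_total_similarity =
      (z[i, 3] - cc$zbar[["secrecy"]]) * tot_alcsim,
    control_from_alcohol = zc * (z[i, 1] - cc$zbar[["alcohol"]]),
    secrecy_average_similarity = tot_secsim / max(1, outdeg),
    secrecy_alter_average_drinking = zc * tot_alc / max(1, outdeg),
    alcohol_gender = , control_gender = , secrecy_gender = zc * g[i],
    alcohol_fsm = , control_fsm = , secrecy_fsm = zc * f[i],
    stop("unknown effect ", name))
}

# summed evaluation statistics over actors, by brute force
oracle_state_stats <- function(st, spec) {
  tab <- spec$effects
  cc <- spec$centering
  n <- nrow(st$adjacency)
  out <- setNames(numeric(nrow(tab)), tab$name)
  for (k in seq_len(nrow(tab))) {
    nm <- tab$name[k]
    if (tab$dependent[k] == "network") {
      for (i in seq_len(n)) out[nm] <- out[nm] + oracle_net_stat(nm, i, st, cc)
    } else {
      dcol <- match(tab$dependent[k], c("alcohol", "control", "secrecy"))
      for (i in seq_len(n))
        out[nm] <- out[nm] + oracle_beh_stat(nm, i, st$behavior[i, dcol], st, cc)
    }
  }
  out
}

# exact stationary tie density of the outdegree-only microstep chain: rows
# evolve independently; each row is a reversible birth-death chain over its
# outdegree with candidate-set normalizers Z_d (validated against a full
# 64-state enumeration for n = 3)
oracle_outdegree_density <- function(theta, n, cap = 10) {
  m <- n - 1
  dmax <- min(m, cap)
  Z <- function(d) {
    avail <- if (d < cap) m - d else 0
    exp(theta * d) * (1 + avail * exp(theta) + d * exp(-theta))
  }
  logw <- numeric(dmax + 1)
  for (d in 0:(dmax - 1))
    logw[d + 2] <- logw[d + 1] + theta + log(Z(d + 1)) - log(Z(d))
  w <- exp(logw - max(logw))
  cnt <- choose(m, 0:dmax)
  sum(cnt * w * (0:dmax)) / (m * sum(cnt * w))
}

# exact embedded transition matrix of the single-actor behavior chain on
# levels 1..K under linear + quadratic shape parameters
oracle_behavior_chain <- function(theta_lin, theta_quad, zbar, K = 4) {
  P <- matrix(0, K, K)
  f <- function(z) theta_lin * (z - zbar) + theta_quad * (z - zbar)^2
  for (z in 1:K) {
    cand <- intersect((z - 1):(z + 1), 1:K)
    w <- exp(sapply(cand, f) - max(sapply(cand, f)))
    P[z, cand] <- w / sum(w)
  }
  P
}

stationary_of <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# minimal stand-in fit object for table construction (synthetic parameters)
fake_fit <- function(par, covariance, spec, school_id = "f1",
                     school_type = "coed", converged = TRUE) {
  structure(
    list(school_id = school_id, school_type = school_type,
         theta = par, par = par, se = sqrt(diag(covariance)),
         covariance = covariance, t_ratios = setNames(rep(0, length(par)),
                                                      names(par)),
         overall_ratio = 0, converged = converged, n_phase3 = 0,
         seed = 0L, spec = spec),
    class = "saom_fit")
}

# small spec whose centering constants are set by hand (via a crafted panel)
spec_with_centering <- function(zbar_alcohol = 2.0, behaviors = "alcohol",
                                effects = c("outdegree", "alcohol_alter",
                                            "alcohol_ego",
                                            "alcohol_similarity")) {
  # panel engineered so the alcohol mean equals zbar_alcohol
  n <- 8
  lv <- rep(round(zbar_alcohol), n)
  adj <- matrix(0L, n, n); adj[1, 2] <- 1L
  st1 <- list(adjacency = adj,
              behavior = cbind(lv, rep(2L, n), rep(2L, n)),
              gender = rep(0L, n), fsm = rep(0L, n))
  p <- panel_from_states(st1, st1)
  sp <- model_spec(p, effects = effects, behaviors = behaviors)
  sp$centering$zbar["alcohol"] <- zbar_alcohol
  sp
}
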