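# Synthetic multi-school studies with known ground truth, emulating the
# structure of a five-wave adolescent cohort: 22 schools of 60-210 pupils,
# up-to-10 friendship nominations, drinking prevalence rising from ~5% weekly
# at entry, tertiled parental-control and secrecy scores, and wave-level
# absence missingness.

#' Configuration of a synthetic study
#'
#' The defaults are the study conditions every downstream module is exercised
#' under: school counts by gender status, the size range, five annual waves,
#' a true parameter vector whose magnitudes echo plausible pooled estimates
#' (strong negative density, strong reciprocity, moderate transitivity and
#' popularity, gender and deprivation assortativity, drinking-similarity
#' selection and total-similarity influence), a positive alcohol drift that
#' carries weekly prevalence from about 5% toward 40% over four periods, and
#' 12% wave-level absence.
#'
#' Moderator offsets define school-context ground truth: by default
#' boys-only schools get a `+0.4` offset on the secrecy-alter tie effect (a
#' context contrast the meta-regression should recover).
#'
#' @param n_coed,n_girls,n_boys school counts by type.
#' @param size_range inclusive pupil-count range.
#' @param waves number of observation waves (>= 2).
#' @param theta named true parameter vector; unnamed effects are zero.
#' @param rates per-actor opportunity rates per period (named:
#'   network/alcohol/control/secrecy).
#' @param behaviors behavior dimensions that co-evolve.
#' @param effects effect names in the generating (and default fitted) model;
#'   `NULL` = full catalog for `behaviors`.
#' @param wave1_alcohol probabilities of levels 1..4 at wave 1.
#' @param wave1_control,wave1_secrecy probabilities of tertiles 1..3.
#' @param mean_outdegree target mean outdegree of the wave-1 graph.
#' @param gender_homophily odds multiplier for same-gender wave-1 ties in
#'   coeducational schools.
#' @param fsm_rate free-school-meal eligibility probability.
#' @param absence_prob per actor-wave absence probability in `[0, 0.5]`.
#' @param moderator_offsets named list of named vectors added to `theta` by
#'   school type (`boys`, `girls`, `single_sex`).
#' @param seed master seed; per-school sub-seeds derive from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_coed = 9, n_girls = 8, n_boys = 5,
                         size_range = c(60, 210), waves = 5,
                         theta = NULL, rates = NULL,
                         behaviors = c("alcohol", "control", "secrecy"),
                         effects = NULL,
                         wave1_alcohol = c(0.60, 0.27, 0.08, 0.05),
                         wave1_control = c(1, 1, 1) / 3,
                         wave1_secrecy = c(1, 1, 1) / 3,
                         mean_outdegree = 4, gender_homophily = 4,
                         fsm_rate = 0.2, absence_prob = 0.12,
                         moderator_offsets = list(boys = c(secrecy_alter = 0.4)),
                         seed = 1L) {
  stopifnot(waves >= 2, absence_prob >= 0, absence_prob <= 0.5,
            size_range[1] >= 3, size_range[2] >= size_range[1])
  theta_default <- c(
    outdegree = -2.2, reciprocity = 1.5, transitive_triplets = 0.3,
    indegree_popularity_sqrt = 0.2, same_gender = 0.5, fsm_similarity = 0.2,
    alcohol_similarity = 0.35, control_similarity = 0.12,
    alcohol_total_similarity = 0.46,
    secrecy_average_similarity = 1.2, control_from_alcohol = -0.25,
    alcohol_linear = 0.55, alcohol_quadratic = 0.05
  )
  th <- theta_default
  if (!is.null(theta)) {
    th <- if (is.null(names(theta))) theta else {
      th[names(theta)] <- theta; th
    }
  }
  rt <- c(network = 5, alcohol = 1.6, control = 0.7, secrecy = 0.7)
  if (!is.null(rates)) rt[names(rates)] <- rates
  structure(
    list(n_coed = n_coed, n_girls = n_girls, n_boys = n_boys,
         size_range = size_range, waves = waves, theta = th, rates = rt,
         behaviors = intersect(.beh_dims, behaviors), effects = effects,
         wave1_alcohol = wave1_alcohol / sum(wave1_alcohol),
         wave1_control = wave1_control / sum(wave1_control),
         wave1_secrecy = wave1_secrecy / sum(wave1_secrecy),
         mean_outdegree = mean_outdegree,
         gender_homophily = gender_homophily, fsm_rate = fsm_rate,
         absence_prob = absence_prob,
         moderator_offsets = moderator_offsets, seed = as.integer(seed)),
    class = "synth_config")
}

# deterministic per-school sub-seed below 2^31
.school_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + index * 7919) %% (2^31 - 1)) + 1L
}

.school_types <- function(config) {
  rep(c("coed", "girls", "boys"),
      c(config$n_coed, config$n_girls, config$n_boys))
}

# homophilous wave-1 random graph with mean outdegree ~ target, cap respected
.wave1_network <- function(n, gender, mean_outdegree, homophily) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    w <- ifelse(gender == gender[i], homophily, 1)
    w[i] <- 0
    k <- min(.nomination_cap, max(0L, rbinom(1, n - 1L,
                                             min(0.9, mean_outdegree / (n - 1L)))))
    if (k > 0) {
      alters <- sample.int(n, k, prob = w / sum(w))
      adj[i, alters] <- 1L
    }
  }
  diag(adj) <- 0L
  adj
}

#' Generate one synthetic school
#'
#' Draws the school size and covariates, initializes wave 1 (homophilous
#' random friendship graph, behaviors from the configured wave-1
#' distributions), applies the school type's moderator offsets to the true
#' parameters, simulates the remaining waves with [simulate_panel()], and
#' injects wave-level absence with [inject_missingness()].
#'
#' @param config a [synth_config].
#' @param school_index 1-based index into the study (determines type and
#'   sub-seed).
#' @return A list with the `panel` ([school_panel]) and the `ground_truth`
#'   (true theta after offsets, rates, sub-seed, school type).
#' @export
generate_school <- function(config, school_index) {
  types <- .school_types(config)
  stopifnot(school_index >= 1, school_index <= length(types))
  type <- types[school_index]
  sub_seed <- .school_seed(config$seed, school_index)
  set.seed(sub_seed)

  sizes <- seq(config$size_range[1], config$size_range[2])
  n <- if (length(sizes) == 1) sizes else sample(sizes, 1)
  gender <- switch(type,
    coed = rbinom(n, 1, 0.5),
    girls = rep(1L, n),
    boys = rep(0L, n))
  fsm <- rbinom(n, 1, config$fsm_rate)
  beh <- cbind(
    alcohol = sample(1:4, n, TRUE, config$wave1_alcohol),
    control = sample(1:3, n, TRUE, config$wave1_control),
    secrecy = sample(1:3, n, TRUE, config$wave1_secrecy))
  adj <- .wave1_network(n, gender, config$mean_outdegree,
                        config$gender_homophily)

  theta <- config$theta
  off <- config$moderator_offsets
  apply_off <- function(theta, o) {
    keep <- intersect(names(o), names(theta))
    theta[keep] <- theta[keep] + o[keep]
    extra <- setdiff(names(o), names(theta))
    c(theta, o[extra])
  }
  if (type == "boys" && !is.null(off$boys)) theta <- apply_off(theta, off$boys)
  if (type == "girls" && !is.null(off$girls)) theta <- apply_off(theta, off$girls)
  if (type != "coed" && !is.null(off$single_sex))
    theta <- apply_off(theta, off$single_sex)

  # spec for simulation: centering constants from a provisional wave-1 panel
  proto <- school_panel(
    school_id = sprintf("s%02d", school_index), school_type = type,
    actor_ids = sprintf("a%03d", seq_len(n)),
    adjacency = list(adj, adj), alcohol = cbind(beh[, 1], beh[, 1]),
    control = cbind(beh[, 2], beh[, 2]), secrecy = cbind(beh[, 3], beh[, 3]),
    gender = gender, fsm = fsm)
  spec <- model_spec(proto, effects = config$effects,
                     behaviors = config$behaviors)

  rates <- config$rates
  rates[!names(rates) %in% c("network", spec$behaviors)] <- 0
  panel <- simulate_panel(
    list(adjacency = adj, behavior = beh, gender = gender, fsm = fsm),
    theta = theta, rates = rates, spec = spec,
    n_periods = config$waves - 1,
    school_id = sprintf("s%02d", school_index),
    school_type = type)
  panel <- inject_missingness(panel, config$absence_prob)

  list(panel = panel,
       ground_truth = list(theta = theta, rates = rates,
                           seed = sub_seed, school_type = type,
                           school_id = panel$school_id, spec = spec))
}

#' Generate a full synthetic study
#'
#' All schools with independent sub-seeds derived from the master seed, plus
#' the school metadata table (including realized year-3 weekly drinking
#' prevalence). Optionally writes the panels in the CSV dialect of
#' [save_panel()] together with `ground_truth.json`.
#'
#' @param config a [synth_config].
#' @param out_dir optional output directory.
#' @return A list: `panels`, `ground_truth`, `metadata` tibble.
#' @export
generate_study <- function(config = synth_config(), out_dir = NULL) {
  types <- .school_types(config)
  res <- lapply(seq_along(types), function(k) generate_school(config, k))
  panels <- lapply(res, `[[`, "panel")
  gt <- lapply(res, `[[`, "ground_truth")
  metadata <- tibble::tibble(
    school_id = vapply(panels, function(p) p$school_id, character(1)),
    school_type = vapply(panels, function(p) p$school_type, character(1)),
    n_pupils = vapply(panels, function(p) p$n, numeric(1)),
    year3_weekly_prevalence = vapply(panels, function(p)
      p$year3_weekly_prevalence, numeric(1)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (p in panels) save_panel(p, out_dir)
    write.csv(metadata, file.path(out_dir, "school_metadata.csv"),
              row.names = FALSE)
    gt_json <- lapply(gt, function(g) {
      g$theta <- as.list(g$theta); g$rates <- as.list(g$rates)
      g[setdiff(names(g), "spec")]
    })
    jsonlite::write_json(gt_json, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(panels = panels, ground_truth = gt, metadata = metadata)
}

#' Inject wave-level absence missingness
#'
#' Marks each actor-wave absent independently with probability
#' `absence_prob`; an absent actor-wave loses its whole nomination out-row
#' and all behavior values. Wave-1 absences are capped so at least 80% of the
#' first wave stays observed. Observed entries are never altered.
#'
#' @param panel a fully observed [school_panel].
#' @param absence_prob probability in `[0, 0.5]`.
#' @param seed optional integer seed.
#' @return The panel with missingness applied.
#' @export
inject_missingness <- function(panel, absence_prob, seed = NULL) {
  stopifnot(absence_prob >= 0, absence_prob <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  if (absence_prob == 0) return(panel)
  n <- panel$n; M <- panel$n_waves
  absent <- matrix(rbinom(n * M, 1, absence_prob) == 1L, n, M)
  cap1 <- floor(0.2 * n)
  if (sum(absent[, 1]) > cap1) {
    keep_absent <- sample(which(absent[, 1]), cap1)
    absent[, 1] <- FALSE
    absent[keep_absent, 1] <- TRUE
  }
  for (m in seq_len(M)) {
    idx <- which(absent[, m])
    if (!length(idx)) next
    panel$adjacency[[m]][idx, ] <- NA_integer_
    panel$alcohol[idx, m] <- NA_integer_
    panel$control[idx, m] <- NA_integer_
    panel$secrecy[idx, m] <- NA_integer_
    panel$present[idx, m] <- FALSE
  }
  validate_panel(panel)
  panel
}
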