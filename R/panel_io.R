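# Longitudinal school panels: construction, validation, CSV round trip,
# recoding and school-level filtering.

#' Construct a school panel
#'
#' A `school_panel` holds everything the co-evolution model needs for one
#' school: the roster of pupils, one directed friendship adjacency matrix per
#' annual wave (up to `r .nomination_cap` nominations per pupil), the three
#' ordinal behavior dimensions (drinking frequency 1--4, parental-control and
#' secrecy tertiles 1--3), the constant covariates gender and free-school-meal
#' (FSM) eligibility, and school metadata.
#'
#' Missingness convention: a pupil absent on survey day has their whole
#' nomination out-row and all behavior values missing for that wave; a present
#' pupil's unlisted alters are observed zeros (roster instruments imply
#' non-ties).
#'
#' @param school_id character scalar.
#' @param school_type one of `"coed"`, `"girls"`, `"boys"`.
#' @param actor_ids character vector of pupil identifiers (length n).
#' @param adjacency list of n x n integer matrices (0/1/`NA`), one per wave;
#'   diagonal must be zero and row sums at most `r .nomination_cap`.
#' @param alcohol,control,secrecy n x M integer matrices (`NA` = missing);
#'   alcohol in 1..4, control and secrecy in 1..3.
#' @param gender,fsm integer vectors (0/1), constant over waves.
#' @param present n x M logical matrix; `FALSE` marks wave-level absence.
#' @param year3_weekly_prevalence share of Year 3 pupils drinking weekly or
#'   more often, in `[0, 1]`.
#' @param control_score,secrecy_score optional n x M numeric matrices of raw
#'   scale scores (kept for serialization; tertiles are derived from them).
#' @return An object of class `school_panel`.
#' @export
school_panel <- function(school_id, school_type, actor_ids, adjacency,
                         alcohol, control, secrecy, gender, fsm,
                         present = NULL, year3_weekly_prevalence = NA_real_,
                         control_score = NULL, secrecy_score = NULL) {
  n <- length(actor_ids)
  M <- length(adjacency)
  if (is.null(present)) {
    present <- matrix(TRUE, n, M)
    for (m in seq_len(M)) present[, m] <- !apply(is.na(adjacency[[m]]), 1, all)
  }
  panel <- structure(
    list(
      school_id = as.character(school_id),
      school_type = match.arg(school_type, c("coed", "girls", "boys")),
      actor_ids = as.character(actor_ids),
      n = n, n_waves = M,
      adjacency = lapply(adjacency, function(x) {
        x <- as.matrix(x); storage.mode(x) <- "integer"
        dimnames(x) <- list(actor_ids, actor_ids); x
      }),
      present = present,
      alcohol = .beh_matrix(alcohol, n, M, actor_ids),
      control = .beh_matrix(control, n, M, actor_ids),
      secrecy = .beh_matrix(secrecy, n, M, actor_ids),
      gender = as.integer(gender), fsm = as.integer(fsm),
      year3_weekly_prevalence = as.numeric(year3_weekly_prevalence),
      control_score = control_score, secrecy_score = secrecy_score
    ),
    class = "school_panel"
  )
  validate_panel(panel)
}

.beh_matrix <- function(x, n, M, ids) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == n, ncol(x) == M)
  storage.mode(x) <- "integer"
  rownames(x) <- ids
  x
}

#' Validate a school panel
#'
#' Checks all structural invariants: square ternary adjacency matrices with
#' zero diagonal and out-degree at most `r .nomination_cap`, at least two
#' waves, behavior levels within range, single-sex gender consistency, and a
#' prevalence value in `[0, 1]`.
#'
#' @param panel a [school_panel].
#' @return The panel, invisibly unchanged, or an error.
#' @export
validate_panel <- function(panel) {
  n <- panel$n; M <- panel$n_waves
  if (M < 2) abort("a school panel needs at least 2 waves")
  for (m in seq_len(M)) {
    x <- panel$adjacency[[m]]
    if (!all(dim(x) == c(n, n))) abort("adjacency matrices must be n x n")
    if (any(diag(x) != 0, na.rm = TRUE))
      abort(sprintf("self-nomination in wave %d", m))
    if (!all(x %in% c(0L, 1L, NA)))
      abort(sprintf("adjacency entries must be 0, 1 or missing (wave %d)", m))
    rs <- rowSums(x, na.rm = TRUE)
    if (any(rs > .nomination_cap))
      abort(sprintf("more than %d nominations for an actor in wave %d",
                    .nomination_cap, m))
  }
  for (b in .beh_dims) {
    v <- panel[[b]]
    bad <- !(v %in% c(.beh_levels[[b]], NA))
    if (any(bad)) abort(sprintf("%s values out of range", b))
  }
  if (!all(panel$gender %in% 0:1) || !all(panel$fsm %in% 0:1))
    abort("gender and fsm must be binary")
  if (panel$school_type == "girls" && any(panel$gender != 1L))
    abort("girls school with non-female pupils")
  if (panel$school_type == "boys" && any(panel$gender != 0L))
    abort("boys school with female pupils")
  p <- panel$year3_weekly_prevalence
  if (!is.na(p) && (p < 0 || p > 1))
    abort("year3_weekly_prevalence must be in [0, 1]")
  invisible(panel)
}

#' @export
print.school_panel <- function(x, ...) {
  cat(sprintf("<school_panel> %s (%s): %d pupils, %d waves\n",
              x$school_id, x$school_type, x$n, x$n_waves))
  obs <- mean(x$present)
  cat(sprintf("  observed actor-waves: %.1f%%; year-3 weekly prevalence: %s\n",
              100 * obs,
              ifelse(is.na(x$year3_weekly_prevalence), "NA",
                     sprintf("%.2f", x$year3_weekly_prevalence))))
  invisible(x)
}

#' Recode the two alcohol questionnaire items to the 4-category scale
#'
#' Ever-use (yes/no) and drinking frequency combine into a single ordinal
#' variable: 1 = never, 2 = infrequent (has drunk alcohol but not regularly),
#' 3 = monthly, 4 = weekly or more frequently. A respondent who has drunk
#' alcohol but reports no current frequency is an infrequent drinker (2).
#'
#' @param ever_used logical/0-1 vector (or "yes"/"no").
#' @param frequency_item character vector with levels `none`, `infrequent`,
#'   `monthly`, `weekly_plus`.
#' @return Integer vector in 1..4; `NA` where either item is missing.
#' @export
#' @examples
#' recode_alcohol(c(0, 1, 1), c("none", "monthly", "weekly_plus"))
recode_alcohol <- function(ever_used, frequency_item) {
  ever <- .as_binary(ever_used)
  freq <- as.character(frequency_item)
  ok <- freq %in% c("none", "infrequent", "monthly", "weekly_plus") | is.na(freq)
  if (!all(ok)) abort(sprintf("unknown frequency level: %s",
                              paste(unique(freq[!ok]), collapse = ", ")))
  bad <- !is.na(ever) & !is.na(freq) & ever == 0L & freq != "none"
  if (any(bad))
    abort("inconsistent alcohol items: never-used respondents cannot report a drinking frequency")
  out <- rep(NA_integer_, length(ever))
  known <- !is.na(ever) & !is.na(freq)
  out[known & ever == 0L] <- 1L
  out[known & ever == 1L & freq == "none"] <- 2L
  out[known & ever == 1L & freq == "infrequent"] <- 2L
  out[known & ever == 1L & freq == "monthly"] <- 3L
  out[known & ever == 1L & freq == "weekly_plus"] <- 4L
  out
}

.as_binary <- function(x) {
  if (is.character(x)) x <- match(tolower(x), c("no", "yes")) - 1L
  if (is.logical(x)) x <- as.integer(x)
  x <- as.integer(x)
  if (any(!(x %in% c(0L, 1L, NA)))) abort("binary item must be 0/1 or yes/no")
  x
}

#' Split scores into tertiles
#'
#' Maps scores to ranks 1 (lowest third) to 3 (highest third) using the
#' empirical 1/3 and 2/3 quantiles of the non-missing values. Values equal to
#' a boundary go to the lower tertile; a constant vector maps to tertile 2.
#' The result depends only on the rank order of the scores.
#'
#' @param scores numeric vector, possibly with `NA`.
#' @return Integer vector in 1..3 with `NA` preserved.
#' @export
#' @examples
#' tertile_split(1:9)
tertile_split <- function(scores) {
  obs <- scores[!is.na(scores)]
  if (length(obs) < 3)
    abort("tertile_split needs at least 3 non-missing scores")
  if (length(unique(obs)) == 1L) {
    out <- rep(NA_integer_, length(scores))
    out[!is.na(scores)] <- 2L
    return(out)
  }
  q <- quantile(obs, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  out <- rep(NA_integer_, length(scores))
  idx <- !is.na(scores)
  out[idx] <- 1L + (scores[idx] > q[1]) + (scores[idx] > q[2])
  out
}

#' Drop schools with too much missing nomination data
#'
#' Retains panels whose fraction of actor-waves with a fully missing
#' nomination out-row is strictly below `threshold` (default 20%).
#'
#' @param panels list of [school_panel] objects.
#' @param threshold exclusion threshold in `(0, 1]`.
#' @return The retained sublist.
#' @export
filter_schools <- function(panels, threshold = 0.20) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- vapply(panels, function(p) missing_fraction(p) < threshold, logical(1))
  panels[keep]
}

#' Fraction of actor-waves with fully missing nomination data
#' @param panel a [school_panel].
#' @return A number in `[0, 1]`.
#' @export
missing_fraction <- function(panel) {
  miss <- vapply(seq_len(panel$n_waves), function(m)
    sum(apply(is.na(panel$adjacency[[m]]), 1, all)), numeric(1))
  sum(miss) / (panel$n * panel$n_waves)
}

# ---- CSV dialect -----------------------------------------------------------

#' Load one school's panel from CSV files
#'
#' Reads the per-wave edge lists (`school_id, wave, ego_id, alter_id`), the
#' actor-wave attribute table and a school metadata descriptor, validates
#' them, recodes alcohol via [recode_alcohol()] and tertiles the control and
#' secrecy scale scores per school-wave via [tertile_split()].
#'
#' The attribute file has one row per actor-wave with columns `school_id,
#' wave, actor_id, present, gender, fsm, ever_alcohol, alcohol_freq,
#' control_score, secrecy_score` (empty cell = missing). If integer columns
#' `control_level`/`secrecy_level` are present (written by [save_panel()])
#' they are used directly instead of re-tertiling, so a save/load round trip
#' is exact.
#'
#' @param network_files character vector of per-wave edge-list CSV paths, in
#'   wave order.
#' @param attribute_file path to the actor-wave attribute CSV.
#' @param metadata a one-row data frame or named list with `school_id`,
#'   `school_type` and `year3_weekly_prevalence`.
#' @return A validated [school_panel].
#' @export
load_panel <- function(network_files, attribute_file, metadata) {
  for (f in c(network_files, attribute_file))
    if (!file.exists(f)) abort(sprintf("file not found: %s", f))
  metadata <- as.list(metadata)

  att <- read.csv(attribute_file, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
  need <- c("school_id", "wave", "actor_id", "present", "gender", "fsm",
            "ever_alcohol", "alcohol_freq", "control_score", "secrecy_score")
  missing_cols <- setdiff(need, names(att))
  if (length(missing_cols))
    abort(sprintf("attribute file lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))

  actor_ids <- unique(as.character(att$actor_id))
  n <- length(actor_ids)
  M <- max(att$wave)
  if (length(network_files) != M)
    abort(sprintf("expected %d edge-list files (one per wave), got %d",
                  M, length(network_files)))
  idx <- function(a) match(as.character(a), actor_ids)

  present <- matrix(FALSE, n, M)
  alc <- con <- sec <- matrix(NA_integer_, n, M)
  con_score <- sec_score <- matrix(NA_real_, n, M)
  gender <- fsm <- rep(NA_integer_, n)
  has_levels <- all(c("control_level", "secrecy_level") %in% names(att))

  for (r in seq_len(nrow(att))) {
    i <- idx(att$actor_id[r]); m <- att$wave[r]
    present[i, m] <- att$present[r] == 1
    if (is.na(gender[i]) && !is.na(att$gender[r])) gender[i] <- att$gender[r]
    if (is.na(fsm[i]) && !is.na(att$fsm[r])) fsm[i] <- att$fsm[r]
    con_score[i, m] <- att$control_score[r]
    sec_score[i, m] <- att$secrecy_score[r]
  }
  # alcohol recode is vectorized over the whole table
  alc_vals <- recode_alcohol(att$ever_alcohol, att$alcohol_freq)
  for (r in seq_len(nrow(att)))
    alc[idx(att$actor_id[r]), att$wave[r]] <- alc_vals[r]

  if (has_levels) {
    for (r in seq_len(nrow(att))) {
      i <- idx(att$actor_id[r]); m <- att$wave[r]
      con[i, m] <- att$control_level[r]
      sec[i, m] <- att$secrecy_level[r]
    }
  } else {
    for (m in seq_len(M)) {
      if (sum(!is.na(con_score[, m])) >= 3) con[, m] <- tertile_split(con_score[, m])
      if (sum(!is.na(sec_score[, m])) >= 3) sec[, m] <- tertile_split(sec_score[, m])
    }
  }

  adjacency <- vector("list", M)
  for (m in seq_len(M)) {
    x <- matrix(0L, n, n)
    ed <- read.csv(network_files[m], stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
    need_e <- c("school_id", "wave", "ego_id", "alter_id")
    if (!all(need_e %in% names(ed)))
      abort(sprintf("edge list %s lacks columns: %s", network_files[m],
                    paste(setdiff(need_e, names(ed)), collapse = ", ")))
    if (nrow(ed)) {
      if (any(is.na(ed$ego_id)) || any(is.na(ed$alter_id)))
        abort(sprintf("malformed row in %s", network_files[m]))
      ei <- idx(ed$ego_id); ai <- idx(ed$alter_id)
      if (anyNA(ei) || anyNA(ai)) {
        bad <- unique(c(ed$ego_id[is.na(ei)], ed$alter_id[is.na(ai)]))
        abort(sprintf("%s references unknown actors: %s", network_files[m],
                      paste(bad, collapse = ", ")))
      }
      if (any(ei == ai))
        abort(sprintf("self-nomination in %s (line %d)", network_files[m],
                      which(ei == ai)[1] + 1L))
      x[cbind(ei, ai)] <- 1L
      counts <- table(ei)
      if (any(counts > .nomination_cap))
        abort(sprintf("actor %s lists more than %d friends in wave %d",
                      actor_ids[as.integer(names(counts)[counts > .nomination_cap])][1],
                      .nomination_cap, m))
    }
    diag(x) <- 0L
    # absent actor-waves: the entire out-row (diagonal included) is missing,
    # so fully missing rows stay recognizable
    x[!present[, m], ] <- NA_integer_
    adjacency[[m]] <- x
  }

  school_panel(
    school_id = metadata$school_id, school_type = metadata$school_type,
    actor_ids = actor_ids, adjacency = adjacency,
    alcohol = alc, control = con, secrecy = sec,
    gender = gender, fsm = fsm, present = present,
    year3_weekly_prevalence = as.numeric(metadata$year3_weekly_prevalence),
    control_score = con_score, secrecy_score = sec_score
  )
}

#' Write a school panel to the CSV dialect read by [load_panel()]
#'
#' @param panel a [school_panel].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the written file paths (`network_files`,
#'   `attribute_file`, `metadata_file`).
#' @export
save_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sid <- panel$school_id
  n <- panel$n; M <- panel$n_waves

  network_files <- file.path(dir, sprintf("%s_edges_wave%d.csv", sid, seq_len(M)))
  for (m in seq_len(M)) {
    x <- panel$adjacency[[m]]
    ij <- which(x == 1L, arr.ind = TRUE)
    ed <- data.frame(school_id = sid, wave = m,
                     ego_id = panel$actor_ids[ij[, 1]],
                     alter_id = panel$actor_ids[ij[, 2]])
    write.csv(ed[order(ed$ego_id, ed$alter_id), ], network_files[m],
              row.names = FALSE, quote = FALSE)
  }

  freq_label <- c("none", "infrequent", "monthly", "weekly_plus")
  rows <- expand.grid(i = seq_len(n), wave = seq_len(M))
  att <- data.frame(
    school_id = sid, wave = rows$wave, actor_id = panel$actor_ids[rows$i],
    present = as.integer(panel$present[cbind(rows$i, rows$wave)]),
    gender = panel$gender[rows$i], fsm = panel$fsm[rows$i],
    ever_alcohol = ifelse(is.na(panel$alcohol[cbind(rows$i, rows$wave)]), NA,
                          as.integer(panel$alcohol[cbind(rows$i, rows$wave)] > 1L)),
    alcohol_freq = ifelse(is.na(panel$alcohol[cbind(rows$i, rows$wave)]), NA,
                          freq_label[panel$alcohol[cbind(rows$i, rows$wave)]]),
    control_score = if (is.null(panel$control_score)) NA_real_ else
      panel$control_score[cbind(rows$i, rows$wave)],
    secrecy_score = if (is.null(panel$secrecy_score)) NA_real_ else
      panel$secrecy_score[cbind(rows$i, rows$wave)],
    control_level = panel$control[cbind(rows$i, rows$wave)],
    secrecy_level = panel$secrecy[cbind(rows$i, rows$wave)]
  )
  # frequency 1 ("never") maps to ever_alcohol = 0 with frequency none
  att$alcohol_freq[!is.na(att$ever_alcohol) & att$ever_alcohol == 0L] <- "none"
  attribute_file <- file.path(dir, sprintf("%s_attributes.csv", sid))
  write.csv(att[order(att$wave, att$actor_id), ], attribute_file,
            row.names = FALSE, quote = FALSE)

  metadata_file <- file.path(dir, sprintf("%s_metadata.csv", sid))
  write.csv(data.frame(school_id = sid, school_type = panel$school_type,
                       year3_weekly_prevalence = panel$year3_weekly_prevalence),
            metadata_file, row.names = FALSE, quote = FALSE)
  invisible(list(network_files = network_files, attribute_file = attribute_file,
                 metadata_file = metadata_file))
}

#' Impute missing panel entries for simulation
#'
#' Missing behavior values are carried forward from the last observation;
#' wave-1 missing behaviors take the school-wave mode. A missing nomination
#' out-row is carried forward from the previous wave (zeros at wave 1).
#' Imputed entries feed the simulator but are excluded from observed change
#' (rate) targets, which use the observation masks returned here.
#'
#' @param panel a [school_panel].
#' @return A list with per-wave complete `adjacency` and `behavior` (n x 3
#'   integer matrices, columns alcohol/control/secrecy), the logical
#'   `row_observed` (n x M) mask, and per-dimension `beh_observed` masks.
#' @export
impute_panel <- function(panel) {
  n <- panel$n; M <- panel$n_waves
  row_obs <- sapply(seq_len(M), function(m)
    !apply(is.na(panel$adjacency[[m]]), 1, all))
  row_obs <- matrix(row_obs, n, M)

  adjacency <- vector("list", M)
  prev <- matrix(0L, n, n)
  for (m in seq_len(M)) {
    x <- panel$adjacency[[m]]
    for (i in seq_len(n)) if (!row_obs[i, m]) x[i, ] <- prev[i, ]
    x[is.na(x)] <- 0L   # partial missingness inside an observed row
    diag(x) <- 0L
    adjacency[[m]] <- x
    prev <- x
  }

  beh_observed <- list()
  behavior <- rep(list(matrix(NA_integer_, n, 3)), M)
  for (d in seq_along(.beh_dims)) {
    b <- .beh_dims[d]
    v <- panel[[b]]
    beh_observed[[b]] <- !is.na(v)
    filled <- v
    # wave-1 mode of the observed values (midpoint when nothing observed)
    w1 <- filled[, 1]
    if (all(is.na(w1))) {
      mode1 <- as.integer(round(median(.beh_levels[[b]])))
    } else {
      tab <- table(w1)
      mode1 <- as.integer(names(tab)[which.max(tab)])
    }
    w1[is.na(w1)] <- mode1
    filled[, 1] <- w1
    for (m in 2:M) {
      nas <- is.na(filled[, m])
      filled[nas, m] <- filled[nas, m - 1]
    }
    for (m in seq_len(M)) behavior[[m]][, d] <- filled[, m]
  }
  list(adjacency = adjacency, behavior = behavior,
       row_observed = row_obs, beh_observed = beh_observed)
}
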