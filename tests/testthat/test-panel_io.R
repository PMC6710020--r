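test_that("alcohol recode maps the questionnaire items onto the 4-point scale", {
  expect_identical(recode_alcohol(0, "none"), 1L)
  expect_identical(recode_alcohol(1, "weekly_plus"), 4L)
  expect_identical(
    recode_alcohol(c(0, 1, 1, 1, 1), c("none", "none", "infrequent",
                                       "monthly", "weekly_plus")),
    c(1L, 2L, 2L, 3L, 4L))
  # surjective onto 1..4 over the consistent combinations
  expect_setequal(
    recode_alcohol(c(0, 1, 1, 1), c("none", "infrequent", "monthly",
                                    "weekly_plus")), 1:4)
  expect_error(recode_alcohol(0, "monthly"), "inconsistent")
  expect_true(is.na(recode_alcohol(NA, "monthly")))
})

test_that("tertile split follows the empirical thirds with lower-tertile ties", {
  expect_identical(tertile_split(1:9), rep(1:3, each = 3L))
  # constant vector: degenerate, everything in the middle tertile
  expect_identical(tertile_split(rep(5, 4)), rep(2L, 4))
  # missing preserved
  expect_identical(tertile_split(c(1, NA, 2, 3)), c(1L, NA, 2L, 3L))
  expect_error(tertile_split(c(NA, NA, NA)), "non-missing")
  # 30 distinct draws split exactly 10/10/10
  set.seed(5)
  x <- runif(30)
  expect_equal(unname(table(tertile_split(x))), c(10, 10, 10),
               ignore_attr = TRUE)
})

test_that("tertile split depends only on rank order", {
  set.seed(7)
  for (r in 1:20) {
    x <- rnorm(25)
    expect_identical(tertile_split(x), tertile_split(exp(2 * x)))
  }
})

test_that("school filter drops panels at or above the missingness threshold", {
  base <- rand_state(10, 0.2)
  make_panel_with_missing <- function(frac) {
    p <- panel_from_states(base, rand_state(10, 0.2))
    k <- round(frac * 20)  # 10 actors x 2 waves
    if (k > 0) {
      cells <- utils::head(expand.grid(i = 1:10, m = 1:2), k)
      for (r in seq_len(nrow(cells))) {
        p$adjacency[[cells$m[r]]][cells$i[r], ] <- NA_integer_
        p$present[cells$i[r], cells$m[r]] <- FALSE
      }
    }
    p
  }
  set.seed(3)
  p00 <- make_panel_with_missing(0)
  p20 <- make_panel_with_missing(0.20)
  p25 <- make_panel_with_missing(0.25)
  expect_equal(missing_fraction(p25), 0.25)
  kept <- filter_schools(list(p00, p20, p25))
  expect_length(kept, 1)       # exactly-20% is excluded (strict <)
  expect_identical(kept[[1]], p00)
})

test_that("panel validation enforces the structural invariants", {
  st <- rand_state(5)
  bad <- st$adjacency; bad[2, 2] <- 1L
  expect_error(panel_from_states(modifyList(st, list(adjacency = bad)), st),
               "self-nomination")
  crowded <- matrix(0L, 12, 12); crowded[1, 2:12] <- 1L
  st2 <- rand_state(12)
  expect_error(
    panel_from_states(modifyList(st2, list(adjacency = crowded)), st2),
    "nominations")
  # single-sex consistency
  g <- rand_state(4, coed = FALSE)
  expect_error(school_panel(
    school_id = "b", school_type = "boys",
    actor_ids = letters[1:4], adjacency = list(g$adjacency, g$adjacency),
    alcohol = cbind(g$behavior[, 1], g$behavior[, 1]),
    control = cbind(g$behavior[, 2], g$behavior[, 2]),
    secrecy = cbind(g$behavior[, 3], g$behavior[, 3]),
    gender = g$gender, fsm = g$fsm), "boys school")
})

test_that("CSV round trip preserves the panel exactly", {
  set.seed(11)
  cfg <- synth_config(waves = 3, size_range = c(12, 15), absence_prob = 0.15)
  p <- generate_school(cfg, 1)$panel
  dir <- withr::local_tempdir()
  files <- save_panel(p, dir)
  p2 <- load_panel(files$network_files, files$attribute_file,
                   list(school_id = p$school_id, school_type = p$school_type,
                        year3_weekly_prevalence = p$year3_weekly_prevalence))
  for (fld in c("school_id", "school_type", "actor_ids", "gender", "fsm",
                "alcohol", "control", "secrecy", "present",
                "year3_weekly_prevalence")) {
    expect_equal(p2[[fld]], p[[fld]], ignore_attr = TRUE, label = fld)
  }
  for (m in seq_len(p$n_waves))
    expect_equal(p2$adjacency[[m]], p$adjacency[[m]], ignore_attr = TRUE)
})

test_that("loading validates edge lists against the roster and the cap", {
  dir <- withr::local_tempdir()
  att <- data.frame(
    school_id = "x", wave = rep(1:2, each = 3),
    actor_id = rep(c("a", "b", "c"), 2), present = 1,
    gender = 0, fsm = 0, ever_alcohol = 0, alcohol_freq = "none",
    control_score = c(1, 2, 3, 1, 2, 3), secrecy_score = c(3, 2, 1, 3, 2, 1))
  af <- file.path(dir, "att.csv"); write.csv(att, af, row.names = FALSE)
  ef <- file.path(dir, c("w1.csv", "w2.csv"))
  empty <- data.frame(school_id = character(0), wave = integer(0),
                      ego_id = character(0), alter_id = character(0))
  write.csv(empty, ef[1], row.names = FALSE)
  write.csv(empty, ef[2], row.names = FALSE)
  meta <- list(school_id = "x", school_type = "coed",
               year3_weekly_prevalence = 0.1)

  # empty edge lists give an all-zero (not missing) adjacency
  p <- load_panel(ef, af, meta)
  expect_true(all(p$adjacency[[1]] == 0))
  expect_true(all(p$present))

  write.csv(data.frame(school_id = "x", wave = 1, ego_id = "a",
                       alter_id = "a"), ef[1], row.names = FALSE)
  expect_error(load_panel(ef, af, meta), "self-nomination")

  write.csv(data.frame(school_id = "x", wave = 1, ego_id = "a",
                       alter_id = "zz"), ef[1], row.names = FALSE)
  expect_error(load_panel(ef, af, meta), "unknown actors")
})

test_that("imputation carries observations forward and flags masks", {
  s1 <- rand_state(6, 0.3); s2 <- rand_state(6, 0.3)
  p <- panel_from_states(s1, s2)
  p$adjacency[[2]][3, ] <- NA_integer_
  p$alcohol[4, 2] <- NA_integer_
  p$present[3, 2] <- FALSE
  imp <- impute_panel(p)
  expect_equal(imp$adjacency[[2]][3, ], imp$adjacency[[1]][3, ])
  expect_equal(imp$behavior[[2]][4, 1], imp$behavior[[1]][4, 1])
  expect_false(imp$row_observed[3, 2])
  expect_false(imp$beh_observed$alcohol[4, 2])
  expect_true(all(!is.na(imp$adjacency[[2]])))
})
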