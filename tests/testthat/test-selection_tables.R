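# build a stand-in fit with chosen selection parameters and covariance
selection_fit <- function(ego, alter, sim, Sigma = NULL, zbar = 2.0,
                          school_id = "s1", school_type = "coed") {
  spec <- spec_with_centering(zbar_alcohol = zbar)
  par <- c(rate_network_p1 = 3, outdegree = -2, alcohol_alter = alter,
           alcohol_ego = ego, alcohol_similarity = sim)
  V <- diag(0.01, 5)
  dimnames(V) <- list(names(par), names(par))
  if (!is.null(Sigma)) {
    idx <- c("alcohol_ego", "alcohol_alter", "alcohol_similarity")
    V[idx, idx] <- Sigma
  }
  fake_fit(par, V, spec, school_id = school_id, school_type = school_type)
}

test_that("the worked cell reproduces the hand computation", {
  # ego .01, alter .03, sim .35, school mean 2.0, alcohol range 3:
  # at cell (4, 4) the similarity terms cancel and the log-odds is
  # (.01 + .03) * 2 = .08
  fit <- selection_fit(ego = 0.01, alter = 0.03, sim = 0.35, zbar = 2.0)
  tb <- school_log_odds_table(fit, "alcohol")
  expect_equal(tb$log_odds["4", "4"], 0.08, tolerance = 1e-12)
  expect_equal(exp(tb$log_odds["4", "4"]), exp(0.08))
})

test_that("the mean-mean reference cell has log-odds zero and OR one", {
  fit <- selection_fit(0.1, 0.2, 0.5, zbar = 2.0)
  tb <- school_log_odds_table(fit, "alcohol", categories = c(1, 2, 3, 4))
  expect_equal(tb$log_odds["2", "2"], 0)        # 2.0 is the school mean
  expect_equal(tb$variance["2", "2"], 0)
  pooled <- pool_selection_tables(list(tb, tb))
  expect_identical(unname(pooled$or["2", "2"]), 1)
})

test_that("equal ego and alter parameters give a symmetric table", {
  fit <- selection_fit(0.07, 0.07, 0.4)
  tb <- school_log_odds_table(fit, "alcohol")
  expect_equal(unname(tb$log_odds), unname(t(tb$log_odds)), tolerance = 1e-12)
})

test_that("cellwise pooling matches the closed-form inverse-variance oracle", {
  f1 <- selection_fit(0.02, 0.05, 0.3, school_id = "a")
  f2 <- selection_fit(0.02, 0.05, 0.3, school_id = "b")
  t1 <- school_log_odds_table(f1, "alcohol")
  t2 <- school_log_odds_table(f2, "alcohol")
  # identical tables: pooled equals each input (idempotence)
  pooled <- pool_selection_tables(list(t1, t2))
  expect_equal(pooled$log_odds, t1$log_odds, tolerance = 1e-10)

  # perturb one table: tau2 = 0 cells must match hand inverse-variance math
  t2b <- t2
  t2b$log_odds <- t2$log_odds * 1.01
  pooled2 <- pool_selection_tables(list(t1, t2b))
  for (e in 1:4) for (a in 1:4) {
    if (e == 2 && a == 2) next
    y <- c(t1$log_odds[e, a], t2b$log_odds[e, a])
    v <- c(t1$variance[e, a], t2b$variance[e, a])
    tau2 <- estimate_tau2(y, sqrt(v))
    w <- 1 / (v + tau2)
    expect_equal(pooled2$log_odds[e, a], sum(w * y) / sum(w),
                 tolerance = 1e-10)
  }
})

test_that("a cell is flagged exactly when its OR interval excludes one", {
  f1 <- selection_fit(0.3, 0.3, 0.9, school_id = "a")
  f2 <- selection_fit(0.28, 0.33, 0.85, school_id = "b")
  pooled <- pool_selection_tables(list(
    school_log_odds_table(f1, "alcohol"),
    school_log_odds_table(f2, "alcohol")))
  flag_by_or <- pooled$or_low > 1 | pooled$or_high < 1
  expect_identical(pooled$flagged, flag_by_or)
  td <- tidy(pooled)
  expect_equal(nrow(td), 16)
  expect_true(all(td$or >= td$or_low & td$or <= td$or_high))
})

test_that("asymmetry contrasts are antisymmetric and zero for symmetric tables", {
  fsym <- selection_fit(0.1, 0.1, 0.4)
  tb <- pool_selection_tables(list(school_log_odds_table(fsym, "alcohol"),
                                   school_log_odds_table(fsym, "alcohol")))
  expect_equal(asymmetry_contrast(tb, 1, 4)$estimate, 0, tolerance = 1e-12)

  fasym <- selection_fit(0.2, -0.1, 0.3)
  tb2 <- pool_selection_tables(list(school_log_odds_table(fasym, "alcohol"),
                                    school_log_odds_table(fasym, "alcohol")))
  c14 <- asymmetry_contrast(tb2, 1, 4)
  c41 <- asymmetry_contrast(tb2, 4, 1)
  expect_equal(c14$estimate, -c41$estimate)
  expect_error(asymmetry_contrast(tb2, 2, 2), "distinct")

  # exact per-school contrast: (b_ego - b_alt) (v_e - v_a)
  ex <- school_asymmetry_contrast(fasym, "alcohol", 4, 1)
  expect_equal(ex$estimate, (0.2 - (-0.1)) * 3, tolerance = 1e-12)
})

test_that("a larger similarity parameter depresses dissimilar-dyad odds", {
  # under the mean-mean reference construction the similarity term enters a
  # cell as b_sim (sim(v_e, v_a) - 1), so diagonal cells (sim = 1) do not
  # move with b_sim while every off-diagonal cell strictly decreases
  lo <- selection_fit(0.02, 0.02, 0.2)
  hi <- selection_fit(0.02, 0.02, 0.8)
  t_lo <- school_log_odds_table(lo, "alcohol")
  t_hi <- school_log_odds_table(hi, "alcohol")
  for (k in 1:4)
    expect_equal(t_hi$log_odds[k, k], t_lo$log_odds[k, k], tolerance = 1e-12)
  for (e in 1:4) for (a in 1:4) {
    if (e == a) next
    expect_lt(t_hi$log_odds[e, a], t_lo$log_odds[e, a])
  }
})

test_that("mismatched grids and missing effects are rejected", {
  f <- selection_fit(0.1, 0.1, 0.3)
  t1 <- school_log_odds_table(f, "alcohol")
  t2 <- school_log_odds_table(f, "alcohol", categories = 1:3)
  expect_error(pool_selection_tables(list(t1, t2)), "mismatched")
  expect_error(school_log_odds_table(f, "secrecy"), "lacks")
})
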