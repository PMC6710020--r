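test_that("Paule-Mandel tau2 solves its defining identity", {
  # identical estimates: no heterogeneity
  expect_equal(estimate_tau2(c(1, 1, 1), c(0.5, 1, 2)), 0)
  # hand-solved two-study case: 2 / (1 + tau2) = 1
  expect_equal(estimate_tau2(c(0, 2), c(1, 1)), 1, tolerance = 1e-6)
  # location invariance under an intercept-only design
  set.seed(12)
  y <- rnorm(8); s <- runif(8, 0.3, 1)
  expect_equal(estimate_tau2(y, s), estimate_tau2(y + 5, s),
               tolerance = 1e-8)
  expect_error(estimate_tau2(1, 1), "at least 2")
})

test_that("Paule-Mandel tau2 matches a grid-search oracle and metafor", {
  set.seed(13)
  y <- c(0.1, 0.5, -0.2, 0.8, 0.35)
  s <- c(0.2, 0.3, 0.25, 0.4, 0.3)
  got <- estimate_tau2(y, s)
  # brute-force grid search on the defining identity
  qfun <- function(t2) {
    w <- 1 / (s^2 + t2)
    mu <- sum(w * y) / sum(w)
    sum(w * (y - mu)^2) - (length(y) - 1)
  }
  grid <- seq(0, 2, by = 1e-6)
  oracle <- grid[which.min(abs(vapply(grid, qfun, numeric(1))))]
  expect_equal(got, oracle, tolerance = 1e-5)
  skip_if_not_installed("metafor")
  mf <- metafor::rma(yi = y, sei = s, method = "PM")
  expect_lt(abs(got - mf$tau2), 1e-6)
})

test_that("random-effects pooling reduces to inverse variance at tau2 = 0", {
  y <- c(0.2, 0.25, 0.22); s <- c(0.1, 0.2, 0.15)
  expect_equal(estimate_tau2(y, s), 0)
  pooled <- pool_random_effects(y, s)
  w <- 1 / s^2
  expect_equal(pooled$estimate, sum(w * y) / sum(w), tolerance = 1e-12)
  expect_equal(pooled$std.error, 1 / sqrt(sum(w)), tolerance = 1e-12)
  # two schools with equal ses: arithmetic mean
  p2 <- pool_random_effects(c(0, 2), c(1, 1))
  expect_equal(p2$estimate, 1)
  # single school: pass-through, flagged
  p1 <- pool_random_effects(0.4, 0.1)
  expect_false(p1$pooled)
  expect_equal(p1$estimate, 0.4)
  # interval contains the estimate; p in [0, 1]
  expect_true(pooled$conf.low < pooled$estimate &
                pooled$estimate < pooled$conf.high)
  expect_true(pooled$p.value >= 0 && pooled$p.value <= 1)
})

test_that("pooling matches metafor's Paule-Mandel fit", {
  skip_if_not_installed("metafor")
  set.seed(14)
  y <- rnorm(9, 0.3, 0.4); s <- runif(9, 0.1, 0.5)
  ours <- pool_random_effects(y, s)
  mf <- metafor::rma(yi = y, sei = s, method = "PM")
  expect_lt(abs(ours$estimate - mf$beta[1, 1]), 1e-5)
  expect_lt(abs(ours$std.error - mf$se), 1e-5)
})

test_that("moderator encoding uses coed reference and centered prevalence", {
  md <- tibble::tibble(
    school_id = c("a", "b", "c"),
    school_type = c("coed", "boys", "girls"),
    year3_weekly_prevalence = c(0.2, 0.3, 0.1))
  X <- encode_moderators(md)
  expect_equal(colnames(X), c("intercept", "boys", "girls", "prevalence_c"))
  expect_equal(unname(X["a", ]), c(1, 0, 0, 0))  # coed at mean prevalence
  expect_equal(unname(X["b", 2:3]), c(1, 0))
  expect_equal(sum(X[, "prevalence_c"]), 0)
  expect_error(encode_moderators(tibble::tibble(
    school_type = "mixed", year3_weekly_prevalence = 0.2)), "unknown school type")
})

test_that("meta-regression nests pooling and is invariant to weight scaling", {
  set.seed(15)
  y <- rnorm(10, 0.3, 0.5); s <- runif(10, 0.2, 0.6)
  X1 <- matrix(1, 10, 1, dimnames = list(NULL, "intercept"))
  reg <- meta_regression(y, s, X1)
  pooled <- pool_random_effects(y, s)
  expect_equal(reg$estimate, pooled$estimate, tolerance = 1e-10)
  expect_equal(reg$std.error, pooled$std.error, tolerance = 1e-10)

  md <- tibble::tibble(
    school_type = rep(c("coed", "boys", "girls"), c(4, 3, 3)),
    year3_weekly_prevalence = runif(10, 0.1, 0.4))
  X <- encode_moderators(md)
  r1 <- meta_regression(y, s, X)
  # common rescaling of every weight (all ses doubled, tau2 quadrupled so the
  # weights stay proportional) leaves the WLS coefficients alone
  r2 <- meta_regression(y, 2 * s, X, tau2 = 4 * r1$tau2[1])
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-8)

  Xbad <- cbind(X, dup = X[, "boys"])
  expect_error(meta_regression(y, s, Xbad), "collinear")
})

test_that("meta-regression matches metafor with moderators", {
  skip_if_not_installed("metafor")
  set.seed(16)
  md <- tibble::tibble(
    school_type = rep(c("coed", "boys", "girls"), c(8, 5, 5)),
    year3_weekly_prevalence = runif(18, 0.05, 0.45))
  X <- encode_moderators(md)
  y <- 0.2 + 0.4 * X[, "boys"] + rnorm(18, 0, 0.3)
  s <- runif(18, 0.15, 0.4)
  ours <- meta_regression(y, s, X)
  mf <- metafor::rma(yi = y, sei = s, mods = ~ X[, -1], method = "PM")
  expect_equal(ours$estimate, unname(mf$beta[, 1]), tolerance = 1e-4)
  expect_equal(ours$std.error, unname(mf$se), tolerance = 1e-4)
})

test_that("meta_analyze pools across fitted schools and excludes non-converged fits", {
  set.seed(17)
  spec <- spec_with_centering()
  mk <- function(id, type, est, conv = TRUE) {
    par <- c(rate_network_p1 = 3, outdegree = -2, alcohol_alter = est,
             alcohol_ego = 0.01, alcohol_similarity = 0.3)
    V <- diag(c(0.2, 0.05, 0.01, 0.01, 0.05))
    dimnames(V) <- list(names(par), names(par))
    fake_fit(par, V, spec, school_id = id, school_type = type,
             converged = conv)
  }
  fits <- list(mk("s1", "coed", 0.05), mk("s2", "boys", 0.40),
               mk("s3", "girls", 0.02), mk("s4", "coed", 0.08),
               mk("s5", "boys", -5, conv = FALSE),
               mk("s6", "boys", 0.35), mk("s7", "girls", 0.04))
  md <- tibble::tibble(
    school_id = paste0("s", 1:7),
    school_type = c("coed", "boys", "girls", "coed", "boys", "boys", "girls"),
    year3_weekly_prevalence = c(0.2, 0.3, 0.15, 0.25, 0.5, 0.35, 0.2))
  expect_message(meta <- meta_analyze(fits, md), "non-converged")
  expect_s3_class(meta, "coevo_meta")
  row <- meta[meta$effect == "alcohol_alter", ]
  expect_equal(row$n_schools, 6)
  # the diverging excluded school must not drag the pooled estimate negative
  expect_gt(row$estimate, 0)
  expect_true(all(c("mr_intercept_estimate", "mr_boys_estimate") %in%
                    names(meta)))
})
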