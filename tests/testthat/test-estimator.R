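# Reduced estimation settings used throughout the tests; the vignette
# documents the full defaults.
fast_opts <- estimate_options(n1 = 15, subphases = 2, n2 = 30, n3 = 120,
                              max_restarts = 1)

small_school <- function(seed, n = 25, waves = 3) {
  cfg <- synth_config(
    waves = waves, size_range = c(n, n), absence_prob = 0,
    behaviors = "alcohol",
    effects = c("outdegree", "reciprocity", "alcohol_similarity",
                "alcohol_linear", "alcohol_quadratic",
                "alcohol_total_similarity"),
    rates = c(network = 4, alcohol = 1.3), seed = seed)
  generate_school(cfg, 1)
}

test_that("convergence diagnostics follow their definitions", {
  obs <- c(a = 1, b = -2, c = 0.5)
  # simulations exactly equal to the observation: all diagnostics zero
  S0 <- matrix(rep(obs, each = 10), 10, dimnames = list(NULL, names(obs)))
  d0 <- suppressWarnings(convergence_diagnostics(S0, obs))
  expect_identical(unname(d0$t_ratios), rep(0, 3))
  expect_equal(d0$overall_ratio, 0)

  # one statistic offset by exactly one (empirical) sd
  set.seed(9)
  N <- 4000
  S <- cbind(x = rnorm(N), y = rnorm(N, sd = 2))
  obs2 <- c(x = mean(S[, "x"]) - sd(S[, "x"]), y = mean(S[, "y"]))
  d <- convergence_diagnostics(S, obs2)
  expect_equal(unname(d$t_ratios["x"]), 1, tolerance = 3 / sqrt(N))
  expect_equal(unname(d$t_ratios["y"]), 0, tolerance = 3 / sqrt(N))

  # permutation equivariance
  d_perm <- convergence_diagnostics(S[, c("y", "x")], obs2[c("y", "x")])
  expect_equal(d_perm$t_ratios, d$t_ratios[c("y", "x")])
  expect_equal(d_perm$overall_ratio, d$overall_ratio, tolerance = 1e-10)

  expect_error(convergence_diagnostics(S[1:3, ], obs2), "p \\+ 2")
})

test_that("finite-difference derivative agrees with a central-difference oracle", {
  set.seed(15)
  g <- small_school(200, n = 5, waves = 2)
  panel <- g$panel
  spec <- model_spec(panel, effects = "outdegree", behaviors = character(0))
  prep <- coevonet:::.prepare_school(panel, spec)
  par <- coevonet:::.init_par(prep)

  set.seed(31)
  D <- coevonet:::.deriv_matrix(par, prep, n1 = 400, delta = 0.3)
  # independent central-difference oracle for the outdegree column
  set.seed(77)
  reps <- 800
  delta <- 0.3
  up <- dn <- numeric(reps)
  for (r in 1:reps) {
    ppl <- par; ppl["outdegree"] <- ppl["outdegree"] + delta / 2
    pmi <- par; pmi["outdegree"] <- pmi["outdegree"] - delta / 2
    s <- sample.int(1e8, 1)
    set.seed(s); up[r] <- coevonet:::.sim_targets(ppl, prep)["outdegree"]
    set.seed(s); dn[r] <- coevonet:::.sim_targets(pmi, prep)["outdegree"]
  }
  central <- mean(up - dn) / delta
  expect_lt(abs(D["outdegree", "outdegree"] - central),
            0.1 * abs(central))
})

test_that("doubling derivative replicates shrinks its Monte-Carlo sd by ~ sqrt(2)", {
  set.seed(16)
  g <- small_school(300, n = 15, waves = 2)
  spec <- model_spec(g$panel, effects = "outdegree", behaviors = character(0))
  prep <- coevonet:::.prepare_school(g$panel, spec)
  par <- coevonet:::.init_par(prep)
  col_sd <- function(n1, reps) {
    v <- numeric(reps)
    for (r in seq_len(reps))
      v[r] <- coevonet:::.deriv_matrix(par, prep, n1, 0.3)["outdegree",
                                                           "outdegree"]
    sd(v)
  }
  s1 <- col_sd(8, 24)
  s2 <- col_sd(16, 24)
  expect_gt(s1 / s2, 1.0)   # noisy ratio; sqrt(2) = 1.41 expected
  expect_lt(s1 / s2, 2.1)
})

test_that("a fixed effect keeps its value exactly and reports no standard error", {
  set.seed(17)
  g <- small_school(400)
  spec <- model_spec(g$panel,
                     effects = c("outdegree", "reciprocity", "same_gender",
                                 "alcohol_linear", "alcohol_quadratic"),
                     behaviors = "alcohol", fixed = c(same_gender = 0))
  fit <- estimate_school(g$panel, spec, fast_opts, seed = 5)
  td <- tidy(fit)
  row <- td[td$term == "same_gender", ]
  expect_equal(row$estimate, 0)
  expect_true(is.na(row$std.error))
  expect_true(row$fixed)
  expect_false("same_gender" %in% names(fit$par))
  expect_equal(unname(fit$theta["same_gender"]), 0)
})

test_that("fits are reproducible from (panel, spec, options, seed)", {
  g <- small_school(500)
  f1 <- estimate_school(g$panel, g$ground_truth$spec, fast_opts, seed = 99)
  f2 <- estimate_school(g$panel, g$ground_truth$spec, fast_opts, seed = 99)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$se, f2$se)
  expect_identical(f1$converged, f2$converged)
  g1 <- glance(f1)
  expect_equal(g1$seed, 99)
  expect_s3_class(g1, "tbl_df")
})

test_that("estimation is self-consistent: refitting data simulated at the estimate", {
  set.seed(18)
  g <- small_school(600, n = 30)
  fit <- estimate_school(g$panel, g$ground_truth$spec, fast_opts, seed = 3)
  # simulate a fresh panel at the estimate and refit: estimates should land
  # near the generating values (a reduced double-simulation check)
  st <- list(adjacency = g$panel$adjacency[[1]],
             behavior = cbind(g$panel$alcohol[, 1], g$panel$control[, 1],
                              g$panel$secrecy[, 1]),
             gender = g$panel$gender, fsm = g$panel$fsm)
  rates <- c(network = mean(fit$rates[, "network"]),
             alcohol = mean(fit$rates[, "alcohol"]))
  p2 <- simulate_panel(st, fit$theta, rates, fit$spec, n_periods = 2,
                       seed = 31)
  fit2 <- estimate_school(p2, fit$spec, fast_opts, seed = 32)
  dev <- (fit2$par["outdegree"] - fit$par["outdegree"])
  pooled_se <- sqrt(fit$se["outdegree"]^2 + fit2$se["outdegree"]^2)
  expect_lt(abs(dev), 4 * pooled_se)
})

test_that("fit serialization writes valid JSON", {
  g <- small_school(700, n = 20, waves = 2)
  fit <- estimate_school(g$panel, g$ground_truth$spec, fast_opts, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$school_id, g$panel$school_id)
  expect_equal(length(obj$covariance), obj$covariance_dim^2)
  expect_equal(unlist(obj$parameters), fit$par, tolerance = 1e-12)
})
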