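test_that("dyadic similarity kernel matches its closed form", {
  expect_equal(dyadic_similarity(3, 3, 3), 1.0)
  expect_equal(dyadic_similarity(1, 4, 3), 0.0)
  expect_equal(dyadic_similarity(2, 3, 3), 2 / 3)
  expect_error(dyadic_similarity(1, 2, 0), "positive")
  expect_error(dyadic_similarity(1, 5, 3), "range")
})

test_that("evaluation statistics match brute-force enumeration on random fixtures", {
  set.seed(101)
  for (r in 1:40) {
    n <- sample(4:6, 1)
    s1 <- rand_state(n, runif(1, 0.15, 0.5))
    s2 <- rand_state(n, runif(1, 0.15, 0.5))
    spec <- model_spec(panel_from_states(s1, s2))
    want <- oracle_state_stats(s2, spec)
    got_r <- coevonet:::.state_stats_r(s2, spec)
    got_cpp <- coevonet:::.state_stats_cpp(s2, spec)
    expect_equal(got_r[names(want)], want, tolerance = 1e-12)
    expect_lt(max(abs(got_cpp[names(want)] - want)), 1e-10)
  }
})

test_that("transitive triplet statistic counts the pinned orientation", {
  # ties 1->2, 2->3, 1->3: actor 1 closes one triplet, others none
  x <- matrix(0L, 3, 3); x[1, 2] <- x[2, 3] <- x[1, 3] <- 1L
  st <- list(adjacency = x, behavior = matrix(2L, 3, 3),
             gender = rep(0L, 3), fsm = rep(0L, 3))
  spec <- model_spec(panel_from_states(st, st),
                     effects = "transitive_triplets",
                     behaviors = character(0))
  vals <- vapply(1:3, function(i)
    network_evaluation(i, st, c(transitive_triplets = 1), spec), numeric(1))
  expect_equal(vals, c(1, 0, 0))
})

test_that("network objective is linear in theta and zero on the empty graph", {
  set.seed(21)
  st <- rand_state(5, 0.4)
  spec <- model_spec(panel_from_states(st, st))
  nms <- spec$effects$name[spec$effects$dependent == "network" &
                             !spec$effects$fixed]
  th1 <- setNames(rnorm(length(nms)), nms)
  th2 <- setNames(rnorm(length(nms)), nms)
  f <- function(th) network_evaluation(2, st, th, spec)
  expect_equal(f(th1 + th2), f(th1) + f(th2), tolerance = 1e-10)

  empty <- modifyList(st, list(adjacency = matrix(0L, 5, 5)))
  expect_equal(network_evaluation(2, empty, th1, spec), 0)

  # outdegree-only: theta = -2 with 4 ties gives -8
  x <- matrix(0L, 6, 6); x[1, 2:5] <- 1L
  st4 <- modifyList(st, list(adjacency = rbind(cbind(x[1:5, 1:5])), gender = st$gender))
  st4 <- list(adjacency = x, behavior = matrix(2L, 6, 3),
              gender = rep(0L, 6), fsm = rep(0L, 6))
  spec6 <- model_spec(panel_from_states(st4, st4))
  expect_equal(network_evaluation(1, st4, c(outdegree = -2), spec6), -8)
})

test_that("behavior objective handles isolates and equal-level friends", {
  n <- 5
  x <- matrix(0L, n, n); x[1, c(2, 3)] <- 1L   # actor 1: two friends
  beh <- matrix(2L, n, 3); beh[, 1] <- c(3L, 3L, 3L, 1L, 2L)
  st <- list(adjacency = x, behavior = beh, gender = rep(0L, n),
             fsm = rep(0L, n))
  spec <- model_spec(panel_from_states(st, st))
  sbar <- spec$centering$sbar[["alcohol"]]

  # two friends at the actor's own level: total similarity = 2 (1 - sbar)
  got <- behavior_evaluation(1, "alcohol", 3, st,
                             c(alcohol_total_similarity = 1), spec)
  expect_equal(got, 2 * (1 - sbar))

  # isolate: every similarity / average term vanishes
  for (eff in c("alcohol_total_similarity", "secrecy_average_similarity",
                "secrecy_alter_average_drinking")) {
    beh_name <- if (startsWith(eff, "alc")) "alcohol" else "secrecy"
    th <- setNames(1, eff)
    expect_equal(behavior_evaluation(4, beh_name, 2, st, th, spec), 0,
                 label = eff)
  }
  expect_error(behavior_evaluation(1, "alcohol", 5, st, c(alcohol_linear = 1),
                                   spec), "out of range")
})

test_that("behavior objective matches brute-force enumeration on a toy", {
  set.seed(33)
  st <- rand_state(3, 0.5)
  spec <- model_spec(panel_from_states(st, rand_state(3, 0.5)))
  tab <- spec$effects[spec$effects$dependent == "alcohol", ]
  th <- setNames(runif(nrow(tab), -1, 1), tab$name)
  for (i in 1:3) for (z in 1:4) {
    want <- sum(th * vapply(tab$name, oracle_beh_stat, numeric(1), i = i,
                            zi = z, st = st, cc = spec$centering))
    expect_equal(behavior_evaluation(i, "alcohol", z, st, th, spec), want,
                 tolerance = 1e-12)
  }
})

test_that("observed targets: rates count change, statistics match brute force", {
  set.seed(44)
  s1 <- rand_state(4, 0.4)
  # identical waves: all rate targets zero
  p_same <- panel_from_states(s1, s1)
  spec <- model_spec(p_same)
  tg <- target_statistics(p_same, spec)
  expect_true(all(tg[grep("^rate_", names(tg))] == 0))

  # one toggled tie: network rate target exactly 1
  s2 <- s1
  s2$adjacency[2, 3] <- 1L - s2$adjacency[2, 3]
  tg2 <- target_statistics(panel_from_states(s1, s2), spec)
  expect_equal(unname(tg2["rate_network_p1"]), 1)
  expect_equal(unname(tg2["rate_alcohol_p1"]), 0)

  # 4-actor 2-wave fixture vs independent cross-lagged brute force
  s3 <- rand_state(4, 0.4)
  p <- panel_from_states(s1, s3)
  spec2 <- model_spec(p)
  tg3 <- target_statistics(p, spec2)
  hybrid_net <- list(adjacency = s3$adjacency, behavior = s1$behavior,
                     gender = s1$gender, fsm = s1$fsm)
  want <- oracle_state_stats(hybrid_net, spec2)
  net_names <- spec2$effects$name[spec2$effects$dependent == "network" &
                                    !spec2$effects$fixed]
  expect_equal(tg3[net_names], want[net_names], tolerance = 1e-10)
  for (b in c("alcohol", "control", "secrecy")) {
    dcol <- match(b, c("alcohol", "control", "secrecy"))
    beh_hyb <- s1$behavior; beh_hyb[, dcol] <- s3$behavior[, dcol]
    hyb <- list(adjacency = s1$adjacency, behavior = beh_hyb,
                gender = s1$gender, fsm = s1$fsm)
    wantb <- oracle_state_stats(hyb, spec2)
    bn <- spec2$effects$name[spec2$effects$dependent == b &
                               !spec2$effects$fixed]
    expect_equal(tg3[bn], wantb[bn], tolerance = 1e-10)
  }
})

test_that("targets are invariant to actor relabeling", {
  set.seed(55)
  s1 <- rand_state(5, 0.4); s2 <- rand_state(5, 0.4)
  p <- panel_from_states(s1, s2)
  spec <- model_spec(p)
  perm <- sample(5)
  permute <- function(s) list(
    adjacency = s$adjacency[perm, perm], behavior = s$behavior[perm, ],
    gender = s$gender[perm], fsm = s$fsm[perm])
  p2 <- panel_from_states(permute(s1), permute(s2))
  spec_p <- model_spec(p2)
  expect_equal(target_statistics(p2, spec_p), target_statistics(p, spec),
               tolerance = 1e-10)
})

test_that("fsm similarity reduces to its binary closed form", {
  set.seed(66)
  st <- rand_state(6, 0.4)
  spec <- model_spec(panel_from_states(st, st))
  sbar <- spec$centering$sbar[["fsm"]]
  for (i in 1:6) {
    got <- network_evaluation(i, st, c(fsm_similarity = 1), spec)
    same <- sum(st$adjacency[i, ] * (st$fsm == st$fsm[i]))
    expect_equal(got, same - sbar * sum(st$adjacency[i, ]), tolerance = 1e-12)
  }
})

test_that("same-gender effect is fixed at zero in single-sex schools", {
  st <- rand_state(5, 0.3, coed = FALSE)
  p <- panel_from_states(st, st, school_type = "girls")
  spec <- model_spec(p)
  row <- spec$effects[spec$effects$name == "same_gender", ]
  expect_true(row$fixed)
  expect_equal(row$fixed_value, 0)
  expect_false("same_gender" %in% names(target_statistics(p, spec)))
})
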