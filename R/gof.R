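# Goodness of fit: auxiliary statistics (indegree and outdegree
# distributions, the directed triad census) of observed networks compared
# with the cloud simulated from a fitted model.

.triad_labels <- c("003", "012", "102", "021D", "021U", "021C", "111D",
                   "111U", "030T", "030C", "201", "120D", "120U", "120C",
                   "210", "300")

# canonical representative of each isomorphism class, as edge lists on
# vertices 1..3 (Davis-Leinhardt M-A-N labels, standard ordering)
.triad_reps <- list(
  "003"  = cbind(integer(0), integer(0)),
  "012"  = rbind(c(1, 2)),
  "102"  = rbind(c(1, 2), c(2, 1)),
  "021D" = rbind(c(2, 1), c(2, 3)),
  "021U" = rbind(c(1, 2), c(3, 2)),
  "021C" = rbind(c(1, 2), c(2, 3)),
  "111D" = rbind(c(1, 2), c(2, 1), c(3, 2)),
  "111U" = rbind(c(1, 2), c(2, 1), c(2, 3)),
  "030T" = rbind(c(1, 2), c(3, 2), c(1, 3)),
  "030C" = rbind(c(2, 1), c(3, 2), c(1, 3)),
  "201"  = rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1)),
  "120D" = rbind(c(2, 1), c(2, 3), c(1, 3), c(3, 1)),
  "120U" = rbind(c(1, 2), c(3, 2), c(1, 3), c(3, 1)),
  "120C" = rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 1)),
  "210"  = rbind(c(1, 2), c(2, 3), c(3, 2), c(1, 3), c(3, 1)),
  "300"  = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3), c(3, 1))
)

# 6-bit encoding of a labeled triad: bits (x12, x21, x13, x31, x23, x32)
.triad_code <- function(m) {
  m[1, 2] + 2 * m[2, 1] + 4 * m[1, 3] + 8 * m[3, 1] + 16 * m[2, 3] + 32 * m[3, 2]
}

# lookup[code + 1] = isomorphism class (0-based) for all 64 labeled patterns,
# built once at load by canonicalizing over the 6 vertex permutations
.build_triad_lookup <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  canon <- function(m) {
    min(vapply(perms, function(p) .triad_code(m[p, p]), numeric(1)))
  }
  class_of_canon <- integer(64)
  for (k in seq_along(.triad_reps)) {
    m <- matrix(0L, 3, 3)
    ed <- .triad_reps[[k]]
    if (nrow(ed)) m[ed] <- 1L
    class_of_canon[canon(m) + 1] <- k - 1L
  }
  lookup <- integer(64)
  for (code in 0:63) {
    m <- matrix(0L, 3, 3)
    bits <- as.integer(intToBits(code))[1:6]
    m[1, 2] <- bits[1]; m[2, 1] <- bits[2]; m[1, 3] <- bits[3]
    m[3, 1] <- bits[4]; m[2, 3] <- bits[5]; m[3, 2] <- bits[6]
    lookup[code + 1] <- class_of_canon[canon(m) + 1]
  }
  lookup
}

.triad_env <- new.env(parent = emptyenv())

.triad_lookup <- function() {
  if (is.null(.triad_env$lookup)) .triad_env$lookup <- .build_triad_lookup()
  .triad_env$lookup
}

#' Directed triad census
#'
#' Counts of unordered actor triples in each of the 16 directed-triad
#' isomorphism classes (003 ... 300), by direct classification of all
#' C(n, 3) triples.
#'
#' @param adjacency n x n binary matrix (n >= 3), zero diagonal.
#' @return Named integer vector of length 16 summing to C(n, 3).
#' @export
triad_census <- function(adjacency) {
  x <- as.matrix(adjacency)
  if (nrow(x) < 3) abort("triad census needs at least 3 actors")
  if (any(is.na(x))) abort("triad census needs a complete adjacency matrix")
  storage.mode(x) <- "integer"
  setNames(triad_census_cpp(x, .triad_lookup()), .triad_labels)
}

#' Degree distributions
#'
#' Histograms of indegrees and outdegrees, with degrees above the cap pooled
#' into the top bin.
#'
#' @param adjacency n x n binary matrix.
#' @param in_cap top bin for indegrees (default `r .nomination_cap`).
#' @param out_cap top bin for outdegrees (default `r .nomination_cap`, the
#'   nomination limit).
#' @return List of two named count vectors `indegree` (bins `0..in_cap`) and
#'   `outdegree` (bins `0..out_cap`), each summing to n.
#' @export
degree_distributions <- function(adjacency, in_cap = .nomination_cap,
                                 out_cap = .nomination_cap) {
  x <- as.matrix(adjacency)
  hist_of <- function(deg, cap) {
    deg <- pmin(deg, cap)
    setNames(tabulate(deg + 1L, nbins = cap + 1L), 0:cap)
  }
  list(indegree = hist_of(colSums(x), in_cap),
       outdegree = hist_of(rowSums(x), out_cap))
}

#' Mahalanobis goodness-of-fit test against a simulated reference cloud
#'
#' Distance of the observed auxiliary statistic vector from the simulated
#' mean under the simulated covariance (pseudo-inverse when rank-deficient),
#' with a Monte-Carlo p-value: the proportion of simulated replicates at
#' least as far from the mean as the observation.
#'
#' @param observed_aux length-q observed auxiliary statistics.
#' @param simulated_aux R x q matrix of simulated statistics (R >= q + 2).
#' @return List with `distance`, `p_value`, and the per-replicate distances.
#' @export
gof_test <- function(observed_aux, simulated_aux) {
  S <- as.matrix(simulated_aux)
  R <- nrow(S); q <- ncol(S)
  if (R < q + 2) abort("need at least q + 2 simulated replicates")
  inv_of <- function(Sig) {
    ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(abs(ev), 1)) MASS::ginv(Sig) else solve(Sig)
  }
  mu <- colMeans(S)
  Sinv <- inv_of(cov(S))
  d_obs <- {
    d <- as.numeric(observed_aux) - mu
    sqrt(max(0, drop(t(d) %*% Sinv %*% d)))
  }
  # replicate distances are computed leave-one-out so they are exchangeable
  # with the (out-of-sample) observation; measuring a replicate against a
  # reference cloud that contains it would shrink its distance and bias the
  # Monte-Carlo p-value downward
  d_sim <- vapply(seq_len(R), function(r) {
    Sr <- S[-r, , drop = FALSE]
    d <- S[r, ] - colMeans(Sr)
    sqrt(max(0, drop(t(d) %*% inv_of(cov(Sr)) %*% d)))
  }, numeric(1))
  list(distance = d_obs,
       p_value = mean(d_sim >= d_obs),
       simulated_distances = d_sim)
}

# auxiliary statistic vector of one network state
.aux_stats <- function(adjacency, aux, in_cap, out_cap) {
  out <- c()
  if ("indegree" %in% aux || "outdegree" %in% aux) {
    dd <- degree_distributions(adjacency, in_cap, out_cap)
    if ("indegree" %in% aux)
      out <- c(out, setNames(dd$indegree, paste0("indeg_", names(dd$indegree))))
    if ("outdegree" %in% aux)
      out <- c(out, setNames(dd$outdegree, paste0("outdeg_", names(dd$outdegree))))
  }
  if ("triad_census" %in% aux)
    out <- c(out, setNames(as.numeric(triad_census(adjacency)),
                           paste0("triad_", .triad_labels)))
  out
}

#' Goodness of fit of a fitted school model
#'
#' Simulates `R` replicates of every observation period from the observed
#' (imputed) starting wave at the fitted parameters, computes the auxiliary
#' statistics of each simulated end-of-period network summed over periods,
#' and compares the observed value via [gof_test()]. The simulated
#' distributions (the material behind the published violin plots) are
#' returned in tidy form and can be plotted with [autoplot.coevo_gof()] or
#' exported with [write_gof_csv()].
#'
#' @param fit a `saom_fit`.
#' @param panel the [school_panel] the fit came from.
#' @param R number of simulated replicates.
#' @param aux auxiliary statistic families to include.
#' @param in_cap,out_cap degree histogram caps.
#' @param seed optional integer seed.
#' @return An object of class `coevo_gof`: tidy replicate draws, observed
#'   values, and the Mahalanobis test result.
#' @export
saom_gof <- function(fit, panel, R = 200,
                     aux = c("indegree", "outdegree", "triad_census"),
                     in_cap = 7, out_cap = 7, seed = NULL) {
  aux <- match.arg(aux, c("indegree", "outdegree", "triad_census"),
                   several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  spec <- fit$spec
  prep <- .prepare_school(panel, spec)
  theta <- .full_theta(spec, fit$par[prep$free])
  cs <- .cpp_spec(spec, theta)

  observed <- Reduce(`+`, lapply(2:panel$n_waves, function(m)
    .aux_stats(prep$states[[m]]$adjacency, aux, in_cap, out_cap)))

  sim <- matrix(0, R, length(observed),
                dimnames = list(NULL, names(observed)))
  for (r in seq_len(R)) {
    acc <- 0
    for (m in seq_len(prep$n_periods)) {
      st <- prep$states[[m]]
      r4 <- c(network = 0, alcohol = 0, control = 0, secrecy = 0)
      for (d in prep$dims) r4[d] <- fit$par[sprintf("rate_%s_p%d", d, m)]
      res <- sim_period_cpp(st$adjacency, st$behavior, st$gender, st$fsm,
                            cs, unname(r4), 1.0, as.integer(spec$cap), FALSE)
      res <- .freeze_unobserved(res, prep, m)
      acc <- acc + .aux_stats(res$adjacency, aux, in_cap, out_cap)
    }
    sim[r, ] <- acc
  }

  test <- gof_test(observed, sim)
  draws <- tibble::as_tibble(as.data.frame(sim)) |>
    dplyr::mutate(replicate = dplyr::row_number()) |>
    tidyr::pivot_longer(-"replicate", names_to = "statistic",
                        values_to = "value")
  structure(
    list(school_id = fit$school_id, draws = draws,
         observed = tibble::tibble(statistic = names(observed),
                                   value = as.numeric(observed)),
         distance = test$distance, p_value = test$p_value,
         n_replicates = R),
    class = "coevo_gof")
}

#' @export
print.coevo_gof <- function(x, ...) {
  cat(sprintf("<coevo_gof> school %s: %d replicates, %d auxiliary statistics\n",
              x$school_id, x$n_replicates, nrow(x$observed)))
  cat(sprintf("  Mahalanobis distance %.2f, Monte-Carlo p = %.3f\n",
              x$distance, x$p_value))
  invisible(x)
}

#' Tidy the simulated GOF distributions
#'
#' @param x a `coevo_gof`.
#' @param ... unused.
#' @return A tibble with columns `replicate` (NA for the observed row),
#'   `statistic`, `value`, `observed`.
#' @export
tidy.coevo_gof <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$draws, observed = FALSE),
    dplyr::mutate(x$observed, replicate = NA_integer_, observed = TRUE))
}

#' Export GOF distributions as tidy CSV
#'
#' One row per (replicate, statistic, value) plus observed-row flags.
#'
#' @param x a `coevo_gof`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gof_csv <- function(x, path) {
  write.csv(tidy(x), path, row.names = FALSE)
  invisible(path)
}

#' Violin plot of the simulated auxiliary distributions
#'
#' Violins of the simulated replicate values per auxiliary statistic with the
#' observed value overlaid, the standard visual check of network fit.
#'
#' @param object a `coevo_gof`.
#' @param family show only one statistic family (`"indegree"`, `"outdegree"`,
#'   `"triad"`) or `NULL` for all.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.coevo_gof <- function(object, family = NULL, ...) {
  df <- object$draws
  obs <- object$observed
  if (!is.null(family)) {
    pick <- function(d) d[startsWith(d$statistic, substr(family, 1, 5)), ]
    df <- pick(df); obs <- pick(obs)
  }
  df$statistic <- factor(df$statistic, levels = unique(object$draws$statistic))
  obs$statistic <- factor(obs$statistic, levels = levels(df$statistic))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85", scale = "width") +
    ggplot2::geom_point(data = obs, color = "red", size = 2) +
    ggplot2::labs(x = NULL, y = "count",
                  title = sprintf("Auxiliary fit, school %s (p = %.2f)",
                                  object$school_id, object$p_value)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
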