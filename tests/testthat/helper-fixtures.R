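# Shared fixtures: all test data are built in code.

# Small panel with hand-chosen ties.  Wave 1: 1->2, 2->1, 2->3; wave 2
# differs by one formed and one dissolved tie.
tiny_panel <- function() {
  x1 <- matrix(0, 4, 4)
  x1[1, 2] <- x1[2, 1] <- x1[2, 3] <- 1
  x2 <- matrix(0, 4, 4)
  x2[1, 2] <- x2[2, 1] <- x2[1, 3] <- 1
  cov <- data.frame(age = c(14, 15, 15.5, 16), male = c(1, 0, 1, 0),
                    minority = c(0, 1, 0, 0), race = c(1, 2, 1, 1),
                    parent_drinking = c(1, 2, 1, 3),
                    family_bonding = c(4, 5, 3, 4))
  school_panel("tiny", x1, x2, behavior1 = c(1, 2, 3, 1),
               behavior2 = c(1, 3, 3, 1), covariates = cov)
}

# Panel whose observed Jaccard counts are exactly (f11, f01, f10).
# Ties are laid out deterministically over the off-diagonal cells.
panel_with_counts <- function(f11, f01, f10, n = NULL) {
  need <- f11 + f01 + f10
  n <- n %||% (ceiling(sqrt(need)) + 2)
  cells <- which(diag(n) == 0, arr.ind = TRUE)  # off-diagonal cells
  stopifnot(nrow(cells) >= need)
  x1 <- matrix(0, n, n)
  x2 <- matrix(0, n, n)
  idx <- 1
  take <- function(k) {
    out <- cells[seq(idx, length.out = k), , drop = FALSE]
    idx <<- idx + k
    out
  }
  both <- take(f11); x1[both] <- 1; x2[both] <- 1
  formed <- take(f01); x2[formed] <- 1
  dissolved <- take(f10); x1[dissolved] <- 1
  school_panel("counts", x1, x2, behavior1 = rep(1:2, length.out = n),
               behavior2 = rep(1:2, length.out = n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random directed graph on n actors with tie probability p.
random_digraph <- function(n, p = 0.3) {
  x <- matrix(as.numeric(stats::runif(n * n) < p), n, n)
  diag(x) <- 0
  x
}

# Independent brute-force evaluation of every network effect
# statistic by explicit loops over alters and triples.
brute_network_stat <- function(name, i, x, z, v = NULL, centering) {
  n <- nrow(x)
  js <- setdiff(seq_len(n), i)
  tot <- 0
  switch(name,
    density = sum(x[i, ]),
    reciprocity = {
      for (j in js) tot <- tot + x[i, j] * x[j, i]
      tot
    },
    transitive_triplets = {
      for (j in js) for (h in js)
        if (j != h) tot <- tot + x[i, j] * x[j, h] * x[i, h]
      tot
    },
    three_cycles = {
      for (j in js) for (h in js)
        if (j != h) tot <- tot + x[i, j] * x[j, h] * x[h, i]
      tot
    },
    indegree_popularity = {
      for (j in js) tot <- tot + x[i, j] * sum(x[, j])
      tot
    },
    outdegree_popularity = {
      for (j in js) tot <- tot + x[i, j] * sum(x[j, ])
      tot
    },
    outdegree_activity = sum(x[i, ])^2,
    ego = (v[i] - centering$mean_v) * sum(x[i, ]),
    alter = {
      for (j in js) tot <- tot + x[i, j] * (v[j] - centering$mean_v)
      tot
    },
    similarity = {
      for (j in js)
        tot <- tot + x[i, j] *
          ((1 - abs(v[i] - v[j]) / centering$range_v) - centering$sim_mean_v)
      tot
    },
    same = {
      for (j in js) tot <- tot + x[i, j] * (v[j] == v[i])
      tot
    },
    stop("unknown name")
  )
}

# Centering object built directly from raw vectors (independent of
# compute_centering).
manual_centering <- function(z, covs = list()) {
  pair_mean <- function(v, rng) {
    n <- length(v); tot <- 0
    for (a in seq_len(n)) for (b in seq_len(n))
      if (a != b) tot <- tot + 1 - abs(v[a] - v[b]) / rng
    tot / (n * (n - 1))
  }
  cm <- list(alcohol = mean(z))
  cr <- list(alcohol = 5)
  cs <- list(alcohol = pair_mean(z, 5))
  for (nm in names(covs)) {
    cm[[nm]] <- mean(covs[[nm]])
    cr[[nm]] <- diff(range(covs[[nm]]))
    cs[[nm]] <- if (cr[[nm]] > 0) pair_mean(covs[[nm]], cr[[nm]]) else NA
  }
  structure(list(mean = cm, range = cr, sim_mean = cs,
                 z_mean = mean(z), z_range = 5),
            class = "saom_centering")
}

# Reference softmax written independently of the package internals.
softmax_ref <- function(u) {
  e <- exp(u - max(u))
  e / sum(e)
}

# Small two-effect model used across simulator tests.
density_model <- function(beta = 0, rate = 1) {
  saom_model(list(saom_effect("density", parameter = beta)),
             network_rate = rate)
}

# Compact recovery fixture: the generating model of the small-school
# recovery experiments.  The shape effects are set to a mean-reverting
# regime (negative linear and quadratic) so the behavior process is
# stationary; with a concave objective the influence effect is
# identifiable at modest school sizes.
recovery_model <- function() {
  saom_model(
    network_effects = list(
      saom_effect("density", parameter = -2.0),
      saom_effect("reciprocity", parameter = 1.5),
      saom_effect("similarity", "alcohol", parameter = 1.0)),
    behavior_effects = list(
      saom_effect("linear_shape", parameter = -0.6),
      saom_effect("quadratic_shape", parameter = -0.2),
      saom_effect("average_alter", parameter = 0.5)),
    network_rate = 4, behavior_rate = 3)
}

recovery_config <- function(n = 60L) {
  synthetic_config(n_schools = 1L, school_sizes = n,
                   theta_true = recovery_model(),
                   density_size_ref = n,
                   attrition = list(p_heavy = 0, p_other = 0,
                                    heavy_level = 5L))
}
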