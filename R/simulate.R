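# Continuous-time micro-step simulation of the co-evolution process.
#
# Between the two observation waves, change opportunities arrive as a
# Poisson process with total intensity n * (lambda_net + lambda_beh)
# over a period normalized to length 1.  At each opportunity a uniform
# random actor either toggles one outgoing tie (network side) or moves
# behavior one level (behavior side); the option is drawn by
# multinomial logit over the objective-function values of the candidate
# states, the standard Gumbel-error representation of the random
# utility term.
#
# Utilities are evaluated as objective-function *differences* from the
# current state (change scores); by shift invariance of the logit this
# is identical to evaluating f at every candidate state, and much
# cheaper.  The change scores are verified against the full statistic
# evaluation in the test suite.

# Precompute everything the inner loop needs that does not change
# during a period: per-effect covariate vectors (raw and centered),
# similarity constants, and betas.
make_effect_context <- function(model, covariates, centering) {
  prep_net <- function(e) {
    ctx <- list(name = e$name, beta = e$parameter, label = e$label)
    if (!is.null(e$covariate)) {
      ctx$on_behavior <- identical(e$covariate, "alcohol")
      if (e$name == "same") {
        ctx$v_raw <- effect_covariate(e, NULL, covariates, numeric = FALSE)
      } else if (!ctx$on_behavior) {
        v <- effect_covariate(e, NULL, covariates)
        ctx$v <- v
        ctx$v_centered <- v - centering$mean[[e$covariate]]
      }
      ctx$vbar <- centering$mean[[e$covariate]]
      ctx$rng <- centering$range[[e$covariate]]
      ctx$sim_mean <- centering$sim_mean[[e$covariate]]
      if (e$name == "similarity" &&
          (is.na(ctx$rng) || ctx$rng == 0))
        stop("similarity effect on zero-range covariate '", e$covariate, "'")
    }
    ctx
  }
  prep_beh <- function(e) {
    ctx <- list(name = e$name, beta = e$parameter, label = e$label)
    if (identical(e$name, "covariate")) {
      v <- effect_covariate(e, NULL, covariates)
      ctx$v_centered <- v - centering$mean[[e$covariate]]
    }
    ctx
  }
  list(net = lapply(model$network_effects, prep_net),
       beh = lapply(model$behavior_effects, prep_beh),
       z_mean = centering$z_mean, z_range = centering$z_range)
}

# Change in actor i's network objective for toggling the tie i -> j,
# for all j at once.  Every catalog effect admits the form
# delta_j = (1 - 2 a_j) * c_j with a = x[i, ] and c_j the contribution
# of the tie i -> j to the statistic (possibly depending on a_j for the
# nonlinear degree effects).
network_utility_deltas <- function(i, x, z, ctx, din, dout) {
  n <- ncol(x)
  a <- x[i, ]
  contrib <- numeric(n)
  for (e in ctx$net) {
    c_k <- switch(e$name,
      density = 1,
      reciprocity = x[, i],
      transitive_triplets = as.vector(x %*% a + crossprod(x, a)),
      three_cycles = as.vector(x %*% x[, i]),
      indegree_popularity = din + 1 - a,
      outdegree_popularity = dout,
      outdegree_activity = 2 * dout[i] + 1 - 2 * a,
      ego = if (e$on_behavior) z[i] - e$vbar else e$v_centered[i],
      alter = if (e$on_behavior) z - e$vbar else e$v_centered,
      similarity = {
        v <- if (e$on_behavior) z else e$v
        (1 - abs(v[i] - v) / e$rng) - e$sim_mean
      },
      same = {
        v <- if (e$on_behavior) z else e$v_raw
        as.numeric(v == v[i])
      },
      stop("unknown network effect '", e$name, "'")
    )
    contrib <- contrib + e$beta * c_k
  }
  u <- (1 - 2 * a) * contrib
  u[i] <- 0  # the no-change option
  u
}

# Change in actor i's behavior objective for a one-step move delta.
behavior_utility_delta <- function(i, x, z, ctx, delta) {
  zc <- z[i] - ctx$z_mean
  u <- 0
  for (e in ctx$beh) {
    du <- switch(e$name,
      linear_shape = delta,
      quadratic_shape = (zc + delta)^2 - zc^2,
      average_alter = {
        a <- x[i, ]
        d <- sum(a)
        if (d == 0) 0 else delta * sum(a * (z - ctx$z_mean)) / d
      },
      covariate = delta * e$v_centered[i],
      stop("unknown behavior effect '", e$name, "'")
    )
    u <- u + e$beta * du
  }
  u
}

#' Choice probabilities for a network micro-step
#'
#' Given the current state, returns the multinomial-logit probabilities
#' with which the focal actor, granted a network change opportunity,
#' selects among toggling the tie to each other actor or leaving the
#' network unchanged.  Option utilities are the actor's network
#' objective function evaluated at each post-toggle state; by shift
#' invariance only differences from the current state matter.
#'
#' @param actor focal actor index.
#' @param ties 0/1 adjacency matrix of the current state.
#' @param behavior current behavior level vector.
#' @param model a `saom_model`.
#' @param covariates covariate data frame.
#' @param centering constants from [compute_centering()].
#' @param out_degree_cap optional nomination cap; when the focal
#'   actor's out-degree is at the cap, tie-creating options are
#'   excluded.
#' @return named probability vector: `no_change` first, then
#'   `toggle_<j>` for every other actor `j`, summing to 1.
#' @export
network_choice_probabilities <- function(actor, ties, behavior, model,
                                         covariates = NULL,
                                         centering = NULL,
                                         out_degree_cap = NULL) {
  x <- as.matrix(ties)
  n <- ncol(x)
  if (n < 2) stop("need at least 2 actors for a network micro-step")
  ctx <- make_effect_context(model, covariates,
                             centering %||% null_centering(behavior))
  u <- network_utility_deltas(actor, x, as.numeric(behavior), ctx,
                              colSums(x), rowSums(x))
  if (!is.null(out_degree_cap) && sum(x[actor, ]) >= out_degree_cap)
    u[x[actor, ] == 0 & seq_len(n) != actor] <- -Inf
  pr <- softmax(c(0, u[-actor]))
  names(pr) <- c("no_change",
                 paste0("toggle_", (seq_len(n))[-actor]))
  pr
}

#' Choice probabilities for a behavior micro-step
#'
#' Probabilities over the admissible one-step behavior moves (down one
#' level, stay, up one level; moves beyond the scale bounds are
#' removed), by multinomial logit on the actor's behavior objective.
#'
#' @inheritParams network_choice_probabilities
#' @param n_levels number of behavior categories.
#' @return named probability vector over the admissible subset of
#'   `c("down", "stay", "up")`, summing to 1.
#' @export
behavior_choice_probabilities <- function(actor, ties, behavior, model,
                                          covariates = NULL,
                                          centering = NULL,
                                          n_levels = 6L) {
  x <- as.matrix(ties)
  z <- as.numeric(behavior)
  ctx <- make_effect_context(model, covariates,
                             centering %||% null_centering(behavior))
  deltas <- c(down = -1, stay = 0, up = 1)
  ok <- z[actor] + deltas >= 1 & z[actor] + deltas <= n_levels
  u <- vapply(deltas[ok], function(d)
    behavior_utility_delta(actor, x, z, ctx, d), numeric(1))
  softmax(u)
}

# Minimal centering constants for contexts where only structural
# effects are in play (keeps the exported probability helpers usable
# without a full panel).
null_centering <- function(behavior, n_levels = 6L) {
  z <- as.numeric(behavior)
  structure(list(mean = list(alcohol = mean(z)),
                 range = list(alcohol = n_levels - 1),
                 sim_mean = list(alcohol = 0),
                 z_mean = mean(z), z_range = n_levels - 1),
            class = "saom_centering")
}

# Core event loop, operating on bare state.  Callers must have seeded
# the RNG (or accept the current stream).
sim_engine <- function(x, z, model, ctx, n_levels,
                       record_trace = FALSE, out_degree_cap = NULL) {
  x <- unname(x)
  z <- unname(z)
  n <- ncol(x)
  lam_n <- model$network_rate
  lam_b <- model$behavior_rate
  total <- n * (lam_n + lam_b)
  trace <- if (record_trace) list() else NULL
  steps <- 0L
  if (total > 0) {
    din <- colSums(x)
    dout <- rowSums(x)
    p_net <- lam_n / (lam_n + lam_b)
    clock <- 0
    repeat {
      clock <- clock + stats::rexp(1L, total)
      if (clock > 1) break
      i <- sample.int(n, 1L)
      if (stats::runif(1L) < p_net) {
        u <- network_utility_deltas(i, x, z, ctx, din, dout)
        if (!is.null(out_degree_cap) && dout[i] >= out_degree_cap)
          u[x[i, ] == 0 & seq_len(n) != i] <- -Inf
        j <- sample.int(n, 1L, prob = softmax(u))
        if (j != i) {
          new <- 1 - x[i, j]
          x[i, j] <- new
          din[j] <- din[j] + (2 * new - 1)
          dout[i] <- dout[i] + (2 * new - 1)
        }
        if (record_trace)
          trace[[length(trace) + 1L]] <-
            data.frame(event = steps + 1L, clock = clock, side = "network",
                       actor = i, option = if (j == i) "no_change"
                                           else paste0("toggle_", j))
      } else {
        deltas <- c(-1, 0, 1)
        ok <- z[i] + deltas >= 1 & z[i] + deltas <= n_levels
        dd <- deltas[ok]
        u <- vapply(dd, function(d)
          behavior_utility_delta(i, x, z, ctx, d), numeric(1))
        pick <- dd[sample.int(length(dd), 1L, prob = softmax(u))]
        z[i] <- z[i] + pick
        if (record_trace)
          trace[[length(trace) + 1L]] <-
            data.frame(event = steps + 1L, clock = clock, side = "behavior",
                       actor = i, option = sprintf("move_%+d", pick))
      }
      steps <- steps + 1L
    }
  }
  structure(
    list(ties = x, behavior = z, clock = 1, n_steps = steps,
         trace = if (record_trace) do.call(rbind, trace) else NULL),
    class = "sim_state"
  )
}

#' Simulate one observation period of network-behavior co-evolution
#'
#' Starting from the panel's wave-1 state, runs the continuous-time
#' micro-step chain to the end of the (unit-length) period and returns
#' the final network and behavior.  Identical seed and inputs give
#' identical output.
#'
#' @param panel a `school_panel`; wave 1 provides the starting state.
#' @param model a `saom_model` with rates and effect parameters.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @param record_trace if `TRUE`, the returned state carries a data
#'   frame listing every micro-step (event index, clock time, side,
#'   actor, option).
#' @param out_degree_cap optional nomination cap (e.g. 10 for
#'   name-up-to-ten-friends instruments); `NULL` (default) leaves
#'   out-degrees unconstrained.
#' @param centering precomputed [compute_centering()] constants
#'   (computed from the panel when omitted).
#' @return a `sim_state`: list with `ties`, `behavior`, `n_steps`, and
#'   optionally `trace`.
#' @export
simulate_period <- function(panel, model, seed = NULL,
                            record_trace = FALSE, out_degree_cap = NULL,
                            centering = NULL) {
  stopifnot(inherits(panel, "school_panel"), inherits(model, "saom_model"))
  centering <- centering %||% compute_centering(panel)
  ctx <- make_effect_context(model, panel$covariates, centering)
  with_seed(seed,
    sim_engine(panel$x1, as.numeric(panel$z1), model, ctx, panel$n_levels,
               record_trace = record_trace, out_degree_cap = out_degree_cap))
}

#' Write a micro-step trace to delimited text
#'
#' @param state a `sim_state` produced with `record_trace = TRUE`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_trace <- function(state, file) {
  stopifnot(inherits(state, "sim_state"))
  if (is.null(state$trace)) stop("state carries no trace")
  utils::write.table(state$trace, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# ---------------------------------------------------------------------------
# Target statistics

# Full-state target statistics with non-informative cells excluded:
# outgoing rows of wave-2 non-responders are zeroed, their behavior is
# replaced by the wave-1 (carry-forward) value, and behavior sums run
# over responders only.  The same masking is applied to observed and
# simulated states, so the moment conditions compare like with like
# and nothing a non-responder "did" after wave 1 can move a target.
target_statistics <- function(x, z, panel, model, centering) {
  resp <- panel$responded_wave2
  y <- x
  y[!resp, ] <- 0
  z <- as.numeric(z)
  z[!resp] <- as.numeric(panel$z1)[!resp]
  din <- colSums(y)
  dout <- rowSums(y)
  out <- numeric(0)
  edges <- which(y == 1, arr.ind = TRUE, useNames = FALSE)
  for (e in model$network_effects) {
    val <- switch(e$name,
      density = sum(y),
      reciprocity = sum(y * t(y)),
      transitive_triplets = sum(y * (y %*% y)),
      three_cycles = sum((y %*% y) * t(y)),
      indegree_popularity = sum(din^2),
      outdegree_popularity = sum(din * dout),
      outdegree_activity = sum(dout^2),
      ego = {
        v <- effect_covariate(e, z, panel$covariates)
        sum((v - centering$mean[[e$covariate]]) * dout)
      },
      alter = {
        v <- effect_covariate(e, z, panel$covariates)
        sum(din * (v - centering$mean[[e$covariate]]))
      },
      similarity = {
        v <- effect_covariate(e, z, panel$covariates)
        rng <- centering$range[[e$covariate]]
        sm <- centering$sim_mean[[e$covariate]]
        sum(1 - abs(v[edges[, 1]] - v[edges[, 2]]) / rng - sm)
      },
      same = {
        v <- effect_covariate(e, z, panel$covariates, numeric = FALSE)
        sum(v[edges[, 1]] == v[edges[, 2]])
      }
    )
    out[e$label] <- val
  }
  if (length(model$behavior_effects)) {
    zc <- z - centering$z_mean
    r <- which(resp)
    for (e in model$behavior_effects) {
      val <- switch(e$name,
        linear_shape = sum(zc[r]),
        quadratic_shape = sum(zc[r]^2),
        average_alter = {
          s <- 0
          for (i in r) {
            d <- dout[i]
            if (d > 0) s <- s + zc[i] * sum(y[i, ] * zc) / d
          }
          s
        },
        covariate = {
          v <- effect_covariate(e, z, panel$covariates)
          sum(zc[r] * (v[r] - centering$mean[[e$covariate]]))
        }
      )
      out[e$label] <- val
    }
  }
  out
}

# Hamming-distance rate statistics between a (simulated or observed)
# end state and wave 1, over responder rows only.
rate_statistics <- function(x_end, z_end, panel) {
  resp <- panel$responded_wave2
  out <- c(rate_network =
             sum(abs(x_end[resp, , drop = FALSE] -
                     panel$x1[resp, , drop = FALSE])))
  c(out, rate_behavior = sum(abs(as.numeric(z_end)[resp] -
                                 as.numeric(panel$z1)[resp])))
}

#' Simulated end-of-period target statistics
#'
#' Runs `n_replicates` independent simulations of the observation
#' period from the panel's wave-1 state and extracts, for each, the
#' target statistic vector used by the Method-of-Moments estimator:
#' the two Hamming-distance rate statistics followed by the per-effect
#' totals at the simulated end state (with non-informative cells
#' excluded, matching [observed_targets()]).
#'
#' @param panel a `school_panel` (imputed and filtered).
#' @param model a `saom_model`.
#' @param n_replicates number of Monte Carlo replicates.
#' @param seed master seed; replicate seeds are derived
#'   deterministically, so replicate `r` is reproducible in isolation.
#' @param centering optional precomputed centering constants.
#' @param out_degree_cap optional nomination cap passed to the
#'   simulator.
#' @return numeric matrix, one row per replicate, one column per model
#'   parameter.
#' @export
simulate_targets <- function(panel, model, n_replicates, seed,
                             centering = NULL, out_degree_cap = NULL) {
  stopifnot(inherits(panel, "school_panel"), inherits(model, "saom_model"))
  centering <- centering %||% compute_centering(panel)
  ctx <- make_effect_context(model, panel$covariates, centering)
  p <- length(parameters(model))
  out <- matrix(NA_real_, n_replicates, p,
                dimnames = list(NULL, names(parameters(model))))
  for (r in seq_len(n_replicates)) {
    st <- with_seed(derive_seed(seed, r),
                    sim_engine(panel$x1, as.numeric(panel$z1), model, ctx,
                               panel$n_levels,
                               out_degree_cap = out_degree_cap))
    tg <- c(rate_statistics(st$ties, st$behavior, panel),
            target_statistics(st$ties, st$behavior, panel, model, centering))
    if (!length(model$behavior_effects))
      tg <- tg[names(tg) != "rate_behavior"]
    out[r, ] <- tg[colnames(out)]
  }
  out
}
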