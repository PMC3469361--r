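# Effect catalog: the statistics s_ik(x, z, v) that enter the network
# and behavior objective functions.  Each actor i evaluates candidate
# states through f_i = sum_k beta_k s_ik; the catalog below defines
# every s_ik the package knows about.

.network_effect_types <- c(
  "density", "reciprocity", "transitive_triplets", "three_cycles",
  "indegree_popularity", "outdegree_popularity", "outdegree_activity",
  "ego", "alter", "similarity", "same"
)
.behavior_effect_types <- c(
  "linear_shape", "quadratic_shape", "average_alter", "covariate"
)
.covariate_needed <- c("ego", "alter", "similarity", "same", "covariate")

#' Declare a single model effect
#'
#' An effect couples a statistic from the catalog with an optional
#' covariate reference and a parameter value.  Network-side statistics
#' (for focal actor i, ties x, covariate v, behavior z):
#' \describe{
#'   \item{density}{out-degree, \eqn{\sum_j x_{ij}}}
#'   \item{reciprocity}{mutual dyads, \eqn{\sum_j x_{ij} x_{ji}}}
#'   \item{transitive_triplets}{\eqn{\sum_{j,h} x_{ij} x_{jh} x_{ih}}}
#'   \item{three_cycles}{\eqn{\sum_{j,h} x_{ij} x_{jh} x_{hi}}}
#'   \item{indegree_popularity}{\eqn{\sum_j x_{ij} \sum_h x_{hj}}}
#'   \item{outdegree_popularity}{\eqn{\sum_j x_{ij} \sum_h x_{jh}}}
#'   \item{outdegree_activity}{\eqn{(\sum_j x_{ij})^2}}
#'   \item{ego}{\eqn{(v_i - \bar v) \sum_j x_{ij}}}
#'   \item{alter}{\eqn{\sum_j x_{ij} (v_j - \bar v)}}
#'   \item{similarity}{\eqn{\sum_j x_{ij} (sim_{ij} - \overline{sim})},
#'     with \eqn{sim_{ij} = 1 - |v_i - v_j| / range(v)}}
#'   \item{same}{\eqn{\sum_j x_{ij} 1[v_i = v_j]}}
#' }
#' Behavior-side statistics (centered behavior
#' \eqn{\tilde z_i = z_i - \bar z}):
#' \describe{
#'   \item{linear_shape}{\eqn{\tilde z_i}}
#'   \item{quadratic_shape}{\eqn{\tilde z_i^2}}
#'   \item{average_alter}{\eqn{\tilde z_i \sum_j x_{ij}\tilde z_j /
#'     \sum_j x_{ij}} (0 for actors without out-ties) — the
#'     "average friend behavior" influence effect}
#'   \item{covariate}{\eqn{\tilde z_i (v_i - \bar v)}}
#' }
#' The reserved covariate name `"alcohol"` refers to the behavior
#' variable itself, so selection on behavior is declared as e.g.
#' `saom_effect("similarity", "alcohol")`.
#'
#' @param name statistic name from the catalog above.
#' @param covariate covariate name; required for ego / alter /
#'   similarity / same and behavior covariate effects, disallowed
#'   otherwise.
#' @param parameter the effect's parameter \eqn{\beta_k} (default 0).
#' @param label optional display label; defaults to
#'   `<covariate>_<name>`.
#' @return an object of class `saom_effect`.
#' @export
saom_effect <- function(name, covariate = NULL, parameter = 0,
                        label = NULL) {
  side <- if (name %in% .network_effect_types) "network"
  else if (name %in% .behavior_effect_types) "behavior"
  else stop("unknown effect name: '", name, "'")
  if (name %in% .covariate_needed) {
    if (is.null(covariate))
      stop("effect '", name, "' requires a covariate reference")
  } else if (!is.null(covariate)) {
    stop("effect '", name, "' does not take a covariate")
  }
  structure(
    list(name = name, side = side, covariate = covariate,
         parameter = as.numeric(parameter),
         label = label %||%
           if (is.null(covariate)) name else paste(covariate, name, sep = "_")),
    class = "saom_effect"
  )
}

#' @export
print.saom_effect <- function(x, ...) {
  cat(sprintf("<saom_effect> %-28s side=%-8s beta=% .3f\n",
              x$label, x$side, x$parameter))
  invisible(x)
}

#' Specify a co-evolution model
#'
#' Combines an ordered list of network-side effects, an ordered list of
#' behavior-side effects, and the two rate parameters (the expected
#' number of change opportunities per actor over the observation
#' period).  The network side must contain the density effect and a
#' non-empty behavior side must contain the linear and quadratic shape
#' effects; these play the role of intercepts.
#'
#' @param network_effects list of `saom_effect`s with `side =
#'   "network"`, or character vector of plain (covariate-free)
#'   statistic names.
#' @param behavior_effects list of `saom_effect`s with `side =
#'   "behavior"`; may be empty for a network-only model.
#' @param network_rate,behavior_rate positive rates \eqn{\lambda}.
#' @return an object of class `saom_model`.
#' @export
saom_model <- function(network_effects, behavior_effects = list(),
                       network_rate = 3, behavior_rate = 1.5) {
  as_eff <- function(e) if (is.character(e)) saom_effect(e) else e
  network_effects <- lapply(network_effects, as_eff)
  behavior_effects <- lapply(behavior_effects, as_eff)
  stopifnot(all(vapply(network_effects, inherits, logical(1), "saom_effect")),
            all(vapply(behavior_effects, inherits, logical(1), "saom_effect")))
  if (!all(vapply(network_effects, `[[`, "", "side") == "network"))
    stop("network_effects must all have side 'network'")
  if (length(behavior_effects) &&
      !all(vapply(behavior_effects, `[[`, "", "side") == "behavior"))
    stop("behavior_effects must all have side 'behavior'")
  nl <- vapply(network_effects, `[[`, "", "label")
  bl <- vapply(behavior_effects, `[[`, "", "label")
  if (anyDuplicated(nl) || anyDuplicated(bl))
    stop("effect labels must be unique within a side")
  if (!"density" %in% vapply(network_effects, `[[`, "", "name"))
    stop("the network side must include the density effect")
  if (length(behavior_effects)) {
    bn <- vapply(behavior_effects, `[[`, "", "name")
    if (!all(c("linear_shape", "quadratic_shape") %in% bn))
      stop("a non-empty behavior side must include linear and quadratic shape")
  }
  if (network_rate <= 0 ||
      (length(behavior_effects) && behavior_rate <= 0))
    stop("rates must be positive")
  structure(
    list(network_effects = network_effects,
         behavior_effects = behavior_effects,
         network_rate = as.numeric(network_rate),
         behavior_rate = if (length(behavior_effects))
           as.numeric(behavior_rate) else 0),
    class = "saom_model"
  )
}

#' @export
print.saom_model <- function(x, ...) {
  cat("SAOM specification\n")
  cat(sprintf("  network rate %.3f, behavior rate %.3f\n",
              x$network_rate, x$behavior_rate))
  cat("  network effects:\n")
  for (e in x$network_effects)
    cat(sprintf("    %-28s % .3f\n", e$label, e$parameter))
  if (length(x$behavior_effects)) {
    cat("  behavior effects:\n")
    for (e in x$behavior_effects)
      cat(sprintf("    %-28s % .3f\n", e$label, e$parameter))
  }
  invisible(x)
}

# Named parameter vector in canonical order: rates, then network
# effects, then behavior effects.
#' Extract the model's parameter vector
#' @param model a `saom_model`.
#' @return named numeric vector (rates first, then effect parameters).
#' @export
parameters <- function(model) {
  stopifnot(inherits(model, "saom_model"))
  th <- c(rate_network = model$network_rate)
  if (length(model$behavior_effects))
    th <- c(th, rate_behavior = model$behavior_rate)
  for (e in model$network_effects) th[e$label] <- e$parameter
  for (e in model$behavior_effects) th[e$label] <- e$parameter
  th
}

#' Replace the model's parameter vector
#' @param model a `saom_model`.
#' @param theta named or canonically ordered numeric vector as produced
#'   by [parameters()].
#' @return the updated `saom_model`.
#' @export
set_parameters <- function(model, theta) {
  stopifnot(inherits(model, "saom_model"))
  want <- names(parameters(model))
  if (!is.null(names(theta))) theta <- theta[want]
  if (length(theta) != length(want) || anyNA(theta))
    stop("theta must supply one value per model parameter")
  theta <- stats::setNames(as.numeric(theta), want)
  model$network_rate <- theta[["rate_network"]]
  k <- 1L + as.integer(length(model$behavior_effects) > 0)
  if (length(model$behavior_effects))
    model$behavior_rate <- theta[["rate_behavior"]]
  for (j in seq_along(model$network_effects)) {
    k <- k + 1L
    model$network_effects[[j]]$parameter <- theta[[k]]
  }
  for (j in seq_along(model$behavior_effects)) {
    k <- k + 1L
    model$behavior_effects[[j]]$parameter <- theta[[k]]
  }
  model
}

# ---------------------------------------------------------------------------
# Centering constants

#' Centering constants for a school
#'
#' Effects involving covariates or behavior are computed on centered
#' scores.  Constants are fixed once per school and reused in every
#' simulation for that school: covariate means and ranges; the behavior
#' mean at wave 1 (the wave the simulated process conditions on, so
#' that a model simulated forward from wave 1 is exactly the model the
#' estimator assumes); and, for similarity effects, the mean dyadic
#' similarity over all ordered pairs at wave 1.  The behavior range is
#' fixed by the measurement scale (6 categories, range 5), not by the
#' observed values.
#'
#' @param p a `school_panel`.
#' @return an object of class `saom_centering`: lists `mean`, `range`,
#'   `sim_mean` keyed by covariate name (including `"alcohol"` for the
#'   behavior variable), plus `z_mean` and `z_range`.
#' @export
compute_centering <- function(p) {
  stopifnot(inherits(p, "school_panel"))
  num_cols <- names(p$covariates)[vapply(p$covariates, is.numeric, TRUE)]
  cmean <- list(); crange <- list(); csim <- list()
  pair_sim_mean <- function(v, rng) {
    if (rng == 0) return(NA_real_)
    # mean over ordered pairs i != j of 1 - |v_i - v_j| / range
    n <- length(v)
    tot <- sum(outer(v, v, function(a, b) 1 - abs(a - b) / rng)) - n
    tot / (n * (n - 1))
  }
  for (cn in num_cols) {
    v <- p$covariates[[cn]]
    cmean[[cn]] <- mean(v)
    crange[[cn]] <- diff(range(v))
    csim[[cn]] <- pair_sim_mean(v, crange[[cn]])
  }
  z_range <- p$n_levels - 1
  cmean[["alcohol"]] <- mean(as.numeric(p$z1))
  crange[["alcohol"]] <- z_range
  csim[["alcohol"]] <- pair_sim_mean(as.numeric(p$z1), z_range)
  structure(
    list(mean = cmean, range = crange, sim_mean = csim,
         z_mean = cmean[["alcohol"]], z_range = z_range),
    class = "saom_centering"
  )
}

# Resolve the covariate vector an effect refers to.  `numeric = FALSE`
# keeps categorical codings (used by equality-based "same" effects).
effect_covariate <- function(effect, behavior, covariates, numeric = TRUE) {
  if (identical(effect$covariate, "alcohol")) return(as.numeric(behavior))
  v <- covariates[[effect$covariate]]
  if (is.null(v))
    stop("covariate '", effect$covariate, "' not found")
  if (numeric) as.numeric(v) else v
}

#' Dyadic similarity score
#'
#' `1 - |vi - vj| / range`: 1 for identical values, 0 for maximally
#' different ones (e.g. alcohol levels 1 and 6 on the range-5 scale).
#'
#' @param vi,vj attribute values.
#' @param rng attribute range (positive).
#' @return similarity in `[0, 1]`.
#' @export
sim_score <- function(vi, vj, rng) {
  if (rng == 0) stop("similarity undefined for zero-range covariate")
  1 - abs(vi - vj) / rng
}

# ---------------------------------------------------------------------------
# Reference (per-actor) statistic evaluation

#' Evaluate one network effect statistic for a focal actor
#'
#' Direct evaluation of the catalog definition (see [saom_effect()]) at
#' a given network/behavior state.  This is the reference
#' implementation used for target statistics and for verifying the
#' incremental change scores used inside the simulator.
#'
#' @param effect a network-side `saom_effect`.
#' @param actor focal actor index (1-based).
#' @param ties 0/1 adjacency matrix.
#' @param behavior behavior level vector.
#' @param covariates covariate data frame.
#' @param centering constants from [compute_centering()].
#' @return the statistic's numeric value for the focal actor.
#' @export
network_effect_statistic <- function(effect, actor, ties, behavior,
                                     covariates, centering) {
  stopifnot(inherits(effect, "saom_effect"), effect$side == "network")
  x <- ties
  i <- actor
  a <- x[i, ]
  switch(effect$name,
    density = sum(a),
    reciprocity = sum(a * x[, i]),
    transitive_triplets = sum(a * (x %*% a)),
    three_cycles = sum(a * (x %*% x[, i])),
    indegree_popularity = sum(a * colSums(x)),
    outdegree_popularity = sum(a * rowSums(x)),
    outdegree_activity = sum(a)^2,
    ego = {
      v <- effect_covariate(effect, behavior, covariates)
      (v[i] - centering$mean[[effect$covariate]]) * sum(a)
    },
    alter = {
      v <- effect_covariate(effect, behavior, covariates)
      sum(a * (v - centering$mean[[effect$covariate]]))
    },
    similarity = {
      v <- effect_covariate(effect, behavior, covariates)
      rng <- centering$range[[effect$covariate]]
      sm <- centering$sim_mean[[effect$covariate]]
      if (rng == 0 || is.na(sm))
        stop("similarity undefined for zero-range covariate '",
             effect$covariate, "'")
      sum(a * (sim_score(v[i], v, rng) - sm))
    },
    same = {
      v <- effect_covariate(effect, behavior, covariates, numeric = FALSE)
      sum(a * (v == v[i]))
    },
    stop("unknown network effect '", effect$name, "'")
  )
}

#' Evaluate one behavior effect statistic for a focal actor
#'
#' See [saom_effect()] for the catalog definitions.  The average-alter
#' influence statistic is 0 by convention for actors without outgoing
#' ties.
#'
#' @inheritParams network_effect_statistic
#' @param effect a behavior-side `saom_effect`.
#' @return the statistic's numeric value for the focal actor.
#' @export
behavior_effect_statistic <- function(effect, actor, ties, behavior,
                                      covariates, centering) {
  stopifnot(inherits(effect, "saom_effect"), effect$side == "behavior")
  i <- actor
  zc <- as.numeric(behavior) - centering$z_mean
  switch(effect$name,
    linear_shape = zc[i],
    quadratic_shape = zc[i]^2,
    average_alter = {
      a <- ties[i, ]
      d <- sum(a)
      if (d == 0) 0 else zc[i] * sum(a * zc) / d
    },
    covariate = {
      v <- effect_covariate(effect, behavior, covariates)
      zc[i] * (v[i] - centering$mean[[effect$covariate]])
    },
    stop("unknown behavior effect '", effect$name, "'")
  )
}

# ---------------------------------------------------------------------------
# Standard effect sets

#' Full network-selection effect set
#'
#' The 19-effect network evolution specification used in the full
#' analysis: structural effects (density, reciprocity, transitive
#' triplets, 3-cycles, in/out-degree popularity, out-degree activity),
#' ego/alter/similarity or same effects for age, gender and
#' race/ethnicity, and ego/alter/similarity effects for alcohol use.
#'
#' @return list of `saom_effect`s.
#' @export
network_selection_effects <- function() {
  list(
    saom_effect("density"),
    saom_effect("reciprocity"),
    saom_effect("transitive_triplets"),
    saom_effect("three_cycles"),
    saom_effect("indegree_popularity"),
    saom_effect("outdegree_popularity"),
    saom_effect("outdegree_activity"),
    saom_effect("ego", "age"),
    saom_effect("alter", "age"),
    saom_effect("similarity", "age"),
    saom_effect("ego", "male"),
    saom_effect("alter", "male"),
    saom_effect("same", "male", label = "gender_same"),
    saom_effect("ego", "minority"),
    saom_effect("alter", "minority"),
    saom_effect("same", "race", label = "race_same"),
    saom_effect("ego", "alcohol"),
    saom_effect("alter", "alcohol"),
    saom_effect("similarity", "alcohol")
  )
}

#' Full behavior-evolution effect set
#'
#' The 8-effect alcohol-use evolution specification: linear and
#' quadratic shape, average friend alcohol use (influence), and
#' covariate effects of age, gender, minority status, parental drinking
#' and family bonding.
#'
#' @return list of `saom_effect`s.
#' @export
behavior_evolution_effects <- function() {
  list(
    saom_effect("linear_shape"),
    saom_effect("quadratic_shape"),
    saom_effect("average_alter"),
    saom_effect("covariate", "age"),
    saom_effect("covariate", "male"),
    saom_effect("covariate", "minority"),
    saom_effect("covariate", "parent_drinking"),
    saom_effect("covariate", "family_bonding")
  )
}
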