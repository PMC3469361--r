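# Method-of-Moments estimation.  The estimator solves
#   E_theta S(X(t2), Z(t2)) = s_obs
# by Robbins-Monro stochastic approximation: phase 1 estimates the
# sensitivity of the expected targets to the parameters by
# common-random-number finite differences, phase 2 iterates damped
# quasi-Newton updates with one simulation per step (Polyak-averaged
# within subphases of halving gain), and phase 3 freezes the estimate
# and simulates a large replicate set for convergence t-ratios and the
# sandwich covariance matrix.

#' Observed Method-of-Moments target statistics
#'
#' The moment conditions equate the expected simulated targets to the
#' statistics of the wave-2 observation: for each rate parameter the
#' Hamming change count between waves (ties, respectively behavior
#' levels), and for each evaluation effect the statistic total at the
#' wave-2 state.  Cells filled by carry-forward imputation are
#' non-informative and contribute to no sum: non-responders' outgoing
#' rows are excluded throughout.
#'
#' @param panel a `school_panel`, imputed ([impute_locf()]) and
#'   filtered ([filter_isolates()]).
#' @param model a `saom_model`.
#' @param centering optional precomputed [compute_centering()]
#'   constants.
#' @return named numeric vector in canonical parameter order.
#' @export
observed_targets <- function(panel, model, centering = NULL) {
  stopifnot(inherits(panel, "school_panel"), inherits(model, "saom_model"))
  if (anyNA(panel$x2) || anyNA(panel$z2))
    stop("panel has unimputed wave-2 data; run impute_locf() first")
  centering <- centering %||% compute_centering(panel)
  rates <- rate_statistics(panel$x2, panel$z2, panel)
  if (rates[["rate_network"]] == 0)
    stop("degenerate data: no observed tie change between waves")
  if (length(model$behavior_effects) && rates[["rate_behavior"]] == 0)
    stop("degenerate data: no observed behavior change between waves")
  tg <- c(rates, target_statistics(panel$x2, panel$z2, panel, model,
                                   centering))
  if (!length(model$behavior_effects))
    tg <- tg[names(tg) != "rate_behavior"]
  tg[names(parameters(model))]
}

#' Estimate the target-sensitivity matrix
#'
#' Finite-difference estimate of \eqn{D = \partial E S / \partial
#' \theta} with common random numbers: for each parameter the period is
#' re-simulated at \eqn{\theta \pm \epsilon e_k} under identical
#' replicate seeds and the column is the central difference of the
#' replicate-mean targets.  Pairing the seeds removes most Monte Carlo
#' noise from the difference.  The step is halved when a simulation
#' returns non-finite targets; rate parameters use a step no larger
#' than half their value so the rate stays positive.
#'
#' @param panel a `school_panel`.
#' @param model a `saom_model` (supplies the effect set).
#' @param theta parameter vector at which to differentiate.
#' @param n1 number of paired replicates (must be at least the
#'   parameter count plus 3).
#' @param seed master seed for the replicate streams.
#' @param eps base finite-difference step (absolute).
#' @param centering optional precomputed centering constants.
#' @return a square matrix, rows = targets, columns = parameters.
#' @export
estimate_derivative <- function(panel, model, theta, n1, seed,
                                eps = 0.1, centering = NULL) {
  centering <- centering %||% compute_centering(panel)
  theta <- theta[names(parameters(model))]
  p <- length(theta)
  if (n1 < p + 3) stop("n1 must be at least the parameter count plus 3")
  rate_idx <- grep("^rate_", names(theta))
  D <- matrix(0, p, p, dimnames = list(names(theta), names(theta)))
  for (k in seq_len(p)) {
    ek <- eps
    if (k %in% rate_idx) ek <- min(eps, theta[[k]] / 2)
    repeat {
      th_p <- theta; th_p[[k]] <- th_p[[k]] + ek
      th_m <- theta; th_m[[k]] <- th_m[[k]] - ek
      sp <- simulate_targets(panel, set_parameters(model, th_p), n1,
                             seed = seed, centering = centering)
      sm <- simulate_targets(panel, set_parameters(model, th_m), n1,
                             seed = seed, centering = centering)
      if (all(is.finite(sp)) && all(is.finite(sm))) {
        D[, k] <- (colMeans(sp) - colMeans(sm)) / (2 * ek)
        break
      }
      ek <- ek / 2
      if (ek < 1e-4) stop("derivative estimation failed for parameter ",
                          names(theta)[k])
    }
  }
  if (!all(is.finite(D)) || kappa(D) > 1e8)
    stop("ill-conditioned sensitivity matrix; consider a smaller effect set")
  D
}

#' Estimation control settings
#'
#' Phase sizes and tuning constants for [fit_school()].  The `scaled`
#' profile shrinks every phase for quick runs (continuous testing,
#' exploratory fits) at the price of noisier standard errors.
#'
#' @param n1 paired replicates for the sensitivity matrix.
#' @param n2 integer vector of phase-2 iteration counts, one per
#'   subphase; the Robbins-Monro gain is halved between subphases.
#' @param n3 phase-3 replicates for diagnostics and covariance.
#' @param gain initial Robbins-Monro gain \eqn{a_0}.
#' @param eps finite-difference step for the sensitivity matrix.
#' @param t_threshold convergence bound on the largest absolute
#'   per-effect t-ratio (community convention 0.10).
#' @param max_restarts additional phase-2 passes attempted when the
#'   convergence criterion fails.
#' @param step_cap bound on the absolute size of a single phase-2
#'   parameter update.
#' @param phase2_blend weight of the full sensitivity matrix in the
#'   phase-2 update direction (0 = pure per-coordinate scaling,
#'   1 = full Newton); the default 0.5 trades robustness to matrix
#'   noise against mobility along correlated parameter directions.
#' @param rate_bounds admissible range for rate parameters during
#'   optimisation.
#' @param scaled use the reduced profile.
#' @return a list of class `saom_control`.
#' @export
saom_control <- function(n1 = 40L, n2 = c(50L, 100L, 200L, 300L), n3 = 500L,
                         gain = 0.2, eps = 0.15, t_threshold = 0.10,
                         max_restarts = 3L, step_cap = 1,
                         phase2_blend = 0.5,
                         rate_bounds = c(0.05, 100), scaled = FALSE) {
  if (scaled) {
    if (missing(n1)) n1 <- 24L
    if (missing(n2)) n2 <- c(30L, 60L, 120L, 180L)
    if (missing(n3)) n3 <- 400L
    if (missing(max_restarts)) max_restarts <- 2L
  }
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 n3 = as.integer(n3), gain = gain, eps = eps,
                 t_threshold = t_threshold,
                 max_restarts = as.integer(max_restarts),
                 step_cap = step_cap, phase2_blend = phase2_blend,
                 rate_bounds = rate_bounds, scaled = scaled),
            class = "saom_control")
}

#' Fit a co-evolution model to one school by Method of Moments
#'
#' Three-phase Robbins-Monro stochastic approximation.  Phase 1
#' estimates the target-sensitivity matrix at the starting value
#' (rates initialised at the observed change count per actor, all
#' effect parameters at 0 except density at -1).  Phase 2 runs
#' subphases of damped updates
#' \eqn{\theta \leftarrow \theta - a D^{-1} (S_{sim} - s_{obs})}, one
#' simulation per update, halving the gain between subphases and
#' averaging the trajectory within each subphase.  Phase 3 freezes the
#' estimate, simulates `n3` replicates for the per-parameter
#' convergence t-ratios (simulated-minus-observed target mean over
#' simulated SD), re-estimates the sensitivity matrix at the solution,
#' and forms the covariance \eqn{D^{-1} \Sigma (D^{-1})'}.  If the
#' largest absolute evaluation-effect t-ratio is 0.10 or more, phase 2
#' is re-entered from the current estimate up to `max_restarts` times.
#'
#' @param panel a `school_panel`, already imputed and filtered.
#' @param model a `saom_model` defining the effect set (its stored
#'   parameter values are ignored; estimation starts from the standard
#'   initial values).
#' @param control a [saom_control()] list.
#' @param seed integer master seed; recorded in the fit so every
#'   reported number is replayable.
#' @param out_degree_cap optional nomination cap passed to the
#'   simulator.
#' @return an object of class `school_fit` with components `theta`,
#'   `se`, `t_conv`, `vcov`, `converged`, `n_phase2_iterations`,
#'   `targets_observed`, `phase3_targets`, the fitted `model`, and
#'   bookkeeping fields.
#' @export
fit_school <- function(panel, model, control = saom_control(), seed = 1L,
                       out_degree_cap = NULL) {
  stopifnot(inherits(panel, "school_panel"), inherits(model, "saom_model"),
            inherits(control, "saom_control"))
  centering <- compute_centering(panel)
  s_obs <- observed_targets(panel, model, centering)
  p <- length(s_obs)
  has_beh <- length(model$behavior_effects) > 0

  # standard starting value
  theta <- stats::setNames(numeric(p), names(s_obs))
  theta[["rate_network"]] <- max(s_obs[["rate_network"]] / panel$n, 0.5)
  if (has_beh)
    theta[["rate_behavior"]] <- max(s_obs[["rate_behavior"]] / panel$n, 0.5)
  for (e in model$network_effects)
    theta[[e$label]] <- if (e$name == "density") -1 else 0

  rate_idx <- grep("^rate_", names(theta))
  clamp <- function(th) {
    th[rate_idx] <- pmin(pmax(th[rate_idx], control$rate_bounds[1]),
                         control$rate_bounds[2])
    # keep evaluation parameters out of the saturation region where
    # choice probabilities degenerate and derivatives vanish
    th[-rate_idx] <- pmin(pmax(th[-rate_idx], -12), 12)
    th
  }

  phase2 <- function(theta, D, seed_base, gain = NULL, cap = NULL) {
    # Partially diagonalized quasi-Newton steps: the off-diagonal
    # entries of the simulated sensitivity matrix carry enough Monte
    # Carlo noise that pure full-matrix updates are unstable, while
    # pure per-coordinate scaling cannot move along correlated
    # parameter directions.  Blending the two (default half and half)
    # keeps the robustness of the diagonal and most of the ridge
    # mobility of the full matrix.
    dvec <- diag(D)
    # a non-positive diagonal sensitivity is Monte Carlo noise (every
    # target is increasing in its own parameter); freeze that
    # coordinate entirely until the matrix is re-estimated — flooring
    # the pivot instead would make the blended matrix near-singular
    # and catapult the frozen coordinate
    good <- is.finite(dvec) & dvec >= 1e-6
    Db <- control$phase2_blend * (D - diag(dvec, nrow = p)) +
      diag(pmax(dvec, 1e-6), nrow = p)
    Dg <- Db[good, good, drop = FALSE]
    newton <- function(resid) {
      st <- numeric(p)
      sg <- tryCatch(solve(Dg, resid[good]), error = function(e) NULL)
      if (is.null(sg) || !all(is.finite(sg)))
        sg <- resid[good] / dvec[good]
      st[good] <- sg
      st
    }
    gain <- gain %||% control$gain
    cap <- cap %||% control$step_cap
    it <- 0L
    for (s in seq_along(control$n2)) {
      a <- gain / 2^(s - 1)
      traj <- matrix(NA_real_, control$n2[s], p)
      for (m in seq_len(control$n2[s])) {
        it <- it + 1L
        s_sim <- simulate_targets(panel, set_parameters(model, theta), 1L,
                                  seed = derive_seed(seed_base, it),
                                  centering = centering,
                                  out_degree_cap = out_degree_cap)[1L, ]
        step <- a * newton(s_sim - s_obs)
        step <- pmin(pmax(step, -cap), cap)
        theta <- clamp(theta - step)
        traj[m, ] <- theta
      }
      # Polyak average over the subphase, discarding the first quarter
      # as burn-in so the transient from the subphase start does not
      # bias the average
      keep <- seq.int(max(1L, floor(control$n2[s] / 4) + 1L),
                      control$n2[s])
      theta <- stats::setNames(colMeans(traj[keep, , drop = FALSE]),
                               names(theta))
    }
    list(theta = theta, iterations = it)
  }

  phase3 <- function(theta, seed_base) {
    tg <- simulate_targets(panel, set_parameters(model, theta), control$n3,
                           seed = seed_base, centering = centering,
                           out_degree_cap = out_degree_cap)
    mu <- colMeans(tg)
    sdv <- apply(tg, 2L, stats::sd)
    t_conv <- (mu - s_obs) / ifelse(sdv > 0, sdv, NA_real_)
    D <- NULL
    for (mult in c(1, 2)) {  # widen the step once if near-singular
      D <- tryCatch(
        estimate_derivative(panel, set_parameters(model, theta), theta,
                            2L * control$n1,
                            seed = derive_seed(seed_base, 777L * mult),
                            eps = control$eps * mult,
                            centering = centering),
        error = function(e) NULL)
      if (!is.null(D)) break
    }
    if (is.null(D)) {
      V <- matrix(NA_real_, p, p, dimnames = list(names(theta),
                                                  names(theta)))
      return(list(t_conv = t_conv, D = NULL, vcov = V, targets = tg,
                  singular = TRUE))
    }
    Dinv <- solve(D)
    V <- Dinv %*% stats::cov(tg) %*% t(Dinv)
    dimnames(V) <- list(names(theta), names(theta))
    list(t_conv = t_conv, D = D, vcov = V, targets = tg,
         resid = mu - s_obs, singular = FALSE)
  }

  eval_labels <- setdiff(names(theta), names(theta)[rate_idx])

  D <- estimate_derivative(panel, set_parameters(model, theta), theta,
                           control$n1, seed = derive_seed(seed, 10000L),
                           eps = control$eps, centering = centering)
  n_iter <- 0L
  restarts <- 0L
  best <- NULL  # best pass so far by worst evaluation t-ratio
  repeat {
    p2 <- phase2(theta, D, derive_seed(seed, 20000L + 100000L * restarts),
                 gain = if (restarts > 0) control$gain / 2 else control$gain,
                 cap = if (restarts > 0) control$step_cap / 2 else
                   control$step_cap)
    theta <- p2$theta
    n_iter <- n_iter + p2$iterations
    p3 <- phase3(theta, derive_seed(seed, 30000L + 100000L * restarts))
    # convergence is judged on the moment t-ratios alone; a singular
    # sensitivity matrix only prevents standard-error computation
    tmax <- max(abs(p3$t_conv[eval_labels]), na.rm = TRUE)
    if (is.null(best) || tmax < best$tmax)
      best <- list(theta = theta, p3 = p3, tmax = tmax,
                   restarts = restarts)
    converged <- tmax < control$t_threshold
    if (converged || restarts >= control$max_restarts) break
    restarts <- restarts + 1L
    if (!is.null(p3$D)) {
      D <- p3$D  # refreshed sensitivity for the next pass
      # one full-matrix Newton correction from the precise phase-3
      # residual mean, kept only if a common-seed check confirms it
      # reduces the worst standardised residual (the full inverse can
      # overshoot along weakly identified directions)
      corr <- tryCatch(solve(D, p3$resid), error = function(e) NULL)
      if (!is.null(corr)) {
        cand <- clamp(theta - pmin(pmax(corr, -1), 1))
        probe_seed <- derive_seed(seed, 40000L + 100000L * restarts)
        probe <- function(th) {
          tg <- simulate_targets(panel, set_parameters(model, th), 40L,
                                 seed = probe_seed, centering = centering,
                                 out_degree_cap = out_degree_cap)
          sdv <- apply(tg, 2L, stats::sd)
          max(abs((colMeans(tg) - s_obs) /
                    ifelse(sdv > 0, sdv, Inf))[eval_labels])
        }
        if (probe(cand) < probe(theta)) theta <- cand
      }
    }
  }
  # report the best pass: later restarts are not guaranteed to improve
  # on earlier ones when identification is weak
  theta <- best$theta
  p3 <- best$p3
  converged <- best$tmax < control$t_threshold
  if (!converged)
    warning("school '", panel$school_id, "': estimation did not converge (",
            "max |t| = ",
            formatC(best$tmax, digits = 3, format = "f"), ")")

  se <- sqrt(pmax(diag(p3$vcov), 0))
  structure(
    list(school_id = panel$school_id, n_actors = panel$n,
         theta = theta, se = se, t_conv = p3$t_conv, vcov = p3$vcov,
         D = p3$D, converged = converged,
         n_phase2_iterations = n_iter, n_phase3_replicates = control$n3,
         restarts = restarts, seed = seed,
         targets_observed = s_obs, phase3_targets = p3$targets,
         model = set_parameters(model, theta), control = control,
         centering = centering),
    class = "school_fit"
  )
}

#' @export
print.school_fit <- function(x, ...) {
  cat("SAOM Method-of-Moments fit: school '", x$school_id, "' (n = ",
      x$n_actors, ")\n", sep = "")
  cat(if (x$converged) "  converged" else "  NOT converged",
      sprintf(" (max |t| = %.3f, %d phase-2 iterations, %d restarts)\n",
              max(abs(x$t_conv), na.rm = TRUE), x$n_phase2_iterations,
              x$restarts))
  print(summary(x), ...)
  invisible(x)
}

#' @export
summary.school_fit <- function(object, ...) {
  p <- two_sided_p(object, check_convergence = FALSE)
  data.frame(parameter = names(object$theta),
             estimate = unname(object$theta),
             se = unname(object$se),
             t_conv = unname(object$t_conv),
             p_two_sided = p$p_two_sided,
             row.names = NULL)
}

#' @export
coef.school_fit <- function(object, ...) object$theta

#' @export
vcov.school_fit <- function(object, ...) object$vcov

#' Simulate observation periods from a fitted school model
#'
#' @param object a `school_fit`.
#' @param nsim number of simulated periods.
#' @param seed master seed for replicate streams.
#' @param panel the `school_panel` supplying the starting state.
#' @param ... unused.
#' @return a list of `sim_state` objects.
#' @export
simulate.school_fit <- function(object, nsim = 1, seed = 1L,
                                panel, ...) {
  stopifnot(inherits(panel, "school_panel"))
  lapply(seq_len(nsim), function(r)
    simulate_period(panel, object$model, seed = derive_seed(seed, r),
                    centering = object$centering))
}

#' Normal-approximation p-values for fitted parameters
#'
#' Right-sided, left-sided and two-sided p-values from the Gaussian
#' reference for \eqn{\hat\theta / se}; these are the per-school inputs
#' to the Fisher combination across schools.
#'
#' @param fit a converged `school_fit`.
#' @param check_convergence error when the fit did not converge
#'   (default `TRUE`).
#' @return data frame with columns `parameter`, `z`, `p_right`,
#'   `p_left`, `p_two_sided`.
#' @export
two_sided_p <- function(fit, check_convergence = TRUE) {
  stopifnot(inherits(fit, "school_fit"))
  if (check_convergence && !fit$converged)
    stop("p-values require a converged fit")
  if (any(!is.na(fit$se) & fit$se == 0))
    stop("zero standard error; p-values undefined")
  z <- fit$theta / fit$se
  pr <- 1 - stats::pnorm(z)
  pl <- stats::pnorm(z)
  data.frame(parameter = names(fit$theta), z = unname(z),
             p_right = unname(pr), p_left = unname(pl),
             p_two_sided = unname(2 * pmin(pr, pl)), row.names = NULL)
}

#' Write a per-school fit report
#'
#' One row per parameter with the estimate, standard error and
#' convergence t-ratio — the per-school analogue of a pooled results
#' table.
#'
#' @param fits a `school_fit` or list of them.
#' @param file output path (delimited text).
#' @param sep field separator.
#' @return invisibly, the report data frame.
#' @export
write_fit_report <- function(fits, file, sep = "\t") {
  if (inherits(fits, "school_fit")) fits <- list(fits)
  rows <- do.call(rbind, lapply(fits, function(f) {
    s <- summary(f)
    data.frame(school_id = f$school_id, effect = s$parameter,
               beta = s$estimate, se = s$se, t_conv = s$t_conv,
               converged = f$converged)
  }))
  utils::write.table(format(rows, digits = 6, trim = TRUE), file, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(rows)
}
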