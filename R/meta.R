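# Cross-school meta-analysis of per-school SAOM estimates.

#' Snijders-Baerveldt two-stage meta-analysis of one effect
#'
#' Treats the per-school estimates as draws from a population of
#' schools, \eqn{\hat\theta_j = \mu + U_j + E_j} with between-school
#' variance \eqn{Var(U_j) = \sigma^2} and known within-school variance
#' \eqn{se_j^2}.  Estimated by iterated weighted least squares with
#' weights \eqn{1/(se_j^2 + \hat\sigma^2)}, updating
#' \eqn{\hat\sigma^2} by the method of moments on the weighted
#' residual sum of squares (truncated at 0) until the change falls
#' below 1e-8 (at most 100 iterations).  With \eqn{\hat\sigma^2 = 0}
#' the procedure collapses to fixed-effect inverse-variance pooling.
#' The two-sided p-value for \eqn{\mu} uses a t reference with
#' `N - 1` degrees of freedom, an honest small-sample choice at a
#' dozen schools.
#'
#' @param estimates per-school effect estimates.
#' @param ses their standard errors (all positive).
#' @return list with `mu_hat`, `se_mu`, `p_two_sided`,
#'   `sigma_between` (between-school SD), `n_schools`, `iterations`.
#' @export
snijders_baerveldt_test <- function(estimates, ses) {
  estimates <- as.numeric(estimates)
  ses <- as.numeric(ses)
  ok <- is.finite(estimates) & is.finite(ses)
  estimates <- estimates[ok]; ses <- ses[ok]
  N <- length(estimates)
  if (N < 2) stop("at least 2 schools are required")
  if (any(ses <= 0)) stop("standard errors must be positive")
  v <- ses^2
  sigma2 <- max(stats::var(estimates) - mean(v), 0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- 1 / (v + sigma2)
    mu <- sum(w * estimates) / sum(w)
    q <- sum(w * (estimates - mu)^2)
    # moment step: Q has expectation N - 1 at the true sigma^2
    slope <- sum(w^2 * (estimates - mu)^2)
    if (slope <= 0) break
    new <- max(sigma2 + (q - (N - 1)) / slope, 0)
    if (abs(new - sigma2) < 1e-8 || iter >= 100L) { sigma2 <- new; break }
    sigma2 <- new
  }
  w <- 1 / (v + sigma2)
  mu <- sum(w * estimates) / sum(w)
  se_mu <- sqrt(1 / sum(w))
  tval <- mu / se_mu
  list(mu_hat = mu, se_mu = se_mu,
       p_two_sided = 2 * stats::pt(-abs(tval), df = N - 1),
       sigma_between = sqrt(sigma2), n_schools = N, iterations = iter)
}

#' Fisher's combination of one-sided p-values across schools
#'
#' Pools N independent one-sided p-values through
#' \eqn{T = -2 \sum_j \log p_j}, referred to a chi-square distribution
#' with 2N degrees of freedom.  Applied once to the right-sided
#' p-values (evidence that the effect is positive in at least some
#' schools) and once to the left-sided ones.
#'
#' @param one_sided_ps vector of p-values in (0, 1]; values below
#'   1e-12 are clamped with a warning.
#' @return list with `statistic`, `df`, and `combined_p`.
#' @export
fisher_combination <- function(one_sided_ps) {
  p <- as.numeric(one_sided_ps)
  if (!length(p)) stop("no p-values supplied")
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    if (any(is.finite(p) & p <= 0)) {
      warning("p-values at or below 0 clamped to 1e-12")
      p[p <= 0] <- 1e-12
    }
    if (any(!is.finite(p) | p > 1)) stop("p-values must lie in (0, 1]")
  }
  if (any(p < 1e-12)) {
    warning("p-values below 1e-12 clamped")
    p[p < 1e-12] <- 1e-12
  }
  T <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(statistic = T, df = df,
       combined_p = stats::pchisq(T, df = df, lower.tail = FALSE))
}

#' Significance verdict for a pooled effect
#'
#' An effect is declared significant when either one-sided Fisher
#' combination is at or below `alpha_fisher` (0.025 by default, the
#' multiplicity-halved level for the right/left pair) or the
#' Snijders-Baerveldt two-sided p is below `alpha_sb` (0.05).  When the
#' two procedures disagree, the Fisher result is treated as decisive —
#' the combination test is robust to the wide spread of school sizes —
#' and the provenance note records the conflict.
#'
#' @param meta a list or one-row data frame with fields
#'   `fisher_right_p`, `fisher_left_p`, `p_two_sided`.
#' @param alpha_fisher level for each one-sided combination test
#'   (boundary inclusive).
#' @param alpha_sb level for the Snijders-Baerveldt two-sided test
#'   (strict).
#' @return list with `significant` (logical) and `note` (character).
#' @export
significance_verdict <- function(meta, alpha_fisher = 0.025,
                                 alpha_sb = 0.05) {
  fr <- meta$fisher_right_p
  fl <- meta$fisher_left_p
  sb <- meta$p_two_sided
  fisher_sig <- isTRUE(fr <= alpha_fisher) || isTRUE(fl <= alpha_fisher)
  sb_sig <- isTRUE(sb < alpha_sb)
  significant <- fisher_sig || sb_sig
  note <- if (fisher_sig == sb_sig) {
    "Fisher and Snijders-Baerveldt tests agree"
  } else {
    paste0("tests conflict (Fisher ",
           if (fisher_sig) "significant" else "not significant",
           ", Snijders-Baerveldt ",
           if (sb_sig) "significant" else "not significant",
           "); Fisher taken as decisive")
  }
  list(significant = significant, note = note)
}

#' Odds-ratio interpretation of a selection coefficient
#'
#' A similarity selection coefficient is the log-odds contrast between
#' a friendship tie to an identical alter and one to a maximally
#' different alter; exponentiation converts it to an odds ratio
#' (reported to two decimals).  When a standard error is supplied, a
#' normal-approximation interval \eqn{\exp(\beta \pm 1.96 se)} is
#' attached.
#'
#' @param beta the coefficient.
#' @param se optional standard error.
#' @return list with `odds_ratio` (exact), `odds_ratio_2dp` (reporting
#'   value), and, when `se` is given, `ci` (a length-2 vector) and
#'   `ci_type = "normal approximation"`.
#' @export
selection_odds_ratio <- function(beta, se = NULL) {
  out <- list(odds_ratio = exp(beta),
              odds_ratio_2dp = round(exp(beta), 2))
  if (!is.null(se)) {
    out$ci <- exp(beta + c(-1, 1) * 1.96 * se)
    out$ci_type <- "normal approximation"
  }
  out
}

#' Pool per-school fits across schools, one row per effect
#'
#' For every model parameter (rates excluded), combines the converged
#' per-school estimates with the Snijders-Baerveldt test and both
#' one-sided Fisher combinations, and applies the significance verdict
#' rule.
#'
#' @param fits list of `school_fit` objects; non-converged fits are
#'   dropped with a warning.
#' @param side restrict to `"network"` or `"behavior"` effects
#'   (default both).
#' @param alpha_fisher,alpha_sb verdict levels, see
#'   [significance_verdict()].
#' @return a data frame of class `saom_meta` with columns `effect`,
#'   `side`, `mu_hat`, `se_mu`, `p_two_sided`, `sigma_between`,
#'   `fisher_right_p`, `fisher_left_p`, `significant`, `n_schools`,
#'   `note`.
#' @export
meta_analyze <- function(fits, side = c("network", "behavior"),
                         alpha_fisher = 0.025, alpha_sb = 0.05) {
  stopifnot(all(vapply(fits, inherits, logical(1), "school_fit")))
  side <- match.arg(side, several.ok = TRUE)
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (any(!conv))
    warning(sum(!conv), " non-converged school fit(s) excluded from ",
            "meta-analysis: ",
            paste(vapply(fits[!conv], `[[`, "", "school_id"),
                  collapse = ", "))
  fits <- fits[conv]
  if (length(fits) < 2) stop("fewer than 2 converged schools")
  model <- fits[[1]]$model
  effs <- c(if ("network" %in% side) model$network_effects,
            if ("behavior" %in% side) model$behavior_effects)
  rows <- lapply(effs, function(e) {
    est <- vapply(fits, function(f) f$theta[[e$label]], numeric(1))
    ses <- vapply(fits, function(f) f$se[[e$label]], numeric(1))
    keep <- is.finite(est) & is.finite(ses) & ses > 0
    if (sum(keep) < 2)
      stop("fewer than 2 schools with usable standard errors for effect '",
           e$label, "'")
    ps <- lapply(fits[keep], two_sided_p)
    pr <- vapply(ps, function(d) d$p_right[d$parameter == e$label],
                 numeric(1))
    pl <- vapply(ps, function(d) d$p_left[d$parameter == e$label],
                 numeric(1))
    sb <- snijders_baerveldt_test(est[keep], ses[keep])
    fr <- fisher_combination(pmax(pr, 1e-12))
    fl <- fisher_combination(pmax(pl, 1e-12))
    row <- data.frame(effect = e$label, side = e$side,
                      mu_hat = sb$mu_hat, se_mu = sb$se_mu,
                      p_two_sided = sb$p_two_sided,
                      sigma_between = sb$sigma_between,
                      fisher_right_p = fr$combined_p,
                      fisher_left_p = fl$combined_p,
                      n_schools = sb$n_schools)
    v <- significance_verdict(row, alpha_fisher, alpha_sb)
    row$significant <- v$significant
    row$note <- v$note
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("saom_meta", class(out))
  out
}

#' @export
print.saom_meta <- function(x, digits = 3, ...) {
  cat("Cross-school meta-analysis (", x$n_schools[1], " schools)\n",
      sep = "")
  df <- data.frame(effect = x$effect,
                   beta = round(x$mu_hat, digits),
                   se = round(x$se_mu, digits),
                   p = round(x$p_two_sided, digits),
                   between_sd = round(x$sigma_between, digits),
                   fisher_right = round(x$fisher_right_p, digits),
                   fisher_left = round(x$fisher_left_p, digits),
                   sig = ifelse(x$significant, "*", ""))
  print(df, row.names = FALSE)
  invisible(x)
}
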