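# Method-of-Moments machinery: targets, sensitivity estimation,
# p-values, and a compact fitting smoke test.

test_that("observed targets reproduce direct counts", {
  p <- tiny_panel()
  m <- saom_model(list(saom_effect("density", parameter = -1),
                       saom_effect("reciprocity")),
                  network_rate = 2)
  tg <- observed_targets(p, m)
  # one tie formed (1->3) and one dissolved (2->3): rate target 2
  expect_equal(tg[["rate_network"]], 2)
  expect_equal(tg[["density"]], sum(p$x2))
  expect_equal(tg[["reciprocity"]], sum(p$x2 * t(p$x2)))

  # a panel with exactly one formed tie and none dissolved
  x1 <- matrix(0, 3, 3)
  x2 <- x1; x2[1, 2] <- 1
  q <- school_panel("s", x1, x2, c(1, 2, 1), c(1, 2, 1))
  expect_equal(observed_targets(q, m)[["rate_network"]], 1)

  # identical waves: the rate is unidentifiable
  r <- school_panel("s", x2, x2, c(1, 2, 1), c(1, 2, 1))
  expect_error(observed_targets(r, m), "degenerate")

  # density target on a wave-2 graph with 7 ties
  x7 <- matrix(0, 4, 4)
  x7[cbind(c(1, 1, 1, 2, 2, 3, 4), c(2, 3, 4, 1, 3, 4, 1))] <- 1
  s <- school_panel("s", matrix(0, 4, 4) + diag(0, 4), x7,
                    rep(1:2, 2), rep(1:2, 2))
  expect_equal(observed_targets(s, m)[["density"]], 7)
})

test_that("behavior-side targets require observed behavior change", {
  m <- saom_model(list(saom_effect("density")),
                  list(saom_effect("linear_shape"),
                       saom_effect("quadratic_shape")),
                  network_rate = 2, behavior_rate = 1)
  x1 <- matrix(0, 3, 3); x2 <- x1; x2[1, 2] <- 1
  p <- school_panel("s", x1, x2, c(1, 2, 3), c(1, 2, 3))
  expect_error(observed_targets(p, m), "no observed behavior change")
})

test_that("imputed cells contribute to no target sum", {
  cfg <- recovery_config(40L)
  base <- generate_school_panel(cfg, 1, seed = 1234)
  m <- recovery_model()
  # mark two actors as non-responders and impute
  p <- base
  p$responded_wave2[c(3, 9)] <- FALSE
  p$x2[c(3, 9), ] <- NA; p$z2[c(3, 9)] <- NA
  p <- impute_locf(p)
  t1 <- observed_targets(p, m)
  # replace the carried-forward rows and behavior with arbitrary values
  q <- p
  q$x2[3, ] <- 0; q$x2[3, c(1, 2, 5)] <- 1; q$x2[3, 3] <- 0
  q$x2[9, ] <- 0; q$x2[9, 20:25] <- 1
  q$z2[c(3, 9)] <- c(6L, 6L)
  t2 <- observed_targets(q, m)
  expect_equal(t2, t1)
})

test_that("estimates are equivariant to effect declaration order", {
  p <- tiny_panel()
  m_ab <- saom_model(list(saom_effect("density"),
                          saom_effect("reciprocity")), network_rate = 2)
  m_ba <- saom_model(list(saom_effect("reciprocity"),
                          saom_effect("density")), network_rate = 2)
  ta <- observed_targets(p, m_ab)
  tb <- observed_targets(p, m_ba)
  expect_equal(ta[c("density", "reciprocity")],
               tb[c("density", "reciprocity")])
})

test_that("the sensitivity of a target to its own parameter is positive", {
  cfg <- recovery_config(30L)
  p <- generate_school_panel(cfg, 1, seed = 41)
  m <- saom_model(list(saom_effect("density", parameter = -1.5),
                       saom_effect("reciprocity", parameter = 1)),
                  network_rate = 3)
  th <- parameters(m)
  D <- estimate_derivative(p, m, th, n1 = 8, seed = 17)
  expect_true(all(diag(D) > 0))
  expect_equal(dim(D), c(3L, 3L))
  expect_error(estimate_derivative(p, m, th, n1 = 4, seed = 17),
               "at least")
})

test_that("common random numbers cut the variance of the difference", {
  cfg <- recovery_config(30L)
  p <- generate_school_panel(cfg, 1, seed = 43)
  m <- density_model(-1.5, rate = 3)
  th_p <- parameters(m); th_p[["density"]] <- th_p[["density"]] + 0.15
  th_m <- parameters(m); th_m[["density"]] <- th_m[["density"]] - 0.15
  m_p <- set_parameters(m, th_p); m_m <- set_parameters(m, th_m)
  paired <- vapply(1:30, function(r) {
    simulate_targets(p, m_p, 1, seed = 100 + r)[1, "density"] -
      simulate_targets(p, m_m, 1, seed = 100 + r)[1, "density"]
  }, numeric(1))
  indep <- vapply(1:30, function(r) {
    simulate_targets(p, m_p, 1, seed = 100 + r)[1, "density"] -
      simulate_targets(p, m_m, 1, seed = 500 + r)[1, "density"]
  }, numeric(1))
  expect_lt(stats::var(paired), stats::var(indep))
})

test_that("normal-approximation p-values behave as advertised", {
  fit <- structure(list(theta = c(density = 0, reciprocity = 1.96),
                        se = c(density = 1, reciprocity = 1),
                        converged = TRUE),
                   class = "school_fit")
  pv <- two_sided_p(fit)
  expect_equal(pv$p_two_sided[1], 1)
  expect_equal(pv$p_two_sided[2], 0.05, tolerance = 1e-3)
  expect_equal(pv$p_right + pv$p_left, c(1, 1))
  fit$se[1] <- 0
  expect_error(two_sided_p(fit), "zero standard error")
  fit2 <- structure(list(theta = c(a = 1), se = c(a = 0.5),
                         converged = FALSE), class = "school_fit")
  expect_error(two_sided_p(fit2), "converged")
})

test_that("a compact network-only fit converges and recovers", {
  m_true <- saom_model(
    list(saom_effect("density", parameter = -2),
         saom_effect("reciprocity", parameter = 1.5)),
    network_rate = 4)
  cfg <- synthetic_config(n_schools = 1L, school_sizes = 50L,
                          theta_true = m_true, density_size_ref = 50,
                          attrition = list(p_heavy = 0, p_other = 0,
                                           heavy_level = 5L))
  p <- generate_school_panel(cfg, 1, seed = 2024)
  ctl <- saom_control(n1 = 10L, n2 = c(20L, 25L, 30L), n3 = 150L,
                      scaled = TRUE)
  f <- fit_school(p, m_true, control = ctl, seed = 99)
  expect_s3_class(f, "school_fit")
  expect_true(f$converged)
  expect_lt(max(abs(f$t_conv[c("density", "reciprocity")])), 0.10)
  th <- parameters(m_true)
  expect_true(all(abs(f$theta - th) <= 3 * f$se))
  expect_true(all(f$se[c("density", "reciprocity")] > 0))
  # methods
  expect_equal(coef(f), f$theta)
  expect_equal(dim(vcov(f)), c(3L, 3L))
  s <- summary(f)
  expect_equal(nrow(s), 3)
  # replayability: identical seed gives an identical fit
  f2 <- fit_school(p, m_true, control = ctl, seed = 99)
  expect_identical(f$theta, f2$theta)
  # simulate() from the fitted model
  sims <- simulate(f, nsim = 2, seed = 5, panel = p)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "sim_state")
})

test_that("fit reports are written one row per school and effect", {
  fit <- structure(list(school_id = "s1", n_actors = 40,
                        theta = c(rate_network = 3, density = -2),
                        se = c(rate_network = 0.5, density = 0.2),
                        t_conv = c(rate_network = 0.01, density = -0.02),
                        converged = TRUE, seed = 7),
                   class = "school_fit")
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- write_fit_report(fit, f)
  got <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(got), 2)
  expect_equal(got$effect, c("rate_network", "density"))
  expect_equal(got$converged, c(TRUE, TRUE))
})
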