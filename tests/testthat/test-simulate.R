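# Micro-step choice probabilities and the continuous-time event loop.

test_that("network choice probabilities reproduce hand-computed logits", {
  z <- c(1, 1, 1)
  # beta = 0: utility-free uniformity over no-change and both toggles
  m0 <- density_model(0)
  expect_equal(unname(network_choice_probabilities(1, matrix(0, 3, 3), z, m0)),
               rep(1 / 3, 3))
  # density beta = ln 2, no current ties: softmax over (0, ln2, ln2)
  m <- density_model(log(2))
  expect_equal(unname(network_choice_probabilities(1, matrix(0, 3, 3), z, m)),
               c(1 / 5, 2 / 5, 2 / 5))
  # both ties present: dropping one forgoes ln 2 -> (1/2, 1/4, 1/4)
  x <- matrix(0, 3, 3); x[1, 2] <- x[1, 3] <- 1
  expect_equal(unname(network_choice_probabilities(1, x, z, m)),
               c(1 / 2, 1 / 4, 1 / 4))
})

test_that("choice probabilities normalise and equal full objective evaluation", {
  # dual route: utilities from incremental change scores must equal
  # softmax over the objective evaluated at every post-toggle state
  # (shift invariance of the logit)
  model <- saom_model(
    list(saom_effect("density", parameter = -1.2),
         saom_effect("reciprocity", parameter = 0.8),
         saom_effect("transitive_triplets", parameter = 0.4),
         saom_effect("three_cycles", parameter = -0.3),
         saom_effect("indegree_popularity", parameter = 0.1),
         saom_effect("outdegree_activity", parameter = -0.05),
         saom_effect("similarity", "alcohol", parameter = 0.9),
         saom_effect("ego", "v", parameter = 0.2),
         saom_effect("same", "v", parameter = 0.3)),
    network_rate = 2)
  withr::with_seed(11, {
    for (rep in 1:40) {
      n <- sample(4:7, 1)
      x <- random_digraph(n, 0.35)
      z <- sample(1:6, n, replace = TRUE)
      v <- sample(1:3, n, replace = TRUE)
      cov <- data.frame(v = v)
      cen <- manual_centering(z, list(v = v))
      if (cen$range$v == 0) next
      i <- sample(n, 1)
      pr <- network_choice_probabilities(i, x, z, model, cov, cen)
      expect_equal(sum(pr), 1, tolerance = 1e-12)
      expect_true(all(pr > 0))
      # brute force: evaluate f_i at each candidate state
      f_at <- function(xs) {
        sum(vapply(model$network_effects, function(e)
          e$parameter *
            network_effect_statistic(e, i, xs, z, cov, cen), numeric(1)))
      }
      utils_full <- c(f_at(x), vapply(setdiff(seq_len(n), i), function(j) {
        xs <- x; xs[i, j] <- 1 - xs[i, j]; f_at(xs)
      }, numeric(1)))
      expect_equal(unname(pr), exp(utils_full - max(utils_full)) /
                     sum(exp(utils_full - max(utils_full))),
                   tolerance = 1e-10)
    }
  })
})

test_that("behavior choice probabilities truncate at scale bounds", {
  m <- saom_model(list(saom_effect("density")),
                  list(saom_effect("linear_shape"),
                       saom_effect("quadratic_shape")),
                  network_rate = 1, behavior_rate = 1)
  x <- matrix(0, 3, 3)
  # interior level, all beta 0: uniform over down/stay/up
  expect_equal(unname(behavior_choice_probabilities(2, x, c(1, 3, 6), m)),
               rep(1 / 3, 3))
  # at the maximum: only down/stay remain
  pr_max <- behavior_choice_probabilities(3, x, c(1, 3, 6), m)
  expect_equal(names(pr_max), c("down", "stay"))
  expect_equal(unname(pr_max), c(1 / 2, 1 / 2))
  # strong positive linear shape pushes upward
  m_up <- saom_model(list(saom_effect("density")),
                     list(saom_effect("linear_shape", parameter = 2),
                          saom_effect("quadratic_shape")),
                     network_rate = 1, behavior_rate = 1)
  pr <- behavior_choice_probabilities(2, x, c(1, 3, 6), m_up)
  expect_gt(pr[["up"]], pr[["down"]])
})

test_that("zero rates leave the state untouched and seeds give determinism", {
  p <- tiny_panel()
  m <- saom_model(list(saom_effect("density", parameter = -1)),
                  network_rate = 1e-12)
  out <- simulate_period(p, m, seed = 5)
  expect_equal(out$ties, unname(p$x1))
  expect_equal(out$behavior, as.numeric(p$z1))

  m2 <- recovery_model()
  cfg <- recovery_config(30L)
  panel <- generate_school_panel(cfg, 1, seed = 9)
  a <- simulate_period(panel, m2, seed = 77)
  b <- simulate_period(panel, m2, seed = 77)
  expect_identical(a$ties, b$ties)
  expect_identical(a$behavior, b$behavior)
  c2 <- simulate_period(panel, m2, seed = 78)
  expect_false(identical(a$ties, c2$ties))
})

test_that("a frozen side stays exactly constant", {
  cfg <- recovery_config(25L)
  panel <- generate_school_panel(cfg, 1, seed = 4)
  m <- recovery_model()
  m$behavior_rate <- 1e-14   # behavior frozen
  out <- simulate_period(panel, m, seed = 3)
  expect_equal(out$behavior, as.numeric(panel$z1))
  expect_false(identical(out$ties, unname(panel$x1)))
  m_net0 <- recovery_model()
  m_net0$network_rate <- 1e-14  # ties frozen
  out2 <- simulate_period(panel, m_net0, seed = 3)
  expect_equal(out2$ties, unname(panel$x1))
})

test_that("the chain respects hard state constraints and records a trace", {
  cfg <- recovery_config(20L)
  panel <- generate_school_panel(cfg, 1, seed = 12)
  out <- simulate_period(panel, recovery_model(), seed = 6,
                         record_trace = TRUE)
  expect_true(all(diag(out$ties) == 0))
  expect_true(all(out$behavior >= 1 & out$behavior <= 6))
  expect_s3_class(out$trace, "data.frame")
  expect_equal(nrow(out$trace), out$n_steps)
  expect_true(all(out$trace$clock <= 1))
  expect_true(all(out$trace$side %in% c("network", "behavior")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trace(out, f)
  expect_equal(nrow(utils::read.table(f, header = TRUE, sep = "\t")),
               out$n_steps)
})

test_that("an out-degree cap excludes tie creation at the cap", {
  p <- tiny_panel()
  m <- density_model(2)
  # actor 1 already has 1 tie; cap at 1 forbids creating more
  pr <- network_choice_probabilities(1, p$x1, p$z1, m, p$covariates,
                                     compute_centering(p),
                                     out_degree_cap = 1)
  expect_equal(pr[["toggle_3"]], 0)
  expect_equal(pr[["toggle_4"]], 0)
  expect_gt(pr[["toggle_2"]], 0)  # dropping the existing tie stays allowed
  cfg <- recovery_config(25L)
  panel <- generate_school_panel(cfg, 1, seed = 19)
  out <- simulate_period(panel, recovery_model(), seed = 2,
                         out_degree_cap = 3)
  expect_true(all(rowSums(out$ties) <= pmax(rowSums(panel$x1), 3)))
})

test_that("micro-step counts are Poisson with intensity n (lambda_n + lambda_b)", {
  p <- tiny_panel()  # n = 4
  m <- saom_model(list(saom_effect("density")),
                  list(saom_effect("linear_shape"),
                       saom_effect("quadratic_shape")),
                  network_rate = 2, behavior_rate = 1)
  lambda <- 4 * (2 + 1)
  counts <- withr::with_seed(88, vapply(1:400, function(r)
    simulate_period(p, m, seed = NULL)$n_steps, numeric(1)))
  expect_equal(mean(counts), lambda, tolerance = 0.08)
  # chi-square goodness of fit against the Poisson reference
  br <- c(-0.5, stats::qpois(seq(0.1, 0.9, by = 0.2), lambda), Inf)
  obs <- table(cut(counts, br))
  pr <- diff(stats::ppois(c(-1, stats::qpois(seq(0.1, 0.9, by = 0.2),
                                             lambda), Inf), lambda))
  gof <- suppressWarnings(stats::chisq.test(obs, p = pr, rescale.p = TRUE))
  expect_gt(gof$p.value, 0.001)
})

test_that("the zero-utility toggle chain mixes to density one half", {
  # with all beta = 0 every tie configuration is equally likely at
  # stationarity, so expected density is 0.5
  n <- 4
  x0 <- matrix(0, n, n)
  p <- school_panel("s", x0, x0, rep(2, n), rep(2, n))
  m <- density_model(0, rate = 25)  # ~100 events: ample mixing at n = 4
  dens <- withr::with_seed(314, vapply(1:400, function(r) {
    st <- simulate_period(p, m, seed = NULL)
    sum(st$ties) / (n * (n - 1))
  }, numeric(1)))
  expect_equal(mean(dens), 0.5, tolerance = 0.025)
})

test_that("simulated target replicates are independent of replicate count", {
  cfg <- recovery_config(25L)
  panel <- generate_school_panel(cfg, 1, seed = 33)
  m <- recovery_model()
  t5 <- simulate_targets(panel, m, 5, seed = 99)
  t2 <- simulate_targets(panel, m, 2, seed = 99)
  expect_equal(t5[1:2, ], t2)
  expect_equal(colnames(t5), names(parameters(m)))
})

test_that("simulated target means match observed targets at the generating theta", {
  # model self-consistency: at theta_true the moment equations hold in
  # expectation, so replicate means sit within Monte Carlo error of the
  # observed wave-2 targets (averaged over panels to damp draw noise)
  m <- recovery_model()
  cfg <- recovery_config(40L)
  tstats <- withr::with_seed(7, sapply(1:6, function(k) {
    panel <- generate_school_panel(cfg, 1, seed = 5000 + k)
    s_obs <- observed_targets(panel, m)
    tg <- simulate_targets(panel, m, 80, seed = 60 + k)
    (colMeans(tg) - s_obs) / apply(tg, 2, stats::sd)
  }))
  expect_true(all(abs(rowMeans(tstats)) < 3 / sqrt(6) + 0.5))
})
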