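# Effect catalog: hand examples, brute-force oracle, invariances.

test_that("structural statistics match hand-enumerated examples", {
  cen <- manual_centering(c(1, 2, 3))
  cov <- data.frame()
  ties <- matrix(0, 3, 3); ties[1, 2] <- ties[2, 1] <- ties[2, 3] <- 1
  expect_equal(network_effect_statistic(saom_effect("density"), 2,
                                        ties, c(1, 2, 3), cov, cen), 2)
  expect_equal(network_effect_statistic(saom_effect("reciprocity"), 2,
                                        ties, c(1, 2, 3), cov, cen), 1)
  tt <- matrix(0, 3, 3); tt[1, 2] <- tt[2, 3] <- tt[1, 3] <- 1
  expect_equal(network_effect_statistic(saom_effect("transitive_triplets"),
                                        1, tt, c(1, 2, 3), cov, cen), 1)
  cyc <- matrix(0, 3, 3); cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 1
  expect_equal(network_effect_statistic(saom_effect("three_cycles"), 1,
                                        cyc, c(1, 2, 3), cov, cen), 1)
})

test_that("similarity scores follow 1 - |vi - vj| / range", {
  # alcohol levels 1 vs 6 are maximally different: similarity 0
  expect_equal(sim_score(1, 6, 5), 0)
  expect_equal(sim_score(2, 4, 5), 0.6)
  # symmetry, range, identity
  withr::with_seed(3, {
    v <- sample(1:6, 30, replace = TRUE)
    for (k in 1:30) {
      a <- sample(30, 1); b <- sample(30, 1)
      s_ab <- sim_score(v[a], v[b], 5)
      expect_equal(s_ab, sim_score(v[b], v[a], 5))
      expect_true(s_ab >= 0 && s_ab <= 1)
      expect_equal(s_ab == 1, v[a] == v[b])
    }
  })
})

test_that("every network statistic matches brute-force enumeration on random graphs", {
  specs <- list(
    list(eff = saom_effect("density"), name = "density"),
    list(eff = saom_effect("reciprocity"), name = "reciprocity"),
    list(eff = saom_effect("transitive_triplets"),
         name = "transitive_triplets"),
    list(eff = saom_effect("three_cycles"), name = "three_cycles"),
    list(eff = saom_effect("indegree_popularity"),
         name = "indegree_popularity"),
    list(eff = saom_effect("outdegree_popularity"),
         name = "outdegree_popularity"),
    list(eff = saom_effect("outdegree_activity"),
         name = "outdegree_activity"),
    list(eff = saom_effect("ego", "v"), name = "ego"),
    list(eff = saom_effect("alter", "v"), name = "alter"),
    list(eff = saom_effect("similarity", "v"), name = "similarity"),
    list(eff = saom_effect("same", "v"), name = "same")
  )
  withr::with_seed(20240701, {
    for (g in 1:220) {
      n <- sample(3:7, 1)
      x <- random_digraph(n, stats::runif(1, 0.15, 0.6))
      z <- sample(1:6, n, replace = TRUE)
      v <- sample(1:4, n, replace = TRUE)
      cen <- manual_centering(z, list(v = v))
      if (cen$range$v == 0) next
      cov <- data.frame(v = v)
      i <- sample(n, 1)
      for (sp in specs) {
        got <- network_effect_statistic(sp$eff, i, x, z, cov, cen)
        want <- brute_network_stat(
          sp$name, i, x, z, v,
          list(mean_v = cen$mean$v, range_v = cen$range$v,
               sim_mean_v = cen$sim_mean$v))
        expect_equal(got, want,
                     info = paste(sp$name, "graph", g, "actor", i))
      }
    }
  })
})

test_that("statistics are equivariant under actor relabeling", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      n <- sample(4:7, 1)
      x <- random_digraph(n, 0.4)
      z <- sample(1:6, n, replace = TRUE)
      v <- stats::runif(n, 12, 18)
      cen <- manual_centering(z, list(v = v))
      perm <- sample(n)
      xp <- x[perm, perm]
      zp <- z[perm]
      vp <- v[perm]
      cov <- data.frame(v = v); covp <- data.frame(v = vp)
      for (nm in list(saom_effect("transitive_triplets"),
                      saom_effect("indegree_popularity"),
                      saom_effect("similarity", "v"))) {
        i <- sample(n, 1)
        expect_equal(
          network_effect_statistic(nm, i, x, z, cov, cen),
          network_effect_statistic(nm, which(perm == i), xp, zp, covp, cen))
      }
    }
  })
})

test_that("behavior statistics follow the catalog conventions", {
  x <- matrix(0, 3, 3); x[1, 2] <- x[1, 3] <- 1
  cov <- data.frame(age = c(14, 15, 16))
  # z_i at the mean: every shape statistic vanishes
  cen <- manual_centering(c(2, 2, 2), list(age = cov$age))
  for (e in list(saom_effect("linear_shape"),
                 saom_effect("quadratic_shape"),
                 saom_effect("average_alter"),
                 saom_effect("covariate", "age")))
    expect_equal(behavior_effect_statistic(e, 1, x, c(2, 2, 2), cov, cen), 0)
  # isolate: average-alter defined as 0
  cen2 <- manual_centering(c(4, 2, 2), list(age = cov$age))
  expect_equal(behavior_effect_statistic(saom_effect("average_alter"), 2,
                                         x, c(4, 2, 2), cov, cen2), 0)
  # centered z_i = 1 with two friends at centered (1, 3):
  # 1 * mean(1, 3) = 2
  cen3 <- structure(list(mean = list(alcohol = 3), range = list(alcohol = 5),
                         sim_mean = list(alcohol = 0), z_mean = 3,
                         z_range = 5), class = "saom_centering")
  z <- c(4, 4, 6)  # centered: 1, 1, 3
  expect_equal(behavior_effect_statistic(saom_effect("average_alter"), 1,
                                         x, z, cov, cen3), 2)
})

test_that("centering constants are fixed per school and match arithmetic", {
  p <- tiny_panel()
  cen <- compute_centering(p)
  expect_equal(cen$mean$male, 0.5)
  expect_equal(cen$range$alcohol, 5)
  expect_equal(cen$z_mean, mean(p$z1))
  # mean similarity over ordered pairs at wave 1, by direct loop
  ms <- manual_centering(p$z1)$sim_mean$alcohol
  expect_equal(cen$sim_mean$alcohol, ms)

  cov4 <- data.frame(v = c(0, 1, 1, 1))
  q <- school_panel("s", matrix(0, 4, 4), matrix(0, 4, 4),
                    rep(1, 4), rep(1, 4), covariates = cov4)
  expect_equal(compute_centering(q)$mean$v, 0.75)
  expect_equal(compute_centering(q)$z_mean, 1)
})

test_that("declaration errors are caught", {
  expect_error(saom_effect("not_a_stat"), "unknown effect")
  expect_error(saom_effect("similarity"), "requires a covariate")
  expect_error(saom_effect("density", covariate = "age"),
               "does not take")
  cen <- manual_centering(c(1, 2), list(v = c(3, 3)))
  expect_error(
    network_effect_statistic(saom_effect("similarity", "v"), 1,
                             matrix(0, 2, 2), c(1, 2),
                             data.frame(v = c(3, 3)), cen),
    "zero-range")
})

test_that("model specification enforces required effects and rates", {
  expect_error(saom_model(list(saom_effect("reciprocity"))), "density")
  expect_error(saom_model(list(saom_effect("density")),
                          list(saom_effect("average_alter"))),
               "linear and quadratic")
  expect_error(saom_model(list(saom_effect("density")),
                          network_rate = 0), "positive")
  m <- saom_model(network_selection_effects(),
                  behavior_evolution_effects())
  expect_length(m$network_effects, 19)
  expect_length(m$behavior_effects, 8)
  th <- parameters(m)
  expect_length(th, 2 + 19 + 8)
  m2 <- set_parameters(m, th + 0.5)
  expect_equal(parameters(m2), th + 0.5)
})
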