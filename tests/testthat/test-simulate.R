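test_that("scenario defaults encode the documented study conditions", {
  cfg <- scenario_defaults("sim1", "F", seed = 1)
  expect_identical(c(cfg$n1, cfg$n2, cfg$n0, cfg$p1, cfg$p2),
                   c(250L, 250L, 500L, 8L, 8L))
  expect_identical(cfg$block_kappa, 0)
  expect_gt(scenario_defaults("sim2", "B")$lambda,
            scenario_defaults("sim2", "F")$lambda)
  expect_error(scenario_defaults("sim1", "X"), "scenario")
  expect_error(scenario_defaults("sim1", "F", lambda = 0.5), "unknown parameter")
  expect_error(scenario_defaults("sim2", "F", p1 = 1), "at least 2")
  # overrides land in the config
  expect_identical(scenario_defaults("sim2", "F", lambda = 0.9)$lambda, 0.9)
})

test_that("simulation is deterministic given the seed", {
  cfg <- scenario_defaults("sim2", "N", seed = 123, n1 = 40, n2 = 40,
                           n0 = 40, p1 = 4, p2 = 4)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_scenario(scenario_defaults("sim2", "N", seed = 124,
                                            n1 = 40, n2 = 40, n0 = 40,
                                            p1 = 4, p2 = 4))
  expect_false(identical(s1$matrix$values, s3$matrix$values))
})

test_that("generated matrices carry the declared structure and truth", {
  cfg <- scenario_defaults("sim1", "N", seed = 5, n1 = 30, n2 = 20, n0 = 10)
  sim <- simulate_scenario(cfg)
  expect_identical(dim(sim$matrix), c(60L, 16L))
  expect_identical(as.vector(table(sim$truth)[c("A", "B", "none")]),
                   c(30L, 20L, 10L))
  expect_identical(names(sim$truth), rownames(sim$matrix$values))
  expect_identical(unname(sim$matrix$conditions),
                   rep(c("A", "B"), each = 8))
})

test_that("parameter domains are enforced", {
  cfg <- scenario_defaults("sim2", "F", seed = 1)
  cfg$lambda <- 1.5
  expect_error(simulate_sim2(cfg), "lambda")
  cfg1 <- scenario_defaults("sim1", "F", seed = 1)
  cfg1$block_kappa <- -0.1
  expect_error(simulate_sim1(cfg1), "block_kappa")
  cfg1$block_kappa <- 0
  cfg1$block_rho <- -0.5  # not positive definite for p = 8
  expect_error(simulate_sim1(cfg1), "positive definite")
  expect_error(simulate_sim1(scenario_defaults("sim2", "F")), "sim1")
  expect_error(simulate_sim2(scenario_defaults("sim1", "F")), "sim2")
})

test_that("total leakage collapses the two condition directions", {
  sim <- simulate_scenario(scenario_defaults("sim2", "B", seed = 3,
                                             lambda = 1, leak_sd = 0))
  sp <- fit_pca(sim$matrix)
  d <- build_directions(sp)
  cosv <- abs(sum(d$vectors[1, ] * d$vectors[2, ])) /
    sqrt(sum(d$vectors[1, ]^2) * sum(d$vectors[2, ]^2))
  expect_gt(cosv, 0.9)
})

test_that("confound warnings separate the favorable and very-bad regimes", {
  warn_at <- function(sc) {
    mean(vapply(1:20, function(s) {
      sim <- simulate_scenario(scenario_defaults("sim2", sc, seed = 2000 + s))
      sp <- fit_pca(sim$matrix)
      check_direction_coherence(sp, build_directions(sp))$warn_confound
    }, logical(1)))
  }
  expect_lt(warn_at("F"), 0.05)
  expect_gt(warn_at("B"), 0.5)
})

test_that("identity-correlation blocks leave conditions unstructured", {
  # independence limit: no block effect, no background module
  cfg <- scenario_defaults("sim1", "F", seed = 10, n1 = 150, n2 = 150,
                           n0 = 0, block_mean = 0, block_rho = 0,
                           base_jitter = 0, null_shared_frac = 0)
  sim <- simulate_scenario(cfg)
  v <- sim$matrix$values
  within <- cor(v[, 1:8])
  expect_lt(mean(abs(within[upper.tri(within)])), 0.08)
})

test_that("marginals stay normal when effects are switched off", {
  fails <- 0L
  for (s in 1:20) {
    cfg <- scenario_defaults("sim1", "F", seed = 300 + s, n1 = 60, n2 = 60,
                             n0 = 0, block_mean = 0, block_rho = 0,
                             base_jitter = 0, null_shared_frac = 0, p1 = 3,
                             p2 = 3)
    sim <- simulate_scenario(cfg)
    p <- apply(sim$matrix$values, 2, function(col) shapiro.test(col)$p.value)
    fails <- fails + sum(p < 0.01)
  }
  expect_lte(fails / (20 * 6), 0.05)
})

test_that("gene-group separation degrades monotonically across scenarios", {
  sil <- function(sc) {
    mean(vapply(1:20, function(s) {
      sim <- simulate_scenario(scenario_defaults("sim1", sc, seed = 400 + s))
      sp <- fit_pca(sim$matrix)
      de <- sim$truth != "none"
      sc2 <- sp$gene_scores[de, ]
      si <- cluster::silhouette(as.integer(factor(sim$truth[de])), dist(sc2))
      mean(si[, "sil_width"])
    }, numeric(1)))
  }
  s <- vapply(c("F", "N", "U", "B"), sil, numeric(1))
  expect_gt(s[["F"]], 0.5)        # favorable: groups separate on the plane
  expect_true(all(diff(s) < 0))   # confusion strictly increases F -> B
})

test_that("replicate confusion grows monotonically in the scenario axis", {
  coss <- vapply(c("F", "N", "U", "B"), function(sc) {
    mean(vapply(1:20, function(s) {
      sim <- simulate_scenario(scenario_defaults("sim2", sc, seed = 500 + s))
      sp <- fit_pca(sim$matrix)
      d <- build_directions(sp)
      abs(sum(d$vectors[1, ] * d$vectors[2, ])) /
        sqrt(sum(d$vectors[1, ]^2) * sum(d$vectors[2, ]^2))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(coss) > 0))
})

test_that("simulations export to the standard text formats with provenance", {
  sim <- simulate_scenario(scenario_defaults("sim1", "F", seed = 1, n1 = 10,
                                             n2 = 10, n0 = 5, p1 = 3, p2 = 3))
  mp <- tempfile(); dp <- tempfile(); tp <- tempfile(); cp <- tempfile()
  write_simulation(sim, mp, dp, tp, cp)
  back <- read_expression(mp, dp)
  expect_equal(back$values, sim$matrix$values, tolerance = 1e-9)
  tr <- read.table(tp, header = TRUE, sep = "\t")
  expect_identical(nrow(tr), 25L)
  cfg <- jsonlite::read_json(cp)
  expect_identical(cfg$mode, "sim1")
  expect_identical(cfg$seed, 1L)
})
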