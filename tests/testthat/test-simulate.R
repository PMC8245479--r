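test_that("simulation config validation rejects impossible settings", {
  expect_error(sim_config(n_parents = 1), "n_parents")
  expect_error(sim_config(maf_floor = 0.5), "maf_floor")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(h2_per_harvest = c(0.5, 1.2)), "h2")
  expect_error(sim_config(h2_per_harvest = c(0, 0.5)), "h2")
  bad <- matrix(c(1, 0.9, 0.2, 1), 2, 2)
  expect_error(sim_config(h2_per_harvest = c(0.3, 0.3), genetic_corr = bad),
               "symmetric")
  sing <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(sim_config(h2_per_harvest = c(0.3, 0.3), genetic_corr = sing),
               "semi-definite")
})

test_that("genotype simulation is deterministic and honours missing_rate", {
  cfg <- sim_config(n_parents = 10, n_progeny = 50, n_markers = 80,
                    n_qtl_sim = 40, h2_per_harvest = 0.3, n_blocks = 2,
                    harvest_means = 0, missing_rate = 0, seed = 21)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$genotypes, g2$genotypes)
  expect_false(anyNA(g1$genotypes))
  expect_true(all(g1$genotypes %in% 0:2))

  cfg$missing_rate <- 0.1
  g3 <- simulate_genotypes(cfg)
  expect_gt(mean(is.na(g3$genotypes)), 0.05)
  expect_lt(mean(is.na(g3$genotypes)), 0.15)
  # the unmasked matrix is what the mask was applied to
  expect_identical(g3$complete[!is.na(g3$genotypes)],
                   g3$genotypes[!is.na(g3$genotypes)])
})

test_that("every progeny descends from two parents of the crossing plan", {
  pop <- quick_pop(n = 90, m = 50, qtl = 30, seed = 2)
  ped <- pop$pedigree
  expect_equal(nrow(ped), 90)
  expect_true(all(ped$sire %in% rownames(pop$parents)))
  expect_true(all(ped$dam %in% rownames(pop$parents)))
  expect_true(all(ped$sire != ped$dam))
  # round-robin plan spreads progeny as evenly as integer division allows
  fam <- table(paste(ped$sire, ped$dam))
  expect_lte(max(fam) - min(fam), 1)
  # Mendelian consistency: opposite homozygous parents give heterozygotes
  for (i in sample(nrow(ped), 20)) {
    s <- pop$parents[ped$sire[i], ]
    d <- pop$parents[ped$dam[i], ]
    both0 <- s == 0 & d == 0
    both2 <- s == 2 & d == 2
    opp <- (s == 0 & d == 2) | (s == 2 & d == 0)
    kid <- pop$genotypes_complete[ped$progeny[i], ]
    expect_true(all(kid[both0] == 0))
    expect_true(all(kid[both2] == 2))
    expect_true(all(kid[opp] == 1))
  }
})

test_that("progeny allele frequencies track the parental mean frequency", {
  cfg <- sim_config(n_parents = 40, n_progeny = 10000, n_markers = 200,
                    n_qtl_sim = 100, h2_per_harvest = 0.3, n_blocks = 1,
                    harvest_means = 0, maf_floor = 0.05, missing_rate = 0,
                    seed = 17)
  g <- simulate_genotypes(cfg)
  parent_freq <- colMeans(g$parents) / 2
  progeny_freq <- colMeans(g$complete) / 2
  frac_close <- mean(abs(progeny_freq - parent_freq) <= 0.03)
  expect_gte(frac_close, 0.95)
})

test_that("noise-free phenotypes equal breeding value plus harvest mean", {
  cfg <- sim_config(n_parents = 12, n_progeny = 60, n_markers = 100,
                    n_qtl_sim = 50, h2_per_harvest = c(1, 1), n_blocks = 3,
                    block_sd = 0, harvest_means = c(10, 20),
                    missing_rate = 0, seed = 4)
  pop <- simulate_population(cfg)
  ph <- pop$phenotypes
  tbv <- pop$truth$true_breeding_values
  expected <- cfg$harvest_means[ph$harvest] +
    tbv[cbind(match(ph$individual, rownames(tbv)), ph$harvest)]
  expect_equal(ph$value, expected, tolerance = 1e-12)
})

test_that("uncorrelated harvests give uncorrelated true breeding values", {
  # realized genetic correlation carries sampling noise from the causal
  # effect draws and from family structure, so calibration is checked on
  # the mean across seeds
  r <- sapply(1:5, function(s) {
    cfg <- sim_config(n_parents = 40, n_progeny = 2000, n_markers = 300,
                      n_qtl_sim = 250, h2_per_harvest = c(0.3, 0.3),
                      genetic_corr = diag(2), n_blocks = 1,
                      harvest_means = 0, missing_rate = 0, seed = 30 + s)
    tbv <- simulate_population(cfg)$truth$true_breeding_values
    cor(tbv[, 1], tbv[, 2])
  })
  expect_lt(abs(mean(r)), 0.1)
})

test_that("cross-harvest correlation of breeding values matches the target", {
  corr <- matrix(c(1, 0.3, 0.3, 0.3, 1, 0.8, 0.3, 0.8, 1), 3, 3)
  realized <- matrix(0, 3, 3)
  for (s in 1:6) {
    cfg <- sim_config(n_parents = 60, n_progeny = 2000, n_markers = 700,
                      n_qtl_sim = 600, h2_per_harvest = c(0.3, 0.3, 0.3),
                      genetic_corr = corr, n_blocks = 1, harvest_means = 0,
                      missing_rate = 0, seed = 12 + s)
    pop <- simulate_population(cfg)
    realized <- realized + cor(pop$truth$true_breeding_values) / 6
  }
  expect_lt(max(abs(realized - corr)), 0.05)
})

test_that("realized single-record heritability matches its target", {
  cfg <- sim_config(n_parents = 40, n_progeny = 2000, n_markers = 300,
                    n_qtl_sim = 200, h2_per_harvest = 0.25, n_blocks = 1,
                    block_sd = 0, harvest_means = 0, missing_rate = 0,
                    seed = 8)
  pop <- simulate_population(cfg)
  tbv <- pop$truth$true_breeding_values[, 1]
  mu <- tapply(pop$phenotypes$value, pop$phenotypes$individual, mean)
  h2_real <- var(tbv) / var(mu[names(tbv)])
  expect_lt(abs(h2_real - 0.25), 0.04)
})

test_that("heritability calibration holds on average across seeds", {
  targets <- c(0.2, 0.3)
  h2_hat <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    cfg <- sim_config(n_parents = 30, n_progeny = 1000, n_markers = 200,
                      n_qtl_sim = 150, h2_per_harvest = targets,
                      genetic_corr = diag(2), n_blocks = 2, block_sd = 2,
                      harvest_means = c(0, 0), missing_rate = 0, seed = 100 + s)
    pop <- simulate_population(cfg)
    tbv <- pop$truth$true_breeding_values
    for (h in 1:2) {
      ph <- pop$phenotypes[pop$phenotypes$harvest == h, ]
      resid <- ph$value -
        tbv[cbind(match(ph$individual, rownames(tbv)), h)] -
        pop$truth$block_effects[cbind(h, ph$block)]
      vg <- var(tbv[, h])
      h2_hat[s, h] <- vg / (vg + var(resid))
    }
  }
  expect_lt(abs(mean(h2_hat[, 1]) - 0.2), 0.03)
  expect_lt(abs(mean(h2_hat[, 2]) - 0.3), 0.03)
})

test_that("causal effects exist only at causal markers", {
  pop <- quick_pop(n = 50, m = 80, qtl = 30, seed = 6)
  eff <- pop$truth$causal_effects
  expect_equal(nrow(eff), 30)
  expect_setequal(rownames(eff), pop$truth$causal_markers)
  expect_true(all(pop$truth$causal_markers %in% colnames(pop$genotypes)))
  # breeding values are reproducible from dosages and causal effects alone,
  # confirming non-causal markers carry zero effect
  tbv <- pop$genotypes_complete[, rownames(eff)] %*% eff
  expect_equal(unname(tbv), unname(pop$truth$true_breeding_values),
               tolerance = 1e-12)
})
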