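test_that("mixed-model solution matches the block-absorbed ridge oracle", {
  inst <- random_instance(n = 30, m = 50, p = 2, seed = 11)
  lambda <- 2
  sol <- solve_mme(inst$y, inst$X, inst$Z, ridge = lambda)

  # oracle: absorb the fixed effects, then dense ridge closed form
  X <- inst$X; Z <- inst$Z; y <- inst$y
  Mx <- diag(nrow(X)) - X %*% solve(crossprod(X), t(X))
  a_oracle <- solve(crossprod(Z, Mx %*% Z) + diag(lambda, ncol(Z)),
                    crossprod(Z, Mx %*% y))
  expect_lt(max(abs(sol$effects - drop(a_oracle))), 1e-8)

  # and the full dense block solve reproduces both blocks
  Mfull <- rbind(cbind(crossprod(X), crossprod(X, Z)),
                 cbind(crossprod(Z, X), crossprod(Z) + diag(lambda, ncol(Z))))
  full <- solve(Mfull, c(crossprod(X, y), crossprod(Z, y)))
  expect_lt(max(abs(c(sol$beta, sol$effects) - full)), 1e-8)

  # plugging the solution back reproduces the right-hand side
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  recon <- Mfull %*% c(sol$beta, sol$effects)
  expect_lt(max(abs(recon - rhs)) / max(abs(rhs)), 1e-8)
})

test_that("extreme shrinkage and degenerate responses behave as limits", {
  inst <- random_instance(n = 40, m = 60, seed = 12)
  sol <- solve_mme(inst$y, inst$X, inst$Z, ridge = 1e12)
  expect_lt(max(abs(sol$effects)), 1e-6)

  ycon <- rep(3.25, 40)
  solc <- solve_mme(ycon, matrix(1, 40, 1), inst$Z, ridge = 5)
  expect_lt(max(abs(solc$effects)), 1e-8)
  expect_equal(unname(solc$beta), 3.25, tolerance = 1e-8)
})

test_that("shrinkage norm is non-increasing in the ridge parameter", {
  inst <- random_instance(n = 40, m = 80, seed = 13)
  norms <- sapply(c(0.1, 1, 10, 100, 1000), function(l) {
    sum(solve_mme(inst$y, inst$X, inst$Z, ridge = l)$effects^2)
  })
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("RR-BLUP breeding values equal the GBLUP formulation", {
  inst <- random_instance(n = 50, m = 100, p = 1, seed = 14)
  sigma2_g <- 2; sigma2_e <- 1
  m <- ncol(inst$Z)
  sol <- solve_mme(inst$y, inst$X, inst$Z, ridge = sigma2_e * m / sigma2_g)
  gebv_rr <- drop(inst$Z %*% sol$effects)

  # individual-level BLUP with genomic covariance G = ZZ' sigma2_m
  G <- tcrossprod(inst$Z) * sigma2_g / m
  V <- G + diag(sigma2_e, nrow(G))
  Vi <- solve(V)
  beta <- solve(crossprod(inst$X, Vi %*% inst$X),
                crossprod(inst$X, Vi %*% inst$y))
  gebv_gb <- drop(G %*% Vi %*% (inst$y - inst$X %*% beta))
  expect_lt(max(abs(gebv_rr - gebv_gb)), 1e-6)
})

test_that("GEBV are invariant to marker and individual ordering", {
  pop <- quick_pop(n = 60, m = 80, qtl = 50, seed = 15)
  ph <- pop$phenotypes[pop$phenotypes$harvest == 1, ]
  f1 <- rrblup(value ~ factor(block), data = ph, genotypes = pop$genotypes)

  perm_m <- sample(ncol(pop$genotypes))
  perm_i <- sample(nrow(pop$genotypes))
  f2 <- rrblup(value ~ factor(block), data = ph,
               genotypes = pop$genotypes[perm_i, perm_m])
  expect_equal(f1$gebv, f2$gebv[names(f1$gebv)], tolerance = 1e-8)
  expect_equal(f1$effects[colnames(pop$genotypes)],
               f2$effects[colnames(pop$genotypes)], tolerance = 1e-8)
})

test_that("predict_gebv agrees with an elementwise double loop", {
  set.seed(16)
  Z <- matrix(rnorm(20 * 40), 20, 40,
              dimnames = list(sprintf("I%02d", 1:20), sprintf("M%02d", 1:40)))
  a <- setNames(rnorm(40), colnames(Z))
  g <- predict_gebv(Z, a)
  loop <- numeric(20)
  for (j in 1:20) {
    acc <- 0
    for (i in 1:40) acc <- acc + Z[j, i] * a[i]
    loop[j] <- acc
  }
  expect_equal(unname(g), loop, tolerance = 1e-12)

  # trivial cases
  expect_true(all(predict_gebv(Z, setNames(rep(0, 40), colnames(Z))) == 0))
  z1 <- matrix(c(-1, 0, 1), 3, 1, dimnames = list(NULL, "M1"))
  expect_equal(unname(predict_gebv(z1, c(M1 = 1))), c(-1, 0, 1))
})

test_that("marker-id mismatches are reported, not silently aligned", {
  Z <- matrix(0, 3, 3, dimnames = list(NULL, c("A", "B", "C")))
  a <- c(A = 1, B = 2, D = 3)
  expect_error(predict_gebv(Z, a), "only in Z.*C.*only in effects.*D")
})

test_that("rank-deficient fixed designs fail naming the aliased columns", {
  inst <- random_instance(n = 30, m = 20, seed = 17)
  Xbad <- cbind(inst$X, dup = inst$X[, 2])
  expect_error(solve_mme(inst$y, Xbad, inst$Z, ridge = 1), "dup")
  expect_error(solve_mme(inst$y, inst$X, inst$Z, ridge = 0), "positive")
})

test_that("REML recovers the noise-free and pure-noise limits", {
  # heritability one: phenotype is exactly the breeding value
  pop <- quick_pop(n = 300, m = 150, qtl = 150, h2 = c(1), blocks = 1,
                   block_sd = 0, means = 0, seed = 18)
  ph <- pop$phenotypes
  fit <- rrblup(value ~ 1, data = ph, genotypes = pop$genotypes)
  expect_lt(fit$varcomp$sigma2_e / fit$varcomp$sigma2_p, 0.05)

  # pure noise: genetic fraction near zero
  set.seed(19)
  noise <- data.frame(individual = rownames(pop$genotypes)[1:300],
                      value = rnorm(300))
  Z <- standardize_markers(pop$genotypes)
  vc <- estimate_variance_components(noise$value, matrix(1, 300, 1),
                                     Z[noise$individual, ])
  expect_lt(vc$sigma2_g / vc$sigma2_p, 0.1)
})

test_that("REML point estimates agree between the two entry points", {
  pop <- quick_pop(n = 120, m = 100, qtl = 60, seed = 20)
  ph <- pop$phenotypes[pop$phenotypes$harvest == 1, ]
  fit <- rrblup(value ~ factor(block), data = ph, genotypes = pop$genotypes)

  uids <- sort(unique(ph$individual))
  Z <- standardize_markers(pop$genotypes[uids, ])
  X <- model.matrix(~ factor(block), ph)
  vc <- estimate_variance_components(ph$value, X, Z[ph$individual, ])
  expect_equal(fit$varcomp$sigma2_g, vc$sigma2_g, tolerance = 1e-6)
  expect_equal(fit$varcomp$sigma2_e, vc$sigma2_e, tolerance = 1e-6)
  expect_true(is.data.frame(vc$trace) && nrow(vc$trace) > 5)
})

test_that("new individuals are scored on the frozen training scale", {
  pop <- quick_pop(n = 80, m = 60, qtl = 40, seed = 22)
  ph <- pop$phenotypes[pop$phenotypes$harvest == 1 &
                         pop$phenotypes$individual %in%
                           rownames(pop$genotypes)[1:60], ]
  fit <- rrblup(value ~ factor(block), data = ph,
                genotypes = pop$genotypes[1:60, ])
  newg <- pop$genotypes[61:80, ]
  pred <- predict(fit, newdata = newg)
  Znew <- standardize_markers(newg, center = fit$center, scale = fit$scale)
  expect_equal(pred, predict_gebv(Znew, fit$effects), tolerance = 1e-12)
  # training GEBV returned unchanged without newdata
  expect_identical(predict(fit), fit$gebv)
})

test_that("accessor methods expose the fitted model components", {
  pop <- quick_pop(n = 60, m = 50, qtl = 30, seed = 23)
  ph <- pop$phenotypes[pop$phenotypes$harvest == 1, ]
  fit <- rrblup(value ~ factor(block), data = ph, genotypes = pop$genotypes)
  expect_length(coef(fit), 50)
  expect_length(coef(fit, "fixed"), 2)
  expect_equal(unname(fitted(fit) + residuals(fit)), ph$value,
               tolerance = 1e-10)
  expect_output(print(fit), "RR-BLUP")
  expect_output(print(summary(fit)), "Variance components")
})
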