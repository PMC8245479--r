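# Shared fixtures, built in code.

# 20 x 5 toy dosage matrix with hand-countable QC outcomes:
#   M1 clean, MAF 0.5          -> retained at (0.95, 0.04)
#   M2 one missing call of 20  -> call rate exactly 0.95, retained
#   M3 all-missing-but-one, observed call 0 -> fails call rate AND MAF
#   M4 monomorphic (all 0)     -> fails MAF
#   M5 clean, intermediate MAF -> retained
toy_qc_matrix <- function() {
  m <- cbind(
    M1 = rep(c(0, 2), 10),
    M2 = c(NA, rep(c(1, 2), c(10, 9))),
    M3 = c(0, rep(NA, 19)),
    M4 = rep(0, 20),
    M5 = rep(c(0, 1, 2, 1), 5)
  )
  rownames(m) <- sprintf("I%02d", 1:20)
  m
}

# small synthetic population for fast model tests; maf_floor is kept high
# so no marker drifts to fixation and the matrices can be standardized
# without a QC pass
quick_pop <- function(n = 160, m = 200, qtl = 120, h2 = c(0.3, 0.3),
                      corr = NULL, blocks = 2, seed = 1,
                      missing_rate = 0, block_sd = 1,
                      means = c(100, 200)) {
  cfg <- sim_config(
    n_parents = 30, maf_floor = 0.2,
    n_progeny = n, n_markers = m, n_qtl_sim = qtl,
    h2_per_harvest = h2, genetic_corr = corr, n_blocks = blocks,
    block_sd = block_sd, missing_rate = missing_rate,
    harvest_means = rep_len(means, length(h2)), seed = seed
  )
  simulate_population(cfg)
}

# random dense RR-BLUP instance for algebra tests
random_instance <- function(n = 50, m = 100, p = 2, seed = 42) {
  set.seed(seed)
  Z <- matrix(rnorm(n * m), n, m,
              dimnames = list(sprintf("I%03d", 1:n), sprintf("M%03d", 1:m)))
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (p > 1) {
    X <- cbind(X, matrix(rnorm(n * (p - 1)), n, p - 1,
                         dimnames = list(NULL, paste0("x", seq_len(p - 1)))))
  }
  y <- rnorm(n)
  list(y = y, X = X, Z = Z)
}
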