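#' Simulation settings for a synthetic breeding population
#'
#' Builds and validates the configuration for the synthetic-data generator.
#' The defaults emulate a perennial-crop breeding trial: 386 progeny from
#' crosses among 42 parents, genotyped at 811 biallelic SNPs, with grain
#' yield recorded over three harvests in a randomized block design with six
#' replicates. Per-harvest narrow-sense heritabilities default to 0.18,
#' 0.19 and 0.20 on the plot-record scale, and the genetic correlation
#' between harvests defaults to 0.3 between the first harvest and the later
#' two and 0.8 between harvests two and three, so that early-harvest models
#' transfer poorly and late-harvest models transfer well.
#'
#' @param n_parents number of parents in the crossing population.
#' @param n_progeny number of genotyped and phenotyped progeny.
#' @param n_markers number of biallelic SNP markers.
#' @param n_qtl_sim number of causal markers (a subset of the panel).
#' @param h2_per_harvest narrow-sense heritability of single plot records,
#'   one value per harvest, each in (0, 1].
#' @param genetic_corr harvest-by-harvest genetic correlation matrix
#'   (symmetric, positive semi-definite, unit diagonal).
#' @param n_harvests number of harvests.
#' @param n_blocks number of replicate blocks.
#' @param block_sd standard deviation of block effects, trait units.
#' @param maf_floor lower bound for simulated parental allele frequencies;
#'   frequencies are drawn uniformly on \[maf_floor, 1 - maf_floor\].
#' @param missing_rate probability that a genotype call is masked missing.
#' @param harvest_means trait mean per harvest (g per plant).
#' @param seed integer seed; every run with the same config is identical.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_parents = 42L,
                       n_progeny = 386L,
                       n_markers = 811L,
                       n_qtl_sim = 400L,
                       h2_per_harvest = c(0.18, 0.19, 0.20),
                       genetic_corr = NULL,
                       n_harvests = length(h2_per_harvest),
                       n_blocks = 6L,
                       block_sd = 10,
                       maf_floor = 0.05,
                       missing_rate = 0.02,
                       harvest_means = c(173.76, 760.85, 1075.52),
                       seed = 1L) {
  if (is.null(genetic_corr)) {
    genetic_corr <- diag(n_harvests)
    if (n_harvests == 3L) {
      genetic_corr[1, 2] <- genetic_corr[2, 1] <- 0.3
      genetic_corr[1, 3] <- genetic_corr[3, 1] <- 0.3
      genetic_corr[2, 3] <- genetic_corr[3, 2] <- 0.8
    } else if (n_harvests == 2L) {
      genetic_corr[1, 2] <- genetic_corr[2, 1] <- 0.5
    }
  }
  harvest_means <- rep_len(harvest_means, n_harvests)
  h2_per_harvest <- rep_len(h2_per_harvest, n_harvests)

  cfg <- list(
    n_parents = as.integer(n_parents), n_progeny = as.integer(n_progeny),
    n_markers = as.integer(n_markers), n_qtl_sim = as.integer(n_qtl_sim),
    h2_per_harvest = h2_per_harvest, genetic_corr = genetic_corr,
    n_harvests = as.integer(n_harvests), n_blocks = as.integer(n_blocks),
    block_sd = block_sd, maf_floor = maf_floor,
    missing_rate = missing_rate, harvest_means = harvest_means,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_parents < 2L) stop("n_parents must be at least 2")
  for (fld in c("n_progeny", "n_markers", "n_qtl_sim", "n_harvests", "n_blocks")) {
    if (cfg[[fld]] < 1L) stop(sprintf("%s must be positive", fld))
  }
  if (cfg$n_qtl_sim > cfg$n_markers) stop("n_qtl_sim cannot exceed n_markers")
  if (cfg$maf_floor <= 0 || cfg$maf_floor >= 0.5) {
    stop("maf_floor must lie strictly between 0 and 0.5")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (any(cfg$h2_per_harvest <= 0 | cfg$h2_per_harvest > 1)) {
    stop("h2_per_harvest values must lie in (0, 1]")
  }
  G <- cfg$genetic_corr
  if (!is.matrix(G) || nrow(G) != cfg$n_harvests || ncol(G) != cfg$n_harvests) {
    stop("genetic_corr must be an n_harvests x n_harvests matrix")
  }
  if (max(abs(G - t(G))) > 1e-8) stop("genetic_corr must be symmetric")
  if (max(abs(diag(G) - 1)) > 1e-8) stop("genetic_corr must have unit diagonal")
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("genetic_corr must be positive semi-definite")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic breeding-population configuration\n")
  cat(sprintf("  %d progeny from %d parents; %d markers (%d causal)\n",
              x$n_progeny, x$n_parents, x$n_markers, x$n_qtl_sim))
  cat(sprintf("  %d harvest(s) x %d blocks; h2 = %s; missing rate %.3f\n",
              x$n_harvests, x$n_blocks,
              paste(format(x$h2_per_harvest), collapse = ", "),
              x$missing_rate))
  invisible(x)
}

#' Simulate genotypes for a multi-parent crossing population
#'
#' Parent genotypes are drawn marker-by-marker from Hardy-Weinberg
#' proportions at allele frequencies sampled uniformly on
#' \[maf_floor, 1 - maf_floor\]. Progeny are produced by Mendelian gamete
#' sampling (each parent transmits the alternate allele with probability
#' dosage/2) under a round-robin crossing plan that pairs parent i with
#' parent i + 1 cyclically and spreads progeny across crosses as evenly as
#' integer division allows. Genotype calls are then masked missing
#' independently at `missing_rate`. Linkage disequilibrium arises only from
#' family structure: loci are unlinked.
#'
#' @param config a [sim_config()].
#' @return A list with `genotypes` (progeny-by-marker dosage matrix with
#'   `NA` for masked calls), `complete` (the unmasked matrix),
#'   `parents` (parent dosage matrix), `pedigree` (data frame of progeny,
#'   sire, dam), and `allele_freq` (the parental allele frequencies drawn).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  np <- config$n_parents
  m  <- config$n_markers

  p <- runif(m, config$maf_floor, 1 - config$maf_floor)
  parents <- matrix(rbinom(np * m, 2L, rep(p, each = np)), nrow = np, ncol = m)
  marker_ids <- sprintf("M%04d", seq_len(m))
  parent_ids <- sprintf("P%03d", seq_len(np))
  dimnames(parents) <- list(parent_ids, marker_ids)

  # round-robin crossing plan: cross c mates parent c with parent c+1 (mod np)
  crosses <- cbind(sire = seq_len(np), dam = c(seq_len(np)[-1], 1L))
  cross_of <- rep_len(seq_len(np), config$n_progeny)

  n <- config$n_progeny
  sire_g <- parents[crosses[cross_of, "sire"], , drop = FALSE]
  dam_g  <- parents[crosses[cross_of, "dam"],  , drop = FALSE]
  gamete <- function(g) {
    matrix(rbinom(length(g), 1L, as.vector(g) / 2), nrow = nrow(g))
  }
  progeny <- gamete(sire_g) + gamete(dam_g)
  progeny_ids <- sprintf("I%04d", seq_len(n))
  dimnames(progeny) <- list(progeny_ids, marker_ids)

  observed <- progeny
  if (config$missing_rate > 0) {
    mask <- matrix(runif(n * m) < config$missing_rate, nrow = n)
    observed[mask] <- NA_integer_
  }

  list(
    genotypes = observed,
    complete = progeny,
    parents = parents,
    pedigree = data.frame(
      progeny = progeny_ids,
      sire = parent_ids[crosses[cross_of, "sire"]],
      dam = parent_ids[crosses[cross_of, "dam"]],
      stringsAsFactors = FALSE
    ),
    allele_freq = stats::setNames(p, marker_ids)
  )
}

#' Simulate multi-harvest phenotypes on top of simulated genotypes
#'
#' A random subset of `n_qtl_sim` markers is causal. Their additive effects
#' are drawn per marker from a multivariate normal across harvests with
#' correlation `genetic_corr`, so the true breeding values of the same
#' individuals are genetically correlated between harvests. The true
#' breeding value at a harvest is the dosage-weighted sum of causal
#' effects; residual variance is scaled per harvest so the narrow-sense
#' heritability of single plot records (genetic variance over genetic plus
#' residual variance; block effects are design effects and excluded from
#' the denominator) equals `h2_per_harvest`. One record is emitted per
#' individual x harvest x block, with block effects drawn once per
#' (harvest, block) at standard deviation `block_sd`.
#'
#' @param genotypes progeny dosage matrix; missing cells are imputed by the
#'   marker mean before computing breeding values.
#' @param config a [sim_config()].
#' @return A list with `phenotypes` (long data frame: individual, harvest,
#'   block, value), and `truth` (true breeding values, causal marker ids,
#'   causal effect matrix, realized genetic and residual variances).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  validate_sim_config(config)
  if (any(is.na(genotypes))) {
    genotypes <- impute_markers(genotypes)
  }
  set.seed(config$seed + 1L)
  n <- nrow(genotypes)
  H <- config$n_harvests

  causal <- sort(sample.int(config$n_markers, config$n_qtl_sim))
  # matrix square root tolerates a singular correlation (e.g. perfect
  # cross-harvest correlation), where Cholesky would fail
  eg <- eigen(config$genetic_corr, symmetric = TRUE)
  croot <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  effects <- matrix(stats::rnorm(config$n_qtl_sim * H), ncol = H) %*% croot
  rownames(effects) <- colnames(genotypes)[causal]

  tbv <- genotypes[, causal, drop = FALSE] %*% effects
  colnames(tbv) <- paste0("harvest", seq_len(H))

  var_g <- apply(tbv, 2, stats::var)
  var_e <- var_g * (1 - config$h2_per_harvest) / config$h2_per_harvest

  block_eff <- matrix(stats::rnorm(H * config$n_blocks, sd = config$block_sd),
                      nrow = H)

  recs <- expand.grid(
    individual = rownames(genotypes),
    block = seq_len(config$n_blocks),
    harvest = seq_len(H),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  idx <- match(recs$individual, rownames(genotypes))
  recs$value <- config$harvest_means[recs$harvest] +
    tbv[cbind(idx, recs$harvest)] +
    block_eff[cbind(recs$harvest, recs$block)] +
    stats::rnorm(nrow(recs), sd = sqrt(var_e[recs$harvest]))
  recs <- recs[, c("individual", "harvest", "block", "value")]

  list(
    phenotypes = recs,
    truth = list(
      true_breeding_values = tbv,
      causal_markers = colnames(genotypes)[causal],
      causal_effects = effects,
      var_genetic = var_g,
      var_residual = var_e,
      block_effects = block_eff
    )
  )
}

#' Simulate a complete genotyped and phenotyped breeding population
#'
#' Convenience wrapper running [simulate_genotypes()] and
#' [simulate_phenotypes()] (on the unmasked dosages, so ground truth is not
#' distorted by missingness).
#'
#' @param config a [sim_config()].
#' @return A list with `genotypes` (masked), `genotypes_complete`,
#'   `phenotypes`, `truth`, `pedigree`, `parents`, and the `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  g <- simulate_genotypes(config)
  ph <- simulate_phenotypes(g$complete, config)
  list(
    genotypes = g$genotypes,
    genotypes_complete = g$complete,
    phenotypes = ph$phenotypes,
    truth = c(ph$truth, list(parent_allele_freq = g$allele_freq)),
    pedigree = g$pedigree,
    parents = g$parents,
    config = config
  )
}
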