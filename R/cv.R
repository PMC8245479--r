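#' Balanced random fold assignment
#'
#' Partitions NT individuals into k non-overlapping folds whose sizes
#' differ by at most one, uniformly at random, deterministically for a
#' given seed. With k = 10 this is the usual 9/10 training, 1/10
#' validation split.
#'
#' @param NT number of individuals.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return An object of class `fold_plan`: `assignments` (fold index per
#'   individual position), `sizes`, `k`, `NT`, `seed`.
#' @export
make_folds <- function(NT, k = 10L, seed = 1L) {
  NT <- as.integer(NT); k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (NT < k) stop("cannot make ", k, " folds from ", NT, " individuals")
  base <- NT %/% k
  extra <- NT %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  set.seed(seed)
  assignments <- sample(rep(seq_len(k), times = sizes))
  structure(list(assignments = assignments,
                 sizes = tabulate(assignments, nbins = k),
                 k = k, NT = NT, seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("%d-fold plan over %d individuals (seed %d); fold sizes: %s\n",
              x$k, x$NT, x$seed, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

# Shared CV engine: trains RR-BLUP within each fold on the training
# individuals' records for `harvest` and predicts the held-out
# individuals. Standardization parameters (marker means/SDs, also used for
# imputation) come from the training rows only, unless .standardize =
# "all" (kept for demonstrating the leakage effect; never the default).
cv_engine <- function(genotypes, phenotypes, harvest = NULL, k = 10L,
                      seed = 1L, aggregate = c("records", "means"),
                      .standardize = c("training", "all")) {
  aggregate <- match.arg(aggregate)
  .standardize <- match.arg(.standardize)
  ph <- phenotypes
  if (!is.null(harvest)) ph <- ph[ph$harvest %in% harvest, , drop = FALSE]
  if (nrow(ph) == 0L) stop("no phenotype records for harvest ", harvest)
  ids <- sort(unique(as.character(ph$individual)))
  missing_geno <- setdiff(ids, rownames(genotypes))
  if (length(missing_geno)) {
    stop("no genotypes for phenotyped individual(s): ",
         paste(utils::head(missing_geno, 5), collapse = ", "))
  }
  obs_mean <- tapply(ph$value, as.character(ph$individual), mean)[ids]

  if (aggregate == "means") {
    mu <- tapply(ph$value, ph$individual, mean)
    ph <- data.frame(individual = names(mu), value = as.numeric(mu),
                     stringsAsFactors = FALSE)
    form <- value ~ 1
  } else {
    ph <- ph[, c("individual", "block", "value")]
    form <- if (length(unique(ph$block)) > 1L) {
      value ~ factor(block)
    } else {
      value ~ 1
    }
  }

  folds <- make_folds(length(ids), k = k, seed = seed)
  oof <- stats::setNames(rep(NA_real_, length(ids)), ids)
  per_fold <- vector("list", folds$k)

  G_all <- genotypes[ids, , drop = FALSE]
  for (f in seq_len(folds$k)) {
    train_ids <- ids[folds$assignments != f]
    val_ids <- ids[folds$assignments == f]
    if (.standardize == "training") {
      Gtr <- G_all[train_ids, , drop = FALSE]
      # a marker can be monomorphic within a training fold even after
      # global QC; it carries no information there and is dropped for
      # this fold only
      ctr <- colMeans(Gtr, na.rm = TRUE)
      vtr <- colMeans(impute_markers(Gtr, ctr)^2) - ctr^2
      Gtr <- Gtr[, vtr > 1e-10, drop = FALSE]
      Zt <- standardize_markers(Gtr)
    } else {
      Zfull <- standardize_markers(G_all)
      Zt <- Zfull[train_ids, , drop = FALSE]
      attr(Zt, "center") <- attr(Zfull, "center")
      attr(Zt, "scale") <- attr(Zfull, "scale")
    }
    tr <- ph[ph$individual %in% train_ids, , drop = FALSE]
    mf <- stats::model.frame(form, tr)
    y <- stats::model.response(mf)
    X <- stats::model.matrix(form, mf)
    Zrec <- Zt[as.character(tr$individual), , drop = FALSE]
    fit <- rrblup_fit(y, X, Zrec, keep_mme = FALSE)
    Zv <- standardize_markers(G_all[val_ids, colnames(Zt), drop = FALSE],
                              center = attr(Zt, "center"),
                              scale = attr(Zt, "scale"))
    oof[val_ids] <- drop(Zv %*% fit$effects)
    per_fold[[f]] <- list(fold = f, n_train = length(train_ids),
                          n_validate = length(val_ids),
                          sigma2_g = fit$varcomp$sigma2_g,
                          sigma2_e = fit$varcomp$sigma2_e,
                          h2 = fit$varcomp$h2)
  }

  list(folds = folds, oof_gebv = oof, obs_mean = obs_mean,
       per_fold = per_fold, harvest = harvest, aggregate = aggregate)
}

#' Tenfold cross-validation of genomic prediction
#'
#' Runs k-fold cross-validation within one harvest: for each fold,
#' variance components and marker effects are estimated on the 9/10
#' training individuals (marker standardization and imputation parameters
#' frozen from the training rows, so no information leaks from the
#' validation set), the held-out 1/10 are scored, and the out-of-fold GEBV
#' are assembled so every individual is predicted exactly once. The
#' predictive ability r_yg is the Pearson correlation between out-of-fold
#' GEBV and observed phenotypes (individual means across blocks).
#'
#' @param genotypes post-QC dosage matrix (individuals x markers, rownames
#'   are individual ids; `NA` allowed, imputed within folds).
#' @param phenotypes long data frame (individual, harvest, block, value).
#' @param harvest which harvest to analyse (`NULL` = all records pooled).
#' @param k number of folds, default 10.
#' @param seed integer seed for the fold assignment.
#' @param aggregate fit plot-level `"records"` with block fixed effects
#'   (default) or individual `"means"` with intercept only.
#' @param repetitions number of independent CV repetitions; with more than
#'   one, r_yg is averaged and the first repetition's fold detail is kept.
#' @return An object of class `cv_result`: `r_yg`, `oof_gebv`, `obs_mean`,
#'   `folds`, `per_fold`, and (if repeated) `r_yg_reps`.
#' @export
cross_validate <- function(genotypes, phenotypes, harvest = NULL, k = 10L,
                           seed = 1L, aggregate = c("records", "means"),
                           repetitions = 1L) {
  aggregate <- match.arg(aggregate)
  reps <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    reps[[r]] <- cv_engine(genotypes, phenotypes, harvest = harvest, k = k,
                           seed = seed + (r - 1L), aggregate = aggregate)
  }
  eng <- reps[[1L]]
  r_all <- vapply(reps, function(e) safe_cor(e$oof_gebv, e$obs_mean),
                  numeric(1))
  res <- structure(list(
    r_yg = mean(r_all), r_yg_reps = r_all,
    oof_gebv = eng$oof_gebv, obs_mean = eng$obs_mean,
    folds = eng$folds, per_fold = eng$per_fold,
    harvest = harvest, aggregate = aggregate, k = eng$folds$k,
    seed = as.integer(seed)
  ), class = "cv_result")
  res
}

safe_cor <- function(x, y) {
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    warning("correlation undefined: constant predictions or phenotypes")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation%s (%s phenotypes)\n", x$k,
              if (is.null(x$harvest)) "" else
                paste0(", harvest ", paste(x$harvest, collapse = "+")),
              x$aggregate))
  cat(sprintf("  predictive ability r_yg = %.4f", x$r_yg))
  if (length(x$r_yg_reps) > 1L) {
    cat(sprintf("  (mean of %d repetitions)", length(x$r_yg_reps)))
  }
  cat("\n")
  h2s <- vapply(x$per_fold, `[[`, numeric(1), "h2")
  cat(sprintf("  per-fold h2: %.3f-%.3f\n", min(h2s), max(h2s)))
  invisible(x)
}
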