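#' Estimated breeding values for one harvest
#'
#' EBV are BLUPs of individual genetic values from the mixed model with
#' marker-based (genomic-relationship) covariance Z Z' / n and block fixed
#' effects, fitted on all records of the harvest. By the RR-BLUP / GBLUP
#' equivalence these equal Z a-hat from the full-data marker-effect fit.
#' They serve as the validation target when a model trained on an earlier
#' harvest is transferred forward. Adjusted phenotypic means can be used
#' instead via `method = "means"` (block effects removed by least
#' squares).
#'
#' @param genotypes post-QC dosage matrix (rownames are individual ids).
#' @param phenotypes long data frame (individual, harvest, block, value).
#' @param harvest which harvest to compute EBV for.
#' @param method `"gblup"` (default) or `"means"` (block-adjusted
#'   phenotypic means).
#' @return Named vector of EBV (one per individual).
#' @export
compute_ebv <- function(genotypes, phenotypes, harvest,
                        method = c("gblup", "means")) {
  method <- match.arg(method)
  ph <- phenotypes[phenotypes$harvest %in% harvest, , drop = FALSE]
  if (nrow(ph) == 0L) stop("no phenotype records for harvest ", harvest)
  ids <- sort(unique(as.character(ph$individual)))
  missing_geno <- setdiff(ids, rownames(genotypes))
  if (length(missing_geno)) {
    stop("no genotypes for phenotyped individual(s): ",
         paste(utils::head(missing_geno, 5), collapse = ", "))
  }
  if (method == "means") {
    form <- if (length(unique(ph$block)) > 1L) {
      value ~ factor(individual) + factor(block)
    } else {
      value ~ factor(individual)
    }
    fit <- stats::lm(form, data = ph)
    # individual effect + intercept = block-adjusted mean
    ce <- stats::coef(fit)
    eff <- c(0, ce[grep("^factor\\(individual\\)", names(ce))])
    return(stats::setNames(ce[1] + eff, ids))
  }
  form <- if (length(unique(ph$block)) > 1L) value ~ factor(block) else value ~ 1
  fit <- rrblup(form, data = ph, genotypes = genotypes, keep_mme = FALSE)
  fit$gebv
}

#' Cross-harvest model-transfer accuracy
#'
#' Trains marker effects on harvest `train_harvest` within a k-fold
#' cross-validation (so every individual's GEBV is predicted by a model
#' that never saw its own training-harvest phenotype) and correlates the
#' assembled out-of-fold GEBV with the individuals' EBV at harvest
#' `test_harvest`. With `train_harvest == test_harvest` and
#' `target = "phenotype"` this reduces exactly to [cross_validate()]'s
#' predictive ability (same folds for the same seed). Pooled training on
#' several harvests is supported by passing a vector as `train_harvest`.
#'
#' @param genotypes post-QC dosage matrix.
#' @param phenotypes long data frame (individual, harvest, block, value).
#' @param train_harvest harvest(s) whose phenotypes train the model.
#' @param test_harvest harvest whose EBV (or mean phenotypes) are the
#'   validation target.
#' @param k folds, default 10.
#' @param seed fold seed.
#' @param aggregate `"records"` (default) or `"means"`, as in
#'   [cross_validate()].
#' @param target `"ebv"` (default; genomic BLUP at the test harvest) or
#'   `"phenotype"` (individual-mean phenotypes at the test harvest).
#' @return An object of class `transfer_result`: `accuracy`,
#'   `train_harvest`, `test_harvest`, `oof_gebv`, `target_values`,
#'   `folds`.
#' @export
transfer_accuracy <- function(genotypes, phenotypes, train_harvest,
                              test_harvest, k = 10L, seed = 1L,
                              aggregate = c("records", "means"),
                              target = c("ebv", "phenotype")) {
  aggregate <- match.arg(aggregate)
  target <- match.arg(target)

  train_ids <- sort(unique(as.character(
    phenotypes$individual[phenotypes$harvest %in% train_harvest])))
  test_ids <- sort(unique(as.character(
    phenotypes$individual[phenotypes$harvest %in% test_harvest])))
  common <- intersect(train_ids, test_ids)
  if (length(common) < 2L) {
    stop("training and testing harvests share no (or almost no) individuals")
  }
  if (length(common) < length(train_ids) || length(common) < length(test_ids)) {
    warning("harvests phenotype different individual sets; using the ",
            length(common), " in common")
    keep <- phenotypes$individual %in% common
    phenotypes <- phenotypes[keep, , drop = FALSE]
  }

  eng <- cv_engine(genotypes, phenotypes, harvest = train_harvest, k = k,
                   seed = seed, aggregate = aggregate)

  tv <- if (target == "ebv") {
    compute_ebv(genotypes, phenotypes, harvest = test_harvest)
  } else {
    phj <- phenotypes[phenotypes$harvest %in% test_harvest, , drop = FALSE]
    tapply(phj$value, as.character(phj$individual), mean)
  }
  tv <- tv[names(eng$oof_gebv)]

  structure(list(
    train_harvest = train_harvest, test_harvest = test_harvest,
    accuracy = safe_cor(eng$oof_gebv, as.numeric(tv)),
    oof_gebv = eng$oof_gebv, target_values = tv, target = target,
    folds = eng$folds, aggregate = aggregate, k = eng$folds$k,
    seed = as.integer(seed)
  ), class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf(
    "Harvest transfer %s -> %s (%d-fold, target = %s): accuracy = %.4f\n",
    paste(x$train_harvest, collapse = "+"), x$test_harvest, x$k, x$target,
    x$accuracy))
  invisible(x)
}
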