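#' Fit an RR-BLUP genomic prediction model
#'
#' Fits the mixed linear model y = X b + Z a + e, where b are fixed
#' effects given by `formula`, a are random marker effects with common
#' variance sigma2_m (so the total genetic variance is sigma2_g =
#' n_markers * sigma2_m), and e is i.i.d. residual. Variance components
#' are estimated by REML, profiling the ratio sigma2_e / sigma2_g on the
#' spectrum of the marker-based relationship matrix Z Z' / n (computed
#' through the much smaller Z'Z); marker effects then solve the genomic
#' mixed-model equations
#' \deqn{[X'X, X'Z; Z'X, Z'Z + I \lambda] [b; a] = [X'y; Z'y]}
#' with ridge \eqn{\lambda = \sigma^2_e / (\sigma^2_g / n)}. Genomic
#' estimated breeding values are g_j = sum_i Z_ij a_i.
#'
#' @param formula model formula for the fixed effects, e.g.
#'   `value ~ factor(block)`; the response is the phenotype. An intercept
#'   is always sensible; factors use treatment (drop-first) coding.
#' @param data long-format data frame with one row per record, containing
#'   the formula variables and an `id` column naming the genotyped
#'   individual for each record.
#' @param genotypes individuals x markers matrix with rownames matching
#'   the id column: either raw 0/1/2 dosages (standardized internally over
#'   the individuals present in `data`, missing cells imputed by marker
#'   mean) or an already-standardized matrix from
#'   [standardize_markers()] (detected by its `center` attribute).
#' @param id name of the individual identifier column in `data`.
#' @param varcomp optional list with `sigma2_g` and `sigma2_e` to skip
#'   REML and plug in known variance components.
#' @param keep_mme keep the Cholesky factor of the coefficient matrix (a
#'   few MB at typical marker counts), needed by
#'   [prediction_error_variance()].
#' @param ratio_bounds search interval for the REML variance ratio
#'   sigma2_e / sigma2_g.
#' @return An object of class `rrblup` with components `varcomp` (class
#'   `varcomp`), `beta` (fixed effects), `effects` (marker effects),
#'   `gebv` (per training individual), `fitted`, `residuals`, the frozen
#'   standardization parameters, and the REML profile trace. Supports
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' pop <- simulate_population(sim_config(n_progeny = 80, n_markers = 120,
#'                                       n_qtl_sim = 60, seed = 3))
#' ph1 <- subset(pop$phenotypes, harvest == 1)
#' fit <- rrblup(value ~ factor(block), data = ph1,
#'               genotypes = pop$genotypes)
#' fit
#' cor(fit$gebv, pop$truth$true_breeding_values[names(fit$gebv), 1])
#' @export
rrblup <- function(formula, data, genotypes, id = "individual",
                   varcomp = NULL, keep_mme = TRUE,
                   ratio_bounds = c(1e-8, 1e8)) {
  stopifnot(is.data.frame(data), id %in% names(data))
  ids <- as.character(data[[id]])
  uids <- sort(unique(ids))
  if (is.null(rownames(genotypes))) {
    stop("genotypes must have rownames matching the id column")
  }
  missing_geno <- setdiff(uids, rownames(genotypes))
  if (length(missing_geno)) {
    stop("no genotypes for phenotyped individual(s): ",
         paste(utils::head(missing_geno, 5), collapse = ", "),
         if (length(missing_geno) > 5) " ...")
  }

  if (is.null(attr(genotypes, "center"))) {
    Zi <- standardize_markers(genotypes[uids, , drop = FALSE])
  } else {
    Zi <- genotypes[uids, , drop = FALSE]
    attr(Zi, "center") <- attr(genotypes, "center")
    attr(Zi, "scale") <- attr(genotypes, "scale")
  }

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  Z <- Zi[ids, , drop = FALSE]

  fit <- rrblup_fit(y, X, Z, varcomp = varcomp, keep_mme = keep_mme,
                    ratio_bounds = ratio_bounds)
  fit$gebv <- drop(Zi %*% fit$effects)
  names(fit$gebv) <- uids
  fit$Z_individuals <- Zi
  fit$center <- attr(Zi, "center")
  fit$scale <- attr(Zi, "scale")
  fit$id <- ids
  fit$call <- match.call()
  fit
}

# Low-level fitter on explicit (y, X, Z). Shared by rrblup() and the
# cross-validation engine.
rrblup_fit <- function(y, X, Z, varcomp = NULL, keep_mme = TRUE,
                       ratio_bounds = c(1e-8, 1e8)) {
  n <- length(y)
  p <- ncol(X)
  m <- ncol(Z)
  if (nrow(X) != n || nrow(Z) != n) stop("row counts of y, X, Z disagree")
  if (n <= p) stop("need more observations than fixed effects")

  C   <- crossprod(Z)        # m x m
  ZtX <- crossprod(Z, X)
  Zty <- drop(crossprod(Z, y))
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y^2)

  if (is.null(varcomp)) {
    vc <- reml_spectral(y, X, C, ZtX, Zty, XtX, Xty, yty, m,
                        ratio_bounds = ratio_bounds)
  } else {
    stopifnot(all(c("sigma2_g", "sigma2_e") %in% names(varcomp)))
    vc <- new_varcomp(varcomp$sigma2_g, varcomp$sigma2_e, m, trace = NULL)
  }

  if (!is.finite(vc$ridge)) {
    # degenerate fit (zero genetic variance, e.g. constant response):
    # effects shrink to zero and the model collapses to OLS
    sol <- list(beta = solve(XtX, Xty), effects = rep(0, m), chol = NULL)
    keep_mme <- FALSE
  } else {
    sol <- solve_mme_crossprod(XtX, ZtX, C, Xty, Zty, vc$ridge,
                               keep_chol = keep_mme)
  }
  beta <- sol$beta
  names(beta) <- colnames(X)
  a <- sol$effects
  names(a) <- colnames(Z)

  fitted <- drop(X %*% beta + Z %*% a)
  structure(list(
    varcomp = vc, beta = beta, effects = a,
    fitted = fitted, residuals = y - fitted, y = y,
    n_obs = n, n_markers = m,
    mme_chol = if (keep_mme) sol$chol else NULL,
    n_fixed = p
  ), class = "rrblup")
}

new_varcomp <- function(sigma2_g, sigma2_e, n_markers, trace = NULL,
                        boundary = FALSE) {
  structure(list(
    sigma2_m = sigma2_g / n_markers,
    sigma2_g = sigma2_g,
    sigma2_e = sigma2_e,
    sigma2_a = sigma2_g,
    sigma2_p = sigma2_g + sigma2_e,
    ridge = if (sigma2_g > 0) sigma2_e * n_markers / sigma2_g else Inf,
    h2 = if (sigma2_g + sigma2_e > 0) sigma2_g / (sigma2_g + sigma2_e) else NA_real_,
    n_markers = n_markers,
    trace = trace,
    boundary = boundary
  ), class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat("Variance components (REML unless supplied)\n")
  cat(sprintf("  sigma2_g (total genetic):  %.6g\n", x$sigma2_g))
  cat(sprintf("  sigma2_e (residual):       %.6g\n", x$sigma2_e))
  cat(sprintf("  sigma2_m (per marker):     %.6g   (n = %d markers)\n",
              x$sigma2_m, x$n_markers))
  cat(sprintf("  ridge lambda:              %.6g\n", x$ridge))
  cat(sprintf("  h2 (record scale):         %.4f\n", x$h2))
  invisible(x)
}

# REML profile likelihood over theta = sigma2_e / sigma2_g, using the
# low-rank spectrum of K = ZZ'/m obtained from eigen(Z'Z). Directions
# orthogonal to the column space of Z carry variance sigma2_e only and are
# handled in closed form, so cost is O(m^3) + O(r p^2) per profile point
# regardless of the number of records.
reml_spectral <- function(y, X, C, ZtX, Zty, XtX, Xty, yty, m,
                          ratio_bounds = c(1e-8, 1e8)) {
  n <- length(y)
  p <- ncol(X)
  eg <- eigen(C, symmetric = TRUE)
  keep <- eg$values > max(eg$values, 0) * 1e-10
  r <- sum(keep)
  if (r == 0L) stop("Z has no signal (all-zero columns?)")
  ev <- eg$values[keep]
  V <- eg$vectors[, keep, drop = FALSE]
  d <- ev / m                                   # nonzero eigenvalues of ZZ'/m
  isq <- 1 / sqrt(ev)
  X1 <- isq * crossprod(V, ZtX)                 # r x p, = U_r' X
  y1 <- drop(isq * crossprod(V, Zty))           # r,    = U_r' y
  X1tX1 <- crossprod(X1)
  X1ty1 <- drop(crossprod(X1, y1))
  y1ty1 <- sum(y1^2)

  trace <- new.env(parent = emptyenv())
  trace$log_theta <- numeric(0)
  trace$crit <- numeric(0)

  crit <- function(log_theta) {
    theta <- exp(log_theta)
    w <- 1 / (d + theta)
    A <- crossprod(X1, X1 * w) + (XtX - X1tX1) / theta
    cvec <- drop(crossprod(X1, y1 * w)) + (Xty - X1ty1) / theta
    q <- sum(y1^2 * w) + (yty - y1ty1) / theta
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    u <- backsolve(ch, cvec, transpose = TRUE)
    rss <- max(q - sum(u^2), 1e-300)
    val <- (n - p) * log(rss) + sum(log(d + theta)) + (n - r) * log(theta) +
      2 * sum(log(diag(ch)))
    trace$log_theta <- c(trace$log_theta, log_theta)
    trace$crit <- c(trace$crit, val)
    val
  }

  opt <- stats::optimize(crit, interval = log(ratio_bounds), tol = 1e-10)
  theta <- exp(opt$minimum)
  boundary <- opt$minimum < log(ratio_bounds[1]) + 1e-3 ||
    opt$minimum > log(ratio_bounds[2]) - 1e-3

  # variance estimates at the optimum
  w <- 1 / (d + theta)
  A <- crossprod(X1, X1 * w) + (XtX - X1tX1) / theta
  cvec <- drop(crossprod(X1, y1 * w)) + (Xty - X1ty1) / theta
  q <- sum(y1^2 * w) + (yty - y1ty1) / theta
  beta <- solve(A, cvec)
  rss <- max(q - sum(cvec * beta), 0)
  sigma2_g <- rss / (n - p)
  sigma2_e <- theta * sigma2_g

  vc <- new_varcomp(sigma2_g, sigma2_e, m,
                    trace = data.frame(log_theta = trace$log_theta,
                                       criterion = trace$crit),
                    boundary = boundary)
  if (boundary && sigma2_g > 0) {
    # a boundary solution is the REML answer for degenerate data (pure
    # noise or noise-free); flagged rather than treated as an error
    vc$note <- "variance ratio at search boundary"
  }
  vc
}

#' Estimate RR-BLUP variance components by REML
#'
#' Standalone access to the REML machinery used by [rrblup()]: estimates
#' the total genetic variance sigma2_g (equivalently the per-marker
#' variance sigma2_m = sigma2_g / n) and residual variance sigma2_e for
#' the model with genomic covariance Z Z' / n, by one-dimensional
#' profile-likelihood optimization over the variance ratio after spectral
#' decomposition.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (include the intercept column).
#' @param Z standardized marker matrix, one row per observation.
#' @param ratio_bounds search interval for sigma2_e / sigma2_g.
#' @return A `varcomp` object; its `trace` component holds the profile
#'   evaluations, `boundary` flags an optimum at the search edge.
#' @export
estimate_variance_components <- function(y, X, Z,
                                         ratio_bounds = c(1e-8, 1e8)) {
  n <- length(y)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  if (nrow(X) != n || nrow(Z) != n) stop("row counts of y, X, Z disagree")
  if (n <= ncol(X)) stop("need more observations than fixed effects")
  reml_spectral(y, X, crossprod(Z), crossprod(Z, X), drop(crossprod(Z, y)),
                crossprod(X), drop(crossprod(X, y)), sum(y^2), ncol(Z),
                ratio_bounds = ratio_bounds)
}

#' Solve the genomic mixed-model equations
#'
#' Solves the block system
#' \deqn{[X'X, X'Z; Z'X, Z'Z + I \lambda] [b; a] = [X'y; Z'y]}
#' by Cholesky factorization of the (symmetric positive-definite)
#' coefficient matrix.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix, full column rank.
#' @param Z marker matrix (standardized), one row per observation.
#' @param ridge the shrinkage parameter lambda = sigma2_e / (sigma2_g / n),
#'   strictly positive.
#' @return A list with `beta` (fixed effects) and `effects` (marker
#'   effects).
#' @export
solve_mme <- function(y, X, Z, ridge) {
  if (!is.finite(ridge) || ridge <= 0) stop("ridge must be a positive number")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular X'X; aliased fixed-effect column(s): ",
         paste(aliased, collapse = ", "))
  }
  sol <- solve_mme_crossprod(crossprod(X), crossprod(Z, X), crossprod(Z),
                             drop(crossprod(X, y)), drop(crossprod(Z, y)),
                             ridge, keep_chol = FALSE)
  list(beta = stats::setNames(sol$beta, colnames(X)),
       effects = stats::setNames(sol$effects, colnames(Z)))
}

solve_mme_crossprod <- function(XtX, ZtX, C, Xty, Zty, ridge,
                                keep_chol = FALSE) {
  p <- ncol(XtX)
  m <- ncol(C)
  M <- rbind(cbind(XtX, t(ZtX)),
             cbind(ZtX, C + diag(ridge, m)))
  ch <- chol(M)
  sol <- backsolve(ch, backsolve(ch, c(Xty, Zty), transpose = TRUE))
  list(beta = sol[seq_len(p)], effects = sol[-seq_len(p)],
       chol = if (keep_chol) ch else NULL)
}

#' Genomic estimated breeding values from marker effects
#'
#' Computes g = Z a, matching markers by id and reporting any mismatch
#' between the marker sets of `Z` and `effects`.
#'
#' @param Z standardized genotype matrix (individuals x markers); for
#'   individuals absent from training, standardize with the training
#'   `center`/`scale` (see [standardize_markers()]).
#' @param effects named vector of marker effects (or an `rrblup` fit).
#' @return Named vector of GEBV, one per row of `Z`.
#' @export
predict_gebv <- function(Z, effects) {
  if (inherits(effects, "rrblup")) effects <- effects$effects
  if (!is.null(names(effects)) && !is.null(colnames(Z))) {
    only_z <- setdiff(colnames(Z), names(effects))
    only_e <- setdiff(names(effects), colnames(Z))
    if (length(only_z) || length(only_e)) {
      stop("marker ids of Z and effects differ; only in Z: {",
           paste(utils::head(only_z, 5), collapse = ", "),
           "}, only in effects: {",
           paste(utils::head(only_e, 5), collapse = ", "), "}")
    }
    Z <- Z[, names(effects), drop = FALSE]
  } else if (ncol(Z) != length(effects)) {
    stop("Z has ", ncol(Z), " markers but effects has ", length(effects))
  }
  stats::setNames(drop(Z %*% effects), rownames(Z))
}

#' Average prediction-error variance of genomic breeding values
#'
#' PEV of an individual's genetic value g_j = z_j' a under the fitted
#' model, computed from the marker-effect block of the inverse mixed-model
#' coefficient matrix: PEV_j = sigma2_e * z_j' C^{aa} z_j. Used to derive
#' the accuracy of (phenotype-based) BLUP selection,
#' r = sqrt(1 - PEV / sigma2_g).
#'
#' @param fit an [rrblup()] fit with `keep_mme = TRUE`.
#' @return A list with `pev` (mean over individuals), `pev_individual`,
#'   and the model's `sigma2_g`.
#' @export
prediction_error_variance <- function(fit) {
  stopifnot(inherits(fit, "rrblup"))
  if (is.null(fit$mme_chol)) {
    stop("fit was created with keep_mme = FALSE; refit to compute PEV")
  }
  if (is.null(fit$Z_individuals)) {
    stop("fit carries no individual genotype matrix")
  }
  p <- fit$n_fixed
  Minv <- chol2inv(fit$mme_chol)
  Caa <- Minv[-seq_len(p), -seq_len(p), drop = FALSE]
  Zi <- fit$Z_individuals
  pev_i <- fit$varcomp$sigma2_e * rowSums((Zi %*% Caa) * Zi)
  list(pev = mean(pev_i),
       pev_individual = stats::setNames(pev_i, rownames(Zi)),
       sigma2_g = fit$varcomp$sigma2_g)
}

#' @export
print.rrblup <- function(x, ...) {
  cat("RR-BLUP genomic prediction model\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  %d records, %d markers, %d fixed effect(s)\n",
              x$n_obs, x$n_markers, x$n_fixed))
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g, h2 = %.3f, lambda = %.4g\n",
              x$varcomp$sigma2_g, x$varcomp$sigma2_e, x$varcomp$h2,
              x$varcomp$ridge))
  invisible(x)
}

#' @export
summary.rrblup <- function(object, ...) {
  structure(list(
    call = object$call,
    n_obs = object$n_obs, n_markers = object$n_markers,
    n_individuals = if (!is.null(object$gebv)) length(object$gebv) else NA,
    varcomp = object$varcomp,
    beta = object$beta,
    effects_sd = stats::sd(object$effects),
    gebv_range = if (!is.null(object$gebv)) range(object$gebv) else NULL
  ), class = "summary.rrblup")
}

#' @export
print.summary.rrblup <- function(x, ...) {
  cat("RR-BLUP model summary\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Records: %d   Individuals: %s   Markers: %d\n",
              x$n_obs, x$n_individuals, x$n_markers))
  print(x$varcomp)
  cat("Fixed effects:\n")
  print(x$beta)
  cat(sprintf("Marker-effect SD: %.4g\n", x$effects_sd))
  if (!is.null(x$gebv_range)) {
    cat(sprintf("GEBV range: [%.4g, %.4g]\n",
                x$gebv_range[1], x$gebv_range[2]))
  }
  invisible(x)
}

#' @export
coef.rrblup <- function(object, which = c("markers", "fixed"), ...) {
  which <- match.arg(which)
  if (which == "markers") object$effects else object$beta
}

#' @export
fitted.rrblup <- function(object, ...) object$fitted

#' @export
residuals.rrblup <- function(object, ...) object$residuals

#' Predict breeding values for (possibly new) individuals
#'
#' @param object an [rrblup()] fit.
#' @param newdata raw dosage matrix (individuals x markers) for the
#'   individuals to score; standardized with the training-set center and
#'   scale (missing cells imputed by the training marker mean). If
#'   omitted, returns the training GEBV.
#' @param ... unused.
#' @return Named vector of GEBV.
#' @export
predict.rrblup <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$gebv)
  if (is.null(object$center)) {
    stop("fit carries no standardization parameters; refit via rrblup()")
  }
  Z <- standardize_markers(newdata[, names(object$center), drop = FALSE],
                           center = object$center, scale = object$scale)
  predict_gebv(Z, object$effects)
}

#' Plot GEBV against observed individual-mean phenotypes
#'
#' @param x an [rrblup()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rrblup <- function(x, ...) {
  if (is.null(x$gebv)) stop("fit carries no GEBV")
  obs <- tapply(x$y, x$id, mean)[names(x$gebv)]
  graphics::plot(x$gebv, obs,
                 xlab = "Genomic estimated breeding value",
                 ylab = "Observed phenotype (individual mean)", ...)
  graphics::abline(stats::lm(obs ~ x$gebv), lty = 2)
  invisible(x)
}
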