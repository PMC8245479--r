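#' Accuracy of genomic selection from predictive ability
#'
#' Rescales the predictive ability by the heritabilities,
#' r_gg = r_yg / sqrt(h2_a * h2_g), treating genomic heritability as the
#' proportion of phenotypic heritability captured by the marker panel
#' (i.e. accounting for imperfect linkage disequilibrium between markers
#' and QTL). Values above 1 (possible with rounded inputs) are clamped to
#' 1 with a warning.
#'
#' @param r_yg predictive ability (correlation of GEBV with phenotype).
#' @param h2_a narrow-sense heritability.
#' @param h2_g genomic heritability.
#' @return The selection accuracy r_gg.
#' @export
gws_accuracy <- function(r_yg, h2_a, h2_g = h2_a) {
  if (!is.finite(h2_a) || !is.finite(h2_g) || h2_a * h2_g <= 0) {
    stop("h2_a * h2_g must be positive")
  }
  r <- r_yg / sqrt(h2_a * h2_g)
  if (any(r > 1)) {
    warning("accuracy above 1 clamped to 1 (rounded or inconsistent inputs)")
    r <- pmin(r, 1)
  }
  r
}

eff_q <- function(r, scale) {
  switch(scale, reliability = r, accuracy = r^2,
         stop("scale must be 'reliability' or 'accuracy'"))
}

#' Number of QTL implied by an observed selection accuracy
#'
#' n_qtl = (1 - q) * N * h2_g / q, where q is the observed accuracy
#' entered directly (`scale = "reliability"`, the default, which matches
#' the structure of published required-population tables) or its square
#' (`scale = "accuracy"`, the formula read literally with q = r^2).
#'
#' @param r_obs observed accuracy, strictly between 0 and 1.
#' @param N number of individuals evaluated.
#' @param h2_g genomic heritability.
#' @param scale `"reliability"` or `"accuracy"` (see Details).
#' @return Implied number of QTL (continuous; not rounded).
#' @export
n_qtl_estimate <- function(r_obs, N, h2_g,
                           scale = c("reliability", "accuracy")) {
  scale <- match.arg(scale)
  if (any(r_obs <= 0 | r_obs >= 1)) {
    stop("r_obs must lie strictly between 0 and 1")
  }
  q <- eff_q(r_obs, scale)
  (1 - q) * N * h2_g / q
}

#' Individuals required to reach a desired selection accuracy
#'
#' Ni = q * n_qtl / ((1 - q) * h2_g), the inverse of [n_qtl_estimate()]:
#' evaluating it at the n_qtl implied by an observed accuracy on N
#' individuals returns N.
#'
#' @param r_desired desired accuracy, strictly between 0 and 1.
#' @param n_qtl number of QTL controlling the trait.
#' @param h2_g genomic heritability.
#' @param scale `"reliability"` (default) or `"accuracy"`.
#' @param rounding `"nearest"` (default) or `"ceiling"`; a required count
#'   is naturally a ceiling but published tables round to nearest.
#' @return Required number of individuals (integer-rounded).
#' @export
individuals_required <- function(r_desired, n_qtl, h2_g,
                                 scale = c("reliability", "accuracy"),
                                 rounding = c("nearest", "ceiling")) {
  scale <- match.arg(scale)
  rounding <- match.arg(rounding)
  if (any(r_desired <= 0 | r_desired >= 1)) {
    stop("r_desired must lie strictly between 0 and 1")
  }
  if (h2_g <= 0) stop("h2_g must be positive")
  q <- eff_q(r_desired, scale)
  ni <- q * n_qtl / ((1 - q) * h2_g)
  if (rounding == "nearest") round(ni) else ceiling(ni)
}

#' Required-individuals table over a grid of desired accuracies
#'
#' @param desired vector of desired accuracies.
#' @param n_qtl,h2_g,scale,rounding as in [individuals_required()].
#' @return Data frame with columns `desired_accuracy` and `n_required`.
#' @export
ni_table <- function(desired = seq(0.4, 0.9, by = 0.1), n_qtl, h2_g,
                     scale = c("reliability", "accuracy"),
                     rounding = c("nearest", "ceiling")) {
  data.frame(
    desired_accuracy = desired,
    n_required = individuals_required(desired, n_qtl, h2_g,
                                      scale = match.arg(scale),
                                      rounding = match.arg(rounding))
  )
}

#' Accuracy of phenotypic (BLUP) selection from prediction-error variance
#'
#' r_yy = sqrt(1 - PEV / sigma2_g), where PEV is the prediction-error
#' variance of the individual genetic-value BLUPs and sigma2_g the
#' genotypic variance of the population.
#'
#' @param pev prediction-error variance, in \[0, sigma2_g\].
#' @param sigma2_g genotypic variance, positive.
#' @return Accuracy in \[0, 1\].
#' @export
phenotypic_accuracy <- function(pev, sigma2_g) {
  if (sigma2_g <= 0) stop("sigma2_g must be positive")
  if (any(pev < 0) || any(pev > sigma2_g)) {
    stop("pev must lie between 0 and sigma2_g")
  }
  sqrt(1 - pev / sigma2_g)
}

#' Efficiency of genomic over phenotypic selection (IRPS)
#'
#' efficiency = (r_gg * Tf) / (r_yy * Tgws); the increase relative to
#' phenotypic selection is IRPS = (efficiency - 1) * 100 percent. Tf and
#' Tgws are the cycle lengths of phenotypic and genomic selection in the
#' same time unit (only their ratio matters); genomic selection typically
#' halves the cycle, Tf = 2 * Tgws.
#'
#' @param r_g_hat genomic selection accuracy r_gg.
#' @param r_y_hat phenotypic selection accuracy r_yy.
#' @param tf phenotypic cycle length.
#' @param tgws genomic cycle length.
#' @return List with `efficiency` and `irps_percent`.
#' @export
irps <- function(r_g_hat, r_y_hat, tf = 2, tgws = 1) {
  if (any(c(r_g_hat, r_y_hat, tf, tgws) <= 0)) {
    stop("all arguments must be positive")
  }
  eff <- (r_g_hat * tf) / (r_y_hat * tgws)
  list(efficiency = eff, irps_percent = (eff - 1) * 100)
}

#' Narrow-sense and genomic heritability from variance components
#'
#' h2_a = sigma2_a / sigma2_p from the fitted components. The genomic
#' heritability h2_g is defined by the same ratio when the components are
#' marker-based (as here); supply `h2_g` to use an external estimate of
#' the marker-captured fraction instead.
#'
#' @param vc a `varcomp` object (from [rrblup()] or
#'   [estimate_variance_components()]).
#' @param h2_g optional externally supplied genomic heritability.
#' @param reps number of records averaged per individual on the scale the
#'   heritability should refer to: 1 (default) gives the single-record
#'   heritability sigma2_a / sigma2_p; r > 1 gives the entry-mean
#'   heritability sigma2_a / (sigma2_a + sigma2_e / r).
#' @return List with `h2_a` and `h2_g`, both in \[0, 1\].
#' @export
narrow_and_genomic_h2 <- function(vc, h2_g = NULL, reps = 1) {
  if (!is.finite(vc$sigma2_p) || vc$sigma2_p <= 0) {
    stop("phenotypic variance must be positive")
  }
  h2_a <- vc$sigma2_a / (vc$sigma2_a + vc$sigma2_e / reps)
  list(h2_a = h2_a, h2_g = if (is.null(h2_g)) h2_a else h2_g)
}

#' Assemble the full selection-metrics report
#'
#' Combines a cross-validation result and a full-data fit into the
#' derived selection statistics: predictive ability, heritabilities, GWS
#' accuracy, implied QTL number, the required-individuals table,
#' PEV-based phenotypic accuracy, and the efficiency of genomic over
#' phenotypic selection.
#'
#' @param cv a `cv_result` from [cross_validate()].
#' @param fit the corresponding full-data [rrblup()] fit (with
#'   `keep_mme = TRUE`, for PEV).
#' @param h2_g optional external genomic heritability (defaults to the
#'   fit's h2_a).
#' @param tf,tgws phenotypic and genomic cycle lengths.
#' @param desired grid of desired accuracies for the Ni table.
#' @param scale `"reliability"` (default) or `"accuracy"` for the
#'   Ni / n_qtl formulas.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(cv, fit, h2_g = NULL, tf = 2, tgws = 1,
                           desired = seq(0.4, 0.9, by = 0.1),
                           scale = c("reliability", "accuracy")) {
  scale <- match.arg(scale)
  stopifnot(inherits(cv, "cv_result"), inherits(fit, "rrblup"))
  # r_yg correlates GEBV with entry means, so the Eq.-4 rescaling must use
  # the heritability on the entry-mean scale; the single-record value is
  # reported alongside as h2_record
  reps <- fit$n_obs / length(fit$gebv)
  h2 <- narrow_and_genomic_h2(fit$varcomp, h2_g = h2_g, reps = reps)
  r_g_hat <- gws_accuracy(cv$r_yg, h2$h2_a, h2$h2_g)
  pv <- prediction_error_variance(fit)
  pev <- min(pv$pev, pv$sigma2_g)   # mean PEV can exceed sigma2_g only by
                                    # sampling noise in z'z; clamp
  r_y_hat <- phenotypic_accuracy(pev, pv$sigma2_g)
  N <- length(cv$oof_gebv)
  # accuracies at or beyond [0, 1] (possible with noisy inputs after the
  # Eq.-4 rescaling) would make the implied-QTL and efficiency formulas
  # degenerate; evaluate them just inside the open interval
  r_eff <- min(max(r_g_hat, 1e-3), 0.999)
  nq <- n_qtl_estimate(r_eff, N, h2$h2_g, scale = scale)
  eff <- irps(r_eff, r_y_hat, tf = tf, tgws = tgws)
  structure(list(
    r_yg = cv$r_yg, h2_a = h2$h2_a, h2_g = h2$h2_g,
    h2_record = fit$varcomp$h2, records_per_individual = reps,
    r_g_hat = r_g_hat, r_g_eff = r_eff, r_y_hat = r_y_hat,
    pev = pev, sigma2_g_pop = pv$sigma2_g,
    n_qtl = nq, N = N,
    ni_table = ni_table(desired, n_qtl = nq, h2_g = h2$h2_g, scale = scale),
    tf = tf, tgws = tgws,
    efficiency = eff$efficiency, irps_percent = eff$irps_percent,
    scale = scale, harvest = cv$harvest
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Selection metrics",
      if (!is.null(x$harvest)) sprintf("(harvest %s)",
                                       paste(x$harvest, collapse = "+")),
      "\n")
  cat(sprintf("  predictive ability r_yg:    %.4f\n", x$r_yg))
  cat(sprintf("  h2_a = %.4f, h2_g = %.4f\n", x$h2_a, x$h2_g))
  cat(sprintf("  GWS accuracy r_gg:          %.4f\n", x$r_g_hat))
  cat(sprintf("  phenotypic accuracy r_yy:   %.4f  (PEV = %.4g, sigma2_g = %.4g)\n",
              x$r_y_hat, x$pev, x$sigma2_g_pop))
  cat(sprintf("  implied n_qtl:              %.1f  (N = %d, scale = %s)\n",
              x$n_qtl, x$N, x$scale))
  cat(sprintf("  efficiency = %.3f, IRPS = %.2f%%  (Tf/Tgws = %.2f)\n",
              x$efficiency, x$irps_percent, x$tf / x$tgws))
  cat("  individuals required:\n")
  tb <- x$ni_table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("    accuracy %.2f -> %d\n",
                tb$desired_accuracy[i], tb$n_required[i]))
  }
  invisible(x)
}
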