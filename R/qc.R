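#' Critical minor-allele-frequency level for a population of size N
#'
#' The exclusion threshold below which a minor allele is too rare to be
#' informative in a population of N genotypes: 1 / sqrt(2N). At N = 386
#' this gives 0.036, i.e. 0.04 at two decimals.
#'
#' @param n_individuals number of genotyped individuals (N).
#' @return The critical MAF, a fraction in (0, 1].
#' @export
maf_critical_level <- function(n_individuals) {
  if (length(n_individuals) != 1L || !is.finite(n_individuals) ||
      n_individuals <= 0) {
    stop("n_individuals must be a single positive number")
  }
  1 / sqrt(2 * n_individuals)
}

#' Per-marker call rate
#'
#' Fraction of non-missing genotype calls in a marker column.
#'
#' @param x a vector of dosages with `NA` for missing calls.
#' @return Fraction in \[0, 1\].
#' @export
marker_call_rate <- function(x) {
  if (length(x) < 1L) stop("empty genotype column")
  mean(!is.na(x))
}

#' Per-marker minor allele frequency
#'
#' Computed over non-missing calls: p = sum(dosage) / (2 * n_obs),
#' MAF = min(p, 1 - p).
#'
#' @param x a vector of 0/1/2 dosages with `NA` for missing calls.
#' @return Fraction in \[0, 0.5\].
#' @export
marker_maf <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("cannot compute MAF: all calls missing")
  p <- sum(x) / (2 * length(x))
  min(p, 1 - p)
}

#' Filter markers by call rate and minor allele frequency
#'
#' Retains markers with call rate >= `call_rate_min` and MAF strictly
#' greater than the MAF threshold (the strict inequality mirrors the usual
#' "MAF > x%" filter convention; call rate uses >=). With
#' `maf_min = "auto"` the threshold is the population-size critical level
#' [maf_critical_level()] at N = number of individuals. A marker failing
#' both rules is counted under both.
#'
#' @param genotypes individuals x markers dosage matrix, `NA` missing.
#' @param call_rate_min minimum call rate, default 0.95.
#' @param maf_min MAF threshold, or `"auto"` for 1/sqrt(2N).
#' @return A list with `genotypes` (retained columns) and `report`
#'   (a `qc_report`: counts per exclusion reason and a per-marker table).
#' @export
apply_qc <- function(genotypes, call_rate_min = 0.95, maf_min = "auto") {
  if (!is.matrix(genotypes) || ncol(genotypes) == 0L || nrow(genotypes) == 0L) {
    stop("genotypes must be a non-empty matrix")
  }
  if (call_rate_min <= 0 || call_rate_min > 1) {
    stop("call_rate_min must lie in (0, 1]")
  }
  n_ind <- nrow(genotypes)
  maf_thr <- if (identical(maf_min, "auto")) {
    maf_critical_level(n_ind)
  } else {
    as.numeric(maf_min)
  }

  cr <- apply(genotypes, 2, marker_call_rate)
  maf <- apply(genotypes, 2, function(x) {
    if (all(is.na(x))) NA_real_ else marker_maf(x)
  })
  pass_cr <- cr >= call_rate_min
  pass_maf <- !is.na(maf) & maf > maf_thr
  keep <- pass_cr & pass_maf

  report <- structure(list(
    n_input_markers = ncol(genotypes),
    n_failed_call_rate = sum(!pass_cr),
    n_failed_maf = sum(!pass_maf),
    n_retained = sum(keep),
    call_rate_min = call_rate_min,
    maf_min = maf_thr,
    maf_min_mode = if (identical(maf_min, "auto")) "auto" else "fixed",
    markers = data.frame(
      marker = colnames(genotypes) %||% sprintf("M%04d", seq_len(ncol(genotypes))),
      call_rate = unname(cr),
      maf = unname(maf),
      pass_call_rate = unname(pass_cr),
      pass_maf = unname(pass_maf),
      retained = unname(keep),
      stringsAsFactors = FALSE
    )
  ), class = "qc_report")

  if (report$n_retained == 0L) {
    warning("no markers passed QC at the given thresholds")
  }
  list(genotypes = genotypes[, keep, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker QC report\n")
  cat(sprintf("  input markers:        %d\n", x$n_input_markers))
  cat(sprintf("  failed call rate:     %d  (threshold >= %.3f)\n",
              x$n_failed_call_rate, x$call_rate_min))
  cat(sprintf("  failed MAF:           %d  (threshold > %.4f%s)\n",
              x$n_failed_maf, x$maf_min,
              if (x$maf_min_mode == "auto") ", auto 1/sqrt(2N)" else ""))
  cat(sprintf("  retained:             %d\n", x$n_retained))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Impute missing dosages by the marker mean
#'
#' @param genotypes dosage matrix with `NA` for missing calls.
#' @param center optional per-column means to impute with (e.g. frozen from
#'   a training set); defaults to the observed column means of `genotypes`.
#' @return The matrix with `NA` cells replaced.
#' @export
impute_markers <- function(genotypes, center = NULL) {
  if (is.null(center)) {
    center <- colMeans(genotypes, na.rm = TRUE)
  }
  nas <- which(is.na(genotypes))
  if (length(nas)) {
    genotypes[nas] <- center[((nas - 1L) %/% nrow(genotypes)) + 1L]
  }
  genotypes
}

#' Impute and standardize a dosage matrix into the Z matrix
#'
#' Missing cells are imputed by the marker mean, then each column is
#' centered and scaled to unit variance. By default the population variance
#' (divide by n) is used; `var = "sample"` switches to the n - 1 divisor.
#' When `center`/`scale` are supplied (frozen from a training set) they are
#' applied as-is, so validation individuals are standardized on the
#' training scale.
#'
#' @param genotypes dosage matrix, `NA` allowed.
#' @param center,scale optional frozen standardization parameters.
#' @param var variance convention used when computing `scale` from the
#'   data: `"population"` (default) or `"sample"`.
#' @return The standardized matrix with attributes `center`, `scale` and
#'   `var`.
#' @export
standardize_markers <- function(genotypes, center = NULL, scale = NULL,
                                var = c("population", "sample")) {
  var <- match.arg(var)
  frozen <- !is.null(center)
  if (is.null(center)) center <- colMeans(genotypes, na.rm = TRUE)
  genotypes <- impute_markers(genotypes, center = center)
  if (is.null(scale)) {
    n <- nrow(genotypes)
    ss <- colMeans(genotypes^2) - (colMeans(genotypes))^2
    if (var == "sample") ss <- ss * n / (n - 1)
    scale <- sqrt(ss)
    bad <- which(scale < 1e-10)
    if (length(bad)) {
      stop("zero-variance marker column(s) after imputation (QC skipped?): ",
           paste(colnames(genotypes)[bad] %||% bad, collapse = ", "))
    }
  }
  Z <- sweep(sweep(genotypes, 2L, center, "-"), 2L, scale, "/")
  attr(Z, "center") <- center
  attr(Z, "scale") <- scale
  attr(Z, "var") <- if (frozen) "frozen" else var
  Z
}
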