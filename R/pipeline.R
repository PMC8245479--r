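#' Build and validate a pipeline run configuration
#'
#' A run either simulates its inputs (`simulation` = arguments for
#' [sim_config()]) or reads them from files (`inputs` = list with
#' `genotypes` pointing to a TSV or VCF and `phenotypes` to a CSV);
#' exactly one of the two must be given. Remaining sections tune the
#' stages and default to the settings of a standard genomic-selection
#' trial analysis: call rate 0.95, MAF threshold at the population
#' critical level, tenfold CV, plot-record model with block fixed
#' effects, a halved genomic cycle (Tf/Tgws = 2), and a 0.40-0.90 grid of
#' desired accuracies.
#'
#' @param simulation named list of [sim_config()] arguments, or NULL.
#' @param inputs list(genotypes=, phenotypes=) of file paths, or NULL.
#' @param qc list(call_rate_min=, maf_min=).
#' @param model list(aggregate= "records" or "means").
#' @param cv list(k=, seed=).
#' @param metrics list(tf=, tgws=, desired=, scale=, h2_g=).
#' @param transfer list(pairs = list(c(train, test), ...)); NULL computes
#'   all forward pairs between harvests.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(simulation = list(), inputs = NULL,
                       qc = list(), model = list(), cv = list(),
                       metrics = list(), transfer = list()) {
  has_sim <- !is.null(simulation)
  has_inp <- !is.null(inputs)
  if (has_sim == has_inp) {
    stop("exactly one of `simulation` and `inputs` must be given")
  }
  if (has_inp && !all(c("genotypes", "phenotypes") %in% names(inputs))) {
    stop("inputs must name `genotypes` and `phenotypes` files")
  }
  qc <- utils::modifyList(list(call_rate_min = 0.95, maf_min = "auto"), qc)
  model <- utils::modifyList(list(aggregate = "records"), model)
  cv <- utils::modifyList(list(k = 10L, seed = 1L), cv)
  metrics <- utils::modifyList(
    list(tf = 2, tgws = 1, desired = seq(0.4, 0.9, by = 0.1),
         scale = "reliability", h2_g = NULL), metrics)
  transfer <- utils::modifyList(list(pairs = NULL), transfer %||% list())
  structure(list(simulation = simulation, inputs = inputs, qc = qc,
                 model = model, cv = cv, metrics = metrics,
                 transfer = transfer),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("simulation", "inputs", "qc", "model", "cv", "metrics",
             "transfer")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$transfer$pairs)) {
    raw$transfer$pairs <- lapply(raw$transfer$pairs, as.integer)
  }
  do.call(run_config, raw)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full genomic-selection analysis pipeline
#'
#' Executes simulate (optional) -> marker QC -> per-harvest tenfold CV ->
#' selection metrics -> cross-harvest transfer, writing every stage's
#' outputs plus a manifest (inputs, seed, package version, output
#' checksums) and a machine-readable `summary.json` to `out_dir`.
#' Re-running with the same configuration reproduces all numeric outputs.
#'
#' @param config a [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @param out_dir output directory, created if absent.
#' @param seed overrides both the simulation seed and the CV fold seed
#'   when given.
#' @return Invisibly, a list with the per-stage results (`qc`, `cv`,
#'   `metrics`, `transfer`, `summary`, `out_dir`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(f) { files <<- c(files, f); f }

  if (!is.null(seed)) {
    config$cv$seed <- as.integer(seed)
    if (!is.null(config$simulation)) config$simulation$seed <- as.integer(seed)
  }

  # --- stage: simulate (or load) -------------------------------------
  if (!is.null(config$simulation)) {
    stage_log("simulate", "generating synthetic population")
    pop <- run_stage("simulate", {
      cfg <- do.call(sim_config, config$simulation)
      simulate_population(cfg)
    })
    geno <- pop$genotypes
    pheno <- pop$phenotypes
    write_genotypes_tsv(geno, emit(file.path(out_dir, "genotypes.tsv")))
    write_genotypes_vcf(geno, emit(file.path(out_dir, "genotypes.vcf")))
    write_phenotypes_csv(pheno, emit(file.path(out_dir, "phenotypes.csv")))
    tbv <- data.frame(individual = rownames(pop$truth$true_breeding_values),
                      pop$truth$true_breeding_values, check.names = FALSE)
    utils::write.csv(tbv, emit(file.path(out_dir, "truth_tbv.csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(pop$pedigree, emit(file.path(out_dir, "pedigree.csv")),
                     row.names = FALSE, quote = FALSE)
  } else {
    stage_log("simulate", "skipped; loading inputs")
    gp <- config$inputs$genotypes
    geno <- run_stage("load", {
      if (grepl("\\.vcf(\\.gz)?$", gp)) read_genotypes_vcf(gp)
      else read_genotypes_tsv(gp)
    })
    pheno <- run_stage("load", read_phenotypes_csv(config$inputs$phenotypes))
  }

  # --- stage: qc -----------------------------------------------------
  stage_log("qc", "call rate >= %.2f, MAF > %s", config$qc$call_rate_min,
            if (identical(config$qc$maf_min, "auto")) "auto (1/sqrt(2N))"
            else format(config$qc$maf_min))
  qcres <- run_stage("qc", apply_qc(geno,
                                    call_rate_min = config$qc$call_rate_min,
                                    maf_min = config$qc$maf_min))
  geno_qc <- qcres$genotypes
  stage_log("qc", "%d of %d markers retained",
            qcres$report$n_retained, qcres$report$n_input_markers)
  utils::write.csv(qcres$report$markers,
                   emit(file.path(out_dir, "qc_report.csv")),
                   row.names = FALSE, quote = FALSE)

  harvests <- sort(unique(pheno$harvest))
  aggregate <- config$model$aggregate

  # --- stage: cv -----------------------------------------------------
  cvs <- list(); fits <- list()
  for (h in harvests) {
    stage_log("cv", "harvest %s: %d-fold CV", h, config$cv$k)
    cvs[[as.character(h)]] <- run_stage("cv", cross_validate(
      geno_qc, pheno, harvest = h, k = config$cv$k,
      seed = config$cv$seed, aggregate = aggregate))
    ph <- pheno[pheno$harvest == h, , drop = FALSE]
    form <- if (aggregate == "records" && length(unique(ph$block)) > 1L) {
      value ~ factor(block)
    } else {
      value ~ 1
    }
    if (aggregate == "means") {
      mu <- tapply(ph$value, ph$individual, mean)
      ph <- data.frame(individual = names(mu), value = as.numeric(mu))
    }
    fits[[as.character(h)]] <- run_stage("cv", rrblup(
      form, data = ph, genotypes = geno_qc))
    oof <- cvs[[as.character(h)]]$oof_gebv
    utils::write.csv(
      data.frame(individual = names(oof), oof_gebv = as.numeric(oof),
                 obs_mean = as.numeric(cvs[[as.character(h)]]$obs_mean)),
      emit(file.path(out_dir, sprintf("cv_harvest%s.csv", h))),
      row.names = FALSE, quote = FALSE)
  }

  # --- stage: metrics ------------------------------------------------
  stage_log("metrics", "selection statistics per harvest")
  mets <- list()
  for (h in harvests) {
    mets[[as.character(h)]] <- run_stage("metrics", metrics_report(
      cvs[[as.character(h)]], fits[[as.character(h)]],
      h2_g = config$metrics$h2_g,
      tf = config$metrics$tf, tgws = config$metrics$tgws,
      desired = config$metrics$desired, scale = config$metrics$scale))
  }
  ni_all <- do.call(rbind, lapply(names(mets), function(h) {
    cbind(harvest = h, mets[[h]]$ni_table)
  }))
  utils::write.csv(ni_all, emit(file.path(out_dir, "ni_table.csv")),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    lapply(mets, function(m) m[c("r_yg", "h2_a", "h2_g", "r_g_hat",
                                 "r_y_hat", "pev", "sigma2_g_pop", "n_qtl",
                                 "efficiency", "irps_percent")]),
    emit(file.path(out_dir, "metrics.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- stage: transfer -----------------------------------------------
  pairs <- config$transfer$pairs
  if (is.null(pairs) && length(harvests) > 1L) {
    pairs <- list()
    for (i in seq_along(harvests)) {
      for (j in seq_along(harvests)) {
        if (i < j) pairs[[length(pairs) + 1L]] <- c(harvests[i], harvests[j])
      }
    }
  }
  transfers <- list()
  for (pr in pairs) {
    stage_log("transfer", "harvest %s -> %s", pr[1], pr[2])
    tr <- run_stage("transfer", transfer_accuracy(
      geno_qc, pheno, train_harvest = pr[1], test_harvest = pr[2],
      k = config$cv$k, seed = config$cv$seed, aggregate = aggregate))
    key <- sprintf("%s_to_%s", pr[1], pr[2])
    transfers[[key]] <- tr
    utils::write.csv(
      data.frame(individual = names(tr$oof_gebv),
                 gebv_train = as.numeric(tr$oof_gebv),
                 ebv_test = as.numeric(tr$target_values)),
      emit(file.path(out_dir, sprintf("transfer_%s.csv", key))),
      row.names = FALSE, quote = FALSE)
  }

  # --- summary + manifest --------------------------------------------
  summary <- list(
    seed = config$cv$seed,
    n_individuals = nrow(geno_qc),
    n_markers_input = qcres$report$n_input_markers,
    n_markers_retained = qcres$report$n_retained,
    maf_threshold = qcres$report$maf_min,
    harvests = as.list(stats::setNames(lapply(names(cvs), function(h) list(
      r_yg = cvs[[h]]$r_yg,
      h2 = fits[[h]]$varcomp$h2,
      sigma2_g = fits[[h]]$varcomp$sigma2_g,
      sigma2_e = fits[[h]]$varcomp$sigma2_e,
      gws_accuracy = mets[[h]]$r_g_hat,
      phenotypic_accuracy = mets[[h]]$r_y_hat,
      n_qtl = mets[[h]]$n_qtl,
      efficiency = mets[[h]]$efficiency,
      irps_percent = mets[[h]]$irps_percent
    )), names(cvs))),
    transfers = lapply(transfers, function(t) t$accuracy)
  )
  jsonlite::write_json(summary, emit(file.path(out_dir, "summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "harvestgs",
    version = as.character(utils::packageVersion("harvestgs")),
    stages = c("simulate", "qc", "cv", "metrics", "transfer"),
    seed = config$cv$seed,
    config = unclass(config),
    outputs = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)

  report <- c(
    "Genomic selection pipeline report",
    sprintf("Individuals: %d   Markers retained: %d / %d",
            nrow(geno_qc), qcres$report$n_retained,
            qcres$report$n_input_markers),
    sprintf("MAF threshold applied: %.4f", qcres$report$maf_min),
    "",
    "Per-harvest results:",
    vapply(names(cvs), function(h) sprintf(
      "  harvest %s: h2 = %.3f, r_yg = %.3f, r_gg = %.3f, IRPS = %.1f%%",
      h, fits[[h]]$varcomp$h2, cvs[[h]]$r_yg, mets[[h]]$r_g_hat,
      mets[[h]]$irps_percent), character(1)),
    "",
    "Transfers:",
    vapply(names(transfers), function(k) sprintf(
      "  %s: accuracy = %.3f", k, transfers[[k]]$accuracy), character(1))
  )
  writeLines(report, file.path(out_dir, "report.txt"))

  invisible(list(qc = qcres$report, cv = cvs, fits = fits, metrics = mets,
                 transfer = transfers, summary = summary,
                 out_dir = out_dir))
}
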