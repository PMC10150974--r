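#' Default pipeline configuration
#'
#' @param input_prefix PLINK triplet stem to analyse; `NULL` simulates a
#'   cohort from `sim` instead.
#' @param out_dir artefact directory.
#' @param sim a [sim_config()] (used when `input_prefix` is `NULL`).
#' @param qc a [qc_thresholds()].
#' @param experiments which of the five experiments to run.
#' @param experiment an [experiment_config()] shared by all experiments.
#' @param seed global seed, propagated to every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(input_prefix = NULL, out_dir = "gwaswd-run",
                       sim = sim_config(), qc = qc_thresholds(),
                       experiments = 1:5,
                       experiment = experiment_config(),
                       seed = 1L) {
  list(input_prefix = input_prefix, out_dir = out_dir, sim = sim, qc = qc,
       experiments = experiments, experiment = experiment,
       seed = as.integer(seed))
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML or JSON configuration, applies defaults, and checks every
#' constraint, aggregating all violations rather than stopping at the
#' first.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return A `run_config` on success; otherwise an error listing every
#'   violation.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  raw <- raw %||% list()

  errors <- character(0)
  note <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))

  if (!is.null(raw[["input_prefix"]]) &&
      !all(file.exists(paste0(raw[["input_prefix"]],
                              c(".bed", ".bim", ".fam")))))
    note("input_prefix: path not found (%s)", raw[["input_prefix"]])

  qc_args <- raw[["qc"]] %||% list()
  for (nm in c("snp_missing_max", "sample_missing_max", "maf_min")) {
    v <- qc_args[[nm]]
    if (!is.null(v) && (!is.numeric(v) || v < 0 || v > 1))
      note("qc$%s: frequency out of range [0, 1]", nm)
  }
  for (nm in c("hwe_controls_p", "hwe_cases_p")) {
    v <- qc_args[[nm]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0 || v >= 1))
      note("qc$%s: significance out of range (0, 1)", nm)
  }
  exps <- raw[["experiments"]] %||% 1:5
  if (!all(exps %in% 1:5)) note("experiments: must be within 1..5")
  ec_args <- raw[["experiment"]] %||% list()
  if (!is.null(ec_args$quartile) &&
      (ec_args$quartile <= 0 || ec_args$quartile > 1))
    note("experiment$quartile: fraction out of range (0, 1]")
  if (!is.null(ec_args$leakage) &&
      !ec_args$leakage %in% c("fold-safe", "paper-protocol"))
    note("experiment$leakage: must be fold-safe or paper-protocol")
  seed <- raw[["seed"]] %||% 1L
  if (!is.numeric(seed) || seed != floor(seed))
    note("seed: must be an integer")

  sim_args <- raw[["sim"]] %||% list()
  cfg <- tryCatch({
    qc <- do.call(qc_thresholds, qc_args[names(qc_args) %in%
                                           names(formals(qc_thresholds))])
    sim <- do.call(sim_config, sim_args[names(sim_args) %in%
                                          names(formals(sim_config))])
    ec <- do.call(experiment_config,
                  ec_args[names(ec_args) %in%
                            names(formals(experiment_config))])
    run_config(input_prefix = raw[["input_prefix"]],
               out_dir = raw[["out_dir"]] %||% "gwaswd-run",
               sim = sim, qc = qc, experiments = as.integer(exps),
               experiment = ec, seed = as.integer(seed))
  }, error = function(e) {
    note("%s", conditionMessage(e))
    NULL
  })
  if (length(errors))
    stopf("invalid configuration:\n%s",
          paste0("  - ", errors, collapse = "\n"))
  cfg
}

.report_to_list <- function(rep) {
  models <- lapply(rep$models, function(m) {
    h <- m$holdout
    list(holdout = list(accuracy = h$accuracy, precision = h$precision,
                        recall = h$recall, f1 = h$f1,
                        roc_auc = h$roc$auc, pr_auc = h$pr$auc,
                        counts = unclass(h$counts)),
         cv = m$cv)
  })
  list(exp_id = rep$exp_id, n_features = length(rep$features),
       features = rep$features,
       n_deep_snps = length(rep$deep_snps %||% character(0)),
       models = models)
}

#' Run the full pipeline
#'
#' Simulate (or read) a cohort, run QC, the association scan, feature
#' selection and the requested experiments, extract rules from the
#' experiment-1 random forest, and write every artefact plus a manifest
#' with stage file hashes under `config$out_dir`.
#'
#' @param config a [run_config()] (or a path accepted by
#'   [validate_config()]).
#' @return The manifest, invisibly; artefacts are on disk.
#' @export
pipeline_run <- function(config = run_config()) {
  if (is.character(config)) config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  logf <- function(fmt, ...) message(sprintf(paste0("[gwaswd] ", fmt), ...))

  if (is.null(config$input_prefix)) {
    logf("simulate: %d cases / %d controls",
         config$sim$n_cases, config$sim$n_controls)
    sim <- simulate_cohort(config$sim)
    write_cohort(sim$G, sim$truth, out("cohort"))
    G <- sim$G
  } else {
    logf("read: %s", config$input_prefix)
    G <- read_plink(config$input_prefix)
  }

  qc_res <- run_qc(G, config$qc)
  for (s in qc_res$report$steps)
    logf("qc %-18s removed %d %ss", s$step, s$n_removed, s$item_type)
  jsonlite::write_json(
    list(dim_in = qc_res$report$dim_in, dim_out = qc_res$report$dim_out,
         steps = lapply(qc_res$report$steps, function(s)
           s[c("step", "item_type", "n_removed", "ids")])),
    out("qc_report.json"), auto_unbox = TRUE, digits = NA)
  write_plink(qc_res$G, out("qc"))

  assoc <- run_association(qc_res$G)
  utils::write.table(assoc, out("association.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lambda <- genomic_lambda(assoc$p[!is.na(assoc$p)])
  jsonlite::write_json(list(lambda = lambda,
                            n_tests = sum(!is.na(assoc$p))),
                       out("inflation.json"), auto_unbox = TRUE, digits = NA)
  logf("association: %d SNPs scanned, lambda %.3f",
       nrow(assoc), lambda)

  ec <- config$experiment
  ec$seed <- config$seed
  reports <- list()
  for (e in config$experiments) {
    logf("experiment %d", e)
    rep <- run_experiment(e, qc_res$G, ec)
    reports[[as.character(e)]] <- rep
    jsonlite::write_json(.report_to_list(rep),
                         out(sprintf("exp%d_report.json", e)),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("1" %in% names(reports) &&
      !is.null(reports[["1"]]$models$rf)) {
    rep1 <- reports[["1"]]
    X <- one_hot_encode(qc_res$G)$X
    te <- rep1$split$test
    rules <- extract_rules(rep1$models$rf$model,
                           X[te, rep1$features, drop = FALSE],
                           phenotype01(qc_res$G)[te])
    write_rules(rules, out("rules.txt"))
    jsonlite::write_json(
      lapply(rules$rules, function(r)
        list(conditions = paste(r$features, r$values, sep = "="),
             class = r$class, support = r$support,
             confidence = r$confidence)),
      out("rules.json"), auto_unbox = TRUE, digits = NA)
  }

  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("gwaswd")),
    seed = config$seed,
    experiments = config$experiments,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(config$out_dir, files))), files)))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
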