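#' Default end-to-end run configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]. All
#' thresholds default to the package's standard analysis values.
#' The configuration is plain-list / YAML serializable and is echoed
#' verbatim into the output directory of every run.
#'
#' @param out_dir Output directory for artifacts.
#' @param simulate `NULL`, or a list of [sim_config()] arguments plus
#'   optional `overlap_fraction` (simulates a train/test cohort pair).
#' @param input `NULL`, or a list with `train_ped`, `train_map` and
#'   optionally `test_ped`, `test_map`.
#' @param qc List of [apply_qc()] thresholds; `enabled = FALSE` skips QC.
#' @param model List of [ma_risk()] criteria.
#' @param crossval `NULL` or list with `k`.
#' @param sweep `NULL` or list with `maf_ceilings`, `p_grid`,
#'   `include_haplotype`.
#' @param seed Root seed of the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, simulate = list(), input = NULL,
                       qc = list(enabled = TRUE),
                       model = list(maf_ceiling = 0.4, p_threshold = 0.05,
                                    direction = "cases_enriched"),
                       crossval = list(k = 10L),
                       sweep = NULL, seed = 1L) {
  cfg <- list(out_dir = out_dir, simulate = simulate, input = input,
              qc = qc, model = model, crossval = crossval, sweep = sweep,
              seed = as.integer(seed))
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @return For `write_run_config`, invisibly `path`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — simulate (or read PED/MAP),
#' quality control, minor-allele statistics (MAC + group ANOVA), risk
#' model training, scoring, external evaluation, k-fold cross-validation
#' and the model sweep — writing every intermediate table as
#' tab-separated text into `config$out_dir` together with a verbatim
#' YAML echo of the configuration and a log naming the package version,
#' seed and config hash. A stage failure aborts with the stage name;
#' artifacts of completed stages are retained.
#'
#' @param config A [run_config()] list or the path to its YAML file.
#' @return Invisibly, a list with the main in-memory results (`qc`,
#'   `mac_anova`, `model`, `evaluation`, `crossval`, `sweep`,
#'   `artifacts`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  echo <- file.path(out, "config_echo.yaml")
  write_run_config(config, echo)
  cfg_hash <- unname(tools::md5sum(echo))
  log_path <- file.path(out, "run_log.txt")
  logln <- function(...) cat(paste0(format(Sys.time(), "%H:%M:%S "), ...,
                                    "\n"), file = log_path, append = TRUE)
  cat(sprintf("maburden %s | seed %d | config %s\n",
              as.character(utils::packageVersion("maburden")),
              config$seed, cfg_hash), file = log_path)
  stage <- function(name, expr) {
    logln("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  results <- list(artifacts = c(config = echo, log = log_path))
  add_artifact <- function(name, path) {
    a <- results$artifacts; a[[name]] <- path
    results$artifacts <<- a
  }
  tsv <- function(df, name) {
    path <- file.path(out, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    add_artifact(name, path)
    path
  }

  cohorts <- stage("input", {
    if (!is.null(config$input)) {
      train <- read_ped_map(config$input$train_ped, config$input$train_map)
      test <- if (!is.null(config$input$test_ped))
        read_ped_map(config$input$test_ped, config$input$test_map)
      list(train = train, test = test)
    } else {
      sim_args <- config$simulate
      overlap <- sim_args$overlap_fraction %||% 1
      sim_args$overlap_fraction <- NULL
      sim_args$seed <- sim_args$seed %||% config$seed
      cc <- do.call(sim_config, sim_args)
      pair <- simulate_cohort_pair(cc, cc, snp_overlap_fraction = overlap)
      tsv(pair$a$truth, "truth_train")
      tsv(pair$b$truth, "truth_test")
      list(train = pair$a$cohort, test = pair$b$cohort)
    }
  })

  if (isTRUE(config$qc$enabled %||% TRUE)) {
    qc <- stage("quality_control", {
      args <- config$qc[setdiff(names(config$qc), "enabled")]
      do.call(apply_qc, c(list(cohorts$train), args))
    })
    cohorts$train <- qc$matrix
    tsv(qc$report, "qc_report")
    results$qc <- qc$report
  }

  results$mac_anova <- stage("ma_statistics", {
    ma_set <- compute_control_maf(cohorts$train)
    mac <- compute_mac(cohorts$train, ma_set)
    tsv(mac, "mac_profile")
    an <- compare_group_means(split(mac$mac[!mac$undefined],
                                    mac$phenotype[!mac$undefined]))
    tsv(data.frame(F = an$F, p_value = an$p_value), "mac_anova")
    an
  })

  results$model <- stage("train", {
    mod <- do.call(ma_risk, c(list(cohorts$train), config$model))
    tsv(mod$association, "association")
    tsv(mod$snps, "risk_model")
    tsv(mod$train_scores, "scores_train")
    mod
  })

  if (!is.null(cohorts$test)) {
    results$evaluation <- stage("external_validation", {
      ev <- external_validate(cohorts$train, cohorts$test,
                              model = results$model)
      tsv(ev$scores, "scores_test")
      tsv(ev$report$roc, "roc_test")
      tsv(data.frame(auc = ev$report$auc,
                     auc_lo = ev$report$auc_ci[1L],
                     auc_hi = ev$report$auc_ci[2L],
                     tpr = ev$report$tpr,
                     tpr_lo = ev$report$tpr_ci[1L],
                     tpr_hi = ev$report$tpr_ci[2L],
                     threshold = ev$report$threshold), "evaluation")
      ev$report
    })
  }

  if (!is.null(config$crossval)) {
    results$crossval <- stage("crossval", {
      cv <- kfold_cross_validate(cohorts$train,
                                 k = config$crossval$k %||% 10L,
                                 maf_ceiling = config$model$maf_ceiling %||% 0.4,
                                 p_threshold = config$model$p_threshold %||% 0.05,
                                 seed = config$seed)
      tsv(cv$folds, "crossval")
      cv
    })
  }

  if (!is.null(config$sweep) && !is.null(cohorts$test)) {
    results$sweep <- stage("sweep", {
      sw <- do.call(model_sweep,
                    c(list(cohorts$train, cohorts$test), config$sweep))
      tsv(sw, "sweep")
      sw
    })
  }
  logln("done")
  invisible(results)
}
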