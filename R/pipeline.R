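#' Read and validate a pipeline configuration
#'
#' Configurations are YAML files with a `version`, a global `seed`, an output
#' directory `outdir`, and one block per requested stage among `simulate`,
#' `fit`, `select`, `counterfactual`, `evaluate`. Unknown top-level keys are
#' a validation error. Every stochastic stage derives its stream from the
#' global seed plus the stage name.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  known <- c("version", "seed", "outdir", "normalize",
             "simulate", "fit", "select", "counterfactual", "evaluate", "files")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg$version <- cfg$version %||% 1L
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (is.null(cfg$outdir)) stop("config requires an outdir")
  structure(cfg, class = "run_config")
}

load_pipeline_collection <- function(cfg, state) {
  if (!is.null(state$collection)) return(state$collection)
  f <- cfg$files
  if (is.null(f)) stop("no simulate stage and no input files configured")
  read_study(f$counts, f$samples, f$interventions, f$covariates %||% NULL)
}

#' Run the configured pipeline stages
#'
#' Executes the requested stages in order (simulate, fit, select,
#' counterfactual, evaluate), writing each stage's artifacts under
#' `cfg$outdir` and a `manifest.json` recording the package version, the
#' per-stage derived seeds, input checksums and wall-clock times. Running the
#' same config and seed twice yields byte-identical TSV outputs.
#'
#' @param cfg a `run_config` from [read_run_config()] (or a path to one).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg) || !inherits(cfg, "run_config")) cfg <- read_run_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(version = as.character(utils::packageVersion("tfmicro")),
                   config_version = cfg$version, seed = cfg$seed,
                   stages = list())
  if (!is.null(cfg$files))
    manifest$inputs <- lapply(cfg$files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  state <- list()
  stamp <- function(name, seed, t0, extra = list()) {
    manifest$stages[[name]] <<- c(list(seed = seed,
                                       wall_clock_sec = round(as.numeric(Sys.time()) - t0, 3)),
                                  extra)
  }
  norm_spec <- normalization_spec(cfg$normalize %||% "none")

  if (!is.null(cfg$simulate)) {
    p <- cfg$simulate; t0 <- as.numeric(Sys.time())
    seed <- derive_seed(cfg$seed, "simulate")
    tf_log("stage simulate: J = ", p$J, ", subjects = ", p$subjects, ", T = ", p$T)
    params <- generate_params(
      J = p$J, D = p$D %||% 1L, S = p$S %||% 0L, rank = p$rank %||% 2L,
      pi_nonnull = p$pi_nonnull %||% 0.2,
      signal_strength = p$signal %||% 1,
      P = p$P %||% 2L, Q = p$Q %||% 2L, phi = p$phi %||% 1,
      lambda = p$lambda %||% 0.1, alpha = p$alpha %||% 10, seed = seed)
    sim <- simulate_dataset(params, n_subjects = p$subjects, T_len = p$T,
                            seed = derive_seed(seed, "counts"))
    comment <- paste0("tfmicro v", manifest$version, " seed=", cfg$seed)
    write_study(sim$collection, cfg$outdir, comment = comment)
    truth_df <- data.frame(taxon = rownames(sim$truth), sim$truth)
    write.table(truth_df, file.path(cfg$outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    pj <- sim$params; pj$A <- NULL; pj$B <- NULL; pj$C <- NULL; pj$Sigma <- NULL
    jsonlite::write_json(unclass(pj), file.path(cfg$outdir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
    state$collection <- sim$collection
    state$truth <- sim$truth
    stamp("simulate", seed, t0)
  }

  collection <- load_pipeline_collection(cfg, state)
  if (norm_spec$method != "none")
    collection <- apply_normalization(collection, norm_spec)

  if (!is.null(cfg$fit)) {
    p <- cfg$fit; t0 <- as.numeric(Sys.time())
    seed <- derive_seed(cfg$seed, "fit")
    tf_log("stage fit: P = ", p$P %||% 2L, ", Q = ", p$Q %||% 2L)
    config <- boosting_config(
      n_iterations = p$iterations %||% 500L,
      learning_rate = p$learning_rate %||% 0.1,
      max_interactions = p$max_interactions %||% 20L,
      screen_method = p$screen_method %||% "none",
      random_seed = seed)
    design <- tile_windows(collection, p$P %||% 2L, p$Q %||% 2L, stride = 1L)
    model <- fit_transfer(design, config = config,
                          normalization = collection$normalization)
    write_tf_model(model, file.path(cfg$outdir, "model.json"))
    state$model <- model
    stamp("fit", seed, t0)
  }

  if (!is.null(cfg$select)) {
    p <- cfg$select; t0 <- as.numeric(Sys.time())
    seed <- derive_seed(cfg$seed, "select")
    config <- boosting_config(
      n_iterations = p$iterations %||% 500L,
      learning_rate = p$learning_rate %||% 0.1,
      screen_method = p$screen_method %||% "none", random_seed = seed)
    tf_log("stage select: q = ", p$q %||% 0.2, ", splits = ", p$n_splits %||% 25L)
    res <- multi_split_select(collection, config,
                              P = p$P %||% 2L, Q = p$Q %||% 2L,
                              q = p$q %||% 0.2,
                              n_splits = p$n_splits %||% 25L, seed = seed)
    sel_df <- data.frame(
      taxon = collection$taxa,
      inclusion_rate = as.numeric(res$inclusion_rates),
      selected = seq_along(collection$taxa) %in% res$selected)
    write.table(sel_df, file.path(cfg$outdir, "mirrors.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(q = res$q, n_splits = res$n_splits, seed = seed,
           thresholds = vapply(res$splits, `[[`, 0, "threshold")),
      file.path(cfg$outdir, "mirrors_summary.json"),
      auto_unbox = TRUE, digits = NA)
    state$selection <- res
    stamp("select", seed, t0)
  }

  if (!is.null(cfg$counterfactual)) {
    p <- cfg$counterfactual; t0 <- as.numeric(Sys.time())
    seed <- derive_seed(cfg$seed, "counterfactual")
    model <- state$model %||% read_tf_model(p$model)
    h <- p$horizon %||% 5L
    on_v <- p$on_value %||% 1; off_v <- p$off_value %||% 0
    tf_log("stage counterfactual: horizon = ", h)
    res <- simulate_counterfactuals(
      model, collection,
      W_on = matrix(on_v, model$D, h), W_off = matrix(off_v, model$D, h),
      horizon = h)
    write_counterfactuals(res, file.path(cfg$outdir, "counterfactuals.tsv"))
    stamp("counterfactual", seed, t0)
  }

  if (!is.null(cfg$evaluate)) {
    p <- cfg$evaluate; t0 <- as.numeric(Sys.time())
    seed <- derive_seed(cfg$seed, "evaluate")
    tf_log("stage evaluate: folds = ", p$folds %||% 4L)
    config <- boosting_config(n_iterations = p$iterations %||% 500L,
                              random_seed = seed)
    rep <- cv_forecast_mae(collection, P = p$P %||% 2L, Q = p$Q %||% 2L,
                           config = config, n_folds = p$folds %||% 4L,
                           h_max = p$h_max %||% 5L, seed = seed)
    jsonlite::write_json(
      list(mae_by_horizon = as.list(rep$mae_by_horizon), seed = seed),
      file.path(cfg$outdir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
    write.table(data.frame(fold = rownames(rep$mae), rep$mae),
                file.path(cfg$outdir, "evaluation_folds.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    stamp("evaluate", seed, t0)
  }

  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
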