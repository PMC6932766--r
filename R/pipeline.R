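#' Read a run configuration from YAML
#'
#' Schema (version 1), all blocks optional with package defaults:
#' ```yaml
#' version: 1
#' output_dir: runs/demo
#' split_seed: 17
#' experiments: [NC/AD, NC/LMCI, NC/EMCI, NC/SMC]
#' prep:    {target_size: 200, segment_size: 10, crop_threshold: 0}
#' net:     {n_hidden: 45, learning_rate: 0.00079, momentum: 0.90,
#'           min_rms: 0.003, max_epochs: 50000, seed: 1}
#' phantom: {n_per_class: 100, seed: 7, noise_sigma: 0.08}
#' # alternatively point at real data instead of a phantom block:
#' # manifest: data/manifest.csv
#' # features: runs/demo/features.csv   # reuse precomputed features
#' ```
#'
#' @param path YAML file.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$version) && raw$version != 1)
    stop_amypet("unsupported run config version: %s", raw$version,
                class = "amypet_validation_error")
  build_run_config(raw)
}

build_run_config <- function(raw) {
  exps <- raw$experiments %||% c("NC/AD", "NC/LMCI", "NC/EMCI", "NC/SMC")
  allowed <- paste0("NC/", setdiff(AMYPET_CLASSES, "NC"))
  if (!all(exps %in% allowed))
    stop_amypet("experiments must be drawn from {%s}",
                paste(allowed, collapse = ", "),
                class = "amypet_validation_error")
  cfg <- list(
    prep = do.call(prep_config, raw$prep %||% list()),
    net = do.call(network_config, raw$net %||% list()),
    phantom = if (!is.null(raw$phantom)) {
      ph <- raw$phantom
      if (!is.null(ph$effect_size)) ph$effect_size <- unlist(ph$effect_size)
      do.call(phantom_config, ph)
    },
    manifest = raw$manifest,
    features = raw$features,
    experiments = exps,
    split_seed = as.integer(raw$split_seed %||% 1L),
    output_dir = raw$output_dir %||% "amypet-run"
  )
  structure(cfg, class = "run_config")
}

#' Run the full workflow: (simulate) -> prepare -> train/evaluate
#'
#' Resolves the input features (precomputed CSV, a manifest of images, or a
#' freshly simulated phantom dataset, in that order of preference), then runs
#' each configured binary experiment with an independent network (experiment
#' `i` uses network seed `net$seed + i - 1`). Writes per-experiment report
#' JSONs, a `summary.csv` mirroring the published results-table columns
#' (sensitivity/specificity/accuracy), and a `provenance.json` with every
#' seed and a hash of the resolved configuration, sufficient to reproduce
#' the run exactly.
#'
#' @param cfg a `run_config` from [read_run_config()], or a raw list with the
#'   same fields.
#' @return Invisibly, a list with the summary `data.frame` and the list of
#'   `experiment_result`s.
#' @export
run_all <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- build_run_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_amypet("[%s] %s", name, conditionMessage(e),
                  class = "amypet_stage_error"))
  }

  features <- if (!is.null(cfg$features)) {
    stage("load-features",
          utils::read.csv(cfg$features, stringsAsFactors = FALSE))
  } else {
    manifest <- if (!is.null(cfg$manifest)) {
      stage("load-manifest", load_manifest(cfg$manifest))
    } else if (!is.null(cfg$phantom)) {
      stage("simulate",
            generate_dataset(cfg$phantom, file.path(cfg$output_dir, "data")))
    } else {
      stop_amypet("[input] run config needs one of: features, manifest, phantom",
                  class = "amypet_stage_error")
    }
    f <- stage("prepare", prepare_manifest(manifest, cfg$prep))
    utils::write.csv(f, file.path(cfg$output_dir, "features.csv"),
                     row.names = FALSE)
    f
  }

  results <- list()
  for (i in seq_along(cfg$experiments)) {
    exp_name <- cfg$experiments[i]
    classes <- strsplit(exp_name, "/", fixed = TRUE)[[1]]
    net_cfg <- cfg$net
    net_cfg$seed <- cfg$net$seed + i - 1L  # independent network per experiment
    res <- stage(exp_name,
                 run_experiment(features, classes, net_cfg, cfg$split_seed))
    results[[exp_name]] <- res
    rep_path <- file.path(cfg$output_dir,
                          paste0("report-", gsub("/", "-", exp_name), ".json"))
    jsonlite::write_json(list(
      experiment = exp_name,
      counts = unclass(res$report$counts),
      sensitivity = res$report$sensitivity,
      specificity = res$report$specificity,
      accuracy = res$report$accuracy,
      train_accuracy = res$train_accuracy,
      epochs_run = res$train$epochs_run,
      final_rms = res$train$final_rms,
      converged = res$train$converged,
      net_seed = net_cfg$seed,
      split_seed = cfg$split_seed
    ), rep_path, auto_unbox = TRUE, digits = NA)
  }

  summary_df <- data.frame(
    experiment = names(results),
    sensitivity = vapply(results, function(r) r$report$sensitivity, 0),
    specificity = vapply(results, function(r) r$report$specificity, 0),
    accuracy = vapply(results, function(r) r$report$accuracy, 0),
    train_accuracy = vapply(results, function(r) r$train_accuracy, 0),
    epochs = vapply(results, function(r) r$train$epochs_run, 0L),
    final_rms = vapply(results, function(r) r$train$final_rms, 0),
    row.names = NULL
  )
  utils::write.csv(summary_df, file.path(cfg$output_dir, "summary.csv"),
                   row.names = FALSE)

  cfg_json <- jsonlite::toJSON(
    cfg[c("experiments", "split_seed")] |>
      c(list(prep = unclass(cfg$prep), net = unclass(cfg$net),
             phantom = if (!is.null(cfg$phantom)) unclass(cfg$phantom))),
    auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("amypet")),
    config = jsonlite::fromJSON(as.character(cfg_json)),
    config_md5 = unname(tools::md5sum(tmp)),
    net_seeds = cfg$net$seed + seq_along(cfg$experiments) - 1L,
    split_seed = cfg$split_seed,
    phantom_seed = if (!is.null(cfg$phantom)) cfg$phantom$seed
  ), file.path(cfg$output_dir, "provenance.json"),
  auto_unbox = TRUE, digits = NA)
  unlink(tmp)

  invisible(list(summary = summary_df, results = results))
}
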