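# End-to-end orchestration: simulate -> features -> train -> predict ->
# vote -> chain -> evaluate, with stage caching keyed on input hashes and
# the relevant configuration subset, and a JSON run manifest.

#' Pipeline run configuration
#'
#' Collects every path and parameter of a full run. Defaults follow the
#' method: window 50 bp, expression filter mean 10, vote threshold 3,
#' bootstrap 100 x 10%, 10 CV folds and 10 optimization iterations. If
#' `gff`/`coverage` are NULL a synthetic data set is simulated into the
#' output directory first.
#'
#' @param out_dir Output directory for all artifacts.
#' @param gff Path to a GFF3 annotation (NULL = simulate).
#' @param coverage Character vector of per-base coverage file paths, one
#'   per sample/replicate (NULL = simulate).
#' @param labels Path to a pair-label TSV (NULL = simulate, or predict
#'   without training labels).
#' @param model Optional path to a saved suite directory; when given the
#'   training stage is skipped and this model is used.
#' @param seed Master seed.
#' @param window,offset,min_mean,same_strand_only Featurization settings.
#' @param threshold Vote threshold k.
#' @param min_replicates,consensus Replicate-consensus settings (consensus
#'   is applied when more than one coverage sample is present).
#' @param optimize,opt_iterations,folds Hyperparameter optimization
#'   settings.
#' @param n_boot,fraction Bootstrap evaluation settings.
#' @param simulate List of [simulation_config()] overrides for the
#'   simulation stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, gff = NULL, coverage = NULL, labels = NULL,
                       model = NULL, seed = 1009731L, window = 50L,
                       offset = 0L, min_mean = 10, same_strand_only = FALSE,
                       threshold = 3L, min_replicates = 2L,
                       consensus = "unanimous", optimize = FALSE,
                       opt_iterations = 10L, folds = 10L, n_boot = 100L,
                       fraction = 0.10, simulate = list()) {
  structure(as.list(environment()), class = "run_config")
}

#' Read / write a run configuration as JSON
#' @param path JSON file path.
#' @param config A [run_config()].
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` the path, invisibly.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(vals$simulate)) vals$simulate <- as.list(vals$simulate)
  cfg <- do.call(run_config, vals[!vapply(vals, is.null, logical(1))])
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config[!vapply(config, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# hash a stage: md5 over parameter string + input-file md5s
.stage_key <- function(params, input_files = character(0)) {
  input_files <- input_files[file.exists(input_files)]
  hashes <- if (length(input_files)) unname(tools::md5sum(input_files)) else
    character(0)
  txt <- paste(c(vapply(params, function(p) paste(format(p), collapse = ","),
                        character(1)), hashes), collapse = ";")
  f <- tempfile(); writeLines(txt, f); on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' Executes the stages in order (simulate when no inputs are given,
#' features, train, predict, vote, chain, evaluate when labels exist),
#' writing all artifacts and a `manifest.json` (inputs, md5 hashes, seeds,
#' package version, per-stage status) into `config$out_dir`. A stage whose
#' outputs exist and whose inputs/parameters are unchanged is skipped
#' unless `force = TRUE`.
#'
#' @param config A [run_config()].
#' @param force Re-run all stages regardless of the cache.
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  manifest_path <- file.path(out, "manifest.json")
  prev <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL
  stages <- list()
  run_stage <- function(name, params, inputs, outputs, fun) {
    key <- .stage_key(params, inputs)
    cached <- !force && all(file.exists(outputs)) &&
      !is.null(prev) && identical(prev$stages[[name]]$key, key)
    if (cached) {
      say("stage ", name, ": cached, skipping")
      status <- "skipped"
    } else {
      say("stage ", name, ": running")
      tryCatch(fun(), error = function(e)
        stop("pipeline stage '", name, "' failed on ",
             paste(inputs, collapse = ", "), ": ", conditionMessage(e),
             call. = FALSE))
      status <- "run"
    }
    stages[[name]] <<- list(
      key = key, status = status, inputs = inputs, outputs = outputs,
      output_md5 = as.list(tools::md5sum(outputs[file.exists(outputs)])))
    invisible(NULL)
  }

  # stage 1: simulate (only when no annotation/coverage supplied)
  if (is.null(config$gff) || is.null(config$coverage)) {
    sim_dir <- file.path(out, "sim")
    sim_cfg <- do.call(simulation_config,
                       utils::modifyList(list(seed = config$seed),
                                         config$simulate))
    n_rep <- sim_cfg$n_replicates
    sim_out <- c(file.path(sim_dir, "genes.gff3"),
                 file.path(sim_dir, "labels.tsv"),
                 file.path(sim_dir, paste0("coverage_rep", seq_len(n_rep),
                                           ".tsv")))
    run_stage("simulate", sim_cfg, character(0), sim_out, function() {
      truth <- simulate_genome(sim_cfg)
      tracks <- simulate_coverage(truth, sim_cfg)
      write_simulation(truth, tracks, sim_dir)
    })
    config$gff <- sim_out[1]
    config$labels <- sim_out[2]
    config$coverage <- sim_out[-(1:2)]
  }

  # stage 2: features
  feat_path <- file.path(out, "features.tsv")
  feat_params <- config[c("window", "offset", "min_mean", "same_strand_only",
                          "seed")]
  run_stage("features", feat_params,
            c(config$gff, config$coverage,
              if (!is.null(config$labels)) config$labels),
            feat_path, function() {
    genes <- read_gff3_genes(config$gff)
    labels <- if (!is.null(config$labels)) read_pair_labels(config$labels)
    feats <- do.call(rbind, lapply(seq_along(config$coverage), function(i) {
      track <- read_coverage(config$coverage[i],
                             sample_id = paste0("rep", i))
      extract_features(genes, track, labels = labels,
                       min_mean = config$min_mean, window = config$window,
                       offset = config$offset,
                       same_strand_only = config$same_strand_only)
    }))
    write_feature_table(feats, feat_path)
  })

  # stage 3: train (skipped when a model is supplied)
  model_dir <- if (!is.null(config$model)) config$model else
    file.path(out, "model")
  if (is.null(config$model)) {
    run_stage("train",
              config[c("seed", "optimize", "opt_iterations", "folds")],
              feat_path, file.path(model_dir, "metadata.json"), function() {
      feats <- read_feature_table(feat_path)
      if (!"label" %in% names(feats))
        stop("training requires labelled features (supply `labels`)")
      suite <- train_suite(feats, optimize = config$optimize,
                           seed = config$seed,
                           opt_control = list(iterations = config$opt_iterations,
                                              folds = config$folds))
      save_suite(suite, model_dir)
    })
  }

  # stage 4: predict
  pred_path <- file.path(out, "predictions.tsv")
  run_stage("predict", list(seed = config$seed),
            c(feat_path, file.path(model_dir, "metadata.json")),
            pred_path, function() {
    suite <- load_suite(model_dir)
    feats <- read_feature_table(feat_path)
    write_predictions(predict_suite(suite, feats), pred_path)
  })

  # stage 5: vote (replicate consensus when several samples are present)
  calls_path <- file.path(out, "calls.tsv")
  run_stage("vote", config[c("threshold", "min_replicates", "consensus")],
            pred_path, calls_path, function() {
    preds <- read_predictions(pred_path)
    tallied <- if (length(unique(preds$sample_id)) >= config$min_replicates &&
                     length(unique(preds$sample_id)) > 1L) {
      tally_votes(replicate_consensus(preds,
                                      min_replicates = config$min_replicates,
                                      mode = config$consensus))
    } else tally_votes(preds)
    tallied$call <- as.integer(tallied$votes >= config$threshold)
    .write_tsv(tallied, calls_path)
  })

  # stage 6: chain
  operons_path <- file.path(out, "operons.tsv")
  run_stage("chain", config["threshold"], c(calls_path, config$gff),
            operons_path, function() {
    calls <- read.delim(calls_path, stringsAsFactors = FALSE)
    genes <- read_gff3_genes(config$gff)
    .write_tsv(string_operons(calls, genes, threshold = config$threshold),
               operons_path)
  })

  # stage 7: evaluate (needs labels)
  if (!is.null(config$labels)) {
    report_path <- file.path(out, "report.json")
    run_stage("evaluate", config[c("threshold", "n_boot", "fraction", "seed")],
              c(calls_path, config$labels), report_path, function() {
      calls <- read.delim(calls_path, stringsAsFactors = FALSE)
      labels <- read_pair_labels(config$labels)
      cm <- confusion_metrics(calls, labels)
      boot <- lapply(c(recall = "recall", specificity = "specificity"),
                     function(m) {
        b <- bootstrap_ci(m, calls, labels, n_boot = config$n_boot,
                          fraction = config$fraction, seed = config$seed)
        b[c("mean", "lower", "upper")]
      })
      report <- list(threshold = config$threshold,
                     n_pairs = cm$n_pairs,
                     recall = cm$recall, specificity = cm$specificity,
                     confusion = cm[c("tp", "fp", "tn", "fn")],
                     bootstrap = boot)
      jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    })
  }

  manifest <- list(
    package = "operonvoter",
    version = as.character(utils::packageVersion("operonvoter")),
    seed = config$seed,
    inputs = list(gff = config$gff, coverage = config$coverage,
                  labels = config$labels),
    stages = stages)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
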