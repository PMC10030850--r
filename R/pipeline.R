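#' Load a pipeline configuration
#'
#' A single declarative YAML file drives the whole run. Top-level keys:
#' `inputs` (paths per omic kind plus optional `clinical`, `mutations`,
#' `segmeans`), `preprocess`, `autoencoder`, `consensus`, `characterize`,
#' `classify`, `seed`, `out`. Every key has a package default; CLI flags
#' override file values.
#'
#' @param path YAML file path
#' @return a `pipeline_config` list
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(default_pipeline_config(cfg), class = "pipeline_config")
}

default_pipeline_config <- function(cfg = list()) {
  modifyList(list(
    inputs = list(),
    preprocess = list(max_zero_fraction = 0.20, max_missing_fraction = 0.10,
                      knn_k = 5L, top_n_variable = 2000L),
    autoencoder = list(method = "ae", encoder_widths = c(2000L, 1000L, 500L),
                       latent_width = 100L, max_epochs = 100L, patience = 5L,
                       batch_size = 24L, val_fraction = 0.10,
                       learning_rate = 1e-3, n_components = 100L),
    consensus = list(k_min = 2L, k_max = 10L, resamples = 1000L,
                     fraction = 0.8, u1 = 0.1, u2 = 0.9,
                     excluded_k = integer(0)),
    characterize = list(q_threshold = 0.05, sd_min = 0.2,
                        cnv_threshold = 0.3, cnv_p = 0.01),
    classify = list(enabled = TRUE, mode = "linear", holdout = FALSE,
                    step = 0.05, test_fraction = 0.1, fast = FALSE),
    seed = 1L,
    out = "omicsubtyper_out"
  ), cfg)
}

#' Validate a pipeline configuration without running anything
#'
#' @param cfg a `pipeline_config` (or plain list)
#' @return character vector of problems (empty when valid)
#' @export
validate_config <- function(cfg) {
  cfg <- default_pipeline_config(unclass(cfg))
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)
  for (nm in names(cfg$inputs)) {
    if (!file.exists(cfg$inputs[[nm]]))
      add(sprintf("inputs$%s: missing path %s", nm, cfg$inputs[[nm]]))
  }
  pp <- cfg$preprocess
  for (f in c("max_zero_fraction", "max_missing_fraction")) {
    if (pp[[f]] < 0 || pp[[f]] > 1)
      add(sprintf("preprocess$%s out of [0, 1]", f))
  }
  cs <- cfg$consensus
  if (!(cs$u1 >= 0 && cs$u1 < cs$u2 && cs$u2 <= 1))
    add("consensus: need 0 <= u1 < u2 <= 1")
  if (cs$fraction <= 0 || cs$fraction > 1)
    add("consensus$fraction out of (0, 1]")
  if (cs$k_min < 2 || cs$k_max < cs$k_min)
    add("consensus: invalid k range")
  if (!cfg$classify$mode %in% c("linear", "stacked_lr", "stacked_ffnn"))
    add("classify$mode unknown")
  problems
}

stage_log <- function(dir, stage, ...) {
  msg <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                 sprintf(...))
  cat(msg, "\n", sep = "")
  cat(msg, "\n", sep = "", file = file.path(dir, "pipeline.log"),
      append = TRUE)
}

#' Run the end-to-end pipeline
#'
#' preprocess -> stack -> integrate (AE or PCA) -> consensus clustering and
#' K selection -> characterization (when clinical data is supplied) ->
#' fused classifier training. Every stage derives its own seed from the
#' master seed; artifacts and a JSON run manifest land in `cfg$out`.
#'
#' @param cfg a `pipeline_config` (see [read_pipeline_config()])
#' @param force overwrite a non-empty output directory
#' @return invisible list of in-memory stage results
#' @export
run_pipeline <- function(cfg, force = FALSE) {
  cfg <- default_pipeline_config(unclass(cfg))
  out <- cfg$out
  if (dir.exists(out) && length(dir(out)) > 0 && !force)
    stop_omics("output directory %s is not empty (use force = TRUE)", out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed

  kinds <- intersect(names(cfg$inputs),
                     c("F1_mrna", "F2_mirna", "F3_methylation", "F4_protein"))
  if (length(kinds) == 0) stop_omics("no omic inputs configured")
  pp_cfg <- preprocess_config(cfg$preprocess$max_zero_fraction,
                              cfg$preprocess$max_missing_fraction,
                              cfg$preprocess$knn_k,
                              cfg$preprocess$top_n_variable)
  processed <- list()
  for (k in kinds) {
    stage_log(out, "preprocess", "omic %s", k)
    raw <- read_omic_matrix(cfg$inputs[[k]], k)
    processed[[k]] <- preprocess_omic(raw, pp_cfg)
  }
  stack <- stack_omics(processed)
  stage_log(out, "stack", "%d samples x %d features",
            nrow(stack$values), ncol(stack$values))
  write_matrix_tsv(stack$values, file.path(out, "stack.tsv"))

  ae_cfg <- cfg$autoencoder
  if (identical(ae_cfg$method, "pca")) {
    latent <- pca_reduce(stack, ae_cfg$n_components)
    stage_log(out, "integrate", "PCA to %d components", ncol(latent))
  } else {
    enc <- train_autoencoder(
      stack,
      ae_architecture(ae_cfg$encoder_widths, ae_cfg$latent_width),
      ae_train_config(ae_cfg$max_epochs, ae_cfg$patience, ae_cfg$batch_size,
                      ae_cfg$val_fraction, ae_cfg$learning_rate,
                      seed = derive_seed(seed, "autoencoder")))
    latent <- encode(enc, stack)
    stage_log(out, "integrate", "AE latent %d, best epoch %d",
              ncol(latent), enc$best_epoch)
  }
  write_matrix_tsv(latent, file.path(out, "latent.tsv"))

  cs <- cfg$consensus
  profile <- build_pac_profile(latent, cs$k_min:cs$k_max, cs$resamples,
                               cs$fraction, cs$u1, cs$u2,
                               seed = derive_seed(seed, "consensus"))
  write.table(profile$pac, file.path(out, "pac_profile.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  K <- select_k(profile, excluded = cs$excluded_k)
  labels <- final_labels(profile$records[[paste0("K", K)]]$consensus, K,
                         seed = derive_seed(seed, "final_labels"))
  stage_log(out, "cluster", "selected K = %d by minimal PAC", K)
  write.table(data.frame(sample_id = labels$sample_ids,
                         cluster = labels$labels),
              file.path(out, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  characterization <- NULL
  if (!is.null(cfg$inputs$clinical)) {
    cl <- read.delim(cfg$inputs$clinical)
    idx <- match(labels$sample_ids, cl$sample_id)
    if (anyNA(idx)) {
      stage_log(out, "characterize",
                "warning: clinical table misses %d samples, skipped",
                sum(is.na(idx)))
    } else {
      surv <- survival_table(labels$sample_ids, cl$os_time_months[idx],
                             cl$os_event[idx], labels$labels, "OS")
      lr <- logrank_test(surv)
      km <- km_estimate(surv)
      characterization <- list(os_logrank = lr, km = km)
      for (g in names(km))
        write.table(km[[g]]$curve,
                    file.path(out, sprintf("km_cluster%s.tsv", g)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      stage_log(out, "characterize", "OS log-rank chi2 %.3f p %.4g",
                lr$statistic, lr$p)
    }
  } else {
    stage_log(out, "characterize", "no clinical table; survival skipped")
  }

  classifier <- NULL
  if (isTRUE(cfg$classify$enabled)) {
    sp <- split_train_test(latent, labels$labels,
                           cfg$classify$test_fraction,
                           derive_seed(seed, "traintest"))
    classifier <- train_fused(latent[sp$train, , drop = FALSE],
                              labels$labels[sp$train],
                              mode = cfg$classify$mode,
                              holdout = isTRUE(cfg$classify$holdout),
                              specs = default_base_specs(
                                derive_seed(seed, "classify"),
                                fast = isTRUE(cfg$classify$fast)),
                              step = cfg$classify$step,
                              seed = derive_seed(seed, "classify"))
    pred <- predict(classifier, latent[sp$test, , drop = FALSE])
    acc <- evaluate_accuracy(pred$labels, labels$labels[sp$test])
    stage_log(out, "classify", "fused (%s) test accuracy %.3f",
              cfg$classify$mode, acc)
    if (classifier$mode == "linear")
      write.table(data.frame(weight = names(classifier$weights),
                             value = as.numeric(classifier$weights)),
                  file.path(out, "fusion_weights.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }

  manifest <- list(package_version =
                     as.character(utils::packageVersion("omicsubtyper")),
                   seed = seed,
                   stage_seeds = list(
                     autoencoder = derive_seed(seed, "autoencoder"),
                     consensus = derive_seed(seed, "consensus"),
                     final_labels = derive_seed(seed, "final_labels"),
                     classify = derive_seed(seed, "classify")),
                   config = cfg[setdiff(names(cfg), "inputs")],
                   selected_k = K)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(stack = stack, latent = latent, profile = profile,
                 K = K, labels = labels,
                 characterization = characterization,
                 classifier = classifier, out = out))
}

#' Command-line entry point
#'
#' Subcommands: `simulate --n --clusters --effect --seed --out`,
#' `run --config <yaml> [--force]`, `validate --config <yaml>`. Invoked by
#' the `inst/cli/omicsubtyper` script.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`)
#' @return exit status, invisibly
#' @export
omicsubtyper_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: omicsubtyper <simulate|run|validate> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (i < length(rest) && !startsWith(rest[i + 1], "--")) {
      opts[[key]] <- rest[i + 1]
      i <- i + 2
    } else {
      opts[[key]] <- TRUE
      i <- i + 1
    }
  }
  switch(cmd,
    simulate = {
      cfg <- sim_config(n_samples = as.integer(opts$n %||% 300),
                        n_clusters = as.integer(opts$clusters %||% 5),
                        effect_size = as.numeric(opts$effect %||% 3),
                        seed = as.integer(opts$seed %||% 1))
      write_simulated_dataset(cfg, opts$out %||% "simulated")
      cat("wrote", opts$out %||% "simulated", "\n")
    },
    run = {
      cfg <- read_pipeline_config(opts$config)
      run_pipeline(cfg, force = isTRUE(opts$force))
    },
    validate = {
      problems <- validate_config(read_pipeline_config(opts$config))
      if (length(problems)) {
        cat(problems, sep = "\n")
        return(invisible(1L))
      }
      cat("config OK\n")
    },
    stop_omics("unknown subcommand '%s'", cmd))
  invisible(0L)
}
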