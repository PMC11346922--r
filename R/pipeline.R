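# Experiment orchestration: config schema, stage guard, and the
# simulate -> split -> pretrain -> finetune -> evaluate -> challenge ->
# saliency pipeline.

required_blocks <- c("phantoms", "augmentation", "contrastive", "encoder",
                     "pretrain", "finetune", "splitting", "evaluation")

#' Validate an experiment configuration
#'
#' Pre-flight schema check: every required block must be present and
#' well-formed before any stage runs; violations are reported together.
#'
#' @param config a nested list (e.g. from [yaml::read_yaml()]).
#' @return The config, invisibly, with constructor-validated sub-configs
#'   attached as attributes.
#' @export
validate_experiment_config <- function(config) {
  missing_blocks <- setdiff(required_blocks, names(config))
  if (length(missing_blocks))
    stop_config("experiment config lacks block(s): ",
                paste(missing_blocks, collapse = ", "))
  problems <- character(0)
  built <- list()
  try_block <- function(name, fun, args) {
    r <- tryCatch(do.call(fun, args), error = function(e) e)
    if (inherits(r, "error"))
      problems <<- c(problems, paste0(name, ": ", conditionMessage(r)))
    else built[[name]] <<- r
  }
  ph <- config$phantoms
  try_block("phantoms", cohort_config, ph[names(ph) %in% names(formals(cohort_config))])
  au <- config$augmentation
  try_block("augmentation", augmentation_config,
            au[names(au) %in% names(formals(augmentation_config))])
  co <- config$contrastive
  try_block("contrastive", contrastive_config,
            co[names(co) %in% names(formals(contrastive_config))])
  en <- config$encoder
  try_block("encoder", encoder_spec,
            en[names(en) %in% names(formals(encoder_spec))])
  pt <- config$pretrain
  try_block("pretrain", pretrain_config,
            pt[names(pt) %in% names(formals(pretrain_config))])
  ft <- config$finetune
  try_block("finetune", finetune_config,
            ft[names(ft) %in% names(formals(finetune_config))])
  if (length(problems))
    stop_config("invalid experiment config:\n  ",
                paste(problems, collapse = "\n  "))
  attr(config, "built") <- built
  invisible(config)
}

# stage guard: run `fun` once per (dir, key); re-running with an unchanged
# key is a no-op that returns the cached result
stage_guard <- function(dir, key, fun) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(dir, ".stage_hash")
  cache <- file.path(dir, ".stage_result.rds")
  if (file.exists(marker) && file.exists(cache) &&
      identical(readLines(marker, warn = FALSE), key)) {
    return(readRDS(cache))
  }
  result <- fun()
  saveRDS(result, cache)
  writeLines(key, marker)
  result
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

report_from_metrics <- function(rep) {
  list(n = rep$n, threshold = rep$threshold, auc = rep$auc,
       ftmh = rep$ftmh[c("precision", "sensitivity", "specificity", "f1")],
       control = rep$control[c("precision", "sensitivity", "specificity", "f1")],
       counts = rep$ftmh$counts[c("tp", "fp", "fn", "tn")])
}

#' Run one replicate: pre-train, fine-tune the ensemble, evaluate
#'
#' The encoder is pre-trained contrastively on the replicate's training
#' eyes with the lowest-numbered fold reserved for pre-training
#' validation, then an equal-weight ensemble of frozen-encoder classifier
#' heads is fine-tuned across all folds and evaluated on the replicate's
#' holdout (central B-scans only). With `pretrain_encoder = FALSE` the
#' randomly initialized encoder goes straight to fine-tuning (the
#' frozen-random control arm).
#'
#' @param volumes,manifest the full cohort.
#' @param plan a `split_plan` with `fold_assignment` attached.
#' @param enc_spec an [encoder_spec()].
#' @param contrastive,augmentation,pretrain_cfg,finetune_cfg stage
#'   configurations.
#' @param seed integer seed.
#' @param pretrain_encoder logical.
#' @param threshold decision threshold for evaluation.
#' @return A list with `ensemble`, `metrics` (a [metrics_report()]),
#'   `pretrain_history` (`NULL` for the control arm), `predictions`.
#' @export
run_replicate <- function(volumes, manifest, plan, enc_spec, contrastive,
                          augmentation, pretrain_cfg, finetune_cfg, seed = 1,
                          pretrain_encoder = TRUE, threshold = 0.5) {
  if (is.null(plan$fold_assignment))
    stop_config("plan has no fold assignment; run assign_folds() first")
  fold_assignment <- plan$fold_assignment
  train_m <- manifest[manifest$eye_id %in% plan$train_eye_ids, , drop = FALSE]
  encoder <- build_encoder(enc_spec, seed = derive_seed(seed, "encoder"))
  pre_hist <- NULL
  proj_head <- NULL
  if (pretrain_encoder) {
    val_fold <- min(fold_assignment)
    val_ids <- names(fold_assignment)[fold_assignment == val_fold]
    tr_ids <- setdiff(plan$train_eye_ids, val_ids)
    fit <- pretrain(volumes[tr_ids],
                    train_m[train_m$eye_id %in% tr_ids, , drop = FALSE],
                    volumes[val_ids],
                    train_m[train_m$eye_id %in% val_ids, , drop = FALSE],
                    encoder, contrastive, augmentation, pretrain_cfg,
                    seed = derive_seed(seed, "pretrain"))
    encoder <- fit$encoder
    pre_hist <- fit$history
    proj_head <- fit$projection_head
  }
  ensemble <- train_ensemble(encoder, volumes[plan$train_eye_ids], train_m,
                             fold_assignment, finetune_cfg,
                             augmentation = augmentation,
                             init_trunk = proj_head,
                             seed = derive_seed(seed, "ensemble"))
  test_m <- manifest[manifest$eye_id %in% plan$test_eye_ids, , drop = FALSE]
  images <- lapply(test_m$eye_id, function(id) central_slice(volumes[[id]]))
  pred <- ensemble_predict(ensemble, images)
  labels <- test_m$diagnosis == "FTMH"
  metrics <- metrics_report(labels, pred$score, threshold)
  list(ensemble = ensemble, metrics = metrics, pretrain_history = pre_hist,
       predictions = data.frame(eye_id = test_m$eye_id, label = labels,
                                score = pred$score, predicted = pred$label,
                                stringsAsFactors = FALSE))
}

#' Run the full experiment from a configuration
#'
#' Orchestrates simulate -> split -> (per replicate) pretrain + finetune +
#' evaluate -> challenge -> saliency, with per-stage seeds fanned out from
#' the global seed and a content-hash guard that makes re-running a
#' completed stage a no-op. All JSON reports are bit-exactly reproducible
#' from `(config, seed)` in single-threaded mode.
#'
#' @param config path to a YAML experiment config, or an equivalent nested
#'   list. Blocks: `phantoms`, `augmentation`, `contrastive`, `encoder`,
#'   `pretrain`, `finetune`, `splitting`, `evaluation`, plus optional
#'   `challenge` (`n_lamellar`), `seed`, `output`, `n_replicates`.
#' @param seed overrides `config$seed`.
#' @param out overrides `config$output` (run directory).
#' @param stop_after optionally stop after `"simulate"`, `"split"`,
#'   `"replicates"` or `"challenge"`.
#' @return Invisibly, a list with the run directory, per-replicate
#'   metrics, the summary table and challenge accuracy.
#' @export
run_experiment <- function(config, seed = NULL, out = NULL,
                           stop_after = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- validate_experiment_config(config)
  built <- attr(config, "built")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  out <- out %||% config$output %||% "rascl_run"
  n_replicates <- config$splitting$n_replicates %||% config$n_replicates %||% 3L
  k <- config$splitting$k %||% 8L
  threshold <- config$evaluation$threshold %||% 0.5
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_key <- content_hash(list(config = config, seed = seed))
  write_report_json(config, file.path(out, "config_used.json"))

  # --- simulate ---------------------------------------------------------
  cohort <- stage_guard(file.path(out, "dataset"), cfg_key, function() {
    ch <- generate_cohort(built$phantoms, seed = derive_seed(seed, "cohort"))
    write_cohort(ch, file.path(out, "dataset"))
    ch
  })
  if (identical(stop_after, "simulate")) return(invisible(list(dir = out)))

  # --- split ------------------------------------------------------------
  tc <- config$splitting$test_counts
  test_counts <- if (is.null(tc)) c(FTMH = 10, control = 40) else
    c(FTMH = tc$FTMH, control = tc$control)
  plans <- stage_guard(file.path(out, "splits"), cfg_key, function() {
    p <- make_replicates(cohort$manifest, n_replicates, test_counts,
                         seed = derive_seed(seed, "split"))
    p <- assign_folds(p, cohort$manifest, k = k,
                      seed = derive_seed(seed, "folds"),
                      n_restarts = config$splitting$n_restarts %||% 50,
                      n_swaps = config$splitting$n_swaps %||% 500)
    for (r in seq_along(p)) {
      write_report_json(
        list(replicate_id = r, test_eye_ids = p[[r]]$test_eye_ids,
             fold_assignment = as.list(p[[r]]$fold_assignment)),
        file.path(out, "splits", sprintf("replicate_%d.json", r)))
    }
    p
  })
  if (identical(stop_after, "split")) return(invisible(list(dir = out)))

  # --- replicates: pretrain + finetune + evaluate -----------------------
  reports <- vector("list", length(plans))
  ensembles <- vector("list", length(plans))
  for (r in seq_along(plans)) {
    rdir <- file.path(out, sprintf("replicate_%d", r))
    res <- stage_guard(rdir, cfg_key, function() {
      rr <- run_replicate(cohort$volumes, cohort$manifest, plans[[r]],
                          built$encoder, built$contrastive,
                          built$augmentation, built$pretrain,
                          built$finetune, seed = derive_seed(seed, "rep", r),
                          threshold = threshold)
      save_checkpoint(list(spec = built$encoder,
                           params = encoder_params(rr$ensemble$encoder),
                           history = rr$pretrain_history),
                      file.path(rdir, "encoder.rds"))
      if (!is.null(rr$pretrain_history))
        write_report_json(rr$pretrain_history,
                          file.path(rdir, "pretrain_history.json"))
      write_report_json(report_from_metrics(rr$metrics),
                        file.path(rdir, "metrics.json"))
      write_report_json(rr$predictions, file.path(rdir, "predictions.json"))
      rr
    })
    reports[[r]] <- res$metrics
    ensembles[[r]] <- res$ensemble
  }
  summary_tab <- aggregate_replicates(reports)
  write_report_json(summary_tab, file.path(out, "summary.json"))
  if (identical(stop_after, "replicates"))
    return(invisible(list(dir = out, reports = reports, summary = summary_tab)))

  # --- challenge --------------------------------------------------------
  challenge_acc <- NULL
  n_lam <- config$challenge$n_lamellar %||% 0L
  if (n_lam > 0) {
    challenge_acc <- stage_guard(file.path(out, "challenge"), cfg_key,
                                 function() {
      ch_cfg <- built$phantoms
      ch_cfg$n_lamellar <- n_lam
      ch <- generate_challenge_set(ch_cfg, seed = derive_seed(seed, "challenge"))
      accs <- vapply(ensembles, function(e)
        evaluate_challenge(e, ch$volumes)$accuracy, numeric(1))
      write_report_json(list(per_replicate = accs, mean_accuracy = mean(accs)),
                        file.path(out, "challenge", "challenge.json"))
      mean(accs)
    })
  }
  if (identical(stop_after, "challenge"))
    return(invisible(list(dir = out, reports = reports, summary = summary_tab,
                          challenge_accuracy = challenge_acc)))

  # --- saliency ---------------------------------------------------------
  stage_guard(file.path(out, "saliency"), cfg_key, function() {
    test_m <- cohort$manifest[cohort$manifest$eye_id %in%
                                plans[[1]]$test_eye_ids, , drop = FALSE]
    pick <- c(test_m$eye_id[test_m$diagnosis == "FTMH"][1],
              test_m$eye_id[test_m$diagnosis != "FTMH"][1])
    ens <- ensembles[[1]]
    for (id in pick[!is.na(pick)]) {
      img <- central_slice(cohort$volumes[[id]])
      sal <- saliency_map(ens$encoder, ens$heads[[1]], img, target_class = 2L)
      utils::write.csv(round(sal, 6),
                       file.path(out, "saliency", paste0(id, "_ftmh_saliency.csv")),
                       row.names = FALSE)
    }
    TRUE
  })
  invisible(list(dir = out, reports = reports, summary = summary_tab,
                 challenge_accuracy = challenge_acc))
}

#' Path to the bundled desk-scale benchmark configuration
#' @return File path of `desk_benchmark.yaml` shipped with the package.
#' @export
desk_benchmark_config <- function()
  system.file("extdata", "desk_benchmark.yaml", package = "rascl",
              mustWork = TRUE)
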