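# End-to-end pipeline plumbing: one configuration object drives synthesis,
# preprocessing, training, folding, inference and evaluation, with every
# stochastic stage seeded from the single run seed so reruns are identical.

#' Closed-form cost summary of a configuration
#'
#' Combines the latency model, the first-layer operation counts with and
#' without the merged convolution-pooling rewrite, and the second-layer
#' convolutional operation counts into one report.
#'
#' @param cfg A `bdscnn_config`.
#' @return Named list: `MC`, `MD`, `L`, `LB`, `LB_pipelined`, `n_blocks`,
#'   `mcp_ops`, `mcp_baseline_ops`, `coperation`,
#'   `coperation_conventional`, `kernel_count`, `kernel_params`,
#'   `dsc_param_reduction`, plus storage totals.
#' @examples
#' unlist(cost_summary(bdscnn_config())[c("L", "LB", "LB_pipelined")])
#' @export
cost_summary <- function(cfg = bdscnn_config()) {
  lat <- latency_report(cfg)
  sto <- storage_report(cfg)
  cp <- count_params_and_ops(cfg, "dsc")
  cpc <- count_params_and_ops(cfg, "conventional")
  list(MC = lat$MC, MD = lat$MD, L = lat$L, LB = lat$LB,
       LB_pipelined = lat$LB_pipelined, n_blocks = lat$n_blocks,
       mcp_ops = mcp_op_count(cfg, "mcp"),
       mcp_baseline_ops = mcp_op_count(cfg, "baseline"),
       coperation = cp$coperation,
       coperation_conventional = cpc$coperation,
       kernel_count = cp$kernel_count,
       kernel_params = cp$kernel_params_total,
       dsc_param_reduction = cp$dsc_param_reduction,
       storage_layerwise = sto$layerwise_total,
       storage_blockwise = sto$blockwise_total)
}

#' Construct a pipeline run configuration
#'
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param n_beats Total synthetic beats to generate.
#' @param n_records Number of synthetic records they are spread over.
#' @param class_mix Class probabilities (N, S, V, F, Q).
#' @param scheme Dataset splitting scheme (see [split_spec()]).
#' @param epochs,batch_size,patience Training-loop controls
#'   (see [train_bdscnn()]).
#' @param balance_train Z-score-augment the training partition up to its
#'   largest class count.
#' @param mode Inference engine for evaluation.
#' @param cfg A `bdscnn_config`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_beats = 2000L, n_records = 4L,
                       class_mix = rep(0.2, 5),
                       scheme = c("patient_specific", "patient_wise"),
                       epochs = 30L, batch_size = 128L, patience = 10L,
                       balance_train = TRUE,
                       mode = c("layerwise", "blockwise"),
                       cfg = bdscnn_config()) {
  structure(list(seed = as.integer(seed), n_beats = as.integer(n_beats),
                 n_records = as.integer(n_records), class_mix = class_mix,
                 scheme = match.arg(scheme), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 balance_train = isTRUE(balance_train),
                 mode = match.arg(mode), cfg = cfg),
            class = "run_config")
}

#' Run the full pipeline on synthetic data
#'
#' Generates seeded synthetic records, segments and splits them, optionally
#' balances the training partition (validation and test are never
#' augmented), rasterizes beats, trains the binarized network, folds it for
#' integer-only inference, classifies the held-out test partition and
#' reports the confusion matrix, metric block and closed-form cost summary.
#'
#' @param rc A `run_config`.
#' @param out_dir Optional directory; when given, the model bundle, folded
#'   bundle, test manifest, per-beat predictions CSV and a summary JSON are
#'   written there.
#' @param verbose Print stage progress.
#' @return List with `weights`, `folded`, `confusion`, `report`, `cost`,
#'   `datasets` (sizes) and `config`.
#' @export
run_pipeline <- function(rc = run_config(), out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(rc, "run_config"))
  cfg <- rc$cfg
  say <- function(...) if (verbose) message(...)

  per_rec <- rep(rc$n_beats %/% rc$n_records, rc$n_records)
  extra <- rc$n_beats - sum(per_rec)
  if (extra > 0) per_rec[seq_len(extra)] <- per_rec[seq_len(extra)] + 1L
  say("synthesizing ", rc$n_beats, " beats over ", rc$n_records, " records")
  records <- lapply(seq_len(rc$n_records), function(r) {
    generate_record(per_rec[r], rc$class_mix, rng_seed = rc$seed * 1000L + r,
                    record_id = sprintf("synth%02d", r))
  })
  beats <- segment_records(records)
  parts <- split_dataset(beats, split_spec(rc$scheme, rng_seed = rc$seed + 1L))
  train_beats <- parts$train
  if (rc$balance_train) {
    target <- max(table(train_beats$label))
    train_beats <- zscore_augment(train_beats, target, rng_seed = rc$seed + 2L)
  }
  say("building datasets (train ", length(train_beats$label), ", val ",
      length(parts$val$label), ", test ", length(parts$test$label), ")")
  ds_train <- build_dataset(train_beats, cfg)
  ds_val <- build_dataset(parts$val, cfg)
  ds_test <- build_dataset(parts$test, cfg)

  say("training")
  w <- train_bdscnn(ds_train, ds_val, cfg, rng_seed = rc$seed + 3L,
                    epochs = rc$epochs, batch_size = rc$batch_size,
                    patience = rc$patience, verbose = verbose)
  fm <- fold_model(w)
  say("evaluating (", rc$mode, ")")
  ev <- evaluate_model(ds_test, fm, mode = rc$mode)

  out <- list(weights = w, folded = fm, confusion = ev$confusion,
              report = ev$report, cost = cost_summary(cfg),
              datasets = c(train = length(ds_train$label),
                           val = length(ds_val$label),
                           test = length(ds_test$label)),
              config = rc)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_bundle(w, file.path(out_dir, "model.bundle.json"))
    write_bundle(fm, file.path(out_dir, "folded.bundle.json"))
    write_manifest(ds_test, file.path(out_dir, "test.manifest.jsonl"))
    utils::write.csv(data.frame(beat = seq_along(ev$pred),
                                predicted = ev$pred,
                                truth = ds_test$label),
                     file.path(out_dir, "predictions.csv"), row.names = FALSE)
    summary_doc <- list(seed = rc$seed, confusion = ev$confusion,
                        metrics = ev$report$table,
                        accuracy = ev$report$accuracy,
                        macro_f1 = ev$report$macro_f1, cost = out$cost,
                        datasets = as.list(out$datasets))
    jsonlite::write_json(summary_doc, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
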