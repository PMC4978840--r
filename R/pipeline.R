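# File-based workflow commands behind the command-line interface
# (inst/cli/gpcr188). Each run writes a JSON manifest recording its full
# parameterisation and seed next to its outputs.

write_run_manifest <- function(out_path, command, params) {
  manifest <- c(list(command = command,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                params)
  path <- paste0(out_path, ".run.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

resolve_groupings <- function(property_table = NULL) {
  if (is.null(property_table)) default_groupings() else read_property_table(property_table)
}

#' Simulate synthetic positive/negative FASTA files
#'
#' Writes `positives.fasta`, `negatives.fasta` and a manifest into `out_dir`.
#'
#' @param out_dir output directory (created if missing).
#' @param n_pos,n_neg,seed,... generator settings, see [generator_config()].
#' @return named character vector of the two FASTA paths, invisibly.
#' @export
run_simulate <- function(out_dir, n_pos = 100, n_neg = 400, seed = 1, ...) {
  cfg <- generator_config(n_pos = n_pos, n_neg = n_neg, seed = seed, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pos_path <- file.path(out_dir, "positives.fasta")
  neg_path <- file.path(out_dir, "negatives.fasta")
  write_fasta(generate_positive(cfg), pos_path)
  write_fasta(generate_negative(cfg), neg_path)
  write_run_manifest(file.path(out_dir, "simulate"), "simulate", unclass(cfg))
  message(sprintf("simulate: wrote %d positive and %d negative sequences to %s",
                  cfg$n_pos, cfg$n_neg, out_dir))
  invisible(c(positives = pos_path, negatives = neg_path))
}

#' Encode positive and negative FASTA files into a labeled ARFF
#'
#' Positives are labeled +1, negatives -1; the combined 188D dataset is
#' written as ARFF.
#'
#' @param pos_fasta,neg_fasta input FASTA paths.
#' @param out_arff output ARFF path.
#' @param policy residue policy for [read_fasta()].
#' @param property_table optional path to a groupings config overriding the
#'   defaults ([read_property_table()]).
#' @return the combined `gpcr_dataset`, invisibly.
#' @export
run_encode <- function(pos_fasta, neg_fasta, out_arff, policy = "map",
                       property_table = NULL) {
  groupings <- resolve_groupings(property_table)
  pos <- read_fasta(pos_fasta, policy)
  neg <- read_fasta(neg_fasta, policy)
  if (nrow(pos) == 0L) stop("no positive records")
  if (nrow(neg) == 0L) stop("no negative records")
  data <- combine_datasets(encode_many(pos, groupings, label = 1L),
                           encode_many(neg, groupings, label = -1L))
  write_arff(data, out_arff)
  write_run_manifest(out_arff, "encode",
                     list(pos_fasta = pos_fasta, neg_fasta = neg_fasta,
                          policy = policy,
                          property_table = property_table %||% "default",
                          n_pos = nrow(pos), n_neg = nrow(neg)))
  message(sprintf("encode: %d positives + %d negatives -> %s",
                  nrow(pos), nrow(neg), out_arff))
  invisible(data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validate a labeled ARFF dataset
#'
#' Runs [gpcr_crossval()] on the dataset and writes the per-fold + mean/SD
#' report as a tab-separated table.
#'
#' @param arff_in labeled ARFF path.
#' @param report_out output TSV path.
#' @param k,smote_percent,k_neighbors,n_trees,max_features,min_leaf,seed
#'   passed to [gpcr_crossval()].
#' @return the `gpcr_cv`, invisibly.
#' @export
run_crossval <- function(arff_in, report_out, k = 5, smote_percent = 300,
                         k_neighbors = 5, n_trees = 100, max_features = "sqrt",
                         min_leaf = 1, seed = 1) {
  data <- read_arff(arff_in)
  cv <- gpcr_crossval(data, k = k, smote_percent = smote_percent,
                      k_neighbors = k_neighbors, n_trees = n_trees,
                      max_features = max_features, min_leaf = min_leaf,
                      seed = seed)
  write_cv_report(cv, report_out)
  write_run_manifest(report_out, "crossval", cv$config)
  print(cv)
  invisible(cv)
}

#' Train a classifier and persist it
#'
#' Input may be a labeled ARFF, or a pair of FASTA files encoded on the fly.
#' The model file stores the property tables used, so later predictions on
#' FASTA input reuse them.
#'
#' @param model_out output model path.
#' @param arff_in labeled ARFF path (alternative to the FASTA pair).
#' @param pos_fasta,neg_fasta FASTA inputs (alternative to `arff_in`).
#' @param smote_percent SMOTE applied to the training minority class before
#'   fitting (default 300; 0 disables).
#' @param policy,property_table encoding options for FASTA input.
#' @param n_trees,max_features,min_leaf,seed forest settings.
#' @return the fitted `gpcr_rf`, invisibly.
#' @export
run_train <- function(model_out, arff_in = NULL, pos_fasta = NULL, neg_fasta = NULL,
                      smote_percent = 300, policy = "map", property_table = NULL,
                      n_trees = 100, max_features = "sqrt", min_leaf = 1, seed = 1) {
  groupings <- resolve_groupings(property_table)
  data <- if (!is.null(arff_in)) {
    read_arff(arff_in)
  } else {
    if (is.null(pos_fasta) || is.null(neg_fasta)) {
      stop("provide either arff_in or both pos_fasta and neg_fasta")
    }
    combine_datasets(encode_many(read_fasta(pos_fasta, policy), groupings, 1L),
                     encode_many(read_fasta(neg_fasta, policy), groupings, -1L))
  }
  if (smote_percent > 0) {
    minority <- if (sum(data$y == 1L) <= sum(data$y == -1L)) 1L else -1L
    syn <- smote(subset_dataset(data, which(data$y == minority)),
                 smote_config(percent = smote_percent, seed = derive_seed(seed, 100L)))
    data <- combine_datasets(data, syn)
  }
  model <- gpcr_rf(data, forest_config(n_trees = n_trees, max_features = max_features,
                                       min_leaf = min_leaf, seed = derive_seed(seed, 200L)))
  model$groupings <- groupings
  save_model(model, model_out)
  write_run_manifest(model_out, "train",
                     list(arff_in = arff_in %||% "", pos_fasta = pos_fasta %||% "",
                          neg_fasta = neg_fasta %||% "", smote_percent = smote_percent,
                          n_trees = n_trees, seed = seed,
                          property_table = property_table %||% "default"))
  message(sprintf("train: fitted %d-tree forest on %d vectors -> %s",
                  n_trees, nrow(data$x), model_out))
  invisible(model)
}

#' Predict with a persisted model
#'
#' Input may be FASTA (encoded with the property tables stored in the model)
#' or ARFF (labels optional). Writes a tab-separated table of id, score and
#' predicted label.
#'
#' @param model_in model path written by [run_train()] / [save_model()].
#' @param input FASTA or ARFF input path (by extension: `.arff` = ARFF).
#' @param out output TSV path.
#' @param policy residue policy for FASTA input.
#' @return the predictions `data.frame`, invisibly.
#' @export
run_predict <- function(model_in, input, out, policy = "map") {
  model <- load_model(model_in)
  is_arff <- grepl("\\.arff$", input, ignore.case = TRUE)
  data <- if (is_arff) {
    read_arff(input)
  } else {
    groupings <- model$groupings %||% default_groupings()
    if (!is.null(model$groupings)) message("predict: using property tables stored in the model")
    encode_many(read_fasta(input, policy), groupings)
  }
  pred <- predict(model, data)
  utils::write.table(pred, out, sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(out, "predict",
                     list(model_in = model_in, input = input, n = nrow(pred)))
  invisible(pred)
}

#' Evaluate a predictions table against true labels
#'
#' `pred_tsv` must carry `score` and `label` columns (as written by
#' [run_predict()]) plus a `truth` column of +1/-1 labels, or truth is
#' supplied separately.
#'
#' @param pred_tsv predictions TSV.
#' @param report_out output path for the metric table.
#' @param truth optional vector of true labels overriding a `truth` column.
#' @return the `gpcr_eval`, invisibly.
#' @export
run_evaluate <- function(pred_tsv, report_out, truth = NULL) {
  pred <- utils::read.delim(pred_tsv, stringsAsFactors = FALSE)
  if (is.null(truth)) {
    if (!"truth" %in% names(pred)) stop("predictions table has no 'truth' column and no truth supplied")
    truth <- pred$truth
  }
  report <- evaluate_predictions(truth, pred$score, pred$label)
  vals <- unlist(report[eval_metric_names])
  utils::write.table(data.frame(metric = names(vals), value = vals),
                     report_out, sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(report_out, "evaluate", list(pred_tsv = pred_tsv, n = length(truth)))
  print(report)
  invisible(report)
}
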