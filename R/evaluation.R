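# Subject-level aggregation by majority vote, the precision/recall/F1/
# accuracy metric suite (AD = positive class), and the end-to-end experiment
# runner for both systems.

#' Majority vote over segment labels
#'
#' Returns the label predicted for the majority of a subject's segments;
#' a tie goes to NONAD (documented rule — it favors the healthy class and
#' keeps the decision deterministic).
#'
#' @param segment_labels Non-empty vector of `"AD"`/`"NONAD"` labels.
#' @return A single label.
#' @export
majority_vote <- function(segment_labels) {
  if (length(segment_labels) == 0L) {
    stop("cannot vote over zero segments", call. = FALSE)
  }
  n_ad <- sum(segment_labels == "AD")
  if (n_ad > length(segment_labels) - n_ad) "AD" else "NONAD"
}

#' Confusion counts over subject predictions
#'
#' AD is the positive class.
#'
#' @param preds Data frame with columns `true` and `predicted` (one row per
#'   subject), both in `{AD, NONAD}`.
#' @return List of class `confusion_counts` with tp, fp, fn, tn.
#' @export
confusion_counts <- function(preds) {
  if (anyNA(preds$true) || is.null(preds$true)) {
    stop("every prediction needs a true label", call. = FALSE)
  }
  structure(list(
    tp = sum(preds$true == "AD" & preds$predicted == "AD"),
    fp = sum(preds$true == "NONAD" & preds$predicted == "AD"),
    fn = sum(preds$true == "AD" & preds$predicted == "NONAD"),
    tn = sum(preds$true == "NONAD" & preds$predicted == "NONAD")),
    class = "confusion_counts")
}

#' Precision, recall, F1 and accuracy from confusion counts
#'
#' Standard definitions with AD positive: precision = tp/(tp+fp), recall =
#' tp/(tp+fn), F1 = 2PR/(P+R), accuracy = (tp+tn)/n. A zero denominator
#' yields 0 with a warning.
#'
#' @param c A [confusion_counts()].
#' @return List of class `metrics` with precision, recall, f1, accuracy.
#' @export
compute_metrics <- function(c) {
  n <- c$tp + c$fp + c$fn + c$tn
  stopifnot(n >= 1)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0",
              call. = FALSE)
      0
    } else num / den
  }
  precision <- safe_div(c$tp, c$tp + c$fp, "precision")
  recall <- safe_div(c$tp, c$tp + c$fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  structure(list(precision = precision, recall = recall, f1 = f1,
                 accuracy = (c$tp + c$tn) / n),
            class = "metrics")
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf("precision %.3f  recall %.3f  F1 %.3f  accuracy %.3f\n",
              x$precision, x$recall, x$f1, x$accuracy))
  invisible(x)
}

#' Run one end-to-end screening experiment
#'
#' Generates (or accepts) a corpus, standardizes it, builds a
#' speaker-disjoint stratified 80/20 split, trains the chosen system on the
#' training subjects only, predicts each held-out subject and reports
#' subject-level metrics. For the embedding system, PCA whitening and the
#' segment classifier are fitted on training-subject segments only and
#' subject decisions aggregate segment predictions by majority vote;
#' segment-level metrics are reported alongside. DemCNN makes one
#' whole-recording decision per subject. Everything is seeded, so two runs
#' with the same configuration produce identical reports.
#'
#' @param system `"embedding"` or `"demcnn"`.
#' @param corpus Either a [corpus_spec()] (the corpus is generated) or a
#'   list with `recordings` and `manifest`.
#' @param train_fraction Fraction of speakers per class used for training.
#' @param seed Experiment seed (split, classifier seeds, training).
#' @param classifier A [classifier_spec()] for the embedding system
#'   (default linear SVM).
#' @param n_components Whitening dimensionality for the embedding system,
#'   default 128 (requires at least that many training segments).
#' @param embedder Embedder for the embedding system.
#' @param cnn_config A [demcnn_config()] for the DemCNN system.
#' @param schedule A [train_schedule()] for the DemCNN system.
#' @return A report list: system, seed, config echo, train/test subject
#'   ids, per-subject prediction data frame (`subject_id,true,predicted,
#'   votes_ad,votes_nonad`), subject-level `metrics`, and for the embedding
#'   system `segment_metrics` as well.
#' @export
run_experiment <- function(system = c("embedding", "demcnn"),
                           corpus, train_fraction = 0.8, seed = 1L,
                           classifier = classifier_spec("LINEAR_SVM",
                                                        seed = seed),
                           n_components = 128L,
                           embedder = surrogate_embedder(),
                           cnn_config = demcnn_config(seed = seed),
                           schedule = train_schedule()) {
  system <- match.arg(system)
  if (inherits(corpus, "corpus_spec")) corpus <- generate_corpus(corpus)
  recs <- lapply(corpus$recordings, standardize_recording)
  names(recs) <- vapply(recs, `[[`, "", "subject_id")
  split <- speaker_partition(corpus$manifest, train_fraction, seed)
  train_ids <- split$train$subject_id
  test_ids <- split$test$subject_id
  truth <- stats::setNames(corpus$manifest$label, corpus$manifest$subject_id)

  if (system == "embedding") {
    train_raw <- extract_features(recs[train_ids], embedder)
    whitening <- fit_whitening(train_raw$features, n_components)
    train_feat <- apply_whitening(whitening, train_raw$features)
    model <- train_segment_classifier(train_feat, train_raw$meta$label,
                                      classifier)
    test_set <- extract_features(recs[test_ids], embedder,
                                 whitening = whitening)
    seg_pred <- predict_segments(model, test_set$features)
    per_subject <- do.call(rbind, lapply(test_ids, function(id) {
      labs <- seg_pred[test_set$meta$subject_id == id]
      data.frame(subject_id = id, true = unname(truth[id]),
                 predicted = majority_vote(labs),
                 votes_ad = sum(labs == "AD"),
                 votes_nonad = sum(labs == "NONAD"),
                 stringsAsFactors = FALSE)
    }))
    seg_truth <- test_set$meta$label
    segment_metrics <- compute_metrics(confusion_counts(
      data.frame(true = seg_truth, predicted = seg_pred)))
    config_echo <- list(classifier = classifier$kind,
                        classifier_seed = classifier$seed,
                        embedder = embedder$name,
                        n_components = n_components)
    extra <- list(segment_metrics = segment_metrics)
  } else {
    Xtr <- demcnn_prepare_batch(recs[train_ids], cnn_config)
    model0 <- build_demcnn(cnn_config)
    fit <- fit_two_step(model0, Xtr, truth[train_ids], schedule,
                        seed = seed)
    Xte <- demcnn_prepare_batch(recs[test_ids], cnn_config)
    pred <- demcnn_predict(fit$model, Xte)
    per_subject <- data.frame(subject_id = test_ids,
                              true = unname(truth[test_ids]),
                              predicted = unname(pred),
                              votes_ad = NA_integer_,
                              votes_nonad = NA_integer_,
                              stringsAsFactors = FALSE)
    config_echo <- list(decimation = cnn_config$decimation_factors,
                        input_len = cnn_config$input_len,
                        schedule = unclass(schedule),
                        selected_step2_lr = fit$selected_lr)
    extra <- list(history = fit$history)
  }
  metrics <- compute_metrics(confusion_counts(per_subject))
  c(list(system = system, seed = seed, train_fraction = train_fraction,
         config = config_echo, train_subjects = sort(train_ids),
         test_subjects = sort(test_ids), predictions = per_subject,
         metrics = metrics),
    extra)
}

#' Write an experiment report
#'
#' Serializes the report as JSON (stable key order, no timestamps) and the
#' per-subject predictions as CSV next to it.
#'
#' @param report A [run_experiment()] report.
#' @param path Output JSON path; the CSV gets the same stem.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  body <- report
  body$predictions <- NULL
  body$history <- NULL
  for (nm in c("metrics", "segment_metrics")) {
    if (!is.null(body[[nm]])) body[[nm]] <- unclass(body[[nm]])
  }
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(report$predictions,
                   sub("\\.json$", "_predictions.csv", path),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
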