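test_that("majority vote follows strict majority with ties to NONAD", {
  expect_equal(majority_vote(c("AD", "AD", "NONAD")), "AD")
  expect_equal(majority_vote(c("AD", "NONAD")), "NONAD")
  expect_equal(majority_vote("AD"), "AD")
  expect_error(majority_vote(character(0)), "zero segments")
})

test_that("majority vote agrees with brute-force count-and-argmax on 1000 random multisets", {
  for (i in 1:1000) {
    labs <- withr::with_seed(i, sample(c("AD", "NONAD"),
                                       sample(1:15, 1), replace = TRUE))
    counts <- table(factor(labs, levels = c("NONAD", "AD")))
    want <- if (counts["AD"] > counts["NONAD"]) "AD" else "NONAD"
    expect_identical(majority_vote(labs), want)
  }
})

test_that("confusion counts treat AD as positive and always sum to n", {
  all_right <- data.frame(true = rep(c("AD", "NONAD"), each = 4),
                          predicted = rep(c("AD", "NONAD"), each = 4))
  cc <- confusion_counts(all_right)
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = 4L, fp = 0L, fn = 0L, tn = 4L))
  flipped <- all_right
  flipped$predicted <- rev(flipped$predicted)
  cc2 <- confusion_counts(flipped)
  expect_equal(unlist(cc2[c("tp", "fp", "fn", "tn")]),
               c(tp = 0L, fp = 4L, fn = 4L, tn = 0L))
  for (i in 1:20) {
    df <- withr::with_seed(i, data.frame(
      true = sample(c("AD", "NONAD"), 17, replace = TRUE),
      predicted = sample(c("AD", "NONAD"), 17, replace = TRUE)))
    cci <- confusion_counts(df)
    expect_equal(cci$tp + cci$fp + cci$fn + cci$tn, 17)
  }
  expect_error(confusion_counts(data.frame(predicted = "AD")), "true label")
})

test_that("metrics reproduce their closed forms and warn on empty denominators", {
  m <- compute_metrics(structure(list(tp = 3, fp = 1, fn = 1, tn = 5),
                                 class = "confusion_counts"))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, 0.8)

  perfect <- compute_metrics(structure(list(tp = 5, fp = 0, fn = 0, tn = 5),
                                       class = "confusion_counts"))
  expect_equal(unlist(perfect[c("precision", "recall", "f1", "accuracy")]),
               c(precision = 1, recall = 1, f1 = 1, accuracy = 1))

  expect_warning(
    none <- compute_metrics(structure(list(tp = 0, fp = 0, fn = 2, tn = 6),
                                      class = "confusion_counts")),
    "precision")
  expect_equal(none$precision, 0)
})

test_that("the embedding experiment runner produces a complete, reproducible report", {
  spec <- corpus_spec(5, duration_s = 4, seed = 31)
  rep1 <- run_experiment("embedding", spec, seed = 7,
                         classifier = classifier_spec("NN1", seed = 7),
                         n_components = 16L)
  expect_equal(length(rep1$test_subjects), 2)
  expect_equal(length(rep1$train_subjects), 8)
  expect_length(intersect(rep1$train_subjects, rep1$test_subjects), 0)
  expect_equal(sort(c(rep1$train_subjects, rep1$test_subjects)),
               sort(generate_corpus(spec)$manifest$subject_id))
  expect_equal(rep1$predictions$votes_ad + rep1$predictions$votes_nonad,
               rep(4, 2))  # floor(4 s / 0.96 s) patches per subject
  expect_s3_class(rep1$metrics, "metrics")
  expect_s3_class(rep1$segment_metrics, "metrics")

  rep2 <- run_experiment("embedding", spec, seed = 7,
                         classifier = classifier_spec("NN1", seed = 7),
                         n_components = 16L)
  expect_identical(rep1, rep2)
})

test_that("reports serialize to identical JSON across repeated runs", {
  spec <- corpus_spec(3, duration_s = 3, seed = 13)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.json"); p2 <- file.path(d, "b.json")
  write_report(run_experiment("embedding", spec, seed = 2,
                              n_components = 8L), p1)
  write_report(run_experiment("embedding", spec, seed = 2,
                              n_components = 8L), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_true(file.exists(file.path(d, "a_predictions.csv")))
})
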