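test_that("confusion counts are exact with AD as the positive class", {
  perfect <- confusion_counts(rep(c(0, 1), each = 5), rep(c(0, 1), each = 5))
  expect_equal(unclass(perfect)[c("TP", "TN", "FP", "FN")],
               list(TP = 5L, TN = 5L, FP = 0L, FN = 0L), ignore_attr = TRUE)
  all_pos <- confusion_counts(rep(c(0, 1), each = 5), rep(1, 10))
  expect_equal(all_pos$TP, 5)
  expect_equal(all_pos$FP, 5)
  expect_equal(all_pos$TN + all_pos$FN, 0)
  expect_error(confusion_counts(c(0, 1), c(1)), "equal length")
})

test_that("metric formulas match direct arithmetic", {
  m <- classification_metrics(
    structure(list(TP = 4, FP = 1, FN = 1, TN = 4), class = "confusion_counts"))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  m2 <- classification_metrics(
    structure(list(TP = 3, FP = 1, FN = 2, TN = 4), class = "confusion_counts"))
  expect_equal(m2$accuracy, 0.7)
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$recall, 0.6)
  expect_equal(m2$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  m3 <- classification_metrics(
    structure(list(TP = 6, FP = 0, FN = 0, TN = 4), class = "confusion_counts"))
  expect_equal(unlist(m3[c("accuracy", "precision", "recall", "f1")]),
               rep(1, 4), ignore_attr = TRUE)
})

test_that("zero-denominator metrics are reported missing, not coerced to 0", {
  cc <- confusion_counts(c(1, 1, 0), c(0, 0, 0))  # no positive predictions
  expect_warning(m <- classification_metrics(cc), "precision undefined")
  expect_true(is.na(m$precision))
  expect_equal(m$recall, 0)
  expect_error(classification_metrics(
    structure(list(TP = 0, FP = 0, FN = 0, TN = 0),
              class = "confusion_counts")), "all zero")
})

test_that("metrics are invariant under joint permutation of labels", {
  set.seed(17)
  truth <- sample(c(0, 1), 40, replace = TRUE)
  pred <- sample(c(0, 1), 40, replace = TRUE)
  perm <- sample(40)
  a <- classification_metrics(confusion_counts(truth, pred))
  b <- classification_metrics(confusion_counts(truth[perm], pred[perm]))
  expect_equal(a, b)
})

test_that("accuracy equals the matching-position rate on random labels", {
  set.seed(23)
  for (i in 1:200) {
    truth <- sample(c(0, 1), 25, replace = TRUE)
    pred <- sample(c(0, 1), 25, replace = TRUE)
    acc <- classification_metrics(confusion_counts(truth, pred))$accuracy
    expect_equal(acc, mean(truth == pred))
  }
})

# Balanced synthetic accuracy tables for the ANOVA tests.
make_table <- function(cell_fun, features = c("A", "B"),
                       classifiers = c("x", "y"), reps = 2) {
  rows <- expand.grid(feature = features, classifier = classifiers,
                      run = seq_len(reps), stringsAsFactors = FALSE)
  rows$accuracy <- mapply(cell_fun, rows$feature, rows$classifier, rows$run)
  rows
}

test_that("a constant accuracy table yields zero F and p = 1 everywhere", {
  tab <- make_table(function(f, c, r) 0.7)
  res <- two_way_anova(tab)
  expect_equal(res$anova_table$F, rep(0, 3))
  expect_equal(res$anova_table$p, rep(1, 3))
})

test_that("sums of squares match a hand-computed decomposition on a 2x2x2 table", {
  tab <- make_table(function(f, c, r) {
    0.5 + 0.1 * (f == "B") + 0.05 * (c == "y") +
      0.02 * (f == "B" && c == "y") + 0.01 * (r == 2)
  })
  res <- two_way_anova(tab)
  # manual balanced two-way decomposition
  g <- mean(tab$accuracy)
  fm <- tapply(tab$accuracy, tab$feature, mean)
  cm <- tapply(tab$accuracy, tab$classifier, mean)
  cellm <- tapply(tab$accuracy, list(tab$feature, tab$classifier), mean)
  n_f <- 4; n_c <- 4; n_cell <- 2
  ss_f <- n_f * sum((fm - g)^2)
  ss_c <- n_c * sum((cm - g)^2)
  ss_cells <- n_cell * sum((cellm - g)^2)
  ss_int <- ss_cells - ss_f - ss_c
  get_ss <- function(e) res$anova_table$sum_sq[res$anova_table$effect == e]
  expect_equal(get_ss("feature"), ss_f, tolerance = 1e-10)
  expect_equal(get_ss("classifier"), ss_c, tolerance = 1e-10)
  expect_equal(get_ss("interaction"), ss_int, tolerance = 1e-10)
})

test_that("the sum-of-squares decomposition is complete on balanced designs", {
  set.seed(29)
  tab <- make_table(function(f, c, r) stats::runif(1, 0.4, 0.9),
                    features = c("A", "B", "C"), classifiers = c("x", "y"),
                    reps = 4)
  res <- two_way_anova(tab)
  fit <- stats::aov(accuracy ~ feature * classifier,
                    data = transform(tab, feature = factor(feature),
                                     classifier = factor(classifier)))
  ss_resid <- sum(stats::residuals(fit)^2)
  ss_total <- sum((tab$accuracy - mean(tab$accuracy))^2)
  expect_equal(sum(res$anova_table$sum_sq) + ss_resid, ss_total,
               tolerance = 1e-8)
})

test_that("an injected feature shift is detected as a main effect", {
  set.seed(37)
  hits <- vapply(1:20, function(i) {
    tab <- make_table(function(f, c, r)
      stats::rnorm(1, 0.6 + 0.2 * (f == "B"), 0.01),
      features = c("A", "B"), classifiers = c("u", "v", "w", "x", "y"),
      reps = 5)
    p <- two_way_anova(tab)$anova_table
    p$p[p$effect == "feature"] < 0.05
  }, logical(1))
  expect_true(all(hits))
})

test_that("a significant interaction triggers the Tukey cell comparison", {
  set.seed(41)
  tab <- make_table(function(f, c, r)
    stats::rnorm(1, 0.6 + 0.25 * (f == "B" && c == "y"), 0.01),
    reps = 5)
  res <- two_way_anova(tab)
  expect_true(res$interaction_significant)
  expect_s3_class(res$tukey, "data.frame")
  expect_equal(res$best_cell, "B:y")
  expect_false("A:x" %in% res$best_group)
})

test_that("unbalanced designs are rejected with the deficient cells named", {
  tab <- make_table(function(f, c, r) 0.5, reps = 3)
  tab <- tab[-1, ]  # knock one replicate out of cell A:x
  expect_error(two_way_anova(tab), "A:x")
  expect_error(two_way_anova(data.frame(feature = "A", classifier = "x",
                                        accuracy = 0.5)), "2 levels")
})

test_that("ANOVA reports serialize to JSON and accuracies plot", {
  set.seed(43)
  tab <- make_table(function(f, c, r) stats::rnorm(1, 0.7, 0.05), reps = 3)
  res <- two_way_anova(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_anova_report(res, path)
  doc <- jsonlite::read_json(path)
  expect_equal(length(doc$anova_table), 3L)
  p <- plot_accuracy_summary(data.frame(stream = tab$feature,
                                        classifier = tab$classifier,
                                        accuracy = tab$accuracy))
  expect_s3_class(p, "ggplot")
})
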