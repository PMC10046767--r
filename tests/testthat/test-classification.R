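# Two linearly separable Gaussian clusters in 5 dimensions.
separable_data <- function(n_per_class = 30, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * 5, 0), ncol = 5),
             matrix(stats::rnorm(n_per_class * 5, 6), ncol = 5))
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

test_that("every classifier separates two distant clusters perfectly", {
  d <- separable_data()
  for (cls in c("lda", "dt", "knn", "svm", "tb")) {
    model <- train_classifier(d$x, d$y, cls, seed = 3)
    expect_equal(stats::predict(model, d$x), d$y,
                 info = paste("classifier:", cls))
  }
})

test_that("training requires both classes with at least two segments each", {
  d <- separable_data()
  expect_error(train_classifier(d$x[1:30, ], d$y[1:30], "dt"), "single class")
  expect_error(train_classifier(d$x[c(1:5, 31), ], d$y[c(1:5, 31)], "dt"),
               "at least 2")
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  set.seed(77)
  n <- 200
  x <- matrix(stats::rnorm(n * 4), ncol = 4)
  y <- rep(c(0L, 1L), each = n / 2)      # labels carry no signal
  folds <- sample(rep(1:5, length.out = n))
  preds <- integer(n)
  for (k in 1:5) {
    model <- train_classifier(x[folds != k, ], y[folds != k], "dt", seed = k)
    preds[folds == k] <- stats::predict(model, x[folds == k, , drop = FALSE])
  }
  acc <- mean(preds == y)
  expect_gte(acc, 0.35)   # binomial null band at n = 200
  expect_lte(acc, 0.65)
})

test_that("training and prediction are deterministic given the seed", {
  d <- separable_data(seed = 5)
  test_x <- separable_data(seed = 6)$x
  for (cls in c("knn", "tb")) {  # the two with internal randomness
    p1 <- stats::predict(train_classifier(d$x, d$y, cls, seed = 11), test_x)
    p2 <- stats::predict(train_classifier(d$x, d$y, cls, seed = 11), test_x)
    expect_identical(p1, p2, info = cls)
  }
})

test_that("the shrinkage discriminant handles more features than segments", {
  set.seed(9)
  n <- 20; p <- 300
  x <- matrix(stats::rnorm(n * p), n, p)
  y <- rep(c(0L, 1L), each = n / 2)
  x[y == 1L, 1:10] <- x[y == 1L, 1:10] + 3
  model <- train_classifier(x, y, "lda", seed = 1)
  expect_true(inherits(model$fit, "shrinkage_lda"))
  expect_equal(stats::predict(model, x), y)
})

test_that("majority_vote returns the modal label with ties toward AD", {
  expect_equal(majority_vote(c(1, 1, 0)), 1L)
  expect_equal(majority_vote(c(0, 0, 0, 1)), 0L)
  expect_equal(majority_vote(c(1, 0)), 1L)       # declared tie rule
  expect_error(majority_vote(integer(0)), "empty")
  expect_error(majority_vote(c(0, 2)), "0 or 1")
})

test_that("majority_vote is permutation invariant and flips with its votes", {
  set.seed(13)
  for (i in 1:50) {
    votes <- sample(c(0L, 1L), sample(1:15, 1), replace = TRUE)
    expect_equal(majority_vote(votes), majority_vote(sample(votes)))
    if (mean(votes) != 0.5)  # non-tied votes flip cleanly
      expect_equal(majority_vote(1L - votes), 1L - majority_vote(votes))
  }
})

test_that("predict_subject aggregates segment votes", {
  d <- separable_data()
  model <- train_classifier(d$x, d$y, "lda", seed = 2)
  sp <- predict_subject(model, d$x[31:35, ], subject_id = "s1")
  expect_equal(sp$predicted, 1L)
  expect_equal(sp$vote_fraction, 1)
  expect_equal(sp$n_votes, 5L)
  single <- predict_subject(model, d$x[1, , drop = FALSE])
  expect_equal(single$predicted, stats::predict(model, d$x[1, , drop = FALSE]))
})

test_that("the ensemble pools segment votes across streams", {
  expect_equal(ensemble_predict(list(c(1, 1), c(1, 1, 1)))$predicted, 1L)
  # unanimous but opposite streams -> pooled tie -> AD by rule
  expect_equal(ensemble_predict(list(c(1, 1, 1), c(0, 0, 0)))$predicted, 1L)
  # pooled [1,1,0,0,1,0,0] -> majority 0
  sp <- ensemble_predict(list(c(1, 1, 0, 0, 1), c(0, 0)))
  expect_equal(sp$predicted, 0L)
  expect_equal(sp$n_votes, 7L)
  expect_error(ensemble_predict(list()), "non-empty")
  expect_error(ensemble_predict(list(c(1, 0), integer(0))), "at least one")
})

test_that("a single-stream ensemble equals the plain subject vote", {
  d <- separable_data()
  model <- train_classifier(d$x, d$y, "svm", seed = 4)
  seg <- d$x[c(1:3, 31:34), ]
  votes <- stats::predict(model, seg)
  expect_equal(ensemble_predict(list(votes))$predicted,
               predict_subject(model, seg)$predicted)
})

test_that("run_experiment produces a complete, reproducible ledger", {
  corp <- tiny_corpus(n = 3, duration = 20, seed = 15)
  exp1 <- run_experiment(corp, streams = "vad_pause", classifiers = "dt",
                         n_runs = 2, seed = 5)
  exp2 <- run_experiment(corp, streams = "vad_pause", classifiers = "dt",
                         n_runs = 2, seed = 5)
  expect_identical(exp1$predictions, exp2$predictions)
  expect_equal(sort(unique(exp1$predictions$run)), 1:2)
  expect_equal(nrow(exp1$metrics), 2L)  # one metric row per run
  expect_true(all(c("run", "stream", "classifier", "subject_id", "true",
                    "predicted", "vote_fraction") %in%
                    names(exp1$predictions)))
  # subject-disjoint split: test subjects only in the ledger, 2 per run
  # (one held-out subject per class at train_fraction 0.7)
  expect_equal(as.integer(table(exp1$predictions$run)), c(2L, 2L))
})

test_that("multi-stream experiments add ensemble rows per classifier", {
  corp <- tiny_corpus(n = 3, duration = 16, seed = 19)
  exp <- run_experiment(corp, streams = c("vad_pause", "egemaps"),
                        classifiers = "dt", n_runs = 1, seed = 3)
  expect_setequal(unique(exp$predictions$stream),
                  c("vad_pause", "egemaps", "ensemble"))
  ens <- exp$predictions[exp$predictions$stream == "ensemble", ]
  expect_gt(nrow(ens), 0)
})
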