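# Segment-level classification with subject-level majority voting.
#
# Five classic classifiers operate on per-segment feature vectors (the binary
# pause sequence of a 4 s window, or a functional acoustic profile). A
# subject's diagnosis is the majority vote over its segment predictions; the
# ensemble pools segment votes across feature streams before voting. Exact
# ties break toward the positive (AD) class: in a screening context the
# sensitive direction is preferred, and the rule is explicit and testable.

CLASSIFIER_TYPES <- c("lda", "dt", "knn", "svm", "tb")

#' Train a segment-level classifier
#'
#' Supported types: `"lda"` (linear discriminant analysis; switches to a
#' diagonal-shrinkage variant when features outnumber segments), `"dt"`
#' (CART decision tree, Gini split), `"knn"` (k-nearest neighbour, k = 5,
#' Euclidean), `"svm"` (support vector machine, linear kernel, C = 1,
#' SMO-type solver), `"tb"` (tree bagger: 100 bootstrap-aggregated trees).
#' Distance/margin-based classifiers (lda, knn, svm) standardize features
#' with training-set statistics; tree-based ones use raw features.
#'
#' @param features Numeric matrix, one row per segment.
#' @param labels Binary segment labels (0/1), at least 2 per class.
#' @param classifier One of `"lda"`, `"dt"`, `"knn"`, `"svm"`, `"tb"`.
#' @param seed Integer seed making the fit (and any tie-breaking at
#'   prediction time) deterministic.
#' @param scale Standardize features? Default depends on the classifier.
#' @return Object of class `pausekit_classifier`.
#' @export
train_classifier <- function(features, labels,
                             classifier = c("lda", "dt", "knn", "svm", "tb"),
                             seed = 1L, scale = NULL) {
  classifier <- match.arg(classifier)
  x <- as.matrix(features)
  y <- as.integer(labels)
  if (length(y) != nrow(x)) stop("labels must match feature rows")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  tab <- table(factor(y, levels = c(0L, 1L)))
  if (any(tab == 0L))
    stop("training set contains a single class; need both 0 and 1")
  if (any(tab < 2L)) stop("need at least 2 segments per class")
  if (is.null(scale)) scale <- classifier %in% c("lda", "knn", "svm")

  sds <- apply(x, 2L, stats::sd)
  keep <- which(is.finite(sds) & sds > 1e-12)
  if (!length(keep)) stop("all features are constant on the training set")
  xk <- x[, keep, drop = FALSE]
  scaler <- NULL
  if (scale) {
    sc <- scale_features(xk)
    xk <- sc$train
    scaler <- list(center = sc$center, scale = sc$scale)
  }
  yf <- factor(y, levels = c(0L, 1L))
  set.seed(as.integer(seed))
  fit <- switch(classifier,
    lda = if (ncol(xk) >= nrow(xk) - 2L) fit_shrinkage_lda(xk, y)
          else suppressWarnings(MASS::lda(xk, grouping = yf)),
    dt = {
      df <- data.frame(.y = yf, xk)
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    knn = list(x = xk, y = yf, k = 5L),
    svm = e1071::svm(xk, yf, kernel = "linear", cost = 1, scale = FALSE),
    tb = randomForest::randomForest(xk, yf, ntree = 100L, mtry = ncol(xk),
                                    replace = TRUE))
  structure(list(type = classifier, fit = fit, keep = keep, scaler = scaler,
                 seed = as.integer(seed),
                 config = list(knn_k = 5L, svm_cost = 1, tb_ntree = 100L,
                               scaled = scale)),
            class = "pausekit_classifier")
}

# Diagonal-shrinkage linear discriminant for p >= n streams: pooled
# within-class variances shrunk toward their mean with intensity p/(p+n).
fit_shrinkage_lda <- function(x, y) {
  n <- nrow(x); p <- ncol(x)
  mu0 <- colMeans(x[y == 0L, , drop = FALSE])
  mu1 <- colMeans(x[y == 1L, , drop = FALSE])
  c0 <- sweep(x[y == 0L, , drop = FALSE], 2L, mu0)
  c1 <- sweep(x[y == 1L, , drop = FALSE], 2L, mu1)
  v <- (colSums(c0^2) + colSums(c1^2)) / max(n - 2L, 1L)
  lambda <- p / (p + n)
  v <- (1 - lambda) * v + lambda * mean(v)
  v <- pmax(v, 1e-12)
  w <- (mu1 - mu0) / v
  thresh <- sum(w * (mu0 + mu1)) / 2 +
    log(sum(y == 0L) / sum(y == 1L))
  structure(list(w = w, thresh = thresh), class = "shrinkage_lda")
}

predict_shrinkage_lda <- function(object, newdata) {
  as.integer(as.numeric(newdata %*% object$w) > object$thresh)
}

#' Predict segment labels
#'
#' @param object A trained [train_classifier()] model.
#' @param newdata Feature matrix with the training-time columns.
#' @param ... Unused.
#' @return Integer vector of 0/1 segment predictions.
#' @export
predict.pausekit_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$keep, drop = FALSE]
  if (!is.null(object$scaler)) {
    x <- sweep(x, 2L, object$scaler$center, "-")
    x <- sweep(x, 2L, object$scaler$scale, "/")
  }
  set.seed(object$seed + 1L)  # knn distance/vote ties are broken at random
  out <- switch(object$type,
    lda = if (inherits(object$fit, "shrinkage_lda"))
            predict_shrinkage_lda(object$fit, x)
          else as.integer(as.character(stats::predict(object$fit, x)$class)),
    dt = as.integer(as.character(
      stats::predict(object$fit, data.frame(x), type = "class"))),
    knn = as.integer(as.character(
      class::knn(object$fit$x, x, object$fit$y, k = object$fit$k))),
    svm = as.integer(as.character(stats::predict(object$fit, x))),
    tb = as.integer(as.character(stats::predict(object$fit, x))))
  out
}

#' Majority vote over binary segment votes
#'
#' Returns the modal label; an exact tie returns 1 (AD), the declared,
#' sensitivity-favouring rule.
#'
#' @param votes Non-empty vector over \{0, 1\}.
#' @return 0 or 1.
#' @export
majority_vote <- function(votes) {
  if (length(votes) < 1L) stop("cannot vote over an empty vote set")
  if (!all(votes %in% c(0, 1))) stop("votes must be 0 or 1")
  if (mean(votes) >= 0.5) 1L else 0L
}

#' Aggregate one subject's segment predictions
#'
#' @param model A trained [train_classifier()] model.
#' @param segments Feature matrix of that subject's segments (>= 1 row).
#' @param subject_id Optional subject id.
#' @return Object of class `subject_prediction`: list with `subject_id`,
#'   `predicted`, `vote_fraction` (fraction of votes for class 1), `n_votes`.
#' @export
predict_subject <- function(model, segments, subject_id = NA_character_) {
  segments <- as.matrix(segments)
  if (nrow(segments) < 1L) stop("need at least one segment")
  votes <- stats::predict(model, segments)
  subject_prediction(subject_id, votes)
}

subject_prediction <- function(subject_id, votes) {
  structure(list(subject_id = as.character(subject_id),
                 predicted = majority_vote(votes),
                 vote_fraction = mean(votes == 1),
                 n_votes = length(votes)),
            class = "subject_prediction")
}

#' @export
print.subject_prediction <- function(x, ...) {
  cat(sprintf("<subject_prediction> %s -> %d (%.0f%% of %d votes)\n",
              x$subject_id, x$predicted, 100 * x$vote_fraction, x$n_votes))
  invisible(x)
}

#' Ensemble vote across feature streams
#'
#' Pools all segment-level votes of one subject from every stream into a
#' single vote set and applies the majority rule, so each stream contributes
#' proportionally to its segment count. With a single stream this reduces to
#' [predict_subject()]'s vote.
#'
#' @param stream_votes List of 0/1 vote vectors, one per feature stream.
#' @param subject_id Optional subject id.
#' @return A `subject_prediction`.
#' @export
ensemble_predict <- function(stream_votes, subject_id = NA_character_) {
  if (!is.list(stream_votes) || length(stream_votes) < 1L)
    stop("'stream_votes' must be a non-empty list of vote vectors")
  if (any(!vapply(stream_votes, length, integer(1))))
    stop("every stream must contribute at least one segment vote")
  subject_prediction(subject_id, unlist(stream_votes))
}

# -- Experiment driver --------------------------------------------------------

#' Run the full classification experiment
#'
#' For each run the subjects are split (subject-disjoint, stratified) into a
#' training and test set with a run-specific derived seed, every
#' (stream x classifier) combination is trained on training-set segments and
#' evaluated on held-out subjects via majority voting, and — when several
#' streams are requested — the ensemble pools segment votes across streams
#' per classifier. Repeating runs with reshuffled splits mirrors the
#' five-run averaged evaluation protocol.
#'
#' @param corpus A `speech_corpus` from [generate_corpus()], or a manifest
#'   data.frame with `subject_id`, `audio_path`, `label` columns pointing at
#'   WAV files on disk.
#' @param streams Feature streams: any of `"vad_pause"`, `"compare2013"`,
#'   `"egemaps"`.
#' @param classifiers Classifier types (see [train_classifier()]).
#' @param n_runs Number of reshuffled runs (default 5).
#' @param seed Base seed; run r uses `seed + r`.
#' @param train_fraction Fraction of subjects (per class) used for training
#'   (default 0.7).
#' @param vad_model A [vad_model()]; `NULL` fits one on the corpus itself.
#' @param frame_duration VAD frame length in seconds (default 0.03).
#' @param segment_duration Segment length in seconds (default 4).
#' @return Object of class `pause_experiment`: list with `predictions`
#'   (run/stream/classifier/subject ledger), `metrics` (per-run metric rows),
#'   `vad_model`, `config`.
#' @export
run_experiment <- function(corpus, streams = "vad_pause",
                           classifiers = "tb", n_runs = 5L, seed = 1L,
                           train_fraction = 0.7, vad_model = NULL,
                           frame_duration = 0.03, segment_duration = 4) {
  streams <- match.arg(streams, c("vad_pause", "compare2013", "egemaps"),
                       several.ok = TRUE)
  classifiers <- match.arg(classifiers, CLASSIFIER_TYPES, several.ok = TRUE)
  if (n_runs < 1L) stop("'n_runs' must be at least 1")
  cd <- corpus_data(corpus)
  if (any(is.na(cd$manifest$label)))
    stop("run_experiment() needs a fully labeled manifest")

  ems <- NULL
  if ("vad_pause" %in% streams) {
    # one energy pass shared between VAD calibration and frame labeling
    ems <- lapply(cd$signals, function(s)
      energies_of_frames(frame_audio(s, frame_duration), s$sample_rate))
    if (is.null(vad_model))
      vad_model <- fit_vad_model_from_energies(ems)
  }

  feats <- lapply(streams, function(stream) {
    per_subj <- lapply(seq_along(cd$signals), function(i) {
      sig <- cd$signals[[i]]
      sid <- cd$manifest$subject_id[i]
      m <- if (stream == "vad_pause") {
        labels <- vad_labels_from_energies(vad_model, ems[[i]]$E, ems[[i]]$E_t)
        ps <- pause_sequence(labels, frame_duration, subject_id = sid)
        segment_pauses(ps, segment_duration)$segments
      } else {
        extract_feature_matrix(sig, stream, segment_duration)
      }
      list(x = m, subject = rep(sid, nrow(m)))
    })
    list(x = do.call(rbind, lapply(per_subj, `[[`, "x")),
         subject = unlist(lapply(per_subj, `[[`, "subject")))
  })
  names(feats) <- streams
  labels_of <- stats::setNames(cd$manifest$label, cd$manifest$subject_id)

  pred_rows <- list()
  for (run in seq_len(n_runs)) {
    run_seed <- as.integer(seed) + run
    set.seed(run_seed)
    split <- split_subjects(cd$manifest, train_fraction)
    votes <- list()  # votes[[classifier]][[stream]][[subject]]
    for (stream in streams) {
      fx <- feats[[stream]]
      tr <- fx$subject %in% split$train
      y_tr <- labels_of[fx$subject[tr]]
      for (cls in classifiers) {
        model <- train_classifier(fx$x[tr, , drop = FALSE], y_tr, cls,
                                  seed = run_seed)
        for (sid in split$test) {
          rows <- fx$subject == sid
          sv <- stats::predict(model, fx$x[rows, , drop = FALSE])
          votes[[cls]][[stream]][[sid]] <- sv
          sp <- subject_prediction(sid, sv)
          pred_rows[[length(pred_rows) + 1L]] <- data.frame(
            run = run, stream = stream, classifier = cls, subject_id = sid,
            true = unname(labels_of[sid]), predicted = sp$predicted,
            vote_fraction = sp$vote_fraction, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(streams) > 1L) {
      for (cls in classifiers) {
        for (sid in split$test) {
          sp <- ensemble_predict(lapply(votes[[cls]], `[[`, sid), sid)
          pred_rows[[length(pred_rows) + 1L]] <- data.frame(
            run = run, stream = "ensemble", classifier = cls,
            subject_id = sid, true = unname(labels_of[sid]),
            predicted = sp$predicted, vote_fraction = sp$vote_fraction,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  predictions <- do.call(rbind, pred_rows)
  structure(list(predictions = predictions,
                 metrics = experiment_metrics(predictions),
                 vad_model = vad_model,
                 config = list(streams = streams, classifiers = classifiers,
                               n_runs = n_runs, seed = seed,
                               train_fraction = train_fraction,
                               frame_duration = frame_duration,
                               segment_duration = segment_duration)),
            class = "pause_experiment")
}

#' @export
print.pause_experiment <- function(x, ...) {
  cat("<pause_experiment>", x$config$n_runs, "run(s),",
      paste(x$config$streams, collapse = "+"), "x",
      paste(x$config$classifiers, collapse = "/"), "\n")
  agg <- stats::aggregate(accuracy ~ stream + classifier, x$metrics, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

# Per-run metric table from the subject-level prediction ledger.
experiment_metrics <- function(predictions) {
  combos <- unique(predictions[c("run", "stream", "classifier")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- predictions$run == combos$run[i] &
      predictions$stream == combos$stream[i] &
      predictions$classifier == combos$classifier[i]
    cc <- confusion_counts(predictions$true[sel], predictions$predicted[sel])
    m <- suppressWarnings(classification_metrics(cc))
    data.frame(combos[i, , drop = FALSE], accuracy = m$accuracy,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Normalize a corpus argument to list(signals, manifest).
corpus_data <- function(corpus) {
  if (inherits(corpus, "speech_corpus"))
    return(list(signals = corpus$signals, manifest = corpus$manifest))
  if (is.data.frame(corpus)) {
    validate_manifest(corpus)
    signals <- lapply(corpus$audio_path, function(p) preprocess(read_wav(p)))
    return(list(signals = signals, manifest = corpus))
  }
  stop("'corpus' must be a speech_corpus or a manifest data.frame")
}

# Stratified subject-disjoint split; at least one test subject per class.
split_subjects <- function(manifest, train_fraction) {
  train <- character(0)
  for (lab in unique(manifest$label)) {
    ids <- manifest$subject_id[manifest$label == lab]
    n_tr <- max(1L, min(length(ids) - 1L, round(train_fraction * length(ids))))
    train <- c(train, sample(ids)[seq_len(n_tr)])
  }
  list(train = train,
       test = setdiff(manifest$subject_id, train))
}
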