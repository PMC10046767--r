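# Subject-level evaluation: confusion counts, the four standard binary
# classification metrics, and a two-way (feature x classifier) analysis of
# variance over per-run accuracies with a Tukey HSD follow-up. The positive
# class is AD (label 1) throughout.

#' Confusion counts for binary predictions
#'
#' AD (1) is the positive class.
#'
#' @param true_labels,predicted_labels Equal-length binary vectors.
#' @return Object of class `confusion_counts`: list with `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
confusion_counts <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("true and predicted label vectors must have equal length")
  if (!all(true_labels %in% c(0, 1)) || !all(predicted_labels %in% c(0, 1)))
    stop("labels must be binary 0/1")
  structure(list(
    TP = sum(true_labels == 1 & predicted_labels == 1),
    FP = sum(true_labels == 0 & predicted_labels == 1),
    FN = sum(true_labels == 1 & predicted_labels == 0),
    TN = sum(true_labels == 0 & predicted_labels == 0)),
    class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), Precision = TP/(TP+FP),
#' Recall = TP/(TP+FN), F1 = 2*Precision*Recall/(Precision+Recall).
#' A metric whose denominator is zero is reported as `NA` with a warning
#' rather than coerced to 0, so run averages are not silently biased.
#'
#' @param counts A [confusion_counts()].
#' @return Object of class `metrics_report`: list with `accuracy`,
#'   `precision`, `recall`, `f1` (proportions in `[0, 1]`).
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0L) stop("confusion counts are all zero; nothing was evaluated")
  acc <- (counts$TP + counts$TN) / n
  prec <- if (counts$TP + counts$FP > 0) counts$TP / (counts$TP + counts$FP)
          else { warning("precision undefined: no positive predictions"); NA_real_ }
  rec <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN)
         else { warning("recall undefined: no positive subjects"); NA_real_ }
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) {
    if (!is.na(prec) && !is.na(rec))
      warning("F1 undefined: precision + recall is zero")
    NA_real_
  } else 2 * prec * rec / (prec + rec)
  structure(list(accuracy = acc, precision = prec, recall = rec, f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> accuracy %.1f%%, precision %.1f%%, recall %.1f%%, F1 %.1f%%\n",
    100 * x$accuracy, 100 * x$precision, 100 * x$recall, 100 * x$f1))
  invisible(x)
}

#' Two-way ANOVA over per-run accuracies
#'
#' Tests the effect of the feature stream and the classifier (and their
#' interaction) on classification accuracy with type-II sums of squares on a
#' balanced design. When the interaction is significant at `alpha`, an
#' all-pairs Tukey HSD over the feature x classifier cells identifies the
#' best-performing cell and the cells not significantly different from it.
#' Effects with zero sum of squares (e.g. a constant table) are reported as
#' F = 0, p = 1.
#'
#' @param accuracy_table Data.frame with columns `feature`, `classifier`,
#'   `run`, `accuracy`; every cell needs the same number (>= 2) of runs.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Object of class `pause_anova`: list with `anova_table` (effect,
#'   df, sum_sq, F, p), `cell_means`, `interaction_significant`, `tukey`
#'   (pairwise cell comparisons or NULL), `best_cell`, `best_group`
#'   (cells not significantly below the best).
#' @export
two_way_anova <- function(accuracy_table, alpha = 0.05) {
  need <- c("feature", "classifier", "accuracy")
  if (!all(need %in% names(accuracy_table)))
    stop("accuracy table must have columns: ", paste(need, collapse = ", "))
  df <- accuracy_table
  df$feature <- factor(df$feature)
  df$classifier <- factor(df$classifier)
  if (nlevels(df$feature) < 2L || nlevels(df$classifier) < 2L)
    stop("need at least 2 levels per factor")
  counts <- table(df$feature, df$classifier)
  if (any(counts < 2L) || length(unique(as.vector(counts))) != 1L) {
    bad <- which(counts != max(counts), arr.ind = TRUE)
    bad_cells <- apply(bad, 1L, function(i)
      paste0(rownames(counts)[i[1L]], ":", colnames(counts)[i[2L]]))
    stop("unbalanced design; deficient cells: ",
         paste(unique(bad_cells), collapse = ", "))
  }
  fit <- stats::aov(accuracy ~ feature * classifier, data = df)
  a2 <- tryCatch(car::Anova(fit, type = 2),
                 error = function(e) NULL)
  if (is.null(a2)) {  # zero residual variance; fall back to raw SS
    a1 <- summary(fit)[[1L]]
    tab <- data.frame(effect = trimws(rownames(a1)[1:3]),
                      df = a1$Df[1:3], sum_sq = a1$`Sum Sq`[1:3],
                      F = NA_real_, p = NA_real_)
    resid_ss <- a1$`Sum Sq`[4L]
  } else {
    tab <- data.frame(effect = trimws(rownames(a2)[1:3]),
                      df = a2$Df[1:3], sum_sq = a2$`Sum Sq`[1:3],
                      F = a2$`F value`[1:3], p = a2$`Pr(>F)`[1:3])
    resid_ss <- a2$`Sum Sq`[4L]
  }
  tab$effect <- c("feature", "classifier", "interaction")
  degenerate <- tab$sum_sq < 1e-12 & (is.na(tab$F) | resid_ss < 1e-12)
  tab$F[degenerate] <- 0
  tab$p[degenerate] <- 1
  cell_means <- stats::aggregate(accuracy ~ feature + classifier, df, mean)
  cell_means <- cell_means[order(-cell_means$accuracy), ]
  rownames(cell_means) <- NULL

  inter_p <- tab$p[tab$effect == "interaction"]
  interaction_significant <- is.finite(inter_p) && inter_p < alpha
  tukey <- NULL
  best_cell <- paste0(cell_means$feature[1L], ":", cell_means$classifier[1L])
  best_group <- best_cell
  if (interaction_significant) {
    tk <- stats::TukeyHSD(fit, "feature:classifier", conf.level = 1 - alpha)
    tkd <- as.data.frame(tk$`feature:classifier`)
    tkd$pair <- rownames(tkd)
    rownames(tkd) <- NULL
    tukey <- tkd
    # cells whose comparison with the best cell is not significant
    involves_best <- grepl(best_cell, tkd$pair, fixed = TRUE)
    ns <- tkd$pair[involves_best & tkd$`p adj` >= alpha]
    others <- unlist(lapply(strsplit(ns, "-", fixed = TRUE), setdiff, best_cell))
    best_group <- unique(c(best_cell, others))
  }
  structure(list(anova_table = tab, cell_means = cell_means,
                 interaction_significant = interaction_significant,
                 tukey = tukey, best_cell = best_cell,
                 best_group = best_group, alpha = alpha),
            class = "pause_anova")
}

#' @export
print.pause_anova <- function(x, ...) {
  cat("<pause_anova> two-way ANOVA (feature x classifier)\n")
  print(x$anova_table, row.names = FALSE)
  cat("best cell:", x$best_cell, "\n")
  if (x$interaction_significant)
    cat("not significantly below best:",
        paste(setdiff(x$best_group, x$best_cell), collapse = ", "), "\n")
  invisible(x)
}

#' Write an ANOVA report as JSON
#' @param anova A `pause_anova` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anova_report <- function(anova, path) {
  stopifnot(inherits(anova, "pause_anova"))
  jsonlite::write_json(
    list(anova_table = anova$anova_table, cell_means = anova$cell_means,
         interaction_significant = anova$interaction_significant,
         best_cell = anova$best_cell, best_group = anova$best_group,
         alpha = anova$alpha),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Box plot of per-run accuracy by stream and classifier
#'
#' @param metrics Data.frame with columns `stream`, `classifier`, `accuracy`
#'   (one row per run), e.g. the `metrics` element of [run_experiment()].
#' @param file Optional image path to save to.
#' @return The ggplot object, invisibly.
#' @export
plot_accuracy_summary <- function(metrics, file = NULL) {
  stopifnot(all(c("stream", "classifier", "accuracy") %in% names(metrics)))
  p <- ggplot2::ggplot(metrics,
                       ggplot2::aes(x = .data$classifier, y = .data$accuracy,
                                    fill = .data$stream)) +
    ggplot2::geom_boxplot(position = "dodge") +
    ggplot2::labs(x = NULL, y = "subject-level accuracy", fill = "feature") +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 7, height = 4)
  invisible(p)
}
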