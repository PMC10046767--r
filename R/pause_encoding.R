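# The VAD Pause feature: a binary per-frame sequence (1 = voiced frame,
# 0 = non-voiced frame) at fixed frame duration, used directly as the
# classifier input after segmentation into fixed-length windows.

#' Construct a pause sequence
#'
#' Packages per-frame voiced/non-voiced decisions with their time base. This
#' binary sequence is the pause feature itself.
#'
#' @param labels Vector over \{0, 1\}: 0 = non-voiced frame, 1 = voiced frame.
#' @param frame_duration Frame length in seconds (default 0.03).
#' @param subject_id Optional subject id.
#' @return Object of class `pause_sequence`: list with `labels` (integer),
#'   `frame_duration`, `subject_id`.
#' @export
pause_sequence <- function(labels, frame_duration = 0.03,
                           subject_id = NA_character_) {
  if (length(labels) < 1L) stop("pause sequence labels must be non-empty")
  if (!all(labels %in% c(0, 1)))
    stop("pause sequence labels must be 0 (non-voiced) or 1 (voiced)")
  if (!is.numeric(frame_duration) || frame_duration <= 0)
    stop("'frame_duration' must be positive")
  structure(list(labels = as.integer(labels),
                 frame_duration = frame_duration,
                 subject_id = as.character(subject_id)),
            class = "pause_sequence")
}

#' @export
print.pause_sequence <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<pause_sequence> %s: %d frames x %.3f s (%.2f s), voiced %.1f%%\n",
              x$subject_id, n, x$frame_duration, n * x$frame_duration,
              100 * mean(x$labels)))
  invisible(x)
}

#' @export
length.pause_sequence <- function(x) length(x$labels)

#' Segment a pause sequence into fixed-length windows
#'
#' Cuts the sequence into consecutive non-overlapping blocks of
#' `floor(segment_duration / frame_duration)` frames (133 frames for the
#' default 4 s / 0.03 s); a trailing remainder shorter than one segment is
#' dropped. Each segment inherits the subject id (and, downstream, the
#' subject's diagnosis label).
#'
#' @param seq A [pause_sequence()].
#' @param segment_duration Segment length in seconds (default 4).
#' @return Object of class `segment_set`: list with `segments` (matrix, one
#'   row per segment), `segment_frames`, `dropped_frames`, `subject_id`,
#'   `frame_duration`.
#' @export
segment_pauses <- function(seq, segment_duration = 4) {
  stopifnot(inherits(seq, "pause_sequence"))
  if (segment_duration < seq$frame_duration)
    stop("'segment_duration' must be at least one frame long")
  seg_frames <- floor(segment_duration / seq$frame_duration)
  n <- length(seq$labels)
  n_seg <- n %/% seg_frames
  if (n_seg < 1L)
    stop(sprintf("sequence (%d frames) is shorter than one segment (%d frames)",
                 n, seg_frames))
  m <- matrix(seq$labels[seq_len(n_seg * seg_frames)], nrow = n_seg, byrow = TRUE)
  structure(list(segments = m, segment_frames = seg_frames,
                 dropped_frames = n - n_seg * seg_frames,
                 subject_id = seq$subject_id,
                 frame_duration = seq$frame_duration),
            class = "segment_set")
}

#' Pause summary statistics
#'
#' Quantifies the pause structure of a sequence: the number of maximal runs
#' of non-voiced frames, their mean duration, and the fraction of time spent
#' pausing vs voiced. AD speech typically shows more and longer pauses than
#' control speech.
#'
#' @param seq A [pause_sequence()].
#' @return Object of class `pause_stats`: list with `pause_count`,
#'   `mean_pause_duration` (s; 0 when there are no pauses),
#'   `pause_time_fraction`, `voiced_fraction`.
#' @export
pause_stats <- function(seq) {
  stopifnot(inherits(seq, "pause_sequence"))
  r <- rle(seq$labels)
  pause_count <- sum(r$values == 0L)
  zero_frames <- sum(seq$labels == 0L)
  structure(list(
    pause_count = pause_count,
    mean_pause_duration = if (pause_count > 0)
      zero_frames * seq$frame_duration / pause_count else 0,
    pause_time_fraction = zero_frames / length(seq$labels),
    voiced_fraction = 1 - zero_frames / length(seq$labels)),
    class = "pause_stats")
}

#' @export
print.pause_stats <- function(x, ...) {
  cat(sprintf("<pause_stats> %d pauses, mean %.3f s, pause time %.1f%%\n",
              x$pause_count, x$mean_pause_duration,
              100 * x$pause_time_fraction))
  invisible(x)
}

# -- Serialization ------------------------------------------------------------

#' Write a pause sequence as CSV
#'
#' One row per frame with columns `frame_index` (1-based), `t_start`
#' (seconds), `label`.
#'
#' @param seq A [pause_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pause_csv <- function(seq, path) {
  stopifnot(inherits(seq, "pause_sequence"))
  n <- length(seq$labels)
  df <- data.frame(frame_index = seq_len(n),
                   t_start = (seq_len(n) - 1L) * seq$frame_duration,
                   label = seq$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pause sequence from CSV
#' @param path Path written by [write_pause_csv()].
#' @param subject_id Optional subject id to attach.
#' @return A [pause_sequence()].
#' @export
read_pause_csv <- function(path, subject_id = NA_character_) {
  df <- utils::read.csv(path)
  if (!all(c("frame_index", "t_start", "label") %in% names(df)))
    stop("not a pause-sequence CSV: ", path)
  fd <- if (nrow(df) >= 2L) df$t_start[2L] - df$t_start[1L] else 0.03
  pause_sequence(df$label, frame_duration = fd, subject_id = subject_id)
}

#' Write a pause sequence in compact one-line form
#'
#' A single line of 0/1 characters; frame duration is stored on a leading
#' comment line.
#'
#' @param seq A [pause_sequence()].
#' @param path Output path (conventionally `.seq`).
#' @return `path`, invisibly.
#' @export
write_pause_seq <- function(seq, path) {
  stopifnot(inherits(seq, "pause_sequence"))
  writeLines(c(sprintf("#frame_duration=%.17g", seq$frame_duration),
               paste(seq$labels, collapse = "")), path)
  invisible(path)
}

#' Read a compact pause-sequence file
#' @param path Path written by [write_pause_seq()].
#' @param subject_id Optional subject id to attach.
#' @return A [pause_sequence()].
#' @export
read_pause_seq <- function(path, subject_id = NA_character_) {
  lines <- readLines(path)
  fd <- 0.03
  if (grepl("^#frame_duration=", lines[1L])) {
    fd <- as.numeric(sub("^#frame_duration=", "", lines[1L]))
    lines <- lines[-1L]
  }
  labels <- as.integer(strsplit(lines[1L], "")[[1L]])
  pause_sequence(labels, frame_duration = fd, subject_id = subject_id)
}

# -- Visualization ------------------------------------------------------------

#' Raster plot comparing pause sequences
#'
#' Renders each sequence as a row of frame markers over time, voiced frames
#' in blue and non-voiced frames in red, optionally grouped into panels
#' (e.g. AD vs control) for visual comparison of pause structure.
#'
#' @param sequences A [pause_sequence()] or list of them.
#' @param groups Optional vector of group labels, one per sequence.
#' @param file Optional image path; when given the plot is saved there.
#' @param width,height Size in inches when saving (defaults 8 x 4).
#' @return The ggplot object, invisibly.
#' @export
plot_pause_comparison <- function(sequences, groups = NULL, file = NULL,
                                  width = 8, height = 4) {
  if (inherits(sequences, "pause_sequence")) sequences <- list(sequences)
  stopifnot(length(sequences) >= 1L,
            all(vapply(sequences, inherits, logical(1), "pause_sequence")))
  if (!is.null(groups) && length(groups) != length(sequences))
    stop("'groups' must have one entry per sequence")
  df <- do.call(rbind, lapply(seq_along(sequences), function(i) {
    s <- sequences[[i]]
    data.frame(
      row = if (!is.na(s$subject_id)) s$subject_id else paste0("seq", i),
      time = (seq_along(s$labels) - 1L) * s$frame_duration,
      state = factor(ifelse(s$labels == 1L, "voiced", "non-voiced"),
                     levels = c("voiced", "non-voiced")),
      group = if (is.null(groups)) "all" else as.character(groups[i]),
      stringsAsFactors = FALSE)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$row,
                                        colour = .data$state)) +
    ggplot2::geom_point(shape = 8, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(voiced = "blue",
                                            `non-voiced` = "red")) +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(groups)) p <- p + ggplot2::facet_grid(group ~ ., scales = "free_y",
                                                     space = "free_y")
  if (!is.null(file)) ggplot2::ggsave(file, p, width = width, height = height)
  invisible(p)
}
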