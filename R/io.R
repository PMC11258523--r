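# Delimited-text interchange formats.
#
# Three tab-delimited tables move between stages:
#   opinion log   : user_id  clip_id  label  event_index
#                   [qscore_at_submission  eligible]
#   clip manifest : clip_id  patient_id  split  [reference_label]  (+extras)
#   expert labels : clip_id + one column per expert id
# Labels are canonical uppercase tokens only (see bline_classes()).

read_tsv_raw <- function(path) {
  if (!file.exists(path)) {
    stop_crowdbline("io_error", sprintf("file not found: %s", path))
  }
  utils::read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = character(0), quote = "",
                    comment.char = "")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_crowdbline(
      "format_error",
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", "))
    )
  }
  invisible(df)
}

write_tsv_raw <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Read an opinion log
#'
#' An opinion log has one row per submitted labeling event, ordered by a
#' single global integer `event_index` (the authoritative submission order;
#' the platform log carries no timestamps). Optional columns
#' `qscore_at_submission` and `eligible` hold the labeler's quality score at
#' the moment of submission and whether that score cleared the eligibility
#' threshold; when absent they are filled with `NA` (not yet scored) and
#' `FALSE`.
#'
#' @param path path to a tab-delimited opinion log.
#' @return A data frame of class `opinion_log` with columns `user_id`,
#'   `clip_id`, `label`, `event_index`, `qscore_at_submission`, `eligible`,
#'   sorted by `event_index`.
#' @seealso [write_opinion_log()], [replay_contest()]
#' @export
read_opinion_log <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, c("user_id", "clip_id", "label", "event_index"),
                  "opinion log")
  check_labels(df$label, where = "opinion log")
  ev <- suppressWarnings(as.integer(df$event_index))
  if (anyNA(ev)) {
    stop_crowdbline("format_error", "event_index must be integer")
  }
  if (anyDuplicated(ev)) {
    stop_crowdbline("integrity_error",
                    sprintf("duplicate event_index: %d", ev[duplicated(ev)][1L]))
  }
  q <- if ("qscore_at_submission" %in% names(df)) {
    suppressWarnings(as.numeric(ifelse(df$qscore_at_submission == "",
                                       NA, df$qscore_at_submission)))
  } else {
    rep(NA_real_, nrow(df))
  }
  el <- if ("eligible" %in% names(df)) {
    df$eligible %in% c("TRUE", "true", "1")
  } else {
    rep(FALSE, nrow(df))
  }
  out <- data.frame(user_id = df$user_id, clip_id = df$clip_id,
                    label = df$label, event_index = ev,
                    qscore_at_submission = q, eligible = el,
                    stringsAsFactors = FALSE)
  out <- out[order(out$event_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("opinion_log", "data.frame")
  out
}

#' Write an opinion log
#'
#' @param opinions an `opinion_log` data frame sorted by `event_index`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_opinion_log <- function(opinions, path) {
  stopifnot(is.data.frame(opinions))
  if (is.unsorted(opinions$event_index, strictly = TRUE)) {
    stop_crowdbline("ordering_error",
                    "opinions must be strictly sorted by event_index")
  }
  cols <- c("user_id", "clip_id", "label", "event_index")
  opt <- intersect(c("qscore_at_submission", "eligible"), names(opinions))
  write_tsv_raw(as.data.frame(opinions)[, c(cols, opt), drop = FALSE], path)
}

#' Read a clip manifest
#'
#' The manifest lists every clip in a contest with its patient, split
#' (`TRAINING`, `TEST` or `UNLABELED`) and, for TRAINING/TEST clips, the
#' expert-consensus reference label. A reference label on an UNLABELED row is
#' ignored with a warning. Extra columns are preserved on round-trip but never
#' used in computation.
#'
#' @param path path to a tab-delimited clip manifest.
#' @return A data frame of class `clip_manifest` keyed by `clip_id`.
#' @export
read_clip_manifest <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, c("clip_id", "patient_id", "split"), "clip manifest")
  if (anyDuplicated(df$clip_id)) {
    stop_crowdbline("integrity_error",
                    sprintf("duplicate clip_id: %s",
                            df$clip_id[duplicated(df$clip_id)][1L]))
  }
  bad <- !df$split %in% valid_splits()
  if (any(bad)) {
    stop_crowdbline("format_error",
                    sprintf("unknown split '%s' (row %d)",
                            df$split[bad][1L], which(bad)[1L]))
  }
  ref <- if ("reference_label" %in% names(df)) {
    ifelse(df$reference_label == "", NA_character_, df$reference_label)
  } else {
    rep(NA_character_, nrow(df))
  }
  check_labels(ref, where = "clip manifest reference_label", na_ok = TRUE)
  labeled <- df$split %in% c("TRAINING", "TEST")
  if (any(labeled & is.na(ref))) {
    i <- which(labeled & is.na(ref))[1L]
    stop_crowdbline(
      "format_error",
      sprintf("clip %s has split %s but no reference_label",
              df$clip_id[i], df$split[i])
    )
  }
  stray <- !labeled & !is.na(ref)
  if (any(stray)) {
    warning(sprintf("%d UNLABELED clip(s) carry a reference_label; ignored",
                    sum(stray)))
    ref[stray] <- NA_character_
  }
  df$reference_label <- ref
  front <- c("clip_id", "patient_id", "split", "reference_label")
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("clip_manifest", "data.frame")
  df
}

#' Write a clip manifest
#'
#' @param clips a `clip_manifest` data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_clip_manifest <- function(clips, path) {
  stopifnot(is.data.frame(clips),
            all(c("clip_id", "patient_id", "split") %in% names(clips)))
  write_tsv_raw(as.data.frame(clips), path)
}

#' Read or write an expert label table
#'
#' One row per clip, one column per expert; every expert must label every
#' clip (the reference-standard construction requires complete coverage).
#'
#' @param path path to a tab-delimited expert table (`clip_id` + one column
#'   per expert id).
#' @return For the reader, a data frame of class `expert_labels`.
#' @export
read_expert_labels <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, "clip_id", "expert label table")
  if (ncol(df) < 2L) {
    stop_crowdbline("format_error", "expert label table has no expert columns")
  }
  if (anyDuplicated(df$clip_id)) {
    stop_crowdbline("integrity_error",
                    sprintf("duplicate clip_id: %s",
                            df$clip_id[duplicated(df$clip_id)][1L]))
  }
  for (e in setdiff(names(df), "clip_id")) {
    if (any(df[[e]] == "")) {
      stop_crowdbline("coverage_error",
                      sprintf("expert %s is missing a label for clip %s",
                              e, df$clip_id[df[[e]] == ""][1L]))
    }
    check_labels(df[[e]], where = sprintf("expert %s", e))
  }
  rownames(df) <- NULL
  class(df) <- c("expert_labels", "data.frame")
  df
}

#' @rdname read_expert_labels
#' @param experts an `expert_labels` data frame.
#' @export
write_expert_labels <- function(experts, path) {
  stopifnot(is.data.frame(experts), "clip_id" %in% names(experts))
  write_tsv_raw(as.data.frame(experts), path)
}

expert_ids <- function(experts) setdiff(names(experts), "clip_id")

#' Write a reference standard as tab-delimited text
#'
#' Columns: `clip_id`, `label`, `source`, `excluded_expert` (empty for the
#' full consensus).
#'
#' @param standard a `reference_standard` object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_reference_standard <- function(standard, path) {
  stopifnot(inherits(standard, "reference_standard"))
  df <- data.frame(
    clip_id = names(standard$labels),
    label = unname(standard$labels),
    source = standard$source,
    excluded_expert = if (is.na(standard$excluded_expert)) "" else
      standard$excluded_expert,
    stringsAsFactors = FALSE
  )
  write_tsv_raw(df, path)
}
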