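#' The three-way B-line label space
#'
#' Lung ultrasound clips are classified by the highest B-line severity present
#' anywhere in the clip: no B-lines, one or more discrete B-lines, or
#' confluent B-lines. Labels are stored everywhere as the canonical uppercase
#' tokens returned here; synonyms are rejected by the readers, never coerced.
#'
#' @return Character vector of the three canonical class tokens, in increasing
#'   severity order.
#' @examples
#' bline_classes()
#' bline_severity("CONFLUENT")
#' @export
bline_classes <- function() {
  c("NO_BLINES", "DISCRETE", "CONFLUENT")
}

#' @describeIn bline_classes Severity rank (0, 1, 2) of a vector of labels.
#'   `NO_BLINES < DISCRETE < CONFLUENT`.
#' @param labels character vector of class tokens.
#' @export
bline_severity <- function(labels) {
  r <- match(labels, bline_classes()) - 1L
  if (anyNA(r) && !anyNA(labels)) {
    bad <- labels[is.na(r)][1L]
    stop_crowdbline("parse_error", sprintf("unknown B-line label '%s'", bad))
  }
  r
}

# Validate a vector of label tokens; `where` names the offending source for
# the error message. NA allowed only when na_ok.
check_labels <- function(labels, where = "labels", na_ok = FALSE) {
  ok <- labels %in% bline_classes()
  if (na_ok) ok <- ok | is.na(labels)
  if (!all(ok)) {
    i <- which(!ok)[1L]
    stop_crowdbline(
      "parse_error",
      sprintf("unknown B-line label '%s' in %s (row %d)", labels[i], where, i)
    )
  }
  invisible(labels)
}

# Structured error helper: all package errors carry class
# "crowdbline_<type>" so callers/tests can condition on them.
stop_crowdbline <- function(type, msg, call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("crowdbline_", type), "crowdbline_error",
              "error", "condition"),
    list(message = msg, call = call)
  )
  stop(cond)
}

valid_splits <- function() c("TRAINING", "TEST", "UNLABELED")
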