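# Expert reference standards.
#
# The reference label of a training or test clip is the majority of the six
# experts' opinions, with ties broken uniformly at random. A companion set of
# six "leave-one-out" standards repeats the construction with each expert's
# opinion removed, so that an expert (or the crowd) can be scored against a
# consensus their own vote did not influence.

#' Majority label of a multiset of votes, ties broken uniformly at random
#'
#' @param votes character vector of class tokens (order is irrelevant).
#' @param rng_seed optional integer seed; `NULL` draws from the current RNG.
#' @return A single class token with maximal vote count; among tied maxima
#'   one is chosen uniformly at random.
#' @examples
#' majority_label(c("NO_BLINES", "NO_BLINES", "DISCRETE"))
#' @export
majority_label <- function(votes, rng_seed = NULL) {
  if (length(votes) == 0L) {
    stop_crowdbline("argument_error", "votes must be nonempty")
  }
  counts <- count_votes(votes)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  with_seed(rng_seed, top[sample.int(length(top), 1L)])
}

# Tally a vote vector into the fixed 3-class count vector.
count_votes <- function(votes) {
  idx <- match(votes, bline_classes())
  if (anyNA(idx)) {
    stop_crowdbline("parse_error",
                    sprintf("unknown B-line label '%s'", votes[is.na(idx)][1L]))
  }
  counts <- tabulate(idx, nbins = 3L)
  names(counts) <- bline_classes()
  counts
}

new_reference_standard <- function(labels, source, excluded_expert, rng_seed) {
  structure(
    list(labels = labels, source = source,
         excluded_expert = excluded_expert, rng_seed = rng_seed),
    class = "reference_standard"
  )
}

#' Build the full expert-consensus reference standard
#'
#' One label per clip via majority rule over all experts, ties broken
#' randomly on a stream seeded by `rng_seed`, so the construction is
#' reproducible bit-for-bit.
#'
#' @param experts an `expert_labels` data frame (`clip_id` + one column per
#'   expert); every expert must cover every clip.
#' @param rng_seed integer seed for tie-breaking.
#' @return A `reference_standard` object: `labels` is a named character
#'   vector (clip -> class), `source` is `"FULL_CONSENSUS"`.
#' @seealso [build_leave_one_out()]
#' @export
build_full_consensus <- function(experts, rng_seed = 1L) {
  mat <- expert_matrix(experts)
  s <- rng_stream(derive_seed(rng_seed, "full_consensus"))
  labels <- stream_eval(s, apply(mat, 1L, majority_label))
  new_reference_standard(labels, "FULL_CONSENSUS", NA_character_, rng_seed)
}

#' Build the leave-one-out reference standards
#'
#' One standard per expert, each the majority of the remaining experts'
#' labels. Each standard's tie-breaks come from a seed derived from
#' `(rng_seed, excluded expert)`, so recomputing one standard never shifts
#' another's random draws.
#'
#' @inheritParams build_full_consensus
#' @return An object of class `loo_set`: a named list of
#'   `reference_standard`s, one per excluded expert.
#' @export
build_leave_one_out <- function(experts, rng_seed = 1L) {
  mat <- expert_matrix(experts)
  if (ncol(mat) < 3L) {
    stop_crowdbline("argument_error",
                    "leave-one-out standards need at least 3 experts")
  }
  standards <- lapply(colnames(mat), function(e) {
    sub <- mat[, setdiff(colnames(mat), e), drop = FALSE]
    s <- rng_stream(derive_seed(rng_seed, c("leave_one_out", e)))
    labels <- stream_eval(s, apply(sub, 1L, majority_label))
    new_reference_standard(labels, "LEAVE_ONE_OUT", e, rng_seed)
  })
  names(standards) <- colnames(mat)
  structure(standards, class = "loo_set")
}

# expert_labels data frame -> clips x experts character matrix with
# coverage validation.
expert_matrix <- function(experts) {
  stopifnot(is.data.frame(experts), "clip_id" %in% names(experts))
  ids <- expert_ids(experts)
  if (length(ids) < 1L) {
    stop_crowdbline("argument_error", "no expert columns")
  }
  mat <- as.matrix(as.data.frame(experts)[, ids, drop = FALSE])
  rownames(mat) <- experts$clip_id
  for (e in ids) {
    col <- mat[, e]
    if (any(is.na(col) | col == "")) {
      stop_crowdbline(
        "coverage_error",
        sprintf("expert %s is missing a label for clip %s",
                e, rownames(mat)[which(is.na(col) | col == "")[1L]])
      )
    }
  }
  mat
}

# Resolve a reference argument (reference_standard or named character
# vector) to a named label vector.
reference_labels <- function(reference) {
  if (inherits(reference, "reference_standard")) return(reference$labels)
  if (is.character(reference) && !is.null(names(reference))) return(reference)
  stop_crowdbline("argument_error",
                  "reference must be a reference_standard or a named character vector")
}

#' @export
print.reference_standard <- function(x, ...) {
  cat(sprintf("<reference_standard> %s%s, %d clips\n", x$source,
              if (!is.na(x$excluded_expert))
                paste0(" (excluding ", x$excluded_expert, ")") else "",
              length(x$labels)))
  print(round(100 * prop.table(count_votes(x$labels)), 1))
  invisible(x)
}

#' @export
print.loo_set <- function(x, ...) {
  cat(sprintf("<loo_set> %d leave-one-out reference standards: %s\n",
              length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}
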