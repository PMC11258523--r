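# Contest engine: event-ordered replay of a labeling contest.
#
# Each opinion is processed in global submission order. The labeler's Qscore
# (trailing-window correctness on feedback clips) is stamped BEFORE the
# opinion can update their history, so an opinion never contributes to its
# own eligibility. Eligible opinions on unlabeled clips enter a per-clip
# tally that keeps only each user's most recent vote; the tally is checked
# against the stopping rules (vote lead, opinion cap) after every update.
# Once a clip reaches consensus it is promoted to a feedback clip and its
# label is frozen.

#' Contest engine configuration
#'
#' Defaults follow the live deployment of the labeling platform: Qscore is
#' the trailing mean correctness over the last 50 feedback opinions, forced
#' to 0 until 25 feedback opinions have accrued; opinions submitted with a
#' Qscore below 80% are discarded; crowd consensus on an unlabeled clip is
#' reached at a 3-vote lead or once 15 (deduplicated, eligible) opinions have
#' accumulated.
#'
#' @param qscore_window trailing window length for the Qscore (opinions).
#' @param qscore_min_history feedback opinions required before the Qscore can
#'   leave 0.
#' @param eligibility_threshold minimum Qscore (inclusive) for an opinion to
#'   count toward crowd consensus.
#' @param consensus_lead vote lead between top and runner-up class that
#'   triggers consensus.
#' @param consensus_cap tally size at which consensus is forced (majority,
#'   ties broken randomly).
#' @param rng_seed integer seed for the engine's tie-breaking stream.
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(qscore_window = 50L, qscore_min_history = 25L,
                          eligibility_threshold = 0.80,
                          consensus_lead = 3L, consensus_cap = 15L,
                          rng_seed = 1L) {
  cfg <- list(
    qscore_window = as.integer(qscore_window),
    qscore_min_history = as.integer(qscore_min_history),
    eligibility_threshold = eligibility_threshold,
    consensus_lead = as.integer(consensus_lead),
    consensus_cap = as.integer(consensus_cap),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(cfg$qscore_window > 0L, cfg$qscore_min_history > 0L,
            cfg$eligibility_threshold > 0, cfg$eligibility_threshold <= 1,
            cfg$consensus_lead > 0L,
            cfg$consensus_lead <= cfg$consensus_cap)
  class(cfg) <- "engine_config"
  cfg
}

#' Current Qscore of a feedback-correctness history
#'
#' @param history logical (or 0/1) vector of per-opinion correctness on
#'   feedback clips, oldest first.
#' @param config an [engine_config()].
#' @return 0 while the history is shorter than `qscore_min_history`,
#'   otherwise the mean of the last `min(qscore_window, length)` entries.
#' @examples
#' current_qscore(rep(TRUE, 24)) # still 0: history too short
#' current_qscore(c(rep(TRUE, 40), rep(FALSE, 10)))
#' @export
current_qscore <- function(history, config = engine_config()) {
  n <- length(history)
  if (n < config$qscore_min_history) return(0)
  w <- min(config$qscore_window, n)
  mean(as.numeric(history[(n - w + 1L):n]))
}

#' Check the crowd-consensus stopping rules on a vote tally
#'
#' @param votes named character vector: one (most recent, eligible) label per
#'   user currently voting on the clip.
#' @param config an [engine_config()].
#' @param rng_seed optional seed for the cap-rule tie-break; `NULL` uses the
#'   current RNG.
#' @return `NULL` while neither rule fires; otherwise a list with `label`,
#'   `vote_counts`, `n_opinions_used`, `stop_reason` (`"LEAD"` or `"CAP"`)
#'   and `tie_broken`.
#' @export
check_consensus <- function(votes, config = engine_config(), rng_seed = NULL) {
  if (length(votes) == 0L) return(NULL)
  counts <- count_votes(votes)
  ord <- sort(counts, decreasing = TRUE)
  if (ord[[1L]] - ord[[2L]] >= config$consensus_lead) {
    return(list(label = names(ord)[1L], vote_counts = counts,
                n_opinions_used = sum(counts), stop_reason = "LEAD",
                tie_broken = FALSE))
  }
  if (length(votes) >= config$consensus_cap) {
    top <- names(counts)[counts == max(counts)]
    tie <- length(top) > 1L
    label <- if (tie) with_seed(rng_seed, top[sample.int(length(top), 1L)])
             else top
    return(list(label = label, vote_counts = counts,
                n_opinions_used = sum(counts), stop_reason = "CAP",
                tie_broken = tie))
  }
  NULL
}

# --- internal mutable engine state -----------------------------------------

new_engine_state <- function(clips, config) {
  stopifnot(is.data.frame(clips),
            all(c("clip_id", "split") %in% names(clips)))
  es <- new.env(parent = emptyenv())
  es$config <- config
  es$clips <- clips
  es$split <- stats::setNames(clips$split, clips$clip_id)
  es$users <- new.env(parent = emptyenv())
  es$user_ids <- character(0)
  es$fb <- new.env(parent = emptyenv())        # clip -> current feedback label
  es$pending <- new.env(parent = emptyenv())   # clip -> named label vector
  es$consensus <- new.env(parent = emptyenv()) # clip -> consensus record
  es$rng <- rng_stream(derive_seed(config$rng_seed, "engine"))
  es$last_event <- -Inf
  tr <- which(clips$split == "TRAINING")
  for (i in tr) es$fb[[clips$clip_id[i]]] <- clips$reference_label[i]
  es
}

engine_user <- function(es, uid) {
  u <- es$users[[uid]]
  if (is.null(u)) {
    u <- new.env(parent = emptyenv())
    u$hist <- logical(64L)
    u$n <- 0L
    es$users[[uid]] <- u
    es$user_ids <- c(es$user_ids, uid)
  }
  u
}

user_qscore <- function(u, config) {
  if (u$n < config$qscore_min_history) return(0)
  w <- min(config$qscore_window, u$n)
  mean(u$hist[(u$n - w + 1L):u$n])
}

# Process one opinion; returns list(qscore, eligible, promotion-or-NULL).
engine_step <- function(es, user_id, clip_id, label, event_index) {
  cfg <- es$config
  if (event_index <= es$last_event) {
    stop_crowdbline("ordering_error",
                    sprintf("event_index %d out of order", event_index))
  }
  es$last_event <- event_index
  if (is.na(es$split[clip_id])) {
    stop_crowdbline("integrity_error",
                    sprintf("opinion on unknown clip %s", clip_id))
  }
  u <- engine_user(es, user_id)
  q <- user_qscore(u, cfg)
  eligible <- q >= cfg$eligibility_threshold
  promotion <- NULL
  fb <- es$fb[[clip_id]]
  if (!is.null(fb)) {
    # feedback clip: record correctness (after stamping q above)
    if (u$n == length(u$hist)) u$hist <- c(u$hist, logical(length(u$hist)))
    u$n <- u$n + 1L
    u$hist[u$n] <- (label == fb)
  } else if (eligible && identical(es$split[[clip_id]], "UNLABELED") &&
             is.null(es$consensus[[clip_id]])) {
    v <- es$pending[[clip_id]]
    if (is.null(v)) v <- character(0)
    v[user_id] <- label # most recent vote per user wins
    es$pending[[clip_id]] <- v
    res <- stream_eval(es$rng, check_consensus(v, cfg))
    if (!is.null(res)) {
      res$clip_id <- clip_id
      es$consensus[[clip_id]] <- res
      es$fb[[clip_id]] <- res$label # promoted to feedback clip; frozen
      promotion <- res
    }
  }
  list(qscore = q, eligible = eligible, promotion = promotion)
}

consensus_table <- function(es) {
  ids <- sort(ls(es$consensus))
  rows <- lapply(ids, function(cid) {
    r <- es$consensus[[cid]]
    data.frame(clip_id = cid, label = r$label,
               n_opinions_used = r$n_opinions_used,
               stop_reason = r$stop_reason, tie_broken = r$tie_broken,
               votes_NO_BLINES = r$vote_counts[["NO_BLINES"]],
               votes_DISCRETE = r$vote_counts[["DISCRETE"]],
               votes_CONFLUENT = r$vote_counts[["CONFLUENT"]],
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(clip_id = character(0), label = character(0),
                      n_opinions_used = integer(0), stop_reason = character(0),
                      tie_broken = logical(0), votes_NO_BLINES = integer(0),
                      votes_DISCRETE = integer(0), votes_CONFLUENT = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

user_table <- function(es) {
  ids <- es$user_ids
  n_fb <- vapply(ids, function(uid) es$users[[uid]]$n, integer(1))
  q <- vapply(ids, function(uid) user_qscore(es$users[[uid]], es$config),
              numeric(1))
  data.frame(user_id = ids, n_feedback_opinions = n_fb, final_qscore = q,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Replay a labeling contest from an opinion log
#'
#' Processes every opinion in event order through the engine: Qscore
#' stamping, eligibility filtering, most-recent-per-user deduplication,
#' consensus stopping rules, and promotion of unlabeled clips to feedback
#' clips. The whole replay is deterministic given `config$rng_seed`.
#'
#' @param opinions an `opinion_log` data frame (strictly sorted by
#'   `event_index`).
#' @param clips a `clip_manifest` data frame covering every clip in the log.
#' @param config an [engine_config()].
#' @return An object of class `contest_state` with components
#'   `annotated_log` (the log with `qscore_at_submission` and `eligible`
#'   stamped), `consensus` (one row per promoted clip), `users` (final
#'   per-user history length and Qscore), `config`, and the internal engine
#'   state (used by [finalize_exhausted()]).
#' @seealso [finalize_exhausted()], [opinion_pools()]
#' @export
replay_contest <- function(opinions, clips, config = engine_config()) {
  stopifnot(is.data.frame(opinions))
  if (is.unsorted(opinions$event_index, strictly = TRUE)) {
    stop_crowdbline("ordering_error",
                    "opinions must be strictly sorted by event_index")
  }
  es <- new_engine_state(clips, config)
  n <- nrow(opinions)
  qs <- numeric(n)
  el <- logical(n)
  uid <- opinions$user_id
  cid <- opinions$clip_id
  lab <- opinions$label
  ev <- opinions$event_index
  for (i in seq_len(n)) {
    r <- engine_step(es, uid[i], cid[i], lab[i], ev[i])
    qs[i] <- r$qscore
    el[i] <- r$eligible
  }
  log <- as.data.frame(opinions)
  log$qscore_at_submission <- qs
  log$eligible <- el
  class(log) <- c("opinion_log", "data.frame")
  structure(
    list(annotated_log = log, consensus = consensus_table(es),
         users = user_table(es), config = config, engine = es),
    class = "contest_state"
  )
}

#' Assign majority labels to clips whose tally never reached consensus
#'
#' A log can end before the stopping rules fire for every unlabeled clip
#' (the live contest ran until they did; a truncated or simulated log may
#' not). Clips with a nonempty tally receive the majority of their final
#' tally with `stop_reason = "EXHAUSTED"`; clips with no eligible votes stay
#' unlabeled.
#'
#' @param state a `contest_state` from [replay_contest()].
#' @param rng_seed optional seed for tie-breaking (default: derived from the
#'   engine config seed).
#' @return The updated `contest_state`.
#' @export
finalize_exhausted <- function(state, rng_seed = NULL) {
  stopifnot(inherits(state, "contest_state"))
  es <- state$engine
  if (is.null(rng_seed)) rng_seed <- derive_seed(es$config$rng_seed, "exhausted")
  s <- rng_stream(rng_seed)
  for (cid in sort(ls(es$pending))) {
    if (!is.null(es$consensus[[cid]])) next
    v <- es$pending[[cid]]
    if (length(v) == 0L) next
    counts <- count_votes(v)
    top <- names(counts)[counts == max(counts)]
    tie <- length(top) > 1L
    label <- if (tie) stream_eval(s, top[sample.int(length(top), 1L)]) else top
    es$consensus[[cid]] <- list(clip_id = cid, label = label,
                                vote_counts = counts,
                                n_opinions_used = sum(counts),
                                stop_reason = "EXHAUSTED", tie_broken = tie)
    es$fb[[cid]] <- label
  }
  state$consensus <- consensus_table(es)
  state
}

#' @export
print.contest_state <- function(x, ...) {
  cat(sprintf("<contest_state> %d opinions from %d users on %d clips\n",
              nrow(x$annotated_log), nrow(x$users), nrow(x$engine$clips)))
  cat(sprintf("  eligible opinions: %d (%.1f%%)\n",
              sum(x$annotated_log$eligible),
              100 * mean(x$annotated_log$eligible)))
  cat(sprintf("  clips with crowd consensus: %d\n", nrow(x$consensus)))
  invisible(x)
}

#' @export
summary.contest_state <- function(object, ...) {
  log <- object$annotated_log
  out <- list(
    n_opinions = nrow(log),
    n_users = nrow(object$users),
    n_eligible = sum(log$eligible),
    n_eligible_users = length(unique(log$user_id[log$eligible])),
    n_consensus = nrow(object$consensus),
    stop_reasons = table(object$consensus$stop_reason)
  )
  class(out) <- "summary.contest_state"
  out
}

#' @export
print.summary.contest_state <- function(x, ...) {
  cat(sprintf("Opinions: %d from %d users; %d eligible from %d users\n",
              x$n_opinions, x$n_users, x$n_eligible, x$n_eligible_users))
  cat(sprintf("Crowd-consensus clips: %d\n", x$n_consensus))
  if (length(x$stop_reasons)) print(x$stop_reasons)
  invisible(x)
}

# --- offline aggregation over an annotated log ------------------------------

#' Per-clip opinion pools from an annotated log
#'
#' Collects the labels submitted on each clip, optionally restricted to
#' eligible opinions and deduplicated to each user's most recent opinion —
#' the same filtering the live consensus rules apply. Used for retrospective
#' crowd labels on test clips, vote-proportion ROC curves, and opinion
#' subsampling.
#'
#' @param log an annotated `opinion_log` (e.g. from [replay_contest()]).
#' @param clip_set character vector of clip ids to pool.
#' @param eligible_only keep only opinions stamped eligible.
#' @param dedup keep only each user's most recent opinion per clip.
#' @return A named list, clip id -> character vector of labels. Clips with
#'   no qualifying opinions are present with an empty vector.
#' @export
opinion_pools <- function(log, clip_set, eligible_only = TRUE, dedup = TRUE) {
  d <- as.data.frame(log)
  d <- d[d$clip_id %in% clip_set, , drop = FALSE]
  if (eligible_only) d <- d[d$eligible, , drop = FALSE]
  d <- d[order(d$event_index), , drop = FALSE]
  if (dedup) {
    key <- paste(d$clip_id, d$user_id, sep = "\r")
    d <- d[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  pools <- split(d$label, factor(d$clip_id, levels = sort(unique(clip_set))))
  lapply(pools, as.character)
}

#' Retrospective crowd consensus labels from opinion pools
#'
#' Majority label per clip over its full opinion pool, ties broken randomly.
#' This is how crowd labels are assigned to test clips, which never enter the
#' live stopping rules.
#'
#' @param pools a list from [opinion_pools()].
#' @param rng_seed integer seed for tie-breaking.
#' @return Named character vector clip -> label; clips with empty pools are
#'   dropped with a warning.
#' @export
crowd_labels <- function(pools, rng_seed = 1L) {
  empty <- vapply(pools, length, integer(1)) == 0L
  if (any(empty)) {
    warning(sprintf("%d clip(s) have no qualifying opinions; dropped",
                    sum(empty)))
    pools <- pools[!empty]
  }
  s <- rng_stream(derive_seed(rng_seed, "crowd_labels"))
  stream_eval(s, vapply(pools, majority_label, character(1)))
}

#' Per-clip vote fractions over the three classes
#'
#' @param pools a list from [opinion_pools()].
#' @return Numeric matrix (clips x 3 classes) of vote fractions; rows sum
#'   to 1. Clips with empty pools are dropped.
#' @export
vote_fractions <- function(pools) {
  pools <- pools[vapply(pools, length, integer(1)) > 0L]
  t(vapply(pools, function(v) count_votes(v) / length(v), numeric(3)))
}
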