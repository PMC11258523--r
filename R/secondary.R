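# Secondary analyses: Monte Carlo opinion subsampling, trailing-window
# learning curves, and skilled-user identification.

#' Monte Carlo concordance of k-opinion crowd subsamples
#'
#' Estimates the concordance the crowd labels would have had if only `k`
#' opinions had been collected per clip: in each replicate, `min(k, n)`
#' opinions are drawn without replacement from every clip's eligible,
#' deduplicated opinion pool, the majority (ties broken uniformly at random)
#' is scored against the reference, and the across-clip concordance is
#' recorded. Only the class composition of a subsample matters for the
#' majority, so draws are taken directly from the multivariate
#' hypergeometric distribution of subsample class counts — equivalent to
#' sampling individual opinions, but vectorized over replicates.
#'
#' @param pools named list, clip -> character vector of (eligible,
#'   deduplicated) labels, e.g. from [opinion_pools()]. Clips with empty
#'   pools are excluded with a warning.
#' @param reference a `reference_standard` (or named character vector).
#' @param k number of opinions to draw per clip.
#' @param n_mc Monte Carlo replicates.
#' @param rng_seed integer seed.
#' @return A list with `mean` and `se` (percentages over replicates;
#'   `se = sd(replicates) / sqrt(n_mc)`), `k`, `n_mc` and `n_clips`.
#' @export
subsample_concordance <- function(pools, reference, k, n_mc = 1000L,
                                  rng_seed = 1L) {
  stopifnot(k >= 1L, n_mc >= 1L)
  ref <- reference_labels(reference)
  empty <- vapply(pools, length, integer(1)) == 0L
  if (any(empty)) {
    warning(sprintf("%d clip(s) have no eligible opinions; excluded",
                    sum(empty)))
    pools <- pools[!empty]
  }
  if (!length(pools)) {
    stop_crowdbline("argument_error", "no clips with opinions to subsample")
  }
  s <- rng_stream(derive_seed(rng_seed, c("subsample", k)))
  correct <- stream_eval(s, {
    acc <- matrix(0, nrow = n_mc, ncol = length(pools))
    for (j in seq_along(pools)) {
      acc[, j] <- subsample_correct(pools[[j]], ref[[names(pools)[j]]],
                                    k, n_mc)
    }
    acc
  })
  reps <- rowMeans(correct)
  list(mean = 100 * mean(reps),
       se = 100 * stats::sd(reps) / sqrt(n_mc),
       k = as.integer(k), n_mc = as.integer(n_mc),
       n_clips = length(pools))
}

# Per-replicate correctness indicator for one clip: draw class counts of a
# without-replacement subsample of size min(k, n) from the pool, then check
# whether the reference class wins the majority (uniform tie-break).
subsample_correct <- function(pool, ref_label, k, n_mc) {
  counts <- count_votes(pool)
  n <- sum(counts)
  kk <- min(k, n)
  x1 <- stats::rhyper(n_mc, counts[[1L]], n - counts[[1L]], kk)
  x2 <- stats::rhyper(n_mc, counts[[2L]], counts[[3L]], kk - x1)
  x3 <- kk - x1 - x2
  cnt <- cbind(x1, x2, x3)
  maxc <- pmax(x1, x2, x3)
  nties <- (x1 == maxc) + (x2 == maxc) + (x3 == maxc)
  ref_idx <- match(ref_label, bline_classes())
  is_top <- cnt[, ref_idx] == maxc
  as.numeric(is_top & stats::runif(n_mc) < 1 / nties)
}

# Expected full-pool concordance: per clip, P(majority of the whole pool is
# the reference class) accounting only for tie-break randomness.
full_pool_concordance <- function(pools, reference) {
  ref <- reference_labels(reference)
  pools <- pools[vapply(pools, length, integer(1)) > 0L]
  p <- vapply(names(pools), function(cid) {
    counts <- count_votes(pools[[cid]])
    top <- names(counts)[counts == max(counts)]
    if (ref[[cid]] %in% top) 1 / length(top) else 0
  }, numeric(1))
  100 * mean(p)
}

#' Opinions-needed curve: subsample concordance over a grid of k
#'
#' Runs [subsample_concordance()] for each `k` and reports the smallest `k`
#' whose mean concordance comes within `knee_margin` percentage points of
#' the expected full-pool concordance (the "opinions needed" knee).
#'
#' @inheritParams subsample_concordance
#' @param k_values increasing integer vector of opinion counts.
#' @param knee_margin percentage-point margin defining "near the maximum".
#' @return An object of class `subsample_curve`: a data frame `curve`
#'   (`k`, `mean`, `se`, `n_clips`) plus `full_pool` (expected full-pool
#'   concordance), `knee_k`, `n_mc` and `rng_seed`.
#' @export
build_subsample_curve <- function(pools, reference, k_values = seq(1L, 15L, 2L),
                                  n_mc = 1000L, rng_seed = 1L,
                                  knee_margin = 1) {
  stopifnot(!is.unsorted(k_values, strictly = TRUE))
  rows <- lapply(k_values, function(k) {
    r <- subsample_concordance(pools, reference, k, n_mc, rng_seed)
    data.frame(k = r$k, mean = r$mean, se = r$se, n_clips = r$n_clips)
  })
  curve <- do.call(rbind, rows)
  full <- full_pool_concordance(pools, reference)
  near <- curve$k[curve$mean >= full - knee_margin]
  structure(
    list(curve = curve, full_pool = full,
         knee_k = if (length(near)) min(near) else NA_integer_,
         knee_margin = knee_margin, n_mc = as.integer(n_mc),
         rng_seed = as.integer(rng_seed)),
    class = "subsample_curve"
  )
}

#' @export
print.subsample_curve <- function(x, ...) {
  cat(sprintf(
    "<subsample_curve> full-pool concordance %.1f%%; %d opinions reach within %.1f point(s)\n",
    x$full_pool, x$knee_k, x$knee_margin))
  print(transform(x$curve, mean = round(mean, 2), se = round(se, 3)),
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.subsample_curve <- function(x, ...) {
  plot(x$curve$k, x$curve$mean, type = "b", xlab = "Opinions sampled per clip",
       ylab = "Concordance (%)", ...)
  graphics::abline(h = x$full_pool, lty = 3)
  if (!is.na(x$knee_k)) graphics::abline(v = x$knee_k, lty = 3)
  invisible(x)
}

#' Trailing-window learning curve over test-set opinions
#'
#' For each user, every opinion on a test-set clip is scored against the
#' reference, and a trailing mean over the last `window` such opinions is
#' computed at each submission (all opinions count, including repeat visits
#' to a clip). Curve point `i` averages the trailing concordance at users'
#' i-th test-set opinion over all users who made at least `i` of them;
#' points supported by fewer than `min_users` users are dropped.
#'
#' @param log an `opinion_log` (annotation columns not required).
#' @param reference a `reference_standard` (or named character vector)
#'   covering the test set.
#' @param test_set character vector of test clip ids.
#' @param users optional character vector restricting the cohort (e.g. the
#'   skilled users, or the experts of a pseudo-log); `NULL` means every user
#'   in the log.
#' @param window trailing window length in opinions.
#' @param min_users minimum users supporting a reported point.
#' @return An object of class `learning_curve`: data frame with `i`
#'   (test-set opinion ordinal), `mean` and `se` (percent), `n_users`.
#' @export
learning_curve <- function(log, reference, test_set, users = NULL,
                           window = 25L, min_users = 5L) {
  ref <- reference_labels(reference)
  d <- as.data.frame(log)
  d <- d[d$clip_id %in% test_set, , drop = FALSE]
  if (!is.null(users)) d <- d[d$user_id %in% users, , drop = FALSE]
  if (!nrow(d)) {
    stop_crowdbline("argument_error", "empty cohort: no test-set opinions")
  }
  d <- d[order(d$event_index), , drop = FALSE]
  d$correct <- as.numeric(d$label == ref[d$clip_id])
  traj <- lapply(split(d$correct, d$user_id), trailing_mean, window = window)
  max_i <- max(vapply(traj, length, integer(1)))
  rows <- lapply(seq_len(max_i), function(i) {
    vals <- unlist(lapply(traj, function(tr) if (length(tr) >= i) tr[i]))
    data.frame(i = i, mean = 100 * mean(vals),
               se = if (length(vals) > 1L)
                 100 * stats::sd(vals) / sqrt(length(vals)) else NA_real_,
               n_users = length(vals))
  })
  curve <- do.call(rbind, rows)
  curve <- curve[curve$n_users >= min_users, , drop = FALSE]
  rownames(curve) <- NULL
  structure(list(curve = curve, window = as.integer(window),
                 min_users = as.integer(min_users)),
            class = "learning_curve")
}

# Trailing mean over the last `window` entries at each position.
trailing_mean <- function(x, window) {
  n <- length(x)
  cs <- cumsum(x)
  lo <- pmax(seq_len(n) - window, 0L)
  (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
}

#' @export
print.learning_curve <- function(x, ...) {
  cv <- x$curve
  cat(sprintf(
    "<learning_curve> window %d, %d points (i = %d..%d), final mean %.1f%%\n",
    x$window, nrow(cv), min(cv$i), max(cv$i), cv$mean[nrow(cv)]))
  invisible(x)
}

#' @export
plot.learning_curve <- function(x, ...) {
  plot(x$curve$i, x$curve$mean, type = "l",
       xlab = "Test-set opinions submitted",
       ylab = "Trailing concordance (%)", ...)
  invisible(x)
}

#' Identify skilled crowd users
#'
#' A skilled user submitted at least one opinion on a test clip at a moment
#' when their trailing-average concordance (the stamped Qscore) was at or
#' above the threshold.
#'
#' @param log an annotated `opinion_log` (with `qscore_at_submission`).
#' @param test_set character vector of test clip ids.
#' @param threshold inclusive Qscore threshold.
#' @return Sorted character vector of user ids.
#' @export
identify_skilled_users <- function(log, test_set, threshold = 0.80) {
  d <- as.data.frame(log)
  hit <- d$clip_id %in% test_set &
    !is.na(d$qscore_at_submission) &
    d$qscore_at_submission >= threshold
  sort(unique(d$user_id[hit]))
}

#' Write a curve table as tab-delimited text
#'
#' @param x a `subsample_curve` or `learning_curve`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_curve <- function(x, path) {
  if (inherits(x, "subsample_curve") || inherits(x, "learning_curve")) {
    write_tsv_raw(x$curve, path)
  } else {
    stop_crowdbline("argument_error", "not a curve object")
  }
}
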