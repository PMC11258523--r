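# Concordance and agreement statistics.
#
# Concordance is the percentage of labels matching a reference standard over
# a clip set; per-class concordance stratifies by the REFERENCE label, and
# balanced concordance is the unweighted mean of the three per-class values
# (prevalence-free). Leave-one-out variants score against consensus labels
# the rater's own vote did not influence. All internal comparisons use full
# precision; rounding happens only at reporting time.

new_concordance_report <- function(per_clip, ref_labels, clip_set) {
  per_class <- vapply(bline_classes(), function(cl) {
    idx <- names(per_clip)[ref_labels[names(per_clip)] == cl]
    if (!length(idx)) return(NA_real_)
    100 * mean(per_clip[idx])
  }, numeric(1))
  structure(
    list(overall = 100 * mean(per_clip),
         per_class = per_class,
         balanced = mean(per_class),
         n_clips = length(per_clip),
         per_clip = per_clip),
    class = "concordance_report"
  )
}

#' Concordance of a label map with a reference standard
#'
#' @param labels named character vector, clip -> label.
#' @param reference a `reference_standard` (or named character vector).
#' @param clip_set clip ids to score (default: every clip in `labels`).
#' @return A `concordance_report`: `overall` and `balanced` percentages,
#'   `per_class` percentages stratified by the reference label, `n_clips`,
#'   and the per-clip 0/1 match indicators `per_clip`.
#' @examples
#' ref <- c(a = "NO_BLINES", b = "DISCRETE")
#' concordance(c(a = "NO_BLINES", b = "CONFLUENT"), ref)$overall
#' @export
concordance <- function(labels, reference, clip_set = names(labels)) {
  ref <- reference_labels(reference)
  miss <- setdiff(clip_set, names(labels))
  if (length(miss)) {
    stop_crowdbline("coverage_error",
                    sprintf("no label for clip(s): %s",
                            paste(utils::head(miss, 3), collapse = ", ")))
  }
  miss <- setdiff(clip_set, names(ref))
  if (length(miss)) {
    stop_crowdbline("coverage_error",
                    sprintf("reference lacks clip(s): %s",
                            paste(utils::head(miss, 3), collapse = ", ")))
  }
  per_clip <- as.numeric(labels[clip_set] == ref[clip_set])
  names(per_clip) <- clip_set
  new_concordance_report(per_clip, ref, clip_set)
}

#' Mean and standard error of a set of expert concordances
#'
#' @param values numeric vector of per-expert concordance percentages
#'   (length >= 2).
#' @return An `expert_summary`: `per_expert`, `mean`, `sd` (sample SD,
#'   n - 1 denominator) and `se` (SD / sqrt(n)).
#' @export
summarize_expert_concordances <- function(values) {
  if (length(values) < 2L) {
    stop_crowdbline("argument_error", "need at least 2 expert concordances")
  }
  structure(
    list(per_expert = values, mean = mean(values),
         sd = stats::sd(values),
         se = stats::sd(values) / sqrt(length(values))),
    class = "expert_summary"
  )
}

#' @export
print.expert_summary <- function(x, ...) {
  cat(sprintf("<expert_summary> n=%d mean=%.1f (SD %.1f, SE %.1f)\n",
              length(x$per_expert), x$mean, x$sd, x$se))
  invisible(x)
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> overall %.1f%%, balanced %.1f%% (n=%d)\n",
              x$overall, x$balanced, x$n_clips))
  print(round(x$per_class, 1))
  invisible(x)
}

#' Crowd concordance with the leave-one-out reference standards
#'
#' Each clip's concordance is the fraction of the leave-one-out standards
#' whose label the crowd label matches; the overall concordance is the mean
#' of these per-clip fractions.
#'
#' @param crowd named character vector of crowd labels.
#' @param loo a `loo_set` from [build_leave_one_out()].
#' @param clip_set clip ids to score.
#' @param class_reference optional `reference_standard` used only to
#'   stratify the per-class breakdown (typically the full consensus); `NULL`
#'   leaves `per_class` as `NA`.
#' @return A `concordance_report` whose `per_clip` entries are fractions
#'   in \[0, 1\].
#' @export
loo_crowd_concordance <- function(crowd, loo, clip_set = names(crowd),
                                  class_reference = NULL) {
  stopifnot(inherits(loo, "loo_set"))
  match_mat <- vapply(loo, function(std) {
    as.numeric(crowd[clip_set] == std$labels[clip_set])
  }, numeric(length(clip_set)))
  if (is.null(dim(match_mat))) match_mat <- matrix(match_mat, nrow = 1L)
  per_clip <- rowMeans(match_mat)
  names(per_clip) <- clip_set
  if (anyNA(per_clip)) {
    stop_crowdbline("coverage_error",
                    "crowd labels or standards do not cover clip_set")
  }
  if (is.null(class_reference)) {
    structure(
      list(overall = 100 * mean(per_clip),
           per_class = stats::setNames(rep(NA_real_, 3), bline_classes()),
           balanced = NA_real_, n_clips = length(per_clip),
           per_clip = per_clip),
      class = "concordance_report"
    )
  } else {
    new_concordance_report(per_clip, reference_labels(class_reference),
                           clip_set)
  }
}

#' Expert concordances with their own leave-one-out standards
#'
#' Each expert is scored only against the standard that excludes their own
#' opinion, removing self-agreement inflation.
#'
#' @param experts an `expert_labels` data frame.
#' @param loo a `loo_set`; must contain a standard per expert column.
#' @param clip_set clip ids to score.
#' @return An `expert_summary` (per-expert percentages named by expert).
#' @export
loo_expert_concordance <- function(experts, loo,
                                   clip_set = experts$clip_id) {
  stopifnot(inherits(loo, "loo_set"))
  ids <- expert_ids(experts)
  miss <- setdiff(ids, names(loo))
  if (length(miss)) {
    stop_crowdbline("pairing_error",
                    sprintf("no leave-one-out standard excluding expert %s",
                            miss[1L]))
  }
  mat <- expert_matrix(experts)
  vals <- vapply(ids, function(e) {
    std <- loo[[e]]$labels
    100 * mean(mat[clip_set, e] == std[clip_set])
  }, numeric(1))
  out <- summarize_expert_concordances(vals)
  names(out$per_expert) <- ids
  out
}

#' One-vs-rest ROC of crowd vote proportions against a reference standard
#'
#' For a target class, the score of each clip is the fraction of crowd votes
#' for that class; the empirical ROC sweeps every distinct observed score as
#' a threshold to predict whether the reference label is the target class.
#' The AUC (trapezoid rule) equals the normalized Mann-Whitney U statistic.
#'
#' @param fractions numeric matrix (clips x 3 classes) of vote fractions,
#'   e.g. from [vote_fractions()]; rows must sum to 1.
#' @param reference a `reference_standard` (or named character vector).
#' @param target target class token.
#' @param tol tolerance on the row sums.
#' @return A list of class `roc_result` with `target_class`, `points`
#'   (data frame `fpr`, `tpr`, including (0,0) and (1,1)) and `auc`.
#' @export
vote_proportion_roc <- function(fractions, reference, target, tol = 1e-6) {
  stopifnot(target %in% bline_classes(), is.matrix(fractions))
  if (any(abs(rowSums(fractions) - 1) > tol)) {
    stop_crowdbline("normalization_error",
                    "vote fractions must sum to 1 per clip")
  }
  ref <- reference_labels(reference)
  clip_set <- rownames(fractions)
  truth <- ref[clip_set] == target
  if (anyNA(truth)) {
    stop_crowdbline("coverage_error", "reference does not cover all clips")
  }
  scores <- fractions[, target]
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) {
    stop_crowdbline("argument_error",
                    "ROC needs both positive and negative clips")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- cumsum(truth[ord])
  neg <- cumsum(!truth[ord])
  keep <- c(s[-length(s)] != s[-1L], TRUE) # last index of each distinct score
  pts <- data.frame(fpr = c(0, neg[keep] / n0, 1),
                    tpr = c(0, pos[keep] / n1, 1))
  pts <- unique(pts)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(target_class = target, points = pts, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> target %s, AUC %.3f (%d points)\n",
              x$target_class, x$auc, nrow(x$points)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("%s (AUC %.2f)", x$target_class, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Paired t test on per-clip crowd vs expert concordance codings
#'
#' The crowd entry for a clip is its concordance indicator (0/1 against the
#' full consensus, or the fraction of leave-one-out standards matched); the
#' expert entry is the fraction of experts correct on that clip. The test is
#' the classic paired t on the per-clip differences.
#'
#' @param crowd,expert equal-length numeric vectors of per-clip fractions.
#' @return A list with `t`, `df`, `p` (two-sided), `mean_diff` and
#'   `degenerate`. Identical vectors give `t = 0`, `p = 1`; constant nonzero
#'   differences have an undefined t (sd of differences is 0) and are
#'   reported with `degenerate = TRUE`, `p = NA`, plus a warning.
#' @export
paired_concordance_test <- function(crowd, expert) {
  stopifnot(length(crowd) == length(expert), length(crowd) >= 2L)
  d <- crowd - expert
  n <- length(d)
  sd_d <- stats::sd(d)
  # tolerance absorbs floating-point jitter in constant differences
  if (sd_d < 1e-10 * (1 + abs(mean(d)))) {
    if (abs(mean(d)) < 1e-12) {
      return(list(t = 0, df = n - 1L, p = 1, mean_diff = 0,
                  degenerate = FALSE))
    }
    warning("differences have zero variance; p-value undefined")
    return(list(t = NA_real_, df = n - 1L, p = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  list(t = t_stat, df = n - 1L,
       p = 2 * stats::pt(-abs(t_stat), df = n - 1L),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Modal-class agreement fraction of each clip's opinion pool
#'
#' Internal agreement of a group on a clip: the fraction of the group's
#' opinions that go to the clip's modal class (for the crowd, all opinions
#' including repeats; for the experts, the six expert opinions).
#'
#' @param pools named list, clip -> character vector of labels.
#' @return Named numeric vector of fractions; empty pools are dropped.
#' @export
internal_agreement <- function(pools) {
  pools <- pools[vapply(pools, length, integer(1)) > 0L]
  vapply(pools, function(v) max(count_votes(v)) / length(v), numeric(1))
}

#' Pearson correlation between crowd and expert internal agreement
#'
#' @param crowd_agreement,expert_agreement named numeric vectors over the
#'   same clips (fractions from [internal_agreement()]).
#' @return A list with `r`, `p` (two-sided) and `n`; constant input gives
#'   `r = NA` with a warning.
#' @export
agreement_correlation <- function(crowd_agreement, expert_agreement) {
  clip_set <- intersect(names(crowd_agreement), names(expert_agreement))
  x <- crowd_agreement[clip_set]
  y <- expert_agreement[clip_set]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant agreement vector; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mann-Whitney U test between two groups of agreement fractions
#'
#' Two-sided, with the tie-corrected normal approximation (ties are the rule
#' for agreement fractions). Used to compare expert internal agreement on
#' clips where the crowd matched the reference versus clips where it did not.
#'
#' @param group_a,group_b numeric vectors.
#' @return A list with `U` (number of (a, b) pairs with a > b, counting ties
#'   half) and `p`.
#' @export
agreement_rank_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = FALSE, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}
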