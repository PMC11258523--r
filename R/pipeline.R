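# End-to-end orchestration: simulate a contest to disk, evaluate a contest
# from its interchange files, and recompute the published summary arithmetic.

#' Simulate a contest and write its interchange files
#'
#' Runs the full generator: clips, expert labels, the expert-consensus
#' reference labels for TRAINING/TEST clips, labeler profiles and the
#' contest opinion stream; writes `clip_manifest.tsv`, `expert_labels.tsv`,
#' `opinion_log.tsv` and a `run_manifest.json` holding the configuration,
#' seeds and MD5 digests of every output (two runs with the same manifest
#' are byte-identical).
#'
#' @param config a [simulation_config()].
#' @param engine an [engine_config()]; its `rng_seed` defaults to a child of
#'   the simulation seed.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`clips`, `experts`,
#'   `profiles`, `log`, `reference`) and the written `paths`.
#' @export
run_simulation <- function(config = simulation_config(),
                           engine = NULL, outdir) {
  if (is.null(engine)) {
    engine <- engine_config(rng_seed = derive_seed(config$rng_seed, "engine_cfg"))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  clips <- generate_clips(config)
  experts <- simulate_experts(config, clips)
  ref <- build_full_consensus(experts,
                              rng_seed = derive_seed(config$rng_seed, "reference"))
  lab <- clips$split %in% c("TRAINING", "TEST")
  clips$reference_label[lab] <- unname(ref$labels[clips$clip_id[lab]])
  profiles <- labeler_profiles(config)
  log <- simulate_contest(config, clips, profiles, engine)

  paths <- c(clip_manifest = file.path(outdir, "clip_manifest.tsv"),
             expert_labels = file.path(outdir, "expert_labels.tsv"),
             opinion_log = file.path(outdir, "opinion_log.tsv"),
             run_manifest = file.path(outdir, "run_manifest.json"))
  write_clip_manifest(clips, paths[["clip_manifest"]])
  write_expert_labels(experts, paths[["expert_labels"]])
  write_opinion_log(log, paths[["opinion_log"]])
  write_run_manifest(paths[["run_manifest"]],
                     config = unclass(config), engine = unclass(engine),
                     outputs = paths[names(paths) != "run_manifest"])
  invisible(list(clips = clips, experts = experts, profiles = profiles,
                 log = log, reference = ref, paths = paths))
}

write_run_manifest <- function(path, config, engine, outputs) {
  digests <- as.list(tools::md5sum(unname(unlist(outputs))))
  names(digests) <- basename(names(digests))
  manifest <- list(
    artifact = "crowdbline",
    version = as.character(utils::packageVersion("crowdbline")),
    config = config,
    engine = engine,
    outputs = digests
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Evaluate a contest: references, replay, and every reported statistic
#'
#' Orchestrates the full analysis on interchange files or in-memory objects:
#' builds the full and leave-one-out expert reference standards, replays the
#' contest through the engine, derives retrospective crowd labels for the
#' test set, and computes concordances (overall, per-class, balanced;
#' full-consensus and leave-one-out), the paired tests, vote-proportion ROC
#' curves, internal-agreement correlation and rank test, the opinion
#' subsampling curve, learning curves for the whole crowd / skilled users /
#' experts, and the skilled-user roster.
#'
#' @param log an `opinion_log` or path.
#' @param clips a `clip_manifest` or path.
#' @param experts an `expert_labels` table or path.
#' @param engine an [engine_config()].
#' @param rng_seed seed for the evaluation's own randomness (reference
#'   tie-breaks, crowd-label tie-breaks, Monte Carlo subsampling).
#' @param n_mc Monte Carlo replicates per opinion count in the subsampling
#'   curve.
#' @param k_values opinion counts for the subsampling curve.
#' @param roc_eligible_only use quality-filtered (eligible, deduplicated)
#'   opinions for vote fractions (the default); `FALSE` uses all opinions.
#' @param outdir optional directory; when given, the report (JSON), the
#'   consensus table, the annotated log, curves and a run manifest are
#'   written there.
#' @return An object of class `evaluation_report` (a nested list; see
#'   `print()` for the headline view).
#' @export
run_evaluation <- function(log, clips, experts, engine = engine_config(),
                           rng_seed = 1L, n_mc = 1000L,
                           k_values = seq(1L, 15L, 2L),
                           roc_eligible_only = TRUE, outdir = NULL) {
  if (is.character(log)) log <- read_opinion_log(log)
  if (is.character(clips)) clips <- read_clip_manifest(clips)
  if (is.character(experts)) experts <- read_expert_labels(experts)

  test_set <- clips$clip_id[clips$split == "TEST"]
  ref <- build_full_consensus(experts,
                              rng_seed = derive_seed(rng_seed, "reference"))
  loo <- build_leave_one_out(experts,
                             rng_seed = derive_seed(rng_seed, "reference"))

  state <- replay_contest(log, clips, engine)
  alog <- state$annotated_log

  pools_f <- opinion_pools(alog, test_set, eligible_only = TRUE, dedup = TRUE)
  covered <- names(pools_f)[vapply(pools_f, length, integer(1)) > 0L]
  crowd <- suppressWarnings(
    crowd_labels(pools_f, rng_seed = derive_seed(rng_seed, "crowd"))
  )

  # --- concordance vs the full consensus ---
  crowd_conc <- concordance(crowd, ref, covered)
  emat <- expert_matrix(experts)
  expert_conc <- lapply(expert_ids(experts), function(e) {
    concordance(stats::setNames(emat[, e], rownames(emat)), ref, covered)
  })
  names(expert_conc) <- expert_ids(experts)
  expert_overall <- summarize_expert_concordances(
    vapply(expert_conc, `[[`, numeric(1), "overall"))

  # --- leave-one-out concordance ---
  crowd_loo <- loo_crowd_concordance(crowd, loo, covered,
                                     class_reference = ref)
  expert_loo <- loo_expert_concordance(experts, loo, covered)

  # --- paired tests (per-clip codings) ---
  expert_frac <- rowMeans(emat[covered, , drop = FALSE] ==
                            ref$labels[covered])
  t_full <- paired_concordance_test(crowd_conc$per_clip, expert_frac)
  loo_expert_frac <- rowMeans(vapply(expert_ids(experts), function(e) {
    as.numeric(emat[covered, e] == loo[[e]]$labels[covered])
  }, numeric(length(covered))))
  t_loo <- paired_concordance_test(crowd_loo$per_clip, loo_expert_frac)

  # --- ROC per class ---
  roc_pools <- if (roc_eligible_only) pools_f else
    opinion_pools(alog, test_set, eligible_only = FALSE, dedup = FALSE)
  fr <- vote_fractions(roc_pools)
  # a class absent from the covered test set has no ROC
  roc <- lapply(bline_classes(), function(cl) {
    tryCatch(vote_proportion_roc(fr, ref, cl),
             crowdbline_argument_error = function(e)
               structure(list(target_class = cl, points = NULL,
                              auc = NA_real_), class = "roc_result"))
  })
  names(roc) <- bline_classes()

  # --- internal agreement ---
  pools_all <- opinion_pools(alog, test_set, eligible_only = FALSE,
                             dedup = FALSE)
  crowd_agree <- internal_agreement(pools_all)
  expert_pools <- lapply(stats::setNames(covered, covered),
                         function(cid) emat[cid, ])
  expert_agree <- internal_agreement(expert_pools)
  agree_cor <- agreement_correlation(crowd_agree, expert_agree)
  matched <- names(crowd_conc$per_clip)[crowd_conc$per_clip == 1]
  unmatched <- setdiff(covered, matched)
  agree_rank <- if (length(matched) && length(unmatched)) {
    agreement_rank_test(expert_agree[matched], expert_agree[unmatched])
  } else {
    list(U = NA_real_, p = NA_real_)
  }
  high <- names(crowd_agree)[crowd_agree >= 0.80]
  high <- intersect(high, covered)
  high_agree_conc <- if (length(high)) {
    100 * mean(crowd_conc$per_clip[high])
  } else {
    NA_real_
  }

  # --- secondary analyses ---
  subsample <- suppressWarnings(
    build_subsample_curve(pools_f, ref, k_values = k_values, n_mc = n_mc,
                          rng_seed = derive_seed(rng_seed, "subsample"))
  )
  skilled <- identify_skilled_users(alog, test_set)
  lc_all <- learning_curve(alog, ref, test_set)
  lc_skilled <- if (length(skilled) >= 5L) {
    learning_curve(alog, ref, test_set, users = skilled)
  } else {
    NULL
  }
  expert_log <- expert_pseudo_log(experts, covered)
  lc_expert <- learning_curve(expert_log, ref, covered, min_users = 2L)

  report <- structure(list(
    n_opinions = nrow(alog),
    n_users = length(unique(alog$user_id)),
    n_eligible_opinions = sum(alog$eligible),
    n_eligible_users = length(unique(alog$user_id[alog$eligible])),
    n_test_clips = length(covered),
    consensus = state$consensus,
    reference = ref,
    crowd_labels = crowd,
    crowd_concordance = crowd_conc,
    expert_concordance = expert_conc,
    expert_summary = expert_overall,
    crowd_loo_concordance = crowd_loo,
    expert_loo_summary = expert_loo,
    paired_test_full = t_full,
    paired_test_loo = t_loo,
    roc = roc,
    agreement_correlation = agree_cor,
    agreement_rank_test = agree_rank,
    high_agreement_concordance = high_agree_conc,
    subsample_curve = subsample,
    learning_curves = list(all_crowd = lc_all, skilled_crowd = lc_skilled,
                           experts = lc_expert),
    skilled_users = skilled,
    engine = engine,
    rng_seed = as.integer(rng_seed)
  ), class = "evaluation_report")

  if (!is.null(outdir)) write_evaluation(report, state, outdir)
  report
}

# Experts have no event stream; give them one (clip order randomized per
# expert from a seed) so the learning-curve machinery applies.
expert_pseudo_log <- function(experts, clip_set, rng_seed = 1L) {
  ids <- expert_ids(experts)
  emat <- expert_matrix(experts)
  s <- rng_stream(derive_seed(rng_seed, "expert_log"))
  rows <- stream_eval(s, lapply(seq_along(ids), function(k) {
    ord <- sample(clip_set)
    data.frame(user_id = ids[k], clip_id = ord,
               label = unname(emat[ord, ids[k]]),
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  out$event_index <- seq_len(nrow(out))
  out$qscore_at_submission <- NA_real_
  out$eligible <- FALSE
  class(out) <- c("opinion_log", "data.frame")
  out
}

write_evaluation <- function(report, state, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(report = file.path(outdir, "report.json"),
             annotated_log = file.path(outdir, "annotated_log.tsv"),
             consensus = file.path(outdir, "consensus.tsv"),
             subsample_curve = file.path(outdir, "subsample_curve.tsv"),
             learning_curve_all = file.path(outdir, "learning_curve_all.tsv"))
  jsonlite::write_json(report_json(report), paths[["report"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  write_opinion_log(state$annotated_log, paths[["annotated_log"]])
  write_tsv_raw(state$consensus, paths[["consensus"]])
  write_curve(report$subsample_curve, paths[["subsample_curve"]])
  write_curve(report$learning_curves$all_crowd, paths[["learning_curve_all"]])
  write_run_manifest(file.path(outdir, "run_manifest.json"),
                     config = list(rng_seed = report$rng_seed),
                     engine = unclass(report$engine),
                     outputs = paths)
  invisible(paths)
}

# Flatten the report into JSON-friendly structures.
report_json <- function(r) {
  conc <- function(x) list(overall = x$overall,
                           per_class = as.list(x$per_class),
                           balanced = x$balanced, n_clips = x$n_clips)
  list(
    opinions = list(total = r$n_opinions, users = r$n_users,
                    eligible = r$n_eligible_opinions,
                    eligible_users = r$n_eligible_users),
    crowd_concordance = conc(r$crowd_concordance),
    expert_concordance = list(
      per_expert = as.list(vapply(r$expert_concordance, `[[`, numeric(1),
                                  "overall")),
      mean = r$expert_summary$mean, sd = r$expert_summary$sd,
      se = r$expert_summary$se),
    leave_one_out = list(
      crowd = conc(r$crowd_loo_concordance),
      expert_mean = r$expert_loo_summary$mean,
      expert_sd = r$expert_loo_summary$sd,
      expert_se = r$expert_loo_summary$se,
      expert_per_expert = as.list(r$expert_loo_summary$per_expert)),
    paired_tests = list(full = r$paired_test_full[c("t", "df", "p")],
                        leave_one_out = r$paired_test_loo[c("t", "df", "p")]),
    roc_auc = lapply(r$roc, `[[`, "auc"),
    agreement = list(pearson_r = r$agreement_correlation$r,
                     pearson_p = r$agreement_correlation$p,
                     rank_U = r$agreement_rank_test$U,
                     rank_p = r$agreement_rank_test$p,
                     high_agreement_concordance = r$high_agreement_concordance),
    subsample = list(knee_k = r$subsample_curve$knee_k,
                     full_pool = r$subsample_curve$full_pool,
                     curve = r$subsample_curve$curve),
    skilled_users = list(n = length(r$skilled_users))
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d opinions (%d eligible) from %d users (%d eligible)\n",
              x$n_opinions, x$n_eligible_opinions, x$n_users,
              x$n_eligible_users))
  cat(sprintf("Test clips scored: %d\n", x$n_test_clips))
  cat(sprintf("Crowd concordance: %.1f%% (balanced %.1f%%)\n",
              x$crowd_concordance$overall, x$crowd_concordance$balanced))
  cat(sprintf("Mean expert concordance: %.1f%% (SE %.1f)  [p = %.3g]\n",
              x$expert_summary$mean, x$expert_summary$se,
              x$paired_test_full$p))
  cat(sprintf("Leave-one-out: crowd %.1f%% vs experts %.1f%% (SE %.1f)  [p = %.3g]\n",
              x$crowd_loo_concordance$overall, x$expert_loo_summary$mean,
              x$expert_loo_summary$se, x$paired_test_loo$p))
  cat(sprintf("ROC AUC: %s\n",
              paste(sprintf("%s %.2f", names(x$roc),
                            vapply(x$roc, `[[`, numeric(1), "auc")),
                    collapse = ", ")))
  cat(sprintf("Agreement correlation r = %.2f; opinions needed (knee) k = %s\n",
              x$agreement_correlation$r, x$subsample_curve$knee_k))
  cat(sprintf("Skilled users: %d\n", length(x$skilled_users)))
  invisible(x)
}
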