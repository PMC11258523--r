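# Synthetic crowd simulator.
#
# Generates clip manifests, expert label tables and contest opinion streams
# with the statistical structure the analysis pipeline assumes: a 3-class
# label space with skewed priors, a minority of intrinsically ambiguous
# ("hard") clips that degrade every rater's accuracy (inducing correlated
# crowd/expert disagreement), static experts of heterogeneous accuracy,
# and crowd labelers who learn toward a personal asymptote as they receive
# feedback. Everything is deterministic given the config seed.

#' Simulation configuration
#'
#' Defaults describe a desk-scale contest (600 clips, 100 users, roughly
#' 20,000 opinions) with the class mix, expert accuracy spread, crowd
#' learning asymptote and ambiguity level of a realistic lung-ultrasound
#' B-line labeling contest: class priors 70/18/12, six experts spanning
#' 77-91% accuracy, crowd users starting near 55% and learning toward a
#' mean asymptote of 80%, and ~12% hard clips (roughly the share of clips
#' on which an expert panel fails to reach a two-thirds supermajority).
#'
#' @param n_clips_training,n_clips_test,n_clips_unlabeled clips per split.
#' @param class_priors length-3 probability vector over
#'   (NO_BLINES, DISCRETE, CONFLUENT).
#' @param ambiguity_fraction fraction of clips drawn "hard".
#' @param hard_clip_confusability multiplicative accuracy penalty on hard
#'   clips, applied to every rater (crowd and expert).
#' @param n_experts number of experts.
#' @param expert_accuracies per-expert accuracy on easy clips.
#' @param n_users number of crowd users.
#' @param user_initial_accuracy_mean,user_initial_accuracy_sd distribution
#'   of users' starting accuracy.
#' @param user_asymptote_mean,user_asymptote_sd distribution of users'
#'   asymptotic accuracy.
#' @param learning_rate exponential learning-rate constant per feedback
#'   opinion seen.
#' @param opinions_per_user_mean,opinions_per_user_shape negative-binomial
#'   mean and shape of each user's total opinion count (skewed engagement).
#' @param medical_experience_rate fraction of users flagged as having prior
#'   medical experience (metadata only; does not alter skill).
#' @param adjacent_confusion_bias probability that an error lands on the
#'   severity-adjacent class rather than uniformly on the other two.
#' @param rng_seed master integer seed; all stages derive child streams.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_clips_training = 200L, n_clips_test = 200L,
                              n_clips_unlabeled = 200L,
                              class_priors = c(0.70, 0.18, 0.12),
                              ambiguity_fraction = 0.12,
                              hard_clip_confusability = 0.20,
                              n_experts = 6L,
                              expert_accuracies = c(0.77, 0.81, 0.85,
                                                    0.87, 0.88, 0.91),
                              n_users = 100L,
                              user_initial_accuracy_mean = 0.55,
                              user_initial_accuracy_sd = 0.05,
                              user_asymptote_mean = 0.80,
                              user_asymptote_sd = 0.05,
                              learning_rate = 0.05,
                              opinions_per_user_mean = 200,
                              opinions_per_user_shape = 2,
                              medical_experience_rate = 0.45,
                              adjacent_confusion_bias = 0.8,
                              rng_seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    length(class_priors) == 3L, abs(sum(class_priors) - 1) < 1e-8,
    all(class_priors >= 0),
    ambiguity_fraction >= 0, ambiguity_fraction <= 1,
    hard_clip_confusability >= 0, hard_clip_confusability < 1,
    length(expert_accuracies) == n_experts,
    all(expert_accuracies > 1 / 3), all(expert_accuracies <= 1),
    n_clips_training >= 0, n_clips_test >= 0, n_clips_unlabeled >= 0,
    n_users >= 0, learning_rate >= 0,
    adjacent_confusion_bias >= 0, adjacent_confusion_bias <= 1
  )
  cfg$rng_seed <- as.integer(rng_seed)
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a synthetic clip population
#'
#' True classes are drawn from the configured priors; an
#' `ambiguity_fraction` of clips is flagged hard. Splits are assigned at the
#' patient level (about 10 clips per patient), so no patient ever spans two
#' splits. The latent columns `true_class` and `hard` are simulator-side
#' ground truth: they ride along as extra manifest columns but are never
#' read by the analysis pipeline.
#'
#' @param config a [simulation_config()].
#' @return A `clip_manifest` data frame with extra columns `true_class` and
#'   `hard`; `reference_label` is `NA` (filled later from the simulated
#'   expert consensus by [run_simulation()]).
#' @export
generate_clips <- function(config) {
  s <- rng_stream(derive_seed(config$rng_seed, "clips"))
  splits <- rep(c("TRAINING", "TEST", "UNLABELED"),
                c(config$n_clips_training, config$n_clips_test,
                  config$n_clips_unlabeled))
  n <- length(splits)
  stream_eval(s, {
    true_class <- sample(bline_classes(), n, replace = TRUE,
                         prob = config$class_priors)
    hard <- stats::runif(n) < config$ambiguity_fraction
    # ~10 clips per patient, patients nested within split
    patient <- unlist(lapply(unique(splits), function(sp) {
      m <- sum(splits == sp)
      sprintf("P_%s_%03d", substr(sp, 1, 2), ceiling(seq_len(m) / 10))
    }))
    df <- data.frame(
      clip_id = sprintf("C%04d", seq_len(n)),
      patient_id = patient,
      split = splits,
      reference_label = NA_character_,
      true_class = true_class,
      hard = hard,
      stringsAsFactors = FALSE
    )
    class(df) <- c("clip_manifest", "data.frame")
    df
  })
}

# Accuracy of a labeler at feedback-opinion count t (exponential approach
# to the asymptote), with the hard-clip penalty applied multiplicatively.
labeler_accuracy <- function(profile, t, hard, config) {
  a <- profile$asymptote -
    (profile$asymptote - profile$initial) * exp(-config$learning_rate * t)
  ifelse(hard, a * (1 - config$hard_clip_confusability), a)
}

#' Draw labeler profiles for the synthetic crowd
#'
#' @param config a [simulation_config()].
#' @return A data frame with one row per user: `user_id`, `initial`,
#'   `asymptote` (both clamped to (0.34, 1)), `n_opinions` and
#'   `medical_experience`.
#' @export
labeler_profiles <- function(config) {
  s <- rng_stream(derive_seed(config$rng_seed, "profiles"))
  n <- config$n_users
  stream_eval(s, {
    clamp <- function(x) pmin(pmax(x, 0.34), 1)
    data.frame(
      user_id = sprintf("U%03d", seq_len(n)),
      initial = clamp(stats::rnorm(n, config$user_initial_accuracy_mean,
                                   config$user_initial_accuracy_sd)),
      asymptote = clamp(stats::rnorm(n, config$user_asymptote_mean,
                                     config$user_asymptote_sd)),
      n_opinions = pmax(1L, stats::rnbinom(n, size = config$opinions_per_user_shape,
                                           mu = config$opinions_per_user_mean)),
      medical_experience = stats::runif(n) < config$medical_experience_rate,
      stringsAsFactors = FALSE
    )
  })
}

# Vectorized noisy-rater draw: with probability acc the true class,
# otherwise an error that lands on the severity-adjacent class with
# probability adjacent_confusion_bias (uniform over both neighbours for the
# middle class), else uniformly on the other classes. Draws from the
# current RNG.
sample_labels <- function(true_class, acc, config) {
  n <- length(true_class)
  stopifnot(length(acc) == n)
  cls <- bline_classes()
  idx <- match(true_class, cls)
  out <- true_class
  err <- stats::runif(n) >= acc
  if (any(err)) {
    b <- config$adjacent_confusion_bias
    for (i in which(err)) {
      others <- cls[-idx[i]]
      if (idx[i] == 2L) {
        # both neighbours are adjacent; bias is moot
        out[i] <- others[sample.int(2L, 1L)]
      } else {
        adjacent <- cls[2L] # DISCRETE neighbours both extremes
        far <- setdiff(others, adjacent)
        out[i] <- if (stats::runif(1L) < b) adjacent else
          c(adjacent, far)[sample.int(2L, 1L)]
      }
    }
  }
  out
}

#' Sample one opinion from a labeler profile
#'
#' @param profile one row of [labeler_profiles()] (or any list with
#'   `initial` and `asymptote`).
#' @param clip one row of a generated clip manifest (needs `true_class` and
#'   `hard`).
#' @param t the labeler's feedback-opinion count so far (learning clock).
#' @param config a [simulation_config()].
#' @param rng_seed optional seed; `NULL` draws from the current RNG.
#' @return A class token.
#' @export
sample_opinion <- function(profile, clip, t, config, rng_seed = NULL) {
  acc <- labeler_accuracy(profile, t, isTRUE(clip$hard), config)
  with_seed(rng_seed, sample_labels(clip$true_class, acc, config))
}

#' Simulate the expert label table
#'
#' Each expert labels every TRAINING and TEST clip once through the static
#' noisy-rater model (no learning); hard clips degrade expert accuracy by
#' the same multiplicative penalty as crowd accuracy, which is what couples
#' crowd and expert disagreement on ambiguous clips.
#'
#' @param config a [simulation_config()].
#' @param clips a clip manifest from [generate_clips()].
#' @return An `expert_labels` data frame (`clip_id` + `expert_1..n`).
#' @export
simulate_experts <- function(config, clips) {
  s <- rng_stream(derive_seed(config$rng_seed, "experts"))
  d <- clips[clips$split %in% c("TRAINING", "TEST"), , drop = FALSE]
  stream_eval(s, {
    out <- data.frame(clip_id = d$clip_id, stringsAsFactors = FALSE)
    for (e in seq_len(config$n_experts)) {
      acc <- ifelse(d$hard,
                    config$expert_accuracies[e] *
                      (1 - config$hard_clip_confusability),
                    config$expert_accuracies[e])
      out[[sprintf("expert_%d", e)]] <- sample_labels(d$true_class, acc, config)
    }
    class(out) <- c("expert_labels", "data.frame")
    out
  })
}

#' Simulate a full gamified labeling contest
#'
#' Produces an event-ordered opinion stream. Users are interleaved in a
#' random global order; each user alternates between feedback clips
#' (stratified to be equally likely to carry each of the three classes among
#' currently available feedback labels, falling back to the available
#' classes when one is absent) and nonfeedback clips (uniform over test
#' clips and still-unlabeled clips). A user's learning clock advances by one
#' per feedback clip seen. The contest engine runs inline so that clips
#' promoted to feedback status immediately join the feedback pool; replaying
#' the returned log with the same `engine` config reproduces the identical
#' contest state.
#'
#' @param config a [simulation_config()].
#' @param clips manifest from [generate_clips()] with TRAINING
#'   `reference_label`s filled in (see [run_simulation()]).
#' @param profiles data frame from [labeler_profiles()].
#' @param engine an [engine_config()].
#' @return An `opinion_log` data frame (`user_id`, `clip_id`, `label`,
#'   `event_index`), unannotated.
#' @export
simulate_contest <- function(config, clips, profiles,
                             engine = engine_config()) {
  if (nrow(profiles) == 0L) {
    out <- data.frame(user_id = character(0), clip_id = character(0),
                      label = character(0), event_index = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("opinion_log", "data.frame")
    return(out)
  }
  stopifnot(all(c("true_class", "hard") %in% names(clips)))
  tr <- clips$split == "TRAINING"
  if (any(tr & is.na(clips$reference_label))) {
    stop_crowdbline("argument_error",
                    "TRAINING clips need reference_label before simulation")
  }
  s <- rng_stream(derive_seed(config$rng_seed, "contest"))
  es <- new_engine_state(clips, engine)

  # mutable pools
  fb_class <- stats::setNames(clips$reference_label[tr], clips$clip_id[tr])
  fb_pool <- split(names(fb_class), factor(fb_class, levels = bline_classes()))
  nonfb <- clips$clip_id[clips$split != "TRAINING"]
  hard_of <- stats::setNames(clips$hard, clips$clip_id)
  true_of <- stats::setNames(clips$true_class, clips$clip_id)

  schedule <- stream_eval(s, sample(rep(profiles$user_id, profiles$n_opinions)))
  n <- length(schedule)
  uidx <- match(schedule, profiles$user_id)
  init_v <- profiles$initial
  asym_v <- profiles$asymptote
  lambda <- config$learning_rate
  penalty <- 1 - config$hard_clip_confusability
  t_clock <- stats::setNames(rep(0L, nrow(profiles)), profiles$user_id)
  want_fb <- stats::setNames(rep(TRUE, nrow(profiles)), profiles$user_id)
  clip_out <- character(n)
  label_out <- character(n)
  warned_fallback <- FALSE

  for (i in seq_len(n)) {
    uid <- schedule[i]
    j <- uidx[i]
    pick_fb <- want_fb[[uid]]
    cid <- stream_eval(s, {
      if (pick_fb) {
        avail <- which(lengths(fb_pool) > 0L)
        if (length(avail) == 0L) {
          pick_fb <- FALSE
          nonfb[sample.int(length(nonfb), 1L)]
        } else {
          if (length(avail) < 3L && !warned_fallback) {
            warned_fallback <- TRUE
            warning("feedback pool missing a class; stratifying over available classes")
          }
          pool <- fb_pool[[avail[sample.int(length(avail), 1L)]]]
          pool[sample.int(length(pool), 1L)]
        }
      } else {
        nonfb[sample.int(length(nonfb), 1L)]
      }
    })
    acc <- asym_v[j] - (asym_v[j] - init_v[j]) * exp(-lambda * t_clock[[uid]])
    if (hard_of[[cid]]) acc <- acc * penalty
    lab <- stream_eval(s, sample_labels(true_of[[cid]], acc, config))
    clip_out[i] <- cid
    label_out[i] <- lab
    r <- engine_step(es, uid, cid, lab, i)
    if (pick_fb) t_clock[[uid]] <- t_clock[[uid]] + 1L
    want_fb[[uid]] <- !pick_fb
    if (!is.null(r$promotion)) {
      pc <- r$promotion$label
      fb_pool[[pc]] <- c(fb_pool[[pc]], cid)
      nonfb <- nonfb[nonfb != cid]
    }
  }
  out <- data.frame(user_id = schedule, clip_id = clip_out, label = label_out,
                    event_index = seq_len(n), stringsAsFactors = FALSE)
  class(out) <- c("opinion_log", "data.frame")
  out
}
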