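# Shared fixture builders. Everything is generated in code; the desk-scale
# contest used by the parameter-recovery checks is simulated once per test
# run and cached.

fixture_cache <- new.env(parent = emptyenv())

# Exact P(majority of a size-k without-replacement subsample equals ref),
# by enumeration of all subsets (pools small enough for combn).
enum_subsample_prob <- function(pool, ref, k) {
  n <- length(pool)
  kk <- min(k, n)
  sets <- utils::combn(n, kk)
  mean(apply(sets, 2, function(ix) {
    counts <- table(factor(pool[ix], levels = bline_classes()))
    top <- names(counts)[counts == max(counts)]
    if (ref %in% top) 1 / length(top) else 0
  }))
}

# A random but valid opinion log (for round-trip properties).
random_opinion_log <- function(n, seed = 1) {
  set.seed(seed)
  out <- data.frame(
    user_id = sprintf("U%02d", sample.int(20, n, replace = TRUE)),
    clip_id = sprintf("C%03d", sample.int(50, n, replace = TRUE)),
    label = sample(bline_classes(), n, replace = TRUE),
    event_index = seq_len(n),
    qscore_at_submission = round(runif(n), 3),
    eligible = runif(n) > 0.5,
    stringsAsFactors = FALSE
  )
  class(out) <- c("opinion_log", "data.frame")
  out
}

# Minimal manifest: n_tr TRAINING clips (all labeled `tr_label`), n_un
# UNLABELED, n_te TEST.
tiny_manifest <- function(n_tr = 2, n_un = 1, n_te = 0,
                          tr_label = "NO_BLINES") {
  n <- n_tr + n_un + n_te
  data.frame(
    clip_id = sprintf("C%02d", seq_len(n)),
    patient_id = sprintf("P%02d", seq_len(n)),
    split = rep(c("TRAINING", "UNLABELED", "TEST"), c(n_tr, n_un, n_te)),
    reference_label = c(rep(tr_label, n_tr), rep(NA_character_, n_un),
                        rep(tr_label, n_te)),
    stringsAsFactors = FALSE
  )
}

# A log that warms `users` to a perfect Qscore (25 correct TRAINING
# opinions each on clip tr_clip labeled tr_label), then appends `votes`
# (list of c(user, clip, label)).
warmed_log <- function(users, votes, tr_clip = "C01",
                       tr_label = "NO_BLINES", n_warm = 25) {
  warm <- expand.grid(user_id = users, rep = seq_len(n_warm),
                      stringsAsFactors = FALSE)
  rows <- data.frame(user_id = warm$user_id, clip_id = tr_clip,
                     label = tr_label, stringsAsFactors = FALSE)
  if (length(votes)) {
    extra <- do.call(rbind, lapply(votes, function(v) {
      data.frame(user_id = v[1], clip_id = v[2], label = v[3],
                 stringsAsFactors = FALSE)
    }))
    rows <- rbind(rows, extra)
  }
  rows$event_index <- seq_len(nrow(rows))
  class(rows) <- c("opinion_log", "data.frame")
  rows
}

# Desk-scale simulated contest (600 clips, 100 users, ~20k opinions) with
# replayed state and reference standards; cached across tests.
desk_fixture <- function() {
  if (!is.null(fixture_cache$desk)) return(fixture_cache$desk)
  seed <- 1L
  cfg <- simulation_config(rng_seed = seed)
  eng <- engine_config(rng_seed = derive_seed(seed, "engine_cfg"))
  clips <- generate_clips(cfg)
  experts <- simulate_experts(cfg, clips)
  ref <- build_full_consensus(experts, rng_seed = derive_seed(seed, "reference"))
  lab <- clips$split %in% c("TRAINING", "TEST")
  clips$reference_label[lab] <- unname(ref$labels[clips$clip_id[lab]])
  profiles <- labeler_profiles(cfg)
  log <- simulate_contest(cfg, clips, profiles, eng)
  state <- replay_contest(log, clips, eng)
  fixture_cache$desk <- list(
    config = cfg, engine = eng, clips = clips, experts = experts,
    reference = ref, profiles = profiles, log = log, state = state,
    test_set = clips$clip_id[clips$split == "TEST"],
    truth = stats::setNames(clips$true_class, clips$clip_id)
  )
  fixture_cache$desk
}

# A small but complete world where everyone is perfectly accurate.
perfect_fixture <- function() {
  if (!is.null(fixture_cache$perfect)) return(fixture_cache$perfect)
  cfg <- simulation_config(
    n_clips_training = 30, n_clips_test = 60, n_clips_unlabeled = 10,
    ambiguity_fraction = 0, n_users = 20,
    user_initial_accuracy_mean = 1, user_initial_accuracy_sd = 0,
    user_asymptote_mean = 1, user_asymptote_sd = 0,
    expert_accuracies = rep(1, 6),
    opinions_per_user_mean = 150, opinions_per_user_shape = 10,
    rng_seed = 5L
  )
  fixture_cache$perfect <- list(config = cfg,
                                sim = run_simulation(cfg, outdir = tempfile()))
  fixture_cache$perfect
}
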