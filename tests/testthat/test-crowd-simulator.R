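# Synthetic crowd generator.

test_that("clip generation honors priors, ambiguity and patient-level splits", {
  cfg <- simulation_config(n_clips_training = 10, n_clips_test = 10,
                           n_clips_unlabeled = 5,
                           class_priors = c(1, 0, 0),
                           ambiguity_fraction = 0, rng_seed = 3)
  clips <- generate_clips(cfg)
  expect_true(all(clips$true_class == "NO_BLINES"))
  expect_false(any(clips$hard))
  # no patient spans two splits
  expect_true(all(rowSums(table(clips$patient_id, clips$split) > 0) == 1))

  cfg2 <- simulation_config(n_clips_training = 0, n_clips_test = 10000,
                            n_clips_unlabeled = 0, rng_seed = 4)
  clips2 <- generate_clips(cfg2)
  freq <- prop.table(table(factor(clips2$true_class,
                                  levels = bline_classes())))
  expect_lt(max(abs(freq - c(0.70, 0.18, 0.12))), 0.02)
  expect_lt(abs(mean(clips2$hard) - 0.12), 0.02)
})

test_that("the noisy-rater model hits its accuracy and adjacency targets", {
  cfg <- simulation_config(rng_seed = 5)
  clip_easy <- list(true_class = "NO_BLINES", hard = FALSE)
  perfect <- list(initial = 1, asymptote = 1)
  expect_identical(sample_opinion(perfect, clip_easy, 0, cfg, rng_seed = 1),
                   "NO_BLINES")

  p80 <- list(initial = 0.8, asymptote = 0.8)
  set.seed(20)
  draws <- replicate(10000, sample_opinion(p80, clip_easy, 0, cfg))
  expect_lt(abs(mean(draws == "NO_BLINES") - 0.8), 0.015)

  # full adjacency bias: every error from NO_BLINES is DISCRETE
  cfg_adj <- simulation_config(adjacent_confusion_bias = 1, rng_seed = 5)
  p0 <- list(initial = 0.34, asymptote = 0.34)
  set.seed(21)
  draws <- replicate(2000, sample_opinion(p0, clip_easy, 0, cfg_adj))
  expect_setequal(unique(draws), c("NO_BLINES", "DISCRETE"))

  # learning: a(0) = a0, a(t) -> asymptote monotonically
  prof <- list(initial = 0.5, asymptote = 0.9)
  a <- vapply(c(0, 5, 20, 100),
              function(t) crowdbline:::labeler_accuracy(prof, t, FALSE, cfg),
              numeric(1))
  expect_equal(a[1], 0.5)
  expect_true(all(diff(a) > 0))
  expect_lt(abs(a[4] - 0.9), 0.01)
  # hard clips apply the multiplicative penalty
  expect_equal(crowdbline:::labeler_accuracy(prof, 0, TRUE, cfg),
               0.5 * (1 - cfg$hard_clip_confusability))
})

test_that("simulated experts recover their configured accuracy spread", {
  cfg <- simulation_config(n_clips_training = 0, n_clips_test = 3000,
                           n_clips_unlabeled = 0, ambiguity_fraction = 0,
                           rng_seed = 6)
  clips <- generate_clips(cfg)
  experts <- simulate_experts(cfg, clips)
  truth <- setNames(clips$true_class, clips$clip_id)
  acc <- vapply(paste0("expert_", 1:6), function(e)
    mean(experts[[e]] == truth[experts$clip_id]), numeric(1))
  expect_lt(max(abs(acc - cfg$expert_accuracies)), 0.03)

  # perfect experts reproduce the latent truth exactly
  cfg1 <- simulation_config(n_clips_training = 0, n_clips_test = 50,
                            n_clips_unlabeled = 0, ambiguity_fraction = 0,
                            expert_accuracies = rep(1, 6), rng_seed = 6)
  clips1 <- generate_clips(cfg1)
  e1 <- simulate_experts(cfg1, clips1)
  for (e in paste0("expert_", 1:6)) {
    expect_identical(e1[[e]], clips1$true_class)
  }
})

test_that("ambiguous clips depress expert unanimity", {
  base <- list(n_clips_training = 0, n_clips_test = 1500,
               n_clips_unlabeled = 0, rng_seed = 7)
  unanimity <- function(amb) {
    cfg <- do.call(simulation_config,
                   c(base, list(ambiguity_fraction = amb)))
    clips <- generate_clips(cfg)
    experts <- simulate_experts(cfg, clips)
    mat <- as.matrix(experts[, -1])
    mean(apply(mat, 1, function(v) length(unique(v)) == 1))
  }
  expect_gt(unanimity(0), unanimity(0.5))
})

test_that("contest streams stratify feedback classes and respect scale", {
  cfg <- simulation_config(n_clips_training = 60, n_clips_test = 20,
                           n_clips_unlabeled = 0, n_users = 20,
                           opinions_per_user_mean = 150,
                           opinions_per_user_shape = 10, rng_seed = 8)
  clips <- generate_clips(cfg)
  experts <- simulate_experts(cfg, clips)
  ref <- build_full_consensus(experts, rng_seed = 8)
  lab <- clips$split != "UNLABELED"
  clips$reference_label[lab] <- unname(ref$labels[clips$clip_id[lab]])
  profiles <- labeler_profiles(cfg)
  log <- simulate_contest(cfg, clips, profiles, engine_config(rng_seed = 8))
  # opinions on training (feedback) clips are ~uniform over the three
  # reference classes even though the class prevalences are 70/18/12
  fb <- log[log$clip_id %in% clips$clip_id[clips$split == "TRAINING"], ]
  served <- table(factor(clips$reference_label[match(fb$clip_id,
                                                     clips$clip_id)],
                         levels = bline_classes()))
  expect_lt(max(abs(prop.table(served) - 1 / 3)), 0.05)
  # alternation: about half of all opinions are on feedback clips
  expect_lt(abs(nrow(fb) / nrow(log) - 0.5), 0.05)
})

test_that("zero users give an empty log; empty world stays empty", {
  cfg <- simulation_config(n_users = 0, rng_seed = 9)
  clips <- generate_clips(cfg)
  experts <- simulate_experts(cfg, clips)
  ref <- build_full_consensus(experts, rng_seed = 9)
  lab <- clips$split %in% c("TRAINING", "TEST")
  clips$reference_label[lab] <- unname(ref$labels[clips$clip_id[lab]])
  log <- simulate_contest(cfg, clips, labeler_profiles(cfg))
  expect_identical(nrow(log), 0L)
})

test_that("with ample accurate opinions every unlabeled clip reaches consensus", {
  cfg <- simulation_config(n_clips_training = 30, n_clips_test = 10,
                           n_clips_unlabeled = 8, n_users = 40,
                           ambiguity_fraction = 0,
                           user_initial_accuracy_mean = 0.95,
                           user_initial_accuracy_sd = 0,
                           user_asymptote_mean = 0.95,
                           user_asymptote_sd = 0,
                           opinions_per_user_mean = 200,
                           opinions_per_user_shape = 10, rng_seed = 10)
  clips <- generate_clips(cfg)
  experts <- simulate_experts(cfg, clips)
  ref <- build_full_consensus(experts, rng_seed = 10)
  lab <- clips$split %in% c("TRAINING", "TEST")
  clips$reference_label[lab] <- unname(ref$labels[clips$clip_id[lab]])
  eng <- engine_config(rng_seed = 10)
  log <- simulate_contest(cfg, clips, labeler_profiles(cfg), eng)
  st <- replay_contest(log, clips, eng)
  expect_identical(sort(st$consensus$clip_id),
                   sort(clips$clip_id[clips$split == "UNLABELED"]))
  # replaying the simulated log reproduces the promotions made inline
  st2 <- replay_contest(log, clips, eng)
  expect_identical(st$consensus, st2$consensus)
})

test_that("a lone voter can never trigger the lead rule (dedup interplay)", {
  clips <- tiny_manifest(n_tr = 1, n_un = 1)
  votes <- lapply(1:10, function(i) c("u1", "C02", "NO_BLINES"))
  st <- replay_contest(warmed_log("u1", votes), clips)
  expect_identical(nrow(st$consensus), 0L)
  expect_identical(length(st$engine$pending[["C02"]]), 1L)
})

test_that("the quality filter enriches latent accuracy (filter validity)", {
  d <- desk_fixture()
  al <- d$state$annotated_log
  correct <- al$label == d$truth[al$clip_id]
  expect_gt(mean(correct[al$eligible]), mean(correct))
})

test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- simulation_config(n_clips_training = 20, n_clips_test = 10,
                           n_clips_unlabeled = 5, n_users = 10,
                           opinions_per_user_mean = 60, rng_seed = 11)
  run <- function() {
    clips <- generate_clips(cfg)
    experts <- simulate_experts(cfg, clips)
    ref <- build_full_consensus(experts, rng_seed = 11)
    lab <- clips$split %in% c("TRAINING", "TEST")
    clips$reference_label[lab] <- unname(ref$labels[clips$clip_id[lab]])
    list(clips = clips, experts = experts,
         log = simulate_contest(cfg, clips, labeler_profiles(cfg),
                                engine_config(rng_seed = 11)))
  }
  expect_identical(run(), run())
})
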