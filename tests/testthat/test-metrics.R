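# Concordance, agreement and ROC statistics.

random_labels <- function(n, prefix = "c") {
  setNames(sample(bline_classes(), n, replace = TRUE),
           sprintf("%s%04d", prefix, seq_len(n)))
}

test_that("concordance: identity is 100%, chance is ~33%, strata are correct", {
  set.seed(1)
  ref <- random_labels(200)
  self <- concordance(ref, ref)
  expect_equal(self$overall, 100)
  expect_equal(unname(self$per_class), rep(100, 3))
  expect_equal(self$balanced, 100)

  labels <- random_labels(5000)
  ref2 <- setNames(sample(bline_classes(), 5000, replace = TRUE),
                   names(labels))
  r <- concordance(labels, ref2)
  expect_lt(abs(r$overall - 100 / 3), 3) # +-3 SD of binomial at n = 5000
  # per-class values recomputed by hand
  for (cl in bline_classes()) {
    idx <- names(ref2)[ref2 == cl]
    expect_equal(r$per_class[[cl]], 100 * mean(labels[idx] == cl))
  }
  expect_equal(r$balanced, mean(r$per_class))
  expect_error(concordance(labels[-1], ref2, names(ref2)),
               class = "crowdbline_coverage_error")
})

test_that("balanced concordance ignores prevalence while overall does not", {
  # skewed reference: 90 NO, 5 DISCRETE, 5 CONFLUENT; labeler always right
  # on NO, always wrong on the rest
  ref <- setNames(rep(bline_classes(), c(90, 5, 5)), sprintf("c%03d", 1:100))
  lab <- setNames(rep("NO_BLINES", 100), names(ref))
  r <- concordance(lab, ref)
  expect_equal(r$overall, 90)
  expect_equal(r$balanced, 100 / 3)
})

test_that("expert summaries give mean, SD and SE with the n-1 denominator", {
  s <- summarize_expert_concordances(c(77.2, 81.3, 84.8, 87.3, 88.4, 90.9))
  expect_equal(round(s$mean, 1), 85.0)
  s2 <- summarize_expert_concordances(c(75.8, 77.8, 79.8, 81.8, 83.3, 86.4))
  expect_equal(round(s2$mean, 1), 80.8)
  expect_equal(round(s2$se, 1), 1.6)
  expect_equal(s2$se, s2$sd / sqrt(6))
  expect_equal(summarize_expert_concordances(rep(80, 4))$se, 0)
  expect_error(summarize_expert_concordances(80),
               class = "crowdbline_argument_error")
})

test_that("leave-one-out crowd concordance equals the brute-force double loop", {
  set.seed(3)
  experts <- data.frame(clip_id = sprintf("c%02d", 1:40),
                        stringsAsFactors = FALSE)
  for (e in paste0("e", 1:6)) {
    experts[[e]] <- sample(bline_classes(), 40, replace = TRUE,
                           prob = c(0.6, 0.25, 0.15))
  }
  loo <- build_leave_one_out(experts, rng_seed = 9)
  crowd <- random_labels(40, prefix = "")
  names(crowd) <- experts$clip_id
  r <- loo_crowd_concordance(crowd, loo, experts$clip_id)
  # oracle: plain double loop over clips x standards
  acc <- 0
  for (cid in experts$clip_id) {
    m <- 0
    for (e in names(loo)) m <- m + (crowd[[cid]] == loo[[e]]$labels[[cid]])
    acc <- acc + m / 6
  }
  expect_equal(r$overall, 100 * acc / 40)
  # crowd matching all six standards everywhere scores 100
  full <- build_full_consensus(experts, rng_seed = 9)
  una <- experts
  for (e in paste0("e", 2:6)) una[[e]] <- una$e1
  loo_u <- build_leave_one_out(una, rng_seed = 9)
  expect_equal(loo_crowd_concordance(setNames(una$e1, una$clip_id),
                                     loo_u)$overall, 100)
  # half/full split: one clip 3 of 6, one clip 6 of 6 -> 75%
  expect_equal(100 * mean(c(0.5, 1)), 75)
})

test_that("leave-one-out expert concordance matches hand enumeration", {
  experts <- data.frame(
    clip_id = c("c1", "c2", "c3", "c4"),
    e1 = c("NO_BLINES", "NO_BLINES", "DISCRETE", "CONFLUENT"),
    e2 = c("NO_BLINES", "DISCRETE", "DISCRETE", "CONFLUENT"),
    e3 = c("DISCRETE", "DISCRETE", "DISCRETE", "NO_BLINES"),
    stringsAsFactors = FALSE
  )
  loo <- build_leave_one_out(experts, rng_seed = 2)
  r <- loo_expert_concordance(experts, loo)
  # hand check: e3 vs majority of e1+e2
  # c1: e1,e2 = NO,NO -> NO; e3 DISCRETE (miss)
  # c2: NO,DISCRETE tie -> random; c3: DISCRETE,DISCRETE -> hit
  # c4: CONFLUENT,CONFLUENT -> CONFLUENT; e3 NO (miss)
  hits_e3 <- mean(experts$e3 == loo$e3$labels[experts$clip_id])
  expect_equal(r$per_expert[["e3"]], 100 * hits_e3)
  expect_true(r$per_expert[["e3"]] %in% c(25, 50))
  # experts identical to each other match their LOO standards everywhere
  una <- experts
  una$e1 <- una$e2 <- una$e3
  loo_u <- build_leave_one_out(una, rng_seed = 2)
  expect_equal(unname(loo_expert_concordance(una, loo_u)$per_expert),
               rep(100, 3))
})

test_that("self-vote removal lowers mean expert concordance (85 -> 81 pattern)", {
  d <- desk_fixture()
  loo <- build_leave_one_out(d$experts, rng_seed = 13)
  covered <- d$experts$clip_id
  emat <- as.matrix(d$experts[, -1])
  rownames(emat) <- d$experts$clip_id
  full_vals <- vapply(colnames(emat), function(e)
    100 * mean(emat[, e] == d$reference$labels[rownames(emat)]), numeric(1))
  loo_vals <- loo_expert_concordance(d$experts, loo)$per_expert
  expect_lt(mean(loo_vals), mean(full_vals))
})

test_that("ROC handles separation, chance, and tied scores", {
  # perfect separation
  sc <- c(rep(0.9, 5), rep(0.1, 5))
  fr <- cbind(NO_BLINES = sc, DISCRETE = 1 - sc, CONFLUENT = 0)
  rownames(fr) <- sprintf("c%02d", 1:10)
  ref <- setNames(rep(c("NO_BLINES", "DISCRETE"), each = 5), rownames(fr))
  r <- vote_proportion_roc(fr, ref, "NO_BLINES")
  expect_equal(r$auc, 1)
  expect_equal(r$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ], use.names = FALSE), c(1, 1))

  # chance on a large random instance
  set.seed(6)
  n <- 4000
  sc <- round(runif(n), 2)
  fr <- cbind(NO_BLINES = sc, DISCRETE = 1 - sc, CONFLUENT = 0)
  rownames(fr) <- sprintf("c%04d", 1:n)
  ref <- setNames(sample(c("NO_BLINES", "DISCRETE"), n, replace = TRUE),
                  rownames(fr))
  expect_lt(abs(vote_proportion_roc(fr, ref, "NO_BLINES")$auc - 0.5), 0.05)

  # unnormalized fractions are rejected
  bad <- fr
  bad[1, 1] <- 2
  expect_error(vote_proportion_roc(bad, ref, "NO_BLINES"),
               class = "crowdbline_normalization_error")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  sc <- sample(seq(0, 1, by = 0.05), 60, replace = TRUE)
  ref <- setNames(sample(c("NO_BLINES", "DISCRETE"), 60, replace = TRUE),
                  sprintf("c%02d", 1:60))
  mk <- function(s) {
    m <- cbind(NO_BLINES = s, DISCRETE = 1 - s, CONFLUENT = 0)
    rownames(m) <- names(ref)
    m
  }
  a1 <- vote_proportion_roc(mk(sc), ref, "NO_BLINES")$auc
  a2 <- vote_proportion_roc(mk(sc^3), ref, "NO_BLINES")$auc
  expect_equal(a1, a2)
})

test_that("paired concordance test matches the closed form and flags degeneracy", {
  x <- c(1, 0, 1, 1, 0, 1)
  expect_equal(paired_concordance_test(x, x),
               list(t = 0, df = 5L, p = 1, mean_diff = 0, degenerate = FALSE))
  expect_warning(r <- paired_concordance_test(x, x - 0.1), "zero variance")
  expect_true(r$degenerate)
  expect_true(is.na(r$p))
  set.seed(9)
  for (rep in 1:20) {
    a <- runif(15)
    b <- runif(15)
    r <- paired_concordance_test(a, b)
    tt <- t.test(a, b, paired = TRUE)
    expect_equal(r$t, unname(tt$statistic))
    expect_equal(r$p, tt$p.value)
  }
})

test_that("internal agreement and its correlation behave as defined", {
  pools <- list(c1 = c("NO_BLINES", "NO_BLINES", "DISCRETE"),
                c2 = rep("CONFLUENT", 4),
                c3 = character(0))
  ia <- internal_agreement(pools)
  expect_equal(ia, c(c1 = 2 / 3, c2 = 1))

  x <- setNames(c(0.2, 0.4, 0.6, 0.8, 1.0), paste0("c", 1:5))
  expect_equal(agreement_correlation(x, x)$r, 1)
  # closed-form check on a 5-point hand example
  y <- setNames(c(0.5, 0.3, 0.9, 0.6, 0.8), paste0("c", 1:5))
  r <- agreement_correlation(x, y)
  expect_equal(r$r, cov(x, y) / (sd(x) * sd(y)))
  set.seed(10)
  a <- setNames(runif(1000), paste0("c", 1:1000))
  b <- setNames(runif(1000), paste0("c", 1:1000))
  expect_lt(abs(agreement_correlation(a, b)$r), 0.1)
  expect_warning(agreement_correlation(setNames(rep(0.5, 5), names(x)), y),
                 "constant")
})

test_that("rank test: maximal U under separation, U matches the pair count", {
  a <- c(0.9, 0.95, 1.0)
  b <- c(0.1, 0.2)
  expect_equal(agreement_rank_test(a, b)$U, 6) # n1 * n2
  # brute-force pair-count oracle (ties count half) for n1 = n2 = 4
  set.seed(11)
  for (rep in 1:20) {
    g1 <- sample(seq(0, 1, 0.25), 4, replace = TRUE)
    g2 <- sample(seq(0, 1, 0.25), 4, replace = TRUE)
    u_oracle <- sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
    expect_equal(agreement_rank_test(g1, g2)$U, u_oracle)
  }
  # same multiset: symmetric, p near 1
  expect_gt(agreement_rank_test(c(1, 2, 3, 4), c(4, 3, 2, 1))$p, 0.9)
})
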