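test_that("transition tables count successors including end of bout", {
  bs <- make_bout_set(list(c("x", "a"), c("x", "l"), c("x", "a"), "x"))
  tt <- transition_table(bs, "x")
  expect_equal(tt$n_renditions, 4)
  expect_equal(tt$counts[["a"]], 2L)
  expect_equal(tt$counts[["l"]], 1L)
  expect_equal(tt$counts[["END"]], 1L)
  expect_equal(tp_to(tt, "a"), 0.5)
  expect_equal(sum(tt$probabilities), 1)

  # END outcomes can be dropped on request
  tt2 <- transition_table(bs, "x", include_end = FALSE)
  expect_equal(tt2$n_renditions, 3)
  expect_equal(tp_to(tt2, "a"), 2 / 3)

  # absent branch syllable: flagged undefined
  tt3 <- transition_table(bs, "q")
  expect_true(tt3$undefined)
  expect_equal(tt3$n_renditions, 0)
  expect_true(is.na(tp_to(tt3, "a")))
})

test_that("catch-only tables use only flagged renditions", {
  bs <- make_bout_set(list(c("x", "a"), c("x", "l"), c("x", "a")))
  # catch flags: only the 'l' rendition is a catch trial
  fb <- data.frame(file_id = c("f0001", "f0002", "f0003"), bout_index = 1L,
                   rendition_index = 1L, outcome = c("a", "l", "a"),
                   is_catch = c(FALSE, TRUE, FALSE),
                   wn_delivered = c(TRUE, FALSE, TRUE))
  bs <- attach_feedback(bs, fb)
  tt <- transition_table(bs, "x", catch_only = TRUE)
  expect_equal(tt$n_renditions, 1)
  expect_equal(tp_to(tt, "a"), 0)   # all target renditions were non-catch
  expect_equal(tp_to(tt, "l"), 1)
  # without flags, catch_only errors
  bs2 <- make_bout_set(list(c("x", "a")))
  expect_error(transition_table(bs2, "x", catch_only = TRUE),
               "feedback log")
})

test_that("transition tables match a full recount on random bouts", {
  set.seed(21)
  for (rep in 1:100) {
    labels <- random_bouts(sample(3:15, 1))
    bs <- make_bout_set(labels)
    tt <- transition_table(bs, "x")
    want <- oracle_transition_counts(labels, "x")
    expect_equal(tt$n_renditions, length(want))
    if (length(want) > 0) {
      wt <- table(want)
      for (o in names(wt)) {
        expect_equal(tt$counts[[o]], as.integer(wt[[o]]))
      }
      expect_equal(sum(tt$probabilities), 1)
    } else {
      expect_true(tt$undefined)
    }
  }
})

test_that("transition counts are conserved under bout reordering", {
  set.seed(22)
  labels <- random_bouts(12)
  tt1 <- transition_table(make_bout_set(labels), "x")
  tt2 <- transition_table(make_bout_set(rev(labels)), "x")
  expect_equal(tt1$counts[order(names(tt1$counts))],
               tt2$counts[order(names(tt2$counts))])
})

test_that("degree of learning is the percent reduction from baseline", {
  expect_equal(degree_of_learning(0.5, 0.25), 50)
  expect_equal(degree_of_learning(0.4, 0.4), 0)
  expect_equal(degree_of_learning(0.2, 0.3), -50)
  expect_error(degree_of_learning(0, 0.1), "undefined")
})

test_that("best training day is the earliest minimum of catch-trial TP", {
  expect_equal(best_training_day(c(T1 = 0.4, T2 = 0.2, T3 = 0.3)), "T2")
  expect_equal(best_training_day(c(T1 = 0.2, T2 = 0.2)), "T1")
  # screen phases are ignored even when lower
  expect_equal(best_training_day(c(BS = 0.1, T1 = 0.5, T2 = 0.4, PS1 = 0.05)),
               "T2")
  expect_error(best_training_day(c(BS = 0.5)), "no training day")
  set.seed(23)
  for (rep in 1:100) {
    k <- sample(2:5, 1)
    v <- stats::setNames(round(runif(k), 2), paste0("T", 1:k))
    want <- names(v)[which(v == min(v))[1]]
    expect_equal(best_training_day(v), want)
  }
})

test_that("transition entropy is zero for stereotyped syntax", {
  # strictly alternating song: deterministic successors once the final
  # end-of-bout transition is set aside
  expect_equal(bout_transition_entropy(rep(c("a", "b"), 10),
                                       include_end = FALSE), 0)
  # with END counted, determinism requires a consistent bout ending
  expect_equal(bout_transition_entropy(c("a", "b", "c")), 0)
  expect_equal(bout_transition_entropy("a"), 0)
  # one 50/50 branch emitting half of all transitions, others
  # deterministic: TE = 1 bit * 0.5
  expect_equal(bout_transition_entropy(c("x", "a", "x", "b")), 0.5)
})

test_that("entropy in nats equals bits times ln 2 exactly", {
  set.seed(24)
  for (rep in 1:50) {
    lb <- random_bouts(1, max_len = 30)[[1]]
    te2 <- bout_transition_entropy(lb, log_base = 2)
    tee <- bout_transition_entropy(lb, log_base = exp(1))
    expect_equal(tee, te2 * log(2), tolerance = 1e-12)
    expect_gte(te2, 0)
  }
})

test_that("per-bout entropy matches the contingency-table oracle", {
  set.seed(25)
  for (rep in 1:100) {
    lb <- random_bouts(1, alphabet = c("x", "a", "l", "b"),
                       max_len = 25)[[1]]
    expect_equal(bout_transition_entropy(lb), oracle_te(lb),
                 tolerance = 1e-12)
    expect_equal(bout_transition_entropy(lb, include_end = FALSE),
                 oracle_te(lb, include_end = FALSE), tolerance = 1e-12)
  }
})

test_that("mean transition entropy averages per-bout values", {
  bs <- make_bout_set(list(c("x", "a", "x", "b"), c("x", "a", "x", "b")))
  es <- mean_transition_entropy(bs)
  expect_equal(es$per_bout_te, c(0.5, 0.5))
  expect_equal(es$mean_te, 0.5)
  expect_equal(es$log_base, 2)
  # deterministic bouts give zero mean
  bs0 <- make_bout_set(list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(mean_transition_entropy(bs0)$mean_te, 0)
  expect_error(mean_transition_entropy(list()), "empty")
  # mixture matches the oracle mean
  set.seed(26)
  labels <- random_bouts(20, max_len = 15)
  es2 <- mean_transition_entropy(make_bout_set(labels))
  expect_equal(es2$mean_te, mean(vapply(labels, oracle_te, 0)),
               tolerance = 1e-12)
})

test_that("song rate counts bouts in the half-open clock window", {
  mk_at <- function(times) {
    labels <- rep(list(c("x", "a")), length(times))
    rows <- lapply(seq_along(times), function(b) {
      t0 <- as.POSIXct(paste("2024-01-01", times[b]), tz = "UTC")
      data.frame(file_id = sprintf("g%02d", b), file_start = t0,
                 singer = "s", label = c("x", "a"), onset_s = c(0, 0.2),
                 offset_s = c(0.1, 0.3), stringsAsFactors = FALSE)
    })
    segment_bouts(do.call(rbind, rows), 2)
  }
  bs <- mk_at(c("08:00:00", "09:30:00", "12:00:00", "16:59:59", "17:00:00"))
  # 09:30 is counted, 17:00 is not
  expect_equal(song_rate(bs, "2024-01-01"), 3)
  expect_equal(song_rate(bs, "2024-01-02"), 0)
  # random times agree with a linear scan
  set.seed(27)
  for (rep in 1:20) {
    secs <- sort(sample(0:86399, 30))
    times <- format(as.POSIXct(secs, origin = "2024-01-01", tz = "UTC"),
                    "%H:%M:%S")
    bs <- mk_at(times)
    want <- sum(secs >= 9.5 * 3600 & secs < 17 * 3600)
    expect_equal(song_rate(bs, "2024-01-01"), want)
  }
})

test_that("chunk durations span onset of first to offset of last syllable", {
  t0 <- as.POSIXct("2024-01-01 10:00:00", tz = "UTC")
  ev <- data.frame(file_id = "f1", file_start = t0, singer = "s",
                   label = c("a", "b"), onset_s = c(0, 0.2),
                   offset_s = c(0.1, 0.35), stringsAsFactors = FALSE)
  bs <- segment_bouts(ev, 2)
  expect_equal(chunk_durations(bs, c("a", "b")), 0.35)
  expect_equal(chunk_durations(bs, c("q", "r")), numeric(0))
  # overlapping candidates: "aa" in "aaa" matches only once (leftmost)
  bs3 <- make_bout_set(list(c("a", "a", "a")), syl_dur = 0.1, gap = 0.05)
  expect_length(chunk_durations(bs3, c("a", "a")), 1)
})

test_that("chunk matching agrees with the enumerate-then-greedy oracle", {
  set.seed(28)
  for (rep in 1:100) {
    lb <- sample(c("a", "b"), sample(4:20, 1), replace = TRUE)
    chunk <- sample(c("a", "b"), sample(2:3, 1), replace = TRUE)
    bs <- make_bout_set(list(lb))
    got <- chunk_durations(bs, chunk)
    starts <- oracle_chunk_starts(lb, chunk)
    # reconstruct expected durations from the fixture's regular timing
    step <- 0.15
    want <- rep((length(chunk) - 1) * step + 0.1, length(starts))
    expect_equal(sort(got), sort(want), tolerance = 1e-9)
  }
})

test_that("binned learning curves follow the 50-bout convention", {
  set.seed(29)
  labels <- rep(list(c("x", "a")), 120)
  bs <- make_bout_set(labels)
  cv <- binned_learning_curve(bs, "x", "a", bin_size = 50)
  expect_equal(nrow(cv), 3)
  expect_equal(cv$complete, c(TRUE, TRUE, FALSE))
  expect_equal(cv$n_bouts, c(50L, 50L, 20L))
  expect_equal(cv$tp_target, c(1, 1, 1))  # constant outcome stream
})

test_that("binned curves match a windowed recount on random streams", {
  set.seed(30)
  for (rep in 1:100) {
    n <- sample(20:120, 1)
    bin <- sample(c(10, 25, 50), 1)
    labels <- random_bouts(n, max_len = 6)
    bs <- make_bout_set(labels)
    got <- binned_learning_curve(bs, "x", "a", bin_size = bin)
    # recount on bouts ordered as the bout table orders them
    ord_labels <- lapply(split(bs$events$label, bs$events$bout_id)
                         [bs$bouts$bout_id], identity)
    want <- oracle_binned(ord_labels, "x", "a", bin)
    expect_equal(got$tp_target, want$tp_target)
    expect_equal(got$n_renditions, want$n_renditions)
  }
})

test_that("the common early-learning bin comes from the slowest singer", {
  mk_curve <- function(n_bouts, bin = 50) {
    data.frame(bin = seq_len(ceiling(n_bouts / bin)),
               tp_target = 0.5,
               n_renditions = 10,
               n_bouts = c(rep(bin, n_bouts %/% bin),
                           if (n_bouts %% bin) n_bouts %% bin),
               complete = c(rep(TRUE, n_bouts %/% bin),
                            if (n_bouts %% bin) FALSE))
  }
  curves <- list(MA = mk_curve(400), MF = mk_curve(210), MM = mk_curve(320))
  expect_equal(last_complete_bin(curves), 4)   # floor(210 / 50)
  eq <- list(MA = mk_curve(200), MF = mk_curve(200), MM = mk_curve(200))
  expect_equal(last_complete_bin(eq), 4)
  # a reference context without a single complete bin is an error
  none <- list(MA = mk_curve(400), MF = mk_curve(210), MM = mk_curve(30))
  expect_error(last_complete_bin(none), "MM has no complete bin")
  # a context missing the chosen bin is an error naming it
  broken <- list(MA = mk_curve(400), MF = mk_curve(210), MM = mk_curve(320))
  broken$MA$complete[4] <- FALSE
  expect_error(last_complete_bin(broken), "MA")
  set.seed(31)
  for (rep in 1:100) {
    ns <- sample(60:500, 3)
    cs <- list(MA = mk_curve(ns[1]), MF = mk_curve(ns[2]),
               MM = mk_curve(ns[3]))
    expect_equal(last_complete_bin(cs), min(ns) %/% 50)
  }
})

test_that("relative learning speed scales inversely with song rate", {
  expect_equal(relative_learning_speed(50, 500), 0.1)
  expect_equal(relative_learning_speed(0, 123), 0)
  expect_equal(relative_learning_speed(40, 400),
               relative_learning_speed(40, 200) / 2)
  expect_error(relative_learning_speed(50, 0), "positive")
})

test_that("targeting accuracy classifies hits, misses and false positives", {
  mk_log <- function(hits, fp, misses, catches = 0) {
    data.frame(
      outcome = c(rep("a", hits + misses), rep("l", fp),
                  rep("a", catches)),
      is_catch = c(rep(FALSE, hits + misses + fp), rep(TRUE, catches)),
      wn_delivered = c(rep(TRUE, hits), rep(FALSE, misses),
                       rep(TRUE, fp), rep(FALSE, catches)),
      stringsAsFactors = FALSE)
  }
  ta <- targeting_accuracy(mk_log(93, 4, 3), "a")
  expect_equal(ta$accuracy, 93)
  expect_false(ta$excluded)
  ta2 <- targeting_accuracy(mk_log(70, 0, 30), "a")
  expect_equal(ta2$accuracy, 70)
  expect_true(ta2$excluded)
  # catch trials never enter the denominator
  ta3 <- targeting_accuracy(mk_log(93, 4, 3, catches = 50), "a")
  expect_equal(ta3$accuracy, 93)
  # empty denominator is undefined, not an exclusion
  ta4 <- targeting_accuracy(mk_log(0, 0, 0, catches = 5), "a")
  expect_true(ta4$undefined)
  expect_true(is.na(ta4$accuracy))
})

test_that("simulated targeting accuracy matches programmed rates", {
  run <- recovery_run()
  fb <- run$feedback
  ta <- targeting_accuracy(fb, "a")
  # expected accuracy: hits / (hits + misses + fp)
  # = 0.93 p / (p + 0.02 (1 - p)) averaged over the target probability;
  # bound it with the two extremes of the programmed trajectory
  acc_at <- function(p) 100 * 0.93 * p / (p + 0.02 * (1 - p))
  expect_gt(ta$accuracy, acc_at(0.40) - 1)
  expect_lt(ta$accuracy, acc_at(0.80) + 1)
  expect_false(ta$excluded)
})

test_that("learning_result runs the full per-context computation", {
  run <- recovery_run()
  lr <- run$results$learning
  expect_setequal(lr$context, c("MA", "MF", "MM"))
  expect_true(all(grepl("^T[0-9]$", lr$best_day)))
  expect_true(all(lr$tp_baseline > lr$tp_best_day))
  per_day <- run$results$per_day_tp
  expect_true(all(per_day$catch_only == grepl("^T", per_day$phase)))
})
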