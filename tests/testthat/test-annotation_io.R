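make_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("file_id,file_start_iso8601,singer,label,onset_s,offset_s",
               rows), path)
  path
}

test_that("annotation reader parses well-formed files and round-trips", {
  p <- make_csv(c(
    "f1,2024-01-01T09:00:00,b1,x,0.0,0.1",
    "f1,2024-01-01T09:00:00,b1,a,0.2,0.3",
    "f1,2024-01-01T09:00:00,b1,l,0.4,0.5"))
  ev <- read_annotations(p)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$label, c("x", "a", "l"))
  expect_s3_class(ev$file_start, "POSIXct")
  expect_equal(as.numeric(ev$t_on - ev$file_start, units = "secs"),
               ev$onset_s, tolerance = 1e-6)

  out <- tempfile(fileext = ".csv")
  write_annotations(ev, out)
  ev2 <- read_annotations(out)
  expect_equal(ev2$label, ev$label)
  expect_equal(ev2$onset_s, ev$onset_s)
  expect_equal(as.numeric(ev2$file_start), as.numeric(ev$file_start))
})

test_that("annotation reader handles empty files and rejects bad rows", {
  expect_equal(nrow(read_annotations(make_csv(character(0)))), 0)

  # offset before onset violates the event invariant
  bad <- make_csv(c("f1,2024-01-01T09:00:00,b1,x,0.5,0.4"))
  expect_error(read_annotations(bad), "offset_s <= onset_s")

  # unparseable numeric field is reported with its line number
  mal <- make_csv(c("f1,2024-01-01T09:00:00,b1,x,0.0,0.1",
                    "f1,2024-01-01T09:00:00,b1,a,oops,0.3"))
  expect_error(read_annotations(mal), "line 3")

  # missing column
  p <- tempfile(fileext = ".csv")
  writeLines(c("file_id,singer,label", "f1,b1,x"), p)
  expect_error(read_annotations(p), "required column")
})

test_that("bout segmentation applies the silence-gap threshold", {
  # gaps of 0.1, 0.3, 2.5, 0.2 s between five syllables: the 2.5 s silence
  # splits the stream into bouts of 3 and 2
  onset <- c(0, 0.2, 0.6, 3.2, 3.5)
  offset <- onset + 0.1
  ev <- data.frame(file_id = "f1",
                   file_start = as.POSIXct("2024-01-01 09:00:00", tz = "UTC"),
                   singer = "b1", label = "x", onset_s = onset,
                   offset_s = offset, stringsAsFactors = FALSE)
  ev$label <- letters[1:5]
  bs <- segment_bouts(ev, gap_threshold = 2)
  expect_equal(n_bouts(bs), 2)
  expect_equal(sort(bs$bouts$n_events), c(2L, 3L))

  # a single event is its own bout
  bs1 <- segment_bouts(ev[1, ], gap_threshold = 2)
  expect_equal(n_bouts(bs1), 1)
  expect_equal(bs1$bouts$n_events, 1L)

  # a gap exactly at threshold starts a new bout
  ev2 <- ev[1:2, ]
  ev2$onset_s <- c(0, 2.1)
  ev2$offset_s <- c(0.1, 2.2)
  expect_equal(n_bouts(segment_bouts(ev2, gap_threshold = 2)), 2)
  expect_equal(n_bouts(segment_bouts(ev2, gap_threshold = 2.001)), 1)

  # unsorted input is rejected
  expect_error(segment_bouts(ev[c(2, 1, 3, 4, 5), ]), "not time-ordered")
})

test_that("segmentation of random streams matches a brute-force gap scan", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(2:100, 1)
    dur <- runif(n, 0.05, 0.3)
    gap <- stats::rexp(n - 1, rate = 1 / 1.5)  # gaps straddle the threshold
    onset <- cumsum(c(0, dur[-n] + gap))
    offset <- onset + dur
    ev <- data.frame(file_id = "f1",
                     file_start = as.POSIXct("2024-01-01", tz = "UTC"),
                     singer = "b1", label = "x", onset_s = onset,
                     offset_s = offset, stringsAsFactors = FALSE)
    bs <- segment_bouts(ev, gap_threshold = 2)
    sizes <- oracle_segment(onset, offset, 2)
    expect_equal(n_bouts(bs), length(sizes))
    ord <- order(bs$bouts$bout_start)
    expect_equal(bs$bouts$n_events[ord], sizes)
    # conservation: every event in exactly one bout
    expect_equal(sum(bs$bouts$n_events), n)
  }
})

test_that("segmentation is idempotent", {
  set.seed(7)
  n <- 60
  dur <- runif(n, 0.05, 0.2)
  gap <- stats::rexp(n - 1, 1 / 1.5)
  onset <- cumsum(c(0, dur[-n] + gap))
  ev <- data.frame(file_id = "f1",
                   file_start = as.POSIXct("2024-01-01", tz = "UTC"),
                   singer = "b1", label = "x", onset_s = onset,
                   offset_s = onset + dur, stringsAsFactors = FALSE)
  bs1 <- segment_bouts(ev, gap_threshold = 2)
  bs2 <- segment_bouts(bs1$events[, names(ev)], gap_threshold = 2)
  expect_equal(bs2$bouts$n_events, bs1$bouts$n_events)
  expect_equal(bs2$events$bout_id, bs1$events$bout_id)
})

two_singer_events <- function(sub_on, sub_off, part_on, part_off,
                              file_id = "f1") {
  t0 <- as.POSIXct("2024-01-01 09:00:00", tz = "UTC")
  one <- function(singer, label, on, off) {
    if (length(on) == 0) return(NULL)
    data.frame(file_id = file_id, file_start = t0, singer = singer,
               label = label, onset_s = on, offset_s = off,
               stringsAsFactors = FALSE)
  }
  df <- rbind(one("subj", "x", sub_on, sub_off),
              one("partner", "p", part_on, part_off))
  df[order(df$onset_s), ]
}

test_that("mixed-singing exclusion follows the overlap rule", {
  # subject-only file is kept with zero overlap
  ev <- two_singer_events(c(0, 0.2), c(0.1, 0.3), numeric(0), numeric(0))
  bs <- segment_bouts(ev, 2)
  flt <- filter_mixed_bouts(bs, "subj")
  expect_false(any(flt$report$excluded))
  expect_equal(flt$report$overlap_fraction, 0)

  # partner fully overlapping the subject's bout: excluded at any
  # threshold < 1
  ev <- two_singer_events(c(0, 0.2), c(0.1, 0.3), 0, 0.4)
  bs <- segment_bouts(ev, 2)
  for (thr in c(0, 0.5, 0.99)) {
    flt <- filter_mixed_bouts(bs, "subj", overlap_threshold = thr)
    expect_true(flt$report$excluded)
  }
  expect_equal(flt$report$overlap_fraction, 1)

  # partner-only file is excluded outright (alongside a kept subject file)
  ev <- rbind(
    two_singer_events(numeric(0), numeric(0), c(0, 0.2), c(0.1, 0.3),
                      file_id = "f_partner"),
    two_singer_events(c(0, 0.2), c(0.1, 0.3), numeric(0), numeric(0),
                      file_id = "f_subject"))
  bs <- segment_bouts(ev, 2)
  flt <- filter_mixed_bouts(bs, "subj")
  rep_p <- flt$report[flt$report$file_id == "f_partner", ]
  expect_true(rep_p$excluded)
  expect_equal(rep_p$reason, "partner_only")
  expect_false(flt$report$excluded[flt$report$file_id == "f_subject"])
  expect_equal(unique(flt$kept$events$singer), "subj")

  expect_error(filter_mixed_bouts(bs, "nobody"), "unknown singer")
})

test_that("overlap fractions match a time-discretization oracle", {
  set.seed(11)
  for (rep in 1:100) {
    ns <- sample(1:6, 1)
    np <- sample(1:6, 1)
    mk <- function(n) {
      # guaranteed spacing keeps one singer's own syllables disjoint
      on <- sort(runif(n, 0, 2)) + (seq_len(n) - 1) * 0.08
      len <- runif(n, 0.02, 0.07)
      list(on = on, off = on + len)
    }
    s <- mk(ns); p <- mk(np)
    ev <- two_singer_events(s$on, s$off, p$on, p$off)
    bs <- segment_bouts(ev, 10)  # force a single subject bout
    flt <- filter_mixed_bouts(bs, "subj", overlap_threshold = 1)
    got <- flt$report$overlap_fraction
    want <- oracle_overlap_grid(s$on, s$off, p$on, p$off, step = 5e-5) /
      sum(s$off - s$on)
    want <- min(1, want)
    expect_lt(abs(got - want), 0.01)
  }
})

test_that("raising the overlap threshold never excludes more files", {
  set.seed(13)
  t0 <- as.POSIXct("2024-01-01 09:00:00", tz = "UTC")
  rows <- list()
  for (f in 1:20) {
    on_s <- sort(runif(4, 0, 2))
    on_p <- sort(runif(3, 0, 2))
    rows[[f]] <- rbind(
      data.frame(file_id = sprintf("f%02d", f), file_start = t0 + f * 100,
                 singer = "subj", label = "x", onset_s = on_s,
                 offset_s = on_s + 0.15, stringsAsFactors = FALSE),
      data.frame(file_id = sprintf("f%02d", f), file_start = t0 + f * 100,
                 singer = "partner", label = "p", onset_s = on_p,
                 offset_s = on_p + 0.15, stringsAsFactors = FALSE))
    rows[[f]] <- rows[[f]][order(rows[[f]]$onset_s), ]
  }
  ev <- do.call(rbind, rows)
  # avoid duplicate-onset collisions across singers within a file
  ev <- ev[!duplicated(paste(ev$file_id, ev$singer, ev$onset_s)), ]
  bs <- segment_bouts(ev, 10)
  thresholds <- c(0, 0.1, 0.25, 0.5, 0.9, 1)
  n_excluded <- vapply(thresholds, function(tr) {
    sum(filter_mixed_bouts(bs, "subj", tr)$report$excluded)
  }, 0)
  expect_true(all(diff(n_excluded) <= 0))
})

test_that("schedule assignment stamps phases and contexts by date", {
  sch <- experiment_schedule("b1", c("MA", "MF", "MM"), "2024-01-01", 4)
  labels <- list(c("x", "a"), c("x", "l"))
  bs <- make_bout_set(labels, start = "2024-01-02T10:00:00")
  bs <- assign_schedule(bs, sch)
  expect_equal(unique(bs$bouts$phase), "T1")
  expect_equal(unique(bs$bouts$context), "MA")
  # unscheduled days stay NA
  bs2 <- assign_schedule(make_bout_set(labels, start = "2030-01-01T10:00:00"),
                         sch)
  expect_true(all(is.na(bs2$bouts$phase)))
})
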