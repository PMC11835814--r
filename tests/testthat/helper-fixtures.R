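# Programmatic fixtures shared across the test files.

# Build a bout_set from a list of label vectors: one source file per bout,
# constant syllable duration and within-bout gap, files spaced far apart.
make_bout_set <- function(bout_labels, syl_dur = 0.1, gap = 0.05,
                          singer = "subj", gap_threshold = 2,
                          start = "2024-01-01T10:00:00") {
  t0 <- as.POSIXct(start, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  rows <- lapply(seq_along(bout_labels), function(b) {
    lb <- bout_labels[[b]]
    onset <- (seq_along(lb) - 1) * (syl_dur + gap)
    data.frame(file_id = sprintf("f%04d", b),
               file_start = t0 + (b - 1) * 60,
               singer = singer, label = lb,
               onset_s = onset, offset_s = onset + syl_dur,
               stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, rows)
  events$t_on <- events$file_start + events$onset_s
  segment_bouts(events, gap_threshold = gap_threshold)
}

# random label-vector bouts over a small alphabet, guaranteed non-empty
random_bouts <- function(n_bouts, alphabet = c("x", "a", "l"),
                         min_len = 1, max_len = 12) {
  lapply(seq_len(n_bouts), function(i) {
    sample(alphabet, sample(min_len:max_len, 1), replace = TRUE)
  })
}

# a single-rendition song model: one branch visit per bout
single_rendition_model <- function(p_target = 0.6, p_alt = 0.3,
                                   p_end = 0.1) {
  song_model(
    repertoire = c("x", "a", "l"),
    transitions = list(x = c(a = p_target, l = p_alt, END = p_end),
                       a = c(END = 1), l = c(END = 1)),
    branch_syllable = "x", target_branch = "a", start_token = "x")
}

# compact configuration for fast end-to-end pipeline runs
small_config <- function(seed = 5, bouts_per_day = 20, learning_rate = 0.05) {
  cfg <- default_run_config(subject = "testbird", seed = seed)
  for (ctx in names(cfg$profiles)) {
    cfg$profiles[[ctx]]$bouts_per_day_mean <- bouts_per_day
  }
  cfg$learning$learning_rate <- learning_rate
  cfg$analysis$bin_size <- 5L   # matched to the reduced bout counts
  cfg
}

# Parameter-recovery run at the reference configuration: default song model
# and dynamics, ~200 bouts/day in every context, seed 1. Cached so the
# acceptance checks share one simulation.
.recovery_cache <- new.env(parent = emptyenv())

recovery_config <- function() {
  cfg <- default_run_config(subject = "recovery", seed = 1)
  for (ctx in names(cfg$profiles)) {
    cfg$profiles[[ctx]]$bouts_per_day_mean <- 200
  }
  cfg
}

recovery_run <- function() {
  if (!is.null(.recovery_cache$run)) return(.recovery_cache$run)
  cfg <- recovery_config()
  data_dir <- file.path(tempdir(), "branchlearn-recovery-ds")
  results_dir <- file.path(tempdir(), "branchlearn-recovery-res")
  cmd_simulate(cfg, data_dir, quiet = TRUE)
  res <- cmd_analyze(cfg, data_dir, results_dir, quiet = TRUE)
  truth <- utils::read.csv(file.path(data_dir, "ground_truth.csv"),
                           stringsAsFactors = FALSE)
  feedback <- utils::read.csv(file.path(data_dir, "feedback_log.csv"),
                              stringsAsFactors = FALSE)
  .recovery_cache$run <- list(config = cfg, results = res, truth = truth,
                              feedback = feedback, data_dir = data_dir,
                              results_dir = results_dir)
  .recovery_cache$run
}
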