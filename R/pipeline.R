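#' Default run configuration
#'
#' A complete nested configuration for the simulate/analyze/report workflow:
#' the generative song model, per-context output profiles, the feedback and
#' learning parameters, the schedule, and the analysis settings (bin size,
#' entropy log base, rate window, chunk, exclusion thresholds).
#'
#' @param subject Subject identifier.
#' @param seed Integer seed.
#' @return Nested configuration list.
#' @export
default_run_config <- function(subject = "bird01", seed = 42) {
  list(
    subject = subject,
    seed = as.integer(seed),
    start_date = "2024-03-01",
    context_order = c("MF", "MA", "MM"),
    training_days = 4L,
    model = list(
      repertoire = c("i", "x", "a", "l"),
      start_token = "i",
      branch_syllable = "x",
      target_branch = "a",
      transitions = list(i = list(x = 1),
                         x = list(a = 0.80, l = 0.19, END = 0.01),
                         a = list(x = 0.99, END = 0.01),
                         l = list(x = 0.99, END = 0.01)),
      syllable_duration = list(mean = 0.08, sd = 0.01),
      gap_duration = list(mean = 0.06, sd = 0.01),
      max_bout_length = 400L),
    profiles = list(
      MA = list(bouts_per_day_mean = 200, tempo_factor = 1.00,
                entropy_factor = 0),
      MF = list(bouts_per_day_mean = 140, tempo_factor = 0.98,
                entropy_factor = 0),
      MM = list(bouts_per_day_mean = 140, tempo_factor = 0.97,
                entropy_factor = 0)),
    feedback = list(hit_rate = 0.93, false_positive_rate = 0.02,
                    catch_fraction = 0.10, wn_duration = 0.040),
    learning = list(learning_rate = 0.05, floor = 0.40,
                    relaxation_rate = 0.12),
    analysis = list(bin_size = 50L, entropy_log_base = 2,
                    overlap_threshold = 0, accuracy_threshold = 75,
                    gap_threshold = 2,
                    rate_window = c("09:30", "17:00"),
                    chunk = c("x", "a")))
}

#' Read a run configuration from YAML
#' @param path YAML file path.
#' @return Configuration list, validated by [validate_run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_run_config(yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks presence and coherence of the configuration fields and names the
#' offending field on failure.
#'
#' @param config Configuration list.
#' @return The configuration, invisibly, on success.
#' @export
validate_run_config <- function(config) {
  need <- c("subject", "seed", "start_date", "context_order",
            "training_days", "model", "profiles", "feedback", "learning",
            "analysis")
  for (f in need) {
    if (is.null(config[[f]])) stop("config error: missing field '", f, "'")
  }
  m <- config$model
  if (!(m$branch_syllable %in% unlist(m$repertoire))) {
    stop("config error: model.branch_syllable '", m$branch_syllable,
         "' not in model.repertoire")
  }
  row <- m$transitions[[m$branch_syllable]]
  if (is.null(row) || is.null(row[[m$target_branch]]) ||
      row[[m$target_branch]] <= 0) {
    stop("config error: model.target_branch '", m$target_branch,
         "' has no probability after the branch syllable")
  }
  if (!setequal(names(config$profiles), unlist(config$context_order))) {
    stop("config error: profiles must cover exactly the contexts in ",
         "context_order")
  }
  invisible(config)
}

# Build simulator objects from a configuration.
.config_objects <- function(config) {
  m <- config$model
  model <- song_model(
    repertoire = unlist(m$repertoire),
    transitions = lapply(m$transitions, unlist),
    branch_syllable = m$branch_syllable,
    target_branch = m$target_branch,
    start_token = m$start_token,
    syl_dur_mean = m$syllable_duration$mean,
    syl_dur_sd = m$syllable_duration$sd,
    gap_dur_mean = m$gap_duration$mean,
    gap_dur_sd = m$gap_duration$sd,
    max_bout_length = m$max_bout_length)
  profiles <- lapply(names(config$profiles), function(ctx) {
    p <- config$profiles[[ctx]]
    context_profile(ctx, p$bouts_per_day_mean, p$tempo_factor,
                    p$entropy_factor)
  })
  names(profiles) <- names(config$profiles)
  fb <- feedback_model(config$feedback$hit_rate,
                       config$feedback$false_positive_rate,
                       config$feedback$catch_fraction,
                       config$feedback$wn_duration)
  dyn <- learning_dynamics(config$learning$learning_rate,
                           config$learning$floor,
                           config$learning$relaxation_rate)
  schedule <- experiment_schedule(config$subject,
                                  unlist(config$context_order),
                                  config$start_date, config$training_days)
  list(model = model, profiles = profiles, fb = fb, dyn = dyn,
       schedule = schedule)
}

# Stable hash of a configuration for provenance stamping.
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

.log_info <- function(..., quiet = FALSE) {
  if (!quiet) message("[branchlearn] ", ...)
}

#' Simulate an experiment and write the dataset
#'
#' Runs the closed-loop simulator under the configuration and writes the
#' dataset directory: `annotations.csv`, `feedback_log.csv`,
#' `ground_truth.csv`, `schedule.csv`, plus a `manifest.json` carrying the
#' configuration hash and seed for provenance.
#'
#' @param config Configuration list (see [default_run_config()]) or a YAML
#'   path.
#' @param out_dir Dataset output directory.
#' @param quiet Suppress progress messages.
#' @return `out_dir`, invisibly.
#' @export
cmd_simulate <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  obj <- .config_objects(config)
  .log_info("simulating subject ", config$subject, " (seed ", config$seed,
            ")", quiet = quiet)
  sim <- simulate_experiment(obj$model, obj$schedule, obj$profiles, obj$fb,
                             obj$dyn, seed = config$seed)
  write_simulation(sim, out_dir)
  manifest <- list(subject = config$subject, seed = config$seed,
                   config_hash = .config_hash(config),
                   n_days = nrow(sim$truth),
                   n_syllables = nrow(sim$events),
                   n_renditions_logged = if (is.null(sim$feedback)) 0L else
                     nrow(sim$feedback))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .log_info("wrote dataset with ", nrow(sim$events), " syllables over ",
            nrow(sim$truth), " days to ", out_dir, quiet = quiet)
  invisible(out_dir)
}

#' Analyze a dataset directory
#'
#' The full analysis chain: read annotations, segment bouts, apply the
#' mixed-singing exclusion, label phases from the schedule, attach the
#' feedback log, then compute per-context learning (catch trials on
#' training days), per-day transition probabilities, baseline transition
#' entropy, song rate, chunk-duration song speed, first-training-day binned
#' learning curves with the common early-learning bin, targeting accuracy
#' per training day (days under the accuracy threshold are excluded from
#' learning, with the exclusion logged), and per-context baseline-vs-best
#' proportion tests. Results are written as tidy CSVs.
#'
#' @param config Configuration list or YAML path.
#' @param data_dir Dataset directory from [cmd_simulate()] (or identically
#'   laid out real data).
#' @param out_dir Results output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of the result tables.
#' @export
cmd_analyze <- function(config, data_dir, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  an <- config$analysis
  branch <- config$model$branch_syllable
  target <- config$model$target_branch
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  events <- read_annotations(file.path(data_dir, "annotations.csv"))
  .log_info("read ", nrow(events), " annotated syllables", quiet = quiet)
  bs <- segment_bouts(events, gap_threshold = an$gap_threshold)
  .log_info("segmented ", n_bouts(bs), " bouts", quiet = quiet)

  flt <- filter_mixed_bouts(bs, config$subject,
                            overlap_threshold = an$overlap_threshold)
  n_excl <- sum(flt$report$excluded)
  .log_info("mixed-singing exclusion: ", n_excl, " of ",
            nrow(flt$report), " files excluded", quiet = quiet)
  write_exclusion_report(flt$report, file.path(out_dir, "exclusions.csv"))
  bs <- flt$kept

  schedule <- utils::read.csv(file.path(data_dir, "schedule.csv"),
                              stringsAsFactors = FALSE)
  schedule$date <- as.Date(schedule$date)
  bs <- assign_schedule(bs, schedule)
  fb_path <- file.path(data_dir, "feedback_log.csv")
  feedback <- utils::read.csv(fb_path, stringsAsFactors = FALSE,
                              colClasses = c(file_id = "character"))
  bs <- attach_feedback(bs, feedback)

  contexts <- unique(schedule$context)
  missing_ph <- setdiff(c("BS", "T1"), unique(stats::na.omit(bs$bouts$phase)))
  if (length(missing_ph) > 0) {
    stop("dataset lacks required phase(s): ",
         paste(missing_ph, collapse = ", "))
  }

  # per training day targeting accuracy; exclusion below threshold
  fb_bout <- merge(feedback,
                   bs$bouts[, c("file_id", "bout_index", "phase", "context")],
                   by = c("file_id", "bout_index"))
  targeting <- do.call(rbind, lapply(split(
    fb_bout, list(fb_bout$context, fb_bout$phase), drop = TRUE),
    function(d) {
      ta <- targeting_accuracy(d, target, threshold = an$accuracy_threshold)
      data.frame(context = d$context[1], phase = d$phase[1],
                 accuracy = ta$accuracy, hits = ta$hits,
                 false_positives = ta$false_positives, misses = ta$misses,
                 excluded = ta$excluded, stringsAsFactors = FALSE)
    }))
  rownames(targeting) <- NULL
  utils::write.csv(targeting, file.path(out_dir, "targeting.csv"),
                   row.names = FALSE)
  for (i in which(targeting$excluded)) {
    .log_info("excluding ", targeting$phase[i], "_", targeting$context[i],
              ": targeting accuracy ",
              round(targeting$accuracy[i], 1), "% < ",
              an$accuracy_threshold, "%", quiet = quiet)
  }

  learning_rows <- list()
  per_day_rows <- list()
  curves <- list()
  for (ctx in contexts) {
    ctx_bs <- subset_context(bs, ctx)
    excl <- targeting$phase[targeting$context == ctx & targeting$excluded]
    lr <- learning_result(ctx_bs, branch, target, excluded_phases = excl)
    ord <- schedule$order_index[schedule$context == ctx][1]
    learning_rows[[ctx]] <- data.frame(
      subject = config$subject, context = ctx, order_index = ord,
      tp_baseline = lr$tp_baseline, best_day = lr$best_day,
      tp_best_day = lr$tp_best_day,
      learning_percent = lr$learning_percent, stringsAsFactors = FALSE)
    pd <- lr$per_day_tp
    pd$subject <- config$subject
    pd$context <- ctx
    per_day_rows[[ctx]] <- pd
    # first-training-day binned curve
    t1 <- .subset_phase(ctx_bs, "T1")
    curves[[ctx]] <- binned_learning_curve(t1, branch, target,
                                           bin_size = an$bin_size)
    .log_info("context ", ctx, ": learning ",
              round(lr$learning_percent, 1), "% (best day ", lr$best_day,
              ", ", sum(pd$n_renditions[pd$catch_only]),
              " catch renditions used)", quiet = quiet)
  }
  learning <- do.call(rbind, learning_rows)
  rownames(learning) <- NULL
  per_day <- do.call(rbind, per_day_rows)
  rownames(per_day) <- NULL

  common_bin <- last_complete_bin(curves)
  curve_tab <- do.call(rbind, lapply(names(curves), function(ctx) {
    cv <- curves[[ctx]]
    cv$context <- ctx
    cv$common_bin <- cv$bin == common_bin
    cv
  }))

  # learning at the end of T1, read at the common bin, and relative speed
  rate_rows <- list()
  speed_rows <- list()
  entropy_rows <- list()
  early_rows <- list()
  for (ctx in contexts) {
    ctx_bs <- subset_context(bs, ctx)
    sched_ctx <- schedule[schedule$context == ctx, ]
    full_days <- sched_ctx[sched_ctx$phase %in%
                             c("BS", paste0("T", 1:5)), ]
    rates <- vapply(seq_len(nrow(full_days)), function(i) {
      song_rate(ctx_bs, full_days$date[i], an$rate_window[1],
                an$rate_window[2])
    }, 0)
    rate_rows[[ctx]] <- data.frame(
      subject = config$subject, context = ctx, phase = full_days$phase,
      date = full_days$date, n_bouts = rates, stringsAsFactors = FALSE)
    bs_phase <- .subset_phase(ctx_bs, "BS")
    dur <- chunk_durations(bs_phase, unlist(an$chunk))
    speed_rows[[ctx]] <- data.frame(
      subject = config$subject, context = ctx,
      n_chunks = length(dur),
      mean_duration_s = if (length(dur) > 0) mean(dur) else NA_real_,
      sd_duration_s = if (length(dur) > 1) stats::sd(dur) else NA_real_,
      stringsAsFactors = FALSE)
    es <- mean_transition_entropy(bs_phase, log_base = an$entropy_log_base)
    entropy_rows[[ctx]] <- data.frame(
      subject = config$subject, context = ctx,
      bout_index = seq_along(es$per_bout_te), te = es$per_bout_te,
      log_base = an$entropy_log_base, stringsAsFactors = FALSE)
    cv <- curves[[ctx]]
    tp_bin <- cv$tp_target[cv$bin == common_bin]
    lr_pct <- learning$learning_percent[learning$context == ctx]
    total_rate <- sum(rate_rows[[ctx]]$n_bouts)
    early_rows[[ctx]] <- data.frame(
      subject = config$subject, context = ctx, common_bin = common_bin,
      tp_common_bin = tp_bin,
      early_learning_percent = degree_of_learning(
        learning$tp_baseline[learning$context == ctx], tp_bin),
      total_song_rate = total_rate,
      relative_learning_speed = relative_learning_speed(lr_pct, total_rate),
      stringsAsFactors = FALSE)
  }
  song_rate_tab <- do.call(rbind, rate_rows)
  song_speed_tab <- do.call(rbind, speed_rows)
  entropy_tab <- do.call(rbind, entropy_rows)
  early_tab <- do.call(rbind, early_rows)
  rownames(song_rate_tab) <- rownames(song_speed_tab) <-
    rownames(entropy_tab) <- rownames(early_tab) <- NULL

  # per-context proportion test: baseline vs best training day target counts
  prop_tests <- list()
  for (ctx in contexts) {
    ctx_bs <- subset_context(bs, ctx)
    tt_bs <- transition_table(.subset_phase(ctx_bs, "BS"), branch)
    best <- learning$best_day[learning$context == ctx]
    tt_best <- transition_table(.subset_phase(ctx_bs, best), branch,
                                catch_only = TRUE)
    k1 <- if (is.na(tt_bs$counts[target])) 0L else tt_bs$counts[[target]]
    k2 <- if (is.na(tt_best$counts[target])) 0L else tt_best$counts[[target]]
    prop_tests[[ctx]] <- two_proportion_test(
      k1, tt_bs$n_renditions, k2, tt_best$n_renditions,
      groups = c("BS", best))
  }
  write_test_results(prop_tests, file.path(out_dir, "proportion_tests.csv"))

  utils::write.csv(learning, file.path(out_dir, "learning.csv"),
                   row.names = FALSE)
  utils::write.csv(per_day, file.path(out_dir, "per_day_tp.csv"),
                   row.names = FALSE)
  utils::write.csv(curve_tab, file.path(out_dir, "binned_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(song_rate_tab, file.path(out_dir, "song_rate.csv"),
                   row.names = FALSE)
  utils::write.csv(song_speed_tab, file.path(out_dir, "song_speed.csv"),
                   row.names = FALSE)
  utils::write.csv(entropy_tab, file.path(out_dir, "entropy.csv"),
                   row.names = FALSE)
  utils::write.csv(early_tab, file.path(out_dir, "early_learning.csv"),
                   row.names = FALSE)
  manifest <- list(subject = config$subject, seed = config$seed,
                   config_hash = .config_hash(config),
                   data_dir = normalizePath(data_dir),
                   files_excluded = n_excl,
                   days_excluded_low_accuracy =
                     sum(targeting$excluded))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(learning = learning, per_day_tp = per_day,
                 binned_curves = curve_tab, song_rate = song_rate_tab,
                 song_speed = song_speed_tab, entropy = entropy_tab,
                 early_learning = early_tab, targeting = targeting))
}

#' Summarize analysis results
#'
#' Builds one summary table per figure-level result from the CSVs written by
#' [cmd_analyze()]: learning by context, learning by training order,
#' first-day binned curves, song rate by context, song speed by context, and
#' transition entropy by context. No new quantities are computed here; every
#' number is read from a results CSV.
#'
#' @param results_dir Results directory from [cmd_analyze()].
#' @param quiet Suppress printing of the tables.
#' @return Named list of the six summary data frames, invisibly.
#' @export
cmd_report <- function(results_dir, quiet = FALSE) {
  need <- c("learning.csv", "per_day_tp.csv", "binned_curves.csv",
            "song_rate.csv", "song_speed.csv", "entropy.csv")
  have <- file.exists(file.path(results_dir, need))
  if (!any(have)) stop("no analysis results found in ", results_dir)
  if (!all(have)) {
    warning("partial results: missing ",
            paste(need[!have], collapse = ", "))
  }
  rd <- function(f) utils::read.csv(file.path(results_dir, f),
                                    stringsAsFactors = FALSE)
  tables <- list()
  if (have[1]) {
    learning <- rd("learning.csv")
    tables$learning_by_context <- learning[
      order(learning$context),
      c("subject", "context", "tp_baseline", "tp_best_day", "best_day",
        "learning_percent")]
    tables$learning_by_order <- learning[
      order(learning$order_index),
      c("subject", "order_index", "context", "learning_percent")]
  }
  if (have[3]) {
    curves <- rd("binned_curves.csv")
    tables$first_day_curves <- curves[
      curves$complete | curves$common_bin,
      c("context", "bin", "tp_target", "n_renditions", "complete",
        "common_bin")]
  }
  if (have[4]) {
    sr <- rd("song_rate.csv")
    agg <- stats::aggregate(n_bouts ~ subject + context, data = sr, FUN = mean)
    names(agg)[names(agg) == "n_bouts"] <- "mean_bouts_per_day"
    tables$song_rate_by_context <- agg
  }
  if (have[5]) tables$song_speed_by_context <- rd("song_speed.csv")
  if (have[6]) {
    te <- rd("entropy.csv")
    agg <- stats::aggregate(te ~ subject + context, data = te, FUN = mean)
    names(agg)[names(agg) == "te"] <- "mean_te"
    tables$entropy_by_context <- agg
  }
  if (!quiet) {
    for (nm in names(tables)) {
      cat("\n== ", nm, " ==\n", sep = "")
      print(tables[[nm]], row.names = FALSE, digits = 4)
    }
  }
  invisible(tables)
}
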