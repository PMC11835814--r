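#' Transition table at a branch point
#'
#' Counts every occurrence of the branch syllable across the given bouts and
#' tabulates its immediate successor, with the end of a bout (`"END"`)
#' counted as an outcome in its own right. Probabilities are relative
#' frequencies. With `catch_only = TRUE` only renditions flagged as catch
#' trials (feedback withheld) enter the table; this requires an attached
#' feedback log (see [attach_feedback()]).
#'
#' @param bs A `bout_set`.
#' @param branch_syllable Branch-point syllable label.
#' @param catch_only Restrict to catch-trial renditions. Default `FALSE`.
#' @param include_end Count bout-final branch renditions as `"END"`
#'   outcomes. Default `TRUE`; when `FALSE` they are dropped.
#' @return An object of class `transition_table`: list with
#'   `branch_syllable`, `counts` (named integer), `probabilities`,
#'   `n_renditions`, `catch_only`. With zero renditions, `probabilities`
#'   is `NA` and the table is flagged `undefined`.
#' @export
transition_table <- function(bs, branch_syllable, catch_only = FALSE,
                             include_end = TRUE) {
  rend <- branch_renditions(bs, branch_syllable)
  if (catch_only) {
    if (all(is.na(rend$is_catch)) && nrow(rend) > 0) {
      stop("catch_only = TRUE requires catch flags; attach a feedback log")
    }
    rend <- rend[!is.na(rend$is_catch) & rend$is_catch, , drop = FALSE]
  }
  if (!include_end) rend <- rend[rend$outcome != "END", , drop = FALSE]
  counts <- table(rend$outcome)
  counts <- stats::setNames(as.integer(counts), names(counts))
  n <- sum(counts)
  probs <- if (n > 0) counts / n else stats::setNames(numeric(0), character(0))
  structure(list(branch_syllable = branch_syllable, counts = counts,
                 probabilities = probs, n_renditions = n,
                 catch_only = catch_only, undefined = n == 0),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat("transition_table from '", x$branch_syllable, "' (n = ",
      x$n_renditions, if (x$catch_only) ", catch trials only" else "",
      ")\n", sep = "")
  if (x$undefined) {
    cat("  no renditions; probabilities undefined\n")
  } else {
    print(round(x$probabilities, 4))
  }
  invisible(x)
}

#' Probability of one outcome in a transition table
#'
#' Convenience accessor; returns 0 for an outcome never observed and `NA`
#' for an undefined (empty) table.
#'
#' @param tt A `transition_table`.
#' @param outcome Outcome token (successor label or `"END"`).
#' @return Numeric probability.
#' @export
tp_to <- function(tt, outcome) {
  stopifnot(inherits(tt, "transition_table"))
  if (tt$undefined) return(NA_real_)
  p <- tt$probabilities[outcome]
  if (is.na(p)) 0 else unname(p)
}

#' Degree of learning from baseline and best-day transition probabilities
#'
#' Learning, in percent, is the reduction of the target-branch transition
#' probability on the best training day relative to baseline screening:
#' `100 - (tp_best / tp_baseline * 100)`. Negative values indicate an
#' increase (worsening).
#'
#' @param tp_baseline Target TP during baseline screening; must be > 0.
#' @param tp_best Target TP on the best day of training.
#' @return Learning in percent.
#' @export
degree_of_learning <- function(tp_baseline, tp_best) {
  if (!is.finite(tp_baseline) || tp_baseline <= 0) {
    stop("degree of learning is undefined for a zero baseline ",
         "transition probability")
  }
  100 - (tp_best / tp_baseline * 100)
}

#' Best training day: minimum catch-trial transition probability
#'
#' Among the training days (phases `T1..T5`), returns the one with the
#' lowest transition probability to the target; ties are broken in favor of
#' the earliest day.
#'
#' @param per_day_tp Named numeric vector of target TPs keyed by phase
#'   label, or the `per_day_tp` data frame of a [learning_result()].
#' @return The phase label of the best training day.
#' @export
best_training_day <- function(per_day_tp) {
  if (is.data.frame(per_day_tp)) {
    per_day_tp <- stats::setNames(per_day_tp$tp_target, per_day_tp$phase)
  }
  tr <- per_day_tp[grepl("^T[0-9]$", names(per_day_tp))]
  tr <- tr[is.finite(tr)]
  if (length(tr) == 0) stop("no training day with renditions")
  tr <- tr[order(as.integer(sub("^T", "", names(tr))))]
  names(tr)[which.min(tr)]   # which.min takes the first (earliest) minimum
}

#' Per-bout transition entropy
#'
#' Within one bout, every syllable position emits a transition to its
#' successor (the final position transitions to `"END"`). For each syllable
#' type `b` the Shannon entropy `H_b` of its successor distribution is
#' computed, and the bout's transition entropy is the frequency-weighted sum
#' `TE = sum_b H_b P(b)`, where `P(b)` is the fraction of transitions
#' emitted by `b`. A fully stereotyped bout has `TE = 0`.
#'
#' @param bout Character vector of syllable labels in production order, or a
#'   `song_bout` from [sample_bout()].
#' @param log_base Logarithm base for the entropy, 2 (bits, default) or
#'   `exp(1)` (nats).
#' @param include_end Count the final transition to `"END"`. Default `TRUE`.
#' @return Non-negative transition entropy.
#' @export
bout_transition_entropy <- function(bout, log_base = 2, include_end = TRUE) {
  labels <- if (inherits(bout, "song_bout")) bout$labels else bout
  stopifnot(is.character(labels), length(labels) >= 1)
  from <- labels
  to <- c(labels[-1], "END")
  if (!include_end) {
    from <- from[-length(from)]
    to <- to[-length(to)]
    if (length(from) == 0) return(0)
  }
  n <- length(from)
  te <- 0
  for (b in unique(from)) {
    succ <- to[from == b]
    p_out <- table(succ) / length(succ)
    h_b <- -sum(p_out * log(p_out, base = log_base))
    te <- te + h_b * (length(succ) / n)
  }
  te
}

#' Mean transition entropy over bouts
#'
#' Computes the per-bout transition entropy for every bout in the set and
#' averages. The log base is recorded in the result.
#'
#' @param bs A `bout_set` (or list of label vectors / `song_bout`s).
#' @param log_base Entropy logarithm base (default 2).
#' @param include_end Count transitions to the end of the bout.
#' @return An object of class `entropy_summary`: list with `per_bout_te`,
#'   `mean_te`, `log_base`, and `bout_id` when available.
#' @export
mean_transition_entropy <- function(bs, log_base = 2, include_end = TRUE) {
  if (inherits(bs, "bout_set")) {
    if (nrow(bs$bouts) == 0) stop("empty bout set")
    lab <- split(bs$events$label, bs$events$bout_id)
    lab <- lab[bs$bouts$bout_id]
    ids <- bs$bouts$bout_id
  } else {
    if (length(bs) == 0) stop("empty bout list")
    lab <- lapply(bs, function(b) if (inherits(b, "song_bout")) b$labels else b)
    ids <- as.character(seq_along(lab))
  }
  te <- vapply(lab, bout_transition_entropy, 0,
               log_base = log_base, include_end = include_end)
  structure(list(per_bout_te = unname(te), mean_te = mean(te),
                 log_base = log_base, bout_id = ids),
            class = "entropy_summary")
}

#' @export
print.entropy_summary <- function(x, ...) {
  cat("entropy_summary:", length(x$per_bout_te), "bouts, mean TE",
      format(x$mean_te, digits = 4),
      if (x$log_base == 2) "bits" else "nats", "\n")
  invisible(x)
}

#' Song rate: bouts begun within a daily clock window
#'
#' Counts bouts whose start time falls on the given day within the half-open
#' clock window `[window_start, window_end)`, by default 09:30 to 17:00.
#'
#' @param bs A `bout_set`.
#' @param day `Date` (or string) of interest.
#' @param window_start,window_end Clock times `"HH:MM"` (or `"HH:MM:SS"`).
#' @return Integer bout count.
#' @export
song_rate <- function(bs, day, window_start = "09:30",
                      window_end = "17:00") {
  stopifnot(inherits(bs, "bout_set"))
  day <- as.Date(day)
  lo <- as.POSIXct(paste(day, .pad_hms(window_start)), tz = "UTC")
  hi <- as.POSIXct(paste(day, .pad_hms(window_end)), tz = "UTC")
  sum(bs$bouts$bout_start >= lo & bs$bouts$bout_start < hi)
}

.pad_hms <- function(x) {
  if (grepl("^[0-9]{1,2}:[0-9]{2}$", x)) paste0(x, ":00") else x
}

#' Durations of a fixed syllable sequence (chunk) within bouts
#'
#' Finds exact, leftmost, non-overlapping occurrences of the token sequence
#' `chunk` inside each bout and returns, for each occurrence, the time from
#' the onset of its first syllable to the offset of its last. The measure
#' deliberately includes the silent gaps inside the chunk, so it reflects
#' overall song speed.
#'
#' @param bs A `bout_set`.
#' @param chunk Character vector of at least two syllable labels.
#' @return Numeric vector of durations in seconds (empty if the chunk never
#'   occurs).
#' @export
chunk_durations <- function(bs, chunk) {
  stopifnot(inherits(bs, "bout_set"), length(chunk) >= 2)
  ev <- bs$events
  idx_by_bout <- split(seq_len(nrow(ev)), ev$bout_id)
  out_l <- lapply(idx_by_bout, function(idx) {
    starts <- .match_chunk(ev$label[idx], chunk)
    if (length(starts) == 0) return(numeric(0))
    ev$offset_s[idx][starts + length(chunk) - 1L] - ev$onset_s[idx][starts]
  })
  out <- unlist(out_l)
  if (is.null(out)) numeric(0) else unname(out)
}

# Leftmost non-overlapping exact matches of `chunk` in `labels`;
# returns start indices.
.match_chunk <- function(labels, chunk) {
  k <- length(chunk)
  n <- length(labels)
  starts <- integer(0)
  i <- 1L
  while (i <= n - k + 1L) {
    if (all(labels[i:(i + k - 1L)] == chunk)) {
      starts <- c(starts, i)
      i <- i + k            # non-overlapping: jump past the match
    } else {
      i <- i + 1L
    }
  }
  starts
}

#' Binned learning curve within a training day
#'
#' Splits the chronologically ordered bouts into consecutive bins of
#' `bin_size` bouts (default 50) and computes the target-branch transition
#' probability within each bin from all renditions in that bin. A trailing
#' bin with fewer than `bin_size` bouts is reported but flagged incomplete.
#'
#' @param bs A `bout_set`, assumed chronologically ordered (as produced by
#'   [segment_bouts()]).
#' @param branch_syllable Branch-point syllable.
#' @param target_branch Target outcome token.
#' @param bin_size Bouts per bin; default 50.
#' @return Data frame `bin`, `tp_target`, `n_renditions`, `n_bouts`,
#'   `complete`.
#' @export
binned_learning_curve <- function(bs, branch_syllable, target_branch,
                                  bin_size = 50) {
  stopifnot(inherits(bs, "bout_set"), bin_size >= 1)
  ids <- bs$bouts$bout_id
  if (length(ids) == 0) {
    return(data.frame(bin = integer(0), tp_target = numeric(0),
                      n_renditions = integer(0), n_bouts = integer(0),
                      complete = logical(0)))
  }
  bin_of_bout <- stats::setNames(((seq_along(ids) - 1L) %/% bin_size) + 1L,
                                 ids)
  rend <- branch_renditions(bs, branch_syllable)
  rend$bin <- bin_of_bout[rend$bout_id]
  n_bins <- max(bin_of_bout)
  out <- data.frame(bin = seq_len(n_bins))
  out$tp_target <- NA_real_
  out$n_renditions <- 0L
  for (b in seq_len(n_bins)) {
    rb <- rend[rend$bin == b, , drop = FALSE]
    out$n_renditions[b] <- nrow(rb)
    if (nrow(rb) > 0) {
      out$tp_target[b] <- mean(rb$outcome == target_branch)
    }
  }
  out$n_bouts <- as.integer(table(factor(bin_of_bout, levels = seq_len(n_bins))))
  out$complete <- out$n_bouts == bin_size
  out
}

#' Common early-learning bin across contexts
#'
#' To compare early learning across social contexts with different song
#' rates, the curve is read at the last complete bin of the context with the
#' fewest first-day bouts, and that same bin index is used for every other
#' context.
#'
#' @param curves Named list (one element per context) of binned curves from
#'   [binned_learning_curve()].
#' @return Integer bin index.
#' @export
last_complete_bin <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1)
  n_bouts <- vapply(curves, function(cv) sum(cv$n_bouts), 0)
  ref <- names(curves)[which.min(n_bouts)]
  idx <- max(c(0L, curves[[ref]]$bin[curves[[ref]]$complete]))
  if (idx == 0L) stop("context ", ref, " has no complete bin")
  for (ctx in names(curves)) {
    cv <- curves[[ctx]]
    if (!any(cv$bin == idx & cv$complete)) {
      stop("context ", ctx, " lacks complete bin ", idx)
    }
  }
  idx
}

#' Relative speed of learning
#'
#' Degree of learning divided by total song rate, expressing how much
#' sequence change the bird achieved per song bout produced.
#'
#' @param learning_percent Degree of learning in percent.
#' @param total_song_rate Total bout count over the relevant period; > 0.
#' @return `learning_percent / total_song_rate`.
#' @export
relative_learning_speed <- function(learning_percent, total_song_rate) {
  if (!is.finite(total_song_rate) || total_song_rate <= 0) {
    stop("total_song_rate must be positive")
  }
  learning_percent / total_song_rate
}

#' White-noise targeting accuracy
#'
#' From a feedback log with per-rendition outcomes and delivery flags,
#' classifies each non-catch rendition as a correct hit (target outcome,
#' noise delivered), a miss (target outcome, no noise) or a false positive
#' (non-target outcome, noise delivered), and reports
#' `hits / (hits + false positives + misses) * 100`. Days below the
#' exclusion threshold (75% by default) are flagged for removal from the
#' learning analysis. Catch trials never enter the denominator.
#'
#' @param feedback Feedback log data frame with columns `outcome`,
#'   `is_catch`, `wn_delivered`.
#' @param target_branch Target outcome token.
#' @param threshold Exclusion threshold in percent; default 75.
#' @return List `accuracy` (percent, `NA` if the denominator is empty),
#'   `hits`, `false_positives`, `misses`, `excluded` (logical),
#'   `undefined` (logical).
#' @export
targeting_accuracy <- function(feedback, target_branch, threshold = 75) {
  fbnc <- feedback[!feedback$is_catch, , drop = FALSE]
  on_target <- fbnc$outcome == target_branch
  hits <- sum(on_target & fbnc$wn_delivered)
  misses <- sum(on_target & !fbnc$wn_delivered)
  fp <- sum(!on_target & fbnc$wn_delivered)
  denom <- hits + misses + fp
  if (denom == 0) {
    return(list(accuracy = NA_real_, hits = 0L, false_positives = 0L,
                misses = 0L, excluded = FALSE, undefined = TRUE))
  }
  acc <- hits / denom * 100
  list(accuracy = acc, hits = hits, false_positives = fp, misses = misses,
       excluded = acc < threshold, undefined = FALSE)
}

#' Quantify learning for one social context
#'
#' The full learning computation for one context block of an experiment:
#' the baseline target transition probability from all baseline-screening
#' renditions, per-day catch-trial probabilities on training days (feedback
#' is withheld on catch trials, so these measure learning uncontaminated by
#' the stimulus), all-rendition probabilities on post-screen days, the best
#' (lowest-probability) training day, and the resulting degree of learning.
#'
#' @param bs A `bout_set` restricted to one context, with phases assigned
#'   (see [assign_schedule()]) and a feedback log attached.
#' @param branch_syllable Branch-point syllable.
#' @param target_branch Targeted outcome token.
#' @param excluded_phases Phases to drop (e.g. training days failing the
#'   targeting-accuracy criterion).
#' @return An object of class `learning_result`: list with `tp_baseline`,
#'   `per_day_tp` (data frame `phase`, `tp_target`, `n_renditions`,
#'   `catch_only`), `best_day`, `tp_best_day`, `learning_percent`.
#' @export
learning_result <- function(bs, branch_syllable, target_branch,
                            excluded_phases = NULL) {
  stopifnot(inherits(bs, "bout_set"))
  phases <- unique(stats::na.omit(bs$bouts$phase))
  if (!("BS" %in% phases)) stop("missing baseline screening (BS) bouts")
  if (!any(grepl("^T[0-9]$", phases))) stop("missing training-day bouts")
  phases <- setdiff(phases, excluded_phases)
  phases <- phases[order(match(phases, .phase_levels()))]
  rows <- lapply(phases, function(ph) {
    sub <- .subset_phase(bs, ph)
    catch_only <- grepl("^T[0-9]$", ph)
    tt <- transition_table(sub, branch_syllable, catch_only = catch_only)
    data.frame(phase = ph,
               tp_target = if (tt$undefined) NA_real_ else
                 tp_to(tt, target_branch),
               n_renditions = tt$n_renditions,
               catch_only = catch_only, stringsAsFactors = FALSE)
  })
  per_day <- do.call(rbind, rows)
  tp_baseline <- per_day$tp_target[per_day$phase == "BS"]
  best <- best_training_day(stats::setNames(per_day$tp_target,
                                            per_day$phase))
  tp_best <- per_day$tp_target[per_day$phase == best]
  structure(list(tp_baseline = tp_baseline, per_day_tp = per_day,
                 best_day = best, tp_best_day = tp_best,
                 learning_percent = degree_of_learning(tp_baseline, tp_best)),
            class = "learning_result")
}

.phase_levels <- function() c("BS", paste0("T", 1:5), paste0("PS", 1:3))

.subset_phase <- function(bs, phase) {
  keep <- !is.na(bs$bouts$phase) & bs$bouts$phase == phase
  bt <- bs$bouts[keep, , drop = FALSE]
  ev <- bs$events[bs$events$bout_id %in% bt$bout_id, , drop = FALSE]
  .new_bout_set(ev, bt, bs$gap_threshold, bs$feedback)
}

#' Restrict a bout set to one social context
#'
#' @param bs A `bout_set` with contexts assigned.
#' @param context Context label (`"MA"`, `"MF"`, `"MM"`).
#' @return The restricted `bout_set`.
#' @export
subset_context <- function(bs, context) {
  stopifnot(inherits(bs, "bout_set"))
  keep <- !is.na(bs$bouts$context) & bs$bouts$context == context
  bt <- bs$bouts[keep, , drop = FALSE]
  ev <- bs$events[bs$events$bout_id %in% bt$bout_id, , drop = FALSE]
  .new_bout_set(ev, bt, bs$gap_threshold, bs$feedback)
}

#' @export
print.learning_result <- function(x, ...) {
  cat("learning_result: baseline TP", format(x$tp_baseline, digits = 3),
      "-> best day", x$best_day, "TP", format(x$tp_best_day, digits = 3),
      "; learning", format(x$learning_percent, digits = 3), "%\n")
  invisible(x)
}
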