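#' Generative model of variable song syntax
#'
#' Defines a first-order Markov model of song: a repertoire of syllable
#' tokens, a row-stochastic transition matrix over tokens plus the absorbing
#' `END` outcome, a designated branch-point syllable with a targeted branch,
#' and Gaussian syllable/gap duration parameters. This is the generative core
#' of the experiment simulator, not a fit to any particular bird.
#'
#' @param repertoire Character vector of syllable tokens.
#' @param transitions Named list: for each token, a named numeric vector of
#'   outcome probabilities over `repertoire` and `"END"`. Each row must sum
#'   to 1 within 1e-9.
#' @param branch_syllable Token at which outcomes branch.
#' @param target_branch Outcome token targeted with white noise; must have
#'   nonzero initial probability after `branch_syllable`.
#' @param start_token Token that begins every bout (introductory note).
#' @param syl_dur_mean,syl_dur_sd Syllable duration mean and sd, seconds.
#' @param gap_dur_mean,gap_dur_sd Within-bout silent gap mean and sd, seconds.
#' @param max_bout_length Hard cap on events per bout.
#' @return An object of class `song_model`.
#' @export
song_model <- function(repertoire, transitions, branch_syllable,
                       target_branch, start_token = repertoire[1],
                       syl_dur_mean = 0.08, syl_dur_sd = 0.01,
                       gap_dur_mean = 0.06, gap_dur_sd = 0.01,
                       max_bout_length = 400L) {
  stopifnot(is.character(repertoire), length(repertoire) >= 1,
            branch_syllable %in% repertoire,
            start_token %in% repertoire,
            syl_dur_mean > 0, gap_dur_mean > 0,
            syl_dur_sd >= 0, gap_dur_sd >= 0, max_bout_length >= 1)
  outcomes <- c(repertoire, "END")
  P <- matrix(0, nrow = length(repertoire), ncol = length(outcomes),
              dimnames = list(repertoire, outcomes))
  for (tok in names(transitions)) {
    if (!tok %in% repertoire) stop("transition row for unknown token: ", tok)
    row <- transitions[[tok]]
    if (!all(names(row) %in% outcomes)) {
      stop("unknown outcome in row '", tok, "': ",
           paste(setdiff(names(row), outcomes), collapse = ", "))
    }
    P[tok, names(row)] <- row
  }
  .check_stochastic(P)
  if (P[branch_syllable, target_branch] <= 0) {
    stop("target_branch '", target_branch,
         "' has zero initial probability after '", branch_syllable, "'")
  }
  structure(list(repertoire = repertoire, transition = P,
                 branch_syllable = branch_syllable,
                 target_branch = target_branch, start_token = start_token,
                 syl_dur_mean = syl_dur_mean, syl_dur_sd = syl_dur_sd,
                 gap_dur_mean = gap_dur_mean, gap_dur_sd = gap_dur_sd,
                 max_bout_length = as.integer(max_bout_length)),
            class = "song_model")
}

.check_stochastic <- function(P, tol = 1e-9) {
  s <- rowSums(P)
  if (any(abs(s - 1) > tol) || any(P < 0)) {
    stop("non-stochastic transition row(s): ",
         paste(rownames(P)[abs(s - 1) > tol | apply(P < 0, 1, any)],
               collapse = ", "))
  }
  invisible(P)
}

#' @export
print.song_model <- function(x, ...) {
  cat("song_model:", length(x$repertoire), "tokens, branch '",
      x$branch_syllable, "' -> target '", x$target_branch, "' (p = ",
      format(x$transition[x$branch_syllable, x$target_branch], digits = 3),
      ")\n", sep = "")
  invisible(x)
}

#' Default four-token song model
#'
#' A compact Bengalese-finch-like syntax: an introductory note `i`, a
#' branch-point syllable `x` whose outcomes are the targeted branch `a`
#' (p = 0.80), the alternative branch `l` (p = 0.19), or the end of the bout
#' (p = 0.01), with both branches looping back to `x`. Bouts are long
#' (around fifty branch renditions on average), as Bengalese bouts run to
#' hundreds of syllables.
#'
#' @return A `song_model`.
#' @export
default_song_model <- function() {
  song_model(
    repertoire = c("i", "x", "a", "l"),
    transitions = list(
      i = c(x = 1),
      x = c(a = 0.80, l = 0.19, END = 0.01),
      a = c(x = 0.99, END = 0.01),
      l = c(x = 0.99, END = 0.01)),
    branch_syllable = "x", target_branch = "a", start_token = "i")
}

#' Social-context profile
#'
#' Captures the context dependence of song output: how much the bird sings
#' (`bouts_per_day_mean`), how fast (`tempo_factor` multiplies syllable and
#' gap durations; values below 1 mean faster song), and how stereotyped the
#' sequencing is (`entropy_factor` interpolates every transition row toward
#' its modal outcome; 0 leaves the syntax unchanged, 1 makes it
#' deterministic).
#'
#' @param context One of `"MA"`, `"MF"`, `"MM"`.
#' @param bouts_per_day_mean Mean bouts sung per day; positive.
#' @param tempo_factor Positive multiplicative duration scaling.
#' @param entropy_factor Determinism interpolation weight in \[0, 1\].
#' @return An object of class `context_profile`.
#' @export
context_profile <- function(context, bouts_per_day_mean = 200,
                            tempo_factor = 1, entropy_factor = 0) {
  stopifnot(context %in% c("MA", "MF", "MM"),
            bouts_per_day_mean > 0, tempo_factor > 0,
            entropy_factor >= 0, entropy_factor <= 1)
  structure(list(context = context,
                 bouts_per_day_mean = bouts_per_day_mean,
                 tempo_factor = tempo_factor,
                 entropy_factor = entropy_factor),
            class = "context_profile")
}

#' Default context profiles
#'
#' Singing rate is markedly reduced and tempo slightly increased in the
#' social contexts relative to the single-housed condition; sequencing
#' entropy is left unchanged across contexts.
#'
#' @return Named list of [context_profile()] objects for MA, MF and MM.
#' @export
default_context_profiles <- function() {
  list(MA = context_profile("MA", bouts_per_day_mean = 200,
                            tempo_factor = 1.00, entropy_factor = 0),
       MF = context_profile("MF", bouts_per_day_mean = 140,
                            tempo_factor = 0.98, entropy_factor = 0),
       MM = context_profile("MM", bouts_per_day_mean = 140,
                            tempo_factor = 0.97, entropy_factor = 0))
}

#' White-noise feedback model
#'
#' Event-level model of the real-time template matcher: when the target
#' branch is sung on a non-catch rendition, white noise is delivered with
#' probability `hit_rate`; non-target outcomes trigger spurious noise with
#' probability `false_positive_rate`. A fixed fraction of renditions are
#' catch trials on which feedback is always withheld.
#'
#' @param hit_rate P(WN | target outcome, not catch).
#' @param false_positive_rate P(WN | non-target outcome, not catch).
#' @param catch_fraction P(rendition is a catch trial). Default 0.10.
#' @param wn_duration White-noise burst duration in seconds. Default 0.040.
#' @return An object of class `feedback_model`.
#' @export
feedback_model <- function(hit_rate = 0.93, false_positive_rate = 0.02,
                           catch_fraction = 0.10, wn_duration = 0.040) {
  p <- c(hit_rate, false_positive_rate, catch_fraction)
  stopifnot(all(p >= 0 & p <= 1), wn_duration > 0)
  structure(list(hit_rate = hit_rate,
                 false_positive_rate = false_positive_rate,
                 catch_fraction = catch_fraction,
                 wn_duration = wn_duration),
            class = "feedback_model")
}

#' Reinforcement-learning dynamics of the target transition
#'
#' Each white-noise experience on the target branch multiplicatively
#' decrements the target transition probability,
#' p <- max(floor, p (1 - learning_rate)), with the removed mass
#' redistributed proportionally over the non-target outcomes so the row
#' remains stochastic. On days without feedback the probability drifts back
#' toward baseline at `relaxation_rate` per calendar day.
#'
#' @param learning_rate Per-experience decrement in \[0, 1).
#' @param floor Minimum attainable target probability.
#' @param relaxation_rate Per-day fractional return toward baseline when
#'   feedback is off.
#' @return An object of class `learning_dynamics`.
#' @export
learning_dynamics <- function(learning_rate = 0.05, floor = 0.40,
                              relaxation_rate = 0.12) {
  stopifnot(learning_rate >= 0, learning_rate < 1,
            floor >= 0, floor < 1,
            relaxation_rate >= 0, relaxation_rate <= 1)
  structure(list(learning_rate = learning_rate, floor = floor,
                 relaxation_rate = relaxation_rate),
            class = "learning_dynamics")
}

#' Build a per-subject experiment schedule
#'
#' One block per social context, in the given order: one baseline-screening
#' day (BS), 4-5 training days (T1..T5), a post-screening day immediately
#' after training (PS1) and further screens roughly one and two weeks after
#' the end of training (PS2, PS3). Blocks are separated by a return to the
#' aviary.
#'
#' @param subject Subject identifier.
#' @param context_order Permutation of `c("MA","MF","MM")`.
#' @param start_date First BS day (`Date` or string).
#' @param training_days Number of training days per block, 4 or 5 (recycled
#'   across contexts).
#' @return Data frame `subject`, `context`, `order_index`, `phase`, `date`.
#' @export
experiment_schedule <- function(subject, context_order = c("MA", "MF", "MM"),
                                start_date = "2024-01-01",
                                training_days = 4) {
  stopifnot(setequal(context_order, c("MA", "MF", "MM")),
            length(context_order) == 3)
  training_days <- rep_len(training_days, 3)
  if (!all(training_days %in% 4:5)) stop("training spans 4-5 days")
  d <- as.Date(start_date)
  rows <- list()
  for (k in 1:3) {
    nt <- training_days[k]
    phases <- c("BS", paste0("T", seq_len(nt)), "PS1", "PS2", "PS3")
    t_last <- d + nt                       # date of last training day
    dates <- c(d, d + seq_len(nt), t_last + 1, t_last + 7, t_last + 14)
    rows[[k]] <- data.frame(subject = subject, context = context_order[k],
                            order_index = k, phase = phases, date = dates,
                            stringsAsFactors = FALSE)
    d <- t_last + 16                       # next BS after return to aviary
  }
  do.call(rbind, rows)
}

# ---- sampling ----------------------------------------------------------

# Context-adjusted transition matrix: interpolate every row toward its modal
# outcome by entropy_factor.
.adjust_matrix <- function(P, entropy_factor) {
  if (entropy_factor == 0) return(P)
  for (i in seq_len(nrow(P))) {
    row <- P[i, ]
    mode <- which.max(row)
    det <- numeric(length(row))
    det[mode] <- 1
    P[i, ] <- (1 - entropy_factor) * row + entropy_factor * det
  }
  P
}

# Markov walk over precomputed row cumulative sums. Returns integer token
# indices (columns of P), excluding END.
.sample_token_path <- function(cum, start_idx, n_tokens, max_len) {
  path <- integer(max_len)
  path[1] <- start_idx
  i <- 1L
  u <- stats::runif(max_len)
  while (i < max_len) {
    nxt <- findInterval(u[i], cum[path[i], ]) + 1L
    if (nxt > n_tokens) break  # END
    i <- i + 1L
    path[i] <- nxt
  }
  path[seq_len(i)]
}

#' Sample one song bout from a song model
#'
#' Performs a first-order Markov walk from the model's start token until the
#' `END` outcome or the bout-length cap, draws syllable and gap durations
#' from the model's Gaussian parameters scaled by the context's tempo
#' factor, and records a branch rendition (outcome successor or `"END"`) for
#' every occurrence of the branch syllable.
#'
#' @param model A [song_model()].
#' @param profile A [context_profile()]; its `entropy_factor` reshapes the
#'   transition rows and its `tempo_factor` scales durations.
#' @return A `song_bout`: list with `labels`, `onset_s`, `offset_s` (seconds
#'   from bout start) and `renditions` (data frame `position`, `outcome`,
#'   `is_catch`, `wn_delivered`).
#' @export
sample_bout <- function(model, profile = context_profile("MA")) {
  stopifnot(inherits(model, "song_model"), inherits(profile, "context_profile"))
  P <- .adjust_matrix(model$transition, profile$entropy_factor)
  .check_stochastic(P)
  cum <- t(apply(P, 1, cumsum))
  n_tok <- length(model$repertoire)
  path <- .sample_token_path(cum, match(model$start_token, model$repertoire),
                             n_tok, model$max_bout_length)
  labels <- model$repertoire[path]
  n <- length(labels)
  dur <- pmax(0.005, stats::rnorm(n, model$syl_dur_mean, model$syl_dur_sd)) *
    profile$tempo_factor
  gap <- pmax(0.005, stats::rnorm(n, model$gap_dur_mean, model$gap_dur_sd)) *
    profile$tempo_factor
  onset <- cumsum(c(0, dur[-n] + gap[-n]))
  offset <- onset + dur
  pos <- which(labels == model$branch_syllable)
  outcome <- c(labels[-1], "END")[pos]
  rend <- data.frame(position = pos, outcome = outcome,
                     is_catch = rep(NA, length(pos)),
                     wn_delivered = rep(NA, length(pos)),
                     stringsAsFactors = FALSE)
  structure(list(labels = labels, onset_s = onset, offset_s = offset,
                 renditions = rend), class = "song_bout")
}

#' Apply closed-loop feedback to one branch rendition
#'
#' Stochastically flags the rendition as a catch trial, decides white-noise
#' delivery from the feedback model's hit / false-positive rates, and, when
#' noise lands on the target outcome, applies the learning update to the
#' model's branch row (multiplicative decrement with proportional
#' redistribution over the non-target outcomes; see [learning_dynamics()]).
#'
#' @param model A [song_model()].
#' @param rendition One-row data frame with at least `outcome`.
#' @param fb A [feedback_model()].
#' @param dyn A [learning_dynamics()].
#' @return List with the (possibly updated) `model` and the `rendition`
#'   carrying resolved `is_catch` and `wn_delivered` flags.
#' @export
apply_feedback <- function(model, rendition, fb, dyn) {
  stopifnot(inherits(model, "song_model"), inherits(fb, "feedback_model"),
            inherits(dyn, "learning_dynamics"), nrow(rendition) == 1)
  outcome <- rendition$outcome
  is_catch <- stats::runif(1) < fb$catch_fraction
  wn <- FALSE
  if (!is_catch) {
    p_wn <- if (outcome == model$target_branch) fb$hit_rate else
      fb$false_positive_rate
    wn <- stats::runif(1) < p_wn
  }
  if (wn && outcome == model$target_branch && dyn$learning_rate > 0) {
    model$transition <- .update_target_row(model$transition,
                                           model$branch_syllable,
                                           model$target_branch, dyn)
  }
  rendition$is_catch <- is_catch
  rendition$wn_delivered <- wn
  list(model = model, rendition = rendition)
}

# One learning step on the branch row: decrement target, renormalize the
# non-target outcomes proportionally.
.update_target_row <- function(P, branch, target, dyn) {
  row <- P[branch, ]
  p_old <- row[target]
  p_new <- max(dyn$floor, p_old * (1 - dyn$learning_rate))
  if (p_old < 1) {
    scale <- (1 - p_new) / (1 - p_old)
    row <- row * scale
  }
  row[target] <- p_new
  P[branch, ] <- row / sum(row)
  P
}

# Per-day relaxation toward the baseline target probability.
.relax_target <- function(P, P0, branch, target, rate, days) {
  if (rate == 0 || days <= 0) return(P)
  p0 <- P0[branch, target]
  p <- P[branch, target]
  p_new <- p0 - (p0 - p) * (1 - rate)^days
  row <- P[branch, ]
  if (p < 1) row <- row * (1 - p_new) / (1 - p)
  row[target] <- p_new
  P[branch, ] <- row / sum(row)
  P
}

#' Simulate a complete reinforcement-learning experiment
#'
#' Runs the closed loop over a full per-subject schedule: for each scheduled
#' day it draws a dispersed bout count around the context's
#' `bouts_per_day_mean` (negative binomial, size 20), samples bouts from the
#' current transition matrix, and on training days passes every branch
#' rendition through the feedback loop (10% catch trials by default,
#' imperfect hits and false positives, per-experience learning update).
#' Baseline and post-screen days are feedback-free; between feedback-free
#' days the target probability relaxes toward baseline. The learning state
#' resets to the base model at the start of each context block.
#'
#' @param model A [song_model()]; its transition matrix is the baseline.
#' @param schedule Schedule data frame from [experiment_schedule()].
#' @param profiles Named list of [context_profile()] covering every context
#'   in the schedule.
#' @param fb A [feedback_model()].
#' @param dyn A [learning_dynamics()].
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return An object of class `sim_experiment`: list with `events`
#'   (annotation table, one file per bout), `feedback` (feedback log, one
#'   row per training-day rendition), `truth` (per-day programmed target
#'   probability: at day start, `p_start`, and averaged over that day's
#'   renditions, `p_mean`), and the `schedule`.
#' @export
simulate_experiment <- function(model, schedule, profiles = default_context_profiles(),
                                fb = feedback_model(), dyn = learning_dynamics(),
                                seed = 1) {
  stopifnot(inherits(model, "song_model"), inherits(fb, "feedback_model"),
            inherits(dyn, "learning_dynamics"))
  missing_ctx <- setdiff(unique(schedule$context), names(profiles))
  if (length(missing_ctx) > 0) {
    stop("no context profile for: ", paste(missing_ctx, collapse = ", "))
  }
  set.seed(as.integer(seed))
  subject <- schedule$subject[1]
  base_P <- model$transition
  branch <- model$branch_syllable
  target <- model$target_branch
  n_tok <- length(model$repertoire)
  start_idx <- match(model$start_token, model$repertoire)

  ev_acc <- list(); fb_acc <- list(); truth_acc <- list()
  day_seq <- order(schedule$date)
  cur_block <- -1L
  P <- base_P
  last_date <- NULL

  for (ri in day_seq) {
    day <- schedule[ri, ]
    prof <- profiles[[day$context]]
    training <- grepl("^T[0-9]$", day$phase)
    if (day$order_index != cur_block) {      # new context block: fresh bird
      cur_block <- day$order_index
      P <- base_P
      last_date <- NULL
    }
    if (!training && !is.null(last_date)) {
      P <- .relax_target(P, base_P, branch, target, dyn$relaxation_rate,
                         as.numeric(day$date - last_date))
    }
    last_date <- day$date
    p_start <- P[branch, target]

    n_bouts <- max(1L, stats::rnbinom(1, size = 20,
                                      mu = prof$bouts_per_day_mean))
    # bout start times: uniform in the 08:00-18:00 singing window with a
    # guaranteed >= 3 s silent spacing so re-segmentation cannot merge bouts
    day0 <- as.POSIXct(paste(day$date, "08:00:00"), tz = "UTC")
    window_s <- 10 * 3600
    slots <- sort(stats::runif(n_bouts, 0, window_s - 60))

    tempo <- prof$tempo_factor
    P_ctx <- NULL
    P_ctx_cum <- NULL
    labels_l <- vector("list", n_bouts)
    onsets_l <- vector("list", n_bouts)
    offsets_l <- vector("list", n_bouts)
    file_ids <- character(n_bouts)
    file_starts <- numeric(n_bouts)
    t_cursor <- 0
    p_used_sum <- 0; n_rend_day <- 0L; n_catch_day <- 0L
    fb_day <- list()

    for (b in seq_len(n_bouts)) {
      if (is.null(P_ctx_cum)) {
        # the bird sings from the context-adjusted matrix; truth is recorded
        # on the same scale so catch-trial estimates are comparable
        P_ctx <- .adjust_matrix(P, prof$entropy_factor)
        P_ctx_cum <- t(apply(P_ctx, 1, cumsum))
      }
      path <- .sample_token_path(P_ctx_cum, start_idx, n_tok,
                                 model$max_bout_length)
      labels <- model$repertoire[path]
      n <- length(labels)
      dur <- pmax(0.005, stats::rnorm(n, model$syl_dur_mean,
                                      model$syl_dur_sd)) * tempo
      gap <- pmax(0.005, stats::rnorm(n, model$gap_dur_mean,
                                      model$gap_dur_sd)) * tempo
      onset <- cumsum(c(0, dur[-n] + gap[-n]))
      offset <- onset + dur
      start_s <- max(slots[b], t_cursor)
      t_cursor <- start_s + offset[n] + 3     # enforce inter-bout silence
      file_ids[b] <- sprintf("%s_%s_%s_%04d.wav", subject, day$context,
                             format(day$date, "%Y%m%d"), b)
      file_starts[b] <- as.numeric(day0) + start_s
      labels_l[[b]] <- labels
      onsets_l[[b]] <- onset
      offsets_l[[b]] <- offset

      pos <- which(labels == branch)
      if (length(pos) > 0) {
        outcome <- c(labels[-1], "END")[pos]
        p_bout <- P_ctx[branch, target]
        p_used_sum <- p_used_sum + length(pos) * p_bout
        n_rend_day <- n_rend_day + length(pos)
        if (training) {
          nr <- length(pos)
          is_catch <- stats::runif(nr) < fb$catch_fraction
          n_catch_day <- n_catch_day + sum(is_catch)
          on_target <- outcome == target
          wn <- !is_catch &
            stats::runif(nr) < ifelse(on_target, fb$hit_rate,
                                      fb$false_positive_rate)
          n_upd <- sum(wn & on_target)
          if (n_upd > 0 && dyn$learning_rate > 0) {
            for (k in seq_len(n_upd)) {
              P <- .update_target_row(P, branch, target, dyn)
            }
            P_ctx_cum <- NULL                 # matrix changed; rebuild
          }
          fb_day[[length(fb_day) + 1L]] <- list(
            file_id = file_ids[b], bout_index = 1L,
            rendition_index = seq_len(nr), outcome = outcome,
            is_catch = is_catch, wn_delivered = wn)
        }
      }
    }

    n_ev <- lengths(labels_l)
    ev_acc[[length(ev_acc) + 1L]] <- data.frame(
      file_id = rep(file_ids, n_ev),
      file_start = as.POSIXct(rep(file_starts, n_ev), origin = "1970-01-01",
                              tz = "UTC"),
      singer = subject,
      label = unlist(labels_l),
      onset_s = unlist(onsets_l),
      offset_s = unlist(offsets_l),
      stringsAsFactors = FALSE)
    if (length(fb_day) > 0) {
      fb_acc[[length(fb_acc) + 1L]] <- data.frame(
        file_id = rep(vapply(fb_day, `[[`, "", "file_id"),
                      vapply(fb_day, function(z) length(z$rendition_index),
                             0L)),
        bout_index = 1L,
        rendition_index = unlist(lapply(fb_day, `[[`, "rendition_index")),
        outcome = unlist(lapply(fb_day, `[[`, "outcome")),
        is_catch = unlist(lapply(fb_day, `[[`, "is_catch")),
        wn_delivered = unlist(lapply(fb_day, `[[`, "wn_delivered")),
        stringsAsFactors = FALSE)
    }
    truth_acc[[length(truth_acc) + 1L]] <- data.frame(
      date = day$date, phase = day$phase, context = day$context,
      order_index = day$order_index,
      p_start = p_start,
      p_mean = if (n_rend_day > 0) p_used_sum / n_rend_day else p_start,
      n_renditions = n_rend_day, n_catch = n_catch_day,
      n_bouts = n_bouts, stringsAsFactors = FALSE)
  }

  events <- do.call(rbind, ev_acc)
  events$t_on <- events$file_start + events$onset_s
  feedback <- if (length(fb_acc) > 0) do.call(rbind, fb_acc) else NULL
  truth <- do.call(rbind, truth_acc)
  structure(list(events = events, feedback = feedback, truth = truth,
                 schedule = schedule, seed = as.integer(seed)),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("sim_experiment:", nrow(x$truth), "days,", nrow(x$events),
      "syllables,", if (is.null(x$feedback)) 0L else nrow(x$feedback),
      "logged renditions (seed", x$seed, ")\n")
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits `annotations.csv` (package CSV dialect), `feedback_log.csv`,
#' `ground_truth.csv` and `schedule.csv` into `dir`.
#'
#' @param sim A `sim_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotations(sim$events, file.path(dir, "annotations.csv"))
  fb <- sim$feedback
  if (is.null(fb)) {
    fb <- data.frame(file_id = character(0), bout_index = integer(0),
                     rendition_index = integer(0), outcome = character(0),
                     is_catch = logical(0), wn_delivered = logical(0))
  }
  utils::write.csv(fb, file.path(dir, "feedback_log.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$schedule, file.path(dir, "schedule.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
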