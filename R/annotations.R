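#' Read syllable-level song annotations
#'
#' Reads a syllable annotation table in the package's CSV dialect: one row per
#' annotated syllable with columns `file_id`, `file_start_iso8601`, `singer`,
#' `label`, `onset_s`, `offset_s`. Onsets and offsets are seconds from the
#' start of the source audio file; `file_start_iso8601` anchors the file on
#' the experiment clock so bouts can be placed on calendar days.
#'
#' @param path Path to a UTF-8 CSV file with the required header.
#' @return A data frame of validated syllable events with columns `file_id`,
#'   `file_start` (`POSIXct`, UTC), `singer`, `label`, `onset_s`, `offset_s`,
#'   and the derived absolute onset `t_on` (`POSIXct`). Row order within each
#'   file is preserved.
#' @seealso [write_annotations()], [segment_bouts()]
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  required <- c("file_id", "file_start_iso8601", "singer", "label",
                "onset_s", "offset_s")
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    stop("annotation file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(file_id = "character",
                                       file_start_iso8601 = "character",
                                       singer = "character",
                                       label = "character"),
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0) {
    return(.empty_events())
  }
  onset <- suppressWarnings(as.numeric(df$onset_s))
  offset <- suppressWarnings(as.numeric(df$offset_s))
  bad <- which(is.na(onset) | is.na(offset) | is.na(df$file_id) |
                 df$label == "" | is.na(df$label))
  if (length(bad) > 0) {
    stop("malformed annotation row at line ", bad[1] + 1L,
         " of ", path, " (header is line 1)")
  }
  fs <- .parse_iso8601(df$file_start_iso8601)
  if (anyNA(fs)) {
    stop("malformed file_start_iso8601 at line ",
         which(is.na(fs))[1] + 1L, " of ", path)
  }
  events <- data.frame(file_id = df$file_id, file_start = fs,
                       singer = df$singer, label = df$label,
                       onset_s = onset, offset_s = offset,
                       stringsAsFactors = FALSE)
  validate_events(events)
  events$t_on <- events$file_start + events$onset_s
  events
}

#' Write syllable annotations in the package CSV dialect
#'
#' @param events Event data frame as returned by [read_annotations()] or
#'   produced by the simulator.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  out <- data.frame(file_id = events$file_id,
                    file_start_iso8601 = .format_iso8601(events$file_start),
                    singer = events$singer,
                    label = events$label,
                    onset_s = events$onset_s,
                    offset_s = events$offset_s,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Validate the per-event invariants shared by the reader and the simulator.
validate_events <- function(events) {
  if (any(events$onset_s < 0)) {
    stop("validation error: negative onset_s at row ",
         which(events$onset_s < 0)[1])
  }
  bad <- which(events$offset_s <= events$onset_s)
  if (length(bad) > 0) {
    stop("validation error: offset_s <= onset_s at row ", bad[1])
  }
  key <- paste(events$file_id, events$singer, events$onset_s)
  if (anyDuplicated(key)) {
    stop("validation error: duplicate (file, singer, onset) at row ",
         which(duplicated(key))[1])
  }
  invisible(events)
}

.empty_events <- function() {
  data.frame(file_id = character(0),
             file_start = as.POSIXct(character(0), tz = "UTC"),
             singer = character(0), label = character(0),
             onset_s = numeric(0), offset_s = numeric(0),
             t_on = as.POSIXct(character(0), tz = "UTC"),
             stringsAsFactors = FALSE)
}

.parse_iso8601 <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
}

.format_iso8601 <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
}

#' Segment annotated syllables into song bouts
#'
#' A song bout is a continuous period of song: consecutive syllables of one
#' singer whose silent gap (next onset minus previous offset) stays below the
#' segmentation threshold. A gap greater than or equal to `gap_threshold`
#' (default 2 s) starts a new bout, as does a source-file boundary; bouts are
#' never merged across files. Segmentation is performed independently per
#' singer, so interleaved song of two co-housed birds yields separate bout
#' streams.
#'
#' @param events Syllable event data frame (see [read_annotations()]),
#'   time-ordered within each file.
#' @param gap_threshold Silent gap, in seconds, at or above which a new bout
#'   starts. Must be positive. Default 2.
#' @return A `bout_set`: a list with `events` (the input plus a `bout_id`
#'   column), `bouts` (one row per bout: `bout_id`, `file_id`,
#'   `bout_index` within file, `singer`, `bout_start`, `bout_end`,
#'   `n_events`, `phase`, `context`), and the `gap_threshold` used.
#' @export
segment_bouts <- function(events, gap_threshold = 2) {
  stopifnot(is.numeric(gap_threshold), length(gap_threshold) == 1L,
            gap_threshold > 0)
  if (is.null(events$t_on)) {
    events$t_on <- events$file_start + events$onset_s
  }
  # events must be time-ordered within each file
  ord_ok <- tapply(as.numeric(events$t_on), events$file_id,
                   function(v) !is.unsorted(v))
  if (length(ord_ok) > 0 && !all(unlist(ord_ok))) {
    stop("events are not time-ordered within file(s): ",
         paste(names(ord_ok)[!unlist(ord_ok)], collapse = ", "))
  }
  if (nrow(events) == 0) {
    return(.new_bout_set(cbind(events, bout_id = character(0)),
                         .empty_bout_table(), gap_threshold))
  }
  validate_events(events)
  # stable split by (file, singer); order within groups is preserved
  grp <- interaction(events$file_id, events$singer, drop = TRUE)
  idx_split <- split(seq_len(nrow(events)), grp)
  bout_id <- character(nrow(events))
  bout_rows <- vector("list", length(idx_split))
  for (g in seq_along(idx_split)) {
    idx <- idx_split[[g]]
    on <- events$onset_s[idx]
    off <- events$offset_s[idx]
    gap <- on[-1] - off[-length(off)]
    new_bout <- c(TRUE, gap >= gap_threshold)
    b <- cumsum(new_bout)
    fid <- events$file_id[idx[1]]
    singer <- events$singer[idx[1]]
    ids <- sprintf("%s#%s#%03d", fid, singer, b)
    bout_id[idx] <- ids
    first <- idx[!duplicated(b)]
    last <- idx[!duplicated(b, fromLast = TRUE)]
    bout_rows[[g]] <- data.frame(
      bout_id = ids[!duplicated(b)],
      file_id = fid,
      bout_index = seq_len(max(b)),
      singer = singer,
      bout_start = events$t_on[first],
      bout_end = events$file_start[last] + events$offset_s[last],
      n_events = as.integer(table(b)),
      stringsAsFactors = FALSE)
  }
  bouts <- do.call(rbind, bout_rows)
  bouts <- bouts[order(bouts$bout_start, bouts$bout_id), , drop = FALSE]
  rownames(bouts) <- NULL
  bouts$phase <- NA_character_
  bouts$context <- NA_character_
  events$bout_id <- bout_id
  .new_bout_set(events, bouts, gap_threshold)
}

.empty_bout_table <- function() {
  data.frame(bout_id = character(0), file_id = character(0),
             bout_index = integer(0), singer = character(0),
             bout_start = as.POSIXct(character(0), tz = "UTC"),
             bout_end = as.POSIXct(character(0), tz = "UTC"),
             n_events = integer(0), phase = character(0),
             context = character(0), stringsAsFactors = FALSE)
}

.new_bout_set <- function(events, bouts, gap_threshold, feedback = NULL) {
  structure(list(events = events, bouts = bouts,
                 gap_threshold = gap_threshold, feedback = feedback),
            class = "bout_set")
}

#' @export
print.bout_set <- function(x, ...) {
  cat("bout_set:", nrow(x$bouts), "bouts,", nrow(x$events), "syllables,",
      "gap threshold", x$gap_threshold, "s\n")
  if (!all(is.na(x$bouts$phase))) {
    cat("  phases:", paste(unique(stats::na.omit(x$bouts$phase)),
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of bouts in a bout set
#' @param bs A `bout_set`.
#' @return Integer bout count.
#' @export
n_bouts <- function(bs) nrow(bs$bouts)

#' Exclude files with substantial cross-singer temporal overlap
#'
#' In the male-male context a recording file can contain song from both
#' birds. Files holding only the partner's song are dropped outright; files
#' with mixed song are dropped when the summed temporal intersection between
#' the two singers' syllables exceeds `overlap_threshold` times the subject's
#' total bout duration in that file. Files with subject-only song are always
#' kept.
#'
#' @param bs A `bout_set` possibly containing events from two singers.
#' @param subject Singer identifier of the focal bird.
#' @param overlap_threshold Fraction of subject bout duration above which a
#'   mixed file is excluded. Default 0: any measurable overlap excludes.
#' @return A list with `kept` (a `bout_set` restricted to the subject's bouts
#'   in retained files) and `report` (data frame `file_id`,
#'   `overlap_fraction`, `excluded`, `reason`).
#' @export
filter_mixed_bouts <- function(bs, subject, overlap_threshold = 0) {
  stopifnot(inherits(bs, "bout_set"),
            overlap_threshold >= 0, overlap_threshold <= 1)
  ev <- bs$events
  singers <- unique(ev$singer)
  # a set in which the subject never sings is legitimate (all files are
  # then partner-only); an id foreign to a multi-singer set is an error
  if (length(singers) > 1 && !(subject %in% singers)) {
    stop("unknown singer id: ", subject)
  }
  files <- unique(ev$file_id)
  idx_by_file <- split(seq_len(nrow(ev)), factor(ev$file_id, levels = files))
  frac <- numeric(length(files))
  excluded <- logical(length(files))
  reason <- character(length(files))
  for (i in seq_along(files)) {
    fe <- ev[idx_by_file[[i]], , drop = FALSE]
    subj <- fe[fe$singer == subject, , drop = FALSE]
    part <- fe[fe$singer != subject, , drop = FALSE]
    if (nrow(subj) == 0) {
      frac[i] <- 0
      excluded[i] <- TRUE
      reason[i] <- "partner_only"
      next
    }
    if (nrow(part) == 0) {
      frac[i] <- 0
      reason[i] <- "subject_only"
      next
    }
    ov <- .interval_overlap_total(subj$onset_s, subj$offset_s,
                                  part$onset_s, part$offset_s)
    dur <- sum(subj$offset_s - subj$onset_s)
    frac[i] <- if (dur > 0) min(1, ov / dur) else 0
    excluded[i] <- frac[i] > overlap_threshold
    reason[i] <- if (excluded[i]) "mixed_overlap" else "mixed_kept"
  }
  report <- data.frame(file_id = files, overlap_fraction = frac,
                       excluded = excluded, reason = reason,
                       stringsAsFactors = FALSE)
  keep_files <- files[!excluded]
  keep_ev <- ev[ev$file_id %in% keep_files & ev$singer == subject, ,
                drop = FALSE]
  keep_bt <- bs$bouts[bs$bouts$file_id %in% keep_files &
                        bs$bouts$singer == subject, , drop = FALSE]
  keep_ev <- keep_ev[keep_ev$bout_id %in% keep_bt$bout_id, , drop = FALSE]
  kept <- .new_bout_set(keep_ev, keep_bt, bs$gap_threshold, bs$feedback)
  list(kept = kept, report = report)
}

# Total length of the intersection between two sets of [on, off) intervals.
# Both sets are assumed internally non-overlapping (true for one singer's
# syllables); the pairwise intersections are then disjoint and summable.
.interval_overlap_total <- function(on1, off1, on2, off2) {
  total <- 0
  for (j in seq_along(on2)) {
    lo <- pmax(on1, on2[j])
    hi <- pmin(off1, off2[j])
    total <- total + sum(pmax(0, hi - lo))
  }
  total
}

#' Write an exclusion report as CSV
#' @param report Report data frame from [filter_mixed_bouts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  utils::write.csv(report[, c("file_id", "overlap_fraction", "excluded")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Label bouts with experiment phase and social context
#'
#' Matches each bout's calendar date against an experiment schedule and
#' stamps the bout with the phase (BS, T1..T5, PS1..PS3) and social context
#' (MA, MF, MM) of that day. Bouts on unscheduled days keep `NA` labels.
#'
#' @param bs A `bout_set`.
#' @param schedule Schedule data frame from [experiment_schedule()].
#' @return The `bout_set` with `phase` and `context` filled in.
#' @export
assign_schedule <- function(bs, schedule) {
  stopifnot(inherits(bs, "bout_set"))
  dates <- as.Date(bs$bouts$bout_start, tz = "UTC")
  m <- match(dates, as.Date(schedule$date))
  bs$bouts$phase <- ifelse(is.na(m), NA_character_, schedule$phase[m])
  bs$bouts$context <- ifelse(is.na(m), NA_character_, schedule$context[m])
  bs
}

#' Attach a white-noise feedback log to segmented bouts
#'
#' Joins a feedback log (one row per branch rendition:
#' `file_id,bout_index,rendition_index,outcome,is_catch,wn_delivered`) to the
#' bouts of a `bout_set`, so that catch-trial-restricted statistics can be
#' computed. Renditions are matched by file, bout index within file, and the
#' running index of the branch syllable within the bout.
#'
#' @param bs A `bout_set`.
#' @param feedback Feedback log data frame or path to its CSV.
#' @return The `bout_set` with a `feedback` element keyed by
#'   `bout_id` and `rendition_index`.
#' @export
attach_feedback <- function(bs, feedback) {
  stopifnot(inherits(bs, "bout_set"))
  if (is.character(feedback)) {
    feedback <- utils::read.csv(feedback, stringsAsFactors = FALSE,
                                colClasses = c(file_id = "character"))
  }
  need <- c("file_id", "bout_index", "rendition_index", "outcome",
            "is_catch", "wn_delivered")
  stopifnot(all(need %in% names(feedback)))
  key_fb <- paste(feedback$file_id, feedback$bout_index)
  key_bt <- paste(bs$bouts$file_id, bs$bouts$bout_index)
  m <- match(key_fb, key_bt)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " feedback rows reference bouts absent from the ",
            "bout set (dropped)")
  }
  feedback$bout_id <- bs$bouts$bout_id[m]
  feedback <- feedback[!is.na(m), , drop = FALSE]
  feedback$is_catch <- as.logical(feedback$is_catch)
  feedback$wn_delivered <- as.logical(feedback$wn_delivered)
  bs$feedback <- feedback
  bs
}

#' Enumerate branch-point renditions in segmented bouts
#'
#' A rendition is one occurrence of the branch syllable; its outcome is the
#' immediately following syllable label, or `"END"` when the branch syllable
#' closes the bout. When a feedback log is attached, catch and white-noise
#' flags are joined in.
#'
#' @param bs A `bout_set`.
#' @param branch_syllable Branch-point syllable label.
#' @return Data frame `bout_id`, `rendition_index`, `position` (event index
#'   within bout), `outcome`, `is_catch`, `wn_delivered`.
#' @export
branch_renditions <- function(bs, branch_syllable) {
  stopifnot(inherits(bs, "bout_set"))
  ev <- bs$events
  if (nrow(ev) == 0) {
    return(data.frame(bout_id = character(0), rendition_index = integer(0),
                      position = integer(0), outcome = character(0),
                      is_catch = logical(0), wn_delivered = logical(0)))
  }
  # successor label within bout; END at the bout's final event
  nxt <- c(ev$label[-1], "END")
  last_of_bout <- c(ev$bout_id[-1] != ev$bout_id[-nrow(ev)], TRUE)
  nxt[last_of_bout] <- "END"
  hit <- which(ev$label == branch_syllable)
  rend <- data.frame(bout_id = ev$bout_id[hit],
                     position = hit, outcome = nxt[hit],
                     stringsAsFactors = FALSE)
  rend$rendition_index <- stats::ave(rend$position, rend$bout_id,
                                     FUN = seq_along)
  # recover the within-bout event position
  first_pos <- stats::ave(seq_len(nrow(ev)), ev$bout_id, FUN = min)
  rend$position <- hit - first_pos[hit] + 1L
  rend$is_catch <- rep(NA, nrow(rend))
  rend$wn_delivered <- rep(NA, nrow(rend))
  if (!is.null(bs$feedback)) {
    k1 <- paste(rend$bout_id, rend$rendition_index)
    k2 <- paste(bs$feedback$bout_id, bs$feedback$rendition_index)
    m <- match(k1, k2)
    rend$is_catch <- bs$feedback$is_catch[m]
    rend$wn_delivered <- bs$feedback$wn_delivered[m]
  }
  rend[, c("bout_id", "rendition_index", "position", "outcome",
           "is_catch", "wn_delivered")]
}
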