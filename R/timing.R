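#' Timing parameters of the block-design subtraction task
#'
#' Describes one run of the arithmetic verification task: a format block
#' presents the reference magnitude (900 ms) followed by three subtraction
#' trials, each a short fixation (300 ms) plus an item (4400 ms), giving a
#' 15-s block. Fixation blocks (15 s) and format blocks strictly alternate;
#' each of the three formats (dot arrays, Arabic digits, number words)
#' contributes four blocks per run, i.e. 12 trials per format per run, over
#' four runs.
#'
#' @param reference_ms Reference-magnitude presentation duration (ms).
#' @param trial_fixation_ms Within-trial fixation duration (ms).
#' @param item_ms Subtraction-item duration (ms); also the response deadline.
#' @param items_per_block Subtraction trials per format block.
#' @param blocks_per_format Format blocks per format per run.
#' @param formats Ordered format labels.
#' @param fixation_block_s Fixation-block duration (s).
#' @param tr_s Repetition time of the scanner (s).
#' @param n_runs Number of runs per subject.
#' @return An object of class `timing_params`.
#' @examples
#' tp <- timing_params()
#' format_block_duration_s(tp)  # 15
#' @export
timing_params <- function(reference_ms = 900, trial_fixation_ms = 300,
                          item_ms = 4400, items_per_block = 3,
                          blocks_per_format = 4,
                          formats = c("dots", "digits", "words"),
                          fixation_block_s = 15, tr_s = 3, n_runs = 4) {
  check_positive(reference_ms, "reference_ms")
  check_positive(trial_fixation_ms, "trial_fixation_ms")
  check_positive(item_ms, "item_ms")
  check_count(items_per_block, "items_per_block")
  check_count(blocks_per_format, "blocks_per_format")
  check_positive(fixation_block_s, "fixation_block_s")
  check_positive(tr_s, "tr_s")
  check_count(n_runs, "n_runs")
  if (!is.character(formats) || length(formats) < 1 || anyDuplicated(formats))
    stop("'formats' must be distinct labels")
  structure(list(reference_ms = reference_ms,
                 trial_fixation_ms = trial_fixation_ms, item_ms = item_ms,
                 items_per_block = as.integer(items_per_block),
                 blocks_per_format = as.integer(blocks_per_format),
                 formats = formats, fixation_block_s = fixation_block_s,
                 tr_s = tr_s, n_runs = as.integer(n_runs)),
            class = "timing_params")
}

#' Duration of one format block implied by the trial timings
#'
#' @param timing A [timing_params()] object.
#' @return Duration in seconds (reference + trials).
#' @export
format_block_duration_s <- function(timing) {
  stopifnot(inherits(timing, "timing_params"))
  (timing$reference_ms + timing$items_per_block *
     (timing$trial_fixation_ms + timing$item_ms)) / 1000
}

#' Reference magnitudes across runs
#'
#' The task reference alternates between 4 and 5 in the fixed order
#' 4, 5, 4, 5 across runs.
#' @param run_index 1-based run number.
#' @return 4 or 5.
#' @keywords internal
reference_magnitude_for_run <- function(run_index) {
  c(4L, 5L, 4L, 5L)[((run_index - 1L) %% 4L) + 1L]
}

#' Generate the event layout of one task run
#'
#' Lays out strictly alternating fixation and format blocks (the run starts
#' and ends with fixation). The order of the format blocks is a seeded
#' permutation balanced within the run: the blocks are arranged as
#' `blocks_per_format` consecutive cycles, each cycle a random permutation of
#' the formats, so every format appears once per cycle.
#'
#' @param timing A [timing_params()] object.
#' @param run_index 1-based run number (selects the reference magnitude and
#'   the run's randomisation substream).
#' @param seed Integer seed controlling block order; `NULL` uses the current
#'   RNG state.
#' @return An object of class `run_design`: a list with `events` (data frame
#'   of onset_s, duration_s, condition), `trials` (per-trial onsets),
#'   `n_scans`, `total_duration_s`, `reference_magnitude`, `run_index` and
#'   the `timing` used.
#' @examples
#' rd <- generate_run_design(timing_params(), run_index = 1, seed = 1)
#' table(rd$trials$format)  # 12 trials per format
#' @export
generate_run_design <- function(timing, run_index = 1L, seed = NULL) {
  stopifnot(inherits(timing, "timing_params"))
  run_index <- check_count(run_index, "run_index")
  fmts <- timing$formats
  n_fmt <- length(fmts)
  run_seed <- if (is.null(seed)) NULL else derive_seed(seed, run_index)
  order_idx <- with_seed(run_seed, {
    unlist(lapply(seq_len(timing$blocks_per_format),
                  function(i) sample.int(n_fmt)))
  })
  block_formats <- fmts[order_idx]

  fmt_dur <- format_block_duration_s(timing)
  fix_dur <- timing$fixation_block_s
  events <- list()
  trials <- list()
  t0 <- 0
  add_fix <- function(t0) {
    events[[length(events) + 1L]] <<- data.frame(
      onset_s = t0, duration_s = fix_dur, condition = "fixation")
    t0 + fix_dur
  }
  t0 <- add_fix(t0)
  for (b in seq_along(block_formats)) {
    f <- block_formats[b]
    events[[length(events) + 1L]] <- data.frame(
      onset_s = t0, duration_s = fmt_dur, condition = f)
    for (k in seq_len(timing$items_per_block)) {
      on_k <- t0 + timing$reference_ms / 1000 +
        (k - 1) * (timing$trial_fixation_ms + timing$item_ms) / 1000 +
        timing$trial_fixation_ms / 1000
      trials[[length(trials) + 1L]] <- data.frame(
        format = f, block = b, item = k, onset_s = on_k,
        duration_s = timing$item_ms / 1000)
    }
    t0 <- t0 + fmt_dur
    t0 <- add_fix(t0)
  }
  events <- do.call(rbind, events)
  trials <- do.call(rbind, trials)
  total <- t0
  structure(list(events = events, trials = trials,
                 n_scans = as.integer(ceiling(total / timing$tr_s)),
                 total_duration_s = total,
                 reference_magnitude = reference_magnitude_for_run(run_index),
                 run_index = run_index, timing = timing),
            class = "run_design")
}

#' Write run events as a BIDS-style TSV
#'
#' Columns `onset`, `duration`, `trial_type` in seconds.
#' @param design A `run_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(design, path) {
  stopifnot(inherits(design, "run_design"))
  ev <- data.frame(onset = design$events$onset_s,
                   duration = design$events$duration_s,
                   trial_type = design$events$condition)
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV
#' @param path File with columns onset, duration, trial_type.
#' @return Data frame with onset_s, duration_s, condition.
#' @export
read_events_tsv <- function(path) {
  ev <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("numeric", "numeric", "character"))
  data.frame(onset_s = ev$onset, duration_s = ev$duration,
             condition = ev$trial_type)
}
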