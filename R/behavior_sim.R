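#' Default group-by-format behavioural effect configuration
#'
#' Per-cell generating values for trial accuracy, reaction time and
#' non-response probability. The defaults encode the qualitative pattern the
#' simulator is meant to emulate: children with dyscalculia (DC and DLDC)
#' are most impaired on the non-symbolic dot format, and all disorder groups
#' respond more slowly than typically developing children.
#'
#' @return Data frame with columns group, format, accuracy, rt_mean_s,
#'   rt_sd_s, p_nonresponse.
#' @export
default_behavior_effects <- function() {
  g <- c("TD", "DL", "DC", "DLDC")
  f <- c("dots", "digits", "words")
  cfg <- expand.grid(group = g, format = f, stringsAsFactors = FALSE)
  acc <- c(TD = 0, DL = 0, DC = 0, DLDC = 0)
  cfg$accuracy <- c(
    # dots          digits          words      (TD, DL, DC, DLDC each)
    0.92, 0.90, 0.78, 0.75,
    0.93, 0.91, 0.86, 0.84,
    0.90, 0.85, 0.84, 0.80)
  cfg$rt_mean_s <- c(
    1.9, 2.1, 2.4, 2.5,
    1.8, 2.0, 2.1, 2.2,
    2.0, 2.3, 2.2, 2.4)
  cfg$rt_sd_s <- 0.5
  cfg$p_nonresponse <- c(
    0.02, 0.04, 0.08, 0.09,
    0.02, 0.04, 0.05, 0.06,
    0.02, 0.05, 0.05, 0.06)
  cfg
}

#' Simulate a trial-level behavioural table
#'
#' Draws, for every subject and scored trial slot (n_runs x blocks x items
#' per format), a non-response indicator, a correctness indicator and a
#' reaction time. Non-response trials carry missing correctness and RT
#' (participants who do not answer within the item deadline produce neither
#' a score nor a time). RTs are Gaussian around the configured cell mean,
#' truncated to (0, item deadline].
#'
#' @param structure A [group_structure()].
#' @param effects_config Data frame as returned by
#'   [default_behavior_effects()].
#' @param timing A [timing_params()] (sets trials per format and deadline).
#' @param seed Integer seed.
#' @return A `behavioral_table` data frame: subject_id, dyslexia,
#'   dyscalculia, group, format, run, trial_index, correct (0/1/NA),
#'   rt_s (NA iff non-response).
#' @export
generate_behavior <- function(structure,
                              effects_config = default_behavior_effects(),
                              timing = timing_params(), seed = NULL) {
  stopifnot(inherits(structure, "group_structure"))
  need <- c("group", "format", "accuracy", "rt_mean_s", "rt_sd_s",
            "p_nonresponse")
  if (!all(need %in% names(effects_config)))
    stop("effects_config must provide columns: ",
         paste(need, collapse = ", "))
  if (any(effects_config$accuracy < 0 | effects_config$accuracy > 1 |
          effects_config$p_nonresponse < 0 |
          effects_config$p_nonresponse > 1))
    stop("accuracy and p_nonresponse must lie in [0, 1]")
  subjects <- cohort_subjects(structure)
  fmts <- timing$formats
  per_fmt <- timing$n_runs * timing$blocks_per_format * timing$items_per_block
  deadline <- timing$item_ms / 1000

  with_seed(seed, {
    rows <- vector("list", nrow(subjects) * length(fmts))
    k <- 0L
    for (i in seq_len(nrow(subjects))) {
      for (f in fmts) {
        cfg <- effects_config[effects_config$group ==
                                as.character(subjects$group[i]) &
                              effects_config$format == f, ]
        if (nrow(cfg) != 1)
          stop("effects_config must have exactly one row per group x format")
        nr <- rbinom(per_fmt, 1, cfg$p_nonresponse) == 1
        correct <- ifelse(nr, NA_integer_,
                          rbinom(per_fmt, 1, cfg$accuracy))
        rt <- rnorm(per_fmt, cfg$rt_mean_s, cfg$rt_sd_s)
        rt <- pmin(pmax(rt, 0.05), deadline)
        rt[nr] <- NA_real_
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject_id = subjects$subject_id[i],
          dyslexia = subjects$dyslexia[i],
          dyscalculia = subjects$dyscalculia[i],
          group = subjects$group[i], format = f,
          run = rep(seq_len(timing$n_runs),
                    each = per_fmt / timing$n_runs),
          trial_index = seq_len(per_fmt), correct = correct, rt_s = rt)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("behavioral_table", "data.frame")
    out
  })
}
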