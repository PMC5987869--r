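#' Exclude non-response trials and summarise them
#'
#' Trials without a response (or answered after the item deadline, which the
#' simulator also records as non-response) are removed before accuracy and
#' RT aggregation; their counts are reported per subject x format cell. A
#' cell whose scored-trial count is zero is flagged: its accuracy and RT are
#' undefined.
#'
#' @param table A `behavioral_table` data frame.
#' @return List with `scored` (rows with a response) and `summary` (per
#'   subject x format: n_trials, n_nonresponse, pct_nonresponse, n_scored,
#'   flagged_empty).
#' @export
filter_trials <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("subject_id", "format", "correct") %in% names(table)))
  missing_tr <- is.na(table$correct)
  scored <- table[!missing_tr, , drop = FALSE]
  agg <- aggregate(cbind(n_trials = rep(1, nrow(table)),
                         n_nonresponse = as.integer(missing_tr)) ~
                     subject_id + format, data = table, FUN = sum)
  agg$pct_nonresponse <- 100 * agg$n_nonresponse / agg$n_trials
  agg$n_scored <- agg$n_trials - agg$n_nonresponse
  agg$flagged_empty <- agg$n_scored == 0
  list(scored = scored, summary = agg)
}

#' Per-subject, per-format behavioural cell means
#'
#' Accuracy is the percentage correct over scored trials; RT is averaged
#' over correct trials by default (all scored trials with
#' `rt_trials = "all"`); non-response is the percentage of excluded trials.
#' Cells with no qualifying trials yield `NA`.
#'
#' @param table A `behavioral_table`.
#' @param rt_trials `"correct"` or `"all"`.
#' @return Data frame: subject_id, dyslexia, dyscalculia, group, format,
#'   accuracy_pct, mean_rt_s, nonresponse_pct.
#' @export
behavior_cell_means <- function(table, rt_trials = c("correct", "all")) {
  rt_trials <- match.arg(rt_trials)
  ft <- filter_trials(table)
  scored <- ft$scored
  key <- unique(table[, c("subject_id", "dyslexia", "dyscalculia",
                          "group", "format")])
  cell <- function(sid, f) {
    sc <- scored[scored$subject_id == sid & scored$format == f, ]
    acc <- if (nrow(sc)) 100 * mean(sc$correct) else NA_real_
    rt_rows <- if (rt_trials == "correct") sc[sc$correct == 1, ] else sc
    rt <- if (nrow(rt_rows)) mean(rt_rows$rt_s) else NA_real_
    c(acc, rt)
  }
  vals <- t(mapply(cell, key$subject_id, key$format))
  key$accuracy_pct <- vals[, 1]
  key$mean_rt_s <- vals[, 2]
  nr <- ft$summary
  key$nonresponse_pct <- nr$pct_nonresponse[
    match(paste(key$subject_id, key$format),
          paste(nr$subject_id, nr$format))]
  rownames(key) <- NULL
  key
}

#' Mixed 2 x 2 x 3 ANOVA on behavioural cell means
#'
#' Dyslexia presence and dyscalculia presence are between-subject factors;
#' format (dots vs digits vs number words) is a within-subject factor. The
#' seven effects (Format, DL, DC, Format x DL, Format x DC, DL x DC,
#' Format x DL x DC) are tested with Type III sums of squares; within- and
#' between-subject error strata are partitioned in the standard split-plot
#' way and no sphericity correction is applied (format F tests use the
#' uncorrected 2 and 2(N - 4) degrees of freedom). Subjects missing any
#' format cell are dropped listwise.
#'
#' @param cells Data frame from [behavior_cell_means()].
#' @param measure Column to analyse (`"accuracy_pct"`, `"mean_rt_s"` or
#'   `"nonresponse_pct"`).
#' @return An `anova_table` data frame: effect, df_num, df_den, F, p.
#' @export
mixed_anova <- function(cells, measure = "accuracy_pct") {
  stopifnot(measure %in% names(cells))
  fmts <- unique(as.character(cells$format))
  wide <- reshape(cells[, c("subject_id", "dyslexia", "dyscalculia",
                            "format", measure)],
                  idvar = c("subject_id", "dyslexia", "dyscalculia"),
                  timevar = "format", direction = "wide")
  ycols <- paste0(measure, ".", fmts)
  wide <- wide[stats::complete.cases(wide[, ycols]), , drop = FALSE]
  wide$dl <- factor(ifelse(wide$dyslexia, "yes", "no"))
  wide$dc <- factor(ifelse(wide$dyscalculia, "yes", "no"))
  tab <- table(wide$dl, wide$dc)
  if (length(tab) < 4 || any(tab < 2))
    stop("each dyslexia x dyscalculia cell needs at least 2 complete ",
         "subjects")
  Y <- as.matrix(wide[, ycols])
  colnames(Y) <- fmts
  mlm <- lm(Y ~ dl * dc, data = wide,
            contrasts = list(dl = "contr.sum", dc = "contr.sum"))
  idata <- data.frame(format = factor(fmts, levels = fmts))
  av <- car::Anova(mlm, idata = idata, idesign = ~format, type = 3)
  uni <- suppressWarnings(summary(av, multivariate = FALSE))$univariate.tests
  fcol <- intersect(c("F value", "F"), colnames(uni))[1]
  pick <- function(row_name, label) {
    r <- uni[row_name, ]
    Fv <- unname(r[fcol])
    pv <- unname(r["Pr(>F)"])
    # a numerically zero effect SS is a zero effect even when the error
    # stratum is also zero (identical cell means)
    if (r["Sum Sq"] < 1e-8 * (1 + mean(Y)^2)) { Fv <- 0; pv <- 1 }
    data.frame(effect = label, df_num = unname(r["num Df"]),
               df_den = unname(r["den Df"]), F = Fv, p = pv)
  }
  out <- rbind(pick("format", "Format"),
               pick("dl", "DL"),
               pick("dc", "DC"),
               pick("dl:format", "Format:DL"),
               pick("dc:format", "Format:DC"),
               pick("dl:dc", "DL:DC"),
               pick("dl:dc:format", "Format:DL:DC"))
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Bonferroni adjustment
#'
#' @param p Raw p-values.
#' @param m Family size (defaults to `length(p)`).
#' @return Adjusted p-values, `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1) stop("family size must be >= 1")
  pmin(1, m * p)
}

#' Bonferroni-corrected pairwise format comparisons
#'
#' Paired t-tests between formats on the marginal per-subject cell means,
#' with Bonferroni correction over the family of format pairs.
#'
#' @param cells Data frame from [behavior_cell_means()].
#' @param measure Column to analyse.
#' @return Data frame: comparison, t, df, p_raw, p_adjusted.
#' @export
bonferroni_pairwise <- function(cells, measure = "accuracy_pct") {
  fmts <- unique(as.character(cells$format))
  prs <- utils::combn(fmts, 2, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    a <- cells[cells$format == pr[1], c("subject_id", measure)]
    b <- cells[cells$format == pr[2], c("subject_id", measure)]
    m <- merge(a, b, by = "subject_id")
    m <- m[stats::complete.cases(m), ]
    tt <- stats::t.test(m[[paste0(measure, ".x")]],
                        m[[paste0(measure, ".y")]], paired = TRUE)
    data.frame(comparison = paste(pr, collapse = " vs "),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni_adjust(out$p_raw, nrow(out))
  out
}
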