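#' Motion quality-control thresholds
#'
#' Run-exclusion thresholds on the realignment parameters: a run is
#' discarded when any single axis moves by more than one voxel size on
#' `n_consecutive` consecutive scan-to-scan transitions (axis rule), or when
#' the Euclidean combination of all six displacement components exceeds one
#' voxel size on any transition (Euclidean rule). Both comparisons are
#' strict ("more than"): a displacement exactly equal to the voxel size does
#' not trigger either rule. Subjects retaining fewer than
#' `min_run_fraction` of their runs are excluded from all analyses; exactly
#' half retained counts as retained. Rotations enter both rules as arc
#' length on a sphere of radius `rotation_radius_mm` unless
#' `translations_only` is set.
#'
#' @param voxel_size_mm Exclusion threshold, one voxel size (mm).
#' @param n_consecutive Consecutive suprathreshold transitions the axis rule
#'   requires.
#' @param min_run_fraction Minimum retained-run fraction for a subject.
#' @param rotation_radius_mm Radius converting rotations to mm.
#' @param translations_only If `TRUE`, rotations are ignored by both rules.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(voxel_size_mm = 2.2, n_consecutive = 2L,
                          min_run_fraction = 0.5, rotation_radius_mm = 50,
                          translations_only = FALSE) {
  check_positive(voxel_size_mm, "voxel_size_mm")
  check_count(n_consecutive, "n_consecutive")
  check_fraction(min_run_fraction, "min_run_fraction")
  if (min_run_fraction == 0) stop("'min_run_fraction' must be > 0")
  check_positive(rotation_radius_mm, "rotation_radius_mm")
  structure(list(voxel_size_mm = voxel_size_mm,
                 n_consecutive = as.integer(n_consecutive),
                 min_run_fraction = min_run_fraction,
                 rotation_radius_mm = rotation_radius_mm,
                 translations_only = isTRUE(translations_only)),
            class = "qc_thresholds")
}

#' Scan-to-scan displacement table
#'
#' Absolute parameter change between consecutive scans, per axis. Rotation
#' deltas are expressed as arc length (`|delta theta| * radius`) so all six
#' columns share the mm scale.
#'
#' @param trace A `motion_trace` (n x 6 matrix, >= 2 scans).
#' @param radius Sphere radius (mm) for the rotation arc lengths.
#' @return (n - 1) x 6 matrix of absolute displacements in mm.
#' @export
scan_to_scan_displacement <- function(trace, radius = 50) {
  m <- unclass(trace)
  if (!is.matrix(m) || ncol(m) != 6)
    stop("'trace' must be an n x 6 motion matrix")
  if (nrow(m) < 2) stop("motion trace needs at least 2 scans")
  d <- abs(diff(m))
  d[, 4:6] <- d[, 4:6] * radius
  colnames(d) <- colnames(m)
  d
}

#' Euclidean per-transition motion
#'
#' The Euclidean norm over the six scan-to-scan displacement components
#' (rotations as arc lengths), an additive summary of motion in all
#' directions between consecutive time points.
#'
#' @inheritParams scan_to_scan_displacement
#' @return Numeric vector of length n - 1.
#' @export
euclidean_motion <- function(trace, radius = 50) {
  d <- scan_to_scan_displacement(trace, radius)
  sqrt(rowSums(d^2))
}

run_qc_record <- function(trace, thresholds) {
  d <- scan_to_scan_displacement(trace, thresholds$rotation_radius_mm)
  if (thresholds$translations_only) d <- d[, 1:3, drop = FALSE]
  eu <- sqrt(rowSums(d^2))
  thr <- thresholds$voxel_size_mm
  k <- thresholds$n_consecutive
  over <- d > thr
  axis_hit <- FALSE
  if (nrow(over) >= k) {
    for (a in seq_len(ncol(over))) {
      r <- rle(over[, a])
      if (any(r$values & r$lengths >= k)) { axis_hit <- TRUE; break }
    }
  }
  eu_hit <- any(eu > thr)
  reasons <- c(if (axis_hit) "axis_rule", if (eu_hit) "euclidean_rule")
  list(excluded = axis_hit || eu_hit,
       reasons = reasons %||% character(0),
       max_axis_disp_mm = max(d), max_euclidean_mm = max(eu))
}

#' Run-level motion exclusion
#'
#' Applies the axis and Euclidean exclusion rules to every run of every
#' subject.
#'
#' @param traces Named list (one element per subject) of lists of
#'   `motion_trace` objects (one per run).
#' @param thresholds A [qc_thresholds()].
#' @return A `qc_report`: list with `runs` (data frame subject_id,
#'   run_index, excluded, reasons, max_axis_disp_mm, max_euclidean_mm) and
#'   `thresholds`.
#' @export
exclude_runs <- function(traces, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (is.null(names(traces)))
    names(traces) <- sprintf("sub-%03d", seq_along(traces))
  rows <- list()
  for (sid in names(traces)) {
    runs <- traces[[sid]]
    for (r in seq_along(runs)) {
      rec <- run_qc_record(runs[[r]], thresholds)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, run_index = r, excluded = rec$excluded,
        reasons = paste(rec$reasons, collapse = "+"),
        max_axis_disp_mm = rec$max_axis_disp_mm,
        max_euclidean_mm = rec$max_euclidean_mm)
    }
  }
  structure(list(runs = do.call(rbind, rows), thresholds = thresholds),
            class = "qc_report")
}

#' Subject-level exclusion from a run-level QC report
#'
#' A subject is retained iff the fraction of retained runs is at least
#' `min_run_fraction` (strictly-less-than-half retained means excluded, so
#' 2 of 4 runs kept is enough).
#'
#' @param report A `qc_report` from [exclude_runs()].
#' @param thresholds A [qc_thresholds()]; defaults to the report's own.
#' @return The report with a `subjects` data frame added (subject_id,
#'   n_runs, runs_retained, retained_fraction, subject_excluded) and
#'   `retained` (character vector of retained subject ids).
#' @export
exclude_subjects <- function(report, thresholds = report$thresholds) {
  stopifnot(inherits(report, "qc_report"))
  rr <- report$runs
  agg <- aggregate(cbind(n_runs = rep(1, nrow(rr)),
                         runs_retained = !rr$excluded) ~ subject_id,
                   data = rr, FUN = sum)
  agg$retained_fraction <- agg$runs_retained / agg$n_runs
  agg$subject_excluded <- agg$retained_fraction < thresholds$min_run_fraction
  report$subjects <- agg
  report$retained <- agg$subject_id[!agg$subject_excluded]
  report
}

#' Group comparison of residual motion after QC
#'
#' One-way ANOVAs across the four diagnostic groups on (i) each retained
#' subject's mean per-transition Euclidean motion, (ii) cumulative Euclidean
#' motion per run, and (iii) the number of retained runs, using retained
#' runs of retained subjects only.
#'
#' @param traces Named per-subject lists of `motion_trace` objects.
#' @param report A `qc_report` that has passed through [exclude_subjects()].
#' @param groups Data frame with subject_id and group (e.g. from
#'   [cohort_subjects()]).
#' @return Data frame: measure, F, df1, df2, p.
#' @export
compare_group_motion <- function(traces, report, groups) {
  stopifnot(inherits(report, "qc_report"), !is.null(report$subjects))
  keep <- report$retained
  g <- groups$group[match(keep, groups$subject_id)]
  g <- factor(g, levels = levels(factor(groups$group)))
  if (any(table(g) < 2))
    stop("each group needs at least 2 retained subjects")
  radius <- report$thresholds$rotation_radius_mm
  per_subj <- lapply(keep, function(sid) {
    rr <- report$runs[report$runs$subject_id == sid, ]
    kept <- rr$run_index[!rr$excluded]
    eu <- unlist(lapply(kept, function(r)
      euclidean_motion(traces[[sid]][[r]], radius)))
    c(mean_motion = mean(eu),
      cumulative_motion = sum(eu) / length(kept),
      runs_retained = length(kept))
  })
  m <- do.call(rbind, per_subj)
  one <- function(y, label) {
    fit <- aov(y ~ g)
    s <- summary(fit)[[1]]
    Fv <- s$`F value`[1]
    pv <- s$`Pr(>F)`[1]
    if (s$`Sum Sq`[1] < 1e-10 * (1 + mean(y)^2)) { Fv <- 0; pv <- 1 }
    data.frame(measure = label, F = Fv, df1 = s$Df[1],
               df2 = s$Df[2], p = pv)
  }
  rbind(one(m[, "mean_motion"], "mean_euclidean_motion"),
        one(m[, "cumulative_motion"], "cumulative_motion_per_run"),
        one(m[, "runs_retained"], "runs_retained"))
}

#' Write a QC report as TSV plus JSON summary
#' @param report A `qc_report` (after [exclude_subjects()]).
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_qc_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "qc_runs.tsv")
  p2 <- file.path(dir, "qc_subjects.tsv")
  p3 <- file.path(dir, "qc_summary.json")
  write.table(report$runs, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$subjects, p2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(
    n_subjects = nrow(report$subjects),
    n_retained = length(report$retained),
    pct_runs_excluded = 100 * mean(report$runs$excluded),
    thresholds = unclass(report$thresholds)),
    p3, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(p1, p2, p3))
}
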