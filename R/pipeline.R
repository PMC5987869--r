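#' Default pipeline configuration
#'
#' Nested configuration for the end-to-end run: cohort simulation, motion
#' QC, first-level contrast estimation, group univariate analysis, MVPA and
#' behavioural statistics. Unknown keys anywhere in an override list are
#' rejected, and the resolved configuration is echoed into the output
#' directory. One global seed derives an independent substream per stage,
#' so disabling one stage leaves the others' randomness untouched.
#'
#' @param ... Named overrides of the defaults, with the same nesting (e.g.
#'   `mvpa = list(n_repetitions = 100)`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = file.path(tempdir(), "arithmvpa-run"),
    stages = list(simulate = TRUE, qc = TRUE, first_level = TRUE,
                  group = TRUE, mvpa = TRUE, behavior = TRUE),
    cohort = list(n_td = 22L, n_dl = 14L, n_dc = 8L, n_dldc = 8L,
                  effect_size_delta = 3.5, rho_shared = 1,
                  sigma_subject = 1, sigma_noise = 1,
                  comorbid_rule = "additive",
                  grid_shape = c(16L, 16L, 16L),
                  motion_severity = 0.05, excessive_motion_prob = 0.1),
    qc = list(voxel_size_mm = 2.2, n_consecutive = 2L,
              min_run_fraction = 0.5),
    first_level = list(mode = "truth", fwhm_mm = 0, combine = "concat"),
    group = list(q = 0.05, alpha_uncorrected = 0.001),
    mvpa = list(n_repetitions = 100L, n_permutations = 100L,
                classifier = "linear_svm", rois = "whole"),
    behavior = list(rt_trials = "correct"))
  overrides <- list(...)
  merge_checked <- function(base, over, path = "") {
    for (nm in names(over)) {
      if (!nm %in% names(base))
        stop("unknown configuration key: ", path, nm)
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_checked(base[[nm]], over[[nm]],
                                    paste0(path, nm, "$"))
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  cfg <- merge_checked(defaults, overrides)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate, qc,
#' first-level, group, mvpa, behavior — writing each stage's tables under
#' the configured output directory and collecting key summaries in a run
#' report. Identical configuration and seed give identical summary tables.
#' A stage failure stops the run naming the stage; completed stages'
#' outputs are retained.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report`: list with per-stage `status`, key `tables`, and
#'   an output `files` manifest with md5 checksums.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report <- list(status = list(), tables = list(), files = character(0))
  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) {
      report$status[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    report$status[[name]] <<- "done"
    invisible(res)
  }
  cc <- config$cohort
  cohort <- NULL
  qc <- NULL

  run_stage("simulate", function() {
    gs <- group_structure(cc$n_td, cc$n_dl, cc$n_dc, cc$n_dldc,
                          effect_size_delta = cc$effect_size_delta,
                          rho_shared = cc$rho_shared,
                          sigma_subject = cc$sigma_subject,
                          sigma_noise = cc$sigma_noise,
                          comorbid_rule = cc$comorbid_rule)
    cohort <<- simulate_cohort(gs, grid_shape = cc$grid_shape,
                               motion_severity = cc$motion_severity,
                               excessive_motion_prob =
                                 cc$excessive_motion_prob,
                               seed = derive_seed(config$seed, "simulate"))
    write.table(cohort$subjects,
                file.path(config$out_dir, "participants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  })
  if (is.null(cohort))
    stop("pipeline stage 'simulate' must be enabled; later stages need it")

  run_stage("qc", function() {
    thr <- qc_thresholds(config$qc$voxel_size_mm, config$qc$n_consecutive,
                         config$qc$min_run_fraction)
    qc <<- exclude_subjects(exclude_runs(cohort$motions, thr))
    write_qc_report(qc, config$out_dir)
    report$tables$qc <<- qc$subjects
    report$tables$qc_group_motion <<-
      tryCatch(compare_group_motion(cohort$motions, qc, cohort$subjects),
               error = function(e) NULL)
  })
  retained <- if (!is.null(qc)) qc$retained else cohort$subjects$subject_id
  retained_runs <- if (!is.null(qc)) {
    split(qc$runs$run_index[!qc$runs$excluded],
          qc$runs$subject_id[!qc$runs$excluded])[retained]
  } else NULL

  maps <- NULL
  run_stage("first_level", function() {
    maps <<- cohort_contrast_maps(
      cohort, mode = config$first_level$mode,
      retained_runs = retained_runs, subjects = retained,
      fwhm_mm = config$first_level$fwhm_mm)
  })

  run_stage("group", function() {
    if (is.null(maps)) stop("first_level stage output is required")
    flags <- cohort$subjects[match(retained, cohort$subjects$subject_id), ]
    rows <- list()
    for (f in cohort$timing$formats) {
      sm <- voxelwise_factorial_anova(maps[[f]], flags,
                                      mask = cohort$amplitude$mask)
      for (lab in names(sm)) {
        fdr <- fdr_correct(sm[[lab]], q = config$group$q,
                           mask = cohort$amplitude$mask)
        unc <- uncorrected_mask(sm[[lab]],
                                alpha = config$group$alpha_uncorrected,
                                mask = cohort$amplitude$mask)
        rows[[length(rows) + 1L]] <- data.frame(
          format = f, effect = lab,
          n_fdr = fdr$n_suprathreshold, n_uncorrected = unc$n_suprathreshold)
      }
    }
    tab <- do.call(rbind, rows)
    write.table(tab, file.path(config$out_dir, "group_suprathreshold.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$tables$group <<- tab
  })

  run_stage("mvpa", function() {
    if (is.null(maps)) stop("first_level stage output is required")
    labels <- cohort$subjects$group[match(retained,
                                          cohort$subjects$subject_id)]
    roi_all <- roi_set_from_labels(cohort$roi_labels)
    roi_set <- roi_all[intersect(config$mvpa$rois, names(roi_all))]
    if (!length(roi_set)) stop("no configured ROI matches the label set")
    cfg <- lpocv_config(config$mvpa$n_repetitions,
                        config$mvpa$n_permutations,
                        classifier = config$mvpa$classifier,
                        seed = derive_seed(config$seed, "mvpa"))
    suite <- run_mvpa_suite(maps, labels, roi_set, cfg)
    write.table(suite$results, file.path(config$out_dir, "mvpa_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$tables$mvpa <<- suite$results
  })

  run_stage("behavior", function() {
    beh <- cohort$behavior[cohort$behavior$subject_id %in% retained, ]
    cells <- behavior_cell_means(beh, rt_trials = config$behavior$rt_trials)
    tabs <- lapply(c(accuracy_pct = "accuracy_pct",
                     mean_rt_s = "mean_rt_s",
                     nonresponse_pct = "nonresponse_pct"),
                   function(m) {
      tb <- mixed_anova(cells, m)
      tb$measure <- m
      tb
    })
    tab <- do.call(rbind, tabs)
    write.table(tab, file.path(config$out_dir, "behavior_anova.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$tables$behavior <<- tab
  })

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  report$files <- data.frame(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  report$out_dir <- config$out_dir
  class(report) <- "run_report"
  report
}

#' Render a human-readable pipeline report
#'
#' Writes a markdown summary of the enabled stages (QC exclusions, group
#' suprathreshold counts, the MVPA accuracy grid, the behavioural ANOVA
#' table) to `report.md` in the run directory; re-rendering is idempotent.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return The markdown lines, invisibly.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  lines <- c("# Pipeline run report", "",
             paste0("- stage ", names(report$status), ": ",
                    unlist(report$status)))
  md_table <- function(df) {
    if (is.null(df) || !nrow(df)) return("(empty)")
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(r)
        paste0("| ", paste(r, collapse = " | "), " |")))
  }
  for (nm in names(report$tables)) {
    lines <- c(lines, "", paste("##", nm), "", md_table(report$tables[[nm]]))
  }
  path <- file.path(report$out_dir, "report.md")
  writeLines(lines, path)
  invisible(lines)
}
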