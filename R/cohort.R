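#' Simulate a complete synthetic study cohort
#'
#' Assembles everything one study emulation needs: the subject table (four
#' diagnostic groups), per-subject per-run task designs (block order
#' randomised per run, reference magnitudes in the fixed 4/5/4/5 order),
#' per-run motion traces with an optional fraction of excessive-motion runs
#' (a 3 mm spike on two consecutive transitions, which the QC rules must
#' catch), latent per-format amplitude maps carrying the group structure,
#' and a trial-level behavioural table. BOLD time series are synthesised on
#' demand by [synthesize_cohort_bold()] rather than stored. A single seed
#' drives independent substreams for each component, so the cohort is fully
#' reproducible and any component can be regenerated in isolation.
#'
#' @param structure A [group_structure()].
#' @param timing A [timing_params()].
#' @param grid_shape 3D grid dimensions.
#' @param roi_labels Optional ROI label array; defaults built from
#'   `grid_shape`.
#' @param motion_severity Random-walk step sd (mm) of ordinary motion.
#' @param excessive_motion_prob Probability that a run receives an
#'   excessive-motion spike.
#' @param effects_config Behavioural effect configuration.
#' @param seed Integer seed.
#' @return A `cohort` object.
#' @export
simulate_cohort <- function(structure = group_structure(),
                            timing = timing_params(),
                            grid_shape = c(16, 16, 16), roi_labels = NULL,
                            motion_severity = 0.05,
                            excessive_motion_prob = 0.1,
                            effects_config = default_behavior_effects(),
                            seed = 1) {
  stopifnot(inherits(structure, "group_structure"),
            inherits(timing, "timing_params"))
  subjects <- cohort_subjects(structure)
  if (is.null(roi_labels)) roi_labels <- make_roi_labels(grid_shape)
  amplitude <- generate_amplitude_maps(structure, grid_shape, roi_labels,
                                       formats = timing$formats,
                                       seed = derive_seed(seed, "amplitude"))
  n_sub <- nrow(subjects)
  designs <- vector("list", n_sub)
  motions <- vector("list", n_sub)
  names(designs) <- names(motions) <- subjects$subject_id
  spike_flags <- with_seed(derive_seed(seed, "qcflags"),
    matrix(runif(n_sub * timing$n_runs) < excessive_motion_prob,
           n_sub, timing$n_runs))
  for (i in seq_len(n_sub)) {
    designs[[i]] <- lapply(seq_len(timing$n_runs), function(r)
      generate_run_design(timing, r,
                          seed = derive_seed(seed, i * 101 + r)))
    motions[[i]] <- lapply(seq_len(timing$n_runs), function(r) {
      ns <- designs[[i]][[r]]$n_scans
      spike <- if (spike_flags[i, r]) {
        list(transition_index = max(1L, ns %/% 2L), axis = 1L,
             magnitude_mm = 3, n_consecutive = 2L)
      } else NULL
      generate_motion_trace(ns, severity = motion_severity,
                            spike_spec = spike,
                            seed = derive_seed(seed, i * 1009 + r))
    })
  }
  behavior <- generate_behavior(structure, effects_config, timing,
                                seed = derive_seed(seed, "behavior"))
  structure(list(subjects = subjects, structure = structure,
                 timing = timing, amplitude = amplitude,
                 designs = designs, motions = motions,
                 behavior = behavior, roi_labels = roi_labels,
                 grid_shape = grid_shape, seed = seed),
            class = "cohort")
}

#' Synthesise the BOLD runs of one subject
#'
#' @param cohort A `cohort`.
#' @param subject_id Subject identifier.
#' @param noise,motion_coupling,baseline,hrf Passed to
#'   [synthesize_bold()]; noise defaults come from the cohort's group
#'   structure (`sigma_noise`, AR(1) 0.3).
#' @return List of 4D arrays, one per run.
#' @export
synthesize_cohort_bold <- function(cohort, subject_id,
                                   noise = NULL, motion_coupling = 0,
                                   baseline = 100, hrf = "double_gamma") {
  stopifnot(inherits(cohort, "cohort"))
  i <- match(subject_id, cohort$subjects$subject_id)
  if (is.na(i)) stop("unknown subject '", subject_id, "'")
  if (is.null(noise))
    noise <- list(ar1 = 0.3, sigma = cohort$structure$sigma_noise)
  amp <- cohort$amplitude$maps[[i]]
  lapply(seq_along(cohort$designs[[i]]), function(r)
    synthesize_bold(amp, cohort$designs[[i]][[r]],
                    cohort$motions[[i]][[r]], noise = noise,
                    motion_coupling = motion_coupling, baseline = baseline,
                    mask = cohort$amplitude$mask, hrf = hrf,
                    seed = derive_seed(cohort$seed, i * 7717 + r)))
}

#' Per-subject contrast maps for every format
#'
#' `mode = "truth"` returns each subject's latent amplitude maps directly
#' (the exact values a noiseless GLM would recover), the fast substrate for
#' MVPA simulations. `mode = "glm"` synthesises each retained run's BOLD
#' series and estimates the maps with the first-level GLM.
#'
#' @param cohort A `cohort`.
#' @param mode `"truth"` or `"glm"`.
#' @param retained_runs Optional named list (per subject) of retained run
#'   indices (from motion QC); defaults to all runs.
#' @param subjects Optional subject ids to include (default all).
#' @param fwhm_mm Smoothing applied in `"glm"` mode.
#' @param noise,motion_coupling Passed to BOLD synthesis in `"glm"` mode.
#' @return Named list per format of named per-subject 3D arrays.
#' @export
cohort_contrast_maps <- function(cohort, mode = c("truth", "glm"),
                                 retained_runs = NULL, subjects = NULL,
                                 fwhm_mm = 0, noise = NULL,
                                 motion_coupling = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "cohort"))
  ids <- subjects %||% cohort$subjects$subject_id
  fmts <- cohort$timing$formats
  out <- lapply(fmts, function(f) {
    maps <- lapply(ids, function(sid) {
      i <- match(sid, cohort$subjects$subject_id)
      if (mode == "truth") {
        cohort$amplitude$maps[[i]][[f]]
      } else NULL
      })
    names(maps) <- ids
    maps
  })
  names(out) <- fmts
  if (mode == "glm") {
    for (sid in ids) {
      i <- match(sid, cohort$subjects$subject_id)
      keep <- retained_runs[[sid]] %||% seq_along(cohort$designs[[i]])
      bold <- synthesize_cohort_bold(cohort, sid, noise = noise,
                                     motion_coupling = motion_coupling)
      cm <- fit_subject_contrasts(bold[keep], cohort$designs[[i]][keep],
                                  cohort$motions[[i]][keep],
                                  mask = cohort$amplitude$mask,
                                  fwhm_mm = fwhm_mm,
                                  voxel_size_mm =
                                    cohort$amplitude$voxel_size_mm,
                                  subject_id = sid)
      for (f in fmts) out[[f]][[sid]] <- cm[[f]]$values
    }
  }
  out
}

#' ROI mask set from a label volume
#'
#' One logical mask per label plus `whole` (all labelled voxels), mirroring
#' an analysis over lobe-level regions and whole-brain grey matter.
#'
#' @param roi_labels Integer label array with a `roi_names` attribute.
#' @return Named list of logical arrays.
#' @export
roi_set_from_labels <- function(roi_labels) {
  nms <- attr(roi_labels, "roi_names") %||%
    paste0("roi", sort(unique(roi_labels[roi_labels > 0])))
  out <- lapply(seq_along(nms), function(k) roi_labels == k)
  names(out) <- nms
  out$whole <- roi_labels > 0
  out
}

#' Export a cohort to disk
#'
#' Writes events and motion as per-run TSVs, the behavioural table as TSV,
#' ROI labels and latent truth maps as NIfTI, and a JSON manifest.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory.
#' @param bold If `TRUE`, also synthesise and write 4D BOLD NIfTIs
#'   (large; off by default).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, bold = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vx <- cohort$amplitude$voxel_size_mm
  write.table(cohort$subjects, file.path(dir, "participants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_map_nifti(cohort$roi_labels + 0, file.path(dir, "roi_labels.nii.gz"),
                  voxel_size_mm = vx)
  for (sid in cohort$subjects$subject_id) {
    i <- match(sid, cohort$subjects$subject_id)
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    for (r in seq_along(cohort$designs[[i]])) {
      write_events_tsv(cohort$designs[[i]][[r]],
                       file.path(sdir, sprintf("run-%d_events.tsv", r)))
      write_motion_tsv(cohort$motions[[i]][[r]],
                       file.path(sdir, sprintf("run-%d_motion.tsv", r)))
    }
    for (f in cohort$timing$formats)
      write_map_nifti(cohort$amplitude$maps[[i]][[f]],
                      file.path(sdir, sprintf("truth_%s.nii.gz", f)),
                      voxel_size_mm = vx)
    if (bold) {
      runs <- synthesize_cohort_bold(cohort, sid)
      for (r in seq_along(runs)) {
        img <- RNifti::asNifti(runs[[r]], pixdim = c(rep(vx, 3),
                                                     cohort$timing$tr_s))
        RNifti::writeNifti(img,
                           file.path(sdir, sprintf("run-%d_bold.nii.gz", r)))
      }
    }
  }
  manifest <- list(
    n_subjects = nrow(cohort$subjects),
    groups = as.list(table(cohort$subjects$group)),
    n_runs = cohort$timing$n_runs, seed = cohort$seed,
    grid_shape = cohort$grid_shape, voxel_size_mm = vx,
    formats = cohort$timing$formats)
  mp <- file.path(dir, "cohort.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}
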