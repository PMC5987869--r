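test_that("run design reproduces the task's block and trial structure", {
  tp <- timing_params()
  expect_equal(format_block_duration_s(tp), 15)
  rd <- generate_run_design(tp, run_index = 1, seed = 1)
  # 12 trials per format per run, four blocks per format
  expect_equal(as.vector(table(rd$trials$format)), rep(12L, 3))
  fmt_ev <- rd$events[rd$events$condition != "fixation", ]
  expect_equal(as.vector(table(fmt_ev$condition)), rep(4L, 3))
  # strict alternation: fixation before and after every format block
  expect_equal(rd$events$condition[seq(1, nrow(rd$events), by = 2)],
               rep("fixation", 13))
  # events ordered and non-overlapping
  expect_true(all(diff(rd$events$onset_s) > 0))
  ends <- rd$events$onset_s + rd$events$duration_s
  expect_true(all(ends[-nrow(rd$events)] <= rd$events$onset_s[-1] + 1e-12))
  expect_equal(rd$n_scans, ceiling(rd$total_duration_s / tp$tr_s))
  # reference magnitudes follow the fixed 4 5 4 5 order
  expect_equal(vapply(1:4, function(r)
    generate_run_design(tp, r, seed = 1)$reference_magnitude, integer(1)),
    c(4L, 5L, 4L, 5L))
})

test_that("degenerate and invalid timing parameters are handled", {
  tp1 <- timing_params(items_per_block = 1, blocks_per_format = 1)
  rd1 <- generate_run_design(tp1, 1, seed = 1)
  expect_equal(as.vector(table(rd1$trials$format)), rep(1L, 3))
  expect_error(timing_params(item_ms = -1), "item_ms")
  expect_error(timing_params(fixation_block_s = 0), "fixation_block_s")
})

test_that("generators are deterministic under a fixed seed", {
  tp <- timing_params()
  expect_identical(generate_run_design(tp, 2, seed = 7),
                   generate_run_design(tp, 2, seed = 7))
  expect_identical(generate_motion_trace(30, 0.1, seed = 3),
                   generate_motion_trace(30, 0.1, seed = 3))
  gs <- group_structure(2, 2, 2, 2)
  expect_identical(
    generate_amplitude_maps(gs, c(5, 5, 5), seed = 4),
    generate_amplitude_maps(gs, c(5, 5, 5), seed = 4))
  expect_identical(generate_behavior(gs, seed = 5),
                   generate_behavior(gs, seed = 5))
})

test_that("motion traces honour severity and spike specification", {
  z <- generate_motion_trace(20, severity = 0, seed = 1)
  expect_true(all(z == 0))
  spiked <- generate_motion_trace(
    50, severity = 0,
    spike_spec = list(transition_index = 10, axis = 1,
                      magnitude_mm = 2.5, n_consecutive = 2), seed = 1)
  d <- scan_to_scan_displacement(spiked)
  expect_equal(unname(d[10:11, 1]), c(2.5, 2.5))
  rep <- exclude_runs(list(s = list(spiked)))
  expect_true(rep$runs$excluded)
  expect_error(generate_motion_trace(
    10, 0, spike_spec = list(transition_index = 20, magnitude_mm = 1)),
    "out of range")
  expect_error(generate_motion_trace(1, 0.1), "n_scans")
})

test_that("amplitude deviation geometry follows rho_shared", {
  grid <- c(12, 12, 12)
  rl <- make_roi_labels(grid, mask = "full")
  # rho = 1: DL and DC deviations are the same vector
  a1 <- generate_amplitude_maps(
    group_structure(2, 2, 2, 2, rho_shared = 1), grid, rl, seed = 1)
  expect_equal(a1$truth$dots$dev_dl, a1$truth$dots$dev_dc)
  # rho = 0: orthogonal by construction
  a0 <- generate_amplitude_maps(
    group_structure(2, 2, 2, 2, rho_shared = 0), grid, rl, seed = 1)
  v1 <- a0$truth$dots$dev_dl[a0$mask]
  v2 <- a0$truth$dots$dev_dc[a0$mask]
  expect_lt(abs(sum(v1 * v2)), 1e-10)
  # delta = 0: all groups share the mean map
  anull <- generate_amplitude_maps(
    group_structure(2, 2, 2, 2, effect_size_delta = 0, sigma_subject = 0),
    grid, rl, seed = 2)
  expect_equal(anull$maps[[1]]$dots, anull$maps[[8]]$dots)
  expect_error(group_structure(rho_shared = 1.2), "rho_shared")
})

test_that("group-mean deviations recover rho_shared as subject noise vanishes", {
  grid <- c(12, 12, 12)
  rl <- make_roi_labels(grid, mask = "full")
  for (rho in c(0, 0.5, 1)) {
    amp <- generate_amplitude_maps(
      group_structure(4, 4, 4, 4, rho_shared = rho, sigma_subject = 0.01),
      grid, rl, seed = 10 + round(10 * rho))
    expect_equal(recover_group_deviations(amp, "dots")$cor_dl_dc, rho,
                 tolerance = 0.05)
  }
})

test_that("synthetic BOLD matches its forward model", {
  fx <- tiny_run()
  dims <- c(4, 4, 4)
  amp <- lapply(c(dots = 1, digits = 2, words = 3), function(k)
    array(k * 0.5, dims))
  # zero amplitude, zero noise: constant baseline
  amp0 <- lapply(amp, function(a) a * 0)
  b0 <- synthesize_bold(amp0, fx$design, fx$motion,
                        noise = list(ar1 = 0, sigma = 0), baseline = 50)
  expect_true(all(b0 == 50))
  # mismatched scan counts rejected
  short_mo <- generate_motion_trace(fx$design$n_scans - 1, 0, seed = 1)
  expect_error(synthesize_bold(amp, fx$design, short_mo), "n_scans")
})

test_that("AR(1) noise has the configured lag-1 autocorrelation", {
  # oracle: pooled lag-1 sample autocorrelation over >= 10,000 samples
  fx <- tiny_run(items = 3L, blocks = 4L)
  n <- fx$design$n_scans
  dims <- c(10, 10, 1)
  amp <- list(dots = array(0, dims), digits = array(0, dims),
              words = array(0, dims))
  b <- synthesize_bold(amp, fx$design, fx$motion,
                       noise = list(ar1 = 0.3, sigma = 1), baseline = 0,
                       seed = 11)
  Y <- t(matrix(b, prod(dims), n))
  expect_gt(length(Y), 10000)
  num <- sum(Y[-1, ] * Y[-n, ])
  den <- sum(Y^2)
  expect_lt(abs(num / den - 0.3), 0.05)
})

test_that("behavioural simulator honours its effect configuration", {
  gs <- group_structure(2, 2, 2, 2)
  cfg <- default_behavior_effects()
  # invalid probabilities rejected
  bad <- cfg; bad$p_nonresponse[1] <- 1.4
  expect_error(generate_behavior(gs, bad), "\\[0, 1\\]")
  # flat config: group means equal within sampling error (large n)
  flat <- cfg
  flat$accuracy <- 0.85; flat$rt_mean_s <- 2; flat$p_nonresponse <- 0.03
  gs_big <- group_structure(60, 60, 60, 60)
  beh <- generate_behavior(gs_big, flat, seed = 1)
  cells <- behavior_cell_means(beh)
  gm <- tapply(cells$accuracy_pct, cells$group, mean)
  expect_lt(max(gm) - min(gm), 2.5)
  # configured impairment direction: dyscalculia groups worse on dots
  beh2 <- generate_behavior(gs_big, cfg, seed = 2)
  cells2 <- behavior_cell_means(beh2)
  dots <- cells2[cells2$format == "dots", ]
  dc_groups <- dots$group %in% c("DC", "DLDC")
  expect_lt(mean(dots$accuracy_pct[dc_groups]),
            mean(dots$accuracy_pct[!dc_groups]))
})

test_that("a fully non-responding cell is flagged, not fatal", {
  gs <- group_structure(2, 2, 2, 2)
  cfg <- default_behavior_effects()
  cfg$p_nonresponse[cfg$group == "DC" & cfg$format == "dots"] <- 1
  beh <- generate_behavior(gs, cfg, seed = 3)
  ft <- filter_trials(beh)
  dc_ids <- unique(beh$subject_id[beh$group == "DC"])
  flagged <- ft$summary[ft$summary$subject_id %in% dc_ids &
                          ft$summary$format == "dots", ]
  expect_true(all(flagged$flagged_empty))
  cells <- behavior_cell_means(beh)
  expect_true(all(is.na(
    cells$accuracy_pct[cells$group == "DC" & cells$format == "dots"])))
})

test_that("cohort assembly is complete, reproducible and exportable", {
  gs <- group_structure(2, 2, 2, 2)
  co <- simulate_cohort(gs, grid_shape = c(6, 6, 6), seed = 5)
  expect_equal(nrow(co$subjects), 8)
  expect_equal(length(co$designs[[1]]), co$timing$n_runs)
  # trial-slot conservation per subject
  slots <- with(co$timing,
                n_runs * length(formats) * blocks_per_format *
                  items_per_block)
  expect_equal(sum(co$behavior$subject_id == "sub-001"), slots)
  co2 <- simulate_cohort(gs, grid_shape = c(6, 6, 6), seed = 5)
  expect_identical(co$behavior, co2$behavior)
  expect_identical(co$amplitude$maps, co2$amplitude$maps)
  # round-trip export of events and motion
  d <- withr::local_tempdir()
  write_cohort(co, d)
  ev <- read_events_tsv(file.path(d, "sub-001", "run-1_events.tsv"))
  expect_equal(ev$onset_s, co$designs[[1]][[1]]$events$onset_s)
  mo <- read_motion_tsv(file.path(d, "sub-001", "run-1_motion.tsv"))
  expect_equal(unclass(mo), unclass(co$motions[[1]][[1]]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(file.exists(file.path(d, "cohort.json")))
})
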