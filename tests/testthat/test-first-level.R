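test_that("gaussian smoothing preserves constants and matches the kernel", {
  g <- array(3.7, c(8, 8, 8))
  expect_equal(smooth_volume(g, 10, 2.2), g)
  expect_identical(smooth_volume(g, 0, 2.2), g)
  # impulse response: central profile ratios follow the analytic gaussian
  d <- 21
  imp <- array(0, c(d, d, d)); c0 <- 11
  imp[c0, c0, c0] <- 1
  sm <- smooth_volume(imp, 10, 2.2)
  sigma <- 10 / (2 * sqrt(2 * log(2))) / 2.2
  prof <- sm[c0 + 0:4, c0, c0] / sm[c0, c0, c0]
  expect_equal(prof, exp(-(0:4)^2 / (2 * sigma^2)), tolerance = 1e-10)
  expect_error(smooth_volume(imp, 10, 0), "voxel_size_mm")
})

test_that("design matrix columns are the convolved block boxcars", {
  fx <- tiny_run(items = 3L, blocks = 4L)
  # without convolution, each format column is 1 exactly on its blocks
  dm0 <- build_design_matrix(fx$design, fx$motion, hrf = "none")
  scan_t <- (seq_len(fx$design$n_scans) - 1) * fx$timing$tr_s
  for (f in fx$timing$formats) {
    ev <- fx$design$events[fx$design$events$condition == f, ]
    inside <- rowSums(vapply(seq_len(nrow(ev)), function(k)
      scan_t >= ev$onset_s[k] & scan_t < ev$onset_s[k] + ev$duration_s[k],
      logical(fx$design$n_scans))) > 0
    expect_equal(unname(dm0$X[, f]), as.numeric(inside))
  }
  # convolved version exists for every format + motion + intercept
  dm <- build_design_matrix(fx$design, fx$motion)
  expect_equal(ncol(dm$X), 3 + 6 + 1)
  # a zero-motion trace drops its columns rather than breaking rank
  still <- generate_motion_trace(fx$design$n_scans, 0, seed = 1)
  dm_still <- build_design_matrix(fx$design, still)
  expect_equal(ncol(dm_still$X), 3 + 1)
})

test_that("glm betas equal an independent normal-equations solve", {
  fx <- tiny_run()
  dm <- build_design_matrix(fx$design, fx$motion)
  set.seed(42)
  V <- 50
  Y <- matrix(rnorm(fx$design$n_scans * V), fx$design$n_scans, V)
  fit <- fit_glm(Y, dm)
  oracle <- solve(t(dm$X) %*% dm$X, t(dm$X) %*% Y)
  expect_lt(max(abs(fit$betas - oracle)), 1e-10)
  # intercept-only signal: format betas are zero
  Y0 <- matrix(5, fx$design$n_scans, 3)
  fit0 <- fit_glm(Y0, dm)
  expect_lt(max(abs(fit0$betas[fx$timing$formats, ])), 1e-10)
})

test_that("noiseless synthesis round-trips through the GLM exactly", {
  fx <- tiny_run(items = 3L, blocks = 4L)
  dims <- c(5, 5, 5)
  set.seed(7)
  amp <- list(dots = array(rnorm(125), dims),
              digits = array(rnorm(125), dims),
              words = array(rnorm(125), dims))
  bold <- synthesize_bold(amp, fx$design, fx$motion,
                          noise = list(ar1 = 0, sigma = 0))
  cm <- fit_subject_contrasts(list(bold), list(fx$design), list(fx$motion))
  for (f in names(amp))
    expect_lt(max(abs(cm[[f]]$values - amp[[f]])), 1e-8)
  # linearity: doubling amplitudes doubles the contrast
  amp2 <- lapply(amp, function(a) 2 * a)
  bold2 <- synthesize_bold(amp2, fx$design, fx$motion,
                           noise = list(ar1 = 0, sigma = 0))
  cm2 <- fit_subject_contrasts(list(bold2), list(fx$design),
                               list(fx$motion))
  expect_equal(cm2$dots$values, 2 * cm$dots$values, tolerance = 1e-8)
})

test_that("multi-run concatenation agrees with single-run fits", {
  fx1 <- tiny_run(items = 3L, blocks = 4L, seed = 1, run_index = 1)
  dims <- c(4, 4, 1)
  set.seed(8)
  amp <- list(dots = array(rnorm(16), dims),
              digits = array(rnorm(16), dims),
              words = array(rnorm(16), dims))
  b1 <- synthesize_bold(amp, fx1$design, fx1$motion,
                        noise = list(ar1 = 0, sigma = 0))
  single <- fit_subject_contrasts(list(b1), list(fx1$design),
                                  list(fx1$motion))
  fx2 <- tiny_run(items = 3L, blocks = 4L, seed = 2, run_index = 2)
  b2 <- synthesize_bold(amp, fx2$design, fx2$motion,
                        noise = list(ar1 = 0, sigma = 0))
  multi <- fit_subject_contrasts(list(b1, b2),
                                 list(fx1$design, fx2$design),
                                 list(fx1$motion, fx2$motion))
  for (f in names(amp)) {
    expect_lt(max(abs(single[[f]]$values - amp[[f]])), 1e-8)
    expect_lt(max(abs(multi[[f]]$values - amp[[f]])), 1e-8)
  }
  avg <- fit_subject_contrasts(list(b1, b2),
                               list(fx1$design, fx2$design),
                               list(fx1$motion, fx2$motion),
                               combine = "average")
  expect_lt(max(abs(avg$dots$values - amp$dots)), 1e-8)
})

test_that("contrast t statistics are null-calibrated", {
  fx <- tiny_run(items = 3L, blocks = 4L)
  dm <- build_design_matrix(fx$design, fx$motion)
  n <- fx$design$n_scans
  set.seed(99)
  V <- 4000
  Y <- matrix(rnorm(n * V), n, V)  # zero amplitude, white noise
  fit <- fit_glm(Y, dm)
  cm <- contrast_map(fit, "dots")
  crit <- qt(0.975, cm$dof)
  expect_lt(abs(mean(abs(cm$t_values) > crit) - 0.05), 0.015)
})

test_that("nifti round trip preserves a contrast map", {
  arr <- array(rnorm(27), c(3, 3, 3))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_map_nifti(arr, p)
  back <- read_map_nifti(p)
  expect_equal(back, arr, tolerance = 1e-6)
})
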