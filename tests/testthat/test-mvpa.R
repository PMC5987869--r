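test_that("pattern extraction indexes ROI voxels deterministically", {
  set.seed(40)
  X <- matrix(rnorm(5 * 24), 5, 24)
  maps <- matrix_to_maps(X, dims = c(4, 3, 2))
  roi1 <- array(FALSE, c(4, 3, 2)); roi1[2, 1, 1] <- TRUE
  p1 <- extract_patterns(maps, roi1, rep("TD", 5))
  expect_equal(ncol(p1$values), 1)
  expect_equal(unname(p1$values[, 1]), X[, 2])  # column-major index 2
  whole <- extract_patterns(maps, array(TRUE, c(4, 3, 2)), rep("TD", 5))
  expect_equal(ncol(whole$values), 24)
  expect_equal(whole$values, X, ignore_attr = TRUE)
  expect_error(extract_patterns(maps, array(FALSE, c(4, 3, 2)),
                                rep("TD", 5)), "empty")
})

test_that("per-subject mean-centering removes row offsets exactly", {
  set.seed(41)
  X <- matrix(rnorm(6 * 20), 6, 20)
  maps <- matrix_to_maps(X)
  pat <- extract_patterns(maps, array(TRUE, c(20, 1, 1)), rep("TD", 6))
  cen <- mean_center_subject(pat)
  expect_lt(max(abs(rowMeans(cen$values))), 1e-10)
  # constant rows become zero
  Xc <- matrix(7, 2, 10)
  pc <- mean_center_subject(extract_patterns(
    matrix_to_maps(Xc), array(TRUE, c(10, 1, 1)), rep("TD", 2)))
  expect_true(all(pc$values == 0))
  # offset invariance
  X2 <- X + rnorm(6)  # per-subject offsets (recycled down columns)
  pat2 <- extract_patterns(matrix_to_maps(X2), array(TRUE, c(20, 1, 1)),
                           rep("TD", 6))
  expect_equal(mean_center_subject(pat2)$values, cen$values,
               tolerance = 1e-12)
})

test_that("the C++ linear SVM agrees with the e1071 reference", {
  set.seed(42)
  for (r in 1:10) {
    n <- sample(8:20, 1); p <- sample(c(5, 40, 120), 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c(1, -1), length.out = n)[sample(n)]
    mine <- arithmvpa:::.svm_linear_cpp(X, y, 1.0)
    ref <- e1071::svm(X, factor(y, levels = c(1, -1)), kernel = "linear",
                      cost = 1, scale = FALSE)
    # libsvm orients its decision toward whichever class appears first
    sgn <- if (y[1] == 1) 1 else -1
    w_ref <- sgn * drop(t(ref$coefs) %*% ref$SV)
    expect_lt(max(abs(mine$w - w_ref)), 1e-3)
    expect_lt(abs(mine$rho - sgn * ref$rho), 1e-3)
    sc <- X %*% mine$w - mine$rho
    dv <- sgn * attributes(predict(ref, X,
                                   decision.values = TRUE))$decision.values
    expect_lt(max(abs(sc - dv)), 5e-3)
  }
})

test_that("LPOCV separates separable groups and is chance on null data", {
  dev <- rep(c(2.5, -2.5), length.out = 50)
  sep <- two_group_patterns(8, 8, 50, dev = dev, seed = 1)
  cfg <- lpocv_config(100, 100, seed = 2)
  r_sep <- lpocv_classify(sep, "TD", "DL", cfg)
  expect_gte(r_sep$mean_accuracy, 0.95)
  expect_true(r_sep$significant)
  null <- two_group_patterns(8, 8, 50, seed = 3)
  r_null <- lpocv_classify(null, "TD", "DL", lpocv_config(400, 50,
                                                          seed = 4))
  expect_lt(abs(r_null$mean_accuracy - 0.5), 0.15)
  expect_false(r_null$significant)
  expect_true(all(r_null$accuracies >= 0 & r_null$accuracies <= 1))
  expect_error(lpocv_classify(sep, "TD", "missing"), "2 subjects")
})

test_that("accuracy is invariant to swapping the group labels", {
  dev <- rep(c(1, -1), length.out = 40)
  pat <- two_group_patterns(8, 8, 40, dev = dev, seed = 5)
  cfg <- lpocv_config(300, 1, seed = 6)
  ab <- lpocv_classify(pat, "TD", "DL", cfg, null = FALSE)$mean_accuracy
  ba <- lpocv_classify(pat, "DL", "TD", cfg, null = FALSE)$mean_accuracy
  expect_equal(ab, ba, tolerance = 0.06)
})

test_that("adding a constant to one subject's voxels changes nothing", {
  dev <- rep(c(1.5, -1.5), length.out = 30)
  set.seed(7)
  XA <- matrix(rnorm(6 * 30), 6, 30)
  XB <- matrix(rnorm(6 * 30), 6, 30) + rep(dev, each = 6)
  build <- function(X) {
    mean_center_subject(extract_patterns(
      matrix_to_maps(X), array(TRUE, c(30, 1, 1)),
      rep(c("TD", "DL"), each = 6)))
  }
  X1 <- rbind(XA, XB)
  X2 <- X1; X2[3, ] <- X2[3, ] + 42
  cfg <- lpocv_config(50, 10, seed = 8)
  r1 <- lpocv_classify(build(X1), "TD", "DL", cfg)
  r2 <- lpocv_classify(build(X2), "TD", "DL", cfg)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_identical(r1$null_distribution, r2$null_distribution)
})

test_that("permutation null is centred on chance with a sane cutoff", {
  pat <- two_group_patterns(8, 8, 60, seed = 9)
  pc <- permutation_cutoff(pat, "TD", "DL",
                           lpocv_config(1, 500, seed = 10))
  expect_equal(mean(pc$null_distribution), 0.5, tolerance = 0.02)
  expect_gt(pc$cutoff_95, 0.5)
  expect_lt(pc$cutoff_95, 0.9)
  # single permutation: cutoff equals that accuracy
  pc1 <- permutation_cutoff(pat, "TD", "DL",
                            lpocv_config(1, 1, seed = 11))
  expect_equal(pc1$cutoff_95, pc1$null_distribution[1])
})

test_that("generalization transfers along shared axes and not orthogonal ones", {
  v <- 60
  set.seed(12)
  base <- qr.Q(qr(matrix(rnorm(v * 2), v, 2)))
  s1 <- base[, 1] * 6; s2 <- base[, 2] * 6
  make3 <- function(dev_x, dev_y, seed) {
    arithmvpa:::with_seed(seed, {
      X <- rbind(matrix(rnorm(8 * v), 8, v),
                 matrix(rnorm(8 * v), 8, v) + rep(dev_x, each = 8),
                 matrix(rnorm(8 * v), 8, v) + rep(dev_y, each = 8))
      mean_center_subject(extract_patterns(
        matrix_to_maps(X), array(TRUE, c(v, 1, 1)),
        rep(c("TD", "DL", "DC"), each = 8)))
    })
  }
  cfg <- lpocv_config(100, 100, seed = 13)
  shared <- make3(s1, s1, 14)  # identical deviations
  g1 <- generalize(shared, "TD", "DL", "DC", cfg)
  expect_gte(g1$mean_accuracy, 0.9)
  expect_true(g1$significant)
  orth <- make3(s1, s2, 15)  # orthogonal deviations
  g0 <- generalize(orth, "TD", "DL", "DC", cfg)
  expect_lt(abs(g0$mean_accuracy - 0.5), 0.15)
  direct <- lpocv_classify(orth, "TD", "DL", cfg)
  expect_gte(direct$mean_accuracy, 0.9)
  expect_equal(g1$mean_accuracy,
               mean(c(g1$acc_train_x_test_y, g1$acc_train_y_test_x)),
               tolerance = 1e-10)
  expect_error(generalize(shared, "TD", "DL", "DL", cfg), "disjoint")
})

test_that("generalization to an exchangeable group reduces to classification", {
  v <- 50
  dev <- rep(c(2, -2), length.out = v)
  set.seed(16)
  X <- rbind(matrix(rnorm(8 * v), 8, v),
             matrix(rnorm(8 * v), 8, v) + rep(dev, each = 8),
             matrix(rnorm(8 * v), 8, v) + rep(dev, each = 8))
  pat <- mean_center_subject(extract_patterns(
    matrix_to_maps(X), array(TRUE, c(v, 1, 1)),
    rep(c("TD", "DL", "DC"), each = 8)))
  cfg <- lpocv_config(150, 1, seed = 17)
  g <- generalize(pat, "TD", "DL", "DC", cfg)
  d <- lpocv_classify(pat, "TD", "DL", cfg, null = FALSE)
  expect_equal(g$mean_accuracy, d$mean_accuracy, tolerance = 0.1)
})

test_that("TD-vs-disorder accuracy grows with the effect size", {
  accs <- vapply(c(0, 1.5, 3, 6), function(delta) {
    gs <- group_structure(6, 6, 2, 2, effect_size_delta = delta,
                          sigma_subject = 1)
    amp <- generate_amplitude_maps(gs, c(6, 6, 6),
                                   make_roi_labels(c(6, 6, 6),
                                                   mask = "full"),
                                   seed = 18)
    maps <- lapply(seq_len(16), function(i) amp$maps[[i]]$dots)
    pat <- mean_center_subject(extract_patterns(
      maps, amp$mask, amp$subjects$group))
    lpocv_classify(pat, "TD", "DL", lpocv_config(60, 1, seed = 19),
                   null = FALSE)$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.05))  # non-decreasing up to MC error
  expect_gt(accs[4], accs[1])
})

test_that("the suite covers every ROI x format x comparison cell", {
  gs <- group_structure(3, 3, 3, 3, effect_size_delta = 4,
                        sigma_subject = 1)
  amp <- generate_amplitude_maps(gs, c(6, 6, 6), seed = 20)
  ids <- amp$subjects$subject_id
  maps <- list(
    dots = setNames(lapply(seq_along(ids),
                           function(i) amp$maps[[i]]$dots), ids),
    digits = setNames(lapply(seq_along(ids),
                             function(i) amp$maps[[i]]$digits), ids))
  rois <- roi_set_from_labels(amp$roi_labels)[c("parietal", "whole")]
  cfg <- lpocv_config(10, 10, seed = 21)
  suite <- run_mvpa_suite(maps, amp$subjects$group, rois, cfg)
  expect_equal(nrow(suite$results), 2 * 2 * (6 + 3))
  expect_equal(sum(suite$results$analysis == "generalization"), 2 * 2 * 3)
  suite2 <- run_mvpa_suite(maps, amp$subjects$group, rois, cfg)
  expect_identical(suite$results, suite2$results)
})

test_that("the LDA classifier variant runs end to end", {
  dev <- rep(c(3.5, -3.5), length.out = 10)
  pat <- two_group_patterns(6, 6, 10, dev = dev, seed = 22)
  r <- lpocv_classify(pat, "TD", "DL",
                      lpocv_config(30, 30, classifier = "lda", seed = 23))
  expect_gte(r$mean_accuracy, 0.8)
  expect_true(is.finite(r$cutoff_95))
})
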