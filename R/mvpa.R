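#' Extract an ROI pattern matrix from per-subject contrast maps
#'
#' Rows are subjects, columns the in-ROI voxels in fixed array order, so
#' repeated extractions are bitwise identical.
#'
#' @param contrast_maps Per-subject list of `contrast_map_vol` or 3D arrays
#'   sharing a grid.
#' @param roi_mask Logical 3D array (non-empty) selecting the ROI.
#' @param labels Per-subject group labels (factor or character).
#' @param roi_name Name carried on the result.
#' @param contrast_label Contrast (format) the maps came from.
#' @return A `pattern_matrix`: list with `values` (subjects x voxels),
#'   `labels`, `subject_ids`, `roi_name`, `contrast_label`, `centered`.
#' @export
extract_patterns <- function(contrast_maps, roi_mask, labels,
                             roi_name = "roi",
                             contrast_label = NA_character_) {
  if (!any(roi_mask)) stop("ROI mask is empty")
  if (length(labels) != length(contrast_maps))
    stop("one label per subject required")
  mm <- maps_to_matrix(contrast_maps, roi_mask)
  sid <- names(contrast_maps) %||% sprintf("sub-%03d",
                                           seq_along(contrast_maps))
  if (anyNA(mm$Y)) stop("patterns contain missing values")
  structure(list(values = mm$Y, labels = factor(labels),
                 subject_ids = sid, roi_name = roi_name,
                 contrast_label = contrast_label, centered = FALSE),
            class = "pattern_matrix")
}

#' Mean-center each subject's pattern
#'
#' Subtracts every row's mean, removing between-subject differences in
#' overall activation level so classification rests on the spatial pattern
#' alone.
#'
#' @param patterns A `pattern_matrix`.
#' @return The centered `pattern_matrix` (`centered = TRUE`).
#' @export
mean_center_subject <- function(patterns) {
  stopifnot(inherits(patterns, "pattern_matrix"))
  patterns$values <- patterns$values - rowMeans(patterns$values)
  patterns$centered <- TRUE
  patterns
}

#' Leave-pair-out cross-validation configuration
#'
#' @param n_repetitions LPOCV repetitions for the observed accuracy.
#' @param n_permutations Monte-Carlo permutation iterations for the null.
#' @param classifier `"linear_svm"` (soft-margin, unit regularisation;
#'   default) or `"lda"`.
#' @param balance Subsample the larger group to the smaller group's size
#'   each repetition (the default; `FALSE` only for equal-sized groups).
#' @param pairing `"bijection"` (one random pairing covering each subject
#'   once per pass; default) or `"cross"` (all cross-group pairs).
#' @param perm_scheme `"train_only"` (training labels permuted, test pairs
#'   scored against true labels; default) or `"full"` (subject labels
#'   permuted throughout, a sensitivity mode).
#' @param seed Integer seed or `NULL`.
#' @return An `lpocv_config` object.
#' @export
lpocv_config <- function(n_repetitions = 1000, n_permutations = 1000,
                         classifier = c("linear_svm", "lda"),
                         balance = TRUE,
                         pairing = c("bijection", "cross"),
                         perm_scheme = c("train_only", "full"),
                         seed = NULL) {
  check_count(n_repetitions, "n_repetitions")
  check_count(n_permutations, "n_permutations")
  structure(list(n_repetitions = as.integer(n_repetitions),
                 n_permutations = as.integer(n_permutations),
                 classifier = match.arg(classifier),
                 balance = isTRUE(balance),
                 pairing = match.arg(pairing),
                 perm_scheme = match.arg(perm_scheme), seed = seed),
            class = "lpocv_config")
}

# classifier factory: returns f(Xtr, y_pm1, Xte) -> decision scores,
# positive meaning the +1 class; exactly zero is a tie.
make_classifier <- function(name) {
  switch(name,
    linear_svm = function(Xtr, y, Xte) {
      fit <- .svm_linear_cpp(Xtr, y, 1.0)
      as.numeric(Xte %*% fit$w - fit$rho)
    },
    lda = function(Xtr, y, Xte) {
      fit <- suppressWarnings(MASS::lda(Xtr, grouping = factor(y)))
      post <- stats::predict(fit, Xte)$posterior
      as.numeric(post[, "1"] - post[, "-1"])
    },
    stop("unknown classifier '", name, "'"))
}

# one LPOCV pass over paired, balanced groups.
# Xall: 2n x p, rows 1..n = group A (+1), n+1..2n = group B (-1),
# row i paired with row n+i. Returns fraction of the 2n test subjects
# classified correctly (ties, score == 0, go to the first class, +1).
lpocv_pass <- function(Xall, n, clf, permute_train = FALSE) {
  y <- c(rep(1, n), rep(-1, n))
  correct <- 0L
  for (i in seq_len(n)) {
    test <- c(i, n + i)
    ytr <- y[-test]
    if (permute_train) ytr <- sample(ytr)
    sc <- clf(Xall[-test, , drop = FALSE], ytr,
              Xall[test, , drop = FALSE])
    pred <- ifelse(sc >= 0, 1, -1)
    correct <- correct + sum(pred == y[test])
  }
  correct / (2 * n)
}

# all-cross-pairs variant: every (i, j) pair is a fold.
lpocv_pass_cross <- function(Xall, n, clf, permute_train = FALSE) {
  y <- c(rep(1, n), rep(-1, n))
  correct <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    test <- c(i, n + j)
    ytr <- y[-test]
    if (permute_train) ytr <- sample(ytr)
    sc <- clf(Xall[-test, , drop = FALSE], ytr,
              Xall[test, , drop = FALSE])
    pred <- ifelse(sc >= 0, 1, -1)
    correct <- correct + sum(pred == y[test])
  }
  correct / (2 * n * n)
}

balanced_pass_input <- function(XA, XB, balance) {
  nA <- nrow(XA); nB <- nrow(XB)
  n <- min(nA, nB)
  if (!balance && nA != nB)
    stop("groups differ in size; balancing is required")
  ia <- if (nA > n) sample.int(nA, n) else sample.int(nA)
  ib <- if (nB > n) sample.int(nB, n) else sample.int(nB)
  list(X = rbind(XA[ia, , drop = FALSE], XB[ib, , drop = FALSE]), n = n)
}

group_rows <- function(patterns, groups) {
  which(as.character(patterns$labels) %in% groups)
}

#' Leave-pair-out cross-validated subject classification
#'
#' Trains a linear classifier to separate two subject groups from their
#' ROI activation patterns and estimates accuracy by leave-pair-out
#' cross-validation: per repetition the larger group is randomly subsampled
#' to the smaller group's size n, a random bijection forms n disjoint test
#' pairs (one subject per group), and for each pair the classifier is
#' trained on the remaining 2(n - 1) subjects and tested on the held-out
#' pair; the pass accuracy is the fraction of the 2n test subjects
#' classified correctly, averaged over `n_repetitions` passes. Significance
#' comes from a Monte-Carlo permutation null: each of `n_permutations`
#' iterations runs one pass with the training labels randomly permuted
#' (test pairs scored against true labels), and the cutoff is the 95th
#' percentile of these null accuracies.
#'
#' @param patterns A (preferably mean-centered) `pattern_matrix`.
#' @param group_a,group_b Character vectors of group labels forming the
#'   two classes (e.g. `"TD"` vs `c("DL", "DLDC")`).
#' @param config An [lpocv_config()].
#' @param null If `FALSE`, skip the permutation null (no cutoff).
#' @return A `classification_result`: mean_accuracy, accuracies (per
#'   repetition), null_distribution, cutoff_95, significant,
#'   comparison_label, roi_name, contrast_label, n_per_group.
#' @export
lpocv_classify <- function(patterns, group_a, group_b,
                           config = lpocv_config(), null = TRUE) {
  stopifnot(inherits(patterns, "pattern_matrix"),
            inherits(config, "lpocv_config"))
  ia <- group_rows(patterns, group_a)
  ib <- group_rows(patterns, group_b)
  if (length(intersect(ia, ib)))
    stop("groups share subjects; remove the overlap first")
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 subjects")
  XA <- patterns$values[ia, , drop = FALSE]
  XB <- patterns$values[ib, , drop = FALSE]
  clf <- make_classifier(config$classifier)
  pass_fun <- if (config$pairing == "cross") lpocv_pass_cross else lpocv_pass
  res <- with_seed(config$seed, {
    acc <- vapply(seq_len(config$n_repetitions), function(r) {
      bp <- balanced_pass_input(XA, XB, config$balance)
      pass_fun(bp$X, bp$n, clf)
    }, numeric(1))
    nulls <- if (null) {
      vapply(seq_len(config$n_permutations), function(r) {
        bp <- balanced_pass_input(XA, XB, config$balance)
        if (config$perm_scheme == "full") {
          flip <- sample.int(2 * bp$n)
          pass_fun(bp$X[flip, , drop = FALSE], bp$n, clf)
        } else {
          pass_fun(bp$X, bp$n, clf, permute_train = TRUE)
        }
      }, numeric(1))
    } else numeric(0)
    list(acc = acc, nulls = nulls)
  })
  cutoff <- if (length(res$nulls)) {
    unname(quantile(res$nulls, 0.95))
  } else NA_real_
  structure(list(
    mean_accuracy = mean(res$acc), accuracies = res$acc,
    null_distribution = res$nulls, cutoff_95 = cutoff,
    significant = if (is.na(cutoff)) NA else mean(res$acc) > cutoff,
    comparison_label = paste(paste(group_a, collapse = "+"), "vs",
                             paste(group_b, collapse = "+")),
    roi_name = patterns$roi_name,
    contrast_label = patterns$contrast_label,
    n_per_group = min(length(ia), length(ib))),
    class = "classification_result")
}

#' Monte-Carlo permutation null for LPOCV classification
#'
#' Runs `n_permutations` LPOCV passes with permuted training labels and
#' returns the null accuracies and their 95th percentile.
#'
#' @inheritParams lpocv_classify
#' @return List with `null_distribution` and `cutoff_95`.
#' @export
permutation_cutoff <- function(patterns, group_a, group_b,
                               config = lpocv_config()) {
  cfg <- config
  cfg$n_repetitions <- 1L
  r <- lpocv_classify(patterns, group_a, group_b, cfg, null = TRUE)
  list(null_distribution = r$null_distribution, cutoff_95 = r$cutoff_95)
}

# one generalization repetition: trains controls-vs-X, tests controls-vs-Y
# pairs, and vice versa; returns both directional accuracies.
generalization_rep <- function(Xtd, Xx, Xy, clf, permute_train = FALSE) {
  n <- nrow(Xtd)
  one_dir <- function(Xtrain_dis, Xtest_dis) {
    correct <- 0L
    for (i in seq_len(n)) {
      Xtr <- rbind(Xtd[-i, , drop = FALSE], Xtrain_dis)
      ytr <- c(rep(1, n - 1), rep(-1, n))
      if (permute_train) ytr <- sample(ytr)
      sc <- clf(Xtr, ytr, rbind(Xtd[i, , drop = FALSE],
                                Xtest_dis[i, , drop = FALSE]))
      pred <- ifelse(sc >= 0, 1, -1)
      correct <- correct + sum(pred == c(1, -1))
    }
    correct / (2 * n)
  }
  c(xy = one_dir(Xx, Xy), yx = one_dir(Xy, Xx))
}

#' Bidirectional cross-disorder subject generalization
#'
#' Tests whether two disorder groups deviate from controls along similar
#' pattern directions: a classifier trained to separate controls (TD) from
#' disorder group X is tested on separating held-out controls from disorder
#' group Y, and vice versa; the two directional accuracies are averaged.
#' Per repetition all three groups are subsampled to a common size n; each
#' test pair couples one held-out control with one Y subject (controls in a
#' test pair are never in that fold's training set), and training uses the
#' remaining n - 1 controls versus the full X subsample. Significance uses
#' the same permuted-training-labels Monte-Carlo null as
#' [lpocv_classify()]. High generalization accuracy implies X and Y
#' patterns are similar enough to fool the classifier.
#'
#' @param patterns A mean-centered `pattern_matrix`.
#' @param control Control group label (default `"TD"`).
#' @param group_x,group_y The two disorder groups to generalize across.
#' @param config An [lpocv_config()].
#' @return A `generalization_result`: acc_train_x_test_y,
#'   acc_train_y_test_x, mean_accuracy, null_distribution, cutoff_95,
#'   significant, comparison_label, roi_name, contrast_label.
#' @export
generalize <- function(patterns, control = "TD", group_x, group_y,
                       config = lpocv_config()) {
  stopifnot(inherits(patterns, "pattern_matrix"))
  itd <- group_rows(patterns, control)
  ix <- group_rows(patterns, group_x)
  iy <- group_rows(patterns, group_y)
  if (length(intersect(ix, iy)) || length(intersect(itd, c(ix, iy))))
    stop("control and the two disorder groups must be disjoint")
  if (min(length(itd), length(ix), length(iy)) < 2)
    stop("each group needs at least 2 subjects")
  Xtd0 <- patterns$values[itd, , drop = FALSE]
  Xx0 <- patterns$values[ix, , drop = FALSE]
  Xy0 <- patterns$values[iy, , drop = FALSE]
  n <- min(nrow(Xtd0), nrow(Xx0), nrow(Xy0))
  clf <- make_classifier(config$classifier)
  sub_n <- function(X) X[sample.int(nrow(X), n), , drop = FALSE]
  res <- with_seed(config$seed, {
    dirs <- vapply(seq_len(config$n_repetitions), function(r) {
      Xtd <- sub_n(Xtd0); Xx <- sub_n(Xx0); Xy <- sub_n(Xy0)
      generalization_rep(Xtd, Xx, Xy, clf)
    }, numeric(2))
    nulls <- vapply(seq_len(config$n_permutations), function(r) {
      Xtd <- sub_n(Xtd0); Xx <- sub_n(Xx0); Xy <- sub_n(Xy0)
      mean(generalization_rep(Xtd, Xx, Xy, clf, permute_train = TRUE))
    }, numeric(1))
    list(acc = colMeans(dirs), nulls = nulls, dir = rowMeans(dirs))
  })
  cutoff <- unname(quantile(res$nulls, 0.95))
  structure(list(
    acc_train_x_test_y = res$dir[1], acc_train_y_test_x = res$dir[2],
    mean_accuracy = mean(res$acc), accuracies = res$acc,
    null_distribution = res$nulls, cutoff_95 = cutoff,
    significant = mean(res$acc) > cutoff,
    comparison_label = paste0(group_x, "<->", group_y),
    roi_name = patterns$roi_name,
    contrast_label = patterns$contrast_label, n_per_group = n),
    class = "generalization_result")
}

#' Run the full MVPA suite over ROIs, formats and comparisons
#'
#' For every ROI and format: the six group classifications (TD vs DL+DLDC,
#' TD vs DC+DLDC, TD vs DL, TD vs DC, TD vs DLDC, DL vs DC) and the three
#' bidirectional generalizations (DL<->DC, DL<->DLDC, DC<->DLDC), each with
#' its own permutation cutoff. Patterns are mean-centered per subject
#' before classification. Cells whose groups are missing are skipped with a
#' warning.
#'
#' @param contrast_maps_by_format Named list (per format) of per-subject
#'   lists of `contrast_map_vol` or 3D arrays.
#' @param labels Per-subject group labels (TD/DL/DC/DLDC).
#' @param roi_set Named list of logical 3D ROI masks.
#' @param config An [lpocv_config()]; its seed derives one substream per
#'   cell so cells are reproducible independently.
#' @return An `mvpa_suite`: list with `results` (data frame: roi, format,
#'   analysis, comparison, accuracy, cutoff_95, significant, n_per_group)
#'   and `details` (the full result objects).
#' @export
run_mvpa_suite <- function(contrast_maps_by_format, labels, roi_set,
                           config = lpocv_config()) {
  comparisons <- list(
    list(a = "TD", b = c("DL", "DLDC")),
    list(a = "TD", b = c("DC", "DLDC")),
    list(a = "TD", b = "DL"),
    list(a = "TD", b = "DC"),
    list(a = "TD", b = "DLDC"),
    list(a = "DL", b = "DC"))
  gens <- list(c("DL", "DC"), c("DL", "DLDC"), c("DC", "DLDC"))
  rows <- list()
  details <- list()
  cell <- 0L
  for (roi in names(roi_set)) {
    for (fmt in names(contrast_maps_by_format)) {
      pat <- extract_patterns(contrast_maps_by_format[[fmt]],
                              roi_set[[roi]], labels,
                              roi_name = roi, contrast_label = fmt)
      pat <- mean_center_subject(pat)
      for (cmp in comparisons) {
        cell <- cell + 1L
        cfg <- config
        if (!is.null(config$seed)) cfg$seed <- derive_seed(config$seed, cell)
        res <- tryCatch(
          lpocv_classify(pat, cmp$a, cmp$b, cfg),
          error = function(e) {
            warning("classification cell skipped (", conditionMessage(e),
                    ")")
            NULL
          })
        if (is.null(res)) next
        details[[length(details) + 1L]] <- res
        rows[[length(rows) + 1L]] <- data.frame(
          roi = roi, format = fmt, analysis = "classification",
          comparison = res$comparison_label,
          accuracy = res$mean_accuracy, cutoff_95 = res$cutoff_95,
          significant = res$significant, n_per_group = res$n_per_group)
      }
      for (gp in gens) {
        cell <- cell + 1L
        cfg <- config
        if (!is.null(config$seed)) cfg$seed <- derive_seed(config$seed, cell)
        res <- tryCatch(
          generalize(pat, "TD", gp[1], gp[2], cfg),
          error = function(e) {
            warning("generalization cell skipped (", conditionMessage(e),
                    ")")
            NULL
          })
        if (is.null(res)) next
        details[[length(details) + 1L]] <- res
        rows[[length(rows) + 1L]] <- data.frame(
          roi = roi, format = fmt, analysis = "generalization",
          comparison = res$comparison_label,
          accuracy = res$mean_accuracy, cutoff_95 = res$cutoff_95,
          significant = res$significant, n_per_group = res$n_per_group)
      }
    }
  }
  structure(list(results = do.call(rbind, rows), details = details,
                 config = config),
            class = "mvpa_suite")
}
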