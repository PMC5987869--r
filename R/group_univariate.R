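#' Stack per-subject contrast maps into a subjects x voxels matrix
#'
#' @param contrast_maps List of `contrast_map_vol` objects or 3D arrays,
#'   one per subject, sharing a grid.
#' @param mask Logical 3D array of analysed voxels (default: all finite).
#' @return List with `Y` (subjects x voxels), `mask`, `dims`.
#' @export
maps_to_matrix <- function(contrast_maps, mask = NULL) {
  vols <- lapply(contrast_maps, function(m)
    if (inherits(m, "contrast_map_vol")) m$values else m)
  dims <- dim(vols[[1]])
  if (!all(vapply(vols, function(v) identical(dim(v), dims), logical(1))))
    stop("all contrast maps must share the same grid")
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  idx <- which(mask)
  Y <- do.call(rbind, lapply(vols, function(v) as.numeric(v)[idx]))
  list(Y = Y, mask = mask, dims = dims)
}

stat_map_obj <- function(label, stat, p, df, type, dims, mask) {
  to_vol <- function(v) {
    if (is.null(dims)) return(v)
    a <- array(NA_real_, dim = dims)
    a[which(mask)] <- v
    a
  }
  structure(list(effect_label = label, stat_values = to_vol(stat),
                 p_values = to_vol(p), df = df, type = type),
            class = "stat_map")
}

two_sample_t <- function(Y, ia, ib) {
  n1 <- length(ia); n2 <- length(ib)
  m1 <- colMeans(Y[ia, , drop = FALSE])
  m2 <- colMeans(Y[ib, , drop = FALSE])
  v1 <- apply(Y[ia, , drop = FALSE], 2, var)
  v2 <- apply(Y[ib, , drop = FALSE], 2, var)
  s2p <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(s2p * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, p = 2 * pt(abs(t), df, lower.tail = FALSE), df = df)
}

#' Voxelwise 2 x 2 between-subject factorial ANOVA on contrast maps
#'
#' Per voxel, fits `value ~ dyslexia * dyscalculia` with sum-to-zero coding
#' and reports Type III F tests for the dyslexia main effect, the
#' dyscalculia main effect and their interaction (with one numerator degree
#' of freedom each, the Type III F equals the squared coefficient t in the
#' effect-coded full model, exact also for the unbalanced 22/14/8/8
#' design). Alongside, directional two-sample pooled-t maps are produced
#' for the planned group comparisons (TD vs DL+DLDC, TD vs DC+DLDC, TD vs
#' DL, TD vs DC, TD vs DLDC) plus a one-way F across DL/DC/DLDC.
#' Comparisons whose groups are absent are skipped with a warning.
#'
#' @param contrast_maps Per-subject list of `contrast_map_vol` or 3D
#'   arrays, in the same order as `flags`.
#' @param flags Data frame with logical columns `dyslexia`, `dyscalculia`
#'   (one row per subject).
#' @param mask Logical 3D array restricting the analysis (the FDR
#'   denominator must exclude background).
#' @return Named list of `stat_map` objects: `DL_main`, `DC_main`,
#'   `DLxDC`, `TD_gt_DL_DLDC`, `TD_gt_DC_DLDC`, `TD_gt_DL`, `TD_gt_DC`,
#'   `TD_gt_DLDC`, `DL_DC_DLDC_oneway`.
#' @export
voxelwise_factorial_anova <- function(contrast_maps, flags, mask = NULL) {
  stopifnot(nrow(flags) == length(contrast_maps),
            all(c("dyslexia", "dyscalculia") %in% names(flags)))
  mm <- maps_to_matrix(contrast_maps, mask)
  Y <- mm$Y
  n <- nrow(Y)
  dl <- ifelse(flags$dyslexia, 1, -1)
  dc <- ifelse(flags$dyscalculia, 1, -1)
  cells <- table(dl, dc)
  if (length(cells) < 4 || any(cells < 2))
    stop("the factorial model needs >= 2 subjects in each of the 4 cells")
  X <- cbind(intercept = 1, dl = dl, dc = dc, dlxdc = dl * dc)
  fit <- lm.fit(X, Y)
  dof <- n - 4L
  sigma2 <- colSums(as.matrix(fit$residuals)^2) / dof
  xtx_inv <- chol2inv(chol(crossprod(X)))
  out <- list()
  for (eff in c("dl", "dc", "dlxdc")) {
    j <- match(eff, colnames(X))
    Fv <- as.matrix(fit$coefficients)[j, ]^2 / (sigma2 * xtx_inv[j, j])
    p <- pf(Fv, 1, dof, lower.tail = FALSE)
    p[sigma2 == 0] <- 0
    lab <- c(dl = "DL_main", dc = "DC_main", dlxdc = "DLxDC")[[eff]]
    out[[lab]] <- stat_map_obj(lab, Fv, p, c(1, dof), "F", mm$dims, mm$mask)
  }

  grp <- ifelse(flags$dyslexia & flags$dyscalculia, "DLDC",
                ifelse(flags$dyslexia, "DL",
                       ifelse(flags$dyscalculia, "DC", "TD")))
  pairwise <- list(
    TD_gt_DL_DLDC = list(a = "TD", b = c("DL", "DLDC")),
    TD_gt_DC_DLDC = list(a = "TD", b = c("DC", "DLDC")),
    TD_gt_DL = list(a = "TD", b = "DL"),
    TD_gt_DC = list(a = "TD", b = "DC"),
    TD_gt_DLDC = list(a = "TD", b = "DLDC"))
  for (lab in names(pairwise)) {
    ia <- which(grp %in% pairwise[[lab]]$a)
    ib <- which(grp %in% pairwise[[lab]]$b)
    if (length(ia) < 2 || length(ib) < 2) {
      warning("comparison ", lab, " skipped: a group is missing")
      next
    }
    tt <- two_sample_t(Y, ia, ib)
    out[[lab]] <- stat_map_obj(lab, tt$t, tt$p, tt$df, "t", mm$dims, mm$mask)
  }

  idx3 <- lapply(c("DL", "DC", "DLDC"), function(g) which(grp == g))
  if (all(vapply(idx3, length, integer(1)) >= 2)) {
    k <- 3L
    ns <- vapply(idx3, length, integer(1))
    gm <- lapply(idx3, function(i) colMeans(Y[i, , drop = FALSE]))
    allm <- colMeans(Y[unlist(idx3), , drop = FALSE])
    ssb <- Reduce(`+`, lapply(seq_len(k), function(i)
      ns[i] * (gm[[i]] - allm)^2))
    ssw <- Reduce(`+`, lapply(seq_len(k), function(i)
      colSums(sweep(Y[idx3[[i]], , drop = FALSE], 2, gm[[i]])^2)))
    df2 <- sum(ns) - k
    Fv <- (ssb / (k - 1)) / (ssw / df2)
    p <- pf(Fv, k - 1, df2, lower.tail = FALSE)
    p[ssw == 0] <- 0
    out$DL_DC_DLDC_oneway <- stat_map_obj("DL_DC_DLDC_oneway", Fv, p,
                                          c(k - 1, df2), "F",
                                          mm$dims, mm$mask)
  } else {
    warning("one-way DL/DC/DLDC comparison skipped: a group is missing")
  }
  out
}

#' Benjamini-Hochberg FDR thresholding of a p map
#'
#' Step-up FDR over the in-mask voxels: a voxel is suprathreshold when its
#' BH-adjusted p-value is at most `q`.
#'
#' @param p_grid 3D p-value array (or numeric vector), or a `stat_map`.
#' @param q FDR level.
#' @param mask Optional logical array restricting the correction.
#' @return A `threshold_result`: list with `mask` (same shape as input),
#'   `method`, `level`, `n_suprathreshold`.
#' @export
fdr_correct <- function(p_grid, q = 0.05, mask = NULL) {
  if (inherits(p_grid, "stat_map")) p_grid <- p_grid$p_values
  check_fraction(q, "q")
  if (is.null(mask)) mask <- !is.na(p_grid)
  idx <- which(mask & !is.na(p_grid))
  p <- p_grid[idx]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  rej <- array(FALSE, dim = if (is.null(dim(p_grid))) length(p_grid)
               else dim(p_grid))
  if (length(p)) rej[idx] <- p.adjust(p, method = "BH") <= q
  structure(list(mask = rej, method = "fdr", level = q,
                 n_suprathreshold = sum(rej)),
            class = "threshold_result")
}

#' Uncorrected p < alpha thresholding
#'
#' Strict elementwise comparison: `p` exactly equal to `alpha` is not
#' suprathreshold.
#'
#' @inheritParams fdr_correct
#' @param alpha Uncorrected level (default 0.001).
#' @return A `threshold_result`.
#' @export
uncorrected_mask <- function(p_grid, alpha = 0.001, mask = NULL) {
  if (inherits(p_grid, "stat_map")) p_grid <- p_grid$p_values
  check_fraction(alpha, "alpha")
  if (is.null(mask)) mask <- !is.na(p_grid)
  keep <- which(mask & !is.na(p_grid))
  rej <- array(FALSE, dim = if (is.null(dim(p_grid))) length(p_grid)
               else dim(p_grid))
  rej[keep] <- p_grid[keep] < alpha
  structure(list(mask = rej, method = "uncorrected", level = alpha,
                 n_suprathreshold = sum(rej)),
            class = "threshold_result")
}
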