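#' Gaussian spatial smoothing of a 3D or 4D volume
#'
#' Separable isotropic Gaussian filter with
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis, expressed in voxel units via
#' `voxel_size_mm`. Boundaries are reflective, so constant fields are
#' preserved exactly and small synthetic grids suffer no rim attenuation.
#' `fwhm_mm = 0` is the identity.
#'
#' @param grid 3D array, or 4D array smoothed volume-by-volume.
#' @param fwhm_mm Full width at half maximum of the kernel (mm).
#' @param voxel_size_mm Isotropic voxel size (mm).
#' @return Array of the same shape.
#' @export
smooth_volume <- function(grid, fwhm_mm = 10, voxel_size_mm = 2.2) {
  check_positive(voxel_size_mm, "voxel_size_mm")
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) return(grid)
  nd <- length(dim(grid))
  if (!nd %in% c(3, 4)) stop("'grid' must be a 3D or 4D array")
  if (nd == 4) {
    out <- grid
    for (v in seq_len(dim(grid)[4]))
      out[, , , v] <- smooth_volume(grid[, , , v], fwhm_mm, voxel_size_mm)
    return(out)
  }
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  rad <- max(1L, ceiling(4 * sigma))
  off <- (-rad):rad
  kern <- exp(-off^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  smat <- function(d) {
    S <- matrix(0, d, d)
    for (i in seq_len(d)) {
      j <- i + off
      # reflect indices at the boundaries (mirror without repetition)
      j <- ifelse(j < 1, 2 - j, j)
      j <- ifelse(j > d, 2 * d - j, j)
      j <- pmin(pmax(j, 1L), d)
      for (k in seq_along(j)) S[i, j[k]] <- S[i, j[k]] + kern[k]
    }
    S
  }
  d <- dim(grid)
  a <- grid
  # axis 1
  a <- array(smat(d[1]) %*% matrix(a, d[1]), dim = d)
  # axis 2
  a <- aperm(array(smat(d[2]) %*% matrix(aperm(a, c(2, 1, 3)), d[2]),
                   dim = d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  a <- aperm(array(smat(d[3]) %*% matrix(aperm(a, c(3, 1, 2)), d[3]),
                   dim = d[c(3, 1, 2)]), c(2, 3, 1))
  a
}

#' Build the first-level design matrix for one run
#'
#' One column per format: the block boxcar convolved with the response
#' function (fixation is the implicit baseline and gets no column), the six
#' realignment parameters as nuisance regressors (demeaned; all-zero
#' parameters are dropped), and an intercept. Condition columns that are
#' identically zero (a run with no blocks of that format) are dropped with a
#' warning. Rank deficiency among the remaining columns is an error naming
#' the offending columns.
#'
#' @param design A `run_design`.
#' @param motion A `motion_trace` with `design$n_scans` rows.
#' @param hrf `"double_gamma"` or `"none"`.
#' @return A `design_matrix` object: list with `X`, `labels`,
#'   `condition_cols`, `n_scans`, `hrf`.
#' @export
build_design_matrix <- function(design, motion, hrf = "double_gamma") {
  stopifnot(inherits(design, "run_design"))
  if (nrow(motion) != design$n_scans)
    stop("motion trace rows and design n_scans disagree")
  Xc <- condition_regressors(design, hrf = hrf)
  zero <- colSums(abs(Xc)) == 0
  if (any(zero)) {
    warning("condition column(s) with no blocks dropped: ",
            paste(colnames(Xc)[zero], collapse = ", "))
    Xc <- Xc[, !zero, drop = FALSE]
  }
  M <- scale(unclass(motion), center = TRUE, scale = FALSE)
  keep_m <- apply(M, 2, function(x) any(x != 0))
  M <- M[, keep_m, drop = FALSE]
  X <- cbind(Xc, M, intercept = 1)
  labels <- c(colnames(Xc), colnames(unclass(motion))[keep_m], "intercept")
  colnames(X) <- labels
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- labels[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, labels = labels,
                 condition_cols = colnames(Xc),
                 n_scans = design$n_scans, hrf = hrf),
            class = "design_matrix")
}

#' Concatenated multi-run design matrix
#'
#' Stacks the retained runs' condition and (per-run demeaned) motion
#' regressors and adds one intercept per run, the symmetric way of pooling
#' runs when some were removed by QC.
#'
#' @param designs List of `run_design` objects (retained runs).
#' @param motions List of matching `motion_trace` objects.
#' @param hrf Response function.
#' @return A `design_matrix` with per-run intercepts `run1..runK`.
#' @export
build_multirun_design <- function(designs, motions, hrf = "double_gamma") {
  stopifnot(length(designs) >= 1, length(designs) == length(motions))
  parts <- lapply(seq_along(designs), function(i) {
    Xc <- condition_regressors(designs[[i]], hrf = hrf)
    M <- scale(unclass(motions[[i]]), center = TRUE, scale = FALSE)
    list(Xc = Xc, M = M, n = designs[[i]]$n_scans)
  })
  fmts <- colnames(parts[[1]]$Xc)
  Xc <- do.call(rbind, lapply(parts, `[[`, "Xc"))
  M <- do.call(rbind, lapply(parts, `[[`, "M"))
  keep_m <- apply(M, 2, function(x) any(x != 0))
  M <- M[, keep_m, drop = FALSE]
  ns <- vapply(parts, `[[`, integer(1), "n")
  runs <- matrix(0, sum(ns), length(ns),
                 dimnames = list(NULL, paste0("run", seq_along(ns))))
  at <- 0L
  for (i in seq_along(ns)) {
    runs[(at + 1):(at + ns[i]), i] <- 1
    at <- at + ns[i]
  }
  zero <- colSums(abs(Xc)) == 0
  if (any(zero)) {
    warning("condition column(s) with no blocks dropped: ",
            paste(fmts[zero], collapse = ", "))
    Xc <- Xc[, !zero, drop = FALSE]
  }
  X <- cbind(Xc, M, runs)
  labels <- colnames(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- labels[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, labels = labels, condition_cols = colnames(Xc),
                 n_scans = sum(ns), hrf = hrf),
            class = "design_matrix")
}

#' Voxelwise ordinary least squares GLM
#'
#' Fits every in-mask voxel's time series against the design matrix by OLS.
#'
#' @param bold 4D array (x, y, z, scan) or an n_scans x voxels matrix.
#' @param design A `design_matrix`.
#' @param mask Optional logical 3D array restricting the fit.
#' @return A `glm_fit`: list with `betas` (columns = voxels), `sigma2`
#'   (residual variance per voxel), `dof`, `xtx_inv_diag`, `labels`,
#'   `mask`, `dims`.
#' @export
fit_glm <- function(bold, design, mask = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  if (is.matrix(bold)) {
    Y <- bold
    dims <- NULL
  } else {
    dims <- dim(bold)[1:3]
    if (is.null(mask)) mask <- array(TRUE, dim = dims)
    Y <- t(matrix(bold, prod(dims), dim(bold)[4])[which(mask), , drop = FALSE])
  }
  if (nrow(Y) != nrow(X))
    stop("number of scans in 'bold' and design matrix disagree")
  fit <- lm.fit(X, Y)
  rank <- fit$rank
  dof <- nrow(X) - rank
  res <- as.matrix(fit$residuals)
  sigma2 <- colSums(res^2) / dof
  xtx_inv <- chol2inv(chol(crossprod(X)))
  betas <- as.matrix(fit$coefficients)
  rownames(betas) <- design$labels
  structure(list(betas = betas, sigma2 = sigma2, dof = dof,
                 xtx_inv_diag = diag(xtx_inv), labels = design$labels,
                 condition_cols = design$condition_cols,
                 mask = mask, dims = dims),
            class = "glm_fit")
}

vec_to_vol <- function(v, dims, mask) {
  a <- array(NA_real_, dim = dims)
  a[which(mask)] <- v
  a
}

#' Contrast map for one format versus fixation
#'
#' With fixation as the implicit GLM baseline, the format-versus-fixation
#' contrast estimate is that format's beta; `t = estimate / SE` with the
#' residual degrees of freedom of the (possibly concatenated) fit.
#'
#' @param fit A `glm_fit`.
#' @param contrast_label One of the fitted condition columns.
#' @param subject_id Identifier carried along with the map.
#' @return A `contrast_map_vol`: list with 3D `values` and `t_values`
#'   arrays (or vectors for matrix input), `dof`, `subject_id`,
#'   `contrast_label`.
#' @export
contrast_map <- function(fit, contrast_label, subject_id = NA_character_) {
  stopifnot(inherits(fit, "glm_fit"))
  if (!contrast_label %in% fit$condition_cols)
    stop("no fitted condition column named '", contrast_label, "'")
  j <- match(contrast_label, fit$labels)
  est <- fit$betas[j, ]
  se <- sqrt(fit$sigma2 * fit$xtx_inv_diag[j])
  tv <- est / se
  if (!is.null(fit$dims)) {
    est <- vec_to_vol(est, fit$dims, fit$mask)
    tv <- vec_to_vol(tv, fit$dims, fit$mask)
  }
  structure(list(values = est, t_values = tv, dof = fit$dof,
                 subject_id = subject_id, contrast_label = contrast_label),
            class = "contrast_map_vol")
}

#' Per-subject contrast maps from retained runs
#'
#' Smooths each retained run, then combines runs either by fitting one
#' concatenated GLM with per-run intercepts (default) or by averaging
#' per-run contrast estimates (`combine = "average"`, in which case t maps
#' are across-run mean / SE with runs - 1 degrees of freedom).
#'
#' @param bold_runs List of 4D arrays (retained runs).
#' @param designs,motions Matching lists of `run_design` / `motion_trace`.
#' @param mask Logical 3D array of analysed voxels.
#' @param fwhm_mm Smoothing kernel FWHM (0 disables smoothing).
#' @param voxel_size_mm Voxel size for smoothing.
#' @param hrf Response function.
#' @param combine `"concat"` or `"average"`.
#' @param subject_id Identifier stamped on the maps.
#' @return Named list (one `contrast_map_vol` per format).
#' @export
fit_subject_contrasts <- function(bold_runs, designs, motions, mask = NULL,
                                  fwhm_mm = 0, voxel_size_mm = 2.2,
                                  hrf = "double_gamma",
                                  combine = c("concat", "average"),
                                  subject_id = NA_character_) {
  combine <- match.arg(combine)
  stopifnot(length(bold_runs) >= 1,
            length(bold_runs) == length(designs),
            length(designs) == length(motions))
  if (fwhm_mm > 0)
    bold_runs <- lapply(bold_runs, smooth_volume, fwhm_mm = fwhm_mm,
                        voxel_size_mm = voxel_size_mm)
  fmts <- designs[[1]]$timing$formats
  if (combine == "concat" || length(bold_runs) == 1L) {
    des <- if (length(bold_runs) == 1L) {
      build_design_matrix(designs[[1]], motions[[1]], hrf = hrf)
    } else {
      build_multirun_design(designs, motions, hrf = hrf)
    }
    dims <- dim(bold_runs[[1]])[1:3]
    if (is.null(mask)) mask <- array(TRUE, dim = dims)
    Y <- do.call(rbind, lapply(bold_runs, function(b)
      t(matrix(b, prod(dims), dim(b)[4])[which(mask), , drop = FALSE])))
    fit <- fit_glm(Y, des)
    fit$dims <- dims
    fit$mask <- mask
    out <- lapply(fmts, function(f)
      contrast_map(fit, f, subject_id = subject_id))
  } else {
    per_run <- lapply(seq_along(bold_runs), function(i) {
      des <- build_design_matrix(designs[[i]], motions[[i]], hrf = hrf)
      fit_glm(bold_runs[[i]], des, mask = mask)
    })
    out <- lapply(fmts, function(f) {
      maps <- lapply(per_run, contrast_map, contrast_label = f,
                     subject_id = subject_id)
      vals <- simplify2array(lapply(maps, `[[`, "values"))
      nd <- length(dim(vals))
      mean_v <- apply(vals, seq_len(nd - 1), mean)
      k <- length(maps)
      tv <- if (k > 1) {
        sd_v <- apply(vals, seq_len(nd - 1), sd)
        mean_v / (sd_v / sqrt(k))
      } else maps[[1]]$t_values
      structure(list(values = mean_v, t_values = tv,
                     dof = max(1L, k - 1L), subject_id = subject_id,
                     contrast_label = f),
                class = "contrast_map_vol")
    })
  }
  names(out) <- fmts
  out
}

#' Write a 3D map as NIfTI
#' @param map 3D array or `contrast_map_vol` (its `values` are written).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel_size_mm Isotropic voxel size stored in the header.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path, voxel_size_mm = 2.2) {
  arr <- if (inherits(map, "contrast_map_vol")) map$values else map
  img <- RNifti::asNifti(arr, pixdim = rep(voxel_size_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#' @param path NIfTI file.
#' @return Numeric array.
#' @export
read_map_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}
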