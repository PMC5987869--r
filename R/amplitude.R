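#' Group structure of the simulated cohort
#'
#' Encodes the four diagnostic groups — typically developing (TD),
#' dyslexia-only (DL), dyscalculia-only (DC) and comorbid (DLDC) — with the
#' study's group sizes as defaults (22/14/8/8, total 52), and the latent
#' geometry of the disorder-related activation deviations. Each disorder
#' deviates from the TD mean pattern along a voxel pattern of norm
#' `effect_size_delta`; a fraction `rho_shared` of that deviation's variance
#' lies along a component common to DL and DC, so `rho_shared = 1` makes the
#' two disorders deviate identically (the similarity hypothesis the package
#' is built to probe) and `rho_shared = 0` makes them deviate orthogonally.
#'
#' @param n_td,n_dl,n_dc,n_dldc Group sizes (each >= 2; leave-pair-out
#'   cross-validation needs pairs).
#' @param effect_size_delta Norm of each disorder's deviation pattern, in
#'   map units (units of the GLM contrast estimates).
#' @param rho_shared Fraction in \[0, 1\] of deviation variance shared
#'   between DL and DC.
#' @param sigma_subject Standard deviation of per-subject, per-voxel
#'   idiosyncratic pattern noise (map units).
#' @param sigma_noise Standard deviation of scan-level BOLD noise used when
#'   time series are synthesised (signal units).
#' @param comorbid_rule How the comorbid group's deviation combines the two
#'   disorder deviations: `"additive"` (sum; the default) or `"average"`.
#' @return An object of class `group_structure`.
#' @export
group_structure <- function(n_td = 22, n_dl = 14, n_dc = 8, n_dldc = 8,
                            effect_size_delta = 3.5, rho_shared = 1,
                            sigma_subject = 1, sigma_noise = 1,
                            comorbid_rule = c("additive", "average")) {
  for (nm in c("n_td", "n_dl", "n_dc", "n_dldc"))
    check_count(get(nm), nm, min = 2L)
  check_fraction(rho_shared, "rho_shared")
  if (effect_size_delta < 0) stop("'effect_size_delta' must be >= 0")
  if (sigma_subject < 0 || sigma_noise < 0)
    stop("dispersion parameters must be >= 0")
  comorbid_rule <- match.arg(comorbid_rule)
  structure(list(n_td = as.integer(n_td), n_dl = as.integer(n_dl),
                 n_dc = as.integer(n_dc), n_dldc = as.integer(n_dldc),
                 effect_size_delta = effect_size_delta,
                 rho_shared = rho_shared, sigma_subject = sigma_subject,
                 sigma_noise = sigma_noise, comorbid_rule = comorbid_rule),
            class = "group_structure")
}

#' Subject table implied by a group structure
#'
#' @param structure A [group_structure()].
#' @return Data frame with subject_id, dyslexia, dyscalculia (logicals) and
#'   group (factor TD/DL/DC/DLDC).
#' @export
cohort_subjects <- function(structure) {
  stopifnot(inherits(structure, "group_structure"))
  grp <- rep(c("TD", "DL", "DC", "DLDC"),
             c(structure$n_td, structure$n_dl, structure$n_dc,
               structure$n_dldc))
  n <- length(grp)
  data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    dyslexia = grp %in% c("DL", "DLDC"),
    dyscalculia = grp %in% c("DC", "DLDC"),
    group = factor(grp, levels = c("TD", "DL", "DC", "DLDC")))
}

#' Build a desk-scale ROI label volume
#'
#' Partitions a voxel grid into named regions of interest. With
#' `mask = "ellipsoid"` an in-brain mask (voxels inside the inscribed
#' ellipsoid) is cut into `length(roi_names)` slabs along the z axis,
#' standing in for lobe-level anatomical masks; `mask = "full"` labels every
#' voxel. Label 0 is background.
#'
#' @param grid_shape Integer vector of 3 grid dimensions.
#' @param roi_names Names of the regions (slabs, bottom to top).
#' @param mask `"ellipsoid"` or `"full"`.
#' @return 3D integer array with attribute `roi_names`.
#' @export
make_roi_labels <- function(grid_shape = c(16, 16, 16),
                            roi_names = c("occipital", "parietal",
                                          "frontal", "temporal"),
                            mask = c("ellipsoid", "full")) {
  mask <- match.arg(mask)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= length(roi_names)))
  d <- as.integer(grid_shape)
  idx <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  inside <- if (mask == "full") rep(TRUE, nrow(idx)) else {
    cx <- (d + 1) / 2
    ((idx$x - cx[1]) / (d[1] / 2))^2 + ((idx$y - cx[2]) / (d[2] / 2))^2 +
      ((idx$z - cx[3]) / (d[3] / 2))^2 <= 1
  }
  k <- length(roi_names)
  slab <- pmin(k, 1L + ((idx$z - 1L) * k) %/% d[3])
  lab <- ifelse(inside, slab, 0L)
  arr <- array(as.integer(lab), dim = d)
  attr(arr, "roi_names") <- roi_names
  arr
}

#' Generate per-subject latent activation amplitude maps
#'
#' For subject i in group g and format f, the per-voxel amplitude is
#' `A_i = mu_f + z_DL(g) * dev_DL + z_DC(g) * dev_DC + e_i`, where `z_DL`,
#' `z_DC` indicate the presence of each disorder, `e_i` is subject noise
#' with sd `sigma_subject`, and the deviations are built from mutually
#' orthogonal unit-norm voxel patterns `s`, `u_DL`, `u_DC` as
#' `dev_DL = delta * (sqrt(rho) * s + sqrt(1 - rho) * u_DL)` (and likewise
#' for DC), so that `cor(dev_DL, dev_DC) = rho_shared` by construction. The
#' comorbid group's deviation follows `comorbid_rule`. Patterns are drawn
#' independently per format. All latent truth is stored so downstream
#' estimates can be compared against it exactly.
#'
#' @param structure A [group_structure()].
#' @param grid_shape 3D grid dimensions (default 16^3 at 2.2 mm isotropic).
#' @param roi_labels Optional ROI label array from [make_roi_labels()];
#'   built with defaults when `NULL`.
#' @param formats Format labels.
#' @param seed Integer seed.
#' @param voxel_size_mm Isotropic voxel size, mm.
#' @return An object of class `amplitude_truth`: list with `maps`
#'   (per-subject list of per-format 3D arrays), `subjects`, `roi_labels`,
#'   `mask` (logical 3D array), `truth` (per-format mu, dev_dl, dev_dc,
#'   dev_dldc as 3D arrays), `structure`, `voxel_size_mm`.
#' @export
generate_amplitude_maps <- function(structure, grid_shape = c(16, 16, 16),
                                    roi_labels = NULL,
                                    formats = c("dots", "digits", "words"),
                                    seed = NULL, voxel_size_mm = 2.2) {
  stopifnot(inherits(structure, "group_structure"))
  if (is.null(roi_labels)) roi_labels <- make_roi_labels(grid_shape)
  if (!all(dim(roi_labels) == grid_shape))
    stop("roi_labels dimensions must match grid_shape")
  mask <- roi_labels > 0
  V <- sum(mask)
  if (V < 3) stop("in-mask grid too small for the latent pattern basis")
  subjects <- cohort_subjects(structure)
  rho <- structure$rho_shared
  delta <- structure$effect_size_delta

  res <- with_seed(seed, {
    truth <- list()
    maps <- vector("list", nrow(subjects))
    names(maps) <- subjects$subject_id
    for (f in formats) {
      mu <- 1 + 0.5 * rnorm(V)
      basis <- qr.Q(qr(matrix(rnorm(V * 3), V, 3)))
      s <- basis[, 1]; u_dl <- basis[, 2]; u_dc <- basis[, 3]
      dev_dl <- delta * (sqrt(rho) * s + sqrt(1 - rho) * u_dl)
      dev_dc <- delta * (sqrt(rho) * s + sqrt(1 - rho) * u_dc)
      dev_dldc <- switch(structure$comorbid_rule,
                         additive = dev_dl + dev_dc,
                         average = (dev_dl + dev_dc) / 2)
      truth[[f]] <- list(mu = mu, dev_dl = dev_dl, dev_dc = dev_dc,
                         dev_dldc = dev_dldc)
      for (i in seq_len(nrow(subjects))) {
        dev <- numeric(V)
        if (subjects$dyslexia[i] && subjects$dyscalculia[i]) {
          dev <- dev_dldc
        } else if (subjects$dyslexia[i]) {
          dev <- dev_dl
        } else if (subjects$dyscalculia[i]) {
          dev <- dev_dc
        }
        vals <- mu + dev + structure$sigma_subject * rnorm(V)
        arr <- array(0, dim = grid_shape)
        arr[mask] <- vals
        maps[[i]][[f]] <- arr
      }
    }
    list(truth = truth, maps = maps)
  })

  to_array <- function(v) { a <- array(0, dim = grid_shape); a[mask] <- v; a }
  truth_arrays <- lapply(res$truth, function(tf) lapply(tf, to_array))
  structure(list(maps = res$maps, subjects = subjects,
                 roi_labels = roi_labels, mask = mask,
                 truth = truth_arrays, structure = structure,
                 formats = formats, voxel_size_mm = voxel_size_mm),
            class = "amplitude_truth")
}

#' Empirical group-mean deviation patterns
#'
#' Estimates each disorder group's deviation from the TD mean pattern by
#' subtracting the TD group-mean map from the disorder group-mean map,
#' restricted to the in-brain mask. As subject noise shrinks, the sample
#' correlation between the DL and DC deviations approaches the configured
#' `rho_shared`.
#'
#' @param amp An `amplitude_truth` object.
#' @param format Format label.
#' @return List with vectors `dev_dl`, `dev_dc` (in-mask voxels) and their
#'   correlation `cor_dl_dc`.
#' @export
recover_group_deviations <- function(amp, format = amp$formats[1]) {
  stopifnot(inherits(amp, "amplitude_truth"))
  grp <- amp$subjects$group
  mean_map <- function(g) {
    ids <- which(grp == g)
    Reduce(`+`, lapply(ids, function(i) amp$maps[[i]][[format]])) /
      length(ids)
  }
  td <- mean_map("TD")
  dev_dl <- (mean_map("DL") - td)[amp$mask]
  dev_dc <- (mean_map("DC") - td)[amp$mask]
  list(dev_dl = dev_dl, dev_dc = dev_dc,
       cor_dl_dc = stats::cor(dev_dl, dev_dc))
}
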