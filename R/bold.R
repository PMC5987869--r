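#' Canonical double-gamma haemodynamic response function
#'
#' The standard delayed, dispersed BOLD impulse response: a gamma density
#' peaking near 5 s minus a 1/6-weighted undershoot gamma peaking near 15 s,
#' normalised to unit integral so a sustained block reaches a steady-state
#' response equal to the underlying amplitude.
#'
#' @param t Time points (s).
#' @return Response values at `t`.
#' @export
hrf_double_gamma <- function(t) {
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

#' Condition regressors for one run
#'
#' Builds one regressor per format: a boxcar over that format's blocks,
#' optionally convolved with the canonical double-gamma response, sampled at
#' the scan times `(0, TR, 2 TR, ...)`. Fixation is the implicit baseline and
#' gets no regressor.
#'
#' @param design A `run_design`.
#' @param hrf `"double_gamma"` or `"none"` (raw boxcars).
#' @param dt Microtime resolution (s) for the convolution grid.
#' @return `n_scans` x formats numeric matrix with format column names.
#' @export
condition_regressors <- function(design, hrf = c("double_gamma", "none"),
                                 dt = 0.1) {
  stopifnot(inherits(design, "run_design"))
  hrf <- match.arg(hrf)
  timing <- design$timing
  n <- design$n_scans
  fmts <- timing$formats
  total <- max(design$total_duration_s, n * timing$tr_s)
  grid_t <- seq(0, total + 32, by = dt)
  kern <- hrf_double_gamma(seq(0, 32, by = dt))
  kern <- kern / sum(kern * dt) * dt  # unit-sum discrete kernel
  out <- matrix(0, n, length(fmts), dimnames = list(NULL, fmts))
  scan_t <- (seq_len(n) - 1L) * timing$tr_s
  for (f in fmts) {
    ev <- design$events[design$events$condition == f, , drop = FALSE]
    box <- numeric(length(grid_t))
    for (k in seq_len(nrow(ev))) {
      box[grid_t >= ev$onset_s[k] &
            grid_t < ev$onset_s[k] + ev$duration_s[k]] <- 1
    }
    x <- if (hrf == "none") box else {
      cv <- stats::filter(c(box, numeric(length(kern))), kern,
                          method = "convolution", sides = 1)
      as.numeric(cv)[seq_along(box)]
    }
    x[is.na(x)] <- 0
    out[, f] <- x[pmin(length(x), round(scan_t / dt) + 1L)]
  }
  out
}

#' Synthesise a 4D BOLD run from latent amplitudes
#'
#' Forward model matched to the first-level GLM: each voxel's time series is
#' `baseline + sum_f amplitude_f(v) * x_f(t) + motion_coupling * m(t) +
#' AR(1) noise`, where `x_f` is the format regressor from
#' [condition_regressors()] (same response function the GLM uses), `m(t)` is
#' the sum of the six realignment parameters (rotations on the mm scale is
#' the caller's concern; the raw parameters are summed), and the noise is a
#' stationary AR(1) process with lag-1 autocorrelation `ar1` and marginal
#' standard deviation `sigma`.
#'
#' @param amplitude Named list of per-format 3D amplitude arrays (one entry
#'   per format in `design$timing$formats`), e.g. one subject's entry from
#'   [generate_amplitude_maps()].
#' @param design A `run_design`.
#' @param motion A `motion_trace` with `design$n_scans` rows.
#' @param noise List with `ar1` (lag-1 autocorrelation in \[0, 1)) and
#'   `sigma` (marginal sd, signal units).
#' @param motion_coupling Scalar coupling of the summed motion parameters
#'   into every voxel's signal.
#' @param baseline Constant signal offset.
#' @param mask Optional logical 3D array; voxels outside it are returned as
#'   exact zeros.
#' @param hrf Response function passed to [condition_regressors()].
#' @param seed Integer seed or `NULL`.
#' @return 4D array (x, y, z, scan).
#' @export
synthesize_bold <- function(amplitude, design, motion,
                            noise = list(ar1 = 0.3, sigma = 1),
                            motion_coupling = 0, baseline = 100,
                            mask = NULL, hrf = "double_gamma", seed = NULL) {
  stopifnot(inherits(design, "run_design"))
  fmts <- design$timing$formats
  if (!all(fmts %in% names(amplitude)))
    stop("'amplitude' must contain one 3D array per format")
  dims <- dim(amplitude[[fmts[1]]])
  if (nrow(motion) != design$n_scans)
    stop("motion trace rows and design n_scans disagree")
  ar1 <- noise$ar1 %||% 0
  sigma <- noise$sigma %||% 0
  if (ar1 < 0 || ar1 >= 1) stop("'ar1' must lie in [0, 1)")
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  V <- sum(mask)
  n <- design$n_scans
  X <- condition_regressors(design, hrf = hrf)

  A <- vapply(fmts, function(f) amplitude[[f]][mask], numeric(V))
  sig <- tcrossprod(A, X)                # V x n
  sig <- sig + baseline
  if (motion_coupling != 0) {
    m <- rowSums(unclass(motion))
    sig <- sig + rep(motion_coupling * m, each = V)
  }
  if (sigma > 0) {
    e <- with_seed(seed, matrix(rnorm(V * n), V, n))
    if (ar1 > 0) {
      e <- e * sqrt(1 - ar1^2)
      e[, 1] <- e[, 1] / sqrt(1 - ar1^2)
      for (t in 2:n) e[, t] <- ar1 * e[, t - 1] + e[, t]
    }
    sig <- sig + sigma * e
  }
  out <- array(0, dim = c(dims, n))
  idx <- which(mask)
  flat <- matrix(out, prod(dims), n)
  flat[idx, ] <- sig
  array(flat, dim = c(dims, n))
}
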