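# shared fixture builders (everything is generated in code at test time)

# per-subject 3D maps from a subjects x voxels matrix, as run_mvpa_suite
# and extract_patterns expect them
matrix_to_maps <- function(X, dims = c(ncol(X), 1, 1)) {
  stopifnot(prod(dims) == ncol(X))
  maps <- lapply(seq_len(nrow(X)), function(i) array(X[i, ], dims))
  names(maps) <- sprintf("sub-%03d", seq_len(nrow(X)))
  maps
}

# two-group Gaussian pattern sample: group B shifted by `dev` (a vector of
# per-voxel offsets); returns a centered pattern_matrix
two_group_patterns <- function(n_a, n_b, v, dev = numeric(v), sd = 1,
                               labels = c("TD", "DL"), seed = NULL) {
  arithmvpa:::with_seed(seed, {
    XA <- matrix(rnorm(n_a * v, sd = sd), n_a, v)
    XB <- matrix(rnorm(n_b * v, sd = sd), n_b, v) +
      matrix(dev, n_b, v, byrow = TRUE)
    maps <- matrix_to_maps(rbind(XA, XB))
    pat <- extract_patterns(maps, array(TRUE, c(v, 1, 1)),
                            rep(labels, c(n_a, n_b)))
    mean_center_subject(pat)
  })
}

# tiny run design + still motion for first-level tests
tiny_run <- function(items = 1L, blocks = 2L, tr = 3, seed = 1,
                     run_index = 1L) {
  tp <- timing_params(items_per_block = items, blocks_per_format = blocks,
                      tr_s = tr)
  rd <- generate_run_design(tp, run_index = run_index, seed = seed)
  mo <- generate_motion_trace(rd$n_scans, severity = 0.02,
                              seed = seed + 1000L)
  list(timing = tp, design = rd, motion = mo)
}
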