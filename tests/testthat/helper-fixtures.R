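# Shared fixtures built in code.

# Noise-free simulation parameters with a given target think amplitude.
quiet_params <- function(think = 2, background = numeric()) {
  sim_params(noise_sd = 0, drift_amplitude = 0, global_sd = 0,
             amplitudes = list(target = c(think = think),
                               background = background))
}

# A statmap from a function of voxel indices on a small grid.
grid_statmap <- function(gs, f, stat_type = "z") {
  arr <- array(0, gs)
  idx <- arrayInd(seq_len(prod(gs)), gs)
  arr[] <- f(idx[, 1], idx[, 2], idx[, 3])
  statmap(arr, stat_type = stat_type)
}

# Cuboid logical mask on a grid.
cube_mask <- function(gs, lo, hi) {
  m <- array(FALSE, gs)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

# Subject contrast maps sharing a true effect inside `mask` plus
# independent voxel noise; returns a list of nf_statmap.
effect_subject_maps <- function(n_subjects, gs, mask = NULL, effect = 0,
                                noise_sd = 1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_subjects), function(i) {
    arr <- array(rnorm(prod(gs), sd = noise_sd), gs)
    if (!is.null(mask)) arr[mask] <- arr[mask] + effect
    statmap(arr, stat_type = "contrast")
  })
}
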