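# Functional and structural labeling of statistic maps: spatial correlation
# with template network maps, probabilistic-atlas parcellation, and
# tri-color paradigm-overlap maps.

#' Spatial correlation of a statistic map with template networks
#'
#' Pearson correlation, over in-mask voxels, between the (by default
#' unthresholded) statistic map and each template weight map. The mask is
#' the intersection of the map's and the template set's masks. The
#' correlation is invariant to any positive affine transform of the map.
#'
#' @param map An `nf_statmap`.
#' @param templates An `nf_template_set` (see [make_template_set()]).
#' @return An `nf_label_report` tibble, one row per template, sorted by
#'   decreasing r: `template` (index), `label`, `r`.
#' @export
spatial_correlation <- function(map, templates) {
  stopifnot(inherits(map, "nf_statmap"), inherits(templates, "nf_template_set"))
  grid <- dim(map$values)
  if (!identical(grid, dim(templates$maps)[1:3])) {
    abort("Map and templates are on different grids.", class = "rtnf_data_error")
  }
  mask <- map$mask & templates$mask
  if (sum(mask) < 10) {
    abort("Mask overlap below 10 voxels.", class = "rtnf_data_error")
  }
  v <- map$values[mask]
  if (stats::sd(v) == 0) {
    abort("Statistic map has zero variance within the mask.",
          class = "rtnf_data_error")
  }
  n_t <- dim(templates$maps)[4]
  r <- vapply(seq_len(n_t), function(k) {
    tv <- templates$maps[, , , k][mask]
    if (stats::sd(tv) == 0) {
      abort(sprintf("Template %d has zero variance within the mask.", k),
            class = "rtnf_data_error")
    }
    stats::cor(v, tv)
  }, numeric(1))
  out <- tibble(template = seq_len(n_t), label = templates$labels, r = r) |>
    dplyr::arrange(dplyr::desc(.data$r))
  structure(out, class = c("nf_label_report", class(out)),
            mask_voxels = sum(mask))
}

#' Parcellate a statistic map with a probabilistic atlas
#'
#' Binarizes each atlas region at probability `p_thresh` and reports, per
#' region, the number of supra-threshold map voxels falling inside it and
#' their peak statistic.
#'
#' @param map An `nf_statmap`; voxels with nonzero values are counted (use a
#'   thresholded map).
#' @param atlas An `nf_atlas` (see [make_probabilistic_atlas()]).
#' @param p_thresh Probability threshold for region membership.
#' @return A tibble, one row per region: `region`, `label`, `n_voxels`,
#'   `peak_stat` (`NA` when the region holds no active voxel).
#' @export
parcellate <- function(map, atlas, p_thresh = 0.25) {
  stopifnot(inherits(map, "nf_statmap"), inherits(atlas, "nf_atlas"))
  if (!identical(dim(map$values), dim(atlas$prob)[1:3])) {
    abort("Map and atlas are on different grids.", class = "rtnf_data_error")
  }
  n_r <- dim(atlas$prob)[4]
  if (n_r < 1) {
    abort("Atlas holds no regions.", class = "rtnf_data_error")
  }
  bin <- lapply(seq_len(n_r), function(r) atlas$prob[, , , r] >= p_thresh)
  if (!any(vapply(bin, any, logical(1)))) {
    # no region survives thresholding: nothing to report
    return(tibble(region = integer(0), label = character(0),
                  n_voxels = integer(0), peak_stat = numeric(0)))
  }
  active <- map$mask & map$values != 0
  rows <- lapply(seq_len(n_r), function(r) {
    vox <- active & bin[[r]]
    tibble(region = r, label = atlas$labels[r],
           n_voxels = sum(vox),
           peak_stat = if (any(vox)) max(map$values[vox]) else NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' Paradigm-overlap map
#'
#' Labels each voxel by which paradigm's thresholded map activates it:
#' `both` for conjunction voxels (plus any voxel active in both thresholded
#' maps), `parallel_only` / `serial_only` for voxels unique to one map, and
#' `none` elsewhere. The three active labels are pairwise disjoint and
#' cover the union of the two thresholded maps.
#'
#' @param parallel_thr,serial_thr Thresholded `nf_statmap`s (nonzero voxels
#'   are active); typically the disjunction outputs.
#' @param conjunction_thr Thresholded conjunction `nf_statmap` (or logical
#'   array).
#' @return An `nf_overlap_map`: list with `labels` (character 3D array) and
#'   `counts` (tibble of voxels per label).
#' @export
overlap_map <- function(parallel_thr, serial_thr, conjunction_thr) {
  check_same_grid(parallel_thr, serial_thr)
  grid <- dim(parallel_thr$values)
  conj <- conjunction_voxels(conjunction_thr, grid)
  p_act <- parallel_thr$values != 0
  s_act <- serial_thr$values != 0
  lab <- array("none", grid)
  lab[p_act & !s_act & !conj] <- "parallel_only"
  lab[s_act & !p_act & !conj] <- "serial_only"
  lab[conj | (p_act & s_act)] <- "both"
  counts <- tibble(label = c("parallel_only", "serial_only", "both", "none"),
                   n_voxels = c(sum(lab == "parallel_only"),
                                sum(lab == "serial_only"),
                                sum(lab == "both"),
                                sum(lab == "none")))
  structure(list(labels = lab, counts = counts), class = "nf_overlap_map")
}

#' @export
print.nf_overlap_map <- function(x, ...) {
  cat("<nf_overlap_map>\n")
  print(x$counts)
  invisible(x)
}
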