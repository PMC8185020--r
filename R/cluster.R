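# Cluster-level inference on statistic maps: supra-threshold components by
# face (6-neighbor) connectivity, family-wise-error control by sign-flip
# permutation of subject maps (max-cluster-size null), and the derived
# conjunction (voxelwise minimum statistic) and disjunction (exclusive
# masking) analyses.

# Label connected components of a logical 3D array under face connectivity.
# Returns an integer array (0 = background) and a size table.
label_components <- function(supra) {
  d <- dim(supra)
  labels <- array(0L, d)
  idx_all <- which(supra)
  if (length(idx_all) == 0) {
    return(list(labels = labels, sizes = integer(0)))
  }
  nx <- d[1]; nxy <- d[1] * d[2]
  coords <- arrayInd(idx_all, d)
  lin <- function(x, y, z) x + (y - 1L) * nx + (z - 1L) * nxy
  in_set <- array(FALSE, d); in_set[idx_all] <- TRUE
  cur <- 0L
  sizes <- integer(0)
  for (s in seq_along(idx_all)) {
    start <- idx_all[s]
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    count <- 0L
    while (length(queue) > 0) {
      v <- queue
      count <- count + length(v)
      queue <- integer(0)
      ci <- arrayInd(v, d)
      for (step in list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                        c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))) {
        nb <- ci + matrix(step, nrow(ci), 3, byrow = TRUE)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        nl <- lin(nb[ok, 1], nb[ok, 2], nb[ok, 3])
        nl <- nl[in_set[nl] & labels[nl] == 0L]
        if (length(nl) > 0) {
          labels[nl] <- cur
          queue <- c(queue, nl)
        }
      }
      queue <- unique(queue)
    }
    sizes[cur] <- count
  }
  list(labels = labels, sizes = sizes)
}

max_cluster_size <- function(values, mask, z_form) {
  supra <- array(FALSE, dim(mask))
  supra[mask] <- values[mask] > z_form
  comp <- label_components(supra)
  if (length(comp$sizes) == 0) 0L else max(comp$sizes)
}

# Sign matrices for the permutation null: exhaustive (all 2^n patterns,
# identity included) when feasible, otherwise n_perm random draws.
sign_patterns <- function(n_subjects, n_perm) {
  if (2^n_subjects <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n_subjects)))
    list(signs = unname(signs), exhaustive = TRUE)
  } else {
    signs <- matrix(sample(c(1, -1), n_perm * n_subjects, replace = TRUE),
                    n_perm, n_subjects)
    list(signs = signs, exhaustive = FALSE)
  }
}

#' Cluster-level thresholding with permutation FWE correction
#'
#' Forms supra-threshold clusters (`z > z_form`, face connectivity) on a
#' group z map and retains clusters whose size is significant at level
#' `alpha` under the max-cluster-size null obtained by sign-flip
#' permutation of the subject maps: each permutation flips the sign of a
#' random subset of subjects, recomputes the group z map and records its
#' largest supra-threshold cluster. All `2^n` sign patterns are enumerated
#' when that is cheaper than `n_perm` draws. Without subject maps the
#' clusters are formed but carry `NA` corrected p-values and are all
#' retained.
#'
#' @param zmap Group `nf_statmap` (z).
#' @param z_form Cluster-forming threshold (z > 0).
#' @param alpha Cluster-level FWE significance threshold.
#' @param subject_maps Optional list of subject contrast `nf_statmap`s (or
#'   the matrix attached by [group_one_sample()]) used for the permutation
#'   null.
#' @param n_perm Number of permutations (upper bound; exhaustive
#'   enumeration used when `2^n <= n_perm`).
#' @param seed Integer seed for the permutation draws.
#' @param exclude Optional logical array of voxels to remove before
#'   thresholding (exclusive mask), applied to the observed and every
#'   permuted map.
#' @return An `nf_cluster_result`: list with `map` (thresholded
#'   `nf_statmap`, zero outside surviving clusters), `clusters` (tibble:
#'   `cluster`, `n_voxels`, `peak_z`, `peak_x/y/z`, `p_fwe`), and
#'   `null_max_size` (the permutation null sample).
#' @export
cluster_threshold <- function(zmap, z_form = 3.1, alpha = 0.05,
                              subject_maps = NULL, n_perm = 1000, seed = 1,
                              exclude = NULL) {
  stopifnot(inherits(zmap, "nf_statmap"), z_form > 0, alpha > 0, alpha < 1)
  mask <- zmap$mask
  if (!is.null(exclude)) mask <- mask & !exclude
  supra <- array(FALSE, dim(mask))
  supra[mask] <- zmap$values[mask] > z_form
  comp <- label_components(supra)

  M <- subject_matrix(subject_maps, zmap, mask)
  null_max <- NULL
  exhaustive <- FALSE
  if (!is.null(M) && length(comp$sizes) > 0) {
    sp <- with_seed(seed, sign_patterns(ncol(M), n_perm))
    exhaustive <- sp$exhaustive
    null_max <- vapply(seq_len(nrow(sp$signs)), function(i) {
      zp <- group_z_values(M, sp$signs[i, ])
      arr <- array(-Inf, dim(mask)); arr[mask] <- zp
      max_cluster_size(arr, mask, z_form)
    }, numeric(1))
  }

  cl <- cluster_table(zmap, comp, null_max, exhaustive)
  keep <- if (is.null(null_max)) rep(TRUE, nrow(cl)) else cl$p_fwe <= alpha
  out_vals <- array(0, dim(zmap$values))
  keep_ids <- cl$cluster[keep]
  sel <- comp$labels %in% keep_ids
  out_vals[sel] <- zmap$values[sel]
  thr_map <- statmap(out_vals, mask, zmap$voxel_mm,
                     stat_type = zmap$stat_type,
                     meta = c(zmap$meta,
                              list(z_form = z_form, alpha = alpha,
                                   method = if (is.null(null_max)) "uncorrected"
                                            else if (exhaustive) "sign_flip_exhaustive"
                                            else "sign_flip_permutation")))
  structure(list(map = thr_map, clusters = cl[keep, ],
                 all_clusters = cl, null_max_size = null_max,
                 labels = comp$labels),
            class = "nf_cluster_result")
}

subject_matrix <- function(subject_maps, zmap, mask) {
  if (is.null(subject_maps)) {
    M <- attr(zmap, "subject_values")
    if (is.null(M)) return(NULL)
    src_mask <- attr(zmap, "subject_mask")
    if (!is.null(src_mask) && !identical(src_mask, mask)) {
      if (all(mask[!src_mask] == FALSE)) {
        M <- M[mask[src_mask], , drop = FALSE]   # restriction to a sub-mask
      } else {
        return(NULL)
      }
    }
    if (nrow(M) != sum(mask)) return(NULL)
    return(M)
  }
  if (is.matrix(subject_maps)) return(subject_maps)
  vapply(subject_maps, function(m) m$values[mask], numeric(sum(mask)))
}

cluster_table <- function(zmap, comp, null_max, exhaustive) {
  k <- length(comp$sizes)
  if (k == 0) {
    return(tibble(cluster = integer(0), n_voxels = integer(0),
                  peak_z = numeric(0), peak_x = integer(0),
                  peak_y = integer(0), peak_z_idx = integer(0),
                  p_fwe = numeric(0)))
  }
  rows <- lapply(seq_len(k), function(i) {
    vox <- which(comp$labels == i)
    pk <- vox[which.max(zmap$values[vox])]
    ci <- arrayInd(pk, dim(zmap$values))
    p <- if (is.null(null_max)) {
      NA_real_
    } else if (exhaustive) {
      mean(null_max >= comp$sizes[i])
    } else {
      (1 + sum(null_max >= comp$sizes[i])) / (length(null_max) + 1)
    }
    tibble(cluster = i, n_voxels = comp$sizes[i],
           peak_z = zmap$values[pk],
           peak_x = ci[1], peak_y = ci[2], peak_z_idx = ci[3],
           p_fwe = p)
  })
  dplyr::bind_rows(rows)
}

#' Conjunction analysis (minimum statistic)
#'
#' Computes the voxelwise minimum of two group z maps and cluster-thresholds
#' it (defaults: clusters of z > 2.3 at FWE 0.01). When subject maps are
#' supplied for both groups the permutation null flips each group's
#' subjects independently and recomputes the minimum map.
#'
#' @param z1,z2 Group `nf_statmap`s on a common grid.
#' @param z_form,alpha Cluster-forming threshold and FWE level.
#' @param subject_maps1,subject_maps2 Optional per-group subject maps (or
#'   matrices) for the permutation null.
#' @param n_perm,seed Permutation settings.
#' @return An `nf_cluster_result` for the minimum-statistic map.
#' @export
conjunction <- function(z1, z2, z_form = 2.3, alpha = 0.01,
                        subject_maps1 = NULL, subject_maps2 = NULL,
                        n_perm = 1000, seed = 1) {
  check_same_grid(z1, z2)
  mask <- z1$mask & z2$mask
  vals <- pmin(z1$values, z2$values)
  vals[!mask] <- 0
  minmap <- statmap(vals, mask, z1$voxel_mm, stat_type = "z",
                    meta = list(analysis = "conjunction"))
  M1 <- subject_matrix(subject_maps1, z1, mask)
  M2 <- subject_matrix(subject_maps2, z2, mask)
  if (is.null(M1) || is.null(M2)) {
    return(cluster_threshold(minmap, z_form, alpha, subject_maps = NULL))
  }
  supra <- array(FALSE, dim(mask)); supra[mask] <- vals[mask] > z_form
  comp <- label_components(supra)
  null_max <- NULL
  exhaustive <- FALSE
  if (length(comp$sizes) > 0) {
    n_tot <- ncol(M1) + ncol(M2)
    sp <- with_seed(seed, sign_patterns(n_tot, n_perm))
    exhaustive <- sp$exhaustive
    null_max <- vapply(seq_len(nrow(sp$signs)), function(i) {
      s1 <- sp$signs[i, seq_len(ncol(M1))]
      s2 <- sp$signs[i, ncol(M1) + seq_len(ncol(M2))]
      zp <- pmin(group_z_values(M1, s1), group_z_values(M2, s2))
      arr <- array(-Inf, dim(mask)); arr[mask] <- zp
      max_cluster_size(arr, mask, z_form)
    }, numeric(1))
  }
  cl <- cluster_table(minmap, comp, null_max, exhaustive)
  keep <- if (is.null(null_max)) rep(TRUE, nrow(cl)) else cl$p_fwe <= alpha
  out_vals <- array(0, dim(vals))
  sel <- comp$labels %in% cl$cluster[keep]
  out_vals[sel] <- vals[sel]
  thr_map <- statmap(out_vals, mask, z1$voxel_mm, stat_type = "z",
                     meta = list(analysis = "conjunction", z_form = z_form,
                                 alpha = alpha))
  structure(list(map = thr_map, clusters = cl[keep, ], all_clusters = cl,
                 null_max_size = null_max, labels = comp$labels),
            class = "nf_cluster_result")
}

#' Disjunction analysis (exclusive masking)
#'
#' Removes the conjunction's voxels from a group z map and re-thresholds the
#' remainder (defaults: clusters of z > 3.1 at FWE 0.05), isolating
#' paradigm-specific activation.
#'
#' @param zmap Group `nf_statmap`.
#' @param conjunction_mask Logical 3D array, an `nf_statmap` of the
#'   thresholded conjunction (nonzero voxels are excluded), or an
#'   `nf_cluster_result` from [conjunction()].
#' @param z_form,alpha Cluster-forming threshold and FWE level.
#' @param subject_maps,n_perm,seed Permutation settings (see
#'   [cluster_threshold()]).
#' @return An `nf_cluster_result`.
#' @export
disjunction <- function(zmap, conjunction_mask, z_form = 3.1, alpha = 0.05,
                        subject_maps = NULL, n_perm = 1000, seed = 1) {
  excl <- conjunction_voxels(conjunction_mask, dim(zmap$values))
  cluster_threshold(zmap, z_form, alpha, subject_maps = subject_maps,
                    n_perm = n_perm, seed = seed, exclude = excl)
}

conjunction_voxels <- function(x, grid) {
  if (inherits(x, "nf_cluster_result")) x <- x$map
  if (inherits(x, "nf_statmap")) x <- x$values != 0
  x <- as.array(x)
  if (!identical(dim(x), as.integer(grid))) {
    abort("Conjunction mask grid does not match the statistic map.",
          class = "rtnf_data_error")
  }
  x & TRUE
}

#' @export
print.nf_cluster_result <- function(x, ...) {
  cat(sprintf("<nf_cluster_result: %d surviving cluster(s)>\n", nrow(x$clusters)))
  print(x$clusters)
  invisible(x)
}

#' Write a cluster table to TSV
#'
#' @param result An `nf_cluster_result`.
#' @param path Output file path.
#' @export
write_cluster_table <- function(result, path) {
  readr::write_tsv(result$clusters, path)
  invisible(path)
}
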