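test_that("component labeling uses face connectivity", {
  gs <- c(5, 5, 5)
  supra <- array(FALSE, gs)
  supra[1:2, 1, 1] <- TRUE          # one 2-voxel cluster
  supra[4, 4, 4] <- TRUE            # isolated voxel
  supra[5, 5, 5] <- TRUE            # diagonal neighbor: separate cluster
  comp <- rtnf:::label_components(supra)
  expect_equal(sort(comp$sizes), c(1L, 1L, 2L))
  expect_equal(max(comp$labels), 3L)

  # cross-check against igraph components on the lattice graph
  vox <- which(supra)
  ci <- arrayInd(vox, gs)
  adj <- outer(seq_along(vox), seq_along(vox), Vectorize(function(i, j) {
    sum(abs(ci[i, ] - ci[j, ])) == 1
  }))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  expect_equal(sort(igraph::components(g)$csize), sort(comp$sizes))
})

test_that("sub-threshold maps give empty results", {
  gs <- c(6, 6, 6)
  zm <- grid_statmap(gs, function(x, y, z) 0.5)
  res <- cluster_threshold(zm, z_form = 3.1, alpha = 0.05)
  expect_equal(nrow(res$clusters), 0)
  expect_true(all(res$map$values == 0))
})

test_that("a coherent strong effect survives as exactly one cluster", {
  gs <- c(8, 8, 8)
  mask <- cube_mask(gs, c(3, 3, 3), c(6, 6, 6))
  maps <- effect_subject_maps(8, gs, mask, effect = 6, noise_sd = 0.5, seed = 12)
  gz <- group_one_sample(maps)
  res <- cluster_threshold(gz, 3.1, 0.05, n_perm = 300, seed = 3)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$n_voxels, sum(mask))
  expect_lte(res$clusters$p_fwe, 0.05)
  # surviving voxels are a subset of the supra-threshold input voxels
  expect_true(all(gz$values[res$map$values != 0] > 3.1))
})

test_that("permutation null on 4 subjects matches exhaustive enumeration", {
  gs <- c(6, 6, 6)
  mask <- cube_mask(gs, c(2, 2, 2), c(4, 4, 4))
  maps <- effect_subject_maps(4, gs, mask, effect = 3, noise_sd = 1, seed = 13)
  gz <- group_one_sample(maps)
  z_form <- 2.0
  res <- cluster_threshold(gz, z_form, alpha = 0.25, n_perm = 1000, seed = 1)

  # independent enumeration of all 2^4 sign patterns with direct formulas
  M <- sapply(maps, function(m) as.vector(m$values))
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), 4)))
  oracle <- apply(signs, 1, function(sg) {
    Ms <- sweep(M, 2, sg, `*`)
    tt <- apply(Ms, 1, function(v) mean(v) / (sd(v) / 2))
    zz <- sign(tt) * qnorm(pt(abs(tt), 3, lower.tail = FALSE), lower.tail = FALSE)
    supra <- array(zz > z_form, gs)
    vox <- which(supra)
    if (length(vox) == 0) return(0L)
    ci <- arrayInd(vox, gs)
    adj <- outer(seq_along(vox), seq_along(vox), Vectorize(function(i, j) {
      sum(abs(ci[i, ] - ci[j, ])) == 1
    }))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    max(igraph::components(g)$csize)
  })
  expect_equal(sort(res$null_max_size), sort(as.numeric(oracle)))
  # observed max-cluster p from the table equals its enumeration rank
  obs_max <- max(res$all_clusters$n_voxels)
  expect_equal(min(res$all_clusters$p_fwe),
               mean(oracle >= obs_max))
})

test_that("permutation cluster correction controls family-wise error", {
  gs <- c(7, 7, 7)
  any_hit <- vapply(1:60, function(i) {
    maps <- effect_subject_maps(6, gs, seed = 400 + i)   # pure null
    gz <- group_one_sample(maps)
    res <- cluster_threshold(gz, 2.3, alpha = 0.05, n_perm = 100, seed = i)
    nrow(res$clusters) > 0
  }, logical(1))
  rate <- mean(any_hit)
  se <- sqrt(0.05 * 0.95 / length(any_hit))
  expect_lte(rate, 0.05 + 2 * se)
})

test_that("conjunction is the cluster-thresholded minimum statistic", {
  gs <- c(8, 8, 8)
  maskA <- cube_mask(gs, c(2, 2, 2), c(4, 4, 4))
  maskB <- cube_mask(gs, c(6, 6, 6), c(8, 8, 8))
  mapsA <- effect_subject_maps(6, gs, maskA, effect = 6, noise_sd = 0.1, seed = 14)
  mapsB <- effect_subject_maps(6, gs, maskB, effect = 6, noise_sd = 0.1, seed = 15)
  zA <- group_one_sample(mapsA)
  zB <- group_one_sample(mapsB)

  # min identity: conjunction of a map with itself forms exactly the
  # clusters of the map's own thresholding (the permutation null differs —
  # independent group flips — so only the cluster structure must agree)
  self <- conjunction(zA, zA, z_form = 2.3, alpha = 0.05, n_perm = 200, seed = 2)
  direct <- cluster_threshold(zA, 2.3, 0.05, n_perm = 200, seed = 2)
  expect_equal(self$all_clusters[c("cluster", "n_voxels", "peak_z")],
               direct$all_clusters[c("cluster", "n_voxels", "peak_z")])
  cube_id <- direct$all_clusters$cluster[which.max(direct$all_clusters$n_voxels)]
  expect_true(cube_id %in% self$clusters$cluster)
  expect_true(cube_id %in% direct$clusters$cluster)
  sel <- self$labels == cube_id
  expect_equal(self$map$values[sel], zA$values[sel])

  # disjoint activations: empty conjunction
  dis <- conjunction(zA, zB, n_perm = 200, seed = 2)
  expect_equal(nrow(dis$clusters), 0)

  # min-statistic property on the surviving voxels
  vals <- pmin(zA$values, zB$values)
  act <- self$map$values != 0
  expect_true(all(self$map$values[act] <= zA$values[act] + 1e-12))
  expect_true(all(dis$map$values == 0))
})

test_that("disjunction isolates paradigm-specific activation", {
  gs <- c(9, 9, 9)
  shared <- cube_mask(gs, c(2, 2, 2), c(4, 4, 4))
  unique_p <- cube_mask(gs, c(6, 6, 6), c(8, 8, 8))
  both <- shared | unique_p
  mapsP <- effect_subject_maps(8, gs, both, effect = 7, noise_sd = 0.4, seed = 16)
  mapsS <- effect_subject_maps(8, gs, shared, effect = 7, noise_sd = 0.4, seed = 17)
  zP <- group_one_sample(mapsP)
  zS <- group_one_sample(mapsS)
  conj <- conjunction(zP, zS, n_perm = 300, seed = 4)
  expect_gt(sum(conj$map$values != 0), 0)

  disj <- disjunction(zP, conj, n_perm = 300, seed = 4)
  act <- disj$map$values != 0
  # retains only the paradigm-unique region
  expect_true(all(which(act) %in% which(unique_p)))
  expect_gt(sum(act & unique_p), 0)
  expect_equal(sum(act & conj$map$values != 0), 0)

  # empty conjunction mask: disjunction = plain thresholding
  empty <- array(FALSE, gs)
  d2 <- disjunction(zP, empty, n_perm = 300, seed = 4)
  d3 <- cluster_threshold(zP, 3.1, 0.05, n_perm = 300, seed = 4)
  expect_equal(d2$map$values, d3$map$values)

  # map entirely inside the exclusive mask: empty result
  d4 <- disjunction(zS, array(TRUE, gs), n_perm = 100, seed = 4)
  expect_equal(nrow(d4$clusters), 0)
})
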