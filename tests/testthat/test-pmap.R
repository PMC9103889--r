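make_small_runs <- function(n_runs, n_frames, seed = 1) {
  prot <- generate_toy_protein(12, seed = seed)
  xyz <- as.matrix(prot[, c("x", "y", "z")])
  shift <- round(c(16, 16, 16) - colMeans(xyz))
  prot[, c("x", "y", "z")] <- sweep(xyz, 2, shift, "+")
  hot <- c(floor(max(prot$x[prot$heavy]) + 6) + 0.5, 16.5, 16.5)
  truth <- planted_truth(hot, occupancy = 0.5, box = c(32, 32, 32), seed = seed)
  runs <- lapply(seq_len(n_runs), function(k)
    generate_msmd_trajectory(prot, truth, n_frames = n_frames, n_probes = 3,
                             run_id = paste0("r", k), seed = seed * 100 + k))
  list(trajs = lapply(runs, `[[`, "trajectory"), truth = runs[[1]]$truth)
}

test_that("a single in-shell probe atom gives a single-support PMAP", {
  prot <- fix_residue("ALA", 1, c(5, 5, 5), cb = c(5, 6.5, 5))
  probe <- fix_probe_atoms(c(8.2, 5.2, 5.2))
  snap <- snapshot(10, rbind(prot, probe))
  traj <- trajectory("one", list(snap))
  grid <- grid_from_points(as.matrix(prot[, c("x", "y", "z")]), margin = 8)
  pm <- compute_pmap(traj, grid = grid)
  # all three probe atoms land in the shell; mass sums to 1
  expect_equal(sum(pm$grid$values), 1.0)

  # shrink the shell so only the anchor atom's voxel survives (mask centers
  # are voxel centers, so reference the center of the containing voxel)
  anchor_center <- voxel_centers(grid, voxel_of(grid, c(8.2, 5.2, 5.2)))
  tight_mask <- mask_within_distance(grid, anchor_center, 0.2)
  pm2 <- compute_pmap(traj, grid = grid, mask = tight_mask)
  expect_equal(max(pm2$grid$values), 1.0)
  expect_equal(sum(pm2$grid$values > 0), 1)
})

test_that("PMAP equals the flat frames-by-atoms occupancy oracle", {
  runs <- make_small_runs(1, 40, seed = 9)
  traj <- fit_protein_to_reference(runs$trajs[[1]])
  pm <- compute_pmap(traj)
  expect_equal(sum(pm$grid$values[pm$mask$member]), 1.0, tolerance = 1e-9)

  # independent flat loop: count probe heavy atoms per voxel, keep shell,
  # divide by the total in-shell count
  g <- pm$grid
  counts <- array(0, dim = g$shape)
  for (snap in traj$snapshots) {
    for (pr in probe_atoms(snap)) {
      h <- pr[pr$heavy, ]
      for (a in seq_len(nrow(h))) {
        idx <- floor((c(h$x[a], h$y[a], h$z[a]) - g$origin) / g$spacing) + 1
        if (all(idx >= 1) && all(idx <= g$shape))
          counts[idx[1], idx[2], idx[3]] <- counts[idx[1], idx[2], idx[3]] + 1
      }
    }
  }
  counts[!pm$mask$member] <- 0
  expect_equal(pm$grid$values, counts / sum(counts), tolerance = 1e-12)

  # degenerate: a mask far from every probe atom
  far_mask <- mask_within_distance(g, matrix(g$origin + 0.5, 1), 0.4)
  expect_error(compute_pmap(traj, grid = g, mask = far_mask), "degenerate")
})

test_that("max-PMAP dominates the runs and its shell sum is in [1, n_runs]", {
  runs <- make_small_runs(5, 25, seed = 10)
  ref <- runs$trajs[[1]]$snapshots[[1]]
  fitted <- lapply(runs$trajs, fit_protein_to_reference, reference = ref)
  prot <- as.matrix(protein_atoms(ref, heavy_only = TRUE)[, c("x", "y", "z")])
  grid <- grid_from_points(prot)
  mask <- mask_within_distance(grid, prot, 5)
  pmaps <- lapply(fitted, compute_pmap, grid = grid, mask = mask)

  mp <- compute_max_pmap(pmaps)
  expect_equal(mp$n_runs, 5)
  for (pm in pmaps) expect_true(all(mp$grid$values >= pm$grid$values))
  shell_sum <- sum(mp$grid$values[mask$member])
  expect_gte(shell_sum, 1.0)
  expect_lte(shell_sum, 5.0)

  # k = 1: the max-PMAP is the PMAP
  expect_equal(compute_max_pmap(pmaps[1])$grid$values, pmaps[[1]]$grid$values)

  # masks must be shared
  other <- mask_within_distance(grid, prot, 4.5)
  pm_other <- compute_pmap(fitted[[2]], grid = grid, mask = other)
  expect_error(compute_max_pmap(list(pmaps[[1]], pm_other)), "mask")
})

test_that("preferable surface threshold is inclusive and sweeps are nested", {
  g <- grid3d(c(0, 0, 0), c(5, 5, 5), 1)
  mask <- mask_within_distance(g, c(2.5, 2.5, 2.5), 100)
  g$values[2, 2, 2] <- 0.2
  g$values[3, 3, 3] <- 0.6
  g$values[4, 4, 4] <- 0.2
  g$values <- g$values / sum(g$values)
  g$values <- g$values * 5  # fake max-PMAP-like scale with a 0.2 voxel
  g$values[2, 2, 2] <- 0.2  # force the exact boundary value
  mp <- structure(list(grid = g, mask = mask, n_runs = 1), class = "max_pmap")

  s <- preferable_surface(mp, 0.2)
  expect_true(s$member[2, 2, 2])  # exactly 0.2 is a member

  expect_warning(preferable_surface(mp, 10), "empty")

  sizes <- vapply(c(0.1, 0.2, 0.4),
                  function(th) nrow(preferable_surface(mp, th)$voxels),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))  # nested decreasing surfaces
})

test_that("PMAP voxel assignment is invariant under lattice-compatible rigid moves", {
  runs <- make_small_runs(1, 20, seed = 12)
  traj <- runs$trajs[[1]]
  prot <- as.matrix(protein_atoms(traj$snapshots[[1]],
                                  heavy_only = TRUE)[, c("x", "y", "z")])
  grid <- grid_from_points(prot)
  mask <- mask_within_distance(grid, prot, 5)
  pm <- compute_pmap(traj, grid = grid, mask = mask)

  # integer translation moves grid and atoms together: values identical
  tr <- c(3, -2, 5)
  traj2 <- fix_transform_traj(traj, diag(3), tr)
  grid2 <- grid3d(grid$origin + tr, grid$shape, grid$spacing)
  mask2 <- mask_within_distance(grid2, sweep(prot, 2, tr, "+"), 5)
  pm2 <- compute_pmap(traj2, grid = grid2, mask = mask2)
  expect_identical(pm2$grid$values, pm$grid$values)

  # 90-degree rotation about z maps the lattice onto itself: the value
  # multiset on the shell is unchanged
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  traj3 <- fix_transform_traj(traj, R90, c(0, 0, 0))
  prot3 <- apply_rigid(prot, R90, c(0, 0, 0))
  grid3 <- grid_from_points(prot3)
  mask3 <- mask_within_distance(grid3, prot3, 5)
  pm3 <- compute_pmap(traj3, grid = grid3, mask = mask3)
  expect_equal(sort(pm3$grid$values[pm3$grid$values > 0]),
               sort(pm$grid$values[pm$grid$values > 0]), tolerance = 1e-12)
})
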