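test_that("snapshot schedule follows the half-open (t_start, t_end] convention", {
  expect_length(snapshot_schedule(0, 0, 10), 0)
  # brute-force enumeration oracle
  expect_equal(snapshot_schedule(0, 1000, 10), seq(10, 1000, by = 10))
  set.seed(14)
  for (rep in 1:50) {
    t0 <- runif(1, 0, 1e4)
    t1 <- t0 + runif(1, 0, 1e4)
    dt <- runif(1, 1, 100)
    expect_length(snapshot_schedule(t0, t1, dt), floor((t1 - t0) / dt + 1e-9))
  }
  expect_error(snapshot_schedule(0, 100, 0), "interval")
  expect_error(snapshot_schedule(100, 0, 10), "t_end")
})

test_that("probe count from concentration uses Avogadro rounding and is linear", {
  # 0.25 * 6.02214076e23 * 1e6 * 1e-27 = 150.55, rounds to 151
  expect_identical(probe_count_for_concentration(1e6, 0.25), 151L)
  expect_error(probe_count_for_concentration(1e6, 0), "molarity")
  expect_error(probe_count_for_concentration(-1, 0.25), "box_volume")
  for (v in c(5e5, 1e6, 2e6, 4e6)) {
    n1 <- probe_count_for_concentration(v, 0.25)
    n2 <- probe_count_for_concentration(2 * v, 0.25)
    expect_lte(abs(n2 - 2 * n1), 1)  # linear to within rounding
  }
})

test_that("multi-model PDB writer/reader round-trips a synthetic trajectory", {
  prot <- generate_toy_protein(8, seed = 2)
  truth <- planted_truth(c(20.5, 10.5, 10.5), occupancy = 0.8,
                         box = c(30, 30, 30))
  gen <- generate_msmd_trajectory(prot, truth, n_frames = 5, n_probes = 2,
                                  seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(gen$trajectory, path)
  back <- read_multimodel_pdb(path, "PRB")

  expect_length(back$snapshots, 5)
  for (m in seq_len(5)) {
    a0 <- gen$trajectory$snapshots[[m]]$atoms
    a1 <- back$snapshots[[m]]$atoms
    expect_equal(nrow(a1), nrow(a0))
    expect_equal(a1$name, a0$name)
    expect_equal(a1$resname, a0$resname)
    expect_equal(a1$is_probe, a0$is_probe)
    expect_equal(as.matrix(a1[, c("x", "y", "z")]),
                 as.matrix(a0[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
  expect_equal(back$snapshots[[1]]$box, c(30, 30, 30))
  expect_length(probe_atoms(back$snapshots[[1]]), 2)

  expect_error(read_multimodel_pdb(path, "XXX"), "probe residue name")
})

test_that("PDB reader rejects malformed trajectories", {
  prot <- generate_toy_protein(5, seed = 4)
  truth <- planted_truth(c(18.5, 9.5, 9.5), box = c(26, 26, 26))
  gen <- generate_msmd_trajectory(prot, truth, n_frames = 2, n_probes = 1,
                                  seed = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(gen$trajectory, path)

  lines <- readLines(path)
  no_model <- lines[!grepl("^(MODEL|ENDMDL)", lines)]
  f1 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(no_model, f1)
  expect_error(read_multimodel_pdb(f1, "PRB"), "no MODEL")

  # drop one atom from model 2 -> atom-count consistency error naming it
  atom_lines <- grep("^ATOM", lines)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[-atom_lines[length(atom_lines)]], f2)
  expect_error(read_multimodel_pdb(f2, "PRB"), "model 2")
})

test_that("kabsch recovers rigid motions and agrees with the quaternion oracle", {
  set.seed(31)
  x <- matrix(rnorm(36), ncol = 3)
  R <- fix_random_rotation()
  tr <- c(3, -2, 7)
  y <- apply_rigid(x, R, tr)

  f <- kabsch(x, y)
  expect_lt(f$rmsd, 1e-9)
  expect_equal(f$rotation, R, tolerance = 1e-9)
  expect_equal(f$translation, tr, tolerance = 1e-9)

  # noisy case: must match Horn's quaternion method
  for (rep in 1:20) {
    x <- matrix(rnorm(30), ncol = 3)
    y <- apply_rigid(x, fix_random_rotation(), rnorm(3)) +
      matrix(rnorm(30, sd = 0.1), ncol = 3)
    f1 <- kabsch(x, y)
    f2 <- oracle_horn_superpose(x, y)
    expect_equal(f1$rmsd, f2$rmsd, tolerance = 1e-9)
    expect_equal(f1$rotation, f2$rotation, tolerance = 1e-6)
  }

  expect_error(kabsch(x[1:2, ], y[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "collinear")
})

test_that("fit_protein_to_reference aligns rigid copies and preserves geometry", {
  prot <- generate_toy_protein(10, seed = 6)
  truth <- planted_truth(c(22.5, 11.5, 11.5), box = c(32, 32, 32))
  gen <- generate_msmd_trajectory(prot, truth, n_frames = 4, n_probes = 1,
                                  seed = 7)
  traj <- gen$trajectory

  # scramble each frame by a different rigid motion
  set.seed(77)
  scrambled <- traj
  for (m in 2:4)
    scrambled$snapshots[[m]] <- fix_transform_traj(
      trajectory("tmp", traj$snapshots[m], timestep = 10),
      fix_random_rotation(), rnorm(3, sd = 5))$snapshots[[1]]

  fitted <- fit_protein_to_reference(scrambled)
  expect_lt(max(attr(fitted, "rmsd")), 1e-9)

  # intra-snapshot distances are untouched (the transform is rigid)
  a0 <- scrambled$snapshots[[2]]$atoms
  a1 <- fitted$snapshots[[2]]$atoms
  d0 <- dist(as.matrix(a0[, c("x", "y", "z")]))
  d1 <- dist(as.matrix(a1[, c("x", "y", "z")]))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-6)

  # idempotence: re-fitting an aligned trajectory changes nothing
  refit <- fit_protein_to_reference(fitted)
  expect_equal(refit$snapshots[[3]]$atoms$x, fitted$snapshots[[3]]$atoms$x,
               tolerance = 1e-6)

  # noisy frames: post-fit RMSD sits at the noise floor of the Horn oracle
  noisy <- traj
  set.seed(41)
  for (m in seq_along(noisy$snapshots)) {
    a <- noisy$snapshots[[m]]$atoms
    xyz <- apply_rigid(as.matrix(a[, c("x", "y", "z")]),
                       fix_random_rotation(), rnorm(3, sd = 3)) +
      matrix(rnorm(3 * nrow(a), sd = 0.1), ncol = 3)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    noisy$snapshots[[m]]$atoms <- a
  }
  fitted_n <- fit_protein_to_reference(noisy)
  ref_ca <- protein_atoms(noisy$snapshots[[1]])
  ref_ca <- as.matrix(ref_ca[ref_ca$name == "CA", c("x", "y", "z")])
  for (m in 2:4) {
    ca <- protein_atoms(noisy$snapshots[[m]])
    ca <- as.matrix(ca[ca$name == "CA", c("x", "y", "z")])
    expect_equal(attr(fitted_n, "rmsd")[m],
                 oracle_horn_superpose(ca, ref_ca)$rmsd, tolerance = 1e-9)
  }
})

test_that("trajectory constructor validates the time axis", {
  prot <- generate_toy_protein(5, seed = 8)
  mk <- function(t) snapshot(t, prot, box = NULL)
  expect_error(trajectory("r", list(mk(10), mk(10))), "increasing")
  expect_error(trajectory("r", list(mk(10), mk(20), mk(40))), "evenly spaced")
  tr <- trajectory("r", list(mk(10), mk(20), mk(30)))
  expect_equal(tr$timestep, 10)
})
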