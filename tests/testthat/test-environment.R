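test_that("residue classification matches the five-type scheme", {
  scheme <- residue_type_scheme()
  expected <- c(
    ASP = "acidic", GLU = "acidic",
    ARG = "basic", HIS = "basic", LYS = "basic",
    ASN = "hydrophilic", CYS = "hydrophilic", GLN = "hydrophilic",
    SER = "hydrophilic", THR = "hydrophilic",
    ALA = "hydrophobic", ILE = "hydrophobic", LEU = "hydrophobic",
    MET = "hydrophobic", PRO = "hydrophobic", VAL = "hydrophobic",
    PHE = "aromatic", TRP = "aromatic", TYR = "aromatic",
    GLY = "excluded")
  expect_equal(classify_residue(names(expected), scheme), unname(expected))
  expect_error(classify_residue("XYZ", scheme), "unknown residue")
  expect_warning(got <- classify_residue(c("ASP", "XYZ"), scheme,
                                         on_unknown = "exclude"), "XYZ")
  expect_equal(got, c("acidic", "excluded"))
})

test_that("residues_within applies the inclusive 4 A heavy-atom criterion", {
  probe <- matrix(c(0, 0, 0), 1)
  # backbones far away so only the CB distance (the controlled one) matters
  prot <- rbind(
    fix_residue("ASP", 1, c(50, 50, 50), cb = c(3.9, 0, 0)),
    fix_residue("SER", 2, c(50, 60, 50), cb = c(4.0, 0, 0)),
    fix_residue("LEU", 3, c(50, 70, 50), cb = c(4.1, 0, 0)))
  got <- residues_within(probe, prot, cutoff = 4)
  expect_setequal(got$resname, c("ASP", "SER"))  # 4.0 inclusive, 4.1 out

  far <- residues_within(matrix(c(500, 0, 0), 1), prot, cutoff = 4)
  expect_equal(nrow(far), 0)

  # hydrogen atoms never count
  protH <- prot
  protH$element[protH$name == "CB" & protH$resname == "LEU"] <- "H"
  protH$heavy[protH$name == "CB" & protH$resname == "LEU"] <- FALSE
  gotH <- residues_within(probe, protH, cutoff = 4.2)
  expect_false("LEU" %in% gotH$resname)
})

test_that("residues_within matches the all-pairs oracle on random systems", {
  set.seed(15)
  for (rep in 1:20) {
    n_res <- sample(10:50, 1)
    prot <- do.call(rbind, lapply(seq_len(n_res), function(r)
      fix_residue(sample(c("ASP", "LYS", "SER", "LEU", "PHE", "GLY"), 1), r,
                  runif(3, 0, 25), cb = runif(3, 0, 25))))
    probe <- matrix(runif(9, 0, 25), ncol = 3)
    got <- residues_within(probe, prot, cutoff = 4)
    expect_equal(sort(paste(got$chain, got$resno, sep = ":")),
                 oracle_residues_within(probe, prot, 4))
  }
})

test_that("probe_on_surface detection rules agree with the voxel-lookup oracle", {
  surf <- fix_surface(c(0, 0, 0), c(10, 10, 10),
                      rbind(c(3, 3, 3), c(7, 7, 7)))
  expect_true(probe_on_surface(matrix(c(2.5, 2.5, 2.5), 1), surf))
  expect_false(probe_on_surface(matrix(c(5.5, 5.5, 5.5), 1), surf))

  set.seed(16)
  for (rep in 1:50) {
    probe <- matrix(runif(9, -1, 11), ncol = 3)
    expect_identical(probe_on_surface(probe, surf),
                     oracle_on_surface(probe, surf))
  }

  # centroid and all-atom rules
  two <- rbind(c(2.5, 2.5, 2.5), c(5.6, 5.6, 5.6))  # one in, one out
  expect_true(probe_on_surface(two, surf, rule = "any"))
  expect_false(probe_on_surface(two, surf, rule = "all"))
  expect_false(probe_on_surface(two, surf, rule = "centroid"))
  both <- rbind(c(2.5, 2.5, 2.5), c(2.6, 2.6, 2.6))
  expect_true(probe_on_surface(both, surf, rule = "all"))
})

test_that("superpose_probe recovers rotations and exploits symmetry mappings", {
  tmpl <- toy_probe_template()
  ref <- tmpl$coords

  # identity
  f0 <- superpose_probe(ref, ref, tmpl$alignment_atoms, tmpl$symmetry_mappings)
  expect_lt(f0$rmsd, 1e-12)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-9)

  # random proper rotation: recovered, and agrees with the quaternion oracle
  set.seed(17)
  for (rep in 1:10) {
    R <- fix_random_rotation(); tr <- rnorm(3, sd = 4)
    mob <- apply_rigid(ref, R, tr)
    rownames(mob) <- rownames(ref)
    f <- superpose_probe(mob, ref, tmpl$alignment_atoms)
    expect_lt(f$rmsd, 1e-9)
    horn <- oracle_horn_superpose(mob, ref)
    expect_equal(f$rotation, horn$rotation, tolerance = 1e-6)
  }

  # benzene rotated 60 degrees in-plane: zero RMSD under the ring mappings
  benz <- probe_preset("benzene")
  th <- pi / 3
  R60 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  mob <- benz$coords %*% t(R60)
  rownames(mob) <- rownames(benz$coords)
  sym <- superpose_probe(mob, benz$coords, benz$alignment_atoms,
                         benz$symmetry_mappings)
  expect_lt(sym$rmsd, 1e-9)
  expect_equal(det(sym$rotation), 1, tolerance = 1e-9)

  # a non-planar probe whose atom swap is a reflection: only the symmetry
  # mapping rescues the fit, because reflections are never returned
  np <- rbind(A1 = c(0, 0, 0), A2 = c(1.5, 0, 0.4),
              A3 = c(0.7, 1.1, 0.9), A4 = c(0.7, -1.1, 0.9))
  swapped <- np[c("A1", "A2", "A4", "A3"), ]
  rownames(swapped) <- c("A1", "A2", "A3", "A4")  # labels swapped in place
  plain <- superpose_probe(swapped, np, rownames(np))
  expect_gt(plain$rmsd, 0.3)                 # improper fit refused, honest RMSD
  expect_equal(det(plain$rotation), 1, tolerance = 1e-9)
  mapped <- superpose_probe(swapped, np, rownames(np),
                            list(rownames(np), c("A1", "A2", "A4", "A3")))
  expect_lt(mapped$rmsd, 1e-12)

  # degenerate (collinear) alignment atoms
  line <- cbind(1:3, 0, 0); rownames(line) <- c("A1", "A2", "A3")
  expect_error(superpose_probe(line, line, c("A1", "A2", "A3")), "collinear")
})

test_that("extract_environments gates, counts and aligns correctly", {
  # constructed single-frame case: one on-surface probe, two residues in
  # contact, one far residue
  probe <- fix_probe_atoms(c(5.5, 5.5, 5.5))
  prot <- rbind(
    fix_residue("ASP", 1, c(50, 50, 50), cb = c(2.6, 5.5, 5.5)),
    fix_residue("LYS", 2, c(50, 60, 50), cb = c(5.5, 8.3, 5.5)),
    fix_residue("SER", 3, c(50, 70, 50), cb = c(25, 25, 25)))
  snap <- snapshot(10, rbind(prot, probe))
  traj <- trajectory("t", list(snap))
  surf <- fix_surface(c(0, 0, 0), c(12, 12, 12), rbind(c(6, 6, 6)))
  tmpl <- toy_probe_template()

  envs <- extract_environments(traj, surf, tmpl)
  expect_length(envs, 1)
  expect_equal(sort(envs[[1]]$residues$resname), c("ASP", "LYS"))
  expect_lt(envs[[1]]$rmsd, 1e-9)
  # probe is mapped onto the reference coordinates exactly
  got <- as.matrix(envs[[1]]$probe[, c("x", "y", "z")])
  rownames(got) <- envs[[1]]$probe$name
  expect_equal(got[tmpl$alignment_atoms, ],
               tmpl$coords[tmpl$alignment_atoms, ], tolerance = 1e-9,
               ignore_attr = TRUE)

  # probes that never touch the surface yield an empty set
  surf_far <- fix_surface(c(0, 0, 0), c(12, 12, 12), rbind(c(1, 1, 1)))
  expect_length(extract_environments(traj, surf_far, tmpl), 0)
})

test_that("environment counts on planted data equal the scripted gate count", {
  prot <- generate_toy_protein(12, seed = 19)
  xyz <- as.matrix(prot[, c("x", "y", "z")])
  prot[, c("x", "y", "z")] <- sweep(xyz, 2, round(c(16, 16, 16) - colMeans(xyz)), "+")
  hot <- c(floor(max(prot$x[prot$heavy]) + 6) + 0.5, 16.5, 16.5)
  truth <- planted_truth(hot, occupancy = 0.6, box = c(32, 32, 32))
  gen <- generate_msmd_trajectory(prot, truth, n_frames = 30, n_probes = 3,
                                  seed = 20)
  traj <- fit_protein_to_reference(gen$trajectory)
  pm <- compute_pmap(traj)
  surf <- preferable_surface(compute_max_pmap(list(pm)), 0.2)
  tmpl <- toy_probe_template()
  envs <- extract_environments(traj, surf, tmpl)

  # independent recount of (frame, copy) pairs passing the on-surface gate
  n_expected <- 0
  for (snap in traj$snapshots)
    for (pr in probe_atoms(snap, heavy_only = TRUE))
      if (oracle_on_surface(as.matrix(pr[, c("x", "y", "z")]), surf))
        n_expected <- n_expected + 1
  expect_length(envs, n_expected)
  expect_equal(attr(envs, "n_checked"), 30 * 3)
})
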