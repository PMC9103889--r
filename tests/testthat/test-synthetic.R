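test_that("toy protein honours composition, glycine and determinism", {
  p1 <- generate_toy_protein(10, composition = c(acidic = 1), seed = 1)
  expect_equal(length(unique(p1$resno)), 10)
  expect_true(all(unique(p1$resname) %in% c("ASP", "GLU")))
  expect_equal(sum(p1$name == "CB"), 10)
  # CA-CB bond length is the standard 1.53 A
  for (r in 1:3) {
    ca <- p1[p1$resno == r & p1$name == "CA", c("x", "y", "z")]
    cb <- p1[p1$resno == r & p1$name == "CB", c("x", "y", "z")]
    expect_equal(sqrt(sum((ca - cb)^2)), 1.53, tolerance = 1e-9)
  }

  pg <- generate_toy_protein(10, composition = c(glycine = 1), seed = 2)
  expect_true(all(pg$resname == "GLY"))
  expect_equal(sum(pg$name == "CB"), 0)

  pa <- generate_toy_protein(15, seed = 33)
  pb <- generate_toy_protein(15, seed = 33)
  expect_identical(pa, pb)

  expect_error(generate_toy_protein(10, composition = c(junk = 1)),
               "composition")
  expect_error(generate_toy_protein(2), "n_residues")
})

test_that("random placement respects the minimum-image separation", {
  pos <- random_probe_placement(c(100, 100, 100), 20, 20, seed = 3)
  expect_equal(dim(pos), c(20, 3))
  for (i in 1:19) for (j in (i + 1):20) {
    d <- pos[i, ] - pos[j, ]
    d <- d - 100 * round(d / 100)
    expect_gte(sqrt(sum(d^2)), 20)
  }
  expect_equal(dim(random_probe_placement(c(10, 10, 10), 1, 5, seed = 4)),
               c(1, 3))
  expect_error(random_probe_placement(c(30, 30, 30), 50, 25, seed = 5,
                                      max_attempts = 50),
               "packing infeasible")
})

test_that("planted truth validates occupancy and residue types", {
  expect_error(planted_truth(c(1, 1, 1), occupancy = 0), "occupancy")
  expect_error(planted_truth(c(1, 1, 1), occupancy = 1.2), "occupancy")
  expect_error(planted_truth(c(1, 1, 1),
                             residues = list(list(resname = "GLY",
                                                  offset = NULL))),
               "excluded")
  tt <- planted_truth(c(1, 1, 1), occupancy = 1)
  expect_s3_class(tt, "planted_truth")
})

test_that("hotspot visits follow the declared occupancy statistics", {
  prot <- generate_toy_protein(8, seed = 6)
  xyz <- as.matrix(prot[, c("x", "y", "z")])
  prot[, c("x", "y", "z")] <- sweep(xyz, 2, round(c(14, 14, 14) - colMeans(xyz)), "+")
  hot <- c(floor(max(prot$x[prot$heavy]) + 6) + 0.5, 14.5, 14.5)
  truth <- planted_truth(hot, occupancy = 0.3, box = c(30, 30, 30))

  # occupancy 1, jitter 0: the anchor atom sits on the hotspot every frame
  gen1 <- generate_msmd_trajectory(prot, planted_truth(hot, occupancy = 1,
                                                       box = c(30, 30, 30)),
                                   n_frames = 10, n_probes = 1, seed = 7,
                                   jitter = 0)
  for (snap in gen1$trajectory$snapshots) {
    pr <- probe_atoms(snap, "X:901")
    anchors <- as.matrix(pr[, c("x", "y", "z")])
    expect_true(any(apply(anchors, 1, function(p) sqrt(sum((p - hot)^2)) < 1e-9)))
  }

  # occupancy 0.3 over 500 frames: empirical visit fraction within the 99%
  # binomial band
  gen <- generate_msmd_trajectory(prot, truth, n_frames = 500, n_probes = 2,
                                  seed = 8, jitter = 0)
  visits <- sum(vapply(gen$trajectory$snapshots, function(snap) {
    pr <- probe_atoms(snap, "X:901")
    min(sqrt(colSums((t(as.matrix(pr[, c("x", "y", "z")])) - hot)^2))) < 1e-6
  }, logical(1)))
  band <- qbinom(c(0.005, 0.995), 500, 0.3)
  expect_gte(visits, band[1])
  expect_lte(visits, band[2])

  # bulk copies never intrude into the 6 A clearance of the protein
  prot_heavy <- as.matrix(prot[prot$heavy, c("x", "y", "z")])
  for (snap in gen$trajectory$snapshots[1:50]) {
    pr <- probe_atoms(snap, "X:902")
    d2 <- Inf
    for (a in seq_len(nrow(pr)))
      d2 <- min(d2, min((prot_heavy[, 1] - pr$x[a])^2 +
                          (prot_heavy[, 2] - pr$y[a])^2 +
                          (prot_heavy[, 3] - pr$z[a])^2))
    expect_gte(sqrt(d2), 6 - 4 * 0)  # jitter 0: exact clearance
  }

  # bit-reproducible under a fixed seed
  g1 <- generate_msmd_trajectory(prot, truth, n_frames = 5, n_probes = 2,
                                 seed = 99)
  g2 <- generate_msmd_trajectory(prot, truth, n_frames = 5, n_probes = 2,
                                 seed = 99)
  expect_identical(g1$trajectory$snapshots[[5]]$atoms,
                   g2$trajectory$snapshots[[5]]$atoms)
})

test_that("the generator records the expected reference-frame CB target", {
  prot <- generate_toy_protein(8, seed = 10)
  hot <- c(30.5, 15.5, 15.5)
  truth <- planted_truth(hot, box = c(40, 40, 40))
  gen <- generate_msmd_trajectory(prot, truth, n_frames = 1, n_probes = 1,
                                  seed = 11)
  tmpl <- toy_probe_template()
  off <- gen$truth$residues[[1]]$offset
  # default offset: 3 A from the template centroid along its symmetry axis
  expect_equal(as.numeric(tmpl$coords["C1", ] + off),
               as.numeric(colMeans(tmpl$coords) + c(-3, 0, 0)),
               tolerance = 1e-9)
  expect_equal(gen$truth$expected_cb_ref[[1]],
               as.numeric(tmpl$coords["C1", ] + off))
  # the planted CB really sits at hotspot + offset in the lab frame
  snap <- gen$trajectory$snapshots[[1]]
  planted <- protein_atoms(snap)
  planted <- planted[planted$resno == max(planted$resno) &
                       planted$name == "CB", ]
  expect_equal(c(planted$x, planted$y, planted$z), hot + off,
               tolerance = 1e-9)
})
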