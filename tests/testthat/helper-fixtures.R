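# Small in-code fixtures shared by the tests.

# one residue's atoms at explicit positions (CB optional)
fix_residue <- function(resname, resno, ca, cb = NULL, chain = "A") {
  names <- c("N", "CA", "C", "O")
  coords <- rbind(ca + c(-1.2, 0.8, 0), ca, ca + c(1.3, 0.7, 0),
                  ca + c(1.3, 0.7, 1.2))
  el <- c("N", "C", "C", "O")
  if (!is.null(cb)) {
    names <- c(names, "CB")
    coords <- rbind(coords, cb)
    el <- c(el, "C")
  }
  probemap::atom_table(name = names, resname = resname, chain = chain,
                       resno = resno, coords = coords, element = el)
}

# one rigid probe copy of the toy template, anchor atom C1 at `at`
fix_probe_atoms <- function(at, id = "X:901", resname = "PRB") {
  tmpl <- probemap::toy_probe_template()
  xyz <- sweep(tmpl$coords, 2, tmpl$coords["C1", ]) # anchor at origin
  xyz <- sweep(xyz, 2, at, "+")
  probemap::atom_table(name = rownames(tmpl$coords), resname = resname,
                       chain = "X", resno = 901, coords = xyz,
                       element = tmpl$elements, record = "HETATM",
                       is_probe = TRUE, probe_id = id)
}

# trajectory of a single one-atom probe following `pos` (n x 3), with a
# minimal 3-residue protein far away so constructors are satisfied
fix_probe_walk_traj <- function(pos, box = NULL, timestep = 10) {
  prot <- do.call(rbind, lapply(1:3, function(r)
    fix_residue("ALA", r, c(100 + 4 * r, 100, 100), cb = c(100 + 4 * r, 101.5, 100))))
  snaps <- lapply(seq_len(nrow(pos)), function(t) {
    probe <- probemap::atom_table(name = "C1", resname = "PRB", chain = "X",
                                  resno = 901, coords = pos[t, , drop = FALSE],
                                  element = "C", record = "HETATM",
                                  is_probe = TRUE, probe_id = "X:901")
    probemap::snapshot(time = t * timestep, atoms = rbind(prot, probe), box = box)
  })
  probemap::trajectory("walk", snaps, timestep = timestep)
}

# a preferable_surface containing exactly the given voxel indices
fix_surface <- function(origin, shape, voxels, spacing = 1, theta = 0.2) {
  member <- array(FALSE, dim = shape)
  vox <- as.matrix(voxels)
  member[vox] <- TRUE
  structure(list(
    voxels = data.frame(i = vox[, 1], j = vox[, 2], k = vox[, 3], value = theta),
    member = member, theta = theta, origin = origin, shape = as.integer(shape),
    spacing = spacing), class = "preferable_surface")
}

# random proper rotation for invariance tests
fix_random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# apply one global rigid transform to every snapshot of a trajectory
fix_transform_traj <- function(traj, R, tr) {
  for (m in seq_along(traj$snapshots)) {
    a <- traj$snapshots[[m]]$atoms
    xyz <- probemap::apply_rigid(as.matrix(a[, c("x", "y", "z")]), R, tr)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    traj$snapshots[[m]]$atoms <- a
  }
  traj
}
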