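# Independent brute-force oracles.  These deliberately share no code with
# the package implementations: binning compares every point against every
# voxel's bounds, masking does the all-pairs distance check, superposition
# uses Horn's quaternion method instead of SVD.

# O(N * V) binning: for each voxel, count the points inside its half-open box
oracle_bin_counts <- function(origin, shape, spacing, points) {
  counts <- array(0, dim = shape)
  for (k in seq_len(shape[3])) for (j in seq_len(shape[2])) for (i in seq_len(shape[1])) {
    lo <- origin + (c(i, j, k) - 1) * spacing
    hi <- lo + spacing
    inside <- points[, 1] >= lo[1] & points[, 1] < hi[1] &
      points[, 2] >= lo[2] & points[, 2] < hi[2] &
      points[, 3] >= lo[3] & points[, 3] < hi[3]
    counts[i, j, k] <- sum(inside)
  }
  counts
}

# exhaustive voxel-center vs reference-point distance check
oracle_mask_member <- function(origin, shape, spacing, ref, cutoff) {
  member <- array(FALSE, dim = shape)
  for (k in seq_len(shape[3])) for (j in seq_len(shape[2])) for (i in seq_len(shape[1])) {
    ctr <- origin + (c(i, j, k) - 0.5) * spacing
    d2 <- (ref[, 1] - ctr[1])^2 + (ref[, 2] - ctr[2])^2 + (ref[, 3] - ctr[3])^2
    member[i, j, k] <- min(d2) <= cutoff^2
  }
  member
}

# Horn's closed-form quaternion superposition (proper rotation only)
oracle_horn_superpose <- function(mobile, target) {
  mu_m <- colMeans(mobile); mu_t <- colMeans(target)
  P <- sweep(mobile, 2, mu_m); Q <- sweep(target, 2, mu_t)
  S <- crossprod(P, Q)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, which.max(ev$values)]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)
  ), 3, 3, byrow = TRUE)
  fitted <- P %*% t(R)
  list(rotation = R, translation = as.numeric(mu_t - R %*% mu_m),
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

# all-pairs residue extraction: double loop over residues and probe atoms
oracle_residues_within <- function(probe_xyz, protein, cutoff) {
  prot <- protein[protein$heavy, , drop = FALSE]
  keys <- unique(paste(prot$chain, prot$resno, sep = ":"))
  hits <- character(0)
  for (key in keys) {
    sel <- prot[paste(prot$chain, prot$resno, sep = ":") == key, , drop = FALSE]
    found <- FALSE
    for (a in seq_len(nrow(sel))) {
      for (b in seq_len(nrow(probe_xyz))) {
        d <- sqrt(sum((c(sel$x[a], sel$y[a], sel$z[a]) - probe_xyz[b, ])^2))
        if (d <= cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hits <- c(hits, key)
  }
  sort(hits)
}

# per-atom voxel lookup against the surface voxel list
oracle_on_surface <- function(probe_xyz, surface) {
  vox <- surface$voxels
  for (a in seq_len(nrow(probe_xyz))) {
    idx <- floor((probe_xyz[a, ] - surface$origin) / surface$spacing) + 1
    if (any(idx < 1) || any(idx > surface$shape)) next
    if (any(vox$i == idx[1] & vox$j == idx[2] & vox$k == idx[3])) return(TRUE)
  }
  FALSE
}

# two-pointer displacement series with explicit minimum-image loop
oracle_displacement <- function(pos, box, nlag) {
  n <- nrow(pos)
  out <- numeric(0)
  for (t in (nlag + 1):n) {
    d <- pos[t, ] - pos[t - nlag, ]
    if (!is.null(box)) for (ax in 1:3) d[ax] <- d[ax] - box[ax] * round(d[ax] / box[ax])
    out <- c(out, sqrt(sum(d^2)))
  }
  out
}
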