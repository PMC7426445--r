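# Independent oracles and small fixture builders shared across the suite.

# Exhaustive average-linkage clustering: recomputes every cross-pair average
# from the original matrix at every step (O(F^3) per merge), merges the
# lexicographically-first minimum pair, stops before the first merge whose
# average distance exceeds the cutoff. Returns the partition as a list of
# member vectors.
oracle_average_linkage <- function(d, cutoff) {
  clusters <- as.list(seq_len(nrow(d)))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- NULL; best_d <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best_d - 1e-15) { best_d <- avg; best <- c(i, j) }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  clusters
}

# Canonical form of a partition (for label-free comparison).
canonical_partition <- function(members) {
  members <- lapply(members, function(m) sort(as.integer(m)))
  unname(members[order(vapply(members, min, integer(1)))])
}

partition_from_labels <- function(labels) {
  canonical_partition(split(seq_along(labels), labels))
}

# Random symmetric distance matrix with zero diagonal.
random_distance_matrix <- function(f) {
  m <- matrix(0, f, f)
  m[upper.tri(m)] <- runif(f * (f - 1) / 2, 0.1, 3)
  m + t(m)
}

# Rotation matrix from a unit quaternion (w, x, y, z).
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# Minimal hand-built topology: n atoms, one per residue, chain A, all carbon.
toy_topology <- function(n, chain = "A", name = "CA") {
  atoms <- data.frame(serial = seq_len(n), name = name, element = "C",
                      vdw = 1.70, resindex = seq_len(n), resname = "ALA",
                      resseq = seq_len(n), chain = chain, icode = "",
                      heavy = TRUE, stringsAsFactors = FALSE)
  residues <- data.frame(chain = chain, resseq = seq_len(n), icode = "",
                         resname = "ALA",
                         key = residue_key(chain, seq_len(n)),
                         stringsAsFactors = FALSE)
  topology(atoms, residues)
}

# Ensemble from a list of N x 3 coordinate matrices over a toy topology.
toy_ensemble <- function(frames, chain = "A") {
  n <- nrow(frames[[1]])
  co <- array(0, dim = c(n, 3, length(frames)))
  for (i in seq_along(frames)) co[, , i] <- frames[[i]]
  ensemble(toy_topology(n, chain = chain), co)
}

# Write a small multi-model PDB text fixture; coords is a list of N x 3
# matrices, atom names/chains parallel vectors.
write_pdb_fixture <- function(path, coords, names = NULL, chain = "H",
                              resseq = NULL, elements = NULL,
                              drop_atom_in_model = NULL) {
  n <- nrow(coords[[1]])
  if (is.null(names)) names <- rep("CA", n)
  if (is.null(resseq)) resseq <- seq_len(n)
  if (is.null(elements)) elements <- rep(" C", n)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(coords)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- coords[[m]]
    for (a in seq_len(n)) {
      if (!is.null(drop_atom_in_model) && m == drop_atom_in_model && a == n) next
      nm <- if (nchar(names[a]) < 4) paste0(" ", names[a]) else names[a]
      writeLines(sprintf("ATOM  %5d %-4s ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                         a, nm, chain, resseq[a],
                         xyz[a, 1], xyz[a, 2], xyz[a, 3],
                         trimws(elements[a])), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

# Place a 4th atom at a prescribed dihedral angle about the b2 axis, given
# three anchor atoms; used to construct known-psi test geometries.
place_dihedral_atom <- function(p1, p2, p3, angle, bond = 1.5,
                                bond_angle = 110 * pi / 180) {
  b1 <- p2 - p1; b2 <- p3 - p2
  e2 <- b2 / sqrt(sum(b2^2))
  u <- b1 - sum(b1 * e2) * e2
  c1 <- -u / sqrt(sum(u^2))          # cis direction: same side as p1
  c3 <- c(e2[2] * c1[3] - e2[3] * c1[2],
          e2[3] * c1[1] - e2[1] * c1[3],
          e2[1] * c1[2] - e2[2] * c1[1])
  d <- bond * (cos(pi - bond_angle) * e2 +
                 sin(pi - bond_angle) * (cos(angle) * c1 + sin(angle) * c3))
  p3 + d
}
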