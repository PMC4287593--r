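# Shared fixtures and independent oracles for the test suite.

# random proper rotation via QR of a Gaussian matrix (draws from the
# caller's RNG stream; wrap in set.seed for determinism)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

random_transform <- function(scale = 5) {
  rt_new(random_rotation(), rnorm(3, sd = scale))
}

# independent composition oracle: 4x4 homogeneous matrices multiplied with %*%
homogeneous <- function(T) rbind(cbind(T$R, T$t), c(0, 0, 0, 1))

max_transform_diff <- function(T1, T2) {
  max(abs(homogeneous(T1) - homogeneous(T2)))
}

# 12-triangle axis-aligned unit cube [0,1]^3, outward-oriented
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  mesh_new(v, f)
}

# minimal PDB fixtures written as fixed-column ATOM records
pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          element, altloc = " ") {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, altloc, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], element)
}

write_three_residue_pdb <- function(path) {
  # hand-placed 3-residue backbone; CA coordinates are the reference values
  # asserted in the terminus tests
  lines <- c(
    pdb_atom_line(1, " N  ", "ALA", "A", 1, c(0.000, 0.000, 0.000), "N"),
    pdb_atom_line(2, " CA ", "ALA", "A", 1, c(1.458, 0.000, 0.000), "C"),
    pdb_atom_line(3, " C  ", "ALA", "A", 1, c(2.009, 1.420, 0.000), "C"),
    pdb_atom_line(4, " N  ", "GLY", "A", 2, c(3.332, 1.536, 0.000), "N"),
    pdb_atom_line(5, " CA ", "GLY", "A", 2, c(4.040, 2.839, 0.000), "C"),
    pdb_atom_line(6, " C  ", "GLY", "A", 2, c(5.530, 2.626, 0.000), "C"),
    pdb_atom_line(7, " N  ", "SER", "A", 3, c(6.302, 3.690, 0.100), "N"),
    pdb_atom_line(8, " CA ", "SER", "A", 3, c(7.751, 3.660, 0.250), "C"),
    "END")
  writeLines(lines, path)
  path
}

three_residue_ca <- list(first = c(1.458, 0, 0), last = c(7.751, 3.660, 0.250))

write_two_chain_pdb <- function(path) {
  lines <- c(
    pdb_atom_line(1, " CA ", "ALA", "A", 1, c(0, 0, 0), "C"),
    pdb_atom_line(2, " CA ", "ALA", "A", 2, c(3.8, 0, 0), "C"),
    pdb_atom_line(3, " CA ", "GLY", "B", 1, c(0, 10, 0), "C"),
    pdb_atom_line(4, " CA ", "GLY", "B", 2, c(3.8, 10, 0), "C"),
    pdb_atom_line(5, " CA ", "GLY", "B", 3, c(7.6, 10, 0), "C"),
    "END")
  writeLines(lines, path)
  path
}

# brute-force scene collision oracle: exhaustive triangle pairs on every
# object pair involving a moving object (mirrors the pair bookkeeping of
# scene_collisions but with no spatial acceleration)
brute_scene_pairs <- function(scene, moving_ids) {
  ids <- scene_object_ids(scene)
  out <- character(0)
  seen <- character(0)
  for (m in moving_ids) {
    for (o in ids) {
      if (o == m) next
      p <- sort(c(m, o))
      key <- paste(p, collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      o1 <- scene$objects[[p[1]]]; o2 <- scene$objects[[p[2]]]
      cts <- collide_pair_brute(o1$mesh, o1$pose, o2$mesh, o2$pose)
      if (nrow(cts) > 0) out <- c(out, key)
    }
  }
  sort(out)
}

report_pair_keys <- function(report) {
  if (nrow(report$colliding_pairs) == 0) return(character(0))
  sort(paste(report$colliding_pairs$id1, report$colliding_pairs$id2, sep = "|"))
}

# brute-force internal collision oracle for a chain: all copy pairs
brute_chain_pairs <- function(chain) {
  out <- character(0)
  for (i in seq_len(chain$n - 1)) {
    for (j in (i + 1):chain$n) {
      cts <- collide_pair_brute(chain$base_mesh, chain$copy_poses[[i]],
                                chain$base_mesh, chain$copy_poses[[j]])
      if (nrow(cts) > 0) out <- c(out, paste(i, j, sep = "|"))
    }
  }
  sort(out)
}

# random scene of fixture meshes in a box, for the oracle-equivalence tests
random_scene <- function(n_objects, box = 6, max_subdiv = 1) {
  scene <- scene_new()
  for (i in seq_len(n_objects)) {
    kind <- sample(c("sphere", "ellipsoid", "blob"), 1)
    subdiv <- sample(0:max_subdiv, 1)
    mesh <- make_fixture(kind, radius = runif(1, 0.6, 1.4),
                         semi_axes = runif(3, 0.5, 1.5),
                         subdivisions = subdiv, seed = sample.int(1e6, 1))
    scene <- scene_add_object(scene, mesh, id = sprintf("o%02d", i),
                              pose = rt_new(random_rotation(),
                                            runif(3, -box / 2, box / 2)))
  }
  scene
}
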