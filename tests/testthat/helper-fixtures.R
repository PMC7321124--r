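# Shared fixtures: all built in code at test time.

# Minimal PDB with known atom typing: ALA backbone + CB, and a zinc ion.
writeToyPDB <- function(path, coords = NULL) {
  if (is.null(coords))
    coords <- rbind(c(1.0, 0.0, 0.0), c(0.0, 1.5, 0.0), c(0.0, 0.0, 2.0))
  lines <- c(
    sprintf("ATOM  %5d  CB  ALA A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1, coords[1, 1], coords[1, 2], coords[1, 3]),
    sprintf("ATOM  %5d  O   ALA A   1    %8.3f%8.3f%8.3f  1.00  0.00           O",
            2, coords[2, 1], coords[2, 2], coords[2, 3]),
    sprintf("ATOM  %5d ZN    ZN A   2    %8.3f%8.3f%8.3f  1.00  0.00          ZN",
            3, coords[3, 1], coords[3, 2], coords[3, 3]),
    "END")
  writeLines(lines, path)
  path
}

# Two-carbon ligand with unit bond; heavy atoms at (0,0,0) and (2,0,0).
writeToySDF <- function(path, elements = c("C", "C"),
                        coords = rbind(c(0, 0, 0), c(2, 0, 0)),
                        bonds = cbind(1, 2, 1)) {
  DockSelect:::.writeToySDF(elements, coords, bonds, path)
  path
}

# Vectorized brute-force voxelization oracle: per-channel maximum of the
# occupancy kernel over every (voxel, atom) pair, computed independently of
# the compiled path.
bruteForceVoxelize <- function(pocket, center = pocket@center, edge = 24,
                               resolution = 1) {
  E <- as.integer(edge / resolution)
  origin <- center - edge / 2
  ax <- origin[1] + (seq_len(E) - 0.5) * resolution
  ay <- origin[2] + (seq_len(E) - 0.5) * resolution
  az <- origin[3] + (seq_len(E) - 0.5) * resolution
  centers <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  out <- array(0, c(8, E, E, E))
  for (ch in 1:8) {
    atoms <- which(pocket@channels[, ch])
    if (!length(atoms)) next
    acc <- rep(0, nrow(centers))
    for (a in atoms) {
      r <- sqrt((centers[, 1] - pocket@coords[a, 1])^2 +
                  (centers[, 2] - pocket@coords[a, 2])^2 +
                  (centers[, 3] - pocket@coords[a, 3])^2)
      occ <- ifelse(r == 0, 1, 1 - exp(-(pocket@radii[a] / r)^12))
      acc <- pmax(acc, occ)
    }
    out[ch, , , ] <- array(acc, c(E, E, E))
  }
  out
}

# Small synthetic dataset for training/evaluation tests.
tinyDataset <- function(n = 16, P = 4, families = 4, seed = 7,
                        preset = "default") {
  makeBenchmark(syntheticConfig(n_complexes = n, n_families = families,
                                n_protocols = P, pocket_atoms = c(20, 40),
                                seed = seed, preset = preset))
}

# Small network configuration that keeps training tests fast.
tinyModelConfig <- function(P = 4) {
  modelConfig(n_protocols = P, conv_channels = c(4, 8), conv_strides = c(2, 2),
              ligand_widths = c(64, 48, 32), protein_latent = 32)
}
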