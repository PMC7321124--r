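# Synthetic benchmark generator. Emulates the statistical structure the
# pipeline assumes — pockets as pharmacophore-typed atom clouds in a 15 A
# sphere, ligand features as sparse fingerprint bits plus correlated
# Gaussian descriptors, and per-protocol label triples generated by a
# planted noisy function of the features — so that learnability and
# parameter-recovery can be tested without any external data.

# Catalog of realistic protein atom types (residue, atom name, element)
# with sampling weights; channel flags follow from the bundled typing
# rules, so a pocket written to PDB and re-read reproduces its flags.
.ATOM_CATALOG <- data.frame(
  resname = c("ALA", "ALA", "ALA", "ALA", "ALA",
              "LEU", "LEU", "VAL", "PHE", "PHE", "PHE",
              "TYR", "TYR", "TRP", "TRP",
              "SER", "THR", "ASP", "ASP", "GLU",
              "ASN", "GLN", "LYS", "ARG", "ARG",
              "HIS", "MET", "ZN", "MG"),
  atomname = c("N", "CA", "C", "O", "CB",
               "CD1", "CG", "CG1", "CG", "CZ", "CE1",
               "OH", "CE1", "NE1", "CZ2",
               "OG", "OG1", "OD1", "CG", "OE1",
               "ND2", "OE1", "NZ", "NH1", "CZ",
               "NE2", "SD", "ZN", "MG"),
  element = c("N", "C", "C", "O", "C",
              "C", "C", "C", "C", "C", "C",
              "O", "C", "N", "C",
              "O", "O", "O", "C", "O",
              "N", "O", "N", "N", "C",
              "N", "S", "ZN", "MG"),
  weight = c(8, 10, 8, 8, 6,
             4, 3, 4, 3, 2, 2,
             2, 2, 1, 1,
             3, 3, 2, 2, 2,
             2, 2, 2, 2, 1,
             2, 1, 0.3, 0.2),
  stringsAsFactors = FALSE)

#' Synthetic benchmark configuration
#'
#' Parameters of [makeBenchmark()]. Defaults describe a realistic
#' desk-scale benchmark: 200 complexes over 20 protein families with
#' Zipf-distributed sizes, pockets of 60-160 atoms in a 15 Angstrom
#' sphere, 14 protocols, 20 poses per protocol, crystal resolutions
#' uniform in 1.5-3.0 Angstrom, and label noise of 0.3 Angstrom on
#' rmsd_ave. `preset = "signal-dominant"` lowers the label noise to 0.1
#' Angstrom and strengthens the descriptor contribution — the
#' configuration used for learnability checks, where the question is
#' whether the network recovers a signal that is known to be present.
#'
#' @param n_complexes number of complexes.
#' @param n_families number of protein families.
#' @param n_protocols protocols in the registry (<= 14 named; beyond that,
#'   synthetic names are appended).
#' @param pocket_atoms length-2 range of pocket atom counts.
#' @param radius pocket sphere radius (Angstrom).
#' @param noise_sd Gaussian noise on rmsd_ave (Angstrom).
#' @param n_poses poses per protocol (upper bound of n_rmsd).
#' @param bit_density Bernoulli rate of fingerprint bits.
#' @param d_latent dimension of the planted latent factor.
#' @param w_pocket,w_fingerprint,w_descriptor block weights of the planted
#'   projection.
#' @param family_sd scale of the per-family latent offset.
#' @param count_slope steepness `a` of the n_rmsd success probability
#'   `plogis(-a * (rmsd_ave - resolution))`.
#' @param seed master seed.
#' @param preset `"default"` or `"signal-dominant"`.
#' @return a config list (class `SyntheticConfig`).
#' @export
syntheticConfig <- function(n_complexes = 200, n_families = 20,
                            n_protocols = 14, pocket_atoms = c(60, 160),
                            radius = 15, noise_sd = 0.3, n_poses = 20,
                            bit_density = 0.05, d_latent = 8,
                            w_pocket = 0.5, w_fingerprint = 0.5,
                            w_descriptor = 1.0, family_sd = 0.3,
                            count_slope = 1.5, seed = 1,
                            preset = c("default", "signal-dominant")) {
  preset <- match.arg(preset)
  if (preset == "signal-dominant") {
    noise_sd <- 0.1
    w_descriptor <- 1.5
    family_sd <- 0.15
  }
  stopifnot(n_complexes > 0, n_families > 0, n_protocols > 0,
            noise_sd >= 0, n_poses > 0)
  structure(list(n_complexes = as.integer(n_complexes),
                 n_families = as.integer(n_families),
                 n_protocols = as.integer(n_protocols),
                 pocket_atoms = pocket_atoms, radius = radius,
                 noise_sd = noise_sd, n_poses = as.integer(n_poses),
                 bit_density = bit_density, d_latent = as.integer(d_latent),
                 w_pocket = w_pocket, w_fingerprint = w_fingerprint,
                 w_descriptor = w_descriptor, family_sd = family_sd,
                 count_slope = count_slope, seed = as.integer(seed),
                 preset = preset),
            class = "SyntheticConfig")
}

#' Generate a random pocket
#'
#' Atoms are drawn from a catalog of realistic (residue, atom name,
#' element) protein atom types and placed uniformly in a sphere of the
#' given radius; coordinates are rounded to 0.001 Angstrom (PDB precision)
#' so a pocket round-trips exactly through PDB files. Channel flags come
#' from the bundled typing rules. Uses the current RNG state — call
#' [set.seed()] for reproducibility.
#'
#' @param n_atoms number of atoms (>= 0).
#' @param radius sphere radius (Angstrom).
#' @param center sphere center.
#' @return a [PocketStructure-class].
#' @export
generatePocket <- function(n_atoms, radius = 15, center = c(0, 0, 0)) {
  stopifnot(n_atoms >= 0)
  if (n_atoms == 0)
    return(PocketStructure(matrix(numeric(0), 0, 3), character(0),
                           character(0), character(0), center = center))
  rows <- sample.int(nrow(.ATOM_CATALOG), n_atoms, replace = TRUE,
                     prob = .ATOM_CATALOG$weight)
  dir <- matrix(rnorm(3 * n_atoms), n_atoms, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  r <- radius * runif(n_atoms)^(1 / 3)
  coords <- round(dir * r + matrix(center, n_atoms, 3, byrow = TRUE), 3)
  pocket <- PocketStructure(coords, .ATOM_CATALOG$element[rows],
                            .ATOM_CATALOG$resname[rows],
                            .ATOM_CATALOG$atomname[rows], center = center)
  suppressMessages(assignChannels(pocket))
}

#' Generate random ligand features
#'
#' Fingerprint bits are Bernoulli with the configured density; descriptors
#' are multivariate normal with an AR(1) covariance (`cov_rho`; 0 gives
#' independent descriptors). Uses the current RNG state.
#'
#' @param n_bits fingerprint length.
#' @param n_desc descriptor count.
#' @param bit_density Bernoulli rate of the bits.
#' @param cov_rho AR(1) correlation of neighboring descriptors.
#' @return a [LigandFeatures-class].
#' @export
generateLigandFeatures <- function(n_bits = 1024, n_desc = 183,
                                   bit_density = 0.05, cov_rho = 0.3) {
  bits <- rbinom(n_bits, 1, bit_density)
  z <- rnorm(n_desc)
  if (cov_rho != 0) {
    # AR(1) process: stationary unit-variance chain
    d <- numeric(n_desc)
    d[1] <- z[1]
    for (i in 2:n_desc)
      d[i] <- cov_rho * d[i - 1] + sqrt(1 - cov_rho^2) * z[i]
  } else d <- z
  new("LigandFeatures", fingerprint = as.integer(bits), descriptors = d,
      standardized = FALSE)
}

# Low-dimensional numeric summary of a pocket, the pocket part of the
# planted-label inputs: atom count, channel fractions, radial moments.
#' @rdname generatePocket
#' @param pocket a [PocketStructure-class].
#' @export
pocketSummary <- function(pocket) {
  n <- nAtoms(pocket)
  if (n == 0) return(c(n = 0, setNames(rep(0, 8), channelNames()),
                       r_mean = 0, r_sd = 0, vdw_mean = 0))
  d <- sqrt(rowSums((pocket@coords -
                       matrix(pocket@center, n, 3, byrow = TRUE))^2))
  c(n = n / 100, colMeans(pocket@channels), r_mean = mean(d) / 15,
    r_sd = sd(d) / 15, vdw_mean = mean(pocket@radii))
}

#' Generate planted label triples
#'
#' The planted model: a latent factor `z` is a fixed random projection of
#' the pocket summary, fingerprint and descriptors (block-weighted);
#' per-protocol `rmsd_ave = softplus(w_p' z + b_p) + noise`, `rmsd_min =
#' c * rmsd_ave` with `c ~ U(0.25, 1)` per complex, and `n_rmsd ~
#' Binomial(n_poses, plogis(-a * (rmsd_ave - resolution)))`, so smaller
#' RMSD yields larger pose counts. Protocol weights share a common prior
#' with protocol-specific perturbation scales, giving "easy" and "hard"
#' protocols.
#'
#' @param z n x d latent factor matrix (see [makeBenchmark()]).
#' @param weights list per protocol: `w` (d-vector), `bias`, as drawn by
#'   [makeBenchmark()].
#' @param noise_sd Gaussian noise sd on rmsd_ave (Angstrom).
#' @param n_poses poses per protocol.
#' @param resolutions per-complex crystal resolutions (Angstrom).
#' @param count_slope slope `a` of the count success probability.
#' @param registry protocol names.
#' @param ids complex ids.
#' @return a [LabelMatrix-class].
#' @export
generateLabels <- function(z, weights, noise_sd, n_poses, resolutions,
                           count_slope = 1.5, registry = protocolRegistry(),
                           ids = rownames(z)) {
  n <- nrow(z)
  P <- length(weights)
  vals <- array(NA_real_, c(n, P, 3))
  cmin <- runif(n, 0.25, 1)
  for (p in seq_len(P)) {
    lin <- as.numeric(z %*% weights[[p]]$w) + weights[[p]]$bias
    ave <- log1p(exp(pmin(lin, 30))) + rnorm(n, sd = noise_sd)
    ave <- pmax(ave, 0.05)
    mn <- cmin * ave
    prob <- plogis(-count_slope * (ave - resolutions))
    nr <- rbinom(n, n_poses, prob)
    vals[, p, 1] <- mn
    vals[, p, 2] <- ave
    vals[, p, 3] <- nr
  }
  LabelMatrix(vals, registry = registry, ids = ids)
}

.syntheticRegistry <- function(P) {
  base <- protocolRegistry()
  if (P <= length(base)) return(base[seq_len(P)])
  c(base, paste0("protocol-", seq_len(P - length(base))))
}

#' Assemble a synthetic benchmark dataset
#'
#' Generates pockets, ligand features, family labels (Zipf-distributed
#' family sizes with a per-family latent offset, so protein-aware splits
#' matter) and planted label triples, fully determined by the config seed.
#' The planted latent factors and protocol weights are kept in the
#' dataset's `meta` slot for parameter-recovery tests.
#'
#' @param config a [syntheticConfig()].
#' @return a [DockingDataset-class].
#' @export
makeBenchmark <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  n <- config$n_complexes
  ids <- sprintf("cpx%04d", seq_len(n))
  famnames <- sprintf("FAM%03d", seq_len(config$n_families))
  famprob <- (1 / seq_len(config$n_families))
  families <- setNames(sample(famnames, n, replace = TRUE,
                              prob = famprob / sum(famprob)), ids)
  # ensure every family appears at least once when n allows it
  missing <- setdiff(famnames, unique(families))
  if (length(missing) && n >= config$n_families)
    families[sample(n, length(missing))] <- missing

  pockets <- lapply(seq_len(n), function(i)
    generatePocket(sample(config$pocket_atoms[1]:config$pocket_atoms[2], 1),
                   radius = config$radius))
  feats <- lapply(seq_len(n), function(i)
    generateLigandFeatures(bit_density = config$bit_density))
  fp <- do.call(rbind, lapply(feats, function(f) f@fingerprint))
  desc <- do.call(rbind, lapply(feats, function(f) f@descriptors))
  rownames(fp) <- rownames(desc) <- ids
  colnames(desc) <- descriptorNames()

  summ <- do.call(rbind, lapply(pockets, pocketSummary))
  d <- config$d_latent
  # fixed random projections, one per feature block, scaled by block weight
  Ppk <- matrix(rnorm(d * ncol(summ), sd = 1 / sqrt(ncol(summ))), d)
  Pfp <- matrix(rnorm(d * ncol(fp), sd = 1 / sqrt(sum(fp) / n)), d)
  Pds <- matrix(rnorm(d * ncol(desc), sd = 1 / sqrt(ncol(desc))), d)
  famOff <- matrix(rnorm(d * config$n_families, sd = config$family_sd), d,
                   dimnames = list(NULL, famnames))
  z <- config$w_pocket * summ %*% t(Ppk) +
    config$w_fingerprint * fp %*% t(Pfp) +
    config$w_descriptor * desc %*% t(Pds) +
    t(famOff[, families])
  rownames(z) <- ids

  P <- config$n_protocols
  registry <- .syntheticRegistry(P)
  w0 <- rnorm(d)
  pert <- runif(P, 0.2, 1.2)   # protocol-specific perturbation scale
  weights <- lapply(seq_len(P), function(p)
    list(w = w0 + rnorm(d, sd = pert[p]),
         bias = rnorm(1, mean = 1.5, sd = 0.6)))

  resolutions <- setNames(round(runif(n, 1.5, 3.0), 2), ids)
  labels <- generateLabels(z, weights, config$noise_sd, config$n_poses,
                           resolutions, config$count_slope, registry, ids)
  new("DockingDataset", ids = ids, pockets = pockets, fingerprints = fp,
      descriptors = desc, labels = labels, families = families,
      resolutions = resolutions, nPoses = config$n_poses,
      meta = list(latent = z, weights = weights, config = config))
}

# --- fixture serialization -------------------------------------------------

.writePocketPDB <- function(pocket, path) {
  n <- nAtoms(pocket)
  an <- pocket@atomnames
  # PDB columns 13-16: pad 1-3 char names with a leading space
  an <- ifelse(nchar(an) <= 3, sprintf(" %-3s", an), sprintf("%-4s", an))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n), an, pocket@resnames, seq_len(n),
    pocket@coords[, 1], pocket@coords[, 2], pocket@coords[, 3],
    1, 0, .normElement(pocket@elements))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

.readPocketPDB <- function(path, center) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  pocket <- PocketStructure(cbind(at$x, at$y, at$z), trimws(at$elesy),
                            trimws(at$resid), trimws(at$elety),
                            center = center)
  suppressMessages(assignChannels(pocket))
}

# Minimal V2000 SDF writer for toy ligand fixtures (atoms + single bonds).
.writeToySDF <- function(elements, coords, bonds, path, title = "toy") {
  n <- length(elements)
  lines <- c(title, "  DockSelect", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     n, nrow(bonds)))
  lines <- c(lines, sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    coords[, 1], coords[, 2], coords[, 3], elements))
  if (nrow(bonds))
    lines <- c(lines, sprintf("%3d%3d%3d  0", bonds[, 1], bonds[, 2],
                              bonds[, 3]))
  writeLines(c(lines, "M  END", "$$$$"), path)
  invisible(path)
}

#' Write / read a benchmark as plain-text fixtures
#'
#' `writeBenchmark()` lays a dataset out as standard files: one PDB per
#' pocket (`pockets/`), the long-format label CSV, a family map JSON, a
#' complex metadata CSV (resolution, pose count, pocket center) and a
#' ligand feature CSV (fingerprint as a bit string plus descriptor
#' columns). `readBenchmark()` reconstructs the [DockingDataset-class];
#' the round trip is exact.
#'
#' @param dataset a [DockingDataset-class].
#' @param dir output directory (created if needed).
#' @return `writeBenchmark()`: `dir` invisibly; `readBenchmark()`: the
#'   dataset.
#' @export
writeBenchmark <- function(dataset, dir) {
  stopifnot(is(dataset, "DockingDataset"))
  dir.create(file.path(dir, "pockets"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_along(dataset@ids))
    .writePocketPDB(dataset@pockets[[i]],
                    file.path(dir, "pockets",
                              paste0(dataset@ids[i], ".pdb")))
  writeLabelTable(dataset@labels, file.path(dir, "labels.csv"))
  jsonlite::write_json(as.list(dataset@families),
                       file.path(dir, "families.json"), auto_unbox = TRUE)
  centers <- t(vapply(dataset@pockets, function(p) p@center, numeric(3)))
  meta <- data.frame(complex_id = dataset@ids,
                     resolution = dataset@resolutions,
                     n_poses = dataset@nPoses,
                     cx = centers[, 1], cy = centers[, 2], cz = centers[, 3])
  write.csv(meta, file.path(dir, "complexes.csv"), row.names = FALSE,
            quote = FALSE)
  lig <- data.frame(complex_id = dataset@ids,
                    fingerprint = apply(dataset@fingerprints, 1, paste,
                                        collapse = ""),
                    stringsAsFactors = FALSE)
  lig <- cbind(lig, as.data.frame(signif(dataset@descriptors, 15)))
  write.csv(lig, file.path(dir, "ligands.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}

#' @rdname writeBenchmark
#' @export
readBenchmark <- function(dir) {
  meta <- read.csv(file.path(dir, "complexes.csv"),
                   stringsAsFactors = FALSE)
  ids <- meta$complex_id
  labels <- loadLabelTable(file.path(dir, "labels.csv"),
                           registry = .registryFromLabels(
                             file.path(dir, "labels.csv")))
  families <- unlist(jsonlite::read_json(file.path(dir, "families.json"),
                                         simplifyVector = TRUE))
  pockets <- lapply(seq_along(ids), function(i)
    .readPocketPDB(file.path(dir, "pockets", paste0(ids[i], ".pdb")),
                   center = c(meta$cx[i], meta$cy[i], meta$cz[i])))
  lig <- read.csv(file.path(dir, "ligands.csv"), stringsAsFactors = FALSE,
                  colClasses = c(fingerprint = "character"))
  fp <- t(vapply(strsplit(lig$fingerprint, ""), as.integer,
                 integer(nchar(lig$fingerprint[1]))))
  desc <- as.matrix(lig[, -(1:2)])
  rownames(fp) <- rownames(desc) <- ids
  colnames(desc) <- descriptorNames()[seq_len(ncol(desc))]
  new("DockingDataset", ids = ids, pockets = pockets, fingerprints = fp,
      descriptors = desc, labels = labels,
      families = setNames(families[ids], ids),
      resolutions = setNames(meta$resolution, ids),
      nPoses = as.integer(meta$n_poses[1]), meta = list())
}

# registry stored implicitly as the protocols present in the label table,
# in default-registry order (synthetic extras appended in name order)
.registryFromLabels <- function(path) {
  prot <- unique(read.csv(path, stringsAsFactors = FALSE)$protocol)
  base <- protocolRegistry()
  c(base[base %in% prot], sort(setdiff(prot, base)))
}
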