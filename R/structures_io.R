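# Structure input: protein/ligand loading, pocket extraction around the
# ligand center of mass, and self-docking label statistics.

.moleculeFromSDF <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  bonds <- if (nrow(bb)) {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  list(elements = elements, coords = coords, bonds = bonds,
       charges = rep(0L, length(elements)))
}

.heavy <- function(elements) .normElement(elements) != "H"

# Restrict a molecular graph to heavy atoms, remapping bond indices.
.heavyGraph <- function(mol) {
  keep <- which(.heavy(mol$elements))
  map <- match(seq_along(mol$elements), keep)
  b <- mol$bonds
  b <- b[b$a1 %in% keep & b$a2 %in% keep, , drop = FALSE]
  b$a1 <- map[b$a1]; b$a2 <- map[b$a2]
  list(elements = mol$elements[keep],
       coords = mol$coords[keep, , drop = FALSE],
       bonds = b, charges = mol$charges[keep])
}

#' Mass-weighted heavy-atom center of a molecule
#'
#' @param mol a molecular graph as returned inside [loadComplex()] records
#'   (fields `elements`, `coords`).
#' @return numeric length-3 center of mass (Angstrom), hydrogens excluded.
#' @export
ligandCenter <- function(mol) {
  keep <- .heavy(mol$elements)
  if (!any(keep)) stop("ligand has no heavy atoms")
  m <- .elementProperty(mol$elements[keep], "mass")
  colSums(mol$coords[keep, , drop = FALSE] * m) / sum(m)
}

#' Load a protein-ligand complex
#'
#' Reads a protein structure (PDB) and its co-crystallized ligand (SDF,
#' first molecule), checks that the ligand has at least one heavy atom, and
#' computes the ligand heavy-atom center of mass that pocket extraction and
#' voxelization are anchored to. Coordinates are kept in the input frame;
#' no re-centering happens at load time.
#'
#' @param protein_path path to a PDB file.
#' @param ligand_path path to an SDF file (the first molecule is used).
#' @param resolution crystal resolution in Angstrom (> 0); the per-complex
#'   threshold under which docked poses count towards n_rmsd.
#' @param id complex identifier; defaults to the protein file stem.
#' @return a list of class `ComplexRecord` with fields `id`, `protein`
#'   (data.frame: element, x, y, z, resname, atomname), `ligand` (molecular
#'   graph), `ligand_center`, `resolution`.
#' @export
loadComplex <- function(protein_path, ligand_path, resolution,
                        id = sub("\\.pdb$", "", basename(protein_path))) {
  if (!file.exists(protein_path))
    stop("protein file not found: ", protein_path)
  if (!file.exists(ligand_path))
    stop("ligand file not found: ", ligand_path)
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("resolution must be a positive number (Angstrom)")
  pdb <- tryCatch(bio3d::read.pdb(protein_path, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse PDB file: ", conditionMessage(e)))
  at <- pdb$atom
  elements <- trimws(at$elesy)
  blank <- is.na(elements) | elements == ""
  # fall back to the first letter of the atom name when the element column
  # is absent (common in minimal PDB files)
  elements[blank] <- substr(trimws(at$elety[blank]), 1, 1)
  protein <- data.frame(element = elements, x = at$x, y = at$y, z = at$z,
                        resname = trimws(at$resid),
                        atomname = trimws(at$elety),
                        stringsAsFactors = FALSE)
  protein <- protein[protein$resname != "HOH", , drop = FALSE]
  sdfset <- tryCatch(ChemmineR::read.SDFset(ligand_path),
                     error = function(e)
                       stop("failed to parse SDF file: ", conditionMessage(e)))
  if (length(sdfset) < 1) stop("SDF file contains no molecules")
  mol <- .moleculeFromSDF(sdfset[[1]])
  if (!any(.heavy(mol$elements)))
    stop("ligand has no heavy atoms")
  structure(list(id = id, protein = protein, ligand = mol,
                 ligand_center = ligandCenter(mol),
                 resolution = resolution),
            class = "ComplexRecord")
}

#' Extract the binding pocket around the ligand
#'
#' Returns exactly those protein heavy atoms whose Euclidean distance from
#' the ligand heavy-atom center of mass is at most `radius` (default 15
#' Angstrom, the sphere used to define the binding site for docking).
#' Each atom receives its bundled van der Waals radius, and pharmacophore
#' channel flags are assigned from the bundled typing rules (see
#' [assignChannels()]). Extraction is idempotent: re-extracting an already
#' extracted pocket with the same radius returns the same atom set.
#'
#' @param record a `ComplexRecord` from [loadComplex()], or an existing
#'   [PocketStructure-class] (re-filtered around its own center).
#' @param radius sphere radius in Angstrom (> 0).
#' @param assign assign channel flags from the bundled rules (default TRUE).
#' @return a [PocketStructure-class]; empty (with a warning) if no protein
#'   heavy atom lies within the sphere.
#' @export
extractPocket <- function(record, radius = 15, assign = TRUE) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (is(record, "PocketStructure")) {
    d <- sqrt(rowSums((record@coords -
                         matrix(record@center, nAtoms(record), 3,
                                byrow = TRUE))^2))
    keep <- d <= radius
    return(new("PocketStructure",
               coords = record@coords[keep, , drop = FALSE],
               radii = record@radii[keep],
               channels = record@channels[keep, , drop = FALSE],
               elements = record@elements[keep],
               resnames = record@resnames[keep],
               atomnames = record@atomnames[keep],
               center = record@center))
  }
  stopifnot(inherits(record, "ComplexRecord"))
  p <- record$protein
  p <- p[.heavy(p$element), , drop = FALSE]
  ctr <- record$ligand_center
  d <- sqrt((p$x - ctr[1])^2 + (p$y - ctr[2])^2 + (p$z - ctr[3])^2)
  p <- p[d <= radius, , drop = FALSE]
  if (nrow(p) == 0)
    warning("empty pocket: no protein heavy atom within ", radius,
            " A of the ligand center")
  pocket <- PocketStructure(cbind(p$x, p$y, p$z), p$element, p$resname,
                            p$atomname, center = ctr)
  if (assign && nAtoms(pocket) > 0) pocket <- assignChannels(pocket)
  pocket
}

#' Self-docking label triple from a pose RMSD list
#'
#' Reduces the RMSDs of the generated poses to the three statistics used as
#' regression targets: the minimum RMSD, the arithmetic mean RMSD, and the
#' number of poses with an RMSD strictly below the crystal resolution.
#'
#' @param pose_rmsds non-empty numeric vector of pose RMSDs (Angstrom, >= 0).
#' @param resolution crystal resolution in Angstrom (> 0).
#' @return named numeric vector (rmsd_min, rmsd_ave, n_rmsd).
#' @examples
#' computeLabelTriple(c(0.8, 1.5, 2.2, 3.0), resolution = 2.0)
#' @export
computeLabelTriple <- function(pose_rmsds, resolution) {
  if (length(pose_rmsds) == 0) stop("pose_rmsds must be non-empty")
  if (any(!is.finite(pose_rmsds)) || any(pose_rmsds < 0))
    stop("pose RMSDs must be finite and >= 0")
  if (!is.numeric(resolution) || resolution <= 0)
    stop("resolution must be > 0")
  c(rmsd_min = min(pose_rmsds),
    rmsd_ave = mean(pose_rmsds),
    n_rmsd = sum(pose_rmsds < resolution))
}

#' Read a long-format label table
#'
#' Reads a delimited table with columns `complex_id`, `protocol`,
#' `rmsd_min`, `rmsd_ave`, `n_rmsd` (one row per complex-protocol pair, the
#' tidy form of a docking benchmark output) into a [LabelMatrix-class].
#' Protocols not in the registry are rejected by name; duplicated
#' (complex, protocol) rows are an error; combinations absent from the
#' table are masked as missing.
#'
#' @param path path to a CSV file.
#' @param registry protocol registry; defaults to [protocolRegistry()].
#' @return a [LabelMatrix-class].
#' @seealso [writeLabelTable()] for the exact-round-trip writer.
#' @export
loadLabelTable <- function(path, registry = protocolRegistry()) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("complex_id", "protocol", "rmsd_min", "rmsd_ave", "n_rmsd")
  if (!all(need %in% names(tab)))
    stop("label table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$protocol), registry)
  if (length(bad))
    stop("unknown protocol name(s): ", paste(bad, collapse = ", "))
  key <- paste(tab$complex_id, tab$protocol)
  if (anyDuplicated(key))
    stop("duplicate (complex, protocol) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  ids <- unique(tab$complex_id)
  vals <- array(NA_real_, c(length(ids), length(registry), 3))
  i <- match(tab$complex_id, ids)
  j <- match(tab$protocol, registry)
  vals[cbind(i, j, 1L)] <- tab$rmsd_min
  vals[cbind(i, j, 2L)] <- tab$rmsd_ave
  vals[cbind(i, j, 3L)] <- tab$n_rmsd
  LabelMatrix(vals, registry = registry, ids = ids)
}

#' Write a LabelMatrix as a long-format CSV
#'
#' Writes one row per observed (complex, protocol) pair with full (17
#' significant digit) precision, so that [loadLabelTable()] reproduces the
#' matrix bit-exactly.
#'
#' @param labels a [LabelMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeLabelTable <- function(labels, path) {
  stopifnot(is(labels, "LabelMatrix"))
  v <- labels@values
  ids <- dimnames(v)[[1]]
  obs <- which(labels@mask, arr.ind = TRUE)
  num <- function(x) sub("e([+-])0(\\d)$", "e\\1\\2", sprintf("%.17g", x))
  df <- data.frame(
    complex_id = ids[obs[, 1]],
    protocol = labels@registry[obs[, 2]],
    rmsd_min = num(v[cbind(obs, 1L)]),
    rmsd_ave = num(v[cbind(obs, 2L)]),
    n_rmsd = num(v[cbind(obs, 3L)]),
    stringsAsFactors = FALSE)
  df <- df[order(match(df$complex_id, ids), match(df$protocol,
                                                  labels@registry)), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
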