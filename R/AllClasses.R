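#' Pharmacophore channel names, in fixed grid order
#'
#' The eight channels of the voxel representation, in the order used by every
#' grid in the package: hydrophobic, aromatic, hydrogen-bond acceptor,
#' hydrogen-bond donor, positive ionizable, negative ionizable, metallic,
#' total excluded volume.
#'
#' @return character vector of length 8.
#' @examples
#' channelNames()
#' @export
channelNames <- function() {
  c("hydrophobic", "aromatic", "hbond_acceptor", "hbond_donor",
    "positive_ionizable", "negative_ionizable", "metallic",
    "excluded_volume")
}

#' Default docking-protocol registry
#'
#' The 14 protocol abbreviations (search algorithm + scoring function pairs
#' across AutoDock, Glide, GOLD, PLANTS, rDock and Vina) that the model
#' predicts by default, in fixed registry order.
#'
#' @return character vector of protocol abbreviations.
#' @examples
#' protocolRegistry()
#' @export
protocolRegistry <- function() {
  c("autodock-ls", "autodock-lga", "autodock-ga", "glide-sp",
    "gold-asp", "gold-chemscore", "gold-goldscore", "gold-plp",
    "plants-chemplp", "plants-plp", "plants-plp95",
    "rdock-std", "rdock-solv", "vina-std")
}

# ---------------------------------------------------------------------------
#  PocketStructure
# ---------------------------------------------------------------------------

#' PocketStructure: typed atom cloud of a binding site
#'
#' Heavy atoms of a protein binding pocket: coordinates (Angstrom), van der
#' Waals radii, per-atom pharmacophore channel flags (8 columns in
#' [channelNames()] order), and the atom context (element, residue name,
#' atom name) needed by the channel typing rules. The `center` is the
#' ligand heavy-atom center of mass the pocket was extracted around.
#'
#' @slot coords numeric matrix (n x 3), Angstrom.
#' @slot radii numeric vector, per-atom van der Waals radius (> 0).
#' @slot channels logical matrix (n x 8); column 8 (excluded volume) is TRUE
#'   for every heavy atom.
#' @slot elements,resnames,atomnames character vectors of length n.
#' @slot center numeric length-3 vector, Angstrom.
#' @exportClass PocketStructure
setClass("PocketStructure",
  representation(coords = "matrix", radii = "numeric", channels = "matrix",
                 elements = "character", resnames = "character",
                 atomnames = "character", center = "numeric"),
  validity = function(object) {
    n <- nrow(object@coords)
    msg <- character()
    if (ncol(object@coords) != 3) msg <- c(msg, "coords must be n x 3")
    if (length(object@radii) != n) msg <- c(msg, "radii length mismatch")
    if (n > 0 && any(object@radii <= 0)) msg <- c(msg, "radii must be > 0")
    if (!is.logical(object@channels) || ncol(object@channels) != 8)
      msg <- c(msg, "channels must be a logical n x 8 matrix")
    if (nrow(object@channels) != n) msg <- c(msg, "channels row mismatch")
    if (n > 0 && !all(object@channels[, 8]))
      msg <- c(msg, "excluded-volume flag must be TRUE for every heavy atom")
    if (length(object@center) != 3) msg <- c(msg, "center must be length 3")
    if (length(object@elements) != n || length(object@resnames) != n ||
        length(object@atomnames) != n)
      msg <- c(msg, "atom context length mismatch")
    if (length(msg)) msg else TRUE
  })

#' Construct a PocketStructure
#'
#' @param coords numeric n x 3 matrix of heavy-atom coordinates (Angstrom).
#' @param elements character vector of element symbols.
#' @param resnames,atomnames character vectors of residue and atom names
#'   (PDB conventions); used by the channel typing rules.
#' @param center numeric length-3 pocket center (Angstrom).
#' @param channels optional logical n x 8 flag matrix; by default only the
#'   excluded-volume flag is set and [assignChannels()] fills the rest.
#' @return a [PocketStructure-class] object.
#' @examples
#' p <- PocketStructure(matrix(0, 1, 3), "C", "ALA", "CB", center = c(0, 0, 0))
#' nAtoms(p)
#' @export
PocketStructure <- function(coords, elements, resnames = rep("UNK", n),
                            atomnames = elements, center = c(0, 0, 0),
                            channels = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  if (is.null(channels)) {
    channels <- matrix(FALSE, n, 8)
    channels[, 8] <- TRUE
  }
  colnames(channels) <- channelNames()
  new("PocketStructure", coords = coords, radii = vdwRadius(elements),
      channels = channels, elements = as.character(elements),
      resnames = as.character(resnames), atomnames = as.character(atomnames),
      center = as.numeric(center))
}

# ---------------------------------------------------------------------------
#  VoxelGrid
# ---------------------------------------------------------------------------

#' VoxelGrid: 8-channel pharmacophore occupancy grid
#'
#' Occupancy tensor of shape 8 x E x E x E with values in \[0, 1\], one layer
#' per pharmacophore channel. `origin` is the Cartesian position of the grid
#' corner; voxel (i, j, k) (0-based) has its center at
#' `origin + (i + 0.5, j + 0.5, k + 0.5) * resolution`.
#'
#' @slot values numeric array, dim c(8, E, E, E), all values in \[0, 1\].
#' @slot origin numeric length-3 vector (Angstrom).
#' @slot resolution numeric, Angstrom per voxel.
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(values = "array", origin = "numeric", resolution = "numeric"),
  validity = function(object) {
    d <- dim(object@values)
    msg <- character()
    if (length(d) != 4 || d[1] != 8)
      msg <- c(msg, "values must be an 8 x E x E x E array")
    if (length(d) == 4 && (d[2] != d[3] || d[3] != d[4]))
      msg <- c(msg, "grid must be cubic")
    rng <- range(object@values)
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
      msg <- c(msg, "voxel values must lie in [0, 1]")
    if (object@resolution <= 0) msg <- c(msg, "resolution must be > 0")
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
#  LigandFeatures
# ---------------------------------------------------------------------------

#' LigandFeatures: fingerprint plus descriptor encoding of a ligand
#'
#' A 1024-bit hashed circular fingerprint (bond radius 2) and a real-valued
#' physicochemical descriptor vector (183 descriptors by default). The
#' `standardized` flag records whether the descriptors have been transformed
#' by training-fold z-scoring (see [standardizeDescriptors()]).
#'
#' @slot fingerprint integer vector of 0/1 bits, length 1024.
#' @slot descriptors numeric vector, length fixed across a dataset.
#' @slot standardized logical scalar.
#' @exportClass LigandFeatures
setClass("LigandFeatures",
  representation(fingerprint = "integer", descriptors = "numeric",
                 standardized = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@fingerprint) != 1024)
      msg <- c(msg, "fingerprint must have 1024 bits")
    if (!all(object@fingerprint %in% c(0L, 1L)))
      msg <- c(msg, "fingerprint bits must be 0/1")
    if (length(object@standardized) != 1)
      msg <- c(msg, "standardized must be a scalar")
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
#  LabelMatrix
# ---------------------------------------------------------------------------

#' LabelMatrix: per-complex, per-protocol docking-quality labels
#'
#' For each complex and each protocol in the registry, the label triple
#' (rmsd_min, rmsd_ave, n_rmsd): minimum pose RMSD, mean pose RMSD
#' (Angstrom) and the count of poses with RMSD strictly below the crystal
#' resolution. Missing (complex, protocol) entries are flagged in `mask`
#' (FALSE = missing), never silently zero.
#'
#' @slot values numeric array, dim c(n_complex, n_protocol, 3) with the third
#'   dimension named rmsd_min, rmsd_ave, n_rmsd.
#' @slot mask logical matrix (n_complex x n_protocol), TRUE where observed.
#' @slot registry character vector of protocol names (column order).
#' @exportClass LabelMatrix
setClass("LabelMatrix",
  representation(values = "array", mask = "matrix", registry = "character"),
  validity = function(object) {
    d <- dim(object@values)
    msg <- character()
    if (length(d) != 3 || d[3] != 3)
      msg <- c(msg, "values must be n x P x 3")
    if (d[2] != length(object@registry))
      msg <- c(msg, "protocol dimension must match registry")
    if (!identical(dim(object@mask), d[1:2]))
      msg <- c(msg, "mask must be n x P")
    obs <- object@values[, , , drop = FALSE]
    obs <- obs[!is.na(obs)]
    if (length(obs) && any(obs < 0))
      msg <- c(msg, "labels must be non-negative")
    mn <- object@values[, , 1]; av <- object@values[, , 2]
    ok <- !is.na(mn) & !is.na(av)
    if (any(mn[ok] > av[ok] + 1e-9))
      msg <- c(msg, "rmsd_min must not exceed rmsd_ave")
    if (length(msg)) msg else TRUE
  })

#' Construct a LabelMatrix
#'
#' @param values numeric n x P x 3 array (third dimension: rmsd_min,
#'   rmsd_ave, n_rmsd). Missing entries may be NA; they are masked.
#' @param registry character vector of protocol names, length P.
#' @param ids character vector of complex ids, length n.
#' @return a [LabelMatrix-class] object.
#' @export
LabelMatrix <- function(values, registry = protocolRegistry(),
                        ids = rownames(values)) {
  if (is.null(ids)) ids <- paste0("cpx", seq_len(dim(values)[1]))
  dimnames(values) <- list(ids, registry,
                           c("rmsd_min", "rmsd_ave", "n_rmsd"))
  mask <- !apply(is.na(values), c(1, 2), any)
  new("LabelMatrix", values = values, mask = mask, registry = registry)
}

# ---------------------------------------------------------------------------
#  SplitPlan
# ---------------------------------------------------------------------------

#' SplitPlan: k-fold assignment of complexes
#'
#' Assignment of every complex to exactly one of k folds (0-based indices)
#' under one of the four split strategies: `random`, `ligand_scaffold`,
#' `protein_classes`, or `protein_classes_balanced`. A plan is fully
#' reproducible from (strategy, k, seed, inputs).
#'
#' @slot strategy character, one of the four strategy names.
#' @slot k integer fold count.
#' @slot assignment named integer vector, complex id -> fold in \[0, k).
#' @slot seed integer seed the plan was built from (NA when unused).
#' @exportClass SplitPlan
setClass("SplitPlan",
  representation(strategy = "character", k = "integer",
                 assignment = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    ok <- c("random", "ligand_scaffold", "protein_classes",
            "protein_classes_balanced")
    if (!object@strategy %in% ok)
      msg <- c(msg, "unknown strategy")
    if (is.null(names(object@assignment)))
      msg <- c(msg, "assignment must be named by complex id")
    if (any(duplicated(names(object@assignment))))
      msg <- c(msg, "duplicate complex ids")
    if (length(object@assignment) &&
        (min(object@assignment) < 0 || max(object@assignment) >= object@k))
      msg <- c(msg, "fold indices must lie in [0, k)")
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
#  DockingDataset
# ---------------------------------------------------------------------------

#' DockingDataset: assembled benchmark for training and evaluation
#'
#' Container pairing, for every complex: the pocket structure, ligand
#' fingerprint and descriptor features, the label matrix, protein family
#' annotation, and the crystal resolution (the per-complex threshold under
#' which poses count towards n_rmsd).
#'
#' @slot ids character vector of complex ids.
#' @slot pockets list of [PocketStructure-class] objects.
#' @slot fingerprints integer matrix (n x 1024) of fingerprint bits.
#' @slot descriptors numeric matrix (n x D).
#' @slot labels [LabelMatrix-class].
#' @slot families named character vector, complex id -> family label.
#' @slot resolutions named numeric vector, Angstrom.
#' @slot nPoses integer, poses generated per protocol (n_rmsd upper bound).
#' @slot meta list of free-form metadata (e.g. the planted latent factors of
#'   a synthetic benchmark).
#' @exportClass DockingDataset
setClass("DockingDataset",
  representation(ids = "character", pockets = "list", fingerprints = "matrix",
                 descriptors = "matrix", labels = "LabelMatrix",
                 families = "character", resolutions = "numeric",
                 nPoses = "integer", meta = "list"),
  validity = function(object) {
    n <- length(object@ids)
    msg <- character()
    if (length(object@pockets) != n) msg <- c(msg, "pockets length mismatch")
    if (nrow(object@fingerprints) != n) msg <- c(msg, "fingerprint rows mismatch")
    if (nrow(object@descriptors) != n) msg <- c(msg, "descriptor rows mismatch")
    if (dim(object@labels@values)[1] != n) msg <- c(msg, "label rows mismatch")
    if (length(object@families) != n) msg <- c(msg, "families length mismatch")
    if (length(object@resolutions) != n) msg <- c(msg, "resolutions mismatch")
    if (n > 0 && any(object@resolutions <= 0))
      msg <- c(msg, "resolutions must be > 0")
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
#  DockingModel
# ---------------------------------------------------------------------------

#' DockingModel: the two-legged multi-task network
#'
#' Holds the architecture configuration, all learnable parameters, and the
#' featurization metadata (channel order, descriptor standardizer, protocol
#' registry) that makes inference self-describing. Built by [buildModel()],
#' fitted by [trainFold()].
#'
#' @slot config list, see [modelConfig()].
#' @slot params list of parameter matrices/vectors.
#' @slot featMeta list: channel names, registry, descriptor standardizer.
#' @slot trained logical scalar.
#' @exportClass DockingModel
setClass("DockingModel",
  representation(config = "list", params = "list", featMeta = "list",
                 trained = "logical"))

# ---------------------------------------------------------------------------
#  show methods and small accessors
# ---------------------------------------------------------------------------

setMethod("show", "PocketStructure", function(object) {
  cat(sprintf("PocketStructure: %d heavy atoms, center (%.2f, %.2f, %.2f) A\n",
              nrow(object@coords), object@center[1], object@center[2],
              object@center[3]))
  if (nrow(object@coords)) {
    on <- colSums(object@channels)
    cat("  channel atoms:",
        paste(sprintf("%s=%d", abbreviate(channelNames(), 6), on),
              collapse = " "), "\n")
  }
})

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "VoxelGrid: %d channels x %d^3 voxels, %.2f A/voxel, max occupancy %.3f\n",
    d[1], d[2], object@resolution, max(object@values)))
})

setMethod("show", "LabelMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("LabelMatrix: %d complexes x %d protocols (%d missing entries)\n",
              d[1], d[2], sum(!object@mask)))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: strategy '%s', k = %d, %d complexes (seed %s)\n",
              object@strategy, object@k, length(object@assignment),
              ifelse(is.na(object@seed), "none", object@seed)))
  print(table(fold = object@assignment))
})

setMethod("show", "DockingDataset", function(object) {
  cat(sprintf(
    "DockingDataset: %d complexes, %d protocols, %d families, %d descriptors\n",
    length(object@ids), length(object@labels@registry),
    length(unique(object@families)), ncol(object@descriptors)))
})

setMethod("show", "DockingModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "DockingModel (%s): conv channels (%s), latent %d+%d, %d protocols\n",
    if (object@trained) "trained" else "untrained",
    paste(cfg$conv_channels, collapse = ","),
    cfg$protein_latent, cfg$ligand_latent, cfg$n_protocols))
})

#' @describeIn PocketStructure number of heavy atoms in the pocket.
#' @param x a PocketStructure.
#' @export
nAtoms <- function(x) {
  stopifnot(is(x, "PocketStructure"))
  nrow(x@coords)
}

#' Accessors for dataset and label containers
#'
#' `labelValues()` returns the n x P x 3 label array, `labelMask()` the
#' observation mask, `datasetIds()` the complex ids, `gridValues()` the raw
#' voxel array of a grid, `foldAssignment()` the named fold vector of a plan.
#'
#' @param x the object to access.
#' @return the corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
labelValues <- function(x) {
  if (is(x, "DockingDataset")) x <- x@labels
  stopifnot(is(x, "LabelMatrix"))
  x@values
}

#' @rdname accessors
#' @export
labelMask <- function(x) {
  if (is(x, "DockingDataset")) x <- x@labels
  stopifnot(is(x, "LabelMatrix"))
  x@mask
}

#' @rdname accessors
#' @export
datasetIds <- function(x) {
  stopifnot(is(x, "DockingDataset"))
  x@ids
}

#' @rdname accessors
#' @export
gridValues <- function(x) {
  stopifnot(is(x, "VoxelGrid"))
  x@values
}

#' @rdname accessors
#' @export
foldAssignment <- function(x) {
  stopifnot(is(x, "SplitPlan"))
  x@assignment
}
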