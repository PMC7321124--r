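# Voxelization of a pocket into the 8-channel occupancy grid, and the
# random-rotation augmentation used during training.

#' Occupancy contribution of one atom to one voxel
#'
#' The pair-correlation occupancy `1 - exp(-(rvdw / r)^12)` of an atom with
#' van der Waals radius `rvdw` at Euclidean distance `r` from a voxel
#' center. Monotonically decreasing in `r`, tends to 1 as `r -> 0` (the
#' value at `r = 0` is defined as this limit) and to 0 as `r -> Inf`; at
#' `r = rvdw` it equals `1 - exp(-1)`.
#'
#' @param r distance(s) in Angstrom, >= 0.
#' @param rvdw van der Waals radius in Angstrom, > 0.
#' @return occupancy value(s) in \[0, 1\].
#' @examples
#' voxelContribution(1.7, 1.7)   # 1 - exp(-1)
#' @export
voxelContribution <- function(r, rvdw) {
  if (any(r < 0)) stop("r must be >= 0")
  if (any(rvdw <= 0)) stop("rvdw must be > 0")
  out <- ifelse(r == 0, 1, 1 - exp(-(rvdw / r)^12))
  unname(out)
}

#' Voxelize a pocket into an 8-channel occupancy grid
#'
#' Lays a cubic grid of `edge / resolution` voxels per axis, centered at
#' `center` (by default the pocket's own ligand center), and computes for
#' every channel and voxel the maximum [voxelContribution()] over the atoms
#' carrying that channel flag. Atoms outside the grid still contribute to
#' voxels within reach; no cutoff is applied. The default 24 Angstrom cube
#' at 1 Angstrom resolution gives the 8 x 24 x 24 x 24 network input.
#'
#' @param pocket a [PocketStructure-class] with channel flags assigned.
#' @param center grid center (Angstrom); default `pocket@center`.
#' @param edge cube edge length in Angstrom.
#' @param resolution voxel size in Angstrom; `edge / resolution` must be a
#'   positive integer.
#' @return a [VoxelGrid-class].
#' @export
voxelizePocket <- function(pocket, center = pocket@center, edge = 24,
                           resolution = 1) {
  stopifnot(is(pocket, "PocketStructure"))
  E <- edge / resolution
  if (!isTRUE(all.equal(E, round(E))) || E <= 0)
    stop("edge / resolution must be a positive integer")
  E <- as.integer(round(E))
  origin <- center - edge / 2
  if (nAtoms(pocket) == 0) {
    vals <- array(0, c(8, E, E, E))
  } else {
    v <- voxelize_cpp(pocket@coords, pocket@radii, pocket@channels,
                      origin, E, resolution)
    vals <- array(v, c(8, E, E, E))
  }
  new("VoxelGrid", values = vals, origin = as.numeric(origin),
      resolution = resolution)
}

#' Uniformly random proper rotation matrix
#'
#' Draws a rotation uniformly over SO(3) via a normalized quaternion sampled
#' from the current R random-number state (seed with [set.seed()]).
#'
#' @return a 3 x 3 rotation matrix with determinant +1.
#' @export
randomRotationMatrix <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

#' Rotate coordinates about a pivot
#'
#' Applies a proper rotation about `pivot` — by default a fresh uniformly
#' random rotation from the current RNG state (the training augmentation);
#' pass `rotation` explicitly for a deterministic transform. Pairwise
#' distances and distances to the pivot are preserved.
#'
#' @param coords numeric n x 3 matrix.
#' @param pivot numeric length-3 rotation center.
#' @param rotation optional 3 x 3 rotation matrix; default random.
#' @return rotated n x 3 matrix.
#' @export
randomRotation <- function(coords, pivot, rotation = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (is.null(rotation)) rotation <- randomRotationMatrix()
  ctr <- matrix(pivot, nrow(coords), 3, byrow = TRUE)
  (coords - ctr) %*% t(rotation) + ctr
}

#' Rotate a pocket about its center
#'
#' Convenience wrapper: returns the pocket with its atom coordinates rotated
#' about the pocket center (the ligand center of mass), leaving radii and
#' channel flags untouched. This is the augmentation transform applied to
#' training pockets before re-voxelization.
#'
#' @param pocket a [PocketStructure-class].
#' @param rotation optional 3 x 3 rotation matrix; default random.
#' @return the rotated pocket.
#' @export
rotatePocket <- function(pocket, rotation = NULL) {
  stopifnot(is(pocket, "PocketStructure"))
  pocket@coords <- randomRotation(pocket@coords, pocket@center, rotation)
  pocket
}

#' Export / import a voxel grid
#'
#' `writeVoxelGrid()` stores the raw occupancy tensor as little-endian
#' doubles next to a JSON sidecar holding the shape, channel names, origin
#' and resolution; `readVoxelGrid()` restores the [VoxelGrid-class].
#'
#' @param grid a [VoxelGrid-class].
#' @param path output path for the binary tensor; the sidecar is
#'   `paste0(path, ".json")`.
#' @return `writeVoxelGrid()`: `path` invisibly; `readVoxelGrid()`: the grid.
#' @export
writeVoxelGrid <- function(grid, path) {
  stopifnot(is(grid, "VoxelGrid"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(grid@values), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(shape = dim(grid@values), channels = channelNames(),
         origin = grid@origin, resolution = grid@resolution),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeVoxelGrid
#' @export
readVoxelGrid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  new("VoxelGrid", values = array(vals, meta$shape),
      origin = meta$origin, resolution = meta$resolution)
}
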