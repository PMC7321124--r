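# Ligand featurization: hashed circular fingerprint (bond radius 2, folded
# to 1024 bits) and a fixed panel of 183 physicochemical / topological
# descriptors computed on the heavy-atom molecular graph. The fingerprint is
# a package implementation of the extended-connectivity scheme; it is
# deterministic but not bit-compatible with any external toolkit.

#' Read a ligand molecule
#'
#' `readLigand()` parses the first molecule of an SDF file;
#' `parseSMILES()` parses a SMILES string (3D coordinates are not needed for
#' ligand featurization). Both return the internal molecular-graph record
#' (elements, coordinates, bonds with orders, formal charges).
#'
#' @param path path to an SDF file.
#' @return a molecular graph list.
#' @export
readLigand <- function(path) {
  if (!file.exists(path)) stop("ligand file not found: ", path)
  sdfset <- ChemmineR::read.SDFset(path)
  if (length(sdfset) < 1) stop("SDF file contains no molecules")
  mol <- .moleculeFromSDF(sdfset[[1]])
  if (!any(.heavy(mol$elements))) stop("ligand has no heavy atoms")
  mol
}

#' @rdname readLigand
#' @param smiles a SMILES string.
#' @export
parseSMILES <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("SMILES input requires the ChemmineOB package")
  sdf <- tryCatch(ChemmineR::smiles2sdf(smiles),
                  error = function(e)
                    stop("failed to parse SMILES: ", conditionMessage(e)))
  mol <- .moleculeFromSDF(sdf[[1]])
  if (!any(.heavy(mol$elements))) stop("ligand has no heavy atoms")
  mol
}

# --- graph helpers ---------------------------------------------------------

.adjacency <- function(mol) {
  n <- length(mol$elements)
  adj <- vector("list", n)
  ord <- vector("list", n)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    adj[[b$a1[i]]] <- c(adj[[b$a1[i]]], b$a2[i])
    adj[[b$a2[i]]] <- c(adj[[b$a2[i]]], b$a1[i])
    o <- b$order[i]
    ord[[b$a1[i]]] <- c(ord[[b$a1[i]]], o)
    ord[[b$a2[i]]] <- c(ord[[b$a2[i]]], o)
  }
  list(nbr = adj, ord = ord)
}

# topological distance matrix by BFS (Inf when disconnected)
.topoDist <- function(adj, n) {
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    front <- s
    while (length(front)) {
      nxt <- unique(unlist(adj$nbr[front]))
      nxt <- nxt[is.infinite(d[nxt])]
      if (!length(nxt)) break
      d[nxt] <- d[front[1]] + 1
      front <- nxt
    }
    D[s, ] <- d
  }
  D
}

# effective bond order: aromatic (4) counts 1.5
.bondOrderValue <- function(o) ifelse(o == 4, 1.5, o)

# implicit hydrogen count from standard valences
.implicitH <- function(mol, adj) {
  n <- length(mol$elements)
  val <- .elementProperty(mol$elements, "valence")
  bsum <- vapply(seq_len(n), function(i)
    sum(.bondOrderValue(adj$ord[[i]])), numeric(1))
  pmax(0, round(val + mol$charges - bsum))
}

# TRUE for bonds that lie on a cycle; returns per-atom ring membership too
.ringInfo <- function(mol, adj) {
  n <- length(mol$elements)
  b <- mol$bonds
  inRingBond <- logical(nrow(b))
  cycles <- list()
  if (nrow(b)) {
    for (i in seq_len(nrow(b))) {
      # shortest alternative path between the endpoints without this bond
      src <- b$a1[i]; dst <- b$a2[i]
      d <- rep(Inf, n); d[src] <- 0; parent <- rep(NA_integer_, n)
      front <- src
      while (length(front) && is.infinite(d[dst])) {
        newfront <- integer()
        for (u in front) {
          for (jj in seq_along(adj$nbr[[u]])) {
            v <- adj$nbr[[u]][jj]
            if (u == src && v == dst) next
            if (u == dst && v == src) next
            if (is.infinite(d[v])) {
              d[v] <- d[u] + 1; parent[v] <- u
              newfront <- c(newfront, v)
            }
          }
        }
        front <- newfront
      }
      if (is.finite(d[dst])) {
        inRingBond[i] <- TRUE
        path <- dst
        while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
        cycles[[length(cycles) + 1]] <- sort(path)
      }
    }
  }
  cycles <- unique(cycles)
  inRingAtom <- rep(FALSE, n)
  for (cy in cycles) inRingAtom[cy] <- TRUE
  list(bond = inRingBond, atom = inRingAtom, cycles = cycles)
}

# --- fingerprint -----------------------------------------------------------

.hashInts <- function(xs) {
  # 31-bit FNV-style rolling hash, exact in double arithmetic
  h <- 2166136261 %% 2147483647
  for (x in xs) {
    h <- (h * 16777619 + (x %% 2147483647) + 1) %% 2147483647
  }
  h
}

#' Hashed circular fingerprint of a ligand
#'
#' Computes an extended-connectivity-style fingerprint on the heavy-atom
#' graph: per-atom invariants (element, heavy degree, bonded-order sum,
#' implicit hydrogens, formal charge, ring membership) are iteratively
#' updated over `radius` bond shells, and every environment identifier is
#' folded into `nbits` bits. Deterministic; two structurally different
#' molecules almost surely differ in at least one bit.
#'
#' @param mol molecular graph from [readLigand()] or [parseSMILES()].
#' @param nbits fingerprint length (default 1024).
#' @param radius neighborhood radius in bonds (default 2).
#' @return integer vector of `nbits` 0/1 values.
#' @export
ligandFingerprint <- function(mol, nbits = 1024, radius = 2) {
  mol <- .heavyGraph(mol)
  n <- length(mol$elements)
  if (n == 0) stop("molecule has no heavy atoms")
  adj <- .adjacency(mol)
  ring <- .ringInfo(mol, adj)
  hyd <- .implicitH(mol, adj)
  elcode <- match(.normElement(mol$elements), rownames(.ELEMENT_TABLE),
                  nomatch = 0L)
  deg <- lengths(adj$nbr)
  inv <- vapply(seq_len(n), function(i)
    .hashInts(c(elcode[i], deg[i],
                round(2 * sum(.bondOrderValue(adj$ord[[i]]))), hyd[i],
                mol$charges[i] + 8, as.integer(ring$atom[i]))),
    numeric(1))
  ids <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(i) {
      if (deg[i] == 0) return(.hashInts(c(r, inv[i])))
      pairs <- cbind(round(2 * .bondOrderValue(adj$ord[[i]])),
                     inv[adj$nbr[[i]]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      .hashInts(c(r, inv[i], t(pairs)))
    }, numeric(1))
    ids <- c(ids, inv)
  }
  bits <- integer(nbits)
  bits[(unique(ids) %% nbits) + 1] <- 1L
  bits
}

# --- descriptors -----------------------------------------------------------

.DESC_PROPS <- c("mass", "en", "vdw", "polar")
.DESC_PAIR_ELEMS <- c("C", "N", "O", "S", "P", "X")  # X = any halogen

#' Names of the default descriptor panel
#'
#' The 183 descriptors computed by [ligandDescriptors()]: element counts,
#' global size/shape/charge descriptors, degree and ring-size counts,
#' element-pair bond counts, Moreau-Broto / Moran / Geary topological
#' autocorrelations of atomic mass, electronegativity, van der Waals radius,
#' polarizability and degree, and classical connectivity indices.
#'
#' @return character vector of length 183.
#' @export
descriptorNames <- function() {
  props <- c(.DESC_PROPS, "degree")
  pairs <- outer(.DESC_PAIR_ELEMS, .DESC_PAIR_ELEMS, paste, sep = "")
  pairs <- pairs[upper.tri(pairs, diag = TRUE)]
  c(paste0("count_", c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
                       "B", "Si", "Se", "other")),
    c("mol_weight", "n_heavy", "n_bonds", "n_rings", "n_aromatic_atoms",
      "n_rotatable", "total_charge", "n_hbd", "n_hba", "n_hetero",
      "max_degree", "mean_bond_order"),
    paste0("n_deg", 1:4),
    paste0("n_ring", 3:8),
    paste0("bond_", pairs),
    as.vector(outer(0:7, props, function(l, p) paste0("ats_", p, "_", l))),
    as.vector(outer(1:8, props, function(l, p) paste0("moran_", p, "_", l))),
    as.vector(outer(1:8, props, function(l, p) paste0("geary_", p, "_", l))),
    c("zagreb1", "zagreb2", "chi0", "chi1", "chi0v", "chi1v", "wiener"))
}

#' Physicochemical descriptor vector of a ligand
#'
#' Computes the fixed panel named by [descriptorNames()] on the heavy-atom
#' graph (183 descriptors by default). Autocorrelation descriptors of a
#' property with zero variance are undefined; any non-finite value is
#' replaced by 0 and reported via a single warning.
#'
#' @param mol molecular graph from [readLigand()] or [parseSMILES()].
#' @param names descriptor subset to compute (default: the full panel).
#' @return named numeric vector.
#' @export
ligandDescriptors <- function(mol, names = descriptorNames()) {
  mol <- .heavyGraph(mol)
  n <- length(mol$elements)
  if (n == 0) stop("molecule has no heavy atoms")
  adj <- .adjacency(mol)
  ring <- .ringInfo(mol, adj)
  hyd <- .implicitH(mol, adj)
  el <- .normElement(mol$elements)
  deg <- lengths(adj$nbr)
  b <- mol$bonds
  bo <- .bondOrderValue(b$order)
  D <- .topoDist(adj, n)

  halogens <- c("F", "CL", "BR", "I")
  out <- c(
    count_C = sum(el == "C"), count_N = sum(el == "N"),
    count_O = sum(el == "O"), count_S = sum(el == "S"),
    count_P = sum(el == "P"), count_F = sum(el == "F"),
    count_Cl = sum(el == "CL"), count_Br = sum(el == "BR"),
    count_I = sum(el == "I"), count_B = sum(el == "B"),
    count_Si = sum(el == "SI"), count_Se = sum(el == "SE"),
    count_other = sum(!el %in% c("C", "N", "O", "S", "P", "B", "SI", "SE",
                                 halogens)))

  aromAtom <- rep(FALSE, n)
  if (nrow(b)) {
    ar <- b$order == 4
    aromAtom[unique(c(b$a1[ar], b$a2[ar]))] <- TRUE
    # kekulized aromatic rings: 5/6-rings with >= 2 double bonds
    for (cy in ring$cycles) {
      if (!length(cy) %in% c(5, 6)) next
      ncyc <- sum(b$a1 %in% cy & b$a2 %in% cy & b$order == 2)
      if (ncyc >= 2) aromAtom[cy] <- TRUE
    }
  }
  rotatable <- if (nrow(b))
    sum(b$order == 1 & !ring$bond & deg[b$a1] > 1 & deg[b$a2] > 1) else 0
  hbd <- sum(el %in% c("N", "O", "S") & hyd > 0)
  hba <- sum(el %in% c("N", "O"))
  # connected components from the distance matrix, for the cyclomatic number
  ncomp <- length(unique(apply(is.finite(D), 1, function(r) min(which(r)))))
  out <- c(out,
    mol_weight = sum(.elementProperty(el, "mass")) + 1.008 * sum(hyd),
    n_heavy = n, n_bonds = nrow(b),
    n_rings = nrow(b) - n + ncomp,
    n_aromatic_atoms = sum(aromAtom), n_rotatable = rotatable,
    total_charge = sum(mol$charges), n_hbd = hbd, n_hba = hba,
    n_hetero = sum(el != "C"), max_degree = max(deg),
    mean_bond_order = if (nrow(b)) mean(bo) else 0)

  out <- c(out, setNames(vapply(1:4, function(k) sum(deg == k), numeric(1)),
                         paste0("n_deg", 1:4)))
  ringSizes <- lengths(ring$cycles)
  out <- c(out, setNames(vapply(3:8, function(k) sum(ringSizes == k),
                                numeric(1)), paste0("n_ring", 3:8)))

  pe <- function(e) ifelse(e %in% halogens, "X",
                           ifelse(e %in% .DESC_PAIR_ELEMS, e, NA))
  pairNames <- outer(.DESC_PAIR_ELEMS, .DESC_PAIR_ELEMS, paste, sep = "")
  pairNames <- pairNames[upper.tri(pairNames, diag = TRUE)]
  pv <- setNames(numeric(length(pairNames)), pairNames)
  if (nrow(b)) {
    i1 <- match(pe(el[b$a1]), .DESC_PAIR_ELEMS)
    i2 <- match(pe(el[b$a2]), .DESC_PAIR_ELEMS)
    for (i in seq_len(nrow(b))) {
      if (is.na(i1[i]) || is.na(i2[i])) next
      lo <- min(i1[i], i2[i]); hi <- max(i1[i], i2[i])
      key <- paste0(.DESC_PAIR_ELEMS[lo], .DESC_PAIR_ELEMS[hi])
      pv[key] <- pv[key] + 1
    }
  }
  out <- c(out, setNames(pv, paste0("bond_", names(pv))))

  propMat <- cbind(mass = .elementProperty(el, "mass"),
                   en = .elementProperty(el, "en"),
                   vdw = .elementProperty(el, "vdw"),
                   polar = .elementProperty(el, "polar"),
                   degree = deg)
  for (p in colnames(propMat)) {
    v <- propMat[, p]
    ats <- vapply(0:7, function(lag) {
      if (lag == 0) return(sum(v^2))
      idx <- which(D == lag, arr.ind = TRUE)
      sum(v[idx[, 1]] * v[idx[, 2]]) / 2
    }, numeric(1))
    out <- c(out, setNames(ats, paste0("ats_", p, "_", 0:7)))
  }
  for (p in colnames(propMat)) {
    v <- propMat[, p]; vc <- v - mean(v); s2 <- sum(vc^2)
    mor <- vapply(1:8, function(lag) {
      idx <- which(D == lag, arr.ind = TRUE)
      if (nrow(idx) == 0) return(0)
      (n * sum(vc[idx[, 1]] * vc[idx[, 2]])) / (nrow(idx) * s2)
    }, numeric(1))
    out <- c(out, setNames(mor, paste0("moran_", p, "_", 1:8)))
  }
  for (p in colnames(propMat)) {
    v <- propMat[, p]; s2 <- sum((v - mean(v))^2)
    gea <- vapply(1:8, function(lag) {
      idx <- which(D == lag, arr.ind = TRUE)  # ordered pairs, W = nrow(idx)
      if (nrow(idx) == 0) return(0)
      ((n - 1) * sum((v[idx[, 1]] - v[idx[, 2]])^2)) / (2 * nrow(idx) * s2)
    }, numeric(1))
    out <- c(out, setNames(gea, paste0("geary_", p, "_", 1:8)))
  }

  dv <- pmax(.elementProperty(el, "valence") - hyd, 1)
  chi0 <- sum(1 / sqrt(pmax(deg, 1)))
  chi1 <- if (nrow(b)) sum(1 / sqrt(deg[b$a1] * deg[b$a2])) else 0
  chi0v <- sum(1 / sqrt(dv))
  chi1v <- if (nrow(b)) sum(1 / sqrt(dv[b$a1] * dv[b$a2])) else 0
  finD <- D[upper.tri(D)]
  out <- c(out,
    zagreb1 = sum(deg^2),
    zagreb2 = if (nrow(b)) sum(deg[b$a1] * deg[b$a2]) else 0,
    chi0 = chi0, chi1 = chi1, chi0v = chi0v, chi1v = chi1v,
    wiener = sum(finD[is.finite(finD)]))

  out <- out[names]
  bad <- !is.finite(out)
  if (any(bad)) {
    warning(sum(bad), " non-finite descriptor value(s) replaced by 0")
    out[bad] <- 0
  }
  out
}

#' Combined ligand features
#'
#' Convenience constructor: fingerprint plus (unstandardized) descriptors as
#' a [LigandFeatures-class] object.
#'
#' @param mol molecular graph.
#' @return a [LigandFeatures-class].
#' @export
ligandFeatures <- function(mol) {
  new("LigandFeatures", fingerprint = ligandFingerprint(mol),
      descriptors = ligandDescriptors(mol), standardized = FALSE)
}

# --- descriptor standardization -------------------------------------------

#' Fit a descriptor standardizer on a training fold
#'
#' Computes per-descriptor mean and population standard deviation
#' (n-denominator, so the two-point column (0, 2) transforms to (-1, 1))
#' on the training rows only; constant descriptors receive scale 1 (so
#' they transform to zero). Validation and test descriptors must be
#' transformed with the training statistics via [applyStandardizer()],
#' never with their own.
#'
#' @param train_matrix numeric matrix (rows = training complexes).
#' @return an object of class `DescriptorStandardizer` (list: center, scale).
#' @export
standardizeDescriptors <- function(train_matrix) {
  train_matrix <- as.matrix(train_matrix)
  if (nrow(train_matrix) < 2)
    stop("need at least 2 training rows to fit a standardizer")
  ctr <- colMeans(train_matrix)
  scl <- sqrt(colMeans(sweep(train_matrix, 2, ctr)^2))
  scl[!is.finite(scl) | scl == 0] <- 1
  structure(list(center = ctr, scale = scl),
            class = "DescriptorStandardizer")
}

#' @rdname standardizeDescriptors
#' @param transform a fitted `DescriptorStandardizer`.
#' @param x numeric matrix (or vector) to transform.
#' @export
applyStandardizer <- function(transform, x) {
  stopifnot(inherits(transform, "DescriptorStandardizer"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sweep(sweep(x, 2, transform$center, "-"), 2, transform$scale, "/")
}
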