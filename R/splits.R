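# The four cross-validation split constructors: random, ligand-scaffold
# (k-means on fingerprints), protein-family (whole families per fold), and
# balanced protein-family (stratified within family).

.newPlan <- function(strategy, k, assignment, seed) {
  new("SplitPlan", strategy = strategy, k = as.integer(k),
      assignment = setNames(as.integer(assignment), names(assignment)),
      seed = as.integer(seed))
}

#' Random k-fold split
#'
#' Uniformly shuffles the complexes and deals them into k folds whose sizes
#' differ by at most one.
#'
#' @param ids character vector of complex ids.
#' @param k fold count (default 5).
#' @param seed integer seed.
#' @return a [SplitPlan-class].
#' @export
randomSplit <- function(ids, k = 5, seed = 1) {
  n <- length(ids)
  if (k > n) stop("k must not exceed the number of complexes")
  set.seed(seed)
  perm <- sample(n)
  folds <- rep(seq_len(k) - 1L, length.out = n)  # sizes differ by <= 1
  assignment <- integer(n)
  assignment[perm] <- folds
  names(assignment) <- ids
  .newPlan("random", k, assignment, seed)
}

#' Ligand-scaffold split by fingerprint clustering
#'
#' Groups complexes by k-means clustering of their ligand fingerprint bit
#' vectors (Euclidean metric on 0/1 bits, k clusters = k folds, seeded
#' initialization from distinct fingerprints), so chemically similar
#' ligands share a fold. Cluster sizes are inherently unequal; that is the
#' point of a scaffold split.
#'
#' @param fingerprints numeric/integer matrix, one row per complex; row
#'   names are the complex ids.
#' @param k fold count (default 5).
#' @param seed integer seed.
#' @return a [SplitPlan-class].
#' @export
scaffoldSplit <- function(fingerprints, k = 5, seed = 1) {
  fp <- as.matrix(fingerprints)
  ids <- rownames(fp)
  if (is.null(ids)) ids <- paste0("cpx", seq_len(nrow(fp)))
  uni <- unique(fp)
  if (nrow(uni) < k)
    stop("fewer distinct fingerprints (", nrow(uni), ") than folds (", k, ")")
  set.seed(seed)
  centers <- uni[sample(nrow(uni), k), , drop = FALSE]
  km <- kmeans(fp, centers = centers, iter.max = 100)
  assignment <- setNames(km$cluster - 1L, ids)
  .newPlan("ligand_scaffold", k, assignment, seed)
}

#' Protein-family split (whole families per fold)
#'
#' Assigns whole protein families (e.g. PFAM annotations) to folds so that
#' no family spans two folds, balancing complex counts by first-fit-
#' decreasing bin packing with per-fold capacity `ceiling(n / k)`: families
#' are sorted by size (ties by name), and each is placed in the first fold
#' it fits; a family that fits nowhere goes to the least-loaded fold. If a
#' fold ends up empty, the smallest families are moved from the most loaded
#' folds to fill it.
#'
#' @param family_labels named character vector, complex id -> family.
#' @param k fold count (default 5).
#' @return a [SplitPlan-class].
#' @export
proteinClassSplit <- function(family_labels, k = 5) {
  fams <- table(family_labels)
  if (length(fams) < k)
    stop("need at least k = ", k, " families, got ", length(fams))
  ord <- order(-as.integer(fams), names(fams))
  sizes <- as.integer(fams)[ord]
  fnames <- names(fams)[ord]
  cap <- ceiling(length(family_labels) / k)
  load <- integer(k)
  fold_of <- setNames(integer(length(fnames)), fnames)
  for (i in seq_along(fnames)) {
    fits <- which(load + sizes[i] <= cap)
    dest <- if (length(fits)) fits[1] else which.min(load)
    fold_of[fnames[i]] <- dest - 1L
    load[dest] <- load[dest] + sizes[i]
  }
  while (any(load == 0)) {
    empty <- which(load == 0)[1]
    nfam <- tabulate(fold_of + 1L, nbins = k)
    donors <- which(nfam >= 2)
    if (!length(donors)) break
    src <- donors[which.max(load[donors])]
    members <- names(fold_of)[fold_of == src - 1L]
    fam <- members[which.min(fams[members])]
    load[src] <- load[src] - as.integer(fams[fam])
    load[empty] <- as.integer(fams[fam])
    fold_of[fam] <- empty - 1L
  }
  assignment <- fold_of[as.character(family_labels)]
  names(assignment) <- names(family_labels)
  .newPlan("protein_classes", k, assignment, NA_integer_)
}

#' Balanced protein-family split (stratified within family)
#'
#' Stratified k-fold: within each family the members are shuffled (seeded)
#' and dealt round-robin to the folds starting at a seeded random offset,
#' so every fold's validation set holds about `1/k` of each family —
#' exactly `size/k` when the family size is divisible by k — and no fold is
#' systematically favored by the small families.
#'
#' @param family_labels named character vector, complex id -> family.
#' @param k fold count (default 5).
#' @param val_fraction must equal `1/k` (the held-out share per fold).
#' @param seed integer seed.
#' @return a [SplitPlan-class].
#' @export
balancedProteinSplit <- function(family_labels, k = 5, val_fraction = 1 / k,
                                 seed = 1) {
  if (!isTRUE(all.equal(val_fraction, 1 / k)))
    stop("val_fraction must equal 1/k for a k-fold scheme")
  set.seed(seed)
  assignment <- setNames(rep(NA_integer_, length(family_labels)),
                         names(family_labels))
  for (fam in unique(family_labels)) {
    members <- names(family_labels)[family_labels == fam]
    members <- sample(members)
    offset <- sample.int(k, 1) - 1L
    assignment[members] <-
      (offset + seq_along(members) - 1L) %% k
  }
  .newPlan("protein_classes_balanced", k, assignment, seed)
}

#' Serialize / restore a split plan
#'
#' Plans are written as JSON (strategy, k, seed, assignment) for exact
#' reuse across runs.
#'
#' @param plan a [SplitPlan-class].
#' @param path output JSON path.
#' @return `writeSplitPlan()`: `path` invisibly; `readSplitPlan()`: the plan.
#' @export
writeSplitPlan <- function(plan, path) {
  stopifnot(is(plan, "SplitPlan"))
  jsonlite::write_json(
    list(strategy = plan@strategy, k = plan@k,
         seed = if (is.na(plan@seed)) NULL else plan@seed,
         assignment = as.list(plan@assignment)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSplitPlan
#' @export
readSplitPlan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  .newPlan(x$strategy, x$k, unlist(x$assignment),
           if (is.null(x$seed)) NA_integer_ else x$seed)
}
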