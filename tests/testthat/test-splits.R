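ids <- function(n) sprintf("c%03d", seq_len(n))

expect_partition <- function(plan, all_ids) {
  a <- foldAssignment(plan)
  expect_setequal(names(a), all_ids)
  expect_false(any(duplicated(names(a))))
  expect_true(all(a >= 0 & a < plan@k))
}

test_that("random splits are balanced, seeded partitions", {
  p <- randomSplit(ids(10), k = 5, seed = 3)
  expect_partition(p, ids(10))
  expect_equal(as.integer(table(foldAssignment(p))), rep(2L, 5))
  p11 <- randomSplit(ids(11), k = 5, seed = 3)
  expect_equal(sort(as.integer(table(foldAssignment(p11)))), c(2L, 2L, 2L, 2L, 3L))
  expect_identical(foldAssignment(randomSplit(ids(30), 5, seed = 9)),
                   foldAssignment(randomSplit(ids(30), 5, seed = 9)))
  expect_error(randomSplit(ids(4), k = 5), "exceed")
})

test_that("scaffold splits cluster fingerprints into folds", {
  # two well-separated blobs: folds must be exactly the blobs
  set.seed(2)
  blobA <- matrix(rep(c(rep(1, 16), rep(0, 16)), 5), 5, byrow = TRUE)
  blobB <- matrix(rep(c(rep(0, 16), rep(1, 16)), 5), 5, byrow = TRUE)
  blobA[cbind(1:5, 1:5)] <- 0        # make rows distinct within blobs
  blobB[cbind(1:5, 17:21)] <- 0
  fp <- rbind(blobA, blobB)
  rownames(fp) <- ids(10)
  p <- scaffoldSplit(fp, k = 2, seed = 1)
  expect_partition(p, ids(10))
  a <- foldAssignment(p)
  expect_length(unique(a[1:5]), 1)
  expect_length(unique(a[6:10]), 1)
  expect_false(a[1] == a[6])
  # identical fingerprints always share a fold
  fp2 <- rbind(fp, fp[1, , drop = FALSE], fp[1, , drop = FALSE])
  rownames(fp2) <- ids(12)
  p2 <- scaffoldSplit(fp2, k = 2, seed = 1)
  a2 <- foldAssignment(p2)
  expect_equal(a2["c011"], a2["c001"], ignore_attr = TRUE)
  expect_equal(a2["c012"], a2["c001"], ignore_attr = TRUE)
  expect_identical(foldAssignment(scaffoldSplit(fp, 2, seed = 5)),
                   foldAssignment(scaffoldSplit(fp, 2, seed = 5)))
  expect_error(scaffoldSplit(fp[c(1, 1, 1), ], k = 2), "distinct")
})

test_that("protein-class splits never break a family apart", {
  fam <- setNames(rep(paste0("F", 1:6), c(6, 4, 3, 3, 2, 2)), ids(20))
  p <- proteinClassSplit(fam, k = 2)
  expect_partition(p, ids(20))
  a <- foldAssignment(p)
  for (f in unique(fam))
    expect_length(unique(a[names(fam)[fam == f]]), 1)
  # first-fit-decreasing with capacity ceiling(n/k): 6+4 | 3+3+2+2
  expect_equal(sort(as.integer(table(a))), c(10L, 10L))
  # five equal families over five folds: one family per fold
  fam5 <- setNames(rep(paste0("G", 1:5), each = 5), ids(25))
  p5 <- proteinClassSplit(fam5, k = 5)
  expect_equal(as.integer(table(foldAssignment(p5))), rep(5L, 5))
  expect_error(proteinClassSplit(fam[1:5], k = 6), "at least k")
})

test_that("balanced protein splits stratify every family across folds", {
  fam <- setNames(rep(c("A", "B"), each = 10), ids(20))
  p <- balancedProteinSplit(fam, k = 5, seed = 2)
  expect_partition(p, ids(20))
  a <- foldAssignment(p)
  for (f in c("A", "B"))                     # size 10, k 5 -> exactly 2 per fold
    expect_equal(as.integer(table(a[names(fam)[fam == f]])), rep(2L, 5))
  # a singleton family lands in exactly one fold
  fam1 <- setNames(c(rep("A", 9), "solo"), ids(10))
  a1 <- foldAssignment(balancedProteinSplit(fam1, k = 5, seed = 4))
  expect_length(a1[["c010"]], 1)
  expect_error(balancedProteinSplit(fam, k = 5, val_fraction = 0.5),
               "1/k")
})

test_that("all four strategies yield exact partitions on random instances", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    k <- sample(2:5, 1)
    id <- ids(n)
    fam <- setNames(sample(paste0("F", 1:max(k, 6)), n, replace = TRUE), id)
    while (length(unique(fam)) < k)
      fam[sample(n, 1)] <- paste0("F", length(unique(fam)) + 1)
    fp <- matrix(rbinom(n * 32, 1, 0.4), n)
    rownames(fp) <- id
    plans <- list(randomSplit(id, k, seed = i),
                  proteinClassSplit(fam, k),
                  balancedProteinSplit(fam, k, seed = i))
    if (nrow(unique(fp)) >= k)
      plans <- c(plans, list(scaffoldSplit(fp, k, seed = i)))
    for (p in plans) expect_partition(p, id)
    # family cohesion, exhaustively
    a <- foldAssignment(plans[[2]])
    expect_true(all(tapply(a[names(fam)], fam, function(x)
      length(unique(x))) == 1))
    # balanced split: exact size/k per fold for divisible families
    ab <- foldAssignment(plans[[3]])
    for (f in unique(fam)) {
      sz <- sum(fam == f)
      if (sz %% k == 0)
        expect_equal(as.integer(table(factor(ab[names(fam)[fam == f]],
                                         levels = 0:(k - 1)))),
                     rep(sz %/% k, k))
    }
  }
})

test_that("split plans serialize to JSON and back unchanged", {
  fam <- setNames(rep(c("A", "B", "C"), each = 5), ids(15))
  for (p in list(randomSplit(ids(15), 5, seed = 1),
                 proteinClassSplit(fam, k = 3),
                 balancedProteinSplit(fam, k = 5, seed = 2))) {
    path <- withr::local_tempfile(fileext = ".json")
    writeSplitPlan(p, path)
    q <- readSplitPlan(path)
    expect_identical(foldAssignment(q), foldAssignment(p))
    expect_identical(q@strategy, p@strategy)
    expect_identical(q@k, p@k)
  }
})
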