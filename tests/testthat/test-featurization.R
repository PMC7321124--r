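test_that("occupancy kernel has its analytic values and limits", {
  expect_equal(voxelContribution(1.7, 1.7), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(voxelContribution(3.6, 1.8), 1 - exp(-0.5^12),
               tolerance = 1e-12)
  expect_lt(voxelContribution(18, 1.8), 2e-12)      # r = 10 rvdw
  expect_equal(voxelContribution(0, 1.8), 1)         # limit at r = 0
  # monotone non-increasing everywhere (ties only where the exponential
  # saturates in floating point), strictly decreasing in the working range
  r <- seq(0.1, 10, by = 0.1)
  expect_true(all(diff(voxelContribution(r, 1.7)) <= 0))
  rmid <- seq(2, 6, by = 0.1)
  expect_true(all(diff(voxelContribution(rmid, 1.7)) < 0))
  expect_error(voxelContribution(-1, 1.7))
  expect_error(voxelContribution(1, 0))
})

test_that("voxelization matches the brute-force double-loop oracle", {
  set.seed(21)
  for (rep in 1:3) {
    pocket <- generatePocket(sample(3:10, 1))
    grid <- gridValues(voxelizePocket(pocket))
    oracle <- bruteForceVoxelize(pocket)
    expect_lt(max(abs(grid - oracle)), 1e-12)
  }
})

test_that("voxel grids have the contracted shape and range", {
  set.seed(4)
  pocket <- generatePocket(30)
  g <- voxelizePocket(pocket)
  expect_equal(dim(gridValues(g)), c(8, 24, 24, 24))
  expect_true(all(gridValues(g) >= 0 & gridValues(g) <= 1))
  # non-integral edge/resolution rejected
  expect_error(voxelizePocket(pocket, edge = 24, resolution = 0.7),
               "positive integer")
  # adding an atom never decreases any voxel (max aggregation)
  bigger <- pocket
  bigger@coords <- rbind(pocket@coords, c(1, 1, 1))
  bigger@radii <- c(pocket@radii, 1.7)
  bigger@channels <- rbind(pocket@channels, rep(TRUE, 8))
  bigger@elements <- c(pocket@elements, "C")
  bigger@resnames <- c(pocket@resnames, "ALA")
  bigger@atomnames <- c(pocket@atomnames, "CB")
  g2 <- voxelizePocket(bigger)
  expect_true(all(gridValues(g2) - gridValues(g) >= -1e-15))
})

test_that("an axis-aligned 90-degree rotation permutes the grid exactly", {
  set.seed(33)
  pocket <- generatePocket(12)
  g <- gridValues(voxelizePocket(pocket))
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rot <- rotatePocket(pocket, rotation = Rz)
  gr <- gridValues(voxelizePocket(rot))
  # value at rotated voxel equals value at the pre-image voxel
  perm <- g
  for (i in 1:24) for (j in 1:24) perm[, i, j, ] <- g[, j, 25 - i, ]
  expect_equal(gr, perm, tolerance = 1e-12)
  # a single hydrophobic atom at the grid center: hydrophobic layer is
  # symmetric under the rotation group of the cube, other channels silent
  single <- PocketStructure(matrix(0, 1, 3), "C", "ALA", "CB",
                            center = c(0, 0, 0))
  single <- suppressMessages(assignChannels(single))
  gs <- gridValues(voxelizePocket(single))
  expect_equal(gs[1, , , ], aperm(gs[1, , , ], c(2, 1, 3)))
  expect_equal(gs[1, , , ], gs[1, 24:1, , ])
  expect_equal(max(abs(gs[2:7, , , ])), 0)
  expect_gt(max(gs[8, , , ]), 0.99)   # excluded volume at the center voxel
})

test_that("random rotations are proper isometries about the pivot", {
  set.seed(5)
  coords <- matrix(rnorm(30), 10, 3)
  pivot <- c(1, -2, 0.5)
  # identity hook
  expect_equal(randomRotation(coords, pivot, rotation = diag(3)), coords)
  for (i in 1:10) {
    R <- randomRotationMatrix()
    expect_equal(det(R), 1, tolerance = 1e-9)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
    rot <- randomRotation(coords, pivot, rotation = R)
    d0 <- sqrt(rowSums((coords - matrix(pivot, 10, 3, byrow = TRUE))^2))
    d1 <- sqrt(rowSums((rot - matrix(pivot, 10, 3, byrow = TRUE))^2))
    expect_equal(d0, d1, tolerance = 1e-9)
    expect_equal(as.numeric(dist(coords)), as.numeric(dist(rot)),
                 tolerance = 1e-9)
  }
})

test_that("fingerprints are deterministic 1024-bit vectors that separate molecules", {
  ethane <- parseSMILES("CC")
  ethanol <- parseSMILES("CCO")
  f1 <- ligandFingerprint(ethane)
  f2 <- ligandFingerprint(ethanol)
  expect_length(f1, 1024)
  expect_true(all(f1 %in% c(0L, 1L)))
  expect_identical(f1, ligandFingerprint(parseSMILES("CC")))
  expect_false(identical(f1, f2))
})

test_that("the descriptor panel is fixed-length, deterministic and finite", {
  mol <- parseSMILES("CC(=O)Oc1ccccc1C(=O)O")   # aspirin
  d <- ligandDescriptors(mol)
  expect_length(d, 183)
  expect_identical(names(d), descriptorNames())
  expect_true(all(is.finite(d)))
  expect_identical(d, ligandDescriptors(mol))
  expect_equal(unname(d["n_aromatic_atoms"]), 6)
  expect_equal(unname(d["count_O"]), 4)
  # zero-variance autocorrelations are zeroed with one warning
  expect_warning(de <- ligandDescriptors(parseSMILES("CC")), "non-finite")
  expect_true(all(is.finite(de)))
})

test_that("descriptor standardization uses training statistics only", {
  # two-point z-score
  expect_equal(as.numeric(applyStandardizer(
    standardizeDescriptors(matrix(c(0, 2), 2, 1)), matrix(c(0, 2), 2, 1))),
    c(-1, 1))
  set.seed(8)
  train <- cbind(matrix(rnorm(50 * 4, mean = 3, sd = 2), 50), 7)  # col 5 constant
  val <- cbind(matrix(rnorm(10 * 4), 10), 7)
  std <- standardizeDescriptors(train)
  zt <- applyStandardizer(std, train)
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_lt(max(abs(colMeans(zt))), 1e-8)
  expect_equal(unname(apply(zt[, 1:4], 2, popSd)), rep(1, 4),
               tolerance = 1e-8)
  expect_equal(max(abs(zt[, 5])), 0)          # constant column -> zeros
  zv <- applyStandardizer(std, val)
  # validation rows use training statistics, never their own
  expect_equal(zv, sweep(sweep(val, 2, colMeans(train)), 2,
                         c(apply(train[, 1:4], 2, popSd), 1), "/"))
  expect_error(standardizeDescriptors(matrix(1, 1, 3)), "at least 2")
})
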