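test_that("label triple reduces a pose RMSD list to (min, mean, count)", {
  expect_equal(computeLabelTriple(c(0.8, 1.5, 2.2, 3.0), 2.0),
               c(rmsd_min = 0.8, rmsd_ave = 1.875, n_rmsd = 2))
  # count is strictly-below: a pose at exactly the resolution does not count
  expect_equal(unname(computeLabelTriple(c(1.0, 1.0, 1.0), 0.5)[3]), 0)
  expect_equal(unname(computeLabelTriple(c(2.0, 3.0), 2.0)[3]), 0)
  expect_error(computeLabelTriple(numeric(0), 2.0), "non-empty")
  expect_error(computeLabelTriple(c(1, -1), 2.0))
  expect_error(computeLabelTriple(c(1, 2), 0))
})

test_that("label triple invariants hold on random pose lists", {
  set.seed(11)
  for (i in 1:50) {
    rmsds <- runif(sample(1:20, 1), 0, 8)
    res <- runif(1, 0.8, 3)
    tri <- computeLabelTriple(rmsds, res)
    expect_lte(tri["rmsd_min"], tri["rmsd_ave"])
    expect_lte(tri["n_rmsd"], length(rmsds))
    perm <- computeLabelTriple(rmsds[sample.int(length(rmsds))], res)
    expect_equal(tri, perm)
  }
})

test_that("loadComplex preserves atom counts and computes the ligand center", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeToyPDB(pdb)
  writeToySDF(sdf)
  rec <- loadComplex(pdb, sdf, resolution = 2.0)
  expect_equal(nrow(rec$protein), 3)
  expect_equal(length(rec$ligand$elements), 2)
  # equal-mass heavy atoms at (0,0,0) and (2,0,0)
  expect_equal(unname(rec$ligand_center), c(1, 0, 0))
  expect_error(loadComplex(pdb, "no_such_file.sdf", 2.0), "not found")
  expect_error(loadComplex(pdb, sdf, resolution = -1), "positive")
})

test_that("pocket extraction keeps exactly the atoms inside the sphere", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  sdf <- withr::local_tempfile(fileext = ".sdf")
  # ligand center will be (1, 0, 0); place atoms at controlled distances
  writeToyPDB(pdb, coords = rbind(c(15.9, 0, 0),   # distance 14.9 -> in
                                  c(16.1, 0, 0),   # distance 15.1 -> out
                                  c(1.0, 3, 0)))   # distance 3    -> in
  writeToySDF(sdf)
  rec <- loadComplex(pdb, sdf, resolution = 2.0)
  pocket <- extractPocket(rec, radius = 15)
  expect_equal(nAtoms(pocket), 2)
  d <- sqrt(rowSums((pocket@coords -
                       matrix(pocket@center, 2, 3, byrow = TRUE))^2))
  expect_true(all(d <= 15))
  # all atoms within a generous radius -> every protein heavy atom kept
  expect_equal(nAtoms(extractPocket(rec, radius = 100)), 3)
  # idempotence on an already-extracted pocket
  again <- extractPocket(pocket, radius = 15)
  expect_equal(again@coords, pocket@coords)
  expect_equal(again@channels, pocket@channels)
  # far-away ligand -> empty pocket with a warning, still voxelizable
  writeToySDF(sdf, coords = rbind(c(500, 0, 0), c(502, 0, 0)))
  recfar <- loadComplex(pdb, sdf, resolution = 2.0)
  expect_warning(pfar <- extractPocket(recfar), "empty pocket")
  expect_equal(nAtoms(pfar), 0)
  expect_equal(max(gridValues(voxelizePocket(pfar))), 0)
  expect_error(extractPocket(rec, radius = 0), "radius")
})

test_that("label tables load, validate protocols, and round-trip exactly", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  set.seed(3)
  reg <- protocolRegistry()
  df <- expand.grid(complex_id = c("c1", "c2"), protocol = reg,
                    stringsAsFactors = FALSE)
  ave <- runif(nrow(df), 1, 6)
  df$rmsd_min <- ave * runif(nrow(df), 0.3, 1)
  df$rmsd_ave <- ave
  df$n_rmsd <- rpois(nrow(df), 3)
  write.csv(df, tmp, row.names = FALSE)
  lm <- loadLabelTable(tmp)
  expect_equal(dim(labelValues(lm)), c(2L, 14L, 3L))
  expect_true(all(labelMask(lm)))
  # a named protocol maps to its registry position
  i <- which(df$complex_id == "c1" & df$protocol == "gold-asp")
  expect_equal(labelValues(lm)["c1", "gold-asp", "rmsd_ave"],
               df$rmsd_ave[i])
  # unknown protocol rejected by name
  bad <- df
  bad$protocol[1] <- "foo"
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(loadLabelTable(tmp), "foo")
  # duplicated (complex, protocol) rejected
  dup <- rbind(df, df[1, ])
  write.csv(dup, tmp, row.names = FALSE)
  expect_error(loadLabelTable(tmp), "duplicate")
  # absent combinations are masked, not zeroed
  sparse <- df[-2, ]
  write.csv(sparse, tmp, row.names = FALSE)
  lms <- loadLabelTable(tmp)
  expect_equal(sum(!labelMask(lms)), 1L)
  expect_true(is.na(labelValues(lms)[df$complex_id[2], df$protocol[2], 1]))
  # bit-exact round trip through the writer
  out <- withr::local_tempfile(fileext = ".csv")
  writeLabelTable(lm, out)
  lm2 <- loadLabelTable(out)
  expect_identical(labelValues(lm2), labelValues(lm))
  expect_identical(labelMask(lm2), labelMask(lm))
})

test_that("pharmacophore typing follows the bundled rules", {
  pocket <- PocketStructure(
    coords = matrix(rnorm(12), 4, 3),
    elements = c("ZN", "O", "C", "C"),
    resnames = c("ZN", "ALA", "ALA", "UNX"),
    atomnames = c("ZN", "O", "CB", "XX"))
  pocket <- suppressMessages(assignChannels(pocket))
  ch <- pocket@channels
  expect_true(ch[1, "metallic"])
  expect_true(ch[2, "hbond_acceptor"])   # backbone carbonyl oxygen
  expect_true(ch[3, "hydrophobic"])      # alanine CB
  # unknown atom: excluded volume only
  expect_equal(sum(ch[4, ]), 1L)
  expect_true(all(ch[, "excluded_volume"]))
  # the uncovered atom is reported once
  expect_message(assignChannels(pocket), "matched no typing rule")
})
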