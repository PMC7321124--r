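test_that("the default architecture meets its shape contract", {
  cfg <- modelConfig()
  expect_equal(cfg$protein_latent + cfg$ligand_latent, 1024L)
  expect_equal(cfg$n_protocols, 14L)
  set.seed(2)
  model <- buildModel(cfg)
  N <- 3
  Xvox <- matrix(runif(8 * 24^3 * N), ncol = N)
  Xlig <- matrix(rnorm(cfg$ligand_dim * N), ncol = N)
  fwd <- DockSelect:::.netForward(model@params, cfg, Xvox, Xlig)
  expect_equal(nrow(fwd$latent), 1024L)
  expect_length(fwd$pred, 3)
  for (h in fwd$pred) {
    expect_equal(dim(h), c(14L, N))
    expect_true(all(h >= 0))
  }
  # configuration errors surface at build time
  expect_error(modelConfig(conv_channels = c(4, 4), conv_strides = c(2, 2, 2)),
               "equal length")
  expect_error(modelConfig(n_protocols = 0), "n_protocols")
  expect_error(modelConfig(grid_edge = 4, conv_pad = 0,
                           conv_strides = rep(2, 5)),
               "below 1 voxel")
})

test_that("Poisson negative log-likelihood matches its closed form", {
  expect_equal(poissonNLL(0, 1), 1.0)
  expect_equal(poissonNLL(1, 1), 1 - log(1 + 1e-8))
  expect_equal(poissonNLL(2, 3), 3 - 2 * log(3 + 1e-8) + log(2))
  expect_equal(poissonNLL(2, 3), 1.4959, tolerance = 1e-4)
  expect_error(poissonNLL(-1, 1), "non-negative")
  # minimized at yhat = y for integer y >= 1 (grid scan)
  grid <- seq(0.05, 12, by = 0.05)
  for (y in 1:5) {
    losses <- vapply(grid, function(g) poissonNLL(y, g), numeric(1))
    expect_equal(grid[which.min(losses)], y, tolerance = 0.051)
  }
})

test_that("MSE and combined loss sum the three objectives over the mask", {
  expect_equal(mseLoss(c(1, 2), c(1, 2)), 0)
  expect_equal(mseLoss(0, 2), 4)
  expect_equal(mseLoss(c(1, 2), c(2, 4)), 2.5)
  expect_error(mseLoss(1:3, 1:2), "length mismatch")

  set.seed(6)
  n <- 5; P <- 4
  labels <- array(runif(n * P * 3, 1, 4), c(n, P, 3))
  labels[, , 1] <- pmin(labels[, , 1], labels[, , 2])
  labels[, , 3] <- rpois(n * P, 3)
  pred <- array(runif(n * P * 3, 0.5, 4), c(n, P, 3))
  mask <- matrix(TRUE, n, P)
  got <- combinedLoss(labels, pred, mask)
  manual <- mseLoss(labels[, , 1], pred[, , 1]) +
    mseLoss(labels[, , 2], pred[, , 2]) +
    poissonNLL(labels[, , 3], pred[, , 3])
  expect_equal(got, manual)
  # perfect RMSD heads and y = yhat = 1 counts: Poisson floor of 1
  l2 <- array(1, c(2, 3, 3)); p2 <- l2
  expect_equal(combinedLoss(l2, p2, matrix(TRUE, 2, 3)), 1.0,
               tolerance = 1e-6)
  # masking a protocol equals removing it from the dataset
  mask2 <- mask; mask2[, 2] <- FALSE
  expect_equal(combinedLoss(labels, pred, mask2),
               combinedLoss(labels[, -2, , drop = FALSE],
                            pred[, -2, , drop = FALSE],
                            mask[, -2, drop = FALSE]))
  expect_error(combinedLoss(labels, pred, mask & FALSE), "masked")
})

test_that("analytic gradients agree with finite differences everywhere", {
  cfg <- modelConfig(n_protocols = 3, grid_edge = 8,
                     conv_channels = c(4, 6), conv_strides = c(2, 2),
                     ligand_dim = 10, ligand_widths = c(8, 6, 5),
                     protein_latent = 7)
  set.seed(1)
  model <- buildModel(cfg)
  ns <- asNamespace("DockSelect")
  N <- 4
  Xv <- matrix(runif(8 * 8^3 * N), ncol = N)
  Xl <- matrix(rnorm(10 * N), ncol = N)
  labels <- array(abs(rnorm(N * 3 * 3)) + 0.5, c(N, 3, 3))
  labels[, , 3] <- rpois(N * 3, 3)
  mask <- matrix(TRUE, N, 3); mask[1, 2] <- FALSE
  fwd <- ns$.netForward(model@params, cfg, Xv, Xl, train = TRUE,
                        cache = TRUE)
  lg <- ns$.lossAndGrads(labels, fwd$pred, mask)
  gr <- ns$.netBackward(model@params, cfg, fwd, lg$dHeads)
  lossAt <- function(p)
    ns$.lossAndGrads(labels,
                     ns$.netForward(p, cfg, Xv, Xl, train = TRUE)$pred,
                     mask)$loss
  eps <- 1e-6
  getAt <- function(obj, path) {
    for (k in path) obj <- obj[[k]]
    obj
  }
  bump <- function(p, path, i, d) {
    if (length(path) == 2) p[[path[[1]]]][[path[[2]]]][i] <-
        p[[path[[1]]]][[path[[2]]]][i] + d
    else p[[path[[1]]]][[path[[2]]]][[path[[3]]]][i] <-
        p[[path[[1]]]][[path[[2]]]][[path[[3]]]][i] + d
    p
  }
  cases <- list(list(list("conv", 1, "W"), 5), list(list("conv", 2, "b"), 2),
                list(list("proj", "W"), 11), list(list("lig", 2, "W"), 3),
                list(list("bn", "gamma"), 4), list(list("bn", "beta"), 9),
                list(list("heads", 1, "W"), 7),
                list(list("heads", 3, "b"), 2))
  for (cs in cases) {
    path <- cs[[1]]; i <- cs[[2]]
    g <- getAt(gr, path)[i]
    fd <- (lossAt(bump(model@params, path, i, eps)) -
             lossAt(bump(model@params, path, i, -eps))) / (2 * eps)
    expect_equal(g, fd, tolerance = 1e-5,
                 label = paste("grad", paste(unlist(path), collapse = ".")))
  }
})

test_that("loss is invariant to batch order and inference is deterministic", {
  ds <- tinyDataset(n = 10, P = 4)
  cfg <- tinyModelConfig(P = 4)
  set.seed(3)
  model <- buildModel(cfg)
  feats <- featurizeDataset(ds, standardizeDescriptors(ds@descriptors))
  labels <- labelValues(ds); mask <- labelMask(ds)
  ns <- asNamespace("DockSelect")
  perm <- sample(10)
  f1 <- ns$.netForward(model@params, cfg, feats$Xvox, feats$Xlig,
                       train = TRUE)
  f2 <- ns$.netForward(model@params, cfg, feats$Xvox[, perm],
                       feats$Xlig[, perm], train = TRUE)
  l1 <- ns$.lossAndGrads(labels, f1$pred, mask)$loss
  l2 <- ns$.lossAndGrads(labels[perm, , , drop = FALSE], f2$pred,
                         mask[perm, , drop = FALSE])$loss
  expect_equal(l1, l2, tolerance = 1e-12)
  # evaluation mode: repeated single-sample inference identical
  p1 <- predictFeatures(model, feats$Xvox[, 1, drop = FALSE],
                        feats$Xlig[, 1, drop = FALSE])
  p2 <- predictFeatures(model, feats$Xvox[, 1, drop = FALSE],
                        feats$Xlig[, 1, drop = FALSE])
  expect_identical(p1, p2)
  expect_true(all(p1$rmsd_min >= 0 & p1$rmsd_ave >= 0 & p1$n_rmsd >= 0))
})
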