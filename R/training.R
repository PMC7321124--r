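# Training: per-fold optimization (Adam, exponential learning-rate decay,
# batch size 32, optional per-sample rotation augmentation) and k-fold
# cross-validation.

#' Training configuration
#'
#' Default schedule: 200 epochs of Adam with
#' `beta1 = 0.99`, `beta2 = 0.999` (note that 0.99 is an unusual
#' first-moment decay — 0.9 is the conventional value — and it is
#' overridable), starting learning rate `1e-3` decayed by
#' `gamma = 0.95` per epoch (`lr_e = lr0 * gamma^e`, epoch 0-based), batch
#' size 32, and rotation augmentation on: each training pocket is
#' re-voxelized after a fresh uniform random rotation about the ligand
#' center, once per sample per epoch. Validation always uses unrotated
#' grids. No early stopping, weight decay or gradient clipping is applied
#' by default.
#'
#' @param epochs training epochs.
#' @param lr0 initial learning rate.
#' @param gamma exponential decay factor per epoch.
#' @param batch_size samples per optimizer step.
#' @param beta1,beta2 Adam moment decays.
#' @param augment logical; rotation augmentation of training pockets.
#' @param seed master seed; fans out to initialization, shuffling and
#'   rotation streams.
#' @param verbose print one line per epoch.
#' @return a config list (class `TrainConfig`).
#' @export
trainConfig <- function(epochs = 200, lr0 = 1e-3, gamma = 0.95,
                        batch_size = 32, beta1 = 0.99, beta2 = 0.999,
                        augment = TRUE, seed = 1, verbose = FALSE) {
  stopifnot(epochs >= 1, lr0 > 0, gamma > 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), lr0 = lr0, gamma = gamma,
                 batch_size = as.integer(batch_size), beta1 = beta1,
                 beta2 = beta2, augment = isTRUE(augment),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "TrainConfig")
}

#' Learning rate at a given epoch
#'
#' @param config a [trainConfig()].
#' @param epoch 0-based epoch index.
#' @return `lr0 * gamma^epoch`.
#' @export
learningRate <- function(config, epoch) config$lr0 * config$gamma^epoch

# Voxel feature matrix ((C*E^3) x n) for a list of pockets.
.voxelMatrix <- function(pockets, edge, resolution) {
  cols <- lapply(pockets, function(p)
    as.numeric(gridValues(voxelizePocket(p, edge = edge,
                                         resolution = resolution))))
  do.call(cbind, cols)
}

#' Featurize a dataset for the network
#'
#' Voxelizes every pocket (unrotated) and assembles the ligand input
#' matrix. Descriptors are standardized with `standardizer` when given
#' (training-fold statistics); otherwise left raw.
#'
#' @param dataset a [DockingDataset-class].
#' @param standardizer optional `DescriptorStandardizer`.
#' @param edge,resolution grid geometry (Angstrom).
#' @return list: `Xvox` ((C*E^3) x n), `Xlig` (ligand_dim x n).
#' @export
featurizeDataset <- function(dataset, standardizer = NULL, edge = 24,
                             resolution = 1) {
  stopifnot(is(dataset, "DockingDataset"))
  Xvox <- .voxelMatrix(dataset@pockets, edge, resolution)
  desc <- dataset@descriptors
  if (!is.null(standardizer)) desc <- applyStandardizer(standardizer, desc)
  Xlig <- rbind(t(dataset@fingerprints), t(desc))
  list(Xvox = Xvox, Xlig = Xlig)
}

#' Train the model on one cross-validation fold
#'
#' Trains on every complex outside the held-out fold and records the
#' combined loss on both partitions per epoch. The descriptor standardizer
#' is fitted on the training fold only; validation grids are never rotated
#' and validation batches never update the optimizer or the batch-norm
#' running statistics. With `config$augment`, every training pocket is
#' re-voxelized under a fresh random rotation each epoch.
#'
#' @param dataset a [DockingDataset-class].
#' @param plan a [SplitPlan-class] covering the dataset ids.
#' @param fold held-out fold index in `[0, k)`.
#' @param model_config a [modelConfig()]; `n_protocols` must match the
#'   dataset registry.
#' @param config a [trainConfig()].
#' @return list: `model` (trained [DockingModel-class]), `history`
#'   (data.frame: epoch, lr, train_loss, val_loss).
#' @export
trainFold <- function(dataset, plan, fold, model_config = modelConfig(),
                      config = trainConfig()) {
  stopifnot(is(dataset, "DockingDataset"), is(plan, "SplitPlan"))
  if (fold < 0 || fold >= plan@k) stop("fold must lie in [0, k)")
  av <- plan@assignment[dataset@ids]
  if (any(is.na(av))) stop("plan does not cover every dataset complex")
  tr <- which(av != fold)
  va <- which(av == fold)
  if (!length(tr)) stop("empty training set for fold ", fold)

  # named substreams derived from the master seed
  baseSeed <- (config$seed + 7919L * (fold + 1L)) %% .Machine$integer.max
  std <- standardizeDescriptors(dataset@descriptors[tr, , drop = FALSE])
  desc <- applyStandardizer(std, dataset@descriptors)
  Xlig <- rbind(t(dataset@fingerprints), t(desc))
  edge <- model_config$grid_edge
  res <- 1  # Angstrom per voxel
  Xvox <- .voxelMatrix(dataset@pockets, edge, res)

  set.seed(baseSeed)               # initialization stream
  model <- buildModel(model_config)
  params <- model@params
  state <- .adamInit(params)
  labels <- labelValues(dataset)
  mask <- labelMask(dataset)

  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_loss = numeric())
  nb <- ceiling(length(tr) / config$batch_size)
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- learningRate(config, epoch)
    set.seed((baseSeed + 31L * epoch + 1L) %% .Machine$integer.max)
    ord <- sample(tr)
    if (config$augment) {
      Xtr <- matrix(0, nrow(Xvox), length(ord))
      for (j in seq_along(ord)) {
        p <- rotatePocket(dataset@pockets[[ord[j]]])
        Xtr[, j] <- as.numeric(gridValues(voxelizePocket(p, edge = edge,
                                                         resolution = res)))
      }
    }
    eloss <- 0
    for (bi in seq_len(nb)) {
      sel <- ((bi - 1) * config$batch_size + 1):min(bi * config$batch_size,
                                                    length(ord))
      idx <- ord[sel]
      Xb <- if (config$augment) Xtr[, sel, drop = FALSE]
            else Xvox[, idx, drop = FALSE]
      fwd <- .netForward(params, model_config, Xb,
                         Xlig[, idx, drop = FALSE], train = TRUE,
                         cache = TRUE)
      params$bn$run_mean <- fwd$run_mean
      params$bn$run_var <- fwd$run_var
      lg <- .lossAndGrads(labels[idx, , , drop = FALSE], fwd$pred,
                          mask[idx, , drop = FALSE])
      grads <- .netBackward(params, model_config, fwd, lg$dHeads)
      state <- .adamStep(params, grads, state, lr, config$beta1,
                         config$beta2)
      eloss <- eloss + lg$loss * length(sel)
    }
    eloss <- eloss / length(tr)
    vloss <- if (length(va)) {
      fwd <- .netForward(params, model_config, Xvox[, va, drop = FALSE],
                         Xlig[, va, drop = FALSE], train = FALSE)
      combinedLoss(labels[va, , , drop = FALSE], fwd$pred,
                   mask[va, , drop = FALSE])
    } else NA_real_
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         train_loss = eloss,
                                         val_loss = vloss))
    if (config$verbose)
      message(sprintf("fold %d epoch %3d lr %.2e train %.4f val %.4f",
                      fold, epoch, lr, eloss, vloss))
  }
  model@params <- params
  model@trained <- TRUE
  model@featMeta$standardizer <- std
  model@featMeta$registry <- dataset@labels@registry
  list(model = model, history = history)
}

#' k-fold cross-validation
#'
#' Trains one model per fold (each complex is validated exactly once) and
#' assembles out-of-fold predictions plus the protocol-centric and
#' ligand-centric metric tables, aggregated as mean (+/- 1 standard
#' deviation) across folds.
#'
#' @param dataset a [DockingDataset-class].
#' @param plan a [SplitPlan-class].
#' @param model_config a [modelConfig()].
#' @param config a [trainConfig()].
#' @return list: `models` (one per fold), `history` (per fold),
#'   `predictions` (n x P x 3 out-of-fold array), `perProtocol`,
#'   `ligandCentric` (metric tables).
#' @export
crossValidate <- function(dataset, plan, model_config = modelConfig(),
                          config = trainConfig()) {
  k <- plan@k
  n <- length(dataset@ids)
  P <- length(dataset@labels@registry)
  preds <- array(NA_real_, c(n, P, 3),
                 dimnames = dimnames(labelValues(dataset)))
  models <- vector("list", k)
  history <- vector("list", k)
  for (fold in seq_len(k) - 1L) {
    fit <- trainFold(dataset, plan, fold, model_config, config)
    models[[fold + 1]] <- fit$model
    history[[fold + 1]] <- fit$history
    va <- which(plan@assignment[dataset@ids] == fold)
    if (length(va)) {
      pr <- predictDataset(fit$model, dataset, indices = va)
      preds[va, , 1] <- pr$rmsd_min
      preds[va, , 2] <- pr$rmsd_ave
      preds[va, , 3] <- pr$n_rmsd
    }
  }
  list(models = models, history = history, predictions = preds,
       perProtocol = perProtocolEval(preds, dataset@labels, plan),
       ligandCentric = ligandCentricEval(preds, dataset@labels, plan))
}

#' Predict label triples for dataset complexes
#'
#' Featurizes the selected complexes with the model's stored standardizer
#' and runs evaluation-mode inference. Predicted n_rmsd rates are reported
#' as-is (unbounded); clamping to `[0, n_poses]` happens at selection time.
#'
#' @param model a trained [DockingModel-class].
#' @param dataset a [DockingDataset-class].
#' @param indices complex indices to predict (default: all).
#' @return list of n x P matrices `rmsd_min`, `rmsd_ave`, `n_rmsd`.
#' @export
predictDataset <- function(model, dataset, indices = seq_along(dataset@ids)) {
  stopifnot(is(model, "DockingModel"))
  std <- model@featMeta$standardizer
  desc <- dataset@descriptors[indices, , drop = FALSE]
  if (!is.null(std)) desc <- applyStandardizer(std, desc)
  Xlig <- rbind(t(dataset@fingerprints[indices, , drop = FALSE]), t(desc))
  Xvox <- .voxelMatrix(dataset@pockets[indices], model@config$grid_edge, 1)
  predictFeatures(model, Xvox, Xlig)
}

#' Aggregate per-fold values as mean and standard deviation
#'
#' @param x numeric vector of per-fold metric values.
#' @return named numeric: mean and sd (sd 0 for a single fold).
#' @export
foldAggregate <- function(x) {
  x <- x[is.finite(x)]
  c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
}
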