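# The two-legged multi-task network. The pocket leg is five 3D convolutions
# with ReLU activations followed by a linear projection; the ligand leg is
# three linear layers with ReLU. The two 512-wide latents are concatenated
# into a 1024 vector, batch-normalized, and fed to three per-protocol linear
# output heads with ReLU: predicted rmsd_min, rmsd_ave (Angstrom) and the
# n_rmsd Poisson rate. Forward, backward and the Adam optimizer are
# implemented here (convolutions in compiled code); there is no external
# deep-learning dependency.

.convOutSize <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1

#' Network architecture configuration
#'
#' Defaults: a 24-voxel, 8-channel grid passes through five 3 x 3 x 3
#' convolutions with channels (8, 8, 16, 16, 32) and strides (2, 2, 1, 2,
#' 1) (24 -> 12 -> 6 -> 6 -> 3 -> 3 voxels per axis), is flattened and
#' projected to a 512-wide protein latent; the 1207-long ligand vector
#' (1024 fingerprint bits + 183 standardized descriptors) passes through
#' linear layers (768, 640, 512). The two latents concatenate to 1024.
#' Conv widths are sized for single-CPU training; all fields are
#' overridable.
#'
#' @param n_protocols number of protocols predicted per head.
#' @param grid_edge voxels per axis of the input grid.
#' @param grid_channels input channels (pharmacophore layers).
#' @param conv_channels integer vector of output channels per conv layer.
#' @param conv_kernel odd kernel size shared by all conv layers.
#' @param conv_strides integer vector of strides, same length as
#'   `conv_channels`.
#' @param conv_pad zero-padding per side.
#' @param ligand_dim length of the ligand input vector.
#' @param ligand_widths widths of the three ligand linear layers; the last
#'   is the ligand latent.
#' @param protein_latent width of the protein latent projection.
#' @return a validated config list (class `ModelConfig`).
#' @export
modelConfig <- function(n_protocols = 14, grid_edge = 24, grid_channels = 8,
                        conv_channels = c(8, 8, 16, 16, 32),
                        conv_kernel = 3,
                        conv_strides = c(2, 2, 1, 2, 1),
                        conv_pad = 1,
                        ligand_dim = 1024 + 183,
                        ligand_widths = c(768, 640, 512),
                        protein_latent = 512) {
  if (n_protocols < 1) stop("n_protocols must be >= 1")
  if (length(conv_channels) != length(conv_strides))
    stop("conv_channels and conv_strides must have equal length")
  edge <- grid_edge
  for (s in conv_strides) {
    edge <- .convOutSize(edge, conv_kernel, s, conv_pad)
    if (edge < 1) stop("conv stack reduces the grid below 1 voxel")
  }
  cfg <- list(n_protocols = as.integer(n_protocols),
              grid_edge = as.integer(grid_edge),
              grid_channels = as.integer(grid_channels),
              conv_channels = as.integer(conv_channels),
              conv_kernel = as.integer(conv_kernel),
              conv_strides = as.integer(conv_strides),
              conv_pad = as.integer(conv_pad),
              ligand_dim = as.integer(ligand_dim),
              ligand_widths = as.integer(ligand_widths),
              protein_latent = as.integer(protein_latent),
              ligand_latent = as.integer(ligand_widths[length(ligand_widths)]),
              flat_dim = as.integer(conv_channels[length(conv_channels)] *
                                      edge^3))
  cfg$latent_dim <- cfg$protein_latent + cfg$ligand_latent
  class(cfg) <- "ModelConfig"
  cfg
}

.initLinear <- function(n_out, n_in, bias = 0) {
  list(W = matrix(rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in),
       b = rep(bias, n_out))
}

#' Build an untrained model
#'
#' Initializes all parameters (He-scaled Gaussian weights; output-head
#' biases start at 1 so the ReLU heads are active for the non-negative
#' targets) from the current RNG state — call [set.seed()] first for
#' reproducible initialization.
#'
#' @param config a [modelConfig()] list.
#' @return a [DockingModel-class] with fresh parameters.
#' @export
buildModel <- function(config = modelConfig()) {
  stopifnot(inherits(config, "ModelConfig"))
  k3 <- config$conv_kernel^3
  cin <- c(config$grid_channels, head(config$conv_channels, -1))
  params <- list(
    conv = lapply(seq_along(config$conv_channels), function(l)
      .initLinear(config$conv_channels[l], cin[l] * k3)),
    proj = .initLinear(config$protein_latent, config$flat_dim),
    lig = {
      widths <- config$ligand_widths
      ins <- c(config$ligand_dim, head(widths, -1))
      lapply(seq_along(widths), function(l) .initLinear(widths[l], ins[l]))
    },
    bn = list(gamma = rep(1, config$latent_dim),
              beta = rep(0, config$latent_dim),
              run_mean = rep(0, config$latent_dim),
              run_var = rep(1, config$latent_dim)),
    heads = lapply(1:3, function(t)
      .initLinear(config$n_protocols, config$latent_dim, bias = 1)))
  new("DockingModel", config = unclass(config), params = params,
      featMeta = list(channels = channelNames(),
                      registry = protocolRegistry()[
                        seq_len(min(config$n_protocols, 14))],
                      standardizer = NULL),
      trained = FALSE)
}

.relu <- function(x) { x[x < 0] <- 0; x }

# Forward pass. Xvox: (C*E^3) x N matrix; Xlig: ligand_dim x N matrix.
# Returns predictions (3 heads, P x N each), the concatenated latent, and,
# when cache = TRUE, the intermediate activations needed for backward.
# train = TRUE uses batch statistics in the batch-norm layer and returns
# updated running statistics; train = FALSE uses the stored running stats.
.netForward <- function(params, cfg, Xvox, Xlig, train = FALSE,
                        cache = FALSE, bn_momentum = 0.1) {
  N <- ncol(Xvox)
  acts <- list(conv = vector("list", length(params$conv) + 1))
  acts$conv[[1]] <- Xvox
  dims <- c(cfg$grid_channels, rep(cfg$grid_edge, 3))
  dimlist <- list(dims)
  A <- Xvox
  for (l in seq_along(params$conv)) {
    Z <- conv3d_fwd(A, as.integer(dims), params$conv[[l]]$W,
                    params$conv[[l]]$b, cfg$conv_kernel,
                    cfg$conv_strides[l], cfg$conv_pad)
    A <- .relu(Z)
    e <- .convOutSize(dims[2], cfg$conv_kernel, cfg$conv_strides[l],
                      cfg$conv_pad)
    dims <- c(cfg$conv_channels[l], rep(e, 3))
    dimlist[[l + 1]] <- dims
    acts$conv[[l + 1]] <- A
  }
  Zp <- params$proj$W %*% A + params$proj$b
  Hp <- .relu(Zp)
  acts$proj_in <- A
  acts$proj_out <- Hp

  acts$lig <- vector("list", length(params$lig) + 1)
  acts$lig[[1]] <- Xlig
  L <- Xlig
  for (l in seq_along(params$lig)) {
    L <- .relu(params$lig[[l]]$W %*% L + params$lig[[l]]$b)
    acts$lig[[l + 1]] <- L
  }

  H <- rbind(Hp, L)                      # latent_dim x N
  if (train) {
    mu <- rowMeans(H)
    va <- rowMeans((H - mu)^2)
    run_mean <- (1 - bn_momentum) * params$bn$run_mean + bn_momentum * mu
    nfac <- if (N > 1) N / (N - 1) else 1
    run_var <- (1 - bn_momentum) * params$bn$run_var + bn_momentum * va * nfac
  } else {
    mu <- params$bn$run_mean
    va <- params$bn$run_var
    run_mean <- params$bn$run_mean
    run_var <- params$bn$run_var
  }
  inv_sd <- 1 / sqrt(va + 1e-5)
  Xhat <- (H - mu) * inv_sd
  B <- params$bn$gamma * Xhat + params$bn$beta

  heads <- lapply(params$heads, function(h) .relu(h$W %*% B + h$b))
  out <- list(pred = heads, latent = H,
              run_mean = run_mean, run_var = run_var)
  if (cache) {
    acts$H <- H; acts$Xhat <- Xhat; acts$inv_sd <- inv_sd
    acts$B <- B; acts$dims <- dimlist
    out$cache <- acts
  }
  out
}

# Backward pass. dHeads: list of 3 gradients w.r.t. the head outputs
# (P x N), before the head ReLU mask. Returns gradients shaped like params.
.netBackward <- function(params, cfg, fwd, dHeads) {
  acts <- fwd$cache
  N <- ncol(acts$B)
  grads <- list(conv = vector("list", length(params$conv)),
                lig = vector("list", length(params$lig)))
  dB <- matrix(0, nrow(acts$B), N)
  grads$heads <- vector("list", 3)
  for (t in 1:3) {
    Yt <- fwd$pred[[t]]
    dZ <- dHeads[[t]] * (Yt > 0)
    grads$heads[[t]] <- list(W = dZ %*% t(acts$B), b = rowSums(dZ))
    dB <- dB + t(params$heads[[t]]$W) %*% dZ
  }
  # batch-norm backward (batch statistics)
  grads$bn <- list(gamma = rowSums(dB * acts$Xhat), beta = rowSums(dB),
                   run_mean = 0, run_var = 0)
  dXhat <- dB * params$bn$gamma
  dH <- (1 / N) * acts$inv_sd *
    (N * dXhat - rowSums(dXhat) -
       acts$Xhat * rowSums(dXhat * acts$Xhat))

  np <- cfg$protein_latent
  dHp <- dH[seq_len(np), , drop = FALSE]
  dL <- dH[(np + 1):nrow(dH), , drop = FALSE]

  # ligand leg
  for (l in rev(seq_along(params$lig))) {
    A_out <- acts$lig[[l + 1]]
    dZ <- dL * (A_out > 0)
    grads$lig[[l]] <- list(W = dZ %*% t(acts$lig[[l]]), b = rowSums(dZ))
    dL <- t(params$lig[[l]]$W) %*% dZ
  }

  # protein projection
  dZp <- dHp * (acts$proj_out > 0)
  grads$proj <- list(W = dZp %*% t(acts$proj_in), b = rowSums(dZp))
  dA <- t(params$proj$W) %*% dZp

  # conv stack (the input gradient of the first layer is never used)
  for (l in rev(seq_along(params$conv))) {
    A_out <- acts$conv[[l + 1]]
    dZ <- dA * (A_out > 0)
    bw <- conv3d_bwd(acts$conv[[l]], as.integer(acts$dims[[l]]),
                     params$conv[[l]]$W, dZ, cfg$conv_kernel,
                     cfg$conv_strides[l], cfg$conv_pad, need_dx = l > 1)
    grads$conv[[l]] <- list(W = bw$dW, b = as.numeric(bw$db))
    dA <- bw$dX
  }
  grads
}

#' Poisson negative log-likelihood
#'
#' `yhat - y * log(yhat + eps) + log(y!)`, averaged over elements; the
#' `eps` guard keeps the logarithm finite when a ReLU head emits a zero
#' rate. `log(y!)` is computed via the log-gamma function. Minimized (for
#' fixed integer `y >= 1`) at `yhat = y`.
#'
#' @param y observed counts (non-negative integers).
#' @param yhat predicted rates (>= 0), same length.
#' @param eps guard added inside the logarithm.
#' @return mean loss (scalar).
#' @examples
#' poissonNLL(2, 3)   # 3 - 2*log(3) + log(2)
#' @export
poissonNLL <- function(y, yhat, eps = 1e-8) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (any(y < 0)) stop("counts must be non-negative")
  if (any(yhat < 0)) stop("rates must be non-negative")
  mean(yhat - y * log(yhat + eps) + lgamma(y + 1))
}

#' Mean squared error
#'
#' @param y,yhat numeric vectors of equal length.
#' @return mean of squared differences.
#' @export
mseLoss <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  mean((y - yhat)^2)
}

#' Combined multi-task loss
#'
#' The unweighted sum of the three objectives: MSE on rmsd_min, MSE on
#' rmsd_ave, and Poisson negative log-likelihood on n_rmsd, each averaged
#' over the non-masked (complex, protocol) entries. Masked entries
#' contribute nothing to any term.
#'
#' @param labels numeric array n x P x 3 (rmsd_min, rmsd_ave, n_rmsd).
#' @param pred list of three P x n prediction matrices (head order as in
#'   labels), as returned by [predictDataset()] internals, or an n x P x 3
#'   array.
#' @param mask logical n x P matrix, TRUE where observed.
#' @return scalar loss.
#' @export
combinedLoss <- function(labels, pred, mask = NULL) {
  if (is.list(pred)) {
    pred <- array(c(t(pred[[1]]), t(pred[[2]]), t(pred[[3]])),
                  dim = dim(labels))
  }
  stopifnot(identical(dim(pred), dim(labels)))
  if (is.null(mask)) mask <- !apply(is.na(labels), c(1, 2), any)
  if (!any(mask)) stop("all label entries are masked")
  m <- which(mask)
  mse1 <- mean((labels[, , 1][m] - pred[, , 1][m])^2)
  mse2 <- mean((labels[, , 2][m] - pred[, , 2][m])^2)
  pois <- poissonNLL(labels[, , 3][m], pred[, , 3][m])
  mse1 + mse2 + pois
}

# Loss and head-output gradients for one batch.
# labels: N x P x 3 array; pred: list of three P x N matrices;
# mask: N x P logical. Gradients are scaled by 1/n_observed.
.lossAndGrads <- function(labels, pred, mask) {
  nobs <- sum(mask)
  if (nobs == 0) stop("batch has no observed labels")
  tmask <- t(mask)                       # P x N
  dHeads <- vector("list", 3)
  loss <- 0
  for (t in 1:2) {
    y <- t(labels[, , t]); yh <- pred[[t]]
    r <- (yh - y) * tmask
    r[is.na(r)] <- 0
    loss <- loss + sum(r^2) / nobs
    dHeads[[t]] <- 2 * r / nobs
  }
  y <- t(labels[, , 3]); yh <- pred[[3]]
  eps <- 1e-8
  ll <- (yh - y * log(yh + eps) + lgamma(y + 1)) * tmask
  ll[is.na(ll)] <- 0
  loss <- loss + sum(ll) / nobs
  d <- (1 - y / (yh + eps)) * tmask
  d[is.na(d)] <- 0
  dHeads[[3]] <- d / nobs
  list(loss = loss, dHeads = dHeads)
}

# --- Adam ------------------------------------------------------------------

.adamInit <- function(params) {
  zero <- function(x) x * 0
  list(m = rapply(params, zero, how = "replace"),
       v = rapply(params, zero, how = "replace"), t = 0L)
}

# One Adam update over the trainable parameters. The parameter, first- and
# second-moment tensors are updated in place (they are owned exclusively by
# the training loop); batch-norm running statistics are carried in the
# forward pass, not by the optimizer. Returns the state with its step
# counter advanced.
.adamStep <- function(params, grads, state, lr, beta1 = 0.99,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) adam_update(p, g, m, v, lr, beta1, beta2,
                                          eps, state$t)
  for (l in seq_along(params$conv)) {
    upd(params$conv[[l]]$W, grads$conv[[l]]$W,
        state$m$conv[[l]]$W, state$v$conv[[l]]$W)
    upd(params$conv[[l]]$b, grads$conv[[l]]$b,
        state$m$conv[[l]]$b, state$v$conv[[l]]$b)
  }
  upd(params$proj$W, grads$proj$W, state$m$proj$W, state$v$proj$W)
  upd(params$proj$b, grads$proj$b, state$m$proj$b, state$v$proj$b)
  for (l in seq_along(params$lig)) {
    upd(params$lig[[l]]$W, grads$lig[[l]]$W,
        state$m$lig[[l]]$W, state$v$lig[[l]]$W)
    upd(params$lig[[l]]$b, grads$lig[[l]]$b,
        state$m$lig[[l]]$b, state$v$lig[[l]]$b)
  }
  upd(params$bn$gamma, grads$bn$gamma, state$m$bn$gamma, state$v$bn$gamma)
  upd(params$bn$beta, grads$bn$beta, state$m$bn$beta, state$v$bn$beta)
  for (t in 1:3) {
    upd(params$heads[[t]]$W, grads$heads[[t]]$W,
        state$m$heads[[t]]$W, state$v$heads[[t]]$W)
    upd(params$heads[[t]]$b, grads$heads[[t]]$b,
        state$m$heads[[t]]$b, state$v$heads[[t]]$b)
  }
  state
}

#' Predict label triples for featurized inputs
#'
#' Runs the network in evaluation mode (batch-norm uses its stored running
#' statistics, so single-sample inference is deterministic) on a feature
#' batch and returns the three P-column prediction matrices.
#'
#' @param model a trained [DockingModel-class].
#' @param Xvox voxel feature matrix, (channels x edge^3) x n.
#' @param Xlig ligand feature matrix, ligand_dim x n.
#' @return list of matrices `rmsd_min`, `rmsd_ave`, `n_rmsd`, each n x P.
#' @export
predictFeatures <- function(model, Xvox, Xlig) {
  stopifnot(is(model, "DockingModel"))
  fwd <- .netForward(model@params, model@config, Xvox, Xlig, train = FALSE)
  list(rmsd_min = t(fwd$pred[[1]]), rmsd_ave = t(fwd$pred[[2]]),
       n_rmsd = t(fwd$pred[[3]]))
}
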