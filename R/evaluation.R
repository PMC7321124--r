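# Evaluation statistics: per-protocol and ligand-centric RMSE / Pearson R
# tables, the protocol-selection policy, and the one-sided Mann-Whitney
# comparison of model-selected against fixed protocols.

.TARGETS <- c("rmsd_min", "rmsd_ave", "n_rmsd")

#' Pearson correlation with explicit degenerate handling
#'
#' Standard product-moment correlation; returns `NA` (flagged missing)
#' when either input has zero variance, where the coefficient is
#' undefined.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \[-1, 1\], or `NA`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least 2 observations")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

.rmse <- function(x, y) sqrt(mean((x - y)^2))

# Out-of-fold prediction array check + per-fold index list.
.foldIndices <- function(plan, ids) {
  av <- plan@assignment[ids]
  if (any(is.na(av))) stop("plan does not cover every complex")
  lapply(seq_len(plan@k) - 1L, function(f) which(av == f))
}

#' Protocol-centric evaluation table
#'
#' For every protocol and every target (rmsd_min, rmsd_ave, n_rmsd),
#' computes RMSE and Pearson R over each fold's validation complexes and
#' aggregates as mean (+/- 1 sd) across folds, plus an `Average` row over
#' protocols per target.
#'
#' @param predictions n x P x 3 out-of-fold prediction array (e.g. from
#'   [crossValidate()]), rows named by complex id.
#' @param labels a [LabelMatrix-class].
#' @param plan the [SplitPlan-class] the predictions were produced under.
#' @return data.frame: protocol, target, rmse_mean, rmse_sd, r_mean, r_sd.
#' @export
perProtocolEval <- function(predictions, labels, plan) {
  stopifnot(is(labels, "LabelMatrix"))
  v <- labels@values
  ids <- dimnames(v)[[1]]
  if (any(is.na(predictions[labels@mask])))
    stop("predictions missing for some observed validation entries")
  fidx <- .foldIndices(plan, ids)
  P <- length(labels@registry)
  rows <- list()
  for (t in 1:3) {
    rm_f <- matrix(NA_real_, plan@k, P)
    r_f <- matrix(NA_real_, plan@k, P)
    for (f in seq_len(plan@k)) {
      va <- fidx[[f]]
      for (p in seq_len(P)) {
        ok <- va[labels@mask[va, p]]
        if (length(ok) < 2) next
        rm_f[f, p] <- .rmse(v[ok, p, t], predictions[ok, p, t])
        r_f[f, p] <- pearsonR(v[ok, p, t], predictions[ok, p, t])
      }
    }
    for (p in seq_len(P)) {
      rows[[length(rows) + 1]] <- data.frame(
        protocol = labels@registry[p], target = .TARGETS[t],
        rmse_mean = foldAggregate(rm_f[, p])[1],
        rmse_sd = foldAggregate(rm_f[, p])[2],
        r_mean = foldAggregate(r_f[, p])[1],
        r_sd = foldAggregate(r_f[, p])[2])
    }
    # Average row: mean over protocols of the per-protocol fold means
    pm_rm <- vapply(seq_len(P), function(p) foldAggregate(rm_f[, p])[1],
                    numeric(1))
    pm_r <- vapply(seq_len(P), function(p) foldAggregate(r_f[, p])[1],
                   numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      protocol = "Average", target = .TARGETS[t],
      rmse_mean = mean(pm_rm, na.rm = TRUE),
      rmse_sd = sd(pm_rm, na.rm = TRUE),
      r_mean = mean(pm_r, na.rm = TRUE), r_sd = sd(pm_r, na.rm = TRUE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ligand-centric evaluation
#'
#' Pools all observed (complex, protocol) pairs of each fold's validation
#' set into a single vector pair per target, computes R and RMSE on the
#' pool, and aggregates mean (+/- 1 sd) over folds. `method =
#' "per_complex"` instead computes R across protocols within each
#' validation complex and averages — an alternative reading of a
#' ligand-centric metric, off by default.
#'
#' @param predictions n x P x 3 out-of-fold prediction array.
#' @param labels a [LabelMatrix-class].
#' @param plan the governing [SplitPlan-class].
#' @param method `"pooled"` (default) or `"per_complex"`.
#' @return data.frame: target, r_mean, r_sd, rmse_mean, rmse_sd.
#' @export
ligandCentricEval <- function(predictions, labels, plan,
                              method = c("pooled", "per_complex")) {
  method <- match.arg(method)
  v <- labels@values
  ids <- dimnames(v)[[1]]
  fidx <- .foldIndices(plan, ids)
  rows <- lapply(1:3, function(t) {
    rv <- rmv <- numeric(plan@k)
    for (f in seq_len(plan@k)) {
      va <- fidx[[f]]
      m <- labels@mask[va, , drop = FALSE]
      yt <- v[va, , t][m]
      yh <- predictions[va, , t][m]
      if (method == "pooled") {
        rv[f] <- pearsonR(yt, yh)
        rmv[f] <- .rmse(yt, yh)
      } else {
        rc <- vapply(seq_along(va), function(i) {
          ok <- labels@mask[va[i], ]
          if (sum(ok) < 2) return(NA_real_)
          pearsonR(v[va[i], ok, t], predictions[va[i], ok, t])
        }, numeric(1))
        rv[f] <- mean(rc, na.rm = TRUE)
        rmv[f] <- .rmse(yt, yh)
      }
    }
    data.frame(target = .TARGETS[t],
               r_mean = foldAggregate(rv)[1], r_sd = foldAggregate(rv)[2],
               rmse_mean = foldAggregate(rmv)[1],
               rmse_sd = foldAggregate(rmv)[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Protocol-selection policy
#'
#' For rmsd_min and rmsd_ave the protocol with the minimum predicted value
#' is chosen; for n_rmsd the maximum. Ties break to the lowest registry
#' index.
#'
#' @param prediction either a list with numeric P-vectors `rmsd_min`,
#'   `rmsd_ave`, `n_rmsd` (one complex) or n x P matrices (many).
#' @param registry protocol names; defaults to [protocolRegistry()]
#'   truncated to P.
#' @return data.frame with the chosen protocol index (1-based) and name
#'   per target, one row per complex.
#' @export
selectProtocol <- function(prediction, registry = NULL) {
  asMat <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1) else x
  mn <- asMat(prediction$rmsd_min)
  av <- asMat(prediction$rmsd_ave)
  nr <- asMat(prediction$n_rmsd)
  P <- ncol(av)
  if (is.null(registry)) registry <- protocolRegistry()[seq_len(P)]
  i_min <- apply(mn, 1, which.min)
  i_ave <- apply(av, 1, which.min)
  i_n <- apply(nr, 1, which.max)
  data.frame(rmsd_min_idx = i_min, rmsd_min = registry[i_min],
             rmsd_ave_idx = i_ave, rmsd_ave = registry[i_ave],
             n_rmsd_idx = i_n, n_rmsd = registry[i_n],
             stringsAsFactors = FALSE)
}

#' One-sided two-sample Mann-Whitney test
#'
#' Rank-sum comparison of two samples. The p-value is exact (distribution
#' enumeration) when the combined sample size is at most 12 and there are
#' no ties, and a normal approximation with tie correction otherwise.
#' `alternative = "less"` tests whether `x` is stochastically smaller
#' than `y`.
#'
#' @param x,y non-empty numeric samples.
#' @param alternative `"less"` or `"greater"`.
#' @return list: `U` (the Mann-Whitney U statistic for `x`), `p.value`.
#' @export
mannWhitneyOneSided <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  list(U = unname(wt$statistic), p.value = wt$p.value)
}

#' Apply the selection policy and collect experimental outcomes
#'
#' Runs [selectProtocol()] on the predictions and attaches, per complex
#' and target, the experimentally measured value of the chosen protocol.
#' Predicted n_rmsd rates are clamped to `[0, n_poses]` before the argmax.
#'
#' @param predictions n x P x 3 prediction array.
#' @param labels a [LabelMatrix-class] with the experimental values.
#' @param n_poses pose count cap for the n_rmsd clamp (default 20).
#' @return data.frame (one row per complex): chosen protocol and
#'   experimental value per target.
#' @export
applySelection <- function(predictions, labels, n_poses = 20) {
  stopifnot(is(labels, "LabelMatrix"))
  v <- labels@values
  pred <- list(rmsd_min = predictions[, , 1], rmsd_ave = predictions[, , 2],
               n_rmsd = pmin(pmax(predictions[, , 3], 0), n_poses))
  sel <- selectProtocol(pred, registry = labels@registry)
  n <- nrow(sel)
  sel$rmsd_min_value <- v[cbind(seq_len(n), sel$rmsd_min_idx, 1L)]
  sel$rmsd_ave_value <- v[cbind(seq_len(n), sel$rmsd_ave_idx, 2L)]
  sel$n_rmsd_value <- v[cbind(seq_len(n), sel$n_rmsd_idx, 3L)]
  sel$complex_id <- dimnames(v)[[1]]
  sel
}

#' Compare model selections against every fixed protocol
#'
#' For each target, compares the distribution of experimental values under
#' the model-chosen protocols against each fixed protocol with a one-sided
#' Mann-Whitney test ("less" for the RMSD targets, "greater" for n_rmsd)
#' and flags significance at `alpha`. No multiple-testing correction is
#' applied by default; `bonferroni = TRUE` divides `alpha` by the number
#' of protocols.
#'
#' @param selection output of [applySelection()].
#' @param labels the [LabelMatrix-class] used for selection.
#' @param alpha significance level (default 0.01).
#' @param bonferroni apply a Bonferroni correction (default FALSE).
#' @return data.frame with one row per (target, protocol): the selected
#'   and fixed-protocol means, p-value, and significance flag.
#' @export
selectionComparison <- function(selection, labels, alpha = 0.01,
                                bonferroni = FALSE) {
  stopifnot(is(labels, "LabelMatrix"))
  v <- labels@values
  P <- length(labels@registry)
  thr <- if (bonferroni) alpha / P else alpha
  rows <- list()
  specs <- list(list(t = 1L, col = "rmsd_min_value", alt = "less"),
                list(t = 2L, col = "rmsd_ave_value", alt = "less"),
                list(t = 3L, col = "n_rmsd_value", alt = "greater"))
  for (s in specs) {
    chosen <- selection[[s$col]]
    chosen <- chosen[!is.na(chosen)]
    for (p in seq_len(P)) {
      fixed <- v[, p, s$t][labels@mask[, p]]
      mw <- mannWhitneyOneSided(chosen, fixed, alternative = s$alt)
      rows[[length(rows) + 1]] <- data.frame(
        target = .TARGETS[s$t], protocol = labels@registry[p],
        selected_mean = mean(chosen), protocol_mean = mean(fixed),
        p_value = mw$p.value, significant = mw$p.value < thr)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-family evaluation of rmsd_ave predictions
#'
#' Pearson R for the rmsd_ave target restricted to each of the `top_n`
#' most populous protein families (pooled over protocols within a fold's
#' validation members of the family; folds with fewer than 3 validation
#' complexes of the family are flagged missing), averaged over folds.
#' Families are ranked by complex count (descending, ties by name).
#'
#' @param predictions n x P x 3 out-of-fold prediction array.
#' @param labels a [LabelMatrix-class].
#' @param plan the governing [SplitPlan-class].
#' @param families named character vector, complex id -> family.
#' @param top_n number of families to report (all, if fewer exist).
#' @return data.frame: family, n_complexes, r_mean, r_sd, n_folds_used.
#' @export
perFamilyEval <- function(predictions, labels, plan, families, top_n = 30) {
  v <- labels@values
  ids <- dimnames(v)[[1]]
  fam <- families[ids]
  counts <- table(fam)
  ranked <- names(counts)[order(-as.integer(counts), names(counts))]
  ranked <- ranked[seq_len(min(top_n, length(ranked)))]
  fidx <- .foldIndices(plan, ids)
  rows <- lapply(ranked, function(fm) {
    rs <- vapply(seq_len(plan@k), function(f) {
      va <- intersect(fidx[[f]], which(fam == fm))
      if (length(va) < 3) return(NA_real_)
      m <- labels@mask[va, , drop = FALSE]
      pearsonR(v[va, , 2][m], predictions[va, , 2][m])
    }, numeric(1))
    data.frame(family = fm, n_complexes = as.integer(counts[fm]),
               r_mean = mean(rs, na.rm = TRUE),
               r_sd = if (sum(is.finite(rs)) > 1) sd(rs, na.rm = TRUE) else 0,
               n_folds_used = sum(is.finite(rs)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
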