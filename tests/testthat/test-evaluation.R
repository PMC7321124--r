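# Helpers to build a labelled dataset with controllable predictions.
evalFixture <- function(n = 20, P = 4, k = 2, seed = 5) {
  set.seed(seed)
  ids <- sprintf("c%02d", seq_len(n))
  ave <- matrix(runif(n * P, 1, 6), n, P)
  vals <- array(NA_real_, c(n, P, 3))
  vals[, , 1] <- ave * matrix(runif(n * P, 0.3, 1), n, P)
  vals[, , 2] <- ave
  vals[, , 3] <- matrix(rbinom(n * P, 20, 0.3), n, P)
  labels <- LabelMatrix(vals, registry = protocolRegistry()[seq_len(P)],
                        ids = ids)
  plan <- randomSplit(ids, k = k, seed = seed)
  list(labels = labels, plan = plan, values = labelValues(labels))
}

test_that("pearsonR matches hand computation and flags degeneracy", {
  expect_equal(pearsonR(1:5, 1:5), 1.0)
  expect_equal(pearsonR(1:5, -(1:5)), -1.0)
  expect_equal(pearsonR(c(1, 2, 3), c(1, 2, 4)), 0.98198, tolerance = 1e-5)
  expect_true(is.na(pearsonR(c(2, 2, 2), c(1, 2, 3))))
  expect_error(pearsonR(1:3, 1:2), "length mismatch")
  expect_error(pearsonR(1, 1), "at least 2")
})

test_that("protocol-centric evaluation aggregates RMSE and R over folds", {
  fx <- evalFixture()
  perfect <- fx$values
  tab <- perProtocolEval(perfect, fx$labels, fx$plan)
  expect_equal(nrow(tab), (4 + 1) * 3)      # P protocols + Average, 3 targets
  body <- tab[tab$protocol != "Average", ]
  expect_true(all(body$rmse_mean == 0))
  expect_true(all(abs(body$r_mean - 1) < 1e-12))
  # constant shift: RMSE = |shift|, R unchanged at 1
  shifted <- perfect + 0.75
  tabs <- perProtocolEval(shifted, fx$labels, fx$plan)
  bodys <- tabs[tabs$protocol != "Average", ]
  expect_equal(bodys$rmse_mean, rep(0.75, nrow(bodys)), tolerance = 1e-12)
  expect_equal(bodys$r_mean, rep(1, nrow(bodys)), tolerance = 1e-12)
  expect_equal(bodys$rmse_sd, rep(0, nrow(bodys)), tolerance = 1e-12)
  expect_error(perProtocolEval(perfect * NA, fx$labels, fx$plan), "missing")
})

test_that("fold aggregation is mean plus/minus one standard deviation", {
  expect_equal(foldAggregate(c(0.5, 0.7)),
               c(mean = 0.6, sd = sd(c(0.5, 0.7))))
  expect_equal(unname(foldAggregate(c(0.5, 0.7))[2]), 0.1414, tolerance = 1e-3)
  expect_equal(unname(foldAggregate(c(1, 1, 1))[2]), 0)
  # two folds with protocol RMSEs 1.0 and 2.0 report 1.5 (+/- 0.707)
  expect_equal(unname(foldAggregate(c(1, 2))),
               c(1.5, sd(c(1, 2))))
})

test_that("ligand-centric evaluation pools complexes and protocols", {
  fx <- evalFixture()
  tab <- ligandCentricEval(fx$values, fx$labels, fx$plan)
  expect_equal(tab$target, c("rmsd_min", "rmsd_ave", "n_rmsd"))
  expect_true(all(tab$rmse_mean == 0))
  expect_true(all(abs(tab$r_mean - 1) < 1e-12))
  # hand-checked pooled example: 2 complexes x 2 protocols
  vals <- array(0, c(2, 2, 3))
  vals[, , 1] <- vals[, , 2] <- matrix(c(1, 3, 2, 4), 2, 2)
  vals[, , 3] <- 0
  lab <- LabelMatrix(vals, registry = protocolRegistry()[1:2],
                     ids = c("a", "b"))
  plan <- new("SplitPlan", strategy = "random", k = 1L,
              assignment = setNames(c(0L, 0L), c("a", "b")),
              seed = 1L)
  pred <- labelValues(lab)
  pred[, , 2] <- matrix(c(1, 3, 2, 5), 2, 2)
  tab2 <- ligandCentricEval(pred, lab, plan)
  expect_equal(tab2$rmse_mean[2], 0.5)
  expect_equal(tab2$r_mean[2], cor(c(1, 2, 3, 4), c(1, 2, 3, 5)),
               tolerance = 1e-12)
  expect_equal(tab2$r_mean[2], 0.9827, tolerance = 1e-4)
  # per-complex alternative runs and stays in [-1, 1]
  tab3 <- ligandCentricEval(fx$values, fx$labels, fx$plan,
                            method = "per_complex")
  expect_true(all(abs(tab3$r_mean) <= 1))
})

test_that("selection picks argmin RMSD / argmax count with index ties", {
  one <- selectProtocol(list(rmsd_min = 2, rmsd_ave = 2, n_rmsd = 5),
                        registry = "only")
  expect_equal(one$rmsd_ave, "only")
  sel <- selectProtocol(list(rmsd_min = c(1, 2, 3),
                             rmsd_ave = c(2.0, 1.5, 3.0),
                             n_rmsd = c(3, 7, 7)))
  expect_equal(sel$rmsd_ave_idx, 2L)
  expect_equal(sel$n_rmsd_idx, 2L)        # tie broken to lower index
  expect_equal(sel$rmsd_min_idx, 1L)
})

test_that("one-sided Mann-Whitney matches exhaustive enumeration", {
  mw <- mannWhitneyOneSided(c(1, 2), c(3, 4), "less")
  expect_equal(mw$U, 0)
  expect_equal(mw$p.value, 1 / 6, tolerance = 1e-12)
  # full enumeration oracle over all C(n+m, n) rank arrangements
  enumP <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x)
    combos <- utils::combn(length(pooled), n)
    uStat <- function(xi) {
      r <- rank(pooled)
      sum(r[xi]) - n * (n + 1) / 2
    }
    obs <- uStat(seq_len(n))
    us <- apply(combos, 2, function(ix) {
      r <- rank(pooled)
      sum(r[ix]) - n * (n + 1) / 2
    })
    mean(us <= obs)
  }
  set.seed(9)
  for (i in 1:10) {
    x <- round(runif(sample(2:4, 1), 0, 100), 3)
    y <- round(runif(sample(2:4, 1), 0, 100), 3)
    expect_equal(mannWhitneyOneSided(x, y, "less")$p.value, enumP(x, y),
                 tolerance = 1e-10)
    # swapping roles flips the one-sided direction
    expect_equal(mannWhitneyOneSided(y, x, "greater")$p.value,
                 enumP(x, y), tolerance = 1e-10)
  }
  # identical samples: no stochastic dominance
  expect_gte(mannWhitneyOneSided(c(1, 2, 3), c(1, 2, 3), "less")$p.value,
             0.5)
  expect_error(mannWhitneyOneSided(numeric(0), 1:3), "non-empty")
})

test_that("oracle selection dominates every fixed protocol", {
  fx <- evalFixture(n = 40, P = 6)
  sel <- applySelection(fx$values, fx$labels)   # select on the truth
  expect_equal(nrow(sel), 40)
  cmp <- selectionComparison(sel, fx$labels)
  expect_equal(nrow(cmp), 6 * 3)
  for (t in c("rmsd_min_value", "rmsd_ave_value")) {
    ti <- if (t == "rmsd_min_value") 1 else 2
    for (p in 1:6)
      expect_lte(mean(sel[[t]]), mean(fx$values[, p, ti]))
  }
  for (p in 1:6)
    expect_gte(mean(sel$n_rmsd_value), mean(fx$values[, p, 3]))
})

test_that("random selection on exchangeable labels is rarely significant", {
  set.seed(101)
  P <- 5
  sig <- total <- 0
  for (rep in 1:100) {
    vals <- array(NA_real_, c(30, P, 3))
    vals[, , 2] <- matrix(rnorm(30 * P, mean = 4), 30, P)
    vals[, , 1] <- vals[, , 2] * 0.5
    vals[, , 3] <- matrix(rbinom(30 * P, 20, 0.3), 30, P)
    lab <- LabelMatrix(vals, registry = protocolRegistry()[seq_len(P)])
    # a random protocol per complex masquerading as model predictions
    pred <- array(runif(30 * P * 3), c(30, P, 3))
    sel <- applySelection(pred, lab)
    cmp <- selectionComparison(sel, lab, alpha = 0.01)
    sig <- sig + sum(cmp$significant)
    total <- total + nrow(cmp)
  }
  expect_gte(1 - sig / total, 0.95)
})

test_that("per-family evaluation ranks families and respects fold minima", {
  fx <- evalFixture(n = 30, P = 3, k = 2)
  fam <- setNames(rep(c("FA", "FB", "FC"), c(16, 10, 4)),
                  dimnames(fx$values)[[1]])
  tab <- perFamilyEval(fx$values, fx$labels, fx$plan, fam, top_n = 2)
  expect_equal(tab$family, c("FA", "FB"))   # ranked by size desc
  expect_equal(nrow(perFamilyEval(fx$values, fx$labels, fx$plan, fam,
                                  top_n = 30)), 3)
  # a single-family dataset reproduces the ligand-centric pooled R
  fam1 <- setNames(rep("ONLY", 30), names(fam))
  set.seed(2)
  noisy <- fx$values + array(rnorm(length(fx$values), sd = 0.4),
                             dim(fx$values))
  t1 <- perFamilyEval(noisy, fx$labels, fx$plan, fam1)
  t2 <- ligandCentricEval(noisy, fx$labels, fx$plan)
  expect_equal(t1$r_mean[1], t2$r_mean[2], tolerance = 1e-12)
})
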