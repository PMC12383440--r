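test_that("Dice loss matches the squared-denominator closed forms", {
  y <- c(1, 1, 0, 0)
  expect_equal(diceLoss(c(1, 0, 0, 0), y), 1 / 3, tolerance = 1e-5)
  m <- matrix(rbinom(100, 1, 0.4), 10, 10)
  expect_lt(diceLoss(m, m), 1e-4)
  disjoint <- 1 - m
  expect_gt(diceLoss(disjoint, m), 1 - 1e-4)
})

test_that("BCE matches its closed form and a per-pixel loop oracle", {
  expect_equal(bceLoss(0.5, 1), log(2), tolerance = 1e-9)
  expect_lt(bceLoss(c(1, 0, 1), c(1, 0, 1)), 1e-5)
  set.seed(12)
  pred <- runif(10); gt <- rbinom(10, 1, 0.5)
  expect_equal(bceLoss(pred, gt), oracleBce(pred, gt), tolerance = 1e-7)
})

test_that("total loss is the sum of its parts with consistent gradients", {
  set.seed(13)
  pred <- runif(25); gt <- rbinom(25, 1, 0.5)
  tl <- totalLoss(pred, gt)
  expect_equal(tl$total, tl$diceLoss + tl$bceLoss)
  expect_equal(tl$diceLoss, diceLoss(pred, gt))
  expect_equal(tl$bceLoss, bceLoss(pred, gt))
  expect_lt(totalLoss(gt, gt)$total, 1e-4)
  # gradient wrt logits equals the sum of component finite differences
  logits <- rnorm(25)
  lg <- fuseseg:::.lossGrad(matrix(logits, 5, 5), matrix(gt, 5, 5))
  h <- 1e-6
  for (i in c(1, 7, 25)) {
    up <- logits; up[i] <- up[i] + h
    dn <- logits; dn[i] <- dn[i] - h
    fd <- (fuseseg:::.lossGrad(matrix(up, 5, 5), matrix(gt, 5, 5))$total -
           fuseseg:::.lossGrad(matrix(dn, 5, 5), matrix(gt, 5, 5))$total) /
          (2 * h)
    expect_equal(lg$dLogits[i], fd, tolerance = 1e-4)
  }
})

test_that("Dice score equals set counting, with symmetry and conventions", {
  g <- matrix(0, 4, 4); s <- matrix(0, 4, 4)
  g[1, 1:4] <- 1                       # |G| = 4
  s[1, 2:4] <- 1; s[2, 1:3] <- 1       # |S| = 6, overlap 3
  expect_equal(diceScore(g, s), 0.6)
  expect_equal(diceScore(g, g), 1)
  expect_equal(diceScore(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  set.seed(14)
  for (i in 1:200) {
    a <- randomMask(16, 16, runif(1, 0.05, 0.6))
    b <- randomMask(16, 16, runif(1, 0.05, 0.6))
    expect_identical(diceScore(a, b), oracleDice(a, b))
    expect_identical(diceScore(a, b), diceScore(b, a))
  }
})

test_that("Dice loss on binary predictions is 1 - Dice score", {
  set.seed(15)
  for (i in 1:20) {
    a <- randomMask(12, 12); b <- randomMask(12, 12)
    expect_equal(diceLoss(b, a, eps = 0), 1 - diceScore(a, b),
                 tolerance = 1e-12)
  }
})

test_that("HD95 matches hand geometry and an all-pairs oracle", {
  a <- matrix(0, 8, 8); b <- matrix(0, 8, 8)
  a[1, 1] <- 1; b[4, 5] <- 1   # offset (3, 4): distance 5
  expect_equal(hd95(a, b), 5)
  expect_equal(hd95(a, a), 0)
  set.seed(16)
  for (i in 1:50) {
    g <- randomMask(32, 32, runif(1, 0.05, 0.5))
    s <- randomMask(32, 32, runif(1, 0.05, 0.5))
    if (sum(g) == 0 || sum(s) == 0) next
    expect_equal(hd95(g, s), oracleHd(g, s), tolerance = 1e-9)
    # symmetry of the max-of-both-directions rule
    expect_equal(hd95(g, s), hd95(s, g), tolerance = 1e-12)
    # the 95th percentile never exceeds the exact Hausdorff distance
    expect_lte(hd95(g, s), hausdorff(g, s) + 1e-12)
    expect_equal(hausdorff(g, s), oracleHd(g, s, q = 1), tolerance = 1e-9)
  }
})

test_that("empty-mask conventions: penalty diagonal, flagged; both empty 0", {
  e <- matrix(0, 10, 20)
  m <- e; m[5, 5] <- 1
  r <- hd95(e, m, flag = TRUE)
  expect_true(r$flagged)
  expect_equal(r$value, sqrt(9^2 + 19^2))
  expect_equal(hd95(e, e), 0)
})

test_that("size-stratified bins partition the rows and match a loop oracle", {
  rows <- data.frame(gtSize = c(100, 600, 700), dice = c(0.5, 0.8, 0.9))
  sb <- sizeStratified(rows)
  expect_equal(sb$n, c(1L, 2L))
  expect_equal(sb$meanDice[2], 0.85)
  one <- sizeStratified(data.frame(gtSize = c(10, 20), dice = c(0.4, 0.6)))
  expect_equal(one$meanDice[1], 0.5)
  set.seed(17)
  rows <- data.frame(gtSize = sample(0:2999, 500, replace = TRUE),
                     dice = runif(500))
  sb <- sizeStratified(rows, binWidth = 500)
  expect_equal(sum(sb$n), 500L)
  for (b in seq_len(nrow(sb))) {
    sel <- rows$gtSize >= sb$lower[b] & rows$gtSize < sb$upper[b]
    expect_equal(sb$n[b], sum(sel))
    if (sum(sel)) expect_equal(sb$meanDice[b], mean(rows$dice[sel]))
  }
  expect_error(sizeStratified(data.frame(gtSize = -1, dice = 0.5)),
               "negative")
})

test_that("evaluation reports aggregate exactly from their per-slice rows", {
  fit <- cachedTrainedFit()
  rep <- evaluateModel(fit$model, heldOutRecords())
  ps <- perSlice(rep)
  ag <- aggregates(rep)
  expect_equal(ag$meanDice[ag$task == "WT"],
               mean(ps$dice[ps$task == "WT"]))
  expect_equal(ag$sdDice[ag$task == "WT"], stats::sd(ps$dice))
  expect_equal(sum(sizeBins(rep)$n), nrow(ps))
  expect_true(all(ps$dice >= 0 & ps$dice <= 1))
  dir <- withr::local_tempdir()
  writeEvalReport(rep, dir, "t")
  expect_true(file.exists(file.path(dir, "t_per_slice.csv")))
  back <- utils::read.csv(file.path(dir, "t_per_slice.csv"))
  expect_equal(mean(back$dice), ag$meanDice[1])
})
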