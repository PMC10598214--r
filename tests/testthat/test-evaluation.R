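test_that("AUROC matches closed forms and the pair-counting oracle", {
  expect_equal(aurocScore(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(aurocScore(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(aurocScore(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)), 0.75)
  expect_error(aurocScore(c(1, 1), c(0.2, 0.3)), "both classes")
  set.seed(55)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # with ties
    expect_equal(aurocScore(labels, scores), bruteAuroc(labels, scores))
  }
})

test_that("AUROC complementarity holds for tie-free scores", {
  set.seed(66)
  for (rep in 1:20) {
    n <- 10
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq_len(100), n) / 100     # distinct
    expect_equal(aurocScore(labels, scores) +
                   aurocScore(labels, -scores), 1)
  }
})

test_that("Spearman matches rank-formula values including ties", {
  expect_equal(spearmanRho(1:5, (1:5)^3), 1.0)       # monotone transform
  expect_equal(spearmanRho(1:5, rev(1:5)), -1.0)
  expect_equal(spearmanRho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  ## tied cases, frozen from the average-rank Pearson formula
  expect_equal(spearmanRho(c(1, 2, 2, 3), c(1, 2, 3, 4)),
               4.5 / sqrt(4.5 * 5), tolerance = 1e-12)
  expect_equal(spearmanRho(c(1, 1, 2), c(3, 3, 1)), -1)
  expect_error(spearmanRho(c(1, 1, 1), 1:3), "constant")
  expect_error(spearmanRho(1:2, 2:1), "at least 3")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rnorm(20); y <- rnorm(20)
  base <- spearmanRho(x, y)
  expect_equal(spearmanRho(exp(x), y), base)
  expect_equal(spearmanRho(x, 3 * y - 7), base)
  expect_equal(spearmanRho(rank(x), y), base)
})

test_that("energy sign convention: lower REU with higher p is positive", {
  p <- c(0.9, 0.7, 0.4, 0.1)
  energy <- c(-3, -2, -1, 0)   # best binding where p is largest
  expect_equal(spearmanVsEnergy(p, energy), 1.0)
  expect_equal(spearmanVsEnergy(rev(p), energy), -1.0)
})

test_that("top-n energy summary selects by score with positional ties", {
  out <- topNEnergy(c(0.9, 0.1), c(-2, 0), n = 1)
  expect_equal(out$meanEnergy, -2)
  expect_equal(out$pctBelow, 100)
  out2 <- topNEnergy(c(0.9, 0.8, 0.1), c(-2, -0.5, -3), n = 2)
  expect_equal(out2$meanEnergy, -1.25)
  expect_equal(out2$pctBelow, 50)
  ## all energies above tau
  expect_equal(topNEnergy(c(0.5, 0.6), c(0, 1), n = 2)$pctBelow, 0)
  ## n = all returns the global mean
  e <- c(-2, 1, -0.4, 3)
  expect_equal(topNEnergy(runif(4), e, n = 4)$meanEnergy, mean(e))
  expect_error(topNEnergy(c(0.1), c(0), n = 2), "n must lie")
})

test_that("evaluateTracks pools or macro-averages over unmasked positions", {
  t1 <- PredictionTrack("a", c(0.9, 0.8, 0.1, 0.2))
  t2 <- PredictionTrack("b", c(0.7, 0.3, 0.6, 0.4))
  l1 <- LabeledSequence("a", "MKVL", c(1L, 1L, 0L, 0L))
  l2 <- LabeledSequence("b", "MKVL", c(1L, 0L, 1L, 0L),
                        mask = c(TRUE, TRUE, TRUE, FALSE))
  p1 <- PositionEnergyProfile("a", "MKVL", c(-2, -3, 0, 1), rep(1L, 4))
  p2 <- PositionEnergyProfile("b", "MKVL", c(-2, 0, -1.5, NA),
                              c(1L, 1L, 1L, 0L))
  macro <- evaluateTracks(list(t1, t2), list(l1, l2),
                          profiles = list(p1, p2), n = 2)
  expect_equal(macro$auroc, mean(c(1, 1)))
  expect_equal(macro$nPositions, 7L)
  micro <- evaluateTracks(list(t1, t2), list(l1, l2),
                          profiles = list(p1, p2), n = 2,
                          average = "micro")
  pooledP <- c(0.9, 0.8, 0.1, 0.2, 0.7, 0.3, 0.6)
  pooledY <- c(1, 1, 0, 0, 1, 0, 1)
  expect_equal(micro$auroc, bruteAuroc(pooledY, pooledP))
})
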