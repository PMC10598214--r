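test_that("BCE loss matches closed forms, symmetry and weight linearity", {
  expect_equal(bceLoss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(bceLoss(0.5, 1, weight = 2), 2 * log(2), tolerance = 1e-12)
  ## perfect predictions vanish up to the clamp
  expect_lt(bceLoss(c(1, 0), c(1, 0)), 1e-6)
  ## class symmetry: loss(p, 1) == loss(1 - p, 0)
  for (p in c(0.1, 0.42, 0.9))
    expect_equal(bceLoss(p, 1), bceLoss(1 - p, 0), tolerance = 1e-12)
  ## masked positions are excluded; empty mask gives 0
  expect_equal(bceLoss(c(0.5, 0.99), c(1, 0), mask = c(TRUE, FALSE)),
               log(2), tolerance = 1e-12)
  expect_equal(bceLoss(c(0.5), c(1), mask = FALSE), 0)
  expect_error(bceLoss(1.2, 1), "\\[0, 1\\]")
})

test_that("head gradients agree with numerical differentiation", {
  ns <- asNamespace("pepprior")
  set.seed(21)
  for (act in c("relu", "gelu")) {
    d <- 7; n <- 5
    X <- matrix(rnorm(n * d), n, d)
    head <- ns$.initHead(d, c(6L, 5L, 4L), seed = 31)
    y <- c(1, 0, 1, 1, 0)
    mask <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
    w <- 1.3
    lossOf <- function(h) {
      hc <- ns$.headForward(h, X, act)
      bceLoss(hc$p, y, mask, w)
    }
    hc <- ns$.headForward(head, X, act)
    hb <- ns$.headBackward(head, hc,
                           ns$.bceLogitGrad(hc$p, y, mask, w), act)
    eps <- 1e-6
    for (l in 1:4) for (t in 1:4) {
      i <- sample(nrow(head$W[[l]]), 1); j <- sample(ncol(head$W[[l]]), 1)
      h2 <- head
      h2$W[[l]][i, j] <- h2$W[[l]][i, j] + eps
      num <- (lossOf(h2) - lossOf(head)) / eps
      expect_equal(num, hb$gW[[l]][i, j], tolerance = 1e-4)
    }
  }
})

test_that("a zeroed final layer predicts 0.5 everywhere", {
  ns <- asNamespace("pepprior")
  b <- oneHotBackend(1L)
  head <- ns$.initHead(backendDim(b), c(4L, 3L, 2L), seed = 1)
  head$W[[4]][] <- 0
  head$b[[4]][] <- 0
  model <- new("InterfaceModel", backend = b, head = head,
               headConfig = list(hidden = c(4L, 3L, 2L),
                                 activation = "relu"),
               seed = 1L)
  tr <- predict(model, "MKVLW")
  expect_equal(probabilities(tr), rep(0.5, 5))
  ## determinism of predict
  expect_identical(probabilities(predict(model, "MKVLW")),
                   probabilities(tr))
})

test_that("early stopping follows the patience rule on injected schedules", {
  ns <- asNamespace("pepprior")
  s <- ns$.stopSchedule(c(1.0, 0.9, 0.95, 0.97), patience = 2)
  expect_equal(s$stopEpoch, 4L)
  expect_equal(s$bestEpoch, 2L)
  expect_equal(s$reason, "early_stopping")
  ## strictly decreasing loss never triggers
  s2 <- ns$.stopSchedule(seq(1, 0.1, by = -0.1), patience = 1)
  expect_equal(s2$reason, "max_epochs")
  expect_equal(s2$bestEpoch, length(seq(1, 0.1, by = -0.1)))
  ## patience 1 stops at the first non-improvement
  s3 <- ns$.stopSchedule(c(0.5, 0.6, 0.4), patience = 1)
  expect_equal(s3$stopEpoch, 2L)
  expect_equal(s3$bestEpoch, 1L)
})

test_that("training reduces loss on a separable fixture and is seed-reproducible", {
  tr <- makeTinyLabeled(10, 40, seed = 5)
  va <- makeTinyLabeled(4, 40, seed = 6)
  names(va) <- NULL
  va <- lapply(seq_along(va), function(i)
    LabeledSequence(sprintf("v%02d", i), residues(va[[i]]),
                    siteLabels(va[[i]])))
  cfg <- trainingConfig(maxEpochs = 8, seed = 9)
  fit1 <- trainInterfaceModel(oneHotBackend(1L), tr, va,
                              hidden = c(16L, 8L, 4L), trainConfig = cfg)
  expect_lt(tail(fit1$report$trainLoss, 1), fit1$report$trainLoss[1])
  expect_equal(fit1$report$bestEpoch,
               which.min(fit1$report$valLoss))
  fit2 <- trainInterfaceModel(oneHotBackend(1L), tr, va,
                              hidden = c(16L, 8L, 4L), trainConfig = cfg)
  expect_identical(fit1$model@head, fit2$model@head)
})

test_that("training validates its inputs", {
  tr <- makeTinyLabeled(3, 20, seed = 1)
  expect_error(trainInterfaceModel(oneHotBackend(1L), list(), tr),
               "non-empty")
  expect_error(trainInterfaceModel(oneHotBackend(1L), tr, tr),
               "disjoint")
  masked <- lapply(tr, function(s)
    LabeledSequence(sequenceId(s), residues(s), siteLabels(s),
                    mask = rep(FALSE, nchar(residues(s)))))
  va <- makeTinyLabeled(2, 20, seed = 2)
  va <- lapply(seq_along(va), function(i)
    LabeledSequence(sprintf("v%d", i), residues(va[[i]]),
                    siteLabels(va[[i]])))
  expect_error(trainInterfaceModel(oneHotBackend(1L), masked, va),
               "masked")
})

test_that("doubling sequence weights doubles the loss", {
  s <- makeTinyLabeled(1, 30, seed = 3)[[1]]
  p <- runif(30)
  l1 <- bceLoss(p, siteLabels(s), labelMask(s), weight = 1)
  l2 <- bceLoss(p, siteLabels(s), labelMask(s), weight = 2)
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
})

test_that("model checkpoints round-trip through save/load", {
  tr <- makeTinyLabeled(4, 25, seed = 8)
  va <- makeTinyLabeled(2, 25, seed = 9)
  va <- lapply(seq_along(va), function(i)
    LabeledSequence(sprintf("v%d", i), residues(va[[i]]),
                    siteLabels(va[[i]])))
  fit <- trainInterfaceModel(oneHotBackend(1L), tr, va,
                             hidden = c(8L, 6L, 4L),
                             trainConfig = trainingConfig(maxEpochs = 3,
                                                          seed = 2))
  f <- withr::local_tempfile(fileext = ".ckpt")
  saveModel(fit$model, f)
  back <- loadModel(f)
  expect_identical(probabilities(predict(back, "MKVWLA")),
                   probabilities(predict(fit$model, "MKVWLA")))
})
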