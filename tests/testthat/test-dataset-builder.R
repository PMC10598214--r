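test_that("interaction dedup keeps records only when BSA differs by > 100", {
  recs <- data.frame(
    partner_a = c("A", "A", "A", "A", "B"),
    partner_b = c("B", "B", "B", "C", "A"),
    bsa = c(500, 550, 650, 500, 700),
    entry_id = paste0("e", 1:5))
  out <- dedupeInteractions(recs)
  ## e2 within 100 of e1; e3 within 100 of e2? no: compared to kept only
  ## (e1: |650-500| = 150 -> kept); e5 is the same unordered pair as e1
  ## at |700-500| = 200 from e1 but |700-650| = 50 from kept e3 -> dropped
  expect_equal(out$entry_id, c("e1", "e3", "e4"))
  expect_error(dedupeInteractions(transform(recs, bsa = -1)),
               "nonnegative")
})

test_that("record filtering applies the REU and length rules strictly", {
  recs <- data.frame(
    sequence_id = c("s1", "s1", "s2", "s3", "s4"),
    window_start = c(1L, 5L, 1L, 1L, 1L),
    window_length = 10L,
    reu = c(-1500, -999, -2, -2, -2))
  lens <- c(s1 = 100, s2 = 50, s3 = 1023, s4 = 51)
  expect_message(out <- filterPeptideRecords(recs, lens), "dropped")
  ## s1 first record fails REU; s2 (length 50) and s3 (length 1023) fail
  ## the strict open interval; s4 (length 51) survives
  expect_equal(out$sequence_id, c("s1", "s4"))
  expect_equal(out$reu, c(-999, -2))
})

test_that("record filtering rejects out-of-bounds windows by name", {
  recs <- data.frame(sequence_id = "s1", window_start = 95L,
                     window_length = 10L, reu = -2)
  expect_error(filterPeptideRecords(recs, c(s1 = 100)),
               "out of sequence bounds.*s1")
})

test_that("window-to-position aggregation matches the worked example", {
  recs <- data.frame(sequence_id = "s", window_start = 1:3,
                     window_length = 10L, reu = c(-3, -2, -1))
  prof <- windowsToPositions(recs, strrep("A", 12), "s")
  expect_equal(energies(prof)[1], -3)
  expect_equal(positionCoverage(prof)[1], 1L)
  expect_equal(energies(prof)[3], -2)
  expect_equal(positionCoverage(prof)[3], 3L)
  expect_equal(energies(prof)[12], -1)
  expect_equal(positionCoverage(prof)[12], 1L)
})

test_that("aggregation agrees with the brute-force oracle on random instances", {
  set.seed(41)
  for (rep in 1:60) {
    n <- sample(12:40, 1)
    nr <- sample(0:15, 1)
    recs <- if (nr > 0) {
      wl <- pmin(sample(1:10, nr, replace = TRUE), n)
      data.frame(sequence_id = "s",
                 window_start = vapply(wl, function(w)
                   sample.int(n - w + 1L, 1), integer(1)),
                 window_length = wl,
                 reu = round(rnorm(nr, -1, 2), 3))
    } else {
      data.frame(sequence_id = character(), window_start = integer(),
                 window_length = integer(), reu = numeric())
    }
    prof <- windowsToPositions(recs, strrep("A", n), "s")
    oracle <- bruteWindowsToPositions(recs, n)
    expect_equal(energies(prof), oracle$energy)
    expect_equal(positionCoverage(prof), oracle$coverage)
    ## conservation of window mass
    expect_equal(sum(positionCoverage(prof)),
                 sum(recs$window_length))
  }
})

test_that("zero records give an all-missing profile, not an error", {
  recs <- data.frame(sequence_id = character(), window_start = integer(),
                     window_length = integer(), reu = numeric())
  prof <- windowsToPositions(recs, "MKVL", "s")
  expect_true(all(is.na(energies(prof))))
  expect_true(all(positionCoverage(prof) == 0L))
})

test_that("duplicate profiles merge by mean of non-missing energies", {
  p1 <- PositionEnergyProfile("b", "MK", c(-2, NA), c(1L, 0L))
  p2 <- PositionEnergyProfile("a", "MK", c(-4, -6), c(1L, 2L))
  p3 <- PositionEnergyProfile("c", "MKV", c(-1, -1, -1), c(1L, 1L, 1L))
  out <- mergeDuplicateProfiles(list(p1, p2, p3))
  expect_length(out, 2L)
  merged <- out[[1L]]
  expect_equal(sequenceId(merged), "a")          # lexicographically least
  expect_equal(energies(merged), c(-3, -6))      # NA skipped at pos 2
  expect_equal(merged@mergedIds, c("a", "b"))
  expect_equal(sequenceId(out[[2L]]), "c")       # singleton untouched
  expect_equal(energies(out[[2L]]), energies(p3))
})

test_that("binarization uses a strict threshold and masks missing positions", {
  prof <- PositionEnergyProfile("s", "MKVL", c(-1.5, -1, -0.5, NA),
                                c(1L, 1L, 2L, 0L))
  ls <- binarizeProfile(prof)
  expect_equal(siteLabels(ls), c(1L, 0L, 0L, 0L))
  expect_equal(labelMask(ls), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(seqWeight(ls), 1.0)
})

test_that("binarization is monotone in energy", {
  set.seed(7)
  for (rep in 1:25) {
    n <- 15
    e <- rnorm(n, -1, 1)
    prof <- PositionEnergyProfile("s", strrep("A", n), e, rep(1L, n))
    base <- siteLabels(binarizeProfile(prof))
    i <- sample.int(n, 1)
    e2 <- e; e2[i] <- e2[i] - runif(1, 0, 3)   # lower one energy
    low <- siteLabels(binarizeProfile(
      PositionEnergyProfile("s", strrep("A", n), e2, rep(1L, n))))
    expect_true(all(low >= base))              # never flips 1 -> 0
  }
})

test_that("labeled dataset TSV round-trips labels and masks", {
  ls <- list(LabeledSequence("x", "MKVL", c(1L, 0L, 0L, 1L),
                             c(TRUE, TRUE, FALSE, TRUE)))
  prof <- list(PositionEnergyProfile("x", "MKVL", c(-2, 0, NA, -3),
                                     c(1L, 1L, 0L, 1L)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLabeledDataset(ls, f, profiles = prof)
  back <- readLabeledDataset(f)
  expect_equal(siteLabels(back$x), siteLabels(ls[[1]]))
  expect_equal(labelMask(back$x), labelMask(ls[[1]]))
  expect_equal(residues(back$x), "MKVL")
})
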