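test_that("the generator is seed-deterministic", {
  cfg <- generatorConfig(nSequences = 8, seed = 42)
  a <- generateLabeledCorpus(cfg)
  b <- generateLabeledCorpus(cfg)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$energies, b$energies)
  expect_identical(a$motifs, b$motifs)
})

test_that("noiseless motifs are labeled exactly and backgrounds are clean", {
  cfg <- generatorConfig(nSequences = 6, noiseSigma = 0, seed = 5)
  corpus <- generateLabeledCorpus(cfg)
  for (id in names(corpus$labeled)) {
    y <- siteLabels(corpus$labeled[[id]])
    m <- corpus$motifs[corpus$motifs$sequence_id == id, ]
    inMotif <- logical(length(y))
    for (r in seq_len(nrow(m))) inMotif[m$start[r]:m$end[r]] <- TRUE
    expect_equal(y == 1L, inMotif)
  }
})

test_that("background label prevalence matches the Gaussian tail", {
  ## no motifs: P(label = 1) = P(N(0, 0.5) < -1) = pnorm(-2) ~ 2.3%
  cfg <- generatorConfig(nSequences = 1000, lengthRange = c(100L, 100L),
                         motifsPerSequence = 0L, seed = 19)
  corpus <- generateLabeledCorpus(cfg)
  y <- unlist(lapply(corpus$labeled, siteLabels))
  p0 <- pnorm(-2)
  se <- sqrt(p0 * (1 - p0) / length(y))
  expect_lt(abs(mean(y) - p0), 3 * se)
})

test_that("window records invert the builder's aggregation in the noiseless limit", {
  cfg <- generatorConfig(nSequences = 4, noiseSigma = 0, seed = 3)
  corpus <- generateLabeledCorpus(cfg)
  recs <- generateWindowRecords(corpus, windowLength = 10L)
  ## record count per sequence = length - 9
  counts <- table(recs$sequence_id)
  lens <- nchar(as.character(corpus$sequences))
  expect_equal(as.integer(counts[names(lens)]), unname(lens) - 9L)
  ## constant-energy region: interior motif positions recover the effect
  id <- names(corpus$sequences)[1]
  prof <- windowsToPositions(recs[recs$sequence_id == id, ],
                             as.character(corpus$sequences[[id]]), id)
  m <- corpus$motifs[corpus$motifs$sequence_id == id, ][1, ]
  ## a background position far from the motif has exactly energy 0
  far <- which(seq_len(lens[[id]]) < m$start - 20 |
                 seq_len(lens[[id]]) > m$end + 20)
  far <- far[far >= 10 & far <= lens[[id]] - 10]
  if (length(far))
    expect_equal(energies(prof)[far[1]], 0)
})

test_that("double averaging matches the brute-force oracle on tiny instances", {
  ## tiny hand-built corpus: length 12, constant energy c
  corpus <- list(energies = list(s1 = rep(-2, 12)),
                 sequences = Biostrings::AAStringSet(c(s1 = strrep("A", 12))))
  recs <- generateWindowRecords(corpus, windowLength = 10L)
  expect_equal(recs$reu, rep(-2, 3))
  prof <- windowsToPositions(recs, strrep("A", 12), "s1")
  expect_equal(energies(prof), rep(-2, 12))
})

test_that("PPI tables span both policies with recorded motif truth", {
  ppi <- generatePpiTable(5, 1, seed = 2)
  lenient <- applyPolicy(ppi$records, "lenient")
  tab <- buildPartnerTable(lenient)
  for (tg in unique(ppi$truth$target))
    expect_length(partnersOf(tab, tg), 1L)
  ## decoys never survive
  expect_false("DECOY" %in% c(lenient$protein_a, lenient$protein_b))
  ## truth rows cover every partner with in-bounds coordinates
  expect_equal(sort(ppi$truth$partner_id),
               sort(names(ppi$partnerSequences)))
  lens <- setNames(Biostrings::width(ppi$partnerSequences),
                   names(ppi$partnerSequences))
  expect_true(all(ppi$truth$motif_end <= lens[ppi$truth$partner_id]))
  ## determinism
  ppi2 <- generatePpiTable(5, 1, seed = 2)
  expect_identical(ppi$records, ppi2$records)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generatorConfig(lengthRange = c(10L, 5L)))
  expect_error(generatorConfig(motifAlphabetBias = 1.5))
  expect_error(generatorConfig(lengthRange = c(6L, 10L),
                               motifLengthRange = c(8L, 12L)),
               "longer than")
})
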