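test_that("k-mer identity behaves at the extremes", {
  expect_equal(kmerIdentity(strrep("A", 60), strrep("A", 60)), 1)
  expect_equal(kmerIdentity(strrep("A", 60), strrep("W", 60)), 0)
  s <- "MKVLAWTYGGSAC"
  expect_equal(kmerIdentity(s, s), 1)
  ## containment: a subsequence's k-mers are all shared
  expect_equal(kmerIdentity("MKVLAWTY", "MKVLAWTYGGSACDE"), 1)
})

test_that("identical sequences share a cluster and a split", {
  seqs <- c(a = strrep("MKVLAWTY", 8), b = strrep("MKVLAWTY", 8),
            c = strrep("GDERHS", 10))
  out <- clusterSplit(seqs, seed = 3)
  expect_equal(out$cluster_id[out$sequence_id == "a"],
               out$cluster_id[out$sequence_id == "b"])
  expect_equal(out$split[out$sequence_id == "a"],
               out$split[out$sequence_id == "b"])
  expect_false(out$cluster_id[out$sequence_id == "c"] ==
                 out$cluster_id[out$sequence_id == "a"])
})

test_that("transitive identity chains form one component", {
  ## a ~ b and b ~ c via shared halves, a !~ c directly
  half1 <- strrep("MKVLAWTY", 5)
  half2 <- strrep("GDERHSQN", 5)
  half3 <- strrep("CIPFTSVM", 5)
  seqs <- c(a = paste0(half1, half1), b = paste0(half1, half2),
            c = paste0(half2, half2))
  expect_lt(kmerIdentity(seqs["a"], seqs["c"]), 0.25)
  out <- clusterSplit(seqs, seed = 1)
  expect_length(unique(out$cluster_id), 1L)
  ## and an unrelated sequence stays apart
  seqs2 <- c(seqs, d = paste0(half3, half3))
  out2 <- clusterSplit(seqs2, seed = 1)
  expect_length(unique(out2$cluster_id), 2L)
})

test_that("forced-test ids drag their whole cluster into test", {
  seqs <- c(a = strrep("MKVLAWTY", 8), b = strrep("MKVLAWTY", 8),
            c = strrep("GDERHS", 10), d = strrep("CIPFTS", 10))
  expect_warning(out <- clusterSplit(seqs, forcedTestIds = "a", seed = 5),
                 "test target")   # forced cluster exceeds the 13% target
  expect_equal(out$split[out$sequence_id %in% c("a", "b")],
               c("test", "test"))
})

test_that("an oversized forced-test set warns but does not error", {
  seqs <- c(a = strrep("MKVLAWTY", 8), b = strrep("GDERHS", 10))
  expect_warning(out <- clusterSplit(seqs, forcedTestIds = c("a", "b"),
                                     seed = 1),
                 "test target")
  expect_true(all(out$split == "test"))
})

test_that("splits are leakage-free and deterministic on random corpora", {
  for (rep in 1:10) {
    corpus <- generateLabeledCorpus(
      generatorConfig(nSequences = 25, seed = 100 + rep))
    seqs <- as.character(corpus$sequences)
    out1 <- clusterSplit(seqs, seed = rep)
    out2 <- clusterSplit(seqs, seed = rep)
    expect_identical(out1, out2)
    splitOf <- setNames(out1$split, out1$sequence_id)
    edges <- pepprior:::.identityEdges(seqs, 0.25)
    if (nrow(edges))
      expect_true(all(splitOf[edges$a] == splitOf[edges$b]))
  }
})

test_that("precomputed cluster assignments bypass the built-in estimator", {
  seqs <- c(a = strrep("MKVLAW", 10), b = strrep("GDERHS", 10),
            c = strrep("CIPFTS", 10))
  out <- clusterSplit(seqs, clusters = c(a = "c1", b = "c1", c = "c2"),
                      seed = 1)
  expect_equal(out$cluster_id[out$sequence_id == "a"],
               out$cluster_id[out$sequence_id == "b"])
  expect_error(clusterSplit(seqs, clusters = c(a = "c1")), "cover every")
})

test_that("invalid fractions are rejected", {
  seqs <- c(a = strrep("MKVLAW", 10))
  expect_error(clusterSplit(seqs, fractions = c(0.5, 0.5, 0.5)),
               "sum to 1")
})
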