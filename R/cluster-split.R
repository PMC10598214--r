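## Homology-aware dataset splitting.
##
## Sequences linked (directly or transitively) by pairwise identity at or
## above a threshold must land in the same split, so that validation and
## test metrics do not reflect memorization of homologous training
## sequences. Clusters are the connected components of the identity graph.

#' Estimate pairwise sequence identity from shared k-mers
#'
#' Built-in stand-in for an external sequence clusterer: the number of
#' distinct k-mers shared by the two sequences divided by the number of
#' distinct k-mers of the shorter one (containment). Identical sequences
#' score 1; sequences over disjoint alphabets score 0. For sequences
#' shorter than `k`, `k` is reduced to the shorter length.
#'
#' @param a,b Residue strings (character, `AAString`, or length-1
#'   `AAStringSet`).
#' @param k k-mer length (default 5).
#' @return Identity estimate in \[0, 1\].
#' @export
#' @examples
#' kmerIdentity("MKVLAWT", "MKVLAWT")   # 1
#' kmerIdentity(strrep("A", 60), strrep("W", 60))  # 0
kmerIdentity <- function(a, b, k = 5L) {
  a <- .asResidues(a); b <- .asResidues(b)
  kk <- min(k, nchar(a), nchar(b))
  ka <- .kmerSet(a, kk)
  kb <- .kmerSet(b, kk)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

.kmerSet <- function(s, k) {
  n <- nchar(s)
  unique(substring(s, 1:(n - k + 1L), k:n))
}

## Candidate identity edges among a set of sequences via a k-mer inverted
## index: only pairs sharing at least one k-mer are scored exactly.
.identityEdges <- function(chars, minIdentity, k = 5L) {
  ids <- names(chars)
  n <- length(chars)
  kk <- min(k, min(nchar(chars)))
  sets <- lapply(chars, .kmerSet, k = kk)
  index <- split(rep(seq_len(n), lengths(sets)), unlist(sets))
  cand <- unique(do.call(rbind, lapply(index, function(v) {
    if (length(v) < 2L) return(NULL)
    t(utils::combn(sort(v), 2L))
  })))
  if (is.null(cand) || !nrow(cand))
    return(data.frame(a = character(), b = character()))
  keep <- vapply(seq_len(nrow(cand)), function(r) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    shared <- length(intersect(sets[[i]], sets[[j]]))
    shared / min(length(sets[[i]]), length(sets[[j]])) >= minIdentity
  }, logical(1))
  data.frame(a = ids[cand[keep, 1L]], b = ids[cand[keep, 2L]])
}

#' Cluster sequences and assign leakage-free train/val/test splits
#'
#' Builds a graph with an edge between every pair of sequences whose
#' identity estimate is at least `minIdentity`, takes connected
#' components as clusters, and assigns whole clusters to splits:
#' clusters containing any `forcedTestIds` member go to test (with their
#' entire cluster); remaining clusters are assigned largest-first to the
#' split currently furthest below its target fraction, ties among equal
#' sizes broken by seeded order. No cluster ever spans splits.
#'
#' The identity oracle is pluggable: by default the built-in shared-k-mer
#' estimator ([kmerIdentity()]) is used; alternatively pass `clusters`, a
#' named vector of precomputed cluster ids (e.g. parsed from an external
#' clusterer's TSV), and the graph step is skipped.
#'
#' @param sequences Named `AAStringSet` (or named character vector).
#' @param minIdentity Minimum identity for an edge (default 0.25).
#' @param fractions Numeric length-3 `(train, val, test)` target
#'   fractions; positive, summing to 1. Default `c(0.77, 0.10, 0.13)`.
#' @param forcedTestIds Sequence ids whose clusters must go to test
#'   (e.g. partners selected for laboratory follow-up).
#' @param seed Integer seed controlling tie-breaking.
#' @param clusters Optional named integer/character vector: sequence id ->
#'   cluster id, replacing the built-in identity graph.
#' @return `data.frame` with columns `sequence_id`, `cluster_id`
#'   (integer), `split` (`"train"`, `"val"`, `"test"`).
#' @export
clusterSplit <- function(sequences, minIdentity = 0.25,
                         fractions = c(train = 0.77, val = 0.10,
                                       test = 0.13),
                         forcedTestIds = character(), seed = 1L,
                         clusters = NULL) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- as.character(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must carry unique names")
  stopifnot(length(fractions) == 3L)
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be positive and sum to 1")
  ids <- names(sequences)

  if (is.null(clusters)) {
    edges <- .identityEdges(sequences, minIdentity)
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(ids), name = ids)
    if (nrow(edges))
      g <- igraph::add_edges(g, rbind(edges$a, edges$b))
    comp <- igraph::components(g)$membership
    cluster <- as.integer(comp[ids])
  } else {
    if (!all(ids %in% names(clusters)))
      stop("precomputed 'clusters' must cover every sequence id")
    cluster <- as.integer(factor(clusters[ids]))
  }
  names(cluster) <- ids

  sizes <- table(cluster)
  clustIds <- as.integer(names(sizes))
  total <- length(ids)
  assigned <- stats::setNames(numeric(3), c("train", "val", "test"))
  splitOf <- stats::setNames(rep(NA_character_, length(clustIds)),
                             names(sizes))

  forcedClusters <- unique(cluster[intersect(forcedTestIds, ids)])
  if (length(forcedClusters)) {
    splitOf[as.character(forcedClusters)] <- "test"
    assigned["test"] <- sum(sizes[as.character(forcedClusters)])
    if (assigned["test"] / total > fractions[[3L]])
      warning(sprintf(
        "forced-test sequences occupy %.1f%% of the data, above the %.1f%% test target",
        100 * assigned["test"] / total, 100 * fractions[[3L]]))
  }

  remaining <- setdiff(names(sizes), as.character(forcedClusters))
  if (length(remaining)) {
    tie <- .withSeed(seed, stats::runif(length(remaining)))
    ord <- remaining[order(-as.numeric(sizes[remaining]), tie)]
    targets <- stats::setNames(as.numeric(fractions),
                               c("train", "val", "test"))
    for (cl in ord) {
      deficit <- targets - assigned / total
      pick <- names(deficit)[which.max(deficit)]
      splitOf[cl] <- pick
      assigned[pick] <- assigned[pick] + sizes[[cl]]
    }
  }

  data.frame(sequence_id = ids, cluster_id = as.integer(cluster),
             split = unname(splitOf[as.character(cluster)]),
             stringsAsFactors = FALSE, row.names = NULL)
}
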