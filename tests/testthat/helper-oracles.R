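## Independent brute-force oracles used across the suite. These are kept
## deliberately naive (O(n * w) loops, explicit pair enumeration) and
## never share code with the implementation paths they check.

## AUROC by explicit positive-negative pair counting with half credit
## for ties.
bruteAuroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## Per-position mean/count aggregation by looping positions x records.
bruteWindowsToPositions <- function(records, n) {
  energy <- rep(NA_real_, n)
  coverage <- integer(n)
  for (i in seq_len(n)) {
    vals <- c()
    for (r in seq_len(nrow(records))) {
      st <- records$window_start[r]
      en <- st + records$window_length[r] - 1L
      if (i >= st && i <= en) vals <- c(vals, records$reu[r])
    }
    coverage[i] <- length(vals)
    if (length(vals)) energy[i] <- mean(vals)
  }
  list(energy = energy, coverage = coverage)
}

## Local maximum by direct definition: strictly greater than the nearest
## differing value on each side (absent side counts as satisfied), and
## leftmost index of its plateau.
bruteLocalMaxima <- function(s) {
  s <- ifelse(is.na(s), -Inf, s)
  n <- length(s)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (!is.finite(s[i])) next
    if (i > 1 && s[i - 1] == s[i]) next      # not leftmost of plateau
    j <- i - 1
    okL <- TRUE
    if (j >= 1) okL <- s[j] < s[i]
    k <- i + 1
    while (k <= n && s[k] == s[i]) k <- k + 1
    okR <- TRUE
    if (k <= n) okR <- s[k] < s[i]
    if (okL && okR) out <- c(out, i)
  }
  out
}

## Full candidate selection oracle: all windows -> mean score -> local
## maxima -> sort by (-score, start) -> greedy non-overlap -> top n.
bruteSelect <- function(p, L, topN, allowOverlap = FALSE) {
  n <- length(p)
  starts <- seq_len(n - L + 1L)
  s <- vapply(starts, function(i) mean(p[i:(i + L - 1L)]), numeric(1))
  maxima <- bruteLocalMaxima(s)
  ord <- maxima[order(-s[maxima], maxima)]
  chosen <- integer(0)
  taken <- logical(n)
  for (st in ord) {
    span <- st:(st + L - 1L)
    if (!allowOverlap && any(taken[span])) next
    chosen <- c(chosen, st)
    taken[span] <- TRUE
    if (length(chosen) == topN) break
  }
  data.frame(start = chosen, score = s[chosen])
}

## Small labeled fixture: k sequences of length n with given labels drawn
## at a fixed positive rate, one-hot-learnable (positives forced to 'W').
makeTinyLabeled <- function(k, n, seed, posRate = 0.2) {
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    y <- as.integer(runif(n) < posRate)
    chars <- ifelse(y == 1, "W", sample(c("A", "K", "S", "G"), n,
                                        replace = TRUE))
    LabeledSequence(sprintf("t%02d", i), paste(chars, collapse = ""), y)
  })
}
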