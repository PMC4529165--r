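# Independent brute-force oracles used to check the implementation paths.

# Spearman via explicit average ranks + the Pearson formula
bruteSpearman <- function(x, y) {
  avgRank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    # average rank = mean position of equal values in the sorted vector
    r
  }
  rx <- avgRank(x)
  ry <- avgRank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# recursive memoized maximum base-pair count (no traceback), independent of
# the package's dynamic program
bruteMaxPairs <- function(seq, minLoop = 3) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  canPair <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (j - i <= minLoop) return(0L)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- rec(i, j - 1L)
    for (k in i:(j - minLoop - 1L)) {
      if (canPair(ch[k], ch[j])) {
        v <- 1L + rec(k + 1L, j - 1L) + if (k > i) rec(i, k - 1L) else 0L
        if (v > best) best <- v
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, n)
}

# explicit pairwise-loop nucleotide diversity with pairwise gap deletion
brutePi <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  n <- nrow(m)
  acgt <- c("A", "C", "G", "T")
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] %in% acgt & m[j, ] %in% acgt
    vals <- c(vals, sum(m[i, ok] != m[j, ok]) / sum(ok))
  }
  mean(vals)
}

# deterministic Gaussian-shaped histogram without sampling noise
gaussianHistogram <- function(means, sds, weights, nBins = 512,
                              total = 5000) {
  edges <- 0:nBins
  lam <- rep(0, nBins)
  for (k in seq_along(means))
    lam <- lam + weights[k] * total * diff(pnorm(edges, means[k], sds[k]))
  FluorHistogram(edges, round(lam), "oracle")
}

# random additive tree for BioNJ recovery checks
randomAdditiveTree <- function(nTips, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(nTips, rooted = FALSE)
    tr$edge.length <- runif(length(tr$edge.length), 0.2, 2)
    tr
  })
}
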