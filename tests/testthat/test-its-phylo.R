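test_that("type collapsing merges near-identical reads and splits variants", {
  fam1 <- genITSFamily(seed = 6, nTypes = 1, errorRate = 0)
  expect_length(collapseToTypes(fam1$reads), 1L)

  fam2 <- genITSFamily(seed = 6, nTypes = 2, errorRate = 0)
  cl <- collapseToTypes(fam2$reads)
  expect_length(cl, 2L)
  expect_equal(sum(vapply(cl, function(x) x$nReads, 1L)), 28L)

  # singleton one substitution away from a 27-read cluster merges at 0.99
  base <- as.character(fam1$reads[[1]])
  reads <- rep(base, 28)
  substr(reads[28], 50, 50) <- if (substr(base, 50, 50) == "A") "G" else "A"
  merged <- collapseToTypes(Biostrings::DNAStringSet(reads))
  expect_length(merged, 1L)
  # and the majority consensus restores the cluster sequence
  expect_equal(as.character(merged[[1]]$consensus), base)
})

test_that("nucleotide diversity matches the brute-force pairwise oracle", {
  id <- nucleotideDiversity(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(id$pi, 0)
  expect_equal(id$segregatingSites, 0L)
  expect_equal(id$nHaplotypes, 1L)

  two <- nucleotideDiversity(c(a = strrep("A", 100),
                               b = paste0(strrep("A", 99), "G")))
  expect_equal(two$pi, 0.01)
  expect_equal(two$segregatingSites, 1L)

  withr::with_seed(19, {
    for (r in 1:6) {
      n <- sample(3:6, 1)
      len <- 80
      base <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = "")
      seqs <- vapply(seq_len(n), function(i) {
        s <- strsplit(base, "")[[1]]
        k <- sample(0:6, 1)
        pos <- sample(len, k)
        s[pos] <- sample(c("A", "C", "G", "T", "-"), k, replace = TRUE)
        paste(s, collapse = "")
      }, "x")
      got <- nucleotideDiversity(seqs)
      expect_equal(got$pi, brutePi(seqs), tolerance = 1e-12)
    }
  })
  expect_error(nucleotideDiversity(c("ACG", "ACGT")), "length mismatch")
})

test_that("Jukes-Cantor transform matches the closed form", {
  expect_equal(jukesCantor(0), 0)
  expect_equal(jukesCantor(0.3), -0.75 * log(0.6))
  expect_equal(round(jukesCantor(0.3), 5), 0.38312)
  expect_error(jukesCantor(0.75), "saturation")
  expect_equal(jukesCantor(0.8, cap = 5), 5)
  # monotone increasing and >= its argument on (0, 0.75)
  p <- seq(0.01, 0.74, by = 0.01)
  d <- jukesCantor(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("BioNJ recovers additive trees exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  got <- bionjTree(cophenetic(tr))
  expect_equal(ape::dist.topo(ape::unroot(tr), got), structure(0L),
               ignore_attr = TRUE)
  expect_equal(cophenetic(got)[LETTERS[1:4], LETTERS[1:4]],
               cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]],
               tolerance = 1e-9)

  # three taxa: branch lengths from the three-point formulas
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- bionjTree(d3)
  bl <- setNames(t3$edge.length[match(seq_along(t3$tip.label),
                                      t3$edge[, 2])], t3$tip.label)
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)

  # random additive matrices, n <= 8
  for (seed in 1:5) {
    tr <- randomAdditiveTree(sample(4:8, 1), seed)
    got <- bionjTree(cophenetic(tr))
    expect_equal(ape::dist.topo(tr, got), structure(0L), ignore_attr = TRUE)
  }

  # on an ultrametric matrix BioNJ and UPGMA agree on topology
  trc <- withr::with_seed(7, ape::rcoal(6))
  d <- cophenetic(trc)
  expect_equal(ape::dist.topo(ape::unroot(upgmaTree(d)), bionjTree(d)),
               structure(0L), ignore_attr = TRUE)
  expect_error(bionjTree(matrix(c(0, Inf, 1, Inf, 0, 1, 1, 1, 0), 3)),
               "non-finite")
})

test_that("bootstrap supports separate planted clades and are reproducible", {
  withr::with_seed(99, {
    len <- 400
    anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    derive <- function(base, nmut) {
      s <- base
      pos <- sample(len, nmut)
      for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
      s
    }
    gA <- derive(anc, 40)   # ~10% divergence between groups
    gB <- anc
    seqs <- c(
      setNames(lapply(1:4, function(i) derive(gA, 1)), paste0("A", 1:4)),
      setNames(lapply(1:4, function(i) derive(gB, 1)), paste0("B", 1:4)))
    aln <- vapply(seqs, paste, "x", collapse = "")
  })
  tr <- bootstrapSupport(aln, nReps = 100, seed = 42)
  supA <- cladeSupport(tr, paste0("A", 1:4))
  supB <- cladeSupport(tr, paste0("B", 1:4))
  # the root bipartition is trivial in an unrooted tree; at least one of the
  # two complementary planted clades is an internal node with high support
  expect_true(max(supA, supB, na.rm = TRUE) >= 95)

  tr2 <- bootstrapSupport(aln, nReps = 100, seed = 42)
  expect_identical(tr$node.label, tr2$node.label)
  tr3 <- bootstrapSupport(aln, nReps = 100, seed = 43)
  expect_false(identical(tr$node.label, tr3$node.label))
  expect_error(bootstrapSupport(aln, nReps = 0), "nReps")
})

test_that("midpoint rooting balances the two deepest tips", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:6,D:1):1);")
  rooted <- bionjTree(cophenetic(tr), midpointRoot = TRUE)
  depths <- ape::node.depth.edgelength(rooted)[seq_len(4)]
  expect_equal(max(depths[rooted$tip.label == "C"]),
               max(depths[rooted$tip.label != "C"]))
})
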