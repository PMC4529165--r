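test_that("binarize emits one column per observed locus:allele", {
  p <- SSRPanel(list(a = list(L1 = 100L), b = list(L1 = 102L)))
  m <- binarize(p)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m), matrix(c(1L, 0L, 0L, 1L), 2), ignore_attr = TRUE)
  expect_equal(colnames(m), c("L1_100", "L1_102"))

  het <- SSRPanel(list(a = list(L1 = c(100L, 102L)), b = list(L1 = 100L)))
  mh <- binarize(het)
  expect_equal(unname(mh["a", ]), c(1L, 1L))

  # three accessions over two loci, hand enumeration
  p3 <- SSRPanel(list(
    x = list(L1 = c(100L, 104L), L2 = 150L),
    y = list(L1 = 100L, L2 = c(150L, 152L)),
    z = list(L1 = 104L, L2 = 152L)))
  m3 <- binarize(p3)
  expect_equal(colnames(m3), c("L1_100", "L1_104", "L2_150", "L2_152"))
  expect_equal(unname(m3["x", ]), c(1L, 1L, 1L, 0L))
  expect_equal(unname(m3["y", ]), c(1L, 0L, 1L, 1L))
  expect_equal(unname(m3["z", ]), c(0L, 1L, 0L, 1L))

  # missing locus -> zero block, recorded
  pm <- SSRPanel(list(a = list(L1 = 100L, L2 = 150L), b = list(L1 = 100L)))
  mm <- binarize(pm)
  expect_equal(unname(mm["b", "L2_150"]), 0L)
  expect_equal(attr(mm, "missing")$locus, "L2")
})

test_that("neiDistance matches the closed form and its invariants", {
  same <- SSRPanel(list(a = list(L1 = c(100L, 102L), L2 = 150L),
                        b = list(L1 = c(100L, 102L), L2 = 150L)))
  expect_equal(neiDistance(same)["a", "b"], 0)

  p <- SSRPanel(list(a = list(L1 = 100L), b = list(L1 = c(100L, 102L))))
  expect_equal(neiDistance(p)["a", "b"], -log(0.5 / sqrt(0.5)),
               tolerance = 1e-12)

  disjoint <- SSRPanel(list(a = list(L1 = 100L), b = list(L1 = 104L)))
  expect_warning(d <- neiDistance(disjoint, cap = 7), "capped")
  expect_equal(d["a", "b"], 7)

  # symmetry and zero diagonal on random panels
  for (seed in 1:3) {
    sim <- genSSRPanel(nGroups = 2, accessionsPerGroup = 3, nLoci = 8,
                       seed = seed)
    d <- suppressWarnings(neiDistance(sim$panel))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0))
  }

  # shared-band alternative lies in [0, 1] and is 0 for identical profiles
  expect_equal(neiDistance(same, method = "dice")["a", "b"], 0)
  dd <- neiDistance(p, method = "dice")
  expect_gte(dd["a", "b"], 0)
  expect_lte(dd["a", "b"], 1)
})

test_that("UPGMA reproduces hand-computed merges and is ultrametric", {
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgmaTree(d2)
  expect_equal(sort(t2$edge.length), c(1, 1))

  d3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  t3 <- upgmaTree(d3)
  co <- cophenetic(t3)
  expect_equal(co["A", "B"], 2)
  expect_equal(co["A", "C"], 6)
  expect_equal(co["B", "C"], 6)
  expect_lt(depthSpread(t3), 1e-9)

  # reconstruction of a random ultrametric matrix is exact
  for (seed in 4:6) {
    tr <- withr::with_seed(seed, ape::rcoal(6))
    d <- cophenetic(tr)
    rec <- upgmaTree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(rec)),
                 structure(0L, class = NULL), ignore_attr = TRUE)
    expect_equal(cophenetic(rec)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
    expect_lt(depthSpread(rec), 1e-9)
  }
  expect_error(upgmaTree(matrix(c(0, Inf, Inf, 0), 2)), "non-finite")
})

test_that("a duplicated accession sits at distance zero and joins first", {
  sim <- genSSRPanel(nGroups = 1, accessionsPerGroup = 4, nLoci = 10,
                     seed = 2)
  calls <- sim$panel@calls
  calls[["twin"]] <- calls[[1]]
  p <- SSRPanel(calls)
  d <- suppressWarnings(neiDistance(p))
  expect_equal(d[1, "twin"], 0)
  tr <- upgmaTree(d)
  co <- cophenetic(tr)
  expect_equal(co[panelAccessions(p)[1], "twin"], 0)
  expect_true(all(co["twin", colnames(co) != "twin" &
                       colnames(co) != panelAccessions(p)[1]] > 0))
})

test_that("UPGMA deepest split separates planted SSR groups", {
  for (seed in 1:3) {
    sim <- genSSRPanel(nGroups = 2, accessionsPerGroup = 5,
                       withinSharing = 0.9, betweenSharing = 0.05,
                       seed = seed)
    d <- suppressWarnings(neiDistance(sim$panel))
    split <- cutree(hclust(as.dist(d), method = "average"), k = 2)
    tab <- table(split, sim$truth$groups[names(split)])
    # each planted group maps to exactly one side of the deepest split
    expect_true(all(apply(tab, 2, function(x) sum(x > 0)) == 1))
  }
})

test_that("newick export round-trips topology, lengths and odd labels", {
  d3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  t3 <- upgmaTree(d3)
  s <- writeNewick(t3)
  back <- readNewick(s)
  expect_equal(ape::dist.topo(ape::unroot(t3), ape::unroot(back)),
               structure(0L), ignore_attr = TRUE)
  expect_equal(cophenetic(back)[rownames(d3), colnames(d3)],
               cophenetic(t3)[rownames(d3), colnames(d3)])

  d2 <- matrix(c(0, 2, 2, 0), 2,
               dimnames = list(c("sp. nov", "B(x)"), c("sp. nov", "B(x)")))
  tq <- upgmaTree(d2)
  sq <- writeNewick(tq)
  expect_match(sq, "'sp. nov'", fixed = TRUE)
  backq <- readNewick(sq)
  expect_setequal(backq$tip.label, c("sp. nov", "B(x)"))

  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(t3, tmp)
  expect_equal(sort(readNewick(path = tmp)$tip.label), LETTERS[1:3])
})
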