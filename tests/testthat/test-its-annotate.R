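test_that("delineateRegions reproduces the generator's construction", {
  fam <- genITSFamily(seed = 2, errorRate = 0)
  ann <- delineateRegions(fam$truth$template)
  sp <- regionSpans(ann)
  expect_equal(unname(IRanges::width(sp)),
               c(fam$truth$its1Length, fam$truth$r58sLength,
                 fam$truth$its2Length))
  expect_false(ann@deletionFlagged)
  expect_equal(as.character(regionSeq(ann, "r58s")), referenceFiveEightS())
})

test_that("a 2-nt deletion inside the 5.8S is spotted and flagged", {
  fam <- genITSFamily(seed = 3, nTypes = 2, errorRate = 0,
                      typeSpecs = list(list(edit = "none"),
                                       list(edit = "deletion58S",
                                            delStart = 40, delLen = 2)))
  del <- fam$truth$types[[2]]$sequence
  ann <- delineateRegions(del)
  expect_equal(unname(IRanges::width(regionSpans(ann))[2]), 153L)
  expect_true(ann@deletionFlagged)
})

test_that("sequences without a 5.8S are rejected as unannotatable", {
  rnd <- withr::with_seed(8, paste(sample(c("A", "C", "G", "T"), 600,
                                          replace = TRUE), collapse = ""))
  expect_error(delineateRegions(rnd), "unannotatable")
  expect_error(delineateRegions("ACGT"), "shorter than 400")
})

test_that("gcContent counts G, C and S over unambiguous positions", {
  expect_equal(gcContent("ATGC"), 50)
  expect_equal(gcContent("GGCC"), 100)
  expect_equal(gcContent("ATAT"), 0)
  expect_equal(gcContent("GCSN"), 100)  # S counts, N leaves the denominator
  expect_equal(gcContent("AGCN"), 100 * 2 / 3)
  expect_error(gcContent(""), "empty")
  # complement invariance: complement swaps within the AT and GC pairs
  withr::with_seed(10, {
    for (r in 1:10) {
      s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
      comp <- as.character(Biostrings::complement(Biostrings::DNAString(s)))
      expect_equal(gcContent(s), gcContent(comp))
    }
  })
  # a 162-nt span with exactly 100 G/C positions
  s162 <- paste0(strrep("G", 50), strrep("C", 50), strrep("A", 32),
                 strrep("T", 30))
  expect_equal(round(gcContent(s162), 2), 61.73)
})

test_that("motif scanning reports conserved, changed and deleted motifs", {
  expect_equal(scan58SMotifs(referenceFiveEightS())$status,
               rep("conserved", 3))

  # plant the published M2 change: position 9 substituted to A
  m2 <- conservedMotifs()[["M2"]]
  at <- regexpr(m2, referenceFiveEightS(), fixed = TRUE)[1]
  mut <- referenceFiveEightS()
  substr(mut, at + 8L, at + 8L) <- "A"
  rep2 <- scan58SMotifs(mut)
  expect_equal(rep2$status, c("conserved", "changed", "conserved"))
  expect_equal(rep2$changes[2], "nt-9 'A'")
  expect_equal(rep2$n_changed[2], 1L)

  # delete the whole M2 -> not present-deletion
  noM2 <- paste0(substr(referenceFiveEightS(), 1, at - 1),
                 substr(referenceFiveEightS(), at + nchar(m2),
                        nchar(referenceFiveEightS())))
  rep3 <- scan58SMotifs(noM2)
  expect_equal(rep3$status[2], "not present-deletion")
  expect_equal(rep3$n_changed[2], nchar(m2))

  # partial deletion is reported as a range in the table notation
  part <- paste0(substr(referenceFiveEightS(), 1, at - 1),
                 substr(referenceFiveEightS(), at + 3,
                        nchar(referenceFiveEightS())))
  rep4 <- scan58SMotifs(part)
  expect_equal(rep4$status[2], "changed")
  expect_match(rep4$changes[2], "nt1-nt3 'deletion'", fixed = TRUE)
})

test_that("motif scanning integrates with generator-planted disruptions", {
  fam <- genITSFamily(seed = 4, nTypes = 2, errorRate = 0,
                      typeSpecs = list(
                        list(edit = "none"),
                        list(edit = "motif", motifChanges = list(
                          list(motif = "M2", pos = 9, base = "A")))))
  ann <- delineateRegions(fam$truth$types[[2]]$sequence)
  rep <- scan58SMotifs(ann)
  expect_equal(rep$changes[2], "nt-9 'A'")
})
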