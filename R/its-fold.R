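#' @include its-annotate.R
NULL

#' Fold a sequence by base-pair maximization
#'
#' Nussinov-style dynamic program maximizing the number of Watson-Crick plus
#' G-T/G-U wobble pairs with a minimum hairpin loop of `minLoop` unpaired
#' bases. The traceback is deterministic, so identical sequences always give
#' identical structures. This is the built-in structure backend; a
#' thermodynamic (MFE) backend can be plugged in by supplying a function with
#' the same return shape.
#'
#' @param seq character or [Biostrings::DNAString]; T and U are equivalent.
#' @param minLoop minimum number of unpaired bases enclosed by a pair
#'   (default 3).
#' @return list with `structure` (dot-bracket), `n_pairs`, and `pairing`
#'   (integer vector of 1-based partners, 0 = unpaired).
#' @examples
#' foldRna("GGGGGAAAACCCCC")$structure
#' @export
foldRna <- function(seq, minLoop = 3) {
  s <- toupper(as.character(seq))
  if (nchar(s) < 2) stop("sequence too short to fold")
  .nussinov_fold(s, as.integer(minLoop))
}

# Decompose a pairing vector into helical arms. An arm is a maximal chain of
# nested pairs without branching, ending in a hairpin loop; bulges/interior
# loops do not interrupt an arm. Returns a list of arms, 5' to 3', each with
# the chain of pairs, its maximal stack length, and the id of the enclosing
# node (0 = exterior loop).
.foldArms <- function(pairing) {
  n <- length(pairing)
  pairs <- list()   # each c(i, j)
  parent <- integer()
  childCount <- integer()
  stack <- integer()
  openId <- integer(n)
  for (i in seq_len(n)) {
    j <- pairing[i]
    if (j > i) { # opening
      id <- length(pairs) + 1L
      pairs[[id]] <- c(i, j)
      parent[id] <- if (length(stack)) stack[length(stack)] else 0L
      childCount[id] <- 0L
      if (parent[id] > 0L) childCount[parent[id]] <- childCount[parent[id]] + 1L
      stack <- c(stack, id)
      openId[i] <- id
    } else if (j > 0 && j < i) { # closing
      stack <- stack[-length(stack)]
    }
  }
  if (!length(pairs)) return(list())
  # chain ends: hairpin-terminal nodes and multiloop-closing (branching) nodes
  ends <- which(childCount != 1L)
  arms <- lapply(ends, function(t) {
    chain <- t
    cur <- t
    while (parent[cur] > 0L && childCount[parent[cur]] == 1L) {
      cur <- parent[cur]
      chain <- c(chain, cur)
    }
    chain <- rev(chain) # outermost first
    ij <- do.call(rbind, pairs[chain])
    stacks <- 1L
    maxStack <- 1L
    if (nrow(ij) > 1) {
      for (r in 2:nrow(ij)) {
        if (ij[r, 1] == ij[r - 1, 1] + 1L && ij[r, 2] == ij[r - 1, 2] - 1L)
          stacks <- stacks + 1L
        else stacks <- 1L
        maxStack <- max(maxStack, stacks)
      }
    }
    list(pairs = ij, maxStack = maxStack, enclosing = parent[chain[1]],
         terminal = childCount[t] == 0L,
         start = ij[1, 1], outerEnd = ij[1, 2],
         loopStart = ij[nrow(ij), 1], loopEnd = ij[nrow(ij), 2])
  })
  arms[order(vapply(arms, function(a) a$start, 1L))]
}

#' Fold an ITS2 sequence and test the canonical four-helix topology
#'
#' Folds the span with [foldRna()], decomposes the structure into helical
#' arms (chains of >= `minStack` stacked pairs ending in a hairpin loop) and
#' checks the canonical ITS2 criteria: exactly four helices radiating from a
#' common loop, a pyrimidine-pyrimidine mismatch/internal loop in helix II,
#' and the conserved TGGT on the 5' side of helix III.
#'
#' @param seq ITS2 sequence (character or [Biostrings::DNAString]).
#' @param minLoop minimum hairpin loop (default 3).
#' @param minStack minimum stacked pairs for a helix (default 3).
#' @return list with `structure`, `n_pairs`, `n_helices`,
#'   `helix2_pyrimidine_bulge`, `helix3_tggt` and `formed` (`TRUE` iff four
#'   helices in a common-loop topology).
#' @examples
#' fam <- genITSFamily(seed = 1)
#' ann <- delineateRegions(fam$reads[[1]])
#' foldITS2(regionSeq(ann, "its2"))$formed
#' @export
foldITS2 <- function(seq, minLoop = 3, minStack = 3) {
  s <- toupper(as.character(seq))
  if (nchar(s) < 20) stop("span too short to fold")
  f <- foldRna(s, minLoop)
  arms <- .foldArms(f$pairing)
  helices <- Filter(function(a) a$maxStack >= minStack, arms)
  nHel <- length(helices)
  # common-loop topology: exactly four helices, each ending in its own
  # hairpin loop (a >= minStack stem closing a multiloop disqualifies the
  # fold), with mutually disjoint outer intervals. Isolated pairs that a
  # base-pair maximization may sprinkle between helices are not topology.
  starts <- vapply(helices, function(a) a$start, 1L)
  ends <- vapply(helices, function(a) a$outerEnd, 1L)
  disjoint <- nHel > 0 && all(starts[-1] > ends[-nHel])
  allTerminal <- all(vapply(helices, function(a) a$terminal, TRUE))
  formed <- nHel == 4 && disjoint && allTerminal
  bulge <- FALSE
  tggt <- FALSE
  if (nHel >= 2) bulge <- .hasPyrimidineBulge(helices[[2]], s)
  if (nHel >= 3) {
    arm3 <- helices[[3]]
    fiveSide <- substr(s, arm3$start, arm3$loopStart)
    tggt <- grepl("TGGT", fiveSide, fixed = TRUE)
  }
  list(structure = f$structure, n_pairs = f$n_pairs, n_helices = nHel,
       helix2_pyrimidine_bulge = bulge, helix3_tggt = tggt,
       formed = formed)
}

# pyrimidine-pyrimidine interior loop / mismatch anywhere within one arm
.hasPyrimidineBulge <- function(arm, s) {
  ij <- arm$pairs
  if (nrow(ij) < 2) return(FALSE)
  ch <- strsplit(s, "")[[1]]
  for (r in 2:nrow(ij)) {
    lgap <- (ij[r - 1, 1] + 1):(ij[r, 1] - 1)
    rgap <- (ij[r, 2] + 1):(ij[r - 1, 2] - 1)
    lgap <- lgap[lgap <= ij[r, 1] - 1 & lgap >= ij[r - 1, 1] + 1]
    rgap <- rgap[rgap <= ij[r - 1, 2] - 1 & rgap >= ij[r, 2] + 1]
    if (length(lgap) >= 1 && length(rgap) >= 1 &&
        all(ch[c(lgap, rgap)] %in% c("C", "T", "U")))
      return(TRUE)
  }
  FALSE
}

#' Fold a 5.8S sequence and compare it to the reference pairing pattern
#'
#' The query is folded with [foldRna()]; the reference 5.8S is folded the
#' same way (or a reference pairing supplied) and the query/reference
#' sequences are aligned globally. The structure counts as formed when at
#' least `minFrac` of the reference base pairs are recovered at the aligned
#' positions of the query structure.
#'
#' @param seq 5.8S sequence.
#' @param ref reference 5.8S sequence (default [referenceFiveEightS()]).
#' @param refPairing optional integer pairing vector for `ref`; computed by
#'   [foldRna()] when omitted.
#' @param minFrac minimum recovered fraction (default 0.7).
#' @param minLoop minimum hairpin loop (default 3).
#' @return list with `structure`, `n_pairs`, `n_helices`,
#'   `frac_reference_pairs` and `formed`.
#' @export
fold58S <- function(seq, ref = referenceFiveEightS(), refPairing = NULL,
                    minFrac = 0.7, minLoop = 3) {
  s <- toupper(as.character(seq))
  if (nchar(s) < 20) stop("span too short to fold")
  f <- foldRna(s, minLoop)
  if (is.null(refPairing)) refPairing <- foldRna(ref, minLoop)$pairing
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ref),
    subject = Biostrings::DNAString(s), type = "global",
    substitutionMatrix = .subMat(), gapOpening = 1, gapExtension = 1)
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  map <- integer(nchar(ref)) # ref position -> query position (0 = deleted)
  rp <- qp <- 0L
  for (i in seq_along(ap)) {
    if (as_[i] != "-") qp <- qp + 1L
    if (ap[i] != "-") {
      rp <- rp + 1L
      map[rp] <- if (as_[i] != "-") qp else 0L
    }
  }
  refPairs <- which(refPairing > seq_along(refPairing))
  rec <- 0L
  for (a in refPairs) {
    b <- refPairing[a]
    qa <- map[a]; qb <- map[b]
    if (qa > 0 && qb > 0 && f$pairing[qa] == qb) rec <- rec + 1L
  }
  frac <- if (length(refPairs)) rec / length(refPairs) else 0
  arms <- .foldArms(f$pairing)
  list(structure = f$structure, n_pairs = f$n_pairs,
       n_helices = length(Filter(function(a) a$maxStack >= 3, arms)),
       frac_reference_pairs = frac, formed = frac >= minFrac)
}

#' Putative-pseudogene call from ITS feature values
#'
#' A type is called a putative rDNA pseudogene when any of these holds:
#' the ITS2 does not fold into the four-helix topology; the 5.8S does not
#' fold into the reference-like structure; the 5.8S GC content falls below
#' `gcFloor`; or at least `changesFloor` positions across the three
#' conserved 5.8S motifs are changed (substituted or deleted; a fully absent
#' motif contributes its whole length). Thresholds are calibrated on the
#' published feature table and configurable.
#'
#' @param gc58S 5.8S GC content in percent.
#' @param nMotifChanges total changed motif positions across M1-M3.
#' @param its2Formed,r58sFormed logicals from the structure checks.
#' @param gcFloor GC threshold in percent (default 48).
#' @param changesFloor motif-change threshold (default 5).
#' @return list with `pseudogene` (logical) and `reasons` (character).
#' @examples
#' classifyPseudogeneFeatures(57, 0, TRUE, TRUE)$pseudogene   # FALSE
#' classifyPseudogeneFeatures(54, 0, FALSE, TRUE)$pseudogene  # TRUE
#' @export
classifyPseudogeneFeatures <- function(gc58S, nMotifChanges, its2Formed,
                                       r58sFormed, gcFloor = 48,
                                       changesFloor = 5) {
  if (anyNA(c(gc58S, nMotifChanges, its2Formed, r58sFormed)))
    stop("missing feature")
  reasons <- character()
  if (!its2Formed) reasons <- c(reasons, "ITS2 secondary structure not formed")
  if (!r58sFormed) reasons <- c(reasons, "5.8S secondary structure not formed")
  if (gc58S < gcFloor)
    reasons <- c(reasons, sprintf("5.8S GC %.2f%% below %.4g%%", gc58S, gcFloor))
  if (nMotifChanges >= changesFloor)
    reasons <- c(reasons, sprintf("%d motif positions changed (threshold %d)",
                                  nMotifChanges, changesFloor))
  list(pseudogene = length(reasons) > 0, reasons = reasons)
}

#' Putative-pseudogene call for an annotated ITS type
#'
#' Applies [classifyPseudogeneFeatures()] to the features stored in an
#' [ITSType-class] record.
#'
#' @param record an [ITSType-class].
#' @param gcFloor,changesFloor thresholds, see
#'   [classifyPseudogeneFeatures()].
#' @return list with `pseudogene` and `reasons`.
#' @export
classifyPseudogene <- function(record, gcFloor = 48, changesFloor = 5) {
  stopifnot(is(record, "ITSType"))
  if (!nrow(record@motifReport) || !length(record@foldITS2) ||
      !length(record@fold58S))
    stop("missing feature")
  classifyPseudogeneFeatures(record@gc58S, sum(record@motifReport$n_changed),
                             isTRUE(record@foldITS2$formed),
                             isTRUE(record@fold58S$formed),
                             gcFloor, changesFloor)
}
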