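#' @include its-fold.R
NULL

#' Collapse clone reads into ITS types
#'
#' Single-linkage clustering of reads at a pairwise-identity threshold over
#' the aligned core (global alignment; identity = matches / aligned
#' positions). Each cluster is summarized by a column-wise majority consensus
#' over its reads of the most common length; clusters are ordered by size.
#'
#' @param reads a [Biostrings::DNAStringSet] (or named character vector) of
#'   clone reads.
#' @param identityThreshold minimum pairwise identity joining two reads
#'   (default 0.99).
#' @return list of clusters, each with `typeId`, `consensus`
#'   ([Biostrings::DNAString]), `nReads` and `members` (read names).
#' @examples
#' fam <- genITSFamily(seed = 1, nTypes = 2)
#' length(collapseToTypes(fam$reads))
#' @export
collapseToTypes <- function(reads, identityThreshold = 0.99) {
  if (!is(reads, "DNAStringSet")) {
    nm <- names(reads)
    reads <- Biostrings::DNAStringSet(toupper(as.character(reads)))
    names(reads) <- nm
  }
  n <- length(reads)
  if (n < 1) stop("need >= 1 read")
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_len(n))
  cl <- if (n == 1) 1L else {
    idm <- matrix(1, n, n)
    for (i in seq_len(n - 1)) {
      aln <- Biostrings::pairwiseAlignment(
        pattern = reads[(i + 1):n], subject = reads[[i]], type = "global",
        substitutionMatrix = .subMat(), gapOpening = 5, gapExtension = 2)
      pid <- Biostrings::pid(aln, type = "PID1") / 100
      idm[i, (i + 1):n] <- idm[(i + 1):n, i] <- pid
    }
    hc <- hclust(as.dist(1 - idm), method = "single")
    cutree(hc, h = 1 - identityThreshold + 1e-12)
  }
  sizes <- table(cl)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  out <- vector("list", length(ord))
  for (t in seq_along(ord)) {
    members <- which(cl == as.integer(names(sizes)[ord[t]]))
    out[[t]] <- list(typeId = paste0("type", t),
                     consensus = .majorityConsensus(reads[members]),
                     nReads = length(members),
                     members = names(reads)[members])
  }
  out
}

# column-wise majority over the reads of the most common length
.majorityConsensus <- function(reads) {
  w <- Biostrings::width(reads)
  tw <- table(w)
  use <- reads[w == as.integer(names(tw)[which.max(tw)])]
  if (length(use) == 1) return(use[[1]])
  m <- Biostrings::consensusMatrix(use, as.prob = FALSE, baseOnly = TRUE)
  bases <- rownames(m)
  cons <- bases[apply(m, 2, which.max)]
  Biostrings::DNAString(paste(cons, collapse = ""))
}

#' Annotate the ITS types of one accession's clone family
#'
#' Runs the full per-accession ITS pipeline: collapse reads into types,
#' delineate ITS1/5.8S/ITS2, compute per-region GC, scan the conserved 5.8S
#' motifs, fold ITS2 and 5.8S, and call putative pseudogenes.
#'
#' @param reads clone reads ([Biostrings::DNAStringSet] or character).
#' @param accession accession label stored in each record.
#' @param identityThreshold type-collapsing identity (default 0.99).
#' @param ref reference 5.8S; `motifs` the conserved motif set.
#' @param motifs named motif vector (default [conservedMotifs()]).
#' @param gcFloor,changesFloor pseudogene thresholds, see
#'   [classifyPseudogeneFeatures()].
#' @return list of [ITSType-class] records, largest type first.
#' @examples
#' fam <- genITSFamily(seed = 1, nTypes = 2)
#' types <- annotateITSFamily(fam$reads, "demo")
#' vapply(types, isPseudogene, TRUE)
#' @export
annotateITSFamily <- function(reads, accession = "accession",
                              identityThreshold = 0.99,
                              ref = referenceFiveEightS(),
                              motifs = conservedMotifs(),
                              gcFloor = 48, changesFloor = 5) {
  clusters <- collapseToTypes(reads, identityThreshold)
  refPairing <- foldRna(ref)$pairing
  lapply(clusters, function(cl) {
    ann <- delineateRegions(cl$consensus, ref = ref)
    mot <- scan58SMotifs(ann, motifs = motifs, ref = ref)
    f2 <- foldITS2(regionSeq(ann, "its2"))
    f58 <- fold58S(regionSeq(ann, "r58s"), ref = ref,
                   refPairing = refPairing)
    gc58 <- gcContent(regionSeq(ann, "r58s"))
    cls <- classifyPseudogeneFeatures(gc58, sum(mot$n_changed),
                                      f2$formed, f58$formed,
                                      gcFloor, changesFloor)
    new("ITSType", accession = accession, typeId = cl$typeId,
        annotation = ann, gcITS1 = gcContent(regionSeq(ann, "its1")),
        gc58S = gc58, gcITS2 = gcContent(regionSeq(ann, "its2")),
        motifReport = mot, foldITS2 = f2, fold58S = f58,
        pseudogene = cls$pseudogene, reasons = cls$reasons,
        nReads = as.integer(cl$nReads))
  })
}

.alnMatrix <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    if (!is(alignment, "DNAStringSet")) {
      nm <- names(alignment)
      alignment <- Biostrings::DNAStringSet(toupper(as.character(alignment)))
      names(alignment) <- nm
    }
    if (length(unique(Biostrings::width(alignment))) != 1)
      stop("length mismatch: sequences must be aligned to equal length")
    m <- t(vapply(as.character(alignment),
                  function(s) strsplit(s, "")[[1]],
                  character(Biostrings::width(alignment)[1])))
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  m
}

#' Nucleotide diversity, segregating sites and haplotype count
#'
#' Nucleotide diversity is the average pairwise proportion of differing
#' sites, with pairwise deletion of positions where either sequence is a gap
#' or ambiguous. Segregating sites are columns with two or more unambiguous
#' states; haplotypes are exact-match groups of full sequences.
#'
#' @param alignment equal-length sequences ([Biostrings::DNAStringSet],
#'   character vector, or character matrix).
#' @return list with `nSequences`, `pi`, `segregatingSites`, `nHaplotypes`.
#' @examples
#' nucleotideDiversity(c(a = "ACGT", b = "ACGA"))
#' @export
nucleotideDiversity <- function(alignment) {
  m <- .alnMatrix(alignment)
  n <- nrow(m)
  if (n < 2) stop("need >= 2 sequences")
  valid <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  pis <- numeric()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- valid[i, ] & valid[j, ]
    if (!any(ok)) next
    pis <- c(pis, sum(m[i, ok] != m[j, ok]) / sum(ok))
  }
  s <- sum(apply(m, 2, function(col) {
    st <- unique(col[col %in% c("A", "C", "G", "T")])
    length(st) >= 2
  }))
  list(nSequences = n, pi = mean(pis), segregatingSites = s,
       nHaplotypes = length(unique(apply(m, 1, paste, collapse = ""))))
}

#' Jukes-Cantor distance from an observed difference proportion
#'
#' `d = -(3/4) * ln(1 - (4/3) * p)`. Proportions at or beyond the 0.75
#' saturation bound raise an error unless a `cap` is supplied.
#'
#' @param p observed proportion(s) of differing sites, `0 <= p < 0.75`.
#' @param cap optional replacement value for saturated entries.
#' @return substitutions per site.
#' @examples
#' jukesCantor(0.3)   # 0.38307
#' @export
jukesCantor <- function(p, cap = NULL) {
  if (anyNA(p) || any(p < 0)) stop("p must be in [0, 0.75)")
  sat <- p >= 0.75
  if (any(sat) && is.null(cap))
    stop("saturation: observed difference >= 0.75")
  d <- ifelse(sat, NA_real_, -0.75 * log(1 - 4 * p / 3))
  if (!is.null(cap)) d[sat] <- cap
  d
}

#' Pairwise Jukes-Cantor distance matrix from an alignment
#'
#' Observed difference proportions use pairwise deletion (positions where
#' either sequence is a gap or ambiguous are dropped for that pair) and are
#' transformed with [jukesCantor()].
#'
#' @param alignment equal-length sequences (see [nucleotideDiversity()]).
#' @param cap optional cap for saturated pairs (error when `NULL`).
#' @return symmetric numeric matrix.
#' @export
jcDistanceMatrix <- function(alignment, cap = NULL) {
  m <- .alnMatrix(alignment)
  n <- nrow(m)
  valid <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- valid[i, ] & valid[j, ]
    if (!any(ok)) stop("no comparable sites for a pair")
    p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    d[i, j] <- d[j, i] <- jukesCantor(p, cap = cap)
  }
  d
}

#' BioNJ tree from a distance matrix
#'
#' Neighbor-joining with variance-weighted branch combination (BioNJ),
#' exact on additive distance matrices; optional midpoint rooting.
#'
#' @param d symmetric distance matrix or `dist` with finite entries, n >= 3.
#' @param midpointRoot root the unrooted result on its midpoint
#'   (default `FALSE`).
#' @return an [ape::phylo].
#' @export
bionjTree <- function(d, midpointRoot = FALSE) {
  dd <- as.dist(d)
  if (any(!is.finite(dd))) stop("non-finite distances")
  if (attr(dd, "Size") < 3) stop("need >= 3 taxa")
  tr <- ape::bionj(dd)
  if (midpointRoot) tr <- phangorn::midpoint(tr)
  tr
}

#' Non-parametric bootstrap support on a Jukes-Cantor BioNJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the JC + BioNJ
#' tree for each pseudoreplicate, and reports per-bipartition support
#' (percent of replicates) on the full-data tree as node labels.
#' Deterministic under a fixed seed.
#'
#' @param alignment equal-length sequences, >= 4 of them.
#' @param nReps number of pseudoreplicates (default 1000).
#' @param seed RNG seed (default 1).
#' @param cap saturation cap passed to [jcDistanceMatrix()] so that extreme
#'   resamples remain computable (default 5).
#' @return the full-data [ape::phylo] with `node.label` = support percent.
#' @export
bootstrapSupport <- function(alignment, nReps = 1000, seed = 1, cap = 5) {
  if (nReps < 1) stop("nReps must be >= 1")
  m <- .alnMatrix(alignment)
  if (nrow(m) < 4) stop("need >= 4 sequences")
  full <- bionjTree(jcDistanceMatrix(m, cap = cap))
  # root on the first tip so that clade queries (MRCA lookups) behave; the
  # bipartition counting itself stays unrooted
  full <- ape::root(full, outgroup = full$tip.label[1], resolve.root = TRUE)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(nReps), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      bionjTree(jcDistanceMatrix(m[, cols, drop = FALSE], cap = cap))
    })
  })
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- as.character(round(100 * counts / nReps, 1))
  attr(full, "support") <- 100 * counts / nReps
  full
}

#' Bootstrap support of the clade containing a given tip set
#'
#' Convenience accessor: support (percent) attached to the most recent
#' common ancestor of `tips` in a tree produced by [bootstrapSupport()].
#'
#' @param tree tree with `support` attribute / node labels.
#' @param tips character vector of tip labels.
#' @return numeric support in percent (NA for the root).
#' @export
cladeSupport <- function(tree, tips) {
  sup <- attr(tree, "support")
  node <- tryCatch(ape::getMRCA(tree, tips), error = function(e) NA_integer_)
  if (is.na(node) || node == length(tree$tip.label) + 1L) return(NA_real_)
  sup[node - length(tree$tip.label)]
}
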