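#' @include AllClasses.R
NULL

# Synthetic reference 5.8S rRNA gene (155 nt) used as the default location /
# comparison profile. It embeds the three conserved angiosperm 5.8S motifs at
# fixed positions; everything between them is an arbitrary fixed filler. It is
# a package-constructed stand-in, not a database sequence, and is replaceable
# through the `ref` arguments / run configuration.
.REF_58S <- paste0(
  "ACTCTCGGCAACGG",            # 1-14
  "CGATGAAGAACGCAGC",          # 15-30  motif M1
  "ATATCTCGGCTCTCGCATCGATGA",  # 31-54
  "GAATTGCAGAATCC",            # 55-68  motif M2
  "AGCGCCAAGGAACATACCTGCCGAGTCTCGCCGGTT",  # 69-104
  "TTTGAACGCA",                # 105-114 motif M3
  "GGATCGCATCTTGGCCCTCGGATCAGAAGGACTCGAGGGCA"  # 115-155
)

.MOTIFS <- c(M1 = "CGATGAAGAACGCAGC",
             M2 = "GAATTGCAGAATCC",
             M3 = "TTTGAACGCA")

#' Default reference 5.8S sequence (synthetic)
#'
#' A 155-nt synthetic 5.8S reference constructed by the package: the three
#' conserved angiosperm 5.8S motifs (see [conservedMotifs()]) embedded in
#' fixed filler sequence. Serves as the default profile for locating the
#' 5.8S gene, reporting motif changes and comparing secondary structure; any
#' real 5.8S sequence containing the motifs can be supplied in its place.
#'
#' @return character scalar (155 nt).
#' @export
referenceFiveEightS <- function() .REF_58S

#' The three conserved 5.8S motifs
#'
#' Default motif set scanned in the 5.8S gene, the conserved angiosperm
#' motifs M1 (16 nt), M2 (14 nt) and M3 (10 nt). Positions in motif reports
#' are 1-based within each motif ("nt-9" = ninth motif base).
#'
#' @return named character vector of length 3.
#' @export
conservedMotifs <- function() .MOTIFS

.asDNAString <- function(seq) {
  if (is(seq, "DNAString")) return(seq)
  Biostrings::DNAString(toupper(as.character(seq)))
}

# substitution matrix shared by the semi-global / global 5.8S alignments
.subMat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

#' Delineate ITS1, 5.8S and ITS2 within a clone sequence
#'
#' Locates the 5.8S gene by the best semi-global alignment of a reference
#' 5.8S profile against the sequence; ITS1 is everything upstream of the
#' 5.8S start (optionally trimmed at an 18S anchor) and ITS2 everything
#' downstream of its end (optionally trimmed at a 26S anchor). A 5.8S whose
#' alignment to the reference shows internal deletions is flagged as
#' deletion-bearing.
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]), >= 400 nt.
#' @param ref reference 5.8S sequence (default [referenceFiveEightS()]).
#' @param minIdentity minimum fraction of reference positions matched for the
#'   location to be accepted (default 0.70).
#' @param anchor18S,anchor26S optional flanking-gene anchor sequences; when
#'   found (up to 2 mismatches) the spacers are trimmed at them.
#' @return an [ITSAnnotation-class].
#' @examples
#' fam <- genITSFamily(seed = 1)
#' ann <- delineateRegions(fam$reads[[1]])
#' regionSpans(ann)
#' @export
delineateRegions <- function(seq, ref = referenceFiveEightS(),
                             minIdentity = 0.70,
                             anchor18S = NULL, anchor26S = NULL) {
  s <- .asDNAString(seq)
  if (length(s) < 400)
    stop("unannotatable: sequence shorter than 400 nt")
  # gap penalties below the cost of two mismatches, so short deletions are
  # represented as gaps instead of being absorbed into flanking mismatches
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ref), subject = s,
    type = "global-local", substitutionMatrix = .subMat(),
    gapOpening = 1, gapExtension = 1)
  ident <- Biostrings::nmatch(aln) / nchar(ref)
  if (ident < minIdentity)
    stop("unannotatable: best 5.8S alignment identity ",
         sprintf("%.2f", ident), " below ", minIdentity)
  r <- aln@subject@range
  s58 <- IRanges::start(r)
  e58 <- IRanges::end(r)
  # refine the span against the reference: a semi-global location can absorb
  # a few spacer bases in place of a short internal deletion
  ref58 <- .alignTo58S(ref, Biostrings::subseq(s, s58, e58))
  e58 <- s58 + ref58$lastAligned - 1L
  s58 <- s58 + ref58$firstAligned - 1L
  # deletion-bearing = internal reference positions lost in the alignment
  alignedIdx <- which(ref58$refPos > 0L)
  internal <- seq(alignedIdx[1], alignedIdx[length(alignedIdx)])
  hasDeletion <- any(ref58$refPos[internal] == 0L)
  i1s <- 1L
  i2e <- length(s)
  if (!is.null(anchor18S)) {
    hit <- Biostrings::matchPattern(Biostrings::DNAString(anchor18S),
                                    Biostrings::subseq(s, 1L, s58 - 1L),
                                    max.mismatch = 2)
    if (length(hit)) i1s <- IRanges::end(hit)[length(hit)] + 1L
  }
  if (!is.null(anchor26S)) {
    hit <- Biostrings::matchPattern(Biostrings::DNAString(anchor26S),
                                    Biostrings::subseq(s, e58 + 1L),
                                    max.mismatch = 2)
    if (length(hit)) i2e <- e58 + IRanges::start(hit)[1] - 1L
  }
  if (i1s > s58 - 1L || e58 + 1L > i2e)
    stop("unannotatable: empty spacer span")
  new("ITSAnnotation", sequence = s,
      its1 = IRanges::IRanges(i1s, s58 - 1L),
      r58s = IRanges::IRanges(s58, e58),
      its2 = IRanges::IRanges(e58 + 1L, i2e),
      deletionFlagged = hasDeletion)
}

#' GC content of a sequence, in percent
#'
#' `100 * (G + C + S) / (length - N)`: the ambiguous S code counts as G/C
#' and fully ambiguous N positions are excluded from the denominator.
#'
#' @param seq character or [Biostrings::DNAString].
#' @return percentage in `[0, 100]` (full precision; callers format to two
#'   decimals for reporting).
#' @examples
#' gcContent("ATGC")  # 50
#' @export
gcContent <- function(seq) {
  s <- .asDNAString(seq)
  if (length(s) == 0) stop("empty sequence")
  f <- Biostrings::letterFrequency(s, c("G", "C", "S", "N"))
  denom <- length(s) - f[["N"]]
  if (denom == 0) stop("no unambiguous bases")
  100 * (f[["G"]] + f[["C"]] + f[["S"]]) / denom
}

# Global alignment of the observed 5.8S region to the reference; returns the
# observed base (or "-") at each reference position plus the first/last
# observed positions aligned to the reference (to trim stray spacer bases).
.alignTo58S <- function(ref, obs) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ref),
    subject = if (is(obs, "DNAString")) obs else Biostrings::DNAString(obs),
    type = "global", substitutionMatrix = .subMat(),
    gapOpening = 1, gapExtension = 1)
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  refChar <- character(nchar(ref))
  refPos <- integer(nchar(ref))  # observed position per ref position, 0 = gap
  rp <- qp <- 0L
  for (i in seq_along(ap)) {
    if (as_[i] != "-") qp <- qp + 1L
    if (ap[i] != "-") {
      rp <- rp + 1L
      refChar[rp] <- as_[i]
      refPos[rp] <- if (as_[i] != "-") qp else 0L
    }
  }
  aligned <- refPos[refPos > 0L]
  list(refChar = refChar, refPos = refPos,
       firstAligned = if (length(aligned)) aligned[1] else 1L,
       lastAligned = if (length(aligned)) aligned[length(aligned)] else 0L)
}

#' Scan the conserved 5.8S motifs of an annotated sequence
#'
#' The observed 5.8S region is aligned globally to the reference 5.8S and
#' each motif's reference positions are read through the alignment.
#' Substitutions are reported in the table notation `nt-9 'A'` (1-based
#' position within the motif, observed base); deleted stretches as
#' `nt1-nt3 'deletion'`. A motif with at least half of its positions deleted
#' is reported as `not present-deletion`.
#'
#' @param annotation an [ITSAnnotation-class] (or a 5.8S sequence directly).
#' @param motifs named character vector of motifs (default
#'   [conservedMotifs()]); all must occur verbatim in `ref`.
#' @param ref reference 5.8S (default [referenceFiveEightS()]).
#' @return data.frame with columns `motif`, `status` (`conserved`, `changed`
#'   or `not present-deletion`), `changes` (`;`-joined notation, empty when
#'   conserved) and `n_changed` (substituted + deleted positions; a fully
#'   absent motif counts its whole length).
#' @export
scan58SMotifs <- function(annotation, motifs = conservedMotifs(),
                          ref = referenceFiveEightS()) {
  obs <- if (is(annotation, "ITSAnnotation")) regionSeq(annotation, "r58s")
         else .asDNAString(annotation)
  if (length(obs) == 0) stop("5.8S span missing")
  refChar <- .alignTo58S(ref, obs)$refChar
  rows <- lapply(names(motifs), function(nm) {
    motif <- motifs[[nm]]
    at <- regexpr(motif, ref, fixed = TRUE)[1]
    if (at < 0) stop("motif ", nm, " not present in the reference 5.8S")
    L <- nchar(motif)
    obsM <- refChar[at:(at + L - 1L)]
    refM <- strsplit(motif, "")[[1]]
    deleted <- obsM == "-"
    subs <- which(!deleted & obsM != refM)
    if (sum(deleted) >= L / 2) {
      return(data.frame(motif = nm, status = "not present-deletion",
                        changes = "", n_changed = L))
    }
    notes <- character()
    if (any(deleted)) {
      runs <- rle(deleted)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(runs$values)) {
        notes <- c(notes, if (starts[r] == ends[r])
          sprintf("nt-%d 'deletion'", starts[r])
          else sprintf("nt%d-nt%d 'deletion'", starts[r], ends[r]))
      }
    }
    notes <- c(notes, sprintf("nt-%d '%s'", subs, obsM[subs]))
    data.frame(motif = nm,
               status = if (length(notes)) "changed" else "conserved",
               changes = paste(notes, collapse = ";"),
               n_changed = length(subs) + sum(deleted))
  })
  do.call(rbind, rows)
}
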