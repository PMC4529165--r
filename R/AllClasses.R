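#' @include musakit-package.R
NULL

# ---------------------------------------------------------------------------
# FluorHistogram
# ---------------------------------------------------------------------------

#' Binned fluorescence histogram from one flow-cytometry run
#'
#' Container for a relative-fluorescence histogram of propidium-iodide stained
#' nuclei, typically holding two dominant G1 peaks: the sample and the
#' co-chopped internal reference standard.
#'
#' @slot binEdges numeric, strictly increasing channel boundaries (arbitrary
#'   fluorescence units); one more edge than there are counts.
#' @slot counts numeric, non-negative event counts per bin.
#' @slot label character scalar sample identifier.
#'
#' @export
setClass("FluorHistogram",
  representation(binEdges = "numeric", counts = "numeric", label = "character"),
  prototype(label = NA_character_)
)

setValidity("FluorHistogram", function(object) {
  msg <- character()
  if (length(object@counts) < 2) msg <- c(msg, "need at least 2 bins")
  if (length(object@binEdges) != length(object@counts) + 1)
    msg <- c(msg, "length(binEdges) must equal length(counts) + 1")
  if (any(diff(object@binEdges) <= 0))
    msg <- c(msg, "binEdges must be strictly increasing")
  if (any(object@counts < 0) || anyNA(object@counts))
    msg <- c(msg, "counts must be non-negative and non-missing")
  if (length(msg)) msg else TRUE
})

#' Construct a FluorHistogram
#'
#' @param binEdges strictly increasing channel boundaries (length = bins + 1).
#' @param counts non-negative event counts per bin.
#' @param label sample identifier.
#' @return A [FluorHistogram-class] object.
#' @examples
#' h <- FluorHistogram(0:10, c(0, 1, 5, 9, 5, 1, 0, 0, 2, 0), "demo")
#' binCenters(h)
#' @export
FluorHistogram <- function(binEdges, counts, label = NA_character_) {
  new("FluorHistogram", binEdges = as.numeric(binEdges),
      counts = as.numeric(counts), label = as.character(label)[1])
}

#' @describeIn FluorHistogram-class midpoints of the fluorescence bins
#' @param x a `FluorHistogram`
#' @export
binCenters <- function(x) {
  stopifnot(is(x, "FluorHistogram"))
  (x@binEdges[-1] + x@binEdges[-length(x@binEdges)]) / 2
}

#' @describeIn FluorHistogram-class per-bin event counts
#' @export
histCounts <- function(x) {
  stopifnot(is(x, "FluorHistogram"))
  x@counts
}

setMethod("show", "FluorHistogram", function(object) {
  cat("FluorHistogram '", object@label, "': ", length(object@counts),
      " bins over [", object@binEdges[1], ", ",
      object@binEdges[length(object@binEdges)], "], ",
      sum(object@counts), " events\n", sep = "")
})

# ---------------------------------------------------------------------------
# SSRPanel
# ---------------------------------------------------------------------------

#' Microsatellite allele-size profiles for a set of accessions
#'
#' Holds, per accession and per SSR locus, the set of scored allele sizes
#' (fragment lengths in bp). A single observed size at a locus is taken as
#' homozygous; a missing locus is an empty integer vector.
#'
#' @slot calls named list (one element per accession) of named lists
#'   (locus -> integer vector of allele sizes).
#'
#' @export
setClass("SSRPanel", representation(calls = "list"))

setValidity("SSRPanel", function(object) {
  msg <- character()
  if (is.null(names(object@calls)) || anyDuplicated(names(object@calls)))
    msg <- c(msg, "accessions must be uniquely named")
  for (acc in names(object@calls)) {
    prof <- object@calls[[acc]]
    if (!is.list(prof) || is.null(names(prof)))
      msg <- c(msg, paste0("profile of '", acc, "' must be a named list"))
    else {
      if (length(prof) < 1 || length(prof) > 19)
        msg <- c(msg, paste0("'", acc, "': expected 1-19 loci"))
      sizes <- unlist(prof, use.names = FALSE)
      if (length(sizes) && (anyNA(sizes) || any(sizes <= 0)))
        msg <- c(msg, paste0("'", acc, "': allele sizes must be positive"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an SSRPanel
#'
#' @param calls named list per accession; each element a named list mapping
#'   locus to an integer vector of allele sizes (bp). Loci with more than two
#'   alleles are kept but flagged with a warning (diploids are expected to
#'   carry at most two).
#' @return An [SSRPanel-class] object.
#' @examples
#' p <- SSRPanel(list(
#'   acc1 = list(L1 = c(100L, 102L), L2 = 150L),
#'   acc2 = list(L1 = 100L, L2 = 154L)))
#' panelLoci(p)
#' @export
SSRPanel <- function(calls) {
  calls <- lapply(calls, function(prof) lapply(prof, function(a)
    sort(unique(as.integer(a)))))
  obj <- new("SSRPanel", calls = calls)
  k <- vapply(unlist(calls, recursive = FALSE), length, 1L)
  if (any(k > 2))
    warning(sum(k > 2), " locus call(s) with more than 2 alleles (kept)")
  obj
}

#' @describeIn SSRPanel-class accession labels
#' @param x an `SSRPanel`
#' @export
panelAccessions <- function(x) {
  stopifnot(is(x, "SSRPanel"))
  names(x@calls)
}

#' @describeIn SSRPanel-class union of locus names across accessions
#' @export
panelLoci <- function(x) {
  stopifnot(is(x, "SSRPanel"))
  unique(unlist(lapply(x@calls, names), use.names = FALSE))
}

#' @describeIn SSRPanel-class allele calls of one accession
#' @param accession accession label
#' @export
panelCalls <- function(x, accession) {
  stopifnot(is(x, "SSRPanel"))
  x@calls[[accession]]
}

setMethod("show", "SSRPanel", function(object) {
  cat("SSRPanel: ", length(object@calls), " accessions, ",
      length(panelLoci(object)), " loci\n", sep = "")
})

# ---------------------------------------------------------------------------
# ITSAnnotation
# ---------------------------------------------------------------------------

#' Region annotation of an ITS1-5.8S-ITS2 sequence
#'
#' Stores the spans of the two internal transcribed spacers and the 5.8S rRNA
#' gene within one clone sequence. Spans are 1-based closed intervals
#' ([IRanges::IRanges]), disjoint and ordered ITS1 < 5.8S < ITS2. A 5.8S
#' whose alignment against the reference gene shows internal deletions is
#' flagged as deletion-bearing (its span is then shorter than the canonical
#' 153/155 bp).
#'
#' @slot sequence a [Biostrings::DNAString] (uppercase IUPAC).
#' @slot its1,r58s,its2 [IRanges::IRanges] of length 1 each.
#' @slot deletionFlagged logical; `TRUE` when the 5.8S carries deletions
#'   relative to the reference.
#'
#' @export
setClass("ITSAnnotation",
  representation(sequence = "DNAString", its1 = "IRanges", r58s = "IRanges",
                 its2 = "IRanges", deletionFlagged = "logical"))

setValidity("ITSAnnotation", function(object) {
  msg <- character()
  spans <- list(its1 = object@its1, r58s = object@r58s, its2 = object@its2)
  if (any(vapply(spans, length, 1L) != 1))
    msg <- c(msg, "each span must be a single range")
  else {
    s <- vapply(spans, IRanges::start, 1L)
    e <- vapply(spans, IRanges::end, 1L)
    if (!(e[1] < s[2] && e[2] < s[3]))
      msg <- c(msg, "spans must be ordered ITS1 < 5.8S < ITS2")
    if (e[1] + 1L != s[2] || e[2] + 1L != s[3])
      msg <- c(msg, "spans must tile the annotated core contiguously")
    if (any(s < 1) || any(e > length(object@sequence)))
      msg <- c(msg, "spans outside the sequence")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ITSAnnotation-class extract a region's sequence
#' @param x an `ITSAnnotation`
#' @param region one of "its1", "r58s", "its2"
#' @export
regionSeq <- function(x, region = c("its1", "r58s", "its2")) {
  stopifnot(is(x, "ITSAnnotation"))
  region <- match.arg(region)
  r <- slot(x, region)
  Biostrings::subseq(x@sequence, IRanges::start(r), IRanges::end(r))
}

#' @describeIn ITSAnnotation-class region spans as an IRanges with names
#' @export
regionSpans <- function(x) {
  stopifnot(is(x, "ITSAnnotation"))
  out <- c(x@its1, x@r58s, x@its2)
  names(out) <- c("its1", "r58s", "its2")
  out
}

setMethod("show", "ITSAnnotation", function(object) {
  w <- IRanges::width(c(object@its1, object@r58s, object@its2))
  cat("ITSAnnotation: ", length(object@sequence), " nt; ITS1 ", w[1],
      " nt, 5.8S ", w[2], " nt, ITS2 ", w[3], " nt",
      if (object@deletionFlagged) " [5.8S deletion-bearing]", "\n", sep = "")
})

# ---------------------------------------------------------------------------
# ITSType
# ---------------------------------------------------------------------------

#' One ITS sequence type of an accession, with all derived features
#'
#' The per-type record mirrors the feature set used to call ribosomal-DNA
#' pseudogenes: per-region GC content, the state of the three conserved 5.8S
#' motifs, the ITS2 and 5.8S secondary-structure results, and the resulting
#' pseudogene flag with its reasons.
#'
#' @slot accession,typeId character identifiers.
#' @slot annotation an [ITSAnnotation-class].
#' @slot gcITS1,gc58S,gcITS2 numeric GC percentages.
#' @slot motifReport data.frame from [scan58SMotifs()].
#' @slot foldITS2,fold58S lists from [foldITS2()] / [fold58S()].
#' @slot pseudogene logical putative-pseudogene flag.
#' @slot reasons character, criteria that triggered the flag.
#' @slot nReads integer, clone reads collapsed into this type.
#'
#' @export
setClass("ITSType",
  representation(accession = "character", typeId = "character",
                 annotation = "ITSAnnotation", gcITS1 = "numeric",
                 gc58S = "numeric", gcITS2 = "numeric",
                 motifReport = "data.frame", foldITS2 = "list",
                 fold58S = "list", pseudogene = "logical",
                 reasons = "character", nReads = "integer"))

setValidity("ITSType", function(object) {
  gc <- c(object@gcITS1, object@gc58S, object@gcITS2)
  if (any(gc < 0 | gc > 100)) "GC content must be within [0, 100]" else TRUE
})

setMethod("show", "ITSType", function(object) {
  cat("ITSType ", object@accession, "/", object@typeId, " (", object@nReads,
      " reads): GC ", sprintf("%.2f/%.2f/%.2f", object@gcITS1, object@gc58S,
      object@gcITS2), "; ITS2 ",
      if (isTRUE(object@foldITS2$formed)) "four-helices" else "not formed",
      "; 5.8S ",
      if (isTRUE(object@fold58S$formed)) "conserved" else "not formed",
      if (object@pseudogene) "; PSEUDOGENE" else "", "\n", sep = "")
})

#' @describeIn ITSType-class pseudogene flag
#' @param x an `ITSType`
#' @export
isPseudogene <- function(x) {
  stopifnot(is(x, "ITSType"))
  x@pseudogene
}
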