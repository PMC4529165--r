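#' @include its-fold.R
NULL

#' Simulate a two-peak flow-cytometry histogram
#'
#' Emulates the histogram of a chopped sample + internal-standard run: two
#' Gaussian G1 peaks at channel positions proportional to the 2C DNA values
#' (the standard sits at `standardChannel`), Poisson counting noise per bin,
#' and an optional uniform debris continuum. Deterministic under `seed`.
#'
#' @param true2C sample 2C DNA content in pg (default 1.217).
#' @param standard2C internal-standard 2C in pg (default 2.5, soybean).
#' @param cv coefficient of variation of both G1 peaks, percent (> 0).
#' @param nNuclei expected nuclei per G1 peak (default 5000).
#' @param debrisFraction fraction of all events that are uniform debris,
#'   in `[0, 0.5)` (default 0.02).
#' @param nBins number of channels (default 1024, linear scale).
#' @param standardChannel channel of the standard G1 peak (default 500).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return list with `histogram` ([FluorHistogram-class]) and `truth`
#'   (generating peak channels and 2C values).
#' @examples
#' sim <- genFlowHistogram(seed = 7)
#' sim$truth$musaChannel
#' @export
genFlowHistogram <- function(true2C = 1.217, standard2C = 2.5, cv = 2,
                             nNuclei = 5000, debrisFraction = 0.02,
                             nBins = 1024, standardChannel = 500,
                             seed = NULL) {
  stopifnot(true2C > 0, standard2C > 0, cv > 0,
            debrisFraction >= 0, debrisFraction < 0.5, nBins >= 16)
  musaChannel <- standardChannel * true2C / standard2C
  sep <- abs(musaChannel - standardChannel)
  if (sep < 2 * (cv / 100) * max(musaChannel, standardChannel))
    warning("unresolvable spec: peaks within 2 CV of each other")
  edges <- 0:nBins
  lam <- function(mu) {
    s <- (cv / 100) * mu
    nNuclei * diff(pnorm(edges, mu, s))
  }
  lambda <- lam(musaChannel) + lam(standardChannel)
  if (debrisFraction > 0) {
    debris <- debrisFraction / (1 - debrisFraction) * 2 * nNuclei
    lambda <- lambda + debris / nBins
  }
  draw <- function() rpois(nBins, lambda)
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(histogram = FluorHistogram(edges, counts,
         label = sprintf("sim2C_%.3fpg", true2C)),
       truth = list(musaChannel = musaChannel,
                    standardChannel = standardChannel,
                    true2C = true2C, standard2C = standard2C))
}

#' Estimate 2C DNA content from a two-peak histogram
#'
#' Detects the two dominant G1 peaks and applies the internal-standard ratio
#' formula. By default the standard is taken as the upper peak (sample
#' genomes smaller than the standard, the usual soybean setup).
#'
#' @param hist a [FluorHistogram-class] with sample + standard peaks.
#' @param standard2C standard 2C in pg (default 2.5).
#' @param standardPeak `"upper"` (default) or `"lower"`.
#' @param ... passed to [detectG1Peaks()].
#' @return list with `two_c_pg`, `peaks` (the fit table).
#' @export
estimate2C <- function(hist, standard2C = 2.5,
                       standardPeak = c("upper", "lower"), ...) {
  standardPeak <- match.arg(standardPeak)
  pk <- detectG1Peaks(hist, 2, ...)
  std <- if (standardPeak == "upper") pk$mean[2] else pk$mean[1]
  smp <- if (standardPeak == "upper") pk$mean[1] else pk$mean[2]
  list(two_c_pg = compute2C(smp, std, standard2C), peaks = pk)
}

#' Simulate an SSR panel with planted group structure
#'
#' Each locus has a pool of allele sizes partitioned into group-characteristic
#' subsets; an accession draws its alleles from its group's subset with
#' probability `withinSharing` and from the whole pool otherwise. With
#' probability `betweenSharing` a group's subset at a locus is replaced by
#' group 1's (inter-group allele sharing). Deterministic under `seed`.
#'
#' @param nGroups number of planted groups (default 2).
#' @param accessionsPerGroup accessions per group (default 5).
#' @param nLoci number of SSR loci (default 19).
#' @param allelesPerLocus allele-pool size per locus (default 6; at least
#'   `2 * nGroups` so subsets stay distinct).
#' @param withinSharing probability of drawing from the group subset
#'   (default 0.9).
#' @param betweenSharing probability a group shares group 1's subset at a
#'   locus (default 0.05); must be < `withinSharing`.
#' @param seed RNG seed.
#' @return list with `panel` ([SSRPanel-class]) and `truth` (named group
#'   labels).
#' @examples
#' sim <- genSSRPanel(seed = 1)
#' table(sim$truth$groups)
#' @export
genSSRPanel <- function(nGroups = 2, accessionsPerGroup = 5, nLoci = 19,
                        allelesPerLocus = 6, withinSharing = 0.9,
                        betweenSharing = 0.05, seed = 1) {
  stopifnot(withinSharing >= 0, withinSharing <= 1,
            betweenSharing >= 0, betweenSharing <= 1,
            withinSharing > betweenSharing,
            allelesPerLocus >= 2 * nGroups)
  withr::with_seed(seed, {
    loci <- sprintf("L%02d", seq_len(nLoci))
    pool <- lapply(seq_len(nLoci), function(l)
      100L + 10L * l + 2L * (0:(allelesPerLocus - 1)))
    per <- allelesPerLocus %/% nGroups
    subsets <- lapply(seq_len(nLoci), function(l) {
      s <- lapply(seq_len(nGroups), function(g)
        pool[[l]][((g - 1) * per + 1):(g * per)])
      for (g in seq_len(nGroups)[-1])
        if (runif(1) < betweenSharing) s[[g]] <- s[[1]]
      s
    })
    calls <- list()
    groups <- character()
    for (g in seq_len(nGroups)) for (a in seq_len(accessionsPerGroup)) {
      acc <- sprintf("g%d_acc%d", g, a)
      prof <- list()
      for (l in seq_len(nLoci)) {
        k <- sample(1:2, 1)
        src <- if (runif(1) < withinSharing) subsets[[l]][[g]] else pool[[l]]
        prof[[loci[l]]] <- sample(src, min(k, length(src)))
      }
      calls[[acc]] <- prof
      groups[acc] <- paste0("group", g)
    }
    list(panel = SSRPanel(calls), truth = list(groups = groups))
  })
}

# ---------------------------------------------------------------------------
# ITS family simulation
# ---------------------------------------------------------------------------

# Fixed designed ITS2 template: four hairpins around a common exterior loop.
# Stems are distinct G/C words so the base-pair-maximization fold is the
# intended one; helix II carries a C/T 1x1 pyrimidine internal loop, helix
# III carries TGGT on its 5' strand; loops, linkers and tails are poly-A
# (unpairable against the G/C stems).
.designITS2 <- function(targetLength = 210) {
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  a1 <- "GCGGCCCGGC"
  b1 <- "CGGGCC"; b2 <- "GGGCGG"
  c1 <- "GCCTGGTCGCCG"
  d1 <- "GGCGGGGGGC"
  h1 <- paste0(a1, "AAAA", rc(a1))
  h2 <- paste0(b1, "C", b2, "AAAA", rc(b2), "T", rc(b1))
  h3 <- paste0(c1, "AAAAA", rc(c1))
  h4 <- paste0(d1, "AAAA", rc(d1))
  core <- paste0("AAAA", h1, "AAAAA", h2, "AAAAA", h3, "AAAAA", h4)
  pad <- targetLength - nchar(core)
  if (pad < 0) stop("targetLength too short for the designed topology")
  paste0(core, strrep("A", pad))
}

.randomSpacer <- function(len, gc = 0.60) {
  paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

.mutateAt <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

.randomSubstitutions <- function(seq, positions, n) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(positions, min(n, length(positions)))
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

#' Simulate an ITS clone family with planted types and ground truth
#'
#' Builds a functional ITS1-5.8S-ITS2 template — a random ITS1 spacer, the
#' reference 5.8S, and a designed ITS2 that folds into the canonical
#' four-helix topology (pyrimidine-pyrimidine loop in helix II, TGGT on the
#' 5' side of helix III) — then derives sequence types by applying edits:
#'
#' * `"functional"`: substitutions confined to ITS1 (divergent but intact),
#' * `"motif"`: targeted changes in the conserved 5.8S motifs,
#' * `"helix3_scramble"`: shuffles the 5' arm of ITS2 helix III (structure
#'   lost),
#' * `"gc_erosion"`: converts a fraction of 5.8S G/C to A/T (GC decay),
#' * `"deletion58S"`: removes bases inside the 5.8S (153-nt variant).
#'
#' Clone reads are sampled from the types with uniform substitution errors.
#' The truth record carries each type's sequence, its planted features
#' (motif changes, structure outcomes, 5.8S GC) and the pseudogene label
#' implied by [classifyPseudogeneFeatures()].
#'
#' @param seed RNG seed (generation is fully deterministic given it).
#' @param nTypes number of types when `typeSpecs` is not given (default 1);
#'   types beyond the first cycle through helix3_scramble, gc_erosion,
#'   motif and functional edits.
#' @param typeSpecs optional explicit list; each element a list with `edit`
#'   and its parameters (`nDiverge`, `rate`, `motifChanges`, `delStart`,
#'   `delLen`). Types after the first always receive `nDiverge` (default 10)
#'   ITS1 substitutions so that planted types stay distinct.
#' @param readsPerAccession total clone reads (default 28, split evenly).
#' @param errorRate per-base read substitution error (default 0.001).
#' @param its1Length,its2Length spacer lengths; defaults drawn from the
#'   canonical envelopes 215-223 and 205-218.
#' @param accession label prefix for read names.
#' @return list with `reads` ([Biostrings::DNAStringSet]) and `truth`.
#' @examples
#' fam <- genITSFamily(seed = 1, nTypes = 2)
#' fam$truth$types[[2]]$edit
#' @export
genITSFamily <- function(seed = 1, nTypes = 1, typeSpecs = NULL,
                         readsPerAccession = 28, errorRate = 0.001,
                         its1Length = NULL, its2Length = NULL,
                         accession = "acc") {
  withr::with_seed(seed, {
    if (is.null(its1Length)) its1Length <- sample(215:223, 1)
    if (is.null(its2Length)) its2Length <- sample(205:218, 1)
    stopifnot(its1Length >= 215, its1Length <= 223,
              its2Length >= 205, its2Length <= 218)
    its1 <- .randomSpacer(its1Length, gc = 0.60)
    r58s <- referenceFiveEightS()
    its2 <- .designITS2(its2Length)
    template <- paste0(its1, r58s, its2)
    s58 <- its1Length + 1L
    e58 <- its1Length + nchar(r58s)
    if (is.null(typeSpecs)) {
      cycle <- c("helix3_scramble", "gc_erosion", "motif", "functional")
      typeSpecs <- c(list(list(edit = "none")),
                     lapply(seq_len(max(0, nTypes - 1)), function(i)
                       list(edit = cycle[(i - 1) %% 4 + 1])))
    }
    types <- lapply(seq_along(typeSpecs), function(t)
      .applyTypeEdit(template, typeSpecs[[t]], s58, e58, t))
    # reads: split evenly, remainder to the first types
    k <- length(types)
    nr <- rep(readsPerAccession %/% k, k) +
      (seq_len(k) <= readsPerAccession %% k)
    reads <- character(0)
    rnames <- character(0)
    for (t in seq_len(k)) {
      for (r in seq_len(nr[t])) {
        s <- types[[t]]$sequence
        if (errorRate > 0) {
          nerr <- stats::rbinom(1, nchar(s), errorRate)
          if (nerr > 0)
            s <- .randomSubstitutions(s, seq_len(nchar(s)), nerr)
        }
        reads <- c(reads, s)
        rnames <- c(rnames, sprintf("%s_t%d_r%02d", accession, t, r))
      }
      types[[t]]$nReads <- nr[t]
    }
    out <- Biostrings::DNAStringSet(reads)
    names(out) <- rnames
    ord <- sample(length(out)) # shuffle read order
    list(reads = out[ord],
         truth = list(template = template,
                      its1Length = its1Length,
                      r58sLength = nchar(r58s),
                      its2Length = its2Length,
                      types = types, seed = seed))
  })
}

# apply one type edit; returns sequence + planted feature truth
.applyTypeEdit <- function(template, spec, s58, e58, typeIndex) {
  edit <- spec$edit %||% "none"
  seqs <- template
  motifChanges <- list()
  n <- nchar(template)
  its2Start <- e58 + 1L
  # every derived type carries its own ITS1 divergence so that distinct
  # planted types stay below the type-collapsing identity threshold
  if (typeIndex > 1L)
    seqs <- .randomSubstitutions(seqs, seq_len(s58 - 1L),
                                 spec$nDiverge %||% 10)
  if (edit == "functional" || edit == "substitutions") {
    # divergence above is the edit; nothing further
  } else if (edit == "motif") {
    changes <- spec$motifChanges %||% list(
      list(motif = "M2", pos = 9, base = "A"),
      list(motif = "M1", pos = 2, base = "A"))
    for (chg in changes) {
      motif <- conservedMotifs()[[chg$motif]]
      at <- regexpr(motif, referenceFiveEightS(), fixed = TRUE)[1]
      seqs <- .mutateAt(seqs, s58 + at - 1L + chg$pos - 1L, chg$base)
    }
    motifChanges <- changes
  } else if (edit == "helix3_scramble") {
    # disrupt both strands of the designed helix III stem with sequence that
    # cannot stack against the remaining G/C stems
    arm5 <- "GCCTGGTCGCCG"
    arm3 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(arm5)))
    for (arm in c(arm5, arm3)) {
      at <- regexpr(arm, seqs, fixed = TRUE)[1]
      stopifnot(at > 0)
      repl <- paste(sample(c("A", "C"), nchar(arm), replace = TRUE,
                           prob = c(0.7, 0.3)), collapse = "")
      substr(seqs, at, at + nchar(arm) - 1L) <- repl
    }
  } else if (edit == "gc_erosion") {
    rate <- spec$rate %||% 0.16
    ch <- strsplit(seqs, "")[[1]]
    idx <- s58:e58
    gcpos <- idx[ch[idx] %in% c("G", "C")]
    flip <- gcpos[runif(length(gcpos)) < rate]
    ch[flip] <- sample(c("A", "T"), length(flip), replace = TRUE)
    seqs <- paste(ch, collapse = "")
  } else if (edit == "deletion58S") {
    delStart <- spec$delStart %||% 40L
    delLen <- spec$delLen %||% 2L
    if (delLen >= e58 - s58) stop("edit exceeds 5.8S length")
    from <- s58 + delStart - 1L
    seqs <- paste0(substr(seqs, 1, from - 1L),
                   substr(seqs, from + delLen, n))
  } else if (edit != "none") {
    stop("unknown edit: ", edit)
  }
  r58sSeq <- if (edit == "deletion58S")
    substr(seqs, s58, e58 - (spec$delLen %||% 2L))
  else substr(seqs, s58, e58)
  gc58 <- gcContent(r58sSeq)
  nChanged <- if (edit == "motif") length(motifChanges) else 0L
  its2Formed <- !(edit == "helix3_scramble")
  f58 <- fold58S(r58sSeq)$formed
  cls <- classifyPseudogeneFeatures(gc58, nChanged, its2Formed, f58)
  list(typeIndex = typeIndex, edit = edit, sequence = seqs,
       motifChanges = motifChanges, gc58S = gc58,
       expectedITS2Formed = its2Formed, expected58SFormed = f58,
       pseudogene = cls$pseudogene)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
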