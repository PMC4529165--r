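#' @include AllClasses.R
NULL

#' Binary presence/absence coding of SSR allele profiles
#'
#' Each distinct (locus, allele size) pair observed anywhere in the panel
#' becomes one column; a cell is 1 when the accession carries that allele.
#' Loci not scored in an accession give an all-zero block and are recorded in
#' the `"missing"` attribute.
#'
#' @param panel an [SSRPanel-class].
#' @return integer 0/1 matrix, rows = accessions, columns named
#'   `"locus_size"`; attribute `"missing"` is a data.frame of unscored
#'   (accession, locus) pairs.
#' @examples
#' p <- SSRPanel(list(a = list(L1 = 100L), b = list(L1 = 102L)))
#' binarize(p)
#' @export
binarize <- function(panel) {
  stopifnot(is(panel, "SSRPanel"))
  accs <- panelAccessions(panel)
  loci <- panelLoci(panel)
  cols <- character()
  for (loc in loci) {
    sizes <- sort(unique(unlist(lapply(panel@calls, function(p) p[[loc]]))))
    cols <- c(cols, paste(loc, sizes, sep = "_"))
  }
  mat <- matrix(0L, length(accs), length(cols),
                dimnames = list(accs, cols))
  missing <- list()
  for (acc in accs) {
    prof <- panel@calls[[acc]]
    for (loc in loci) {
      a <- prof[[loc]]
      if (is.null(a) || !length(a)) {
        missing[[length(missing) + 1L]] <- data.frame(accession = acc,
                                                      locus = loc)
      } else {
        mat[acc, paste(loc, a, sep = "_")] <- 1L
      }
    }
  }
  attr(mat, "missing") <- if (length(missing)) do.call(rbind, missing)
    else data.frame(accession = character(), locus = character())
  mat
}

# per-locus allele frequencies of one accession: each carried allele 1/k
.alleleFreqs <- function(prof, loc) {
  a <- prof[[loc]]
  if (is.null(a) || !length(a)) return(NULL)
  setNames(rep(1 / length(a), length(a)), as.character(a))
}

#' Nei's genetic distance between SSR profiles
#'
#' Default is Nei's (1972) standard distance on per-accession allele
#' frequencies (a single scored allele is treated as homozygous, frequency 1;
#' two alleles get 1/2 each): with per-locus identities
#' `jx = sum px^2`, `jy = sum py^2`, `jxy = sum px*py` averaged over the loci
#' scored in both accessions, `D = -ln( Jxy / sqrt(Jx * Jy) )`. The
#' shared-band alternative (`method = "dice"`) is `1 - 2*shared/(nx + ny)`
#' over band presence. Pairs sharing no alleles anywhere have infinite
#' standard distance and are capped.
#'
#' @param panel an [SSRPanel-class].
#' @param method `"nei1972"` (default) or `"dice"`.
#' @param cap replacement for infinite distances (default 10); a warning is
#'   emitted when the cap is applied.
#' @return symmetric numeric matrix with zero diagonal.
#' @examples
#' p <- SSRPanel(list(a = list(L1 = 100L), b = list(L1 = c(100L, 102L))))
#' neiDistance(p)   # -ln(0.5 / sqrt(0.5)) = 0.3466
#' @export
neiDistance <- function(panel, method = c("nei1972", "dice"), cap = 10) {
  stopifnot(is(panel, "SSRPanel"))
  method <- match.arg(method)
  accs <- panelAccessions(panel)
  k <- length(accs)
  if (k < 2) stop("need >= 2 accessions")
  loci <- panelLoci(panel)
  d <- matrix(0, k, k, dimnames = list(accs, accs))
  capped <- FALSE
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pi_ <- panel@calls[[accs[i]]]
    pj <- panel@calls[[accs[j]]]
    if (method == "nei1972") {
      jx <- jy <- jxy <- numeric()
      for (loc in loci) {
        fx <- .alleleFreqs(pi_, loc)
        fy <- .alleleFreqs(pj, loc)
        if (is.null(fx) || is.null(fy)) next  # pairwise deletion
        alleles <- union(names(fx), names(fy))
        px <- setNames(rep(0, length(alleles)), alleles)
        py <- px
        px[names(fx)] <- fx
        py[names(fy)] <- fy
        jx <- c(jx, sum(px^2)); jy <- c(jy, sum(py^2))
        jxy <- c(jxy, sum(px * py))
      }
      if (!length(jx))
        stop("no shared scored loci between '", accs[i], "' and '",
             accs[j], "'")
      I <- mean(jxy) / sqrt(mean(jx) * mean(jy))
      val <- if (I <= 0) Inf else -log(I)
    } else {
      shared <- nx <- ny <- 0
      any_loc <- FALSE
      for (loc in loci) {
        ax <- pi_[[loc]]; ay <- pj[[loc]]
        if (is.null(ax) || !length(ax) || is.null(ay) || !length(ay)) next
        any_loc <- TRUE
        shared <- shared + length(intersect(ax, ay))
        nx <- nx + length(unique(ax)); ny <- ny + length(unique(ay))
      }
      if (!any_loc)
        stop("no shared scored loci between '", accs[i], "' and '",
             accs[j], "'")
      val <- 1 - 2 * shared / (nx + ny)
    }
    if (!is.finite(val)) { val <- cap; capped <- TRUE }
    d[i, j] <- d[j, i] <- val
  }
  if (capped)
    warning("infinite Nei distance(s) capped at ", cap)
  d
}

#' UPGMA dendrogram from a distance matrix
#'
#' Agglomerative clustering with size-weighted arithmetic-mean linkage,
#' yielding an ultrametric tree (root-to-tip depth = half the final merge
#' height).
#'
#' @param d symmetric distance matrix (or `dist`) with finite entries.
#' @return an [ape::phylo] tree.
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' ape::write.tree(upgmaTree(d))   # ((A:1,B:1):2,C:3)-shaped
#' @export
upgmaTree <- function(d) {
  dd <- as.dist(d)
  if (any(!is.finite(dd))) stop("non-finite distances")
  phangorn::upgma(dd)
}

# quote labels that would break newick syntax
.newickSafe <- function(labels) {
  bad <- grepl("[][ ():;,']", labels)
  labels[bad] <- paste0("'", gsub("'", "''", labels[bad]), "'")
  labels
}

#' Write a tree as a newick string or file
#'
#' Branch lengths are kept; labels containing newick-reserved characters
#' (spaces, parentheses, colons, ...) are single-quoted so the output
#' round-trips through standard readers.
#'
#' @param tree an [ape::phylo].
#' @param path optional file path; when omitted the newick string is
#'   returned invisibly-visibly (character scalar).
#' @return the newick string (invisibly when written to `path`).
#' @examples
#' tr <- upgmaTree(matrix(c(0, 2, 2, 0), 2, 2,
#'                        dimnames = list(c("A", "B"), c("A", "B"))))
#' writeNewick(tr)
#' @export
writeNewick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tmp <- tree
  # placeholders survive ape's own label munging; quoted originals are
  # substituted back into the string afterwards
  ph <- sprintf("MKTIP%06d", seq_along(tmp$tip.label))
  orig <- tmp$tip.label
  tmp$tip.label <- ph
  if (!is.null(tmp$node.label) && length(tmp$node.label)) {
    phn <- sprintf("MKNODE%06d", seq_along(tmp$node.label))
    orign <- tmp$node.label
    keep <- !is.na(orign) & nzchar(orign)
    tmp$node.label[keep] <- phn[keep]
  }
  s <- ape::write.tree(tmp)
  safe <- .newickSafe(orig)
  for (i in seq_along(ph)) s <- sub(ph[i], safe[i], s, fixed = TRUE)
  if (!is.null(tree$node.label) && length(tree$node.label)) {
    safen <- .newickSafe(orign)
    for (i in seq_along(phn)) if (keep[i])
      s <- sub(phn[i], safen[i], s, fixed = TRUE)
  }
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Read a newick tree
#'
#' @param text newick string (or `NULL` when reading from `path`).
#' @param path file path.
#' @return an [ape::phylo]; single-quoted labels are unquoted.
#' @export
readNewick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse newick")
  unq <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
    x
  }
  tr$tip.label <- unq(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unq(tr$node.label)
  tr
}

#' Maximum spread of root-to-tip depths of a tree
#'
#' Utility for checking ultrametricity: returns the difference between the
#' largest and smallest root-to-tip path length.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return numeric scalar (0 for a perfectly ultrametric tree).
#' @export
depthSpread <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  max(depths[seq_len(nt)]) - min(depths[seq_len(nt)])
}
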