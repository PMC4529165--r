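#' @include AllClasses.R
NULL

#' Read a FASTA file of DNA sequences
#'
#' Order-preserving wrapper that uppercases, accepts IUPAC ambiguity codes
#' and rejects empty records.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) stop("no records in ", path)
  empty <- which(Biostrings::width(x) == 0)
  if (length(empty))
    stop("zero-length record #", empty[1], " ('", names(x)[empty[1]],
         "') in ", path)
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- names(x)
  out
}

#' Write DNA sequences as FASTA
#'
#' @param x [Biostrings::DNAStringSet] or named character vector.
#' @param path output file.
#' @export
writeFasta <- function(x, path) {
  if (!is(x, "DNAStringSet"))
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a two-column histogram text file
#'
#' Accepts whitespace- or comma-separated `channel, count` rows (channel =
#' bin center on a linear scale with unit spacing assumed between centers).
#'
#' @param path text file.
#' @param label sample label (defaults to the file name).
#' @return a [FluorHistogram-class].
#' @export
readHistogramFile <- function(path, label = basename(path)) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- read.table(path, sep = sep, header = FALSE,
                   col.names = c("channel", "count"),
                   colClasses = c("numeric", "numeric"))
  centers <- df$channel
  if (any(diff(centers) <= 0)) stop("channels must be increasing")
  mids <- (centers[-1] + centers[-length(centers)]) / 2
  edges <- c(centers[1] - (mids[1] - centers[1]), mids,
             centers[length(centers)] +
               (centers[length(centers)] - mids[length(mids)]))
  FluorHistogram(edges, df$count, label)
}

#' Write a histogram as two-column text
#'
#' @param hist a [FluorHistogram-class].
#' @param path output file.
#' @param sep column separator (default comma).
#' @export
writeHistogramFile <- function(hist, path, sep = ",") {
  stopifnot(is(hist, "FluorHistogram"))
  df <- data.frame(channel = binCenters(hist), count = histCounts(hist))
  write.table(df, path, sep = sep, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an SSR allele table
#'
#' Accepts wide format (`accession, locus, allele1, allele2`, second allele
#' optional/NA for homozygotes) or long format (`accession, locus, allele`).
#'
#' @param path CSV file with header.
#' @return an [SSRPanel-class].
#' @export
readSSRTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("accession", "locus") %in% names(df)))
    stop("need 'accession' and 'locus' columns")
  acols <- grep("^allele", names(df), value = TRUE)
  if (!length(acols)) stop("need at least one allele column")
  calls <- list()
  for (r in seq_len(nrow(df))) {
    acc <- as.character(df$accession[r])
    loc <- as.character(df$locus[r])
    sizes <- stats::na.omit(as.integer(unlist(df[r, acols])))
    calls[[acc]][[loc]] <- sort(unique(c(calls[[acc]][[loc]], sizes)))
  }
  SSRPanel(calls)
}

#' Write an SSR panel as a long-format allele table
#'
#' @param panel an [SSRPanel-class].
#' @param path output CSV.
#' @export
writeSSRTable <- function(panel, path) {
  stopifnot(is(panel, "SSRPanel"))
  rows <- list()
  for (acc in panelAccessions(panel)) {
    prof <- panelCalls(panel, acc)
    for (loc in names(prof)) for (a in prof[[loc]])
      rows[[length(rows) + 1L]] <- data.frame(accession = acc, locus = loc,
                                              allele = a)
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix (CSV or PHYLIP square)
#'
#' @param d symmetric labelled matrix.
#' @param path output file.
#' @param format `"csv"` (default) or `"phylip"`.
#' @export
writeDistanceMatrix <- function(d, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  d <- as.matrix(d)
  if (format == "csv") {
    write.csv(d, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d)))
      writeLines(paste(formatC(substr(rownames(d)[i], 1, 10), width = -10),
                       paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a distance matrix written by [writeDistanceMatrix()]
#'
#' @param path input file.
#' @param format `"csv"` (default) or `"phylip"`.
#' @return symmetric numeric matrix.
#' @export
readDistanceMatrix <- function(path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
  } else {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[1]))
    parts <- strsplit(trimws(lines[1 + seq_len(n)]), "[ \t]+")
    labs <- vapply(parts, `[`, "", 1)
    m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
    dimnames(m) <- list(labs, labs)
  }
  storage.mode(m) <- "double"
  m
}

#' Run configuration with the pipeline's tunable thresholds
#'
#' Collects every threshold the analysis stages honour, so that a run can be
#' reproduced from its manifest. All values are echoed into the manifest by
#' [writeReports()].
#'
#' @param alpha Bonferroni familywise level (default 0.01).
#' @param standard2C internal-standard 2C in pg (default 2.5).
#' @param gcFloor,changesFloor pseudogene thresholds (defaults 48, 5).
#' @param identityThreshold ITS type-collapsing identity (default 0.99).
#' @param distanceCap cap for infinite Nei distances (default 10).
#' @param minIdentity58S 5.8S location identity threshold (default 0.70).
#' @param ref58S reference 5.8S sequence.
#' @param motifs named conserved-motif vector.
#' @param seed RNG seed recorded for the run.
#' @param outDir output directory.
#' @return a list of class `"runConfig"`.
#' @export
runConfig <- function(alpha = 0.01, standard2C = 2.5, gcFloor = 48,
                      changesFloor = 5, identityThreshold = 0.99,
                      distanceCap = 10, minIdentity58S = 0.70,
                      ref58S = referenceFiveEightS(),
                      motifs = conservedMotifs(), seed = 1,
                      outDir = ".") {
  stopifnot(alpha > 0, alpha < 1, gcFloor >= 0, gcFloor <= 100,
            changesFloor >= 1, identityThreshold > 0, identityThreshold <= 1,
            distanceCap > 0, minIdentity58S > 0, minIdentity58S <= 1)
  structure(list(alpha = alpha, standard2C = standard2C, gcFloor = gcFloor,
                 changesFloor = changesFloor,
                 identityThreshold = identityThreshold,
                 distanceCap = distanceCap, minIdentity58S = minIdentity58S,
                 ref58S = ref58S, motifs = as.list(motifs), seed = seed,
                 outDir = outDir),
            class = "runConfig")
}

#' Write a run configuration to a YAML file
#'
#' @param config a [runConfig()] list.
#' @param path output file.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "runConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration written by [writeRunConfig()]
#'
#' @param path YAML file.
#' @return a `runConfig` list (validated through [runConfig()]).
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(runConfig, c(x[setdiff(names(x), "motifs")],
                       list(motifs = unlist(x$motifs))))
}

# serialize one ITSType record as a report row mirroring the published
# feature-table layout
.typeRow <- function(rec) {
  mot <- rec@motifReport
  cell <- function(i) {
    if (mot$status[i] == "conserved") "conserved"
    else if (mot$status[i] == "not present-deletion") "not present-deletion"
    else mot$changes[i]
  }
  data.frame(
    accession = rec@accession, its_type = rec@typeId,
    gc_its1 = sprintf("%.2f", rec@gcITS1),
    gc_58s = sprintf("%.2f", rec@gc58S),
    gc_its2 = sprintf("%.2f", rec@gcITS2),
    motif_m1 = cell(1), motif_m2 = cell(2), motif_m3 = cell(3),
    its2_structure = if (isTRUE(rec@foldITS2$formed)) "four-helices"
                     else "not formed",
    r58s_structure = if (isTRUE(rec@fold58S$formed)) "conserved"
                     else "not formed",
    note = if (rec@pseudogene) "pseudogene" else "",
    n_reads = rec@nReads)
}

#' Write analysis reports, trees and a reproducibility manifest
#'
#' Emits a per-type feature CSV (published-table layout: GC percentages to
#' two decimals, motif changes in `nt-9 'A'` notation, structure columns,
#' pseudogene note), newick files for any trees, an optional diversity CSV,
#' and a JSON manifest recording the configuration, package version and
#' seed. The manifest is written last, so its presence marks a complete run.
#'
#' @param types list of [ITSType-class] records (may be empty).
#' @param trees named list of [ape::phylo] trees (may be empty).
#' @param stats optional data.frame of diversity statistics.
#' @param outDir output directory (created if needed).
#' @param config a [runConfig()]; defaults echo every threshold.
#' @return invisibly, the manifest path.
#' @export
writeReports <- function(types = list(), trees = list(), stats = NULL,
                         outDir = ".", config = runConfig()) {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory ", outDir)
  probe <- file.path(outDir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop("output directory not writable: ", outDir)
  unlink(probe)
  written <- character()
  typesCsv <- file.path(outDir, "its_types.csv")
  if (length(types)) {
    rows <- do.call(rbind, lapply(types, .typeRow))
  } else {
    rows <- data.frame(accession = character(), its_type = character(),
                       gc_its1 = character(), gc_58s = character(),
                       gc_its2 = character(), motif_m1 = character(),
                       motif_m2 = character(), motif_m3 = character(),
                       its2_structure = character(),
                       r58s_structure = character(), note = character(),
                       n_reads = integer())
  }
  write.csv(rows, typesCsv, row.names = FALSE)
  written <- c(written, typesCsv)
  for (nm in names(trees)) {
    p <- file.path(outDir, paste0(nm, ".nwk"))
    writeNewick(trees[[nm]], p)
    written <- c(written, p)
  }
  if (!is.null(stats)) {
    p <- file.path(outDir, "diversity.csv")
    write.csv(stats, p, row.names = FALSE)
    written <- c(written, p)
  }
  manifest <- file.path(outDir, "manifest.json")
  jsonlite::write_json(
    list(package = "musakit",
         version = as.character(packageVersion("musakit")),
         config = unclass(config),
         files = basename(written)),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Published accession characteristics table
#'
#' The 21-accession summary shipped with the package: section, accession
#' name, ITC code, 2C nuclear DNA content (mean, SD in pg), published
#' monoploid genome size (integer Mbp), Bonferroni grouping letters,
#' chromosome number 2n (NA where roots were unavailable) and 45S/5S rDNA
#' FISH signal counts.
#'
#' @return data.frame with 21 rows.
#' @export
musaAccessionTable <- function() {
  read.csv(system.file("extdata", "musa_accessions.csv",
                       package = "musakit"),
           stringsAsFactors = FALSE)
}

#' Published ITS-type feature table
#'
#' Per-ITS-type sequence characteristics shipped with the package: GC
#' content of ITS1/5.8S/ITS2, the state of the three conserved 5.8S motifs
#' (`conserved`, change notation, or `not present-deletion`), the ITS2 and
#' 5.8S secondary-structure outcomes, and the putative-pseudogene note.
#'
#' @param parsed when `TRUE` (default) adds `n_changes` (changed motif
#'   positions summed over M1-M3, whole-motif deletions counting their full
#'   length), logical `its2_formed`/`r58s_formed`, and logical `pseudogene`.
#' @return data.frame with one row per ITS type.
#' @export
musaITSFeatureTable <- function(parsed = TRUE) {
  df <- read.csv(system.file("extdata", "musa_its_types.csv",
                             package = "musakit"),
                 stringsAsFactors = FALSE)
  if (!parsed) return(df)
  lens <- nchar(conservedMotifs())
  countCell <- function(cell, len) {
    if (cell == "conserved" || cell == "") return(0L)
    if (cell == "not present-deletion") return(len)
    toks <- strsplit(cell, ";", fixed = TRUE)[[1]]
    n <- 0L
    for (tk in toks) {
      rng <- regmatches(tk, regexec("^nt(\\d+)-nt(\\d+) 'deletion'$", tk))[[1]]
      if (length(rng) == 3) n <- n + (as.integer(rng[3]) - as.integer(rng[2]) + 1L)
      else n <- n + 1L
    }
    n
  }
  df$n_changes <- mapply(function(a, b, c) {
    countCell(a, lens[1]) + countCell(b, lens[2]) + countCell(c, lens[3])
  }, df$motif_m1, df$motif_m2, df$motif_m3)
  df$its2_formed <- df$its2_structure == "four-helices"
  df$r58s_formed <- df$r58s_structure == "conserved"
  df$pseudogene <- df$note == "pseudogene"
  df
}
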