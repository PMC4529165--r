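#' @include AllClasses.R
NULL

# bp-per-pg conversion constant: 1 pg DNA = 0.978e9 bp, i.e. 978 Mbp
.MBP_PER_PG <- 978

# round-half-up, matching the integer Mbp convention of genome-size tables
.roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Detect G1 peaks in a fluorescence histogram
#'
#' Finds the dominant G1 peaks of a flow-cytometry histogram by a smoothed
#' local-maximum search followed by a least-squares Gaussian fit in a window
#' around each maximum. With a co-chopped internal standard the histogram is
#' expected to carry two dominant peaks (sample and standard G1 nuclei).
#'
#' @param hist a [FluorHistogram-class].
#' @param nExpected number of peaks to resolve (>= 1).
#' @param smoothWindow moving-average width in bins (odd; default 5).
#' @param noiseFloor fraction of the tallest smoothed bin below which local
#'   maxima are ignored (default 0.05).
#' @param minSeparation minimum separation between peak apexes, in bins
#'   (default `2 * smoothWindow`).
#' @return data.frame with one row per peak, sorted by `mean`: fluorescence
#'   `mean`, coefficient of variation `cv` (percent), and `nuclei` attributed
#'   to the fitted peak.
#' @examples
#' sim <- genFlowHistogram(true2C = 1.217, seed = 7)
#' detectG1Peaks(sim$histogram, 2)
#' @export
detectG1Peaks <- function(hist, nExpected, smoothWindow = 5,
                          noiseFloor = 0.05, minSeparation = 2 * smoothWindow) {
  stopifnot(is(hist, "FluorHistogram"), nExpected >= 1)
  y <- histCounts(hist)
  x <- binCenters(hist)
  if (sum(y) == 0) stop("invalid input: histogram has no events")
  w <- max(1L, as.integer(smoothWindow))
  if (w %% 2 == 0) w <- w + 1L
  ys <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  ys[is.na(ys)] <- 0
  n <- length(ys)
  floorLevel <- noiseFloor * max(ys)
  apex <- which(ys >= floorLevel &
                ys >= c(-Inf, ys[-n]) & ys > c(ys[-1], -Inf))
  if (!length(apex)) stop("peaks unresolved: no local maxima above noise floor")
  # greedy selection by height with a minimum apex separation
  apex <- apex[order(ys[apex], decreasing = TRUE)]
  sel <- integer()
  for (a in apex) {
    if (!length(sel) || all(abs(a - sel) >= minSeparation)) sel <- c(sel, a)
    if (length(sel) == nExpected) break
  }
  if (length(sel) < nExpected)
    stop("peaks unresolved: found ", length(sel), " of ", nExpected,
         " requested peaks")
  binw <- mean(diff(hist@binEdges))
  fits <- lapply(sort(sel), function(a) .fitGaussianPeak(x, y, ys, a, binw))
  out <- do.call(rbind, fits)
  out <- out[order(out$mean), , drop = FALSE]
  # attributed nuclei may not exceed the total event count
  tot <- sum(y)
  if (sum(out$nuclei) > tot) out$nuclei <- out$nuclei * tot / sum(out$nuclei)
  rownames(out) <- NULL
  out
}

# Gaussian fit around one apex; window = apex +/- 3 half-widths at half height
.fitGaussianPeak <- function(x, y, ys, apex, binw) {
  half <- ys[apex] / 2
  l <- apex
  while (l > 1 && ys[l - 1] > half) l <- l - 1
  r <- apex
  n <- length(ys)
  while (r < n && ys[r + 1] > half) r <- r + 1
  hwhm <- max(1L, max(apex - l, r - apex))
  win <- max(1L, apex - 3L * hwhm):min(n, apex + 3L * hwhm)
  xw <- x[win]
  yw <- y[win]
  m0 <- x[apex]
  s0 <- max(hwhm * binw / sqrt(2 * log(2)), binw / 2)
  a0 <- max(y[apex], 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(yw ~ a * exp(-(xw - m)^2 / (2 * s^2)),
                      start = list(a = a0, m = m0, s = s0),
                      lower = c(0, min(xw), binw / 10),
                      upper = c(Inf, max(xw), diff(range(xw))),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    a <- cf[["a"]]; m <- cf[["m"]]; s <- abs(cf[["s"]])
  } else { # moment fallback on the window
    m <- sum(xw * yw) / sum(yw)
    s <- sqrt(sum(yw * (xw - m)^2) / sum(yw))
    a <- max(yw)
  }
  data.frame(mean = m, cv = 100 * s / m,
             nuclei = a * s * sqrt(2 * pi) / binw)
}

#' 2C DNA content from sample and internal-standard G1 peak means
#'
#' The sample 2C DNA amount follows from the ratio of G1 peak positions:
#' `standard2C * musaPeakMean / standardPeakMean`. The default internal
#' standard is soybean with 2C = 2.5 pg.
#'
#' @param musaPeakMean G1 peak mean of the sample (fluorescence units).
#' @param standardPeakMean G1 peak mean of the internal standard.
#' @param standard2C 2C DNA content of the standard in pg (default 2.5).
#' @return 2C DNA content in pg.
#' @examples
#' compute2C(243.4, 500)   # 1.217 pg
#' @export
compute2C <- function(musaPeakMean, standardPeakMean, standard2C = 2.5) {
  if (!all(is.finite(c(musaPeakMean, standardPeakMean, standard2C))) ||
      any(c(musaPeakMean, standardPeakMean, standard2C) <= 0))
    stop("invalid input: peak means and standard 2C must be positive")
  standard2C * musaPeakMean / standardPeakMean
}

#' Convert a DNA amount in pg to megabase pairs
#'
#' Uses 1 pg = 0.978e9 bp, i.e. 978 Mbp per pg.
#'
#' @param pg DNA amount in picograms (>= 0); vectorized.
#' @return Genome size in Mbp.
#' @examples
#' pgToMbp(1)        # 978
#' pgToMbp(0.6085)   # 595.1 -> 1Cx of a 1.217 pg diploid
#' @export
pgToMbp <- function(pg) {
  if (anyNA(pg) || any(pg < 0)) stop("invalid input: pg must be >= 0")
  pg * .MBP_PER_PG
}

#' Monoploid genome size (integer Mbp) from a 2C value
#'
#' For a diploid, 1Cx = 2C / 2; converted with [pgToMbp()] and rounded
#' half-up to an integer, the convention used in genome-size tables.
#'
#' @param twoCpg 2C DNA content in pg; vectorized.
#' @return Integer Mbp per 1Cx.
#' @examples
#' monoploidMbp(c(1.217, 1.772))  # 595, 867
#' @export
monoploidMbp <- function(twoCpg) {
  as.integer(.roundHalfUp(pgToMbp(twoCpg / 2)))
}

#' Aggregate replicate 2C measurements into an accession estimate
#'
#' Each plant's repeated measurements are averaged first; the accession mean
#' and standard deviation are then taken across the plant means (the
#' three-plants-times-three-days design).
#'
#' @param perPlant list of numeric vectors, one vector of 2C measurements
#'   (pg) per plant.
#' @return data.frame with `two_c_pg`, `sd_pg`, `n_plants`, `monoploid_mbp`.
#' @examples
#' aggregateReplicates(list(p1 = c(1.30, 1.30), p2 = 1.31, p3 = 1.32))
#' @export
aggregateReplicates <- function(perPlant) {
  if (!length(perPlant) || !all(vapply(perPlant, length, 1L) >= 1))
    stop("invalid input: need >= 1 plant with >= 1 measurement each")
  pm <- vapply(perPlant, mean, numeric(1))
  m <- mean(pm)
  s <- if (length(pm) > 1) sd(pm) else 0
  data.frame(two_c_pg = m, sd_pg = s, n_plants = length(pm),
             monoploid_mbp = monoploidMbp(m))
}

#' Reconstruct replicate values from a published mean and SD
#'
#' Deterministic symmetric reconstruction used when only summary statistics
#' are available: `n` values of the form `m + s * a * (-1, 0, 1, ...)` whose
#' sample mean is exactly `m` and sample SD exactly `s`. With `n = 3` this is
#' the triplet `{m - s, m, m + s}`.
#'
#' @param m mean.
#' @param s sample standard deviation.
#' @param n number of values (a multiple of 3).
#' @return numeric vector of length `n`.
#' @export
reconstructReplicates <- function(m, s, n = 3) {
  if (n %% 3 != 0 || n < 3) stop("n must be a positive multiple of 3")
  a <- sqrt((n - 1) / (2 * (n / 3)))
  m + s * a * rep(c(-1, 0, 1), n / 3)
}

#' Bonferroni all-pairwise comparison with compact letter display
#'
#' One-way ANOVA with a pooled error mean square, followed by all pairwise
#' t tests at a Bonferroni-adjusted significance level, summarized as a
#' compact letter display: accessions sharing a letter do not differ
#' significantly. Letters are assigned in ascending order of group mean by
#' the insert-and-absorb algorithm.
#'
#' @param values named list of numeric vectors (one per accession, >= 2
#'   values each, e.g. plant means or [reconstructReplicates()] output).
#' @param alpha familywise significance level (default 0.01).
#' @return data.frame with `label`, `mean`, `letters` (ascending mean order);
#'   attribute `"significant"` holds the logical pairwise test matrix.
#' @examples
#' g <- list(a = c(1.0, 1.01, 0.99), b = c(1.0, 1.02, 0.98),
#'           c = c(2.0, 2.01, 1.99))
#' bonferroniLetterGroups(g)
#' @export
bonferroniLetterGroups <- function(values, alpha = 0.01) {
  k <- length(values)
  if (k < 2) stop("need >= 2 accessions")
  if (any(vapply(values, length, 1L) < 2))
    stop("cannot test: every accession needs >= 2 values")
  if (is.null(names(values))) names(values) <- paste0("g", seq_len(k))
  y <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), vapply(values, length, 1L)),
              levels = names(values))
  fit <- aov(y ~ g)
  mse <- deviance(fit) / fit$df.residual
  df <- fit$df.residual
  if (mse <= 0 || df < 1) stop("cannot test: no residual variation")
  m <- vapply(values, mean, numeric(1))
  n <- vapply(values, length, 1L)
  np <- k * (k - 1) / 2
  sig <- matrix(FALSE, k, k, dimnames = list(names(values), names(values)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    tstat <- abs(m[i] - m[j]) / sqrt(mse * (1 / n[i] + 1 / n[j]))
    p <- 2 * pt(-tstat, df)
    sig[i, j] <- sig[j, i] <- p < alpha / np
  }
  sets <- .insertAbsorb(sig)
  sets <- sets[order(vapply(sets, function(s) min(m[s]), numeric(1)))]
  if (length(sets) > 26) stop("more than 26 letter groups")
  letters <- vapply(seq_len(k), function(i) {
    paste0(LETTERS[which(vapply(sets, function(s) i %in% s, TRUE))],
           collapse = "")
  }, character(1))
  out <- data.frame(label = names(values), mean = m, letters = letters,
                    row.names = NULL)
  out <- out[order(out$mean), ]
  rownames(out) <- NULL
  attr(out, "significant") <- sig
  out
}

# insert-and-absorb over the significance matrix (Piepho-style): start from
# one all-inclusive letter, split on each significant pair, drop subsets
.insertAbsorb <- function(sig) {
  k <- nrow(sig)
  sets <- list(seq_len(k))
  idx <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    out <- list()
    for (s in sets) {
      if (all(c(i, j) %in% s)) out <- c(out, list(setdiff(s, i), setdiff(s, j)))
      else out <- c(out, list(s))
    }
    out <- unique(lapply(out, sort))
    keep <- vapply(seq_along(out), function(a)
      !any(vapply(seq_along(out), function(b)
        b != a && all(out[[a]] %in% out[[b]]), TRUE)), TRUE)
    sets <- out[keep]
  }
  sets
}

#' Tie-corrected Spearman rank correlation
#'
#' Average ranks are assigned to ties and the Pearson correlation of the
#' ranks is returned — the convention needed when one variable has few levels
#' (such as diploid chromosome numbers).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @examples
#' spearmanR(1:3, 3:1)  # -1
#' @export
spearmanR <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant vector")
  cor(x, y, method = "spearman")
}

#' Relative interspecific variation of a set of 2C values
#'
#' `(max - min) / min * 100`, the figure used to describe within-section
#' genome-size variation.
#'
#' @param twoC numeric vector of 2C values (pg).
#' @return percentage.
#' @examples
#' relativeVariation(c(1.390, 1.772))  # 27.48
#' @export
relativeVariation <- function(twoC) {
  if (length(twoC) < 2 || any(twoC <= 0)) stop("need >= 2 positive values")
  (max(twoC) - min(twoC)) / min(twoC) * 100
}
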