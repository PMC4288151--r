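#' Bin read-start positions into a coverage track
#'
#' Coverage is the number of sequencing reads whose first mapped base falls
#' in each non-overlapping window of `width_bp` (200 nt by default). The
#' result is a coverage track: one row per bin with its raw count.
#'
#' @param read_starts Integer vector of read-start positions, each in
#'   `[0, length_bp)`.
#' @param chrom A [chromosome_map()].
#' @param width_bp Bin width in bp (default 200).
#' @return A `coverage_track`: a tibble with columns `bin`, `start`, `end`,
#'   `width`, `partial`, `count`, carrying the chromosome map and bin width
#'   as attributes.
#' @examples
#' chrom <- chromosome_map(1000)
#' bin_coverage(c(0, 50, 199, 200), chrom, 200)
#' @export
bin_coverage <- function(read_starts, chrom, width_bp = 200) {
  if (any(read_starts < 0 | read_starts >= chrom$length_bp)) {
    abort("read-start positions must lie in [0, length_bp).")
  }
  bins <- make_bins(chrom, width_bp)
  idx <- pmin(as.integer(read_starts %/% width_bp), nrow(bins) - 1L)
  counts <- tabulate(idx + 1L, nbins = nrow(bins))
  new_coverage_track(dplyr::mutate(bins, count = counts), chrom, width_bp)
}

new_coverage_track <- function(df, chrom, width_bp) {
  structure(
    df,
    chrom = chrom,
    width_bp = width_bp,
    class = c("coverage_track", class(tibble::tibble()))
  )
}

#' @export
#' @rdname bin_coverage
#' @param x A coverage track.
#' @param ... Unused.
print.coverage_track <- function(x, ...) {
  chrom <- attr(x, "chrom")
  cat(sprintf(
    "<coverage_track> %d bins of %s bp on a %s-bp chromosome\n",
    nrow(x), format(attr(x, "width_bp"), big.mark = ","),
    format(chrom$length_bp, big.mark = ",")
  ))
  NextMethod()
}

# Histogram mode on the log2(x + 1) scale: fixed cells of `cell` width
# anchored at 0, ties resolved to the lower cell. Returns the back-transformed
# cell midpoint (a positive factor on the count + 1 scale).
log2_histogram_mode <- function(counts, cell = 0.1) {
  v <- log2(counts + 1)
  k <- as.integer(floor(v / cell))
  tab <- tabulate(k - min(k) + 1L)
  winner <- min(k) + which.max(tab) - 1L  # which.max takes the first = lowest cell on ties
  2^((winner + 0.5) * cell)
}

#' Mode-normalize a coverage track
#'
#' Scales a coverage track so that the most common coverage level maps to
#' zero on the log2 scale. The mode is estimated from a fixed-width histogram
#' (cell 0.1) of `log2(count + 1)` over full (non-partial) bins — optionally
#' restricted to a segment, which is how normalization against only the
#' non-amplified portion of a chromosome is expressed — and the entire track
#' is then expressed as `log2(count + 1) - log2(mode_factor)`. Mode
#' normalization is robust to a subset of bins with altered copy number,
#' unlike mean or median scaling.
#'
#' @param track A `coverage_track` from [bin_coverage()],
#'   [simulate_population_coverage()] or [read_coverage()].
#' @param restrict_to Optional [genomic_segment()]: estimate the mode only
#'   from bins whose start lies in this segment (all bins are still
#'   normalized).
#' @return A `norm_coverage`: the track with a `log2` column added and a
#'   `mode_factor` attribute.
#' @export
mode_normalize <- function(track, restrict_to = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  chrom <- attr(track, "chrom")
  use <- !track$partial
  if (!is.null(restrict_to)) {
    use <- use & in_segment(track$start, restrict_to, chrom)
  }
  if (sum(use) < 10) abort("fewer than 10 full bins available for mode estimation.")
  if (all(track$count[use] == 0)) abort("all counts are zero; cannot mode-normalize.")
  mode_factor <- log2_histogram_mode(track$count[use])
  out <- dplyr::mutate(track, log2 = log2(.data$count + 1) - log2(mode_factor))
  structure(
    out,
    chrom = chrom,
    width_bp = attr(track, "width_bp"),
    mode_factor = mode_factor,
    class = c("norm_coverage", "coverage_track", class(tibble::tibble()))
  )
}

#' The Rc statistic: relative coverage of an origin-centred segment
#'
#' Rc is the ratio of the average coverage of a chromosomal segment (in the
#' motivating analyses, the ~2-Mb region around the replication origin) to
#' the average coverage of the rest of the chromosome. Averages are
#' arithmetic means on the linear scale (the normalized coverage is de-logged
#' first); partial bins are excluded. Rc near 1 means uniform coverage;
#' Rc = 1 + f is expected when a tandem duplication of the segment is present
#' in a fraction f of the genomic DNA molecules.
#'
#' @param norm A `norm_coverage` from [mode_normalize()].
#' @param ori_segment A [genomic_segment()]; bins are attributed by their
#'   start coordinate.
#' @return An `rc_result`: list with elements `Rc`, `ori_segment`,
#'   `boundary_1`, `boundary_2`, `mean_in`, `mean_out`, `n_in`, `n_out`.
#' @export
compute_rc <- function(norm, ori_segment) {
  stopifnot(inherits(norm, "norm_coverage"))
  chrom <- attr(norm, "chrom")
  full <- !norm$partial
  inside <- in_segment(norm$start, ori_segment, chrom) & full
  outside <- !in_segment(norm$start, ori_segment, chrom) & full
  if (!any(inside) || !any(outside)) {
    abort("segment must cover at least one full bin and leave at least one outside.")
  }
  lin <- 2^norm$log2
  mean_in <- mean(lin[inside])
  mean_out <- mean(lin[outside])
  new_rc_result(
    Rc = mean_in / mean_out,
    ori_segment = ori_segment,
    mean_in = mean_in, mean_out = mean_out,
    n_in = sum(inside), n_out = sum(outside)
  )
}

new_rc_result <- function(Rc, ori_segment, mean_in, mean_out, n_in, n_out) {
  structure(
    list(
      Rc = Rc,
      ori_segment = ori_segment,
      boundary_1 = ori_segment$start,
      boundary_2 = ori_segment$end,
      mean_in = mean_in,
      mean_out = mean_out,
      n_in = n_in,
      n_out = n_out
    ),
    class = "rc_result"
  )
}

#' @export
print.rc_result <- function(x, ...) {
  cat(sprintf(
    "<rc_result> Rc = %.4f; segment [%s, %s)%s; mean in/out = %.4f / %.4f\n",
    x$Rc, format(x$boundary_1, big.mark = ","), format(x$boundary_2, big.mark = ","),
    if (x$ori_segment$wraps) " (wraps)" else "", x$mean_in, x$mean_out
  ))
  invisible(x)
}

# Total within-segment sum of squares of x for the circular 2-segmentation at
# full-bin boundary indices (i, j), all pairs at once. x is the log2 vector
# over full bins; si/sj are 0-based boundary indices into that vector.
two_segment_rss <- function(x, si, sj) {
  n <- length(x)
  c1 <- c(0, cumsum(x))
  c2 <- c(0, cumsum(x^2))
  tot1 <- c1[n + 1]
  tot2 <- c2[n + 1]
  s1 <- outer(si, sj, function(i, j) c1[j + 1] - c1[i + 1])
  s2 <- outer(si, sj, function(i, j) c2[j + 1] - c2[i + 1])
  m <- outer(si, sj, function(i, j) j - i)
  rss_in <- s2 - s1^2 / m
  rss_out <- (tot2 - s2) - (tot1 - s1)^2 / (n - m)
  rss <- rss_in + rss_out
  rss[m <= 0 | m >= n] <- Inf
  rss
}

#' Locate the two boundaries of an amplified segment
#'
#' Finds the circular two-segmentation of a normalized coverage track that
#' minimizes the total within-segment sum of squared log2 coverage values —
#' the change-point estimate of the two sharp boundaries that a segmental
#' duplication leaves in read depth. When candidate breakpoints are supplied
#' (e.g. the positions of identical repeat elements), all ordered candidate
#' pairs are scored exhaustively; otherwise a two-stage scan over bin
#' boundaries is used (coarse stride of 10 bins, then stride-1 refinement
#' within +/- 20 bins of the coarse optimum) so that a full-scale 23,000-bin
#' chromosome is scanned in seconds. Ties go to the smallest first boundary,
#' then the shortest origin segment.
#'
#' @param norm A `norm_coverage` from [mode_normalize()].
#' @param candidates Optional numeric vector (length >= 2) of candidate
#'   boundary coordinates in bp; they are snapped to the containing bin
#'   boundary.
#' @param coarse_stride Coarse scan stride in bins (default 10).
#' @param refine Refinement half-width in bins (default 20).
#' @param exhaustive Force a stride-1 exhaustive scan; defaults to `TRUE`
#'   for tracks of at most 5,000 full bins.
#' @param min_segment_frac Minimum length of either segment, as a fraction of
#'   the full bins (default 0.05), applied in scan mode only. The scan
#'   targets large segmental variants; without a floor, the minimum-RSS split
#'   of a structureless track isolates the single most extreme bin and
#'   reports a spuriously high Rc. Candidate mode searches the supplied
#'   pairs unconstrained.
#' @return An `rc_result` whose `ori_segment` is the higher-coverage segment,
#'   so `Rc >= 1` always.
#' @export
detect_breakpoints <- function(norm, candidates = NULL, coarse_stride = 10,
                               refine = 20, exhaustive = NULL,
                               min_segment_frac = 0.05) {
  stopifnot(inherits(norm, "norm_coverage"))
  chrom <- attr(norm, "chrom")
  width <- attr(norm, "width_bp")
  full <- which(!norm$partial)
  x <- norm$log2[full]
  n <- length(x)
  if (n < 20) abort("need at least 20 full bins to scan for breakpoints.")

  if (!is.null(candidates)) {
    cand_bins <- sort(unique(pmin(as.integer(candidates %/% width), n)))
    if (length(cand_bins) < 2) abort("need at least 2 distinct candidate boundaries.")
    best <- best_pair(x, cand_bins)
  } else {
    min_seg <- max(1L, as.integer(ceiling(min_segment_frac * n)))
    if (is.null(exhaustive)) exhaustive <- n <= 5000
    if (exhaustive) {
      best <- best_pair(x, 0:(n - 1), min_seg)
    } else {
      grid <- seq(0L, n - 1L, by = coarse_stride)
      coarse <- best_pair(x, grid, min_seg)
      ref1 <- intersect((coarse[1] - refine):(coarse[1] + refine) %% n, 0:(n - 1))
      ref2 <- intersect((coarse[2] - refine):(coarse[2] + refine) %% n, 0:(n - 1))
      best <- best_pair(x, sort(unique(c(ref1, ref2))), min_seg)
    }
  }

  seg_a <- genomic_segment(best[1] * width, best[2] * width)
  mean_a <- mean(2^x[seg_bins(best[1], best[2], n)])
  mean_b <- mean(2^x[setdiff(seq_len(n), seg_bins(best[1], best[2], n))])
  if (mean_a >= mean_b) {
    new_rc_result(mean_a / mean_b, seg_a, mean_a, mean_b,
                  n_in = (best[2] - best[1]) %% n, n_out = n - (best[2] - best[1]) %% n)
  } else {
    seg_b <- genomic_segment(best[2] * width, best[1] * width)
    new_rc_result(mean_b / mean_a, seg_b, mean_b, mean_a,
                  n_in = n - (best[2] - best[1]) %% n, n_out = (best[2] - best[1]) %% n)
  }
}

# 1-based bin indices of the circular segment [i, j) over n full bins
# (i, j are 0-based boundary indices).
seg_bins <- function(i, j, n) {
  if (i < j) (i + 1):j else c(seq_len(j), if (i < n) (i + 1):n)
}

# Best ordered boundary pair over the given 0-based boundary indices,
# minimizing circular two-segment RSS. Non-wrapping pairs (i < j) cover every
# circular 2-partition, since segment [i, j) and its complement score
# identically. Ties: smallest first boundary, then shortest segment [i, j).
best_pair <- function(x, idx, min_seg = 1L) {
  idx <- sort(unique(as.integer(idx)))
  n <- length(x)
  rss <- two_segment_rss(x, idx, idx)
  rss[!outer(idx, idx, "<")] <- Inf
  if (min_seg > 1L) {
    m <- outer(idx, idx, function(i, j) j - i)
    rss[m < min_seg | n - m < min_seg] <- Inf
  }
  best <- min(rss)
  hits <- which(rss <= best + 1e-9, arr.ind = TRUE)
  i <- idx[hits[, 1]]
  j <- idx[hits[, 2]]
  ord <- order(i, j - i)
  c(i[ord[1]], j[ord[1]])
}

#' Classify a coverage track as displaying the duplication pattern
#'
#' A clone or population is called pattern-positive when its Rc — the
#' coverage ratio of the origin segment over the rest — reaches the
#' threshold. The default threshold 1.5 corresponds to the low end of the
#' Rc range observed in clones carrying the duplication (Rc 1.5-1.8, i.e. a
#' duplication in 60-80% of genomic DNA molecules).
#'
#' @param rc An `rc_result`.
#' @param threshold Minimum Rc for a positive call (default 1.5, inclusive).
#' @return `TRUE` or `FALSE`.
#' @export
classify_pattern <- function(rc, threshold = 1.5) {
  stopifnot(inherits(rc, "rc_result"))
  rc$Rc >= threshold
}
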