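#' Describe a circular bacterial chromosome
#'
#' A chromosome map carries the coordinate system every other function in the
#' package works in: the replicon length, the positions of the origin and
#' terminus of replication, and (optionally) candidate duplication-boundary
#' coordinates such as the positions of identical insertion-sequence copies
#' that can mediate segmental duplication by unequal recombination.
#'
#' All coordinates are 0-based and half-open internally; readers for 1-based
#' formats (GFF3) convert on input.
#'
#' @param length_bp Replicon length in bp (positive integer).
#' @param ori_pos Position of the replication origin, in `[0, length_bp)`.
#' @param ter_pos Position of the replication terminus, in `[0, length_bp)`.
#' @param circular Is the replicon circular? Default `TRUE`; almost every
#'   operation in the package assumes circularity.
#' @param boundary_candidates Optional integer vector of candidate breakpoint
#'   coordinates (e.g. repeat-element positions), each in `[0, length_bp)`.
#' @return An object of class `chromosome_map`.
#' @examples
#' chromosome_map(4.6e6, ori_pos = 1e6, ter_pos = 3.3e6)
#' @export
chromosome_map <- function(length_bp, ori_pos = 0, ter_pos = NULL,
                           circular = TRUE, boundary_candidates = integer()) {
  length_bp <- as.numeric(length_bp)
  if (length(length_bp) != 1 || !is.finite(length_bp) || length_bp < 1) {
    abort("`length_bp` must be a single positive number.")
  }
  if (is.null(ter_pos)) ter_pos <- (ori_pos + length_bp / 2) %% length_bp
  check_pos <- function(p, what) {
    if (any(p < 0 | p >= length_bp)) {
      abort(sprintf("`%s` must lie in [0, length_bp).", what))
    }
  }
  check_pos(ori_pos, "ori_pos")
  check_pos(ter_pos, "ter_pos")
  if (length(boundary_candidates)) check_pos(boundary_candidates, "boundary_candidates")
  structure(
    list(
      length_bp = length_bp,
      circular = isTRUE(circular),
      ori_pos = as.numeric(ori_pos),
      ter_pos = as.numeric(ter_pos),
      boundary_candidates = as.numeric(boundary_candidates)
    ),
    class = "chromosome_map"
  )
}

#' @export
print.chromosome_map <- function(x, ...) {
  cat(sprintf(
    "<chromosome_map> %s bp (%s), ori %s, ter %s, %d boundary candidate(s)\n",
    format(x$length_bp, big.mark = ","),
    if (x$circular) "circular" else "linear",
    format(x$ori_pos, big.mark = ","), format(x$ter_pos, big.mark = ","),
    length(x$boundary_candidates)
  ))
  invisible(x)
}

#' Preset chromosome maps for simulation
#'
#' Two presets of an E. coli-like circular chromosome used throughout the
#' synthetic-data module: a full-scale 4.6-Mb replicon (23,000 bins at the
#' default 200-nt bin width) and a 10%-scale 460-kb desk replicon for fast
#' tests. In both, the origin sits at ~22% of the replicon so that the
#' origin-centred duplication segment returned by [preset_dup_segment()]
#' occupies `[0, 0.435 * length)` (~2 Mb at full scale, i.e. ~40% of the
#' genome) without wrapping.
#'
#' @param scale `"full"` (4.6 Mb) or `"desk"` (460 kb).
#' @return A [chromosome_map()].
#' @export
preset_chromosome <- function(scale = c("full", "desk")) {
  scale <- match.arg(scale)
  L <- if (scale == "full") 4.6e6 else 4.6e5
  chromosome_map(
    length_bp = L,
    ori_pos = L * 10 / 46,
    ter_pos = L * 33 / 46,
    boundary_candidates = c(0, L * 20 / 46)
  )
}

#' @rdname preset_chromosome
#' @param chrom A chromosome map from [preset_chromosome()] (or any map whose
#'   first two `boundary_candidates` delimit the duplication).
#' @export
preset_dup_segment <- function(chrom) {
  stopifnot(inherits(chrom, "chromosome_map"))
  bc <- chrom$boundary_candidates
  if (length(bc) < 2) abort("chromosome map carries fewer than 2 boundary candidates.")
  genomic_segment(bc[1], bc[2])
}

#' Genomic segments on a circular chromosome
#'
#' A segment is a half-open interval `[start, end)`. On a circular chromosome
#' a segment with `start >= end` wraps through the origin of coordinates.
#'
#' @param start,end Segment limits in bp, 0-based half-open.
#' @return An object of class `genomic_segment`.
#' @examples
#' genomic_segment(4.0e6, 0.5e6) # wraps on a circular chromosome
#' @export
genomic_segment <- function(start, end) {
  stopifnot(length(start) == 1, length(end) == 1, is.finite(start), is.finite(end))
  structure(
    list(start = as.numeric(start), end = as.numeric(end), wraps = start >= end),
    class = "genomic_segment"
  )
}

#' @export
print.genomic_segment <- function(x, ...) {
  cat(sprintf(
    "<genomic_segment> [%s, %s)%s\n",
    format(x$start, big.mark = ","), format(x$end, big.mark = ","),
    if (x$wraps) " (wraps)" else ""
  ))
  invisible(x)
}

#' @rdname genomic_segment
#' @param seg A `genomic_segment`.
#' @param chrom A [chromosome_map()].
#' @return `segment_length()`: the segment length `(end - start) mod length`,
#'   strictly positive.
#' @export
segment_length <- function(seg, chrom) {
  len <- (seg$end - seg$start) %% chrom$length_bp
  if (len == 0) len <- chrom$length_bp  # start == end means the whole circle is excluded
  if (len <= 0) abort("degenerate segment (non-positive length).")
  len
}

#' Test positions for membership in a (possibly wrapping) segment
#'
#' Membership uses the half-open convention: `start` is in, `end` is out.
#' Wrapping segments are handled under circular arithmetic, so membership is
#' invariant under a common rotation of positions and segment.
#'
#' @param pos Vector of positions in `[0, length_bp)`.
#' @param seg A [genomic_segment()].
#' @param chrom A [chromosome_map()].
#' @return Logical vector, one element per position.
#' @examples
#' chrom <- chromosome_map(4.6e6)
#' in_segment(1e5, genomic_segment(4.0e6, 5e5), chrom)
#' @export
in_segment <- function(pos, seg, chrom) {
  if (any(pos < 0 | pos >= chrom$length_bp)) {
    abort("positions must lie in [0, length_bp).")
  }
  rel <- (pos - seg$start) %% chrom$length_bp
  rel < segment_length(seg, chrom)
}

#' Tile a chromosome with fixed-width bins
#'
#' Partitions `[0, length_bp)` into consecutive non-overlapping windows of
#' `width_bp`. When the length is not a multiple of the width the final bin is
#' shorter and flagged `partial`; partial bins are retained so the tiling is
#' exact, but every statistic in the package (mode, Rc, breakpoint scan)
#' excludes them.
#'
#' @param chrom A [chromosome_map()].
#' @param width_bp Bin width in bp (default 200, the read-depth window used
#'   throughout the coverage analysis).
#' @return A tibble with columns `bin` (0-based index), `start`, `end`,
#'   `width` and `partial`.
#' @examples
#' make_bins(chromosome_map(1001), 200)
#' @export
make_bins <- function(chrom, width_bp = 200) {
  stopifnot(inherits(chrom, "chromosome_map"))
  width_bp <- as.numeric(width_bp)
  if (length(width_bp) != 1 || width_bp < 1) abort("`width_bp` must be a positive number.")
  if (width_bp > chrom$length_bp) abort("`width_bp` exceeds the chromosome length.")
  n_full <- chrom$length_bp %/% width_bp
  rem <- chrom$length_bp %% width_bp
  starts <- seq(0, by = width_bp, length.out = n_full + (rem > 0))
  ends <- pmin(starts + width_bp, chrom$length_bp)
  tibble::tibble(
    bin = seq_along(starts) - 1L,
    start = starts,
    end = ends,
    width = ends - starts,
    partial = (ends - starts) < width_bp
  )
}

#' Assign genes to fixed-width chromosomal bins
#'
#' Each gene is placed in the bin containing its midpoint,
#' `floor((start + end) / 2)`; the midpoint is symmetric in the gene limits
#' and independent of strand.
#'
#' @param genes A data frame with at least `start` and `end` columns
#'   (0-based half-open gene coordinates).
#' @param bin_size_bp Bin width in bp (e.g. 1e5 for the 100-kb bins of the
#'   expression-domain analysis).
#' @return The input as a tibble with `midpoint` and `bin` columns added.
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", start = 240000, end = 260000)
#' assign_gene_bin(genes, 1e5)
#' @export
assign_gene_bin <- function(genes, bin_size_bp) {
  stopifnot(is.data.frame(genes), all(c("start", "end") %in% names(genes)))
  if (bin_size_bp < 1) abort("`bin_size_bp` must be positive.")
  dplyr::mutate(
    tibble::as_tibble(genes),
    midpoint = floor((.data$start + .data$end) / 2),
    bin = as.integer(.data$midpoint %/% bin_size_bp)
  )
}
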