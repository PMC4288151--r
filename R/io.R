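#' Read and write the package's tabular formats
#'
#' Plain-text readers and writers for the inputs and outputs of the
#' pipeline. All tables are tab-delimited UTF-8 with a header row and no
#' quoting. Coordinates are converted to the internal 0-based half-open
#' convention on input: BED and bedGraph are already 0-based half-open; GFF3
#' is 1-based inclusive and is shifted.
#'
#' @param path File path.
#' @param chrom A [chromosome_map()] (needed to rebuild a coverage track).
#' @param width_bp Bin width of the stored track.
#' @name oriterscan-io
NULL

#' @describeIn oriterscan-io Read a gene annotation. TSV needs columns
#'   `gene_id`, `start`, `end` (0-based half-open) and optionally `strand`;
#'   `.bed` and `.gff`/`.gff3` files are parsed with rtracklayer and
#'   converted.
#' @export
read_gene_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bed", "gff", "gff3")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading BED/GFF requires the rtracklayer package.")
    }
    gr <- rtracklayer::import(path)
    id <- if (!is.null(gr$Name)) gr$Name
      else if (!is.null(gr$ID)) gr$ID
      else if (!is.null(gr$name)) gr$name
      else sprintf("feature_%05d", seq_along(gr))
    tibble::tibble(
      gene_id = as.character(id),
      start = BiocGenerics::start(gr) - 1L,  # GRanges is 1-based inclusive
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr))
    )
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("gene_id", "start", "end")
    if (!all(need %in% names(df))) {
      abort(sprintf("%s: expected columns %s.", path, paste(need, collapse = ", ")))
    }
    if (!"strand" %in% names(df)) df$strand <- "unknown"
    tibble::as_tibble(df[, c("gene_id", "start", "end", "strand")])
  }
}

#' @describeIn oriterscan-io Read a coverage track from bedGraph
#'   (`chrom start end count`, no header) or 2-column TSV
#'   (`bin_start`, `count`, with header).
#' @export
read_coverage <- function(path, chrom, width_bp = 200) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bedgraph", "bg")) {
    df <- readr::read_tsv(path,
      col_names = c("seqname", "start", "end", "count"),
      comment = "#", show_col_types = FALSE, progress = FALSE
    )
    starts <- df$start
    counts <- df$count
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("bin_start", "count") %in% names(df))) {
      abort(sprintf("%s: expected columns bin_start, count.", path))
    }
    starts <- df$bin_start
    counts <- df$count
  }
  bins <- make_bins(chrom, width_bp)
  idx <- match(bins$start, starts)
  if (anyNA(idx)) abort(sprintf("%s does not tile the chromosome at width %d.", path, width_bp))
  new_coverage_track(dplyr::mutate(bins, count = counts[idx]), chrom, width_bp)
}

#' @describeIn oriterscan-io Write a coverage track (raw or normalized) as
#'   bedGraph (`count` column; `seqname` fixed to `"chrom"`).
#' @param track A `coverage_track`.
#' @export
write_coverage_bedgraph <- function(track, path) {
  readr::write_tsv(
    tibble::tibble(seqname = "chrom", start = track$start,
                   end = track$end, count = track$count),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' @describeIn oriterscan-io Read a count or expression matrix: first column
#'   gene id, remaining columns samples/conditions.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @describeIn oriterscan-io Write a matrix with rownames as a `gene_id`
#'   first column.
#' @param m A matrix with rownames.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
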