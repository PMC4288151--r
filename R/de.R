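#' Count reads per gene from read-start positions
#'
#' A read is assigned to the gene whose interval `[start, end)` contains the
#' position of its first mapped base; counting is strand-agnostic. When
#' annotations overlap, the gene earliest by coordinate (then by id) takes
#' precedence. Reads falling in no gene are tallied separately.
#'
#' @param read_starts Integer vector of first-mapped-base positions.
#' @param genes Gene annotation tibble (`gene_id`, `start`, `end`).
#' @return A tibble (`gene_id`, `count`) in annotation order, with the
#'   number of unassigned reads as attribute `n_unassigned`.
#' @export
count_reads_per_gene <- function(read_starts, genes) {
  genes <- tibble::as_tibble(genes)
  ord <- order(genes$start, genes$gene_id)
  g <- genes[ord, ]
  # earliest-by-coordinate gene wins on overlap: gene i only claims the part
  # of [start_i, end_i) not already claimed by any earlier gene
  prev_max_end <- c(-Inf, cummax(g$end)[-nrow(g)])
  eff_start <- pmax(g$start, prev_max_end)
  claim <- which(eff_start < g$end)
  bounds <- as.numeric(rbind(eff_start[claim], g$end[claim]))  # sorted, disjoint
  pos <- findInterval(read_starts, bounds)
  inside <- pos %% 2L == 1L
  counts_sorted <- tabulate(claim[(pos[inside] + 1L) %/% 2L], nbins = nrow(g))
  out <- tibble::tibble(gene_id = genes$gene_id,
                        count = counts_sorted[order(ord)])
  attr(out, "n_unassigned") <- sum(!inside)
  out
}

#' Mode-based per-sample size factors, restricted to a chromosome segment
#'
#' Per-sample normalization factors for a raw count matrix, defined as the
#' histogram mode (cell width 0.1 on `log2(count + 1)`, ties to the lower
#' cell) of the per-gene counts — computed across only the genes whose
#' midpoint lies outside `excluded`, the amplified portion of the genome.
#' Restricting the mode to the non-amplified portion makes the factors
#' insensitive to a segmental duplication inflating a large fraction of
#' genes in one strain, while leaving the factors of strains without the
#' amplification essentially unchanged. For use in fold changes the raw mode
#' factors are rescaled by their geometric mean across samples
#' (`size_factor`), so they are centred at 1 like conventional size factors.
#'
#' @param counts Genes x samples matrix of raw counts (rownames = gene ids),
#'   or a data frame whose first column is `gene_id`.
#' @param genes Gene annotation tibble (`gene_id`, `start`, `end`); required
#'   when `excluded` is given.
#' @param excluded Optional [genomic_segment()] to leave out of mode
#'   estimation (the amplified segment).
#' @param chrom A [chromosome_map()]; required when `excluded` is given.
#' @return A tibble (`sample`, `mode_factor`, `size_factor`).
#' @export
restricted_mode_size_factors <- function(counts, genes = NULL, excluded = NULL,
                                         chrom = NULL) {
  counts <- as_count_matrix(counts)
  keep <- rep(TRUE, nrow(counts))
  if (!is.null(excluded)) {
    if (is.null(genes) || is.null(chrom)) {
      abort("`genes` and `chrom` are required when `excluded` is given.")
    }
    genes <- tibble::as_tibble(genes)
    mid <- floor((genes$start + genes$end) / 2)
    out_ids <- genes$gene_id[!in_segment(mid, excluded, chrom)]
    keep <- rownames(counts) %in% out_ids
  }
  if (sum(keep) < 50) abort("fewer than 50 genes outside the excluded segment.")
  mode_factor <- apply(counts[keep, , drop = FALSE], 2, log2_histogram_mode)
  tibble::tibble(
    sample = colnames(counts),
    mode_factor = unname(mode_factor),
    size_factor = unname(mode_factor / exp(mean(log(mode_factor))))
  )
}

as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    m <- as.matrix(counts[, -1, drop = FALSE])
    rownames(m) <- counts[[1]]
    counts <- m
  }
  if (is.null(rownames(counts))) abort("count matrix must carry gene ids as rownames.")
  if (any(counts < 0)) abort("counts must be non-negative.")
  counts
}

#' Differential expression by exact conditional binomial test
#'
#' Compares two groups of samples gene by gene. Replicate counts are pooled
#' within each group; with pooled counts \eqn{x_A, x_B} and effective sizes
#' \eqn{S_A, S_B} (sums of the groups' size factors), the fold change is
#' \deqn{\log_2 FC = \log_2 \frac{x_A / S_A + 0.5}{x_B / S_B + 0.5}}
#' and the P-value is the two-sided exact binomial test of \eqn{x_A} out of
#' \eqn{x_A + x_B} trials against \eqn{p_0 = S_A / (S_A + S_B)} — exact under
#' Poisson sampling, conditional on the gene's total count. A gene is called
#' `up` when `log2_fc >= log2(fc_threshold)` and `p_value <= p_threshold`
#' (default: at least 2-fold with P <= 1e-5), `down` symmetrically, `ns`
#' otherwise. Genes with zero total count are `ns` with P = 1. No
#' multiple-testing correction is applied; the fixed P cutoff is the calling
#' rule.
#'
#' @param counts Genes x samples count matrix (or data frame with `gene_id`
#'   first column).
#' @param group_a,group_b Character vectors of sample (column) names.
#' @param size_factors Optional tibble from [restricted_mode_size_factors()]
#'   (or any tibble with `sample` and `size_factor`); default: all factors 1.
#' @param fc_threshold Fold-change threshold on the linear scale (default 2).
#' @param p_threshold P-value threshold (default 1e-5).
#' @return A `de_result` tibble: `gene_id`, `count_a`, `count_b`, `log2_fc`,
#'   `p_value`, `call`, with the effective sizes and thresholds as
#'   attributes.
#' @export
differential_expression <- function(counts, group_a, group_b,
                                    size_factors = NULL,
                                    fc_threshold = 2, p_threshold = 1e-5) {
  counts <- as_count_matrix(counts)
  if (!all(c(group_a, group_b) %in% colnames(counts))) {
    abort("`group_a`/`group_b` must name columns of `counts`.")
  }
  if (length(group_a) < 1 || length(group_b) < 1) abort("each group needs >= 1 sample.")
  sf <- if (is.null(size_factors)) {
    stats::setNames(rep(1, ncol(counts)), colnames(counts))
  } else {
    stats::setNames(size_factors$size_factor, size_factors$sample)
  }
  s_a <- sum(sf[group_a])
  s_b <- sum(sf[group_b])
  x_a <- rowSums(counts[, group_a, drop = FALSE])
  x_b <- rowSums(counts[, group_b, drop = FALSE])
  log2_fc <- log2((x_a / s_a + 0.5) / (x_b / s_b + 0.5))
  p0 <- s_a / (s_a + s_b)
  n_tot <- x_a + x_b
  p_value <- vapply(seq_along(x_a), function(i) {
    if (n_tot[i] == 0) return(1)
    binom.test(x_a[i], n_tot[i], p = p0)$p.value
  }, numeric(1))
  lfc_cut <- log2(fc_threshold)
  call <- dplyr::case_when(
    n_tot == 0 ~ "ns",
    log2_fc >= lfc_cut & p_value <= p_threshold ~ "up",
    log2_fc <= -lfc_cut & p_value <= p_threshold ~ "down",
    TRUE ~ "ns"
  )
  structure(
    tibble::tibble(
      gene_id = rownames(counts),
      count_a = unname(x_a), count_b = unname(x_b),
      log2_fc = unname(log2_fc), p_value = p_value, call = call
    ),
    s_a = s_a, s_b = s_b,
    fc_threshold = fc_threshold, p_threshold = p_threshold,
    class = c("de_result", class(tibble::tibble()))
  )
}
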