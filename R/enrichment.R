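#' Count gene-set members in sliding chromosomal windows
#'
#' Slides circular windows of `window_size` along the chromosome in steps of
#' `step` (half a window by default) and counts, in each window, the genes
#' overall and the genes belonging to set G. Genes are located by midpoint;
#' windows wrap across the coordinate origin.
#'
#' @param genes Gene annotation tibble (`gene_id`, `start`, `end`).
#' @param set_g Character vector of gene ids (must be a subset of the
#'   annotation; non-empty).
#' @param chrom A [chromosome_map()].
#' @param window_size Window size in bp.
#' @param step Step between window starts in bp (default `window_size / 2`).
#' @return A tibble with `start`, `end` (window limits; `end` may exceed the
#'   chromosome length to denote wrapping), `n_genes`, `n_set`.
#' @export
window_counts <- function(genes, set_g, chrom, window_size,
                          step = window_size / 2) {
  wm <- window_membership(genes, chrom, window_size, step)
  in_set <- gene_set_indicator(genes, set_g)
  dplyr::mutate(wm$windows,
                n_genes = as.integer(wm$m %*% rep(1, length(in_set))),
                n_set = as.integer(wm$m %*% in_set))
}

gene_set_indicator <- function(genes, set_g) {
  if (length(set_g) == 0) abort("`set_g` is empty.")
  set_g <- unique(set_g)
  if (!all(set_g %in% genes$gene_id)) abort("`set_g` must be a subset of the gene ids.")
  as.numeric(genes$gene_id %in% set_g)
}

# windows x genes 0/1 membership matrix (midpoint rule, circular windows).
# Genes are handled in sorted-midpoint order internally; the matrix columns
# are in the input gene order.
window_membership <- function(genes, chrom, window_size, step) {
  L <- chrom$length_bp
  if (window_size < 1 || window_size > L) abort("`window_size` must be in [1, length_bp].")
  mid <- floor((genes$start + genes$end) / 2) %% L
  starts <- seq(0, L - 1, by = step)
  windows <- tibble::tibble(start = starts, end = starts + window_size)
  m <- matrix(0, nrow(windows), length(mid))
  for (w in seq_len(nrow(windows))) {
    rel <- (mid - windows$start[w]) %% L
    m[w, ] <- as.numeric(rel < window_size)
  }
  list(windows = windows, m = m)
}

#' Positional gene-set enrichment by gene-order shuffling
#'
#' Tests, at each of several window sizes, whether a gene set G is
#' over-represented in any chromosomal window. The null distribution is
#' built by shuffling the gene order in silico: the gene-id-to-location
#' assignment is permuted uniformly (locations fixed, labels shuffled) and
#' all window counts recomputed for each of `n_perm` permutations. Each
#' window's permutation P-value uses the add-one convention,
#' `P = (1 + #\{null >= observed\}) / (1 + n_perm)`, so it is never zero; a
#' window is significant when `P < alpha`. No cross-window multiple-testing
#' correction is applied by default (set `bh = TRUE` for
#' Benjamini-Hochberg-adjusted P-values in an extra column).
#'
#' @inheritParams window_counts
#' @param window_sizes Numeric vector of window sizes in bp
#'   (default 100, 200, 400 and 800 kb).
#' @param n_perm Number of permutations (default 1000; minimum 99).
#' @param alpha Significance level on the permutation P (default 0.01).
#' @param bh Also report Benjamini-Hochberg-adjusted P-values?
#' @param seed Integer seed for the permutations.
#' @return An `enrichment_result` tibble: one row per window per window
#'   size, with `window_size`, `start`, `end`, `n_genes`, `observed`,
#'   `null_mean`, `n_exceed`, `p_value`, `significant`.
#' @export
positional_enrichment <- function(genes, set_g, chrom,
                                  window_sizes = c(1e5, 2e5, 4e5, 8e5),
                                  n_perm = 1000, alpha = 0.01, bh = FALSE,
                                  seed = NULL) {
  if (n_perm < 99) abort("`n_perm` must be at least 99.")
  genes <- dplyr::arrange(tibble::as_tibble(genes), .data$start, .data$gene_id)
  in_set <- gene_set_indicator(genes, set_g)
  n_g <- length(in_set)
  if (!is.null(seed)) set.seed(seed)
  perm <- matrix(0, n_g, n_perm)
  for (p in seq_len(n_perm)) perm[, p] <- in_set[sample.int(n_g)]

  res <- purrr::map(window_sizes, function(ws) {
    wm <- window_membership(genes, chrom, ws, step = ws / 2)
    observed <- as.numeric(wm$m %*% in_set)
    null_counts <- wm$m %*% perm  # windows x n_perm
    n_exceed <- rowSums(null_counts >= observed)
    p_value <- (1 + n_exceed) / (1 + n_perm)
    dplyr::mutate(
      wm$windows,
      window_size = ws,
      n_genes = as.integer(wm$m %*% rep(1, n_g)),
      observed = as.integer(observed),
      null_mean = rowMeans(null_counts),
      n_exceed = as.integer(n_exceed),
      p_value = p_value,
      significant = p_value < alpha,
      .before = 1
    )
  })
  out <- dplyr::relocate(dplyr::bind_rows(res), "window_size", "start", "end")
  if (bh) {
    out <- dplyr::mutate(out, p_adj = stats::p.adjust(.data$p_value, "BH"),
                         .after = "p_value")
  }
  structure(out, alpha = alpha, n_perm = n_perm,
            class = c("enrichment_result", class(tibble::tibble())))
}
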