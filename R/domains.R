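#' Classify gene pairs by expression correlation across a compendium
#'
#' Computes the Pearson correlation coefficient (PCC) between the expression
#' vectors of every unordered gene pair across the conditions of a
#' compendium, and classifies pairs as correlated (PCC >= `threshold`),
#' anti-correlated (PCC <= `-threshold`) or neither; both thresholds are
#' inclusive. Genes with constant expression (zero variance) have no defined
#' PCC; their pairs are excluded and reported. Correlations are computed in
#' gene blocks so the full dense pair matrix is never held at once, and only
#' the classified (non-"neither") pairs are materialized.
#'
#' @param expr Genes x conditions numeric matrix of log-scale expression
#'   values (rownames = gene ids), at least 3 conditions.
#' @param threshold Absolute PCC threshold (default 0.5).
#' @param block_size Genes per block in the pairwise computation.
#' @return A tibble of classified pairs (`gene_a`, `gene_b`, `pcc`, `class`)
#'   with attributes `n_pairs_total`, `n_neither`, `n_excluded` and
#'   `excluded_genes`.
#' @export
classify_pairs <- function(expr, threshold = 0.5, block_size = 512) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) abort("need at least 3 conditions.")
  if (is.null(rownames(expr))) abort("`expr` must carry gene ids as rownames.")
  sds <- apply(expr, 1, sd)
  excluded_genes <- rownames(expr)[sds == 0]
  keep <- sds > 0
  n_all <- nrow(expr)
  x <- expr[keep, , drop = FALSE]
  n <- nrow(x)
  ids <- rownames(x)
  xt <- t(x)

  blocks <- split(seq_len(n), ceiling(seq_len(n) / block_size))
  hits <- list()
  for (bi in seq_along(blocks)) {
    for (bj in bi:length(blocks)) {
      i <- blocks[[bi]]; j <- blocks[[bj]]
      r <- cor(xt[, i, drop = FALSE], xt[, j, drop = FALSE])
      sel <- which(abs(r) >= threshold & outer(i, j, "<"), arr.ind = TRUE)
      if (nrow(sel)) {
        hits[[length(hits) + 1]] <- tibble::tibble(
          gene_a = ids[i[sel[, 1]]],
          gene_b = ids[j[sel[, 2]]],
          pcc = r[sel]
        )
      }
    }
  }
  out <- if (length(hits)) dplyr::bind_rows(hits) else {
    tibble::tibble(gene_a = character(), gene_b = character(), pcc = numeric())
  }
  out <- dplyr::mutate(
    out,
    class = ifelse(.data$pcc >= threshold, "correlated", "anticorrelated")
  )
  n_kept_pairs <- n * (n - 1) / 2
  structure(
    out,
    threshold = threshold,
    n_pairs_total = n_all * (n_all - 1) / 2,
    n_neither = n_kept_pairs - nrow(out),
    n_excluded = n_all * (n_all - 1) / 2 - n_kept_pairs,
    excluded_genes = excluded_genes,
    class = c("pair_classification", class(tibble::tibble()))
  )
}

#' Bin-pair matrices of correlated and anti-correlated gene pairs
#'
#' Bins the chromosome into fixed segments (100 kb by default), assigns each
#' gene to a bin by midpoint, and counts, for every pair of bins, the gene
#' pairs with correlated and with anti-correlated expression. The two
#' symmetric matrices C (correlated) and A (anti-correlated) are the
#' heatmap-ready summaries in which two chromosomal expression domains show
#' up as blocks: within-domain bin pairs rich in correlated pairs,
#' cross-domain bin pairs rich in anti-correlated ones.
#'
#' @param pairs A `pair_classification` from [classify_pairs()].
#' @param genes Gene annotation tibble (`gene_id`, `start`, `end`).
#' @param chrom A [chromosome_map()].
#' @param bin_size Bin size in bp (default 1e5).
#' @return A `binpair_matrix`: list with `C`, `A` (symmetric integer
#'   matrices, bins x bins; within-bin pairs on the diagonal),
#'   `genes_per_bin`, `bin_size`, `n_bins`.
#' @export
binpair_matrix <- function(pairs, genes, chrom, bin_size = 1e5) {
  genes <- assign_gene_bin(tibble::as_tibble(genes), bin_size)
  n_bins <- as.integer(ceiling(chrom$length_bp / bin_size))
  bin_of <- stats::setNames(genes$bin, genes$gene_id)
  if (!all(c(pairs$gene_a, pairs$gene_b) %in% names(bin_of))) {
    abort("every paired gene must appear in the annotation.")
  }
  count_mat <- function(sub) {
    m <- matrix(0L, n_bins, n_bins)
    if (nrow(sub)) {
      i <- bin_of[sub$gene_a] + 1L
      j <- bin_of[sub$gene_b] + 1L
      lo <- pmin(i, j); hi <- pmax(i, j)
      tab <- table(factor(lo, levels = 1:n_bins), factor(hi, levels = 1:n_bins))
      m <- matrix(as.integer(tab), n_bins, n_bins)
      m <- m + t(m) - diag(diag(m))  # symmetrize; within-bin pairs once
    }
    m
  }
  structure(
    list(
      C = count_mat(pairs[pairs$class == "correlated", ]),
      A = count_mat(pairs[pairs$class == "anticorrelated", ]),
      genes_per_bin = tabulate(genes$bin + 1L, nbins = n_bins),
      bin_size = bin_size,
      n_bins = n_bins
    ),
    class = "binpair_matrix"
  )
}

#' @export
print.binpair_matrix <- function(x, ...) {
  cat(sprintf(
    "<binpair_matrix> %d bins of %s bp; %d correlated and %d anti-correlated pairs\n",
    x$n_bins, format(x$bin_size, big.mark = ","),
    (sum(x$C) + sum(diag(x$C))) / 2, (sum(x$A) + sum(diag(x$A))) / 2
  ))
  invisible(x)
}

#' Extract a two-domain partition of the chromosome
#'
#' Searches exhaustively over all ordered pairs of boundary positions on the
#' circular ring of bins for the two-domain partition maximizing
#' \deqn{\mathrm{score} = \sum_{\mathrm{cross\ pairs}} A_{ij} +
#'       \sum_{\mathrm{same\ side}} C_{ij}}
#' i.e. the split that places anti-correlated gene pairs across domains and
#' correlated pairs within them. Ties go to the smallest first boundary,
#' then the smallest second. This is a formalization of reading the two
#' domain blocks off the bin-pair heatmaps.
#'
#' @param bpm A `binpair_matrix`.
#' @return A `domain_partition`: list with `boundary_1`, `boundary_2`
#'   (0-based bin indices; domain 1 is the circular run of bins
#'   `[boundary_1, boundary_2)`), `score`, `domain1_bins`, `domain2_bins`
#'   (0-based), `n_bins`.
#' @export
domain_boundaries <- function(bpm) {
  stopifnot(inherits(bpm, "binpair_matrix"))
  nb <- bpm$n_bins
  if (nb < 4) abort("need at least 4 bins.")
  if (sum(bpm$A) == 0 && sum(bpm$C) == 0) abort("no structure: A and C are all zero.")
  if (sum(bpm$A) == 0) abort("no structure: no anti-correlated pairs.")

  # pair-count forms: for indicator u (domain 1), same-side pairs s(u) and
  # cross pairs use the symmetric matrices; diagonal holds within-bin pairs
  score_of <- function(u) {
    qc <- (t(u) %*% bpm$C %*% u + t(1 - u) %*% bpm$C %*% (1 - u) +
             sum(diag(bpm$C) * 1)) / 2  # off-diag counted twice, diag once per side
    qa <- t(u) %*% bpm$A %*% (1 - u)    # cross pairs (each unordered pair once per orientation pair)
    as.numeric(qc + qa)
  }
  best <- NULL
  for (b1 in 0:(nb - 1)) {
    for (b2 in 0:(nb - 1)) {
      if (b1 == b2) next
      u <- as.numeric(in_ring(0:(nb - 1), b1, b2, nb))
      sc <- score_of(u)
      if (is.null(best) || sc > best$score + 1e-9) {
        best <- list(boundary_1 = b1, boundary_2 = b2, score = sc, u = u)
      }
    }
  }
  structure(
    list(
      boundary_1 = best$boundary_1,
      boundary_2 = best$boundary_2,
      score = best$score,
      domain1_bins = which(best$u == 1) - 1L,
      domain2_bins = which(best$u == 0) - 1L,
      n_bins = nb
    ),
    class = "domain_partition"
  )
}

in_ring <- function(b, from, to, n) ((b - from) %% n) < ((to - from) %% n)

#' @export
print.domain_partition <- function(x, ...) {
  cat(sprintf(
    "<domain_partition> boundaries at bins %d and %d of %d (score %.0f); domain sizes %d / %d\n",
    x$boundary_1, x$boundary_2, x$n_bins, x$score,
    length(x$domain1_bins), length(x$domain2_bins)
  ))
  invisible(x)
}
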