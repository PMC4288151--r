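test_that("classify_pairs applies inclusive PCC thresholds", {
  x <- c(1, 2, 3, 2, 5, 4, 6, 8)
  expr <- rbind(a = x, b = x + 10, c = -2 * x, d = c(1, 2, 3, 1, 2, 3, 1, 2))
  pairs <- classify_pairs(expr)
  key <- paste(pairs$gene_a, pairs$gene_b)
  expect_equal(pairs$class[key == "a b"], "correlated")   # exact copy, PCC 1
  expect_equal(pairs$class[key == "a c"], "anticorrelated")  # negation, PCC -1
  expect_equal(pairs$pcc[key == "a b"], 1)
  expect_equal(pairs$pcc[key == "a c"], -1)

  # hand computation: r((1,2,3), (1,3,2)) = 0.5, inclusive boundary
  expr2 <- rbind(p = c(1, 2, 3), q = c(1, 3, 2))
  p2 <- classify_pairs(expr2)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$pcc, 0.5)
  expect_equal(p2$class, "correlated")
})

test_that("classification is symmetric and invariant to positive affine maps", {
  set.seed(8)
  expr <- matrix(rnorm(10 * 20), 10, dimnames = list(letters[1:10], NULL))
  p1 <- classify_pairs(expr, threshold = 0.3)
  p_rev <- classify_pairs(expr[10:1, ], threshold = 0.3)
  norm_key <- function(p) sort(paste(pmin(p$gene_a, p$gene_b), pmax(p$gene_a, p$gene_b)))
  expect_equal(norm_key(p1), norm_key(p_rev))

  expr_aff <- expr
  expr_aff["a", ] <- 3 * expr["a", ] + 7
  p_aff <- classify_pairs(expr_aff, threshold = 0.3)
  expect_equal(norm_key(p1), norm_key(p_aff))
})

test_that("pair accounting is conserved and constant genes are excluded", {
  set.seed(9)
  expr <- matrix(rnorm(8 * 10), 8, dimnames = list(letters[1:8], NULL))
  expr["h", ] <- 4  # constant gene
  pairs <- classify_pairs(expr, threshold = 0.4)
  expect_equal(attr(pairs, "excluded_genes"), "h")
  expect_equal(attr(pairs, "n_excluded"), 7)  # pairs involving h
  expect_equal(nrow(pairs) + attr(pairs, "n_neither") + attr(pairs, "n_excluded"),
               attr(pairs, "n_pairs_total"))
  expect_equal(attr(pairs, "n_pairs_total"), 8 * 7 / 2)
  # block size does not change the result
  p_small <- classify_pairs(expr, threshold = 0.4, block_size = 3)
  expect_equal(dplyr::arrange(as.data.frame(pairs), gene_a, gene_b),
               dplyr::arrange(as.data.frame(p_small), gene_a, gene_b))
})

test_that("binpair_matrix counts within- and cross-bin pairs", {
  chrom <- toy_chrom(2e5)
  genes <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    start = c(0, 10, 1e5, 1e5 + 10), end = c(9, 19, 1e5 + 9, 1e5 + 19)
  )
  # all 6 pairs correlated: identical vectors
  expr <- matrix(rep(c(1, 2, 3, 4), 4), 4, byrow = TRUE,
                 dimnames = list(genes$gene_id, NULL))
  pairs <- classify_pairs(expr)
  bpm <- binpair_matrix(pairs, genes, chrom, bin_size = 1e5)
  expect_equal(bpm$C, matrix(c(1L, 4L, 4L, 1L), 2))
  expect_equal(bpm$A, matrix(0L, 2, 2))
  expect_equal(bpm$genes_per_bin, c(2, 2))
  expect_true(isSymmetric(bpm$C))
  expect_equal(glance(bpm)$correlated_pairs, 6)

  # no pair classified -> zero matrices
  set.seed(10)
  noise <- matrix(rnorm(4 * 100), 4, dimnames = list(genes$gene_id, NULL))
  p0 <- classify_pairs(noise, threshold = 0.99)
  bpm0 <- binpair_matrix(p0, genes, chrom, bin_size = 1e5)
  expect_true(all(bpm0$C == 0) && all(bpm0$A == 0))
})

test_that("anti-correlated pairs concentrate in cross-domain bin pairs", {
  chrom <- preset_chromosome("full")
  genes <- simulate_gene_annotation(chrom, 400)
  dom <- genomic_segment(1e6, 3.3e6)
  y <- simulate_compendium(genes, chrom, dom, n_conditions = 300,
                           loading = 3, noise_sd = 1, seed = 14)
  pairs <- classify_pairs(y)
  bpm <- binpair_matrix(pairs, genes, chrom, bin_size = 1e5)
  dom_bin <- function(b) b >= 10 & b < 33
  bins <- 0:(bpm$n_bins - 1)
  cross <- outer(dom_bin(bins), dom_bin(bins), "!=")
  a_total <- (sum(bpm$A) + sum(diag(bpm$A))) / 2
  a_cross <- sum(bpm$A[cross]) / 2
  expect_gte(a_cross / a_total, 0.8)
})

test_that("domain_boundaries recovers a planted two-domain structure", {
  chrom <- preset_chromosome("full")
  genes <- simulate_gene_annotation(chrom, 400)
  dom <- genomic_segment(1e6, 3.3e6)  # bins 10..32 of 46
  y <- simulate_compendium(genes, chrom, dom, n_conditions = 300,
                           loading = 3, noise_sd = 1, seed = 16)
  part <- domain_boundaries(binpair_matrix(classify_pairs(y), genes, chrom))
  b <- sort(c(part$boundary_1, part$boundary_2))
  expect_lte(abs(b[1] - 10), 1)
  expect_lte(abs(b[2] - 33), 1)
})

test_that("a single cross entry forces the partition that separates it", {
  bpm <- structure(list(
    C = matrix(0L, 6, 6), A = matrix(0L, 6, 6),
    genes_per_bin = rep(2, 6), bin_size = 100, n_bins = 6L
  ), class = "binpair_matrix")
  bpm$A[2, 5] <- bpm$A[5, 2] <- 3L
  part <- domain_boundaries(bpm)
  side <- oriterscan:::in_ring(0:5, part$boundary_1, part$boundary_2, 6)
  expect_true(xor(side[2], side[5]))
  expect_equal(part$score, 3)
})

test_that("domain extraction is equivariant under bin rotation", {
  chrom <- preset_chromosome("full")
  genes <- simulate_gene_annotation(chrom, 300)
  y <- simulate_compendium(genes, chrom, genomic_segment(1e6, 3.3e6),
                           n_conditions = 200, loading = 3, seed = 17)
  pairs <- classify_pairs(y)
  bpm <- binpair_matrix(pairs, genes, chrom)
  part <- domain_boundaries(bpm)
  rot <- 7L
  perm <- ((0:(bpm$n_bins - 1) - rot) %% bpm$n_bins) + 1L  # new index b holds old b - rot
  bpm_r <- bpm
  bpm_r$C <- bpm$C[perm, perm]
  bpm_r$A <- bpm$A[perm, perm]
  part_r <- domain_boundaries(bpm_r)
  expect_setequal(
    sort(c(part_r$boundary_1, part_r$boundary_2)),
    sort((c(part$boundary_1, part$boundary_2) + rot) %% bpm$n_bins)
  )
})

test_that("structureless input is rejected or scores like its rotation null", {
  bpm0 <- structure(list(C = matrix(0L, 5, 5), A = matrix(0L, 5, 5),
                         genes_per_bin = rep(1, 5), bin_size = 100, n_bins = 5L),
                    class = "binpair_matrix")
  expect_error(domain_boundaries(bpm0), "no structure")

  # null compendium: few or no classified pairs; when any anti-correlated
  # pairs arise by chance, the best split's score is indistinguishable from
  # circularly rotated gene-position assignments
  chrom <- preset_chromosome("full")
  genes <- simulate_gene_annotation(chrom, 300)
  y <- simulate_compendium(genes, chrom, genomic_segment(1e6, 3.3e6),
                           n_conditions = 300, loading = 0, seed = 18)
  pairs <- classify_pairs(y)
  expect_lt(nrow(pairs) / attr(pairs, "n_pairs_total"), 0.001)
  if (nrow(pairs) > 0 && any(pairs$class == "anticorrelated")) {
    bpm <- binpair_matrix(pairs, genes, chrom)
    obs <- domain_boundaries(bpm)$score
    null_scores <- vapply(seq_len(20), function(r) {
      g_rot <- genes
      g_rot$start <- (genes$start + r * 2e5) %% chrom$length_bp
      g_rot$end <- g_rot$start + (genes$end - genes$start)
      domain_boundaries(binpair_matrix(pairs, g_rot, chrom))$score
    }, numeric(1))
    expect_lte(obs, max(null_scores))
  }
})
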