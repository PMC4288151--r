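# Shared fixtures: small chromosomes and gene tables built in code.

toy_chrom <- function(length_bp = 1e6) {
  chromosome_map(length_bp, ori_pos = 0, ter_pos = length_bp / 2)
}

# n genes of equal width tiling a toy chromosome exactly (no gaps)
tiling_genes <- function(chrom, n) {
  w <- chrom$length_bp / n
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    start = w * (seq_len(n) - 1),
    end = w * seq_len(n),
    strand = "+"
  )
}

# constant-count coverage track
constant_track <- function(chrom, count, width_bp = 200) {
  trk <- simulate_population_coverage(chrom, genomic_segment(0, chrom$length_bp / 2),
                                      prevalence = 0, mean_depth = 1,
                                      width_bp = width_bp, seed = 1)
  trk$count <- rep(count, nrow(trk))
  trk
}

expect_same_tibble <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
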