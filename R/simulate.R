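#' Simulate read coverage from a mixed population of genomic DNA molecules
#'
#' Generates a per-bin coverage track for a circular chromosome in which a
#' structural variant — a tandem duplication of `dup_segment`, or a deletion
#' of it — is present in a fraction `prevalence` of the genomic DNA
#' molecules. Bin counts are independent Poisson draws: under a duplication,
#' the expectation is `mean_depth * (1 + prevalence)` inside the segment and
#' `mean_depth` outside; under a deletion it is `mean_depth * (1 -
#' prevalence)` inside the deleted segment and `mean_depth` outside.
#' Per-bin Poisson counts are the sufficient statistics of uniform
#' read sampling for every downstream analysis, so reads themselves are not
#' materialized (see [simulate_read_starts()] when positions are needed).
#'
#' @param chrom A [chromosome_map()], e.g. [preset_chromosome()].
#' @param dup_segment The variant [genomic_segment()].
#' @param prevalence Fraction of molecules carrying the variant, in `[0, 1]`.
#' @param scenario `"duplication"` or `"deletion"`.
#' @param mean_depth Expected reads per bin in unaffected regions
#'   (default 250).
#' @param width_bp Bin width in bp (default 200).
#' @param seed Integer seed; the same seed and parameters give bit-identical
#'   tracks.
#' @return A `coverage_track` (see [bin_coverage()]).
#' @examples
#' chrom <- preset_chromosome("desk")
#' trk <- simulate_population_coverage(chrom, preset_dup_segment(chrom),
#'                                     prevalence = 0.8, seed = 1)
#' @export
simulate_population_coverage <- function(chrom, dup_segment,
                                         prevalence,
                                         scenario = c("duplication", "deletion"),
                                         mean_depth = 250, width_bp = 200,
                                         seed = NULL) {
  scenario <- match.arg(scenario)
  if (prevalence < 0 || prevalence > 1) abort("`prevalence` must be in [0, 1].")
  if (mean_depth <= 0) abort("`mean_depth` must be positive.")
  bins <- make_bins(chrom, width_bp)
  inside <- in_segment(bins$start, dup_segment, chrom)
  lambda <- bin_lambda(inside, scenario, prevalence, mean_depth) *
    (bins$width / width_bp)  # partial bin gets proportionally fewer reads
  if (!is.null(seed)) set.seed(seed)
  counts <- rpois(nrow(bins), lambda)
  new_coverage_track(dplyr::mutate(bins, count = counts), chrom, width_bp)
}

bin_lambda <- function(inside, scenario, prevalence, mean_depth) {
  if (scenario == "duplication") {
    ifelse(inside, mean_depth * (1 + prevalence), mean_depth)
  } else {
    ifelse(inside, mean_depth * (1 - prevalence), mean_depth)
  }
}

#' @rdname simulate_population_coverage
#' @return `simulate_read_starts()`: a sorted integer vector of read-start
#'   positions drawn uniformly within each bin, with per-bin totals Poisson
#'   as above — the read-level counterpart used to exercise [bin_coverage()].
#' @export
simulate_read_starts <- function(chrom, dup_segment, prevalence,
                                 scenario = c("duplication", "deletion"),
                                 mean_depth = 250, width_bp = 200, seed = NULL) {
  trk <- simulate_population_coverage(chrom, dup_segment, prevalence, scenario,
                                      mean_depth, width_bp, seed)
  starts <- purrr::pmap(
    list(trk$start, trk$end, trk$count),
    function(s, e, k) if (k > 0) s + floor(runif(k, 0, e - s)) else numeric()
  )
  sort(unlist(starts))
}

#' Simulate an expression compendium with two anti-correlated chromosomal domains
#'
#' Generates a genes-by-conditions matrix of log-scale expression values
#' emulating an RMA-normalized microarray compendium in which a single latent
#' condition factor loads positively on genes of an origin-centred
#' chromosomal domain and negatively on genes of the terminus-centred
#' complement:
#' \deqn{y_{gc} = \mu_g + s_g \, a \, z_c + \epsilon_{gc}}
#' with \eqn{z_c} standard normal per condition, \eqn{s_g = +1} for genes
#' whose midpoint lies in `domain_segment` and \eqn{-1} otherwise, and
#' \eqn{\epsilon} Gaussian noise. Cross-domain gene pairs then have
#' population correlation \eqn{-a^2 / (a^2 + \sigma^2)}, within-domain pairs
#' the same magnitude positive; `loading = 0` gives a null compendium with no
#' positional structure.
#'
#' @param genes Gene annotation tibble (`gene_id`, `start`, `end`).
#' @param chrom A [chromosome_map()].
#' @param domain_segment [genomic_segment()] delimiting the origin domain;
#'   genes are assigned by midpoint.
#' @param n_conditions Number of conditions (default 300, compendium scale).
#' @param loading Effect size `a` of the latent factor (>= 0).
#' @param noise_sd Residual standard deviation (default 1).
#' @param baseline_mean,baseline_sd Per-gene baseline levels are drawn
#'   Normal(`baseline_mean`, `baseline_sd`), mimicking log-scale RMA values.
#' @param seed Integer seed.
#' @return A numeric matrix (genes x conditions, dimnames set) with the
#'   per-gene domain signs as attribute `domain_sign`.
#' @export
simulate_compendium <- function(genes, chrom, domain_segment,
                                n_conditions = 300, loading = 3, noise_sd = 1,
                                baseline_mean = 8, baseline_sd = 1,
                                seed = NULL) {
  if (loading < 0) abort("`loading` must be non-negative.")
  if (n_conditions < 3) abort("need at least 3 conditions.")
  genes <- tibble::as_tibble(genes)
  mid <- floor((genes$start + genes$end) / 2)
  s <- ifelse(in_segment(mid, domain_segment, chrom), 1, -1)
  n_g <- nrow(genes)
  if (!is.null(seed)) set.seed(seed)
  mu <- rnorm(n_g, baseline_mean, baseline_sd)
  z <- rnorm(n_conditions)
  eps <- matrix(rnorm(n_g * n_conditions, sd = noise_sd), n_g, n_conditions)
  y <- mu + outer(s * loading, z) + eps
  dimnames(y) <- list(genes$gene_id, sprintf("cond_%03d", seq_len(n_conditions)))
  attr(y, "domain_sign") <- stats::setNames(s, genes$gene_id)
  y
}

#' Simulate replicate count matrices with planted regulon and dosage effects
#'
#' Generates raw read counts for two strains (`A`, the perturbed strain, and
#' `B`, the reference) with planted effects of two kinds: transcriptional
#' effects (per-gene-set log2 fold changes of strain A over B) and a gene
#' dosage effect (genes whose midpoint lies in `amplified_segment` have their
#' strain-A expectations multiplied by `dosage_factor`, emulating a segmental
#' duplication present in part of the population). Counts are Poisson (or
#' negative binomial) around library-size-scaled means. A truth table records
#' each gene's planted transcriptional log2 effect and the dosage factor
#' applied, so callers can score recovery.
#'
#' @param genes Gene annotation tibble (`gene_id`, `start`, `end`).
#' @param chrom A [chromosome_map()].
#' @param gene_sets Named list of disjoint gene-id vectors (e.g.
#'   `hns_targets`, `high_expressed`, `rpoS_regulon`).
#' @param set_effects Named numeric vector of log2 effects, one per gene set.
#' @param amplified_segment Optional [genomic_segment()] carrying the dosage
#'   effect in strain A.
#' @param dosage_factor Multiplier on strain-A means inside
#'   `amplified_segment` (1 + prevalence of the duplication; default 1, no
#'   dosage effect).
#' @param n_reps Replicates per strain (default 2).
#' @param base_mean Expected counts per gene in strain B at library size 1
#'   (default 500). A single number or one value per gene.
#' @param lib_sizes Optional relative library sizes, one per sample
#'   (length `2 * n_reps`, strain A first); default all 1.
#' @param dispersion `"poisson"` or `"nb"`.
#' @param nb_size Negative-binomial size parameter when `dispersion = "nb"`.
#' @param seed Integer seed.
#' @return A list with `counts` (genes x samples integer matrix), `samples`
#'   (tibble: `sample`, `strain`, `replicate`, `lib_size`, `amplified`) and
#'   `truth` (tibble: `gene_id`, `log2_effect`, `dosage_factor`).
#' @export
simulate_de_counts <- function(genes, chrom,
                               gene_sets = list(), set_effects = numeric(),
                               amplified_segment = NULL, dosage_factor = 1,
                               n_reps = 2, base_mean = 500, lib_sizes = NULL,
                               dispersion = c("poisson", "nb"), nb_size = 10,
                               seed = NULL) {
  dispersion <- match.arg(dispersion)
  genes <- tibble::as_tibble(genes)
  ids <- genes$gene_id
  if (anyDuplicated(ids)) abort("gene ids must be unique.")
  all_set <- unlist(gene_sets, use.names = FALSE)
  if (anyDuplicated(all_set)) abort("gene sets must be disjoint.")
  if (!all(all_set %in% ids)) abort("gene sets must be subsets of the annotation.")
  if (length(gene_sets) && !setequal(names(gene_sets), names(set_effects))) {
    abort("`set_effects` must name the same sets as `gene_sets`.")
  }

  effect <- stats::setNames(rep(0, length(ids)), ids)
  for (nm in names(gene_sets)) effect[gene_sets[[nm]]] <- set_effects[[nm]]

  dosage <- rep(1, length(ids))
  if (!is.null(amplified_segment) && dosage_factor != 1) {
    mid <- floor((genes$start + genes$end) / 2)
    dosage[in_segment(mid, amplified_segment, chrom)] <- dosage_factor
  }

  n_samples <- 2L * n_reps
  if (is.null(lib_sizes)) lib_sizes <- rep(1, n_samples)
  if (length(lib_sizes) != n_samples) abort("`lib_sizes` must have one value per sample.")
  if (any(lib_sizes <= 0)) abort("library sizes must be positive.")

  samples <- tibble::tibble(
    sample = c(sprintf("A_%d", seq_len(n_reps)), sprintf("B_%d", seq_len(n_reps))),
    strain = rep(c("A", "B"), each = n_reps),
    replicate = rep(seq_len(n_reps), 2),
    lib_size = lib_sizes,
    amplified = rep(c(!is.null(amplified_segment) && dosage_factor != 1, FALSE),
                    each = n_reps)
  )

  mu_b <- rep_len(base_mean, length(ids))
  mu_a <- mu_b * 2^effect * dosage
  mu <- cbind(
    matrix(rep(mu_a, n_reps), ncol = n_reps),
    matrix(rep(mu_b, n_reps), ncol = n_reps)
  ) %*% diag(lib_sizes, n_samples)

  if (!is.null(seed)) set.seed(seed)
  counts <- if (dispersion == "poisson") {
    matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = nb_size), nrow(mu), ncol(mu))
  }
  dimnames(counts) <- list(ids, samples$sample)

  list(
    counts = counts,
    samples = samples,
    truth = tibble::tibble(gene_id = ids, log2_effect = unname(effect),
                           dosage_factor = dosage)
  )
}

#' Simulate an even gene annotation along a chromosome
#'
#' Places `n_genes` equally sized, equally spaced genes around the replicon —
#' a neutral annotation for synthetic experiments where only gene position
#' matters.
#'
#' @param chrom A [chromosome_map()].
#' @param n_genes Number of genes.
#' @param gene_length Gene length in bp; default 60% of the spacing.
#' @return A tibble with `gene_id`, `start`, `end`, `strand`.
#' @export
simulate_gene_annotation <- function(chrom, n_genes, gene_length = NULL) {
  spacing <- chrom$length_bp / n_genes
  if (is.null(gene_length)) gene_length <- floor(0.6 * spacing)
  starts <- floor(spacing * (seq_len(n_genes) - 1))
  tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    start = starts,
    end = pmin(starts + gene_length, chrom$length_bp),
    strand = rep_len(c("+", "-"), n_genes)
  )
}
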