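test_that("bin_coverage counts read starts with half-open bins", {
  chrom <- chromosome_map(1000)
  trk <- bin_coverage(c(0, 50, 199), chrom, 200)
  expect_equal(trk$count, c(3, 0, 0, 0, 0))
  expect_equal(bin_coverage(200, chrom, 200)$count, c(0, 1, 0, 0, 0))
  expect_error(bin_coverage(1000, chrom, 200), "length_bp")
})

test_that("bin_coverage matches a brute-force histogram on random reads", {
  chrom <- chromosome_map(10000)
  set.seed(3)
  reads <- floor(runif(10000, 0, 10000))
  trk <- bin_coverage(reads, chrom, 200)
  brute <- vapply(seq(0, 9800, by = 200), function(s) {
    sum(reads >= s & reads < s + 200)
  }, numeric(1))
  expect_equal(trk$count, brute)
  expect_equal(sum(trk$count), 10000)
})

test_that("round trip: simulated read starts re-bin to the simulated track", {
  chrom <- preset_chromosome("desk")
  seg <- preset_dup_segment(chrom)
  reads <- simulate_read_starts(chrom, seg, 0.5, mean_depth = 5, seed = 9)
  trk <- simulate_population_coverage(chrom, seg, 0.5, mean_depth = 5, seed = 9)
  expect_equal(bin_coverage(reads, chrom, 200)$count, trk$count)
})

test_that("mode_normalize centres the modal coverage at log2 = 0", {
  chrom <- chromosome_map(10000)
  trk <- constant_track(chrom, 100)
  norm <- mode_normalize(trk)
  # mode factor within one histogram cell (factor 2^0.1) of count + 1
  expect_lt(abs(log2(attr(norm, "mode_factor")) - log2(101)), 0.1)
  expect_true(all(abs(norm$log2) < 0.1))
})

test_that("mode_normalize picks the majority level in a bimodal track", {
  chrom <- chromosome_map(10000)  # 50 bins
  trk <- constant_track(chrom, 100)
  trk$count <- rep(c(100, 100, 100, 180, 180), 10)  # 60% at 100, 40% at 180
  norm <- mode_normalize(trk)
  lin <- 2^norm$log2
  expect_lt(abs(log2(attr(norm, "mode_factor")) - log2(101)), 0.1)
  expect_true(all(abs(lin[trk$count == 100] - 1.0) < 0.05))
  expect_true(all(abs(lin[trk$count == 180] - 1.8) < 0.09))
})

test_that("mode-normalized values are invariant to global depth scaling", {
  chrom <- preset_chromosome("desk")
  trk <- simulate_population_coverage(chrom, preset_dup_segment(chrom), 0.8,
                                      mean_depth = 250, seed = 4)
  trk4 <- trk
  trk4$count <- trk$count * 4
  d <- mode_normalize(trk4)$log2 - mode_normalize(trk)$log2
  # +1 pseudocount and mode-cell quantization allow up to one cell of drift
  expect_true(all(abs(d - mean(d)) < 0.05))
  expect_lt(abs(mean(d)), 0.1)
})

test_that("mode_normalize rejects degenerate tracks", {
  chrom <- chromosome_map(10000)
  z <- constant_track(chrom, 0)
  expect_error(mode_normalize(z), "zero")
  few <- chromosome_map(1000)
  expect_error(mode_normalize(constant_track(few, 5)), "fewer than 10")
})

test_that("compute_rc returns linear-scale mean ratios", {
  chrom <- chromosome_map(10000)
  trk <- constant_track(chrom, 250)
  seg <- genomic_segment(0, 4000)
  norm <- mode_normalize(trk)
  expect_equal(compute_rc(norm, seg)$Rc, 1.0)

  # planted exact 2x segment on a noiseless track
  trk$count <- ifelse(trk$start < 4000, 2000, 1000)
  rc <- compute_rc(mode_normalize(trk), seg)
  expect_equal(rc$Rc, 2001 / 1001, tolerance = 1e-12)
  expect_equal(rc$Rc, 2.0, tolerance = 2e-3)
  expect_error(compute_rc(mode_normalize(trk), genomic_segment(0, 10000 - 200)),
               NA) # 1 bin outside is enough
  expect_error(compute_rc(mode_normalize(trk), genomic_segment(0, 10000 - 1)),
               "outside") # every bin start falls inside: nothing left outside
})

test_that("Rc is invariant to multiplying all counts by a constant", {
  chrom <- preset_chromosome("desk")
  seg <- preset_dup_segment(chrom)
  trk <- simulate_population_coverage(chrom, seg, 0.5, mean_depth = 200, seed = 21)
  rc1 <- compute_rc(mode_normalize(trk), seg)$Rc
  for (c_mult in c(3, 10)) {
    trk_c <- trk
    trk_c$count <- trk$count * c_mult
    rc_c <- compute_rc(mode_normalize(trk_c), seg)$Rc
    expect_equal(rc_c, rc1, tolerance = 0.02)
  }
})

test_that("Rc is monotone in planted duplication prevalence", {
  chrom <- preset_chromosome("full")
  seg <- preset_dup_segment(chrom)
  rcs <- vapply(c(0, 0.25, 0.5, 0.8, 1), function(f) {
    trk <- simulate_population_coverage(chrom, seg, f, mean_depth = 250,
                                        seed = 31)
    compute_rc(mode_normalize(trk), seg)$Rc
  }, numeric(1))
  expect_true(all(diff(rcs) > 0))
  expect_equal(rcs, 1 + c(0, 0.25, 0.5, 0.8, 1), tolerance = 0.02)
})

test_that("detect_breakpoints recovers planted boundaries", {
  chrom <- preset_chromosome("desk")
  # planted boundaries at bins 400 and 1400 of 2300
  seg <- genomic_segment(400 * 200, 1400 * 200)
  trk <- simulate_population_coverage(chrom, seg, 0.8, mean_depth = 250, seed = 8)
  bp <- detect_breakpoints(mode_normalize(trk))
  expect_lte(abs(bp$boundary_1 / 200 - 400), 1)
  expect_lte(abs(bp$boundary_2 / 200 - 1400), 1)
  expect_gt(bp$Rc, 1.7)
})

test_that("detect_breakpoints is equivariant under rotation", {
  chrom <- preset_chromosome("desk")
  seg <- genomic_segment(400 * 200, 1400 * 200)
  trk <- simulate_population_coverage(chrom, seg, 0.8, mean_depth = 250, seed = 8)
  shift_bins <- 537
  rot <- trk
  rot$count <- trk$count[((seq_len(nrow(trk)) - 1 - shift_bins) %% nrow(trk)) + 1]
  bp0 <- detect_breakpoints(mode_normalize(trk))
  bp1 <- detect_breakpoints(mode_normalize(rot))
  expect_equal(bp1$boundary_1, (bp0$boundary_1 + shift_bins * 200) %% chrom$length_bp)
  expect_equal(bp1$boundary_2, (bp0$boundary_2 + shift_bins * 200) %% chrom$length_bp)
})

test_that("detect_breakpoints on a structureless track reports Rc near 1", {
  chrom <- preset_chromosome("desk")
  for (s in 1:3) {
    trk <- simulate_population_coverage(chrom, preset_dup_segment(chrom), 0,
                                        mean_depth = 250, seed = 300 + s)
    rc <- detect_breakpoints(mode_normalize(trk))$Rc
    expect_gte(rc, 0.98)
    expect_lte(rc, 1.05)
  }
})

test_that("candidate mode prefers the true pair over decoys on noiseless input", {
  chrom <- preset_chromosome("desk")
  trk <- constant_track(chrom, 1000)
  truth <- c(500, 1500) * 200
  trk$count <- ifelse(trk$start >= truth[1] & trk$start < truth[2], 2000, 1000)
  norm <- mode_normalize(trk)
  decoys <- c(100, 900, 1700, 2100) * 200
  bp <- detect_breakpoints(norm, candidates = c(truth, decoys))
  expect_equal(c(bp$boundary_1, bp$boundary_2), truth)
  # oracle equivalence: exhaustive stride-1 scan lands on the same pair
  ex <- detect_breakpoints(norm, exhaustive = TRUE)
  expect_equal(c(ex$boundary_1, ex$boundary_2), truth)
})

test_that("classify_pattern applies an inclusive Rc threshold", {
  fake_rc <- function(rc) structure(list(Rc = rc), class = "rc_result")
  expect_true(classify_pattern(fake_rc(1.8)))
  expect_false(classify_pattern(fake_rc(1.02)))
  expect_true(classify_pattern(fake_rc(1.5)))
  expect_false(classify_pattern(fake_rc(1.49), threshold = 1.5))
})
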