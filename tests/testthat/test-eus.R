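test_that("colony filter applies strict head and total N fractions", {
  clean <- paste(rep("A", 600), collapse = "")
  head_1n <- paste0("N", substr(clean, 2, 600))
  five_n <- paste0(substr(clean, 1, 100),
                   paste(rep("N", 5), collapse = ""),
                   substr(clean, 106, 600))
  six_n <- paste0(substr(clean, 1, 100),
                  paste(rep("N", 6), collapse = ""),
                  substr(clean, 107, 600))
  short <- "ACGTACGTAC"
  reads <- reads_from_strings(c(clean, head_1n, five_n, six_n, short))
  kept <- filter_colonies(reads)
  # 1 N in the first 20 bases is 5%, not < 5% -> fail; 5 Ns in 600 bases is
  # < 1% -> pass; 6 Ns is exactly 1% -> fail; short reads are rejected
  expect_equal(kept$read_id, c("r001", "r003"))
  expect_equal(attr(kept, "rejects"),
               c(too_short = 1L, head_n = 1L, total_n = 1L))
})

test_that("direction assignment matches primer prefixes, N = mismatch", {
  reads <- reads_from_strings(c(
    "ACGTAGGTTTT",   # forward primer prefix
    "TTGCAGGGGGG",   # reverse primer prefix
    "GGGGGGGGGGG",   # neither
    "NCGTAGGTTTT"    # N in primer region counts as mismatch
  ))
  out <- assign_direction(reads, "ACGTA", "TTGCA")
  expect_equal(out$direction,
               c("forward", "reverse", "unknown", "unknown"))
  expect_equal(assign_direction(reads[4, ], "ACGTA", "TTGCA",
                                max_mismatch = 1)$direction, "forward")
  expect_error(assign_direction(reads_from_strings("ACGTAGG"),
                                "ACGTA", "ACGTA"),
               "both primers")
})

test_that("directional consensus counts bases and truncates at coverage", {
  prof <- build_directional_consensus(
    reads_from_strings(c("ACGT", "ACGT", "ACGT")), min_coverage = 1
  )
  expect_equal(consensus_string(prof), "ACGT")
  expect_equal(prof$agreement, rep(100, 4))
  expect_equal(prof$coverage, rep(3L, 4))

  prof2 <- build_directional_consensus(
    reads_from_strings(c("ACGT", "ACGA", "ACGT")), min_coverage = 1
  )
  expect_equal(prof2$A[4], 1L)
  expect_equal(prof2$T[4], 2L)
  expect_equal(consensus_string(prof2), "ACGT")
  expect_equal(prof2$agreement[4], 100 * 2 / 3, tolerance = 1e-9)

  # truncation: last position with coverage >= min_coverage
  prof3 <- build_directional_consensus(
    reads_from_strings(c("ACGTTT", "ACG")), min_coverage = 2
  )
  expect_equal(nrow(prof3), 3L)
  expect_error(build_directional_consensus(reads_from_strings(character())),
               "no reads")
})

test_that("consensus on error-free simulated reads recovers the template", {
  amp <- make_amplicon(600, seed = 41)
  reads <- simulate_eus_reads(amp$template, n_reads = 150,
                              read_length = 600,
                              error_rate_5prime = 0, error_rate_3prime = 0,
                              p_lowq = 0, orientation_mix = 1, seed = 5)
  prof <- build_directional_consensus(reads, min_coverage = 100)
  expect_equal(consensus_string(prof), amp$template)
  expect_true(all(prof$agreement == 100))
})

test_that("merge picks the longest qualifying overlap (brute-force oracle)", {
  # known template ACGTACGTACGGTTAA split into overlapping halves
  fwd <- build_directional_consensus(reads_from_strings("ACGTACGTAC"),
                                     min_coverage = 1)
  rev <- build_directional_consensus(
    reads_from_strings(reverse_complement("GTACGGTTAA")), min_coverage = 1
  )
  oracle <- oracle_overlap("ACGTACGTAC", "GTACGGTTAA",
                           min_overlap = 4, min_identity = 0.9)
  res <- merge_consensus(fwd, rev, min_overlap = 4)
  expect_equal(res$overlap_length, oracle)
  expect_equal(res$overlap_length, 4L)
  expect_equal(nrow(res$profile), 16L)
  expect_equal(consensus_string(res$profile), "ACGTACGTACGGTTAA")
  expect_equal(res$forward_span, c(1L, 10L))
  expect_equal(res$reverse_span, c(7L, 16L))
})

test_that("merge of identical profiles spans the full length; disjoint fails", {
  seqs <- c("ACGTACGTACGGTTAA", "ACGTACGTACGGTTAA")
  fwd <- build_directional_consensus(reads_from_strings(seqs),
                                     min_coverage = 1)
  rev <- build_directional_consensus(
    reads_from_strings(reverse_complement(seqs)), min_coverage = 1
  )
  res <- merge_consensus(fwd, rev, min_overlap = 10)
  expect_equal(res$overlap_length, 16L)
  expect_equal(consensus_string(res$profile), seqs[1])
  # summed counts: overlap coverage doubles
  expect_equal(unique(res$profile$coverage), 4L)

  other <- build_directional_consensus(
    reads_from_strings(reverse_complement(random_dna(30, seed = 99))),
    min_coverage = 1
  )
  expect_error(merge_consensus(fwd, other, min_overlap = 10),
               class = "barcodekit_merge_failure")
})

test_that("merging is symmetric under swapping forward and reverse roles", {
  amp <- make_amplicon(500, seed = 13)
  reads <- simulate_eus_reads(amp$template, n_reads = 60,
                              read_length = 300,
                              error_rate_5prime = 0, error_rate_3prime = 0,
                              p_lowq = 0, seed = 3)
  fwd <- build_directional_consensus(
    dplyr::filter(reads, direction == "forward"), min_coverage = 1
  )
  rev <- build_directional_consensus(
    dplyr::filter(reads, direction == "reverse"), min_coverage = 1
  )
  ab <- merge_consensus(fwd, rev)
  ba <- merge_consensus(rev, fwd)
  expect_equal(reverse_complement(consensus_string(ba$profile)),
               consensus_string(ab$profile))
  expect_equal(ab$overlap_length, ba$overlap_length)
})

test_that("end-to-end assembly recovers template and constructed overlap", {
  # template sized so the two 300-base read sets overlap by exactly 116
  overlap <- 116
  read_len <- 300
  amp <- make_amplicon(2 * read_len - overlap, seed = 23)
  reads <- simulate_eus_reads(amp$template, n_reads = 600,
                              read_length = read_len,
                              error_rate_5prime = 0, error_rate_3prime = 0,
                              p_lowq = 0, seed = 7)
  res <- eus_assemble(reads, amp$forward_primer, amp$reverse_primer,
                      min_coverage = 100)
  expect_equal(res$consensus, amp$template)
  expect_equal(res$overlap_length, 116L)
  expect_true(all(res$profile$agreement == 100))
})

test_that("assembly with substitution errors still recovers the template", {
  read_len <- 300
  amp <- make_amplicon(2 * read_len - 116, seed = 29)
  reads <- simulate_eus_reads(amp$template, n_reads = 800,
                              read_length = read_len,
                              error_rate_5prime = 0.01,
                              error_rate_3prime = 0.03,
                              p_lowq = 0.005, seed = 17)
  res <- eus_assemble(reads, amp$forward_primer, amp$reverse_primer,
                      min_coverage = 100)
  expect_equal(res$consensus, amp$template)
  expect_gt(min(res$profile$agreement), 90)
  expect_lt(res$stage_counts[["passed_filter"]],
            res$stage_counts[["input"]])
})

test_that("single-direction input fails with an insufficient-coverage error", {
  amp <- make_amplicon(400, seed = 31)
  reads <- simulate_eus_reads(amp$template, n_reads = 100,
                              read_length = 300,
                              error_rate_5prime = 0, error_rate_3prime = 0,
                              p_lowq = 0, orientation_mix = 0, seed = 2)
  expect_error(
    eus_assemble(reads, amp$forward_primer, amp$reverse_primer,
                 min_coverage = 10),
    class = "barcodekit_coverage_failure"
  )
})

test_that("agreement does not decrease when duplicate error-free reads are added", {
  base <- c("ACGTACGTAC", "ACGAACGTAC", "ACGTACGTAC")
  p1 <- build_directional_consensus(reads_from_strings(base),
                                    min_coverage = 1)
  p2 <- build_directional_consensus(
    reads_from_strings(c(base, "ACGTACGTAC", "ACGTACGTAC")),
    min_coverage = 1
  )
  expect_true(all(p2$agreement >= p1$agreement))
})
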