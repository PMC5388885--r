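test_that("CRB construction indexes barcodes and materializes combined locus", {
  recs <- barcode_records(
    species = rep(c("A a", "B b", "C c"), each = 2),
    specimen_id = rep(c("s1", "s2", "s3"), each = 2),
    locus = rep(c("rbcL", "matK"), 3),
    sequence = c("AAAA", "CCCC", "AAAA", "GGGG", "TTTT", "GGGG")
  )
  crb <- build_crb(recs)
  expect_setequal(crb$loci, c("rbcL", "matK", "rbcL+matK"))
  combined <- crb$records[crb$records$locus == "rbcL+matK", ]
  expect_equal(nrow(combined), 3L)
  expect_equal(combined$sequence[combined$specimen_id == "s1"], "AAAACCCC")
  # rbcL AAAA is carried by two species
  idx <- crb$barcode_index[["rbcL"]]
  expect_equal(idx$n_species[idx$sequence == "AAAA"], 2L)

  # specimen missing one locus is excluded from the combined locus only
  partial <- build_crb(recs[-2, ])
  expect_equal(sum(partial$records$locus == "rbcL+matK"), 2L)
  expect_true("s1" %in%
                partial$records$specimen_id[partial$records$locus == "rbcL"])

  expect_error(build_crb(recs[c(1, 1), ]), "duplicate")
})

test_that("IRB sampling reaches exactly n_species and is seed-deterministic", {
  sim <- simulate_crb(n_species = 20, seed = 42)
  irb <- sample_irb(sim$crb, 7, seed = 11)
  expect_equal(dplyr::n_distinct(irb$records$species), 7L)
  expect_true(all(irb$records$specimen_id %in%
                    sim$crb$records$specimen_id))
  irb2 <- sample_irb(sim$crb, 7, seed = 11)
  expect_identical(irb$specimen_ids, irb2$specimen_ids)

  all_sp <- sample_irb(sim$crb, 20, seed = 5)
  expect_equal(dplyr::n_distinct(all_sp$records$species), 20L)
  one <- sample_irb(sim$crb, 1, seed = 5)
  expect_equal(dplyr::n_distinct(one$records$species), 1L)
  expect_error(sample_irb(sim$crb, 21), "n_species")
})

test_that("barcode classification matches the hand-enumerated example", {
  crb <- toy_shared_crb()
  irb <- irb_of(crb, c("a1", "c1"))  # barcodes {X, Y}
  cls <- classify_barcodes(irb, crb, "rbcL")
  expect_equal(cls$n_barcodes, 2L)
  expect_equal(cls$pct_perceived, 100)
  expect_equal(cls$pct_ambiguous, 0)
  expect_equal(cls$pct_false, 50)  # X is shared by two CRB species

  # IRB == CRB: no false species-unique barcodes
  full <- irb_of(crb, c("a1", "b1", "c1"))
  expect_equal(classify_barcodes(full, crb, "rbcL")$pct_false, 0)
  expect_error(classify_barcodes(irb_of(crb, character()), crb, "rbcL"),
               "no records")
})

test_that("classification agrees with a brute-force oracle on random CRBs", {
  for (seed in 1:8) {
    sim <- simulate_crb(n_species = 10, variants_per_species = 1,
                        locus_length = c(rbcL = 40), d_inter = 0.05,
                        p_share = 0.3, seed = seed)
    expect_lte(nrow(sim$records), 30)
    irb <- sample_irb(sim$crb, 5, seed = seed + 100)
    got <- classify_barcodes(irb, sim$crb, "rbcL")
    want <- oracle_classify(irb$records, sim$crb$records, "rbcL")
    expect_equal(got$pct_perceived, unname(want["pct_perceived"]))
    expect_equal(got$pct_ambiguous, unname(want["pct_ambiguous"]))
    expect_equal(got$pct_false, unname(want["pct_false"]))
    # partition invariants
    expect_equal(got$pct_perceived + got$pct_ambiguous, 100)
    expect_lte(got$pct_false, got$pct_perceived)
  }
})

test_that("ESS sampling retains duplicates and stays within the CRB", {
  sim <- simulate_crb(n_species = 15, seed = 3)
  ess <- sample_ess(sim$crb, 15, seed = 9)
  expect_gte(length(ess$specimen_ids), 15)
  expect_true(all(ess$specimen_ids %in% sim$crb$records$specimen_id))
  expect_identical(sample_ess(sim$crb, 15, seed = 9)$specimen_ids,
                   ess$specimen_ids)
  one <- sample_ess(sim$crb, 1, seed = 2)
  expect_equal(unique(one$true_species), one$true_species[1])
})

test_that("exact identification mirrors the worked example and its limits", {
  crb <- toy_shared_crb()
  irb <- irb_of(crb, c("a1", "c1"))
  ess <- ess_of(crb, "a1")  # query barcode X
  out <- identify_specimens(ess, irb, crb, "rbcL")
  expect_equal(out$pct_perceived, 100)  # only species A owns X in the IRB
  expect_equal(out$pct_false, 100)      # but X is ambiguous in the CRB
  expect_equal(out$pct_true, 0)

  # query absent from the IRB -> unknown
  out_b <- identify_specimens(ess_of(crb, "c1"), irb_of(crb, "a1"), crb,
                              "rbcL")
  expect_equal(out_b$pct_unknown, 100)

  # IRB == CRB: exact matching has no unknowns and no false positives
  full <- irb_of(crb, c("a1", "b1", "c1"))
  ess_all <- ess_of(crb, c("a1", "b1", "c1", "a1"))
  out_full <- identify_specimens(ess_all, full, crb, "rbcL")
  expect_equal(out_full$pct_unknown, 0)
  expect_equal(out_full$pct_false, 0)
  expect_equal(out_full$pct_perceived + out_full$pct_ambiguous +
                 out_full$pct_unknown, 100)
  expect_equal(out_full$pct_true + out_full$pct_false,
               out_full$pct_perceived)
})

test_that("threshold matching follows percent identity arithmetic", {
  # 1,000-base references differing at one site: identity 99.9
  base <- random_dna(1000, seed = 15)
  variant <- base
  substr(variant, 500, 500) <- setdiff(c("A", "C", "G", "T"),
                                       substr(base, 500, 500))[1]
  crb <- build_crb(barcode_records(
    species = c("A a", "B b"), specimen_id = c("s1", "s2"),
    locus = "rbcL", sequence = c(base, variant)
  ))
  irb <- irb_of(crb, "s1")
  ess <- ess_of(crb, "s2")
  expect_equal(oracle_identity(base, variant), 99.9)
  at_999 <- identify_specimens(ess, irb, crb, "rbcL",
                               mode = "threshold", threshold = 99.9)
  expect_equal(at_999$pct_perceived, 100)
  at_9995 <- identify_specimens(ess, irb, crb, "rbcL",
                                mode = "threshold", threshold = 99.95)
  expect_equal(at_9995$pct_unknown, 100)
})

test_that("threshold 100 reproduces exact matching bit-for-bit", {
  sim <- simulate_crb(n_species = 12, seed = 21, p_share = 0.2)
  irb <- sample_irb(sim$crb, 6, seed = 4)
  ess <- sample_ess(sim$crb, 8, seed = 5)
  exact <- identify_specimens(ess, irb, sim$crb, "rbcL")
  at100 <- identify_specimens(ess, irb, sim$crb, "rbcL",
                              mode = "threshold", threshold = 100)
  expect_equal(
    exact[, c("pct_perceived", "pct_ambiguous", "pct_unknown", "pct_true",
              "pct_false")],
    at100[, c("pct_perceived", "pct_ambiguous", "pct_unknown", "pct_true",
              "pct_false")]
  )
})

test_that("threshold scan finds the cut separating intra from inter divergence", {
  sim <- simulate_crb(n_species = 25, variants_per_species = 2,
                      locus_length = c(rbcL = 1000), d_inter = 0.02,
                      d_intra = 0.001, p_share = 0, seed = 33)
  irb <- sample_irb(sim$crb, 25, seed = 6)
  ess <- sample_ess(sim$crb, 15, seed = 7)
  scan <- scan_thresholds(ess, irb, sim$crb, "rbcL",
                          grid = seq(97, 99.9, by = 0.1))
  expect_true(scan$o_t %in% seq(97, 99.9, by = 0.1))
  # intraspecific divergence 0.1% vs interspecific 2%: the optimum must
  # tolerate variants (<= 99.9) but exclude other species (> 98)
  expect_gt(scan$o_t, 98)
  expect_lte(scan$o_t, 99.9)
  # a degenerate one-point grid at 100 equals exact matching
  g100 <- scan_thresholds(ess, irb, sim$crb, "rbcL", grid = 100)
  exact <- identify_specimens(ess, irb, sim$crb, "rbcL")
  expect_equal(g100$summaries$pct_true, exact$pct_true)
})

test_that("IRB-size experiment: perceived declines, false vanishes at CRB size", {
  # one record per species: once every species is drawn the IRB holds the
  # complete barcode truth, so false species-unique is exactly zero
  sim1 <- simulate_crb(n_species = 30, p_share = 0.15,
                       variants_per_species = 1, seed = 8)
  exp1 <- run_irb_size_experiment(sim1$crb, "rbcL", n_grid = c(5, 15, 30),
                                  replicates = 60, seed = 100)
  expect_equal(nrow(exp1), 3L)
  expect_equal(exp1$mean_pct_false[exp1$n_species == 30], 0)
  expect_equal(exp1$sd_pct_false[exp1$n_species == 30], 0)
  # perceived species-unique fraction is non-increasing in N_s
  expect_true(all(diff(exp1$mean_pct_perceived) <= 1e-9))

  # with intraspecific variants a complete species list can still miss the
  # variant that exposes a shared barcode: false only declines toward zero
  sim2 <- simulate_crb(n_species = 30, p_share = 0.15,
                       variants_per_species = 2, seed = 8)
  exp2 <- run_irb_size_experiment(sim2$crb, "rbcL", n_grid = c(5, 30),
                                  replicates = 60, seed = 100)
  expect_lt(exp2$mean_pct_false[2], exp2$mean_pct_false[1])
})

test_that("a CRB with no shared barcodes classifies as 100% perceived", {
  sim <- simulate_crb(n_species = 15, p_share = 0, d_inter = 0.05,
                      variants_per_species = 1, seed = 12)
  expect_equal(nrow(sim$truth), 0L)
  exp_tbl <- run_irb_size_experiment(sim$crb, "rbcL", n_grid = c(5, 15),
                                     replicates = 20, seed = 50)
  expect_equal(exp_tbl$mean_pct_perceived, c(100, 100))
})

test_that("genus-level relabelling can only merge species categories", {
  sim <- simulate_crb(n_species = 24, p_share = 0.2, seed = 44)
  recs <- sim$records
  recs_g <- barcode_records(recs$genus, recs$specimen_id, recs$locus,
                            recs$sequence)
  crb_g <- build_crb(recs_g)
  # classify the same specimen set under both labellings: barcodes shared
  # only between congeners stop being ambiguous/false at the genus level,
  # so perceived resolution cannot get worse
  irb_s <- sample_irb(sim$crb, 12, seed = 9)
  irb_g <- irb_of(crb_g, irb_s$specimen_ids)
  cls_s <- classify_barcodes(irb_s, sim$crb, "rbcL")
  cls_g <- classify_barcodes(irb_g, crb_g, "rbcL")
  expect_gte(cls_g$pct_perceived, cls_s$pct_perceived)
  # the genus-level experiment path runs on genus counts
  genus_lvl <- run_irb_size_experiment(sim$crb, "rbcL", n_grid = 5,
                                       replicates = 10, seed = 9,
                                       genus_level = TRUE)
  expect_equal(nrow(genus_lvl), 1L)
  expect_true(genus_lvl$mean_pct_perceived <= 100)
})
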