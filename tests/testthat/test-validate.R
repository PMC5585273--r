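# Isotope-labeling-based and entrapment-based FDR validation.

test_that("the isotope estimator reproduces the replicate worked examples", {
  expect_equal(round(100 * isotope_fdr_counts(3, 705, 735, 1484), 2),
               0.86)
  expect_equal(round(100 * isotope_fdr_counts(5, 713, 714, 1417), 2),
               1.39)
  expect_equal(round(100 * isotope_fdr_counts(2, 743, 681, 1380), 2),
               0.55)
  expect_equal(round(mean(c(0.86, 1.39, 0.55)), 2), 0.93)
  expect_error(isotope_fdr_counts(3, 705, 0, 1484), "decoy NaN")
  expect_error(isotope_fdr_counts(3, 0, 10, 100), "no target")
})

test_that("per-run isotope estimates are averaged across runs", {
  targets <- data.frame(
    run = rep(1:3, c(705, 713, 743)),
    is_nan = c(rep(c(TRUE, FALSE), c(3, 702)),
               rep(c(TRUE, FALSE), c(5, 708)),
               rep(c(TRUE, FALSE), c(2, 741))))
  decoys <- data.frame(
    run = rep(1:3, c(1484, 1417, 1380)),
    is_nan = c(rep(c(TRUE, FALSE), c(735, 749)),
               rep(c(TRUE, FALSE), c(714, 703)),
               rep(c(TRUE, FALSE), c(681, 699))))
  res <- isotope_fdr(targets, decoys)
  expect_equal(round(100 * res$per_run$fdr, 2), c(0.86, 1.39, 0.55))
  expect_equal(res$fdr, mean(res$per_run$fdr))
})

test_that("isotope pairing finds equimolar triplets and flags broken ones", {
  db <- make_small_db(seed = 61, n_prot = 6, n_gly = 6)
  gp <- random_glycopeptide(db, 4, charge = 2)
  sp <- synth_params()
  ms1 <- synth_ms1_triplet(gp, sp, seed = 5)
  gpsm <- data.frame(peptide = gp$peptide, mods = "",
                     glycan_comp = composition_string(gp$glycan),
                     charge = gp$charge, rt = gp$rt)
  res <- pair_isotope_precursors(gpsm, ms1)
  expect_false(res$is_nan)
  expect_true(res$ratio_15n > 0.8 && res$ratio_15n < 1.25)
  expect_true(res$ratio_13c > 0.8 && res$ratio_13c < 1.25)

  # dropped 13C channel -> NaN
  ms1_drop <- synth_ms1_triplet(gp, sp, seed = 5,
                                channels = c("none", "15N"))
  expect_true(pair_isotope_precursors(gpsm, ms1_drop)$is_nan)

  # a wrong composition predicts labeled masses that are absent -> NaN
  wrong <- gpsm
  wrong$glycan_comp <- "H2N2"
  expect_true(pair_isotope_precursors(wrong, ms1)$is_nan)

  # no MS1 scans in the retention-time window -> NaN, not an error
  far <- gpsm
  far$rt <- gp$rt + 10000
  expect_true(pair_isotope_precursors(far, ms1)$is_nan)
})

test_that("the entrapment estimator reproduces the worked example and the mouse-only rule", {
  gpsms <- data.frame(
    peptide_species = c(rep("yeast", 980), rep("mouse", 10),
                        rep("yeast", 10)),
    glycan_species = c(rep("yeast", 990), rep("mouse", 10)))
  expect_equal(entrapment_fdr(gpsms, "mouse"), 0.02)
  # no entrapment-only hits -> 0
  clean <- data.frame(peptide_species = rep("yeast", 50),
                      glycan_species = rep("yeast", 50))
  expect_equal(entrapment_fdr(clean, "mouse"), 0)
  # shared entries (both species) never count as false
  shared <- data.frame(peptide_species = rep("mouse,yeast", 50),
                       glycan_species = rep("yeast,mouse", 50))
  expect_equal(entrapment_fdr(shared, "mouse"), 0)
  # a GPSM false on both counts is counted once
  both <- data.frame(peptide_species = c("mouse", rep("yeast", 99)),
                     glycan_species = c("mouse", rep("yeast", 99)))
  expect_equal(entrapment_fdr(both, "mouse"), 0.01)
  expect_error(entrapment_fdr(gpsms[0, ], "mouse"), "empty")
  expect_error(entrapment_fdr(gpsms, character(0)), "entrapment")
})
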