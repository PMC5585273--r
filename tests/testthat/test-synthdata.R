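# Synthetic spectrum / MS1 / benchmark generation.

small_params <- function(seed = 5)
  synth_params(seed = seed, n_spectra = 30, n_proteins = 10,
               n_entrapment_proteins = 5, n_glycans = 8,
               n_entrapment_glycans = 4, n_shared_glycans = 2)

test_that("spectrum synthesis is deterministic under a seed", {
  db <- make_small_db(seed = 71, n_prot = 6, n_gly = 6)
  gp <- random_glycopeptide(db, 2)
  sp <- synth_params()
  s1 <- synth_spectrum(gp, sp, seed = 9)
  s2 <- synth_spectrum(gp, sp, seed = 9)
  expect_identical(s1$mz, s2$mz)
  expect_identical(s1$intensity, s2$intensity)
  expect_identical(s1$precursor_mz, s2$precursor_mz)
  s3 <- synth_spectrum(gp, sp, seed = 10)
  expect_false(identical(s1$mz, s3$mz))
})

test_that("degenerate parameters reproduce the theoretical ion set exactly", {
  db <- make_small_db(seed = 73, n_prot = 6, n_gly = 6)
  gp <- random_glycopeptide(db, 5, charge = 3)
  sp <- synth_params(p_detect_y = 1, p_detect_by = 1,
                     p_detect_oxonium = 1, noise_peaks = 0,
                     ppm_jitter_sd = 0, precursor_jitter_ppm = 0)
  spec <- synth_spectrum(gp, sp, seed = 1)
  ions <- glycosearch:::theoretical_ions(gp)
  expect_equal(sort(spec$mz),
               sort(c(ions$y_mz, ions$by_mz, ions$oxo_mz)),
               tolerance = 1e-9)
  expect_equal(spec$precursor_neutral, ions$precursor_neutral,
               tolerance = 1e-6)
  # bit-reproducible
  expect_identical(spec$mz, synth_spectrum(gp, sp, seed = 99)$mz)
})

test_that("MS1 triplets close the loop with the isotope validator", {
  db <- make_small_db(seed = 79, n_prot = 6, n_gly = 6)
  gp <- random_glycopeptide(db, 1, charge = 2)
  ms1 <- synth_ms1_triplet(gp, synth_params(), seed = 3)
  expect_gt(length(ms1), 3)
  res <- pair_isotope_precursors(
    data.frame(peptide = gp$peptide, mods = "",
               glycan_comp = composition_string(gp$glycan),
               charge = gp$charge, rt = gp$rt), ms1)
  expect_false(res$is_nan)
  expect_true(res$ratio_15n >= 0.8 && res$ratio_15n <= 1.25)
  expect_true(res$ratio_13c >= 0.8 && res$ratio_13c <= 1.25)
})

test_that("benchmarks are deterministic, complete and file-serializable", {
  b1 <- synth_benchmark(small_params())
  b2 <- synth_benchmark(small_params())
  expect_identical(b1$manifest, b2$manifest)
  expect_identical(b1$spectra[[7]]$mz, b2$spectra[[7]]$mz)
  expect_equal(nrow(b1$manifest), 30)
  expect_length(b1$spectra, 30)
  expect_true(all(c("true", "wrong_peptide") %in% b1$manifest$mode))
  # species partitions present on both databases
  expect_true(any(vapply(b1$glycans, function(g)
    "mouse" %in% g$species, logical(1))))
  expect_true(any(b1$proteins$species == "mouse"))

  dir <- withr::local_tempdir()
  b3 <- synth_benchmark(small_params(), dir = dir)
  expect_true(all(file.exists(unlist(b3$paths))))
  # manifest row count equals MGF block count
  expect_equal(length(read_mgf(b3$paths$mgf)), nrow(b3$manifest))
  expect_gt(length(read_ms1(b3$paths$ms1)), 10)
  expect_equal(nrow(read_fasta_proteins(b3$paths$fasta)),
               nrow(b1$proteins))
})

test_that("false analytes are absent from the searchable database", {
  b <- synth_benchmark(small_params(seed = 11))
  norm <- function(x) gsub("J", "N", x, fixed = TRUE)
  db_peps <- norm(unique(b$peptide_index$peptide))
  false_rows <- b$manifest[b$manifest$mode %in%
                             c("wrong_peptide", "shuffled_peptide"), ]
  expect_gt(nrow(false_rows), 0)
  expect_false(any(norm(false_rows$peptide) %in% db_peps))
  # foreign peptides still land within tolerance of an indexed mass
  foreign <- b$manifest$peptide[b$manifest$mode == "wrong_peptide"]
  for (pep in foreign) {
    m <- peptide_mass(pep)
    expect_lt(min(abs(b$peptide_index$mass - m)) / m * 1e6, 5)
  }
})
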