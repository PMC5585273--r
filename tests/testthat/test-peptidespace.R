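# Digestion, sequon marking, masses, fragments, elemental composition,
# decoys, index lookup.

test_that("tryptic digestion with sequon marking matches the worked fixture", {
  prot <- data.frame(id = "P1", sequence = "MKRNGTKPR")
  dig <- digest(prot, digest_params(max_missed_cleavages = 0,
                                    min_length = 1))
  expect_setequal(dig$peptide[!dig$is_glyco], c("MK", "R", "NGTKPR"))
  expect_setequal(dig$peptide[dig$is_glyco], "JGTKPR")
  expect_equal(dig$glyco_pos[dig$is_glyco], 1L)
})

test_that("N-P-S/T sequons are never marked and sequon-free proteins give no candidates", {
  dig <- digest(data.frame(id = "P", sequence = "AANPSTAKAAAK"),
                digest_params(min_length = 1))
  expect_false(any(dig$is_glyco))
  dig2 <- digest(data.frame(id = "P", sequence = "AAAA"),
                 digest_params(min_length = 1))
  expect_false(any(dig2$is_glyco))
  expect_warning(digest(data.frame(id = "P", sequence = "AAXZK")),
                 "non-standard")
})

test_that("digestion agrees with a cut-point enumeration oracle", {
  set.seed(21)
  aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "")
  for (rep in 1:25) {
    seq <- paste(sample(aa, sample(10:50, 1), replace = TRUE),
                 collapse = "")
    mmc <- sample(0:3, 1)
    dig <- digest(data.frame(id = "X", sequence = seq),
                  digest_params(max_missed_cleavages = mmc,
                                min_length = 1, max_length = 1000))
    expect_equal(sort(dig$peptide[!dig$is_glyco]),
                 oracle_digest(seq, mmc),
                 info = paste(seq, mmc))
  }
})

test_that("peptide masses match reference values", {
  expect_equal(peptide_mass("PEPTIDE"), 799.3600, tolerance = 1e-4)
  expect_equal(peptide_mass("C"), 178.0412, tolerance = 1e-4)  # fixed CAM
  expect_equal(peptide_mass("GG"), 132.0535, tolerance = 1e-4)
  expect_equal(peptide_mass("JGTK"), peptide_mass("NGTK"))  # J weighs as N
  expect_equal(peptide_mass("PEPTIDM", "Oxidation@7") -
                 peptide_mass("PEPTIDM"), 15.9949, tolerance = 1e-4)
  expect_error(peptide_mass(""), "empty")
})

test_that("b/y fragments satisfy the conservation identity", {
  frags <- fragment_ions("GG")
  expect_equal(frags$neutral[frags$type == "b"], 57.02146,
               tolerance = 1e-4)
  expect_equal(frags$neutral[frags$type == "y"], 75.03203,
               tolerance = 1e-4)
  for (pep in c("PEPTIDE", "JGTKPR", "MCMLR")) {
    mods <- if (grepl("M", pep)) "Oxidation@1" else ""
    frags <- fragment_ions(pep, mods)
    n <- nchar(pep)
    expect_equal(nrow(frags), 2 * (n - 1))
    m <- peptide_mass(pep, mods)
    b <- frags$neutral[frags$type == "b"]
    y <- frags$neutral[frags$type == "y"]
    # b_i + y_(n-i) - water = M
    expect_equal(b + rev(y), rep(m, n - 1), tolerance = 1e-9)
  }
})

test_that("elemental composition predicts label shifts and stays mass-consistent", {
  comp <- elemental_composition("GG")
  expect_equal(unname(comp["N"]), 2)
  expect_equal(unname(isotope_shifts(comp)["N15"]), 1.9941,
               tolerance = 1e-4)
  with_gly <- elemental_composition("GG", glycan = c(N = 1))
  expect_equal(unname(with_gly["N"] - comp["N"]), 1)
  expect_equal(unname(with_gly["C"] - comp["C"]), 8)
  # mass from composition equals peptide + glycan mass
  for (pep in c("PEPTIDEK", "JCSGLFNVYGK")) {
    cc <- elemental_composition(pep, "", c(H = 5, N = 2))
    expect_equal(formula_mass(cc),
                 peptide_mass(pep) + glycan_mass(c(H = 5, N = 2)),
                 tolerance = 1e-4)
  }
  expect_error(elemental_composition(""), "empty")
})

test_that("peptide decoys preserve tryptic termini, J marking and the mass distribution", {
  prot <- synth_proteins(20, seed = 31)
  dig <- digest(prot)
  dig <- dig[dig$is_glyco, ]
  dec <- decoy_glyco_peptides(dig)
  expect_equal(nrow(dec), nrow(dig))
  expect_true(all(dec$is_decoy))
  expect_true(all(grepl("J", dec$peptide)))
  expect_equal(vapply(dec$peptide, peptide_mass, numeric(1),
                      USE.NAMES = FALSE),
               vapply(dig$peptide, peptide_mass, numeric(1),
                      USE.NAMES = FALSE))
  # same C-terminal residue for tryptic-anchored peptides (protein
  # C-terminal peptides without K/R are fully reversed)
  anchored <- grepl("[KR]$", dig$peptide)
  expect_equal(substr(dec$peptide, nchar(dec$peptide),
                      nchar(dec$peptide))[anchored],
               substr(dig$peptide, nchar(dig$peptide),
                      nchar(dig$peptide))[anchored])
  # protein-level decoys: same count, KS-similar digested mass spectrum
  decp <- decoy_proteins(prot)
  expect_equal(nrow(decp), nrow(prot))
  md <- digest(decp, digest_params(min_length = 6))
  mt <- digest(prot, digest_params(min_length = 6))
  ks <- suppressWarnings(stats::ks.test(
    vapply(mt$peptide[!mt$is_glyco], peptide_mass, numeric(1)),
    vapply(md$peptide[!md$is_glyco], peptide_mass, numeric(1))))
  expect_gt(ks$p.value, 0.01)
})

test_that("mass lookup equals a linear scan on a random index", {
  prot <- synth_proteins(15, seed = 13)
  idx <- build_peptide_index(prot)
  expect_s3_class(idx, "peptide_index")
  expect_false(is.unsorted(idx$mass))
  # exact and near-miss queries
  q <- idx$mass[100]
  expect_true(any(lookup_peptides(idx, q, 5)$mass == q))
  expect_equal(nrow(lookup_peptides(idx, q * (1 + 10e-6), 5)),
               length(oracle_lookup(idx$mass, q * (1 + 10e-6), 5)))
  set.seed(3)
  for (query in sample(idx$mass, 50) * (1 + runif(50, -8e-6, 8e-6))) {
    got <- lookup_peptides(idx, query, 5)
    expect_equal(sort(got$mass),
                 sort(idx$mass[oracle_lookup(idx$mass, query, 5)]))
  }
})

test_that("variable modifications expand within the per-peptide cap", {
  prot <- data.frame(id = "P1", sequence = "MMMNMSTMMKAAANCSTK")
  idx <- build_peptide_index(prot, digest_params(min_length = 5),
                             decoys = FALSE)
  n_ox <- lengths(regmatches(idx$mods, gregexpr("Oxidation", idx$mods)))
  n_ac <- lengths(regmatches(idx$mods, gregexpr("Acetyl", idx$mods)))
  expect_true(all(n_ox + n_ac <= 3))
  # oxidation only ever sits on M
  for (r in which(n_ox > 0)) {
    md <- glycosearch:::parse_mods(idx$mods[r])
    pos <- md$pos[md$name == "Oxidation"]
    expect_true(all(substring(idx$peptide[r], pos, pos) == "M"))
  }
  # acetyl only on peptides that start the protein
  ac_peps <- gsub("J", "N", idx$peptide[n_ac > 0], fixed = TRUE)
  expect_true(all(startsWith(prot$sequence, ac_peps)))
})

test_that("FASTA round trip preserves ids, sequences and species tags", {
  prot <- synth_proteins(5, seed = 2, species = "yeast")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_proteins(prot, path)
  back <- read_fasta_proteins(path)
  expect_equal(back$id, prot$id)
  expect_equal(back$sequence, prot$sequence)
  expect_equal(back$species, prot$species)
})
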