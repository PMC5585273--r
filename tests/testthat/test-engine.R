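# Coarse open search, fine scoring, combined score and the full search.

PR <- 1.007276466

test_that("coarse search ranks the planted glycan first and filters core-poor glycans", {
  a <- parse_glycan_structure("(N(N(H(H)(H))))", id = "A")
  b <- parse_glycan_structure("(H(H(H(H(H(H))))))", id = "B")
  backbone <- 1200
  spec <- new_spectrum(backbone + a$y_ions$delta + PR,
                       rep(100, nrow(a$y_ions)),
                       precursor_mz = (backbone + a$mass + 2 * PR) / 2,
                       charge = 2)
  out <- coarse_score(spec, list(a, b))
  expect_equal(out$id, "A")
  expect_equal(out$n_matched, nrow(a$y_ions))
  expect_equal(out$backbone, backbone, tolerance = 1e-6)

  # spectrum with only Y0: one core match < 2, everything filtered
  spec0 <- new_spectrum(backbone + PR, 100,
                        (backbone + a$mass + 2 * PR) / 2, 2)
  expect_equal(nrow(coarse_score(spec0, list(a, b))), 0)

  # top_k = 1 keeps exactly one survivor
  db10 <- synth_glycan_db(10, seed = 3)
  spec2 <- new_spectrum(backbone + db10[[4]]$y_ions$delta + PR,
                        rep(10, nrow(db10[[4]]$y_ions)),
                        (backbone + db10[[4]]$mass + 2 * PR) / 2, 2)
  got <- coarse_score(spec2, db10, search_params(top_k_glycans = 1))
  expect_equal(nrow(got), 1)
})

test_that("fine glycan score reproduces the degenerate arithmetic cases", {
  gn <- parse_glycan_structure("(N)")
  backbone <- 1000
  # two matched peaks at the base-peak intensity: each contributes
  # log(e^2) = 2, ratios 1 -> score 4
  spec <- new_spectrum(c(backbone + PR, backbone + 203.0793725 + PR),
                       c(100, 100),
                       (backbone + 203.0793725 + 2 * PR) / 2, 2)
  res <- fine_score_glycan(spec, backbone, gn, detail = TRUE)
  expect_equal(res$score, 4, tolerance = 1e-6)
  expect_equal(res$ratio_ion, 1)
  expect_equal(res$ratio_core, 1)

  # a matched peak exactly at tolerance contributes zero
  tol <- 20
  mz0 <- backbone + PR
  spec_tol <- new_spectrum(c(mz0 * (1 + tol * 1e-6),
                             backbone + 203.0793725 + PR),
                           c(100, 100),
                           (backbone + 203.0793725 + 2 * PR) / 2, 2)
  res_tol <- fine_score_glycan(spec_tol, backbone, gn, detail = TRUE)
  expect_equal(res_tol$score, 2, tolerance = 1e-6)

  # ratio_ion = 0.5 scales by 0.5^alpha
  spec_half <- new_spectrum(c(backbone + PR), 100,
                            (backbone + 203.0793725 + 2 * PR) / 2, 2)
  res_half <- fine_score_glycan(spec_half, backbone, gn, detail = TRUE)
  expect_equal(res_half$ratio_ion, 0.5)
  expect_equal(res_half$score, 2 * 0.5^0.56 * 0.5^0.42, tolerance = 1e-6)
  expect_equal(0.5^0.56, 0.678302, tolerance = 1e-4)
})

test_that("fine peptide score follows the sum-times-ratio form", {
  pep <- "GASPVK"
  frags <- fragment_ions(pep)
  n <- nrow(frags)
  # all fragments present at intensity base/e (normalized e): sum = n
  mz <- frags$neutral + PR
  spec <- new_spectrum(c(mz, 2000), c(rep(100 / exp(1), n), 100),
                       (peptide_mass(pep) + 1500 + 2 * PR) / 2, 2)
  res <- fine_score_peptide(spec, pep, detail = TRUE)
  expect_equal(res$ratio_ion, 1)
  expect_equal(res$score, n, tolerance = 1e-6)

  # no matches -> 0
  spec0 <- new_spectrum(3000, 10, 2000, 2)
  expect_equal(fine_score_peptide(spec0, pep), 0)

  # half the ions matched scales the sum by 0.5^gamma
  half <- frags$neutral[frags$type == "b"] + PR
  spec_h <- new_spectrum(c(half, 2000), c(rep(100 / exp(1),
                                              length(half)), 100),
                         (peptide_mass(pep) + 1500 + 2 * PR) / 2, 2)
  res_h <- fine_score_peptide(spec_h, pep, detail = TRUE)
  expect_equal(res_h$ratio_ion, 0.5)
  expect_equal(res_h$score, res_h$sum_term * 0.5^0.94, tolerance = 1e-9)
  expect_equal(10 * 0.5^0.94, 5.2133, tolerance = 1e-3)
})

test_that("the combined score is the stated convex combination", {
  expect_equal(total_score(10, 20, 0.35), 16.5)
  expect_equal(total_score(0, 0, 0.7), 0)
  for (w in c(0.1, 0.35, 0.9))
    expect_equal(total_score(7, 7, w), 7)
  expect_error(total_score(1, 1, 0))
  # bounds: min <= gp <= max
  set.seed(1)
  g <- runif(50, 0, 30); p <- runif(50, 0, 30)
  gp <- total_score(g, p, 0.35)
  expect_true(all(gp >= pmin(g, p) - 1e-12 & gp <= pmax(g, p) + 1e-12))
})

test_that("adding a matched peak never decreases a fine score", {
  set.seed(17)
  gly <- parse_glycan_structure("(N(N(H(H)(H(F)))))")
  backbone <- 1400
  for (rep in 1:15) {
    deltas <- sample(gly$y_ions$delta, 4)
    mz <- backbone + deltas + PR
    base <- new_spectrum(mz, runif(4, 10, 100),
                         (backbone + gly$mass + 2 * PR) / 2, 2)
    s0 <- fine_score_glycan(base, backbone, gly)
    extra_delta <- sample(setdiff(gly$y_ions$delta, deltas), 1)
    aug <- new_spectrum(c(mz, backbone + extra_delta + PR),
                        c(base$intensity, runif(1, 10, 100)),
                        base$precursor_mz, 2)
    expect_gte(fine_score_glycan(aug, backbone, gly), s0 - 1e-9)
  }
})

test_that("search_spectrum equals exhaustive pair scoring on small databases", {
  db <- make_small_db(seed = 7, n_prot = 8, n_gly = 8)
  glycan_db <- build_glycan_db(db$glycans, seed = 70)
  idx <- db$index
  params <- search_params(top_k_glycans = 100)
  sp <- synth_params(noise_peaks = 40)
  set.seed(91)
  n_checked <- 0
  for (i in 1:12) {
    gp <- random_glycopeptide(db, i, charge = sample(2:3, 1))
    spec <- if (i %% 4 == 0) {
      # noise spectrum at a plausible precursor
      new_spectrum(sort(runif(150, 200, 2000)), runif(150, 1, 100),
                   (peptide_mass(gp$peptide) + gp$glycan$mass +
                      gp$charge * PR) / gp$charge, gp$charge,
                   title = gp$title)
    } else synth_spectrum(gp, sp, seed = 400 + i)
    got <- search_spectrum(spec, glycan_db, idx, params)
    want <- oracle_search(spec, glycan_db, idx, params)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$glycan_id, want$glycan_id)
      expect_equal(got$peptide, want$peptide)
      expect_equal(got$mods, want$mods)
      expect_equal(got$score_gp, want$score_gp, tolerance = 1e-9)
      expect_equal(got$score_g, want$score_g, tolerance = 1e-9)
      expect_equal(got$score_p, want$score_p, tolerance = 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 5)
})

test_that("pure-noise spectra are mostly rejected by the coarse filter", {
  db <- make_small_db(seed = 19, n_prot = 10, n_gly = 12)
  glycan_db <- build_glycan_db(db$glycans, seed = 20)
  set.seed(23)
  n_null <- 0
  for (i in 1:10) {
    spec <- new_spectrum(sort(runif(200, 200, 2000)),
                         runif(200, 1, 100),
                         runif(1, 900, 1400), 3,
                         title = paste0("noise", i))
    if (is.null(search_spectrum(spec, glycan_db, db$index))) n_null <-
        n_null + 1
  }
  expect_gte(n_null, 8)
})

test_that("chimeric co-isolated precursors are both recovered from their MGF entries", {
  db <- make_small_db(seed = 37, n_prot = 10, n_gly = 10)
  glycan_db <- build_glycan_db(db$glycans, seed = 38)
  sp <- synth_params(noise_peaks = 30)
  gp1 <- random_glycopeptide(db, 2, charge = 3)
  gp2 <- random_glycopeptide(db, 9, charge = 2)
  s1 <- synth_spectrum(gp1, sp, seed = 101)
  s2 <- synth_spectrum(gp2, sp, seed = 102)
  merged_mz <- c(s1$mz, s2$mz)
  merged_int <- c(s1$intensity, s2$intensity)
  e1 <- new_spectrum(merged_mz, merged_int, s1$precursor_mz, gp1$charge,
                     title = "chimera", scan = 5)
  e2 <- new_spectrum(merged_mz, merged_int, s2$precursor_mz, gp2$charge,
                     title = "chimera", scan = 5)
  res <- search_spectra(list(e1, e2), glycan_db, db$index)
  expect_equal(nrow(res), 2)
  expect_setequal(gsub("J", "N", res$peptide),
                  gsub("J", "N", c(gp1$peptide, gp2$peptide)))
  expect_setequal(res$glycan_comp,
                  c(composition_string(gp1$glycan$composition),
                    composition_string(gp2$glycan$composition)))
})

test_that("GPSM tables round-trip through TSV and annotation reports render", {
  db <- make_small_db(seed = 57, n_prot = 8, n_gly = 8)
  glycan_db <- build_glycan_db(db$glycans, seed = 58)
  gp <- random_glycopeptide(db, 3)
  spec <- synth_spectrum(gp, synth_params(), seed = 7)
  gpsm <- search_spectrum(spec, glycan_db, db$index)
  expect_s3_class(gpsm, "data.frame")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gpsm_tsv(gpsm, path)
  back <- read_gpsm_tsv(path)
  expect_equal(back$score_gp, gpsm$score_gp, tolerance = 1e-9)
  report <- annotate_gpsm(spec, gpsm, glycan_db)
  expect_true(any(grepl("peak annotation", report)))
  expect_true(any(grepl("mass deviations", report)))
  expect_true(any(grepl("^Y\\+", report)))
})
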