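# Glycan parsing, mass arithmetic, Y-ion enumeration, decoy generation.

test_that("structure strings parse to the right trees and compositions", {
  g <- parse_glycan_structure("(N(N(H(H)(H))))")
  expect_equal(unname(g$composition[c("H", "N")]), c(3L, 2L))
  expect_equal(length(g$symbols), 5)

  single <- parse_glycan_structure("(N)")
  expect_equal(unname(single$composition), 1L)
  expect_equal(names(single$composition), "N")

  expect_error(parse_glycan_structure("(N(N(H(H)(H)))"), "unbalanced")
  expect_error(parse_glycan_structure("(N(X))"), "position 4.*unknown|unknown symbol")
  expect_error(parse_glycan_structure("(N)(H)"), "multiple roots")
  expect_error(parse_glycan_structure(""), "empty")
})

test_that("glycan masses are monoisotopic residue sums", {
  expect_equal(glycan_mass(c(N = 1)), 203.0794, tolerance = 1e-6)
  expect_equal(glycan_mass(c(H = 5, N = 2)), 1216.4229, tolerance = 1e-6)
  expect_equal(glycan_mass("H5N2"), glycan_mass(c(H = 5, N = 2)))
  expect_error(glycan_mass(integer(0)), "empty")
  # composition string round trip
  expect_equal(parse_composition(composition_string(c(H = 5, N = 2, F = 1))),
               c(H = 5L, N = 2L, F = 1L))
})

test_that("Y-ion enumeration matches the stated ladders", {
  chain <- parse_glycan_structure("(N(N(H)))")
  expect_equal(chain$y_ions$delta,
               c(0, 203.0794, 406.1587, 568.2116), tolerance = 1e-4)
  expect_equal(nrow(chain$y_ions), 4)

  core <- parse_glycan_structure("(N(N(H(H)(H))))")
  expect_equal(nrow(core$y_ions), 6)  # branch symmetry collapses by mass
  expect_true(all(core$y_ions$is_core))

  single <- parse_glycan_structure("(N)")
  expect_equal(single$y_ions$delta, c(0, 203.0794), tolerance = 1e-4)

  # deltas strictly increasing, delta 0 present, max delta = glycan mass
  expect_true(all(diff(core$y_ions$delta) > 0))
  expect_equal(max(core$y_ions$delta), core$mass, tolerance = 1e-6)
})

test_that("Y-ion enumeration agrees with exhaustive subtree enumeration", {
  set.seed(11)
  for (rep in 1:40) {
    tr <- random_tree_text(sample(1:8, 1))
    g <- parse_glycan_structure(tr$text)
    expect_equal(round(g$y_ions$delta, 4),
                 oracle_y_deltas(tr$symbols, tr$parent),
                 tolerance = 1e-3)
  }
})

test_that("decoy glycans preserve mass, perturb every nonzero delta, and are reproducible", {
  g <- parse_glycan_structure("(N(N(H(H(H))(H(F)))))")
  d1 <- generate_decoy_glycan(g, seed = 5)
  d2 <- generate_decoy_glycan(g, seed = 5)
  expect_identical(d1$y_ions, d2$y_ions)
  expect_true(d1$is_decoy)
  expect_lt(abs(d1$mass - g$mass), 1e-6)
  # Y0 kept; every nonzero delta at least 1 Da from every target delta
  expect_true(0 %in% d1$y_ions$delta)
  nz <- d1$y_ions$delta[d1$y_ions$delta > 0]
  expect_true(all(vapply(nz, function(x)
    min(abs(x - g$y_ions$delta)) >= 1, logical(1))))

  single <- parse_glycan_structure("(N)")
  ds <- generate_decoy_glycan(single, seed = 1)
  expect_lt(abs(ds$mass - 203.0794), 1e-4)
  expect_true(all(abs(ds$y_ions$delta[ds$y_ions$delta > 0] -
                        203.0794) >= 1))
})

test_that("a decoy database is bijective with its targets", {
  targets <- synth_glycan_db(30, seed = 9)
  db <- build_glycan_db(targets, seed = 2)
  expect_length(db, 60)
  decoys <- Filter(function(g) g$is_decoy, db)
  expect_length(decoys, 30)
  expect_setequal(vapply(decoys, `[[`, character(1), "id"),
                  paste0("DECOY_", vapply(targets, `[[`, character(1),
                                          "id")))
})

test_that("glycan database files round-trip", {
  db <- synth_glycan_db(8, seed = 3, species = "yeast")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_glycan_db(db, path)
  back <- read_glycan_db(path)
  expect_equal(vapply(back, `[[`, character(1), "text"),
               vapply(db, `[[`, character(1), "text"))
  expect_equal(back[[1]]$species, "yeast")
})
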