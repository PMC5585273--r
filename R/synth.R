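# Ground-truth synthetic data: glycan databases, protein FASTA, SCE-HCD
# style MS/MS spectra (Y-ion ladders + b/y ions + oxonium ions + noise),
# 15N/13C-labeled MS1 precursor triplets and complete benchmark sets with
# a truth manifest for FDR calibration.

#' Synthetic-data parameters
#'
#' Defaults define the benchmark study conditions: an equimolar
#' unlabeled/15N/13C analyte mixture, 1000 spectra of which half are
#' deliberately false, fragment detection probabilities 0.8 (Y), 0.6
#' (b/y) and 0.9 (oxonium), log-normal peak intensities, 3 ppm fragment
#' and 0.5 ppm precursor m/z jitter and 80 expected noise peaks per
#' spectrum drawn uniformly over 200--2000 Th from the lower quartile of
#' the signal intensity model.
#'
#' @param seed Master seed; fixes all downstream randomness.
#' @param n_proteins,n_entrapment_proteins Native and entrapment
#'   (foreign-species) protein counts.
#' @param protein_length Length range of synthetic proteins.
#' @param n_glycans,n_entrapment_glycans,n_shared_glycans Native-only,
#'   entrapment-only and shared glycan counts.
#' @param max_extra_residues Residues added beyond the trimannosyl core.
#' @param n_spectra Total MS/MS spectra in a benchmark.
#' @param fraction_false Fraction of deliberately false spectra.
#' @param false_modes Named probabilities over the false-spectrum
#'   constructions: `wrong_peptide` (a foreign random-composition
#'   peptide whose mass falls within the precursor tolerance of a
#'   database peptidoform), `shuffled_peptide` (composition-preserving
#'   shuffle of a database peptide, keeping the C-terminal K/R),
#'   `shifted_precursor` and `noise`.
#' @param p_detect_y,p_detect_by,p_detect_oxonium Per-ion detection
#'   probabilities.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model.
#' @param noise_peaks Expected number of noise peaks (Poisson).
#' @param ppm_jitter_sd Fragment m/z jitter (ppm, s.d.).
#' @param precursor_jitter_ppm Precursor m/z jitter (ppm, s.d.).
#' @param rt_range Retention-time range of the simulated run (s).
#' @param ms1_interval MS1 scan spacing (s).
#' @param triplet_rt_halfwidth Elution half-width of a precursor (s).
#' @param label_channels Isotope channels present in the MS1 mixture.
#' @param channel_cv Log-normal coefficient of variation of the
#'   nominally 1:1:1 channel intensities.
#' @param native_species,entrapment_species Species tags of the two
#'   database partitions.
#' @return A `synth_params` list.
#' @export
synth_params <- function(seed = 1, n_proteins = 60,
                         n_entrapment_proteins = 30,
                         protein_length = c(150, 350),
                         n_glycans = 25, n_entrapment_glycans = 15,
                         n_shared_glycans = 5, max_extra_residues = 5,
                         n_spectra = 1000, fraction_false = 0.5,
                         false_modes = c(wrong_peptide = 0.5,
                                         shuffled_peptide = 0.2,
                                         shifted_precursor = 0.2,
                                         noise = 0.1),
                         p_detect_y = 0.8, p_detect_by = 0.6,
                         p_detect_oxonium = 0.9,
                         intensity_meanlog = log(1e4),
                         intensity_sdlog = 1,
                         noise_peaks = 80, ppm_jitter_sd = 3,
                         precursor_jitter_ppm = 0.5,
                         rt_range = c(300, 3300), ms1_interval = 5,
                         triplet_rt_halfwidth = 20,
                         label_channels = c("none", "15N", "13C"),
                         channel_cv = 0.05,
                         native_species = "yeast",
                         entrapment_species = "mouse") {
  stopifnot(seed == as.integer(seed),
            all(c(p_detect_y, p_detect_by, p_detect_oxonium) >= 0),
            all(c(p_detect_y, p_detect_by, p_detect_oxonium) <= 1),
            fraction_false >= 0, fraction_false <= 1,
            abs(sum(false_modes) - 1) < 1e-9)
  structure(as.list(environment()), class = "synth_params")
}

MONO_WEIGHTS <- c(H = 0.45, N = 0.25, F = 0.15, A = 0.10, G = 0.05)

# Canonical text of a rooted tree (children ordered by subtree string).
glycan_text_of <- function(symbols, parent) {
  n <- length(symbols)
  children <- vector("list", n)
  for (i in seq_len(n))
    if (parent[i] > 0)
      children[[parent[i]]] <- c(children[[parent[i]]], i)
  ser <- function(node) {
    subs <- vapply(children[[node]], ser, character(1))
    paste0("(", symbols[node], paste(sort(subs), collapse = ""), ")")
  }
  ser(which(parent == 0L))
}

#' Generate a random N-glycan database
#'
#' Each glycan is the trimannosyl core `(N(N(H(H)(H))))` extended by up
#' to `max_extra` residues attached at random nodes with field-typical
#' monosaccharide frequencies.  Structures are distinct.
#'
#' @param n Number of glycans.
#' @param seed Integer seed.
#' @param species Species tag(s) applied to every glycan.
#' @param max_extra Maximum residues beyond the core.
#' @param id_prefix Identifier prefix.
#' @return List of `glycan_structure`.
#' @export
synth_glycan_db <- function(n, seed = 1, species = "yeast",
                            max_extra = 5, id_prefix = "G") {
  with_seed(seed, {
    texts <- character(0)
    while (length(texts) < n) {
      symbols <- c("N", "N", "H", "H", "H")
      parent <- c(0L, 1L, 2L, 3L, 3L)
      extra <- sample(0:max_extra, 1)
      for (k in seq_len(extra)) {
        symbols <- c(symbols, sample(names(MONO_WEIGHTS), 1,
                                     prob = MONO_WEIGHTS))
        parent <- c(parent, sample(seq_along(symbols[-length(symbols)]), 1))
      }
      texts <- unique(c(texts, glycan_text_of(symbols, parent)))
    }
    lapply(seq_len(n), function(i)
      parse_glycan_structure(texts[i],
                             id = sprintf("%s%04d", id_prefix, i),
                             species = species))
  })
}

AA_FREQ <- c(A = 0.080, R = 0.050, N = 0.040, D = 0.050, C = 0.015,
             E = 0.060, Q = 0.040, G = 0.070, H = 0.022, I = 0.055,
             L = 0.090, K = 0.060, M = 0.012, F = 0.040, P = 0.047,
             S = 0.070, T = 0.055, W = 0.012, Y = 0.030, V = 0.065)

#' Generate random proteins with guaranteed N-glycosylation sequons
#'
#' @param n Number of proteins.
#' @param seed Integer seed.
#' @param length_range Protein length range.
#' @param species Species tag.
#' @param id_prefix Identifier prefix.
#' @return Protein data.frame (`id`, `sequence`, `species`, `is_decoy`).
#' @export
synth_proteins <- function(n, seed = 1, length_range = c(150, 350),
                           species = "yeast", id_prefix = "P") {
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      len <- sample(length_range[1]:length_range[2], 1)
      res <- sample(names(AA_FREQ), len, replace = TRUE, prob = AA_FREQ)
      n_seq <- max(2L, round(len / 120))
      pos <- sample(seq_len(len - 2), n_seq)
      for (q in pos) {
        res[q] <- "N"
        if (res[q + 1] == "P") res[q + 1] <- "A"
        res[q + 2] <- sample(c("S", "T"), 1)
      }
      paste(res, collapse = "")
    }, character(1))
    data.frame(id = sprintf("%s%04d", id_prefix, seq_len(n)),
               sequence = seqs, species = species, is_decoy = FALSE)
  })
}

# Theoretical ion table of a glycopeptide for spectrum synthesis.
theoretical_ions <- function(gp) {
  pep_m <- peptide_mass(gp$peptide, gp$mods)
  ydelta <- gp$glycan$y_ions$delta
  ycharge <- seq_len(max(1L, gp$charge - 1L))
  y <- expand.grid(delta = ydelta, z = ycharge)
  y_mz <- (pep_m + y$delta) / y$z + PROTON_MASS
  frags <- fragment_ions(gp$peptide, gp$mods)
  b_mz <- frags$neutral + PROTON_MASS
  syms <- names(gp$glycan$composition)
  oxo <- oxonium_table()
  oxo_keep <- (grepl("HexNAc", oxo$name) & "N" %in% syms) |
    (oxo$name %in% c("Hex") & "H" %in% syms) |
    (oxo$name == "HexHexNAc" & all(c("H", "N") %in% syms)) |
    (grepl("NeuAc", oxo$name) & "A" %in% syms) |
    (oxo$name == "NeuGc" & "G" %in% syms)
  list(y_mz = y_mz, by_mz = b_mz, oxo_mz = oxo$mz[oxo_keep],
       precursor_neutral = pep_m + gp$glycan$mass)
}

#' Simulate one SCE-HCD glycopeptide spectrum
#'
#' Peaks are a sampled subset of the theoretical Y ions (charges
#' 1..z-1), singly charged b/y ions and oxonium ions, plus uniform noise
#' peaks; intensities are log-normal (noise from the lower quartile of
#' the signal model) and m/z values are jittered within the ppm model.
#' With detection probabilities 1, zero noise and zero jitter the peak
#' set equals the theoretical ion set exactly.  Deterministic given
#' `seed`.
#'
#' @param gp Glycopeptide: list with `glycan` (a `glycan_structure`),
#'   `peptide` (J-marked sequence), `mods`, `charge`, `rt`, `title`,
#'   `scan`.
#' @param params [synth_params()].
#' @param seed Integer seed (defaults to `params$seed`).
#' @return A `spectrum` with attribute `"truth"` (the planted
#'   identification).
#' @export
synth_spectrum <- function(gp, params = synth_params(),
                           seed = params$seed) {
  ions <- theoretical_ions(gp)
  with_seed(seed, {
    keep_y <- stats::runif(length(ions$y_mz)) < params$p_detect_y
    keep_by <- stats::runif(length(ions$by_mz)) < params$p_detect_by
    keep_ox <- stats::runif(length(ions$oxo_mz)) < params$p_detect_oxonium
    mz <- c(ions$y_mz[keep_y], ions$by_mz[keep_by], ions$oxo_mz[keep_ox])
    inten <- stats::rlnorm(length(mz), params$intensity_meanlog,
                           params$intensity_sdlog)
    n_noise <- stats::rpois(1, params$noise_peaks)
    if (n_noise > 0) {
      mz <- c(mz, stats::runif(n_noise, 200, 2000))
      inten <- c(inten, stats::qlnorm(stats::runif(n_noise, 0, 0.25),
                                      params$intensity_meanlog,
                                      params$intensity_sdlog))
    }
    if (params$ppm_jitter_sd > 0)
      mz <- mz * (1 + stats::rnorm(length(mz), 0,
                                   params$ppm_jitter_sd) * 1e-6)
    prec_mz <- mz_from_neutral(ions$precursor_neutral, gp$charge)
    if (params$precursor_jitter_ppm > 0)
      prec_mz <- prec_mz * (1 + stats::rnorm(1, 0,
                                             params$precursor_jitter_ppm) *
                              1e-6)
    if (!is.null(gp$precursor_shift))
      prec_mz <- prec_mz + gp$precursor_shift / gp$charge
    spec <- new_spectrum(mz, inten, precursor_mz = prec_mz,
                         charge = gp$charge,
                         title = if (is.null(gp$title)) "synthetic" else
                           gp$title,
                         scan = if (is.null(gp$scan)) NA_integer_ else
                           gp$scan,
                         rt = if (is.null(gp$rt)) NA_real_ else gp$rt)
    attr(spec, "truth") <- list(glycan_id = gp$glycan$id,
                                glycan_comp =
                                  composition_string(gp$glycan$composition),
                                peptide = gp$peptide, mods = gp$mods)
    spec
  })
}

#' Simulate the MS1 unlabeled/15N/13C precursor triplet of a glycopeptide
#'
#' MS1 scans across the elution window carry three isotope-channel
#' precursor peaks at m/z shifts predicted from the glycopeptide's
#' nitrogen and carbon counts, with triangular elution profiles and
#' channel intensities within `channel_cv` of 1:1:1.
#'
#' @inheritParams synth_spectrum
#' @param channels Channels to emit (subset of
#'   `c("none", "15N", "13C")`); dropping a channel emulates a missing
#'   labeled partner.
#' @return List of `ms1_scan` objects.
#' @export
synth_ms1_triplet <- function(gp, params = synth_params(),
                              seed = params$seed,
                              channels = params$label_channels) {
  comp <- elemental_composition(gp$peptide, gp$mods,
                                gp$glycan$composition)
  if (comp[["N"]] < 1 || comp[["C"]] < 1)
    stop("glycopeptide without nitrogen or carbon atoms cannot be labeled")
  shifts <- isotope_shifts(comp)
  neutral <- peptide_mass(gp$peptide, gp$mods) + gp$glycan$mass
  ch_mz <- c(none = mz_from_neutral(neutral, gp$charge),
             `15N` = mz_from_neutral(neutral + shifts[["N15"]], gp$charge),
             `13C` = mz_from_neutral(neutral + shifts[["C13"]], gp$charge))
  ch_mz <- ch_mz[names(ch_mz) %in% channels]
  hw <- params$triplet_rt_halfwidth
  grid <- seq(gp$rt - hw, gp$rt + hw, by = params$ms1_interval)
  with_seed(seed, {
    base <- stats::rlnorm(1, params$intensity_meanlog + 2, 0.5)
    factor <- stats::rlnorm(length(ch_mz), 0, params$channel_cv)
    lapply(seq_along(grid), function(i) {
      profile <- 1 - abs(grid[i] - gp$rt) / (hw + params$ms1_interval)
      ord <- order(ch_mz)
      structure(list(scan = i, rt = grid[i], mz = unname(ch_mz[ord]),
                     intensity = unname(base * factor[ord] * profile)),
                class = "ms1_scan")
    })
  })
}

# Sample the true-analyte pool: digested native glyco peptides.
native_glyco_peptides <- function(proteins, dparams = digest_params()) {
  dig <- digest(proteins, dparams)
  dig <- dig[dig$is_glyco, , drop = FALSE]
  if (!nrow(dig)) stop("no glycopeptide candidates in synthetic proteins")
  dig[!duplicated(dig$peptide), , drop = FALSE]
}

shuffle_interior <- function(pep, forbidden) {
  residues <- strsplit(pep, "", fixed = TRUE)[[1]]
  n <- length(residues)
  if (n < 4) return(NULL)
  norm <- function(x) gsub("J", "N", x, fixed = TRUE)
  for (try in 1:20) {
    # shuffle everything except the C-terminal K/R anchor, mirroring the
    # assumption behind pseudo-reversed decoys
    cand <- paste(c(residues[sample(n - 1)], residues[n]), collapse = "")
    # must differ from every database backbone even after normalizing the
    # mass-equivalent J marking, or the "false" analyte would be a
    # correct identification in disguise
    if (norm(cand) != norm(pep) && !(norm(cand) %in% norm(forbidden)) &&
        grepl("J", cand, fixed = TRUE))
      return(cand)
  }
  NULL
}

# Foreign random-composition peptides whose neutral mass lies within
# tol_ppm of some entry of `masses` (sorted).  Used for false spectra
# that a composition-sensitive validator can detect.
foreign_mass_matched_peptides <- function(masses, n_needed, forbidden,
                                          tol_ppm = 4,
                                          length_range = c(8, 30)) {
  found <- character(0)
  norm_forbidden <- gsub("J", "N", forbidden, fixed = TRUE)
  for (round in 1:40) {
    if (length(found) >= n_needed) break
    lens <- sample(length_range[1]:length_range[2], 4000, replace = TRUE)
    cand <- vapply(lens, function(l) {
      res <- sample(names(AA_FREQ), l, replace = TRUE, prob = AA_FREQ)
      res[sample(l - 2, 1)] <- "J"
      res[l] <- sample(c("K", "R"), 1)
      paste(res, collapse = "")
    }, character(1))
    m <- vapply(cand, peptide_mass, numeric(1), USE.NAMES = FALSE)
    i <- findInterval(m, masses)
    near <- pmin(abs(m - masses[pmax(i, 1)]),
                 abs(masses[pmin(i + 1, length(masses))] - m))
    ok <- near / m * 1e6 <= tol_ppm &
      !(gsub("J", "N", cand, fixed = TRUE) %in% norm_forbidden)
    found <- unique(c(found, cand[ok]))
  }
  if (length(found) < n_needed)
    warning("only ", length(found), " of ", n_needed,
            " mass-matched foreign peptides found")
  found
}

#' Generate a complete searchable benchmark with known ground truth
#'
#' Produces MS/MS spectra, MS1 scans with label triplets, a protein set
#' (native + entrapment partitions), a glycan database (native,
#' entrapment and shared partitions) and a truth manifest.  A fraction
#' of spectra are deliberately false: their analyte is absent from the
#' searchable database (interior-shuffled mass-preserving peptides), has
#' a shifted precursor, or is pure noise -- so the realized
#' false-discovery proportion of any accepted GPSM set can be computed
#' from the manifest.  Species tags split the databases into native and
#' entrapment partitions for entrapment-based validation.
#'
#' @param params [synth_params()].
#' @param dir Optional directory; when given, writes `benchmark.mgf`,
#'   `benchmark.ms1`, `proteins.fasta`, `glycans.tsv` and
#'   `manifest.tsv` there.
#' @return List with `spectra`, `ms1`, `proteins`, `glycans`,
#'   `manifest`, `params` and (when written) `paths`.
#' @export
synth_benchmark <- function(params = synth_params(), dir = NULL) {
  glycans_native <- synth_glycan_db(params$n_glycans, params$seed + 11,
                                    species = params$native_species,
                                    max_extra = params$max_extra_residues,
                                    id_prefix = "GN")
  glycans_entrap <- synth_glycan_db(params$n_entrapment_glycans,
                                    params$seed + 23,
                                    species = params$entrapment_species,
                                    max_extra = params$max_extra_residues,
                                    id_prefix = "GE")
  glycans_shared <- synth_glycan_db(params$n_shared_glycans,
                                    params$seed + 37,
                                    species = c(params$native_species,
                                                params$entrapment_species),
                                    max_extra = params$max_extra_residues,
                                    id_prefix = "GS")
  # drop accidental cross-partition duplicates (species would be ambiguous)
  texts <- vapply(c(glycans_native, glycans_entrap, glycans_shared),
                  `[[`, character(1), "text")
  keep <- !duplicated(texts)
  glycans <- c(glycans_native, glycans_entrap, glycans_shared)[keep]
  prot_native <- synth_proteins(params$n_proteins, params$seed + 41,
                                params$protein_length,
                                species = params$native_species,
                                id_prefix = "P")
  prot_entrap <- synth_proteins(params$n_entrapment_proteins,
                                params$seed + 53,
                                params$protein_length,
                                species = params$entrapment_species,
                                id_prefix = "E")
  proteins <- rbind(prot_native, prot_entrap)

  pool <- native_glyco_peptides(prot_native)
  peptide_index <- build_peptide_index(proteins, digest_params())
  all_db_peptides <- unique(peptide_index$peptide)
  native_ids <- vapply(glycans, function(g)
    params$native_species %in% g$species, logical(1))
  gly_pool <- glycans[native_ids]

  n_false <- round(params$n_spectra * params$fraction_false)
  n_true <- params$n_spectra - n_false
  manifest <- vector("list", params$n_spectra)
  spectra <- vector("list", params$n_spectra)
  analytes <- vector("list", params$n_spectra)

  with_seed(params$seed, {
    modes <- c(rep("true", n_true),
               sample(names(params$false_modes), n_false, replace = TRUE,
                      prob = params$false_modes))
    modes <- sample(modes)
    n_foreign <- sum(modes == "wrong_peptide")
    foreign_pool <- if (n_foreign)
      foreign_mass_matched_peptides(peptide_index$mass, n_foreign,
                                    all_db_peptides)
    else character(0)
    foreign_next <- 1L
    rts <- stats::runif(params$n_spectra, params$rt_range[1],
                        params$rt_range[2])
    pep_rows <- sample(nrow(pool), params$n_spectra, replace = TRUE)
    gly_rows <- sample(length(gly_pool), params$n_spectra, replace = TRUE)
    spectrum_seeds <- sample.int(2^30, params$n_spectra)
    for (i in seq_len(params$n_spectra)) {
      mode <- modes[i]
      pep <- pool$peptide[pep_rows[i]]
      glycan <- gly_pool[[gly_rows[i]]]
      shift <- NULL
      if (mode == "wrong_peptide") {
        if (foreign_next <= length(foreign_pool)) {
          pep <- foreign_pool[foreign_next]
          foreign_next <- foreign_next + 1L
        } else mode <- "shuffled_peptide"
      }
      if (mode == "shuffled_peptide") {
        alt <- shuffle_interior(pep, all_db_peptides)
        if (is.null(alt)) mode <- "shifted_precursor" else pep <- alt
      }
      if (mode == "shifted_precursor")
        shift <- sample(c(-1, 1), 1) * stats::runif(1, 0.05, 0.5)
      mass <- peptide_mass(pep) + glycan$mass
      charge <- 2L + (mass > 2400) + (mass > 3600)
      gp <- list(glycan = glycan, peptide = pep, mods = "",
                 charge = charge, rt = rts[i],
                 title = sprintf("SYN_%05d", i), scan = i,
                 precursor_shift = shift)
      if (mode == "noise") {
        n_noise <- stats::rpois(1, 3 * params$noise_peaks)
        mz <- stats::runif(n_noise, 200, 2000)
        inten <- stats::rlnorm(n_noise, params$intensity_meanlog,
                               params$intensity_sdlog)
        spectra[[i]] <- new_spectrum(
          mz, inten, precursor_mz = mz_from_neutral(mass, charge),
          charge = charge, title = gp$title, scan = i, rt = rts[i])
        analytes[[i]] <- NULL
      } else {
        spectra[[i]] <- synth_spectrum(gp, params,
                                       seed = spectrum_seeds[i])
        analytes[[i]] <- gp
      }
      manifest[[i]] <- data.frame(
        title = gp$title, scan = i, rt = rts[i], charge = charge,
        mode = mode, is_true = mode == "true",
        glycan_id = if (mode == "noise") NA_character_ else glycan$id,
        glycan_comp = if (mode == "noise") NA_character_ else
          composition_string(glycan$composition),
        peptide = if (mode == "noise") NA_character_ else pep,
        mods = "")
    }
    ms1 <- build_benchmark_ms1(analytes, params)
  })
  manifest <- do.call(rbind, manifest)
  out <- list(spectra = spectra, ms1 = ms1, proteins = proteins,
              glycans = glycans, manifest = manifest, params = params,
              peptide_index = peptide_index)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(mgf = file.path(dir, "benchmark.mgf"),
                  ms1 = file.path(dir, "benchmark.ms1"),
                  fasta = file.path(dir, "proteins.fasta"),
                  glycans = file.path(dir, "glycans.tsv"),
                  manifest = file.path(dir, "manifest.tsv"))
    write_mgf(spectra, paths$mgf)
    write_ms1(ms1, paths$ms1)
    write_fasta_proteins(proteins, paths$fasta)
    write_glycan_db(glycans, paths$glycans)
    utils::write.table(manifest, paths$manifest, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}

# Global MS1 scan grid carrying every analyte's isotope triplet.
build_benchmark_ms1 <- function(analytes, params) {
  grid <- seq(params$rt_range[1] - 30, params$rt_range[2] + 30,
              by = params$ms1_interval)
  mz_acc <- vector("list", length(grid))
  int_acc <- vector("list", length(grid))
  hw <- params$triplet_rt_halfwidth
  for (gp in analytes) {
    if (is.null(gp)) next
    # triplets sit at the analyte's true mass: a shifted-precursor MS2
    # entry emulates a wrong monoisotope pick, not a shifted molecule
    comp <- elemental_composition(gp$peptide, gp$mods,
                                  gp$glycan$composition)
    shifts <- isotope_shifts(comp)
    neutral <- peptide_mass(gp$peptide, gp$mods) + gp$glycan$mass
    ch_mz <- c(none = mz_from_neutral(neutral, gp$charge),
               `15N` = mz_from_neutral(neutral + shifts[["N15"]],
                                       gp$charge),
               `13C` = mz_from_neutral(neutral + shifts[["C13"]],
                                       gp$charge))
    ch_mz <- ch_mz[names(ch_mz) %in% params$label_channels]
    base <- stats::rlnorm(1, params$intensity_meanlog + 2, 0.5)
    factor <- stats::rlnorm(length(ch_mz), 0, params$channel_cv)
    idx <- which(abs(grid - gp$rt) <= hw)
    for (j in idx) {
      profile <- 1 - abs(grid[j] - gp$rt) / (hw + params$ms1_interval)
      mz_acc[[j]] <- c(mz_acc[[j]], unname(ch_mz))
      int_acc[[j]] <- c(int_acc[[j]], unname(base * factor * profile))
    }
  }
  lapply(seq_along(grid), function(j) {
    mz <- mz_acc[[j]]
    inten <- int_acc[[j]]
    if (is.null(mz)) {
      mz <- numeric(0)
      inten <- numeric(0)
    }
    ord <- order(mz)
    structure(list(scan = j, rt = grid[j], mz = mz[ord],
                   intensity = inten[ord]),
              class = "ms1_scan")
  })
}

#' Synthetic ranking examples with planted exponents
#'
#' Generates within-spectrum candidate features whose planted log-linear
#' score (with exponents `alpha`, `beta` plus Gaussian noise) determines
#' the correct candidate, for exercising the ranking-SVM calibration.
#'
#' @param n_spectra Number of spectra.
#' @param n_candidates Candidates per spectrum.
#' @param alpha,beta Planted exponents.
#' @param noise_sd Gaussian noise on the planted log-score.
#' @param seed Integer seed.
#' @return data.frame consumable by [fit_score_weights()].
#' @export
synth_ranking_examples <- function(n_spectra = 300, n_candidates = 5,
                                   alpha = 0.5, beta = 0.4,
                                   noise_sd = 0.05, seed = 1) {
  with_seed(seed, {
    rows <- lapply(seq_len(n_spectra), function(s) {
      log_sum <- stats::rnorm(n_candidates, log(15), 0.4)
      lri <- log(stats::runif(n_candidates, 0.2, 1))
      lrc <- log(stats::runif(n_candidates, 0.2, 1))
      latent <- log_sum + alpha * lri + beta * lrc +
        stats::rnorm(n_candidates, 0, noise_sd)
      data.frame(spectrum = sprintf("S%04d", s),
                 label = seq_len(n_candidates) == which.max(latent),
                 log_sum = log_sum, log_ratio_ion = lri,
                 log_ratio_core = lrc)
    })
    do.call(rbind, rows)
  })
}
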