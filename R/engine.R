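# Two-stage glycopeptide search: coarse glycan open search by Y-ion
# counting, peptide lookup by backbone mass, and fine scoring of the
# glycan and peptide fragment evidence.

#' Search parameters
#'
#' Defaults follow the engine's reference configuration: +/- 5 ppm
#' precursor and +/- 20 ppm fragment tolerance, top-300 peak filtration,
#' top-100 coarse glycan candidates, at least 2 matched trimannosyl-core
#' ions, and score parameters alpha = 0.56, beta = 0.42, gamma = 0.94,
#' w = 0.35.
#'
#' @param precursor_tol_ppm,fragment_tol_ppm Symmetric mass tolerances.
#' @param top_k_glycans Coarse candidates kept per spectrum.
#' @param min_core_matches Minimum matched trimannosyl-core Y ions.
#' @param top_n_peaks Peak filtration threshold.
#' @param alpha,beta Exponents of the Y-ion and core-ion match ratios in
#'   the glycan score.
#' @param gamma Exponent of the b/y match ratio in the peptide score.
#' @param w Glycan weight of the combined glycopeptide score.
#' @param max_fragment_charge Highest charge state considered for b/y
#'   fragments (Y ions are matched up to precursor charge minus one).
#' @param intensity_scale Normalized base-peak intensity; the default e^2
#'   makes a base-peak match contribute 2 to the score sum and renders
#'   scores invariant to overall spectrum scale.
#' @return A `search_params` list.
#' @export
search_params <- function(precursor_tol_ppm = 5, fragment_tol_ppm = 20,
                          top_k_glycans = 100, min_core_matches = 2,
                          top_n_peaks = 300, alpha = 0.56, beta = 0.42,
                          gamma = 0.94, w = 0.35, max_fragment_charge = 2,
                          intensity_scale = exp(2)) {
  stopifnot(precursor_tol_ppm > 0, fragment_tol_ppm > 0,
            top_k_glycans >= 1, min_core_matches >= 0, top_n_peaks >= 1,
            alpha >= 0, beta >= 0, gamma >= 0, w > 0, w < 1,
            max_fragment_charge >= 1, intensity_scale > 1)
  structure(list(precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_ppm = fragment_tol_ppm,
                 top_k_glycans = as.integer(top_k_glycans),
                 min_core_matches = as.integer(min_core_matches),
                 top_n_peaks = as.integer(top_n_peaks),
                 alpha = alpha, beta = beta, gamma = gamma, w = w,
                 max_fragment_charge = as.integer(max_fragment_charge),
                 intensity_scale = intensity_scale),
            class = "search_params")
}

# Flatten a glycan database into vectors for vectorized coarse scoring.
compile_glycan_db <- function(db) {
  if (inherits(db, "compiled_glycan_db")) return(db)
  n_ions <- vapply(db, function(g) nrow(g$y_ions), integer(1))
  structure(
    list(glycans = db,
         id = vapply(db, `[[`, character(1), "id"),
         mass = vapply(db, `[[`, numeric(1), "mass"),
         is_decoy = vapply(db, `[[`, logical(1), "is_decoy"),
         n_ions = n_ions,
         flat_g = rep.int(seq_along(db), n_ions),
         flat_delta = unlist(lapply(db, function(g) g$y_ions$delta),
                             use.names = FALSE),
         flat_core = unlist(lapply(db, function(g) g$y_ions$is_core),
                            use.names = FALSE)),
    class = "compiled_glycan_db")
}

# Nearest-peak matching: for each theoretical m/z, the index of the
# closest observed peak within tol_ppm, else NA.
match_nearest <- function(spec_mz, theo_mz, tol_ppm) {
  if (!length(spec_mz)) return(rep(NA_integer_, length(theo_mz)))
  idx <- findInterval(theo_mz, spec_mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(spec_mz))
  pick <- lo
  swap <- abs(spec_mz[hi] - theo_mz) < abs(spec_mz[lo] - theo_mz)
  pick[swap] <- hi[swap]
  err <- abs(ppm_error(spec_mz[pick], theo_mz))
  pick[err > tol_ppm] <- NA_integer_
  pick
}

# Enforce "each observed peak matches at most one theoretical ion per
# series; nearest wins" within one series.
dedupe_series <- function(peak_idx, err_ppm) {
  ok <- which(!is.na(peak_idx))
  if (length(ok) < 2) return(peak_idx)
  ord <- ok[order(abs(err_ppm[ok]))]
  seen <- duplicated(peak_idx[ord])
  peak_idx[ord[seen]] <- NA_integer_
  peak_idx
}

#' Coarse glycan open search
#'
#' For each glycan the associated peptide backbone mass is the precursor
#' neutral mass minus the glycan mass; every Y-ion delta is matched at
#' charges 1..(precursor charge - 1) within the fragment tolerance, and
#' the glycan is scored by the number of distinct matched Y deltas.
#' Glycans with fewer than `min_core_matches` matched trimannosyl-core
#' ions are removed; the `top_k_glycans` survivors are kept, ranked by
#' match count, then summed matched intensity, then id.
#'
#' @param spectrum A (peak-filtered) `spectrum`.
#' @param glycan_db List of `glycan_structure` (targets and decoys) or a
#'   compiled database.
#' @param params [search_params()].
#' @return data.frame with columns `glycan` (index into the database),
#'   `id`, `n_matched`, `n_core`, `backbone`, `sum_intensity`.
#' @export
coarse_score <- function(spectrum, glycan_db, params = search_params()) {
  cdb <- compile_glycan_db(glycan_db)
  backbone <- spectrum$precursor_neutral - cdb$mass
  live <- backbone > 0
  empty <- data.frame(glycan = integer(), id = character(),
                      n_matched = integer(), n_core = integer(),
                      backbone = numeric(), sum_intensity = numeric())
  if (!any(live) || !length(spectrum$mz)) return(empty)
  sel <- live[cdb$flat_g]
  fg <- cdb$flat_g[sel]
  fdelta <- cdb$flat_delta[sel]
  fcore <- cdb$flat_core[sel]
  neutral <- backbone[fg] + fdelta
  charges <- seq_len(max(1L, spectrum$charge - 1L))
  matched <- rep(FALSE, length(fg))
  sum_int <- numeric(length(cdb$mass))
  for (z in charges) {
    pk <- match_nearest(spectrum$mz, neutral / z + PROTON_MASS,
                        params$fragment_tol_ppm)
    hit <- !is.na(pk)
    matched <- matched | hit
    if (any(hit)) {
      inc <- rowsum(spectrum$intensity[pk[hit]], fg[hit])
      gi <- as.integer(rownames(inc))
      sum_int[gi] <- sum_int[gi] + inc[, 1]
    }
  }
  n_matched <- tabulate(fg[matched], nbins = length(cdb$mass))
  n_core <- tabulate(fg[matched & fcore], nbins = length(cdb$mass))
  keep <- which(live & n_core >= params$min_core_matches & n_matched > 0)
  if (!length(keep)) return(empty)
  out <- data.frame(glycan = keep, id = cdb$id[keep],
                    n_matched = n_matched[keep], n_core = n_core[keep],
                    backbone = backbone[keep],
                    sum_intensity = sum_int[keep])
  out <- out[order(-out$n_matched, -out$sum_intensity, out$id), ,
             drop = FALSE]
  out <- utils::head(out, params$top_k_glycans)
  rownames(out) <- NULL
  out
}

# Fine glycan scoring kernel.  Returns score, sum-term, match ratios and
# counts; the matched-peak table is built only on request.
fine_glycan_impl <- function(spectrum, backbone_mass, glycan, params,
                             want_matches = FALSE) {
  delta <- glycan$y_ions$delta
  is_core <- glycan$y_ions$is_core
  n_theo <- length(delta)
  zero <- list(score = 0, ratio_ion = 0, ratio_core = 0, sum_term = 0,
               n_matched = 0L, matches = NULL)
  if (!n_theo || !length(spectrum$mz)) return(zero)
  charges <- seq_len(max(1L, spectrum$charge - 1L))
  base <- max(spectrum$intensity)
  tol <- params$fragment_tol_ppm
  delta_hit <- rep(FALSE, n_theo)
  sum_term <- 0
  n_matched <- 0L
  m_delta <- m_charge <- m_err <- numeric(0)
  m_core <- logical(0)
  m_peak <- integer(0)
  for (z in charges) {
    theo_mz <- (backbone_mass + delta) / z + PROTON_MASS
    pk <- match_nearest(spectrum$mz, theo_mz, tol)
    err <- ppm_error(spectrum$mz[pk], theo_mz)
    pk <- dedupe_series(pk, err)
    hit <- !is.na(pk)
    if (!any(hit)) next
    delta_hit <- delta_hit | hit
    n_matched <- n_matched + sum(hit)
    norm <- spectrum$intensity[pk[hit]] / base * params$intensity_scale
    sum_term <- sum_term +
      sum(pmax(0, log(norm)) * (1 - abs(err[hit] / tol)^4))
    if (want_matches) {
      m_delta <- c(m_delta, delta[hit])
      m_core <- c(m_core, is_core[hit])
      m_charge <- c(m_charge, rep(z, sum(hit)))
      m_peak <- c(m_peak, pk[hit])
      m_err <- c(m_err, err[hit])
    }
  }
  ratio_ion <- sum(delta_hit) / n_theo
  n_core_theo <- sum(is_core)
  ratio_core <- if (n_core_theo) sum(delta_hit & is_core) / n_core_theo
  else 1
  matches <- NULL
  if (want_matches)
    matches <- data.frame(delta = m_delta, is_core = m_core,
                          charge = as.integer(m_charge), peak = m_peak,
                          mz = spectrum$mz[m_peak], err_ppm = m_err)
  list(score = sum_term * ratio_ion^params$alpha *
         ratio_core^params$beta,
       ratio_ion = ratio_ion, ratio_core = ratio_core,
       sum_term = sum_term, n_matched = n_matched, matches = matches)
}

# Fine peptide scoring kernel (b/y ions at charges
# 1..max_fragment_charge).
fine_peptide_impl <- function(spectrum, sequence, mods, params,
                              want_matches = FALSE) {
  frags <- fragment_ions(sequence, mods)
  n_theo <- nrow(frags)
  zero <- list(score = 0, ratio_ion = 0, sum_term = 0, n_matched = 0L,
               matches = NULL)
  if (!n_theo || !length(spectrum$mz)) return(zero)
  charges <- seq_len(min(params$max_fragment_charge,
                         max(1L, spectrum$charge)))
  base <- max(spectrum$intensity)
  tol <- params$fragment_tol_ppm
  b_series <- which(frags$type == "b")
  y_series <- which(frags$type == "y")
  frag_hit <- rep(FALSE, n_theo)
  sum_term <- 0
  n_matched <- 0L
  m_type <- character(0)
  m_index <- m_charge <- m_peak <- integer(0)
  m_err <- numeric(0)
  for (z in charges) {
    theo_mz <- frags$neutral / z + PROTON_MASS
    pk <- match_nearest(spectrum$mz, theo_mz, tol)
    err <- ppm_error(spectrum$mz[pk], theo_mz)
    pk[b_series] <- dedupe_series(pk[b_series], err[b_series])
    pk[y_series] <- dedupe_series(pk[y_series], err[y_series])
    hit <- !is.na(pk)
    if (!any(hit)) next
    frag_hit <- frag_hit | hit
    n_matched <- n_matched + sum(hit)
    norm <- spectrum$intensity[pk[hit]] / base * params$intensity_scale
    sum_term <- sum_term +
      sum(pmax(0, log(norm)) * (1 - abs(err[hit] / tol)^4))
    if (want_matches) {
      m_type <- c(m_type, frags$type[hit])
      m_index <- c(m_index, frags$index[hit])
      m_charge <- c(m_charge, rep(z, sum(hit)))
      m_peak <- c(m_peak, pk[hit])
      m_err <- c(m_err, err[hit])
    }
  }
  ratio_ion <- sum(frag_hit) / n_theo
  matches <- NULL
  if (want_matches)
    matches <- data.frame(type = m_type, index = m_index,
                          charge = m_charge, peak = m_peak,
                          mz = spectrum$mz[m_peak], err_ppm = m_err)
  list(score = sum_term * ratio_ion^params$gamma, ratio_ion = ratio_ion,
       sum_term = sum_term, n_matched = n_matched, matches = matches)
}

#' Fine glycan score
#'
#' `Score_G = [sum_i log(inten_i) (1 - |merr_i/tol_i|^4)] *
#' ratio_ion^alpha * ratio_core^beta`, summing over matched Y-ion peaks
#' at charges 1..(precursor charge - 1).  Intensities are normalized so
#' the spectrum base peak equals `intensity_scale` (default e^2) and
#' per-peak contributions are floored at zero; `ratio_ion` and
#' `ratio_core` count distinct Y-ion delta masses (matched at any
#' charge) over the theoretical counts; `tol_i` is the fragment
#' tolerance at each matched peak, so `merr_i/tol_i` is the ppm error
#' over the ppm tolerance.
#'
#' @param spectrum A `spectrum`.
#' @param backbone_mass Neutral peptide backbone mass (Da).
#' @param glycan A `glycan_structure`.
#' @param params [search_params()].
#' @param detail Return the full scoring breakdown.
#' @return The score, or (with `detail = TRUE`) a list with `score`,
#'   `ratio_ion`, `ratio_core`, `sum_term`, `n_matched` and the
#'   matched-peak table `matches`.
#' @export
fine_score_glycan <- function(spectrum, backbone_mass, glycan,
                              params = search_params(), detail = FALSE) {
  res <- fine_glycan_impl(spectrum, backbone_mass, glycan, params,
                          want_matches = detail)
  if (detail) res else res$score
}

#' Fine peptide score
#'
#' `Score_P = [sum_i log(inten_i) (1 - |merr_i/tol_i|^4)] *
#' ratio_ion^gamma` over matched b/y peaks at charges
#' 1..`max_fragment_charge`; `ratio_ion` counts distinct b/y fragments
#' over the `2 (n - 1)` theoretical ones.
#'
#' @inheritParams fine_score_glycan
#' @param sequence Peptide sequence (J-marked).
#' @param mods Variable-modification string.
#' @return The score, or (with `detail = TRUE`) a list with `score`,
#'   `ratio_ion`, `sum_term`, `n_matched` and `matches`.
#' @export
fine_score_peptide <- function(spectrum, sequence, mods = "",
                               params = search_params(), detail = FALSE) {
  res <- fine_peptide_impl(spectrum, sequence, mods, params,
                           want_matches = detail)
  if (detail) res else res$score
}

#' Combined glycopeptide score
#'
#' The weighted sum `w * Score_G + (1 - w) * Score_P`.
#'
#' @param score_g,score_p Component scores.
#' @param w Glycan weight in (0, 1).
#' @return Numeric score.
#' @examples
#' total_score(10, 20, 0.35)  # 16.5
#' @export
total_score <- function(score_g, score_p, w = 0.35) {
  stopifnot(w > 0, w < 1)
  w * score_g + (1 - w) * score_p
}

# Candidate record columns, in output order.
GPSM_COLUMNS <- c("title", "scan", "rt", "precursor_mz", "charge",
                  "glycan_id", "glycan_comp", "glycan_mass", "peptide",
                  "mods", "glyco_pos", "protein", "backbone_mass",
                  "mass_error_ppm", "n_y_matched", "n_core_matched",
                  "n_by_matched", "score_g", "score_p", "score_gp",
                  "glycan_decoy", "peptide_decoy", "glycan_species",
                  "peptide_species", "q_value")

# Assemble a GPSM data.frame from a list of candidate record lists.
gpsm_df <- function(records) {
  cols <- lapply(GPSM_COLUMNS, function(cn)
    unlist(lapply(records, `[[`, cn), use.names = FALSE))
  names(cols) <- GPSM_COLUMNS
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Core search: returns the candidate record list of one spectrum,
# ordered best-first, or NULL.
search_spectrum_core <- function(spectrum, cdb, peptide_index, params) {
  spec <- filter_top_peaks(spectrum, params$top_n_peaks)
  coarse <- coarse_score(spec, cdb, params)
  if (!nrow(coarse)) return(NULL)
  records <- list()
  for (ci in seq_len(nrow(coarse))) {
    glycan <- cdb$glycans[[coarse$glycan[ci]]]
    peps <- lookup_peptides(peptide_index, coarse$backbone[ci],
                            params$precursor_tol_ppm)
    if (!nrow(peps)) next
    for (pi in seq_len(nrow(peps))) {
      fg <- fine_glycan_impl(spec, peps$mass[pi], glycan, params)
      fp <- fine_peptide_impl(spec, peps$peptide[pi], peps$mods[pi],
                              params)
      # a peptide with no matched backbone fragment carries no
      # identification evidence (the peptide engine would not report it)
      if (fp$n_matched < 1L) next
      theo <- peps$mass[pi] + glycan$mass
      records[[length(records) + 1L]] <- list(
        title = spec$title, scan = spec$scan, rt = spec$rt,
        precursor_mz = spec$precursor_mz, charge = spec$charge,
        glycan_id = glycan$id,
        glycan_comp = composition_string(glycan$composition),
        glycan_mass = glycan$mass,
        peptide = peps$peptide[pi], mods = peps$mods[pi],
        glyco_pos = peps$glyco_pos[pi], protein = peps$protein[pi],
        backbone_mass = peps$mass[pi],
        mass_error_ppm = ppm_error(spec$precursor_neutral, theo),
        n_y_matched = fg$n_matched, n_core_matched = coarse$n_core[ci],
        n_by_matched = fp$n_matched,
        score_g = fg$score, score_p = fp$score,
        score_gp = params$w * fg$score + (1 - params$w) * fp$score,
        glycan_decoy = glycan$is_decoy,
        peptide_decoy = peps$is_decoy[pi],
        glycan_species = paste(glycan$species, collapse = ","),
        peptide_species = peps$species[pi],
        q_value = NA_real_)
    }
  }
  if (!length(records)) return(NULL)
  sgp <- vapply(records, `[[`, numeric(1), "score_gp")
  sp <- vapply(records, `[[`, numeric(1), "score_p")
  sg <- vapply(records, `[[`, numeric(1), "score_g")
  gid <- vapply(records, `[[`, character(1), "glycan_id")
  pep <- vapply(records, `[[`, character(1), "peptide")
  mods <- vapply(records, `[[`, character(1), "mods")
  # exact score ties carry no evidence; a deterministic string hash is
  # blind to target/decoy status, whereas lexicographic order is not
  # (decoy sequences are reversals, with measurably different leading
  # characters), which would bias target-decoy competition
  tie <- string_hash31(paste(gid, pep, mods))
  records <- records[order(-sgp, -sp, -sg, tie, gid, pep, mods)]
  # a spectrum whose best target and best decoy explanations are
  # score-identical on all three scores is undecidable: report nothing
  # rather than flip a coin that the FDR estimator must then absorb
  dec1 <- records[[1]]$glycan_decoy || records[[1]]$peptide_decoy
  sgp <- vapply(records, `[[`, numeric(1), "score_gp")
  sp <- vapply(records, `[[`, numeric(1), "score_p")
  sg <- vapply(records, `[[`, numeric(1), "score_g")
  tied <- which(sgp == sgp[1] & sp == sp[1] & sg == sg[1])
  cls <- vapply(records[tied], function(r)
    r$glycan_decoy || r$peptide_decoy, logical(1))
  if (any(cls != dec1)) return(NULL)
  records
}

# Deterministic 31-bit string hash (polynomial rolling hash).
string_hash31 <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Search one spectrum against a glycan database and peptide index
#'
#' Runs coarse glycan scoring, backbone-mass peptide lookup and fine
#' scoring, and returns the highest-scoring glycopeptide-spectrum match
#' (GPSM).  Ties are broken by peptide score, then glycan score, then
#' lexicographic glycan/peptide ids.  Chimeric precursors are handled
#' upstream: each MGF entry of a scan is searched independently.
#'
#' @param spectrum A `spectrum`.
#' @param glycan_db Glycan database (targets + decoys), list or compiled.
#' @param peptide_index A `peptide_index`.
#' @param params [search_params()].
#' @param co_ranked Also return all scored candidates of the spectrum.
#' @return One-row GPSM data.frame (or `NULL` when no candidate
#'   survives): spectrum metadata, glycan id/composition, peptide,
#'   modifications, backbone and theoretical masses, precursor error
#'   (ppm), match counts, the three scores, decoy flags and species
#'   tags.  With `co_ranked = TRUE` the full candidate table is attached
#'   as attribute `"candidates"`.
#' @export
search_spectrum <- function(spectrum, glycan_db, peptide_index,
                            params = search_params(), co_ranked = FALSE) {
  cdb <- compile_glycan_db(glycan_db)
  records <- search_spectrum_core(spectrum, cdb, peptide_index, params)
  if (is.null(records)) return(NULL)
  best <- gpsm_df(records[1])
  if (co_ranked) attr(best, "candidates") <- gpsm_df(records)
  best
}

#' Search many spectra
#'
#' @param spectra List of `spectrum` objects.
#' @param glycan_db,peptide_index,params As in [search_spectrum()].
#' @param progress Print a progress message every 200 spectra.
#' @return data.frame of GPSMs, or `NULL` when nothing matched.
#' @export
search_spectra <- function(spectra, glycan_db, peptide_index,
                           params = search_params(), progress = FALSE) {
  cdb <- compile_glycan_db(glycan_db)
  out <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    rec <- search_spectrum_core(spectra[[i]], cdb, peptide_index, params)
    if (!is.null(rec)) out[[i]] <- rec[[1]]
    if (progress && i %% 200 == 0)
      message("searched ", i, "/", length(spectra), " spectra")
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  gpsm_df(out)
}

#' Write a GPSM table as TSV
#'
#' @param gpsms GPSM data.frame.
#' @param path Output path.
#' @export
write_gpsm_tsv <- function(gpsms, path) {
  utils::write.table(gpsms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GPSM TSV back
#'
#' @param path TSV path written by [write_gpsm_tsv()].
#' @return GPSM data.frame.
#' @export
read_gpsm_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

# Diagnostic (oxonium) ions: annotated in reports, never scored.
oxonium_table <- function() {
  data.frame(
    name = c("HexNAc", "HexNAc-H2O", "HexNAc-2H2O", "HexNAc-frag138",
             "HexNAc-frag126", "Hex", "HexHexNAc", "NeuAc", "NeuAc-H2O",
             "NeuGc"),
    mz = c(MONO_MASS[["N"]] + WATER_MASS + PROTON_MASS,
           MONO_MASS[["N"]] + PROTON_MASS,
           MONO_MASS[["N"]] - WATER_MASS + PROTON_MASS,
           138.054955, 126.054955,
           MONO_MASS[["H"]] + PROTON_MASS,
           MONO_MASS[["H"]] + MONO_MASS[["N"]] + PROTON_MASS,
           MONO_MASS[["A"]] + WATER_MASS + PROTON_MASS,
           MONO_MASS[["A"]] + PROTON_MASS,
           MONO_MASS[["G"]] + WATER_MASS + PROTON_MASS))
}

#' Plain-text spectrum annotation report
#'
#' Mirrors the three-box annotation layout of interactive glycopeptide
#' viewers: a header box (glycosylation site, modifications, spectrum
#' name, precursor deviation, glycan composition, J-marked peptide), a
#' peak-annotation box (Y ions, b/y ions and diagnostic oxonium ions)
#' and a mass-deviation box.
#'
#' @param spectrum The matched `spectrum`.
#' @param gpsm One-row GPSM data.frame from [search_spectrum()].
#' @param glycan_db The glycan database used for the search.
#' @param params [search_params()].
#' @return Character vector of report lines.
#' @export
annotate_gpsm <- function(spectrum, gpsm, glycan_db,
                          params = search_params()) {
  cdb <- compile_glycan_db(glycan_db)
  glycan <- cdb$glycans[[match(gpsm$glycan_id, cdb$id)]]
  spec <- filter_top_peaks(spectrum, params$top_n_peaks)
  fg <- fine_score_glycan(spec, gpsm$backbone_mass, glycan, params,
                          detail = TRUE)
  fp <- fine_score_peptide(spec, gpsm$peptide, gpsm$mods, params,
                           detail = TRUE)
  oxo <- oxonium_table()
  pk <- match_nearest(spec$mz, oxo$mz, params$fragment_tol_ppm)
  oxo_hit <- which(!is.na(pk))
  header <- c(
    "== glycopeptide spectrum match ==",
    sprintf("glysite: %d  mod: %s", gpsm$glyco_pos,
            ifelse(nzchar(gpsm$mods), gpsm$mods, "-")),
    sprintf("spectrum: %s", gpsm$title),
    sprintf("precursor deviation: %.2f ppm", gpsm$mass_error_ppm),
    sprintf("glycan: %s (%s)  peptide: %s", gpsm$glycan_comp,
            gpsm$glycan_id, gpsm$peptide),
    sprintf("scores: G=%.3f P=%.3f GP=%.3f", gpsm$score_g, gpsm$score_p,
            gpsm$score_gp))
  ann <- c("-- peak annotation --",
           sprintf("%-14s %10s %12s %4s", "ion", "m/z", "intensity", "z"))
  if (!is.null(fg$matches) && nrow(fg$matches))
    ann <- c(ann, sprintf("Y+%-12.4f %10.4f %12.1f %4d",
                          fg$matches$delta, fg$matches$mz,
                          spec$intensity[fg$matches$peak],
                          fg$matches$charge))
  if (!is.null(fp$matches) && nrow(fp$matches))
    ann <- c(ann, sprintf("%s%-13d %10.4f %12.1f %4d",
                          fp$matches$type, fp$matches$index,
                          fp$matches$mz,
                          spec$intensity[fp$matches$peak],
                          fp$matches$charge))
  if (length(oxo_hit))
    ann <- c(ann, sprintf("oxonium:%-6s %10.4f %12.1f %4d",
                          oxo$name[oxo_hit], spec$mz[pk[oxo_hit]],
                          spec$intensity[pk[oxo_hit]], 1L))
  dev <- "-- mass deviations (ppm) --"
  if (!is.null(fg$matches) && nrow(fg$matches))
    dev <- c(dev, sprintf("Y+%-12.4f %8.2f", fg$matches$delta,
                          fg$matches$err_ppm))
  if (!is.null(fp$matches) && nrow(fp$matches))
    dev <- c(dev, sprintf("%s%-13d %8.2f", fp$matches$type,
                          fp$matches$index, fp$matches$err_ppm))
  c(header, ann, dev)
}
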