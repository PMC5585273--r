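# Protein digestion, sequon marking, peptide and fragment masses,
# elemental composition and peptide decoys.

AA_LETTERS <- setdiff(names(AA_MASS), "J")

#' Read proteins from a FASTA file
#'
#' @param path FASTA file (standard dialect, wrapped lines allowed).
#' @param species_pattern Regex with one capture group extracting a
#'   comma-separated species tag list from the header, e.g. the default
#'   matches `species=yeast` tokens.
#' @return data.frame with columns `id` (first header token), `sequence`,
#'   `species` (comma-separated tags, possibly "") and `is_decoy`.
#' @export
read_fasta_proteins <- function(path, species_pattern = "species=([^ ]+)") {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1)
  species <- vapply(headers, function(h) {
    m <- regmatches(h, regexec(species_pattern, h))[[1]]
    if (length(m) >= 2) m[2] else ""
  }, character(1), USE.NAMES = FALSE)
  data.frame(id = ids, sequence = as.character(aa), species = species,
             is_decoy = FALSE, row.names = NULL)
}

#' Write proteins to a FASTA file
#'
#' @param proteins data.frame as returned by [read_fasta_proteins()].
#' @param path Output path.
#' @export
write_fasta_proteins <- function(proteins, path) {
  headers <- ifelse(nzchar(proteins$species),
                    paste0(proteins$id, " species=", proteins$species),
                    proteins$id)
  out <- character(2 * nrow(proteins))
  out[c(TRUE, FALSE)] <- paste0(">", headers)
  out[c(FALSE, TRUE)] <- proteins$sequence
  writeLines(out, path)
  invisible(path)
}

#' Digestion parameters
#'
#' Full-tryptic digestion (cleavage C-terminal to K/R, not before P) with
#' up to `max_missed_cleavages` missed cleavages; carbamidomethyl on Cys is
#' fixed; oxidation on Met and protein N-terminal acetylation are the
#' variable modifications, capped at `max_var_mods` per peptide.
#'
#' @param max_missed_cleavages Maximum missed cleavages (default 3).
#' @param min_length,max_length Peptide length bounds (default 6--40).
#' @param variable_mods Character subset of `c("Oxidation", "Acetyl")`.
#' @param max_var_mods Cap on variable modifications per peptide.
#' @return A `digest_params` list.
#' @export
digest_params <- function(max_missed_cleavages = 3, min_length = 6,
                          max_length = 40,
                          variable_mods = c("Oxidation", "Acetyl"),
                          max_var_mods = 3) {
  stopifnot(max_missed_cleavages >= 0, min_length >= 1,
            max_length >= min_length, max_var_mods >= 0)
  variable_mods <- match.arg(variable_mods, c("Oxidation", "Acetyl"),
                             several.ok = TRUE)
  structure(list(max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 variable_mods = variable_mods,
                 max_var_mods = as.integer(max_var_mods)),
            class = "digest_params")
}

# Positions i such that cleavage occurs after residue i.
cleavage_sites <- function(residues) {
  n <- length(residues)
  if (n < 2) return(integer(0))
  which(residues[-n] %in% c("K", "R") & residues[-1] != "P")
}

# Protein positions of N-X-S/T (X != P) sequon asparagines.
sequon_positions <- function(residues) {
  n <- length(residues)
  if (n < 3) return(integer(0))
  idx <- seq_len(n - 2)
  idx[residues[idx] == "N" & residues[idx + 1] != "P" &
        residues[idx + 2] %in% c("S", "T")]
}

#' Digest proteins into tryptic peptides with sequon marking
#'
#' Peptides containing an N-X-S/T (X != P) sequon are additionally emitted
#' once per sequon with that N replaced by J (same mass as N); only these
#' J-marked rows enter the glycopeptide index.  Protein records containing
#' non-standard residues are skipped with a warning.
#'
#' @param proteins data.frame with columns `id`, `sequence` and optionally
#'   `species`, `is_decoy`.
#' @param params A [digest_params()] object.
#' @return data.frame with columns `peptide` (J-marked when `is_glyco`),
#'   `protein`, `start`, `n_missed`, `glyco_pos` (position of J within the
#'   peptide, NA for non-glyco rows), `is_glyco`, `is_decoy`, `species`.
#' @examples
#' prot <- data.frame(id = "P1", sequence = "MKRNGTKPR")
#' digest(prot, digest_params(max_missed_cleavages = 0, min_length = 1))
#' @export
digest <- function(proteins, params = digest_params()) {
  if (is.null(proteins$species)) proteins$species <- ""
  if (is.null(proteins$is_decoy)) proteins$is_decoy <- FALSE
  out <- vector("list", nrow(proteins))
  for (r in seq_len(nrow(proteins))) {
    seqr <- proteins$sequence[r]
    residues <- strsplit(seqr, "", fixed = TRUE)[[1]]
    if (!all(residues %in% AA_LETTERS)) {
      warning("protein ", proteins$id[r],
              " contains non-standard residues; record skipped")
      next
    }
    n <- length(residues)
    bounds <- c(0L, cleavage_sites(residues), n)
    nb <- length(bounds)
    sequons <- sequon_positions(residues)
    # enumerate cut-point pairs (i, j) with <= max_missed_cleavages
    # internal sites
    ii <- rep.int(seq_len(nb - 1L),
                  pmin(params$max_missed_cleavages + 1L,
                       nb - seq_len(nb - 1L)))
    jj <- unlist(lapply(seq_len(nb - 1L), function(i)
      (i + 1L):min(i + params$max_missed_cleavages + 1L, nb)),
      use.names = FALSE)
    from <- bounds[ii] + 1L
    to <- bounds[jj]
    len <- to - from + 1L
    ok <- len >= params$min_length & len <= params$max_length
    from <- from[ok]
    to <- to[ok]
    n_missed <- (jj - ii - 1L)[ok]
    if (!length(from)) next
    pep <- substring(seqr, from, to)
    base <- data.frame(
      peptide = pep, protein = proteins$id[r], start = from,
      n_missed = n_missed, glyco_pos = NA_integer_, is_glyco = FALSE,
      is_decoy = proteins$is_decoy[r], species = proteins$species[r])
    glyco <- NULL
    if (length(sequons)) {
      hits <- which(outer(sequons, from, `>=`) & outer(sequons, to, `<=`),
                    arr.ind = TRUE)
      if (nrow(hits)) {
        q <- sequons[hits[, 1]]
        k <- hits[, 2]
        marked <- pep[k]
        pos <- q - from[k] + 1L
        substr(marked, pos, pos) <- "J"
        glyco <- data.frame(
          peptide = marked, protein = proteins$id[r], start = from[k],
          n_missed = n_missed[k], glyco_pos = pos, is_glyco = TRUE,
          is_decoy = proteins$is_decoy[r], species = proteins$species[r])
      }
    }
    out[[r]] <- rbind(base, glyco)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(peptide = character(), protein = character(),
                      start = integer(), n_missed = integer(),
                      glyco_pos = integer(), is_glyco = logical(),
                      is_decoy = logical(), species = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pseudo-reversed decoy proteins
#'
#' Each tryptic segment (ending at its K/R) is reversed in place keeping
#' the terminal K/R fixed, so decoy peptides preserve tryptic termini and
#' the target precursor-mass distribution.  A palindromic segment may
#' yield a decoy equal to its target; such decoys are kept.
#'
#' @param proteins data.frame as for [digest()].
#' @return data.frame of the same shape with `is_decoy = TRUE` and ids
#'   prefixed `DECOY_`.
#' @export
decoy_proteins <- function(proteins) {
  rev_seq <- vapply(proteins$sequence, function(s) {
    residues <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(residues)
    bounds <- c(0L, cleavage_sites(residues), n)
    segs <- character(length(bounds) - 1)
    for (i in seq_along(segs)) {
      seg <- residues[(bounds[i] + 1L):bounds[i + 1L]]
      m <- length(seg)
      if (m > 1 && seg[m] %in% c("K", "R"))
        seg <- c(rev(seg[-m]), seg[m])
      else
        seg <- rev(seg)
      segs[i] <- paste(seg, collapse = "")
    }
    paste(segs, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out <- proteins
  out$id <- paste0("DECOY_", proteins$id)
  out$sequence <- rev_seq
  out$is_decoy <- TRUE
  out
}

# Modification-string helpers: variable modifications are encoded as
# "Name@pos" joined by ";", with position 0 denoting the N-terminus.
parse_mods <- function(mods) {
  if (is.null(mods) || is.na(mods) || !nzchar(mods))
    return(data.frame(name = character(), pos = integer()))
  parts <- strsplit(mods, ";", fixed = TRUE)[[1]]
  name <- sub("@.*$", "", parts)
  pos <- as.integer(sub("^.*@", "", parts))
  bad <- setdiff(name, names(MODIFICATIONS))
  if (length(bad)) stop("unknown modification(s): ",
                        paste(bad, collapse = ", "))
  data.frame(name = name, pos = pos)
}

# Per-residue variable + fixed modification deltas for a peptide.
residue_mod_deltas <- function(residues, mods) {
  delta <- ifelse(residues == "C", MOD_MASS[["Carbamidomethyl"]], 0)
  md <- parse_mods(mods)
  if (nrow(md)) {
    pos <- ifelse(md$pos == 0L, 1L, md$pos)
    if (any(pos < 1L | pos > length(residues)))
      stop("modification position out of range")
    for (k in seq_len(nrow(md)))
      delta[pos[k]] <- delta[pos[k]] + MOD_MASS[[md$name[k]]]
  }
  delta
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus water plus modification deltas; J is counted
#' as N and carbamidomethyl is applied to every Cys.
#'
#' @param sequence Peptide sequence (may contain J).
#' @param mods Variable-modification string, e.g. `"Oxidation@3"`
#'   (`""` for none; position 0 is the N-terminus).
#' @return Mass in Daltons.
#' @examples
#' peptide_mass("PEPTIDE")  # 799.3600
#' @export
peptide_mass <- function(sequence, mods = "") {
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!length(residues)) stop("empty peptide sequence")
  bad <- setdiff(residues, names(AA_MASS))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  sum(AA_MASS[residues]) + WATER_MASS +
    sum(residue_mod_deltas(residues, mods))
}

#' Neutral b/y fragment masses of a peptide
#'
#' b_i is the sum of the first i (modified) residues; y_i is the sum of the
#' last i residues plus water, so that b_i + y_(n-i) = M + water holds for
#' the neutral-mass convention used throughout.
#'
#' @inheritParams peptide_mass
#' @return data.frame with columns `type` ("b"/"y"), `index` and `neutral`
#'   (Da); `2 * (nchar(sequence) - 1)` rows.
#' @export
fragment_ions <- function(sequence, mods = "") {
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(residues)
  if (n < 2) stop("peptide must have length >= 2")
  delta <- residue_mod_deltas(residues, mods)
  prefix <- cumsum(AA_MASS[residues] + delta)
  i <- seq_len(n - 1)
  data.frame(
    type = rep(c("b", "y"), each = n - 1),
    index = c(i, i),
    neutral = c(prefix[i], prefix[n] - prefix[n - i] + WATER_MASS),
    row.names = NULL
  )
}

#' Elemental composition of a (glyco)peptide
#'
#' Atom counts over C, H, N, O, S of the intact glycopeptide: peptide
#' residues + water + fixed/variable modifications + glycan residues.
#'
#' @inheritParams peptide_mass
#' @param glycan Glycan composition (named counts, composition string or
#'   `glycan_structure`); `NULL` for a bare peptide.
#' @return Named numeric vector `c(C, H, N, O, S)`.
#' @export
elemental_composition <- function(sequence, mods = "", glycan = NULL) {
  if ((is.null(sequence) || !nzchar(sequence)) && is.null(glycan))
    stop("empty peptide and empty glycan")
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!length(residues)) stop("empty peptide sequence")
  comp <- Reduce(function(a, b) add_formulas(a, b),
                 AA_FORMULA[residues], WATER_FORMULA)
  comp <- add_formulas(comp,
                       c(C = 2, H = 3, N = 1, O = 1) * sum(residues == "C"))
  md <- parse_mods(mods)
  for (k in seq_len(nrow(md)))
    comp <- add_formulas(comp, MODIFICATIONS[[md$name[k]]]$formula)
  if (!is.null(glycan)) {
    if (inherits(glycan, "glycan_structure")) glycan <- glycan$composition
    if (is.character(glycan)) glycan <- parse_composition(glycan)
    for (s in names(glycan))
      comp <- add_formulas(comp, MONOSACCHARIDES[[s]] * glycan[[s]])
  }
  comp
}

#' Precursor mass shifts of the 15N and 13C metabolic-label channels
#'
#' @param composition Named atom counts as returned by
#'   [elemental_composition()].
#' @return `c(N15 = ..., C13 = ...)` in Daltons: nitrogen count times
#'   0.9970349 and carbon count times 1.0033548.
#' @export
isotope_shifts <- function(composition) {
  c(N15 = unname(composition["N"]) * N15_SHIFT,
    C13 = unname(composition["C"]) * C13_SHIFT)
}

#' Pseudo-reversed decoy glycopeptides
#'
#' Peptide-level decoys: the interior of each J-marked peptide is
#' reversed keeping the C-terminal K/R in place, with the J residue
#' traveling along.  This preserves the neutral mass, the tryptic
#' terminus and the presence of exactly one marked glycosite, so every
#' target peptidoform has a mass-matched decoy competitor.  A
#' palindromic peptide may yield a decoy equal to its target; such
#' decoys are kept.
#'
#' @param dig data.frame of J-marked digested peptides (rows of
#'   [digest()] with `is_glyco = TRUE`).
#' @return data.frame of the same shape with `is_decoy = TRUE`,
#'   reversed peptides and updated `glyco_pos`.
#' @export
decoy_glyco_peptides <- function(dig) {
  out <- dig
  out$peptide <- vapply(dig$peptide, function(p) {
    res <- strsplit(p, "", fixed = TRUE)[[1]]
    n <- length(res)
    if (n > 1 && res[n] %in% c("K", "R"))
      paste(c(rev(res[-n]), res[n]), collapse = "")
    else
      paste(rev(res), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out$glyco_pos <- vapply(out$peptide, function(p)
    as.integer(regexpr("J", p, fixed = TRUE)), integer(1),
    USE.NAMES = FALSE)
  out$protein <- paste0("DECOY_", dig$protein)
  out$is_decoy <- TRUE
  out
}

#' Build a mass-sorted glycopeptide candidate index
#'
#' Digests the target proteins, keeps J-marked sequon peptides, attaches
#' peptide-level pseudo-reversed decoys (see [decoy_glyco_peptides()]),
#' expands variable modifications (oxidized Met combinations and protein
#' N-terminal acetylation, up to `max_var_mods` per peptide) and sorts
#' by neutral mass.
#'
#' @param proteins Target proteins data.frame (see [read_fasta_proteins()]).
#' @param params A [digest_params()] object.
#' @param decoys Include decoy peptides (default TRUE).
#' @return data.frame of class `peptide_index`, sorted by `mass`, with
#'   columns `peptide`, `mods`, `mass`, `glyco_pos`, `protein`,
#'   `is_decoy`, `species`.
#' @export
build_peptide_index <- function(proteins, params = digest_params(),
                                decoys = TRUE) {
  dig <- digest(proteins, params)
  dig <- dig[dig$is_glyco, , drop = FALSE]
  if (!nrow(dig)) stop("no glycopeptide candidates after digestion")
  if (decoys) dig <- rbind(dig, decoy_glyco_peptides(dig))
  has_ox <- "Oxidation" %in% params$variable_mods
  expand <- lapply(seq_len(nrow(dig)), function(r) {
    pep <- dig$peptide[r]
    mpos <- if (has_ox) {
      m <- gregexpr("M", pep, fixed = TRUE)[[1]]
      if (m[1] == -1L) integer(0) else as.integer(m)
    } else integer(0)
    acetyl_ok <- "Acetyl" %in% params$variable_mods && dig$start[r] == 1L
    mod_strings <- ""
    n_ox_of <- 0L
    kmax <- min(length(mpos), params$max_var_mods)
    if (kmax > 0)
      for (k in seq_len(kmax)) {
        # combn(<scalar>, k) would expand seq_len(<scalar>)
        combos <- if (length(mpos) == 1L) list(mpos)
        else utils::combn(mpos, k, simplify = FALSE)
        mod_strings <- c(mod_strings, vapply(combos, function(cc)
          paste0("Oxidation@", cc, collapse = ";"), character(1)))
        n_ox_of <- c(n_ox_of, rep(k, length(combos)))
      }
    if (acetyl_ok) {
      ac <- ifelse(nzchar(mod_strings),
                   paste0(mod_strings, ";Acetyl@0"), "Acetyl@0")
      mod_strings <- c(mod_strings, ac[n_ox_of + 1L <= params$max_var_mods])
    }
    mod_strings
  })
  counts <- lengths(expand)
  idx <- dig[rep.int(seq_len(nrow(dig)), counts),
             c("peptide", "glyco_pos", "protein", "is_decoy", "species"),
             drop = FALSE]
  idx$mods <- unlist(expand, use.names = FALSE)
  key <- paste(idx$peptide, idx$mods, idx$is_decoy)
  agg_protein <- vapply(split(idx$protein, key), function(p)
    paste(sort(unique(p)), collapse = ";"), character(1))
  agg_species <- vapply(split(idx$species, key), function(s) {
    s <- unique(unlist(strsplit(s[nzchar(s)], ",", fixed = TRUE)))
    paste(sort(s), collapse = ",")
  }, character(1))
  idx <- idx[!duplicated(key), , drop = FALSE]
  key <- key[!duplicated(key)]
  idx$protein <- agg_protein[key]
  idx$species <- agg_species[key]
  base_mass <- vapply(unique(idx$peptide), peptide_mass, numeric(1))
  umods <- unique(idx$mods)
  umod_mass <- vapply(umods, function(m) {
    md <- parse_mods(m)
    if (!nrow(md)) 0 else sum(MOD_MASS[md$name])
  }, numeric(1), USE.NAMES = FALSE)
  idx$mass <- unname(base_mass[idx$peptide]) +
    umod_mass[match(idx$mods, umods)]
  idx <- idx[order(idx$mass), , drop = FALSE]
  rownames(idx) <- NULL
  class(idx) <- c("peptide_index", "data.frame")
  idx
}

#' Look up candidate peptides by backbone mass
#'
#' Binary search over the mass-sorted index for all peptides whose neutral
#' mass lies within `mass * (1 +/- tol_ppm * 1e-6)`.
#'
#' @param index A `peptide_index` from [build_peptide_index()].
#' @param mass Query backbone mass (Da).
#' @param tol_ppm Symmetric tolerance in ppm (default 5).
#' @return The matching rows of `index` (possibly zero rows).
#' @export
lookup_peptides <- function(index, mass, tol_ppm = 5) {
  lo <- mass * (1 - tol_ppm * 1e-6)
  hi <- mass * (1 + tol_ppm * 1e-6)
  from <- findInterval(lo, index$mass, left.open = TRUE) + 1L
  to <- findInterval(hi, index$mass)
  if (from > to) return(index[0, , drop = FALSE])
  index[from:to, , drop = FALSE]
}
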