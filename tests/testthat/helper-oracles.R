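# Independent brute-force oracles used by property tests.  These
# deliberately re-derive results from first principles (bitmask subset
# enumeration, linear scans, naive double loops) so they share no code
# path with the implementation they check.

PROTON <- 1.007276466
MONO <- c(H = 162.0528234, N = 203.0793725, F = 146.0579088,
          A = 291.0954165, G = 307.0903311)
CORE6 <- c(0, MONO[["N"]], 2 * MONO[["N"]], 2 * MONO[["N"]] + MONO[["H"]],
           2 * MONO[["N"]] + 2 * MONO[["H"]],
           2 * MONO[["N"]] + 3 * MONO[["H"]])

# All Y-ion deltas of a rooted tree by exhaustive subset enumeration:
# every subset of nodes that contains the root and is closed under
# parenthood is a root-containing subtree.
oracle_y_deltas <- function(symbols, parent) {
  n <- length(symbols)
  masses <- MONO[symbols]
  deltas <- 0
  for (mask in seq_len(2^n - 1)) {
    in_set <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    if (!in_set[parent == 0]) next
    ok <- TRUE
    for (i in which(in_set))
      if (parent[i] > 0 && !in_set[parent[i]]) { ok <- FALSE; break }
    if (ok) deltas <- c(deltas, sum(masses[in_set]))
  }
  sort(unique(round(deltas, 4)))
}

# Random glycan tree as a bracketed structure string.
random_tree_text <- function(n_nodes) {
  symbols <- sample(names(MONO), n_nodes, replace = TRUE)
  parent <- c(0L, if (n_nodes > 1)
    vapply(2:n_nodes, function(i) sample(i - 1, 1), integer(1)))
  ser <- function(node) {
    kids <- which(parent == node)
    paste0("(", symbols[node],
           paste(vapply(kids, ser, character(1)), collapse = ""), ")")
  }
  list(text = ser(1), symbols = symbols, parent = parent)
}

# Exhaustive tryptic digestion by cut-point enumeration.
oracle_digest <- function(seq, max_missed, min_len = 1, max_len = 1000) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  sites <- which(res[-n] %in% c("K", "R") & res[-1] != "P")
  bounds <- c(0, sites, n)
  peps <- character(0)
  for (a in seq_along(bounds)) for (b in seq_along(bounds)) {
    if (b <= a || b - a - 1 > max_missed) next
    pep <- substr(seq, bounds[a] + 1, bounds[b])
    if (nchar(pep) >= min_len && nchar(pep) <= max_len)
      peps <- c(peps, pep)
  }
  sort(peps)
}

# Linear-scan peptide lookup.
oracle_lookup <- function(masses, query, tol_ppm) {
  which(abs(masses - query) <= query * tol_ppm * 1e-6)
}

# Naive nearest-peak match (double loop), one peak per ion per series.
oracle_match <- function(spec_mz, theo_mz, tol_ppm) {
  cand <- list()
  for (i in seq_along(theo_mz)) {
    err <- (spec_mz - theo_mz[i]) / theo_mz[i] * 1e6
    ok <- which(abs(err) <= tol_ppm)
    if (!length(ok)) next
    j <- ok[which.min(abs(err[ok]))]
    cand[[length(cand) + 1]] <- c(ion = i, peak = j, err = err[j])
  }
  if (!length(cand)) return(NULL)
  m <- do.call(rbind, cand)
  m <- m[order(abs(m[, "err"])), , drop = FALSE]
  m[!duplicated(m[, "peak"]), , drop = FALSE]
}

oracle_sum_term <- function(intens, base, errs, tol_ppm) {
  if (!length(intens)) return(0)
  sum(pmax(0, log(intens / base * exp(2))) * (1 - abs(errs / tol_ppm)^4))
}

# Exhaustive scoring of every (glycan, peptide) pair of a small database,
# replicating the engine contract with plain loops.
oracle_search <- function(spec, glycans, index, params) {
  spec <- filter_top_peaks(spec, params$top_n_peaks)
  if (!length(spec$mz)) return(NULL)
  base <- max(spec$intensity)
  best <- NULL
  for (g in glycans) {
    backbone <- spec$precursor_neutral - g$mass
    if (backbone <= 0) next
    # coarse: distinct deltas matched at charges 1..z-1
    ycharges <- seq_len(max(1, spec$charge - 1))
    hit_delta <- rep(FALSE, nrow(g$y_ions))
    core_hit <- rep(FALSE, nrow(g$y_ions))
    for (i in seq_len(nrow(g$y_ions))) for (z in ycharges) {
      tmz <- (backbone + g$y_ions$delta[i]) / z + PROTON
      if (any(abs((spec$mz - tmz) / tmz * 1e6) <= params$fragment_tol_ppm))
        hit_delta[i] <- TRUE
    }
    if (sum(hit_delta & g$y_ions$is_core) < params$min_core_matches) next
    if (!any(hit_delta)) next
    peps <- index[oracle_lookup(index$mass, backbone,
                                params$precursor_tol_ppm), , drop = FALSE]
    if (!nrow(peps)) next
    for (pi in seq_len(nrow(peps))) {
      # glycan fine score against this peptide's backbone
      sum_g <- 0
      dhit <- rep(FALSE, nrow(g$y_ions))
      for (z in ycharges) {
        tmz <- (peps$mass[pi] + g$y_ions$delta) / z + PROTON
        m <- oracle_match(spec$mz, tmz, params$fragment_tol_ppm)
        if (is.null(m)) next
        dhit[m[, "ion"]] <- TRUE
        sum_g <- sum_g + oracle_sum_term(spec$intensity[m[, "peak"]],
                                         base, m[, "err"],
                                         params$fragment_tol_ppm)
      }
      score_g <- sum_g * (sum(dhit) / nrow(g$y_ions))^params$alpha *
        (sum(dhit & g$y_ions$is_core) /
           max(1, sum(g$y_ions$is_core)))^params$beta
      # peptide fine score
      frags <- fragment_ions(peps$peptide[pi], peps$mods[pi])
      fhit <- rep(FALSE, nrow(frags))
      sum_p <- 0
      n_fp <- 0
      for (z in seq_len(min(params$max_fragment_charge, spec$charge))) {
        for (ty in c("b", "y")) {
          sel <- which(frags$type == ty)
          tmz <- frags$neutral[sel] / z + PROTON
          m <- oracle_match(spec$mz, tmz, params$fragment_tol_ppm)
          if (is.null(m)) next
          fhit[sel[m[, "ion"]]] <- TRUE
          n_fp <- n_fp + nrow(m)
          sum_p <- sum_p + oracle_sum_term(spec$intensity[m[, "peak"]],
                                           base, m[, "err"],
                                           params$fragment_tol_ppm)
        }
      }
      if (n_fp < 1) next
      score_p <- sum_p * (sum(fhit) / nrow(frags))^params$gamma
      rec <- list(glycan_id = g$id, peptide = peps$peptide[pi],
                  mods = peps$mods[pi], score_g = score_g,
                  score_p = score_p,
                  score_gp = params$w * score_g + (1 - params$w) * score_p,
                  is_decoy = g$is_decoy || peps$is_decoy[pi])
      if (is.null(best)) best <- list(rec)
      else best[[length(best) + 1]] <- rec
    }
  }
  if (is.null(best)) return(NULL)
  sgp <- vapply(best, `[[`, numeric(1), "score_gp")
  sp <- vapply(best, `[[`, numeric(1), "score_p")
  sg <- vapply(best, `[[`, numeric(1), "score_g")
  h <- glycosearch:::string_hash31(
    paste(vapply(best, `[[`, character(1), "glycan_id"),
          vapply(best, `[[`, character(1), "peptide"),
          vapply(best, `[[`, character(1), "mods")))
  ord <- order(-sgp, -sp, -sg, h)
  best <- best[ord]
  top <- best[[1]]
  tied <- which(sgp[ord] == top$score_gp & sp[ord] == top$score_p &
                  sg[ord] == top$score_g)
  if (any(vapply(best[tied], `[[`, logical(1), "is_decoy") !=
          top$is_decoy)) return(NULL)
  top
}

# Small shared fixture: proteins, glycans, index built once per file.
make_small_db <- function(seed = 42, n_prot = 12, n_gly = 10) {
  proteins <- synth_proteins(n_prot, seed = seed)
  glycans <- synth_glycan_db(n_gly, seed = seed + 1)
  index <- build_peptide_index(proteins)
  list(proteins = proteins, glycans = glycans, index = index)
}

random_glycopeptide <- function(db, i, charge = 3) {
  dig <- digest(db$proteins)
  dig <- dig[dig$is_glyco, ]
  list(glycan = db$glycans[[(i %% length(db$glycans)) + 1]],
       peptide = dig$peptide[(i * 7) %% nrow(dig) + 1],
       mods = "", charge = charge, rt = 600 + i,
       title = paste0("GP_", i), scan = i)
}
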