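# Glycan structures: bracketed-tree parsing, composition and mass
# arithmetic, Y-ion enumeration and mass-preserving decoy generation.

#' Parse a bracketed glycan structure string
#'
#' The canonical structure dialect is a rooted tree written as nested
#' parentheses over the single-letter monosaccharide symbols H (Hex),
#' N (HexNAc), F (Fuc/dHex), A (NeuAc) and G (NeuGc), e.g.
#' `"(N(N(H(H)(H))))"` for the trimannosyl core.  The root residue is the
#' one attached to the peptide reducing end; the first child of a node is
#' its extension.
#'
#' @param text Structure string.
#' @param id Identifier; defaults to the structure string itself.
#' @param species Character vector of species tags (entrapment bookkeeping).
#' @return An object of class `glycan_structure`: a list with elements
#'   `id`, `text`, `symbols`, `parent` (parent index per node, 0 for the
#'   root), `composition` (named integer counts), `mass`, `y_ions`
#'   (data.frame of Y-ion `delta` masses and `is_core` flags),
#'   `is_decoy` and `species`.
#' @examples
#' g <- parse_glycan_structure("(N(N(H(H)(H))))")
#' g$composition
#' @export
parse_glycan_structure <- function(text, id = text, species = character()) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  chars <- chars[!chars %in% c(" ", "\t")]
  symbols <- character(0)
  parent <- integer(0)
  stack <- integer(0)
  expect_symbol <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      if (expect_symbol)
        stop(sprintf("glycan parse error at position %d of '%s': expected a monosaccharide symbol", i, text))
      if (!length(stack) && length(symbols))
        stop(sprintf("glycan parse error at position %d of '%s': multiple roots", i, text))
      expect_symbol <- TRUE
    } else if (ch == ")") {
      if (expect_symbol || !length(stack))
        stop(sprintf("glycan parse error at position %d of '%s': unbalanced brackets", i, text))
      stack <- stack[-length(stack)]
    } else {
      if (!expect_symbol)
        stop(sprintf("glycan parse error at position %d of '%s': symbol outside brackets", i, text))
      if (!ch %in% names(MONO_MASS))
        stop(sprintf("glycan parse error at position %d of '%s': unknown symbol '%s'", i, text, ch))
      symbols <- c(symbols, ch)
      parent <- c(parent, if (length(stack)) stack[length(stack)] else 0L)
      stack <- c(stack, length(symbols))
      expect_symbol <- FALSE
    }
  }
  if (length(stack) || expect_symbol)
    stop(sprintf("glycan parse error in '%s': unbalanced brackets", text))
  if (!length(symbols))
    stop("empty glycan structure")
  new_glycan(id, text, symbols, parent, species)
}

new_glycan <- function(id, text, symbols, parent, species = character(),
                       is_decoy = FALSE, y_ions = NULL) {
  composition <- glycan_composition_counts(symbols)
  if (is.null(y_ions))
    y_ions <- enumerate_y_ions_tree(symbols, parent)
  structure(
    list(id = id, text = text, symbols = symbols, parent = parent,
         composition = composition,
         mass = sum(composition * MONO_MASS[names(composition)]),
         y_ions = y_ions, is_decoy = is_decoy, species = species),
    class = "glycan_structure"
  )
}

glycan_composition_counts <- function(symbols) {
  counts <- vapply(MONO_ORDER, function(s) sum(symbols == s), integer(1))
  counts[counts > 0L]
}

#' @export
print.glycan_structure <- function(x, ...) {
  cat(sprintf("<glycan %s>%s %s  mass %.4f Da  %d Y ions%s\n",
              x$id, if (x$is_decoy) " [decoy]" else "",
              composition_string(x$composition), x$mass, nrow(x$y_ions),
              if (length(x$species))
                paste0("  [", paste(x$species, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Glycan composition as a compact string
#'
#' @param composition Named integer vector of monosaccharide counts
#'   (or a `glycan_structure`).
#' @return A string such as `"H5N2"` (symbol order H, N, F, A, G; zero
#'   counts omitted).
#' @export
composition_string <- function(composition) {
  if (inherits(composition, "glycan_structure"))
    composition <- composition$composition
  syms <- MONO_ORDER[MONO_ORDER %in% names(composition)]
  counts <- composition[syms]
  syms <- syms[counts > 0]
  counts <- counts[counts > 0]
  paste0(syms, counts, collapse = "")
}

#' Parse a compact composition string such as "H5N2F1"
#'
#' @param text Composition string.
#' @return Named integer vector of monosaccharide counts.
#' @export
parse_composition <- function(text) {
  m <- gregexpr("([HNFAG])([0-9]+)", text)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(text))
    stop("malformed composition string: ", text)
  parts <- regmatches(text, gregexpr("([HNFAG])([0-9]+)", text))[[1]]
  counts <- as.integer(sub("^[HNFAG]", "", parts))
  names(counts) <- substr(parts, 1, 1)
  if (anyDuplicated(names(counts)))
    stop("repeated symbol in composition string: ", text)
  counts
}

#' Monoisotopic mass of a glycan
#'
#' @param x A `glycan_structure`, a named count vector such as
#'   `c(H = 5, N = 2)`, or a composition string such as `"H5N2"`.
#' @return Mass in Daltons (sum of monosaccharide residue masses).
#' @examples
#' glycan_mass(c(N = 1))        # 203.0794
#' glycan_mass("H5N2")          # 1216.4229
#' @export
glycan_mass <- function(x) {
  if (inherits(x, "glycan_structure")) return(x$mass)
  if (is.character(x)) x <- parse_composition(x)
  if (!length(x)) stop("empty glycan composition")
  bad <- setdiff(names(x), names(MONO_MASS))
  if (length(bad)) stop("unknown monosaccharide(s): ",
                        paste(bad, collapse = ", "))
  if (any(x < 0)) stop("negative monosaccharide count")
  sum(MONO_MASS[names(x)] * x)
}

# Y-ion deltas of a rooted tree: one mass per distinct root-containing
# subtree (glycosidic cleavages only), plus delta 0 (Y0, the bare peptide).
# The full-glycan delta (no cleavage) is included.
enumerate_y_ions_tree <- function(symbols, parent) {
  n <- length(symbols)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (p > 0) children[[p]] <- c(children[[p]], i)
  }
  subtree <- function(node) {
    masses <- MONO_MASS[[symbols[node]]]
    for (ch in children[[node]]) {
      cm <- subtree(ch)
      masses <- as.vector(outer(masses, c(0, cm), `+`))
      masses <- masses[!duplicated(round(masses, 4))]
    }
    masses
  }
  root <- which(parent == 0L)
  delta <- c(0, unlist(lapply(root, subtree)))
  delta <- sort(delta[!duplicated(round(delta, 4))])
  data.frame(delta = delta, is_core = core_flags(delta))
}

core_flags <- function(delta) {
  vapply(delta, function(d) any(abs(d - CORE_LADDER) < 1e-4), logical(1))
}

#' Enumerate the Y ions of a glycan structure
#'
#' Y ions are glycan fragments that retain the intact peptide backbone;
#' each corresponds to a root-containing subtree obtained by glycosidic
#' bond cleavages.  Deltas are masses added to the neutral peptide
#' backbone mass; delta 0 is Y0 (the bare peptide) and the full glycan
#' mass is included.  Deltas lying on the trimannosyl-core ladder
#' (pep, +N, +2N, +2N+H, +2N+2H, +2N+3H) are flagged as core ions.
#'
#' @param structure A `glycan_structure`.
#' @return data.frame with columns `delta` (Da, strictly increasing) and
#'   `is_core`.
#' @export
enumerate_y_ions <- function(structure) {
  stopifnot(inherits(structure, "glycan_structure"))
  structure$y_ions
}

#' Generate a mass-preserving decoy glycan
#'
#' The decoy keeps the target's composition (hence its precursor mass
#' contribution) and its Y0 ion, and perturbs every nonzero Y-ion delta by
#' a uniform random offset in \[-30, +30\] Da, rejecting offsets that land
#' within 1 Da of any target delta.  Core flags travel with their deltas,
#' so a decoy competes in the coarse search under the same core-ion filter
#' as its target.  Deterministic given `seed`.
#'
#' @param structure Target (non-decoy) `glycan_structure`.
#' @param seed Integer seed.
#' @param offset_range Half-width of the uniform offset (Da).
#' @param min_separation Minimum distance from any target delta (Da).
#' @return A `glycan_structure` with `is_decoy = TRUE`.
#' @export
generate_decoy_glycan <- function(structure, seed,
                                  offset_range = 30, min_separation = 1) {
  stopifnot(inherits(structure, "glycan_structure"))
  if (structure$is_decoy) stop("input is already a decoy glycan")
  target <- structure$y_ions$delta
  with_seed(as.integer(seed) %% .Machine$integer.max, {
    new_delta <- target
    for (i in which(target > 0)) {
      repeat {
        cand <- target[i] + stats::runif(1, -offset_range, offset_range)
        ok <- cand > 0 &&
          all(abs(cand - target) >= min_separation) &&
          all(abs(cand - new_delta[-i]) >= 0.01)
        if (ok) break
      }
      new_delta[i] <- cand
    }
  })
  y <- data.frame(delta = new_delta, is_core = structure$y_ions$is_core)
  y <- y[order(y$delta), , drop = FALSE]
  rownames(y) <- NULL
  out <- structure
  out$id <- paste0("DECOY_", structure$id)
  out$is_decoy <- TRUE
  out$y_ions <- y
  out
}

#' Read / write a glycan database file
#'
#' One structure string per line; optional further tab-separated fields are
#' species tags.  Lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return `read_glycan_db()` returns a list of `glycan_structure`.
#' @export
read_glycan_db <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    species <- if (length(fields) > 1) fields[-1] else character()
    parse_glycan_structure(fields[1], id = sprintf("G%04d", i),
                           species = species)
  })
}

#' @rdname read_glycan_db
#' @param db List of `glycan_structure`.
#' @export
write_glycan_db <- function(db, path) {
  lines <- vapply(db, function(g) {
    paste(c(g$text, g$species), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Attach mass-preserving decoys to a glycan database
#'
#' @param db List of target `glycan_structure`.
#' @param seed Integer seed; decoy i uses `seed + i`.
#' @return List of targets followed by one decoy per target.
#' @export
build_glycan_db <- function(db, seed = 0) {
  decoys <- lapply(seq_along(db), function(i)
    generate_decoy_glycan(db[[i]], seed = seed + i))
  c(db, decoys)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
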