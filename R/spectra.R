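# MS/MS (MGF) and MS1 peak-list input/output and peak filtration.
# MS2 spectra are assumed already centroided, deisotoped and
# charge-deconvoluted by the upstream converter.

#' Construct an MS/MS spectrum object
#'
#' @param mz,intensity Numeric peak vectors (re-sorted by m/z; intensities
#'   must be positive).
#' @param precursor_mz Precursor m/z (Th).
#' @param charge Precursor charge (2--6 for typical glycopeptides).
#' @param title Spectrum title.
#' @param scan Scan number (optional).
#' @param rt Retention time in seconds (optional).
#' @return A list of class `spectrum` with the peak vectors and a derived
#'   `precursor_neutral` mass (`precursor_mz * z - z * proton`).
#' @export
new_spectrum <- function(mz, intensity, precursor_mz, charge,
                         title = "", scan = NA_integer_, rt = NA_real_) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity <= 0)) stop("intensities must be positive")
  ord <- order(mz)
  structure(
    list(title = title, scan = scan, rt = rt,
         precursor_mz = precursor_mz, charge = as.integer(charge),
         precursor_neutral = neutral_from_mz(precursor_mz, charge) ,
         mz = mz[ord], intensity = intensity[ord]),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s> z=%d, precursor %.4f Th (%.4f Da), %d peaks\n",
              x$title, x$charge, x$precursor_mz, x$precursor_neutral,
              length(x$mz)))
  invisible(x)
}

#' Read an MGF peak-list file
#'
#' Standard Matrix Science dialect: `BEGIN IONS`/`END IONS` blocks with
#' `TITLE`, `PEPMASS`, `CHARGE` (e.g. `3+`), optional `RTINSECONDS` and
#' `SCANS`, then `m/z intensity` peak lines.  Multiple blocks may share a
#' scan (chimeric precursors) and are kept as independent spectra.  Blocks
#' missing `PEPMASS` or `CHARGE` are rejected with a warning; malformed
#' numeric fields raise an error naming the line.
#'
#' @param path MGF file path.
#' @return List of `spectrum` objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end) || any(begin > end))
    stop("malformed MGF: unpaired BEGIN IONS/END IONS")
  spectra <- vector("list", length(begin))
  keep <- logical(length(begin))
  for (b in seq_along(begin)) {
    block <- lines[(begin[b] + 1):(end[b] - 1)]
    block <- block[nzchar(trimws(block))]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[is_kv], "=", fixed = TRUE)
    keys <- vapply(kv, `[[`, character(1), 1)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="),
                   character(1))
    names(vals) <- keys
    if (!"PEPMASS" %in% keys || !"CHARGE" %in% keys) {
      warning("MGF block ", b, " missing PEPMASS or CHARGE; rejected")
      next
    }
    pepmass <- suppressWarnings(
      as.numeric(strsplit(trimws(vals[["PEPMASS"]]), "\\s+")[[1]][1]))
    charge <- suppressWarnings(
      as.integer(sub("\\+$", "", trimws(vals[["CHARGE"]]))))
    if (is.na(pepmass) || is.na(charge))
      stop("malformed PEPMASS/CHARGE in MGF block starting at line ",
           begin[b])
    peak_lines <- block[!is_kv]
    mz <- inten <- numeric(0)
    if (length(peak_lines)) {
      mat <- strsplit(trimws(peak_lines), "\\s+")
      if (any(lengths(mat) < 2))
        stop("malformed peak line near MGF line ",
             begin[b] + which(lengths(mat) < 2)[1])
      mz <- suppressWarnings(as.numeric(vapply(mat, `[[`, character(1), 1)))
      inten <- suppressWarnings(as.numeric(vapply(mat, `[[`,
                                                  character(1), 2)))
      if (anyNA(mz) || anyNA(inten))
        stop("malformed numeric peak value near MGF line ",
             begin[b] + which(is.na(mz) | is.na(inten))[1])
    }
    spectra[[b]] <- new_spectrum(
      mz, inten, precursor_mz = pepmass, charge = charge,
      title = if ("TITLE" %in% keys) vals[["TITLE"]] else paste0("index=", b),
      scan = if ("SCANS" %in% keys) as.integer(vals[["SCANS"]]) else
        NA_integer_,
      rt = if ("RTINSECONDS" %in% keys) as.numeric(vals[["RTINSECONDS"]])
      else NA_real_)
    keep[b] <- TRUE
  }
  spectra[keep]
}

#' Write spectra to an MGF file
#'
#' @param spectra List of `spectrum` objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- vapply(spectra, function(s) {
    header <- c("BEGIN IONS",
                paste0("TITLE=", s$title),
                sprintf("PEPMASS=%.6f", s$precursor_mz),
                sprintf("CHARGE=%d+", s$charge))
    if (!is.na(s$rt)) header <- c(header, sprintf("RTINSECONDS=%.3f", s$rt))
    if (!is.na(s$scan)) header <- c(header, sprintf("SCANS=%d", s$scan))
    paste(c(header, sprintf("%.6f %.2f", s$mz, s$intensity), "END IONS"),
          collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Keep the top-N most intense peaks of a spectrum
#'
#' SCE-HCD glycopeptide spectra have a wide intra-spectrum dynamic range;
#' retaining the 300 most intense peaks is the engine default.  Ties at
#' the cutoff keep the lower-m/z peak first.  Idempotent.
#'
#' @param spectrum A `spectrum`.
#' @param n Number of peaks to keep (default 300).
#' @return The filtered `spectrum`, peaks re-sorted by m/z.
#' @export
filter_top_peaks <- function(spectrum, n = 300) {
  stopifnot(n >= 1)
  if (length(spectrum$mz) <= n) return(spectrum)
  ord <- order(-spectrum$intensity, spectrum$mz)[seq_len(n)]
  ord <- sort(ord)
  spectrum$mz <- spectrum$mz[ord]
  spectrum$intensity <- spectrum$intensity[ord]
  spectrum
}

#' Read an MS1 scan file
#'
#' Simple text dialect: `S <scan>` lines start a scan, `I RTime <seconds>`
#' lines carry the retention time, and bare `m/z intensity` lines are
#' peaks.  `H` header lines are ignored.  A peak line before any `S` line
#' is a format error.  Peaks are sorted by m/z on load.
#'
#' @param path MS1 file path.
#' @return List of `ms1_scan` objects (lists with `scan`, `rt`, `mz`,
#'   `intensity`).
#' @export
read_ms1 <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  scans <- list()
  cur <- NULL
  flush <- function(cur, scans) {
    if (is.null(cur)) return(scans)
    ord <- order(cur$mz)
    cur$mz <- cur$mz[ord]
    cur$intensity <- cur$intensity[ord]
    scans[[length(scans) + 1]] <- structure(cur, class = "ms1_scan")
    scans
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    first <- substr(ln, 1, 1)
    if (first == "H") next
    if (first == "S") {
      scans <- flush(cur, scans)
      fields <- strsplit(ln, "\\s+")[[1]]
      cur <- list(scan = as.integer(fields[2]), rt = NA_real_,
                  mz = numeric(0), intensity = numeric(0))
    } else if (first == "I") {
      if (is.null(cur)) stop("MS1 format error: 'I' line before any 'S'")
      fields <- strsplit(ln, "\\s+")[[1]]
      if (length(fields) >= 3 && fields[2] == "RTime")
        cur$rt <- as.numeric(fields[3])
    } else {
      if (is.null(cur))
        stop("MS1 format error at line ", i, ": peak before any 'S' line")
      fields <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(fields) < 2 || anyNA(fields[1:2]))
        stop("MS1 format error at line ", i, ": malformed peak line")
      cur$mz <- c(cur$mz, fields[1])
      cur$intensity <- c(cur$intensity, fields[2])
    }
  }
  flush(cur, scans)
}

#' Write MS1 scans to a file
#'
#' @param scans List of `ms1_scan` objects.
#' @param path Output path.
#' @export
write_ms1 <- function(scans, path) {
  blocks <- vapply(scans, function(s) {
    paste(c(sprintf("S\t%d\t%d", s$scan, s$scan),
            sprintf("I\tRTime\t%.3f", s$rt),
            sprintf("%.6f %.2f", s$mz, s$intensity)),
          collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n"), path)
  invisible(path)
}
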