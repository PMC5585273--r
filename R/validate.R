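# Search-engine-independent FDR validation: isotope-pair-based (15N/13C
# metabolic labeling) and entrapment-based estimators.

#' Pair a GPSM with its 15N/13C-labeled precursors in MS1
#'
#' The elemental composition of the identified glycopeptide predicts the
#' labeled-channel m/z values (the 15N shift is the nitrogen count times
#' 0.9970349 Da, the 13C shift the carbon count times 1.0033548 Da,
#' divided by the charge).  MS1 scans within `rt_window` seconds of the
#' MS2 trigger are searched within `tol_ppm`; each channel's apex is its
#' maximum summed intensity over the window.  The result is NaN when
#' either labeled partner is absent or its unlabeled:labeled ratio falls
#' outside `1/r_max ... r_max` -- the signature of a false identification
#' in an equimolar unlabeled/15N/13C mixture.
#'
#' @param gpsm One-row GPSM data.frame (or list) with `peptide`, `mods`,
#'   `glycan_comp`, `charge` and `rt`.
#' @param ms1 List of `ms1_scan` objects (see [read_ms1()]).
#' @param tol_ppm Precursor tolerance (default 5 ppm).
#' @param rt_window Half-width of the retention-time window in seconds.
#' @param r_max Accepted ratio band (default 2: ratios in 0.5 to 2).
#' @return One-row data.frame with `ratio_15n`, `ratio_13c`, `is_nan`.
#' @export
pair_isotope_precursors <- function(gpsm, ms1, tol_ppm = 5,
                                    rt_window = 60, r_max = 2) {
  comp <- elemental_composition(gpsm$peptide, gpsm$mods, gpsm$glycan_comp)
  shifts <- isotope_shifts(comp)
  z <- gpsm$charge
  neutral <- peptide_mass(gpsm$peptide, gpsm$mods) +
    glycan_mass(gpsm$glycan_comp)
  mz <- c(none = mz_from_neutral(neutral, z),
          n15 = mz_from_neutral(neutral + shifts[["N15"]], z),
          c13 = mz_from_neutral(neutral + shifts[["C13"]], z))
  rts <- vapply(ms1, `[[`, numeric(1), "rt")
  in_window <- which(abs(rts - gpsm$rt) <= rt_window)
  apex <- c(none = 0, n15 = 0, c13 = 0)
  for (i in in_window) {
    scan <- ms1[[i]]
    for (ch in names(mz)) {
      lo <- mz[[ch]] * (1 - tol_ppm * 1e-6)
      hi <- mz[[ch]] * (1 + tol_ppm * 1e-6)
      from <- findInterval(lo, scan$mz, left.open = TRUE) + 1L
      to <- findInterval(hi, scan$mz)
      if (from <= to)
        apex[ch] <- max(apex[ch], sum(scan$intensity[from:to]))
    }
  }
  ratio_15n <- if (apex["none"] > 0 && apex["n15"] > 0)
    unname(apex["none"] / apex["n15"]) else NaN
  ratio_13c <- if (apex["none"] > 0 && apex["c13"] > 0)
    unname(apex["none"] / apex["c13"]) else NaN
  in_band <- function(r) !is.nan(r) && r >= 1 / r_max && r <= r_max
  data.frame(ratio_15n = ratio_15n, ratio_13c = ratio_13c,
             is_nan = !(in_band(ratio_15n) && in_band(ratio_13c)))
}

#' Isotope pairing for a whole GPSM table
#'
#' @param gpsms GPSM data.frame.
#' @inheritParams pair_isotope_precursors
#' @return `gpsms` with columns `ratio_15n`, `ratio_13c`, `is_nan`
#'   appended.
#' @export
pair_isotope_all <- function(gpsms, ms1, tol_ppm = 5, rt_window = 60,
                             r_max = 2) {
  res <- lapply(seq_len(nrow(gpsms)), function(i)
    pair_isotope_precursors(gpsms[i, , drop = FALSE], ms1, tol_ppm,
                            rt_window, r_max))
  cbind(gpsms, do.call(rbind, res))
}

#' Isotope-based FDR from NaN counts
#'
#' The fraction of target GPSMs with a NaN isotope ratio, divided by the
#' same fraction among decoy GPSMs (all of which are false, so their NaN
#' fraction measures the sensitivity of the NaN test):
#' `(n_nan_target / n_target) / (n_nan_decoy / n_decoy)`.
#'
#' @param n_nan_target,n_target NaN count and total count of target GPSMs.
#' @param n_nan_decoy,n_decoy NaN count and total count of decoy GPSMs.
#' @return The estimated FDR as a fraction.
#' @examples
#' isotope_fdr_counts(3, 705, 735, 1484)  # 0.0086
#' @export
isotope_fdr_counts <- function(n_nan_target, n_target, n_nan_decoy,
                               n_decoy) {
  if (n_target <= 0) stop("no target GPSMs")
  if (n_decoy <= 0 || n_nan_decoy <= 0)
    stop("decoy NaN fraction is zero; isotope-based FDR undefined")
  (n_nan_target / n_target) / (n_nan_decoy / n_decoy)
}

#' Isotope-based FDR from paired results
#'
#' Applies [isotope_fdr_counts()] per run (when a `run` column is
#' present) and averages the per-run estimates, mirroring the
#' per-replicate-then-mean procedure.
#'
#' @param target_results,decoy_results data.frames with an `is_nan`
#'   column and optionally a `run` column.
#' @return List with `fdr` (pooled/mean estimate) and `per_run`
#'   (data.frame of per-run estimates, NULL without run grouping).
#' @export
isotope_fdr <- function(target_results, decoy_results) {
  if (!is.null(target_results$run) && !is.null(decoy_results$run)) {
    runs <- sort(unique(target_results$run))
    per_run <- vapply(runs, function(r) {
      tr <- target_results[target_results$run == r, ]
      dr <- decoy_results[decoy_results$run == r, ]
      isotope_fdr_counts(sum(tr$is_nan), nrow(tr), sum(dr$is_nan),
                         nrow(dr))
    }, numeric(1))
    return(list(fdr = mean(per_run),
                per_run = data.frame(run = runs, fdr = per_run)))
  }
  list(fdr = isotope_fdr_counts(sum(target_results$is_nan),
                                nrow(target_results),
                                sum(decoy_results$is_nan),
                                nrow(decoy_results)),
       per_run = NULL)
}

# TRUE when a comma-separated tag string is non-empty and consists only
# of entrapment tags.
entrapment_only <- function(tags, entrapment_tags) {
  vapply(strsplit(tags, ",", fixed = TRUE), function(tt) {
    tt <- tt[nzchar(tt)]
    length(tt) > 0 && all(tt %in% entrapment_tags)
  }, logical(1))
}

#' Entrapment-based FDR
#'
#' With a foreign-species (entrapment) database mixed into the search,
#' any accepted GPSM whose peptide or glycan carries only entrapment
#' species tags is a certain false positive.  The estimate is
#' `(#entrapment-only-peptide GPSMs + #entrapment-only-glycan GPSMs) /
#' #all GPSMs`; a GPSM false on both counts is counted once.  Entries
#' shared between native and entrapment databases are never counted.
#'
#' @param gpsms Accepted GPSM data.frame with `glycan_species` and
#'   `peptide_species` columns (comma-separated tags).
#' @param entrapment_tags Character vector of entrapment species tags.
#' @return The estimated FDR as a fraction.
#' @examples
#' # 1000 GPSMs, 10 entrapment-only peptides + 10 entrapment-only glycans
#' # give 2% entrapment-based FDR
#' @export
entrapment_fdr <- function(gpsms, entrapment_tags) {
  if (!nrow(gpsms)) stop("empty GPSM set")
  if (!length(entrapment_tags) || !any(nzchar(entrapment_tags)))
    stop("no entrapment species tags supplied; ",
         "the entrapment partition is empty")
  pep_false <- entrapment_only(gpsms$peptide_species, entrapment_tags)
  gly_false <- entrapment_only(gpsms$glycan_species, entrapment_tags)
  sum(pep_false | gly_false) / nrow(gpsms)
}
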