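# Three-level FDR estimation over GPSM sets.  A GPSM is a false
# identification when either its glycan or its peptide is wrong, so
# by inclusion-exclusion
#   FDR(x) = FDR_G(x) + FDR_P(x) - FDR_GandP(x)
# with decoy-ratio estimators at score cutoff x (counts use score >= x):
#   FDR_G      = #(glycan decoy  & peptide target) / #(both target)
#   FDR_P      = #(peptide decoy & glycan target) / #(both target)
#   FDR_GandP  = #(both decoy)                    / #(both target)

fdr_count_curves <- function(gpsms, pseudocount = FALSE) {
  ord <- order(-gpsms$score_gp)
  s <- gpsms$score_gp[ord]
  gd <- gpsms$glycan_decoy[ord]
  pd <- gpsms$peptide_decoy[ord]
  bt <- cumsum(!gd & !pd)
  g_only <- cumsum(gd & !pd)
  p_only <- cumsum(!gd & pd)
  both <- cumsum(gd & pd)
  # at tied scores every member of the tie group shares the counts of the
  # group's last row (>= x semantics)
  last <- ave(seq_along(s), match(s, unique(s)), FUN = max)
  pc <- if (pseudocount) 1 else 0
  denom <- pmax(bt[last], 1)
  fdr_g <- ifelse(bt[last] == 0, 1, (g_only[last] + pc) / denom)
  fdr_p <- ifelse(bt[last] == 0, 1, (p_only[last] + pc) / denom)
  fdr_gp <- ifelse(bt[last] == 0, 1, (both[last] + pc) / denom)
  fdr <- pmin(1, pmax(0, fdr_g + fdr_p - fdr_gp))
  list(order = ord, score = s, fdr_g = fdr_g, fdr_p = fdr_p,
       fdr_gp = fdr_gp, fdr = fdr)
}

eval_step_curve <- function(score_sorted_desc, value, cutoffs) {
  # value at cutoff x = value at the lowest score >= x (counts are
  # cumulative from the top); 0-decoy regions fall back to the first row
  vapply(cutoffs, function(x) {
    i <- findInterval(-x, -score_sorted_desc)  # last index with score >= x
    if (i < 1) 1 else value[i]  # no targets at/above x: undefined, report 1
  }, numeric(1))
}

#' Decoy-based glycan-level FDR curve
#'
#' Default estimator: the number of glycan-decoy/peptide-target GPSMs at
#' or above each cutoff divided by the number of target-target GPSMs.
#' `method = "mixture"` refines the estimate with a two-component
#' semi-parametric mixture on the glycan score in which decoys anchor the
#' incorrect component (pi0 is estimated from the target/decoy ratio in
#' the lower score quartile).
#'
#' @param gpsms GPSM data.frame with `score_gp`, `score_g`,
#'   `glycan_decoy`, `peptide_decoy`.
#' @param cutoffs Score cutoffs at which to evaluate (default: all
#'   observed scores).
#' @param method `"decoy"` (default) or `"mixture"`.
#' @param pseudocount Add +1 to decoy counts (off by default).
#' @return data.frame with columns `cutoff` and `fdr`.
#' @export
glycan_fdr <- function(gpsms, cutoffs = NULL,
                       method = c("decoy", "mixture"),
                       pseudocount = FALSE) {
  method <- match.arg(method)
  cc <- fdr_count_curves(gpsms, pseudocount)
  if (is.null(cutoffs)) cutoffs <- sort(unique(gpsms$score_gp))
  fdr <- eval_step_curve(cc$score, cc$fdr_g, cutoffs)
  if (method == "mixture") {
    dec <- gpsms$score_g[gpsms$glycan_decoy]
    tar <- gpsms$score_g[!gpsms$glycan_decoy]
    if (length(dec) >= 5 && length(tar) >= 5) {
      qcut <- stats::median(dec)
      pi0 <- min(1, (sum(tar <= qcut) / length(tar)) /
                   max(1e-9, sum(dec <= qcut) / length(dec)))
      fdr <- pmin(fdr * pi0, 1)
    }
  }
  data.frame(cutoff = cutoffs, fdr = fdr)
}

#' Decoy-based peptide-level FDR curve
#'
#' Peptide-decoy/glycan-target counts over target-target counts at each
#' cutoff; `joint = TRUE` instead returns the both-decoy joint term.
#'
#' @inheritParams glycan_fdr
#' @param joint Return the glycan-and-peptide joint FDR term.
#' @return data.frame with columns `cutoff` and `fdr`.
#' @export
peptide_fdr <- function(gpsms, cutoffs = NULL, joint = FALSE,
                        pseudocount = FALSE) {
  cc <- fdr_count_curves(gpsms, pseudocount)
  if (is.null(cutoffs)) cutoffs <- sort(unique(gpsms$score_gp))
  val <- if (joint) cc$fdr_gp else cc$fdr_p
  data.frame(cutoff = cutoffs, fdr = eval_step_curve(cc$score, val,
                                                     cutoffs))
}

#' Glycopeptide-level FDR control and q-value assignment
#'
#' Combines the component estimators by inclusion-exclusion, converts the
#' FDR curve to q-values by a cumulative minimum over descending combined
#' score, and reports the accepted target set at `target_level`.
#' Decoy-flagged GPSMs are excluded from the accepted set but retained
#' (with q-values) for validation.
#'
#' @param gpsms GPSM data.frame.
#' @param target_level Accepted q-value level (default 0.01).
#' @param pseudocount Add +1 to decoy counts (off by default).
#' @return An `fdr_report` list: `gpsms` (input plus `fdr_g`, `fdr_p`,
#'   `fdr_gp`, `fdr`, `q_value`), `accepted` (logical over rows),
#'   `threshold` (lowest accepted combined score), `target_level`,
#'   and `n_accepted`.
#' @export
glycopeptide_fdr <- function(gpsms, target_level = 0.01,
                             pseudocount = FALSE) {
  stopifnot(nrow(gpsms) > 0)
  cc <- fdr_count_curves(gpsms, pseudocount)
  q <- rev(cummin(rev(cc$fdr)))
  out <- gpsms[cc$order, , drop = FALSE]
  out$fdr_g <- cc$fdr_g
  out$fdr_p <- cc$fdr_p
  out$fdr_gp <- cc$fdr_gp
  out$fdr <- cc$fdr
  out$q_value <- q
  accepted <- !out$glycan_decoy & !out$peptide_decoy &
    out$q_value <= target_level
  structure(
    list(gpsms = out, accepted = accepted,
         threshold = if (any(accepted)) min(out$score_gp[accepted])
         else NA_real_,
         target_level = target_level, n_accepted = sum(accepted)),
    class = "fdr_report")
}

#' @export
print.fdr_report <- function(x, ...) {
  cat(sprintf("<fdr_report> %d GPSMs, %d accepted at q <= %g (score >= %s)\n",
              nrow(x$gpsms), x$n_accepted, x$target_level,
              ifelse(is.na(x$threshold), "NA",
                     sprintf("%.3f", x$threshold))))
  invisible(x)
}
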