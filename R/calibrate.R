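# Learning-to-rank calibration of the score exponents.  Taking logs of
# the fine glycan score gives
#   log(Score_G) = log(sum-term) + alpha * log(ratio_ion)
#                                + beta  * log(ratio_core),
# linear in (alpha, beta): a correct match should beat every incorrect
# match of the same spectrum, which is a pairwise ranking problem solved
# by a linear SVM on within-spectrum feature differences.  The fitted
# direction is mapped back to exponents by normalizing so that the
# sum-term coefficient is 1.

#' Fit score exponents by pairwise ranking SVM
#'
#' @param examples data.frame with columns `spectrum` (grouping id),
#'   `label` (logical, TRUE for the correct match), `log_sum`
#'   (log sum-term) and `log_ratio_ion`, plus optionally
#'   `log_ratio_core`.  Each spectrum must contribute at least one
#'   correct and one incorrect candidate to form pairs.
#' @param regularization SVM cost parameter C (default 1).
#' @return List with the fitted exponents (`alpha` and `beta` when
#'   `log_ratio_core` is present, else `gamma`), the raw SVM weight
#'   vector `weights`, and the pairwise training accuracy
#'   `pair_accuracy`.
#' @export
fit_score_weights <- function(examples, regularization = 1) {
  feat_cols <- intersect(c("log_sum", "log_ratio_ion", "log_ratio_core"),
                         names(examples))
  stopifnot(all(c("log_sum", "log_ratio_ion") %in% feat_cols))
  groups <- split(seq_len(nrow(examples)), examples$spectrum)
  diffs <- list()
  for (g in groups) {
    pos <- g[examples$label[g]]
    neg <- g[!examples$label[g]]
    if (!length(pos) || !length(neg)) next
    for (p in pos) {
      d <- as.matrix(examples[rep(p, length(neg)), feat_cols, drop = FALSE]) -
        as.matrix(examples[neg, feat_cols, drop = FALSE])
      diffs[[length(diffs) + 1]] <- d
    }
  }
  if (!length(diffs)) stop("no valid correct/incorrect pairs")
  n_spec <- length(unique(examples$spectrum[examples$label]))
  if (length(unique(examples$spectrum)) < 10)
    stop("need at least 10 spectra with valid pairs for calibration")
  d <- do.call(rbind, diffs)
  x <- rbind(d, -d)
  y <- factor(rep(c(1, -1), each = nrow(d)))
  fit <- e1071::svm(x, y, kernel = "linear", cost = regularization,
                    scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  # svm() orders levels internally; orient so that positive differences
  # (correct minus incorrect) get positive margin
  pred <- as.numeric(x %*% w)
  if (stats::cor(pred, as.numeric(as.character(y))) < 0) w <- -w
  if (abs(w[["log_sum"]]) < 1e-12)
    stop("degenerate fit: zero weight on the sum-term feature")
  exps <- w / w[["log_sum"]]
  acc <- mean((d %*% w) > 0)
  out <- list(weights = w, pair_accuracy = acc)
  if ("log_ratio_core" %in% feat_cols) {
    out$alpha <- unname(exps[["log_ratio_ion"]])
    out$beta <- unname(exps[["log_ratio_core"]])
  } else {
    out$gamma <- unname(exps[["log_ratio_ion"]])
  }
  out
}

#' Grid-search the glycan weight of the combined score
#'
#' The exponents are fitted by the ranking SVM; the combined-score weight
#' `w` is chosen by a 1-D grid search maximizing the number of accepted
#' identifications at a fixed glycopeptide FDR on a benchmark GPSM set.
#'
#' @param gpsms Benchmark GPSM data.frame (with decoy flags and
#'   `score_g`, `score_p`).
#' @param grid Candidate weights (default 0.05 to 0.95 by 0.05).
#' @param target_level FDR level at which identifications are counted.
#' @return List with `w` (best weight) and `curve` (data.frame of weight
#'   vs accepted count).
#' @export
fit_total_weight <- function(gpsms, grid = seq(0.05, 0.95, by = 0.05),
                             target_level = 0.01) {
  counts <- vapply(grid, function(w) {
    g <- gpsms
    g$score_gp <- total_score(g$score_g, g$score_p, w)
    glycopeptide_fdr(g, target_level)$n_accepted
  }, numeric(1))
  list(w = grid[which.max(counts)],
       curve = data.frame(w = grid, n_accepted = counts))
}

#' Extract ranking features from scored candidates
#'
#' Converts a candidate table (as attached by
#' `search_spectrum(..., co_ranked = TRUE)` plus a truth label) into the
#' log-feature form consumed by [fit_score_weights()].
#'
#' @param candidates data.frame with `title`, `label`, and detail columns
#'   `sum_term`, `ratio_ion`, `ratio_core` (glycan features) -- rows with
#'   non-positive entries are dropped, since their log-features are
#'   undefined.
#' @return data.frame with `spectrum`, `label`, `log_sum`,
#'   `log_ratio_ion`, `log_ratio_core`.
#' @export
ranking_examples <- function(candidates) {
  keep <- candidates$sum_term > 0 & candidates$ratio_ion > 0 &
    candidates$ratio_core > 0
  cand <- candidates[keep, , drop = FALSE]
  data.frame(spectrum = cand$title, label = cand$label,
             log_sum = log(cand$sum_term),
             log_ratio_ion = log(cand$ratio_ion),
             log_ratio_core = log(cand$ratio_core))
}
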