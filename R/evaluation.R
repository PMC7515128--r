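# ROC construction, AUC, and FPR at fixed TPR.
#
# TPR = TP / N_MoRF and FPR = FP / N_non.  The curve sweeps every
# distinct score as a threshold (plus a +Inf sentinel giving the (0,0)
# endpoint); residues sharing a score enter the confusion matrix
# together, so ties are handled exactly and trapezoidal AUC equals the
# tie-aware Mann-Whitney statistic.

#' ROC curve and AUC
#'
#' @param scores numeric per-residue scores (higher = more MoRF-like).
#' @param labels 0/1 labels (1 = MoRF residue).
#' @return object of class \code{ROCResult}: \code{thresholds}
#'   (descending, +Inf first), \code{tpr}, \code{fpr} (nondecreasing,
#'   endpoints (0,0) and (1,1)), \code{auc}, \code{n_morf}, \code{n_non}.
#' @export
roc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    abort2("scores/labels length mismatch", "morfmlp_evaluation_error")
  n_morf <- sum(labels == 1L)
  n_non <- sum(labels == 0L)
  if (n_morf == 0L || n_non == 0L)
    abort2("ROC needs at least one positive and one negative residue",
           "morfmlp_evaluation_error")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1L - y)[last_of_group]
  tpr <- c(0, tp / n_morf)
  fpr <- c(0, fp / n_non)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, s[last_of_group]),
                 tpr = tpr, fpr = fpr, auc = auc,
                 n_morf = n_morf, n_non = n_non),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROCResult: AUC %.4f (%d MoRF / %d non-MoRF residues)\n",
              x$auc, x$n_morf, x$n_non))
  invisible(x)
}

#' FPR at fixed TPR operating points
#'
#' For each target the smallest FPR among operating points whose TPR
#' reaches the target.
#'
#' @param rocresult a \code{\link{roc}} result.
#' @param tpr_targets TPR levels (default 0.2, 0.3, 0.4).
#' @return named numeric vector of FPR values.
#' @export
fpr_at_tpr <- function(rocresult, tpr_targets = c(0.2, 0.3, 0.4)) {
  stopifnot(inherits(rocresult, "ROCResult"))
  out <- vapply(tpr_targets, function(tt) {
    ok <- rocresult$tpr >= tt
    if (!any(ok)) 1 else min(rocresult$fpr[ok])
  }, numeric(1))
  setNames(out, sprintf("tpr_%g", tpr_targets))
}

#' Evaluate prediction tracks against region annotations
#'
#' Pools residues across all sequences (no per-sequence macro-averaging)
#' and reports AUC plus FPR at TPR 0.2/0.3/0.4.  With
#' \code{strata = "short_long"} positives are additionally split by the
#' length of their containing MoRF region (short: <= 30 residues, long:
#' > 30); each stratum's positives are scored against all pooled
#' negatives.  An empty stratum is omitted from the report.
#'
#' @param tracks list of \code{PredictionTrack}.
#' @param regions data.frame from \code{\link{read_regions}}; every track
#'   sequence must be consistent with it (regions within track length).
#' @param strata "none" or "short_long".
#' @param short_max region length boundary between short and long MoRFs.
#' @return data.frame with columns stratum, auc, fpr_at_tpr0.2/0.3/0.4,
#'   n_morf, n_non.
#' @export
evaluate_run <- function(tracks, regions, strata = c("none", "short_long"),
                         short_max = 30L) {
  strata <- match.arg(strata)
  ids <- vapply(tracks, `[[`, character(1), "sequence_id")
  if (anyDuplicated(ids))
    abort2("duplicate prediction track ids", "morfmlp_evaluation_error")
  unknown <- setdiff(unique(regions$sequence_id), ids)
  if (length(unknown) > 0L)
    abort2(sprintf("regions refer to sequence '%s' with no prediction track",
                   unknown[1L]), "morfmlp_evaluation_error")
  scores <- numeric(0)
  labels <- integer(0)
  reg_len <- integer(0)   # containing-region length per residue, 0 = non-MoRF
  for (tr in tracks) {
    L <- length(tr$scores)
    lab <- integer(L)
    rl <- integer(L)
    sel <- regions[regions$sequence_id == tr$sequence_id, , drop = FALSE]
    for (k in seq_len(nrow(sel))) {
      if (sel$end[k] > L)
        abort2(sprintf("region %d-%d exceeds track length %d of '%s'",
                       sel$start[k], sel$end[k], L, tr$sequence_id),
               "morfmlp_evaluation_error")
      span <- sel$start[k]:sel$end[k]
      lab[span] <- 1L
      # residues in overlapping regions keep the longest containing region
      rl[span] <- pmax(rl[span], sel$end[k] - sel$start[k] + 1L)
    }
    scores <- c(scores, tr$scores)
    labels <- c(labels, lab)
    reg_len <- c(reg_len, rl)
  }
  one_row <- function(stratum, keep_pos) {
    keep <- labels == 0L | keep_pos
    if (sum(labels[keep] == 1L) == 0L) return(NULL)
    r <- roc(scores[keep], labels[keep])
    fa <- fpr_at_tpr(r)
    data.frame(stratum = stratum, auc = r$auc,
               fpr_at_tpr0.2 = fa[[1]], fpr_at_tpr0.3 = fa[[2]],
               fpr_at_tpr0.4 = fa[[3]], n_morf = r$n_morf,
               n_non = r$n_non, stringsAsFactors = FALSE)
  }
  rows <- list(one_row("all", labels == 1L))
  if (strata == "short_long") {
    rows <- c(rows,
              list(one_row("short", labels == 1L & reg_len <= short_max),
                   one_row("long", labels == 1L & reg_len > short_max)))
  }
  do.call(rbind, Filter(Negate(is.null), rows))
}
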