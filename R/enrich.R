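# Exact contingency statistics, motif over-representation (Fisher + Z),
# ChIP-seq peak overlap analysis and ROC/AUC evaluation.

#' One- and two-sided Fisher exact p-value for a 2x2 table
#'
#' The table is `(a, b; c, d)` = (target hits, target non-hits, control
#' hits, control non-hits). With margins fixed, the target hit count follows
#' a hypergeometric distribution; `greater` returns the upper tail
#' `P(X >= a)` (enrichment), `less` the lower tail, and `two_sided` the sum
#' of all outcome probabilities not exceeding the observed one. Degenerate
#' margins give p = 1.
#'
#' @param a,b,c,d nonnegative integer counts.
#' @param side `"greater"`, `"less"` or `"two_sided"`.
#' @return p-value in (0, 1].
#' @export
fisher_exact <- function(a, b, c, d, side = c("greater", "less", "two_sided")) {
  side <- match.arg(side)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  m <- a + c          # total hits
  n <- b + d          # total non-hits
  k <- a + b          # target total
  if (m == 0 || n == 0 || k == 0 || (c + d) == 0) return(1)
  switch(side,
    greater = phyper(a - 1, m, n, k, lower.tail = FALSE),
    less = phyper(a, m, n, k),
    two_sided = {
      support <- max(0, k - n):min(k, m)
      probs <- dhyper(support, m, n, k)
      sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
    })
}

#' Assemble a region-level hit table for one TF
#'
#' A region counts as "hit" when at least one retained site of the TF falls
#' within it (by `region_id`).
#'
#' @param fg_ids,bg_ids region ids of the foreground and background sets.
#' @param hits resolved site hits.
#' @param tf motif id.
#' @return list `a, b, c, d` (fg hits, fg non-hits, bg hits, bg non-hits).
#' @export
region_hit_table <- function(fg_ids, bg_ids, hits, tf) {
  hit_ids <- unique(hits$region_id[hits$motif_id == tf])
  a <- sum(fg_ids %in% hit_ids)
  c <- sum(bg_ids %in% hit_ids)
  list(a = a, b = length(fg_ids) - a, c = c, d = length(bg_ids) - c)
}

#' Motif over-representation in foreground versus background regions
#'
#' Per TF: a one-sided Fisher exact test on the region-level hit counts, and
#' a rate-based Z-score `(x - n p) / sqrt(n p (1 - p))` where `x` is the
#' foreground site count, `n` the foreground nucleotide total and `p` the
#' background site rate per nucleotide. Results are ranked by ascending
#' Fisher p.
#'
#' @param fg_regions,bg_regions `crm_regions` sets.
#' @param hits resolved site hits covering both sets.
#' @param tfs motif ids to test.
#' @return data.frame `motif_id, a, b, c, d, z_score, fisher_p, rank`.
#' @export
overrepresentation <- function(fg_regions, bg_regions, hits, tfs) {
  fg_nt <- sum(fg_regions$end - fg_regions$start)
  bg_nt <- sum(bg_regions$end - bg_regions$start)
  rows <- lapply(tfs, function(tf) {
    tab <- region_hit_table(fg_regions$region_id, bg_regions$region_id,
                            hits, tf)
    x <- sum(hits$motif_id == tf & hits$region_id %in% fg_regions$region_id)
    xb <- sum(hits$motif_id == tf & hits$region_id %in% bg_regions$region_id)
    p <- xb / bg_nt
    z <- if (p > 0 && p < 1) (x - fg_nt * p) / sqrt(fg_nt * p * (1 - p))
         else NA_real_
    data.frame(motif_id = tf, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               z_score = z,
               fisher_p = fisher_exact(tab$a, tab$b, tab$c, tab$d, "greater"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fisher_p, out$motif_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Region-peak overlap flags
#'
#' @param regions `crm_regions`.
#' @param peaks data.frame of peak intervals (`chrom, start, end`).
#' @param min_overlap minimum intersection in bp, default 1.
#' @return logical vector per region.
#' @export
region_peak_overlap <- function(regions, peaks, min_overlap = 1L) {
  vapply(seq_len(nrow(regions)), function(i) {
    p <- peaks[peaks$chrom == regions$chrom[i], , drop = FALSE]
    if (!nrow(p)) return(FALSE)
    any(pmin(p$end, regions$end[i]) - pmax(p$start, regions$start[i]) >=
          min_overlap)
  }, TRUE)
}

#' Peak-overlap contingency analysis
#'
#' Emits the four standard comparisons for two peak conditions (e.g.
#' myoblast and myotube) over responding and non-responding regions:
#' responder versus non-responder within each condition, and condition
#' versus condition within each region group. For each comparison the
#' one-sided Fisher p in the direction of greater overlap for responders /
#' the second condition is reported alongside the opposite side and the
#' two-sided p.
#'
#' @param overlap named list of two logical overlap vectors (one per
#'   condition), both aligned with `responder`.
#' @param responder logical vector of region status.
#' @return data.frame with counts, percentages and p-values per comparison.
#' @export
overlap_contingency <- function(overlap, responder) {
  stopifnot(length(overlap) == 2L, !is.null(names(overlap)))
  conds <- names(overlap)
  row <- function(comparison, a, b, c, d) {
    data.frame(comparison = comparison, a = a, b = b, c = c, d = d,
               pct_target = 100 * a / (a + b), pct_control = 100 * c / (c + d),
               p_greater = fisher_exact(a, b, c, d, "greater"),
               p_less = fisher_exact(a, b, c, d, "less"),
               p_two_sided = fisher_exact(a, b, c, d, "two_sided"),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (cn in conds) {
    ov <- overlap[[cn]]
    out[[length(out) + 1L]] <- row(
      paste0("responder_vs_non@", cn),
      sum(ov & responder), sum(!ov & responder),
      sum(ov & !responder), sum(!ov & !responder))
  }
  for (grp in c(TRUE, FALSE)) {
    o1 <- overlap[[2L]][responder == grp]   # second condition as target
    o2 <- overlap[[1L]][responder == grp]
    out[[length(out) + 1L]] <- row(
      paste0(conds[2L], "_vs_", conds[1L], "@",
             if (grp) "responder" else "non_responder"),
      sum(o1), sum(!o1), sum(o2), sum(!o2))
  }
  do.call(rbind, out)
}

#' ROC curve and AUC from scores and labels
#'
#' The AUC is the tie-corrected rank statistic (Mann-Whitney with midranks);
#' the curve lists TPR/FPR at every distinct threshold, descending.
#'
#' @param scores numeric prediction scores (`-Inf` allowed).
#' @param labels logical or 0/1 truth.
#' @return list of class `roc_curve`: `thresholds, tpr, fpr, auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes required for ROC")
  r <- rank(scores)                  # midranks handle ties
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & scores >= t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / n0, 0)
  structure(list(thresholds = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr),
                 auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' ROC with a conservation filter applied
#'
#' Regions whose maximum conservation score falls below the cutoff have
#' their prediction score set to `-Inf` before the ROC is computed,
#' emulating a hard conservation pre-filter.
#'
#' @inheritParams roc_auc
#' @param max_scores per-region maximum conservation scores.
#' @param cutoff filter threshold.
#' @return `roc_curve`.
#' @export
roc_with_conservation_filter <- function(scores, labels, max_scores, cutoff) {
  stopifnot(length(max_scores) == length(scores))
  scores[max_scores < cutoff] <- -Inf
  roc_auc(scores, labels)
}
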