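# Candidate CRM prediction: oPOSSUM-style search regions around TSSs, sliding
# window motif features, a ridge-penalised logistic discriminator, an additive
# cluster score, and the published exclusion filters (SP1-only predictions,
# optional conservation filter).

#' Build TSS-anchored search regions
#'
#' For each transcription start site the region spans `tss_flank` bp up- and
#' downstream (clipped to the chromosome); protein-coding exon intervals are
#' subtracted, as are `alt_tss_exclusion` bp on either side of each
#' alternative TSS.
#'
#' @param tss data.frame with columns `chrom`, `pos` (0-based TSS positions).
#' @param coding_exons optional data.frame `chrom`, `start`, `end`.
#' @param alt_tss optional data.frame `chrom`, `pos`.
#' @param tss_flank flank size in bp, default 10000.
#' @param alt_tss_exclusion bp removed on each side of an alternative TSS,
#'   default 50.
#' @param chrom_lengths optional named vector used to clip regions.
#' @return `crm_regions` data.frame; ids are `<chrom>:<tss>_<part>`.
#' @export
build_search_regions <- function(tss, coding_exons = NULL, alt_tss = NULL,
                                 tss_flank = 10000L, alt_tss_exclusion = 50L,
                                 chrom_lengths = NULL) {
  if (tss_flank <= alt_tss_exclusion || alt_tss_exclusion < 0)
    stop("need tss_flank > alt_tss_exclusion >= 0")
  out <- list()
  for (i in seq_len(nrow(tss))) {
    chr <- tss$chrom[i]; pos <- tss$pos[i]
    lo <- max(0L, pos - tss_flank)
    hi <- pos + tss_flank
    if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths))
      hi <- min(hi, chrom_lengths[[chr]])
    if (lo >= hi) next
    keep <- to_iranges(lo, hi)
    drop <- IRanges::IRanges()
    if (!is.null(coding_exons)) {
      ce <- coding_exons[coding_exons$chrom == chr, , drop = FALSE]
      if (nrow(ce)) drop <- c(drop, to_iranges(ce$start, ce$end))
    }
    if (!is.null(alt_tss)) {
      at <- alt_tss[alt_tss$chrom == chr, , drop = FALSE]
      if (nrow(at))
        drop <- c(drop, to_iranges(pmax(0L, at$pos - alt_tss_exclusion),
                                   at$pos + alt_tss_exclusion))
    }
    parts <- from_iranges(IRanges::setdiff(keep, drop))
    if (!nrow(parts)) next
    out[[length(out) + 1L]] <- genomic_regions(
      chr, parts$start, parts$end,
      region_id = paste0(chr, ":", pos, "_", seq_len(nrow(parts))))
  }
  if (!length(out)) stop("no search regions produced")
  res <- do.call(rbind, out)
  class(res) <- c("crm_regions", "data.frame")
  res
}

# Newton/IRLS maximum-penalised-likelihood fit of logistic regression with an
# L2 penalty on the non-intercept coefficients. The penalty bounds the
# coefficients for separable data, so the iteration always converges.
ridge_logistic <- function(X, y, ridge, max_iter = 100L, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

feature_names <- function(motif_ids)
  c(paste0("best_", motif_ids), paste0("count_", motif_ids))

#' Sliding-window motif features
#'
#' Tiles each region with fixed-step half-open windows and records, per
#' motif, the best relative score (0 when absent) and the hit count. A hit is
#' assigned to every window it intersects. Hit offsets are region-relative.
#'
#' @param hits data.frame from [scan_regions()].
#' @param regions `crm_regions`; windows are tiled over `[0, end - start)`.
#' @param motif_ids motifs defining the feature columns (order fixed).
#' @param window window width in bp, default 200.
#' @param step tiling step in bp, default 50.
#' @return data.frame: `region_id, win_start, win_end` plus
#'   `best_<motif>`/`count_<motif>` columns.
#' @export
window_features <- function(hits, regions, motif_ids, window = 200L,
                            step = 50L) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    rid <- regions$region_id[i]
    len <- regions$end[i] - regions$start[i]
    ws <- seq.int(0L, max(0L, len - 1L), by = step)
    we <- pmin(ws + window, len)
    keep <- we > ws
    ws <- ws[keep]; we <- we[keep]
    h <- hits[hits$region_id == rid, , drop = FALSE]
    feat <- matrix(0, nrow = length(ws), ncol = 2L * length(motif_ids),
                   dimnames = list(NULL, feature_names(motif_ids)))
    if (nrow(h)) {
      for (k in seq_len(nrow(h))) {
        m <- match(h$motif_id[k], motif_ids)
        if (is.na(m)) next
        inwin <- which(h$offset[k] < we & h$offset[k] + h$length[k] > ws)
        if (!length(inwin)) next
        feat[inwin, m] <- pmax(feat[inwin, m], h$rel_score[k])
        feat[inwin, length(motif_ids) + m] <-
          feat[inwin, length(motif_ids) + m] + 1
      }
    }
    out[[i]] <- cbind(data.frame(region_id = rid, win_start = ws,
                                 win_end = we, stringsAsFactors = FALSE),
                      as.data.frame(feat))
  }
  do.call(rbind, out)
}

#' Train the logistic-regression CRM discriminator
#'
#' Fits a ridge-penalised (L2) logistic regression of class membership on the
#' window feature columns. The small fixed penalty guarantees a finite,
#' deterministic fit even for separable classes.
#'
#' @param positive_windows,negative_windows data.frames from
#'   [window_features()] (both non-empty).
#' @param seed integer seed recorded in the model (fit is deterministic).
#' @param ridge L2 penalty, default 1e-3.
#' @return object of class `lra_model`.
#' @export
train_lra <- function(positive_windows, negative_windows, seed = 1L,
                      ridge = 1e-3) {
  if (!nrow(positive_windows) || !nrow(negative_windows))
    stop("both classes must be non-empty")
  featcols <- grep("^(best|count)_", names(positive_windows), value = TRUE)
  x <- as.matrix(rbind(positive_windows[, featcols, drop = FALSE],
                       negative_windows[, featcols, drop = FALSE]))
  y <- rep(1:0, c(nrow(positive_windows), nrow(negative_windows)))
  beta <- ridge_logistic(cbind(1, x), y, ridge)
  structure(list(weights = setNames(beta[-1L], featcols),
                 intercept = unname(beta[1L]), features = featcols,
                 seed = seed, ridge = ridge), class = "lra_model")
}

#' @export
print.lra_model <- function(x, ...) {
  cat("LRA model:", length(x$features), "features, ridge", x$ridge, "\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Score windows with a trained LRA model
#'
#' @param windows data.frame from [window_features()].
#' @param model `lra_model`.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
lra_score <- function(windows, model) {
  x <- as.matrix(windows[, model$features, drop = FALSE])
  as.numeric(stats::plogis(model$intercept + x %*% model$weights))
}

#' Additive cluster score of a hit set within a window
#'
#' The optimal (maximum-weight) subset of mutually non-overlapping hits is
#' selected by weighted-interval scheduling and its relative scores summed;
#' a penalty proportional to the window fraction left uncovered by the
#' selected hits is subtracted.
#'
#' @param hits data.frame of site hits inside the window (offsets relative to
#'   the window or region, any origin).
#' @param window_len window length in bp.
#' @param gap_penalty penalty per fully uncovered window, default 0.
#' @return numeric score, 0 for an empty hit set at zero penalty.
#' @export
cluster_score <- function(hits, window_len, gap_penalty = 0) {
  if (!nrow(hits)) return(0 - gap_penalty)
  s <- hits$offset; e <- hits$offset + hits$length; w <- hits$rel_score
  ord <- order(e, s)
  s <- s[ord]; e <- e[ord]; w <- w[ord]
  n <- length(s)
  p <- vapply(seq_len(n), function(i) {
    j <- which(e <= s[i]); if (length(j)) max(j) else 0L
  }, 0L)
  M <- numeric(n + 1L)
  take <- logical(n)
  for (i in seq_len(n)) M[i + 1L] <- max(M[i], w[i] + M[p[i] + 1L])
  # backtrack for coverage
  chosen <- integer(0); i <- n
  while (i > 0L) {
    if (w[i] + M[p[i] + 1L] >= M[i]) { chosen <- c(chosen, i); i <- p[i] }
    else i <- i - 1L
  }
  covered <- if (length(chosen)) sum(e[chosen] - s[chosen]) else 0
  M[n + 1L] - gap_penalty * max(0, 1 - covered / window_len)
}

#' Predict CRMs from scored windows
#'
#' Windows scoring at or above `score_cutoff` under the LRA model are merged
#' when overlapping or adjacent; each merged prediction carries the site hits
#' it contains and its best window score. Predictions whose hits are composed
#' entirely of SP1 sites (equivalently: with zero non-SP1 hits) are excluded.
#'
#' @param windows data.frame from [window_features()].
#' @param model `lra_model`.
#' @param hits site hits used to annotate predictions (region-relative).
#' @param score_cutoff minimum LRA probability, default 0.5.
#' @param sp1_id motif id treated as SP1 for the exclusion filter.
#' @return data.frame of predictions: `region_id, start, end, lra_score,
#'   n_hits, n_non_sp1` with a `site_hits` list-column.
#' @export
predict_crms <- function(windows, model, hits, score_cutoff = 0.5,
                         sp1_id = "SP1") {
  windows$lra_score <- lra_score(windows, model)
  sel <- windows[windows$lra_score >= score_cutoff, , drop = FALSE]
  if (!nrow(sel)) return(empty_predictions())
  out <- list()
  for (rid in unique(sel$region_id)) {
    sw <- sel[sel$region_id == rid, , drop = FALSE]
    merged <- from_iranges(IRanges::reduce(to_iranges(sw$win_start,
                                                      sw$win_end)))
    h <- hits[hits$region_id == rid, , drop = FALSE]
    for (i in seq_len(nrow(merged))) {
      ms <- merged$start[i]; me <- merged$end[i]
      inwin <- sw$win_start < me & sw$win_end > ms
      hin <- h[h$offset < me & h$offset + h$length > ms, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        region_id = rid, start = ms, end = me,
        lra_score = max(sw$lra_score[inwin]),
        n_hits = nrow(hin), n_non_sp1 = sum(hin$motif_id != sp1_id),
        stringsAsFactors = FALSE)
      attr(out[[length(out)]], "site_hits") <- hin
    }
  }
  hit_lists <- lapply(out, attr, "site_hits")
  preds <- do.call(rbind, out)
  preds$site_hits <- hit_lists
  keep <- preds$n_non_sp1 > 0
  preds[keep, , drop = FALSE]
}

empty_predictions <- function() {
  df <- data.frame(region_id = character(), start = integer(),
                   end = integer(), lra_score = numeric(),
                   n_hits = integer(), n_non_sp1 = integer(),
                   stringsAsFactors = FALSE)
  df$site_hits <- list()
  df
}

#' Conservation filter on predictions
#'
#' Keeps predictions whose maximum per-base conservation score reaches the
#' cutoff. Prediction coordinates are region-relative; `regions` supplies
#' the genomic anchor for the track lookup.
#'
#' @param predictions data.frame from [predict_crms()].
#' @param track [score_track].
#' @param max_score_cutoff minimum of the region's maximum score.
#' @param regions `crm_regions` matching `predictions$region_id`.
#' @return filtered predictions.
#' @export
conservation_filter <- function(predictions, track, max_score_cutoff,
                                regions) {
  if (!nrow(predictions)) return(predictions)
  anchor <- regions$start[match(predictions$region_id, regions$region_id)]
  if (anyNA(anchor)) stop("predictions reference unknown regions")
  mx <- vapply(seq_len(nrow(predictions)), function(i)
    max(track_values(track, anchor[i] + predictions$start[i],
                     anchor[i] + predictions$end[i])), 0)
  predictions[mx >= max_score_cutoff, , drop = FALSE]
}
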