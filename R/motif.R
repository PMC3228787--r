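# PWM construction and TFBS scanning. Relative scores live on the log-odds
# scale: rel = (s - score_min)/(score_max - score_min), so the best word scores
# 1 and the worst 0, matching the "80% threshold" convention of motif-cluster
# scanners.

BASES <- c("A", "C", "G", "T")

#' Convert a position frequency matrix to a log-odds position weight matrix
#'
#' Weights are `log2((counts + pseudocount * bg) / (colsum + pseudocount) /
#' bg)`. The pseudocount is distributed in proportion to the background
#' composition. `score_min`/`score_max` are the attainable per-word bounds
#' (column-wise sums of the per-column minima/maxima).
#'
#' @param x a [pfm].
#' @param background base frequencies (A, C, G, T), summing to 1.
#' @param pseudocount total pseudocount, default 0.8.
#' @return object of class `pwm` with fields `motif_id`, `weights`,
#'   `score_min`, `score_max`, `background`.
#' @export
pfm_to_pwm <- function(x, background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(inherits(x, "pfm"))
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  if (any(background <= 0)) stop("background frequencies must be positive")
  counts <- x$counts
  if (any(colSums(counts) <= 0)) stop("zero PFM column")
  colsum <- colSums(counts)
  prob <- sweep(counts + pseudocount * background,
                2L, colsum + pseudocount, "/")
  w <- log2(prob / background)
  rownames(w) <- BASES
  structure(list(motif_id = x$motif_id, name = x$name, weights = w,
                 score_min = sum(apply(w, 2L, min)),
                 score_max = sum(apply(w, 2L, max)),
                 background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$motif_id, "length", ncol(x$weights),
      sprintf("score range [%.2f, %.2f]\n", x$score_min, x$score_max))
  invisible(x)
}

encode_dna <- function(seq) {
  code <- match(strsplit(seq, "")[[1L]], c(BASES, "N"))
  if (anyNA(code)) stop("sequence contains characters outside {A,C,G,T,N}")
  code
}

#' Reverse complement a sequence string
#' @param seq character DNA string over `{A,C,G,T,N}`.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1L]]), collapse = ""), "",
           USE.NAMES = FALSE))
}

# 5-row weight matrix: ACGT rows plus the background-expected weight for N.
extended_weights <- function(pwm) {
  rbind(pwm$weights, N = colSums(pwm$weights * pwm$background))
}

# Vectorised scores of every window of length L over the encoded sequence.
window_scores <- function(code, W) {
  L <- ncol(W)
  n <- length(code) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) s <- s + W[code[j:(j + n - 1L)], j]
  s
}

rc_pwm_weights <- function(W) {
  # reverse-complement of a (possibly N-extended) weight matrix
  Wrc <- W[c(4L, 3L, 2L, 1L, if (nrow(W) == 5L) 5L), rev(seq_len(ncol(W))),
           drop = FALSE]
  rownames(Wrc) <- rownames(W)
  Wrc
}

#' Scan a sequence for PWM matches above a relative-score threshold
#'
#' Both strands are scanned; a minus-strand hit at offset `k` matches the
#' reverse complement of the window starting at `k` on the given strand.
#' `N` bases contribute the background-expected column weight.
#'
#' @param seq character DNA sequence.
#' @param pwm a `pwm` object.
#' @param threshold_rel minimum relative score in `[0, 1]`, default 0.8.
#' @param region_id identifier recorded with each hit.
#' @return data.frame of site hits: `region_id, offset, length, strand,
#'   motif_id, abs_score, rel_score`, sorted by offset. Sequences shorter
#'   than the motif return an empty frame.
#' @export
scan_pwm <- function(seq, pwm, threshold_rel = 0.8, region_id = "seq") {
  stopifnot(threshold_rel >= 0, threshold_rel <= 1)
  W <- extended_weights(pwm)
  code <- encode_dna(seq)
  L <- ncol(W)
  rng <- pwm$score_max - pwm$score_min
  hit_frame <- function(scores, strand) {
    if (!length(scores)) return(NULL)
    rel <- if (rng > 0) (scores - pwm$score_min) / rng else rep(1, length(scores))
    keep <- which(rel >= threshold_rel - 1e-12)
    if (!length(keep)) return(NULL)
    data.frame(region_id = region_id, offset = keep - 1L, length = L,
               strand = strand, motif_id = pwm$motif_id,
               abs_score = scores[keep], rel_score = pmin(rel[keep], 1),
               stringsAsFactors = FALSE)
  }
  fwd <- hit_frame(window_scores(code, W), "+")
  rev <- hit_frame(window_scores(code, rc_pwm_weights(W)), "-")
  out <- rbind(fwd, rev)
  if (is.null(out))
    out <- data.frame(region_id = character(), offset = integer(),
                      length = integer(), strand = character(),
                      motif_id = character(), abs_score = numeric(),
                      rel_score = numeric(), stringsAsFactors = FALSE)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Scan many sequences with many PWMs
#'
#' @param seqs named character vector of sequences; names become `region_id`s.
#' @param pwms list of `pwm` objects (or a single one).
#' @param threshold_rel relative-score threshold.
#' @return combined hit data.frame as in [scan_pwm()].
#' @export
scan_regions <- function(seqs, pwms, threshold_rel = 0.8) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  out <- list()
  for (id in names(seqs))
    for (p in pwms)
      out[[length(out) + 1L]] <- scan_pwm(seqs[[id]], p, threshold_rel, id)
  res <- do.call(rbind, out)
  if (is.null(res)) scan_pwm("AAAA", pwms[[1L]], 1)[0, ] else res
}

#' Resolve overlapping hits of the same motif
#'
#' Within each `(region_id, motif_id)` pair, overlapping hits are resolved
#' greedily by descending score: the highest-scoring site is kept and any
#' same-motif hit overlapping it discarded. Ties break by leftmost start,
#' then `+` strand. Hits of different motifs may still overlap.
#'
#' @param hits data.frame from [scan_pwm()].
#' @return filtered hit data.frame.
#' @export
resolve_overlaps <- function(hits) {
  if (!nrow(hits)) return(hits)
  key <- paste(hits$region_id, hits$motif_id, sep = "\r")
  keep <- logical(nrow(hits))
  for (k in unique(key)) {
    idx <- which(key == k)
    ord <- idx[order(-hits$abs_score[idx], hits$offset[idx],
                     hits$strand[idx] != "+")]
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in ord) {
      s <- hits$offset[i]; e <- s + hits$length[i]
      if (!any(s < taken_e & e > taken_s)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Similarity score between two position frequency matrices
#'
#' Columns are compared as frequency vectors with the per-column score
#' `2 - sum(|f_a - f_b|)`, averaged over the aligned columns of the best
#' ungapped offset alignment. Both orientations of the second motif are
#' tried and the overlap must cover at least half of the shorter motif.
#' Scores range from 0 (disjoint point-mass columns) to 2 (identity).
#'
#' @param pfm_a,pfm_b [pfm] objects of length >= 4.
#' @param both_strands also try the reverse-complement orientation of
#'   `pfm_b` (default TRUE); with FALSE only the given-strand alignment is
#'   scored.
#' @return list with `score`, `offset` (columns of `b` shifted right relative
#'   to `a` at the optimum) and `orientation` (`"+"` or `"-"`).
#' @export
matrix_similarity <- function(pfm_a, pfm_b, both_strands = TRUE) {
  stopifnot(inherits(pfm_a, "pfm"), inherits(pfm_b, "pfm"))
  fa <- sweep(pfm_a$counts, 2L, colSums(pfm_a$counts), "/")
  fb0 <- sweep(pfm_b$counts, 2L, colSums(pfm_b$counts), "/")
  La <- ncol(fa); Lb <- ncol(fb0)
  min_olap <- ceiling(min(La, Lb) / 2)
  best <- list(score = -Inf, offset = 0L, orientation = "+")
  for (orient in if (both_strands) c("+", "-") else "+") {
    fb <- if (orient == "+") fb0 else fb0[4:1, Lb:1, drop = FALSE]
    for (off in seq.int(-(Lb - min_olap), La - min_olap)) {
      ja <- max(1L, 1L + off):min(La, Lb + off)
      jb <- ja - off
      if (length(ja) < min_olap) next
      colscore <- 2 - colSums(abs(fa[, ja, drop = FALSE] -
                                    fb[, jb, drop = FALSE]))
      sc <- mean(colscore)
      if (sc > best$score + 1e-12)
        best <- list(score = sc, offset = as.integer(off), orientation = orient)
    }
  }
  best
}
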