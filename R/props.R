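# Sequence-composition, conservation-summary, TSS/CpG context and TFBS
# phylogenetic-depth analytics over labeled region sets.

DINUCS <- as.vector(outer(BASES, BASES, paste0))

#' Nucleotide composition profile of a sequence
#'
#' N bases are dropped before counting. Dinucleotides are counted on the
#' given strand over the overlapping adjacent pairs of the N-stripped
#' sequence. Skews follow the `(G - C)/(G + C)` and `(A - T)/(A + T)`
#' conventions.
#'
#' @param seq character DNA string.
#' @return list with `mono` (4 frequencies), `gc_content`, `gc_skew`,
#'   `at_skew`, `dinuc` (16 frequencies).
#' @export
composition <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  chars <- chars[chars != "N"]
  if (length(chars) < 2L)
    stop("sequence must have at least 2 non-N bases")
  bad <- setdiff(unique(chars), BASES)
  if (length(bad)) stop("unexpected characters: ", paste(bad, collapse = ","))
  mono <- table(factor(chars, levels = BASES))
  mono <- as.numeric(mono) / length(chars)
  names(mono) <- BASES
  pairs <- paste0(chars[-length(chars)], chars[-1L])
  din <- table(factor(pairs, levels = DINUCS))
  din <- as.numeric(din) / (length(chars) - 1L)
  names(din) <- DINUCS
  g <- mono["G"]; c <- mono["C"]; a <- mono["A"]; t <- mono["T"]
  list(mono = mono,
       gc_content = unname(g + c),
       gc_skew = unname(if (g + c > 0) (g - c) / (g + c) else 0),
       at_skew = unname(if (a + t > 0) (a - t) / (a + t) else 0),
       dinuc = din)
}

composition_features <- function(seqs) {
  profs <- lapply(seqs, composition)
  cbind(
    do.call(rbind, lapply(profs, function(p) p$mono)),
    gc_content = vapply(profs, function(p) p$gc_content, 0),
    gc_skew = vapply(profs, function(p) p$gc_skew, 0),
    at_skew = vapply(profs, function(p) p$at_skew, 0),
    do.call(rbind, lapply(profs, function(p) p$dinuc)))
}

#' Compare composition features between two region sets
#'
#' Two-sided Wilcoxon rank-sum tests on the per-region values of each
#' composition feature (mononucleotide frequencies, GC content, skews,
#' dinucleotide frequencies).
#'
#' @param seqs_a,seqs_b character vectors of sequences (both non-empty).
#' @param features subset of feature names; default all.
#' @return data.frame `feature, median_a, median_b, p_value`.
#' @export
compare_composition <- function(seqs_a, seqs_b, features = NULL) {
  if (!length(seqs_a) || !length(seqs_b)) stop("both sets must be non-empty")
  fa <- composition_features(seqs_a)
  fb <- composition_features(seqs_b)
  if (is.null(features)) features <- colnames(fa)
  res <- lapply(features, function(f) {
    p <- suppressWarnings(wilcox.test(fa[, f], fb[, f])$p.value)
    data.frame(feature = f, median_a = median(fa[, f]),
               median_b = median(fb[, f]), p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Conservation summary of one region
#'
#' Computes the mean and maximum per-base score, the fraction of bases with
#' score strictly above `cutoff` (the "conserved make-up", counting runs of
#' any length), and the conserved flag: presence of at least one run of
#' `min_run` consecutive bases each at or above `cutoff`.
#'
#' The two thresholds intentionally differ in strictness (>= for the flag,
#' > for the make-up), mirroring the two published definitions.
#'
#' @param region one-row `crm_regions` (or list with `start`, `end`).
#' @param track [score_track].
#' @param cutoff score threshold, default 0.7.
#' @param min_run minimum run length for `is_conserved`, default 20.
#' @return list `mean_score, max_score, conserved_fraction, is_conserved`.
#' @export
conservation_summary <- function(region, track, cutoff = 0.7, min_run = 20L) {
  v <- track_values(track, region$start[1L], region$end[1L])
  r <- rle(v >= cutoff)
  list(mean_score = mean(v), max_score = max(v),
       conserved_fraction = mean(v > cutoff),
       is_conserved = any(r$values & r$lengths >= min_run))
}

#' Set-level conservation summary table
#'
#' For each region set: the mean of per-region mean scores, the mean of
#' per-region maxima, and the pooled conserved make-up (summed lengths of
#' bases above the cutoff divided by summed region lengths).
#'
#' @param regions `crm_regions` with a grouping column.
#' @param track [score_track].
#' @param group_col column to group by, default `set_label`.
#' @inheritParams conservation_summary
#' @return data.frame `group, mean_score, avg_max_score, conserved_fraction,
#'   n_regions`.
#' @export
summarize_conservation_sets <- function(regions, track, group_col = "set_label",
                                        cutoff = 0.7, min_run = 20L) {
  groups <- split(seq_len(nrow(regions)), regions[[group_col]])
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    sums <- lapply(idx, function(i)
      conservation_summary(regions[i, ], track, cutoff, min_run))
    lens <- regions$end[idx] - regions$start[idx]
    cons_len <- sum(vapply(seq_along(idx), function(k)
      sums[[k]]$conserved_fraction * lens[k], 0))
    data.frame(group = g,
               mean_score = mean(vapply(sums, `[[`, 0, "mean_score")),
               avg_max_score = mean(vapply(sums, `[[`, 0, "max_score")),
               conserved_fraction = cons_len / sum(lens),
               n_regions = length(idx), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Distance from a region to the nearest TSS
#'
#' Returns 0 when a TSS falls inside the half-open region, otherwise the gap
#' in bp to the nearest region base.
#'
#' @param region one-row region (fields `start`, `end`).
#' @param tss_pos numeric vector of TSS positions.
#' @return nonnegative distance in bp.
#' @export
tss_distance <- function(region, tss_pos) {
  s <- region$start[1L]; e <- region$end[1L]
  if (!length(tss_pos)) stop("empty TSS list")
  inside <- tss_pos >= s & tss_pos < e
  if (any(inside)) return(0)
  min(ifelse(tss_pos < s, s - tss_pos, tss_pos - (e - 1L)))
}

#' CpG-island association of a region
#'
#' TRUE when any island interval intersects the region extended by `flank`
#' bp on both sides (half-open flank: an island starting exactly at
#' `end + flank` does not count).
#'
#' @param region one-row region.
#' @param islands data.frame with `start`, `end` (0-based half-open).
#' @param flank flank in bp, default 1000.
#' @export
cpg_island_assoc <- function(region, islands, flank = 1000L) {
  s <- max(0L, region$start[1L] - flank)
  e <- region$end[1L] + flank
  any(islands$start < e & islands$end > s)
}

#' TFBS phylogenetic-depth analysis
#'
#' For each region set and transcription factor, compares the mean
#' conservation score at predicted binding-site positions with the mean at
#' non-site positions (region positions not covered by any retained site of
#' any TF). The per-TF fold is site mean over non-site mean; TFs reaching at
#' least `fold_cut` (inclusive) in the designated responding sets form the
#' selected list, whose per-TF ratios are then compared between sets by
#' two-sample t-tests. TFs whose non-site mean is not positive are skipped
#' with a warning (a ratio of possibly-negative scores is undefined).
#'
#' @param regions `crm_regions` with set labels in `group_col`.
#' @param hits resolved site hits ([resolve_overlaps()]) with
#'   region-relative offsets.
#' @param track [score_track] (typically the unbounded phyloP-like track).
#' @param fold_cut selection threshold, default 2.
#' @param select_groups groups whose folds define the selected TF list;
#'   default all groups with a `responder == TRUE` flavour, else all groups.
#' @param group_col grouping column, default `set_label`.
#' @return list with `per_tf` (data.frame `group, motif_id, site_mean,
#'   nonsite_mean, fold`), `selected_tfs`, and `tests` (pairwise t-tests on
#'   selected-TF folds between groups).
#' @export
tfbs_depth <- function(regions, hits, track, fold_cut = 2,
                       select_groups = NULL, group_col = "set_label") {
  groups <- split(seq_len(nrow(regions)), regions[[group_col]])
  per_tf <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    site_sc <- list(); nonsite_sc <- numeric(0)
    tf_pos <- list()
    for (i in idx) {
      rid <- regions$region_id[i]
      rs <- regions$start[i]; re <- regions$end[i]
      v <- track_values(track, rs, re)
      h <- hits[hits$region_id == rid, , drop = FALSE]
      cov <- logical(re - rs)
      for (k in seq_len(nrow(h))) {
        span <- (h$offset[k] + 1L):min(h$offset[k] + h$length[k], re - rs)
        cov[span] <- TRUE
        tf <- h$motif_id[k]
        tf_pos[[tf]] <- c(tf_pos[[tf]], v[span])
      }
      nonsite_sc <- c(nonsite_sc, v[!cov])
    }
    nb <- mean(nonsite_sc)
    for (tf in names(tf_pos)) {
      if (!is.na(nb) && nb <= 0) {
        warning("non-site mean <= 0 in group ", g, "; TF ", tf, " skipped")
        next
      }
      per_tf[[length(per_tf) + 1L]] <- data.frame(
        group = g, motif_id = tf, site_mean = mean(tf_pos[[tf]]),
        nonsite_mean = nb, fold = mean(tf_pos[[tf]]) / nb,
        stringsAsFactors = FALSE)
    }
  }
  per_tf <- if (length(per_tf)) do.call(rbind, per_tf) else
    data.frame(group = character(), motif_id = character(),
               site_mean = numeric(), nonsite_mean = numeric(),
               fold = numeric())
  if (is.null(select_groups)) select_groups <- unique(per_tf$group)
  sel <- unique(per_tf$motif_id[per_tf$group %in% select_groups &
                                  per_tf$fold >= fold_cut])
  tests <- NULL
  gs <- unique(per_tf$group)
  if (length(gs) >= 2L && length(sel) >= 2L) {
    combs <- utils::combn(gs, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
      f1 <- per_tf$fold[per_tf$group == combs[1L, j] &
                          per_tf$motif_id %in% sel]
      f2 <- per_tf$fold[per_tf$group == combs[2L, j] &
                          per_tf$motif_id %in% sel]
      p <- if (length(f1) >= 2L && length(f2) >= 2L)
        t.test(f1, f2)$p.value else NA_real_
      data.frame(group_a = combs[1L, j], group_b = combs[2L, j],
                 mean_fold_a = mean(f1), mean_fold_b = mean(f2),
                 p_value = p, stringsAsFactors = FALSE)
    }))
  }
  list(per_tf = per_tf, selected_tfs = sel, tests = tests)
}
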