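# Dual-luciferase reporter analysis: LRU threshold QC with renilla flooring,
# technical-replicate averaging, generalized-log (asinh) normalization with
# maximum-likelihood calibration, a moderated differential statistic with
# permutation-estimated FDR, two-phase selection, and the clone-consensus
# positive rule.

#' QC-filter well measurements and compute expression ratios
#'
#' Wells whose firefly signal is below the LRU threshold are failed
#' transfections. When firefly passes but renilla does not, the renilla value
#' is floored to the threshold before the ratio is taken, which bounds the
#' ratio by `firefly / threshold` and suppresses spuriously large ratios.
#' The threshold is inclusive (>=).
#'
#' @param wells plate data.frame (see [read_plate_csv()]).
#' @param threshold minimum LRU, default 1000.
#' @return the input with added columns `qc_status` (`"pass"`/`"failed"`),
#'   `ratio` (NA when failed) and `renilla_floored`.
#' @export
qc_filter <- function(wells, threshold = 1000) {
  wells <- validate_wells(wells)
  pass <- wells$firefly_lru >= threshold
  floored <- pass & wells$renilla_lru < threshold
  denom <- ifelse(floored, threshold, wells$renilla_lru)
  wells$qc_status <- ifelse(pass, "pass", "failed")
  wells$ratio <- ifelse(pass, wells$firefly_lru / denom, NA_real_)
  wells$renilla_floored <- floored
  wells
}

#' Average technical replicates per clone and cell type
#'
#' Passing replicate ratios are averaged within each clone, phase and cell
#' type. If only one replicate passed QC its value is used alone
#' (`single_rep`); clones with no passing replicate for a cell type are
#' excluded from that cell type.
#'
#' @param qc_wells output of [qc_filter()].
#' @return data.frame with one row per clone x phase x cell type:
#'   `clone_id, insert_id, set_label, phase, cell_type, ratio, qc_status`
#'   where `qc_status` is `"pass"`, `"single_rep"` or `"failed"`.
#' @export
average_technical_reps <- function(qc_wells) {
  key <- interaction(qc_wells$clone_id, qc_wells$phase, qc_wells$cell_type,
                     drop = TRUE)
  rows <- lapply(split(seq_len(nrow(qc_wells)), key), function(idx) {
    w <- qc_wells[idx, , drop = FALSE]
    ok <- w$qc_status == "pass"
    data.frame(clone_id = w$clone_id[1L], insert_id = w$insert_id[1L],
               set_label = w$set_label[1L], phase = w$phase[1L],
               cell_type = w$cell_type[1L],
               ratio = if (any(ok)) mean(w$ratio[ok]) else NA_real_,
               qc_status = if (sum(ok) == nrow(w)) "pass"
                           else if (any(ok)) "single_rep" else "failed",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generalized-log (variance-stabilizing) normalization
#'
#' Applies `glog(x; a, b) = asinh((x - a) / b)` with `(a, b)` fitted by
#' maximum likelihood under the additive-multiplicative error model: the
#' profile likelihood of the transformed values being i.i.d. normal,
#' including the transformation Jacobian. The transform is strictly monotone
#' in `x`, and for multiplicative (lognormal-like) noise it renders the
#' spread approximately independent of the mean.
#'
#' @param x numeric vector of expression ratios (a batch, e.g. one cell type
#'   in one phase); at least 8 values.
#' @param group optional replicate-group factor (e.g. clone); per-group means
#'   are profiled out of the likelihood, so only within-group spread informs
#'   the calibration. Without groups the whole batch is one group.
#' @return transformed values with attributes `a` and `b`.
#' @export
normalize_glog <- function(x, group = NULL) {
  x <- as.numeric(x)
  if (length(x) < 8L) stop("glog calibration needs at least 8 values")
  if (anyNA(x)) stop("glog input must not contain NA")
  if (is.null(group)) group <- rep(1L, length(x))
  group <- as.integer(factor(group))
  if (var(x) == 0) {
    out <- asinh(x)
    attr(out, "a") <- 0; attr(out, "b") <- 1
    return(out)
  }
  resid_var <- function(h) {
    centred <- h - ave(h, group)
    mean(centred^2)
  }
  nll <- function(par) {
    a <- par[1L]; b <- exp(par[2L])
    h <- asinh((x - a) / b)
    v <- resid_var(h)
    if (!is.finite(v) || v <= 0) return(1e10)
    length(x) / 2 * log(v) + 0.5 * sum(log(b^2 + (x - a)^2))
  }
  init <- c(0, log(stats::mad(x) + sd(x) / 10 + 1e-6))
  fit <- optim(init, nll, method = "Nelder-Mead",
               control = list(maxit = 500))
  a <- fit$par[1L]; b <- exp(fit$par[2L])
  out <- asinh((x - a) / b)
  attr(out, "a") <- a; attr(out, "b") <- b
  out
}

pooled_s <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  df <- n1 + n2 - 2L
  if (df < 1L) return(NA_real_)
  ss <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
  sqrt((1 / n1 + 1 / n2) * ss / df)
}

d_stats <- function(groups) {
  s <- vapply(groups, function(g) pooled_s(g$mt, g$other), 0)
  s[is.na(s)] <- 0
  s0 <- median(s)
  d <- vapply(seq_along(groups), function(i) {
    diff <- mean(groups[[i]]$mt) - mean(groups[[i]]$other)
    den <- s[i] + s0
    if (den == 0) { if (diff == 0) 0 else sign(diff) * Inf } else diff / den
  }, 0)
  list(d = d, s = s, s0 = s0)
}

#' Moderated differential call: myotube versus other cell types
#'
#' For each clone a moderated statistic `d = (mean_MT - mean_other) /
#' (s + s0)` is computed from normalized replicate-level values, with `s` the
#' pooled within-clone standard error and `s0` the median of the per-clone
#' `s` (the fudge factor that tempers small-variance clones). The false
#' discovery rate of the one-sided (myotube-elevated) call is estimated by
#' permuting cell-type labels within clones: for each candidate cutoff the
#' FDR is the median permutation exceedance count over the observed count.
#' The most permissive cutoff with estimated FDR at or below `fdr` is used.
#'
#' @param values data.frame with columns `clone_id`, `cell_type`, `value`
#'   (normalized) and optionally `tech_rep`; myotube rows form one group,
#'   all others the reference.
#' @param fdr maximum false discovery rate, default 0.05.
#' @param n_perm number of label permutations, default 1000.
#' @param seed RNG seed for the permutations (deterministic output).
#' @return data.frame `clone_id, d, called` with attributes `cutoff`,
#'   `fdr_at_cutoff`, `s0`.
#' @export
differential_call <- function(values, fdr = 0.05, n_perm = 1000L, seed = 1L) {
  stopifnot(all(c("clone_id", "cell_type", "value") %in% names(values)))
  if (is.null(values$tech_rep))
    values$tech_rep <- stats::ave(seq_len(nrow(values)),
                                  values$clone_id, values$cell_type,
                                  FUN = seq_along)
  values$column <- paste(values$cell_type, values$tech_rep, sep = "|")
  columns <- sort(unique(values$column))
  is_mt <- startsWith(columns, "myotube|")
  clones <- unique(values$clone_id)
  per_clone <- lapply(clones, function(cl) {
    v <- values[values$clone_id == cl, , drop = FALSE]
    list(value = v$value, col = match(v$column, columns))
  })
  keep <- vapply(per_clone, function(g)
    any(is_mt[g$col]) && any(!is_mt[g$col]), TRUE)
  per_clone <- per_clone[keep]; clones <- clones[keep]
  if (!length(per_clone)) stop("no clone has both myotube and reference values")
  d_for <- function(mt_mask) {
    groups <- lapply(per_clone, function(g) {
      m <- mt_mask[g$col]
      list(mt = g$value[m], other = g$value[!m])
    })
    ok <- vapply(groups, function(g)
      length(g$mt) >= 1L && length(g$other) >= 1L, TRUE)
    d <- rep(NA_real_, length(groups))
    if (any(ok)) d[ok] <- d_stats(groups[ok])$d
    d
  }
  obs_groups <- lapply(per_clone, function(g)
    list(mt = g$value[is_mt[g$col]], other = g$value[!is_mt[g$col]]))
  obs <- d_stats(obs_groups)
  # one shuffled column labeling per permutation, shared by every clone
  # (two-class unpaired permutation over the common plate layout)
  perm_d <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b)
      d_for(sample(is_mt)), numeric(length(per_clone)))
  })
  perm_d <- matrix(perm_d, nrow = length(per_clone))
  cuts <- sort(unique(obs$d[is.finite(obs$d) & obs$d > 0]))
  cutoff <- Inf; fdr_at <- NA_real_
  for (t in cuts) {                           # most permissive cutoff first
    R <- sum(obs$d >= t)
    if (R == 0) next
    V <- median(apply(perm_d >= t, 2L, sum, na.rm = TRUE))
    est <- min(1, V / R)
    if (est <= fdr) { cutoff <- t; fdr_at <- est; break }
  }
  out <- data.frame(clone_id = clones, d = obs$d,
                    called = obs$d >= cutoff, stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  attr(out, "fdr_at_cutoff") <- fdr_at
  attr(out, "s0") <- obs$s0
  out
}

#' Phase-1 advancement rule
#'
#' A plasmid advances to phase 2 when it selectively directed myotube
#' expression in phase 1: a raw-ratio fold of at least `fold_cut` (inclusive)
#' in myotube over both other cell types, or a positive moderated
#' differential call, or designation as a control row.
#'
#' @param clone_stats data.frame with columns `clone_id`,
#'   `fold_vs_myoblast`, `fold_vs_fibroblast`, `sam_positive`, and optional
#'   logical `control`.
#' @param fold_cut fold threshold, default 2 (inclusive).
#' @return the advanced subset of `clone_stats`.
#' @export
phase1_advance <- function(clone_stats, fold_cut = 2) {
  ctrl <- if (is.null(clone_stats$control)) FALSE else
    isTRUE_vec(clone_stats$control)
  fold_ok <- !is.na(clone_stats$fold_vs_myoblast) &
    clone_stats$fold_vs_myoblast >= fold_cut &
    !is.na(clone_stats$fold_vs_fibroblast) &
    clone_stats$fold_vs_fibroblast >= fold_cut
  adv <- ctrl | isTRUE_vec(clone_stats$sam_positive) | fold_ok
  clone_stats[adv, , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Clone-consensus positive rule per insert
#'
#' An insert is finally called positive only when at least two of its clones
#' were identified as positive and those positives make up at least half of
#' the available clones (phases combined).
#'
#' @param clone_calls data.frame with columns `insert_id`, `clone_id`,
#'   `positive` (one row per clone).
#' @return data.frame `insert_id, n_clones_available, n_clones_positive,
#'   final_call`.
#' @export
consensus_positive <- function(clone_calls) {
  rows <- lapply(split(clone_calls, clone_calls$insert_id), function(g) {
    n <- length(unique(g$clone_id))
    np <- length(unique(g$clone_id[isTRUE_vec(g$positive)]))
    data.frame(insert_id = g$insert_id[1L], n_clones_available = n,
               n_clones_positive = np,
               final_call = np >= 2L && np / n >= 0.5,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parse "positives/available" well strings
#'
#' Converts strings such as `"4/5"` into clone counts for
#' [consensus_positive()].
#'
#' @param x character vector like `"3/6"`.
#' @return data.frame `n_positive, n_available`.
#' @export
parse_positive_wells <- function(x) {
  parts <- strsplit(as.character(x), "/")
  data.frame(n_positive = as.integer(vapply(parts, `[`, "", 1L)),
             n_available = as.integer(vapply(parts, `[`, "", 2L)))
}

#' Full reporter-screen analysis
#'
#' Runs the complete analysis chain on raw plate data: QC filtering,
#' technical-replicate averaging, per-batch (phase x cell type) glog
#' normalization of replicate-level ratios, phase-1 differential calling and
#' advancement, phase-2 differential calling on the advanced plasmids, and
#' the final clone-consensus rule per insert.
#'
#' @param wells plate data.frame (see [read_plate_csv()]).
#' @param fdr FDR for the differential calls, default 0.05.
#' @param n_perm permutations per call, default 1000.
#' @param seed RNG seed.
#' @param fold_cut phase-1 fold threshold, default 2.
#' @param lru_threshold QC threshold, default 1000.
#' @return list with `clone_expression` (averaged ratios), `phase1`,
#'   `phase2` (differential call frames), `clone_calls` and `insert_calls`
#'   (consensus).
#' @export
run_reporter_analysis <- function(wells, fdr = 0.05, n_perm = 1000L,
                                  seed = 1L, fold_cut = 2,
                                  lru_threshold = 1000) {
  qc <- qc_filter(wells, lru_threshold)
  expr <- average_technical_reps(qc)
  ok <- qc[qc$qc_status == "pass", , drop = FALSE]
  # replicate-level normalized values per phase x cell type batch
  ok$value <- NA_real_
  for (ph in unique(ok$phase)) for (ct in unique(ok$cell_type)) {
    idx <- ok$phase == ph & ok$cell_type == ct
    v <- if (sum(idx) >= 8L)
      as.numeric(normalize_glog(ok$ratio[idx], ok$clone_id[idx]))
    else asinh(ok$ratio[idx])
    # calibrate batches to a common location (most clones are unchanged
    # between cell types, so the median is a stable anchor)
    ok$value[idx] <- v - median(v)
  }
  call_phase <- function(ph, clone_subset = NULL, offset = 0L) {
    v <- ok[ok$phase == ph, c("clone_id", "cell_type", "tech_rep", "value")]
    if (!is.null(clone_subset))
      v <- v[v$clone_id %in% clone_subset, , drop = FALSE]
    if (!nrow(v)) return(NULL)
    testable <- vapply(split(v$cell_type, v$clone_id), function(ct)
      any(ct == "myotube") && any(ct != "myotube"), TRUE)
    if (!any(testable)) return(NULL)
    differential_call(v, fdr = fdr, n_perm = n_perm, seed = seed + offset)
  }
  p1 <- call_phase(1L)
  fold_of <- function(ct) {
    e1 <- expr[expr$phase == 1L, , drop = FALSE]
    mt <- vapply(p1$clone_id, function(cl) {
      r <- e1$ratio[e1$clone_id == cl & e1$cell_type == "myotube"]
      if (length(r)) r[1L] else NA_real_
    }, 0)
    ot <- vapply(p1$clone_id, function(cl) {
      r <- e1$ratio[e1$clone_id == cl & e1$cell_type == ct]
      if (length(r)) r[1L] else NA_real_
    }, 0)
    mt / ot
  }
  advanced <- character(0)
  if (!is.null(p1)) {
    stats1 <- data.frame(clone_id = p1$clone_id,
                         fold_vs_myoblast = fold_of("myoblast"),
                         fold_vs_fibroblast = fold_of("fibroblast"),
                         sam_positive = p1$called, stringsAsFactors = FALSE)
    advanced <- phase1_advance(stats1, fold_cut)$clone_id
  }
  p2 <- if (length(advanced)) call_phase(2L, advanced, offset = 1L) else NULL
  pos <- union(if (!is.null(p1)) p1$clone_id[p1$called] else character(0),
               if (!is.null(p2)) p2$clone_id[p2$called] else character(0))
  avail <- unique(ok[, c("clone_id", "insert_id")])
  clone_calls <- data.frame(insert_id = avail$insert_id,
                            clone_id = avail$clone_id,
                            positive = avail$clone_id %in% pos,
                            stringsAsFactors = FALSE)
  list(clone_expression = expr, phase1 = p1, phase2 = p2,
       advanced = advanced, clone_calls = clone_calls,
       insert_calls = consensus_positive(clone_calls))
}
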