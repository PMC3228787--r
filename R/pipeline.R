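# End-to-end orchestration over plain files: simulate -> scan -> predict ->
# assay -> props -> enrich -> roc, with a provenance log (config, seed,
# content hashes) so a rerun with the same seed is byte-identical.

#' Pipeline configuration
#'
#' Aggregates the analysis thresholds (defaults follow the standard screen
#' settings: scan threshold 0.8, conservation 0.7 over 20 bp, 1000 LRU QC,
#' FDR 0.05, 2-fold phase-1 advancement, 2-fold depth selection, 1 kb CpG
#' flank, 10 kb TSS flank with 50 bp alternative-TSS exclusion) and the
#' simulation settings.
#'
#' @param seed master seed.
#' @param sim [sim_config()] for the synthetic inputs.
#' @param scan_threshold PWM relative-score threshold.
#' @param cons_cutoff,cons_min_run conservation-summary parameters.
#' @param lru_threshold QC threshold.
#' @param fdr differential-call FDR.
#' @param fold_cut phase-1 fold threshold.
#' @param depth_fold_cut TFBS-depth selection threshold.
#' @param cpg_flank CpG-island association flank (bp).
#' @param tss_flank,alt_tss_exclusion search-region parameters (bp).
#' @param lra_window,lra_step window feature tiling (bp).
#' @param lra_cutoff LRA probability cutoff for predictions.
#' @param n_perm permutations for the differential call.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            scan_threshold = 0.8, cons_cutoff = 0.7,
                            cons_min_run = 20L, lru_threshold = 1000,
                            fdr = 0.05, fold_cut = 2, depth_fold_cut = 2,
                            cpg_flank = 1000L, tss_flank = 10000L,
                            alt_tss_exclusion = 50L, lra_window = 200L,
                            lra_step = 50L, lra_cutoff = 0.5,
                            n_perm = 500L) {
  structure(as.list(environment()), class = "pipeline_config")
}

# Non-overlapping decoy regions sampled outside the planted CRMs.
sample_decoys <- function(truth, n, len, seed) {
  glen <- nchar(truth$sequence[[1L]])
  chrom <- names(truth$sequence)[1L]
  with_seed(seed, {
    starts <- integer(0)
    occupied_s <- truth$regions$start; occupied_e <- truth$regions$end
    for (i in seq_len(n)) {
      for (try in 1:500) {
        s <- sample.int(glen - len, 1L) - 1L
        if (!any(s < c(occupied_e, starts + len) &
                   s + len > c(occupied_s, starts))) {
          starts <- c(starts, s); break
        }
      }
    }
    genomic_regions(chrom, sort(starts), sort(starts) + len,
                    region_id = paste0("decoy", seq_along(starts)))
  })
}

region_seqs <- function(genome_seq, regions) {
  setNames(substring(genome_seq, regions$start + 1L, regions$end),
           regions$region_id)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a synthetic genome with planted CRMs plus matched decoy
#' regions, conservation tracks, plate data and peak sets; scans for motif
#' hits; trains and applies the window discriminator with the SP1-only and
#' conservation filters; analyses the reporter screen through to insert
#' consensus calls; computes composition/conservation/depth properties and
#' enrichment/overlap/ROC statistics. All stage outputs are written under
#' `out_dir` and hashed into `provenance.json`.
#'
#' @param config [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param verbose print stage progress to stderr.
#' @return invisible list with the in-memory stage results and `files`
#'   (named vector of output paths).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("crm_"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%T"),
                                            "] ", ...)
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files[[name]] <<- path
    path
  }

  say("simulate")
  pfms <- default_motifs()
  truth <- gen_genome(config$sim, pfms)
  tracks <- gen_conservation_track(truth, config$sim)
  # non-responders dominate real screens; 3:1 keeps the batch calibration's
  # "most inserts unchanged" assumption valid
  decoys <- sample_decoys(truth, 3L * config$sim$n_crm,
                          config$sim$crm_length, config$sim$seed + 4L)
  candidates <- rbind(
    genomic_regions(truth$regions$chrom, truth$regions$start,
                    truth$regions$end, truth$regions$region_id,
                    set_label = "muscle", responder = TRUE),
    genomic_regions(decoys$chrom, decoys$start, decoys$end, decoys$region_id,
                    set_label = "background", responder = FALSE))
  class(candidates) <- c("crm_regions", "data.frame")
  inserts <- data.frame(insert_id = candidates$region_id,
                        set_label = candidates$set_label,
                        positive = candidates$responder,
                        stringsAsFactors = FALSE)
  wells <- gen_plate_data(inserts, config$sim)
  sim_mb <- config$sim; sim_mb$peak_overlap_probs <-
    config$sim$peak_overlap_probs * 0.5
  sim_mb$seed <- config$sim$seed + 5L
  peaks <- list(myoblast = gen_peaks(candidates, sim_mb, "peaks_MB"),
                myotube = gen_peaks(candidates, config$sim, "peaks_MT"))
  emit("genome.fa", function(p) write_fasta(truth$sequence, p))
  emit("truth_crms.bed", function(p) write_bed(truth$regions, p))
  emit("candidates.bed", function(p) write_bed(candidates, p))
  emit("phastcons.bedgraph", function(p) write_score_track(tracks$bounded, p))
  emit("phylop.bedgraph", function(p) write_score_track(tracks$unbounded, p))
  emit("plates.csv", function(p) write_plate_csv(wells, p))
  emit("motifs.jaspar", function(p) write_jaspar_pfm(pfms, p))

  say("scan")
  pwms <- lapply(pfms, pfm_to_pwm)
  cand_seqs <- region_seqs(truth$sequence[[1L]], candidates)
  hits <- resolve_overlaps(scan_regions(cand_seqs, pwms,
                                        config$scan_threshold))
  emit("sites.tsv", function(p)
    write.table(hits, p, sep = "\t", quote = FALSE, row.names = FALSE))

  say("predict")
  genome_region <- genomic_regions(names(truth$sequence)[1L], 0L,
                                   nchar(truth$sequence[[1L]]),
                                   region_id = names(truth$sequence)[1L])
  genome_hits <- resolve_overlaps(scan_regions(truth$sequence, pwms,
                                               config$scan_threshold))
  windows <- window_features(genome_hits, genome_region, names(pfms),
                             config$lra_window, config$lra_step)
  in_crm <- vapply(seq_len(nrow(windows)), function(i)
    any(windows$win_start[i] < truth$regions$end &
          windows$win_end[i] > truth$regions$start), TRUE)
  model <- train_lra(windows[in_crm, , drop = FALSE],
                     windows[!in_crm, , drop = FALSE],
                     seed = config$seed)
  preds <- predict_crms(windows, model, genome_hits, config$lra_cutoff)
  preds_cons <- conservation_filter(preds, tracks$bounded,
                                    config$cons_cutoff, genome_region)
  emit("predictions.bed", function(p) {
    pr <- preds; pr$site_hits <- NULL
    write_bed(genomic_regions(genome_region$chrom, pr$start, pr$end,
                              paste0("pred", seq_len(nrow(pr)))),
              p, score = round(1000 * pr$lra_score))
  })

  say("assay")
  assay <- run_reporter_analysis(wells, fdr = config$fdr,
                                 n_perm = config$n_perm, seed = config$seed,
                                 fold_cut = config$fold_cut,
                                 lru_threshold = config$lru_threshold)
  emit("insert_calls.tsv", function(p)
    write.table(assay$insert_calls, p, sep = "\t", quote = FALSE,
                row.names = FALSE))

  say("props")
  comp <- compare_composition(cand_seqs[candidates$responder],
                              cand_seqs[!candidates$responder])
  cons_sets <- summarize_conservation_sets(candidates, tracks$bounded,
                                           group_col = "responder",
                                           cutoff = config$cons_cutoff,
                                           min_run = config$cons_min_run)
  depth <- tfbs_depth(candidates, hits, tracks$unbounded,
                      fold_cut = config$depth_fold_cut,
                      select_groups = "TRUE", group_col = "responder")
  emit("composition.tsv", function(p)
    write.table(comp, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("conservation_sets.tsv", function(p)
    write.table(cons_sets, p, sep = "\t", quote = FALSE, row.names = FALSE))

  say("enrich")
  enr <- overrepresentation(candidates[candidates$responder, ],
                            candidates[!candidates$responder, ],
                            hits, names(pfms))
  ovl <- overlap_contingency(
    list(myoblast = region_peak_overlap(candidates, peaks$myoblast),
         myotube = region_peak_overlap(candidates, peaks$myotube)),
    candidates$responder)
  emit("enrichment.tsv", function(p)
    write.table(enr, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("overlap.tsv", function(p)
    write.table(ovl, p, sep = "\t", quote = FALSE, row.names = FALSE))

  say("roc")
  labels <- in_crm
  windows$lra_score <- lra_score(windows, model)
  roc_plain <- roc_auc(windows$lra_score, labels)
  win_max <- vapply(seq_len(nrow(windows)), function(i)
    max(track_values(tracks$bounded, windows$win_start[i],
                     windows$win_end[i])), 0)
  roc_cons <- roc_with_conservation_filter(windows$lra_score, labels,
                                           win_max, config$cons_cutoff)
  # region-level recovery: each candidate scored by its best window
  cand_windows <- window_features(hits, candidates, names(pfms),
                                  config$lra_window, config$lra_step)
  cand_windows$lra_score <- lra_score(cand_windows, model)
  region_score <- tapply(cand_windows$lra_score, cand_windows$region_id, max)
  roc_recovery <- roc_auc(as.numeric(region_score[candidates$region_id]),
                          candidates$responder)
  emit("roc.tsv", function(p)
    write.table(data.frame(auc_windows = roc_plain$auc,
                           auc_windows_conservation = roc_cons$auc,
                           auc_region_recovery = roc_recovery$auc),
                p, sep = "\t", quote = FALSE, row.names = FALSE))

  prov <- list(seed = config$seed,
               config = config[setdiff(names(config), "sim")],
               sim = unclass(config$sim),
               hashes = as.list(tools::md5sum(unlist(files))))
  names(prov$hashes) <- names(files)
  emit("provenance.json", function(p)
    jsonlite::write_json(prov, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA))
  invisible(list(truth = truth, candidates = candidates, hits = hits,
                 model = model, predictions = preds,
                 predictions_conserved = preds_cons, assay = assay,
                 composition = comp, conservation = cons_sets,
                 depth = depth, enrichment = enr, overlap = ovl,
                 roc = roc_plain, roc_conservation = roc_cons,
                 roc_recovery = roc_recovery, files = files))
}
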