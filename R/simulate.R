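# Seeded generators for every input the pipeline consumes: genomes with
# planted TFBS clusters, conservation tracks elevated over the planted
# elements, lognormal dual-luciferase plate data, and label-dependent
# ChIP-seq-like peak sets.

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate the
#' study conditions of a muscle reporter screen: ~400 bp candidate regions
#' with a +0.03 GC shift in functional modules (0.54 vs 0.51), a 15-fold
#' myotube effect for strong planted enhancers, ~30% multiplicative
#' luminescence noise, occasional transfection failures, and MyoD-like peak
#' overlap rates of 0.58 (responders) vs 0.16 (non-responders).
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs.
#' @param genome_length background genome length in bp.
#' @param background_gc background GC fraction (human-like 0.41).
#' @param n_crm number of planted CRMs.
#' @param crm_length planted CRM span in bp.
#' @param crm_gc_shift added G/C fraction inside planted CRMs.
#' @param motifs_per_crm planted TFBS per CRM.
#' @param conservation_elevation mean conservation lift over planted CRMs.
#' @param site_elevation_factor extra multiplicative lift of planted TFBS
#'   positions over the CRM flank (phylogenetic-depth signal).
#' @param plate_effect_fold myotube/myoblast ratio for planted positives.
#' @param plate_cv coefficient of variation of the lognormal plate noise.
#' @param fail_rate transfection-failure probability per well.
#' @param peak_overlap_probs named probabilities (`responder`,
#'   `non_responder`) that a region is overlapped by a peak.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 50000L, background_gc = 0.41,
                       n_crm = 8L, crm_length = 200L, crm_gc_shift = 0.03,
                       motifs_per_crm = 4L, conservation_elevation = 0.5,
                       site_elevation_factor = 2,
                       plate_effect_fold = 15, plate_cv = 0.3,
                       fail_rate = 0.05,
                       peak_overlap_probs = c(responder = 0.58,
                                              non_responder = 0.16)) {
  probs <- c(background_gc, crm_gc_shift + background_gc, fail_rate,
             peak_overlap_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (plate_effect_fold <= 0) stop("plate_effect_fold must be > 0")
  if (!all(c("responder", "non_responder") %in% names(peak_overlap_probs)))
    stop("peak_overlap_probs needs 'responder' and 'non_responder' entries")
  structure(as.list(environment()), class = "sim_config")
}

iupac_bases <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    N = c("A", "C", "G", "T"))

#' Build a PFM from an IUPAC consensus string
#'
#' Allowed bases at each position receive the dominant count and disallowed
#' bases a small residual, yielding a sharp synthetic motif model.
#'
#' @param motif_id identifier.
#' @param consensus IUPAC string, length >= 4.
#' @param name display name.
#' @param dominant,residual per-column counts for allowed/disallowed bases.
#' @export
consensus_pfm <- function(motif_id, consensus, name = motif_id,
                          dominant = 21, residual = 1) {
  chars <- strsplit(toupper(consensus), "")[[1L]]
  bad <- setdiff(chars, names(iupac_bases))
  if (length(bad)) stop("unknown IUPAC code: ", paste(bad, collapse = ", "))
  counts <- sapply(chars, function(ch) {
    col <- rep(residual, 4); names(col) <- BASES
    col[iupac_bases[[ch]]] <- dominant
    col
  })
  pfm(motif_id, counts, name)
}

#' Synthetic muscle-motif models
#'
#' Five consensus-derived PFMs mimicking the canonical muscle regulators used
#' in CRM prediction: a MEF2-like AT-rich box, an SRF-like CArG box, a
#' Myf-like E-box, a TEAD-like MCAT element and an SP1-like GC box. These are
#' synthetic stand-ins constructed in code, not curated database matrices.
#'
#' @return named list of [pfm] objects.
#' @export
default_motifs <- function() {
  list(
    MEF2 = consensus_pfm("MEF2", "CTAWWWWTAG", "MEF2-like"),
    SRF  = consensus_pfm("SRF",  "CCWWWWWWGG", "SRF-like CArG"),
    MYF  = consensus_pfm("MYF",  "CAGCTG",     "Myf-like E-box"),
    TEAD = consensus_pfm("TEAD", "GGAATG",     "TEAD-like MCAT"),
    SP1  = consensus_pfm("SP1",  "GGGGCGGGG",  "SP1-like GC box")
  )
}

sample_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Sample a word from the PFM column distributions with relative score >= 0.85
# under the derived PWM; falls back to the consensus word.
sample_site_word <- function(p, pwm, max_try = 20L) {
  probs <- sweep(p$counts, 2L, colSums(p$counts), "/")
  L <- ncol(probs)
  for (i in seq_len(max_try)) {
    word <- vapply(seq_len(L),
                   function(j) sample(BASES, 1L, prob = probs[, j]), "")
    s <- sum(pwm$weights[cbind(match(word, BASES), seq_len(L))])
    rel <- (s - pwm$score_min) / (pwm$score_max - pwm$score_min)
    if (rel >= 0.85) return(paste(word, collapse = ""))
  }
  paste(BASES[apply(probs, 2L, which.max)], collapse = "")
}

#' Generate a synthetic genome with planted CRMs
#'
#' The background is i.i.d. with the configured GC fraction. Each planted CRM
#' spans `crm_length` bp regenerated with GC raised by `crm_gc_shift` and
#' carries `motifs_per_crm` non-overlapping high-scoring TFBS words sampled
#' from the supplied motif models (random strand). CRMs are placed without
#' mutual overlap; failure to place them raises an error.
#'
#' @param config [sim_config()].
#' @param pfms list of [pfm] motif models, default [default_motifs()].
#' @param chrom chromosome name for the single synthetic sequence.
#' @return list with `sequence` (named character), `regions`
#'   (`crm_regions` truth), and `sites` (truth data.frame of planted TFBS
#'   with genome coordinates and per-CRM offsets).
#' @export
gen_genome <- function(config, pfms = default_motifs(), chrom = "chrS") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$genome_length
    bases <- sample_bases(n, config$background_gc)
    starts <- integer(0)
    if (config$n_crm > 0L) {
      gap <- 50L
      for (i in seq_len(config$n_crm)) {
        placed <- FALSE
        for (try in 1:200) {
          s <- sample.int(n - config$crm_length, 1L) - 1L
          if (!any(s < starts + config$crm_length + gap &
                     s + config$crm_length + gap > starts)) {
            starts <- c(starts, s); placed <- TRUE; break
          }
        }
        if (!placed) stop("could not place ", config$n_crm,
                          " non-overlapping CRMs in ", n, " bp")
      }
      starts <- sort(starts)
    }
    sites <- list()
    pwms <- lapply(pfms, pfm_to_pwm)
    for (k in seq_along(starts)) {
      s <- starts[k]
      local <- sample_bases(config$crm_length,
                            config$background_gc + config$crm_gc_shift)
      taken_s <- integer(0); taken_e <- integer(0)
      for (m in seq_len(config$motifs_per_crm)) {
        pi <- ((k + m - 2L) %% length(pfms)) + 1L
        word <- sample_site_word(pfms[[pi]], pwms[[pi]])
        L <- nchar(word)
        off <- NA
        for (try in 1:100) {
          o <- sample.int(config$crm_length - L + 1L, 1L) - 1L
          if (!any(o < taken_e & o + L > taken_s)) { off <- o; break }
        }
        if (is.na(off)) next
        strand <- sample(c("+", "-"), 1L)
        planted <- if (strand == "+") word else revcomp(word)
        local[(off + 1L):(off + L)] <- strsplit(planted, "")[[1L]]
        taken_s <- c(taken_s, off); taken_e <- c(taken_e, off + L)
        sites[[length(sites) + 1L]] <- data.frame(
          region_id = paste0("crm", k), motif_id = pfms[[pi]]$motif_id,
          start = s + off, end = s + off + L, offset = off,
          strand = strand, stringsAsFactors = FALSE)
      }
      bases[(s + 1L):(s + config$crm_length)] <- local
    }
    regions <- if (length(starts))
      genomic_regions(chrom, starts, starts + config$crm_length,
                      region_id = paste0("crm", seq_along(starts)))
    else genomic_regions(chrom, 0L, 1L)[0, ]
    sites <- if (length(sites)) do.call(rbind, sites) else
      data.frame(region_id = character(), motif_id = character(),
                 start = integer(), end = integer(), offset = integer(),
                 strand = character())
    sites$chrom <- rep(chrom, nrow(sites))
    list(sequence = setNames(paste(bases, collapse = ""), chrom),
         regions = regions, sites = sites)
  })
}

#' Generate conservation tracks over a synthetic genome
#'
#' Produces a bounded phastCons-like track and an unbounded phyloP-like
#' track. Background scores are low-mean noise; positions inside planted
#' CRMs are lifted by `conservation_elevation` and planted TFBS positions are
#' further lifted so that their mean is `site_elevation_factor` times the CRM
#' flank mean. With elevation 0 the track is statistically flat.
#'
#' @param truth output of [gen_genome()].
#' @param config [sim_config()].
#' @return list with elements `bounded` and `unbounded`, both [score_track].
#' @export
gen_conservation_track <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nchar(truth$sequence[[1L]])
  chrom <- names(truth$sequence)[1L]
  e <- config$conservation_elevation
  sf <- config$site_elevation_factor
  with_seed(config$seed + 1L, {
    crm_mask <- logical(n); site_mask <- logical(n)
    for (i in seq_len(nrow(truth$regions)))
      crm_mask[(truth$regions$start[i] + 1L):truth$regions$end[i]] <- TRUE
    for (i in seq_len(nrow(truth$sites)))
      site_mask[(truth$sites$start[i] + 1L):truth$sites$end[i]] <- TRUE
    b <- rbeta(n, 1, 9)                       # mean 0.1 background
    u <- rnorm(n, 0.1, 0.1)
    if (e > 0) {
      flank <- crm_mask & !site_mask
      b[flank] <- b[flank] + e
      u[flank] <- u[flank] + e
      b[site_mask] <- sf * (b[site_mask] + e)
      u[site_mask] <- sf * (u[site_mask] + e)
    }
    list(bounded = score_track(chrom, 0L, pmin(pmax(b, 0), 1), "bounded01"),
         unbounded = score_track(chrom, 0L, u, "unbounded"))
  })
}

#' Generate dual-luciferase plate measurements
#'
#' For each insert x clone x phase x cell type x technical replicate, renilla
#' is lognormal and firefly is renilla times a baseline ratio times the
#' planted effect (`plate_effect_fold` in myotubes for positive inserts, 1
#' otherwise) times lognormal noise. Phase 1 covers fibroblast, myoblast and
#' myotube; phase 2 only myoblast and myotube (independent plasmid
#' preparations, hence independent draws). With probability `fail_rate` both
#' channels fall below 1000 LRU (failed transfection).
#'
#' @param inserts data.frame with columns `insert_id`, `set_label`,
#'   `positive` (logical planted effect).
#' @param config [sim_config()].
#' @param n_clones clones per insert.
#' @param phases subset of `c(1, 2)`.
#' @param baseline_ratio firefly/renilla baseline.
#' @return data.frame in the plate CSV schema.
#' @export
gen_plate_data <- function(inserts, config, n_clones = 2L, phases = c(1L, 2L),
                           baseline_ratio = 2) {
  stopifnot(inherits(config, "sim_config"),
            all(c("insert_id", "set_label", "positive") %in% names(inserts)))
  sdlog <- sqrt(log(1 + config$plate_cv^2))
  with_seed(config$seed + 2L, {
    rows <- list()
    for (i in seq_len(nrow(inserts))) {
      for (cl in seq_len(n_clones)) {
        clone_id <- paste0(inserts$insert_id[i], "_c", cl)
        for (ph in phases) {
          cells <- if (ph == 1L) c("fibroblast", "myoblast", "myotube")
                   else c("myoblast", "myotube")
          for (ct in cells) for (rep in 1:2) {
            if (runif(1) < config$fail_rate) {
              ff <- runif(1, 100, 999); rr <- runif(1, 100, 999)
            } else {
              rr <- exp(rnorm(1, log(2e4), sdlog))
              eff <- if (isTRUE(inserts$positive[i]) && ct == "myotube")
                config$plate_effect_fold else 1
              ff <- rr * baseline_ratio * eff * exp(rnorm(1, 0, sdlog))
            }
            rows[[length(rows) + 1L]] <- data.frame(
              clone_id = clone_id, insert_id = inserts$insert_id[i],
              set_label = inserts$set_label[i], phase = ph, cell_type = ct,
              tech_rep = rep, firefly_lru = ff, renilla_lru = rr,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate ChIP-seq-like peaks over regions
#'
#' Each region is overlapped by one peak with probability
#' `peak_overlap_probs[status]`, where status is taken from the region's
#' `responder` flag. Peaks extend beyond the region by random flanks.
#'
#' @param regions `crm_regions` with a logical `responder` column.
#' @param config [sim_config()].
#' @param name peak-set name (e.g. `"MyoD_MT"`).
#' @return data.frame of peak intervals (`chrom, start, end, name`).
#' @export
gen_peaks <- function(regions, config, name = "peaks") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(regions$responder)) stop("regions need a 'responder' column")
  probs <- config$peak_overlap_probs
  with_seed(config$seed + 3L, {
    rows <- list()
    for (i in seq_len(nrow(regions))) {
      p <- unname(probs[if (isTRUE(regions$responder[i])) "responder"
                        else "non_responder"])
      if (runif(1) < p) {
        f1 <- sample(20:200, 1L); f2 <- sample(20:200, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = regions$chrom[i],
          start = max(0L, regions$start[i] - f1),
          end = regions$end[i] + f2, name = name, stringsAsFactors = FALSE)
      }
    }
    if (!length(rows))
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character()))
    do.call(rbind, rows)
  })
}
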