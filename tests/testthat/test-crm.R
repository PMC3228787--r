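test_that("search regions: flank, exon subtraction, alternative-TSS holes", {
  tss <- data.frame(chrom = "chr1", pos = 50000L)
  r <- build_search_regions(tss)
  expect_equal(r$start, 40000L)
  expect_equal(r$end, 60000L)

  r2 <- build_search_regions(tss, coding_exons = data.frame(
    chrom = "chr1", start = 49000L, end = 49500L))
  expect_equal(r2$start, c(40000L, 49500L))
  expect_equal(r2$end, c(49000L, 60000L))

  r3 <- build_search_regions(tss, alt_tss = data.frame(chrom = "chr1",
                                                       pos = 55000L))
  expect_equal(r3$start, c(40000L, 55050L))
  expect_equal(r3$end, c(54950L, 60000L))

  # TSS near the chromosome start is clipped
  r4 <- build_search_regions(data.frame(chrom = "chr1", pos = 3000L),
                             chrom_lengths = c(chr1 = 8000L))
  expect_equal(r4$start, 0L)
  expect_equal(r4$end, 8000L)
  expect_error(build_search_regions(tss, tss_flank = 40L,
                                    alt_tss_exclusion = 50L))
})

test_that("window features match a brute-force recount", {
  set.seed(31)
  reg <- genomic_regions("c", 0L, 1000L, "r1")
  n <- 40L
  hits <- data.frame(region_id = "r1",
                     offset = sample(0:990, n, replace = TRUE),
                     length = sample(6:10, n, replace = TRUE),
                     strand = "+",
                     motif_id = sample(c("M1", "M2"), n, replace = TRUE),
                     abs_score = runif(n), rel_score = runif(n, 0.8, 1))
  wf <- window_features(hits, reg, c("M1", "M2"), window = 200L, step = 50L)
  expect_equal(nrow(wf), 20L)
  for (i in seq_len(nrow(wf))) {
    for (m in c("M1", "M2")) {
      inwin <- hits$motif_id == m & hits$offset < wf$win_end[i] &
        hits$offset + hits$length > wf$win_start[i]
      expect_equal(wf[[paste0("count_", m)]][i], sum(inwin))
      expect_equal(wf[[paste0("best_", m)]][i],
                   if (any(inwin)) max(hits$rel_score[inwin]) else 0)
    }
  }
  # empty hit list gives all-zero features
  wf0 <- window_features(hits[0, ], reg, c("M1", "M2"))
  expect_true(all(wf0$count_M1 == 0 & wf0$best_M2 == 0))
})

test_that("LRA training: null, separable, and sign recovery", {
  set.seed(13)
  f <- function(n, mu) data.frame(best_M = rnorm(n, mu, 0.1),
                                  count_M = rnorm(n, mu, 0.1))
  same <- f(100, 0.5)
  m0 <- train_lra(same, same)
  expect_lt(max(abs(m0$weights)), 1e-6)
  expect_equal(roc_auc(lra_score(same, m0), rep(c(TRUE, FALSE), 50))$auc,
               0.5, tolerance = 0.15)

  pos <- f(100, 1); neg <- f(100, 0)
  m1 <- train_lra(pos, neg)
  sc <- lra_score(rbind(pos, neg), m1)
  expect_equal(roc_auc(sc, rep(c(TRUE, FALSE), each = 100))$auc, 1)

  # parameter recovery from a known logistic model
  n <- 2000L
  X <- data.frame(best_A = rnorm(n), count_A = rnorm(n),
                  best_B = rnorm(n), count_B = rnorm(n))
  w_true <- c(2, -1.5, 1, -2)
  p <- stats::plogis(as.matrix(X) %*% w_true)
  y <- runif(n) < p
  m2 <- train_lra(X[y, ], X[!y, ])
  expect_equal(sign(unname(m2$weights)), sign(w_true))
  expect_error(train_lra(pos[0, ], neg))
})

test_that("SP1-only predictions are excluded, mixed ones retained", {
  reg <- genomic_regions("c", 0L, 400L, "r1")
  mk_hit <- function(off, motif) data.frame(
    region_id = "r1", offset = off, length = 8L, strand = "+",
    motif_id = motif, abs_score = 5, rel_score = 0.95)
  model <- structure(list(weights = c(best_SP1 = 1, count_SP1 = 1,
                                      best_MEF2 = 1, count_MEF2 = 1),
                          intercept = 0,
                          features = c("best_SP1", "count_SP1",
                                       "best_MEF2", "count_MEF2")),
                     class = "lra_model")
  sp1_only <- mk_hit(100L, "SP1")
  wf <- window_features(sp1_only, reg, c("SP1", "MEF2"))
  expect_equal(nrow(predict_crms(wf, model, sp1_only, 0.5)), 0L)

  mixed <- rbind(sp1_only, mk_hit(120L, "MEF2"))
  wf2 <- window_features(mixed, reg, c("SP1", "MEF2"))
  pred <- predict_crms(wf2, model, mixed, 0.5)
  expect_equal(nrow(pred), 1L)
  expect_equal(pred$n_non_sp1, 1L)
  # oracle: exclusion is exactly "zero non-SP1 hits"
  expect_true(all(pred$n_non_sp1 > 0))
})

test_that("prediction merging is idempotent and stays inside regions", {
  cfg <- sim_config(seed = 17, genome_length = 20000L, n_crm = 4L)
  g <- gen_genome(cfg)
  pwms <- lapply(default_motifs(), pfm_to_pwm)
  hits <- resolve_overlaps(scan_regions(g$sequence, pwms, 0.8))
  reg <- genomic_regions("chrS", 0L, 20000L, "chrS")
  wf <- window_features(hits, reg, names(pwms))
  in_crm <- vapply(seq_len(nrow(wf)), function(i)
    any(wf$win_start[i] < g$regions$end & wf$win_end[i] > g$regions$start),
    TRUE)
  model <- train_lra(wf[in_crm, ], wf[!in_crm, ])
  pred <- predict_crms(wf, model, hits, 0.5)
  expect_gt(nrow(pred), 0L)
  expect_true(all(pred$start >= 0L & pred$end <= 20000L))
  # merged predictions do not touch or overlap each other
  ord <- order(pred$start)
  if (nrow(pred) > 1L)
    expect_true(all(pred$start[ord][-1L] > pred$end[ord][-nrow(pred)]))
})

test_that("cluster score: base cases and monotonicity under added hits", {
  empty <- data.frame(offset = integer(), length = integer(),
                      rel_score = numeric())
  expect_equal(cluster_score(empty, 200L), 0)
  two <- data.frame(offset = c(0L, 50L), length = 10L, rel_score = 1)
  expect_equal(cluster_score(two, 200L), 2)
  # gap penalty subtracts the uncovered fraction
  expect_equal(cluster_score(two, 200L, gap_penalty = 1), 2 - 180 / 200)
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(1:10, 1L)
    h <- data.frame(offset = sample(0:180, n, replace = TRUE),
                    length = sample(5:15, n, replace = TRUE),
                    rel_score = runif(n, 0.5, 1))
    extra <- data.frame(offset = sample(0:180, 1L),
                        length = sample(5:15, 1L),
                        rel_score = runif(1, 0.5, 1))
    expect_gte(cluster_score(rbind(h, extra), 200L),
               cluster_score(h, 200L) - 1e-12)
  }
})

test_that("planted clusters are recovered at high recall and low FP rate", {
  cfg <- sim_config(seed = 29, genome_length = 50000L, n_crm = 8L,
                    motifs_per_crm = 4L)
  g <- gen_genome(cfg)
  pwms <- lapply(default_motifs(), pfm_to_pwm)
  hits <- resolve_overlaps(scan_regions(g$sequence, pwms, 0.8))
  reg <- genomic_regions("chrS", 0L, 50000L, "chrS")
  wf <- window_features(hits, reg, names(pwms))
  in_crm <- vapply(seq_len(nrow(wf)), function(i)
    any(wf$win_start[i] < g$regions$end & wf$win_end[i] > g$regions$start),
    TRUE)
  model <- train_lra(wf[in_crm, ], wf[!in_crm, ])
  wf$lra_score <- lra_score(wf, model)
  # sweep cutoffs; find best recall with at most 1 false merged
  # prediction per 10 kb (5 allowed on this genome)
  best_recall <- 0
  for (cut in unique(round(wf$lra_score, 2))) {
    pred <- predict_crms(wf, model, hits, cut)
    if (!nrow(pred)) next
    hit_truth <- vapply(seq_len(nrow(pred)), function(i)
      any(pred$start[i] < g$regions$end & pred$end[i] > g$regions$start),
      TRUE)
    fp <- sum(!hit_truth)
    recall <- mean(vapply(seq_len(nrow(g$regions)), function(i)
      any(g$regions$start[i] < pred$end & g$regions$end[i] > pred$start),
      TRUE))
    if (fp <= 5 && recall > best_recall) best_recall <- recall
  }
  expect_gt(best_recall, 0.8)
})

test_that("conservation filter keeps elevated predictions, drops the rest", {
  cfg <- sim_config(seed = 37, genome_length = 20000L, n_crm = 4L)
  g <- gen_genome(cfg)
  tr <- gen_conservation_track(g, cfg)
  reg <- genomic_regions("chrS", 0L, 20000L, "chrS")
  pred <- data.frame(region_id = "chrS",
                     start = c(g$regions$start[1L], 100L),
                     end = c(g$regions$end[1L], 300L),
                     lra_score = 0.9, n_hits = 1L, n_non_sp1 = 1L)
  kept <- conservation_filter(pred, tr$bounded, 0.7, reg)
  expect_true(g$regions$start[1L] %in% kept$start)
  expect_identical(conservation_filter(pred, tr$bounded, 0, reg), pred)
  expect_equal(nrow(conservation_filter(pred, tr$bounded, 1.01, reg)), 0L)
})
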