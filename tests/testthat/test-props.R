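test_that("composition: GC, skews and dinucleotide frequencies", {
  p <- composition("GGCC")
  expect_equal(p$gc_content, 1)
  expect_equal(p$gc_skew, 0)
  expect_equal(unname(composition("AAAA")$dinuc["AA"]), 1)
  p3 <- composition("ACGT")
  expect_equal(unname(p3$dinuc[c("AC", "CG", "GT")]), rep(1 / 3, 3))
  expect_equal(composition("GGGGCC")$gc_skew, (4 - 2) / 6)
  expect_equal(composition("AANNCC")$gc_content, 0.5)  # Ns dropped
  expect_error(composition("NNNN"))
})

test_that("pooled composition equals the length-weighted per-region average", {
  set.seed(3)
  seqs <- vapply(1:5, function(i) random_seq(sample(50:300, 1L)), "")
  pooled <- composition(paste(seqs, collapse = ""))$mono
  lens <- nchar(seqs)
  per <- sapply(seqs, function(s) composition(s)$mono)
  weighted <- as.numeric(per %*% lens) / sum(lens)
  # pooled counting adds one boundary-crossing dinucleotide per junction,
  # but mononucleotide pooling is exact
  expect_equal(unname(pooled), weighted, tolerance = 1e-12)
})

test_that("rank-sum comparison matches an exact enumeration oracle", {
  set.seed(5)
  repeat {               # tie-free fixture so the exact test applies
    a <- vapply(1:6, function(i) random_seq(97, gc = 0.6), "")
    b <- vapply(1:7, function(i) random_seq(101, gc = 0.4), "")
    xa <- vapply(a, function(s) composition(s)$gc_content, 0)
    xb <- vapply(b, function(s) composition(s)$gc_content, 0)
    if (!anyDuplicated(c(xa, xb))) break
  }
  got <- compare_composition(a, b, features = "gc_content")$p_value
  pooled <- c(xa, xb)
  n1 <- length(xa)
  combs <- utils::combn(length(pooled), n1)
  W <- apply(combs, 2L, function(idx) sum(rank(pooled)[idx])) -
    n1 * (n1 + 1) / 2
  w_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p_exact <- min(1, 2 * min(mean(W <= w_obs), mean(W >= w_obs)))
  expect_equal(got, p_exact, tolerance = 1e-10)
})

test_that("planted GC shifts are detected at study-scale sample sizes", {
  # 0.54 vs 0.51 GC, 400-bp regions, 19 vs 250 regions
  hits <- vapply(1:7, function(s) {
    set.seed(s * 13)
    resp <- vapply(1:19, function(i) random_seq(400, gc = 0.54), "")
    non <- vapply(1:250, function(i) random_seq(400, gc = 0.51), "")
    compare_composition(resp, non, features = "gc_content")$p_value < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.5)
})

test_that("conservation summary: run rule, make-up fraction, brute force", {
  tr <- score_track("c", 0L, rep(0.8, 100))
  s <- conservation_summary(list(start = 0L, end = 100L), tr)
  expect_equal(s$mean_score, 0.8)
  expect_equal(s$max_score, 0.8)
  expect_equal(s$conserved_fraction, 1)
  expect_true(s$is_conserved)

  # a 19-bp run at 0.9 does not satisfy the 20-bp requirement
  tr19 <- score_track("c", 0L, c(rep(0.9, 19), rep(0, 81)))
  s19 <- conservation_summary(list(start = 0L, end = 100L), tr19)
  expect_false(s19$is_conserved)
  expect_equal(s19$conserved_fraction, 0.19)

  s0 <- conservation_summary(list(start = 0L, end = 50L),
                             score_track("c", 0L, rep(0, 50)))
  expect_equal(s0$conserved_fraction, 0)
  expect_false(s0$is_conserved)

  # exactly-0.7 bases count for the run rule (>=) but not the make-up (>)
  tr07 <- score_track("c", 0L, rep(0.7, 30))
  s07 <- conservation_summary(list(start = 0L, end = 30L), tr07)
  expect_true(s07$is_conserved)
  expect_equal(s07$conserved_fraction, 0)

  set.seed(19)
  for (rep in 1:10) {
    n <- sample(100:10000, 1L)
    v <- pmin(1, pmax(0, rbeta(n, 0.4, 0.6)))
    tr <- score_track("c", 0L, v)
    got <- conservation_summary(list(start = 0L, end = n), tr)
    ok20 <- FALSE                 # brute-force window scan
    if (n >= 20L) for (i in seq_len(n - 19L))
      if (all(v[i:(i + 19L)] >= 0.7)) { ok20 <- TRUE; break }
    expect_equal(got$is_conserved, ok20)
    expect_equal(got$conserved_fraction, sum(v > 0.7) / n)
  }
})

test_that("set-level conservation pools lengths, not per-region fractions", {
  reg <- genomic_regions("c", c(0L, 100L), c(100L, 400L),
                         set_label = c("muscle", "muscle"))
  tr <- score_track("c", 0L, c(rep(0.9, 100), rep(0, 300)))
  s <- summarize_conservation_sets(reg, tr)
  expect_equal(s$conserved_fraction, 100 / 400)   # pooled, not mean(1, 0)
  expect_equal(s$mean_score, mean(c(0.9, 0)))
  expect_equal(s$avg_max_score, mean(c(0.9, 0)))
})

test_that("TSS distance and CpG-island association boundaries", {
  reg <- list(start = 1000L, end = 1400L)
  expect_equal(tss_distance(reg, c(1200L, 5000L)), 0)
  expect_equal(tss_distance(reg, 900L), 100)
  expect_equal(tss_distance(reg, 1500L), 101)

  isl <- function(s, e) data.frame(start = s, end = e)
  expect_true(cpg_island_assoc(reg, isl(2300L, 2350L)))
  expect_false(cpg_island_assoc(reg, isl(2400L, 2500L)))  # starts at end+1000
  expect_true(cpg_island_assoc(reg, isl(2399L, 2500L)))   # 1 bp into flank
})

test_that("TFBS depth: folds, selection boundary and uniform tracks", {
  reg <- genomic_regions("c", 0L, 1000L, "r1", set_label = "muscle")
  hits <- data.frame(region_id = "r1", offset = c(100L, 300L), length = 50L,
                     strand = "+", motif_id = c("M1", "M2"),
                     abs_score = 5, rel_score = 0.9)
  v <- rep(0.25, 1000)
  v[101:150] <- 0.5                 # M1 sites at exactly 2-fold
  v[301:350] <- 0.25                # M2 sites at 1-fold
  res <- tfbs_depth(reg, hits, score_track("c", 0L, v, "unbounded"))
  m1 <- res$per_tf[res$per_tf$motif_id == "M1", ]
  expect_equal(m1$fold, 2)
  expect_equal(res$selected_tfs, "M1")   # boundary inclusive, M2 at 1x out

  resu <- tfbs_depth(reg, hits, score_track("c", 0L, rep(0.3, 1000),
                                            "unbounded"))
  expect_true(all(abs(resu$per_tf$fold - 1) < 1e-12))
  expect_equal(length(resu$selected_tfs), 0L)

  # negative non-site mean: every TF skipped with a warning
  w <- capture_warnings(
    res_neg <- tfbs_depth(reg, hits, score_track("c", 0L, rep(-0.1, 1000),
                                                 "unbounded")))
  expect_true(length(w) >= 1L && all(grepl("skipped", w)))
  expect_equal(nrow(res_neg$per_tf), 0L)
})

test_that("synthetic site elevation factor 2 yields mean folds near 2", {
  cfg <- sim_config(seed = 51, genome_length = 30000L, n_crm = 10L,
                    conservation_elevation = 0.5, site_elevation_factor = 2)
  g <- gen_genome(cfg)
  tr <- gen_conservation_track(g, cfg)
  reg <- g$regions
  reg$set_label <- rep("muscle", nrow(reg))
  class(reg) <- c("crm_regions", "data.frame")
  hits <- data.frame(region_id = g$sites$region_id,
                     offset = g$sites$offset,
                     length = g$sites$end - g$sites$start,
                     strand = g$sites$strand, motif_id = g$sites$motif_id,
                     abs_score = 1, rel_score = 1)
  res <- tfbs_depth(reg, hits, tr$unbounded)
  expect_equal(mean(res$per_tf$fold), 2, tolerance = 0.2)
})
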