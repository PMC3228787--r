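test_that("log-odds conversion: uniform PFM gives zero weights and bounds", {
  p <- pfm("U", matrix(6, 4, 5))
  w <- pfm_to_pwm(p)
  expect_true(all(abs(w$weights) < 1e-12))
  expect_equal(w$score_min, 0)
  expect_equal(w$score_max, 0)
  # every window of a degenerate (flat) model scores rel 1
  h <- scan_pwm("ACGTACGT", w, 0.9)
  expect_true(all(h$rel_score == 1))
})

test_that("score bounds equal exhaustive word enumeration", {
  set.seed(42)
  for (rep in 1:3) {
    p <- random_pfm("R", L = 5L)
    w <- pfm_to_pwm(p)
    words <- as.matrix(expand.grid(rep(list(1:4), 5)))
    scores <- apply(words, 1L, function(idx)
      sum(w$weights[cbind(idx, 1:5)]))
    expect_equal(w$score_min, min(scores), tolerance = 1e-12)
    expect_equal(w$score_max, max(scores), tolerance = 1e-12)
  }
  # the consensus word attains relative score 1
  w <- pfm_to_pwm(fix_pfm())
  h <- scan_pwm("GGACGTAGG", w, 0.99)
  expect_equal(h$offset[h$strand == "+"], 2L)
  expect_equal(h$rel_score[h$strand == "+"], 1)
})

test_that("scanning matches the exhaustive per-window oracle", {
  set.seed(7)
  for (rep in 1:3) {
    p <- random_pfm(paste0("M", rep), L = sample(4:8, 1L))
    w <- pfm_to_pwm(p)
    s <- random_seq(200)
    # inject some Ns to exercise background-expected scoring
    substr(s, 50, 52) <- "NNN"
    got <- scan_pwm(s, w, 0.7)
    want <- oracle_scan(s, w, 0.7)
    ord <- order(got$offset, got$strand)
    ordw <- order(want$offset, want$strand)
    expect_equal(got$offset[ord], want$offset[ordw])
    expect_equal(got$strand[ord], want$strand[ordw])
    expect_equal(got$abs_score[ord], want$abs_score[ordw], tolerance = 1e-10)
  }
})

test_that("reverse-complemented consensus hits the minus strand, same score", {
  w <- pfm_to_pwm(fix_pfm())
  fwd <- scan_pwm("GGACGTAGG", w, 0.95)
  rev <- scan_pwm(revcomp("GGACGTAGG"), w, 0.95)
  expect_equal(sort(fwd$rel_score), sort(rev$rel_score))
  expect_true(any(rev$strand == "-"))
  # too-short sequence yields an empty frame
  expect_equal(nrow(scan_pwm("ACG", w, 0.5)), 0L)
})

test_that("relative score is invariant under affine weight rescaling", {
  w <- pfm_to_pwm(fix_pfm())
  s <- random_seq(100)
  h1 <- scan_pwm(s, w, 0)
  w2 <- w
  w2$weights <- 3 * w$weights + 0.25          # affine map per cell
  w2$score_min <- 3 * w$score_min + 0.25 * ncol(w$weights)
  w2$score_max <- 3 * w$score_max + 0.25 * ncol(w$weights)
  h2 <- scan_pwm(s, w2, 0)
  expect_equal(h1$rel_score, h2$rel_score, tolerance = 1e-10)
})

test_that("overlap resolution keeps the best same-motif site only", {
  h <- data.frame(region_id = "r", offset = c(0L, 9L), length = 10L,
                  strand = "+", motif_id = "M",
                  abs_score = c(5, 3), rel_score = c(0.9, 0.8))
  expect_equal(resolve_overlaps(h)$abs_score, 5)
  # non-overlapping same-motif hits are both kept
  h$offset <- c(0L, 10L)
  expect_equal(nrow(resolve_overlaps(h)), 2L)
  # overlapping hits of different motifs are both kept
  h$offset <- c(0L, 5L); h$motif_id <- c("M1", "M2")
  expect_equal(nrow(resolve_overlaps(h)), 2L)
})

test_that("overlap resolution matches an independent greedy-by-score oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 30L
    h <- data.frame(region_id = "r",
                    offset = sample(0:80, n, replace = TRUE),
                    length = sample(5:12, n, replace = TRUE),
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    motif_id = sample(c("A", "B"), n, replace = TRUE),
                    abs_score = round(runif(n, 1, 10), 3))
    h$rel_score <- h$abs_score / 10
    got <- resolve_overlaps(h)
    for (m in unique(h$motif_id)) {
      hm <- h[h$motif_id == m, ]
      hm <- hm[order(-hm$abs_score, hm$offset, hm$strand != "+"), ]
      kept <- hm[0, ]
      for (i in seq_len(nrow(hm))) {
        cand <- hm[i, ]
        if (!any(cand$offset < kept$offset + kept$length &
                   cand$offset + cand$length > kept$offset))
          kept <- rbind(kept, cand)
      }
      gm <- got[got$motif_id == m, ]
      expect_setequal(paste(gm$offset, gm$strand, gm$abs_score),
                      paste(kept$offset, kept$strand, kept$abs_score))
      # no two retained same-motif hits overlap
      gm <- gm[order(gm$offset), ]
      if (nrow(gm) > 1L)
        expect_true(all(gm$offset[-1L] >=
                          (gm$offset + gm$length)[-nrow(gm)]))
    }
  }
})

test_that("matrix similarity: identity scores 2, point-mass opposition 0", {
  p <- fix_pfm()
  expect_equal(matrix_similarity(p, p)$score, 2)
  pa <- pfm("A4", matrix(c(24, 0, 0, 0), 4, 4))
  pt <- pfm("T4", matrix(c(0, 0, 0, 24), 4, 4))
  # given-strand comparison: maximal L1 distance in every column
  expect_equal(matrix_similarity(pa, pt, both_strands = FALSE)$score, 0)
  # with both orientations poly-T is the reverse complement of poly-A
  expect_equal(matrix_similarity(pa, pt)$score, 2)
})

test_that("matrix similarity recovers shifts and is symmetric", {
  set.seed(3)
  inner <- random_pfm("IN", 6L)
  shifted <- pfm("SH", cbind(c(5, 5, 5, 5), inner$counts[, 1:5]))
  sim <- matrix_similarity(inner, shifted, both_strands = FALSE)
  expect_equal(sim$score, 2)       # the shifted copy aligns perfectly
  expect_equal(sim$offset, -1L)
  expect_gt(sim$score, matrix_similarity(inner, random_pfm("X", 6L),
                                         both_strands = FALSE)$score)
  for (rep in 1:5) {
    a <- random_pfm("a", sample(4:8, 1L))
    b <- random_pfm("b", sample(4:8, 1L))
    expect_equal(matrix_similarity(a, b)$score,
                 matrix_similarity(b, a)$score, tolerance = 1e-10)
    expect_lte(matrix_similarity(a, b)$score, 2)
  }
  expect_error(matrix_similarity(fix_pfm(),
                                 pfm("S", matrix(1, 4, 4)[, 1:3])))
})
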