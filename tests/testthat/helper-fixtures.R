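# Shared fixtures, built in code.

# A sharp 5-column motif with a unique consensus word ACGTA.
fix_pfm <- function(id = "TEST") {
  pfm(id, matrix(c(20, 1, 1, 1,   # A
                   1, 20, 1, 1,   # C
                   1, 1, 20, 1,   # G
                   1, 1, 1, 20,   # T
                   20, 1, 1, 1),
                 nrow = 4), name = id)
}

random_pfm <- function(id, L = 6L) {
  pfm(id, matrix(sample(0:30, 4L * L, replace = TRUE) + 1L, nrow = 4L))
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Independent brute-force window scoring used as the scan oracle.
oracle_scan <- function(seq, pwm, threshold) {
  L <- ncol(pwm$weights)
  chars <- strsplit(seq, "")[[1L]]
  score_word <- function(word) {
    sum(vapply(seq_len(L), function(j) {
      b <- word[j]
      if (b == "N") sum(pwm$weights[, j] * pwm$background)
      else pwm$weights[b, j]
    }, 0))
  }
  out <- list()
  for (i in seq_len(nchar(seq) - L + 1L)) {
    word <- chars[i:(i + L - 1L)]
    for (strand in c("+", "-")) {
      w <- if (strand == "+") word else
        rev(chartr("ACGTN", "TGCAN", word))
      s <- score_word(w)
      rel <- (s - pwm$score_min) / (pwm$score_max - pwm$score_min)
      if (rel >= threshold - 1e-12)
        out[[length(out) + 1L]] <- data.frame(
          offset = i - 1L, strand = strand, abs_score = s, rel_score = rel)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(offset = integer(), strand = character(),
               abs_score = numeric(), rel_score = numeric())
}

# Plate rows for one clone/cell-type with explicit channel values.
well_row <- function(firefly, renilla, clone = "c1", insert = "i1",
                     phase = 1L, cell = "myotube", rep = 1L) {
  data.frame(clone_id = clone, insert_id = insert, set_label = "muscle",
             phase = phase, cell_type = cell, tech_rep = rep,
             firefly_lru = firefly, renilla_lru = renilla,
             stringsAsFactors = FALSE)
}

extdata <- function(f) system.file("extdata", f, package = "crmscreen")
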