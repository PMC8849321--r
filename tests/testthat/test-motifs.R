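test_that("JASPAR parsing applies the pseudocount per cell and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M1 test", "A [ 1 1 1 ]", "C [ 1 1 1 ]", "G [ 1 1 1 ]",
               "T [ 1 1 1 ]"), tmp)
  p <- read_jaspar(tmp, pseudocount = 0)
  expect_equal(unname(p$probs), matrix(0.25, 3, 4))
  expect_equal(p$id, "M1")

  writeLines(c(">M2", "A 10", "C 0", "G 0", "T 0"), tmp)
  p <- read_jaspar(tmp, pseudocount = 0.1)
  expect_equal(unname(p$probs[1, ]), c(10.1, 0.1, 0.1, 0.1) / 10.4)

  q <- strong_pwm(7, seed = 2)
  out <- withr::local_tempfile(fileext = ".pfm")
  write_jaspar(q, out)
  back <- read_jaspar(out, pseudocount = 0)
  expect_equal(back$probs, q$probs, tolerance = 1e-9)

  writeLines(c(">M3", "A 1 2", "C 1", "G 1 2", "T 1 2"), tmp)
  expect_error(read_jaspar(tmp), "ragged")
})

test_that("log-odds window scores match closed forms and a position loop", {
  expect_equal(score_window(uniform_pwm(6), "ACGTAC"), 0)
  # three probability-1 A columns against uniform background: 3 * log2(4)
  expect_equal(score_window(consensus_pwm("AAA"), "AAA"), 6)
  expect_true(is.na(score_window(strong_pwm(4), "ACNT")))
  expect_error(score_window(strong_pwm(4), "ACGTA"), "length")

  set.seed(5)
  for (i in 1:20) {
    w <- sample(3:10, 1)
    p <- strong_pwm(w, seed = i)
    s <- rand_seq(w)
    codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    want <- 0
    for (j in seq_len(w))
      want <- want + log2(p$probs[j, codes[j]] / p$background[codes[j]])
    expect_equal(score_window(p, s), unname(want), tolerance = 1e-9)
  }
})

test_that("score null has closed-form extremes and full mass", {
  p5 <- consensus_pwm("ACGTA")
  null <- build_score_null(p5)
  # max score only from the consensus word itself
  expect_equal(null$tail[length(null$tail)], 0.25^5)
  # zero-probability windows score -Inf and carry p-value 1
  expect_equal(null_pvalue(null, NA_integer_), 1)

  ps <- strong_pwm(6, seed = 3)
  ns <- build_score_null(ps)
  expect_equal(sum(ns$pmf) + ns$p_neg_inf, 1, tolerance = 1e-12)
  # the minimum of an all-finite support carries the whole distribution
  expect_equal(null_pvalue(ns, ns$min), 1, tolerance = 1e-12)
  # p-values are monotone non-increasing in the score
  pv <- null_pvalue(ns, ns$min:ns$max)
  expect_true(all(diff(pv) <= 1e-15))
})

test_that("score null pmf equals exhaustive enumeration for small widths", {
  cases <- list(uniform_pwm(4), strong_pwm(4, seed = 7), strong_pwm(6, seed = 8),
                consensus_pwm("TTAACC"))
  for (p in cases) {
    null <- build_score_null(p)
    oracle <- naive_null(p)
    got <- stats::setNames(null$pmf, null$min:null$max)
    got <- got[got > 0]
    want <- stats::setNames(oracle$pmf, oracle$scores)
    expect_equal(sort(as.numeric(names(got))),
                 sort(as.numeric(names(want))))
    want <- want[names(got)]
    expect_lt(sum(abs(got - want)), 1e-9)
    expect_equal(null$p_neg_inf, oracle$p_neg_inf, tolerance = 1e-12)
  }
})

test_that("scanning skips Ns, is strand-symmetric, and finds planted motifs", {
  p <- strong_pwm(6, seed = 10)
  expect_equal(nrow(scan_sequence(p, strrep("N", 50))), 0)

  seq <- rand_seq(200, seed = 11)
  fwd <- scan_sequence(p, seq, p_thresh = 0.05)
  rev <- scan_sequence(p, revcomp(seq), p_thresh = 0.05)
  expect_equal(nrow(fwd), nrow(rev))
  # a +-strand hit at [s, e) maps to a --strand hit at [L - e, L - s)
  mirrored <- data.frame(start = 200L - fwd$end,
                         strand = ifelse(fwd$strand == "+", "-", "+"),
                         score = fwd$score)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(rev$start, mirrored$start)
  expect_equal(rev$strand, mirrored$strand)
  expect_equal(rev$score, mirrored$score, tolerance = 1e-12)

  cp <- consensus_pwm("TTGACCAA", id = "planted")
  s <- rand_seq(500, seed = 12)
  substr(s, 101, 108) <- "TTGACCAA"
  substr(s, 301, 308) <- "TTGACCAA"
  hits <- scan_sequence(cp, s)
  expect_true(all(c(100, 300) %in% hits$start))
})

test_that("hit counts behave like the null expects", {
  p <- strong_pwm(8, seed = 20)
  null <- build_score_null(p)
  # at p_thresh = 1 every valid window on both strands is a hit
  s <- rand_seq(300, seed = 21)
  expect_equal(nrow(scan_sequence(p, s, p_thresh = 1, null = null)),
               2 * (300 - 8 + 1))
  sN <- paste0(substr(s, 1, 100), "N", substr(s, 102, 300))
  skipped <- 8  # windows covering the N on one strand
  expect_equal(nrow(scan_sequence(p, sN, p_thresh = 1, null = null)),
               2 * (300 - 8 + 1) - 2 * skipped)
  # background hit rate: at most the nominal threshold, and within Poisson
  # tolerance of the achieved (discreteness-adjusted) rate P(p <= thresh)
  tot <- 0
  for (i in 1:40)
    tot <- tot + nrow(scan_sequence(p, rand_seq(500, seed = 1000 + i),
                                    p_thresh = 1e-2, null = null))
  achieved <- max(null$tail[null$tail <= 1e-2])
  expect_lte(achieved, 1e-2)
  lambda <- 40 * 2 * (500 - 8 + 1) * achieved
  expect_lt(abs(tot - lambda), 5 * sqrt(lambda))
  nominal <- 40 * 2 * (500 - 8 + 1) * 1e-2
  expect_lt(tot, nominal + 5 * sqrt(nominal))
})

test_that("motif counts are revcomp-invariant and recover planted instances", {
  cons <- "TGTTTACTTAGC"
  gen <- Biostrings::DNAStringSet(c(chr1 = {
    s <- rand_seq(600, seed = 30)
    substr(s, 51, 62) <- cons
    substr(s, 201, 212) <- cons
    substr(s, 401, 412) <- cons
    s
  }))
  p <- default_pwms()$FOXA1
  site <- list(chrom = "chr1", start = 50L, end = 550L)
  n1 <- motif_count(p, gen, site)
  expect_gte(n1, 3)
  gen_rc <- Biostrings::DNAStringSet(
    c(chr1 = revcomp(as.character(gen[[1]]))))
  site_rc <- list(chrom = "chr1", start = 600L - 550L, end = 600L - 50L)
  expect_identical(n1, motif_count(p, gen_rc, site_rc))
  # a background window under a strong PWM yields at most a few chance hits
  bg <- Biostrings::DNAStringSet(c(chr1 = rand_seq(600, seed = 31)))
  expect_lte(motif_count(p, bg, site), 4)
})

test_that("aggregate affinity score sums clipped log-odds over all offsets", {
  p <- strong_pwm(4, seed = 40)
  gen <- Biostrings::DNAStringSet(c(chr1 = strrep("N", 30)))
  expect_equal(aggregate_affinity_score(p, gen, list(chrom = "chr1", start = 0L, end = 30L)), 0)

  s <- rand_seq(20, seed = 41)
  gen <- Biostrings::DNAStringSet(c(chr1 = s))
  got <- aggregate_affinity_score(p, gen, list(chrom = "chr1", start = 0L, end = 20L))
  want <- 0
  for (str_seq in c(s, naive_revcomp(s)))
    for (j in 1:(20 - 4 + 1))
      want <- want + max(0, score_window(p, substr(str_seq, j, j + 3)))
  expect_equal(got, want, tolerance = 1e-9)

  # planting one extra consensus instance never decreases the score
  cons <- paste(c("A", "C", "G", "T")[apply(p$probs, 1, which.max)],
                collapse = "")
  s2 <- s; substr(s2, 9, 12) <- cons
  gen2 <- Biostrings::DNAStringSet(c(chr1 = s2))
  expect_gte(aggregate_affinity_score(p, gen2,
                                      list(chrom = "chr1", start = 0L, end = 20L)),
             got - 1e-9)
})
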