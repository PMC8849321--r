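test_that("BED I/O round-trips and rejects malformed lines", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t500\t900\tpk3", "chr1\t100\t200\tpk1",
               "chr1\t50\t120\tpk2"), tmp)
  ps <- read_bed(tmp)
  expect_s3_class(ps, "PeakSet")
  expect_equal(nrow(ps), 3)
  expect_equal(ps$start, c(50L, 100L, 500L))  # sorted
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(ps, out)
  expect_equal(as.data.frame(read_bed(out)), as.data.frame(ps),
               ignore_attr = TRUE)

  writeLines("chr1\t200\t100", tmp)
  expect_error(read_bed(tmp), "line 1.*end <= start")
  writeLines(c("chr1\t10\t20", "chr1\t5"), tmp)
  expect_error(read_bed(tmp), "line 2")
  writeLines("chr1\tten\t20", tmp)
  expect_error(read_bed(tmp), "non-integer")
})

test_that("half-open overlap matches brute-force base-set intersection", {
  expect_true(overlaps(list(chrom = "chr1", start = 100, end = 200),
                       list(chrom = "chr1", start = 199, end = 300)))
  expect_false(overlaps(list(chrom = "chr1", start = 100, end = 200),
                        list(chrom = "chr1", start = 200, end = 300)))
  expect_false(overlaps(list(chrom = "chr1", start = 100, end = 200),
                        list(chrom = "chr2", start = 100, end = 200)))
  # exhaustive over all interval pairs on a small coordinate grid
  for (a1 in 0:5) for (a2 in (a1 + 1):6)
    for (b1 in 0:5) for (b2 in (b1 + 1):6) {
      shared <- length(intersect(seq(a1, a2 - 1), seq(b1, b2 - 1))) > 0
      expect_identical(
        overlaps(list(chrom = "c", start = a1, end = a2),
                 list(chrom = "c", start = b1, end = b2)),
        shared)
    }
})

test_that("replicate merging keeps union spans of two-replicate clusters", {
  r1 <- peak_set("chr1", 100, 200)
  r2 <- peak_set("chr1", 150, 250)
  m <- merge_replicates(r1, r2)
  expect_equal(as.data.frame(m)[, 1:3],
               data.frame(chrom = "chr1", start = 100L, end = 250L))
  expect_equal(nrow(merge_replicates(peak_set("chr1", 100, 200),
                                     peak_set("chr1", 300, 400))), 0)
  # abutting peaks are not overlapping
  expect_equal(nrow(merge_replicates(peak_set("chr1", 100, 200),
                                     peak_set("chr1", 200, 300))), 0)
})

test_that("replicate merging agrees with a connected-component oracle", {
  for (seed in 1:5) {
    r1 <- random_peaks(50, seed = seed)
    r2 <- random_peaks(50, seed = seed + 100)
    got <- merge_replicates(r1, r2)
    want <- naive_reproducible(r1, r2)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(as.data.frame(got)[, c("chrom", "start", "end")], want)
    }
    # commutativity and pairwise disjointness
    swapped <- merge_replicates(r2, r1)
    expect_equal(as.data.frame(got), as.data.frame(swapped))
    if (nrow(got) > 1) {
      same <- got$chrom[-1] == got$chrom[-nrow(got)]
      expect_true(all(got$start[-1][same] >= got$end[-nrow(got)][same]))
    }
  }
})

test_that("gene attribution windows are half-open and match a double loop", {
  genes <- data.frame(id = "g1", chrom = "chr1", tss = 100000, strand = "+")
  expect_named(attribute_to_genes(peak_set("chr1", 120000, 120500),
                                  genes, 25000), "g1")
  # window end is exclusive at tss + half_window
  expect_length(attribute_to_genes(peak_set("chr1", 125000, 125500),
                                   genes, 25000), 0)
  expect_named(attribute_to_genes(peak_set("chr1", 124999, 125500),
                                  genes, 25000), "g1")

  set.seed(4)
  peaks <- random_peaks(200, span = 50000, seed = 4)
  genes <- data.frame(id = sprintf("g%02d", 1:20),
                      chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
                      tss = sample.int(50000, 20), strand = "+")
  half <- 3000
  got <- attribute_to_genes(peaks, genes, half)
  for (i in seq_len(nrow(genes))) {
    want <- which(peaks$chrom == genes$chrom[i] &
                    peaks$start < genes$tss[i] + half &
                    peaks$end > max(genes$tss[i] - half, 0))
    if (length(want)) {
      expect_equal(as.data.frame(got[[genes$id[i]]])[, c("start", "end")],
                   as.data.frame(peaks)[want, c("start", "end")],
                   ignore_attr = TRUE)
    } else {
      expect_null(got[[genes$id[i]]])
    }
  }
  # infinite-window limit: every same-chromosome peak attributed
  all_att <- attribute_to_genes(peaks, genes, 10^9)
  for (i in seq_len(nrow(genes)))
    expect_equal(nrow(all_att[[genes$id[i]]]),
                 sum(peaks$chrom == genes$chrom[i]))
})

test_that("midpoint windows use floor midpoints and clip at edges", {
  w <- midpoint_window(peak_set("chr1", 1000, 1300), 500)
  expect_equal(c(w$start, w$end), c(900L, 1400L))
  w <- midpoint_window(peak_set("chr1", 1000, 1001), 500)
  expect_equal(c(w$start, w$end), c(750L, 1250L))
  # width equal to an even site length returns the site
  w <- midpoint_window(peak_set("chr1", 1000, 1500), 500)
  expect_equal(c(w$start, w$end), c(1000L, 1500L))
  expect_warning(
    w <- midpoint_window(peak_set("chr1", 10, 20), 500,
                         chrom_sizes = c(chr1 = 400L)),
    "clipped")
  expect_equal(c(w$start, w$end), c(0L, 265L))
})

test_that("random inaccessible windows avoid masked space uniformly", {
  gen <- Biostrings::DNAStringSet(c(chr1 = rand_seq(20000, seed = 9)))
  # degenerate: everything masked
  expect_error(sample_random_inaccessible(gen, peak_set("chr1", 0, 20000),
                                          5, 100, seed = 1, max_tries = 500),
               "exhausted")
  # vacuous constraint: empty mask
  empty <- peak_set(character(), integer(), integer())
  ps <- sample_random_inaccessible(gen, empty, 50, 100, seed = 1)
  expect_equal(nrow(ps), 50)
  expect_true(all(ps$end - ps$start == 100))
  # determinism
  ps2 <- sample_random_inaccessible(gen, empty, 50, 100, seed = 1)
  expect_equal(as.data.frame(ps), as.data.frame(ps2))

  # uniformity over allowed start positions: mask [0, 10000)
  mask <- peak_set("chr1", 0, 10000)
  draws <- sample_random_inaccessible(gen, mask, 5000, 100, seed = 2)
  expect_true(all(draws$start >= 10000))
  bins <- cut(draws$start, breaks = seq(10000, 20000 - 100 + 1,
                                        length.out = 11))
  expect_gt(stats::chisq.test(table(bins))$p.value, 0.01)
})
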