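test_that("genome generation is deterministic with the configured composition", {
  cfg <- tiny_sim_config(seed = 1, chrom_sizes = c(chr1 = 100000L))
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(Biostrings::width(g1), 100000L)
  expect_false(identical(
    as.character(generate_genome(tiny_sim_config(seed = 2, chrom_sizes = c(chr1 = 100000L)))),
    as.character(g1)))

  gc1 <- generate_genome(tiny_sim_config(gc_content = 1,
                                         chrom_sizes = c(chr1 = 20000L)))
  expect_equal(sort(unique(strsplit(as.character(gc1[[1]]), "")[[1]])),
               c("C", "G"))

  cfg4 <- tiny_sim_config(seed = 3, gc_content = 0.4,
                          chrom_sizes = c(chr1 = 1000000L))
  g4 <- as.character(generate_genome(cfg4)[[1]])
  gc_obs <- mean(strsplit(g4, "")[[1]] %in% c("G", "C"))
  expect_gt(gc_obs, 0.39); expect_lt(gc_obs, 0.41)

  expect_error(sim_config(chrom_sizes = c(chr1 = 500L)), ">= 10000")
})

test_that("planted sites record their motif content exactly (consensus mode)", {
  cfg <- tiny_sim_config(seed = 5, consensus_motifs = TRUE,
                         chrom_sizes = c(chr1 = 150000L, chr2 = 150000L))
  pwms <- default_pwms()
  gen0 <- generate_genome(cfg)
  res <- plant_sites(gen0, cfg, pwms)
  plan <- res$plan
  expect_equal(nrow(plan), sum(cfg$site_plan_counts))
  expect_true(all(plan$end - plan$start == 500L))
  # windows are pairwise disjoint
  for (ch in unique(plan$chrom)) {
    p <- plan[plan$chrom == ch, ]
    expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
  }
  # FP sites carry 2-4 FOXA1 and 0 HNF4A motifs by default
  fp <- plan[plan$class == "FP", ]
  expect_true(all(fp$foxa1_motifs >= 2 & fp$foxa1_motifs <= 4))
  expect_true(all(fp$hnf4a_motifs == 0))
  hp <- plan[plan$class == "HP", ]
  expect_true(all(hp$hnf4a_motifs >= 3 & hp$hnf4a_motifs <= 6))

  # background windows are untouched
  bg <- plan[plan$class == "background", ]
  for (i in seq_len(nrow(bg)))
    expect_identical(
      as.character(Biostrings::subseq(res$genome[[bg$chrom[i]]],
                                      bg$start[i] + 1L, bg$end[i])),
      as.character(Biostrings::subseq(gen0[[bg$chrom[i]]],
                                      bg$start[i] + 1L, bg$end[i])))

  # consensus-forcing mode: ledger counts equal literal string matches
  cons <- vapply(pwms, function(p)
    paste(c("A", "C", "G", "T")[apply(p$probs, 1, which.max)], collapse = ""),
    "")
  count_matches <- function(seq, word) {
    hits <- 0L
    for (w in c(word, revcomp(word)))
      hits <- hits + length(gregexpr(w, seq, fixed = TRUE)[[1]]) *
        (regexpr(w, seq, fixed = TRUE) > 0)
    hits
  }
  planted <- plan[plan$class %in% c("FP", "HP", "CB"), ]
  for (i in seq_len(nrow(planted))) {
    s <- as.character(Biostrings::subseq(res$genome[[planted$chrom[i]]],
                                         planted$start[i] + 1L,
                                         planted$end[i]))
    expect_equal(count_matches(s, cons[["FOXA1"]]), planted$foxa1_motifs[i])
    expect_equal(count_matches(s, cons[["HNF4A"]]), planted$hnf4a_motifs[i])
  }
})

test_that("peak tracks follow class membership and replicate noise statistics", {
  cfg <- tiny_sim_config(seed = 6)
  pwms <- default_pwms()
  plan <- plant_sites(generate_genome(cfg), cfg, pwms)$plan
  pk <- generate_peaksets(plan, cfg)
  # noise off: replicates are identical in every track
  for (track in names(pk))
    expect_equal(as.data.frame(pk[[track]][[1]]),
                 as.data.frame(pk[[track]][[2]]), ignore_attr = TRUE)
  # one CB site: double tracks only, never single or pre-induction ATAC
  cb <- plan[plan$class == "CB", ][1, ]
  hit <- function(track) any(pk[[track]][[1]]$start == cb$start &
                               pk[[track]][[1]]$chrom == cb$chrom)
  expect_true(hit("FOXA1_double")); expect_true(hit("HNF4A_double"))
  expect_true(hit("ATAC_post"))
  expect_false(hit("FOXA1_single")); expect_false(hit("HNF4A_single"))
  expect_false(hit("ATAC_pre"))
  # accessible classes pre-exist in ATAC, inaccessible do not
  acc <- plan[plan$class == "FOXA1_accessible", ][1, ]
  expect_true(any(pk$ATAC_pre[[1]]$start == acc$start))

  # dropout 0.1: post-merge retention within 3 sd of (1 - 0.1)^2
  cfgn <- tiny_sim_config(
    seed = 7, peak_jitter_sd = 10, peak_dropout = 0.1,
    chrom_sizes = c(chr1 = 1100000L, chr2 = 1100000L),
    site_plan_counts = c(FP = 1000L),
    n_activated = 5L, n_genes = 50L)
  plann <- plant_sites(generate_genome(cfgn), cfgn, pwms)$plan
  pkn <- generate_peaksets(plann, cfgn)
  merged <- merge_replicates(pkn$FOXA1_double[[1]], pkn$FOXA1_double[[2]])
  p_keep <- 0.9^2
  sd3 <- 3 * sqrt(p_keep * (1 - p_keep) / 1000)
  expect_lt(abs(nrow(merged) / 1000 - p_keep), sd3)
})

test_that("counts carry the planted activation signal (and none when lfc = 0)", {
  cfg0 <- tiny_sim_config(seed = 8, activated_lfc = 0, n_genes = 400L)
  plan0 <- plant_sites(generate_genome(cfg0), cfg0, default_pwms())$plan
  r0 <- generate_counts(plan0, cfg0)
  expect_length(r0$activated, 0)
  d0 <- differential_table(r0$counts)
  expect_lt(abs(mean(d0$log2fc)), 0.1)

  # near-Poisson limit: sample means within 5% of planted means
  # (500 activated genes x 3 replicates per condition so the Monte Carlo
  # error on the mean is well under the 5% band)
  cfg1 <- tiny_sim_config(seed = 9, n_genes = 2000L,
                          nb_dispersion = 1e6, n_activated = 500L)
  plan1 <- plant_sites(generate_genome(cfg1), cfg1, default_pwms())$plan
  r1 <- generate_counts(plan1, cfg1)
  cond <- attr(r1$counts, "condition")
  act <- r1$counts[r1$activated, , drop = FALSE]
  # planted: uninduced mean 5, lfc 3 -> induced mean 40
  expect_lt(abs(mean(act[, cond == "uninduced"]) / 5 - 1), 0.05)
  expect_lt(abs(mean(act[, cond == "induced"]) / 40 - 1), 0.05)
})

test_that("tissue table plants exactly the fourfold-enriched truth genes", {
  cfg <- tiny_sim_config(seed = 10, n_genes = 500L)
  truth <- list(liver = sprintf("g%05d", 1:30),
                intestine = sprintf("g%05d", 31:50))
  tab <- generate_tissue_table(cfg, truth)
  liver <- tissue_enriched_genes(tab, "liver")
  expect_setequal(liver$genes, truth$liver)
  gut <- tissue_enriched_genes(tab, "intestine")
  expect_setequal(gut$genes, truth$intestine)
  # no non-truth gene is ever fourfold-enriched anywhere
  for (t in colnames(tab)) {
    enr <- tissue_enriched_genes(tab, t)$genes
    expect_length(setdiff(enr, unlist(truth)), 0)
  }

  # a sub-threshold planted fold is not recovered
  cfg39 <- tiny_sim_config(seed = 10, n_genes = 500L, tissue_fold = 3.9)
  tab39 <- generate_tissue_table(cfg39, truth)
  expect_length(intersect(tissue_enriched_genes(tab39, "liver")$genes,
                          truth$liver), 0)
  expect_error(generate_tissue_table(cfg, list(liver = c("g00001", "g00001"))),
               "disjoint")
})
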