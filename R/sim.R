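SITE_CLASSES <- c("FP", "HP", "BOTH", "CB",
                  "FOXA1_accessible", "FOXA1_inaccessible",
                  "HNF4A_accessible", "HNF4A_inaccessible", "background")

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' define the reference study conditions: a 4-Mb two-chromosome toy genome at
#' human-like GC, ~1,640 planted 500-bp sites whose co-bound class mix is
#' proportional to the observed genome-wide 2023 FP / 3398 HP / 3789 BOTH /
#' 2192 CB split, pioneered-site motif multiplicities of 2-4 (FOXA1) and 3-6
#' (HNF4A), 60 activated genes at log2 fold change 3 from a silent baseline
#' (mean 5 normalized reads, far below the 50-read activation ceiling), and a
#' fourfold planted tissue enrichment.
#'
#' @param seed integer master seed; every generator stage derives its stream
#'   from it, so identical configs give bit-identical outputs.
#' @param chrom_sizes named integer vector of chromosome lengths (bp, each
#'   >= 10000).
#' @param gc_content genome GC fraction in \[0, 1\].
#' @param n_genes number of genes in the annotation and count matrix.
#' @param site_plan_counts named vector: sites to plant per class
#'   (`FP`, `HP`, `BOTH`, `CB`, `FOXA1_accessible`, `FOXA1_inaccessible`,
#'   `HNF4A_accessible`, `HNF4A_inaccessible`, `background`).
#' @param motif_multiplicity nested list `TF -> context -> c(min, max)` of
#'   planted motif copies per site; contexts are `pioneered` (the factor's own
#'   pioneered and inaccessible sites), `accessible`, and `cobound`.
#' @param peak_jitter_sd per-replicate peak boundary jitter sd (bp).
#' @param peak_dropout per-replicate per-peak dropout probability.
#' @param nb_mean baseline negative-binomial mean of non-target genes.
#' @param nb_dispersion negative-binomial size parameter.
#' @param activated_baseline_mean uninduced mean of planted activated genes
#'   (must sit well below the 50-read activation ceiling).
#' @param activated_lfc planted log2 fold change (0 = null simulation, no
#'   genes activated).
#' @param n_activated number of planted activated (liver) genes.
#' @param n_tissues number of tissues in the expression table (>= 2).
#' @param tissue_fold planted own-tissue enrichment fold (>= 4 by default;
#'   the generator guarantees no spurious fourfold gene as long as this stays
#'   above ~1.6).
#' @param window_width planted site window width (bp, even; default 500).
#' @param consensus_motifs if `TRUE`, planted instances are the PWM consensus
#'   string verbatim instead of per-column draws (used for exact oracles).
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_sizes = c(chr1 = 2000000L, chr2 = 2000000L),
                       gc_content = 0.41,
                       n_genes = 5000L,
                       site_plan_counts = c(FP = 202L, HP = 340L, BOTH = 379L,
                                            CB = 219L,
                                            FOXA1_accessible = 100L,
                                            FOXA1_inaccessible = 100L,
                                            HNF4A_accessible = 100L,
                                            HNF4A_inaccessible = 100L,
                                            background = 100L),
                       motif_multiplicity = list(
                         FOXA1 = list(pioneered = c(2L, 4L),
                                      accessible = c(1L, 2L),
                                      cobound = c(0L, 1L)),
                         HNF4A = list(pioneered = c(3L, 6L),
                                      accessible = c(1L, 3L),
                                      cobound = c(0L, 1L))),
                       peak_jitter_sd = 10,
                       peak_dropout = 0.01,
                       nb_mean = 200,
                       nb_dispersion = 10,
                       activated_baseline_mean = 5,
                       activated_lfc = 3,
                       n_activated = 60L,
                       n_tissues = 5L,
                       tissue_fold = 4,
                       window_width = 500L,
                       consensus_motifs = FALSE) {
  stopifnot(length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)))
  if (any(chrom_sizes < 10000)) stop("each chromosome must be >= 10000 bp")
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0, 1]")
  miss <- setdiff(names(site_plan_counts), SITE_CLASSES)
  if (length(miss)) stop("unknown site classes: ", paste(miss, collapse = ", "))
  if (any(site_plan_counts < 0) || n_genes < 0 || n_activated < 0 ||
      n_tissues < 2 || peak_dropout < 0 || peak_dropout > 1 ||
      peak_jitter_sd < 0 || nb_mean <= 0 || nb_dispersion <= 0)
    stop("invalid SimConfig parameter")
  if (window_width %% 2L != 0L) stop("window_width must be even")
  if (n_activated > n_genes) stop("n_activated exceeds n_genes")
  structure(list(seed = as.integer(seed), chrom_sizes = chrom_sizes,
                 gc_content = gc_content, n_genes = as.integer(n_genes),
                 site_plan_counts = site_plan_counts,
                 motif_multiplicity = motif_multiplicity,
                 peak_jitter_sd = peak_jitter_sd, peak_dropout = peak_dropout,
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 activated_baseline_mean = activated_baseline_mean,
                 activated_lfc = activated_lfc,
                 n_activated = as.integer(n_activated),
                 n_tissues = as.integer(n_tissues),
                 tissue_fold = tissue_fold,
                 window_width = as.integer(window_width),
                 consensus_motifs = consensus_motifs),
            class = "SimConfig")
}

# Stage-specific seeds derived from the master seed, so each generator is
# deterministic both standalone and inside the full pipeline.
.stage_seed <- function(config, stage) {
  off <- c(genome = 101L, sites = 202L, peaks = 303L, counts = 404L,
           tissue = 505L, genes = 606L)
  config$seed + off[[stage]]
}

#' Generate a random genome
#'
#' i.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`;
#' deterministic given the config seed.
#'
#' @param config a `SimConfig`.
#' @return A `DNAStringSet`, one entry per chromosome.
#' @export
generate_genome <- function(config) {
  set.seed(.stage_seed(config, "genome"))
  gc <- config$gc_content
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(config$chrom_sizes, function(sz)
    paste(sample(DNA_BASES, sz, replace = TRUE, prob = prob), collapse = ""),
    "")
  gen <- Biostrings::DNAStringSet(seqs)
  names(gen) <- names(config$chrom_sizes)
  gen
}

# multiplicity range for one TF at one site class
.mult_range <- function(config, tf, class) {
  mm <- config$motif_multiplicity[[tf]]
  own_acc <- paste0(tf, "_accessible")
  own_inacc <- paste0(tf, "_inaccessible")
  pio <- if (tf == "FOXA1") "FP" else "HP"
  if (class %in% c(pio, "BOTH", own_inacc)) mm$pioneered
  else if (class == own_acc) mm$accessible
  else if (class == "CB") mm$cobound
  else c(0L, 0L)
}

# sample one motif instance sequence from a PWM (or its consensus)
.draw_instance <- function(p, consensus) {
  if (consensus) {
    paste(DNA_BASES[apply(p$probs, 1, which.max)], collapse = "")
  } else {
    paste(vapply(seq_len(p$width), function(i)
      sample(DNA_BASES, 1L, prob = p$probs[i, ]), ""), collapse = "")
  }
}

#' Plant motif-bearing sites into a genome
#'
#' Selects disjoint `window_width`-bp windows (on a 2-kb grid, shuffled),
#' assigns each a site class, draws the class-specified number of FOXA1 and
#' HNF4A motif instances, and writes each instance — sampled per column from
#' the PWM (or its consensus in `consensus_motifs` mode) — at a random
#' non-overlapping offset and random strand inside the window. Background
#' windows are left untouched. Co-bound-class sites are linked round-robin to
#' the planted activated genes.
#'
#' @param genome a `DNAStringSet` from [generate_genome()].
#' @param config a `SimConfig`.
#' @param pwms named list with `PWM`s `FOXA1` and `HNF4A`.
#' @return list with `genome` (modified) and `plan`: the ground-truth ledger,
#'   a data.frame of class `SitePlan` with columns `chrom`, `start`, `end`,
#'   `class`, `accessible`, `foxa1_motifs`, `hnf4a_motifs`, `gene`.
#' @export
plant_sites <- function(genome, config, pwms) {
  set.seed(.stage_seed(config, "sites"))
  counts <- config$site_plan_counts
  n_sites <- sum(counts)
  ww <- config$window_width
  cand <- do.call(rbind, lapply(names(genome), function(ch) {
    sz <- Biostrings::width(genome)[match(ch, names(genome))]
    starts <- seq(1000L, sz - ww - 1000L, by = 2000L)
    data.frame(chrom = ch, start = starts, stringsAsFactors = FALSE)
  }))
  if (nrow(cand) < n_sites)
    stop(sprintf("cannot place %d disjoint windows; only %d candidate slots",
                 n_sites, nrow(cand)))
  pick <- cand[sample(nrow(cand), n_sites), , drop = FALSE]
  classes <- rep(names(counts), counts)
  plan <- data.frame(chrom = pick$chrom, start = pick$start,
                     end = pick$start + ww, class = classes,
                     accessible = grepl("_accessible$", classes),
                     foxa1_motifs = 0L, hnf4a_motifs = 0L,
                     gene = NA_character_, stringsAsFactors = FALSE)
  edits <- list()  # deferred edits, applied in one replaceAt pass per chrom
  for (i in seq_len(n_sites)) {
    placed <- matrix(integer(0), ncol = 2)  # occupied [start, end) offsets
    for (tf in c("FOXA1", "HNF4A")) {
      r <- .mult_range(config, tf, plan$class[i])
      m <- if (r[2] > r[1]) sample(r[1]:r[2], 1L) else r[1]
      plan[[if (tf == "FOXA1") "foxa1_motifs" else "hnf4a_motifs"]][i] <- m
      if (m == 0L) next
      p <- pwms[[tf]]
      for (k in seq_len(m)) {
        ok <- FALSE
        for (try in 1:1000) {
          off <- sample.int(ww - p$width + 1L, 1L) - 1L
          if (!nrow(placed) ||
              all(off + p$width <= placed[, 1] | off >= placed[, 2])) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("could not place non-overlapping motif instances")
        inst <- .draw_instance(p, config$consensus_motifs)
        if (stats::runif(1) < 0.5) inst <- revcomp(inst)
        at <- plan$start[i] + off
        edits[[length(edits) + 1L]] <- list(chrom = plan$chrom[i],
                                            start = at, width = p$width,
                                            seq = inst)
        placed <- rbind(placed, c(off, off + p$width))
      }
    }
  }
  if (length(edits)) {
    echrom <- vapply(edits, `[[`, "", "chrom")
    for (ch in unique(echrom)) {
      sel <- which(echrom == ch)
      at <- IRanges::IRanges(
        start = vapply(edits[sel], `[[`, 0L, "start") + 1L,
        width = vapply(edits[sel], `[[`, 0L, "width"))
      genome[[ch]] <- Biostrings::replaceAt(
        genome[[ch]], at, vapply(edits[sel], `[[`, "", "seq"))
    }
  }
  # link co-bound sites round-robin to the planted activated genes
  act <- .activated_gene_ids(config)
  cb_rows <- which(plan$class %in% c("FP", "HP", "BOTH", "CB"))
  if (length(act) && length(cb_rows))
    plan$gene[cb_rows] <- act[(seq_along(cb_rows) - 1L) %% length(act) + 1L]
  plan <- plan[order(plan$chrom, plan$start), , drop = FALSE]
  rownames(plan) <- NULL
  class(plan) <- c("SitePlan", "data.frame")
  list(genome = genome, plan = plan)
}

.gene_ids <- function(config) sprintf("g%05d", seq_len(config$n_genes))

# activated gene ids; deterministic given the master seed, drawn from a
# dedicated stream so plant_sites and generate_counts agree.
.activated_gene_ids <- function(config) {
  if (config$n_activated == 0L || config$activated_lfc == 0) return(character())
  set.seed(config$seed + 707L)
  sort(sample(.gene_ids(config), config$n_activated))
}

# which tracks a site class appears in
.class_tracks <- function(class) {
  switch(class,
         FOXA1_accessible = ,
         FOXA1_inaccessible = c("FOXA1_single", "FOXA1_double", "ATAC_post"),
         HNF4A_accessible = ,
         HNF4A_inaccessible = c("HNF4A_single", "HNF4A_double", "ATAC_post"),
         FP = c("FOXA1_single", "FOXA1_double", "HNF4A_double", "ATAC_post"),
         HP = c("HNF4A_single", "FOXA1_double", "HNF4A_double", "ATAC_post"),
         BOTH = c("FOXA1_single", "HNF4A_single", "FOXA1_double",
                  "HNF4A_double", "ATAC_post"),
         CB = c("FOXA1_double", "HNF4A_double", "ATAC_post"),
         background = character())
}

SIM_TRACKS <- c("FOXA1_single", "HNF4A_single", "FOXA1_double", "HNF4A_double",
                "ATAC_pre", "ATAC_post")

#' Generate replicated peak sets from a site plan
#'
#' Each planted site's window becomes a peak in every track its class implies:
#' single-factor sites in their own single- and double-expression tracks,
#' co-bound classes in both double-expression tracks (plus the corresponding
#' single tracks for FP/HP/BOTH), accessible sites in the uninduced ATAC
#' track, and every bound site in the induced ATAC track (bound inaccessible
#' sites are opened). Per replicate, peak boundaries are jittered with the
#' configured Gaussian sd and peaks dropped with the configured probability.
#'
#' @param plan a `SitePlan`.
#' @param config a `SimConfig`.
#' @return named list: track -> list(rep1, rep2) of `PeakSet`s.
#' @export
generate_peaksets <- function(plan, config) {
  set.seed(.stage_seed(config, "peaks"))
  membership <- lapply(plan$class, .class_tracks)
  acc_rows <- which(plan$accessible)
  out <- list()
  for (track in SIM_TRACKS) {
    rows <- if (track == "ATAC_pre") acc_rows else
      which(vapply(membership, function(tr) track %in% tr, TRUE))
    reps <- list()
    for (r in 1:2) {
      st <- plan$start[rows]; en <- plan$end[rows]
      if (config$peak_jitter_sd > 0) {
        st <- st + as.integer(round(stats::rnorm(length(rows), 0, config$peak_jitter_sd)))
        en <- en + as.integer(round(stats::rnorm(length(rows), 0, config$peak_jitter_sd)))
      }
      st <- pmax(st, 0L)
      en <- pmax(en, st + 1L)
      keep <- if (config$peak_dropout > 0)
        stats::runif(length(rows)) >= config$peak_dropout else
          rep(TRUE, length(rows))
      reps[[r]] <- peak_set(plan$chrom[rows][keep], st[keep], en[keep],
                            name = sprintf("site_%05d", rows)[keep],
                            label = sprintf("%s_rep%d", track, r))
    }
    out[[track]] <- reps
  }
  out
}

#' Generate negative-binomial counts with planted activation
#'
#' Three uninduced and three induced samples. Non-target genes draw a
#' log-normal baseline mean around `nb_mean` shared across conditions;
#' planted activated genes (the co-bound-linked gene set) have uninduced mean
#' `activated_baseline_mean` and induced mean
#' `activated_baseline_mean * 2^activated_lfc`. Counts are
#' `NB(mu, size = nb_dispersion)`. With `activated_lfc = 0` the truth set is
#' empty and no gene differs systematically between conditions.
#'
#' @param plan a `SitePlan` (source of the linked activated genes).
#' @param config a `SimConfig`.
#' @return list with `counts` (a `CountMatrix`, 3 + 3 samples) and
#'   `activated` (character vector of planted activated gene ids).
#' @export
generate_counts <- function(plan, config) {
  ids <- .gene_ids(config)
  act <- .activated_gene_ids(config)  # own stream; must precede stage seeding
  set.seed(.stage_seed(config, "counts"))
  base_mu <- stats::rlnorm(config$n_genes, log(config$nb_mean), 0.7)
  mu_un <- base_mu
  mu_in <- base_mu
  if (length(act)) {
    sel <- match(act, ids)
    mu_un[sel] <- config$activated_baseline_mean
    mu_in[sel] <- config$activated_baseline_mean * 2^config$activated_lfc
  }
  cond <- rep(c("uninduced", "induced"), each = 3)
  m <- sapply(seq_along(cond), function(j) {
    mu <- if (cond[j] == "uninduced") mu_un else mu_in
    stats::rnbinom(config$n_genes, mu = mu, size = config$nb_dispersion)
  })
  rownames(m) <- ids
  colnames(m) <- sprintf("%s_%d", cond, c(1:3, 1:3))
  list(counts = count_matrix(m, cond), activated = act)
}

#' Generate a tissue x gene expression table with planted enrichment
#'
#' Every gene draws a log-normal base level and per-tissue multipliers in
#' \[0.8, 1.25\], so no unplanted gene can reach a fourfold tissue excess
#' (max/min multiplier ratio < 1.6). For each truth gene, its own-tissue
#' value is then set to `tissue_fold` times its maximum value elsewhere.
#'
#' @param config a `SimConfig`.
#' @param truth_sets named list: tissue -> character vector of gene ids
#'   (pairwise disjoint).
#' @return numeric matrix, genes (rows, all `n_genes`) x tissues (columns:
#'   `liver`, `intestine`, then `tissue3`, ...).
#' @export
generate_tissue_table <- function(config, truth_sets) {
  set.seed(.stage_seed(config, "tissue"))
  ids <- .gene_ids(config)
  tissues <- c("liver", "intestine",
               sprintf("tissue%d", seq_len(max(config$n_tissues - 2L, 0L)) + 2L))
  tissues <- tissues[seq_len(config$n_tissues)]
  all_truth <- unlist(truth_sets, use.names = FALSE)
  if (anyDuplicated(all_truth)) stop("truth sets must be disjoint")
  if (!all(all_truth %in% ids)) stop("truth genes outside the gene universe")
  if (!all(names(truth_sets) %in% tissues))
    stop("truth set tissue not in the table")
  base <- stats::rlnorm(length(ids), log(100), 0.5)
  m <- base * matrix(stats::runif(length(ids) * length(tissues), 0.8, 1.25),
                     nrow = length(ids))
  # 6-decimal grid so the planted fold relation survives text round-trips
  # exactly (scaling a decimal by the default fold of 4 is binary-exact)
  m <- round(m, 6)
  dimnames(m) <- list(ids, tissues)
  for (t in names(truth_sets)) {
    g <- truth_sets[[t]]
    other <- setdiff(tissues, t)
    m[g, t] <- config$tissue_fold *
      apply(m[g, other, drop = FALSE], 1, max)
  }
  m
}

#' Generate the gene annotation for a simulated dataset
#'
#' Genes linked to planted sites get a TSS within 10 kb of their first linked
#' site (so TSS-window attribution can recover the link); all other genes are
#' placed uniformly at random.
#'
#' @param plan a `SitePlan`.
#' @param config a `SimConfig`.
#' @return data.frame with `id`, `chrom`, `tss`, `strand`.
#' @export
generate_gene_annotation <- function(plan, config) {
  set.seed(.stage_seed(config, "genes"))
  ids <- .gene_ids(config)
  sizes <- config$chrom_sizes
  chrom <- sample(names(sizes), config$n_genes, replace = TRUE,
                  prob = sizes / sum(sizes))
  tss <- floor(stats::runif(config$n_genes) * sizes[chrom])
  linked <- plan[!is.na(plan$gene), , drop = FALSE]
  first <- linked[!duplicated(linked$gene), , drop = FALSE]
  sel <- match(first$gene, ids)
  mid <- first$start + (first$end - first$start) %/% 2L
  off <- as.integer(round(stats::runif(nrow(first), -10000, 10000)))
  chrom[sel] <- first$chrom
  tss[sel] <- pmin(pmax(mid + off, 0L), sizes[first$chrom] - 1L)
  data.frame(id = ids, chrom = chrom, tss = as.integer(tss),
             strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
             stringsAsFactors = FALSE)
}
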