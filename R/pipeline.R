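#' Packaged stand-in PWMs
#'
#' Loads the two synthetic position frequency matrices shipped with the
#' package (a forkhead-like and a DR1-like motif, labelled `*_synthetic`;
#' they are hand-built stand-ins, not JASPAR matrices) as the default
#' FOXA1/HNF4A PWM pair.
#'
#' @param pseudocount passed to [read_jaspar()].
#' @return named list with `PWM`s `FOXA1` and `HNF4A`.
#' @export
default_pwms <- function(pseudocount = 0.1) {
  dir <- system.file("extdata", "motifs", package = "pioneerbind")
  list(FOXA1 = read_jaspar(file.path(dir, "FOXA1_synthetic.pfm"), pseudocount),
       HNF4A = read_jaspar(file.path(dir, "HNF4A_synthetic.pfm"), pseudocount))
}

CHROMHMM_STATES <- c("Promoter", "Enhancer", "Transcribed", "Heterochrom",
                     "Repressed")

# deterministic toy segmentation: 5-kb tiles cycling through the states
.synthetic_segmentation <- function(chrom_sizes, tile = 5000L) {
  rows <- lapply(names(chrom_sizes), function(ch) {
    starts <- seq(0L, chrom_sizes[[ch]] - 1L, by = tile)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + tile, chrom_sizes[[ch]]),
               name = CHROMHMM_STATES[(seq_along(starts) - 1L) %%
                                        length(CHROMHMM_STATES) + 1L],
               stringsAsFactors = FALSE)
  })
  peak_set(do.call(rbind, rows), label = "chromhmm")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.input_error <- function(msg) {
  stop(structure(class = c("pioneerbind_input_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.require_file <- function(path) {
  if (!file.exists(path)) .input_error(paste("missing input file:", path))
  path
}

#' Simulate a complete synthetic dataset on disk
#'
#' Runs the synthetic-data generators end to end — genome, planted sites,
#' replicated peak tracks, counts, tissue table, gene annotation, and a toy
#' chromatin segmentation — and writes everything in plain-text formats
#' (FASTA, BED, TSV, YAML) together with the ground-truth site ledger and a
#' checksum manifest. Bit-identical for identical configs.
#'
#' @param config a [sim_config()].
#' @param outdir output directory.
#' @param pwms named PWM list (default [default_pwms()]).
#' @param force overwrite a non-empty existing directory.
#' @return invisibly, a list with the in-memory objects (`genome`, `plan`,
#'   `peaks`, `counts`, `activated`, `tissue`, `genes`) and `dir`.
#' @export
run_simulate <- function(config, outdir, pwms = default_pwms(), force = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE): ",
         outdir)
  dir.create(file.path(outdir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  genome <- generate_genome(config)
  planted <- plant_sites(genome, config, pwms)
  peaks <- generate_peaksets(planted$plan, config)
  cnt <- generate_counts(planted$plan, config)
  truth_sets <- list(liver = cnt$activated)
  tissue <- generate_tissue_table(config, truth_sets)
  genes <- generate_gene_annotation(planted$plan, config)
  seg <- .synthetic_segmentation(config$chrom_sizes)

  Biostrings::writeXStringSet(planted$genome, file.path(outdir, "genome.fa"))
  for (track in names(peaks))
    for (r in 1:2)
      write_bed(peaks[[track]][[r]],
                file.path(outdir, "peaks", sprintf("%s_rep%d.bed", track, r)))
  counts_df <- data.frame(gene = rownames(cnt$counts),
                          unclass(cnt$counts), check.names = FALSE)
  .write_tsv(counts_df, file.path(outdir, "counts.tsv"))
  tissue_df <- data.frame(gene = rownames(tissue), tissue, check.names = FALSE)
  .write_tsv(tissue_df, file.path(outdir, "tissue.tsv"))
  .write_tsv(as.data.frame(planted$plan), file.path(outdir, "site_plan.tsv"))
  write_gene_annotation(genes, file.path(outdir, "genes.tsv"))
  write_bed(seg, file.path(outdir, "chromhmm.bed"))
  echo <- config
  echo$chrom_sizes <- as.list(config$chrom_sizes)
  echo$site_plan_counts <- as.list(config$site_plan_counts)
  echo <- c(unclass(echo),
            list(conditions = attr(cnt$counts, "condition"),
                 activated_genes = cnt$activated))
  yaml::write_yaml(echo, file.path(outdir, "config.yaml"))
  files <- sort(setdiff(list.files(outdir, recursive = TRUE), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outdir, files))),
                         stringsAsFactors = FALSE)
  .write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(list(genome = planted$genome, plan = planted$plan, peaks = peaks,
                 counts = cnt$counts, activated = cnt$activated,
                 tissue = tissue, genes = genes, dir = outdir))
}

#' Analysis thresholds and switches
#'
#' All stated analysis constants in one place: FIMO-style motif p-value
#' threshold 1e-3, activation rules (log2FC >= 1, < 50 normalized uninduced
#' reads, >= 10 total reads), fourfold tissue enrichment, 25-kb single-TF and
#' 50-kb co-bound TSS half-windows, 500-bp motif windows.
#'
#' @param motif_p motif scan p-value threshold.
#' @param lfc_min,base_max,min_total activation-call thresholds.
#' @param tissue_fold tissue-enrichment fold.
#' @param half_window_single,half_window_cobound TSS attribution half-widths.
#' @param window_width motif analysis window width (bp).
#' @param aggregate_mode [aggregate_affinity_score()] mode.
#' @param seed seed for the random negative window draws.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(motif_p = 1e-3, lfc_min = 1, base_max = 50,
                       min_total = 10, tissue_fold = 4,
                       half_window_single = 25000L,
                       half_window_cobound = 50000L,
                       window_width = 500L,
                       aggregate_mode = "clipped_sum",
                       seed = 1L) {
  stopifnot(motif_p > 0, lfc_min > 0, base_max > 0, tissue_fold > 0,
            half_window_single > 0, half_window_cobound > 0, window_width > 0)
  structure(list(motif_p = motif_p, lfc_min = lfc_min, base_max = base_max,
                 min_total = min_total, tissue_fold = tissue_fold,
                 half_window_single = as.integer(half_window_single),
                 half_window_cobound = as.integer(half_window_cobound),
                 window_width = as.integer(window_width),
                 aggregate_mode = aggregate_mode, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full analysis on a dataset directory
#'
#' Consumes the file layout written by [run_simulate()] (or user-supplied
#' files in the same layout): `genome.fa`, `peaks/<track>_rep{1,2}.bed`,
#' `counts.tsv`, `tissue.tsv`, `genes.tsv`, and optionally `chromhmm.bed`.
#' Executes replicate merging, accessibility/opening classification, the
#' co-binding taxonomy, ChromHMM composition, TSS attribution, activation and
#' tissue enrichment, motif-count group summaries, and the motif-affinity ROC
#' comparisons; writes one TSV/JSON per stage plus `run.log` into `outdir`.
#'
#' @param simdir input dataset directory.
#' @param outdir output directory.
#' @param config a [run_config()].
#' @param pwms named PWM list (default [default_pwms()]).
#' @return invisibly, a named list with every stage result.
#' @export
run_analyze <- function(simdir, outdir, config = run_config(),
                        pwms = default_pwms()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- Biostrings::readDNAStringSet(.require_file(file.path(simdir, "genome.fa")))
  names(genome) <- sub("\\s.*", "", names(genome))
  chrom_sizes <- stats::setNames(Biostrings::width(genome), names(genome))
  merged <- list()
  for (track in SIM_TRACKS) {
    r1 <- read_bed(.require_file(file.path(simdir, "peaks",
                                           paste0(track, "_rep1.bed"))))
    r2 <- read_bed(.require_file(file.path(simdir, "peaks",
                                           paste0(track, "_rep2.bed"))))
    merged[[track]] <- merge_replicates(r1, r2)
    write_bed(merged[[track]],
              file.path(outdir, paste0("merged_", track, ".bed")))
  }
  genes <- read_gene_annotation(.require_file(file.path(simdir, "genes.tsv")))

  # --- single-factor bound sites: accessibility and opening ---
  bound <- list()
  for (tf in c("foxa1", "hnf4a")) {
    sites <- merged[[paste0(toupper(tf), "_single")]]
    df <- as.data.frame(sites)
    df$accessibility <- classify_accessibility(sites, merged$ATAC_pre)
    df$opened <- classify_opened(sites, merged$ATAC_pre, merged$ATAC_post)
    bound[[tf]] <- peak_set(df, label = paste0(tf, "_bound"))
    .write_tsv(as.data.frame(bound[[tf]]),
               file.path(outdir, paste0("binding_sites_", tf, ".tsv")))
  }

  # --- co-bound sites and taxonomy ---
  cb <- cobound_sites(merged$FOXA1_double, merged$HNF4A_double)
  cbdf <- as.data.frame(cb)
  if (nrow(cbdf)) {
    cbdf$cobind_class <- classify_cobinding(cb, merged$FOXA1_single,
                                            merged$HNF4A_single)
    cbdf$accessibility <- classify_accessibility(cb, merged$ATAC_pre)
    cbdf$opened <- classify_opened(cb, merged$ATAC_pre, merged$ATAC_post)
  }
  cobound <- peak_set(cbdf, label = "cobound")
  .write_tsv(as.data.frame(cobound), file.path(outdir, "cobound_sites.tsv"))

  chromhmm <- NULL
  seg_path <- file.path(simdir, "chromhmm.bed")
  if (file.exists(seg_path) && nrow(cobound)) {
    seg <- read_bed(seg_path)
    chromhmm <- chromhmm_fractions(cobound, cobound$cobind_class, seg)
    .write_tsv(chromhmm, file.path(outdir, "chromhmm_fractions.tsv"))
  }

  # --- TSS attribution ---
  attribution <- data.frame(gene = genes$id, stringsAsFactors = FALSE)
  for (tf in c("foxa1", "hnf4a")) {
    att <- attribute_to_genes(bound[[tf]], genes, config$half_window_single)
    attribution[[paste0("n_", tf)]] <-
      vapply(genes$id, function(g)
        if (is.null(att[[g]])) 0L else nrow(att[[g]]), 0L)
  }
  if (nrow(cobound)) {
    att_cb <- attribute_to_genes(cobound, genes, config$half_window_cobound)
    for (cls in c("FP", "HP", "BOTH", "CB"))
      attribution[[paste0("n_", tolower(cls))]] <-
        vapply(genes$id, function(g)
          if (is.null(att_cb[[g]])) 0L else
            sum(att_cb[[g]]$cobind_class == cls), 0L)
  }
  .write_tsv(attribution, file.path(outdir, "gene_attribution.tsv"))

  # --- expression: activation + tissue enrichment ---
  cdf <- utils::read.table(.require_file(file.path(simdir, "counts.tsv")),
                           header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(m) <- cdf$gene
  cond <- ifelse(grepl("^uninduced", colnames(m)), "uninduced", "induced")
  counts <- count_matrix(m, cond)
  diff <- differential_table(counts, min_total = config$min_total)
  activated <- call_activated(diff, config$lfc_min, config$base_max)
  diff$activated <- diff$gene %in% activated
  .write_tsv(diff, file.path(outdir, "activation.tsv"))

  tdf <- utils::read.table(.require_file(file.path(simdir, "tissue.tsv")),
                           header = TRUE, sep = "\t", check.names = FALSE)
  tm <- as.matrix(tdf[, -1, drop = FALSE])
  rownames(tm) <- tdf$gene
  universe <- diff$gene
  act_u <- intersect(activated, universe)
  enr <- do.call(rbind, lapply(colnames(tm), function(t) {
    set <- tissue_enriched_genes(tm, t, config$tissue_fold)
    set_u <- intersect(set$genes, universe)
    k <- length(intersect(act_u, set_u))
    h <- hypergeom_enrichment(k, length(set_u), length(act_u),
                              length(universe))
    data.frame(tissue = t, set_size = length(set_u),
               n_activated = length(act_u), universe = length(universe),
               observed = k, expected = h$expected, pvalue = h$pvalue,
               log10_pvalue = h$log10_pvalue, stringsAsFactors = FALSE)
  }))
  .write_tsv(enr, file.path(outdir, "enrichment.tsv"))

  # --- motif counts per site group ---
  nulls <- lapply(pwms, build_score_null)
  count_group <- function(sites, p) {
    if (is.null(sites) || nrow(sites) == 0) return(numeric(0))
    win <- suppressWarnings(midpoint_window(sites, config$window_width,
                                            chrom_sizes))
    vapply(seq_len(nrow(win)), function(i)
      motif_count(p, genome, win[i, ], config$motif_p,
                  nulls[[p$id]]), 0L)
  }
  nulls <- stats::setNames(nulls, vapply(pwms, `[[`, "", "id"))
  rand <- sample_random_windows(genome, merged$ATAC_pre,
                                max(nrow(bound$foxa1), 1L),
                                config$window_width, seed = config$seed + 99L)
  groups <- list(
    foxa1_fp = count_group(cobound[cobound$cobind_class == "FP", ], pwms$FOXA1),
    hnf4a_hp = count_group(cobound[cobound$cobind_class == "HP", ], pwms$HNF4A),
    foxa1_cb = count_group(cobound[cobound$cobind_class == "CB", ], pwms$FOXA1),
    hnf4a_cb = count_group(cobound[cobound$cobind_class == "CB", ], pwms$HNF4A),
    foxa1_accessible = count_group(
      bound$foxa1[bound$foxa1$accessibility == "accessible", ], pwms$FOXA1),
    foxa1_inaccessible = count_group(
      bound$foxa1[bound$foxa1$accessibility == "inaccessible", ], pwms$FOXA1),
    hnf4a_accessible = count_group(
      bound$hnf4a[bound$hnf4a$accessibility == "accessible", ], pwms$HNF4A),
    hnf4a_inaccessible = count_group(
      bound$hnf4a[bound$hnf4a$accessibility == "inaccessible", ], pwms$HNF4A),
    random_foxa1 = count_group(rand, pwms$FOXA1),
    random_hnf4a = count_group(rand, pwms$HNF4A))
  groups <- groups[lengths(groups) > 0]
  summary <- compare_groups(groups)
  .write_tsv(summary, file.path(outdir, "motif_group_summary.tsv"))

  # --- affinity-model ROCs ---
  rocs <- binding_prediction_experiment(
    genome, pwms, c(bound, list(cobound = cobound)), merged$ATAC_pre,
    seed = config$seed, width = config$window_width)
  auc <- lapply(rocs, function(r)
    list(auc = r$auc, n_pos = r$n_pos, n_neg = r$n_neg))
  jsonlite::write_json(auc, file.path(outdir, "roc_auc.json"),
                       auto_unbox = TRUE, digits = NA)
  pts <- do.call(rbind, lapply(names(rocs), function(n)
    data.frame(comparison = n, threshold = rocs[[n]]$thresholds,
               fpr = rocs[[n]]$fpr, tpr = rocs[[n]]$tpr,
               stringsAsFactors = FALSE)))
  .write_tsv(pts, file.path(outdir, "roc_points.tsv"))

  # --- ground-truth recovery (synthetic runs only) ---
  recovery <- NULL
  plan_path <- file.path(simdir, "site_plan.tsv")
  if (file.exists(plan_path)) {
    plan <- utils::read.table(plan_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    recovery <- evaluate_recovery(plan, bound, cobound)
    jsonlite::write_json(recovery, file.path(outdir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  log <- c(sprintf("pioneerbind %s",
                   as.character(utils::packageVersion("pioneerbind"))),
           sprintf("simdir: %s", basename(simdir)),
           sprintf("seed: %d", config$seed),
           sprintf("config: %s", paste(names(unclass(config)),
                                       vapply(unclass(config), function(x)
                                         paste(x, collapse = ","), ""),
                                       sep = "=", collapse = " ")))
  writeLines(log, file.path(outdir, "run.log"))
  invisible(list(merged = merged, bound = bound, cobound = cobound,
                 chromhmm = chromhmm, attribution = attribution, diff = diff,
                 activated = activated, enrichment = enr,
                 motif_groups = groups, motif_summary = summary, rocs = rocs,
                 recovery = recovery, dir = outdir))
}

# first recovered row overlapping each planted window, NA if none
.match_by_overlap <- function(plan, recovered) {
  out <- rep(NA_integer_, nrow(plan))
  if (!nrow(recovered)) return(out)
  for (ch in unique(plan$chrom)) {
    psel <- which(plan$chrom == ch)
    rsel <- which(recovered$chrom == ch)
    if (!length(rsel)) next
    ir_p <- IRanges::IRanges(plan$start[psel] + 1L, plan$end[psel])
    ir_r <- IRanges::IRanges(recovered$start[rsel] + 1L, recovered$end[rsel])
    hits <- IRanges::findOverlaps(ir_p, ir_r, minoverlap = 1L, select = "first")
    out[psel] <- rsel[hits]
  }
  out
}

#' Score classification recovery against the planted ledger
#'
#' For every planted bound site, checks whether the pipeline's labels match
#' the ground truth. Single-factor sites are looked up (by window overlap) in
#' that factor's classified bound-site table and must match on accessibility
#' and opening (every planted inaccessible bound site is opened by
#' construction). Co-bound-class sites are looked up in the co-bound table
#' and must additionally match their FP/HP/BOTH/CB label. Sites absent from
#' the required track (peaks lost to replicate dropout) count as unrecovered
#' and are excluded from the accuracy denominator.
#'
#' @param plan a `SitePlan` (or its TSV read back).
#' @param bound named list with classified `PeakSet`s `foxa1`, `hnf4a`
#'   (columns `accessibility`, `opened`).
#' @param cobound classified co-bound `PeakSet` (columns `cobind_class`,
#'   `accessibility`, `opened`).
#' @return list: `n_planted`, `n_recovered`, `n_correct`, `recovered_fraction`,
#'   `accuracy` (correct / recovered).
#' @export
evaluate_recovery <- function(plan, bound, cobound) {
  plan <- plan[plan$class != "background", , drop = FALSE]
  n_rec <- 0L; n_cor <- 0L
  single <- list(FOXA1_accessible = "foxa1", FOXA1_inaccessible = "foxa1",
                 HNF4A_accessible = "hnf4a", HNF4A_inaccessible = "hnf4a")
  for (cls in unique(plan$class)) {
    rows <- plan[plan$class == cls, , drop = FALSE]
    if (cls %in% names(single)) {
      tab <- bound[[single[[cls]]]]
      idx <- .match_by_overlap(rows, tab)
      got <- !is.na(idx)
      n_rec <- n_rec + sum(got)
      want_acc <- ifelse(rows$accessible, "accessible", "inaccessible")
      want_open <- !rows$accessible
      n_cor <- n_cor + sum(got &
                             tab$accessibility[idx] == want_acc &
                             tab$opened[idx] == want_open, na.rm = TRUE)
    } else {
      idx <- .match_by_overlap(rows, cobound)
      got <- !is.na(idx)
      n_rec <- n_rec + sum(got)
      n_cor <- n_cor + sum(got &
                             cobound$cobind_class[idx] == cls &
                             cobound$accessibility[idx] == "inaccessible" &
                             cobound$opened[idx], na.rm = TRUE)
    }
  }
  list(n_planted = nrow(plan), n_recovered = n_rec, n_correct = n_cor,
       recovered_fraction = n_rec / nrow(plan),
       accuracy = if (n_rec > 0) n_cor / n_rec else NA_real_)
}

#' Aggregate analysis outputs into one summary JSON
#'
#' Reads the stage outputs of [run_analyze()] from `results_dir` and writes
#' `report.json`: co-binding class counts, the enrichment table, AUCs, motif
#' group summaries, and the recovery report. Missing stage outputs are
#' reported as `null` with a warning.
#'
#' @param results_dir directory written by [run_analyze()].
#' @return invisibly, the report list.
#' @export
run_report <- function(results_dir) {
  if (!dir.exists(results_dir))
    .input_error(paste("missing results directory:", results_dir))
  grab_tsv <- function(name) {
    p <- file.path(results_dir, name)
    if (!file.exists(p)) {
      warning("missing stage output: ", name)
      return(NULL)
    }
    utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  grab_json <- function(name) {
    p <- file.path(results_dir, name)
    if (!file.exists(p)) {
      warning("missing stage output: ", name)
      return(NULL)
    }
    jsonlite::read_json(p, simplifyVector = TRUE)
  }
  cb <- grab_tsv("cobound_sites.tsv")
  report <- list(
    cobound_total = if (is.null(cb)) NULL else nrow(cb),
    cobound_class_counts = if (is.null(cb) || !nrow(cb)) NULL else
      as.list(table(cb$cobind_class)),
    enrichment = grab_tsv("enrichment.tsv"),
    auc = grab_json("roc_auc.json"),
    motif_group_summary = grab_tsv("motif_group_summary.tsv"),
    recovery = grab_json("recovery.json"))
  jsonlite::write_json(report, file.path(results_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
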