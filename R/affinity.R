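#' ROC curve of a score-threshold classifier
#'
#' Sweeps the decision threshold over the union of observed scores (a window
#' is called positive when its score is `>= t`), recording the true- and
#' false-positive rates at each step; tied scores form a single step. The AUC
#' is the trapezoidal area under the empirical (fpr, tpr) curve, which equals
#' the Mann-Whitney U statistic normalized by `n_pos * n_neg`.
#'
#' @param scores_pos,scores_neg numeric scores of the positive / negative
#'   group (each non-empty).
#' @return An object of class `ROCResult`: list with `thresholds` (descending,
#'   starting at `Inf`), `fpr`, `tpr` (non-decreasing from (0,0) to (1,1)),
#'   `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg))
    stop("both score groups must be non-empty")
  thr <- c(Inf, sort(unique(c(scores_pos, scores_neg)), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores_pos >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores_neg >= t), 0)
  n <- length(thr)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-n]) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = length(scores_pos), n_neg = length(scores_neg)),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives vs %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' Boxplot-style group summaries
#'
#' Quartiles and 1.5 x IQR whisker bounds per group, matching the usual
#' boxplot convention (center line = median, box = Q1..Q3, whiskers = most
#' extreme points within 1.5 x IQR of the box).
#'
#' @param groups named list of numeric vectors (each non-empty).
#' @return data.frame with columns `group`, `n`, `q1`, `median`, `q3`,
#'   `whisker_lo`, `whisker_hi`.
#' @export
compare_groups <- function(groups) {
  stopifnot(length(groups) > 0, all(lengths(groups) > 0))
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(x[x >= q[1] - 1.5 * iqr])
    hi <- max(x[x <= q[3] + 1.5 * iqr])
    data.frame(group = g, n = length(x), q1 = q[1], median = q[2], q3 = q[3],
               whisker_lo = lo, whisker_hi = hi, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Aggregate affinity scores of the 500-bp midpoint windows of a PeakSet.
.window_scores <- function(pwms, genome, sites, width = 500L, mode = "clipped_sum") {
  sizes <- Biostrings::width(genome)
  names(sizes) <- names(genome)
  win <- suppressWarnings(midpoint_window(sites, width, chrom_sizes = sizes))
  vapply(seq_len(nrow(win)), function(i)
    aggregate_affinity_score(pwms, genome, win[i, ], mode = mode), 0)
}

#' Can motif content predict binding?
#'
#' Runs the motif-affinity prediction comparisons: (i) accessible bound sites
#' vs length-matched random windows; (ii) inaccessible bound sites vs
#' length-matched random inaccessible windows; (iii) inaccessible co-bound
#' sites vs random inaccessible windows under the combined two-factor score;
#' (iv) FP vs CB and HP vs CB, each under the relevant single factor's PWM.
#' Scores are [aggregate_affinity_score()] values of 500-bp midpoint windows;
#' each negative set is drawn 1:1 with its positives via
#' [sample_random_windows()]. Comparisons with an empty side are skipped with
#' a message.
#'
#' @param genome a `DNAStringSet`.
#' @param pwms named list with elements `FOXA1` and `HNF4A` (`PWM`s).
#' @param bound named list of `PeakSet`s with per-site metadata:
#'   `foxa1`, `hnf4a` (single-factor bound sites with an `accessibility`
#'   column) and `cobound` (with `accessibility` and `cobind_class` columns).
#' @param atac_pre merged uninduced ATAC `PeakSet` (defines "inaccessible"
#'   space for the random draws).
#' @param seed integer seed for the random negative sets.
#' @param width analysis window width (default 500).
#' @return named list of `ROCResult`s.
#' @export
binding_prediction_experiment <- function(genome, pwms, bound, atac_pre, seed,
                                          width = 500L) {
  empty_ps <- peak_set(character(), integer(), integer())
  res <- list()
  kseed <- 0L
  run <- function(name, pos_sites, pwm_list, exclude) {
    kseed <<- kseed + 1L
    if (is.null(pos_sites) || nrow(pos_sites) == 0) {
      message("skipping comparison with empty positive side: ", name)
      return(NULL)
    }
    neg <- sample_random_windows(genome, exclude, nrow(pos_sites), width,
                                 seed = seed + kseed)
    sp <- .window_scores(pwm_list, genome, pos_sites, width)
    sn <- .window_scores(pwm_list, genome, neg, width)
    res[[name]] <<- roc_curve(sp, sn)
  }
  for (tf in c("foxa1", "hnf4a")) {
    b <- bound[[tf]]
    pw <- pwms[[toupper(tf)]]
    run(paste0(tf, "_accessible_vs_random"),
        b[b$accessibility == "accessible", , drop = FALSE], pw, empty_ps)
    run(paste0(tf, "_inaccessible_vs_random"),
        b[b$accessibility == "inaccessible", , drop = FALSE], pw, atac_pre)
  }
  cb <- bound$cobound
  if (!is.null(cb) && nrow(cb)) {
    run("cobound_inaccessible_vs_random",
        cb[cb$accessibility == "inaccessible", , drop = FALSE],
        pwms, atac_pre)
    cbset <- cb[cb$cobind_class == "CB", , drop = FALSE]
    for (cls in c("FP", "HP")) {
      pos <- cb[cb$cobind_class == cls, , drop = FALSE]
      pw <- if (cls == "FP") pwms$FOXA1 else pwms$HNF4A
      name <- paste0(tolower(cls), "_vs_cb")
      if (nrow(pos) && nrow(cbset)) {
        sp <- .window_scores(pw, genome, pos, width)
        sn <- .window_scores(pw, genome, cbset, width)
        res[[name]] <- roc_curve(sp, sn)
      } else message("skipping comparison with empty side: ", name)
    }
  }
  res
}
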