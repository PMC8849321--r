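#' Construct a gene x sample count matrix
#'
#' @param counts non-negative integer matrix, genes in rows (rownames = gene
#'   ids), samples in columns.
#' @param condition character vector per sample, each `"uninduced"` or
#'   `"induced"`; at least one sample per condition.
#' @return An object of class `CountMatrix` (the matrix with a `condition`
#'   attribute).
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  stopifnot(length(condition) == ncol(counts),
            all(condition %in% c("uninduced", "induced")),
            all(c("uninduced", "induced") %in% condition))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  structure(counts, condition = condition, class = c("CountMatrix", class(counts)))
}

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over genes (restricted to
#' genes with a positive count in every sample) of
#' `counts[g, j] / geometric_mean(counts[g, ])`. Dividing a column by its
#' factor gives normalized counts on a common scale.
#'
#' @param counts a `CountMatrix` or plain matrix.
#' @return numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- unclass(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) stop("no gene has positive counts in every sample")
  logm <- log(m[pos, , drop = FALSE])
  loggeo <- rowMeans(logm)
  apply(logm, 2, function(col) exp(stats::median(col - loggeo)))
}

#' Per-gene differential summary
#'
#' Filters out genes with fewer than `min_total` reads summed over all
#' samples, normalizes by [size_factors()], and reports per-condition means
#' and the pseudocounted log2 fold change
#' `log2((induced_mean + pc) / (uninduced_mean + pc))`.
#'
#' @param counts a `CountMatrix`.
#' @param pseudocount added to both means in the fold change (default 1).
#' @param min_total minimum total raw reads for a gene to be kept (default 10).
#' @return data.frame of class `DifferentialTable` with columns `gene`,
#'   `uninduced_norm_mean`, `induced_norm_mean`, `log2fc` (and no `padj`
#'   column; one may be merged in from an external differential analysis).
#' @export
differential_table <- function(counts, pseudocount = 1, min_total = 10) {
  cond <- attr(counts, "condition")
  m <- unclass(counts)
  keep <- rowSums(m) >= min_total
  m <- m[keep, , drop = FALSE]
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  un <- rowMeans(norm[, cond == "uninduced", drop = FALSE])
  ind <- rowMeans(norm[, cond == "induced", drop = FALSE])
  out <- data.frame(gene = rownames(m),
                    uninduced_norm_mean = unname(un),
                    induced_norm_mean = unname(ind),
                    log2fc = log2((unname(ind) + pseudocount) /
                                    (unname(un) + pseudocount)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DifferentialTable", "data.frame")
  out
}

#' Call activated genes
#'
#' A gene is upregulated if `log2fc >= lfc_min` and activated if additionally
#' its uninduced normalized mean is below `base_max` (the "silent before
#' induction" requirement). When the table carries a `padj` column, calls are
#' further restricted to `padj <= padj_max`.
#'
#' @param diff a `DifferentialTable`.
#' @param lfc_min minimum log2 fold change (default 1).
#' @param base_max maximum uninduced normalized mean (default 50).
#' @param padj_max adjusted-p cutoff applied only if `padj` present.
#' @return character vector of activated gene ids.
#' @export
call_activated <- function(diff, lfc_min = 1, base_max = 50, padj_max = 0.05) {
  sel <- diff$log2fc >= lfc_min & diff$uninduced_norm_mean < base_max
  if (!is.null(diff$padj)) sel <- sel & !is.na(diff$padj) & diff$padj <= padj_max
  diff$gene[sel]
}

#' Tissue-enriched gene set (fourfold rule)
#'
#' A gene is enriched in `tissue` iff its expression there is at least `fold`
#' times its maximum expression in any other tissue. A gene expressed only in
#' the tissue of interest (max elsewhere 0, own value > 0) counts as enriched;
#' an all-zero gene does not.
#'
#' @param table numeric matrix or data.frame, genes in rows (rownames = ids),
#'   tissues in columns.
#' @param tissue column name of the tissue of interest.
#' @param fold enrichment fold (default 4).
#' @return list of class `TissueGeneSet`: `tissue`, `genes` (character),
#'   `universe_size`.
#' @export
tissue_enriched_genes <- function(table, tissue, fold = 4) {
  m <- as.matrix(table)
  if (ncol(m) < 2) stop("need at least two tissues")
  if (!tissue %in% colnames(m)) stop("unknown tissue: ", tissue)
  own <- m[, tissue]
  other <- m[, setdiff(colnames(m), tissue), drop = FALSE]
  maxo <- apply(other, 1, max)
  enriched <- (own >= fold * maxo) & (own > 0)
  structure(list(tissue = tissue, genes = rownames(m)[enriched],
                 universe_size = nrow(m)),
            class = "TissueGeneSet")
}

#' Cumulative hypergeometric enrichment
#'
#' Upper-tail probability of observing at least `k` genes of a size-`K` set
#' among `n` draws from a universe of `N`, i.e. `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`, computed in log space for stability at
#' large `N`. Also returns the expected overlap `n * K / N`.
#'
#' @param k_obs observed overlap.
#' @param set_size size `K` of the gene set within the universe.
#' @param n_drawn number of drawn (e.g. activated) genes.
#' @param universe universe size `N`.
#' @return list with `expected`, `pvalue`, and `log10_pvalue` (exact even
#'   when `pvalue` underflows double precision).
#' @export
hypergeom_enrichment <- function(k_obs, set_size, n_drawn, universe) {
  if (any(c(k_obs, set_size, n_drawn, universe) < 0) ||
      set_size > universe || n_drawn > universe ||
      k_obs > min(set_size, n_drawn))
    stop("inconsistent hypergeometric arguments")
  logp <- stats::phyper(k_obs - 1, set_size, universe - set_size, n_drawn,
                        lower.tail = FALSE, log.p = TRUE)
  list(expected = n_drawn * set_size / universe,
       pvalue = exp(logp),
       log10_pvalue = logp / log(10))
}
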