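# Count, for each row of `sites`, overlapping intervals of `other` (>= 1 bp).
.overlap_counts <- function(sites, other) {
  n <- nrow(sites)
  out <- integer(n)
  for (ch in unique(sites$chrom)) {
    sel <- which(sites$chrom == ch)
    ir_s <- IRanges::IRanges(start = sites$start[sel] + 1L, end = sites$end[sel])
    ir_o <- .chrom_iranges(other, ch)
    out[sel] <- if (length(ir_o))
      IRanges::countOverlaps(ir_s, ir_o, minoverlap = 1L) else 0L
  }
  out
}

#' Classify binding sites by prior accessibility
#'
#' A bound site is `accessible` iff it overlaps at least one peak of the
#' uninduced (pre-induction) ATAC set, else `inaccessible` — the
#' "inaccessible prior to induction" contrast.
#'
#' @param binding a `PeakSet` of binding sites.
#' @param atac_pre merged uninduced ATAC `PeakSet`.
#' @return character vector (`"accessible"`/`"inaccessible"`), one per site,
#'   in the order of `binding`.
#' @export
classify_accessibility <- function(binding, atac_pre) {
  ifelse(.overlap_counts(binding, atac_pre) > 0L, "accessible", "inaccessible")
}

#' Flag opened sites
#'
#' A site is `opened` iff it was inaccessible before induction and overlaps
#' at least one induced ATAC peak. Opening is defined only for previously
#' inaccessible sites: an already-accessible site is never "opened".
#'
#' @param binding a `PeakSet` of binding sites.
#' @param atac_pre,atac_post merged uninduced / induced ATAC `PeakSet`s.
#' @return logical vector, one per site.
#' @export
classify_opened <- function(binding, atac_pre, atac_post) {
  acc <- classify_accessibility(binding, atac_pre)
  acc == "inaccessible" & .overlap_counts(binding, atac_post) > 0L
}

#' Derive co-bound sites from the two double-expression tracks
#'
#' Clusters the pooled FOXA1 and HNF4A double-expression peaks by transitive
#' >= 1 bp overlap and emits the union span of every cluster containing at
#' least one peak from each factor.
#'
#' @param foxa1_dbl,hnf4a_dbl replicate-merged `PeakSet`s of the two factors
#'   in the double-expression condition.
#' @return A `PeakSet` of co-bound sites.
#' @export
cobound_sites <- function(foxa1_dbl, hnf4a_dbl) {
  .reproducible_union(foxa1_dbl, hnf4a_dbl, label = "cobound")
}

#' Assign the pioneered/cooperative taxonomy to co-bound sites
#'
#' For each co-bound site: `FP` (FOXA1-pioneered) if it overlaps a peak of the
#' FOXA1-alone track but none of the HNF4A-alone track; `HP` symmetrically;
#' `BOTH` if it overlaps peaks of both single-expression tracks; `CB`
#' (cooperatively bound) if neither factor bound it when expressed alone.
#'
#' @param cobound `PeakSet` from [cobound_sites()].
#' @param foxa1_single,hnf4a_single replicate-merged single-expression
#'   `PeakSet`s.
#' @return character vector in `FP`, `HP`, `BOTH`, `CB`, one per co-bound
#'   site.
#' @export
classify_cobinding <- function(cobound, foxa1_single, hnf4a_single) {
  f <- .overlap_counts(cobound, foxa1_single) > 0L
  h <- .overlap_counts(cobound, hnf4a_single) > 0L
  ifelse(f & h, "BOTH", ifelse(f, "FP", ifelse(h, "HP", "CB")))
}

#' Chromatin-state composition of site classes
#'
#' Assigns each site to the chromatin-state segment with maximal bp overlap
#' (ties broken toward the segment with the leftmost start) and reports, for
#' every class, the fraction of its sites in each state. Sites overlapping no
#' segment are reported under `"unassigned"`. Segments must not overlap one
#' another.
#'
#' @param sites a `PeakSet`.
#' @param classes character vector of class labels, one per site.
#' @param segments a `PeakSet` whose `name` column holds the state label.
#' @return data.frame with columns `class`, `state`, `n`, `fraction`;
#'   fractions sum to 1 within each class.
#' @export
chromhmm_fractions <- function(sites, classes, segments) {
  stopifnot(nrow(sites) == length(classes))
  if (is.null(segments$name)) stop("segments must carry state labels in 'name'")
  for (ch in unique(segments$chrom)) {
    ir <- .chrom_iranges(segments, ch)
    if (length(IRanges::reduce(ir, min.gapwidth = 0L)) != length(ir))
      stop("overlapping ChromHMM segments on ", ch)
  }
  state <- rep("unassigned", nrow(sites))
  for (ch in unique(sites$chrom)) {
    ssel <- which(sites$chrom == ch)
    gsel <- which(segments$chrom == ch)
    if (!length(gsel)) next
    ir_s <- IRanges::IRanges(start = sites$start[ssel] + 1L, end = sites$end[ssel])
    ir_g <- IRanges::IRanges(start = segments$start[gsel] + 1L,
                             end = segments$end[gsel])
    hits <- IRanges::findOverlaps(ir_s, ir_g, minoverlap = 1L)
    if (!length(hits)) next
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- pmin(BiocGenerics::end(ir_s)[q], BiocGenerics::end(ir_g)[s]) -
      pmax(BiocGenerics::start(ir_s)[q], BiocGenerics::start(ir_g)[s]) + 1L
    segstart <- segments$start[gsel][s]
    # per site: max overlap, ties -> leftmost-starting segment
    ord <- order(q, -ov, segstart)
    first <- !duplicated(q[ord])
    state[ssel[q[ord][first]]] <- segments$name[gsel][s[ord][first]]
  }
  tab <- table(class = classes, state = state)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("class", "state", "n")
  tot <- stats::ave(df$n, df$class, FUN = sum)
  df$fraction <- ifelse(tot > 0, df$n / tot, 0)
  rownames(df) <- NULL
  df
}
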