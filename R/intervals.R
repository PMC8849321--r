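#' @importFrom IRanges IRanges findOverlaps reduce countOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Construct a PeakSet
#'
#' A PeakSet is the package's container for genomic intervals: a sorted
#' data.frame of 0-based half-open intervals `[start, end)`, the coordinate
#' convention of BED. All overlap logic in the package operates on PeakSets.
#'
#' @param chrom character vector of chromosome names, or a data.frame with
#'   columns `chrom`, `start`, `end` (and optionally `name`, `strand`).
#' @param start,end integer vectors; 0-based start (inclusive) and end
#'   (exclusive), `start < end`.
#' @param name optional character vector of interval names.
#' @param strand optional character vector in `+`, `-`, `.`.
#' @param label free-text label for the set (e.g. the track it came from).
#' @return An object of class `PeakSet` (a sorted data.frame).
#' @export
peak_set <- function(chrom, start = NULL, end = NULL, name = NULL,
                     strand = NULL, label = "") {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  } else {
    df <- data.frame(chrom = as.character(chrom),
                     start = as.integer(start),
                     end = as.integer(end),
                     stringsAsFactors = FALSE)
    if (!is.null(name)) df$name <- as.character(name)
    if (!is.null(strand)) df$strand <- as.character(strand)
  }
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (nrow(df)) {
    if (any(is.na(df$start) | is.na(df$end) | is.na(df$chrom)))
      stop("PeakSet: NA coordinates")
    if (any(df$start < 0L)) stop("PeakSet: negative start")
    if (any(df$start >= df$end)) stop("PeakSet: start must be < end")
    if (any(!nzchar(df$chrom))) stop("PeakSet: empty chromosome name")
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, class = c("PeakSet", "data.frame"), label = label)
}

#' @export
print.PeakSet <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("PeakSet%s with %d interval(s)\n",
              if (nzchar(lab)) paste0(" '", lab, "'") else "", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

# IRanges view of a PeakSet restricted to one chromosome (1-based closed).
.chrom_iranges <- function(ps, chrom) {
  sel <- ps$chrom == chrom
  IRanges::IRanges(start = ps$start[sel] + 1L, end = ps$end[sel])
}

#' Read a BED file into a PeakSet
#'
#' Accepts BED3+ (tab-separated, no header): chrom, start, end, and optionally
#' name and strand columns. Coordinates are kept 0-based half-open. Lines with
#' `end <= start` or non-numeric coordinates are rejected with the offending
#' line number.
#'
#' @param path path to a BED file.
#' @param label label to attach to the returned PeakSet (default: file name).
#' @return A `PeakSet`.
#' @export
read_bed <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(peak_set(character(), integer(), integer(), label = label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("BED parse error at line %d: fewer than 3 fields",
                 which(nf < 3L)[1]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("BED parse error at line %d: non-integer coordinates", bad[1]))
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: end <= start", bad[1]))
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""), NA_character_)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (any(nf >= 4L)) df$name <- name
  if (any(nf >= 6L)) df$strand <- strand
  peak_set(df, label = label)
}

#' Write a PeakSet as BED
#'
#' Emits BED3 (plus a name column when present), tab-separated, no header,
#' sorted by (chrom, start, end). `write_bed(read_bed(x))` reproduces the
#' coordinates of `x` after sorting.
#'
#' @param peaks a `PeakSet`.
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(peaks))
  df <- as.data.frame(peaks)[, cols, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Do two intervals overlap?
#'
#' Half-open overlap test: `TRUE` iff the intervals are on the same chromosome
#' and share at least 1 bp, i.e. `a$start < b$end && b$start < a$end`.
#' Abutting intervals (`[100,200)` vs `[200,300)`) do not overlap.
#'
#' @param a,b single intervals: lists or one-row data.frames with `chrom`,
#'   `start`, `end`.
#' @return logical scalar.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

# Cluster the pooled intervals of two PeakSets by transitive >=1 bp overlap and
# emit the union span of every cluster containing at least one interval from
# each set. min.gapwidth = 0L keeps abutting intervals in separate clusters.
.reproducible_union <- function(a, b, label = "") {
  chroms <- sort(unique(c(a$chrom, b$chrom)))
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    ch <- chroms[k]
    ir_a <- .chrom_iranges(a, ch)
    ir_b <- .chrom_iranges(b, ch)
    pooled <- c(ir_a, ir_b)
    if (!length(pooled)) next
    red <- IRanges::reduce(pooled, min.gapwidth = 0L)
    keep <- IRanges::countOverlaps(red, ir_a, minoverlap = 1L) > 0L &
      IRanges::countOverlaps(red, ir_b, minoverlap = 1L) > 0L
    red <- red[keep]
    if (length(red))
      out[[k]] <- data.frame(chrom = ch,
                             start = BiocGenerics::start(red) - 1L,
                             end = BiocGenerics::end(red),
                             stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(peak_set(character(), integer(), integer(), label = label))
  peak_set(do.call(rbind, out), label = label)
}

#' Merge replicate peak sets into reproducible peaks
#'
#' Pools the peaks of two replicates, clusters them by transitive >=1 bp
#' overlap, and keeps the union span of every cluster supported by at least
#' one peak from each replicate. Peaks present in only one replicate are
#' dropped. This is the overlap-based reproducibility filter used in place of
#' a model-based replicate analysis.
#'
#' @param rep1,rep2 `PeakSet`s from the two replicates.
#' @return A `PeakSet` of reproducible union-span peaks (pairwise disjoint).
#' @export
merge_replicates <- function(rep1, rep2) {
  .reproducible_union(rep1, rep2,
                      label = paste0("merged(", attr(rep1, "label"), ")"))
}

#' Attribute peaks to genes by TSS proximity
#'
#' A peak is attributed to a gene iff it overlaps the window
#' `[tss - half_window, tss + half_window)`. The window is strand-independent
#' and a peak may be attributed to several genes. Conventional half-windows:
#' 25 kb for single-TF binding sites and 50 kb for co-bound sites.
#'
#' @param peaks a `PeakSet`.
#' @param genes gene annotation data.frame with columns `id`, `chrom`, `tss`.
#' @param half_window half-width of the TSS window in bp (> 0).
#' @return Named list mapping gene id to the `PeakSet` of attributed peaks;
#'   genes with no attributed peak are omitted.
#' @export
attribute_to_genes <- function(peaks, genes, half_window) {
  stopifnot(half_window > 0)
  if (anyDuplicated(genes$id)) stop("gene ids must be unique")
  res <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    psel <- which(peaks$chrom == ch)
    if (!length(psel)) next
    win <- IRanges::IRanges(start = pmax(g$tss - half_window, 0) + 1L,
                            end = g$tss + half_window)
    ir_p <- IRanges::IRanges(start = peaks$start[psel] + 1L,
                             end = peaks$end[psel])
    hits <- IRanges::findOverlaps(win, ir_p, minoverlap = 1L)
    rows_by_gene <- split(psel[S4Vectors::subjectHits(hits)],
                          S4Vectors::queryHits(hits))
    pdf <- as.data.frame(peaks)
    for (i in names(rows_by_gene)) {
      gid <- g$id[as.integer(i)]
      res[[gid]] <- peak_set(pdf[rows_by_gene[[i]], , drop = FALSE],
                             label = gid)
    }
  }
  res
}

#' 500-bp window centered on an interval midpoint
#'
#' Midpoint is `start + floor((end - start) / 2)`; the window is
#' `[mid - width/2, mid + width/2)`. Windows extending beyond a chromosome are
#' clipped (with a warning) when `chrom_sizes` is supplied.
#'
#' @param site a `PeakSet` (vectorized over rows) or a single interval.
#' @param width even window width in bp (default 500).
#' @param chrom_sizes optional named vector of chromosome lengths for clipping.
#' @return A `PeakSet` of windows, one per input interval, in input order of
#'   the sorted input.
#' @export
midpoint_window <- function(site, width = 500L, chrom_sizes = NULL) {
  stopifnot(width %% 2L == 0L, width > 0L)
  if (!is.data.frame(site)) site <- as.data.frame(site)
  mid <- site$start + (site$end - site$start) %/% 2L
  start <- mid - width %/% 2L
  end <- mid + width %/% 2L
  clipped <- start < 0L
  if (!is.null(chrom_sizes)) {
    sz <- unname(chrom_sizes[site$chrom])
    clipped <- clipped | end > sz
    end <- pmin(end, sz)
  }
  start <- pmax(start, 0L)
  if (any(clipped))
    warning(sum(clipped), " window(s) clipped at chromosome boundary")
  out <- data.frame(chrom = site$chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(site$name)) out$name <- site$name
  peak_set(out, label = "midpoint_windows")
}

#' Sample length-matched random windows
#'
#' Draws `n` windows of exactly `length` bp uniformly over genome positions
#' whose window overlaps no interval of `exclude` and contains fewer than 10%
#' non-ACGT bases. Draws are independent (windows may overlap each other).
#' With `exclude` set to the accessible peaks this produces the
#' "length-matched random inaccessible sequences" negative set.
#'
#' @param genome a `DNAStringSet`.
#' @param exclude a `PeakSet` of forbidden intervals (may be empty).
#' @param n number of windows.
#' @param length window length in bp.
#' @param seed integer seed; sampling is deterministic given the seed.
#' @param max_tries rejection-sampling budget (default `1000 * n`).
#' @return A `PeakSet` of `n` windows.
#' @export
sample_random_windows <- function(genome, exclude, n, length, seed,
                                  max_tries = 1000L * n) {
  set.seed(seed)
  sizes <- Biostrings::width(genome)
  names(sizes) <- names(genome)
  avail <- sizes - length
  if (all(avail < 0)) stop("no chromosome can hold a window of that length")
  chroms <- names(sizes)[avail >= 0]
  w <- (avail[chroms] + 1)
  got <- list(); n_got <- 0L; tries <- 0L
  while (n_got < n && tries < max_tries) {
    batch <- min(max(2L * (n - n_got), 64L), max_tries - tries)
    tries <- tries + batch
    ch <- sample(chroms, batch, replace = TRUE, prob = w)
    st <- floor(stats::runif(batch) * (avail[ch] + 1))
    ok <- rep(TRUE, batch)
    for (c2 in unique(ch)) {
      sel <- ch == c2
      ir_e <- .chrom_iranges(exclude, c2)
      if (length(ir_e)) {
        cand <- IRanges::IRanges(start = st[sel] + 1L, end = st[sel] + length)
        ok[sel] <- IRanges::countOverlaps(cand, ir_e, minoverlap = 1L) == 0L
      }
    }
    keep <- which(ok)
    if (length(keep)) {
      seqs <- as.character(Biostrings::subseq(genome[ch[keep]],
                                              start = st[keep] + 1L,
                                              width = length))
      nfrac <- 1 - (nchar(gsub("[^ACGT]", "", seqs)) / length)
      keep <- keep[nfrac < 0.10]
    }
    if (length(keep)) {
      take <- utils::head(keep, n - n_got)
      got[[length(got) + 1L]] <- data.frame(chrom = ch[take],
                                            start = as.integer(st[take]),
                                            end = as.integer(st[take]) + as.integer(length),
                                            stringsAsFactors = FALSE)
      n_got <- n_got + length(take)
    }
  }
  if (n_got < n)
    stop(sprintf("random window sampling exhausted its budget: %d of %d placed",
                 n_got, n))
  df <- do.call(rbind, got)
  df$name <- sprintf("random_%04d", seq_len(nrow(df)))
  peak_set(df, label = "random_windows")
}

#' @rdname sample_random_windows
#' @param accessible a `PeakSet` of accessible regions to avoid.
#' @export
sample_random_inaccessible <- function(genome, accessible, n, length, seed,
                                       max_tries = 1000L * n) {
  sample_random_windows(genome, accessible, n, length, seed, max_tries)
}

#' Read / write the gene annotation table
#'
#' Tab-separated with header: `id`, `chrom`, `tss` (0-based bp), `strand`.
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_gene_annotation <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "tss", "strand") %in% names(g)))
  if (anyDuplicated(g$id)) stop("duplicate gene ids in annotation")
  if (any(g$tss < 0)) stop("negative TSS in annotation")
  g
}

#' @rdname read_gene_annotation
#' @param genes data.frame with columns `id`, `chrom`, `tss`, `strand`.
#' @export
write_gene_annotation <- function(genes, path) {
  utils::write.table(genes[, c("id", "chrom", "tss", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
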