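DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param probs numeric width x 4 matrix of base probabilities, columns in
#'   order A, C, G, T; every row must sum to 1 (tolerance 1e-9).
#' @param id motif identifier.
#' @param background length-4 base composition of the null model (sums to 1;
#'   default uniform).
#' @return An object of class `PWM`: list with `id`, `width`, `probs`,
#'   `background`.
#' @export
pwm <- function(probs, id = "pwm", background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4L, nrow(probs) >= 1L)
  colnames(probs) <- DNA_BASES
  if (any(probs < 0)) stop("PWM probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("PWM rows must each sum to 1")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background must sum to 1")
  structure(list(id = id, width = nrow(probs), probs = probs,
                 background = as.numeric(background)),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s', width %d\n", x$id, x$width))
  print(round(x$probs, 3))
  invisible(x)
}

# width x 4 matrix of per-position log2 odds (may contain -Inf where prob 0).
.pwm_logodds <- function(p) {
  lo <- log2(sweep(p$probs, 2, p$background, "/"))
  lo[p$probs == 0] <- -Inf
  lo
}

#' Read PWMs from a JASPAR PFM text file
#'
#' Parses the JASPAR position frequency matrix format: a `>ID name` header
#' followed by four rows (A, C, G, T) of counts or frequencies, with or
#' without the bracketed `A [ 1 2 3 ]` row style. Each column of counts is
#' converted to probabilities after adding `pseudocount` to every cell.
#'
#' @param path file path.
#' @param pseudocount non-negative value added to each count (default 0.1,
#'   the FIMO convention).
#' @param background length-4 background passed to [pwm()].
#' @return A `PWM` if the file holds one record, else a named list of `PWM`s.
#' @export
read_jaspar <- function(path, pseudocount = 0.1, background = rep(0.25, 4)) {
  stopifnot(pseudocount >= 0)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR header ('>') found in ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4L)
      stop("JASPAR record must have exactly 4 matrix rows, got ", length(block))
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    rows <- lapply(block, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("\\[|\\]", " ", l)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (anyNA(v)) stop("unparseable JASPAR matrix row: ", l)
      v
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("ragged JASPAR matrix rows in record ", id)
    counts <- do.call(rbind, rows)  # 4 x width, rows A,C,G,T
    if (any(counts < 0)) stop("negative counts in JASPAR record ", id)
    counts <- counts + pseudocount
    probs <- t(sweep(counts, 2, colSums(counts), "/"))  # width x 4
    out[[id]] <- pwm(probs, id = id, background = background)
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' Write a PWM in JASPAR PFM format
#'
#' Probabilities are written at full precision, so
#' `read_jaspar(write_jaspar(p), pseudocount = 0)` reproduces them to 1e-9.
#'
#' @param p a `PWM` or list of `PWM`s.
#' @param path output path.
#' @export
write_jaspar <- function(p, path) {
  if (inherits(p, "PWM")) p <- list(p)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in p) {
    writeLines(paste0(">", m$id), con)
    for (j in 1:4)
      writeLines(sprintf("%s [ %s ]", DNA_BASES[j],
                         paste(format(m$probs[, j], digits = 17),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Log-odds score of one window
#'
#' `sum_i log2(probs[i, seq[i]] / background[seq[i]])` in bits. Returns `NA`
#' if the window contains a non-ACGT base.
#'
#' @param p a `PWM`.
#' @param seq character string of length exactly `p$width`.
#' @return score in bits (possibly `-Inf` for zero-probability bases).
#' @export
score_window <- function(p, seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  if (length(codes) != p$width)
    stop("sequence length must equal PWM width")
  if (anyNA(codes)) return(NA_real_)
  lo <- .pwm_logodds(p)
  sum(lo[cbind(seq_len(p$width), codes)])
}

#' Exact null distribution of the integerized PWM score
#'
#' Per-position log-odds scores are integerized at `granularity` bins per bit
#' and the `width` independent per-position distributions under the background
#' are convolved by dynamic programming, giving the exact pmf of the
#' integerized score of a random background window. Positions with probability
#' 0 score `-Inf`; their mass is tracked separately and absorbed into the
#' p-value denominator (any window containing such a base has p-value 1).
#'
#' @param p a `PWM`.
#' @param granularity bins per bit (>= 100; default 1000).
#' @return An object of class `ScoreNull`: list with `granularity`,
#'   `int_scores` (width x 4 integer matrix, `NA` for `-Inf`), `min`, `max`
#'   (integer support bounds), `pmf` (over `min:max`), `tail`
#'   (`tail[s - min + 1] = P(S >= s)`), and `p_neg_inf`.
#' @export
build_score_null <- function(p, granularity = 1000L) {
  stopifnot(granularity >= 100L)
  lo <- .pwm_logodds(p)
  int <- round(lo * granularity)
  int[!is.finite(lo)] <- NA_integer_
  storage.mode(int) <- "integer"
  bg <- p$background
  # DP over positions on an integer offset grid.
  lo_min <- 0L; lo_max <- 0L
  fin_min <- suppressWarnings(apply(int, 1, min, na.rm = TRUE))
  fin_max <- suppressWarnings(apply(int, 1, max, na.rm = TRUE))
  all_na <- apply(is.na(int), 1, all)
  if (any(all_na)) {
    # every base impossible at some position: all windows score -Inf
    return(structure(list(granularity = granularity, int_scores = int,
                          min = 0L, max = 0L, pmf = numeric(1),
                          tail = numeric(1), p_neg_inf = 1),
                     class = "ScoreNull"))
  }
  lo_min <- sum(fin_min); lo_max <- sum(fin_max)
  pmf <- 1
  cur_min <- 0L
  p_inf <- 0
  for (i in seq_len(p$width)) {
    vals <- int[i, ]
    ok <- !is.na(vals)
    p_inf <- p_inf + (1 - p_inf) * sum(bg[!ok])
    newlen <- length(pmf) + (max(vals[ok]) - min(vals[ok]))
    new <- numeric(newlen)
    new_min <- cur_min + min(vals[ok])
    for (j in which(ok)) {
      off <- vals[j] - min(vals[ok])
      idx <- seq_along(pmf) + off
      new[idx] <- new[idx] + bg[j] * pmf
    }
    pmf <- new
    cur_min <- new_min
  }
  tail <- rev(cumsum(rev(pmf)))
  structure(list(granularity = granularity, int_scores = int,
                 min = cur_min, max = cur_min + length(pmf) - 1L,
                 pmf = pmf, tail = tail, p_neg_inf = p_inf),
            class = "ScoreNull")
}

#' @export
print.ScoreNull <- function(x, ...) {
  cat(sprintf("ScoreNull: %d bins/bit, support [%.3f, %.3f] bits, P(-Inf) = %g\n",
              x$granularity, x$min / x$granularity, x$max / x$granularity,
              x$p_neg_inf))
  invisible(x)
}

#' Null p-value of an integerized score
#'
#' `P(S >= s)` under the background; `-Inf` (or any score at or below the
#' support minimum) has p-value 1.
#'
#' @param null a `ScoreNull`.
#' @param int_score integer score(s) on the null's grid (`NA` = `-Inf`).
#' @return numeric vector of p-values in (0, 1].
#' @export
null_pvalue <- function(null, int_score) {
  pv <- rep(1, length(int_score))
  fin <- which(!is.na(int_score))
  if (length(fin)) {
    # a finite observed score always lies inside the finite support
    idx <- pmin(pmax(int_score[fin] - null$min + 1L, 1L), length(null$tail))
    pv[fin] <- null$tail[idx]
  }
  pv
}

# integer codes for a sequence, NA for non-ACGT
.seq_codes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
}

#' Reverse complement of a DNA string
#' @param seq character string (non-ACGT bases map to N).
#' @return character string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Sliding integer scores of pwm over codes (one strand); NA where the window
# contains a non-ACGT base. Returns integer vector of length L - w + 1.
.slide_scores <- function(int_scores, codes) {
  w <- nrow(int_scores)
  L <- length(codes)
  n_off <- L - w + 1L
  if (n_off < 1L) return(integer(0))
  s <- rep(0L, n_off)
  na <- rep(FALSE, n_off)
  for (i in seq_len(w)) {
    v <- int_scores[i, codes[i:(i + n_off - 1L)]]
    vna <- is.na(codes[i:(i + n_off - 1L)]) | is.na(v)
    na <- na | vna
    v[vna] <- 0L
    s <- s + v
  }
  s[na] <- NA_integer_
  s
}

#' Scan a sequence with a PWM, FIMO-style
#'
#' Slides the PWM over both strands (minus strand scored on the reverse
#' complement), computes exact null p-values from the integerized score
#' distribution, and reports every window with `p <= p_thresh`. Windows
#' containing non-ACGT bases are skipped. Overlapping hits and two-strand
#' hits at the same position are all retained.
#'
#' @param p a `PWM`.
#' @param seq DNA string of length >= `p$width`.
#' @param p_thresh p-value threshold (default 1e-3).
#' @param null optional precomputed [build_score_null()] result for `p`.
#' @return data.frame of class `MotifHits`: `start`, `end` (0-based half-open,
#'   relative to `seq`), `strand`, `score` (bits), `pvalue`, `motif`.
#' @export
scan_sequence <- function(p, seq, p_thresh = 1e-3, null = NULL) {
  if (is.null(null)) null <- build_score_null(p)
  w <- p$width
  res <- list()
  for (strand in c("+", "-")) {
    s_seq <- if (strand == "+") seq else revcomp(seq)
    codes <- .seq_codes(s_seq)
    if (length(codes) < w) next
    ints <- .slide_scores(null$int_scores, codes)
    pv <- null_pvalue(null, ints)
    hit <- which(!is.na(ints) & pv <= p_thresh)
    if (!length(hit)) next
    L <- length(codes)
    start0 <- if (strand == "+") hit - 1L else L - (hit - 1L) - w
    res[[strand]] <- data.frame(start = start0, end = start0 + w,
                                strand = strand,
                                score = ints[hit] / null$granularity,
                                pvalue = pv[hit], motif = p$id,
                                stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(start = integer(), end = integer(), strand = character(),
               score = numeric(), pvalue = numeric(), motif = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MotifHits", "data.frame")
  out
}

# Extract the sequence of one interval from a DNAStringSet genome.
.site_seq <- function(genome, site) {
  sz <- Biostrings::width(genome)[match(site$chrom, names(genome))]
  if (is.na(sz)) stop("chromosome not in genome: ", site$chrom)
  s <- max(site$start, 0L); e <- min(site$end, sz)
  if (e - s < site$end - site$start)
    warning("site clipped at chromosome boundary: ",
            site$chrom, ":", site$start, "-", site$end)
  as.character(Biostrings::subseq(genome[[site$chrom]], s + 1L, e))
}

#' Count motif occurrences in a window
#'
#' Number of [scan_sequence()] hits at `p <= p_thresh` inside the window
#' (conventionally a 500-bp midpoint window).
#'
#' @param p a `PWM`.
#' @param genome a `DNAStringSet`.
#' @param site single interval (list/one-row data.frame with `chrom`,
#'   `start`, `end`).
#' @inheritParams scan_sequence
#' @return integer count.
#' @export
motif_count <- function(p, genome, site, p_thresh = 1e-3, null = NULL) {
  nrow(scan_sequence(p, .site_seq(genome, site), p_thresh, null))
}

#' Aggregate motif-affinity score of a window
#'
#' The "summed motif content" of a sequence: with the default
#' `mode = "clipped_sum"`, the sum over the listed PWMs, both strands, and all
#' valid offsets of `max(0, log-odds bits)`, so every window scoring above
#' background contributes however weak, and motif-free sequence contributes
#' ~0. `mode = "relaxed_count"` instead counts hits at a relaxed p-value
#' threshold (`relaxed_p`, default 1). Pass one PWM for a single-factor score
#' or both PWMs for the combined two-factor score.
#'
#' @param pwms a `PWM` or list of `PWM`s.
#' @param genome a `DNAStringSet`.
#' @param site single interval (conventionally a 500-bp window).
#' @param mode `"clipped_sum"` (default) or `"relaxed_count"`.
#' @param relaxed_p threshold for `"relaxed_count"`.
#' @param nulls optional named list of precomputed `ScoreNull`s keyed by
#'   PWM id (used by `"relaxed_count"`).
#' @return numeric score (0 for a window with no valid offsets).
#' @export
aggregate_affinity_score <- function(pwms, genome, site,
                                     mode = c("clipped_sum", "relaxed_count"),
                                     relaxed_p = 1, nulls = NULL) {
  mode <- match.arg(mode)
  if (inherits(pwms, "PWM")) pwms <- list(pwms)
  seq <- .site_seq(genome, site)
  total <- 0
  for (p in pwms) {
    if (mode == "relaxed_count") {
      null <- if (!is.null(nulls)) nulls[[p$id]] else NULL
      total <- total + nrow(scan_sequence(p, seq, relaxed_p, null))
    } else {
      lo <- .pwm_logodds(p)
      for (s_seq in c(seq, revcomp(seq))) {
        codes <- .seq_codes(s_seq)
        if (length(codes) < p$width) next
        sc <- .slide_float_scores(lo, codes)
        total <- total + sum(pmax(sc[!is.na(sc)], 0))
      }
    }
  }
  total
}

# float analogue of .slide_scores
.slide_float_scores <- function(lo, codes) {
  w <- nrow(lo)
  n_off <- length(codes) - w + 1L
  if (n_off < 1L) return(numeric(0))
  s <- numeric(n_off)
  na <- rep(FALSE, n_off)
  for (i in seq_len(w)) {
    idx <- codes[i:(i + n_off - 1L)]
    vna <- is.na(idx)
    v <- numeric(n_off)
    v[!vna] <- lo[i, idx[!vna]]
    na <- na | vna
    s <- s + v
  }
  s[na] <- NA_real_
  s
}
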