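# Independent brute-force oracles and small fixtures used across the suite.
# Everything here is deliberately naive (loops, enumeration) and shares no
# code path with the package implementation it checks.

rand_seq <- function(n, seed = NULL, bases = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# PWM with one dominant base per position (prob `p`), others equal.
strong_pwm <- function(width, seed = 1, p = 0.85, id = "strong") {
  set.seed(seed)
  cons <- sample(4, width, replace = TRUE)
  probs <- matrix((1 - p) / 3, width, 4)
  probs[cbind(seq_len(width), cons)] <- p
  pwm(probs, id = id)
}

# probability-1 columns spelling out `consensus`
consensus_pwm <- function(consensus, id = "consensus") {
  codes <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  probs <- matrix(0, length(codes), 4)
  probs[cbind(seq_along(codes), codes)] <- 1
  pwm(probs, id = id)
}

uniform_pwm <- function(width, id = "uniform") {
  pwm(matrix(0.25, width, 4), id = id)
}

naive_revcomp <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- rev(strsplit(seq, "")[[1]])
  paste(ifelse(ch %in% names(map), map[ch], "N"), collapse = "")
}

# per-position integerized log-odds, the scanning score's defining grid
naive_int_scores <- function(p, granularity = 1000) {
  lo <- log2(sweep(p$probs, 2, p$background, "/"))
  s <- round(lo * granularity)
  s[p$probs == 0] <- NA
  s
}

# exhaustive null: enumerate all 4^width windows under the background
naive_null <- function(p, granularity = 1000) {
  ints <- naive_int_scores(p, granularity)
  w <- nrow(ints)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- rep(0, nrow(grid)); prob <- rep(1, nrow(grid))
  for (i in seq_len(w)) {
    sc <- sc + ints[i, grid[, i]]
    prob <- prob * p$background[grid[, i]]
  }
  fin <- !is.na(sc)
  pmf <- tapply(prob[fin], sc[fin], sum)
  scores <- as.numeric(names(pmf))
  list(scores = scores, pmf = as.numeric(pmf), p_neg_inf = sum(prob[!fin]),
       pvalue = function(s) sum(pmf[scores >= s]))
}

# score every window on both strands with explicit loops; report hits
naive_scan <- function(p, seq, p_thresh = 1e-3, granularity = 1000) {
  nn <- naive_null(p, granularity)
  ints <- naive_int_scores(p, granularity)
  w <- nrow(ints)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else naive_revcomp(seq)
    chars <- strsplit(s, "")[[1]]
    L <- length(chars)
    for (j in seq_len(L - w + 1L)) {
      win <- match(chars[j:(j + w - 1L)], c("A", "C", "G", "T"))
      if (anyNA(win)) next
      sc <- sum(ints[cbind(seq_len(w), win)])
      if (is.na(sc)) next
      pv <- nn$pvalue(sc)
      if (pv <= p_thresh) {
        st <- if (strand == "+") j - 1L else L - (j - 1L) - w
        rows[[length(rows) + 1L]] <-
          data.frame(start = st, end = st + w, strand = strand,
                     score = sc / granularity, pvalue = pv,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), strand = character(),
               score = numeric(), pvalue = numeric())
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# connected components of mutually overlapping intervals (two replicates);
# union spans of components containing both replicates
naive_reproducible <- function(rep1, rep2) {
  df <- rbind(data.frame(chrom = rep1$chrom, start = rep1$start,
                         end = rep1$end, rep = 1L),
              data.frame(chrom = rep2$chrom, start = rep2$start,
                         end = rep2$end, rep = 2L))
  n <- nrow(df)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (df$chrom[i] == df$chrom[j] && df$start[i] < df$end[j] &&
          df$start[j] < df$end[i] && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- NULL
  for (cc in unique(comp)) {
    sel <- comp == cc
    if (length(unique(df$rep[sel])) == 2L)
      out <- rbind(out, data.frame(chrom = df$chrom[sel][1],
                                   start = min(df$start[sel]),
                                   end = max(df$end[sel])))
  }
  if (is.null(out)) return(out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# upper-tail hypergeometric by direct enumeration of draw counts
enum_hypergeom_p <- function(k, K, n, N) {
  js <- max(k, 0):min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), span = 10000,
                         maxlen = 400, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- sample.int(span, n, replace = TRUE)
  peak_set(sample(chroms, n, replace = TRUE), st,
           st + sample.int(maxlen, n, replace = TRUE))
}

# small simulation config for fast tests
tiny_sim_config <- function(seed = 11, noise = FALSE, ...) {
  args <- list(
    seed = seed,
    chrom_sizes = c(chr1 = 200000L, chr2 = 200000L),
    n_genes = 300L,
    site_plan_counts = c(FP = 20L, HP = 25L, BOTH = 25L, CB = 15L,
                         FOXA1_accessible = 10L, FOXA1_inaccessible = 10L,
                         HNF4A_accessible = 10L, HNF4A_inaccessible = 10L,
                         background = 10L),
    n_activated = 15L,
    peak_jitter_sd = if (noise) 10 else 0,
    peak_dropout = if (noise) 0.01 else 0)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}
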