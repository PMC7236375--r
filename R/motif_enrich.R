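#' Position weight matrix motif model
#'
#' Rows are motif positions, columns letter probabilities in `ACGU` order.
#' Scoring uses log2 odds against `background` after adding `pseudo` to
#' every probability (rows renormalized), the usual guard against zero
#' probabilities; `pseudo = 0` is allowed, in which case forbidden letters
#' score minus infinity and can never produce a hit.
#'
#' @param name motif name.
#' @param probs numeric matrix, `width x 4`, rows summing to 1 (within 1e-3).
#' @param background letter probabilities, length 4, summing to 1.
#' @param pseudo pseudocount.
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(name, probs, background = rep(0.25, 4), pseudo = 1e-4) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stopf("motif %s: probability matrix must have 4 columns", name)
  if (nrow(probs) < 4L)
    stopf("motif %s: width %d below the minimum of 4", name, nrow(probs))
  if (any(abs(rowSums(probs) - 1) > 1e-3))
    stopf("motif %s: probability rows must sum to 1 within 1e-3", name)
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0))
    stopf("motif %s: background must be positive and sum to 1", name)
  raw <- probs / rowSums(probs)
  scored <- (raw + pseudo) / (1 + 4 * pseudo)
  colnames(raw) <- colnames(scored) <- c("A", "C", "G", "U")
  structure(list(name = name, width = nrow(raw), raw_probs = raw,
                 probs = scored, background = as.numeric(background),
                 pseudo = pseudo),
            class = "motif_model")
}

#' Single-word motif from a consensus sequence
#'
#' @param name motif name.
#' @param consensus RNA string over `ACGU`.
#' @param ... passed to [motif_model()].
#' @return A `motif_model` putting probability 1 on the consensus letter at
#'   each position.
#' @export
motif_from_consensus <- function(name, consensus, ...) {
  letters4 <- c("A", "C", "G", "U")
  idx <- match(strsplit(chartr("T", "U", toupper(consensus)), "")[[1L]], letters4)
  if (anyNA(idx)) stopf("consensus %s contains non-ACGU letters", consensus)
  probs <- matrix(0, nrow = length(idx), ncol = 4L)
  probs[cbind(seq_along(idx), idx)] <- 1
  motif_model(name, probs, ...)
}

#' @export
print.motif_model <- function(x, ...) {
  letters4 <- c("A", "C", "G", "U")
  cons <- paste(letters4[apply(x$raw_probs, 1L, which.max)], collapse = "")
  cat(sprintf("<motif_model> %s width %d consensus %s pseudo %g\n",
              x$name, x$width, cons, x$pseudo))
  invisible(x)
}

# Quantize the log-odds score matrix onto an integer grid shared by the
# p-value table and the scanner: entry (j,k) becomes round(score/eps) with
# eps = (max achievable - min finite achievable)/granularity, so the table
# is exact for the quantized scores and discretization shifts any score by
# at most width * eps / 2. Minus-infinite scores (pseudo = 0) become NA.
quantize_scores <- function(motif, granularity = 1000L) {
  smat <- log2(motif$probs / rep(motif$background, each = motif$width))
  smat[motif$probs == 0] <- -Inf
  fin <- ifelse(is.finite(smat), smat, NA)
  row_min <- apply(fin, 1L, min, na.rm = TRUE)
  row_max <- apply(fin, 1L, max, na.rm = TRUE)
  rng <- sum(row_max) - sum(row_min)
  # keep quantized integers far from overflow even for degenerate motifs
  # whose finite score range is 0 (single-word consensus matrices)
  max_abs <- max(abs(fin), na.rm = TRUE)
  eps <- max(rng / granularity, max_abs / 1e6, 1e-12)
  q <- round(smat / eps)
  q[!is.finite(smat)] <- NA_integer_
  mode(q) <- "integer"
  list(q = q, eps = eps)
}

#' Exact tail probabilities of PWM scores under the background model
#'
#' Computes, by dynamic-programming convolution of the per-position score
#' distributions over the quantized score grid, the exact probability that
#' a random background word scores at least `t`, for every achievable
#' quantized score `t`. The scanner uses the same quantization, so scan
#' p-values are exact for the scores it assigns.
#'
#' @param motif a `motif_model`.
#' @param granularity number of grid steps spanning the score range.
#' @return Object of class `pwm_pvalue_table` with fields `eps` (score
#'   units per grid step), `q` (quantized score matrix), `qmin_total`,
#'   `tail` (tail probability by grid offset) and `scores` (score in bits
#'   at each offset).
#' @export
score_pvalue_table <- function(motif, granularity = 1000L) {
  qz <- quantize_scores(motif, granularity)
  q <- qz$q
  w <- motif$width
  bg <- motif$background
  row_min <- apply(q, 1L, function(r) min(r, na.rm = TRUE))
  row_max <- apply(q, 1L, function(r) max(r, na.rm = TRUE))
  M <- sum(row_max - row_min)
  dist <- numeric(M + 1L)
  dist[[1L]] <- 1
  neginf <- 0
  for (j in seq_len(w)) {
    nd <- numeric(M + 1L)
    for (k in 1:4) {
      if (is.na(q[j, k])) {
        neginf <- neginf + bg[[k]] * sum(dist)
        next
      }
      o <- q[j, k] - row_min[[j]]
      src <- 1L:(M + 1L - o)
      nd[src + o] <- nd[src + o] + bg[[k]] * dist[src]
    }
    dist <- nd
  }
  tail <- rev(cumsum(rev(dist)))
  structure(list(motif = motif$name, eps = qz$eps, q = q,
                 qmin_total = sum(row_min), tail = tail,
                 scores = (seq_along(tail) - 1L + sum(row_min)) * qz$eps,
                 neginf_mass = neginf, granularity = granularity),
            class = "pwm_pvalue_table")
}

#' Tail probability of a quantized PWM score
#'
#' @param table a [score_pvalue_table()] result.
#' @param qsum integer quantized score sum(s); `NA` means a word containing
#'   a forbidden (minus-infinity) letter.
#' @return `P(score >= qsum * eps)` for each input.
#' @export
pwm_tail_prob <- function(table, qsum) {
  off <- qsum - table$qmin_total
  p <- rep(1, length(qsum))
  above <- !is.na(off) & off > length(table$tail) - 1L
  inside <- !is.na(off) & off >= 0L & !above
  p[above] <- 0
  p[inside] <- table$tail[off[inside] + 1L]
  p  # NA offsets (-Inf words) keep p = 1
}

#' Tail probability of a score in bits
#'
#' @param table a [score_pvalue_table()] result.
#' @param score log-odds score threshold(s) in bits.
#' @return `P(score_random >= score)` under the background model.
#' @export
pwm_pvalue <- function(table, score) {
  pwm_tail_prob(table, round(score / table$eps))
}

#' Scan sequences for motif hits with exact p-values
#'
#' Sense strand only (mRNA); offsets whose window contains `N` are
#' skipped. A hit is any offset whose score tail probability is below
#' `thresh` (FIMO-style).
#'
#' @param motif a `motif_model`.
#' @param seqs named character vector of RNA sequences (`T` accepted).
#' @param thresh p-value threshold.
#' @param granularity score-grid resolution, see [score_pvalue_table()].
#' @param table optional precomputed [score_pvalue_table()] for `motif`.
#' @return `data.frame` of hits: `region_id`, `offset` (0-based), `score`
#'   (bits), `p_value`.
#' @export
scan_regions <- function(motif, seqs, thresh = 0.001, granularity = 1000L,
                         table = NULL) {
  if (is.null(table)) table <- score_pvalue_table(motif, granularity)
  if (is.null(names(seqs))) names(seqs) <- paste0("region", seq_along(seqs))
  w <- motif$width
  letters4 <- c("A", "C", "G", "U")
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- chartr("T", "U", toupper(seqs[[i]]))
    L <- nchar(s)
    if (L < w) next
    li <- match(strsplit(s, "")[[1L]], letters4)  # NA for N
    n_off <- L - w + 1L
    sc <- integer(n_off)
    for (j in seq_len(w)) sc <- sc + table$q[j, li[j:(n_off + j - 1L)]]
    p <- pwm_tail_prob(table, sc)
    # windows containing N give NA scores -> excluded
    hit <- !is.na(sc) & p < thresh
    if (any(hit))
      out[[i]] <- data.frame(region_id = names(seqs)[[i]],
                             offset = which(hit) - 1L,
                             score = sc[hit] * table$eps,
                             p_value = p[hit], stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(region_id = character(), offset = integer(),
                      score = numeric(), p_value = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-region hit indicator
#'
#' @inheritParams scan_regions
#' @return Named logical vector: does each region carry at least one hit?
#' @export
region_has_hit <- function(motif, seqs, thresh = 0.001, granularity = 1000L,
                           table = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("region", seq_along(seqs))
  hits <- scan_regions(motif, seqs, thresh, granularity, table)
  setNames(names(seqs) %in% hits$region_id, names(seqs))
}

#' Estimate a 0-order background from sequences
#'
#' @param seqs character vector of RNA sequences.
#' @return Length-4 probability vector over `ACGU` (add-one smoothed).
#' @export
motif_background_from_seqs <- function(seqs) {
  s <- paste(chartr("T", "U", toupper(seqs)), collapse = "")
  counts <- vapply(c("A", "C", "G", "U"), function(l)
    sum(charToRaw(s) == charToRaw(l)), 0)
  (counts + 1) / (sum(counts) + 4)
}

#' Sample background regions excluding a region set
#'
#' Emulates a transcript-restricted shuffle: fixed-length regions are
#' placed uniformly over all start positions, on the given transcripts,
#' that do not overlap any excluded interval. With `restrict = "3utr"`
#' placements are confined to the 3'UTR, matching a 3'UTR test set.
#'
#' @param transcripts transcript table; only these transcripts are used.
#' @param exclude region `data.frame` of intervals that must not be touched.
#' @param length region length in nt.
#' @param n number of regions to draw (uniform, with replacement).
#' @param seed RNG seed (draws are reproducible and leave the caller's RNG
#'   state untouched).
#' @param restrict `"transcript"` (whole transcript) or `"3utr"`.
#' @return Region `data.frame` with `label = "background"`.
#' @export
sample_background_regions <- function(transcripts, exclude, length = 30L, n,
                                      seed = 1L,
                                      restrict = c("transcript", "3utr")) {
  restrict <- match.arg(restrict)
  pool_tx <- character(0)
  pool_start <- integer(0)
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts$transcript_id[[i]]
    L <- transcripts$length[[i]]
    lo <- if (restrict == "3utr") transcripts$cds_end[[i]] else 0L
    hi <- L - length
    if (hi < lo) { warnf("transcript %s has no room for a %d-nt region", tx, length); next }
    ok <- rep(TRUE, hi - lo + 1L)
    ex <- exclude[exclude$transcript_id == tx, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      # starts s with [s, s+length) overlapping [ex_start, ex_end)
      bs <- max(lo, ex$start[[j]] - length + 1L)
      be <- min(hi, ex$end[[j]] - 1L)
      if (be >= bs) ok[(bs - lo + 1L):(be - lo + 1L)] <- FALSE
    }
    if (!any(ok)) { warnf("transcript %s has no allowed placement", tx); next }
    starts <- (lo:hi)[ok]
    pool_tx <- c(pool_tx, rep(tx, length(starts)))
    pool_start <- c(pool_start, starts)
  }
  if (!length(pool_start)) stopf("no allowed background placement on any transcript")
  pick <- with_seed(seed, sample.int(length(pool_start), n, replace = TRUE))
  out <- data.frame(transcript_id = pool_tx[pick], start = pool_start[pick],
                    end = pool_start[pick] + length, label = "background",
                    score = NA_real_, stringsAsFactors = FALSE)
  # hard exclusion assertion
  for (j in seq_len(nrow(exclude))) {
    same <- out$transcript_id == exclude$transcript_id[[j]]
    if (any(same & out$start < exclude$end[[j]] & out$end > exclude$start[[j]]))
      stopf("internal error: background region overlaps an excluded interval")
  }
  out
}

#' Extract region sequences from transcript sequences
#'
#' @param regions region `data.frame`.
#' @param sequences named character vector of transcript sequences.
#' @return Named character vector of region sequences (names
#'   `transcript:start-end`).
#' @export
region_sequences <- function(regions, sequences) {
  miss <- setdiff(unique(regions$transcript_id), names(sequences))
  if (length(miss)) stopf("no sequence for transcript %s", miss[[1L]])
  out <- substring(sequences[regions$transcript_id], regions$start + 1L,
                   regions$end)
  names(out) <- sprintf("%s:%d-%d", regions$transcript_id, regions$start,
                        regions$end)
  out
}

#' Fisher enrichment of a motif in a test versus reference region set
#'
#' The 2x2 table counts regions (not hits): `a`/`b` regions with/without a
#' hit in the test set, `c`/`d` in the reference set. The enrichment ratio
#' is `(a/b)/(c/d)`; it is infinite (and flagged) when `a > 0` and any of
#' `b`, `c`, `d` is 0. The p-value is the two-sided Fisher's exact test.
#'
#' @param test_hits,ref_hits logical per-region hit indicators.
#' @return One-row `data.frame`: `a`, `b`, `c`, `d`, `ratio`, `p_value`,
#'   `inf_ratio`.
#' @export
motif_enrichment <- function(test_hits, ref_hits) {
  if (!length(test_hits) || !length(ref_hits))
    stopf("test and reference sets must be nonempty")
  a <- sum(test_hits); b <- sum(!test_hits)
  c_ <- sum(ref_hits); d <- sum(!ref_hits)
  inf_ratio <- a > 0 && (b == 0 || c_ == 0 || d == 0)
  ratio <- if (inf_ratio) Inf
  else if (a == 0) 0
  else (a / b) / (c_ / d)
  p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2L))$p.value
  data.frame(a = a, b = b, c = c_, d = d, ratio = ratio, p_value = p,
             inf_ratio = inf_ratio)
}

#' Motif enrichment across a motif collection with BH correction
#'
#' Scans every motif over the test and reference sequences (by default
#' against a shared 0-order background estimated from their union), runs
#' the per-motif Fisher test, and adjusts p-values across motifs by
#' Benjamini-Hochberg. `pct_regions_with_hit` is the percentage of test
#' regions containing at least one hit of the motif.
#'
#' @param motifs named list of `motif_model` objects.
#' @param test_seqs,ref_seqs named character vectors of region sequences.
#' @param thresh scan p-value threshold.
#' @param background optional length-4 background override.
#' @param granularity score-grid resolution.
#' @return `data.frame`, one row per motif: counts, `ratio`, `p_value`,
#'   `fdr`, `pct_regions_with_hit`.
#' @export
enrich_motifs <- function(motifs, test_seqs, ref_seqs, thresh = 0.001,
                          background = NULL, granularity = 1000L) {
  if (is.null(background))
    background <- motif_background_from_seqs(c(test_seqs, ref_seqs))
  rows <- lapply(motifs, function(m) {
    m2 <- motif_model(m$name, m$raw_probs, background = background,
                      pseudo = m$pseudo)
    tab <- score_pvalue_table(m2, granularity)
    th <- region_has_hit(m2, test_seqs, thresh, granularity, tab)
    rh <- region_has_hit(m2, ref_seqs, thresh, granularity, tab)
    cbind(data.frame(motif = m$name, stringsAsFactors = FALSE),
          motif_enrichment(th, rh))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$pct_regions_with_hit <- 100 * out$a / (out$a + out$b)
  out
}

#' Exhaustive k-mer enrichment (diagnostic)
#'
#' A simple substitute for de novo motif discovery: every k-mer occurring
#' in the test set is tested for region-level enrichment against the
#' reference set with Fisher's exact test and BH correction. Diagnostic
#' only; it is not a probabilistic motif model.
#'
#' @param test_seqs,ref_seqs character vectors of region sequences.
#' @param k k-mer length.
#' @return `data.frame` per k-mer with counts, `ratio`, `p_value`, `fdr`,
#'   sorted by p-value.
#' @export
kmer_enrichment <- function(test_seqs, ref_seqs, k = 5L) {
  kmers_of <- function(s) {
    s <- chartr("T", "U", toupper(s))
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  }
  test_sets <- lapply(test_seqs, kmers_of)
  ref_sets <- lapply(ref_seqs, kmers_of)
  univ <- sort(unique(unlist(test_sets)))
  univ <- univ[!grepl("N", univ, fixed = TRUE)]
  if (!length(univ)) stopf("no k-mers in test set")
  rows <- lapply(univ, function(km) {
    th <- vapply(test_sets, function(s) km %in% s, TRUE)
    rh <- vapply(ref_sets, function(s) km %in% s, TRUE)
    cbind(data.frame(kmer = km, stringsAsFactors = FALSE),
          motif_enrichment(th, rh))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}
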