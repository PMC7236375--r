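# Shared fixture builders; everything is generated in code.

tiny_transcripts <- function() {
  data.frame(transcript_id = c("tx1", "tx2"),
             gene_id = c("g1", "g2"),
             length = c(1860L, 1000L),
             utr5_end = c(150L, 100L),
             cds_end = c(1400L, 700L),
             stringsAsFactors = FALSE)
}

write_tiny_transcript_file <- function(df = tiny_transcripts()) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tgene_id\tlength\tutr5_end\tcds_end",
               sprintf("%s\t%s\t%d\t%d\t%d", df$transcript_id, df$gene_id,
                       df$length, df$utr5_end, df$cds_end)), path)
  path
}

random_motif <- function(width = 5L, seed = 1L, pseudo = 1e-4) {
  set.seed(seed)
  probs <- matrix(stats::rgamma(width * 4L, 1), ncol = 4L)
  probs <- probs / rowSums(probs)
  motif_model(sprintf("rand%d_%d", width, seed), probs, pseudo = pseudo)
}

random_rna <- function(n, len, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    "")
}

# brute-force oracle for the window normalization, written independently of
# normalize_rtstops: explicit per-window loops and order statistics
oracle_normalize <- function(stops, window = 200L, step = 30L, lo = 90,
                             hi = 95, scale = 100) {
  n <- length(stops)
  starts <- if (n <= window) 0L else {
    s <- seq.int(0L, n - window, by = step)
    if (s[[length(s)]] + window < n) c(s, n - window) else s
  }
  contrib <- vector("list", n)
  for (s in starts) {
    e <- min(s + window, n)
    vals <- stops[(s + 1L):e]
    m <- length(vals)
    sorted <- sort(vals)
    band <- sorted[max(1L, ceiling(lo / 100 * m)):max(1L, ceiling(hi / 100 * m))]
    norm <- mean(band)
    if (norm == 0) next
    for (i in (s + 1L):e)
      contrib[[i]] <- c(contrib[[i]], stops[[i]] / norm * scale)
  }
  vapply(contrib, function(x) if (is.null(x)) NA_real_ else mean(x), 0)
}

# brute-force interval extend/merge/bin oracle (quadratic)
oracle_regions <- function(windows, tx_len, flank = 10L, bin = 30L) {
  w <- windows[windows$klass != "stable", , drop = FALSE]
  out <- list()
  for (tx in unique(w$transcript_id)) for (kl in unique(w$klass)) {
    g <- w[w$transcript_id == tx & w$klass == kl, , drop = FALSE]
    if (!nrow(g)) next
    iv <- cbind(pmax(0L, g$start - flank), pmin(tx_len[[tx]], g$end + flank))
    repeat {
      merged_any <- FALSE
      i <- 1L
      while (i <= nrow(iv)) {
        j <- i + 1L
        while (j <= nrow(iv)) {
          if (iv[i, 1] <= iv[j, 2] && iv[j, 1] <= iv[i, 2]) {
            iv[i, ] <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
            iv <- iv[-j, , drop = FALSE]
            merged_any <- TRUE
          } else j <- j + 1L
        }
        i <- i + 1L
      }
      if (!merged_any) break
    }
    for (r in seq_len(nrow(iv))) {
      s <- iv[r, 1]
      while (s < iv[r, 2]) {
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = tx, start = s, end = min(s + bin, iv[r, 2]),
          label = kl, stringsAsFactors = FALSE)
        s <- s + bin
      }
    }
  }
  if (!length(out))
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), label = character()))
  res <- do.call(rbind, out)
  res[order(res$transcript_id, res$start, res$label), , drop = FALSE]
}

# exhaustive PWM tail oracle on the quantized score grid
oracle_pwm_tail <- function(motif, granularity = 1000L) {
  tab <- score_pvalue_table(motif, granularity)
  w <- motif$width
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  qs <- vapply(seq_len(nrow(words)), function(i)
    sum(tab$q[cbind(1:w, words[i, ])]), 0L)
  probs <- vapply(seq_len(nrow(words)), function(i)
    prod(motif$background[words[i, ]]), 0)
  list(table = tab, qsum = qs, prob = probs,
       tail_at = function(q) sum(probs[!is.na(qs) & qs >= q]))
}
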