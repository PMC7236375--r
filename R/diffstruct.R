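#' Structurally variable nucleotides between two stages
#'
#' Reports the positions valid in both profiles whose reactivity difference
#' exceeds `cutoff` in absolute value, with the signed difference
#' (stage B minus stage A). Positions invalid in either profile are
#' excluded, not zero-filled.
#'
#' @param profA,profB reactivity vectors of the same transcript.
#' @param cutoff difference cutoff; 0.2 filters most replicate noise.
#' @return `data.frame` with 0-based `pos` and `delta`.
#' @export
call_variable_nucleotides <- function(profA, profB, cutoff = 0.2) {
  if (length(profA) != length(profB))
    stopf("profiles differ in length")
  d <- profB - profA
  keep <- !is.na(d) & abs(d) > cutoff
  data.frame(pos = which(keep) - 1L, delta = d[keep], row.names = NULL)
}

#' Scan disjoint 10-nt windows for structural change
#'
#' Profiles are tiled from position 0 into disjoint windows (a trailing
#' partial window is dropped). Windows with fewer than
#' `ceiling(valid_frac * window)` jointly valid bases are omitted. For the
#' kept windows a two-sided paired t-test is run on the per-base reactivity
#' differences (stage B minus stage A); windows with mean difference
#' `> delta_cut` and `p < alpha` are `less_structural`, `< -delta_cut` and
#' `p < alpha` are `more_structural`, others `stable`. Windows where every
#' difference is identical get `p = 0` when the common value is nonzero
#' (the t statistic diverges) and `p = 1` when it is zero.
#'
#' @param profA,profB reactivity vectors of one transcript at two stages.
#' @param transcript_id transcript identifier attached to the output.
#' @param window window size (nt).
#' @param valid_frac minimum fraction of jointly valid bases per window.
#' @param delta_cut effect-size cutoff on the mean difference.
#' @param alpha significance cutoff (raw p; no multiple-testing correction
#'   is applied, by design).
#' @return `data.frame` of windows: `transcript_id`, `start`, `end`,
#'   `mean_delta`, `p_value`, `n_valid`, `klass`.
#' @export
window_scan <- function(profA, profB, transcript_id = "tx", window = 10L,
                        valid_frac = 0.8, delta_cut = 0.05, alpha = 0.05) {
  if (length(profA) != length(profB))
    stopf("profiles differ in length")
  n <- length(profA)
  n_win <- n %/% window
  if (n_win == 0L)
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), mean_delta = numeric(),
                      p_value = numeric(), n_valid = integer(),
                      klass = character()))
  need <- as.integer(ceiling(valid_frac * window))
  rows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    s <- (w - 1L) * window
    idx <- (s + 1L):(s + window)
    d <- profB[idx] - profA[idx]
    d <- d[!is.na(d)]
    if (length(d) < need) next
    m <- mean(d)
    p <- if (stats::sd(d) == 0) {
      if (d[[1L]] != 0) 0 else 1
    } else stats::t.test(d)$p.value
    klass <- if (m > delta_cut && p < alpha) "less_structural"
    else if (m < -delta_cut && p < alpha) "more_structural"
    else "stable"
    rows[[w]] <- data.frame(transcript_id = transcript_id, start = s,
                            end = s + window, mean_delta = m, p_value = p,
                            n_valid = length(d), klass = klass,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), mean_delta = numeric(),
                      p_value = numeric(), n_valid = integer(),
                      klass = character()))
  do.call(rbind, rows)
}

#' Window scan over a set of transcripts
#'
#' @param setA,setB named lists of reactivity vectors (same transcripts).
#' @param ... passed to [window_scan()].
#' @return Concatenated window `data.frame`.
#' @export
window_scan_set <- function(setA, setB, ...) {
  common <- intersect(names(setA), names(setB))
  if (!length(common))
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), mean_delta = numeric(),
                      p_value = numeric(), n_valid = integer(),
                      klass = character()))
  out <- lapply(common, function(id)
    window_scan(setA[[id]], setB[[id]], transcript_id = id, ...))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Re-bin variable windows into structurally variable regions
#'
#' Stable windows are discarded; the remaining windows are extended by
#' `flank` nt on both sides (clipped to the transcript), merged per
#' transcript and per class when overlapping or book-ended, and each merged
#' interval is partitioned left-to-right into bins of `bin` nt, keeping a
#' final partial bin. Regions inherit the class of their source windows;
#' opposite-direction windows never merge.
#'
#' @param windows window `data.frame` from [window_scan_set()].
#' @param tx_lengths named integer vector of transcript lengths.
#' @param flank extension in nt.
#' @param bin re-binning size in nt.
#' @return Region `data.frame`: `transcript_id`, `start`, `end`, `label`,
#'   `score` (NA).
#' @export
build_regions <- function(windows, tx_lengths, flank = 10L, bin = 30L) {
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), label = character(), score = numeric())
  w <- windows[windows$klass != "stable", , drop = FALSE]
  if (!nrow(w)) return(empty)
  missing <- setdiff(unique(w$transcript_id), names(tx_lengths))
  if (length(missing)) stopf("no length known for transcript %s", missing[[1L]])
  out <- list()
  for (key in unique(paste(w$transcript_id, w$klass, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    tx <- parts[[1L]]; klass <- parts[[2L]]
    g <- w[w$transcript_id == tx & w$klass == klass, , drop = FALSE]
    L <- tx_lengths[[tx]]
    s <- pmax(0L, as.integer(g$start) - flank)
    e <- pmin(L, as.integer(g$end) + flank)
    # merge overlapping or book-ended intervals (1-based closed for IRanges)
    merged <- IRanges::reduce(IRanges::IRanges(start = s + 1L, end = e))
    ms <- IRanges::start(merged) - 1L
    me <- IRanges::end(merged)
    for (i in seq_along(ms)) {
      bs <- seq.int(ms[[i]], me[[i]] - 1L, by = bin)
      be <- pmin(bs + bin, me[[i]])
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tx, start = as.integer(bs), end = as.integer(be),
        label = klass, score = NA_real_, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$transcript_id, res$start, res$label), , drop = FALSE]
}

#' Cross-comparison "hot" structurally variable regions
#'
#' Regions from different stage comparisons that lie on the same transcript,
#' carry the same class, and overlap by at least `min_overlap` nt are
#' clustered (transitively, as connected components of the overlap graph).
#' Each cluster is reported as its merged footprint with the union of
#' contributing comparisons; `n_way` counts the distinct comparisons, so
#' regions found in a single comparison pass through with `n_way = 1`.
#'
#' @param region_sets named list of region `data.frame`s, one per
#'   comparison (names are comparison identifiers).
#' @param min_overlap minimum overlap in nt for two regions to be "shared".
#' @return `data.frame`: `transcript_id`, `start`, `end`, `label`,
#'   `comparisons` (comma-joined), `n_way`.
#' @export
hot_regions <- function(region_sets, min_overlap = 1L) {
  if (length(region_sets) < 2L) stopf("need at least two comparisons")
  if (is.null(names(region_sets)) || any(!nzchar(names(region_sets))))
    stopf("region_sets must be named by comparison")
  all <- do.call(rbind, lapply(names(region_sets), function(cmp) {
    df <- region_sets[[cmp]]
    if (!nrow(df)) return(NULL)
    data.frame(transcript_id = df$transcript_id, start = df$start,
               end = df$end, label = df$label, comparison = cmp,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all) || !nrow(all))
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), label = character(),
                      comparisons = character(), n_way = integer()))
  out <- list()
  for (key in unique(paste(all$transcript_id, all$label, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    g <- all[all$transcript_id == parts[[1L]] & all$label == parts[[2L]], ,
             drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    # sweep: intervals overlap the running cluster when they reach at least
    # min_overlap nt into its footprint
    cs <- g$start[[1L]]; ce <- g$end[[1L]]; members <- 1L
    flush <- function(cs, ce, idx) {
      cmps <- sort(unique(g$comparison[idx]))
      data.frame(transcript_id = parts[[1L]], start = cs, end = ce,
                 label = parts[[2L]],
                 comparisons = paste(cmps, collapse = ","),
                 n_way = length(cmps), stringsAsFactors = FALSE)
    }
    if (nrow(g) > 1L) for (i in 2L:nrow(g)) {
      if (min(ce, g$end[[i]]) - g$start[[i]] >= min_overlap) {
        ce <- max(ce, g$end[[i]])
        members <- c(members, i)
      } else {
        out[[length(out) + 1L]] <- flush(cs, ce, members)
        cs <- g$start[[i]]; ce <- g$end[[i]]; members <- i
      }
    }
    out[[length(out) + 1L]] <- flush(cs, ce, members)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$transcript_id, res$start, res$label), , drop = FALSE]
}

#' Assign a region to a transcript segment
#'
#' The region goes to the segment (5'UTR, CDS or 3'UTR) that covers at
#' least `min_frac` of its length; if no segment reaches that fraction the
#' region is `unassigned`. The default 0.51 reproduces a majority-overlap
#' rule with ties unassigned.
#'
#' @param start,end region bounds, 0-based half-open.
#' @param utr5_end,cds_end,length transcript segment boundaries.
#' @param min_frac minimum covered fraction.
#' @return One of `"5UTR"`, `"CDS"`, `"3UTR"`, `"unassigned"`.
#' @export
assign_segment <- function(start, end, utr5_end, cds_end, length,
                           min_frac = 0.51) {
  if (start < 0L || end > length || start >= end)
    stopf("region [%d,%d) out of bounds for transcript of length %d",
          start, end, length)
  seg_start <- c(0L, utr5_end, cds_end)
  seg_end <- c(utr5_end, cds_end, length)
  ov <- pmax(0L, pmin(end, seg_end) - pmax(start, seg_start))
  i <- which.max(ov)
  if (ov[[i]] / (end - start) >= min_frac) c("5UTR", "CDS", "3UTR")[[i]]
  else "unassigned"
}

#' Segment assignment for a region table
#'
#' @param regions region `data.frame`.
#' @param transcripts transcript table (see [read_transcript_table()]).
#' @param min_frac minimum covered fraction, see [assign_segment()].
#' @return `regions` with a `segment` column.
#' @export
assign_segments <- function(regions, transcripts, min_frac = 0.51) {
  i <- match(regions$transcript_id, transcripts$transcript_id)
  if (anyNA(i))
    stopf("unknown transcript %s in regions", regions$transcript_id[is.na(i)][[1L]])
  regions$segment <- vapply(seq_len(nrow(regions)), function(k)
    assign_segment(regions$start[[k]], regions$end[[k]],
                   transcripts$utr5_end[[i[[k]]]],
                   transcripts$cds_end[[i[[k]]]],
                   transcripts$length[[i[[k]]]], min_frac), "")
  regions
}

#' Segment enrichment of structurally variable regions
#'
#' Expected counts assume regions fall uniformly along transcripts, with
#' segments weighted by their average length share (default 150:1250:460
#' for 5'UTR:CDS:3'UTR). The enrichment ratio is observed/expected; the
#' per-segment Fisher's exact test compares `[observed_s, total - observed_s]`
#' against `[round(expected_s), total - round(expected_s)]`.
#'
#' @param observed named counts for `5UTR`, `CDS`, `3UTR` (a table or named
#'   vector; missing segments count 0; `unassigned` entries are ignored).
#' @param weights segment length weights.
#' @return `data.frame` with `segment`, `observed`, `expected`, `ratio`,
#'   `fisher_p`.
#' @export
segment_enrichment <- function(observed, weights = c(150, 1250, 460)) {
  segs <- c("5UTR", "CDS", "3UTR")
  obs <- setNames(numeric(3L), segs)
  common <- intersect(names(observed), segs)
  obs[common] <- as.numeric(observed[common])
  total <- sum(obs)
  if (total <= 0) stopf("no assigned regions to test")
  expected <- total * weights / sum(weights)
  ratio <- obs / expected
  p <- vapply(seq_along(segs), function(i) {
    e <- round(expected[[i]])
    stats::fisher.test(matrix(c(obs[[i]], total - obs[[i]],
                                e, total - e), nrow = 2L, byrow = TRUE))$p.value
  }, 0)
  data.frame(segment = segs, observed = unname(obs),
             expected = unname(expected), ratio = unname(ratio),
             fisher_p = p, stringsAsFactors = FALSE)
}
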