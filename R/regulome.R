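#' Build binding sites from iCLIP truncation positions
#'
#' Each crosslink-induced truncation is extended by `flank` nt on both
#' sides (clipped to the transcript). With `restrict_3utr`, sites whose
#' center lies outside the 3'UTR are dropped.
#'
#' @param truncations `data.frame` with `transcript_id` and `pos` (0-based
#'   truncation position), or a region table whose `start` is used.
#' @param transcripts transcript table.
#' @param flank extension in nt (default 20, giving 41-nt sites away from
#'   transcript ends).
#' @param restrict_3utr keep only 3'UTR-centered sites?
#' @return Binding-site `data.frame`: `transcript_id`, `center`, `start`,
#'   `end`, `source`, `segment`.
#' @export
truncation_to_sites <- function(truncations, transcripts, flank = 20L,
                                restrict_3utr = TRUE) {
  pos <- if ("pos" %in% names(truncations)) truncations$pos else truncations$start
  i <- match(truncations$transcript_id, transcripts$transcript_id)
  if (anyNA(i))
    stopf("unknown transcript %s in truncations",
          truncations$transcript_id[is.na(i)][[1L]])
  L <- transcripts$length[i]
  if (any(pos < 0L | pos >= L)) stopf("truncation position outside transcript")
  seg <- segment_of(pos, transcripts$utr5_end[i], transcripts$cds_end[i])
  out <- data.frame(transcript_id = truncations$transcript_id,
                    center = as.integer(pos),
                    start = pmax(0L, as.integer(pos) - flank),
                    end = pmin(L, as.integer(pos) + flank + 1L),
                    source = "iclip_truncation", segment = seg,
                    stringsAsFactors = FALSE)
  if (restrict_3utr) out <- out[out$segment == "3UTR", , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Structural metaprofile around binding-site centers
#'
#' For every offset in `-flank..flank`, averages the valid reactivities at
#' `center + offset` over all usable sites. When `min_valid_frac > 0`,
#' sites whose fraction of valid bases over the window is not larger than
#' the cutoff are excluded (the 60% validity rule uses
#' `min_valid_frac = 0.6`).
#'
#' @param profiles named list of reactivity vectors.
#' @param sites binding-site `data.frame` (see [truncation_to_sites()]).
#' @param flank half-window in nt.
#' @param min_valid_frac per-site validity cutoff (strict: kept if
#'   fraction `> min_valid_frac`); 0 disables the filter.
#' @param set_label label attached to the result (`bound`,
#'   `unbound_control`, ...).
#' @return `data.frame` with `offset`, `mean_reactivity`, `n_valid`, plus
#'   attributes `set_label` and `n_sites`.
#' @export
metaprofile <- function(profiles, sites, flank = 20L, min_valid_frac = 0,
                        set_label = "bound") {
  offsets <- -flank:flank
  vals <- matrix(NA_real_, nrow = nrow(sites), ncol = length(offsets))
  for (s in seq_len(nrow(sites))) {
    prof <- profiles[[sites$transcript_id[[s]]]]
    if (is.null(prof)) next
    pos <- sites$center[[s]] + offsets
    inside <- pos >= 0L & pos < length(prof)
    vals[s, inside] <- prof[pos[inside] + 1L]
  }
  frac_valid <- rowMeans(!is.na(vals))
  usable <- if (min_valid_frac > 0) frac_valid > min_valid_frac
  else frac_valid > 0
  if (!any(usable)) stopf("no usable sites for metaprofile")
  vals <- vals[usable, , drop = FALSE]
  out <- data.frame(offset = offsets,
                    mean_reactivity = colMeans(vals, na.rm = TRUE),
                    n_valid = colSums(!is.na(vals)))
  out$mean_reactivity[out$n_valid == 0L] <- NA_real_
  attr(out, "set_label") <- set_label
  attr(out, "n_sites") <- sum(usable)
  out
}

#' Unbound control sites carrying the same motif
#'
#' Scans the transcripts that carry bound sites for all motif occurrences
#' and keeps those whose motif span does not intersect any bound site.
#' Controls are centered on the motif midpoint and extended like bound
#' sites, giving a sequence-matched structural baseline.
#'
#' @param motif a `motif_model`.
#' @param transcripts transcript table with sequences (attribute
#'   `sequence` or `sequences` argument).
#' @param bound bound-site `data.frame`.
#' @param thresh scan p-value threshold.
#' @param flank half-window for the emitted control sites.
#' @param sequences named character vector of transcript sequences.
#' @return Binding-site `data.frame` with `source = "motif_scan"`.
#' @export
unbound_controls <- function(motif, transcripts, bound, thresh = 0.001,
                             flank = 20L,
                             sequences = attr(transcripts, "sequence")) {
  if (is.null(sequences)) stopf("transcript sequences required")
  txs <- intersect(unique(bound$transcript_id), names(sequences))
  if (!length(txs)) stopf("no bound transcript has a sequence")
  hits <- scan_regions(motif, sequences[txs], thresh = thresh)
  if (!nrow(hits))
    return(data.frame(transcript_id = character(), center = integer(),
                      start = integer(), end = integer(), source = character(),
                      segment = character()))
  hits$transcript_id <- sub(":.*$", "", hits$region_id)
  span_start <- hits$offset
  span_end <- hits$offset + motif$width
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    b <- bound[bound$transcript_id == hits$transcript_id[[i]], , drop = FALSE]
    !any(span_start[[i]] < b$end & span_end[[i]] > b$start)
  }, TRUE)
  if (!any(keep)) {
    warnf("every motif occurrence intersects a bound site; empty control set")
    return(data.frame(transcript_id = character(), center = integer(),
                      start = integer(), end = integer(), source = character(),
                      segment = character()))
  }
  hits <- hits[keep, , drop = FALSE]
  i <- match(hits$transcript_id, transcripts$transcript_id)
  center <- hits$offset + motif$width %/% 2L
  L <- transcripts$length[i]
  data.frame(transcript_id = hits$transcript_id, center = as.integer(center),
             start = pmax(0L, as.integer(center) - flank),
             end = pmin(L, as.integer(center) + flank + 1L),
             source = "motif_scan",
             segment = segment_of(center, transcripts$utr5_end[i],
                                  transcripts$cds_end[i]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Group binding sites by structural change between two stages
#'
#' Per site, reactivities at jointly valid bases over the site span are
#' compared between stages with a two-sided paired t-test. Group I ("more
#' structural") sites have lower mean reactivity at the later stage with
#' `|difference| > delta_cut` and `p < alpha`; group II ("less
#' structural") is the mirror image; everything else, including sites with
#' fewer than 3 jointly valid bases, is `unchanged`.
#'
#' @param profA,profB named lists of reactivity vectors for the earlier and
#'   later stage.
#' @param sites binding-site `data.frame`.
#' @param delta_cut effect-size cutoff.
#' @param alpha significance cutoff.
#' @return `data.frame` with per-site means, difference, `p_value`,
#'   `n_valid`, `group` (`I`, `II`, `unchanged`) and `low_coverage` flag.
#' @export
classify_site_structure <- function(profA, profB, sites, delta_cut = 0.05,
                                    alpha = 0.05) {
  n <- nrow(sites)
  mean_a <- mean_b <- pv <- rep(NA_real_, n)
  nv <- integer(n)
  group <- rep("unchanged", n)
  low <- logical(n)
  for (s in seq_len(n)) {
    a <- profA[[sites$transcript_id[[s]]]]
    b <- profB[[sites$transcript_id[[s]]]]
    if (is.null(a) || is.null(b)) { low[[s]] <- TRUE; next }
    idx <- (sites$start[[s]] + 1L):sites$end[[s]]
    av <- a[idx]; bv <- b[idx]
    ok <- !is.na(av) & !is.na(bv)
    nv[[s]] <- sum(ok)
    if (nv[[s]] < 3L) { low[[s]] <- TRUE; next }
    av <- av[ok]; bv <- bv[ok]
    mean_a[[s]] <- mean(av); mean_b[[s]] <- mean(bv)
    d <- bv - av
    pv[[s]] <- if (stats::sd(d) == 0) { if (d[[1L]] != 0) 0 else 1 }
    else stats::t.test(d)$p.value
    delta <- mean_b[[s]] - mean_a[[s]]
    if (abs(delta) > delta_cut && pv[[s]] < alpha)
      group[[s]] <- if (delta < 0) "I" else "II"
  }
  cbind(sites,
        data.frame(mean_react_A = mean_a, mean_react_B = mean_b,
                   delta = mean_b - mean_a, p_value = pv, n_valid = nv,
                   group = group, low_coverage = low,
                   stringsAsFactors = FALSE))
}

#' Reads per kilobase per million mapped reads
#'
#' @param counts per-gene read counts.
#' @param lengths per-gene lengths in nt.
#' @param library_size total mapped reads of the library.
#' @return Per-gene RPKM.
#' @export
rpkm <- function(counts, lengths, library_size) {
  if (any(lengths <= 0)) stopf("gene lengths must be positive")
  if (library_size <= 0) stopf("library size must be positive")
  counts / (lengths / 1e3) / (library_size / 1e6)
}

#' Per-stage RPKM from a long count table
#'
#' RPKM is computed per replicate (library size = total counts of that
#' stage/replicate) and then averaged across replicates within each stage.
#'
#' @param counts long count `data.frame` (see [read_counts_tsv()]).
#' @return Wide `data.frame`: `gene_id`, `length`, one `rpkm_<stage>`
#'   column per stage.
#' @export
rpkm_table <- function(counts) {
  genes <- unique(counts[, c("gene_id", "length")])
  if (anyDuplicated(genes$gene_id)) stopf("inconsistent gene lengths")
  out <- genes
  for (st in unique(counts$stage)) {
    cs <- counts[counts$stage == st, , drop = FALSE]
    reps <- split(cs, cs$replicate)
    mat <- vapply(reps, function(r) {
      r <- r[match(genes$gene_id, r$gene_id), ]
      rpkm(r$count, r$length, sum(r$count))
    }, numeric(nrow(genes)))
    out[[paste0("rpkm_", st)]] <- rowMeans(as.matrix(mat))
  }
  out
}

#' Exact two-library differential expression test
#'
#' An exact binomial two-proportion test: for each gene, `countA` is
#' compared with `countA + countB` under success probability
#' `libA / (libA + libB)` (two-sided). The log2 fold change is computed on
#' library-normalized rates with a pseudocount. p-values are BH-adjusted
#' across genes. The thresholds of the maternal/zygotic classification
#' operate on these outputs; externally computed fold changes and FDRs can
#' be substituted in [classify_genes()].
#'
#' @param countsA,countsB named per-gene integer counts (same genes).
#' @param libA,libB library sizes (defaults: sum of counts).
#' @param pseudo_rate pseudocount added to each normalized rate.
#' @return `data.frame`: `gene_id`, `log2fc` (A over B), `p`, `fdr`.
#' @export
de_test <- function(countsA, countsB, libA = sum(countsA),
                    libB = sum(countsB), pseudo_rate = 1e-9) {
  if (libA <= 0 || libB <= 0) stopf("library sizes must be positive")
  if (length(countsA) != length(countsB)) stopf("count vectors differ in length")
  genes <- names(countsA) %||% as.character(seq_along(countsA))
  prob <- libA / (libA + libB)
  tot <- countsA + countsB
  p <- vapply(seq_along(countsA), function(i) {
    if (tot[[i]] == 0) return(1)
    stats::binom.test(countsA[[i]], tot[[i]], p = prob)$p.value
  }, 0)
  log2fc <- log2((countsA / libA + pseudo_rate) / (countsB / libB + pseudo_rate))
  data.frame(gene_id = genes, log2fc = unname(log2fc), p = unname(p),
             fdr = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Classify genes into maternal decay, maternal stable and zygotic classes
#'
#' Applying the literal thresholds: maternal decay requires
#' `rpkm_early > rpkm_min`, `log2fc > log2(fc_cut)` and `fdr < fdr_cut`
#' (fold change oriented early/late, so decay is positive); maternal
#' stable requires `rpkm_early > rpkm_min`, `log2fc < log2(fc_cut)` and
#' `fdr < fdr_cut`; zygotic requires `rpkm_early < rpkm_min` and
#' `rpkm_late > rpkm_min`. Everything else is `unclassified`. With
#' `symmetric_stable = TRUE` the stable class additionally requires
#' `log2fc > -log2(fc_cut)`, excluding strongly up-regulated genes.
#'
#' @param records `data.frame` with `gene_id`, `rpkm_early`, `rpkm_late`,
#'   `log2fc`, `fdr`.
#' @param rpkm_min expression threshold.
#' @param fc_cut fold-change threshold (linear scale).
#' @param fdr_cut FDR threshold.
#' @param symmetric_stable bound the stable class from below too?
#' @return `records` with a `klass` column (`maternal_decay`,
#'   `maternal_stable`, `zygotic`, `unclassified`).
#' @export
classify_genes <- function(records, rpkm_min = 1, fc_cut = 1.2,
                           fdr_cut = 0.05, symmetric_stable = FALSE) {
  need <- c("gene_id", "rpkm_early", "rpkm_late", "log2fc", "fdr")
  if (!all(need %in% names(records)))
    stopf("records lack columns: %s", paste(setdiff(need, names(records)),
                                            collapse = ", "))
  lfc_cut <- log2(fc_cut)
  decay <- records$rpkm_early > rpkm_min & records$log2fc > lfc_cut &
    records$fdr < fdr_cut
  stable <- records$rpkm_early > rpkm_min & records$log2fc < lfc_cut &
    records$fdr < fdr_cut
  if (symmetric_stable) stable <- stable & records$log2fc > -lfc_cut
  zygotic <- records$rpkm_early < rpkm_min & records$rpkm_late > rpkm_min
  klass <- rep("unclassified", nrow(records))
  klass[zygotic] <- "zygotic"
  klass[stable] <- "maternal_stable"
  klass[decay] <- "maternal_decay"
  records$klass <- klass
  records
}

#' Link binding-site structural groups to mRNA stability
#'
#' Compares the expression log2 fold changes (early over late; positive
#' means decay) of genes whose binding sites become more structured
#' (group I) versus less structured (group II): two-sided Wilcoxon
#' rank-sum p, group-wise empirical CDFs, and the composition of each
#' group across gene classes.
#'
#' @param site_groups `data.frame` with `gene_id` and `group` (from
#'   [classify_site_structure()]; a transcript-to-gene mapping applied by
#'   the caller). A gene with several sites counts once per group it
#'   appears in.
#' @param gene_records classified gene table (see [classify_genes()]).
#' @return List with `wilcox_p`, `summary` (per-group n, median log2fc),
#'   `composition` (fraction of each group in each klass) and `ecdf`
#'   (named list of ECDF functions).
#' @export
stability_association <- function(site_groups, gene_records) {
  gi <- unique(site_groups$gene_id[site_groups$group == "I"])
  gii <- unique(site_groups$gene_id[site_groups$group == "II"])
  ri <- gene_records[gene_records$gene_id %in% gi, , drop = FALSE]
  rii <- gene_records[gene_records$gene_id %in% gii, , drop = FALSE]
  if (nrow(ri) < 2L || nrow(rii) < 2L)
    stopf("need at least 2 genes per structural group")
  w <- stats::wilcox.test(ri$log2fc, rii$log2fc, exact = FALSE)
  if (is.nan(w$p.value)) w$p.value <- 1  # all values tied
  comp <- do.call(rbind, lapply(list(I = ri, II = rii), function(r) {
    kl <- c("maternal_decay", "maternal_stable", "zygotic", "unclassified")
    data.frame(klass = kl,
               fraction = vapply(kl, function(k) mean(r$klass == k), 0),
               n = nrow(r), stringsAsFactors = FALSE, row.names = NULL)
  }))
  comp$group <- rep(c("I", "II"), each = 4L)
  list(wilcox_p = w$p.value,
       summary = data.frame(group = c("I", "II"),
                            n = c(nrow(ri), nrow(rii)),
                            median_log2fc = c(stats::median(ri$log2fc),
                                              stats::median(rii$log2fc))),
       composition = comp,
       ecdf = list(I = stats::ecdf(ri$log2fc), II = stats::ecdf(rii$log2fc)))
}

#' Compare site reactivity against a shuffled background
#'
#' Per-site mean reactivities (sites kept only when more than `min_valid`
#' of their bases have valid reactivity) for RBP binding sites versus
#' shuffled background sites, with a two-sided Wilcoxon rank-sum test.
#'
#' @param sites,shuffled binding-site `data.frame`s.
#' @param profiles named list of reactivity vectors.
#' @param min_valid validity fraction cutoff (strict).
#' @return List with per-set `n`, `mean`, `median`, site-level values and
#'   `wilcox_p`.
#' @export
rbp_site_reactivity_compare <- function(sites, shuffled, profiles,
                                        min_valid = 0.6) {
  site_means <- function(ss) {
    vals <- rep(NA_real_, nrow(ss))
    for (i in seq_len(nrow(ss))) {
      prof <- profiles[[ss$transcript_id[[i]]]]
      if (is.null(prof)) next
      v <- prof[(ss$start[[i]] + 1L):ss$end[[i]]]
      if (mean(!is.na(v)) > min_valid) vals[[i]] <- mean(v, na.rm = TRUE)
    }
    vals[!is.na(vals)]
  }
  a <- site_means(sites)
  b <- site_means(shuffled)
  if (!length(a) || !length(b))
    stopf("empty site set after the %.0f%% validity filter", 100 * min_valid)
  list(site = list(n = length(a), mean = mean(a), median = stats::median(a),
                   values = a),
       background = list(n = length(b), mean = mean(b),
                         median = stats::median(b), values = b),
       wilcox_p = stats::wilcox.test(a, b, exact = FALSE)$p.value)
}
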