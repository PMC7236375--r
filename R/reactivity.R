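#' RT-stop profile for one transcript/condition/replicate
#'
#' Raw probing signal: per-base reverse-transcription stop counts plus the
#' per-base read coverage ("base density") of the same library. Stops and
#' density are counted independently, so `stops[i] <= density[i]` is not
#' required.
#'
#' @param transcript_id transcript identifier.
#' @param stops nonnegative per-base RT-stop counts.
#' @param density nonnegative per-base coverage counts, same length.
#' @param condition `"treated"` (NAI) or `"control"` (DMSO).
#' @param replicate replicate index; `NA` marks a merged profile.
#' @param stage developmental stage label.
#' @return An object of class `rtstop_profile`.
#' @export
rtstop_profile <- function(transcript_id, stops, density,
                           condition = c("treated", "control"),
                           replicate = 1L, stage = "NA") {
  condition <- match.arg(condition)
  stops <- as.numeric(stops)
  density <- as.numeric(density)
  if (length(stops) != length(density))
    stopf("stops and density differ in length for transcript %s", transcript_id)
  if (length(stops) < 1L) stopf("empty profile for transcript %s", transcript_id)
  if (any(stops < 0) || any(density < 0))
    stopf("negative counts in profile for transcript %s", transcript_id)
  structure(list(transcript_id = transcript_id, stops = stops,
                 density = density, condition = condition,
                 replicate = as.integer(replicate), stage = stage),
            class = "rtstop_profile")
}

#' @export
print.rtstop_profile <- function(x, ...) {
  cat(sprintf("<rtstop_profile> %s %s rep %s stage %s: %d nt, mean stop %.2f, mean density %.1f\n",
              x$transcript_id, x$condition,
              ifelse(is.na(x$replicate), "merged", x$replicate), x$stage,
              length(x$stops), mean(x$stops), mean(x$density)))
  invisible(x)
}

#' Parameters of the reactivity calculation
#'
#' Defaults follow the icSHAPE convention: RT stops are normalized in 200-nt
#' windows sliding by 30 nt against the mean of the 90th-95th nearest-rank
#' percentile band scaled to 100; reactivity subtracts `alpha_bg` times the
#' control signal, divides by base density, and is rescaled per transcript by
#' the mean of the `[winsor_hi - winsor_lo, winsor_hi]` percentile band of
#' the raw values, then clipped to `[0, 1]`. Transcripts with mean raw RT
#' stop below `min_avg_stop` or mean density below `min_density` in the
#' treated library are discarded.
#'
#' @param window,step sliding-window size and step (nt).
#' @param rank_lo,rank_hi percentile band of the window normalizer.
#' @param scale multiplier applied after window normalization.
#' @param alpha_bg background-subtraction factor for the control signal.
#' @param min_avg_stop,min_density transcript-level retention thresholds
#'   (inclusive).
#' @param winsor_hi,winsor_lo upper percentile and band width of the final
#'   per-transcript scaling.
#' @return A list of class `reactivity_params`.
#' @export
reactivity_params <- function(window = 200L, step = 30L, rank_lo = 90,
                              rank_hi = 95, scale = 100, alpha_bg = 0.25,
                              min_avg_stop = 2, min_density = 200,
                              winsor_hi = 95, winsor_lo = 5) {
  stopifnot(window > 0L, step > 0L, rank_lo >= 0, rank_lo < rank_hi,
            rank_hi <= 100, winsor_lo > 0, winsor_hi <= 100,
            winsor_hi - winsor_lo >= 0)
  structure(list(window = as.integer(window), step = as.integer(step),
                 rank_lo = rank_lo, rank_hi = rank_hi, scale = scale,
                 alpha_bg = alpha_bg, min_avg_stop = min_avg_stop,
                 min_density = min_density, winsor_hi = winsor_hi,
                 winsor_lo = winsor_lo),
            class = "reactivity_params")
}

#' Combine replicate RT-stop profiles
#'
#' Stops and densities are summed element-wise; the replicate field of the
#' result is `NA`, the merged sentinel.
#'
#' @param profiles list of `rtstop_profile` objects sharing transcript,
#'   condition, stage and length.
#' @return A merged `rtstop_profile`.
#' @export
combine_replicates <- function(profiles) {
  if (inherits(profiles, "rtstop_profile")) profiles <- list(profiles)
  if (!length(profiles)) stopf("no profiles to combine")
  ids <- unique(vapply(profiles, `[[`, "", "transcript_id"))
  conds <- unique(vapply(profiles, `[[`, "", "condition"))
  stages <- unique(vapply(profiles, `[[`, "", "stage"))
  lens <- unique(vapply(profiles, function(p) length(p$stops), 1L))
  if (length(ids) != 1L || length(conds) != 1L || length(stages) != 1L)
    stopf("cannot combine profiles from different transcripts/conditions/stages")
  if (length(lens) != 1L)
    stopf("cannot combine profiles of different lengths for transcript %s", ids)
  rtstop_profile(ids,
                 Reduce(`+`, lapply(profiles, `[[`, "stops")),
                 Reduce(`+`, lapply(profiles, `[[`, "density")),
                 conds, NA_integer_, stages)
}

#' Window-normalize RT-stop counts
#'
#' Windows of `params$window` nt slide along the transcript by `params$step`
#' nt; a final window anchored at the 3' end keeps full size so that every
#' base is covered by full-length windows (a transcript shorter than one
#' window is normalized as a single short window rather than dropped).
#' Within a window every stop count is divided by the mean of the counts in
#' the nearest-rank percentile band `[rank_lo, rank_hi]` and multiplied by
#' `scale`. A window whose normalizer is 0 contributes the invalid marker.
#' The per-base output is the mean of the contributions of all windows
#' covering that base; bases with no valid contribution are `NA`.
#'
#' @param stops numeric vector of per-base RT-stop counts (or an
#'   `rtstop_profile`, in which case its `stops` field is used).
#' @param params a [reactivity_params()] object.
#' @return Numeric vector of normalized stops (`NA` = invalid).
#' @export
normalize_rtstops <- function(stops, params = reactivity_params()) {
  if (inherits(stops, "rtstop_profile")) stops <- stops$stops
  n <- length(stops)
  if (n < 1L) stopf("empty stop vector")
  starts <- if (n <= params$window) 0L else {
    s <- seq.int(0L, n - params$window, by = params$step)
    if (s[[length(s)]] + params$window < n) c(s, n - params$window) else s
  }
  acc <- numeric(n)
  cnt <- integer(n)
  for (s in starts) {
    e <- min(s + params$window, n)
    idx <- (s + 1L):e
    vals <- stops[idx]
    norm <- band_mean(vals, params$rank_lo, params$rank_hi)
    if (is.na(norm) || norm == 0) next  # invalid contribution
    acc[idx] <- acc[idx] + vals / norm * params$scale
    cnt[idx] <- cnt[idx] + 1L
  }
  out <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
  out
}

#' Compute per-base icSHAPE reactivity
#'
#' `raw_i = max(0, treated_i - alpha_bg * control_i) / max(density_i, 1)`;
#' the raw values are then divided by the mean of the nearest-rank
#' percentile band `[winsor_hi - winsor_lo, winsor_hi]` of the valid raw
#' values and clipped to `[0, 1]`. Bases with zero density or an invalid
#' input, and whole transcripts whose scaling normalizer is 0, yield the
#' invalid marker: absence of signal is not evidence of structure.
#'
#' @param treated_norm,control_norm window-normalized stop vectors
#'   (see [normalize_rtstops()]).
#' @param density per-base density of the treated library.
#' @param params a [reactivity_params()] object.
#' @return Numeric vector of reactivities in `[0, 1]` with `NA` invalid.
#' @export
compute_reactivity <- function(treated_norm, control_norm, density,
                               params = reactivity_params()) {
  n <- length(treated_norm)
  if (length(control_norm) != n || length(density) != n)
    stopf("treated, control and density vectors differ in length")
  raw <- pmax(0, treated_norm - params$alpha_bg * control_norm) / pmax(density, 1)
  invalid <- is.na(treated_norm) | is.na(control_norm) | density == 0
  raw[invalid] <- NA_real_
  norm <- band_mean(raw, params$winsor_hi - params$winsor_lo, params$winsor_hi)
  if (is.na(norm) || norm <= 0) return(rep(NA_real_, n))
  out <- pmin(1, pmax(0, raw / norm))
  out[invalid] <- NA_real_
  out
}

#' Transcript-level coverage filter
#'
#' A transcript is retained when its mean raw RT stop is at least
#' `min_avg_stop` and its mean base density at least `min_density` in the
#' treated library (thresholds inclusive; the filter looks at the treated
#' library only).
#'
#' @param profiles named list of combined treated `rtstop_profile` objects,
#'   keyed by transcript.
#' @param params a [reactivity_params()] object.
#' @return List with `retained` (passing subset of `profiles`) and `report`
#'   (`data.frame` with per-transcript means, retention flag and exclusion
#'   reason).
#' @export
filter_transcripts <- function(profiles, params = reactivity_params()) {
  mean_stop <- vapply(profiles, function(p) mean(p$stops), 0)
  mean_density <- vapply(profiles, function(p) mean(p$density), 0)
  ok_stop <- mean_stop >= params$min_avg_stop
  ok_dens <- mean_density >= params$min_density
  keep <- ok_stop & ok_dens
  reason <- rep("", length(profiles))
  reason[!ok_stop] <- "avg_stop"
  reason[ok_stop & !ok_dens] <- "density"
  report <- data.frame(transcript_id = names(profiles),
                       mean_stop = unname(mean_stop),
                       mean_density = unname(mean_density),
                       retained = unname(keep), reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  list(retained = profiles[keep], report = report)
}

#' Full reactivity pipeline for one stage
#'
#' Combines replicates per condition, applies the transcript coverage
#' filter on the combined treated library, window-normalizes treated and
#' control stops, and computes reactivities. The report additionally gives
#' the fraction of valid bases per retained transcript.
#'
#' @param treated,control lists of `rtstop_profile` objects (any mixture of
#'   transcripts and replicates of one condition each).
#' @param params a [reactivity_params()] object.
#' @return List with `profiles` (named list of reactivity vectors) and
#'   `report` (filter report with a `valid_frac` column).
#' @export
reactivity_pipeline <- function(treated, control, params = reactivity_params()) {
  merge_by_tx <- function(profs) {
    by <- split(profs, vapply(profs, `[[`, "", "transcript_id"))
    lapply(by, combine_replicates)
  }
  tr <- merge_by_tx(treated)
  ct <- merge_by_tx(control)
  common <- intersect(names(tr), names(ct))
  if (!length(common)) stopf("no transcript present in both conditions")
  flt <- filter_transcripts(tr[common], params)
  profiles <- lapply(flt$retained, function(p) {
    tn <- normalize_rtstops(p$stops, params)
    cn <- normalize_rtstops(ct[[p$transcript_id]]$stops, params)
    compute_reactivity(tn, cn, p$density, params)
  })
  report <- flt$report
  vf <- vapply(profiles, function(v) mean(!is.na(v)), 0)
  report$valid_frac <- vf[match(report$transcript_id, names(profiles))]
  list(profiles = profiles, report = report)
}

#' Replicate-noise quantiles of reactivity differences
#'
#' Quantifies technical noise between two replicate reactivity sets: the
#' per-base absolute difference over bases valid in both replicates, and
#' the absolute difference of window-mean reactivity for sliding windows
#' (step 1) with at least 80% jointly valid bases. Used to justify the
#' single-base (0.2) and window (0.05) difference cutoffs.
#'
#' @param repA,repB named lists of reactivity vectors covering the same
#'   transcripts.
#' @param window window size in nt.
#' @param base_thresholds,window_thresholds thresholds at which to report
#'   the fraction of differences below threshold.
#' @return List with `base` and `window` components (each carrying `n`,
#'   `fraction_below` and a `quantile` function) and an `empty` flag.
#' @export
replicate_noise_quantiles <- function(repA, repB, window = 10L,
                                      base_thresholds = c(0.2),
                                      window_thresholds = c(0.05)) {
  common <- intersect(names(repA), names(repB))
  base_d <- numeric(0)
  win_d <- numeric(0)
  for (id in common) {
    a <- repA[[id]]; b <- repB[[id]]
    if (length(a) != length(b))
      stopf("replicate profiles for %s differ in length", id)
    ok <- !is.na(a) & !is.na(b)
    base_d <- c(base_d, abs(a - b)[ok])
    n <- length(a)
    if (n >= window) {
      ok_cs <- cumsum(c(0L, as.integer(ok)))
      d <- ifelse(ok, a - b, 0)
      d_cs <- cumsum(c(0, d))
      s <- 1L:(n - window + 1L)
      nv <- ok_cs[s + window] - ok_cs[s]
      keep <- nv >= ceiling(0.8 * window)
      if (any(keep)) {
        sums <- d_cs[s + window] - d_cs[s]
        win_d <- c(win_d, abs(sums[keep] / nv[keep]))
      }
    }
  }
  mk <- function(x, thr) {
    if (!length(x)) return(list(n = 0L, fraction_below = setNames(
      rep(NA_real_, length(thr)), thr), quantile = function(p) NA_real_))
    list(n = length(x),
         fraction_below = setNames(vapply(thr, function(t) mean(x < t), 0),
                                   as.character(thr)),
         quantile = stats::ecdf(x))
  }
  out <- list(base = mk(base_d, base_thresholds),
              window = mk(win_d, window_thresholds),
              empty = length(base_d) == 0L)
  if (out$empty) warnf("no jointly valid positions between replicates")
  out
}

#' Agreement of reactivity with a known secondary structure
#'
#' Treats reactivity as a classifier of unpaired (positive class) versus
#' paired bases: reports the ROC area under the curve with midrank tie
#' handling, and the two-sided unpaired t-test p-value for lower reactivity
#' at paired bases.
#'
#' @param values numeric reactivity vector (`NA` = invalid).
#' @param pairing character vector over `paired`, `unpaired`, `unknown`.
#' @return List with `auc`, `tstat_p`, `n_paired`, `n_unpaired`.
#' @export
structure_auc <- function(values, pairing) {
  if (length(values) != length(pairing))
    stopf("values and pairing differ in length")
  ok <- !is.na(values) & pairing %in% c("paired", "unpaired")
  v <- values[ok]
  pos <- pairing[ok] == "unpaired"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stopf("need at least one paired and one unpaired base with valid reactivity")
  r <- rank(v)  # midranks
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  p <- if (n1 > 1L && n0 > 1L && (stats::sd(v[pos]) > 0 || stats::sd(v[!pos]) > 0))
    stats::t.test(v[pos], v[!pos])$p.value
  else if (n1 > 1L && n0 > 1L)  # both groups constant: separation is exact
    as.numeric(mean(v[pos]) == mean(v[!pos]))
  else NA_real_
  list(auc = auc, tstat_p = p, n_paired = n0, n_unpaired = n1)
}
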