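# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Mean of a nearest-rank percentile band
#'
#' Order statistics whose nearest-rank percentile (ceil(p/100 * n)) falls in
#' `[lo, hi]` are averaged; the band is inclusive on both ends. This is the
#' convention used for every percentile-band normalizer in the package.
#'
#' @param x numeric vector (NAs removed).
#' @param lo,hi percentile bounds in [0, 100], `lo < hi`.
#' @return Mean of the selected order statistics; `NA` if `x` is empty.
#' @keywords internal
band_mean <- function(x, lo, hi) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  r_lo <- max(1L, as.integer(ceiling(lo / 100 * n)))
  r_hi <- max(r_lo, as.integer(ceiling(hi / 100 * n)))
  mean(sort(x, method = "quick")[r_lo:r_hi])
}

# 0-based half-open segment lookup: "5UTR" for p < utr5_end, "CDS" for
# utr5_end <= p < cds_end, "3UTR" otherwise.
segment_of <- function(pos, utr5_end, cds_end) {
  ifelse(pos < utr5_end, "5UTR", ifelse(pos < cds_end, "CDS", "3UTR"))
}

pkg_version <- function() {
  as.character(utils::packageVersion("structvar"))
}

# Header comment written at the top of every file this package emits.
writer_header <- function(what, params = character()) {
  extra <- if (length(params)) paste0(" ", paste(names(params), unlist(params),
                                                 sep = "=", collapse = " ")) else ""
  sprintf("# structvar %s %s%s", pkg_version(), what, extra)
}

# Deterministic local RNG scope: runs `expr` under `seed` and restores the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
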