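#' Read a transcript annotation table
#'
#' The transcript table is the package's annotation contract: a tab-separated
#' file with header columns `transcript_id`, `gene_id`, `length`, `utr5_end`
#' and `cds_end`. Coordinates are 0-based half-open offsets in transcript
#' space, so a position `p` lies in the 5'UTR when `p < utr5_end`, in the CDS
#' when `utr5_end <= p < cds_end`, and in the 3'UTR otherwise.
#'
#' @param path path to the TSV file.
#' @param fasta optional path to a companion FASTA file keyed by
#'   `transcript_id`; sequences are converted to RNA (`T` becomes `U`).
#' @return A `data.frame` with one row per transcript and, when `fasta` is
#'   given, a `sequence` attribute holding a named character vector.
#' @export
read_transcript_table <- function(path, fasta = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) stopf("empty transcript table: %s", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  need <- c("transcript_id", "gene_id", "length", "utr5_end", "cds_end")
  if (!all(need %in% header))
    stopf("transcript table %s lacks columns: %s", path,
          paste(setdiff(need, header), collapse = ", "))
  body <- lines[-1L]
  rows <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad))
    stopf("malformed transcript row at line %d of %s", bad[[1L]] + 1L, path)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  for (col in c("length", "utr5_end", "cds_end")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v)) {
      line <- which(is.na(v))[[1L]] + 1L
      stopf("non-integer '%s' at line %d of %s", col, line, path)
    }
    df[[col]] <- v
  }
  if (anyDuplicated(df$transcript_id))
    stopf("duplicate transcript_id: %s",
          df$transcript_id[duplicated(df$transcript_id)][[1L]])
  validate_transcripts(df)
  df <- df[, need]
  if (!is.null(fasta)) {
    seqs <- read_transcript_fasta(fasta)
    missing <- setdiff(df$transcript_id, names(seqs))
    if (length(missing))
      stopf("FASTA %s lacks sequence for transcript %s", fasta, missing[[1L]])
    seqs <- seqs[df$transcript_id]
    badlen <- which(nchar(seqs) != df$length)
    if (length(badlen))
      stopf("sequence length mismatch for transcript %s",
            df$transcript_id[badlen[[1L]]])
    attr(df, "sequence") <- seqs
  }
  df
}

validate_transcripts <- function(df) {
  bad <- which(!(df$utr5_end >= 0L & df$utr5_end <= df$cds_end &
                   df$cds_end <= df$length & df$length > 0L))
  if (length(bad))
    stopf("invalid segment bounds for transcript %s (need 0 <= utr5_end <= cds_end <= length)",
          df$transcript_id[bad[[1L]]])
  invisible(df)
}

#' Read transcript sequences from FASTA as RNA strings
#'
#' @param path FASTA file.
#' @return Named character vector of sequences over `ACGUN`.
#' @export
read_transcript_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad))
    stopf("non-ACGUN character in FASTA record %s", names(seqs)[bad][[1L]])
  seqs
}

#' Write transcript table and companion FASTA
#'
#' @param transcripts transcript `data.frame` (see [read_transcript_table()]).
#' @param path output TSV path.
#' @param fasta optional output FASTA path; requires a `sequence` attribute
#'   or an explicit `sequences` vector.
#' @param sequences optional named character vector of sequences.
#' @export
write_transcript_table <- function(transcripts, path, fasta = NULL,
                                   sequences = attr(transcripts, "sequence")) {
  validate_transcripts(transcripts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(writer_header("transcript_table"), con)
  writeLines(paste(c("transcript_id", "gene_id", "length", "utr5_end", "cds_end"),
                   collapse = "\t"), con)
  writeLines(sprintf("%s\t%s\t%d\t%d\t%d", transcripts$transcript_id,
                     transcripts$gene_id, transcripts$length,
                     transcripts$utr5_end, transcripts$cds_end), con)
  if (!is.null(fasta)) {
    if (is.null(sequences)) stopf("no sequences available to write FASTA")
    set <- Biostrings::BStringSet(sequences[transcripts$transcript_id])
    Biostrings::writeXStringSet(set, fasta, width = 80L)
  }
  invisible(path)
}

#' Read per-base reactivity profiles (icSHAPE ".out" dialect)
#'
#' One line per transcript: `id`, declared length, a coverage proxy, then one
#' value per base with the literal token `NULL` marking bases without a valid
#' reactivity. Values must lie in `[0, 1]`.
#'
#' @param path input file.
#' @return Named list of numeric vectors; invalid bases are `NA`.
#' @export
read_reactivity_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(tok) < 3L) stopf("malformed reactivity line %d in %s", i, path)
    len <- suppressWarnings(as.integer(tok[[2L]]))
    if (is.na(len) || len < 1L) stopf("bad length field on line %d of %s", i, path)
    vals <- tok[-(1:3)]
    if (length(vals) != len)
      stopf("transcript %s declares %d bases but carries %d values (%s line %d)",
            tok[[1L]], len, length(vals), path, i)
    v <- rep(NA_real_, len)
    num <- vals != "NULL"
    parsed <- suppressWarnings(as.numeric(vals[num]))
    if (anyNA(parsed))
      stopf("non-numeric reactivity token '%s' on line %d of %s",
            vals[num][is.na(parsed)][[1L]], i, path)
    if (any(parsed < 0 | parsed > 1))
      stopf("reactivity outside [0,1] (%.4g) on line %d of %s",
            parsed[parsed < 0 | parsed > 1][[1L]], i, path)
    v[num] <- parsed
    out[[i]] <- v
    ids[[i]] <- tok[[1L]]
  }
  if (anyDuplicated(ids))
    stopf("duplicate transcript_id in %s: %s", path, ids[duplicated(ids)][[1L]])
  names(out) <- ids
  out
}

#' Write reactivity profiles in the ".out" dialect
#'
#' Values are formatted at 6 significant digits; `NA` becomes `NULL`. The
#' third column records the fraction of valid bases as a coverage proxy.
#'
#' @param profiles named list of numeric vectors (`NA` = invalid).
#' @param path output file.
#' @export
write_reactivity_out <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(writer_header("reactivity_out"), con)
  for (id in names(profiles)) {
    v <- profiles[[id]]
    tok <- ifelse(is.na(v), "NULL", formatC(v, format = "g", digits = 6))
    writeLines(paste(c(id, length(v),
                       formatC(mean(!is.na(v)), format = "g", digits = 6), tok),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read motifs from a MEME minimal-format file
#'
#' Accepts alphabets `ACGT` and `ACGU` interchangeably (matrices are stored
#' in `ACGU` order). Letter-probability rows must sum to 1 within 1e-3 and
#' motifs must be at least 4 columns wide.
#'
#' @param path MEME minimal file.
#' @param pseudo pseudocount applied when scoring (see [motif_model()]).
#' @return Named list of `motif_model` objects.
#' @export
read_motif_meme <- function(path, pseudo = 1e-4) {
  lines <- trimws(readLines(path))
  bg <- c(0.25, 0.25, 0.25, 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) && bg_at[[1L]] < length(lines)) {
    tok <- strsplit(lines[[bg_at[[1L]] + 1L]], "\\s+")[[1L]]
    if (length(tok) >= 8L) {
      freq <- as.numeric(tok[c(2L, 4L, 6L, 8L)])
      if (!anyNA(freq)) bg <- freq / sum(freq)
    }
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stopf("no MOTIF entries in %s", path)
  motifs <- list()
  for (s in starts) {
    name <- strsplit(lines[[s]], "\\s+")[[1L]][[2L]]
    hdr <- s + which(startsWith(lines[(s + 1L):length(lines)],
                                "letter-probability matrix"))[[1L]]
    w <- as.integer(sub(".*w\\s*=\\s*(\\d+).*", "\\1", lines[[hdr]]))
    if (is.na(w)) stopf("motif %s: cannot parse width in %s", name, path)
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    if (anyNA(mat) || ncol(mat) != 4L)
      stopf("motif %s: malformed probability matrix in %s", name, path)
    bad <- abs(rowSums(mat) - 1) > 1e-3
    if (any(bad))
      stopf("motif %s: probability row %d sums to %.4f (tolerance 1e-3)",
            name, which(bad)[[1L]], rowSums(mat)[bad][[1L]])
    motifs[[name]] <- motif_model(name, mat, background = bg, pseudo = pseudo)
  }
  motifs
}

#' Write motifs in MEME minimal format
#'
#' @param motifs named list of `motif_model` objects.
#' @param path output file.
#' @export
write_motif_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "Background letter frequencies", sprintf(
                 "A %.6f C %.6f G %.6f U %.6f",
                 motifs[[1L]]$background[1L], motifs[[1L]]$background[2L],
                 motifs[[1L]]$background[3L], motifs[[1L]]$background[4L]), ""),
             con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", m$width), con)
    writeLines(apply(m$raw_probs, 1L, function(r)
      paste(formatC(r, format = "f", digits = 6), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a BED-like region file in transcript coordinates
#'
#' Five tab-separated columns: `transcript_id`, `start`, `end` (0-based
#' half-open), `label`, `score` (`.` for absent). Lines starting with `#`
#' are comments.
#'
#' @param path input file.
#' @return `data.frame` with columns `transcript_id`, `start`, `end`,
#'   `label`, `score`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), label = character(), score = numeric()))
  tok <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(tok) != 5L)
  if (length(bad)) stopf("malformed region line %d in %s", bad[[1L]], path)
  m <- do.call(rbind, tok)
  df <- data.frame(transcript_id = m[, 1L],
                   start = suppressWarnings(as.integer(m[, 2L])),
                   end = suppressWarnings(as.integer(m[, 3L])),
                   label = m[, 4L],
                   score = suppressWarnings(ifelse(m[, 5L] == ".", NA_real_,
                                                   as.numeric(m[, 5L]))),
                   stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end))
    stopf("non-integer coordinates in %s", path)
  if (any(df$start < 0L | df$start >= df$end))
    stopf("invalid interval (need 0 <= start < end) in %s", path)
  df
}

#' Write regions as BED-like text
#'
#' @param regions `data.frame` with columns `transcript_id`, `start`, `end`
#'   and optionally `label` and `score`.
#' @param path output file.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(writer_header("regions_bed"), con)
  if (nrow(regions)) {
    label <- if ("label" %in% names(regions)) regions$label else "."
    score <- if ("score" %in% names(regions)) regions$score else NA_real_
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s", regions$transcript_id,
                       as.integer(regions$start), as.integer(regions$end), label,
                       ifelse(is.na(score), ".",
                              formatC(score, format = "g", digits = 6))), con)
  }
  invisible(path)
}

#' Read per-base RT-stop profiles from a long TSV
#'
#' Columns: `transcript_id`, `position` (0-based), `stops`, `density`,
#' `condition` (`treated`/`control`), `replicate`. Every transcript must
#' cover positions `0..length-1` contiguously within each
#' condition/replicate block.
#'
#' @param path input TSV.
#' @param stage stage label attached to each profile.
#' @return List of `rtstop_profile` objects.
#' @export
read_rtstop_tsv <- function(path, stage = "NA") {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "stops", "density", "condition", "replicate")
  if (!all(need %in% names(df)))
    stopf("RT-stop table %s lacks columns: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  key <- interaction(df$transcript_id, df$condition, df$replicate, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$position), ]
    if (!identical(g$position, seq_len(nrow(g)) - 1L) &&
        !identical(as.integer(g$position), seq_len(nrow(g)) - 1L))
      stopf("non-contiguous positions for transcript %s in %s",
            g$transcript_id[[1L]], path)
    rtstop_profile(g$transcript_id[[1L]], g$stops, g$density,
                   g$condition[[1L]], g$replicate[[1L]], stage)
  })
}

#' Write RT-stop profiles as a long TSV
#'
#' @param profiles list of `rtstop_profile` objects.
#' @param path output TSV.
#' @export
write_rtstop_tsv <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(writer_header("rtstop_tsv"), con)
  writeLines("transcript_id\tposition\tstops\tdensity\tcondition\treplicate", con)
  for (p in profiles) {
    n <- length(p$stops)
    writeLines(sprintf("%s\t%d\t%d\t%d\t%s\t%d", p$transcript_id, 0:(n - 1L),
                       as.integer(p$stops), as.integer(p$density), p$condition,
                       as.integer(p$replicate)), con)
  }
  invisible(path)
}

#' Read a per-gene count table
#'
#' Long TSV with columns `gene_id`, `length`, `stage`, `replicate`, `count`.
#'
#' @param path input TSV.
#' @return `data.frame`.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "length", "stage", "replicate", "count")
  if (!all(need %in% names(df)))
    stopf("count table %s lacks columns: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$count < 0)) stopf("negative count in %s", path)
  df
}

#' Write a per-gene count table
#'
#' @param counts `data.frame` as returned by [read_counts_tsv()].
#' @param path output TSV.
#' @export
write_counts_tsv <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(writer_header("counts_tsv"), con)
  writeLines("gene_id\tlength\tstage\treplicate\tcount", con)
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d", counts$gene_id,
                     as.integer(counts$length), counts$stage,
                     as.integer(counts$replicate), as.integer(counts$count)), con)
  invisible(path)
}
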