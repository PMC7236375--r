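#' Run the full analysis workflow on a fixture directory
#'
#' Wires every stage of the analysis together: per-stage reactivity from
#' RT-stop tables, the differential window scan between the two stages,
#' re-binned variable regions and their segment enrichment, motif
#' enrichment of 3'UTR variable regions against a matched sampled
#' background, iCLIP-derived binding sites with structural grouping and
#' metaprofiles, expression classification, and the structure-stability
#' association. Outputs and a JSON manifest (version, parameters, input
#' and output digests) are written under `out_dir`; reruns with identical
#' inputs and seed are byte-identical, so manifests carry no timestamps.
#'
#' @param fixture_dir directory produced by [emit_fixture()] (or any
#'   directory with the same file layout).
#' @param out_dir output directory (created if absent).
#' @param params a [reactivity_params()] object.
#' @param stages the two stage labels, earlier first.
#' @param seed seed for the background-region sampling.
#' @return Invisibly, a list with every intermediate result.
#' @export
run_pipeline <- function(fixture_dir, out_dir,
                         params = reactivity_params(),
                         stages = c("A", "B"), seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- list(transcripts = file.path(fixture_dir, "transcripts.tsv"),
                 fasta = file.path(fixture_dir, "transcripts.fa"),
                 truncations = file.path(fixture_dir, "truncations.bed"),
                 motifs = file.path(fixture_dir, "motifs.meme"),
                 counts = file.path(fixture_dir, "counts.tsv"))
  for (stage in stages)
    inputs[[paste0("rtstops_", stage)]] <-
      file.path(fixture_dir, sprintf("rtstops_%s.tsv", stage))
  missing <- !file.exists(unlist(inputs))
  if (any(missing)) stopf("missing input file: %s", unlist(inputs)[missing][[1L]])

  transcripts <- read_transcript_table(inputs$transcripts, fasta = inputs$fasta)
  sequences <- attr(transcripts, "sequence")
  tx_lengths <- setNames(transcripts$length, transcripts$transcript_id)
  motifs <- read_motif_meme(inputs$motifs)
  outputs <- list()
  emit <- function(name, path) { outputs[[name]] <<- path; path }

  # per-stage reactivity
  react <- list()
  for (stage in stages) {
    profs <- read_rtstop_tsv(inputs[[paste0("rtstops_", stage)]], stage = stage)
    cond <- vapply(profs, `[[`, "", "condition")
    res <- reactivity_pipeline(profs[cond == "treated"],
                               profs[cond == "control"], params)
    react[[stage]] <- res
    write_reactivity_out(res$profiles,
                         emit(paste0("reactivity_", stage),
                              file.path(out_dir, sprintf("reactivity_%s.out", stage))))
  }
  profA <- react[[stages[[1L]]]]$profiles
  profB <- react[[stages[[2L]]]]$profiles

  # differential windows and re-binned variable regions
  windows <- window_scan_set(profA, profB)
  regions <- build_regions(windows, tx_lengths)
  write_regions_bed(regions, emit("regions", file.path(out_dir, "regions.bed")))
  regions_seg <- if (nrow(regions)) assign_segments(regions, transcripts)
  else cbind(regions, data.frame(segment = character()))
  seg_enrich <- if (nrow(regions_seg))
    segment_enrichment(table(regions_seg$segment)) else NULL
  if (!is.null(seg_enrich))
    utils::write.table(seg_enrich,
                       emit("segment_enrichment",
                            file.path(out_dir, "segment_enrichment.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # motif enrichment of 3'UTR variable regions vs sampled background
  test_regions <- regions_seg[regions_seg$segment == "3UTR", , drop = FALSE]
  enrich <- NULL
  if (nrow(test_regions) >= 5L) {
    src_tx <- transcripts[transcripts$transcript_id %in%
                            test_regions$transcript_id, , drop = FALSE]
    bg_regions <- sample_background_regions(src_tx, test_regions, length = 30L,
                                            n = nrow(test_regions), seed = seed,
                                            restrict = "3utr")
    enrich <- enrich_motifs(motifs,
                            region_sequences(test_regions, sequences),
                            region_sequences(bg_regions, sequences))
    utils::write.table(enrich,
                       emit("motif_enrichment",
                            file.path(out_dir, "motif_enrichment.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # iCLIP sites: structural groups, metaprofiles, stability linkage
  trunc <- read_regions_bed(inputs$truncations)
  sites <- truncation_to_sites(data.frame(transcript_id = trunc$transcript_id,
                                          pos = trunc$start), transcripts)
  site_groups <- classify_site_structure(profA, profB, sites)
  utils::write.table(site_groups[, setdiff(names(site_groups), "low_coverage")],
                     emit("site_groups", file.path(out_dir, "site_groups.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    bound = metaprofile(profA, sites, set_label = "bound"),
    unbound_control = tryCatch({
      ctrl <- unbound_controls(motifs[[1L]], transcripts, sites,
                               sequences = sequences)
      if (nrow(ctrl)) metaprofile(profA, ctrl, set_label = "unbound_control")
      else NULL
    }, error = function(e) NULL))
  meta_df <- do.call(rbind, lapply(names(meta)[!vapply(meta, is.null, TRUE)],
                                   function(nm) cbind(meta[[nm]], set = nm)))
  utils::write.table(meta_df,
                     emit("metaprofile", file.path(out_dir, "metaprofile.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # expression: RPKM, exact DE test, gene classes
  counts <- read_counts_tsv(inputs$counts)
  rk <- rpkm_table(counts)
  st_early <- unique(counts$stage)[[1L]]
  st_late <- unique(counts$stage)[[2L]]
  sum_counts <- function(st) {
    cs <- counts[counts$stage == st, , drop = FALSE]
    tapply(cs$count, cs$gene_id, sum)[rk$gene_id]
  }
  de <- de_test(sum_counts(st_early), sum_counts(st_late))
  records <- data.frame(gene_id = rk$gene_id,
                        rpkm_early = rk[[paste0("rpkm_", st_early)]],
                        rpkm_late = rk[[paste0("rpkm_", st_late)]],
                        log2fc = de$log2fc, fdr = de$fdr,
                        stringsAsFactors = FALSE)
  records <- classify_genes(records)
  utils::write.table(records,
                     emit("gene_classes", file.path(out_dir, "gene_classes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  site_groups$gene_id <- transcripts$gene_id[
    match(site_groups$transcript_id, transcripts$transcript_id)]
  assoc <- tryCatch(stability_association(site_groups, records),
                    error = function(e) NULL)
  if (!is.null(assoc))
    jsonlite::write_json(list(wilcox_p = assoc$wilcox_p,
                              summary = assoc$summary,
                              composition = assoc$composition),
                         emit("association", file.path(out_dir, "association.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(tool = "structvar", version = pkg_version(),
                   subcommand = "pipeline", seed = seed, stages = stages,
                   parameters = unclass(params),
                   input_digests = as.list(tools::md5sum(unlist(inputs))),
                   output_digests = as.list(tools::md5sum(unlist(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(reactivity = react, windows = windows, regions = regions_seg,
                 segment_enrichment = seg_enrich, motif_enrichment = enrich,
                 site_groups = site_groups, metaprofiles = meta,
                 gene_records = records, association = assoc,
                 manifest = manifest, outputs = outputs))
}
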