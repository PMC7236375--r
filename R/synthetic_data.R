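#' Configuration of the synthetic probing study
#'
#' The generator emulates the statistical structure the analysis assumes:
#' hairpin-structured transcripts whose 5'UTR:CDS:3'UTR lengths follow the
#' 150:1250:460 transcriptome average, RT-stop counts that are binomial
#' draws on Poisson read coverage with a higher stop rate at unpaired
#' bases, stage-dependent structure switches planted at U-rich motif sites
#' in 3'UTRs, iCLIP-like truncations at bound sites, and expression decay
#' coupled to the direction of the site switch.
#'
#' @param n_transcripts number of transcripts (one gene each).
#' @param segment_weights 5'UTR:CDS:3'UTR length weights.
#' @param mean_length,length_sd transcript length distribution (nt).
#' @param hairpin_density hairpin stems per kb; each stem pairs two 15-nt
#'   arms around a 10-nt unpaired loop.
#' @param hetero_shape shape of the Gamma(shape, shape) per-base
#'   accessibility multiplier (mean 1) applied to every stop rate. The
#'   multiplier is part of the ground truth: fixed per base, shared across
#'   stages, replicates and conditions, so it models biological base-level
#'   variation (and RT bias, since the control shares it) that cancels in
#'   stage comparisons. `Inf` disables heterogeneity.
#' @param motif planted binding motif (a `motif_model`).
#' @param n_switch_sites number of transcripts given one stage-dependent
#'   structural switch at a motif site in their 3'UTR.
#' @param switch_delta planted reactivity shift at switched and bound
#'   sites: the accessible state elevates the treated stop rate by
#'   `switch_delta` times the transcript's 90th-95th percentile rate band,
#'   which the window normalization maps back to a reactivity shift of
#'   about `switch_delta`.
#' @param coverage_mean mean reads per base (Poisson). The default is
#'   deep: window-level technical noise must sit well below the 0.05
#'   effect-size cutoff for planted switches to be recoverable at low
#'   false discovery rates; the 200x transcript-retention threshold is a
#'   floor, not a typical depth.
#' @param stop_rate_unpaired,stop_rate_paired per-read RT-stop probability
#'   in the treated library by pairing state.
#' @param control_stop_rate per-read stop probability in the control.
#' @param n_replicates replicates per condition and stage.
#' @param n_const_bound constitutively accessible bound motif sites.
#' @param n_unbound motif sites paired at both stages (never bound).
#' @param mutation_rate per-base mutation rate applied to planted motif
#'   instances, exercising PWM scoring below the maximal score.
#' @param decay_coupling probability that a gene whose site gains
#'   structure (group I) is a maternal-decay gene (and that a group II
#'   gene is maternal-stable).
#' @param decay_log2fc expression log2 fold change (early over late) of
#'   decay genes.
#' @param nb_size negative-binomial size (inverse overdispersion) of the
#'   per-replicate counts; the default corresponds to a ~10% biological
#'   CV, appropriate for replicates drawn from pooled embryos.
#' @param seed master RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 40L,
                       segment_weights = c(150, 1250, 460),
                       mean_length = 1860, length_sd = 150,
                       hairpin_density = 12, hetero_shape = 2,
                       motif = motif_from_consensus("Elavl1", "UUUGUUU"),
                       n_switch_sites = 16L, switch_delta = 0.3,
                       coverage_mean = 5000, stop_rate_unpaired = 0.08,
                       stop_rate_paired = 0.02, control_stop_rate = 0.01,
                       n_replicates = 2L, n_const_bound = 8L,
                       n_unbound = 8L, mutation_rate = 0.1,
                       decay_coupling = 0.6, decay_log2fc = 1.0,
                       nb_size = 100, seed = 1L) {
  rates <- c(stop_rate_unpaired, stop_rate_paired, control_stop_rate)
  stopifnot(all(rates > 0), all(rates < 1), all(segment_weights > 0),
            n_transcripts >= 0, switch_delta >= 0,
            decay_coupling >= 0, decay_coupling <= 1)
  structure(list(n_transcripts = as.integer(n_transcripts),
                 segment_weights = segment_weights,
                 mean_length = mean_length, length_sd = length_sd,
                 hairpin_density = hairpin_density,
                 hetero_shape = hetero_shape, motif = motif,
                 n_switch_sites = as.integer(n_switch_sites),
                 switch_delta = switch_delta, coverage_mean = coverage_mean,
                 stop_rate_unpaired = stop_rate_unpaired,
                 stop_rate_paired = stop_rate_paired,
                 control_stop_rate = control_stop_rate,
                 n_replicates = as.integer(n_replicates),
                 n_const_bound = as.integer(n_const_bound),
                 n_unbound = as.integer(n_unbound),
                 mutation_rate = mutation_rate,
                 decay_coupling = decay_coupling,
                 decay_log2fc = decay_log2fc, nb_size = nb_size,
                 seed = as.integer(seed),
                 stages = c("A", "B")),
            class = "sim_config")
}

mutate_word <- function(word, rate) {
  letters4 <- c("A", "C", "G", "U")
  chars <- strsplit(word, "")[[1L]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(ch)
      sample(setdiff(letters4, ch), 1L), "")
  paste(chars, collapse = "")
}

motif_consensus <- function(motif) {
  paste(c("A", "C", "G", "U")[apply(motif$raw_probs, 1L, which.max)],
        collapse = "")
}

#' Generate a ground-truthed synthetic transcriptome
#'
#' Draws transcript models, random sequences, baseline hairpin pairing,
#' and plants three kinds of motif sites in 3'UTRs: stage-dependent switch
#' sites (half gaining, half losing structure between stages A and B),
#' constitutively accessible bound sites, and constitutively paired
#' unbound sites. Per stage, every base carries a treated stop rate
#' determined by its pairing state and accessibility multiplier; planted
#' accessible site bases are elevated by `switch_delta` times the
#' transcript's percentile rate band.
#'
#' @param config a [sim_config()].
#' @return List of class `structvar_truth` with `transcripts`,
#'   `sequences`, `pairing` (per stage), `stop_rate` (per stage),
#'   `switch_sites`, `bound_sites`, `unbound_sites`, `truncations` and
#'   `config`.
#' @export
make_transcriptome <- function(config = sim_config()) {
  with_seed(config$seed, make_transcriptome_impl(config))
}

make_transcriptome_impl <- function(config) {
  letters4 <- c("A", "C", "G", "U")
  n <- config$n_transcripts
  w <- config$segment_weights / sum(config$segment_weights)
  ids <- sprintf("tx%04d", seq_len(max(n, 0L)))
  empty_sites <- data.frame(transcript_id = character(), center = integer(),
                            start = integer(), end = integer(),
                            direction = character(), bound_stage = character(),
                            stringsAsFactors = FALSE)
  truth <- list(transcripts = data.frame(transcript_id = character(),
                                         gene_id = character(),
                                         length = integer(),
                                         utr5_end = integer(),
                                         cds_end = integer(),
                                         stringsAsFactors = FALSE),
                sequences = character(0),
                pairing = list(A = list(), B = list()),
                stop_rate = list(A = list(), B = list()),
                switch_sites = empty_sites, bound_sites = empty_sites,
                unbound_sites = empty_sites,
                truncations = data.frame(transcript_id = character(),
                                         pos = integer(),
                                         stringsAsFactors = FALSE),
                config = config)
  class(truth) <- "structvar_truth"
  if (n == 0L) return(truth)
  L <- pmax(600L, as.integer(round(stats::rnorm(n, config$mean_length,
                                                config$length_sd))))
  utr5 <- as.integer(round(L * w[[1L]]))
  cds <- utr5 + as.integer(round(L * w[[2L]]))
  cds <- pmin(cds, L - 50L)
  truth$transcripts <- data.frame(transcript_id = ids,
                                  gene_id = sub("^tx", "g", ids),
                                  length = L, utr5_end = utr5, cds_end = cds,
                                  stringsAsFactors = FALSE)
  seqs <- vapply(L, function(len)
    paste(sample(letters4, len, replace = TRUE), collapse = ""), "")
  names(seqs) <- ids

  pairing <- lapply(seq_len(n), function(i) {
    p <- logical(L[[i]])
    n_stem <- stats::rpois(1L, config$hairpin_density * L[[i]] / 1000)
    if (n_stem > 0L && L[[i]] > 40L) {
      starts <- sample.int(L[[i]] - 40L, n_stem, replace = TRUE) - 1L
      for (s in starts) {
        p[(s + 1L):(s + 15L)] <- TRUE         # 5' arm
        p[(s + 26L):(s + 40L)] <- TRUE        # 3' arm; loop stays unpaired
      }
    }
    p
  })
  names(pairing) <- ids
  pairA <- pairing
  pairB <- pairing

  # site planting: switch and constitutive bound sites get one transcript
  # each; unbound (paired) motif sites are co-hosted in the distal 3'UTR
  # half of bound transcripts, since structural controls are motif
  # occurrences on the same transcripts that carry binding sites
  site_half <- 10L
  n_hosts <- config$n_switch_sites + config$n_const_bound
  n_sites <- n_hosts + config$n_unbound
  eligible <- which(L - cds >= 4L * (2L * site_half + 1L) + 10L)
  if (n_hosts > length(eligible) || (config$n_unbound > 0L && n_hosts == 0L &&
                                     config$n_unbound > length(eligible)))
    stopf("not enough transcripts with long 3'UTRs for %d planted sites", n_hosts)
  if (n_hosts > 0L && config$n_unbound > n_hosts)
    stopf("n_unbound (%d) cannot exceed the number of bound transcripts (%d)",
          config$n_unbound, n_hosts)
  hosts <- eligible[sample.int(length(eligible), max(n_hosts,
                                                     min(config$n_unbound,
                                                         length(eligible))))]
  kind <- rep(c("switch", "const_bound", "unbound"),
              c(config$n_switch_sites, config$n_const_bound, config$n_unbound))
  host_of <- c(hosts[seq_len(n_hosts)],
               rep_len(hosts, config$n_unbound))
  consensus <- motif_consensus(config$motif)
  mw <- nchar(consensus)
  site_rows <- vector("list", n_sites)
  for (k in seq_len(n_sites)) {
    i <- host_of[[k]]
    mid <- (cds[[i]] + L[[i]]) %/% 2L
    # bound/switch sites use the proximal 3'UTR half, unbound the distal
    if (kind[[k]] == "unbound") {
      lo <- mid + site_half
      hi <- L[[i]] - site_half - 1L
    } else {
      lo <- cds[[i]] + site_half
      hi <- mid - site_half - 1L
    }
    center <- if (hi > lo) lo + sample.int(hi - lo, 1L) else lo
    s0 <- center - site_half
    e0 <- center + site_half + 1L
    word <- mutate_word(consensus, config$mutation_rate)
    m_start <- center - mw %/% 2L
    substr(seqs[[i]], m_start + 1L, m_start + mw) <- word
    span <- (s0 + 1L):e0
    if (kind[[k]] == "switch") {
      gain <- (sum(kind[seq_len(k)] == "switch") %% 2L) == 1L
      # gain: accessible at A, structured at B (group I); else mirrored
      pairA[[i]][span] <- !gain
      pairB[[i]][span] <- gain
      dir <- if (gain) "gain_structure" else "lose_structure"
      bound_stage <- if (gain) "A" else "B"
    } else if (kind[[k]] == "const_bound") {
      pairA[[i]][span] <- FALSE
      pairB[[i]][span] <- FALSE
      dir <- "none"; bound_stage <- "both"
    } else {
      pairA[[i]][span] <- TRUE
      pairB[[i]][span] <- TRUE
      dir <- "none"; bound_stage <- "never"
    }
    site_rows[[k]] <- data.frame(transcript_id = ids[[i]], center = center,
                                 start = s0, end = e0, direction = dir,
                                 bound_stage = bound_stage, kind = kind[[k]],
                                 stringsAsFactors = FALSE)
  }
  sites <- if (n_sites > 0L)
    do.call(rbind, c(site_rows, list(make.row.names = FALSE)))
  else cbind(empty_sites, data.frame(kind = character()))
  truth$sequences <- seqs
  truth$pairing <- list(A = pairA, B = pairB)
  truth$switch_sites <- sites[sites$kind == "switch", , drop = FALSE]
  truth$bound_sites <- sites[sites$kind %in% c("switch", "const_bound"), ,
                             drop = FALSE]
  truth$unbound_sites <- sites[sites$kind == "unbound", , drop = FALSE]
  truth$truncations <- data.frame(transcript_id = truth$bound_sites$transcript_id,
                                  pos = truth$bound_sites$center,
                                  stringsAsFactors = FALSE)

  # per-base accessibility multiplier: fixed in the truth, shared by
  # stages, replicates and both libraries, so it cancels in comparisons
  hetero <- lapply(L, function(len) {
    if (is.finite(config$hetero_shape))
      stats::rgamma(len, shape = config$hetero_shape,
                    rate = config$hetero_shape)
    else rep(1, len)
  })
  names(hetero) <- ids
  truth$accessibility <- hetero

  # per-stage treated stop rates: pairing-state base rate times the
  # multiplier; planted accessible site bases are instead elevated by
  # switch_delta times the transcript's percentile rate band, which the
  # window normalization maps to a reactivity shift of ~switch_delta
  rate_of <- function(stage_pairing) {
    out <- lapply(ids, function(id)
      pmin(0.95, ifelse(stage_pairing[[id]], config$stop_rate_paired,
                        config$stop_rate_unpaired) * hetero[[id]]))
    names(out) <- ids
    out
  }
  truth$stop_rate <- list(A = rate_of(pairA), B = rate_of(pairB))
  for (k in seq_len(nrow(sites))) {
    st <- sites[k, ]
    span <- (st$start + 1L):st$end
    id <- st$transcript_id
    low <- config$stop_rate_paired * hetero[[id]][span]
    for (stage in c("A", "B")) {
      accessible <- !truth$pairing[[stage]][[id]][span]
      base <- truth$stop_rate[[stage]][[id]]
      base[span] <- low  # structured floor before elevation
      band <- band_mean(base, 90, 95)
      truth$stop_rate[[stage]][[id]][span] <-
        pmin(0.95, ifelse(accessible, low + config$switch_delta * band, low))
    }
  }
  truth
}

#' Simulate RT-stop libraries for one stage
#'
#' Per base and replicate, coverage is Poisson with mean
#' `coverage_mean`; treated stops are binomial draws at the base's
#' pairing-state stop rate, control stops at `control_stop_rate` on an
#' independent Poisson coverage.
#'
#' @param truth a `structvar_truth` object.
#' @param config its [sim_config()] (defaults to `truth$config`).
#' @param stage `"A"` or `"B"`.
#' @param seed RNG seed for this stage's libraries.
#' @return List with `treated` and `control`, each a list of
#'   `rtstop_profile` objects (all transcripts times replicates).
#' @export
simulate_rtstops <- function(truth, config = truth$config, stage = "A",
                             seed = config$seed + match(stage, config$stages)) {
  rates <- truth$stop_rate[[stage]]
  if (is.null(rates)) stopf("truth does not cover stage %s", stage)
  with_seed(seed, {
    treated <- list()
    control <- list()
    for (id in names(rates)) {
      L <- length(rates[[id]])
      for (r in seq_len(config$n_replicates)) {
        cov_t <- stats::rpois(L, config$coverage_mean)
        cov_c <- stats::rpois(L, config$coverage_mean)
        treated[[length(treated) + 1L]] <- rtstop_profile(
          id, stats::rbinom(L, cov_t, rates[[id]]), cov_t,
          "treated", r, stage)
        control[[length(control) + 1L]] <- rtstop_profile(
          id, stats::rbinom(L, cov_c, config$control_stop_rate), cov_c,
          "control", r, stage)
      }
    }
    list(treated = treated, control = control)
  })
}

#' Simulate a stage-pair expression experiment
#'
#' Genes carrying a site that gains structure (group I) are
#' maternal-decay with probability `decay_coupling`; genes whose site
#' loses structure are maternal-stable with the same probability. Other
#' genes are a mix of decay, stable, zygotic and low-expressed
#' unclassified genes. Baseline means are log-normal; counts are negative
#' binomial per replicate; decay genes have their late-stage mean scaled
#' by `2^-decay_log2fc`; zygotic genes are near-zero early.
#'
#' @param truth a `structvar_truth` object.
#' @param config its [sim_config()].
#' @param stages labels for the early and late stage columns.
#' @param seed RNG seed.
#' @return List with `counts` (long `data.frame`: `gene_id`, `length`,
#'   `stage`, `replicate`, `count`) and `classes` (`gene_id`,
#'   `true_class`).
#' @export
simulate_expression <- function(truth, config = truth$config,
                                stages = c("early", "late"),
                                seed = config$seed + 100L) {
  tx <- truth$transcripts
  if (!nrow(tx)) stopf("empty transcriptome")
  with_seed(seed, {
    dir_of <- truth$switch_sites$direction[
      match(tx$transcript_id, truth$switch_sites$transcript_id)]
    true_class <- character(nrow(tx))
    for (i in seq_len(nrow(tx))) {
      u <- stats::runif(1L)
      true_class[[i]] <- if (identical(dir_of[[i]], "gain_structure")) {
        if (u < config$decay_coupling) "maternal_decay" else "maternal_stable"
      } else if (identical(dir_of[[i]], "lose_structure")) {
        if (u < config$decay_coupling) "maternal_stable" else "maternal_decay"
      } else {
        if (u < 0.45) "maternal_decay"
        else if (u < 0.80) "maternal_stable"
        else if (u < 0.90) "zygotic" else "unclassified"
      }
    }
    mu <- stats::rlnorm(nrow(tx), meanlog = log(300), sdlog = 0.6)
    mu_early <- ifelse(true_class == "zygotic", 0.005,
                       ifelse(true_class == "unclassified", 0.02, mu))
    mu_late <- ifelse(true_class == "maternal_decay",
                      mu * 2^(-config$decay_log2fc),
                      ifelse(true_class == "zygotic", mu,
                             ifelse(true_class == "unclassified", 0.02, mu)))
    rows <- list()
    for (r in seq_len(config$n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = tx$gene_id, length = tx$length, stage = stages[[1L]],
        replicate = r, count = stats::rnbinom(nrow(tx), mu = mu_early,
                               size = config$nb_size),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = tx$gene_id, length = tx$length, stage = stages[[2L]],
        replicate = r, count = stats::rnbinom(nrow(tx), mu = mu_late,
                               size = config$nb_size),
        stringsAsFactors = FALSE)
    }
    list(counts = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         classes = data.frame(gene_id = tx$gene_id, true_class = true_class,
                              stringsAsFactors = FALSE))
  })
}

#' Emit a complete on-disk fixture
#'
#' Writes every input the pipeline consumes (transcript table, FASTA,
#' RT-stop tables per stage, truncation BED, motif MEME file, count table)
#' plus the serialized ground truth and a manifest. Reruns with the same
#' config are byte-identical; manifests therefore carry no timestamps.
#'
#' @param dir output directory (created if absent).
#' @param config a [sim_config()].
#' @return Invisibly, the ground truth object (with `$files` listing the
#'   emitted paths).
#' @export
emit_fixture <- function(dir, config = sim_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- make_transcriptome(config)
  files <- list(transcripts = file.path(dir, "transcripts.tsv"),
                fasta = file.path(dir, "transcripts.fa"),
                truncations = file.path(dir, "truncations.bed"),
                motifs = file.path(dir, "motifs.meme"),
                counts = file.path(dir, "counts.tsv"),
                truth = file.path(dir, "ground_truth.json"),
                manifest = file.path(dir, "manifest.json"))
  write_transcript_table(truth$transcripts, files$transcripts,
                         fasta = files$fasta, sequences = truth$sequences)
  for (stage in config$stages) {
    sim <- simulate_rtstops(truth, config, stage)
    f <- file.path(dir, sprintf("rtstops_%s.tsv", stage))
    write_rtstop_tsv(c(sim$treated, sim$control), f)
    files[[paste0("rtstops_", stage)]] <- f
  }
  write_regions_bed(data.frame(transcript_id = truth$truncations$transcript_id,
                               start = truth$truncations$pos,
                               end = truth$truncations$pos + 1L,
                               label = "truncation", score = NA_real_,
                               stringsAsFactors = FALSE),
                    files$truncations)
  write_motif_meme(setNames(list(config$motif), config$motif$name),
                   files$motifs)
  expr <- simulate_expression(truth, config)
  write_counts_tsv(expr$counts, files$counts)
  pair_str <- function(p) paste(as.integer(p), collapse = "")
  jsonlite::write_json(list(
    switch_sites = truth$switch_sites,
    bound_sites = truth$bound_sites,
    unbound_sites = truth$unbound_sites,
    gene_classes = expr$classes,
    pairing = list(A = lapply(truth$pairing$A, pair_str),
                   B = lapply(truth$pairing$B, pair_str))),
    files$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  payload <- files[setdiff(names(files), "manifest")]
  jsonlite::write_json(list(
    tool = "structvar", version = pkg_version(), subcommand = "simulate",
    seed = config$seed,
    parameters = config[setdiff(names(config), "motif")],
    motif = config$motif$name,
    digests = as.list(tools::md5sum(unlist(payload)))),
    files$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  truth$expression <- expr
  truth$files <- files
  invisible(truth)
}
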