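test_that("truncations become flanked, clipped, 3'UTR-filtered sites", {
  tx <- data.frame(transcript_id = "tx1", gene_id = "g1", length = 1000L,
                   utr5_end = 100L, cds_end = 400L, stringsAsFactors = FALSE)
  tr <- data.frame(transcript_id = "tx1", pos = c(500L, 5L, 200L),
                   stringsAsFactors = FALSE)
  got <- truncation_to_sites(tr, tx, flank = 20L, restrict_3utr = FALSE)
  expect_equal(got$start, c(480L, 0L, 180L))
  expect_equal(got$end, c(521L, 26L, 221L))
  expect_equal(got$segment, c("3UTR", "5UTR", "CDS"))

  utr3_only <- truncation_to_sites(tr, tx, flank = 20L, restrict_3utr = TRUE)
  expect_equal(utr3_only$center, 500L)
  expect_error(truncation_to_sites(data.frame(transcript_id = "tx1",
                                              pos = 1000L), tx),
               "outside")
})

test_that("metaprofile averages valid reactivities per offset", {
  profiles <- list(tx1 = rep(0.5, 1000))
  sites <- data.frame(transcript_id = "tx1", center = c(100L, 200L),
                      start = c(80L, 180L), end = c(121L, 221L),
                      stringsAsFactors = FALSE)
  mp <- metaprofile(profiles, sites, flank = 20L)
  expect_equal(nrow(mp), 41L)
  expect_equal(mp$mean_reactivity, rep(0.5, 41L))
  expect_equal(mp$n_valid, rep(2L, 41L))

  p2 <- list(tx1 = rep(0.2, 500), tx2 = rep(0.8, 500))
  s2 <- data.frame(transcript_id = c("tx1", "tx2"), center = c(100L, 100L),
                   start = c(80L, 80L), end = c(121L, 121L),
                   stringsAsFactors = FALSE)
  mp2 <- metaprofile(p2, s2, flank = 20L)
  expect_equal(mp2$mean_reactivity[mp2$offset == 0L], 0.5)

  # validity filter removes sparse sites
  p3 <- list(tx1 = c(rep(NA_real_, 90), rep(0.4, 910)))
  s3 <- data.frame(transcript_id = "tx1", center = c(50L, 300L),
                   start = c(30L, 280L), end = c(71L, 321L),
                   stringsAsFactors = FALSE)
  mp3 <- metaprofile(p3, s3, flank = 20L, min_valid_frac = 0.6)
  expect_equal(attr(mp3, "n_sites"), 1L)
  expect_error(metaprofile(p3, s3[1L, ], flank = 20L, min_valid_frac = 0.6),
               "no usable sites")
})

test_that("unbound controls carry the motif and never touch bound sites", {
  set.seed(55)
  cfg <- sim_config(n_transcripts = 12L, n_switch_sites = 4L,
                    n_const_bound = 3L, n_unbound = 3L, seed = 55)
  truth <- make_transcriptome(cfg)
  tx <- truth$transcripts
  attr(tx, "sequence") <- truth$sequences
  bound <- truth$bound_sites
  ctrl <- unbound_controls(cfg$motif, tx, bound, sequences = truth$sequences)
  if (nrow(ctrl)) {
    for (i in seq_len(nrow(ctrl))) {
      b <- bound[bound$transcript_id == ctrl$transcript_id[[i]], , drop = FALSE]
      mw <- cfg$motif$width
      span_s <- ctrl$center[[i]] - mw %/% 2L
      expect_false(any(span_s < b$end & span_s + mw > b$start))
    }
  }
  # planted unbound sites carrying the exact consensus must be recovered
  exact <- vapply(seq_len(nrow(truth$unbound_sites)), function(i) {
    s <- truth$unbound_sites[i, ]
    grepl("UUUGUUU", substr(truth$sequences[[s$transcript_id]],
                            s$start + 1L, s$end), fixed = TRUE)
  }, TRUE)
  expect_true(all(truth$unbound_sites$transcript_id[exact] %in%
                    ctrl$transcript_id))
})

test_that("site structural grouping applies the paired-t and mirrors on swap", {
  profA <- list(tx1 = c(0.8, 0.7, 0.9, 0.8, rep(0.5, 96)))
  profB <- list(tx1 = c(0.2, 0.1, 0.3, 0.25, rep(0.5, 96)))
  sites <- data.frame(transcript_id = "tx1", center = 1L, start = 0L,
                      end = 4L, stringsAsFactors = FALSE)
  got <- classify_site_structure(profA, profB, sites)
  expect_equal(got$group, "I")
  expect_equal(got$delta, mean(c(0.2, 0.1, 0.3, 0.25)) -
                 mean(c(0.8, 0.7, 0.9, 0.8)))
  d <- c(0.2, 0.1, 0.3, 0.25) - c(0.8, 0.7, 0.9, 0.8)
  expect_equal(got$p_value, t.test(d)$p.value)

  mirrored <- classify_site_structure(profB, profA, sites)
  expect_equal(mirrored$group, "II")

  # identical stages: unchanged
  same <- classify_site_structure(profA, profA, sites)
  expect_equal(same$group, "unchanged")

  # fewer than 3 jointly valid bases: unchanged with flag
  profA2 <- list(tx1 = c(0.8, NA, NA, 0.8, rep(0.5, 96)))
  low <- classify_site_structure(profA2, profB, sites)
  expect_equal(low$group, "unchanged")
  expect_true(low$low_coverage)
})

test_that("rpkm follows its unit definition and replicate averaging", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_error(rpkm(1, 100, 0), "library")

  counts <- data.frame(gene_id = rep(c("g1", "g2"), 4),
                       length = rep(c(1000L, 2000L), 4),
                       stage = rep(c("early", "late"), each = 4),
                       replicate = rep(c(1L, 1L, 2L, 2L), 2),
                       count = c(10L, 90L, 30L, 70L, 50L, 50L, 50L, 50L),
                       stringsAsFactors = FALSE)
  rk <- rpkm_table(counts)
  # replicate 1: lib 100 -> g1 rpkm 10/(1)/(1e-4) = 1e5; replicate 2: 3e5
  expect_equal(rk$rpkm_early[rk$gene_id == "g1"], mean(c(1e5, 3e5)))
})

test_that("exact DE test reproduces closed-form binomial and BH values", {
  de <- de_test(c(g1 = 100L), c(g1 = 0L), libA = 1e6, libB = 1e6)
  expect_equal(de$p, 2 * 0.5^100, tolerance = 1e-12)
  expect_gt(de$log2fc, 0)

  # equal rates: log2fc 0, maximal p
  de0 <- de_test(c(g1 = 50L), c(g1 = 50L), libA = 1e6, libB = 1e6)
  expect_equal(de0$log2fc, 0)
  expect_equal(de0$p, 1)

  # hand-computed Benjamini-Hochberg on {0.01, 0.02, 0.04}
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
})

test_that("gene classification applies the literal thresholds and partitions", {
  rec <- data.frame(gene_id = c("decay", "zyg", "stable", "uncl"),
                    rpkm_early = c(5, 0.5, 5, 0.5),
                    rpkm_late = c(2, 3, 5, 0.5),
                    log2fc = c(1.0, -2, 0.1, 0),
                    fdr = c(0.01, 0.001, 0.01, 0.9),
                    stringsAsFactors = FALSE)
  got <- classify_genes(rec)
  expect_equal(got$klass, c("maternal_decay", "zygotic", "maternal_stable",
                            "unclassified"))
  expect_equal(sum(table(got$klass)), nrow(rec))

  # literal rule: a strongly up-regulated expressed gene is "stable";
  # the symmetric option excludes it
  up <- data.frame(gene_id = "up", rpkm_early = 5, rpkm_late = 50,
                   log2fc = -3, fdr = 0.001, stringsAsFactors = FALSE)
  expect_equal(classify_genes(up)$klass, "maternal_stable")
  expect_equal(classify_genes(up, symmetric_stable = TRUE)$klass,
               "unclassified")
})

test_that("stability association separates groups and reports composition", {
  sg <- data.frame(gene_id = c(paste0("gI", 1:20), paste0("gII", 1:20)),
                   group = rep(c("I", "II"), each = 20),
                   stringsAsFactors = FALSE)
  rec <- data.frame(gene_id = sg$gene_id,
                    log2fc = c(seq(1, 2, length.out = 20),
                               seq(-0.5, 0.4, length.out = 20)),
                    klass = rep(c("maternal_decay", "maternal_stable"),
                                each = 20),
                    stringsAsFactors = FALSE)
  got <- stability_association(sg, rec)
  expect_lt(got$wilcox_p, 1e-6)
  comp <- got$composition
  expect_equal(comp$fraction[comp$group == "I" &
                               comp$klass == "maternal_decay"], 1)
  expect_equal(comp$fraction[comp$group == "II" &
                               comp$klass == "maternal_stable"], 1)

  # identical values give p = 1 under the normal approximation
  rec2 <- rec
  rec2$log2fc <- 0.7
  expect_equal(stability_association(sg, rec2)$wilcox_p, 1)
  expect_error(stability_association(sg[c(1, 21), ], rec), "at least 2")
})

test_that("RBP site reactivity comparison enforces the 60% validity filter", {
  profiles <- list(tx1 = c(rep(0.9, 50), rep(NA_real_, 20), rep(0.1, 130)))
  sites <- data.frame(transcript_id = "tx1", start = c(0L, 45L),
                      end = c(41L, 86L), stringsAsFactors = FALSE)
  shuf <- data.frame(transcript_id = "tx1", start = 150L, end = 191L,
                     stringsAsFactors = FALSE)
  got <- rbp_site_reactivity_compare(sites, shuf, profiles)
  # second site has 20/41 < 60% valid bases and is dropped
  expect_equal(got$site$n, 1L)
  expect_equal(got$site$mean, 0.9)
  expect_equal(got$background$mean, 0.1)
  expect_error(rbp_site_reactivity_compare(sites[2L, ], shuf, profiles),
               "validity filter")
})
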