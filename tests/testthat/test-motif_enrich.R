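test_that("single-word motif tail probability is the analytic 4^-width", {
  m <- motif_from_consensus("U5", "UUUUU", pseudo = 0)
  tab <- score_pvalue_table(m)
  max_q <- sum(apply(tab$q, 1L, max, na.rm = TRUE))
  expect_equal(pwm_tail_prob(tab, max_q), 0.25^5, tolerance = 1e-12)
  # any threshold at or below the minimum has tail probability 1
  expect_equal(pwm_pvalue(tab, -1e6), 1)
})

test_that("DP tail probabilities match exhaustive enumeration exactly", {
  for (spec in list(c(5L, 1L), c(5L, 2L), c(7L, 3L), c(8L, 4L))) {
    m <- random_motif(spec[[1L]], seed = spec[[2L]])
    orc <- oracle_pwm_tail(m)
    tab <- orc$table
    for (q in unique(orc$qsum)) {
      expect_lt(abs(pwm_tail_prob(tab, q) - orc$tail_at(q)), 1e-9)
    }
  }
})

test_that("forbidden letters (zero pseudocount) keep unit mass and never hit", {
  m <- motif_from_consensus("UGU", "UGUAA", pseudo = 0)
  tab <- score_pvalue_table(m)
  expect_equal(sum(is.na(tab$q)), 15L)  # 3 allowed letters of 20 cells
  # total probability: finite mass plus minus-infinity mass is 1
  expect_equal(tab$tail[[1L]] + tab$neginf_mass, 1, tolerance = 1e-12)
  hits <- scan_regions(m, c(r1 = "CCCCCCCCCC"), thresh = 0.5)
  expect_equal(nrow(hits), 0L)
})

test_that("scanning finds planted motif occurrences on the sense strand only", {
  m <- motif_from_consensus("Elavl1", "UUUGUUU")
  hits <- scan_regions(m, c(r1 = "AAUUUGUUUAA"), thresh = 0.001)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 2L)
  expect_lt(hits$p_value, 0.001)

  expect_equal(nrow(scan_regions(m, c(r1 = "AAAAAAA"))), 0L)
  # reverse complement of the motif must not match
  expect_equal(nrow(scan_regions(m, c(r1 = "AAAACAAAAA"))), 0L)
  # windows containing N are skipped, sequences shorter than width are fine
  expect_equal(nrow(scan_regions(m, c(r1 = "UUUNUUU", r2 = "UUU"))), 0L)
})

test_that("scanning agrees with a naive per-offset rescanning oracle", {
  m <- random_motif(6L, seed = 9)
  tab <- score_pvalue_table(m)
  seqs <- random_rna(100, 40L, seed = 10)
  names(seqs) <- paste0("r", seq_along(seqs))
  got <- scan_regions(m, seqs, thresh = 0.01, table = tab)
  letters4 <- c("A", "C", "G", "U")
  naive <- list()
  for (id in names(seqs)) {
    chars <- match(strsplit(seqs[[id]], "")[[1L]], letters4)
    for (off in 0:(length(chars) - m$width)) {
      q <- sum(tab$q[cbind(1:m$width, chars[(off + 1):(off + m$width)])])
      p <- pwm_tail_prob(tab, q)
      if (p < 0.01)
        naive[[length(naive) + 1L]] <- data.frame(region_id = id, offset = off)
    }
  }
  naive <- do.call(rbind, naive)
  expect_equal(got[, c("region_id", "offset")], naive, ignore_attr = TRUE)
})

test_that("lowering the threshold never adds hits and nulls hit at the table rate", {
  m <- random_motif(5L, seed = 21)
  tab <- score_pvalue_table(m)
  seqs <- random_rna(300, 50L, seed = 22)
  names(seqs) <- paste0("r", seq_along(seqs))
  loose <- scan_regions(m, seqs, thresh = 0.01, table = tab)
  tight <- scan_regions(m, seqs, thresh = 0.001, table = tab)
  expect_true(all(paste(tight$region_id, tight$offset) %in%
                    paste(loose$region_id, loose$offset)))

  # expected per-offset hit rate equals the largest tail value below thresh
  thr <- 0.01
  exp_rate <- max(c(0, tab$tail[tab$tail < thr]))
  n_off <- 300 * (50 - 5 + 1)
  se <- sqrt(exp_rate * (1 - exp_rate) / n_off)
  expect_lt(abs(nrow(loose) / n_off - exp_rate), 5 * se + 1e-4)
})

test_that("background sampling is uniform over allowed starts and never overlaps", {
  tx <- data.frame(transcript_id = "tx1", gene_id = "g1", length = 100L,
                   utr5_end = 10L, cds_end = 20L, stringsAsFactors = FALSE)
  excl <- data.frame(transcript_id = "tx1", start = 40L, end = 60L,
                     stringsAsFactors = FALSE)
  got <- sample_background_regions(tx, excl, length = 10L, n = 20000L, seed = 4)
  expect_true(all(got$end <= excl$start | got$start >= excl$end))
  allowed <- c(0:30, 60:90)
  expect_setequal(unique(got$start), allowed)
  cs <- chisq.test(table(factor(got$start, levels = allowed)))
  expect_gt(cs$p.value, 0.001)

  # forced placement: exclusion leaves exactly one legal start
  excl2 <- data.frame(transcript_id = "tx1", start = c(0L, 11L),
                      end = c(1L, 100L), stringsAsFactors = FALSE)
  forced <- sample_background_regions(tx, excl2, length = 10L, n = 5L, seed = 1)
  expect_true(all(forced$start == 1L))

  # reproducibility contract
  s1 <- sample_background_regions(tx, excl, length = 10L, n = 50L, seed = 7)
  s2 <- sample_background_regions(tx, excl, length = 10L, n = 50L, seed = 7)
  s3 <- sample_background_regions(tx, excl, length = 10L, n = 50L, seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))

  full <- data.frame(transcript_id = "tx1", start = 0L, end = 100L)
  expect_error(suppressWarnings(
    sample_background_regions(tx, full, length = 10L, n = 5L, seed = 1)),
    "no allowed")
})

test_that("3'UTR-restricted sampling stays inside the 3'UTR", {
  tx <- data.frame(transcript_id = "tx1", gene_id = "g1", length = 200L,
                   utr5_end = 20L, cds_end = 120L, stringsAsFactors = FALSE)
  no_excl <- data.frame(transcript_id = character(), start = integer(),
                        end = integer())
  got <- sample_background_regions(tx, no_excl, length = 30L, n = 200L,
                                   seed = 2, restrict = "3utr")
  expect_true(all(got$start >= 120L & got$end <= 200L))
})

test_that("Fisher enrichment reproduces ratios and the hypergeometric p", {
  even <- motif_enrichment(rep(c(TRUE, FALSE), each = 50),
                           rep(c(TRUE, FALSE), each = 50))
  expect_equal(even$ratio, 1)
  expect_equal(even$p_value, 1)

  res <- motif_enrichment(rep(c(TRUE, FALSE), c(30, 70)),
                          rep(c(TRUE, FALSE), c(10, 90)))
  expect_equal(res$ratio, 27 / 7)
  # exact hypergeometric enumeration oracle
  probs <- dhyper(0:40, 40, 160, 100)
  p_oracle <- sum(probs[probs <= dhyper(30, 40, 160, 100) * (1 + 1e-7)])
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)

  inf <- motif_enrichment(rep(TRUE, 10), rep(c(TRUE, FALSE), c(0, 10)))
  expect_true(is.infinite(inf$ratio) && inf$inf_ratio)
  expect_error(motif_enrichment(logical(0), TRUE), "nonempty")
})

test_that("k-mer diagnostic flags a planted k-mer", {
  set.seed(33)
  test_seqs <- random_rna(60, 30L, seed = 33)
  ref_seqs <- random_rna(60, 30L, seed = 34)
  test_seqs[1:40] <- paste0(substr(test_seqs[1:40], 1, 12), "UGUAA",
                            substr(test_seqs[1:40], 18, 30))
  got <- kmer_enrichment(test_seqs, ref_seqs, k = 5L)
  expect_equal(got$kmer[[1L]], "UGUAA")
  expect_lt(got$fdr[[1L]], 0.05)
})
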