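test_that("variable nucleotides respect the cutoff and validity rule", {
  a <- c(0.1, 0.5, NA, 0.2, 0.4)
  expect_equal(nrow(call_variable_nucleotides(a, a)), 0L)

  b <- c(0.35, 0.5, 0.9, NA, 0.4)
  got <- call_variable_nucleotides(a, b)
  expect_equal(got$pos, 0L)          # NA in either profile excluded
  expect_equal(got$delta, 0.25)
  expect_error(call_variable_nucleotides(a, b[1:4]), "length")
})

test_that("window scan applies validity, effect-size and paired-t rules", {
  # identical profiles: all kept windows stable
  a <- rep(c(0.2, 0.6), 25)
  w0 <- window_scan(a, a)
  expect_true(all(w0$klass == "stable"))
  expect_true(all(w0$p_value == 1))  # zero deltas

  # 8 valid deltas around +0.1: significant less_structural call
  profA <- rep(0.4, 10)
  deltas <- c(0.08, 0.09, 0.095, 0.10, 0.10, 0.105, 0.11, 0.12)
  profB <- profA + c(deltas, 0, 0)
  profA[9:10] <- NA                   # 8 jointly valid bases
  w1 <- window_scan(profA, profB)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$n_valid, 8L)
  expect_equal(w1$mean_delta, mean(deltas))
  expect_equal(w1$p_value, t.test(deltas)$p.value)
  expect_equal(w1$klass, "less_structural")

  # 7 of 10 jointly valid bases: window omitted
  profA2 <- c(rep(0.4, 7), NA, NA, NA)
  w2 <- window_scan(profA2, profA2 + 0.3)
  expect_equal(nrow(w2), 0L)

  # trailing partial window dropped
  expect_equal(nrow(window_scan(rep(0.5, 25), rep(0.5, 25))), 2L)

  # constant nonzero deltas get p = 0
  w3 <- window_scan(rep(0.2, 10), rep(0.35, 10))
  expect_equal(w3$p_value, 0)
  expect_equal(w3$klass, "less_structural")
})

test_that("stage swap exchanges the window classes exactly", {
  set.seed(31)
  a <- pmin(1, pmax(0, runif(200)))
  b <- pmin(1, pmax(0, a + rnorm(200, 0, 0.15)))
  ab <- window_scan(a, b)
  ba <- window_scan(b, a)
  expect_equal(ab$mean_delta, -ba$mean_delta)
  expect_equal(ab$p_value, ba$p_value)
  swap <- c(less_structural = "more_structural",
            more_structural = "less_structural", stable = "stable")
  expect_equal(unname(swap[ab$klass]), ba$klass)
})

test_that("region building extends, merges per class and re-bins to 30 nt", {
  lens <- c(tx1 = 60L, tx2 = 100L)
  w <- data.frame(transcript_id = c("tx1", "tx1"),
                  start = c(10L, 25L), end = c(20L, 35L),
                  klass = "less_structural", stringsAsFactors = FALSE)
  got <- build_regions(w, lens)
  expect_equal(got$start, c(0L, 30L))
  expect_equal(got$end, c(30L, 45L))

  w2 <- data.frame(transcript_id = "tx2", start = 30L, end = 40L,
                   klass = "more_structural", stringsAsFactors = FALSE)
  got2 <- build_regions(w2, lens)
  expect_equal(got2[, c("start", "end")],
               data.frame(start = 20L, end = 50L))

  # overlapping windows of opposite class never merge
  w3 <- data.frame(transcript_id = "tx2", start = c(30L, 35L),
                   end = c(40L, 45L),
                   klass = c("more_structural", "less_structural"),
                   stringsAsFactors = FALSE)
  got3 <- build_regions(w3, lens)
  expect_equal(nrow(got3), 2L)
  expect_setequal(got3$label, c("more_structural", "less_structural"))
})

test_that("region building equals the brute-force merge oracle on random input", {
  set.seed(99)
  lens <- c(tx1 = 300L, tx2 = 200L)
  for (i in 1:200) {
    n <- sample(1:8, 1)
    starts <- sample(seq(0L, 280L, by = 10L), n, replace = TRUE)
    w <- data.frame(transcript_id = sample(names(lens), n, replace = TRUE),
                    start = starts, end = starts + 10L,
                    klass = sample(c("less_structural", "more_structural",
                                     "stable"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
    w <- w[w$end <= lens[w$transcript_id], , drop = FALSE]
    if (!nrow(w)) next
    got <- build_regions(w, lens)
    exp <- oracle_regions(w, lens)
    rownames(got) <- rownames(exp) <- NULL
    expect_equal(got[, c("transcript_id", "start", "end", "label")], exp)
  }
})

test_that("hot regions cluster shared intervals across comparisons", {
  r <- function(tx, s, e, kl = "less_structural")
    data.frame(transcript_id = tx, start = s, end = e, label = kl,
               stringsAsFactors = FALSE)
  # identical region in two comparisons collapses with n_way = 2
  got <- hot_regions(list(c1 = r("tx1", 0L, 30L), c2 = r("tx1", 0L, 30L)))
  expect_equal(nrow(got), 1L)
  expect_equal(got$n_way, 2L)

  # disjoint regions pass through as 1-way
  got2 <- hot_regions(list(c1 = r("tx1", 0L, 30L), c2 = r("tx1", 40L, 70L)))
  expect_equal(got2$n_way, c(1L, 1L))

  # chained overlap forms a single 3-way footprint
  got3 <- hot_regions(list(c1 = r("tx1", 0L, 30L), c2 = r("tx1", 25L, 55L),
                           c3 = r("tx1", 50L, 80L)))
  expect_equal(got3$start, 0L)
  expect_equal(got3$end, 80L)
  expect_equal(got3$n_way, 3L)
  expect_equal(got3$comparisons, "c1,c2,c3")

  # book-ended regions are not shared at min_overlap = 1
  got4 <- hot_regions(list(c1 = r("tx1", 0L, 30L), c2 = r("tx1", 30L, 60L)))
  expect_equal(got4$n_way, c(1L, 1L))
  expect_error(hot_regions(list(c1 = r("tx1", 0L, 30L))), "at least two")
})

test_that("hot-region clusters match a graph connected-components oracle", {
  set.seed(17)
  for (i in 1:50) {
    sets <- lapply(1:3, function(k) {
      n <- sample(0:5, 1)
      if (!n) return(data.frame(transcript_id = character(),
                                start = integer(), end = integer(),
                                label = character()))
      s <- sample(0:170, n, replace = TRUE)
      data.frame(transcript_id = "tx1", start = s, end = s + 30L,
                 label = "less_structural", stringsAsFactors = FALSE)
    })
    names(sets) <- c("c1", "c2", "c3")
    if (sum(vapply(sets, nrow, 0L)) < 2L) next
    got <- hot_regions(sets)
    all_iv <- do.call(rbind, lapply(names(sets), function(cm)
      if (nrow(sets[[cm]])) cbind(sets[[cm]], comparison = cm)))
    # oracle: union-find over pairwise overlap >= 1
    n <- nrow(all_iv)
    parent <- seq_len(n)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (a in seq_len(n)) for (b in seq_len(n))
      if (a < b && all_iv$start[[a]] < all_iv$end[[b]] &&
          all_iv$start[[b]] < all_iv$end[[a]])
        parent[[find(a)]] <- find(b)
    comp <- vapply(seq_len(n), find, 0L)
    exp_n <- length(unique(comp))
    exp_nway <- sort(vapply(split(all_iv$comparison, comp),
                            function(x) length(unique(x)), 0L))
    expect_equal(nrow(got), exp_n)
    expect_equal(sort(got$n_way), unname(exp_nway))
  }
})

test_that("segment assignment implements the majority-overlap rule", {
  # transcript: 5UTR [0,150), CDS [150,1400), 3UTR [1400,1860)
  expect_equal(assign_segment(200L, 230L, 150L, 1400L, 1860L), "CDS")
  # 16 nt in 3UTR, 14 in CDS
  expect_equal(assign_segment(1386L, 1416L, 150L, 1400L, 1860L), "3UTR")
  # exact 15/15 split fails the 0.51 rule
  expect_equal(assign_segment(1385L, 1415L, 150L, 1400L, 1860L), "unassigned")
  expect_error(assign_segment(1850L, 1880L, 150L, 1400L, 1860L), "out of bounds")

  regions <- data.frame(transcript_id = "tx1", start = 10L, end = 40L,
                        label = "x", stringsAsFactors = FALSE)
  got <- assign_segments(regions, tiny_transcripts())
  expect_equal(got$segment, "5UTR")
})

test_that("segment enrichment ratios and Fisher tests follow the length weights", {
  obs <- c(`5UTR` = 150, CDS = 1250, `3UTR` = 460)
  res <- segment_enrichment(obs)
  expect_equal(res$ratio, rep(1, 3))

  res2 <- segment_enrichment(c(`3UTR` = 50))
  expect_equal(res2$ratio[res2$segment == "3UTR"], 1860 / 460)
  expect_lt(res2$fisher_p[res2$segment == "3UTR"], 0.05)
  expect_error(segment_enrichment(c(`5UTR` = 0)), "no assigned")
})
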